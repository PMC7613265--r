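#' Genetic-algorithm configuration
#'
#' Defaults follow common ensemble-optimization practice: ensembles of
#' `ensemble_size` slots (multiplicity encodes weight), a population of 100
#' chromosomes evolved for 500 generations with elitism, and 10 independent
#' repeats whose winners are pooled for the size distributions.
#'
#' @param ensemble_size Number of slots L per ensemble (default 20).
#' @param population Chromosomes per generation (default 100).
#' @param generations Generations per repeat (default 500).
#' @param mutation_rate Per-slot mutation probability (default 0.1).
#' @param crossover_rate One-point crossover probability (default 0.5).
#' @param elites Chromosomes copied unchanged each generation (default 2).
#' @param repeats Independent GA repeats (default 10).
#' @param seed RNG seed.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(ensemble_size = 20, population = 100, generations = 500,
                      mutation_rate = 0.1, crossover_rate = 0.5, elites = 2,
                      repeats = 10, seed = 1) {
  stopifnot(ensemble_size >= 1, population >= 2, generations >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            elites >= 0, elites < population, repeats >= 1)
  structure(list(ensemble_size = as.integer(ensemble_size),
                 population = as.integer(population),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate, crossover_rate = crossover_rate,
                 elites = as.integer(elites), repeats = as.integer(repeats),
                 seed = seed),
            class = "ga_config")
}

#' Reduced chi-square between a theoretical and a target curve
#'
#' The scale `mu` is the weighted least-squares factor
#' `mu = sum(I_t I_e / sigma^2) / sum(I_t^2 / sigma^2)` and
#' `chi2 = sum(((mu I_t - I_e) / sigma)^2) / (K - 1)`.
#'
#' @param theory,target [scattering_curve()] objects on identical q-grids;
#'   `target` must carry `sigma`.
#' @return List with `chi2` and `mu`.
#' @export
chi2_curves <- function(theory, target) {
  stopifnot(inherits(theory, "scattering_curve"), inherits(target, "scattering_curve"))
  if (length(theory$q) != length(target$q) || any(theory$q != target$q))
    stop("q-grid mismatch between theory and target (no silent interpolation)")
  if (is.null(target$sigma)) stop("target curve must carry sigma")
  s2 <- target$sigma^2
  mu <- sum(theory$I * target$I / s2) / sum(theory$I^2 / s2)
  chi2 <- sum((mu * theory$I - target$I)^2 / s2) / (length(target$q) - 1)
  list(chi2 = chi2, mu = mu)
}

#' Average curve of an ensemble
#'
#' Unweighted mean over the member curves; repeated indices act as
#' multiplicity weights.
#'
#' @param pool A [conformer_pool()] with precomputed curves
#'   (see [compute_pool_curves()]).
#' @param member_indices Integer multiset of pool indices.
#' @return A [scattering_curve()].
#' @export
ensemble_curve <- function(pool, member_indices) {
  stopifnot(inherits(pool, "conformer_pool"), !is.null(pool$curves))
  if (length(member_indices) == 0) stop("empty member list")
  if (any(member_indices < 1 | member_indices > nrow(pool$curves)))
    stop("member index out of range")
  scattering_curve(pool$q, colMeans(pool$curves[member_indices, , drop = FALSE]))
}

# vectorized chi2 for a population: E is pop x K matrix of ensemble curves
pop_chi2 <- function(E, target, s2) {
  a <- as.numeric(E %*% (target / s2))
  b <- as.numeric((E * E) %*% (1 / s2))
  cc <- sum(target^2 / s2)
  mu <- a / b
  list(chi2 = (mu^2 * b - 2 * mu * a + cc) / (length(target) - 1), mu = mu)
}

#' Genetic-algorithm ensemble selection
#'
#' Selects sub-ensembles of pool models whose average theoretical curve best
#' fits the target curve. Chromosomes are fixed-length index lists with
#' repetition; each repeat runs elitism, tournament selection, one-point
#' crossover and per-slot mutation, with fitness `-chi2`. The best chi-square
#' is non-increasing across generations within a repeat (elitism), and the
#' overall best across repeats is returned together with every per-repeat
#' winner.
#'
#' @param pool A [conformer_pool()] with curves on the target's q-grid.
#' @param target A [scattering_curve()] with `sigma`.
#' @param config A [ga_config()].
#' @return Object of class `ensemble_fit`: `member_indices`,
#'   `distinct_models` (index, weight), `chi2`, `mu`, `per_repeat_best`
#'   (list of index vectors + chi2), `best_trace` (repeats x generations
#'   matrix of best chi2).
#' @export
gajoe <- function(pool, target, config = ga_config()) {
  stopifnot(inherits(pool, "conformer_pool"), !is.null(pool$curves))
  if (length(pool$q) != length(target$q) || any(pool$q != target$q))
    stop("pool curves are not on the target q-grid")
  if (is.null(target$sigma)) stop("target curve must carry sigma")
  nmod <- nrow(pool$curves)
  L <- config$ensemble_size
  if (nmod < L) stop("pool smaller than the ensemble size")
  Cm <- pool$curves
  tI <- target$I
  s2 <- target$sigma^2
  np <- config$population
  set.seed(config$seed)
  best_overall <- NULL
  per_repeat <- vector("list", config$repeats)
  trace <- matrix(NA_real_, config$repeats, config$generations)
  for (rep_i in seq_len(config$repeats)) {
    P <- matrix(sample.int(nmod, np * L, replace = TRUE), np, L)
    for (gen in seq_len(config$generations)) {
      E <- matrix(0, np, ncol(Cm))
      for (l in seq_len(L)) E <- E + Cm[P[, l], , drop = FALSE]
      E <- E / L
      f <- pop_chi2(E, tI, s2)
      ord <- order(f$chi2)
      trace[rep_i, gen] <- f$chi2[ord[1]]
      if (gen == config$generations) {
        P <- P[ord, , drop = FALSE]
        break
      }
      newP <- matrix(0L, np, L)
      ne <- config$elites
      if (ne > 0) newP[seq_len(ne), ] <- P[ord[seq_len(ne)], , drop = FALSE]
      # truncation selection: parents drawn uniformly from the top quartile
      n_child <- np - ne
      top <- max(2L, np %/% 4L)
      pa <- ord[sample.int(top, n_child, replace = TRUE)]
      pb <- ord[sample.int(top, n_child, replace = TRUE)]
      do_cx <- runif(n_child) < config$crossover_rate
      cxpt <- sample.int(L - 1, n_child, replace = TRUE)
      for (c in seq_len(n_child)) {
        child <- P[pa[c], ]
        if (do_cx[c]) {
          u <- cxpt[c]
          child <- c(P[pa[c], seq_len(u)], P[pb[c], (u + 1):L])
        }
        newP[ne + c, ] <- child
      }
      mut <- matrix(runif(np * L) < config$mutation_rate, np, L)
      if (ne > 0) mut[seq_len(ne), ] <- FALSE
      nmut <- sum(mut)
      if (nmut > 0) newP[mut] <- sample.int(nmod, nmut, replace = TRUE)
      P <- newP
    }
    best_idx <- sort(P[1, ])
    ec <- ensemble_curve(pool, best_idx)
    fit <- chi2_curves(ec, target)
    per_repeat[[rep_i]] <- list(member_indices = best_idx, chi2 = fit$chi2,
                                mu = fit$mu)
    if (is.null(best_overall) || fit$chi2 < best_overall$chi2)
      best_overall <- per_repeat[[rep_i]]
  }
  tab <- table(best_overall$member_indices)
  structure(list(member_indices = best_overall$member_indices,
                 distinct_models = data.frame(
                   index = as.integer(names(tab)),
                   weight = as.numeric(tab) / L),
                 chi2 = best_overall$chi2, mu = best_overall$mu,
                 per_repeat_best = per_repeat, best_trace = trace,
                 config = config),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("ensemble_fit: chi2 = %.3f, mu = %.4g, %d distinct models over %d slots (%d repeats)\n",
              x$chi2, x$mu, nrow(x$distinct_models),
              length(x$member_indices), length(x$per_repeat_best)))
  invisible(x)
}

#' Entropy-based flexibility metric Rflex
#'
#' Histogram of the supplied Rg values over `bins` equal-width bins spanning
#' `bin_range`; `Rflex = 100 * (-sum p_i ln p_i) / ln(bins)`, with
#' `0 ln 0 = 0`. Complete rigidity (all values in one bin) gives 0%;
#' equal occupancy of every bin gives 100%.
#'
#' @param rg_values Numeric vector (Angstrom).
#' @param bins Number of bins (>= 2; default 100).
#' @param bin_range Length-2 range covering all values (default data range,
#'   padded when degenerate).
#' @return Percentage in [0, 100].
#' @export
rflex <- function(rg_values, bins = 100, bin_range = NULL) {
  stopifnot(length(rg_values) >= 1, bins >= 2)
  if (is.null(bin_range)) {
    bin_range <- range(rg_values)
    if (diff(bin_range) == 0) bin_range <- bin_range + c(-0.5, 0.5)
  }
  if (any(rg_values < bin_range[1] | rg_values > bin_range[2]))
    stop("values outside bin_range")
  breaks <- seq(bin_range[1], bin_range[2], length.out = bins + 1)
  counts <- tabulate(findInterval(rg_values, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  p <- counts / sum(counts)
  p <- p[p > 0]
  100 * (-sum(p * log(p))) / log(bins) + 0   # + 0 normalizes IEEE -0
}

#' Ensemble-to-pool size-dispersion ratio Rsigma
#'
#' Standard deviation of the ensemble Rg values divided by that of the pool.
#' A value near 1 means the selected ensembles populate as wide a size range
#' as the random pool.
#'
#' @param ensemble_rgs,pool_rgs Numeric vectors (>= 2 values each).
#' @return Non-negative ratio.
#' @export
rsigma <- function(ensemble_rgs, pool_rgs) {
  stopifnot(length(ensemble_rgs) >= 2, length(pool_rgs) >= 2)
  sp <- sd(pool_rgs)
  if (sp == 0) stop("pool Rg standard deviation is zero")
  sd(ensemble_rgs) / sp
}

#' Flexibility metrics of an ensemble fit
#'
#' Convenience wrapper computing Rflex for the selected models (all
#' per-repeat winners, multiplicity-weighted), Rflex for the pool, and
#' Rsigma, on a shared binning over the pool's Rg range.
#'
#' @param pool A [conformer_pool()].
#' @param fit An `ensemble_fit` from [gajoe()].
#' @param bins Number of Rflex bins (default 100).
#' @return Object of class `flex_metrics`.
#' @export
flex_metrics <- function(pool, fit, bins = 100) {
  stopifnot(inherits(pool, "conformer_pool"), inherits(fit, "ensemble_fit"))
  sel <- unlist(lapply(fit$per_repeat_best, function(x) x$member_indices))
  rng <- range(pool$rg)
  structure(list(rflex_ensemble = rflex(pool$rg[sel], bins, rng),
                 rflex_pool = rflex(pool$rg, bins, rng),
                 rsigma = rsigma(pool$rg[sel], pool$rg),
                 bins = bins, bin_range = rng),
            class = "flex_metrics")
}

#' @export
print.flex_metrics <- function(x, ...) {
  cat(sprintf("flex_metrics: Rflex(ensemble) = %.2f%%, Rflex(pool) = %.2f%%, Rsigma = %.3f\n",
              x$rflex_ensemble, x$rflex_pool, x$rsigma))
  invisible(x)
}

#' Pool versus selected-ensemble size distributions
#'
#' Unit-area histograms of Rg and Dmax for the whole pool and for the members
#' of all per-repeat winning ensembles (multiplicity-weighted).
#'
#' @param pool A [conformer_pool()].
#' @param ensembles List of `ensemble_fit` objects (or a single fit, whose
#'   per-repeat winners are used).
#' @param bins Number of histogram bins (default 30).
#' @return List with data frames `rg` and `dmax` (`mid`, `pool`, `ensemble`
#'   densities).
#' @export
size_distributions <- function(pool, ensembles, bins = 30) {
  stopifnot(inherits(pool, "conformer_pool"))
  if (inherits(ensembles, "ensemble_fit")) ensembles <- list(ensembles)
  sel <- unlist(lapply(ensembles, function(f)
    unlist(lapply(f$per_repeat_best, function(x) x$member_indices))))
  hist2 <- function(vals_pool, vals_sel) {
    rng <- range(c(vals_pool, vals_sel))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1)
    bw <- diff(breaks)[1]
    cp <- tabulate(findInterval(vals_pool, breaks, rightmost.closed = TRUE,
                                all.inside = TRUE), nbins = bins)
    cs <- tabulate(findInterval(vals_sel, breaks, rightmost.closed = TRUE,
                                all.inside = TRUE), nbins = bins)
    data.frame(mid = (breaks[-1] + breaks[-(bins + 1)]) / 2,
               pool = cp / (sum(cp) * bw),
               ensemble = cs / (sum(cs) * bw))
  }
  list(rg = hist2(pool$rg, pool$rg[sel]),
       dmax = hist2(pool$dmax, pool$dmax[sel]))
}
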