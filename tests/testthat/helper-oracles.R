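# Independent brute-force oracles. These deliberately re-derive quantities
# with the most literal implementation available (double loops, exhaustive
# enumeration) so the package's accelerated paths are checked against code
# that shares none of their structure.

# exact Debye sum, plain R double loop
oracle_debye <- function(beads, weights, q) {
  n <- nrow(beads)
  I <- rep(sum(weights^2), length(q))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((beads[i, ] - beads[j, ])^2))
      x <- q * d
      s <- ifelse(x == 0, 1, sin(x) / x)
      I <- I + 2 * weights[i] * weights[j] * s
    }
  }
  I
}

# clash count, plain double loop (chain-adjacent pairs exempt)
oracle_clash_count <- function(beads, chain, threshold) {
  n <- nrow(beads)
  count <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (chain[i] == chain[j] && j - i == 1) next
      if (sqrt(sum((beads[i, ] - beads[j, ])^2)) < threshold) count <- count + 1
    }
  }
  count
}

oracle_dmax <- function(beads) {
  n <- nrow(beads)
  mx <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      mx <- max(mx, sqrt(sum((beads[i, ] - beads[j, ])^2)))
  mx
}

# weighted pair-distance histogram by direct enumeration
oracle_pair_hist <- function(beads, weights, dr) {
  n <- nrow(beads)
  d <- numeric(0); w <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- c(d, sqrt(sum((beads[i, ] - beads[j, ])^2)))
      w <- c(w, weights[i] * weights[j])
    }
  }
  bins <- floor(d / dr)
  vapply(0:max(bins), function(b) sum(w[bins == b]), 0)
}

# charge-patterning delta from its definition, sliding windows in plain R
oracle_delta <- function(ch, blobs = c(5L, 6L)) {
  N <- length(ch)
  fp <- mean(ch > 0); fm <- mean(ch < 0)
  sseq <- if (fp + fm > 0) (fp - fm)^2 / (fp + fm) else 0
  ds <- c()
  for (g in blobs[blobs <= N]) {
    nw <- N - g + 1
    s <- vapply(seq_len(nw), function(i) {
      w <- ch[i:(i + g - 1)]
      gp <- mean(w > 0); gm <- mean(w < 0)
      if (gp + gm > 0) (gp - gm)^2 / (gp + gm) else 0
    }, 0)
    ds <- c(ds, mean((s - sseq)^2))
  }
  mean(ds)
}

# all distinct arrangements of a charge multiset (for exhaustive delta_max)
oracle_arrangements <- function(items) {
  if (length(items) <= 1) return(list(items))
  out <- list()
  for (u in unique(items)) {
    rest <- items[-match(u, items)]
    for (p in oracle_arrangements(rest)) out[[length(out) + 1]] <- c(u, p)
  }
  out
}

oracle_kappa <- function(seq_str, blobs = c(5L, 6L)) {
  res <- strsplit(seq_str, "")[[1]]
  ch <- ifelse(res %in% c("K", "R"), 1L, ifelse(res %in% c("D", "E"), -1L, 0L))
  dmax <- max(vapply(oracle_arrangements(ch), oracle_delta, 0, blobs = blobs))
  oracle_delta(ch, blobs) / dmax
}

# independent implementation of the coil sampling rules (bond 3.8, angle
# U[75,155] deg, dihedral U[-180,180), excluded volume 4.0 between
# non-adjacent linker beads), for distribution-level comparison
oracle_linker <- function(n, tries = 30) {
  repeat {
    pts <- matrix(NA_real_, n + 2, 3)
    pts[1, ] <- c(-3.8, 0, 0); pts[2, ] <- c(0, 0, 0)
    ok_all <- TRUE
    for (i in 3:(n + 2)) {
      placed <- FALSE
      for (t in seq_len(tries)) {
        th <- pi - runif(1, 75, 155) * pi / 180
        ph <- runif(1, -pi, pi)
        b1 <- pts[i - 1, ] - pts[i - 2, ]; b1 <- b1 / sqrt(sum(b1^2))
        ref <- if (abs(b1[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
        n1 <- ref - sum(ref * b1) * b1; n1 <- n1 / sqrt(sum(n1^2))
        n2 <- c(b1[2] * n1[3] - b1[3] * n1[2],
                b1[3] * n1[1] - b1[1] * n1[3],
                b1[1] * n1[2] - b1[2] * n1[1])
        u <- cos(th) * b1 + sin(th) * (cos(ph) * n1 + sin(ph) * n2)
        p <- pts[i - 1, ] + 3.8 * u
        linker_prev <- pts[seq(3, i - 2), , drop = FALSE]  # non-adjacent only
        okk <- i <= 4 || nrow(linker_prev) == 0 ||
          min(rowSums(sweep(linker_prev, 2, p)^2)) >= 16
        if (okk) { pts[i, ] <- p; placed <- TRUE; break }
      }
      if (!placed) { ok_all <- FALSE; break }
    }
    if (ok_all) return(pts[3:(n + 2), , drop = FALSE])
  }
}

# 1-D Wasserstein distance between samples via quantile matching
wasserstein1d <- function(a, b, ngrid = 200) {
  u <- (seq_len(ngrid) - 0.5) / ngrid
  mean(abs(quantile(a, u, names = FALSE) - quantile(b, u, names = FALSE)))
}

# small shared fixture: a desk-scale tetramer pool with curves, built once
shared_tetramer_pool <- local({
  cache <- NULL
  function(n = 120, q = saxsemble::default_q_grid()) {
    key <- list(n, q)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$pool)
    tpl <- make_domain_templates("core_tetramer", radius = 12, n_beads = 60, seed = 3)
    pools <- lapply(1:4, function(k)
      generate_pool(tpl$blueprint, tpl$domains, n = 40, seed = 100 + k))
    pool <- combine_tetramers(pools, tpl$tetramer, n = n, seed = 7)
    pool <- compute_pool_curves(pool, q)
    cache <<- list(key = key, pool = pool)
    pool
  }
})
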