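#' Synthetic rigid-domain templates and blueprints
#'
#' Desk-scale stand-ins for the rigid bodies of a tetrameric
#' rigid-core/flexible-scaffold assembly, with known ground truth.
#'
#' * `"sphere"`: a single ball of beads (uniform density) of radius `radius`.
#' * `"dumbbell"`: two balls joined by a flexible linker.
#' * `"core_tetramer"`: one protomer of an idealized D2 tetramer: an
#'   off-center core ball followed by a flexible scaffold of linkers
#'   interrupted by small rigid microdomains (a membrane-anchor rod, a
#'   helicase-binding site carrying a ligand ball, an enolase-binding site
#'   carrying a second ligand ball) - roughly 320 scaffold residues in all,
#'   emulating the layout scale of the RNase E C-terminal scaffold.
#'
#' @param kind One of `"sphere"`, `"dumbbell"`, `"core_tetramer"`.
#' @param radius Ball radius (Angstrom; default 25).
#' @param n_beads Beads per ball (default 200).
#' @param linker_length Dumbbell linker length (default 20).
#' @param min_sep Minimum bead separation inside ball domains (Angstrom,
#'   default 3.5, keeping templates clash-free; 0 disables the constraint).
#' @param seed RNG seed.
#' @return List with `domains` (named [rigid_domain()] list), `blueprint`
#'   (a [chain_blueprint()]) and, for `"core_tetramer"`, `tetramer`
#'   (a [tetramer_blueprint()]).
#' @export
make_domain_templates <- function(kind = c("sphere", "dumbbell", "core_tetramer"),
                                  radius = 25, n_beads = 200,
                                  linker_length = 20, min_sep = 3.5, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(radius > 0, n_beads >= 1)
  set.seed(seed)
  # uniform ball with a minimum bead separation, so templates are clash-free
  ball <- function(n, R, center = c(0, 0, 0)) {
    if (min_sep <= 0) {
      u <- matrix(rnorm(3 * n), n, 3)
      u <- u / sqrt(rowSums(u^2))
      return(sweep(u * R * runif(n)^(1 / 3), 2, -center))
    }
    out <- matrix(NA_real_, n, 3)
    k <- 0; tries <- 0
    while (k < n && tries < 2000 * n) {
      tries <- tries + 1
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      p <- u * R * runif(1)^(1 / 3)
      if (k == 0 || min(sqrt(rowSums(sweep(out[seq_len(k), , drop = FALSE], 2, p)^2))) >= min_sep) {
        k <- k + 1
        out[k, ] <- p
      }
    }
    if (k < n) stop("cannot place ", n, " beads at min separation ", min_sep,
                    " in radius ", R)
    sweep(out, 2, -center)
  }
  rod <- function(n, center, step = 3.0) {
    cbind(center[1] + step * (seq_len(n) - (n + 1) / 2), center[2], center[3])
  }
  if (kind == "sphere") {
    b <- ball(n_beads, radius)
    dom <- rigid_domain("sphere", b,
                        anchor_in = which.min(b[, 1]), anchor_out = which.max(b[, 1]))
    bp <- chain_blueprint(list(list(type = "rigid", id = "sphere")),
                          core_id = "sphere")
    return(list(domains = list(sphere = dom), blueprint = bp))
  }
  if (kind == "dumbbell") {
    b1 <- ball(n_beads, radius)
    b2 <- ball(n_beads, radius)
    doms <- list(
      lobe1 = rigid_domain("lobe1", b1, anchor_out = which.max(b1[, 1])),
      lobe2 = rigid_domain("lobe2", b2, anchor_in = which.min(b2[, 1])))
    bp <- chain_blueprint(list(list(type = "rigid", id = "lobe1"),
                               list(type = "linker", length = linker_length),
                               list(type = "rigid", id = "lobe2")),
                          core_id = "lobe1")
    return(list(domains = doms, blueprint = bp))
  }
  # core_tetramer: protomer core offset from the D2 origin so the four
  # symmetry copies form a compact, non-overlapping tetramer core
  core_off <- c(radius + 6, radius / 2 + 4, 5)
  core <- ball(n_beads, radius, core_off)
  helix <- rod(21, c(0, 0, 0))
  rbs <- rod(10, c(0, 0, 0))
  ebs <- rod(8, c(0, 0, 0))
  lig1 <- ball(max(20, n_beads %/% 3), radius * 0.7)
  lig2 <- ball(max(20, n_beads %/% 3), radius * 0.7)
  doms <- list(
    core = rigid_domain("core", core, anchor_out = which.max(core[, 1])),
    helixA = rigid_domain("helixA", helix, anchor_in = 1, anchor_out = 21),
    rbs = rigid_domain("rbs", rbs, anchor_in = 1, anchor_out = 10),
    ebs = rigid_domain("ebs", ebs, anchor_in = 1, anchor_out = 8),
    helicase = rigid_domain("helicase", lig1,
                            dock_transform = rigid_transform(t = c(0, radius * 0.7 + 5, 0))),
    enolase = rigid_domain("enolase", lig2,
                           dock_transform = rigid_transform(t = c(0, -radius * 0.7 - 5, 0))))
  bp <- chain_blueprint(
    segments = list(
      list(type = "rigid", id = "core"),
      list(type = "linker", length = 40),
      list(type = "rigid", id = "helixA"),
      list(type = "linker", length = 120),
      list(type = "rigid", id = "rbs"),
      list(type = "linker", length = 80),
      list(type = "rigid", id = "ebs"),
      list(type = "linker", length = 40)),
    ligands = list(list(domain = "helicase", segment = 5, offset = 5),
                   list(domain = "enolase", segment = 7, offset = 4)),
    core_id = "core")
  list(domains = doms, blueprint = bp, tetramer = tetramer_blueprint())
}

#' Planted scattering experiment
#'
#' Builds a noisy target curve from a known sparse mixture of pool models:
#' `I_target(q) = sum_i w_i I_i(q) + N(0, sigma(q))` with the counting-like
#' noise model `sigma(q) = noise * sqrt(I(q) * I(0))` (so `sigma/I = noise`
#' at q = 0).
#'
#' @param pool A [conformer_pool()] with precomputed curves.
#' @param true_weights Numeric vector of mixture weights over pool models,
#'   either full-length or named by pool index; must sum to 1.
#' @param noise Relative sigma at I(0) (default 0.01).
#' @param seed RNG seed.
#' @return Object of class `planted_experiment`: `pool`, `true_indices`,
#'   `true_weights`, `target` (a [scattering_curve()] with sigma), `noise`,
#'   `seed`.
#' @export
make_planted_experiment <- function(pool, true_weights, noise = 0.01, seed = 1) {
  stopifnot(inherits(pool, "conformer_pool"), !is.null(pool$curves))
  nmod <- nrow(pool$curves)
  if (!is.null(names(true_weights))) {
    w <- numeric(nmod)
    w[as.integer(names(true_weights))] <- true_weights
  } else {
    stopifnot(length(true_weights) == nmod)
    w <- true_weights
  }
  if (abs(sum(w) - 1) > 1e-8) stop("true weights must sum to 1")
  mix <- as.numeric(w %*% pool$curves)
  if (noise > 0) {
    sg <- noise * sqrt(pmax(mix, 0) * mix[1])
    sg[sg == 0] <- max(sg) * 1e-6 + .Machine$double.eps
    set.seed(seed)
    I <- mix + rnorm(length(mix), 0, sg)
  } else {
    # exact mixture with a nominal uncertainty column
    sg <- rep(1e-6 * max(mix), length(mix))
    I <- mix
  }
  target <- scattering_curve(pool$q, I, sg)
  structure(list(pool = pool, true_indices = which(w > 0),
                 true_weights = w[w > 0], target = target,
                 noise = noise, seed = seed),
            class = "planted_experiment")
}

#' Synthetic protein-coated liposome volume
#'
#' Spherical membrane shell (Gaussian radial cross-section) plus an outer
#' protein shell separated by a gap, with optional sub-unity angular
#' occupancy (Bernoulli voxel mask, a crude model of discrete bound
#' particles) and white noise. Defaults reproduce the geometry of a
#' 100 Angstrom-radius vesicle whose bound protein layer starts 30 Angstrom
#' beyond the membrane peak and extends 140 Angstrom.
#'
#' @param box Voxels per side (default 80, leaving a generous solvent
#'   margin outside the protein shell for baseline estimation).
#' @param voxel Angstrom per voxel (default 8.8).
#' @param membrane_radius Membrane peak radius (Angstrom, default 100).
#' @param membrane_thickness FWHM of the membrane cross-section (default 40).
#' @param gap Membrane-peak-to-protein-shell distance (default 30).
#' @param protein_extent Protein shell width (default 140).
#' @param amplitudes `c(membrane, protein)` density amplitudes.
#' @param occupancy Protein angular occupancy in (0, 1] (default 1).
#' @param noise_sd White-noise standard deviation (default 0).
#' @param seed RNG seed.
#' @return List with `vol` (a [density_volume()] centered in the box) and
#'   `truth` (membrane_peak_r, gap, extension).
#' @export
make_liposome_volume <- function(box = 80, voxel = 8.8, membrane_radius = 100,
                                 membrane_thickness = 40, gap = 30,
                                 protein_extent = 140,
                                 amplitudes = c(1, 0.5), occupancy = 1,
                                 noise_sd = 0, seed = 1) {
  if (membrane_radius + gap + protein_extent >= box * voxel / 2)
    stop("geometry exceeds half the box")
  set.seed(seed)
  ax <- (seq_len(box) - (box + 1) / 2) * voxel
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  sig <- membrane_thickness / (2 * sqrt(2 * log(2)))
  mem <- amplitudes[1] * exp(-(r - membrane_radius)^2 / (2 * sig^2))
  r_in <- membrane_radius + gap
  prot <- amplitudes[2] * (r >= r_in & r <= r_in + protein_extent)
  if (occupancy < 1)
    prot <- prot * (array(runif(box^3), dim(prot)) < occupancy)
  g <- mem + prot
  if (noise_sd > 0) g <- g + array(rnorm(box^3, 0, noise_sd), dim(g))
  truth <- list(membrane_peak_r = membrane_radius, gap = gap,
                extension = protein_extent)
  list(vol = density_volume(g, voxel,
                            origin = -((box - 1) / 2) * voxel * c(1, 1, 1)),
       truth = truth)
}

#' Charge-patterned synthetic sequence
#'
#' Builds a sequence of exact composition `n * fplus` lysines, `n * fminus`
#' glutamates and neutral glycines, arranged either fully segregated (the
#' block arrangement maximizing the patterning parameter delta, hence
#' kappa = 1), maximally alternating, or randomly shuffled.
#'
#' @param n Sequence length.
#' @param fplus,fminus Charge fractions; `n * f` must be integral.
#' @param arrangement `"segregated"`, `"alternating"` or `"random"`.
#' @param seed RNG seed (used for `"random"`).
#' @return One-letter amino-acid string.
#' @export
make_patterned_sequence <- function(n, fplus, fminus,
                                    arrangement = c("random", "segregated",
                                                    "alternating"),
                                    seed = 1) {
  arrangement <- match.arg(arrangement)
  if (fplus + fminus > 1) stop("fplus + fminus must be <= 1")
  np <- fplus * n; nm <- fminus * n
  if (abs(np - round(np)) > 1e-9 || abs(nm - round(nm)) > 1e-9)
    stop("n * fplus and n * fminus must be integers")
  np <- round(np); nm <- round(nm); n0 <- n - np - nm
  if (np + nm < 2) stop("need at least 2 charged residues")
  to_letters <- function(ch) {
    out <- character(length(ch))
    out[ch > 0] <- "K"; out[ch < 0] <- "E"; out[ch == 0] <- "G"
    paste(out, collapse = "")
  }
  if (arrangement == "segregated") {
    dm <- cpp_deltamax(np, nm, n0, c(5L, 6L))
    return(to_letters(dm$arrangement))
  }
  if (arrangement == "alternating") {
    # interleave signs as evenly as the composition allows, then spread the
    # charges uniformly over the chain
    frac <- c((seq_len(np) - 0.5) / max(np, 1), (seq_len(nm) - 0.5) / max(nm, 1))
    chg <- c(rep(1L, np), rep(-1L, nm))[order(frac)]
    pos <- round(seq(1, n, length.out = np + nm))
    ch <- integer(n)
    ch[pos] <- chg
    return(to_letters(ch))
  }
  set.seed(seed)
  to_letters(sample(c(rep(1L, np), rep(-1L, nm), rep(0L, n0))))
}
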