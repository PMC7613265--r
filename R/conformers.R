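#' Rigid domain
#'
#' A rigid body represented one bead per residue (C-alpha positions, Angstrom).
#' Rigid domains carry the a-priori structural information of the assembly:
#' folded domains and partner enzymes whose internal geometry is never
#' re-sampled during pool generation.
#'
#' @param id Character label.
#' @param beads Nx3 coordinate matrix (Angstrom).
#' @param anchor_in,anchor_out Bead indices where the chain enters/leaves the
#'   domain, or `NA` if the domain is terminal on that side.
#' @param dock_transform Optional [rigid_transform()] placing the domain
#'   relative to its attachment frame (used for ligand domains).
#' @return Object of class `rigid_domain`.
#' @export
rigid_domain <- function(id, beads, anchor_in = NA, anchor_out = NA,
                         dock_transform = NULL) {
  beads <- as.matrix(beads)
  if (ncol(beads) != 3 || nrow(beads) < 1) stop("beads must be an Nx3 matrix with N >= 1")
  if (!all(is.finite(beads))) stop("all bead coordinates must be finite")
  for (a in c(anchor_in, anchor_out))
    if (!is.na(a) && (a < 1 || a > nrow(beads))) stop("anchor index out of range")
  if (!is.null(dock_transform)) stopifnot(inherits(dock_transform, "rigid_transform"))
  structure(list(id = id, beads = beads, anchor_in = anchor_in,
                 anchor_out = anchor_out, dock_transform = dock_transform),
            class = "rigid_domain")
}

#' Chain blueprint
#'
#' Describes one protomer as an ordered alternation of rigid domains and
#' flexible linkers, with partner enzymes attached as rigid ligands so that
#' the conformational search only samples the linkers (the intrinsically
#' disordered scaffold), not the folded bodies.
#'
#' @param segments List of segments, each `list(type = "rigid", id = <domain id>)`
#'   or `list(type = "linker", length = <residues>)`. No two adjacent linkers.
#' @param ligands List of `list(domain = <id>, segment = <segment index>,
#'   offset = <residue offset within segment>)`.
#' @param core_id Id of the rigid domain acting as the oligomerization core.
#' @return Object of class `chain_blueprint`.
#' @export
chain_blueprint <- function(segments, ligands = list(), core_id = NULL) {
  stopifnot(length(segments) >= 1)
  types <- vapply(segments, function(s) s$type, "")
  if (!all(types %in% c("rigid", "linker"))) stop("segment type must be 'rigid' or 'linker'")
  if (any(types[-1] == "linker" & types[-length(types)] == "linker"))
    stop("two adjacent linker segments are not allowed")
  for (s in segments)
    if (s$type == "linker" && s$length < 1) stop("linker lengths must be >= 1")
  structure(list(segments = segments, ligands = ligands, core_id = core_id),
            class = "chain_blueprint")
}

validate_blueprint <- function(blueprint, domains) {
  ids <- names(domains)
  for (s in blueprint$segments)
    if (s$type == "rigid" && !(s$id %in% ids))
      stop("blueprint references missing domain: ", s$id)
  for (lg in blueprint$ligands) {
    if (!(lg$domain %in% ids)) stop("blueprint references missing ligand domain: ", lg$domain)
    if (lg$segment < 1 || lg$segment > length(blueprint$segments))
      stop("ligand attachment segment out of range")
  }
  if (!is.null(blueprint$core_id) && !(blueprint$core_id %in% ids))
    stop("blueprint references missing core domain: ", blueprint$core_id)
  invisible(TRUE)
}

#' Conformer model
#'
#' One member of a conformer pool: bead coordinates with per-bead scattering
#' weights and labels (chain index, segment id, rigid/flexible flag).
#'
#' @param beads Nx3 coordinate matrix (Angstrom).
#' @param weights Per-bead scattering weights (> 0, default 1).
#' @param chain Integer chain index per bead (1-4 for tetramers).
#' @param segment Segment id per bead.
#' @param flexible Logical per bead: TRUE for linker (sampled) beads.
#' @return Object of class `conformer_model`.
#' @export
conformer_model <- function(beads, weights = NULL, chain = NULL,
                            segment = NULL, flexible = NULL) {
  beads <- as.matrix(beads)
  n <- nrow(beads)
  if (n < 1 || ncol(beads) != 3) stop("beads must be an Nx3 matrix")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("length(weights) must equal number of beads")
  if (any(weights <= 0)) stop("weights must be > 0")
  if (is.null(chain)) chain <- rep(1L, n)
  if (is.null(segment)) segment <- rep(1L, n)
  if (is.null(flexible)) flexible <- rep(FALSE, n)
  structure(list(beads = beads, weights = as.numeric(weights),
                 chain = as.integer(chain), segment = as.integer(segment),
                 flexible = as.logical(flexible)),
            class = "conformer_model")
}

#' @export
print.conformer_model <- function(x, ...) {
  cat(sprintf("conformer_model: %d beads, %d chain(s), Rg %.1f A, Dmax %.1f A\n",
              nrow(x$beads), length(unique(x$chain)), model_rg(x), model_dmax(x)))
  invisible(x)
}

#' Sample a self-avoiding random-coil linker
#'
#' Grows a flexible linker of `n_residues` beads from `start_point`, with
#' fixed 3.8 Angstrom virtual bonds, bond angles uniform in
#' `[angle_range[1], angle_range[2]]` degrees and dihedrals uniform in
#' `[-180, 180)`. Every bead keeps at least `excluded_volume` Angstrom from
#' every non-adjacent linker bead and from every context bead; dead ends
#' trigger a whole-linker restart.
#'
#' Draws from R's RNG, so results are reproducible under [set.seed()].
#'
#' @param n_residues Number of linker beads (>= 1).
#' @param start_point Length-3 anchor coordinate; the first bead is placed one
#'   bond length from it.
#' @param start_direction Unit vector giving the outgoing chain direction.
#' @param context_beads Optional Mx3 matrix of already-placed beads to avoid.
#' @param bond_length Virtual bond length (Angstrom, default 3.8).
#' @param excluded_volume Minimum approach distance (Angstrom, default 4.0).
#' @param angle_range Bond-angle range in degrees (default `c(75, 155)`).
#' @param max_attempts Maximum whole-linker restarts before failing (default 500).
#' @return `n_residues` x 3 coordinate matrix.
#' @export
sample_linker <- function(n_residues, start_point, start_direction,
                          context_beads = NULL, bond_length = 3.8,
                          excluded_volume = 4.0, angle_range = c(75, 155),
                          max_attempts = 500) {
  if (n_residues < 1) stop("n_residues must be >= 1")
  if (is.null(context_beads) || NROW(context_beads) == 0)
    context_beads <- matrix(numeric(0), 0, 3)
  context_beads <- as.matrix(context_beads)
  start_direction <- start_direction / sqrt(sum(start_direction^2))
  cpp_sample_linker(as.integer(n_residues), as.numeric(start_point),
                    as.numeric(start_direction) * bond_length, context_beads,
                    bond_length, excluded_volume,
                    angle_range[1], angle_range[2],
                    as.integer(max_attempts), 30L)
}

# place a rigid domain so that its `anchor` bead lands at `target`, with a
# random orientation; retries a few orientations to avoid clashes with context
place_domain <- function(dom, anchor, target, context, excluded_volume = 4.0,
                         tries = 20) {
  best <- NULL
  for (k in seq_len(tries)) {
    R <- random_rotation()
    cen <- dom$beads[anchor, , drop = FALSE]
    xyz <- sweep(dom$beads, 2, as.numeric(cen)) %*% t(R)
    xyz <- sweep(xyz, 2, -as.numeric(target))
    if (nrow(context) == 0) return(xyz)
    dmin <- min_cross_distance(xyz, context)
    if (is.null(best) || dmin > best$dmin) best <- list(xyz = xyz, dmin = dmin)
    if (dmin >= excluded_volume) return(xyz)
  }
  best$xyz
}

min_cross_distance <- function(a, b) {
  # smallest distance between two bead sets (used only for modest sizes)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Build one protomer from a blueprint
#'
#' Walks the blueprint segment by segment: the first rigid domain is kept at
#' its template coordinates; linkers are sampled with [sample_linker()] using
#' all previously placed beads as excluded-volume context; subsequent rigid
#' domains are attached with a random orientation so that their entry anchor
#' continues the chain; ligand domains are finally docked rigidly onto their
#' attachment residue frame via their `dock_transform`.
#'
#' @param blueprint A [chain_blueprint()].
#' @param domains Named list of [rigid_domain()] objects.
#' @param bond_length,excluded_volume,angle_range,max_attempts Passed to the
#'   linker sampler.
#' @return A [conformer_model()] with per-bead segment labels; ligand beads are
#'   labelled with negative segment ids (-1 for the first ligand, and so on).
#' @export
build_protomer <- function(blueprint, domains, bond_length = 3.8,
                           excluded_volume = 4.0, angle_range = c(75, 155),
                           max_attempts = 500) {
  validate_blueprint(blueprint, domains)
  beads <- matrix(numeric(0), 0, 3)
  seg_lab <- integer(0)
  flex <- logical(0)
  last_dir <- c(1, 0, 0)
  for (i in seq_along(blueprint$segments)) {
    s <- blueprint$segments[[i]]
    if (s$type == "rigid") {
      dom <- domains[[s$id]]
      if (nrow(beads) == 0) {
        xyz <- dom$beads
      } else {
        anchor <- if (is.na(dom$anchor_in)) 1L else dom$anchor_in
        target <- beads[nrow(beads), ] + bond_length * last_dir
        # the chain bead the domain bonds to is exempt from the clash check
        xyz <- place_domain(dom, anchor, target, beads[-nrow(beads), , drop = FALSE],
                            excluded_volume)
      }
      cen <- colMeans(xyz)
      out_anchor <- if (is.na(dom$anchor_out)) nrow(xyz) else dom$anchor_out
      v <- xyz[out_anchor, ] - cen
      if (sum(v^2) < 1e-12) v <- last_dir
      last_dir <- v / sqrt(sum(v^2))
      beads <- rbind(beads, xyz)
      seg_lab <- c(seg_lab, rep(i, nrow(xyz)))
      flex <- c(flex, rep(FALSE, nrow(xyz)))
    } else {
      if (nrow(beads) == 0) {
        start <- c(0, 0, 0)
        anchor_row <- 0L
      } else {
        prev <- blueprint$segments[[i - 1]]
        if (prev$type == "rigid") {
          dom <- domains[[prev$id]]
          out_anchor <- if (is.na(dom$anchor_out)) nrow(dom$beads) else dom$anchor_out
          anchor_row <- nrow(beads) - nrow(dom$beads) + out_anchor
        } else anchor_row <- nrow(beads)
        start <- beads[anchor_row, ]
      }
      # the anchor bead is bonded to the first linker bead and exempt from
      # the excluded-volume context
      ctx <- if (anchor_row > 0) beads[-anchor_row, , drop = FALSE] else beads
      xyz <- sample_linker(s$length, start, last_dir, ctx,
                           bond_length = bond_length,
                           excluded_volume = excluded_volume,
                           angle_range = angle_range,
                           max_attempts = max_attempts)
      if (nrow(xyz) >= 2) {
        v <- xyz[nrow(xyz), ] - xyz[nrow(xyz) - 1, ]
        last_dir <- v / sqrt(sum(v^2))
      }
      beads <- rbind(beads, xyz)
      seg_lab <- c(seg_lab, rep(i, nrow(xyz)))
      flex <- c(flex, rep(TRUE, nrow(xyz)))
    }
  }
  # dock ligands on the residue frames of their attachment segments
  for (k in seq_along(blueprint$ligands)) {
    lg <- blueprint$ligands[[k]]
    dom <- domains[[lg$domain]]
    idx <- which(seg_lab == lg$segment & seg_lab > 0)
    at <- idx[min(length(idx), max(1, lg$offset))]
    origin <- beads[at, ]
    nb <- if (at < nrow(beads)) beads[at + 1, ] else beads[at - 1, ]
    Fm <- frame_from_direction(nb - origin)
    tr <- if (is.null(dom$dock_transform)) rigid_transform() else dom$dock_transform
    local <- apply_transform(dom$beads, tr)
    xyz <- sweep(local %*% t(Fm), 2, -origin)
    beads <- rbind(beads, xyz)
    seg_lab <- c(seg_lab, rep(-k, nrow(xyz)))
    flex <- c(flex, rep(FALSE, nrow(xyz)))
  }
  conformer_model(beads, segment = seg_lab, flexible = flex)
}

#' Bead-overlap clash score
#'
#' Number of non-adjacent bead pairs closer than `overlap_threshold`,
#' scaled per 1000 beads. Pairs of consecutive beads within the same chain
#' are exempt (they are bonded). Serves the same filtering role as an
#' all-atom clashscore at the coarse-grained level.
#'
#' @param model A [conformer_model()].
#' @param overlap_threshold Distance below which two beads clash (Angstrom,
#'   default 3.0).
#' @return Non-negative numeric score; 0 for clash-free models.
#' @export
clash_score <- function(model, overlap_threshold = 3.0) {
  n <- nrow(model$beads)
  cpp_clash_count(model$beads, overlap_threshold, model$chain) * 1000 / n
}

#' Radius of gyration of a bead model
#'
#' Weighted RMS distance from the weighted centroid:
#' `sqrt(sum(w_i |r_i - rbar|^2) / sum(w_i))`.
#'
#' @param model A [conformer_model()].
#' @return Rg in Angstrom (0 for a single bead).
#' @export
model_rg <- function(model) {
  w <- model$weights
  cen <- colSums(model$beads * w) / sum(w)
  d2 <- rowSums(sweep(model$beads, 2, cen)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Maximum intra-model distance
#'
#' @param model A [conformer_model()].
#' @return Dmax in Angstrom (0 for a single bead).
#' @export
model_dmax <- function(model) {
  if (nrow(model$beads) < 2) return(0)
  cpp_pair_hist(model$beads, model$weights, 1.0)$dmax
}

#' Conformer pool
#'
#' A list of conformer models with parallel per-model Rg and Dmax vectors,
#' optional precomputed scattering curves, and the RNG seed that produced it.
#'
#' @param models List of [conformer_model()] objects.
#' @param seed Seed recorded for reproducibility (may be `NA`).
#' @param provenance Optional per-model provenance (e.g. source pool indices).
#' @return Object of class `conformer_pool`.
#' @export
conformer_pool <- function(models, seed = NA, provenance = NULL) {
  stopifnot(length(models) >= 1)
  rg <- vapply(models, model_rg, 0)
  dmax <- vapply(models, model_dmax, 0)
  structure(list(models = models, rg = rg, dmax = dmax, curves = NULL,
                 q = NULL, seed = seed, provenance = provenance),
            class = "conformer_pool")
}

#' @export
print.conformer_pool <- function(x, ...) {
  cat(sprintf("conformer_pool: %d models, Rg %.1f-%.1f A, Dmax %.1f-%.1f A%s\n",
              length(x$models), min(x$rg), max(x$rg), min(x$dmax), max(x$dmax),
              if (is.null(x$curves)) "" else ", curves computed"))
  invisible(x)
}

#' @export
length.conformer_pool <- function(x) length(x$models)

#' Generate a pool of protomer conformers
#'
#' Repeatedly calls [build_protomer()] under a fixed seed.
#'
#' @param blueprint A [chain_blueprint()].
#' @param domains Named list of [rigid_domain()] objects.
#' @param n Number of models.
#' @param seed RNG seed.
#' @param ... Passed to [build_protomer()].
#' @return A [conformer_pool()].
#' @export
generate_pool <- function(blueprint, domains, n, seed = 1, ...) {
  set.seed(seed)
  models <- lapply(seq_len(n), function(i) build_protomer(blueprint, domains, ...))
  conformer_pool(models, seed = seed)
}

#' Filter a pool by clash score
#'
#' Retains exactly the models with `clash_score(model) <= max_clash`,
#' preserving order. The default cutoff of 60 mirrors the conventional
#' clashscore threshold used for pool curation.
#'
#' @param pool A [conformer_pool()].
#' @param max_clash Maximum allowed clash score (default 60).
#' @param overlap_threshold Passed to [clash_score()].
#' @return Filtered [conformer_pool()].
#' @export
filter_pool <- function(pool, max_clash = 60, overlap_threshold = 3.0) {
  stopifnot(inherits(pool, "conformer_pool"))
  keep <- vapply(pool$models, clash_score, 0, overlap_threshold = overlap_threshold) <= max_clash
  if (!any(keep)) stop("clash filter removed every model in the pool")
  out <- conformer_pool(pool$models[keep], seed = pool$seed,
                        provenance = if (is.null(pool$provenance)) NULL
                                     else pool$provenance[keep, , drop = FALSE])
  if (!is.null(pool$curves)) {
    out$curves <- pool$curves[keep, , drop = FALSE]
    out$q <- pool$q
  }
  out
}

#' Tetramer blueprint
#'
#' Four rigid transforms mapping a protomer core onto the four core sites of
#' the tetramer reference frame. The default is an idealized D2 core:
#' identity plus 180-degree rotations about x, y and z.
#'
#' @param core_transforms List of 4 [rigid_transform()] objects.
#' @return Object of class `tetramer_blueprint`.
#' @export
tetramer_blueprint <- function(core_transforms = NULL) {
  if (is.null(core_transforms))
    core_transforms <- list(
      rigid_transform(),
      rigid_transform(rotation_about_axis(c(1, 0, 0), pi)),
      rigid_transform(rotation_about_axis(c(0, 1, 0), pi)),
      rigid_transform(rotation_about_axis(c(0, 0, 1), pi)))
  stopifnot(length(core_transforms) == 4)
  for (tr in core_transforms) stopifnot(inherits(tr, "rigid_transform"))
  structure(list(core_transforms = core_transforms), class = "tetramer_blueprint")
}

#' Combine protomer pools into a tetramer pool
#'
#' Draws one protomer uniformly at random (with replacement) from each of the
#' four pools, docks each rigidly onto the tetramer core via the blueprint's
#' core transforms, and accepts the combination if the inter-protomer clash
#' score does not exceed `max_clash`. Rejected combinations are resampled.
#'
#' @param protomer_pools List of 4 [conformer_pool()] objects.
#' @param blueprint A [tetramer_blueprint()].
#' @param n Number of tetramer models to produce.
#' @param seed RNG seed.
#' @param max_clash Maximum inter-protomer clash score (default 60).
#' @param overlap_threshold Clash distance (Angstrom, default 3.0).
#' @return A [conformer_pool()] whose `provenance` is an `n x 4` matrix of
#'   source indices.
#' @export
combine_tetramers <- function(protomer_pools, blueprint = tetramer_blueprint(),
                              n, seed = 1, max_clash = 60,
                              overlap_threshold = 3.0) {
  stopifnot(length(protomer_pools) == 4)
  for (p in protomer_pools) stopifnot(inherits(p, "conformer_pool"), length(p) >= 1)
  set.seed(seed)
  # cache intra-protomer clash counts so the inter-protomer score is cheap
  intra <- lapply(seq_len(4), function(k) {
    vapply(protomer_pools[[k]]$models, function(m)
      cpp_clash_count(m$beads, overlap_threshold, m$chain), 0)
  })
  models <- vector("list", n)
  prov <- matrix(NA_integer_, n, 4)
  attempts <- 0L
  accepted <- 0L
  while (accepted < n) {
    attempts <- attempts + 1L
    idx <- vapply(protomer_pools, function(p) sample.int(length(p), 1), 0L)
    beads <- NULL; wts <- NULL; chain <- NULL; seg <- NULL; flex <- NULL
    for (k in 1:4) {
      m <- protomer_pools[[k]]$models[[idx[k]]]
      xyz <- apply_transform(m$beads, blueprint$core_transforms[[k]])
      beads <- rbind(beads, xyz)
      wts <- c(wts, m$weights)
      chain <- c(chain, rep(k, nrow(xyz)))
      seg <- c(seg, m$segment)
      flex <- c(flex, m$flexible)
    }
    total <- cpp_clash_count(beads, overlap_threshold, as.integer(chain))
    inter <- total - sum(vapply(1:4, function(k) intra[[k]][idx[k]], 0))
    if (inter * 1000 / nrow(beads) <= max_clash) {
      accepted <- accepted + 1L
      models[[accepted]] <- conformer_model(beads, wts, chain, seg, flex)
      prov[accepted, ] <- idx
    }
    if (attempts >= 200L && accepted / attempts < 0.01)
      stop(sprintf("tetramer combination rejection rate above 99%% (%d/%d accepted)",
                   accepted, attempts))
  }
  conformer_pool(models, seed = seed, provenance = prov)
}
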