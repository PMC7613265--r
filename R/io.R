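#' Read a bead model from a PDB file
#'
#' Parses C-alpha ATOM records (via bio3d), preserving chain and residue
#' numbering; the occupancy column is interpreted as the per-bead scattering
#' weight.
#'
#' @param path Path to a PDB file.
#' @return A [conformer_model()]; chain letters are mapped to consecutive
#'   integers (stored in attribute `chain_ids`).
#' @export
read_pdb_model <- function(path) {
  pdb <- bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  if (length(sel$atom) == 0) stop("no C-alpha ATOM records in ", path)
  at <- pdb$atom[sel$atom, ]
  chains <- factor(at$chain, levels = unique(at$chain))
  w <- at$o
  w[is.na(w) | w <= 0] <- 1
  m <- conformer_model(cbind(at$x, at$y, at$z), weights = w,
                       chain = as.integer(chains))
  attr(m, "chain_ids") <- levels(chains)
  attr(m, "resno") <- at$resno
  m
}

#' Read a rigid domain from a PDB file
#'
#' @param path Path to a PDB file.
#' @param id Domain label (default: file name without extension).
#' @param anchor_in,anchor_out,dock_transform Passed to [rigid_domain()].
#' @return A [rigid_domain()].
#' @export
read_pdb_domain <- function(path, id = NULL, anchor_in = NA, anchor_out = NA,
                            dock_transform = NULL) {
  m <- read_pdb_model(path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  rigid_domain(id, m$beads, anchor_in, anchor_out, dock_transform)
}

#' Write a bead model as a C-alpha PDB file
#'
#' One ALA C-alpha record per bead; chains 1-4 become chain IDs A-D and the
#' occupancy column carries the bead weight. Round trips through
#' [read_pdb_model()] reproduce coordinates to the format's 3-decimal
#' precision.
#'
#' @param model A [conformer_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_model <- function(model, path) {
  stopifnot(inherits(model, "conformer_model"))
  n <- nrow(model$beads)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(model$beads)),
                   resno = seq_len(n), resid = rep("ALA", n),
                   elety = rep("CA", n), chain = LETTERS[model$chain],
                   o = model$weights, b = rep(0, n))
  invisible(path)
}

#' Read a 1-D scattering curve from a text file
#'
#' Whitespace-delimited columns `q I [sigma]`; lines starting with `#` and
#' blank lines are skipped.
#'
#' @param path Path to the curve file.
#' @return A [scattering_curve()].
#' @export
read_curve <- function(path) {
  tab <- read.table(path, comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(tab) < 2) stop("curve file needs at least columns q and I")
  scattering_curve(tab[[1]], tab[[2]],
                   sigma = if (ncol(tab) >= 3) tab[[3]] else NULL)
}

#' Write a 1-D scattering curve to a text file
#'
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @param header Optional comment lines (written with a leading `#`).
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, header = NULL) {
  stopifnot(inherits(curve, "scattering_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste("#", h), con)
  writeLines(paste("#", if (is.null(curve$sigma)) "q I" else "q I sigma"), con)
  tab <- cbind(curve$q, curve$I, curve$sigma)
  write.table(format(tab, digits = 10, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a pair-distance distribution to a text file
#'
#' @param pd A `pair_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pofr <- function(pd, path) {
  stopifnot(inherits(pd, "pair_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# P(r), unit area, Dmax = %.4f A", pd$dmax), con)
  write.table(cbind(pd$r, pd$p), con, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Lowercase residues are uppercased with a warning.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- vapply(seqs, function(s) as.character(s)[1], "")
  if (any(grepl("[a-z]", out))) {
    warning("lowercase residues uppercased")
    out <- toupper(out)
  }
  setNames(out, names(seqs))
}
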