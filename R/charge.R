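# Bjellqvist pKa set (the set used by the ProtParam tool): side chains plus
# termini, with residue-specific N-terminal values and C-terminal D/E shifts.
.pk_pos <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
.pk_neg <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
.pk_nterm <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7)
.pk_cterm <- c(D = 4.55, E = 4.75)

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_sequence <- function(seq, strict = TRUE) {
  res <- strsplit(toupper(seq), "")[[1]]
  if (length(res) == 0) stop("empty sequence")
  bad <- which(!(res %in% .aa_alphabet))
  if (length(bad) && strict)
    stop("unknown residue '", res[bad[1]], "' at position ", bad[1])
  res
}

#' Net charge of a protein sequence at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable side chains (D, E, C, Y, H,
#' K, R) and both termini, using the Bjellqvist pKa set. Monotone
#' non-increasing in pH.
#'
#' @param seq One-letter amino-acid string (20 canonical letters).
#' @param pH pH value(s).
#' @param strict Error on unknown residues (default TRUE).
#' @return Net charge in elementary charges (vectorized over `pH`).
#' @export
net_charge <- function(seq, pH, strict = TRUE) {
  res <- check_sequence(seq, strict)
  res <- res[res %in% .aa_alphabet]
  counts <- table(factor(res, levels = .aa_alphabet))
  nt <- res[1]; ct <- res[length(res)]
  pk_nt <- if (nt %in% names(.pk_nterm)) .pk_nterm[[nt]] else .pk_pos[["Nterm"]]
  pk_ct <- if (ct %in% names(.pk_cterm)) .pk_cterm[[ct]] else .pk_neg[["Cterm"]]
  vapply(pH, function(p) {
    pos <- 1 / (1 + 10^(p - pk_nt)) +
      sum(vapply(c("K", "R", "H"), function(a)
        counts[[a]] / (1 + 10^(p - .pk_pos[[a]])), 0))
    neg <- 1 / (1 + 10^(pk_ct - p)) +
      sum(vapply(c("D", "E", "C", "Y"), function(a)
        counts[[a]] / (1 + 10^(.pk_neg[[a]] - p)), 0))
    pos - neg
  }, 0)
}

#' Isoelectric point
#'
#' pH of zero net charge under the Henderson-Hasselbalch model, found by
#' bisection on `[0, 14]` to `|charge| < 1e-4`.
#'
#' @param seq One-letter amino-acid string.
#' @param strict Error on unknown residues.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, strict = TRUE) {
  check_sequence(seq, strict)   # termini make every non-empty sequence ionizable
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    ch <- net_charge(seq, mid, strict)
    if (abs(ch) < 1e-4) break
    if (ch > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Charged-residue fractions
#'
#' `f+ = (K + R) / N`, `f- = (D + E) / N`; histidine is excluded, following
#' the convention of the charge-patterning (kappa) literature. `FCR = f+ + f-`
#' and `NCPR = f+ - f-`.
#'
#' @param seq One-letter amino-acid string.
#' @param strict Error on unknown residues.
#' @return List with `fplus`, `fminus`, `fcr`, `ncpr`.
#' @export
charge_fractions <- function(seq, strict = TRUE) {
  res <- check_sequence(seq, strict)
  n <- length(res)
  fp <- sum(res %in% c("K", "R")) / n
  fm <- sum(res %in% c("D", "E")) / n
  list(fplus = fp, fminus = fm, fcr = fp + fm, ncpr = fp - fm)
}

charge_vector <- function(res) {
  ifelse(res %in% c("K", "R"), 1L, ifelse(res %in% c("D", "E"), -1L, 0L))
}

#' Charge-patterning parameter kappa
#'
#' Das-Pappu patterning parameter. For each blob size g, the local charge
#' asymmetry `sigma = (f+ - f-)^2 / (f+ + f-)` is computed in every sliding
#' window (stride 1; windows without charges contribute 0) and `delta_g` is
#' the mean squared deviation from the whole-sequence asymmetry; `delta` is
#' the mean over blob sizes. `delta_max` is the maximum `delta` over
#' block-segregated rearrangements of the same composition (contiguous
#' positive, negative and neutral blocks with all neutral-spacer placements),
#' and `kappa = delta / delta_max`.
#'
#' @param seq One-letter amino-acid string with >= 2 charged residues.
#' @param blob_sizes Window sizes (default `c(5, 6)`).
#' @param strict Error on unknown residues.
#' @return Object of class `charge_metrics` with `kappa`, `delta`,
#'   `delta_max` plus the fraction fields of [charge_fractions()].
#' @export
kappa_metrics <- function(seq, blob_sizes = c(5, 6), strict = TRUE) {
  res <- check_sequence(seq, strict)
  ch <- charge_vector(res)
  fr <- charge_fractions(seq, strict)
  if (sum(ch != 0) < 2 || fr$fcr == 0)
    stop("kappa undefined: need at least 2 charged residues")
  blobs <- as.integer(blob_sizes[blob_sizes <= length(res)])
  if (length(blobs) == 0) stop("sequence shorter than every blob size")
  delta <- cpp_delta(ch, blobs)
  dm <- cpp_deltamax(sum(ch > 0), sum(ch < 0), sum(ch == 0), blobs)
  kappa <- if (dm$delta_max > 0) delta / dm$delta_max else NA_real_
  structure(list(kappa = kappa, delta = delta, delta_max = dm$delta_max,
                 fplus = fr$fplus, fminus = fr$fminus, fcr = fr$fcr,
                 ncpr = fr$ncpr, blob_sizes = blobs),
            class = "charge_metrics")
}

#' @export
print.charge_metrics <- function(x, ...) {
  cat(sprintf("charge_metrics: kappa = %.3f (delta %.4g / delta_max %.4g), FCR %.3f, NCPR %+.3f\n",
              x$kappa, x$delta, x$delta_max, x$fcr, x$ncpr))
  invisible(x)
}

# Das-Pappu diagram-of-states classification on (f+, f-)
classify_polyampholyte <- function(fp, fm) {
  fcr <- fp + fm; ncpr <- fp - fm
  if (fcr < 0.25) "weak polyampholyte (globule or tadpole)"
  else if (fcr <= 0.35) "boundary (Janus) region"
  else if (abs(ncpr) <= 0.35) "strong polyampholyte"
  else if (ncpr > 0.35) "strong positive polyelectrolyte"
  else "strong negative polyelectrolyte"
}

#' Per-region charge report
#'
#' One row per sequence region with pI, charge fractions, kappa metrics and
#' the diagram-of-states classification. Histidine is counted as ionizable
#' for pI but excluded from f+/FCR/kappa, following the respective tool
#' conventions.
#'
#' @param seq One-letter amino-acid string (the full protein).
#' @param regions Named list of `c(start, end)` pairs (1-based inclusive), or
#'   `NULL` for the whole sequence. Bounds beyond the sequence are clamped
#'   with a warning.
#' @param blob_sizes Passed to [kappa_metrics()].
#' @return A data frame, one row per region.
#' @export
region_report <- function(seq, regions = NULL, blob_sizes = c(5, 6)) {
  res <- check_sequence(seq)
  n <- length(res)
  if (is.null(regions)) regions <- list(full = c(1, n))
  if (length(regions) == 0)
    return(data.frame(region = character(0), start = integer(0), end = integer(0),
                      length = integer(0), pi = numeric(0), fplus = numeric(0),
                      fminus = numeric(0), fcr = numeric(0), ncpr = numeric(0),
                      delta = numeric(0), delta_max = numeric(0),
                      kappa = numeric(0), class = character(0)))
  if (is.null(names(regions)))
    names(regions) <- vapply(regions, function(r) paste(r, collapse = "-"), "")
  rows <- lapply(names(regions), function(nm) {
    r <- regions[[nm]]
    if (r[2] > n) {
      warning("region ", nm, " clamped to sequence length ", n)
      r[2] <- n
    }
    if (r[1] < 1 || r[1] > r[2]) stop("invalid region: ", nm)
    sub <- paste(res[r[1]:r[2]], collapse = "")
    fr <- charge_fractions(sub)
    km <- tryCatch(kappa_metrics(sub, blob_sizes),
                   error = function(e) list(kappa = NA_real_, delta = NA_real_,
                                            delta_max = NA_real_))
    data.frame(region = nm, start = r[1], end = r[2], length = r[2] - r[1] + 1,
               pi = round(isoelectric_point(sub), 2),
               fplus = fr$fplus, fminus = fr$fminus, fcr = fr$fcr,
               ncpr = fr$ncpr, delta = km$delta, delta_max = km$delta_max,
               kappa = km$kappa,
               class = classify_polyampholyte(fr$fplus, fr$fminus))
  })
  do.call(rbind, rows)
}
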