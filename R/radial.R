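#' Density volume
#'
#' A 3-D scalar density map with isotropic voxels, indexed `[x, y, z]`.
#'
#' @param grid 3-D numeric array (>= 16 voxels per side).
#' @param voxel Voxel size (Angstrom per voxel, isotropic).
#' @param origin Length-3 offset of voxel `[1,1,1]` in Angstrom.
#' @return Object of class `density_volume`.
#' @export
density_volume <- function(grid, voxel, origin = c(0, 0, 0)) {
  stopifnot(is.array(grid), length(dim(grid)) == 3, voxel > 0, length(origin) == 3)
  if (any(dim(grid) < 16)) stop("volume must be at least 16 voxels per side")
  if (!all(is.finite(grid))) stop("density values must be finite")
  structure(list(grid = grid, voxel = voxel, origin = as.numeric(origin)),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("density_volume: %d x %d x %d voxels, %.2f A/voxel\n",
              d[1], d[2], d[3], x$voxel))
  invisible(x)
}

# the 60 rotation matrices of the icosahedral rotation group, generated by
# closure from a 2-fold (z) and a 5-fold (vertex) generator; memoized
.ico_cache <- new.env(parent = emptyenv())
icosahedral_rotations <- function() {
  if (!is.null(.ico_cache$R)) return(.ico_cache$R)
  phi <- (1 + sqrt(5)) / 2
  g1 <- rotation_about_axis(c(0, 0, 1), pi)
  g2 <- rotation_about_axis(c(0, 1, phi), 2 * pi / 5)
  key <- function(M) paste(round(M, 9), collapse = ",")
  seen <- new.env(parent = emptyenv())
  elems <- list(diag(3))
  assign(key(diag(3)), TRUE, envir = seen)
  queue <- elems
  while (length(queue) > 0) {
    M <- queue[[1]]; queue <- queue[-1]
    for (g in list(g1, g2)) {
      N <- g %*% M
      k <- key(N)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        elems[[length(elems) + 1]] <- N
        queue[[length(queue) + 1]] <- N
      }
    }
  }
  stopifnot(length(elems) == 60)
  .ico_cache$R <- elems
  elems
}

# average vol over a list of rotation matrices about the volume center
rotational_average <- function(vol, rotations) {
  d <- dim(vol$grid)
  cen <- (d - 1) / 2
  idx <- as.matrix(expand.grid(x = seq_len(d[1]) - 1,
                               y = seq_len(d[2]) - 1,
                               z = seq_len(d[3]) - 1))
  P0 <- sweep(idx, 2, cen)
  acc <- numeric(prod(d))
  nacc <- numeric(prod(d))
  for (R in rotations) {
    pts <- sweep(P0 %*% R, 2, -cen)   # sample at R^T . x equivalent under group
    v <- cpp_trilinear(as.numeric(vol$grid), as.integer(d), pts, NA_real_)
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    nacc <- nacc + ok
  }
  out <- vol$grid
  out[] <- ifelse(nacc > 0, acc / nacc, 0)
  density_volume(out, vol$voxel, vol$origin)
}

#' Icosahedral symmetry averaging
#'
#' Averages the volume over the 60 rotations of the icosahedral rotation
#' group about the volume center (trilinear interpolation). Spherically
#' symmetric volumes are fixed points of this operator.
#'
#' @param vol A [density_volume()] with a cubic grid.
#' @return The symmetrized [density_volume()].
#' @export
icosahedral_average <- function(vol) {
  stopifnot(inherits(vol, "density_volume"))
  d <- dim(vol$grid)
  if (length(unique(d)) != 1) stop("icosahedral averaging requires a cubic volume")
  rotational_average(vol, icosahedral_rotations())
}

#' Rotational averaging about coordinate axes
#'
#' Sequentially averages the volume over rotations about each listed axis in
#' steps of `step_deg` degrees. Used after icosahedral averaging for fine
#' angular smoothing.
#'
#' @param vol A [density_volume()] with a cubic grid.
#' @param axes Character vector from `c("x", "y", "z")`.
#' @param step_deg Angular step; must divide 360 (default 10).
#' @return The averaged [density_volume()].
#' @export
axis_rotational_average <- function(vol, axes = c("x", "y"), step_deg = 10) {
  stopifnot(inherits(vol, "density_volume"))
  d <- dim(vol$grid)
  if (length(unique(d)) != 1) stop("rotational averaging requires a cubic volume")
  if (360 %% step_deg != 0) stop("step_deg must divide 360")
  ax <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  angles <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  for (a in axes) {
    rots <- lapply(angles, function(t) rotation_about_axis(ax[[match.arg(a, names(ax))]], t))
    vol <- rotational_average(vol, rots)
  }
  vol
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(m) {
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m
  th <- pi * (3 - sqrt(5)) * (i - 0.5)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(th), s * sin(th), z)
}

#' 1-D radial density profile
#'
#' Mean density over spherical shells from `center` outwards, in steps of one
#' voxel up to half the box. Each shell of radius r is sampled at
#' `max(100, 4 pi r^2 / voxel^2)` quasi-uniform (Fibonacci) points with
#' trilinear interpolation; points falling outside the grid are dropped.
#'
#' @param vol A [density_volume()].
#' @param center Length-3 position in Angstrom, or `"auto"` to use the
#'   density-weighted centroid of the thresholded high-density shell.
#' @return Object of class `radial_profile` with fields `r`, `rho`,
#'   `n_samples`, `center`.
#' @export
radial_profile <- function(vol, center = "auto") {
  stopifnot(inherits(vol, "density_volume"))
  d <- dim(vol$grid)
  if (identical(center, "auto")) {
    thr <- mean(vol$grid) + sd(as.numeric(vol$grid))
    w <- pmax(vol$grid - thr, 0)
    if (sum(w) == 0) stop("auto-centering failed: no density above threshold")
    idx <- which(w > 0, arr.ind = TRUE) - 1
    ww <- w[w > 0]
    cen_vox <- colSums(idx * ww) / sum(ww)
    center <- vol$origin + cen_vox * vol$voxel
  }
  cen_vox <- (as.numeric(center) - vol$origin) / vol$voxel
  if (any(cen_vox < 0) || any(cen_vox > d - 1)) stop("center outside volume")
  rmax <- min(d) * vol$voxel / 2
  r <- seq(0, rmax, by = vol$voxel)
  rho <- numeric(length(r))
  nsamp <- integer(length(r))
  for (i in seq_along(r)) {
    if (r[i] == 0) {
      v <- cpp_trilinear(as.numeric(vol$grid), as.integer(d),
                         matrix(cen_vox, 1, 3), NA_real_)
    } else {
      m <- max(100, ceiling(4 * pi * r[i]^2 / vol$voxel^2))
      pts <- fibonacci_sphere(m) * (r[i] / vol$voxel)
      pts <- sweep(pts, 2, -cen_vox)
      v <- cpp_trilinear(as.numeric(vol$grid), as.integer(d), pts, NA_real_)
    }
    v <- v[!is.na(v)]
    rho[i] <- if (length(v)) mean(v) else NA_real_
    nsamp[i] <- length(v)
  }
  keep <- !is.na(rho)
  structure(list(r = r[keep], rho = rho[keep], n_samples = nsamp[keep],
                 center = as.numeric(center)),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("radial_profile: %d shells, r 0-%.1f A\n", length(x$r), max(x$r)))
  invisible(x)
}

#' Membrane / gap / extension metrics of a radial profile
#'
#' Identifies the membrane peak (first local maximum exceeding half the
#' profile's dynamic range above baseline), fits a Gaussian to it (width
#' from the uncontaminated inner half-maximum), subtracts it, and measures
#' the protein density shell on the residual: the shell exists when the
#' residual peak beyond the membrane reaches `frac` of the membrane height,
#' and its edges are the interpolated half-maximum crossings of the
#' residual, which locates shell boundaries to sub-voxel accuracy even when
#' the membrane tail overlaps the shell. The baseline is the median of the
#' outer 20% of the radial range (solvent). The gap is measured from the
#' membrane peak to the inner edge of the protein shell; the extension is
#' the width of the shell.
#'
#' @param profile A [radial_profile()].
#' @param frac Detection threshold fraction (default 0.1): the protein shell
#'   must rise above `frac` of the membrane peak height, and the region
#'   searched for edges is where the residual exceeds `frac` of its peak.
#' @return Object of class `profile_metrics`: `membrane_peak_r`, `gap`,
#'   `extension`, `protein_region`, `bimodal`, `protein_present`,
#'   `baseline`, `membrane_outer_r`, `membrane_sigma`.
#' @export
profile_metrics <- function(profile, frac = 0.1) {
  stopifnot(inherits(profile, "radial_profile"))
  r <- profile$r; rho <- profile$rho
  n <- length(r)
  baseline <- median(rho[r >= 0.8 * max(r)])
  gmax <- max(rho)
  if (gmax <= baseline) stop("flat profile: no peak above baseline")
  peak_thr <- baseline + 0.5 * (gmax - baseline)
  is_max <- c(FALSE, rho[2:(n - 1)] >= rho[1:(n - 2)] &
                     rho[2:(n - 1)] >= rho[3:n], FALSE)
  cand <- which(is_max & rho >= peak_thr)
  if (length(cand) == 0) stop("no membrane peak detected")
  ip <- cand[1]
  mem_r <- r[ip]
  A <- rho[ip] - baseline
  # membrane width from the inner half-maximum (inner side is solvent-only)
  half <- baseline + A / 2
  j <- ip
  while (j > 1 && rho[j - 1] > half) j <- j - 1
  sigma_m <- if (j == 1) {
    (mem_r - r[1]) / 1.1774
  } else {
    rh <- r[j - 1] + (r[j] - r[j - 1]) * (half - rho[j - 1]) / (rho[j] - rho[j - 1])
    max(r[2] - r[1], mem_r - rh) / sqrt(2 * log(2))
  }
  # outer width separately (the shell average is slightly asymmetric in r)
  k <- ip
  while (k < n && rho[k + 1] > half) k <- k + 1
  sigma_o <- if (k == n) sigma_m else {
    rh <- r[k] + (r[k + 1] - r[k]) * (rho[k] - half) / (rho[k] - rho[k + 1])
    max(r[2] - r[1], rh - mem_r) / sqrt(2 * log(2))
  }
  sg <- ifelse(r <= mem_r, sigma_m, sigma_o)
  gauss <- baseline + A * exp(-(r - mem_r)^2 / (2 * sg^2))
  res <- rho - gauss
  # outer frac-edge of the membrane peak itself (reported for reference)
  below <- which(rho < baseline + frac * A & seq_len(n) > ip)
  mem_outer_r <- if (length(below)) r[below[1]] else NA_real_
  out <- list(membrane_peak_r = mem_r, baseline = baseline,
              membrane_outer_r = mem_outer_r, membrane_sigma = sigma_m)
  absent <- function() {
    structure(c(out, list(gap = NA_real_, extension = NA_real_,
                          protein_region = c(NA_real_, NA_real_),
                          bimodal = NA, protein_present = FALSE)),
              class = "profile_metrics")
  }
  # protein shell on the membrane-subtracted residual, beyond the peak
  search <- which(r > mem_r + sigma_o)
  if (length(search) < 3) return(absent())
  ipk <- search[which.max(res[search])]
  P <- res[ipk]
  if (P < frac * A) return(absent())
  thr_lo <- frac * P
  thr_half <- P / 2
  # candidate region: contiguous run around the residual peak above frac*P
  i_in <- ipk
  while (i_in > search[1] && res[i_in - 1] >= thr_lo) i_in <- i_in - 1
  i_out <- ipk
  while (i_out < n && res[i_out + 1] >= thr_lo) i_out <- i_out + 1
  cross_up <- function(i) {
    # interpolated upward half-maximum crossing at the inner edge
    k <- ipk
    while (k > i && res[k - 1] >= thr_half) k <- k - 1
    if (k == i || res[k] == res[k - 1]) return(r[max(i, k)])
    r[k - 1] + (r[k] - r[k - 1]) * (thr_half - res[k - 1]) / (res[k] - res[k - 1])
  }
  cross_down <- function(i) {
    k <- ipk
    while (k < i && res[k + 1] >= thr_half) k <- k + 1
    if (k == i || res[k] == res[k + 1]) return(r[min(i, k)])
    r[k] + (r[k + 1] - r[k]) * (res[k] - thr_half) / (res[k] - res[k + 1])
  }
  r_in <- cross_up(i_in)
  r_out <- cross_down(i_out)
  # bimodality within the protein shell: two maxima separated by a >= 10% dip
  reg <- i_in:i_out
  rm_ <- res[reg]
  nr <- length(rm_)
  bimodal <- FALSE
  if (nr >= 3) {
    locmax <- which(c(FALSE, rm_[2:(nr - 1)] > rm_[1:(nr - 2)] &
                             rm_[2:(nr - 1)] >= rm_[3:nr], FALSE))
    if (length(locmax) >= 2) {
      for (a in seq_len(length(locmax) - 1)) {
        for (b in (a + 1):length(locmax)) {
          dip <- min(rm_[locmax[a]:locmax[b]])
          lo <- min(rm_[locmax[a]], rm_[locmax[b]])
          if (dip < 0.9 * lo) bimodal <- TRUE
        }
      }
    }
  }
  structure(c(out, list(gap = r_in - mem_r, extension = r_out - r_in,
                        protein_region = c(r_in, r_out),
                        bimodal = bimodal, protein_present = TRUE)),
            class = "profile_metrics")
}

#' @export
print.profile_metrics <- function(x, ...) {
  if (x$protein_present)
    cat(sprintf("profile_metrics: membrane peak %.1f A, gap %.1f A, extension %.1f A%s\n",
                x$membrane_peak_r, x$gap, x$extension,
                if (isTRUE(x$bimodal)) " (bimodal)" else ""))
  else
    cat(sprintf("profile_metrics: membrane peak %.1f A, no protein shell detected\n",
                x$membrane_peak_r))
  invisible(x)
}

#' Average radial profiles aligned on their membrane peaks
#'
#' Shifts every profile so the membrane peaks coincide (at their mean
#' radius), interpolates onto a common grid, and returns the pointwise mean
#' and standard deviation over the common support.
#'
#' @param profiles List of >= 2 [radial_profile()] objects, each with a
#'   detectable membrane peak.
#' @return A [radial_profile()] whose `rho` is the mean, with extra fields
#'   `sd` and `n_profiles`.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  peaks <- rep(NA_real_, length(profiles))
  for (i in seq_along(profiles)) {
    pm <- try(profile_metrics(profiles[[i]]), silent = TRUE)
    if (!inherits(pm, "try-error")) peaks[i] <- pm$membrane_peak_r
  }
  if (any(is.na(peaks)))
    stop("profiles without a detectable membrane peak: ",
         paste(which(is.na(peaks)), collapse = ", "))
  target_peak <- mean(peaks)
  grid <- profiles[[1]]$r - peaks[1] + target_peak
  vals <- sapply(seq_along(profiles), function(i) {
    approx(profiles[[i]]$r - peaks[i] + target_peak, profiles[[i]]$rho,
           xout = grid)$y
  })
  ok <- rowSums(is.na(vals)) == 0
  structure(list(r = grid[ok],
                 rho = rowMeans(vals[ok, , drop = FALSE]),
                 sd = apply(vals[ok, , drop = FALSE], 1, sd),
                 n_samples = rep(length(profiles), sum(ok)),
                 n_profiles = length(profiles),
                 center = profiles[[1]]$center),
            class = "radial_profile")
}
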