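# smooth spherically-symmetric fixture: Gaussian membrane shell only
smooth_shell <- function(box = 48, seed = 1)
  make_liposome_volume(box = box, membrane_radius = 80, membrane_thickness = 70,
                       gap = 20, protein_extent = 40, amplitudes = c(1, 0),
                       seed = seed)$vol

test_that("the icosahedral rotation set is a 60-element group of rotations", {
  rots <- saxsemble:::icosahedral_rotations()
  expect_length(rots, 60)
  for (R in rots[c(1, 13, 37, 60)]) {
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("icosahedral averaging fixes symmetric volumes and is idempotent", {
  vol <- smooth_shell()
  va <- icosahedral_average(vol)
  rel <- function(a, b) sqrt(mean((a$grid - b$grid)^2)) / sqrt(mean(b$grid^2))
  expect_lt(rel(va, vol), 0.01)
  vb <- icosahedral_average(va)
  expect_lt(rel(vb, va), 0.01)
  # mean density is conserved
  expect_equal(mean(va$grid), mean(vol$grid), tolerance = 1e-3)
  expect_error(icosahedral_average(density_volume(array(0, c(16, 16, 20)), 5)),
               "cubic")
})

test_that("a point source is spread over its 60-point icosahedral orbit", {
  d <- 32
  g <- array(0, c(d, d, d))
  src <- c(24, 18, 15)                      # off-center voxel (1-based)
  g[src[1], src[2], src[3]] <- 1
  vol <- density_volume(g, 5)
  va <- icosahedral_average(vol)
  cen <- (d - 1) / 2
  p0 <- src - 1 - cen
  orbit <- t(vapply(saxsemble:::icosahedral_rotations(),
                    function(R) as.numeric(R %*% p0) + cen, numeric(3)))
  at_orbit <- saxsemble:::cpp_trilinear(as.numeric(va$grid), as.integer(dim(va$grid)),
                                        orbit, 0)
  expect_true(all(at_orbit > 0))
  # mass is conserved and concentrated on the orbit
  expect_equal(sum(va$grid), 1, tolerance = 0.02)
  far <- matrix(cen + c(3, 0, 0, 0, 4, 1, -5, 2, 0, 1, 1, 8), 4, 3, byrow = TRUE)
  expect_lt(max(saxsemble:::cpp_trilinear(as.numeric(va$grid),
                                          as.integer(dim(va$grid)), far, 0)),
            min(at_orbit))
})

test_that("axis rotational averaging rings out off-axis density", {
  d <- 32
  g <- array(0, c(d, d, d))
  g[26, 17, 17] <- 1                        # on the z = center plane
  vol <- density_volume(g, 5)
  vz <- axis_rotational_average(vol, axes = "z", step_deg = 10)
  cen <- (d - 1) / 2
  r0 <- sqrt(sum((c(25, 16, 16) - cen)^2))
  ring <- t(sapply(seq(0, 2 * pi, length.out = 18)[-18], function(a)
    cen + c(r0 * cos(a), r0 * sin(a), 0)))
  on_ring <- saxsemble:::cpp_trilinear(as.numeric(vz$grid), as.integer(dim(vz$grid)),
                                       ring, 0)
  expect_true(all(on_ring > 0))
  expect_lt(vz$grid[16, 16, 16], min(on_ring))   # center stays empty
  expect_error(axis_rotational_average(vol, "z", step_deg = 7), "divide")

  # symmetric input is a fixed point here too
  sym <- smooth_shell(box = 32)
  vs <- axis_rotational_average(sym, axes = c("x", "y"))
  expect_lt(sqrt(mean((vs$grid - sym$grid)^2)) / sqrt(mean(sym$grid^2)), 0.01)
})

test_that("radial profiles recover shells, stay rotation invariant, and flag bad centers", {
  # constant volume gives a constant profile
  uni <- density_volume(array(3, c(24, 24, 24)), 4)
  pu <- radial_profile(uni, center = c(46, 46, 46))
  expect_true(all(abs(pu$rho - 3) < 1e-9))

  # synthetic shell at 100 A, 8.8 A voxels: argmax within one voxel
  lip <- make_liposome_volume(amplitudes = c(1, 0), seed = 2)
  pr <- radial_profile(lip$vol, center = c(0, 0, 0))
  expect_lte(abs(pr$r[which.max(pr$rho)] - 100), 8.8)

  # rotating the volume changes the profile by < 2% RMS
  set.seed(50)
  Rr <- saxsemble:::random_rotation()
  rot <- saxsemble:::rotational_average(lip$vol, list(Rr))
  pr2 <- radial_profile(rot, center = c(0, 0, 0))
  expect_lt(sqrt(mean((pr2$rho - pr$rho)^2)) / sqrt(mean(pr$rho^2)), 0.02)

  # auto-centering lands on the construction center
  expect_lt(max(abs(radial_profile(lip$vol, "auto")$center)), 4)

  expect_error(radial_profile(lip$vol, center = c(1e4, 0, 0)), "outside")
})

test_that("symmetry averaging does not change the radial profile", {
  # smooth two-shell volume: Gaussian membrane plus a broad Gaussian-edged
  # protein band built by mixing two shells of different widths
  lipA <- make_liposome_volume(box = 48, membrane_radius = 80,
                               membrane_thickness = 60, gap = 20,
                               protein_extent = 60, amplitudes = c(1, 0), seed = 3)
  lipB <- make_liposome_volume(box = 48, membrane_radius = 170,
                               membrane_thickness = 90, gap = 5,
                               protein_extent = 20, amplitudes = c(0.5, 0), seed = 3)
  lip <- list(vol = density_volume(lipA$vol$grid + lipB$vol$grid, 8.8,
                                   lipA$vol$origin))
  pr_direct <- radial_profile(lip$vol, center = c(0, 0, 0))
  avg <- axis_rotational_average(icosahedral_average(lip$vol), axes = c("x", "y"))
  pr_avg <- radial_profile(avg, center = c(0, 0, 0))
  n <- min(length(pr_direct$rho), length(pr_avg$rho))
  expect_lt(sqrt(mean((pr_avg$rho[1:n] - pr_direct$rho[1:n])^2)) /
              sqrt(mean(pr_direct$rho[1:n]^2)), 0.02)
})

test_that("profile metrics read membrane peak, gap and extension off a synthetic profile", {
  # analytic profile mirroring the reported vesicle geometry:
  # membrane Gaussian at 100 A (sigma 15), protein plateau 130-270 A
  r <- seq(0, 430, by = 8.8)
  rho <- exp(-(r - 100)^2 / (2 * 15^2)) + 0.55 * (r >= 130 & r <= 270)
  prof <- structure(list(r = r, rho = rho, n_samples = rep(1000, length(r)),
                         center = c(0, 0, 0)), class = "radial_profile")
  pm <- profile_metrics(prof)
  expect_true(pm$protein_present)
  expect_lte(abs(pm$membrane_peak_r - 100), 8.8)
  expect_lte(abs(pm$gap - 30), 8.8)
  expect_lte(abs(pm$extension - 140), 8.8)
  expect_false(pm$bimodal)

  # membrane-only profile: protein shell absent but flagged, not an error
  prof0 <- structure(list(r = r, rho = exp(-(r - 100)^2 / (2 * 15^2)),
                          n_samples = rep(1000, length(r)), center = c(0, 0, 0)),
                     class = "radial_profile")
  pm0 <- profile_metrics(prof0)
  expect_false(pm0$protein_present)
  expect_true(is.na(pm0$extension))

  # two-humped protein shell is reported bimodal
  rho2 <- exp(-(r - 100)^2 / (2 * 15^2)) +
    0.5 * exp(-(r - 160)^2 / (2 * 18^2)) + 0.5 * exp(-(r - 240)^2 / (2 * 18^2))
  prof2 <- structure(list(r = r, rho = rho2, n_samples = rep(1000, length(r)),
                          center = c(0, 0, 0)), class = "radial_profile")
  expect_true(profile_metrics(prof2)$bimodal)

  # flat profile is an error
  flat <- structure(list(r = r, rho = rep(1, length(r)),
                         n_samples = rep(1000, length(r)), center = c(0, 0, 0)),
                    class = "radial_profile")
  expect_error(profile_metrics(flat), "flat")
})

test_that("profile averaging aligns membrane peaks before the pointwise mean", {
  lip <- make_liposome_volume(seed = 4)
  p1 <- radial_profile(lip$vol, center = c(0, 0, 0))
  # identical profiles: mean is the input, sd is zero
  avg0 <- average_profiles(list(p1, p1, p1))
  expect_equal(avg0$rho, approx(p1$r, p1$rho, avg0$r)$y, tolerance = 1e-12)
  expect_true(all(avg0$sd < 1e-12))

  # same shape at shifted radii: alignment recovers the shape with ~zero sd
  shift_prof <- function(dr) {
    p <- p1
    p$r <- p$r + dr
    p
  }
  avg <- average_profiles(list(shift_prof(-10), p1, shift_prof(10)))
  common <- !is.na(approx(p1$r, p1$rho, avg$r)$y)
  expect_lt(max(avg$sd[common]), 1e-9)

  # three-vesicle averaging is the designed use; offenders are named
  flatp <- structure(list(r = p1$r, rho = rep(1, length(p1$r)),
                          n_samples = p1$n_samples, center = c(0, 0, 0)),
                     class = "radial_profile")
  expect_error(average_profiles(list(p1, flatp)), "2")
})
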