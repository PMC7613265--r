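test_that("Debye intensities match closed forms and the exact double sum", {
  q <- default_q_grid()
  # single unit bead scatters flat
  one <- debye_intensity(conformer_model(matrix(0, 1, 3)), q)
  expect_equal(one$I, rep(1, length(q)))

  # two unit beads at 10 A: I(q) = 2 + 2 sin(10q)/(10q)
  two <- debye_intensity(conformer_model(rbind(c(0, 0, 0), c(10, 0, 0))), q,
                         method = "exact")
  closed <- ifelse(q == 0, 4, 2 + 2 * sin(10 * q) / (10 * q))
  expect_equal(two$I, closed, tolerance = 1e-12)

  # histogram acceleration vs the plain-R double-sum oracle, 500 beads
  set.seed(20)
  beads <- matrix(rnorm(1500, sd = 30), 500, 3)
  w <- runif(500, 0.5, 2)
  m <- conformer_model(beads, weights = w)
  Ih <- debye_intensity(m, q)$I
  Io <- oracle_debye(beads, w, q)
  expect_lt(max(abs(Ih - Io) / Io), 0.005)

  # forward intensity at q = 0 is the squared total weight
  expect_equal(Ih[1], sum(w)^2, tolerance = 1e-8)
})

test_that("I(0) equals the squared total weight for arbitrary models", {
  set.seed(21)
  for (n in c(2, 37, 200)) {
    m <- conformer_model(matrix(rnorm(3 * n, sd = 25), n, 3),
                         weights = runif(n, 0.1, 3))
    expect_equal(debye_intensity(m, c(0, 0.1))$I[1], sum(m$weights)^2,
                 tolerance = 1e-8)
  }
})

test_that("Guinier fit inverts an exact Gaussian and handles error cases", {
  q <- default_q_grid()
  g <- guinier_fit(scattering_curve(q, 7 * exp(-q^2 * 40^2 / 3)))
  expect_equal(g$rg, 40, tolerance = 1e-5)
  expect_equal(g$i0, 7, tolerance = 1e-5)
  expect_lte(max(g$q_range_used) * g$rg, 1.3 + 1e-6)

  # rising curve has no Guinier region
  expect_error(guinier_fit(scattering_curve(q, 1 + q^2)), "no Guinier region")
  expect_error(guinier_fit(scattering_curve(q[1:4], exp(-q[1:4]^2))), "fewer than 5")
})

test_that("Guinier Rg of a bead sphere lands within 2% of the closed form", {
  # 20000 beads keep the Monte Carlo error well below the ~1.8% bias that the
  # qRg <= 1.3 Guinier window itself carries for a solid sphere
  tpl <- make_domain_templates("sphere", radius = 50, n_beads = 20000,
                               min_sep = 0, seed = 22)
  m <- conformer_model(tpl$domains$sphere$beads)
  cv <- debye_intensity(m, default_q_grid(n = 301, q_max = 0.15))
  expect_equal(guinier_fit(cv)$rg, sqrt(3 / 5) * 50, tolerance = 0.02)
  # and agrees with the direct-space Rg for this compact model
  expect_equal(guinier_fit(cv)$rg, model_rg(m), tolerance = 0.02)
})

test_that("Guinier fit is unbiased at the percent level under 1% noise", {
  q <- default_q_grid()
  I0 <- 5 * exp(-q^2 * 35^2 / 3)
  set.seed(23)
  rgs <- replicate(100, {
    I <- I0 + rnorm(length(q), 0, 0.01 * I0)
    guinier_fit(scattering_curve(q, abs(I), sigma = 0.01 * I0))$rg
  })
  expect_lt(abs(mean(rgs) - 35) / 35, 0.01)
})

test_that("P(r) from models matches the sphere closed form and the pair oracle", {
  # two beads 10 A apart: single occupied bin
  pd2 <- pdist_from_model(conformer_model(rbind(c(0, 0, 0), c(10, 0, 0))), dr = 2)
  expect_equal(pd2$dmax, 10)
  expect_equal(sum(pd2$p > 0), 1)
  expect_equal(pd2$r[pd2$p > 0], 11, tolerance = 2)   # bin containing r = 10

  # uniform ball: p(r) = 12 x^2 (2 - 3x + x^3) / (2R), x = r / 2R
  tpl <- make_domain_templates("sphere", radius = 50, n_beads = 5000,
                               min_sep = 0, seed = 24)
  pd <- pdist_from_model(conformer_model(tpl$domains$sphere$beads), dr = 2)
  x <- pd$r / 100
  pth <- ifelse(x <= 1, 12 * x^2 * (2 - 3 * x + x^3) / 100, 0)
  expect_lt(max(abs(pd$p - pth)) / max(pth), 0.03)

  # unit area and the second-moment identity <r^2> = 2 Rg^2
  expect_equal(pracma::trapz(pd$r, pd$p), 1, tolerance = 1e-6)
  rg <- model_rg(conformer_model(tpl$domains$sphere$beads))
  expect_equal(pracma::trapz(pd$r, pd$p * pd$r^2), 2 * rg^2, tolerance = 0.01)

  # histogram equals direct pair enumeration on a small model
  set.seed(25)
  beads <- matrix(rnorm(300, sd = 12), 100, 3)
  w <- runif(100, 0.5, 2)
  pdm <- pdist_from_model(conformer_model(beads, weights = w), dr = 1.5)
  counts <- oracle_pair_hist(beads, w, 1.5)
  inner <- pdm$p[2:(length(counts) + 1)]
  expect_equal(inner / sum(inner), counts / sum(counts), tolerance = 1e-12)
})

test_that("indirect transform recovers P(r) from a noiseless curve", {
  tpl <- make_domain_templates("sphere", radius = 40, n_beads = 2000,
                               min_sep = 0, seed = 26)
  m <- conformer_model(tpl$domains$sphere$beads)
  cv <- debye_intensity(m, default_q_grid())
  dm <- model_dmax(m)
  pd_curve <- pdist_from_curve(cv, dmax = dm)
  pd_model <- pdist_from_model(m, dr = 2)
  pm <- approx(pd_model$r, pd_model$p, pd_curve$r, rule = 2)$y
  expect_lt(pracma::trapz(pd_curve$r, abs(pd_curve$p - pm)), 0.05)
  expect_true(all(pd_curve$p >= 0))
  expect_equal(pd_curve$p[1], 0)
  expect_equal(pd_curve$p[length(pd_curve$p)], 0)

  # stronger smoothing cannot roughen the solution
  curvature <- function(alpha)
    sum(diff(diff(pdist_from_curve(cv, dm, alpha = alpha)$p))^2)
  expect_lte(curvature(2), curvature(1) + 1e-12)
})

test_that("normalized Kratky transform has the globular peak and scale invariance", {
  tpl <- make_domain_templates("sphere", radius = 50, n_beads = 3000,
                               min_sep = 0, seed = 27)
  m <- conformer_model(tpl$domains$sphere$beads)
  q <- seq(0, 0.12, length.out = 601)
  cv <- debye_intensity(m, q)
  g <- guinier_fit(cv)
  k <- normalized_kratky(cv, g)
  ipk <- which.max(k$y[k$x < 3])
  expect_equal(k$x[ipk], sqrt(3), tolerance = 0.1 / sqrt(3))
  expect_equal(k$y[ipk], 3 / exp(1), tolerance = 0.05 / (3 / exp(1)))
  expect_equal(k$y[1], 0)

  # invariant to overall intensity scaling
  cv5 <- scattering_curve(cv$q, 5 * cv$I)
  k5 <- normalized_kratky(cv5, guinier_fit(cv5))
  expect_equal(k5$y, k$y, tolerance = 1e-9)

  # flat intensity maps to the parabola y = x^2
  flat <- scattering_curve(q, rep(2, length(q)))
  gf <- structure(list(rg = 10, i0 = 2), class = "guinier_fit")
  kf <- normalized_kratky(flat, gf)
  expect_equal(kf$y, kf$x^2)
})

test_that("flexible-chain curves plateau in the normalized Kratky plot", {
  # Gaussian-coil (Debye) form factor: rises to a plateau, no return to zero
  q <- default_q_grid()
  rg <- 40
  x2 <- (q * rg)^2
  I <- ifelse(x2 == 0, 1, 2 * (exp(-x2) + x2 - 1) / x2^2)
  cv <- scattering_curve(q, I)
  k <- normalized_kratky(cv, guinier_fit(cv))
  tail_y <- k$y[k$x > 4]
  expect_true(all(tail_y > 0.8 * max(k$y)))
})

test_that("concentration-series merging rescales and averages correctly", {
  tpl <- make_domain_templates("sphere", radius = 30, n_beads = 1000,
                               min_sep = 0, seed = 28)
  q <- default_q_grid()
  I <- debye_intensity(conformer_model(tpl$domains$sphere$beads), q)$I
  s1 <- scattering_curve(q, I, sigma = 0.01 * I + 1e-9)
  s2 <- scattering_curve(q, 2 * I, sigma = 0.02 * I + 1e-9)
  merged <- merge_curves(list(s1, s2), c(1, 2))
  expect_lt(max(abs(merged$I - I) / I), 1e-10)

  # averaging gain: merged sigma no larger than the inputs where both agree
  expect_true(all(merged$sigma <= s1$sigma + 1e-15))

  # low-q structure factor on the concentrated curve is excluded
  pert <- ifelse(q < 0.05, 0.85, 1)
  s3 <- scattering_curve(q, 2 * I * pert, sigma = 0.002 * I + 1e-9)
  m2 <- merge_curves(list(s1, s3), c(1, 5))
  expect_lt(max(abs(m2$I[q < 0.05] - I[q < 0.05]) / I[q < 0.05]), 0.01)
  expect_gte(attr(m2, "q_cross"), 0.05)

  # disjoint grids cannot be merged
  sa <- scattering_curve(q[1:30], I[1:30], sigma = 0.01 * I[1:30] + 1e-9)
  sb <- scattering_curve(q[60:101] + 1e-7, I[60:101], sigma = 0.01 * I[60:101] + 1e-9)
  expect_error(merge_curves(list(sa, sb), c(1, 2)), "no q-overlap")
})
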