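test_that("linker sampler respects bond geometry and excluded volume", {
  set.seed(1)
  # single residue sits one bond length from the anchor
  l1 <- sample_linker(1, c(2, -1, 5), c(0, 0, 1))
  expect_equal(sqrt(sum((l1[1, ] - c(2, -1, 5))^2)), 3.8, tolerance = 1e-12)

  # fixed 3.8 A bonds and the contour-length bound
  l10 <- sample_linker(10, c(0, 0, 0), c(1, 0, 0))
  bonds <- sqrt(rowSums(diff(l10)^2))
  expect_equal(bonds, rep(3.8, 9), tolerance = 1e-10)
  expect_lt(sqrt(sum(l10[10, ]^2)), 10 * 3.8 + 1e-9)

  # excluded volume against non-adjacent linker beads and context
  set.seed(2)
  ctx <- matrix(rnorm(60, sd = 8), 20, 3)
  l <- sample_linker(30, c(40, 0, 0), c(1, 0, 0), context_beads = ctx)
  dl <- as.matrix(dist(l))
  nonadj <- abs(row(dl) - col(dl)) >= 2
  expect_gte(min(dl[nonadj]), 4.0)
  cross <- sqrt(outer(rowSums(l^2), rowSums(ctx^2), "+") - 2 * l %*% t(ctx))
  expect_gte(min(cross), 4.0)
})

test_that("linker sampler is deterministic under a seed and fails loudly when boxed in", {
  set.seed(33); a <- sample_linker(25, c(0, 0, 0), c(1, 0, 0))
  set.seed(33); b <- sample_linker(25, c(0, 0, 0), c(1, 0, 0))
  expect_identical(a, b)

  # a cage of context beads around the anchor leaves no room
  th <- seq(0, pi, length.out = 12)
  ph <- seq(0, 2 * pi, length.out = 24)
  cage <- unique(do.call(rbind, lapply(th, function(t)
    cbind(6 * sin(t) * cos(ph), 6 * sin(t) * sin(ph), 6 * cos(t)))))
  set.seed(4)
  expect_error(sample_linker(5, c(0, 0, 0), c(1, 0, 0), context_beads = cage,
                             max_attempts = 20),
               "failed after")
})

test_that("linker end-to-end statistics match an independent implementation", {
  set.seed(7)
  msd_oracle <- mean(replicate(3000, sum(oracle_linker(50)[50, ]^2)))
  set.seed(8)
  msd_pkg <- mean(replicate(10000,
    sum(sample_linker(50, c(0, 0, 0), c(1, 0, 0))[50, ]^2)))
  expect_lt(abs(msd_pkg - msd_oracle) / msd_oracle, 0.15)
})

test_that("build_protomer keeps rigid bodies rigid and the chain connected", {
  tpl <- make_domain_templates("core_tetramer", radius = 12, n_beads = 60, seed = 3)
  set.seed(10)
  p <- build_protomer(tpl$blueprint, tpl$domains)

  # bead bookkeeping: segments plus ligand beads
  expect_equal(nrow(p$beads), 60 + 40 + 21 + 120 + 10 + 80 + 8 + 40 + 2 * 20)

  # intra-domain distance matrices preserved to 1e-6 A
  for (seg_id in c(1, 3, 5, 7)) {
    idx <- which(p$segment == seg_id)
    dom <- tpl$domains[[tpl$blueprint$segments[[seg_id]]$id]]
    expect_lt(max(abs(dist(p$beads[idx, ]) - dist(dom$beads))), 1e-6)
  }
  for (k in 1:2) {
    idx <- which(p$segment == -k)
    dom <- tpl$domains[[tpl$blueprint$ligands[[k]]$domain]]
    expect_lt(max(abs(dist(p$beads[idx, ]) - dist(dom$beads))), 1e-6)
  }

  # chain connectivity: every junction spans one bond length
  for (i in 2:length(tpl$blueprint$segments)) {
    s <- tpl$blueprint$segments[[i]]
    if (s$type == "linker") {
      first_bead <- p$beads[which(p$segment == i)[1], ]
      prev <- tpl$blueprint$segments[[i - 1]]
      dom <- tpl$domains[[prev$id]]
      prev_idx <- which(p$segment == i - 1)
      anchor <- p$beads[prev_idx[dom$anchor_out], ]
      expect_equal(sqrt(sum((first_bead - anchor)^2)), 3.8, tolerance = 1e-9)
    }
  }

  # single-rigid blueprint reproduces the template verbatim
  sph <- make_domain_templates("sphere", radius = 20, n_beads = 50, seed = 5)
  m <- build_protomer(sph$blueprint, sph$domains)
  expect_equal(m$beads, sph$domains$sphere$beads, ignore_attr = TRUE)

  # missing domain id is a validation error
  bad <- chain_blueprint(list(list(type = "rigid", id = "ghost")))
  expect_error(build_protomer(bad, tpl$domains), "missing domain")
})

test_that("dumbbell conformers vary across seeds but never exceed the contour bound", {
  tpl <- make_domain_templates("dumbbell", radius = 10, n_beads = 40,
                               linker_length = 20, seed = 6)
  pool <- generate_pool(tpl$blueprint, tpl$domains, n = 12, seed = 21)
  inter <- vapply(pool$models, function(m) {
    a <- colMeans(m$beads[m$segment == 1, ])
    b <- colMeans(m$beads[m$segment == 3, ])
    sqrt(sum((a - b)^2))
  }, 0)
  expect_gt(sd(inter), 0)   # linker conformations differ between models
  diam <- function(d) oracle_dmax(d$beads)
  contour <- diam(tpl$domains$lobe1) + diam(tpl$domains$lobe2) + 22 * 3.8
  expect_true(all(pool$dmax <= contour))
})

test_that("clash score counts non-adjacent close pairs per 1000 beads", {
  # two distant beads: no clash
  expect_equal(clash_score(conformer_model(rbind(c(0, 0, 0), c(10, 0, 0)))), 0)
  # 10 coincident beads on distinct chains: all 45 pairs clash
  m <- conformer_model(matrix(0, 10, 3), chain = 1:10)
  expect_equal(clash_score(m), 45 * 1000 / 10)
  # consecutive beads of one chain are bonded, not clashing
  chainm <- conformer_model(cbind(seq(0, 3.8 * 9, by = 3.8), 0, 0))
  expect_equal(clash_score(chainm), 0)
  # random model agrees with the O(n^2) oracle
  set.seed(11)
  beads <- matrix(rnorm(300, sd = 6), 100, 3)
  chain <- rep(1:2, each = 50)
  mm <- conformer_model(beads, chain = chain)
  expect_equal(clash_score(mm, 3.0),
               oracle_clash_count(beads, chain, 3.0) * 1000 / 100)
})

test_that("clash filtering retains exactly the passing models and is idempotent", {
  set.seed(12)
  mk <- function(sd) conformer_model(matrix(rnorm(90, sd = sd), 30, 3), chain = 1:30)
  models <- c(lapply(c(2, 2.5, 3), mk), lapply(c(12, 15), mk))
  pool <- conformer_pool(models)
  scores <- vapply(models, clash_score, 0)
  f <- filter_pool(pool, max_clash = 60)
  expect_equal(length(f), sum(scores <= 60))
  expect_identical(filter_pool(f, max_clash = 60)$models, f$models)
  expect_error(filter_pool(pool, max_clash = -1), "removed every model")
})

test_that("model_rg and model_dmax recover closed forms and the brute-force maximum", {
  two <- conformer_model(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(model_rg(two), 5)
  expect_equal(model_dmax(two), 10)

  one <- conformer_model(matrix(1, 1, 3))
  expect_equal(model_rg(one), 0)
  expect_equal(model_dmax(one), 0)

  # uniform ball of radius 50: Rg -> sqrt(3/5) * 50
  tpl <- make_domain_templates("sphere", radius = 50, n_beads = 5000,
                               min_sep = 0, seed = 13)
  m <- conformer_model(tpl$domains$sphere$beads)
  expect_equal(model_rg(m), sqrt(3 / 5) * 50, tolerance = 0.02)

  set.seed(14)
  r100 <- conformer_model(matrix(rnorm(300, sd = 20), 100, 3))
  expect_equal(model_dmax(r100), oracle_dmax(r100$beads), tolerance = 1e-12)

  # weighted Rg follows the weighted definition
  w <- c(3, 1)
  expect_equal(model_rg(conformer_model(rbind(c(0, 0, 0), c(4, 0, 0)), weights = w)),
               sqrt(sum(w * c(1, 3)^2) / 4))
})

test_that("tetramer combination docks cores exactly and records provenance", {
  tpl <- make_domain_templates("core_tetramer", radius = 12, n_beads = 60, seed = 3)
  pools <- lapply(1:4, function(k)
    generate_pool(tpl$blueprint, tpl$domains, n = 3, seed = 200 + k))
  tet <- combine_tetramers(pools, tpl$tetramer, n = 10, seed = 9)
  expect_equal(length(tet), 10)
  expect_equal(dim(tet$provenance), c(10, 4))
  expect_true(all(tet$provenance >= 1 & tet$provenance <= 3))

  # each docked protomer core superposes on its D2 site to numerical precision
  m <- tet$models[[1]]
  for (k in 1:4) {
    idx <- which(m$chain == k & m$segment == 1)
    src <- pools[[k]]$models[[tet$provenance[1, k]]]
    ref <- apply_transform(src$beads[src$segment == 1, ],
                           tpl$tetramer$core_transforms[[k]])
    expect_lt(max(abs(m$beads[idx, ] - ref)), 1e-6)
  }

  # four singleton pools with no clashes give n copies of the one tetramer
  ones <- lapply(pools, function(p) conformer_pool(p$models[1]))
  t1 <- combine_tetramers(ones, tpl$tetramer, n = 4, seed = 1)
  expect_equal(length(t1), 4)
  for (i in 2:4) expect_identical(t1$models[[i]]$beads, t1$models[[1]]$beads)
})

test_that("pools are reproducible from their seed and degenerate without linkers", {
  tpl <- make_domain_templates("dumbbell", radius = 8, n_beads = 20, seed = 15)
  a <- generate_pool(tpl$blueprint, tpl$domains, n = 5, seed = 42)
  b <- generate_pool(tpl$blueprint, tpl$domains, n = 5, seed = 42)
  for (i in 1:5) expect_identical(a$models[[i]]$beads, b$models[[i]]$beads)

  # a blueprint with no flexible segments has a single-valued Rg distribution
  sph <- make_domain_templates("sphere", radius = 20, n_beads = 60, seed = 16)
  rigid <- generate_pool(sph$blueprint, sph$domains, n = 5, seed = 1)
  expect_equal(diff(range(rigid$rg)), 0)
})
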