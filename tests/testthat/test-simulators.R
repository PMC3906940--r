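test_that("simulators are bit-reproducible under a fixed seed", {
  t1 <- simulate_bd_tree(1, 0, 16, seed = 7)
  t2 <- simulate_bd_tree(1, 0, 16, seed = 7)
  expect_identical(write_newick(t1), write_newick(t2))

  p <- bisse_params(0.2, 0.4, 0.05, 0.1, 0.05, 0.05)
  s1 <- simulate_bisse(p, 12, root_state = 1, seed = 3)
  s2 <- simulate_bisse(p, 12, root_state = 1, seed = 3)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))
  expect_identical(s1$states, s2$states)
})

test_that("bd simulator produces exact ultrametric samples", {
  tr <- simulate_bd_tree(1, 0, 16, seed = 7)
  expect_equal(length(tr$tip.label), 16L)        # mu = 0: no pruning
  expect_true(is_ultrametric(tr))

  trbd <- simulate_bd_tree(0.8, 0.4, 25, seed = 11)
  expect_equal(length(trbd$tip.label), 25L)
  expect_true(is_ultrametric(trbd))

  expect_error(simulate_bd_tree(0.2, 0.5, 10), "lambda > mu")
})

test_that("bisse simulator respects trivial state constraints", {
  p0 <- bisse_params(0.5, 0.5, 0, 0, 0, 0)
  sim <- simulate_bisse(p0, 10, root_state = 0, seed = 1)
  expect_true(all(sim$states == 0))
  expect_named(sim$states, sim$tree$tip.label)

  # lambda1 >> lambda0 with small q: state-1 tips dominate in the large
  # majority of replicates
  p <- bisse_params(0.05, 0.5, 0, 0, 0.02, 0.02)
  frac1 <- vapply(1:200, function(s) {
    st <- simulate_bisse(p, 15, root_state = 1, seed = s)$states
    mean(st == 1)
  }, numeric(1L))
  expect_gt(mean(frac1 > 0.5), 0.85)
})

test_that("root age decreases with lambda at fixed diversification", {
  ages <- function(lambda, mu) {
    vapply(1:80, function(s)
      max(salmodiv:::node_ages(simulate_bd_tree(lambda, mu, 20, seed = s))),
      numeric(1L))
  }
  expect_gt(mean(ages(0.3, 0.0)), mean(ages(1.3, 1.0)))
})

test_that("state-independent bisse degenerates to the bd tree process", {
  n_rep <- 200L
  age_bd <- vapply(1:n_rep, function(s)
    max(salmodiv:::node_ages(simulate_bd_tree(0.5, 0.1, 15, seed = s))),
    numeric(1L))
  p <- bisse_params(0.5, 0.5, 0.1, 0.1, 0.3, 0.3)
  age_bi <- vapply(1:n_rep, function(s)
    max(salmodiv:::node_ages(
      simulate_bisse(p, 15, root_state = 0, seed = 10000 + s)$tree)),
    numeric(1L))
  qs <- quantile(age_bd, c(0.25, 0.5, 0.75))
  qb <- quantile(age_bi, c(0.25, 0.5, 0.75))
  expect_lt(max(abs(qs - qb) / qs), 0.35)
  expect_false(isTRUE(suppressWarnings(
    ks.test(age_bd, age_bi)$p.value < 0.001)))
})

test_that("hky alignment simulator honours kappa and position rates", {
  tr <- read_newick("((A:40,B:40):40,C:80);")

  # near-infinite kappa: transversions vanish
  aln <- simulate_alignment(tr, hky_params(kappa = 1000), 300, rate = 0.005,
                            seed = 1)
  sc <- saturation_scan(aln)
  expect_gt(sum(sc$transitions), 20)
  expect_lt(sum(sc$transversions), sum(sc$transitions) / 10)

  # position 3 rate multiplier: third positions diverge fastest
  hky <- hky_params(pos_rates = c(1, 1, 5))
  wins <- vapply(1:100, function(s) {
    a <- simulate_alignment(tr, hky, 120, rate = 0.002, seed = s)
    p3 <- mean(saturation_scan(codon_partition(a, 3))$p_dist)
    p12 <- mean(saturation_scan(codon_partition(a, c(1, 2)))$p_dist)
    p3 > p12
  }, logical(1L))
  expect_gte(mean(wins), 0.95)

  # zero-length branches give identical sequences
  tr0 <- read_newick("((A:0,B:0):1,C:1);")
  a0 <- simulate_alignment(tr0, hky_params(), 50, rate = 0.01, seed = 2)
  expect_identical(a0$seqs[["A"]], a0$seqs[["B"]])
})

test_that("sea-level fixture has the advertised structure", {
  sl <- make_sealevel_fixture(n_points = 1100, seed = 5)
  expect_equal(nrow(sl), 1100L)
  expect_lte(max(sl$age_ma), 130)
  expect_identical(sl, make_sealevel_fixture(n_points = 1100, seed = 5))

  # noise-free fixture: binned means recover the trend exactly at bin
  # midpoints of a linear segment
  sl0 <- make_sealevel_fixture(n_points = 2000, noise_sd = 0, seed = 9)
  b <- bin_time_series(sl0, 1)
  tr <- approx(c(0, 35, 90, 130), c(0, 60, 150, 110), xout = b$mid)$y
  full <- b$n > 10
  expect_lt(max(abs(b$mean[full] - tr[full])), 1.5)
})
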