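test_that("state-independent BiSSE factorises into BD x Mk2", {
  for (s in 1:20) {
    tr <- simulate_bd_tree(0.5, 0.15, 5, seed = 200 + s)
    set.seed(300 + s)
    st <- stats::setNames(rbinom(5, 1, 0.5), tr$tip.label)
    lam <- runif(1, 0.2, 0.8); mu <- runif(1, 0, 0.15)
    q01 <- runif(1, 0.05, 0.4); q10 <- runif(1, 0.05, 0.4)
    p <- bisse_params(lam, lam, mu, mu, q01, q10)
    got <- bisse_loglik(tr, st, p, root_mode = "equal")
    want <- oracle_bd_loglik(tr, lam, mu) +
      oracle_mk2_loglik(tr, st, q01, q10)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("production integrator matches the brute-force RK4 oracle", {
  set.seed(77)
  for (s in 1:6) {
    n <- sample(3:6, 1)
    tr <- simulate_bd_tree(0.6, 0.2, n, seed = 400 + s)
    st <- stats::setNames(rbinom(n, 1, 0.5), tr$tip.label)
    p <- bisse_params(runif(1, 0.1, 0.6), runif(1, 0.1, 0.6),
                      runif(1, 0, 0.2), runif(1, 0, 0.2),
                      runif(1, 0.02, 0.3), runif(1, 0.02, 0.3))
    for (rm in c("obs", "equal", "state0", "state1")) {
      got <- bisse_loglik(tr, st, p, root_mode = rm)
      want <- oracle_bisse_loglik(tr, st, p, root_mode = rm)
      expect_equal(got, want, tolerance = 1e-5)
    }
  }

  # 2-tip tree with a tiny branch length
  t2 <- read_newick("(A:1e-8,B:1e-8);")
  st2 <- c(A = 0L, B = 1L)
  p2 <- bisse_params(0.3, 0.4, 0.1, 0.05, 0.2, 0.15)
  expect_equal(bisse_loglik(t2, st2, p2),
               oracle_bisse_loglik(t2, st2, p2), tolerance = 1e-5)
})

test_that("extinction probabilities vanish when both mu are zero", {
  # with mu = 0 the E system stays at 0, so logL telescopes to the Yule
  # likelihood x Mk2 likelihood; check the state-independent closed form
  tr <- simulate_bd_tree(0.8, 0, 6, seed = 12)
  st <- stats::setNames(c(0, 1, 0, 1, 1, 0), tr$tip.label)
  p <- bisse_params(0.5, 0.5, 0, 0, 0.1, 0.1)
  got <- bisse_loglik(tr, st, p, root_mode = "equal")
  yule <- -0.5 * sum(tr$edge.length) + tr$Nnode * log(0.5)
  expect_equal(got, yule + oracle_mk2_loglik(tr, st, 0.1, 0.1),
               tolerance = 1e-7)
})

test_that("likelihood is invariant to tip relabeling and rotation", {
  sim <- simulate_bisse(bisse_params(0.2, 0.5, 0.05, 0.1, 0.1, 0.1),
                        12, root_state = 0, seed = 9)
  p <- bisse_params(0.25, 0.45, 0.04, 0.12, 0.08, 0.11)
  base <- bisse_loglik(sim$tree, sim$states, p)

  rot <- ape::rotate(sim$tree, length(sim$tree$tip.label) + 1L)
  expect_equal(bisse_loglik(rot, sim$states, p), base, tolerance = 1e-8)

  perm <- sample(length(sim$tree$tip.label))
  ren <- sim$tree
  ren$tip.label <- paste0("x", seq_along(ren$tip.label))
  st2 <- stats::setNames(sim$states, paste0("x", seq_along(sim$states)))
  expect_equal(bisse_loglik(ren, st2[perm], p), base, tolerance = 1e-8)
})

test_that("bisse_loglik validates its input", {
  sim <- simulate_bisse(bisse_params(0.3, 0.3, 0, 0, 0.1, 0.1), 6,
                        root_state = 0, seed = 2)
  p <- bisse_params(0.3, 0.3, 0, 0, 0.1, 0.1)
  expect_error(bisse_loglik(read_newick("((A:1,B:2):1,C:2);"),
                            c(A = 0, B = 1, C = 0), p), "ultrametric")
  bad <- sim$states[-1L]
  expect_error(bisse_loglik(sim$tree, bad, p))
})

test_that("ML honours nesting and the constrained patterns", {
  sim <- simulate_bisse(bisse_params(0.1, 0.35, 0.03, 0.1, 0.02, 0.02),
                        30, root_state = 1, seed = 21)
  free <- bisse_ml(sim$tree, sim$states, n_starts = 3, seed = 1)
  cons <- bisse_ml(sim$tree, sim$states, constrained = TRUE,
                   n_starts = 3, seed = 1)
  expect_equal(free$n_free, 6L)
  expect_equal(cons$n_free, 4L)
  expect_equal(cons$params[["lambda0"]], cons$params[["lambda1"]])
  expect_equal(cons$params[["mu0"]], cons$params[["mu1"]])
  expect_gte(free$loglik, cons$loglik - 1e-6)

  lrt <- bisse_lrt(free, cons)
  expect_equal(unname(lrt$parameter), 2)
  expect_gte(unname(lrt$statistic), 0)
  expect_error(bisse_lrt(cons, free), "not nested")
})

test_that("bisse_lrt reproduces the published chi-squared arithmetic", {
  mk <- function(ll, nf) structure(list(loglik = ll, n_free = nf),
                                   class = "bisse_fit")
  eq <- bisse_lrt(mk(-100, 6), mk(-100, 4))
  expect_equal(unname(eq$statistic), 0)
  expect_equal(eq$p.value, 1)

  # chi2 = 11.4: p = 0.0033 at df 2, p = 0.00073 at df 1 (the printed
  # p = 0.0008 implies the df = 1 convention)
  t2 <- bisse_lrt(mk(-100, 6), mk(-105.7, 4))
  expect_equal(unname(t2$statistic), 11.4)
  expect_equal(round(t2$p.value, 4), 0.0033)
  expect_equal(round(pchisq(11.4, 1, lower.tail = FALSE), 5), 0.00073)
  expect_lt(pchisq(18.44, 1, lower.tail = FALSE), 1e-4)
})
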