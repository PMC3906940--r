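#' BiSSE log-likelihood
#'
#' Likelihood of an ultrametric binary tree plus binary tip states under the
#' binary-state speciation-extinction model: along every branch the
#' extinction probabilities `E0(t)`, `E1(t)` and likelihood densities
#' `D0(t)`, `D1(t)` are propagated backwards in time by an adaptive
#' Runge-Kutta integrator (relative tolerance `rtol`, densities renormalised
#' per branch with an accumulated log-scaler), daughters are combined at
#' nodes as `Di <- Di_left * Di_right * lambda_i`, and the root states are
#' weighted according to `root_mode`:
#' `"obs"` (default) - weights proportional to the root `D` values;
#' `"equal"` - equal weights; `"state0"` / `"state1"` - fixed root state.
#' Sampling of extant species is assumed complete (`Ei = 0` at the tips).
#' `condition_surv = TRUE` additionally conditions on the survival of the
#' two root lineages.
#'
#' @param tree ultrametric binary rooted `"phylo"`.
#' @param states named 0/1 vector covering every tip.
#' @param params a [bisse_params()].
#' @param root_mode root-state treatment, see above.
#' @param condition_surv condition on survival of the root's two daughter
#'   lineages (default `FALSE`).
#' @param rtol per-branch relative integration tolerance.
#' @return the log-likelihood (scalar).
#' @export
bisse_loglik <- function(tree, states, params,
                         root_mode = c("obs", "equal", "state0", "state1"),
                         condition_surv = FALSE, rtol = 1e-8) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "bisse_params"))
  root_mode <- match.arg(root_mode)
  if (!ape::is.binary(tree)) stop("tree contains polytomies")
  if (!is_ultrametric(tree, 1e-4)) stop("tree is not ultrametric")
  st <- match_traits(tree, states)
  phy <- stats::reorder(tree, "postorder")
  .bisse_loglik_cpp(phy$edge, phy$edge.length, length(phy$tip.label),
                    as.integer(st), as.numeric(params),
                    match(root_mode, c("obs", "equal", "state0", "state1")) - 1L,
                    condition_surv, rtol)
}

# pack/unpack between the free-parameter vector (log scale) and the full
# six-rate vector, under the constraint pattern in use.
.bisse_pack <- function(constrained, q_constrained) {
  if (constrained && q_constrained)
    list(n = 3L, names = c("lambda", "mu", "q"),
         expand = function(x) c(x[1L], x[1L], x[2L], x[2L], x[3L], x[3L]))
  else if (constrained)
    list(n = 4L, names = c("lambda", "mu", "q01", "q10"),
         expand = function(x) c(x[1L], x[1L], x[2L], x[2L], x[3L], x[4L]))
  else if (q_constrained)
    list(n = 5L, names = c("lambda0", "lambda1", "mu0", "mu1", "q"),
         expand = function(x) c(x[1L], x[2L], x[3L], x[4L], x[5L], x[5L]))
  else
    list(n = 6L, names = c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10"),
         expand = function(x) x)
}

# crude data-driven starting rates: Yule-style growth estimate for lambda,
# a fraction of it for mu and q.
.bisse_start <- function(tree) {
  n <- length(tree$tip.label)
  age <- max(node_ages(tree))
  lam <- max(log(n / 2) / age, 1e-3)
  c(lambda = lam, mu = lam / 5, q = lam / 10)
}

#' Maximum-likelihood BiSSE fit
#'
#' Multi-start bounded optimisation of [bisse_loglik()] on the log-rate
#' scale (bounds `[1e-8, 1e3]` per rate). The constrained model forces
#' `lambda0 = lambda1` and `mu0 = mu1` (the transition rates stay free
#' unless `q_constrained`), giving the nested pair used to test
#' state-dependent diversification. Ties between starts are broken by the
#' highest log-likelihood, then the smallest parameter norm.
#'
#' @param tree,states,root_mode,condition_surv,rtol as in [bisse_loglik()].
#' @param constrained force `lambda0 = lambda1`, `mu0 = mu1`.
#' @param q_constrained force `q01 = q10`.
#' @param n_starts number of optimisation starts (first from a Yule-style
#'   heuristic, the rest jittered).
#' @param seed optional RNG seed for the start jitter.
#' @return an object of class `"bisse_fit"`: list with `params`
#'   (full six-rate [bisse_params()]), `loglik`, `n_free`, `constrained`,
#'   `q_constrained`, `convergence` (0 = at least one start converged),
#'   `starts` (per-start log-likelihoods).
#' @export
bisse_ml <- function(tree, states, constrained = FALSE, q_constrained = FALSE,
                     n_starts = 5L, seed = NULL,
                     root_mode = "obs", condition_surv = FALSE, rtol = 1e-8) {
  pk <- .bisse_pack(constrained, q_constrained)
  st <- match_traits(tree, states)
  phy <- stats::reorder(tree, "postorder")
  rm_i <- match(match.arg(root_mode, c("obs", "equal", "state0", "state1")),
                c("obs", "equal", "state0", "state1")) - 1L
  nll <- function(logx) {
    p <- pk$expand(exp(logx))
    ll <- tryCatch(.bisse_loglik_cpp(phy$edge, phy$edge.length,
                                     length(phy$tip.label), as.integer(st),
                                     p, rm_i, condition_surv, rtol),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  base <- .bisse_start(tree)
  s0 <- switch(pk$n - 2L,
               c(base["lambda"], base["mu"], base["q"]),                 # 3
               c(base["lambda"], base["mu"], base["q"], base["q"]),      # 4
               c(base["lambda"], base["lambda"], base["mu"], base["mu"],
                 base["q"]),                                             # 5
               c(base["lambda"], base["lambda"], base["mu"], base["mu"],
                 base["q"], base["q"]))                                  # 6
  s0 <- unname(s0)
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(i) {
    if (i == 1L) log(s0) else log(s0) + stats::rnorm(pk$n, 0, 0.75)
  }))
  lb <- rep(log(1e-8), pk$n); ub <- rep(log(1e3), pk$n)
  fits <- lapply(starts, function(p0) {
    f <- tryCatch(stats::optim(pmin(pmax(p0, lb), ub), nll,
                               method = "L-BFGS-B", lower = lb, upper = ub,
                               control = list(maxit = 500)),
                  error = function(e) NULL)
    if (is.null(f))
      f <- stats::optim(pmin(pmax(p0, lb), ub), nll, method = "Nelder-Mead",
                        control = list(maxit = 5000))
    f
  })
  lls <- vapply(fits, function(f) -f$value, numeric(1L))
  norms <- vapply(fits, function(f) sum(exp(f$par)^2), numeric(1L))
  best <- order(-lls, norms)[1L]
  fit <- fits[[best]]
  p_full <- pk$expand(exp(fit$par))
  structure(list(params = bisse_params(p_full[1L], p_full[2L], p_full[3L],
                                       p_full[4L], p_full[5L], p_full[6L]),
                 loglik = -fit$value, n_free = pk$n,
                 constrained = constrained, q_constrained = q_constrained,
                 convergence = min(vapply(fits, `[[`, numeric(1L), "convergence")),
                 starts = lls),
            class = "bisse_fit")
}

#' @export
print.bisse_fit <- function(x, ...) {
  cat("BiSSE", if (x$constrained) "constrained" else "unconstrained",
      "ML fit: logL =", format(x$loglik, digits = 6),
      "(", x$n_free, "free parameters )\n")
  print(round(unclass(x$params), 5))
  invisible(x)
}

#' Likelihood-ratio test between nested BiSSE fits
#'
#' `X2 = 2 (logL_free - logL_constrained)` referred to a chi-squared
#' distribution with df equal to the difference in free parameter counts.
#'
#' @param fit_free,fit_constrained `"bisse_fit"` objects on the same data,
#'   the second nested in the first.
#' @return an `"htest"`.
#' @export
bisse_lrt <- function(fit_free, fit_constrained) {
  stopifnot(inherits(fit_free, "bisse_fit"), inherits(fit_constrained, "bisse_fit"))
  df <- fit_free$n_free - fit_constrained$n_free
  if (df < 1L) stop("models are not nested (no free-parameter difference)")
  stat <- max(0, 2 * (fit_free$loglik - fit_constrained$loglik))
  structure(list(statistic = c("X-squared" = stat), parameter = c(df = df),
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = "Likelihood-ratio test: state-dependent vs equal rates",
                 data.name = "BiSSE fits"), class = "htest")
}
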