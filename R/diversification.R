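#' Lineage-through-time curve
#'
#' Step curve of the number of reconstructed lineages as a function of age
#' on an ultrametric tree: one row per branching event, from the root
#' (2 lineages) to the most recent split (`n` lineages).
#'
#' @param tree ultrametric binary rooted `"phylo"`, >= 3 tips.
#' @param tol ultrametricity tolerance.
#' @return a `data.frame` of class `"ltt_curve"` with columns `age`
#'   (Ma, decreasing) and `lineages`.
#' @export
ltt <- function(tree, tol = 1e-6) {
  bt <- if (inherits(tree, "branching_times")) tree else branching_times(tree, tol)
  structure(data.frame(age = bt$times, lineages = 2:bt$n),
            class = c("ltt_curve", "data.frame"))
}

# Lineage count of an LTT curve at arbitrary ages (step function); NA
# outside [0, root age].
ltt_at <- function(curve, age) {
  root <- max(curve$age)
  n <- max(curve$lineages)
  vapply(age, function(a) {
    if (a > root || a < 0) return(NA_integer_)
    1L + sum(curve$age >= a)
  }, integer(1L))
}

#' Constant-rates test based on the gamma statistic
#'
#' The gamma statistic standardises the positions of a tree's internal
#' nodes against the constant-rate pure-birth expectation: with
#' \eqn{T_i = \sum_{k=2}^{i} k g_k} (cumulative lineage-time through the
#' interval with `i` lineages) and total \eqn{T = T_n},
#' \deqn{\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1} T_i - T/2}
#'   {T\sqrt{1/(12(n-2))}}.}
#' Under constant rates gamma is asymptotically standard normal; gamma > 0
#' means nodes concentrate near the tips (recent acceleration of apparent
#' diversification, or early high extinction), gamma < 0 near the root. The
#' reported p-value is two-tailed, \eqn{p = 2(1 - \Phi(|\gamma|))}.
#'
#' @param x a `"branching_times"` object or an ultrametric `"phylo"`.
#' @return an object of class `"gamma_test"`: list with `gamma`,
#'   `p.value`, `n`.
#' @export
gamma_test <- function(x) {
  bt <- if (inherits(x, "branching_times")) x else branching_times(x)
  n <- bt$n
  if (bt$total <= 0) stop("zero total lineage-time")
  Tn <- bt$total
  mean_Ti <- sum(bt$Ti[seq_len(n - 2L)]) / (n - 2L)   # T_2 .. T_{n-1}
  g <- (mean_Ti - Tn / 2) / (Tn * sqrt(1 / (12 * (n - 2L))))
  structure(list(gamma = g, p.value = 2 * stats::pnorm(-abs(g)), n = n),
            class = "gamma_test")
}

#' @export
print.gamma_test <- function(x, ...) {
  cat("Constant-rates gamma test: gamma =", format(x$gamma, digits = 4),
      ", two-tailed p =", format(x$p.value, digits = 4),
      "(n =", x$n, "tips)\n")
  invisible(x)
}

#' Akaike weights
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AIC_i - \min_j AIC_j} and \eqn{AIC = 2k - 2\log L}.
#'
#' @param logLs log-likelihoods of the candidate models.
#' @param n_params number of free parameters of each model.
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(logLs, n_params) {
  stopifnot(length(logLs) >= 2L, length(logLs) == length(n_params))
  aic <- 2 * n_params - 2 * logLs
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Survival models of branching times
#'
#' Treats the `n - 1` node ages of an ultrametric tree as uncensored
#' waiting-time observations measured backwards from the present and fits
#' three nested hazard models of diversification:
#'
#' * Model A - constant hazard `delta`; closed-form MLE
#'   \eqn{\hat\delta = N / \sum x_i}.
#' * Model B - Weibull hazard \eqn{h(x) = \delta\beta(\delta x)^{\beta-1}};
#'   `beta < 1` concentrates events near the present (recent acceleration
#'   of diversification), `beta > 1` near the root.
#' * Model C - piecewise-constant hazard `delta1` for `x < Tc` and `delta2`
#'   for `x >= Tc`, with the shift age `Tc` either fixed or profiled over
#'   the midpoints of the observed branching times.
#'
#' Models B and C are compared to A by likelihood-ratio tests (df = 1 for
#' A-vs-B; df = 1 for A-vs-C with `Tc` fixed, 2 when profiled - the usual
#' caveat that a profiled changepoint is not a regular parameter applies)
#' and to each other by Akaike weights.
#'
#' @param x a `"branching_times"` object, an ultrametric `"phylo"`, or a
#'   numeric vector of waiting times (> 0).
#' @param breakpoint shift age `Tc` in Ma, or `"profile"` (default) to
#'   profile it.
#' @return an object of class `"survival_models"`: list with elements `A`,
#'   `B`, `C` (each with estimates and `logLik`), `lrt_AB`, `lrt_AC`
#'   (`"htest"`), `akaike_weights` (over B and C), `n`.
#' @export
fit_survival <- function(x, breakpoint = "profile") {
  times <- if (inherits(x, "branching_times")) x$times
           else if (inherits(x, "phylo")) branching_times(x)$times
           else as.numeric(x)
  times <- sort(times, decreasing = TRUE)
  N <- length(times)
  if (N < 3L) stop("need >= 3 waiting-time observations (>= 4 tips)")
  if (any(times <= 0)) stop("waiting times must be > 0")

  ## Model A: exponential
  deltaA <- N / sum(times)
  logLA <- N * log(deltaA) - deltaA * sum(times)

  ## Model B: Weibull
  nllB <- function(par) {
    d <- exp(par[1L]); b <- exp(par[2L])
    -(N * (log(d) + log(b)) + (b - 1) * sum(log(d * times)) - sum((d * times)^b))
  }
  fitB <- stats::optim(c(log(deltaA), 0), nllB, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
  if (!is.finite(fitB$value)) stop("non-finite Weibull optimisation")
  deltaB <- exp(fitB$par[1L]); betaB <- exp(fitB$par[2L])
  logLB <- -fitB$value

  ## Model C: single shift
  fitC_at <- function(Tc) {
    n1 <- sum(times < Tc); n2 <- N - n1
    if (n1 == 0L || n2 == 0L) return(NULL)
    e1 <- sum(pmin(times, Tc)); e2 <- sum(pmax(times - Tc, 0))
    d1 <- n1 / e1; d2 <- n2 / e2
    list(delta1 = d1, delta2 = d2, Tc = Tc,
         logLik = n1 * log(d1) + n2 * log(d2) - d1 * e1 - d2 * e2)
  }
  profiled <- identical(breakpoint, "profile")
  if (profiled) {
    srt <- sort(unique(times))
    cand <- (head(srt, -1L) + tail(srt, -1L)) / 2
    fits <- Filter(Negate(is.null), lapply(cand, fitC_at))
    if (!length(fits)) stop("no admissible breakpoint")
    C <- fits[[which.max(vapply(fits, `[[`, numeric(1L), "logLik"))]]
  } else {
    C <- fitC_at(as.numeric(breakpoint))
    if (is.null(C)) stop("breakpoint leaves an empty regime")
  }

  lrt <- function(l1, l0, df, lab) {
    stat <- max(0, 2 * (l1 - l0))
    structure(list(statistic = c("X-squared" = stat), parameter = c(df = df),
                   p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                   method = paste("Likelihood-ratio test:", lab),
                   data.name = "branching times"), class = "htest")
  }
  dfC <- if (profiled) 2L else 1L
  w <- akaike_weights(c(B = logLB, C = C$logLik), c(2L, if (profiled) 3L else 2L))
  structure(list(
    A = list(delta = deltaA, logLik = logLA),
    B = list(delta = deltaB, beta = betaB, logLik = logLB,
             convergence = fitB$convergence),
    C = c(C, profiled = profiled),
    lrt_AB = lrt(logLB, logLA, 1L, "constant vs Weibull"),
    lrt_AC = lrt(C$logLik, logLA, dfC, "constant vs single shift"),
    akaike_weights = w, n = N + 1L), class = "survival_models")
}

#' @export
print.survival_models <- function(x, ...) {
  cat("Survival models of branching times (", x$n, " tips )\n", sep = "")
  cat(sprintf("  A constant : delta = %.4g                logL = %.3f\n",
              x$A$delta, x$A$logLik))
  cat(sprintf("  B Weibull  : delta = %.4g beta = %.3f    logL = %.3f\n",
              x$B$delta, x$B$beta, x$B$logLik))
  cat(sprintf("  C shift    : delta1 = %.4g delta2 = %.4g Tc = %.3g logL = %.3f\n",
              x$C$delta1, x$C$delta2, x$C$Tc, x$C$logLik))
  cat(sprintf("  LRT A-vs-B : X2 = %.3f p = %.4g | A-vs-C : X2 = %.3f p = %.4g\n",
              x$lrt_AB$statistic, x$lrt_AB$p.value,
              x$lrt_AC$statistic, x$lrt_AC$p.value))
  cat(sprintf("  Akaike weights (B, C): %.3f %.3f\n",
              x$akaike_weights[1L], x$akaike_weights[2L]))
  invisible(x)
}
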