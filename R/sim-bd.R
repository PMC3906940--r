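#' BiSSE parameter set
#'
#' The six rates of the binary-state speciation-extinction model, all in
#' events per lineage per Myr: state-specific speciation rates `lambda0`
#' (state 0, e.g. freshwater) and `lambda1` (state 1, e.g. anadromous),
#' extinction rates `mu0`, `mu1`, and transition rates `q01` (0 to 1) and
#' `q10` (1 to 0).
#'
#' @param lambda0,lambda1 speciation rates (>= 0).
#' @param mu0,mu1 extinction rates (>= 0).
#' @param q01,q10 transition rates (>= 0).
#' @return a named numeric vector of class `"bisse_params"`.
#' @export
bisse_params <- function(lambda0, lambda1, mu0, mu1, q01, q10) {
  p <- c(lambda0 = lambda0, lambda1 = lambda1, mu0 = mu0, mu1 = mu1,
         q01 = q01, q10 = q10)
  if (any(!is.finite(p)) || any(p < 0))
    stop("all six rates must be finite and >= 0")
  structure(p, class = "bisse_params")
}

# Gillespie simulation of the 2-state birth-death process, conditioned on
# reaching `n_tips` extant lineages. When the extant count first reaches
# n_tips the present is set one further Exp(total-rate) waiting time ahead
# (no event is executed there): for a pure-birth process this reproduces the
# constant-rates null exactly (internode intervals g_k ~ Exp(k lambda)).
# Trajectories that go fully extinct (or whose root lineage never splits)
# are rejected and re-drawn, up to `max_tries`.
sim_bd_engine <- function(lambda, mu, q01, q10, n_tips, root_state,
                          max_tries = 1000L) {
  stopifnot(n_tips >= 3L)
  lam <- c(lambda[1L], lambda[length(lambda)])   # per-state rates
  muv <- c(mu[1L], mu[length(mu)])
  qv  <- c(q01, q10)
  max_events <- 200L * n_tips + 2000L

  for (try in seq_len(max_tries)) {
    cap <- 4L * n_tips + 64L
    parent <- integer(cap); t_birth <- numeric(cap); t_end <- numeric(cap)
    state <- integer(cap); fate <- integer(cap)   # 0 alive, 1 split, 2 dead
    ch1 <- integer(cap); ch2 <- integer(cap)
    nlin <- 1L; parent[1L] <- 0L; t_birth[1L] <- 0; state[1L] <- root_state
    alive <- 1L
    t <- 0; ok <- TRUE
    for (ev in seq_len(max_events)) {
      st <- state[alive]
      rate_i <- lam[st + 1L] + muv[st + 1L] + qv[st + 1L]
      tot <- sum(rate_i)
      if (tot <= 0) { ok <- FALSE; break }
      if (length(alive) == n_tips) {
        t <- t + rexp(1L, tot)          # present falls before the next event
        break
      }
      t <- t + rexp(1L, tot)
      i <- alive[sample.int(length(alive), 1L, prob = rate_i)]
      s <- state[i]
      u <- runif(1L) * (lam[s + 1L] + muv[s + 1L] + qv[s + 1L])
      if (u < lam[s + 1L]) {            # speciation
        if (nlin + 2L > cap) {
          cap <- cap * 2L
          length(parent) <- cap; length(t_birth) <- cap; length(t_end) <- cap
          length(state) <- cap; length(fate) <- cap
          length(ch1) <- cap; length(ch2) <- cap
        }
        fate[i] <- 1L; t_end[i] <- t
        for (k in 1:2) {
          nlin <- nlin + 1L
          parent[nlin] <- i; t_birth[nlin] <- t; state[nlin] <- s
          fate[nlin] <- 0L
        }
        ch1[i] <- nlin - 1L; ch2[i] <- nlin
        alive <- c(alive[alive != i], nlin - 1L, nlin)
      } else if (u < lam[s + 1L] + muv[s + 1L]) {   # extinction
        fate[i] <- 2L; t_end[i] <- t
        alive <- alive[alive != i]
        if (length(alive) == 0L) { ok <- FALSE; break }
      } else {                          # state transition
        state[i] <- 1L - s
      }
      if (ev == max_events) ok <- FALSE
    }
    if (!ok || length(alive) != n_tips || fate[1L] != 1L) next

    t_end[alive] <- t
    lab <- paste0("t", seq_len(nlin))
    build <- function(id) {
      len <- t_end[id] - t_birth[id]
      if (fate[id] == 1L)
        paste0("(", build(ch1[id]), ",", build(ch2[id]), "):",
               format(len, digits = 12))
      else paste0(lab[id], ":", format(len, digits = 12))
    }
    nwk <- paste0("(", build(ch1[1L]), ",", build(ch2[1L]), ");")
    phy <- ape::read.tree(text = nwk)
    dead <- lab[seq_len(nlin)][fate[seq_len(nlin)] == 2L]
    if (length(dead)) phy <- ape::drop.tip(phy, dead)
    states <- stats::setNames(state[alive], lab[alive])[phy$tip.label]
    return(list(tree = phy, states = states))
  }
  stop("simulation retry cap exceeded (", max_tries,
       " tries): parameters may be near-degenerate")
}

#' Simulate a birth-death tree conditioned on its tip count
#'
#' Forward (Gillespie) constant-rate birth-death simulation, stopped when
#' the extant lineage count reaches `n_tips` (plus one further exponential
#' waiting time, so that the final internode interval follows its
#' constant-rates distribution); extinct lineages are pruned. With `mu = 0`
#' this is an exact sample from the Yule constant-rates model conditioned on
#' `n_tips`, the null of the gamma test.
#'
#' @param lambda speciation rate (> mu).
#' @param mu extinction rate (>= 0).
#' @param n_tips number of extant tips (>= 3).
#' @param seed optional RNG seed; a fixed seed gives a bit-identical tree.
#' @return an ultrametric binary `"phylo"` with exactly `n_tips` tips.
#' @examples
#' tr <- simulate_bd_tree(1, 0, 16, seed = 7)
#' @export
simulate_bd_tree <- function(lambda, mu = 0, n_tips, seed = NULL) {
  if (!is.finite(lambda) || !is.finite(mu) || mu < 0 || lambda <= mu)
    stop("need lambda > mu >= 0 (non-viable birth-death parameters)")
  with_seed(seed, sim_bd_engine(lambda, mu, 0, 0, n_tips, 0L)$tree)
}

#' Simulate a tree and binary tip states under the BiSSE process
#'
#' Joint forward simulation of the binary-state speciation-extinction
#' process conditioned on `n_tips` extant survivors (rejection of fully
#' extinct trajectories; see [simulate_bd_tree()] for the stopping rule).
#' Extinct lineages are pruned; tip states are the lineage states at the
#' present.
#'
#' @param params a [bisse_params()] object.
#' @param n_tips number of extant tips (>= 3).
#' @param root_state state at the root, 0 or 1.
#' @param seed optional RNG seed.
#' @param max_tries rejection cap before giving up.
#' @return a list with elements `tree` (`"phylo"`) and `states`
#'   (named 0/1 vector in `tree$tip.label` order).
#' @export
simulate_bisse <- function(params, n_tips, root_state = 0L, seed = NULL,
                           max_tries = 1000L) {
  stopifnot(inherits(params, "bisse_params"), root_state %in% c(0L, 1L))
  with_seed(seed,
            sim_bd_engine(params[c("lambda0", "lambda1")],
                          params[c("mu0", "mu1")],
                          params[["q01"]], params[["q10"]],
                          n_tips, as.integer(root_state), max_tries))
}
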