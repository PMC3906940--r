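# Independent oracle implementations used only by the tests. These are
# deliberately written from the model definitions, sharing no code with the
# package internals they check.

# Closed-form constant-rate birth-death tree log-likelihood on an
# ultrametric tree. With E(t) = mu (e^{rt} - 1) / (lambda e^{rt} - mu) the
# extinction probability of a lineage alive at age t (r = lambda - mu), the
# density multiplier along a branch spanning ages [t1, t2] is
#   e^{-r (t2 - t1)} ((1 - E(t2)) / (1 - E(t1)))^2
# (the solution of dD/dt = -(lambda + mu) D + 2 lambda E D), with one factor
# lambda per internal node including the root. Reduces to e^{-lambda len}
# per branch for mu = 0 (Yule). No survival conditioning; matches the
# package's node-combination convention D <- D_l * D_r * lambda.
oracle_bd_loglik <- function(tree, lambda, mu) {
  r <- lambda - mu
  log1mE <- function(t) {
    if (mu == 0) return(rep(0, length(t)))
    log(r) + r * t - log(lambda * exp(r * t) - mu)
  }
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  t1 <- ages[tree$edge[, 2L]]
  t2 <- ages[tree$edge[, 1L]]
  sum(-r * (t2 - t1) + 2 * (log1mE(t2) - log1mE(t1))) +
    tree$Nnode * log(lambda)
}

# Felsenstein pruning for the 2-state Markov chain (Mk2) with
# P_ij(t) = pi_j + (delta_ij - pi_j) e^{-s t}, s = q01 + q10,
# pi = (q10, q01)/s; equal root weights.
oracle_mk2_loglik <- function(tree, states, q01, q10) {
  s <- q01 + q10
  pi <- if (s > 0) c(q10, q01) / s else c(0.5, 0.5)
  Pm <- function(t) {
    if (s == 0) return(diag(2))
    e <- exp(-s * t)
    rbind(c(pi[1] + (1 - pi[1]) * e, pi[2] - pi[2] * e),
          c(pi[1] - pi[1] * e, pi[2] + (1 - pi[2]) * e))
  }
  phy <- stats::reorder(tree, "postorder")
  ntip <- length(phy$tip.label)
  L <- matrix(NA_real_, ntip + phy$Nnode, 2)
  st <- states[phy$tip.label]
  for (i in seq_len(ntip)) L[i, ] <- c(st[i] == 0, st[i] == 1)
  for (r in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[r, 2L]; par <- phy$edge[r, 1L]
    v <- Pm(phy$edge.length[r]) %*% L[ch, ]
    if (is.na(L[par, 1L])) L[par, ] <- v else L[par, ] <- L[par, ] * v
  }
  log(sum(0.5 * L[ntip + 1L, ]))
}

# Brute-force BiSSE log-likelihood: fixed-step classical RK4 on the E/D
# system, written directly from the model equations. Slow; for trees of a
# handful of tips only.
oracle_bisse_loglik <- function(tree, states, pars,
                                root_mode = "obs", steps_per_branch = 4000L) {
  l0 <- pars[[1]]; l1 <- pars[[2]]; m0 <- pars[[3]]; m1 <- pars[[4]]
  q01 <- pars[[5]]; q10 <- pars[[6]]
  deriv <- function(y) {
    E0 <- y[1]; E1 <- y[2]; D0 <- y[3]; D1 <- y[4]
    c(m0 - (l0 + m0 + q01) * E0 + l0 * E0^2 + q01 * E1,
      m1 - (l1 + m1 + q10) * E1 + l1 * E1^2 + q10 * E0,
      -(l0 + m0 + q01) * D0 + q01 * D1 + 2 * l0 * E0 * D0,
      -(l1 + m1 + q10) * D1 + q10 * D0 + 2 * l1 * E1 * D1)
  }
  rk4 <- function(y, len) {
    h <- len / steps_per_branch
    for (i in seq_len(steps_per_branch)) {
      k1 <- deriv(y); k2 <- deriv(y + h / 2 * k1)
      k3 <- deriv(y + h / 2 * k2); k4 <- deriv(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }
  phy <- stats::reorder(tree, "postorder")
  ntip <- length(phy$tip.label)
  st <- states[phy$tip.label]
  Y <- matrix(NA_real_, ntip + phy$Nnode, 4)
  logsc <- 0
  for (i in seq_len(ntip)) Y[i, ] <- c(0, 0, st[i] == 0, st[i] == 1)
  for (r in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[r, 2L]; par <- phy$edge[r, 1L]
    y0 <- Y[ch, ]
    if (ch > ntip) { y0[3] <- y0[3] * l0; y0[4] <- y0[4] * l1 }
    y1 <- rk4(y0, phy$edge.length[r])
    s <- y1[3] + y1[4]
    y1[3:4] <- y1[3:4] / s; logsc <- logsc + log(s)
    if (is.na(Y[par, 1L])) Y[par, ] <- y1
    else Y[par, 3:4] <- Y[par, 3:4] * y1[3:4]
  }
  Dr <- Y[ntip + 1L, 3:4] * c(l0, l1)
  w <- switch(root_mode,
              obs = Dr / sum(Dr),
              equal = c(0.5, 0.5),
              state0 = c(1, 0),
              state1 = c(0, 1))
  log(sum(w * Dr)) + logsc
}

# Small fixture: a 3-subfamily, 6-species tree with 2 outgroups, the shape
# assumed by the WGD gene-tree scenarios (crown age 50 Ma, outgroups at
# 120 / 160 Ma).
fixture_species_tree <- function() {
  read_newick(paste0(
    "(((((Ssal:20,Stru:20):25,(Tthy:25,Tarc:25):20):5,",
    "(Clav:30,Calb:30):20):70,Eluc:120):40,Dret:160);"))
}

fixture_subfamilies <- c(
  Ssal = "Salmoninae", Stru = "Salmoninae",
  Tthy = "Thymallinae", Tarc = "Thymallinae",
  Clav = "Coregoninae", Calb = "Coregoninae",
  Eluc = "outgroup", Dret = "outgroup")
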