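#' HKY substitution parameters with codon-position rate multipliers
#'
#' @param kappa transition/transversion rate ratio (>= 0).
#' @param base_freqs equilibrium base frequencies in order A, C, G, T
#'   (must sum to 1 within 1e-9).
#' @param pos_rates per-codon-position rate multipliers (3 positive values);
#'   position 3 is typically fastest in coding sequence.
#' @return an object of class `"hky_params"`.
#' @export
hky_params <- function(kappa = 2, base_freqs = rep(0.25, 4),
                       pos_rates = c(1, 1, 1)) {
  stopifnot(length(base_freqs) == 4L, length(pos_rates) == 3L)
  if (kappa < 0 || any(base_freqs <= 0) || any(pos_rates <= 0))
    stop("kappa >= 0, frequencies and position rates > 0 required")
  if (abs(sum(base_freqs) - 1) > 1e-9) stop("base frequencies must sum to 1")
  structure(list(kappa = kappa,
                 base_freqs = stats::setNames(base_freqs, c("A", "C", "G", "T")),
                 pos_rates = pos_rates),
            class = "hky_params")
}

# HKY rate matrix, scaled to one expected substitution per unit branch
# length at equilibrium.
.hky_Q <- function(hky) {
  pi <- hky$base_freqs
  k <- hky$kappa
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ti <- paste0(names(pi)[i], names(pi)[j])
    trans <- ti %in% c("AG", "GA", "CT", "TC")
    Q[i, j] <- pi[j] * if (trans) k else 1
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(pi * -diag(Q))
}

# Transition-probability matrix P(t) = expm(Q t) via eigendecomposition.
.hky_P <- function(Q, t) {
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate an in-frame codon alignment along a tree
#'
#' Evolves `3 * n_codons` sites down the tree under the HKY model, with the
#' branch-specific expected number of substitutions per site equal to
#' `branch length * rate * pos_rate[p]` for a site at codon position `p`.
#' The `rate` argument is the explicit clock rate converting the tree's time
#' units (Myr) into substitutions per site, keeping time and divergence
#' scales separate.
#'
#' @param tree rooted `"phylo"` with branch lengths.
#' @param hky an [hky_params()].
#' @param n_codons number of codons (alignment length `3 * n_codons`).
#' @param rate substitutions per site per unit branch length.
#' @param seed optional RNG seed.
#' @return a `"codon_alignment"` (offset 0).
#' @export
simulate_alignment <- function(tree, hky, n_codons, rate = 0.01, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(hky, "hky_params"))
  if (n_codons < 1L) stop("zero-length alignment requested")
  nsites <- 3L * n_codons
  pos <- rep(1:3, n_codons)
  Q <- .hky_Q(hky)
  ntip <- length(tree$tip.label)
  phy <- stats::reorder(tree, "cladewise")     # parents before children
  root <- ntip + 1L

  with_seed(seed, {
    seqs <- matrix(NA_integer_, ntip + phy$Nnode, nsites)
    seqs[root, ] <- sample.int(4L, nsites, replace = TRUE,
                               prob = hky$base_freqs)
    for (r in seq_len(nrow(phy$edge))) {
      par <- phy$edge[r, 1L]; ch <- phy$edge[r, 2L]
      len <- phy$edge.length[r] * rate
      child <- integer(nsites)
      for (p in 1:3) {
        idx <- which(pos == p)
        if (len * hky$pos_rates[p] == 0) { child[idx] <- seqs[par, idx]; next }
        P <- .hky_P(Q, len * hky$pos_rates[p])
        for (s in 1:4) {
          k <- idx[seqs[par, idx] == s]
          if (length(k))
            child[k] <- sample.int(4L, length(k), replace = TRUE, prob = P[s, ])
        }
      }
      seqs[ch, ] <- child
    }
    bases <- c("A", "C", "G", "T")
    out <- apply(seqs[seq_len(ntip), , drop = FALSE], 1L, function(z)
      paste(bases[z], collapse = ""))
    codon_alignment(stats::setNames(out, phy$tip.label), offset = 0L)
  })
}

#' Synthetic sea-level series
#'
#' Generates an irregularly sampled sea-level history with a known
#' piecewise-linear trend plus Gaussian noise, standing in for published
#' oxygen-isotope-derived sea-level curves (flagged synthetic: the default
#' trend only mimics the broad fall from the Late Cretaceous highstand to
#' the Plio-Pleistocene lowstands, not any published series). With
#' `noise_sd = 0` binning recovers the trend exactly.
#'
#' @param n_points number of samples (>= 2); 1100 mimics the density of the
#'   series the binning procedure was designed for.
#' @param trend data.frame with columns `age_ma`, `value`: knots of the
#'   piecewise-linear trend (default spans 0-130 Ma).
#' @param noise_sd Gaussian noise standard deviation (metres).
#' @param seed optional RNG seed.
#' @return a `"sealevel_series"`.
#' @export
make_sealevel_fixture <- function(n_points = 1100L,
                                  trend = data.frame(
                                    age_ma = c(0, 35, 90, 130),
                                    value = c(0, 60, 150, 110)),
                                  noise_sd = 10, seed = NULL) {
  if (n_points < 2L) stop("need >= 2 points")
  stopifnot(all(c("age_ma", "value") %in% names(trend)))
  with_seed(seed, {
    ages <- sort(runif(n_points, min(trend$age_ma), max(trend$age_ma)))
    base <- stats::approx(trend$age_ma, trend$value, xout = ages)$y
    sealevel_series(ages, base + stats::rnorm(n_points, 0, noise_sd))
  })
}
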