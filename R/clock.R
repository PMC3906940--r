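#' Tajima's relative-rate test
#'
#' Tests equality of substitution rates on the two lineages leading to taxa
#' `a` and `b`, using `outgroup` to polarise changes. Over the sites where
#' all three sequences are ungapped and unambiguous, let `m1` be the number
#' of sites where `a` differs from both `b` and the outgroup while `b`
#' equals the outgroup (changes unique to `a`), and `m2` the symmetric count
#' for `b`. Under a molecular clock `m1` and `m2` have equal expectation and
#' `(m1 - m2)^2 / (m1 + m2)` is asymptotically chi-squared with 1 degree of
#' freedom. With `m1 + m2 = 0` the test is vacuous and `p = 1` by
#' convention.
#'
#' @param aln a `"codon_alignment"` containing the three taxa.
#' @param a,b taxa whose rates are compared.
#' @param outgroup outgroup taxon.
#' @return an object of class `"htest"` with extra fields `m1`, `m2`.
#' @export
tajima_rrt <- function(aln, a, b, outgroup) {
  stopifnot(inherits(aln, "codon_alignment"))
  miss <- setdiff(c(a, b, outgroup), aln_taxa(aln))
  if (length(miss)) stop("taxa not in alignment: ", paste(miss, collapse = ", "))
  M <- as.matrix(aln)[c(a, b, outgroup), , drop = FALSE]
  ok <- colSums(M == "-" | M == "N") == 0L
  A <- M[1L, ok]; B <- M[2L, ok]; O <- M[3L, ok]
  m1 <- sum(A != B & A != O & B == O)
  m2 <- sum(B != A & B != O & A == O)
  if (m1 + m2 == 0) { stat <- 0; p <- 1 }
  else { stat <- (m1 - m2)^2 / (m1 + m2); p <- stats::pchisq(stat, 1L, lower.tail = FALSE) }
  structure(list(statistic = c("X-squared" = stat), parameter = c(df = 1L),
                 p.value = p, m1 = m1, m2 = m2,
                 method = "Tajima relative-rate test",
                 data.name = paste(a, "vs", b, "| outgroup", outgroup)),
            class = "htest")
}

# Kimura 2-parameter distance from transition/transversion proportions;
# NA when the log argument is non-positive (saturation).
k2p_distance <- function(P, Q) {
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Pairwise saturation scan
#'
#' For every unordered pair of sequences, counts raw differences,
#' transitions and transversions over the shared ungapped, unambiguous
#' sites, and computes the Kimura 2-parameter (K2P) distance
#' \eqn{d = -\tfrac12 \ln\big((1-2P-Q)\sqrt{1-2Q}\big)} with `P`, `Q` the
#' transition and transversion proportions. Mutational saturation shows up
#' as raw differences growing sublinearly with distance; the attribute
#' `"slope"` holds the least-squares slope of raw differences against K2P
#' distance over the pairs where the distance is defined. Pairs beyond the
#' K2P domain (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) are flagged
#' (`valid = FALSE`) and excluded from the slope.
#'
#' @param aln a `"codon_alignment"` with >= 2 sequences.
#' @return a `data.frame` of class `"saturation_scan"` with columns
#'   `taxon1`, `taxon2`, `sites`, `differences`, `transitions`,
#'   `transversions`, `p_dist`, `k2p`, `ts_tv`, `valid`, and attribute
#'   `"slope"`.
#' @export
saturation_scan <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  taxa <- aln_taxa(aln)
  if (length(taxa) < 2L) stop("need >= 2 sequences")
  M <- as.matrix(aln)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  cmb <- utils::combn(taxa, 2L)
  rows <- lapply(seq_len(ncol(cmb)), function(j) {
    x <- M[cmb[1L, j], ]; y <- M[cmb[2L, j], ]
    ok <- !(x %in% c("-", "N")) & !(y %in% c("-", "N"))
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    diffs <- x != y
    ts <- sum(diffs & purine[x] == purine[y])
    tv <- sum(diffs) - ts
    P <- if (n) ts / n else NA_real_
    Q <- if (n) tv / n else NA_real_
    d <- if (n) k2p_distance(P, Q) else NA_real_
    data.frame(taxon1 = cmb[1L, j], taxon2 = cmb[2L, j], sites = n,
               differences = sum(diffs), transitions = ts, transversions = tv,
               p_dist = if (n) sum(diffs) / n else NA_real_, k2p = d,
               ts_tv = if (tv > 0) ts / tv else Inf, valid = !is.na(d))
  })
  out <- do.call(rbind, rows)
  ok <- out$valid
  slope <- if (sum(ok) >= 2L && stats::var(out$k2p[ok]) > 0) {
    stats::cov(out$k2p[ok], out$differences[ok]) / stats::var(out$k2p[ok])
  } else NA_real_
  attr(out, "slope") <- slope
  class(out) <- c("saturation_scan", "data.frame")
  out
}
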