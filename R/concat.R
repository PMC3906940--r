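#' Enumerate all concatenations of WGD paralogue alignment pairs
#'
#' A paralogue pair contributes two homoeologous alignment blocks of equal
#' length over a shared taxon set. A concatenation assigns, for every pair,
#' one member to paralogue super-row 1 and the other to super-row 2; with
#' `k` pairs there are `2^k` distinct assignments (`2^(k-1)` up to the
#' global swap of the two super-rows, obtained by fixing the first bit
#' to 0). The set is enumerated lazily: alignments are only materialised by
#' [realize_concatenation()] / [sample_concatenations()].
#'
#' @param pairs list of `k` pairs, each a list of two `"codon_alignment"`
#'   objects (members of the pair) sharing taxon set and length.
#' @param outgroups taxon labels to carry as single-copy outgroup rows; they
#'   must have identical sequences in both members of each pair.
#' @return an object of class `"concat_set"` with elements `k`, `n_total`,
#'   `n_canonical`, `block_lengths`.
#' @export
enumerate_concatenations <- function(pairs, outgroups = character(0)) {
  k <- length(pairs)
  if (k < 1L) stop("need >= 1 paralogue pair")
  if (k > 30L) stop("k > 30 not supported (assignment index exceeds integer range)")
  for (i in seq_len(k)) {
    p <- pairs[[i]]
    if (length(p) != 2L || !all(vapply(p, inherits, logical(1L), "codon_alignment")))
      stop("each pair must hold two codon_alignment objects (pair ", i, ")")
    if (!setequal(aln_taxa(p[[1L]]), aln_taxa(p[[2L]])))
      stop("mismatched taxa within pair ", i)
    if (aln_length(p[[1L]]) != aln_length(p[[2L]]))
      stop("members of pair ", i, " differ in length")
    if (!all(outgroups %in% aln_taxa(p[[1L]])))
      stop("outgroup missing from pair ", i)
  }
  structure(list(pairs = pairs, outgroups = outgroups, k = k,
                 n_total = 2^k, n_canonical = 2^(k - 1L),
                 block_lengths = vapply(pairs, function(p)
                   aln_length(p[[1L]]), numeric(1L))),
            class = "concat_set")
}

#' @export
print.concat_set <- function(x, ...) {
  cat("Concatenation set: k =", x$k, "pairs,",
      format(x$n_total, big.mark = ","), "assignments (",
      format(x$n_canonical, big.mark = ","), "canonical ),",
      sum(x$block_lengths), "bp per paralogue\n")
  invisible(x)
}

#' Assignment vector of the i-th concatenation
#'
#' @param set a `"concat_set"`.
#' @param i 0-based assignment index in `0:(n_total - 1)`.
#' @return length-`k` 0/1 vector (little-endian bits of `i`): bit `j` says
#'   which member of pair `j` goes to super-row 1.
#' @export
concat_assignment <- function(set, i) {
  stopifnot(inherits(set, "concat_set"), i >= 0, i < set$n_total)
  as.integer(bitwAnd(bitwShiftR(as.integer(i), 0:(set$k - 1L)), 1L))
}

#' Materialise one concatenation as an alignment
#'
#' Rows are paralogue-clade pseudo-taxa `"species|C1"` / `"species|C2"` for
#' ingroup species and a single row per outgroup species; columns are the
#' `k` pair blocks (total length = sum of block lengths). A species missing
#' from some pair is gap-filled with a message, so matrix dimensions are
#' reproducible.
#'
#' @param set a `"concat_set"`.
#' @param assignment length-`k` 0/1 vector (see [concat_assignment()]).
#' @return a `"codon_alignment"` with attribute `"assignment"`.
#' @export
realize_concatenation <- function(set, assignment) {
  stopifnot(inherits(set, "concat_set"), length(assignment) == set$k,
            all(assignment %in% c(0L, 1L)))
  taxa <- sort(unique(unlist(lapply(set$pairs, function(p) aln_taxa(p[[1L]])))))
  ing <- setdiff(taxa, set$outgroups)
  get_seq <- function(aln, sp, len) {
    s <- aln$seqs[sp]
    if (is.na(s)) {
      message("gap-filling missing sequence for ", sp)
      s <- strrep("-", len)
    }
    s
  }
  block <- function(sp, member_idx) {
    paste(vapply(seq_len(set$k), function(j)
      get_seq(set$pairs[[j]][[member_idx[j]]], sp, set$block_lengths[j]),
      character(1L)), collapse = "")
  }
  m1 <- assignment + 1L            # member index going to super-row 1
  m2 <- 2L - assignment
  seqs <- c(
    stats::setNames(vapply(ing, block, character(1L), member_idx = m1),
                    paste0(ing, "|C1")),
    stats::setNames(vapply(ing, block, character(1L), member_idx = m2),
                    paste0(ing, "|C2")),
    stats::setNames(vapply(set$outgroups, block, character(1L),
                           member_idx = rep(1L, set$k)), set$outgroups))
  out <- codon_alignment(seqs, offset = 0L)
  attr(out, "assignment") <- as.integer(assignment)
  out
}

#' Sample distinct concatenations uniformly without replacement
#'
#' Reproduces the published screening design in which a random subset of all
#' possible paralogue concatenations (e.g. 50 of `2^18`) is analysed.
#'
#' @param set a `"concat_set"`.
#' @param n number of distinct assignments to draw (`n <= n_total`).
#' @param seed optional RNG seed for reproducible draws.
#' @param canonical if `TRUE`, sample from the `2^(k-1)` swap-deduplicated
#'   assignments (first bit fixed to 0).
#' @return list of `"codon_alignment"` objects, each carrying its
#'   `"assignment"` attribute.
#' @export
sample_concatenations <- function(set, n, seed = NULL, canonical = FALSE) {
  stopifnot(inherits(set, "concat_set"))
  total <- if (canonical) set$n_canonical else set$n_total
  if (n > total) stop("n exceeds the number of assignments (", total, ")")
  idx <- with_seed(seed, sample.int(total, n)) - 1
  # canonical assignments are those with first bit 0, i.e. the even indices
  # under the little-endian bit decoding of concat_assignment()
  if (canonical) idx <- idx * 2
  lapply(idx, function(i) realize_concatenation(set, concat_assignment(set, i)))
}

#' Orthologue supermatrix from WGD paralogue pairs
#'
#' Concatenates the `2k` gene blocks of `k` paralogue pairs into a single
#' species-level supermatrix: one row per species, columns ordered as all
#' paralogue-1 blocks followed by all paralogue-2 blocks (total length
#' `2 * sum(block lengths)`). Outgroup species, which carry a single copy,
#' have their sequence duplicated across the two paralogue block sets so
#' that they serve as outgroups to both paralogues. Missing sequences are
#' gap-filled with a message.
#'
#' @param pairs,outgroups as in [enumerate_concatenations()].
#' @return a `"codon_alignment"` (offset 0; in frame when every block length
#'   is a multiple of 3).
#' @export
concat_orthologs <- function(pairs, outgroups = character(0)) {
  set <- enumerate_concatenations(pairs, outgroups)
  taxa <- sort(unique(unlist(lapply(pairs, function(p) aln_taxa(p[[1L]])))))
  row_of <- function(sp) {
    paste(c(vapply(seq_len(set$k), function(j) {
      s <- pairs[[j]][[1L]]$seqs[sp]
      if (is.na(s)) { message("gap-filling missing sequence for ", sp)
                      s <- strrep("-", set$block_lengths[j]) }
      s
    }, character(1L)),
    vapply(seq_len(set$k), function(j) {
      s <- pairs[[j]][[2L]]$seqs[sp]
      if (is.na(s)) { message("gap-filling missing sequence for ", sp)
                      s <- strrep("-", set$block_lengths[j]) }
      s
    }, character(1L))), collapse = "")
  }
  codon_alignment(stats::setNames(vapply(taxa, row_of, character(1L)), taxa),
                  offset = 0L)
}
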