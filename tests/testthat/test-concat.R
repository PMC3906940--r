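# small synthetic paralogue-pair fixtures
make_pairs <- function(k, taxa = c("sp1", "sp2", "sp3"), outgroups = "out",
                       len = 6L, seed = 1) {
  set.seed(seed)
  all_taxa <- c(taxa, outgroups)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  lapply(seq_len(k), function(j) {
    og <- stats::setNames(vapply(outgroups, function(o) rand(len),
                                 character(1L)), outgroups)
    mk <- function() codon_alignment(c(
      stats::setNames(vapply(taxa, function(t) rand(len), character(1L)), taxa),
      og))
    list(mk(), mk())
  })
}

test_that("assignment counting follows 2^k / 2^(k-1)", {
  s1 <- enumerate_concatenations(make_pairs(1), outgroups = "out")
  expect_equal(s1$n_total, 2)
  expect_equal(s1$n_canonical, 1)

  s18 <- enumerate_concatenations(make_pairs(18), outgroups = "out")
  expect_equal(s18$n_total, 262144)
  expect_equal(s18$n_canonical, 131072)

  expect_equal(concat_assignment(s18, 0), rep(0L, 18))
  expect_equal(concat_assignment(s18, 5)[1:4], c(1L, 0L, 1L, 0L))
})

test_that("pair validation catches mismatches", {
  p <- make_pairs(2)
  p[[1L]][[2L]] <- codon_alignment(c(spX = "ACGTGA", out = "ACGTGA"))
  expect_error(enumerate_concatenations(p, "out"), "mismatched taxa")
  q <- make_pairs(2)
  q[[2L]][[2L]] <- codon_alignment(stats::setNames(
    rep("ACGTGACTG", 4), aln_taxa(q[[2L]][[1L]])))
  expect_error(enumerate_concatenations(q, "out"), "differ in length")
})

test_that("a k=2 exhaustive sample covers all four assignments", {
  s <- enumerate_concatenations(make_pairs(2), outgroups = "out")
  alns <- sample_concatenations(s, 4, seed = 1)
  asg <- vapply(alns, function(a) paste(attr(a, "assignment"), collapse = ""),
                character(1L))
  expect_setequal(asg, c("00", "10", "01", "11"))

  # realized rows: species|C1, species|C2 pseudo-taxa + outgroup row
  expect_setequal(aln_taxa(alns[[1L]]),
                  c(paste0(rep(c("sp1", "sp2", "sp3"), 2), "|C",
                           rep(1:2, each = 3)), "out"))
  expect_equal(aln_length(alns[[1L]]), 12L)
})

test_that("sampling is reproducible, distinct, and uniform", {
  s <- enumerate_concatenations(make_pairs(18), outgroups = "out")
  a <- sample_concatenations(s, 50, seed = 99)
  b <- sample_concatenations(s, 50, seed = 99)
  key <- function(z) vapply(z, function(x)
    paste(attr(x, "assignment"), collapse = ""), character(1L))
  expect_identical(key(a), key(b))
  expect_equal(anyDuplicated(key(a)), 0L)

  # uniformity over assignments at k=3, one draw per seed (chi-squared
  # goodness of fit over 10,000 draws)
  s3 <- enumerate_concatenations(make_pairs(3), outgroups = "out")
  draws <- vapply(1:10000, function(i)
    paste(attr(sample_concatenations(s3, 1L, seed = i)[[1L]], "assignment"),
          collapse = ""), character(1L))
  tab <- table(draws)
  expect_equal(length(tab), 8L)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("canonical sampling fixes the first bit", {
  s <- enumerate_concatenations(make_pairs(5), outgroups = "out")
  alns <- sample_concatenations(s, 16, seed = 3, canonical = TRUE)
  firsts <- vapply(alns, function(a) attr(a, "assignment")[1L], integer(1L))
  expect_true(all(firsts == 0L))
})

test_that("missing sequences are gap-filled with a message", {
  p <- make_pairs(2)
  p[[2L]] <- lapply(p[[2L]], function(a)
    codon_alignment(a$seqs[c("sp1", "sp2", "out")]))
  s <- enumerate_concatenations(p, "out")
  expect_message(aln <- realize_concatenation(s, c(0L, 1L)), "gap-filling")
  expect_equal(aln_length(aln), 12L)
  expect_match(aln$seqs[["sp3|C1"]], "^[ACGT]{6}-{6}$")
})

test_that("ortholog supermatrix has the published dimension structure", {
  # 18 blocks summing to 10,833 bp per paralogue -> 21,666 -> 14,444
  lens <- c(rep(600L, 17L), 633L)
  expect_equal(sum(lens), 10833L)
  taxa <- c("sp1", "sp2", "out")
  pairs <- lapply(lens, function(L) {
    row <- function() strrep("ACG", L / 3L)
    mk <- function() codon_alignment(stats::setNames(
      vapply(taxa, function(t) row(), character(1L)), taxa))
    list(mk(), mk())
  })
  sm <- concat_orthologs(pairs, outgroups = "out")
  expect_equal(aln_length(sm), 21666L)
  expect_setequal(aln_taxa(sm), taxa)              # one row per species
  expect_equal(aln_length(codon_partition(sm, c(1, 2))), 14444L)
})
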