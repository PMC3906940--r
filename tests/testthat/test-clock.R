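test_that("tajima_rrt reproduces the closed-form examples", {
  # build sequences with exactly m1 = 6 changes unique to a, m2 = 2 to b
  n <- 40L
  O <- rep("A", n)
  A <- O; B <- O
  A[1:6] <- "G"                 # a differs, b = outgroup
  B[7:8] <- "C"                 # b differs, a = outgroup
  aln <- codon_alignment(c(a = paste(A, collapse = ""),
                           b = paste(B, collapse = ""),
                           o = paste(O, collapse = "")))
  tt <- tajima_rrt(aln, "a", "b", "o")
  expect_equal(tt$m1, 6L)
  expect_equal(tt$m2, 2L)
  expect_equal(unname(tt$statistic), 2.0)
  expect_equal(tt$p.value, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(tt$p.value, 4), 0.1573)

  # symmetry: m1 = m2 -> p = 1
  B2 <- O; B2[1:6] <- "T"
  aln2 <- codon_alignment(c(a = paste(A, collapse = ""),
                            b = paste(B2, collapse = ""),
                            o = paste(O, collapse = "")))
  t2 <- tajima_rrt(aln2, "a", "b", "o")
  expect_equal(t2$m1, t2$m2)
  expect_equal(unname(t2$statistic), 0)
  expect_equal(t2$p.value, 1)

  # identical sequences -> vacuous test
  aln3 <- codon_alignment(c(a = "ACGTGA", b = "ACGTGA", o = "ACGTGA"))
  expect_equal(tajima_rrt(aln3, "a", "b", "o")$p.value, 1)

  expect_error(tajima_rrt(aln3, "a", "b", "zz"), "not in alignment")
})

test_that("tajima_rrt excludes sites with gaps or N in any taxon", {
  aln <- codon_alignment(c(a = "GGGAAA", b = "AAAAAA", o = "AA-AAN"))
  tt <- tajima_rrt(aln, "a", "b", "o")
  expect_equal(tt$m1, 2L)       # sites 3 and 6 are masked
})

test_that("K2P distance matches the closed form and its oracle", {
  expect_equal(salmodiv:::k2p_distance(0.1, 0), -0.5 * log(0.8),
               tolerance = 1e-12)
  expect_equal(round(salmodiv:::k2p_distance(0.1, 0), 4), 0.1116)
  expect_true(is.na(salmodiv:::k2p_distance(0.4, 0.35)))   # saturated

  # cross-check against ape's K80 distance on a simulated alignment
  tr <- read_newick("((A:30,B:30):30,C:60);")
  aln <- simulate_alignment(tr, hky_params(kappa = 3), 400, rate = 0.002,
                            seed = 4)
  sc <- saturation_scan(aln)
  M <- as.matrix(aln)
  bin <- ape::as.DNAbin(tolower(M))
  d_ape <- as.matrix(ape::dist.dna(bin, model = "K80"))
  for (i in seq_len(nrow(sc)))
    expect_equal(sc$k2p[i], d_ape[sc$taxon1[i], sc$taxon2[i]],
                 tolerance = 1e-9)
})

test_that("saturation_scan flags saturated pairs and reports a slope", {
  aln <- codon_alignment(c(
    s1 = "ACGTACGTACGTACGTACGT",
    s2 = "ACGTACGTACGTACGTACGA",   # nearly identical
    s3 = "ACGAACGAACTTACTTACTA",   # diverged
    s4 = "GTACGTACGTACGTACGTAC")) # ~fully different from s1 (saturated)
  sc <- saturation_scan(aln)
  r11 <- sc[sc$taxon1 == "s1" & sc$taxon2 == "s2", ]
  expect_equal(r11$differences, 1L)
  expect_false(sc$valid[sc$taxon1 == "s1" & sc$taxon2 == "s4"])
  expect_true(is.na(sc$k2p[sc$taxon1 == "s1" & sc$taxon2 == "s4"]))
  expect_true(is.finite(attr(sc, "slope")))

  # identical pair: zero differences, zero distance
  aln0 <- codon_alignment(c(x = "ACGTAA", y = "ACGTAA"))
  sc0 <- saturation_scan(aln0)
  expect_equal(sc0$differences, 0L)
  expect_equal(sc0$k2p, 0)
})

test_that("K2P dominates the p-distance on valid pairs", {
  tr <- simulate_bd_tree(0.15, 0, 8, seed = 2)
  aln <- simulate_alignment(tr, hky_params(kappa = 2.5), 300, rate = 0.004,
                            seed = 8)
  sc <- saturation_scan(aln)
  ok <- sc$valid & sc$differences > 0
  expect_true(all(sc$k2p[ok] >= sc$p_dist[ok] - 1e-12))
})
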