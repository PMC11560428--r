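# Family building: clustering, center-star alignment, consensus,
# superfamily classification, composition statistics, rank-sum test.

test_that("greedy clustering groups identical sequences and drops small clusters", {
  set.seed(4)
  s200 <- mitekit:::random_dna(200L)
  junk <- mitekit:::random_dna(200L)
  cl <- cluster_by_identity(c(a = s200, b = s200, c = s200, d = junk))
  expect_equal(length(cl$clusters), 1L)
  expect_setequal(cl$clusters[[1L]], c("a", "b", "c"))
  expect_equal(cl$singletons, "d")
  # two members only: below the minimum family size of 3
  cl2 <- cluster_by_identity(c(a = s200, b = s200))
  expect_equal(length(cl2$clusters), 0L)
  expect_setequal(cl2$singletons, c("a", "b"))
})

test_that("copies mutated at k = 0.05 cluster into one family (brute-force check)", {
  set.seed(9)
  anc <- mitekit:::random_dna(300L)
  copies <- vapply(1:10, function(i) {
    mutate_sequence(anc, 0.05, 2.0, seed = 100L + i)
  }, character(1))
  names(copies) <- sprintf("c%02d", 1:10)
  # oracle: all pairwise identities comfortably above the 0.80 threshold
  ids <- outer(1:10, 1:10, Vectorize(function(i, j) {
    if (i >= j) return(1)
    mitekit:::pairwise_identity_set(copies[[i]], copies[[j]])
  }))
  expect_true(all(ids > 0.80))
  cl <- cluster_by_identity(copies)
  expect_equal(length(cl$clusters), 1L)
  expect_equal(length(cl$clusters[[1L]]), 10L)
})

test_that("center-star alignment satisfies its contracts", {
  a <- center_star_msa(c(x = "ACGT", y = "ACGT", z = "ACGT"))
  expect_identical(unname(a), rep("ACGT", 3L))
  # forced gap opposite the deleted C
  al <- mitekit:::nw_align("ACGT", "AGT")
  expect_identical(al$a, "ACGT")
  expect_identical(al$b, "A-GT")
  # round trip: ungapping any row returns its input; length >= longest input
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(3:6, 1L)
    seqs <- vapply(seq_len(n), function(i) {
      mitekit:::random_dna(sample(30:60, 1L))
    }, character(1))
    names(seqs) <- sprintf("s%d", seq_len(n))
    aln <- center_star_msa(seqs)
    expect_equal(length(unique(nchar(aln))), 1L)
    expect_gte(nchar(aln[1L]), max(nchar(seqs)))
    expect_identical(gsub("-", "", aln, fixed = TRUE), seqs)
  }
})

test_that("majority consensus follows the stated column rules", {
  expect_equal(build_consensus(c("ACGT", "ACGT", "ACTT"))$consensus, "ACGT")
  expect_equal(build_consensus(c("A-GT", "ACGT", "ACGT"))$consensus, "ACGT")
  # ties break by alphabet order A < C < G < T
  expect_equal(build_consensus(c("AT", "TA"))$consensus, "AA")
  # gap-majority columns are dropped
  got <- build_consensus(c("A-C", "A-C", "AGC"))
  expect_equal(got$consensus, "AC")
  expect_equal(got$kept_columns, c(1L, 3L))
})

test_that("consensus of a mutated family recovers the ancestor", {
  set.seed(31)
  anc <- mitekit:::random_dna(250L)
  copies <- vapply(1:12, function(i) {
    mutate_sequence(anc, 0.08, 2.0, seed = 500L + i)
  }, character(1))
  names(copies) <- sprintf("m%02d", 1:12)
  cons <- build_consensus(center_star_msa(copies))$consensus
  expect_gte(mitekit:::pairwise_identity_set(anc, cons), 0.99)
})

test_that("superfamily classification follows the rule table in order", {
  tir <- "GGCCTTGTTCGGTT"
  expect_equal(classify_superfamily(tir, "TA"), "Tc1/Mariner-like")
  expect_equal(classify_superfamily(tir, "TAA"), "PIF/Harbinger-like")
  expect_equal(classify_superfamily(tir, "TTA"), "PIF/Harbinger-like")
  expect_equal(classify_superfamily(tir, "ACGTTGCA"), "hAT-like")
  expect_equal(classify_superfamily(tir, "CTTAGCGTC"), "Mutator-like")
  expect_equal(classify_superfamily(tir, "GCGTC"), "Unknown")
  expect_equal(classify_superfamily("CACTACAAGA", "GCA"), "CACTA-like")
  expect_equal(classify_superfamily("CACTACAAGA", "TA"), "Tc1/Mariner-like")
  expect_equal(classify_superfamily(tir, NA), "Unknown")
  expect_error(classify_superfamily("ACGT", "TA"),
               class = "mitekit_parameter_error")
})

test_that("classification of an age-0 catalog matches the planted proportions", {
  run <- age0_run()
  tr <- run$sim$elements
  key_t <- paste(tr$chrom, tr$start, tr$end)
  key_d <- paste(run$catalog$chrom, run$catalog$start, run$catalog$end)
  m <- match(key_t, key_d)
  got <- vapply(m, function(r) {
    classify_superfamily(run$catalog$tir5[r], run$catalog$tsd[r])
  }, character(1))
  expect_identical(got, tr$superfamily)
})

test_that("at_fraction counts A and T, excluding N", {
  expect_equal(at_fraction("AATT"), 1.0)
  expect_equal(at_fraction("GGCC"), 0.0)
  expect_equal(at_fraction("GGCCTTGTTCGGTT"), 6 / 14)
  expect_equal(at_fraction("ANT"), 1.0)
  expect_error(at_fraction("NNN"), class = "mitekit_parameter_error")
})

test_that("rank_sum_test matches exact enumeration and wilcox.test", {
  got <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, 0)
  expect_equal(got$p, 0.1)
  # symmetry: identical multisets give U = n_a n_b / 2
  expect_equal(rank_sum_test(c(2, 5, 9), c(2, 5, 9))$U, 4.5)
  set.seed(17)
  for (rep in 1:25) {
    na <- sample(2:5, 1L); nb <- sample(2:5, 1L)
    a <- sample(1:12, na, replace = TRUE)  # ties likely
    b <- sample(1:12, nb, replace = TRUE)
    got <- rank_sum_test(a, b)
    r <- rank(c(a, b))
    # identity: U_a + U_b = n_a n_b
    Ub <- sum(r[na + seq_len(nb)]) - nb * (nb + 1) / 2
    expect_equal(got$U + Ub, na * nb)
    # oracle: full enumeration of rank assignments
    combs <- combn(na + nb, na)
    us <- apply(combs, 2L, function(idx) sum(r[idx]) - na * (na + 1) / 2)
    p_exact <- min(1, 2 * min(mean(us <= got$U + 1e-9),
                              mean(us >= got$U - 1e-9)))
    expect_equal(got$p, p_exact)
  }
  # large samples: normal approximation tracks wilcox.test
  set.seed(18)
  a <- rnorm(30); b <- rnorm(25, 0.7)
  got <- rank_sum_test(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-6)
})

test_that("composition stats reproduce hand-computed values", {
  got <- composition_stats(c(100, 200, 300, 50), c(0.5, 0.6, 0.7, 0.2),
                           c("x", "x", "x", "y"))
  x <- got[got$group == "x", ]
  expect_equal(x$n, 3L)
  expect_equal(x$mean_length, 200)
  expect_equal(x$cv_percent, sd(c(100, 200, 300)) / 200 * 100)
  expect_equal(x$at_percent, 60)
})

test_that("build_families assigns HvX# ids by superfamily and size", {
  set.seed(41)
  anc1 <- mitekit:::random_dna(150L)
  anc2 <- mitekit:::random_dna(220L)
  seqs <- c(
    setNames(vapply(1:4, function(i) mutate_sequence(anc1, 0.03, 2, i),
                    character(1)), sprintf("a%d", 1:4)),
    setNames(vapply(1:3, function(i) mutate_sequence(anc2, 0.03, 2, 10 + i),
                    character(1)), sprintf("b%d", 1:3)))
  tirs <- setNames(rep("GGCCTTGTTCGGTT", 7L), names(seqs))
  tsds <- setNames(c(rep("TA", 4L), rep("TAA", 3L)), names(seqs))
  fams <- build_families(seqs, tirs, tsds)
  expect_equal(length(fams$families), 2L)
  labels <- vapply(fams$families, `[[`, character(1), "superfamily")
  ids <- vapply(fams$families, `[[`, character(1), "id")
  expect_setequal(labels, c("Tc1/Mariner-like", "PIF/Harbinger-like"))
  expect_identical(ids[match(c("Tc1/Mariner-like", "PIF/Harbinger-like"),
                             labels)],
                   c("HvT1", "HvP1"))
})
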