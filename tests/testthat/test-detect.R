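# Structural detection: inverted-repeat scan, TSD verification, filtering.

test_that("the maize Wx-B2 reconstruction yields one 128 bp candidate with a 14 bp TIR", {
  fx <- wx_fixture()
  cand <- scan_inverted_repeats(fx$genome)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$tir_length, 14L)
  expect_equal(cand$total_length, 128L)
  expect_equal(cand$tir5, fx$tir)
  expect_equal(cand$tir3, revcomp(fx$tir))
  expect_equal(cand$start, fx$start0)
  expect_equal(cand$end, fx$end0)
})

test_that("degenerate inputs produce no candidates", {
  expect_equal(nrow(scan_inverted_repeats(c(chr1 = strrep("C", 1000L)))), 0L)
  expect_equal(nrow(scan_inverted_repeats(c(chr1 = ""))), 0L)
  # N-rich regions are skipped, not an error
  expect_equal(nrow(scan_inverted_repeats(c(chr1 = strrep("N", 500L)))), 0L)
})

test_that("every planted element is recovered with exact boundaries at age 0", {
  run <- age0_run()
  tr <- run$sim$elements
  key_t <- paste(tr$chrom, tr$start, tr$end)
  key_d <- paste(run$catalog$chrom, run$catalog$start, run$catalog$end)
  expect_true(all(key_t %in% key_d))
  # recovered TSDs equal the planted ones
  m <- match(key_t, key_d)
  expect_identical(run$catalog$tsd[m], tr$tsd)
})

test_that("verify_tsd reports the canonical flanking duplications", {
  el <- paste0("GGCCTTGTTC", strrep("A", 40L), "GAACAAGGCC")
  mk <- function(left, right) {
    g <- c(chr = paste0(strrep("G", 20L), left, el, right, strrep("G", 20L)))
    cand <- data.frame(chrom = "chr", start = 20L + nchar(left),
                       end = 20L + nchar(left) + nchar(el),
                       stringsAsFactors = FALSE)
    verify_tsd(cand, g)
  }
  got <- mk("TAA", "TAA")
  expect_equal(got$tsd, "TAA"); expect_equal(got$tsd_length, 3L)
  expect_true(is.na(mk("GC", "AT")$tsd))
  got <- mk("CATTG", "CATTG")
  expect_equal(got$tsd, "CATTG"); expect_equal(got$tsd_length, 5L)
})

test_that("verify_tsd agrees with brute force over all lengths 2-10", {
  # mirrors the documented contract: longest exact duplication first, the
  # mismatch tolerance only as a fallback
  brute_at <- function(g, s1, e1, maxmm) {
    best <- NULL
    for (L in 2:10) {
      if (s1 - L < 1L || e1 + L > nchar(g)) next
      l <- substr(g, s1 - L, s1 - 1L); r <- substr(g, e1 + 1L, e1 + L)
      mm <- sum(strsplit(l, "")[[1L]] != strsplit(r, "")[[1L]])
      if (mm <= maxmm && (is.null(best) || L > best$len)) {
        best <- list(tsd = l, len = L)
      }
    }
    best
  }
  brute <- function(g, s1, e1, maxmm) {
    brute_at(g, s1, e1, 0L) %||% brute_at(g, s1, e1, maxmm)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  set.seed(21)
  for (rep in 1:40) {
    g <- mitekit:::random_dna(160L)
    s1 <- sample(30:60, 1L); e1 <- sample(90:120, 1L)
    maxmm <- sample(0:1, 1L)
    cand <- data.frame(chrom = "c", start = s1 - 1L, end = e1,
                       stringsAsFactors = FALSE)
    got <- verify_tsd(cand, c(c = g), max_mismatch = maxmm)
    want <- brute(g, s1, e1, maxmm)
    if (is.null(want)) {
      expect_true(is.na(got$tsd))
    } else {
      expect_equal(got$tsd_length, want$len)
      expect_equal(got$tsd, want$tsd)
    }
  }
})

test_that("candidates at a chromosome edge get a flagged absent TSD", {
  g <- c(chr = strrep("ACGT", 30L))
  cand <- data.frame(chrom = "chr", start = 0L, end = 60L,
                     stringsAsFactors = FALSE)
  got <- verify_tsd(cand, g)
  expect_true(is.na(got$tsd))
  expect_true(got$edge_flag)
})

test_that("filter_candidates drops TSD-less rows and duplicate intervals", {
  cand <- data.frame(chrom = "c", start = c(10L, 40L, 40L, 70L),
                     end = c(30L, 60L, 60L, 95L),
                     tsd = c("TA", NA, NA, "TAA"),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(filter_candidates(cand, require_tsd = TRUE)), 2L)
  kept <- filter_candidates(cand, require_tsd = FALSE)
  expect_equal(nrow(kept), 3L)  # the duplicate interval collapses
  expect_identical(kept$start, c(10L, 40L, 70L))
})

test_that("no reported candidate violates the structural bounds", {
  run <- aged_run()
  cat_df <- run$catalog
  expect_true(all(cat_df$total_length >= 50L & cat_df$total_length <= 800L))
  expect_true(all(cat_df$tir_length >= 10L))
  tsdl <- cat_df$tsd_length[!is.na(cat_df$tsd_length)]
  expect_true(all(tsdl >= 2L & tsdl <= 10L))
  # TIR arms never overlap: at least 1 bp interior
  expect_true(all(2L * cat_df$tir_length < cat_df$total_length))
  # reverse-complement consistency up to the recorded mismatch count
  mism <- vapply(seq_len(nrow(cat_df)), function(r) {
    a <- strsplit(cat_df$tir5[r], "")[[1L]]
    b <- strsplit(revcomp(cat_df$tir3[r]), "")[[1L]]
    sum(a != b)
  }, integer(1))
  expect_true(all(mism <= cat_df$tir_mismatches))
})
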