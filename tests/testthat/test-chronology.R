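# Insertion dating: K2P distance, age conversion, JC LTR dating, catalog
# dating and burst histograms.

test_that("k2p_distance matches direct formula evaluation", {
  got <- k2p_distance(strrep("ACGT", 2L), strrep("ACGT", 2L))
  expect_equal(got$P, 0); expect_equal(got$Q, 0); expect_equal(got$k, 0)
  # 20 sites, 2 transitions (A->G), 1 transversion (A->C)
  a <- strrep("A", 20L)
  b <- paste0("GG", "C", strrep("A", 17L))
  got <- k2p_distance(a, b)
  expect_equal(got$sites, 20L)
  expect_equal(got$transitions, 2L)
  expect_equal(got$transversions, 1L)
  expect_equal(got$k, -0.5 * log(0.75) - 0.25 * log(0.9))
  expect_equal(got$k, 0.1702, tolerance = 1e-3)
  # saturation: all-transition comparison leaves the log undefined
  expect_error(k2p_distance(strrep("A", 10L), strrep("G", 10L)),
               class = "mitekit_saturation")
})

test_that("k2p excludes gapped and N columns (pairwise deletion)", {
  got <- k2p_distance("AC-GTN", "ACCGTA")
  expect_equal(got$sites, 4L)
  expect_equal(got$k, 0)
})

test_that("both transition pairs are recognised", {
  expect_equal(k2p_distance("AAAA", "GAAA")$transitions, 1L)
  expect_equal(k2p_distance("CCCC", "TCCC")$transitions, 1L)
  expect_equal(k2p_distance("AAAA", "CAAA")$transversions, 1L)
  expect_equal(k2p_distance("GGGG", "TGGG")$transversions, 1L)
})

test_that("the molecular clock converts divergence to Mya", {
  expect_equal(mite_age(0), 0)
  expect_equal(mite_age(0.026), 1.0)
  expect_equal(mite_age(0.1702), 6.546, tolerance = 1e-3)
  expect_error(mite_age(-0.1), class = "mitekit_parameter_error")
})

test_that("jc_age applies the Jukes-Cantor correction", {
  got <- jc_age(0)
  expect_equal(got$K, 0); expect_equal(got$T, 0)
  expect_equal(jc_age(0.1)$K, -0.75 * log(1 - 0.4 / 3))
  expect_equal(jc_age(0.1)$K, 0.1073, tolerance = 1e-3)
  # K = 0.026 corresponds to 1 Mya under the same clock
  d <- (1 - exp(-4 * 0.026 / 3)) * 3 / 4
  expect_equal(jc_age(d)$T, 1.0, tolerance = 1e-12)
  expect_error(jc_age(0.8), class = "mitekit_saturation")
})

test_that("k2p reduces to JC at the 1:2 transition:transversion split", {
  for (d in c(0.01, 0.02, 0.05)) {
    # counts realizing P = d/3, Q = 2d/3 over 3000 sites
    n <- 3000L
    nts <- round(n * d / 3); ntv <- round(n * 2 * d / 3)
    a <- strrep("A", n)
    b <- paste0(strrep("G", nts), strrep("C", ntv),
                strrep("A", n - nts - ntv))
    k <- k2p_distance(a, b)$k
    dd <- (nts + ntv) / n
    K <- -0.75 * log(1 - 4 * dd / 3)
    expect_lt(abs(k - K), 1e-3)
  }
})

test_that("k is strictly increasing in P and in Q", {
  kof <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  grid <- seq(0.01, 0.2, by = 0.01)
  for (Q in c(0.02, 0.1)) {
    ks <- vapply(grid, kof, numeric(1), Q = Q)
    expect_true(all(diff(ks) > 0))
  }
  for (P in c(0.02, 0.1)) {
    ks <- vapply(grid, function(q) kof(P, q), numeric(1))
    expect_true(all(diff(ks) > 0))
  }
})

test_that("mutate then date recovers the target within binomial noise", {
  set.seed(23)
  for (rep in 1:10) {
    L <- sample(200:600, 1L)
    k <- runif(1L, 0.01, 0.3)
    s <- mitekit:::random_dna(L)
    m <- mutate_sequence(s, k, 2.0, seed = sample.int(1e6, 1L))
    khat <- k2p_distance(s, m)$k
    pq <- k2p_expected_pq(k, 2.0)
    p <- pq$P + pq$Q
    # 3 binomial SDs on the p-distance, propagated through the correction
    tol <- 3 * sqrt(p * (1 - p) / L) / (1 - 2 * p)
    expect_lt(abs(khat - k), tol + 1e-9)
  }
})

test_that("date_catalog dates members against the family consensus", {
  seqs <- c(m1 = "ACGTACGTACGT", m2 = "ACGTACGTACGT", m3 = "ACGTACGTACGT")
  aln <- center_star_msa(seqs)
  cons <- build_consensus(aln)
  fam <- structure(list(families = list(list(
    id = "HvT1", members = names(seqs), alignment = aln,
    consensus = cons$consensus, kept_columns = cons$kept_columns,
    superfamily = "Tc1/Mariner-like")), singletons = character(0)),
    class = "mite_families")
  ages <- date_catalog(fam)
  expect_equal(ages$age_mya, c(0, 0, 0))
  # one transition among 200 sites
  s <- strrep("AC", 100L)
  s2 <- paste0("G", substr(s, 2L, 200L))
  k <- k2p_distance(s, s2)$k
  expect_equal(k, 0.005025, tolerance = 1e-4)
  expect_equal(mite_age(k), 0.1933, tolerance = 1e-3)
})

test_that("burst_histogram finds forced peaks and ignores flat input", {
  got <- burst_histogram(c(2.1, 2.5, 2.9, 12.3), min_peak_count = 1L)
  expect_equal(got$peaks$bin_start, c(2, 12))
  flat <- burst_histogram(rep(seq(0.5, 19.5, by = 1), each = 3L),
                          min_peak_count = 1L)
  expect_equal(nrow(flat$peaks), 0L)
  empty <- burst_histogram(numeric(0))
  expect_equal(nrow(empty$histogram), 0L)
  # count floor suppresses small peaks
  got <- burst_histogram(c(2.1, 2.5, 2.9, 12.3), min_peak_count = 2L)
  expect_equal(got$peaks$bin_start, 2)
})

test_that("LTR pairs are dated from raw divergence or from sequences", {
  got <- date_ltr_pairs(data.frame(id = "L1", d = 0.1))
  expect_equal(got$K, 0.1073, tolerance = 1e-3)
  # saturated pairs are excluded, not truncated
  got <- date_ltr_pairs(data.frame(id = c("L1", "L2"), d = c(0.05, 0.9)))
  expect_equal(got$id, "L1")
  expect_equal(attr(got, "saturated"), "L2")
  # sequence route: two identical LTRs date to zero
  got <- date_ltr_pairs(data.frame(id = "L3", ltr5 = strrep("ACGT", 50L),
                                   ltr3 = strrep("ACGT", 50L)))
  expect_equal(got$age_mya, 0)
})

test_that("simulated LTR pairs recover their planted ages", {
  run <- aged_run()
  ltr <- run$sim$ltrs
  got <- date_ltr_pairs(ltr)
  m <- match(got$id, ltr$id)
  # per-element noise at 300 bp is sizeable; the mean must track truth
  expect_lt(abs(mean(got$age_mya) - mean(ltr$age_mya[m])), 0.4)
})
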