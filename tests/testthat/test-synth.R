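# Synthetic-data generator: mutation model, genome bundles, expression
# matrices and pan-genome catalogs with ground truth.

test_that("mutate_sequence honours the zero-rate and determinism contracts", {
  s <- strrep("ACGT", 50L)
  expect_identical(mutate_sequence(s, 0, 2.0, seed = 1L), s)
  m1 <- mutate_sequence(s, 0.2, 2.0, seed = 99L)
  m2 <- mutate_sequence(s, 0.2, 2.0, seed = 99L)
  expect_identical(m1, m2)
  expect_error(mutate_sequence(s, 0.7, 2.0, 1L),
               class = "mitekit_parameter_error")
  expect_error(mutate_sequence(s, -0.1, 2.0, 1L),
               class = "mitekit_parameter_error")
  expect_error(mutate_sequence("ACGN", 0.1, 2.0, 1L),
               class = "mitekit_alphabet_error")
})

test_that("mutation matches a brute-force Bernoulli oracle and K2P inverts it", {
  s <- strrep("ACGT", 5000L)
  m <- mutate_sequence(s, 0.1, 2.0, seed = 7L)
  p_real <- mean(strsplit(s, "")[[1L]] != strsplit(m, "")[[1L]])
  # oracle: per-site Bernoulli with the exact single-site substitution
  # probability P + Q at k = 0.1
  pq <- k2p_expected_pq(0.1, 2.0)
  p_exp <- pq$P + pq$Q
  n <- nchar(s)
  expect_lt(abs(p_real - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
  expect_lt(abs(k2p_distance(s, m)$k - 0.1), 0.02)
})

test_that("simulated genomes carry a complete, consistent truth table", {
  fams <- default_family_specs(copy_number = 10L)[1:2]
  cfg <- simulation_config(seed = 3L, n_chromosomes = 2L,
                           chrom_length = 60000L, n_genes = 6L,
                           families = fams, ltr_count = 2L)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$elements), 20L)  # 2 families x 10 copies
  # truth load is tied to age by k = 2 r T
  expect_equal(sim$elements$k,
               2 * MITE_SUBSTITUTION_RATE * sim$elements$age_mya * 1e6,
               tolerance = 1e-12)
  # intervals lie within their chromosomes
  expect_true(all(sim$elements$start >= 0))
  expect_true(all(sim$elements$end <=
                    nchar(sim$genome[sim$elements$chrom])))
  # byte-identical reruns under the same config + seed
  sim2 <- simulate_genome(cfg)
  expect_identical(sim$genome, sim2$genome)
  expect_identical(sim$elements, sim2$elements)
})

test_that("an element with drawn age 1 Mya gets true k of 0.026", {
  expect_equal(2 * MITE_SUBSTITUTION_RATE * 1 * 1e6, 0.026)
  # and the truth table reproduces that relation (checked above per row)
  expect_equal(mite_age(0.026), 1.0)
})

test_that("drawn ages reproduce the configured bimodal mixture", {
  run <- aged_run()
  ages <- run$sim$elements$age_mya
  expect_gte(length(ages), 500L)
  h <- tabulate(floor(ages) + 1L, nbins = 20L)
  # the young burst is the global mode, in the [2,3) bin
  expect_equal(which.max(h), 3L)
  # the old component peaks at the configured 12.5 Mya center (allowing
  # one bin of sampling noise at this sample size) and the [12,13) bin
  # carries close to the maximal old-component mass
  old <- h[9:20]  # bins [8,9) ... [19,20)
  expect_true(which.max(old) %in% 4:6)  # bins [11,12), [12,13), [13,14)
  expect_gte(h[13L], 0.8 * max(old))
})

test_that("un-mutated planted elements satisfy the structural criteria", {
  run <- age0_run()
  tr <- run$sim$elements
  expect_true(all(tr$total_length >= 50L & tr$total_length <= 800L))
  expect_true(all(tr$tir_length >= 10L))
  expect_true(all(nchar(tr$tsd) >= 2L & nchar(tr$tsd) <= 10L))
  # ancestors are perfect inverted repeats
  for (nm in names(run$sim$ancestors)) {
    anc <- run$sim$ancestors[[nm]]
    tirl <- tr$tir_length[tr$family == nm][1L]
    expect_identical(substr(anc, 1L, tirl),
                     revcomp(substr(anc, nchar(anc) - tirl + 1L,
                                    nchar(anc))))
  }
})

test_that("realized K2P load regresses on truth with slope 1 +/- 0.1", {
  run <- aged_run()
  tr <- run$sim$elements
  big <- which(tr$total_length >= 200L)
  expect_gte(length(big), 200L)
  khat <- vapply(big, function(i) {
    el <- substr(run$sim$genome[[tr$chrom[i]]], tr$start[i] + 1L, tr$end[i])
    k2p_distance(el, run$sim$ancestors[[tr$family[i]]])$k
  }, numeric(1))
  slope <- unname(coef(lm(khat ~ tr$k[big]))[2L])
  expect_gt(slope, 0.9); expect_lt(slope, 1.1)
})

test_that("simulated expression matrices carry exact tau classes", {
  ex <- simulate_expression(100L, n_tissues = 8L, frac_specific = 0.1,
                            frac_uniform = 0.2, seed = 5L)
  expect_equal(sum(ex$truth$class == "specific"), 10L)
  expect_equal(sum(ex$truth$class == "uniform"), 20L)
  taus <- compute_tau(ex$fpkm)
  tt <- taus$tau[match(ex$truth$gene, taus$gene)]
  expect_true(all(tt[ex$truth$class == "specific"] == 1))
  expect_true(all(tt[ex$truth$class == "uniform"] == 0))
  # specific rows are positive in exactly one tissue
  spec <- ex$fpkm[ex$truth$class == "specific", , drop = FALSE]
  expect_true(all(rowSums(spec > 0) == 1L))
})

test_that("pan-genome catalogs honour the accession plan exactly", {
  fams <- default_family_specs(copy_number = 10L)[1:2]
  sim <- simulate_genome(simulation_config(
    seed = 3L, n_chromosomes = 2L, chrom_length = 60000L, n_genes = 6L,
    families = fams, ltr_count = 0L))
  plan <- list(wild = 2L, landrace = 0L, cultivar = 2L, inserted = 3L,
               lost = 2L, background_absence = 0.1, flank_divergence = 0)
  pg <- simulate_pangenome(sim, plan, seed = 8L)
  expect_equal(sum(pg$truth$status == "inserted"), 3L)
  expect_equal(sum(pg$truth$status == "lost"), 2L)
  ins <- pg$truth$locus[pg$truth$status == "inserted"]
  expect_true(all(pg$presence[ins, c("cultivar1", "cultivar2")] == 1L))
  expect_true(all(pg$presence[ins, c("wild1", "wild2")] == 0L))
  expect_error(simulate_pangenome(sim, list(wild = 0L, cultivar = 2L),
                                  seed = 1L),
               class = "mitekit_parameter_error")
  # determinism
  pg2 <- simulate_pangenome(sim, plan, seed = 8L)
  expect_identical(pg$catalogs, pg2$catalogs)
})
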