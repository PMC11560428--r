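# Shared fixtures. Heavy simulated runs are built lazily and cached for the
# whole session so several test files can reuse them.

.run_cache <- new.env(parent = emptyenv())

# bimodal-age study genome (520 planted elements) plus its detection run
aged_run <- function() {
  if (is.null(.run_cache$aged)) {
    sim <- simulate_genome(simulation_config(seed = 7))
    catalog <- detect_mites(sim$genome, max_tir_mismatch = 2L,
                            tsd_max_mismatch = 1L)
    .run_cache$aged <- list(sim = sim, catalog = catalog)
  }
  .run_cache$aged
}

# same families planted without divergence (effectively age zero)
age0_run <- function() {
  if (is.null(.run_cache$age0)) {
    sim <- simulate_genome(simulation_config(
      seed = 42, age_peaks = list(c(0, 1e-4, 1))))
    catalog <- detect_mites(sim$genome)
    .run_cache$age0 <- list(sim = sim, catalog = catalog)
  }
  .run_cache$age0
}

# families assembled from the planted truth labels (exercises MSA,
# consensus and dating against known ancestors)
truth_families <- function(sim) {
  tr <- sim$elements
  seqs <- vapply(seq_len(nrow(tr)), function(i) {
    substr(sim$genome[[tr$chrom[i]]], tr$start[i] + 1L, tr$end[i])
  }, character(1))
  names(seqs) <- tr$element
  fams <- lapply(split(seq_len(nrow(tr)), tr$family), function(idx) {
    aln <- center_star_msa(seqs[idx])
    cons <- build_consensus(aln)
    list(id = tr$family[idx[1L]], members = names(aln), alignment = aln,
         consensus = cons$consensus, kept_columns = cons$kept_columns,
         superfamily = tr$superfamily[idx[1L]])
  })
  structure(list(families = fams, singletons = character(0)),
            class = "mite_families")
}

# per-candidate truth-family label by largest overlap (NA = no overlap)
label_candidates <- function(truth, cand) {
  lab <- rep(NA_character_, nrow(cand))
  best <- rep(0L, nrow(cand))
  for (t in seq_len(nrow(truth))) {
    ov <- pmin(cand$end, truth$end[t]) - pmax(cand$start, truth$start[t])
    ov[cand$chrom != truth$chrom[t] | ov < 0L] <- 0L
    upd <- ov > best
    lab[upd] <- truth$family[t]
    best[upd] <- ov[upd]
  }
  names(lab) <- cand$element
  lab
}

# which truth elements have a candidate with reciprocal overlap >= recip
detected_flags <- function(truth, cand, recip = 0.5) {
  vapply(seq_len(nrow(truth)), function(t) {
    same <- which(cand$chrom == truth$chrom[t])
    if (!length(same)) return(FALSE)
    ov <- pmin(cand$end[same], truth$end[t]) -
      pmax(cand$start[same], truth$start[t])
    w <- pmax(cand$end[same] - cand$start[same],
              truth$end[t] - truth$start[t])
    any(ov / w >= recip)
  }, logical(1))
}

# the maize Wx-B2 element rebuilt from its printed 14 bp TIR: TIR + 100 A +
# reverse-complement TIR inside 500 bp seeded random flanks
wx_fixture <- function(flank_seed = 1L) {
  tir <- "GGCCTTGTTCGGTT"
  el <- paste0(tir, strrep("A", 100L), revcomp(tir))
  set.seed(flank_seed)
  g <- c(chrA = paste0(mitekit:::random_dna(500L), el,
                       mitekit:::random_dna(500L)))
  list(genome = g, element = el, tir = tir, start0 = 500L,
       end0 = 500L + nchar(el))
}
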