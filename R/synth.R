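# Synthetic genomes with known ground truth. Chromosomes are random
# background sequence; gene models are annotated over it; MITEs are written
# in as TSD + TIR + internal + revcomp(TIR) + TSD blocks, each mutated
# according to an insertion age drawn from a bimodal mixture, with the
# substitution load tied to the age by k = 2 r T (the inverse of the K2P
# dating formula). LTR retrotransposons carry two LTR copies whose pairwise
# divergence matches their drawn age under Jukes-Cantor. Junction bases
# around each un-mutated element are locally resampled so that the planted
# boundary is the unique structurally supported one (no accidental
# inverted-repeat extension past the TSD, no spurious exact direct repeat at
# an outer junction) - a deliberate idealization that makes the planted
# truth identifiable.

MAX_K <- 0.7  # K2P correction stays well-defined below this load

#' Expected K2P transition/transversion proportions at a divergence
#'
#' Exact single-site transition probabilities of the Kimura 2-parameter chain
#' at total divergence `k` split into transitions and transversions by the
#' rate ratio: `P = 1/4 + 1/4 exp(-4b) - 1/2 exp(-2(a+b))`,
#' `Q = 1/2 - 1/2 exp(-4b)` with `a = k R/(R+1)`, `b = k/(2(R+1))`.
#' Inverting with the K2P estimator returns exactly `k`.
#'
#' @param k expected substitutions per site
#' @param ts_tv_ratio transition:transversion rate ratio R
#' @return list with `P` and `Q`
#' @export
k2p_expected_pq <- function(k, ts_tv_ratio = 2.0) {
  R <- ts_tv_ratio
  a <- k * R / (R + 1)
  b <- k / (2 * (R + 1))
  list(P = 0.25 + 0.25 * exp(-4 * b) - 0.5 * exp(-2 * (a + b)),
       Q = 0.5 - 0.5 * exp(-4 * b))
}

# in-stream mutation on the integer encoding (uses the caller's RNG)
mutate_core <- function(b, k_target, ts_tv_ratio) {
  pq <- k2p_expected_pq(k_target, ts_tv_ratio)
  u <- runif(length(b))
  coin <- runif(length(b))
  out <- b
  ts <- u < pq$P
  tv <- !ts & u < pq$P + pq$Q
  out[ts] <- (b[ts] + 2L) %% 4L
  out[tv] <- (b[tv] + ifelse(coin[tv] < 0.5, 1L, 3L)) %% 4L
  out
}

#' Mutate a sequence to a target substitution load
#'
#' Each site is substituted independently with the exact K2P single-site
#' probabilities at divergence `k_target` (see [k2p_expected_pq()]), so the
#' expected per-site substitution proportion equals `P + Q` and the K2P
#' estimator recovers `k_target` without bias. No indels are introduced.
#'
#' @param seq nucleotide string over A/C/G/T
#' @param k_target expected substitutions per site, `0 <= k_target < 0.7`
#' @param ts_tv_ratio transition:transversion rate ratio, default 2.0
#' @param seed integer seed (the call is a pure function of its arguments)
#' @return mutated string of the same length
#' @export
mutate_sequence <- function(seq, k_target, ts_tv_ratio = 2.0, seed = 1L) {
  if (!is.numeric(k_target) || k_target < 0 || k_target >= MAX_K) {
    mk_error(sprintf("k_target must lie in [0, %.1f)", MAX_K),
             "mitekit_parameter_error")
  }
  if (!nzchar(seq)) mk_error("empty sequence", "mitekit_parameter_error")
  validate_dna(seq, allow_n = FALSE)
  if (k_target == 0) return(toupper(seq))
  with_seed(seed, int_to_seq(mutate_core(seq_to_int(seq), k_target,
                                         ts_tv_ratio)))
}

#' Family specification for the simulator
#'
#' @param name family label used in the truth table
#' @param superfamily planted superfamily label
#' @param tir TIR nucleotide string, >= 10 bp
#' @param tsd TSD nucleotide string, 2-10 bp
#' @param internal_length internal-region length; total element length
#'   `2 * nchar(tir) + internal_length` must lie in 50-800 bp
#' @param copy_number copies planted, >= 3
#' @param at_target A/T fraction of the random internal region
#' @return a `family_spec` list
#' @export
family_spec <- function(name, superfamily, tir, tsd, internal_length,
                        copy_number, at_target = 0.6) {
  validate_dna(tir); validate_dna(tsd)
  total <- 2L * nchar(tir) + internal_length
  if (nchar(tir) < 10L) {
    mk_error("TIR must be at least 10 bp", "mitekit_parameter_error")
  }
  if (nchar(tsd) < 2L || nchar(tsd) > 10L) {
    mk_error("TSD must be 2-10 bp", "mitekit_parameter_error")
  }
  if (total < 50L || total > 800L) {
    mk_error("total element length must lie in 50-800 bp",
             "mitekit_parameter_error")
  }
  if (copy_number < 3L) {
    mk_error("copy_number must be >= 3", "mitekit_parameter_error")
  }
  structure(list(name = name, superfamily = superfamily, tir = toupper(tir),
                 tsd = toupper(tsd),
                 internal_length = as.integer(internal_length),
                 copy_number = as.integer(copy_number),
                 at_target = at_target),
            class = "family_spec")
}

#' Default planted family set
#'
#' Eight families spanning the five classical superfamilies plus one without
#' a diagnostic signature: Stowaway-like families with the 2 bp TA TSD and
#' long TIRs, Tourist-like families with the 3 bp TAA TSD and short TIRs,
#' an 8 bp-TSD hAT-like family, a 9 bp-TSD Mutator-like family with long
#' TIRs, a CACTA-like family (CACT TIR prefix, 3 bp non-TAA TSD), and an
#' Unknown family with a 5 bp TSD. Copy numbers default to 65 per family so
#' a default simulation plants 520 elements.
#'
#' @param copy_number copies per family, default 65
#' @return list of [family_spec()] objects
#' @export
default_family_specs <- function(copy_number = 65L) {
  list(
    family_spec("stow1", "Tc1/Mariner-like",
                tir = "CTCCCTCCGTTTCATTTGGTGTCAATTGGACA", tsd = "TA",
                internal_length = 110L, copy_number = copy_number,
                at_target = 0.65),
    family_spec("stow2", "Tc1/Mariner-like",
                tir = "CTAGGGCGTTAAACGGTGACTCCCTAAA", tsd = "TA",
                internal_length = 130L, copy_number = copy_number,
                at_target = 0.65),
    family_spec("tour1", "PIF/Harbinger-like",
                tir = "GGCCTTGTTCGGTT", tsd = "TAA",
                internal_length = 300L, copy_number = copy_number,
                at_target = 0.59),
    family_spec("tour2", "PIF/Harbinger-like",
                tir = "GGGCATGTTCGATTCACCGGAC", tsd = "TAA",
                internal_length = 280L, copy_number = copy_number,
                at_target = 0.59),
    family_spec("hat1", "hAT-like",
                tir = "TAGGGGTGCAAAACCT", tsd = "ACGTTGCA",
                internal_length = 180L, copy_number = copy_number,
                at_target = 0.58),
    family_spec("mut1", "Mutator-like",
                tir = "GGGACGGCTCCCAAAGCGGTAAACTTGTTGGGGACA",
                tsd = "CTTAGCGTC",
                internal_length = 390L, copy_number = copy_number,
                at_target = 0.59),
    family_spec("cacta1", "CACTA-like",
                tir = "CACTACAAGAAAATGGGT", tsd = "GCA",
                internal_length = 200L, copy_number = copy_number,
                at_target = 0.6),
    family_spec("unk1", "Unknown",
                tir = "GGTCCGGTTGCTATCCAACCTG", tsd = "CCGAT",
                internal_length = 150L, copy_number = copy_number,
                at_target = 0.6)
  )
}

#' Simulation configuration
#'
#' @param seed master seed; all outputs are a pure function of config + seed
#' @param n_chromosomes number of chromosomes
#' @param chrom_length chromosome length (bp); must be at least 10x the
#'   longest planted element
#' @param n_genes total number of gene models
#' @param families list of [family_spec()] objects
#' @param age_peaks list of `c(center_mya, sd_mya, weight)` mixture
#'   components; weights must sum to 1. The default mirrors a bimodal
#'   amplification history with a major recent burst at 2.5 Mya and a minor
#'   older one at 12.5 Mya.
#' @param ltr_count LTR retrotransposons planted
#' @param ts_tv_ratio transition:transversion rate ratio of the mutation
#'   model
#' @param background_at A/T fraction of intergenic background
#' @param accession_plan list for [simulate_pangenome()]: counts `wild`,
#'   `landrace`, `cultivar` and event counts `inserted`, `lost`, plus
#'   `background_absence` (per-accession absence rate of ordinary loci) and
#'   `flank_divergence`
#' @param insert_near_genes if TRUE, element placement is biased toward gene
#'   flanks; off by default so region statistics have a uniform null
#' @return a `simulation_config` list
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 3L,
                              chrom_length = 200000L,
                              n_genes = 36L,
                              families = default_family_specs(),
                              age_peaks = list(c(2.5, 0.5, 0.7),
                                               c(12.5, 1.0, 0.3)),
                              ltr_count = 12L,
                              ts_tv_ratio = 2.0,
                              background_at = 0.55,
                              accession_plan = list(
                                wild = 2L, landrace = 1L, cultivar = 2L,
                                inserted = 3L, lost = 2L,
                                background_absence = 0.1,
                                flank_divergence = 0.02),
                              insert_near_genes = FALSE) {
  w <- sum(vapply(age_peaks, `[`, numeric(1), 3L))
  if (abs(w - 1) > 1e-9) {
    mk_error("age peak weights must sum to 1", "mitekit_parameter_error")
  }
  max_el <- max(vapply(families, function(f) {
    2L * nchar(f$tir) + f$internal_length
  }, integer(1)))
  if (chrom_length < 10L * max_el) {
    mk_error("chrom_length must be at least 10x the longest element",
             "mitekit_parameter_error")
  }
  structure(list(seed = seed, n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length, n_genes = n_genes,
                 families = families, age_peaks = age_peaks,
                 ltr_count = ltr_count, ts_tv_ratio = ts_tv_ratio,
                 background_at = background_at,
                 accession_plan = accession_plan,
                 insert_near_genes = insert_near_genes),
            class = "simulation_config")
}

draw_ages <- function(n, age_peaks) {
  comp <- sample.int(length(age_peaks), n, replace = TRUE,
                     prob = vapply(age_peaks, `[`, numeric(1), 3L))
  ages <- numeric(n)
  max_age <- MAX_K / (2 * MITE_SUBSTITUTION_RATE) * 1e-6 - 0.5
  for (i in seq_len(n)) {
    p <- age_peaks[[comp[i]]]
    repeat {
      a <- rnorm(1L, p[1L], p[2L])
      if (a >= 0 && a < max_age) break
    }
    ages[i] <- a
  }
  ages
}

# longest run of complementary pairs outward from the interval [s1, e1]
outward_run <- function(b, s1, e1) {
  t <- 0L
  n <- length(b)
  while (s1 - t - 1L >= 1L && e1 + t + 1L <= n) {
    x1 <- b[s1 - t - 1L]; x2 <- b[e1 + t + 1L]
    if (is.na(x1) || is.na(x2) || x1 != 3L - x2) break
    t <- t + 1L
  }
  t
}

# Resample background bases near a freshly planted block until the planted
# boundary is the unique structurally supported one. b is the chromosome as
# an integer vector; [s1, e1] the element (TSD excluded); the TSD copies sit
# immediately outside. Works on a local window around the block for speed.
# Returns the updated chromosome vector or NULL on failure.
sanitize_junctions <- function(b, s1, e1, tsd_len, at, reach = 13L,
                               max_iter = 80L) {
  n <- length(b)
  pad <- tsd_len + reach + 12L
  w0 <- max(1L, s1 - pad)            # window start in chromosome coords
  w1 <- min(n, e1 + pad)
  wb <- b[w0:w1]
  ls <- s1 - w0 + 1L                 # element bounds in window coords
  le <- e1 - w0 + 1L
  left_zone <- seq.int(max(1L, ls - tsd_len - reach), ls - tsd_len - 1L)
  right_zone <- seq.int(le + tsd_len + 1L,
                        min(length(wb), le + tsd_len + reach))
  probs <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  # exact-duplication conditions only make sense while the two TSD copies
  # are still identical (they decay with element age)
  tsd_intact <- tsd_len > 0L &&
    identical(wb[seq.int(ls - tsd_len, ls - 1L)],
              wb[seq.int(le + 1L, le + tsd_len)])
  for (iter in seq_len(max_iter)) {
    run <- outward_run(wb, ls, le)
    ok <- run <= tsd_len
    if (ok && tsd_intact) {
      seqchar <- int_to_seq(wb)
      # planted boundary must carry the longest exact duplication, and no
      # outer boundary candidate may carry any
      hit <- tsd_at_junction(seqchar, ls, le, 2L, 10L, 0L)
      ok <- !is.null(hit) && hit$len == tsd_len
      if (ok && run > 0L) {
        for (t in seq_len(run)) {
          if (!is.null(tsd_at_junction(seqchar, ls - t, le + t, 2L, 10L,
                                       0L))) {
            ok <- FALSE
            break
          }
        }
      }
    }
    if (ok) {
      b[w0:w1] <- wb
      return(b)
    }
    wb[left_zone] <- sample.int(4L, length(left_zone), replace = TRUE,
                                prob = probs) - 1L
    wb[right_zone] <- sample.int(4L, length(right_zone), replace = TRUE,
                                 prob = probs) - 1L
  }
  NULL
}

#' Simulate a genome with planted MITEs, genes and LTR retrotransposons
#'
#' @param config a [simulation_config()]
#' @param outdir optional output directory; when given, writes `genome.fa`
#'   (60-column FASTA), `genes.gff3`, `elements_truth.tsv` and
#'   `ltr_truth.tsv`
#' @return an object of class `mite_simulation`: list with `genome` (named
#'   character vector), `genes` (data.frame incl. exon structure),
#'   `elements` (truth data.frame: id, chrom, 0-based half-open interval,
#'   family, superfamily, tsd, tir_length, age_mya, k), `ltrs` (truth
#'   data.frame incl. both LTR sequences), `ancestors` (named character
#'   vector of family ancestral elements), and `config`
#' @export
simulate_genome <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  bundle <- with_seed(config$seed, simulate_genome_impl(config))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(bundle$genome, file.path(outdir, "genome.fa"))
    write_gff3(bundle$genes, file.path(outdir, "genes.gff3"))
    write_tsv(bundle$elements, file.path(outdir, "elements_truth.tsv"))
    write_tsv(bundle$ltrs, file.path(outdir, "ltr_truth.tsv"))
  }
  bundle
}

simulate_genome_impl <- function(config) {
  nchr <- config$n_chromosomes
  clen <- config$chrom_length
  chroms <- sprintf("chr%d", seq_len(nchr))
  genome_int <- lapply(seq_len(nchr), function(i) {
    probs <- c(config$background_at / 2, (1 - config$background_at) / 2,
               (1 - config$background_at) / 2, config$background_at / 2)
    sample.int(4L, clen, replace = TRUE, prob = probs) - 1L
  })
  names(genome_int) <- chroms

  # --- gene models: evenly pitched with jitter, non-overlapping ---
  per_chr <- diff(round(seq(0, config$n_genes, length.out = nchr + 1L)))
  edge <- 6000L
  genes <- list()
  gidx <- 0L
  for (ci in seq_len(nchr)) {
    gn <- per_chr[ci]
    if (gn == 0L) next
    pitch <- (clen - 2L * edge) / gn
    for (k in seq_len(gn)) {
      glen <- sample(1200:2400, 1L)
      if (pitch < glen + 400) {
        mk_error("gene placement impossible at requested density",
                 "mitekit_capacity_error")
      }
      jitter <- floor(runif(1L, 0, pitch - glen - 200))
      s0 <- as.integer(edge + (k - 1L) * pitch + jitter)  # 0-based
      n_ex <- sample(1:3, 1L)
      # split the gene into n_ex exons separated by introns
      cuts <- sort(sample(seq(80L, glen - 80L, by = 20L),
                          2L * (n_ex - 1L)))
      bounds <- c(0L, cuts, glen)
      ex_s <- s0 + bounds[seq(1L, length(bounds), by = 2L)]
      ex_e <- s0 + bounds[seq(2L, length(bounds), by = 2L)]
      gidx <- gidx + 1L
      genes[[gidx]] <- data.frame(
        gene = sprintf("G%04d", gidx), chrom = chroms[ci], start = s0,
        end = s0 + glen, strand = sample(c("+", "-"), 1L),
        stringsAsFactors = FALSE)
      genes[[gidx]]$exon_starts <- list(ex_s)
      genes[[gidx]]$exon_ends <- list(ex_e)
    }
  }
  genes <- do.call(rbind, genes)

  exon_iv <- do.call(rbind, lapply(seq_len(nrow(genes)), function(r) {
    data.frame(chrom = genes$chrom[r], s = genes$exon_starts[[r]] + 1L,
               e = genes$exon_ends[[r]], stringsAsFactors = FALSE)
  }))

  # --- ancestral elements per family ---
  specs <- config$families
  ancestors <- vapply(specs, function(f) {
    internal <- random_dna(f$internal_length, at = f$at_target)
    paste0(f$tir, internal, revcomp(f$tir))
  }, character(1))
  names(ancestors) <- vapply(specs, `[[`, character(1), "name")

  # --- placement bookkeeping: occupied intervals per chromosome ---
  occupied <- lapply(chroms, function(ch) exon_iv[exon_iv$chrom == ch,
                                                  c("s", "e"), drop = FALSE])
  names(occupied) <- chroms
  place_block <- function(block_len, margin = 30L) {
    for (try in seq_len(2000L)) {
      ci <- sample.int(nchr, 1L)
      s1 <- sample.int(clen - block_len - 2L * edge, 1L) + edge  # 1-based
      e1 <- s1 + block_len - 1L
      occ <- occupied[[ci]]
      clash <- any(occ$s <= e1 + margin & occ$e >= s1 - margin)
      if (!clash) return(list(ci = ci, s1 = s1, e1 = e1))
    }
    mk_error("element placement impossible at requested density",
             "mitekit_capacity_error")
  }
  reserve_block <- function(ci, s1, e1) {
    occupied[[ci]] <<- rbind(occupied[[ci]], data.frame(s = s1, e = e1))
  }

  # --- plant MITEs ---
  n_el <- sum(vapply(specs, `[[`, integer(1), "copy_number"))
  fam_of <- rep(seq_along(specs),
                vapply(specs, `[[`, integer(1), "copy_number"))
  ages <- draw_ages(n_el, config$age_peaks)
  truth <- vector("list", n_el)
  for (i in seq_len(n_el)) {
    f <- specs[[fam_of[i]]]
    anc <- ancestors[[f$name]]
    tsd_len <- nchar(f$tsd)
    block0 <- paste0(f$tsd, anc, f$tsd)
    k <- 2 * MITE_SUBSTITUTION_RATE * ages[i] * 1e6
    block_int <- seq_to_int(block0)
    if (k > 0) block_int <- mutate_core(block_int, k, config$ts_tv_ratio)
    for (attempt in seq_len(20L)) {
      loc <- place_block(length(block_int))
      ch <- chroms[loc$ci]
      b <- genome_int[[ch]]
      b[loc$s1:loc$e1] <- block_int
      el_s1 <- loc$s1 + tsd_len       # element bounds exclude the TSDs
      el_e1 <- loc$e1 - tsd_len
      b2 <- sanitize_junctions(b, el_s1, el_e1, tsd_len,
                               config$background_at)
      if (!is.null(b2)) {
        genome_int[[ch]] <- b2
        reserve_block(loc$ci, loc$s1, loc$e1)
        break
      }
      if (attempt == 20L) {
        # junction cannot be disambiguated (TSD-internal structure); plant
        # anyway - boundary-exactness claims simply do not cover this copy
        warning(sprintf("element %d planted with ambiguous junction", i))
        genome_int[[ch]] <- b
        reserve_block(loc$ci, loc$s1, loc$e1)
      }
      # otherwise: abandon this site and draw another
    }
    truth[[i]] <- data.frame(
      element = sprintf("T%05d", i), chrom = ch,
      start = el_s1 - 1L, end = el_e1,  # 0-based half-open
      family = f$name, superfamily = f$superfamily, tsd = f$tsd,
      tir_length = nchar(f$tir), total_length = el_e1 - el_s1 + 1L,
      age_mya = ages[i], k = k, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)

  # --- plant LTR retrotransposons ---
  ltr_len <- 300L
  ltr_internal <- 800L
  ltrs <- NULL
  if (config$ltr_count > 0L) {
    rows <- vector("list", config$ltr_count)
    for (i in seq_len(config$ltr_count)) {
      repeat {
        age <- rnorm(1L, 1.5, 0.4)
        if (age >= 0.05) break
      }
      K <- 2 * LTR_MUTATION_RATE * age * 1e6
      anc <- seq_to_int(random_dna(ltr_len, at = config$background_at))
      # each copy diverges independently for half the pair divergence
      ltr5 <- mutate_core(anc, K / 2, 0.5)
      ltr3 <- mutate_core(anc, K / 2, 0.5)
      internal <- seq_to_int(random_dna(ltr_internal,
                                        at = config$background_at))
      block_int <- c(ltr5, internal, ltr3)
      loc <- place_block(length(block_int))
      reserve_block(loc$ci, loc$s1, loc$e1)
      ch <- chroms[loc$ci]
      genome_int[[ch]][loc$s1:loc$e1] <- block_int
      rows[[i]] <- data.frame(
        id = sprintf("L%03d", i), chrom = ch, start = loc$s1 - 1L,
        end = loc$e1, ltr_length = ltr_len, age_mya = age, true_K = K,
        ltr5 = int_to_seq(ltr5), ltr3 = int_to_seq(ltr3),
        stringsAsFactors = FALSE)
    }
    ltrs <- do.call(rbind, rows)
  } else {
    ltrs <- data.frame(id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       ltr_length = integer(0), age_mya = numeric(0),
                       true_K = numeric(0), ltr5 = character(0),
                       ltr3 = character(0), stringsAsFactors = FALSE)
  }

  genome <- vapply(genome_int, int_to_seq, character(1))
  structure(list(genome = genome, genes = genes, elements = truth,
                 ltrs = ltrs, ancestors = ancestors, config = config),
            class = "mite_simulation")
}

#' @export
print.mite_simulation <- function(x, ...) {
  cat(sprintf(
    "mite_simulation: %d chromosome(s) x %d bp, %d genes, %d MITEs (%d families), %d LTR elements\n",
    length(x$genome), nchar(x$genome[[1L]]), nrow(x$genes),
    nrow(x$elements), length(x$ancestors), nrow(x$ltrs)))
  invisible(x)
}

#' Simulate an FPKM matrix with known tissue-specificity classes
#'
#' "Specific" genes express in exactly one tissue (tau = 1), "uniform" genes
#' equally everywhere (tau = 0), the remainder draw i.i.d. log-normal values
#' per tissue.
#'
#' @param n_genes,n_tissues matrix dimensions (`n_tissues >= 2`; the default
#'   16 mirrors a multi-tissue expression atlas)
#' @param frac_specific fraction of specific genes (exact count
#'   `round(frac_specific * n_genes)`)
#' @param frac_uniform fraction of uniform genes
#' @param seed integer seed
#' @param gene_ids optional gene id vector (default `G0001`...)
#' @return list with `fpkm` (matrix genes x tissues) and `truth`
#'   (data.frame: `gene`, `class` in specific/uniform/other)
#' @export
simulate_expression <- function(n_genes, n_tissues = 16L,
                                frac_specific = 0.1, frac_uniform = 0.1,
                                seed = 1L, gene_ids = NULL) {
  if (n_tissues < 2L) {
    mk_error("need at least 2 tissues", "mitekit_parameter_error")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(n_genes))
  with_seed(seed, {
    n_spec <- round(frac_specific * n_genes)
    n_unif <- round(frac_uniform * n_genes)
    cls <- rep("other", n_genes)
    picks <- sample.int(n_genes, n_spec + n_unif)
    cls[picks[seq_len(n_spec)]] <- "specific"
    cls[picks[seq_len(n_unif) + n_spec]] <- "uniform"
    fpkm <- matrix(0, n_genes, n_tissues,
                   dimnames = list(gene_ids,
                                   sprintf("tissue%02d", seq_len(n_tissues))))
    for (i in seq_len(n_genes)) {
      if (cls[i] == "specific") {
        fpkm[i, sample.int(n_tissues, 1L)] <- rlnorm(1L, 2, 0.8)
      } else if (cls[i] == "uniform") {
        fpkm[i, ] <- rlnorm(1L, 2, 0.8)
      } else {
        fpkm[i, ] <- rlnorm(n_tissues, 1, 1)
      }
    }
    list(fpkm = fpkm,
         truth = data.frame(gene = gene_ids, class = cls,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate pan-genome accession catalogs with controlled presence/absence
#'
#' Domestication-inserted loci are present in every cultivar and no wild
#' accession; domestication-lost loci the reverse; landraces carry either
#' state at random; all other loci are present per accession with
#' probability `1 - background_absence` (resampled if a locus would vanish
#' everywhere). Flanks (+/- `flank_bp`) are taken from the reference genome
#' and mutated per accession at `flank_divergence`.
#'
#' @param sim a `mite_simulation` (see [simulate_genome()])
#' @param plan accession plan; defaults to `sim$config$accession_plan`
#' @param seed integer seed
#' @param flank_bp flank width, default 200
#' @return list with `reference` (anchor catalog incl. flanks), `catalogs`
#'   (named list of accession catalogs), `classes` (named vector), `truth`
#'   (data.frame `locus`, `status`), and `presence` (truth 0/1 matrix,
#'   accessions only)
#' @export
simulate_pangenome <- function(sim, plan = NULL, seed = 1L,
                               flank_bp = 200L) {
  stopifnot(inherits(sim, "mite_simulation"))
  if (is.null(plan)) plan <- sim$config$accession_plan
  if (is.null(plan$wild) || plan$wild < 1L ||
      is.null(plan$cultivar) || plan$cultivar < 1L) {
    mk_error("plan needs at least one wild and one cultivar accession",
             "mitekit_parameter_error")
  }
  with_seed(seed, {
    el <- sim$elements
    nl <- nrow(el)
    accs <- c(sprintf("wild%d", seq_len(plan$wild)),
              if (!is.null(plan$landrace) && plan$landrace > 0L)
                sprintf("landrace%d", seq_len(plan$landrace)),
              sprintf("cultivar%d", seq_len(plan$cultivar)))
    classes <- setNames(sub("[0-9]+$", "", accs), accs)
    n_ins <- plan$inserted %||% 0L
    n_lost <- plan$lost %||% 0L
    status <- rep("background", nl)
    picks <- sample.int(nl, n_ins + n_lost)
    status[picks[seq_len(n_ins)]] <- "inserted"
    status[picks[seq_len(n_lost) + n_ins]] <- "lost"
    bg_abs <- plan$background_absence %||% 0.1
    fdiv <- plan$flank_divergence %||% 0.02

    presence <- matrix(0L, nl, length(accs),
                       dimnames = list(el$element, accs))
    wild_cols <- which(classes == "wild")
    cult_cols <- which(classes == "cultivar")
    # domestication calls are pattern-defined, so a background locus must
    # not realize an inserted/lost pattern by chance (resampled if it does)
    is_dom_pattern <- function(v) {
      (all(v[cult_cols] == 1L) && all(v[wild_cols] == 0L)) ||
        (all(v[cult_cols] == 0L) && all(v[wild_cols] == 1L))
    }
    for (li in seq_len(nl)) {
      if (status[li] == "background") {
        repeat {
          v <- as.integer(runif(length(accs)) > bg_abs)
          if (sum(v) > 0L && !is_dom_pattern(v)) break
        }
        presence[li, ] <- v
      } else {
        for (ai in seq_along(accs)) {
          cl <- classes[[ai]]
          presence[li, ai] <- switch(
            status[li],
            inserted = switch(cl, cultivar = 1L, wild = 0L,
                              sample(0:1, 1L)),
            lost = switch(cl, cultivar = 0L, wild = 1L, sample(0:1, 1L)))
        }
      }
    }

    flank_of <- function(li) {
      s <- sim$genome[[el$chrom[li]]]
      tsd_len <- nchar(el$tsd[li])
      up_end <- el$start[li] - tsd_len      # exclude the TSD from anchors
      dn_start <- el$end[li] + tsd_len + 1L
      list(up = substr(s, up_end - flank_bp + 1L, up_end),
           dn = substr(s, dn_start, dn_start + flank_bp - 1L))
    }
    flanks <- lapply(seq_len(nl), flank_of)
    reference <- data.frame(
      locus = el$element, chrom = el$chrom, start = el$start, end = el$end,
      flank_up = vapply(flanks, `[[`, character(1), "up"),
      flank_down = vapply(flanks, `[[`, character(1), "dn"),
      stringsAsFactors = FALSE)

    catalogs <- list()
    for (ai in seq_along(accs)) {
      keep <- which(presence[, ai] == 1L)
      up <- reference$flank_up[keep]
      dn <- reference$flank_down[keep]
      if (fdiv > 0) {
        up <- vapply(up, function(x) {
          int_to_seq(mutate_core(seq_to_int(x), fdiv,
                                 sim$config$ts_tv_ratio))
        }, character(1), USE.NAMES = FALSE)
        dn <- vapply(dn, function(x) {
          int_to_seq(mutate_core(seq_to_int(x), fdiv,
                                 sim$config$ts_tv_ratio))
        }, character(1), USE.NAMES = FALSE)
      }
      catalogs[[accs[ai]]] <- data.frame(
        locus = reference$locus[keep], chrom = reference$chrom[keep],
        start = reference$start[keep], end = reference$end[keep],
        flank_up = up, flank_down = dn, stringsAsFactors = FALSE)
    }
    list(reference = reference, catalogs = catalogs, classes = classes,
         truth = data.frame(locus = el$element, status = status,
                            stringsAsFactors = FALSE),
         presence = presence)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
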