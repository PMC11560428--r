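# End-to-end orchestration from a single JSON config. Stages run in
# dependency order (simulate -> detect -> families -> regions/date ->
# tau/link -> mirna -> pangenome); a manifest records inputs, outputs and row
# counts; completed stages are skipped on re-run and their file outputs are
# reloaded.

STAGE_ORDER <- c("simulate", "detect", "families", "regions", "date", "tau",
                 "link", "mirna", "pangenome")
STAGE_DEPS <- list(
  simulate = character(0),
  detect = character(0),          # needs a genome: simulate or config paths
  families = "detect",
  regions = "detect",
  date = "families",
  tau = character(0),
  link = c("regions", "tau"),
  mirna = "detect",
  pangenome = "simulate"
)

#' Default pipeline parameters
#'
#' All thresholds of the individual stages, overridable per run config.
#' @return named list
#' @export
default_pipeline_params <- function() {
  list(min_tir = 10L, min_len = 50L, max_len = 800L, max_tir_mismatch = 0L,
       tsd_min = 2L, tsd_max = 10L, tsd_max_mismatch = 0L,
       require_tsd = TRUE, identity_threshold = 0.80, min_family_size = 3L,
       flank_bp = 5000L, promoter_bp = 2000L, window = 1e6,
       bin_mya = 1.0, min_peak_count = 3L, tau_min = 1.0,
       flank_identity_min = 0.9, n_tissues = 16L, frac_specific = 0.1,
       frac_uniform = 0.1, n_mirna = 60L, n_mirna_derived = 5L)
}

#' Sample miRNA precursor loci from a simulated genome
#'
#' Places `n_derived` precursors inside planted MITEs and the rest in
#' element-free background, so the MITE-derived fraction of the set is known
#' by construction.
#'
#' @param sim a `mite_simulation`
#' @param n total precursor count
#' @param n_derived precursors placed inside planted MITEs
#' @param seed integer seed
#' @param width precursor width (bp), default 120
#' @return data.frame: `chrom`, `start`, `end`, `mirna`, `truth_origin`
#' @export
simulate_mirna_loci <- function(sim, n, n_derived, seed = 1L, width = 120L) {
  stopifnot(inherits(sim, "mite_simulation"))
  if (n_derived > n) {
    mk_error("n_derived cannot exceed n", "mitekit_parameter_error")
  }
  with_seed(seed, {
    el <- sim$elements
    rows <- vector("list", n)
    host <- sample.int(nrow(el), n_derived, replace = n_derived > nrow(el))
    for (i in seq_len(n_derived)) {
      e <- el[host[i], ]
      w <- min(width, e$end - e$start)
      s <- e$start + sample.int(max(e$end - e$start - w, 1L), 1L) - 1L
      rows[[i]] <- data.frame(chrom = e$chrom, start = s, end = s + w,
                              stringsAsFactors = FALSE)
    }
    clen <- nchar(sim$genome[[1L]])
    for (i in seq.int(n_derived + 1L, length.out = n - n_derived)) {
      repeat {
        ch <- sample(names(sim$genome), 1L)
        s <- sample.int(clen - width - 400L, 1L) + 200L
        onch <- el[el$chrom == ch, , drop = FALSE]
        # keep background precursors clear of planted elements
        if (!any(onch$start <= s + width & onch$end >= s)) break
      }
      rows[[i]] <- data.frame(chrom = ch, start = s, end = s + width,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$mirna <- sprintf("miR%04d", seq_len(n))
    out$truth_origin <- rep(c("MITE-derived", "none"),
                            c(n_derived, n - n_derived))
    out
  })
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    mk_error("config must be a list or a JSON path", "mitekit_parameter_error")
  }
  config
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline from a config
#'
#' The config (list or JSON path) names the stages to run (`stages`), a
#' `seed`, an `outdir`, optional input paths (`genome`, `genes`, `fpkm`,
#' `mirna_bed`, `ltr_bed`) when not simulating, and parameter overrides
#' under `params` (see [default_pipeline_params()]). Completed stages found
#' in an existing manifest with intact outputs are skipped and reloaded.
#'
#' @param config list or JSON path
#' @return the run manifest (list), invisibly; also written to
#'   `outdir/manifest.json`
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$outdir)) mk_error("config needs outdir",
                                    "mitekit_parameter_error")
  seed <- cfg$seed %||% 1L
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages %||% STAGE_ORDER
  stages <- STAGE_ORDER[STAGE_ORDER %in% stages]
  params <- utils::modifyList(default_pipeline_params(), cfg$params %||% list())

  for (st in stages) {
    missing_dep <- setdiff(STAGE_DEPS[[st]], stages)
    if (st == "detect" && !"simulate" %in% stages && is.null(cfg$genome)) {
      missing_dep <- c(missing_dep, "simulate (or a genome path)")
    }
    if (length(missing_dep)) {
      mk_error(sprintf("stage '%s' requires stage(s): %s", st,
                       paste(missing_dep, collapse = ", ")),
               "mitekit_dependency_error")
    }
  }

  manifest_path <- file.path(outdir, "manifest.json")
  prev <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  hash <- config_hash(cfg[setdiff(names(cfg), "outdir")])
  prev_ok <- !is.null(prev) && identical(prev$config_hash, hash)

  state <- new.env(parent = emptyenv())
  manifest <- list(config_hash = hash, seed = seed,
                   version = as.character(utils::packageVersion("mitekit")),
                   stages = list())
  done <- function(name, outputs, rows) {
    manifest$stages[[name]] <<- list(outputs = outputs, rows = rows)
  }
  completed_before <- function(name, outputs) {
    prev_ok && name %in% names(prev$stages) &&
      all(file.exists(file.path(outdir, outputs)))
  }

  p <- function(...) file.path(outdir, ...)

  for (st in stages) {
    switch(st,
      simulate = {
        outs <- c("genome.fa", "genes.gff3", "elements_truth.tsv",
                  "ltr_truth.tsv")
        sim_cfg <- simulation_config(
          seed = seed,
          n_chromosomes = cfg$n_chromosomes %||% 3L,
          chrom_length = cfg$chrom_length %||% 200000L,
          n_genes = cfg$n_genes %||% 36L,
          families = default_family_specs(
            copy_number = cfg$copies_per_family %||% 65L),
          ltr_count = cfg$ltr_count %||% 12L)
        # simulation is cheap and fully seeded: always recomputed in memory
        sim <- simulate_genome(sim_cfg, outdir = outdir)
        state$sim <- sim
        state$genome <- sim$genome
        state$genes <- list(path = p("genes.gff3"))
        done(st, outs, nrow(sim$elements))
      },
      detect = {
        outs <- c("mites.bed", "mites.tsv", "mites.fa")
        if (is.null(state$genome)) state$genome <- load_genome(cfg$genome)
        if (completed_before(st, outs)) {
          cat_df <- read_tsv(p("mites.tsv"))
          class(cat_df) <- c("mite_catalog", "data.frame")
        } else {
          cat_df <- detect_mites(
            state$genome, min_tir = params$min_tir,
            min_len = params$min_len, max_len = params$max_len,
            max_tir_mismatch = params$max_tir_mismatch,
            tsd_min = params$tsd_min, tsd_max = params$tsd_max,
            tsd_max_mismatch = params$tsd_max_mismatch,
            require_tsd = params$require_tsd)
          write_bed6(cat_df, p("mites.bed"))
          write_tsv(as.data.frame(cat_df), p("mites.tsv"))
          write_fasta(element_sequences(cat_df, state$genome), p("mites.fa"))
        }
        state$catalog <- cat_df
        done(st, outs, nrow(cat_df))
      },
      families = {
        outs <- c("families.tsv", "consensus.fa", "superfamily_summary.tsv")
        seqs <- element_sequences(state$catalog, state$genome)
        tir5s <- setNames(state$catalog$tir5, state$catalog$element)
        tsds <- setNames(state$catalog$tsd, state$catalog$element)
        fams <- build_families(seqs, tir5s, tsds,
                               identity_threshold = params$identity_threshold,
                               min_family_size = params$min_family_size)
        state$families <- fams
        memb <- do.call(rbind, lapply(fams$families, function(f) {
          data.frame(family = f$id, element = f$members,
                     superfamily = f$superfamily, stringsAsFactors = FALSE)
        }))
        if (is.null(memb)) {
          memb <- data.frame(family = character(0), element = character(0),
                             superfamily = character(0))
        }
        write_tsv(memb, p("families.tsv"))
        cons <- setNames(
          vapply(fams$families, `[[`, character(1), "consensus"),
          vapply(fams$families, `[[`, character(1), "id"))
        if (length(cons)) write_fasta(cons, p("consensus.fa")) else
          file.create(p("consensus.fa"))
        lens <- setNames(state$catalog$total_length, state$catalog$element)
        ats <- setNames(state$catalog$at_fraction, state$catalog$element)
        if (nrow(memb)) {
          write_tsv(composition_stats(lens[memb$element], ats[memb$element],
                                      memb$superfamily),
                    p("superfamily_summary.tsv"))
        } else {
          file.create(p("superfamily_summary.tsv"))
        }
        done(st, outs, length(fams$families))
      },
      regions = {
        outs <- c("assignments.tsv", "region_summary.tsv",
                  "flank_segments.tsv", "window_density.tsv")
        gm <- read_gene_models(if (!is.null(cfg$genes)) cfg$genes else
                                 p("genes.gff3"))
        asg <- assign_regions(as.data.frame(state$catalog), gm,
                              flank_bp = params$flank_bp,
                              promoter_bp = params$promoter_bp)
        state$assignments <- asg
        write_tsv(as.data.frame(asg), p("assignments.tsv"))
        write_tsv(region_summary(asg), p("region_summary.tsv"))
        write_tsv(flank_segments(asg), p("flank_segments.tsv"))
        write_tsv(window_density(as.data.frame(state$catalog),
                                 vapply(state$genome, nchar, numeric(1)),
                                 window = params$window),
                  p("window_density.tsv"))
        done(st, outs, nrow(asg))
      },
      date = {
        outs <- c("ages.tsv", "age_histogram.tsv", "age_peaks.tsv")
        ages <- date_catalog(state$families)
        state$ages <- ages
        write_tsv(as.data.frame(ages), p("ages.tsv"))
        bh <- burst_histogram(ages$age_mya, bin = params$bin_mya,
                              min_peak_count = params$min_peak_count)
        write_tsv(bh$histogram, p("age_histogram.tsv"))
        write_tsv(bh$peaks, p("age_peaks.tsv"))
        done(st, outs, nrow(ages))
      },
      tau = {
        outs <- "tau.tsv"
        if (!is.null(cfg$fpkm)) {
          fpkm <- cfg$fpkm
        } else {
          n_genes <- if (!is.null(state$sim)) nrow(state$sim$genes) else 100L
          gene_ids <- if (!is.null(state$sim)) state$sim$genes$gene else NULL
          ex <- simulate_expression(n_genes, params$n_tissues,
                                    params$frac_specific,
                                    params$frac_uniform, seed = seed,
                                    gene_ids = gene_ids)
          state$expression_truth <- ex$truth
          fpkm <- ex$fpkm
        }
        taus <- compute_tau(fpkm)
        state$taus <- taus
        write_tsv(taus, p("tau.tsv"))
        done(st, outs, nrow(taus))
      },
      link = {
        outs <- "promoter_links.tsv"
        links <- promoter_specific_links(state$assignments, state$taus,
                                         tau_min = params$tau_min)
        write_tsv(links, p("promoter_links.tsv"))
        done(st, outs, nrow(links))
      },
      mirna = {
        outs <- c("mirna_origins.tsv")
        mir <- if (!is.null(cfg$mirna_bed)) read_bed(cfg$mirna_bed) else
          simulate_mirna_loci(state$sim, params$n_mirna,
                              params$n_mirna_derived, seed = seed)
        ltr_bed <- if (!is.null(cfg$ltr_bed)) read_bed(cfg$ltr_bed)
          else if (!is.null(state$sim)) {
            data.frame(chrom = state$sim$ltrs$chrom,
                       start = state$sim$ltrs$start,
                       end = state$sim$ltrs$end,
                       name = state$sim$ltrs$id, stringsAsFactors = FALSE)
          } else NULL
        orig <- call_origins(mir, as.data.frame(state$catalog), ltr_bed)
        write_tsv(orig, p("mirna_origins.tsv"))
        done(st, outs, nrow(orig))
      },
      pangenome = {
        outs <- c("presence_matrix.tsv", "domestication.tsv")
        pg <- simulate_pangenome(state$sim, seed = seed)
        mat <- match_loci(pg$reference, pg$catalogs,
                          flank_identity_min = params$flank_identity_min)
        acc_mat <- mat[, names(pg$catalogs), drop = FALSE]
        dom <- call_domestication(acc_mat, pg$classes)
        write_tsv(cbind(data.frame(locus = rownames(mat)),
                        as.data.frame(unclass(mat))),
                  p("presence_matrix.tsv"))
        dom_df <- data.frame(
          locus = c(dom$inserted, dom$lost),
          call = rep(c("inserted", "lost"),
                     c(length(dom$inserted), length(dom$lost))),
          stringsAsFactors = FALSE)
        write_tsv(dom_df, p("domestication.tsv"))
        done(st, outs, nrow(dom_df))
      })
  }
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             manifest_path)
  invisible(manifest)
}
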