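# Structural MITE detection. Candidates are inverted-repeat loci found by a
# short exact seed (default 6 bp) matched against its reverse complement
# within the maximum element span, extended inward under a mismatch budget
# and outward on exact matches only. Boundaries are then refined against TSD evidence (a MITE's
# terminal inverted repeat is flanked by a short direct repeat created at
# insertion), the TSD is verified by brute force over lengths 2-10, and
# structurally invalid or TSD-less candidates are filtered.
#
# Coordinates: candidate intervals are 0-based half-open (BED convention);
# 1-based arithmetic is used internally against the chromosome string.

DEFAULT_SEED_LEN <- 6L

kmer_codes <- function(b, n, seed_len) {
  # 4^seed_len codes for every window; NA where the window touches an N
  len <- n - seed_len + 1L
  if (len < 1L) return(list(code = numeric(0), rc = numeric(0)))
  code <- numeric(len)
  rc <- numeric(len)
  for (m in 0:(seed_len - 1L)) {
    w <- b[(1L + m):(len + m)]
    code <- code * 4 + w
    rc <- rc + (3 - w) * 4^m
  }
  list(code = code, rc = rc)
}

scan_one_chromosome <- function(seqchar, chrom, min_tir, min_len, max_len,
                                max_tir_mismatch, seed_len) {
  n <- nchar(seqchar)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), tir_length = integer(0),
                      tir_mismatches = integer(0), stringsAsFactors = FALSE)
  if (n < min_len) return(empty)
  b <- seq_to_int(seqchar)
  kc <- kmer_codes(b, n, seed_len)
  nk <- length(kc$code)

  # seed pairs: positions i and i+d whose seeds are reverse complements
  pis <- list(); pjs <- list(); cnt <- 0L
  for (d in seed_len:(max_len - seed_len)) {
    lim <- nk - d
    if (lim < 1L) break
    hit <- which(kc$rc[seq_len(lim)] == kc$code[(1L + d):nk])
    if (length(hit)) {
      cnt <- cnt + 1L
      pis[[cnt]] <- hit
      pjs[[cnt]] <- hit + d
    }
  }
  if (cnt == 0L) return(empty)
  i <- unlist(pis); j <- unlist(pjs)

  # inward extension under the mismatch budget; TIRs must end on a match and
  # leave >= 1 bp of interior between the arms
  np <- length(i)
  t_in <- rep.int(seed_len, np)       # best TIR span from the seed start
  mm_at_best <- integer(np)
  cum <- integer(np)
  active <- seq_len(np)
  m <- seed_len
  max_half <- (max_len - 1L) %/% 2L
  while (length(active) && m <= max_half) {
    p1 <- i[active] + m
    p2 <- j[active] + seed_len - 1L - m
    ok_pos <- p1 < p2                  # interior >= 1 bp
    x1 <- b[p1]; x2 <- b[p2]
    is_match <- !is.na(x1) & !is.na(x2) & (x1 == 3L - x2) & ok_pos
    cum[active] <- cum[active] + as.integer(!is_match & ok_pos)
    upd <- active[is_match & cum[active] <= max_tir_mismatch]
    t_in[upd] <- m + 1L
    mm_at_best[upd] <- cum[upd]
    active <- active[ok_pos & cum[active] <= max_tir_mismatch]
    m <- m + 1L
  }

  # outward extension on exact matches only (boundary-conservative)
  ext <- integer(np)
  L0 <- j - i + seed_len
  active <- seq_len(np)
  o <- 1L
  repeat {
    p1 <- i[active] - o
    p2 <- j[active] + seed_len - 1L + o
    ok <- p1 >= 1L & p2 <= n & (L0[active] + 2L * o) <= max_len
    x1 <- b[pmax(p1, 1L)]            # clamped: out-of-range handled via ok
    x2 <- b[pmin(p2, n)]
    is_match <- ok & !is.na(x1) & !is.na(x2) & (x1 == 3L - x2)
    ext[active[is_match]] <- o
    active <- active[is_match]
    if (!length(active)) break
    o <- o + 1L
  }

  start1 <- i - ext
  end1 <- j + seed_len - 1L + ext
  tir <- t_in + ext
  L <- end1 - start1 + 1L
  # evidence rule: at least min_tir MATCHED complementary positions, so a
  # tolerated mismatch never substitutes for matched TIR
  keep <- (tir - mm_at_best) >= min_tir &
    L >= min_len & L <= max_len & (2L * tir) <= (L - 1L)
  if (!any(keep)) return(empty)
  out <- data.frame(chrom = chrom, start = start1[keep] - 1L,
                    end = end1[keep], tir_length = tir[keep],
                    tir_mismatches = mm_at_best[keep],
                    stringsAsFactors = FALSE)
  # seeds inside one TIR converge to the same interval after extension
  out <- unique(out)
  # per start: keep the longest TIR, tie-break leftmost end
  out <- out[order(out$start, -out$tir_length, out$end), , drop = FALSE]
  out <- out[!duplicated(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

candidate_fields <- function(cand, seqs) {
  n <- nrow(cand)
  cand$total_length <- cand$end - cand$start
  cand$tir5 <- character(n)
  cand$tir3 <- character(n)
  cand$at_fraction <- numeric(n)
  for (r in seq_len(n)) {
    s <- seqs[[cand$chrom[r]]]
    el <- substr(s, cand$start[r] + 1L, cand$end[r])
    cand$tir5[r] <- substr(el, 1L, cand$tir_length[r])
    cand$tir3[r] <- substr(el, nchar(el) - cand$tir_length[r] + 1L, nchar(el))
    cand$at_fraction[r] <- at_fraction(el)
  }
  cand
}

#' Scan a genome for inverted-repeat MITE candidates
#'
#' Exact seeds (default 6 bp) are matched against their reverse complement
#' within the maximum element span, extended inward allowing up to `max_tir_mismatch`
#' mismatches (TIRs end on a match) and outward on exact matches. Candidates
#' must satisfy `tir_length >= min_tir`, `min_len <= length <= max_len`, and
#' leave at least 1 bp of interior between the TIR arms (palindromic
#' single-arm hits are rejected). Candidates are sorted by start; candidates
#' sharing a start keep the longest TIR (tie-break: leftmost end).
#'
#' @param genome named character vector, `DNAStringSet`, or FASTA path
#' @param min_tir minimum TIR length (>= the seed size), default 10
#' @param min_len,max_len element length bounds, defaults 50 and 800
#' @param max_tir_mismatch inward-extension mismatch budget, default 0
#' @param seed_len exact-match seed size in bp, default 6; smaller seeds
#'   raise sensitivity on diverged TIRs at the cost of more chance
#'   candidates
#' @return data.frame of candidates (0-based half-open `start`/`end`) with
#'   `tir_length`, `tir_mismatches`, `tir5`, `tir3`, `total_length`,
#'   `at_fraction`; no TSD fields yet (see [verify_tsd()])
#' @export
scan_inverted_repeats <- function(genome, min_tir = 10L, min_len = 50L,
                                  max_len = 800L, max_tir_mismatch = 0L,
                                  seed_len = DEFAULT_SEED_LEN) {
  seqs <- load_genome(genome)
  if (min_tir < seed_len) {
    mk_error(sprintf("min_tir below the %d bp seed size is not searchable",
                     seed_len), "mitekit_parameter_error")
  }
  parts <- lapply(names(seqs), function(ch) {
    scan_one_chromosome(seqs[[ch]], ch, min_tir, min_len, max_len,
                        max_tir_mismatch, seed_len)
  })
  out <- do.call(rbind, parts)
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), tir_length = integer(0),
                      tir_mismatches = integer(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  candidate_fields(out, seqs)
}

# longest direct repeat of length in [min_tsd, max_tsd] abutting both ends of
# the 1-based interval [s1, e1]; returns NULL or list(tsd, len, mism)
tsd_at_junction <- function(seqchar, s1, e1, min_tsd, max_tsd, max_mismatch) {
  n <- nchar(seqchar)
  for (L in seq(max_tsd, min_tsd)) {
    if (s1 - L < 1L || e1 + L > n) next
    left <- substr(seqchar, s1 - L, s1 - 1L)
    right <- substr(seqchar, e1 + 1L, e1 + L)
    mism <- sum(strsplit(left, "", fixed = TRUE)[[1L]] !=
                strsplit(right, "", fixed = TRUE)[[1L]])
    if (mism <= max_mismatch) {
      return(list(tsd = left, len = L, mism = mism))
    }
  }
  NULL
}

#' Refine candidate boundaries against TSD evidence
#'
#' Outward seed extension is boundary-conservative but can overrun the true
#' element end when the TSD itself is partially self-complementary (e.g. the
#' `TA` and `TAA` TSDs). For each candidate, trims of 0, 1, ... bp from both
#' ends are tried outermost-first and the first trim whose junctions carry an
#' exact direct repeat (2-10 bp) is adopted; failing that, a second pass
#' allows `tsd_max_mismatch` mismatches; failing both, the candidate is left
#' at its maximal extent.
#'
#' @param candidates data.frame from [scan_inverted_repeats()]
#' @param genome as in [scan_inverted_repeats()]
#' @param min_tir,min_len structural floors preserved while trimming
#' @param tsd_min,tsd_max TSD length bounds
#' @param tsd_max_mismatch mismatch tolerance of the second pass
#' @param max_trim maximum trim tried per end, default 12 bp
#' @return the candidates with adjusted intervals and TIR fields
#' @export
refine_boundaries <- function(candidates, genome, min_tir = 10L,
                              min_len = 50L, tsd_min = 2L, tsd_max = 10L,
                              tsd_max_mismatch = 0L, max_trim = 12L) {
  seqs <- load_genome(genome)
  if (nrow(candidates) == 0L) return(candidates)
  for (r in seq_len(nrow(candidates))) {
    s <- seqs[[candidates$chrom[r]]]
    s1 <- candidates$start[r] + 1L
    e1 <- candidates$end[r]
    tirl <- candidates$tir_length[r]
    L <- e1 - s1 + 1L
    tmax <- min(max_trim, tirl - min_tir, (L - min_len) %/% 2L)
    if (tmax < 0L) tmax <- 0L
    best <- NA_integer_
    for (pass_mm in unique(c(0L, tsd_max_mismatch))) {
      for (t in 0:tmax) {
        hit <- tsd_at_junction(s, s1 + t, e1 - t, tsd_min, tsd_max, pass_mm)
        if (!is.null(hit)) { best <- t; break }
      }
      if (!is.na(best)) break
    }
    if (!is.na(best) && best > 0L) {
      candidates$start[r] <- candidates$start[r] + best
      candidates$end[r] <- candidates$end[r] - best
      candidates$tir_length[r] <- tirl - best
    }
  }
  candidate_fields(candidates[, c("chrom", "start", "end", "tir_length",
                                  "tir_mismatches")], seqs)
}

#' Verify target site duplications for candidates
#'
#' The TSD is the longest flanking duplication of length `min_tsd`-`max_tsd`
#' with at most `max_mismatch` mismatches, immediately abutting both element
#' ends; absent if none. Exact duplications are preferred: when
#' `max_mismatch > 0`, a zero-mismatch pass runs first and the mismatch
#' tolerance is only used as a fallback (a short exact duplication is
#' stronger evidence than a longer one carrying mismatches, which arises
#' frequently by chance). The TSD is not part of the element interval.
#' Candidates at a chromosome edge without margin get an absent TSD and an
#' `edge_flag`.
#'
#' @param candidates data.frame of candidates (one or more rows)
#' @param genome as in [scan_inverted_repeats()]
#' @param min_tsd,max_tsd TSD length bounds, defaults 2 and 10
#' @param max_mismatch mismatch tolerance, default 0
#' @return candidates with `tsd`, `tsd_length`, `tsd_mismatches`, `edge_flag`
#' @export
verify_tsd <- function(candidates, genome, min_tsd = 2L, max_tsd = 10L,
                       max_mismatch = 0L) {
  seqs <- load_genome(genome)
  nr <- nrow(candidates)
  candidates$tsd <- NA_character_
  candidates$tsd_length <- NA_integer_
  candidates$tsd_mismatches <- NA_integer_
  candidates$edge_flag <- FALSE
  for (r in seq_len(nr)) {
    s <- seqs[[candidates$chrom[r]]]
    s1 <- candidates$start[r] + 1L
    e1 <- candidates$end[r]
    if (s1 - min_tsd < 1L || e1 + min_tsd > nchar(s)) {
      candidates$edge_flag[r] <- TRUE
      next
    }
    for (mm in unique(c(0L, max_mismatch))) {
      hit <- tsd_at_junction(s, s1, e1, min_tsd, max_tsd, mm)
      if (!is.null(hit)) {
        candidates$tsd[r] <- hit$tsd
        candidates$tsd_length[r] <- hit$len
        candidates$tsd_mismatches[r] <- hit$mism
        break
      }
    }
  }
  candidates
}

#' Filter a candidate list
#'
#' Optionally drops candidates without a verified TSD, and deduplicates
#' identical intervals (first occurrence kept). Input order is preserved.
#'
#' @param candidates data.frame with TSD fields (see [verify_tsd()])
#' @param require_tsd drop TSD-less candidates? default TRUE
#' @return filtered data.frame
#' @export
filter_candidates <- function(candidates, require_tsd = TRUE) {
  out <- candidates
  if (require_tsd && nrow(out)) {
    out <- out[!is.na(out$tsd), , drop = FALSE]
  }
  if (nrow(out)) {
    key <- paste(out$chrom, out$start, out$end)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Detect MITEs in a genome
#'
#' The full detection stage: [scan_inverted_repeats()] ->
#' [refine_boundaries()] -> [verify_tsd()] -> [filter_candidates()], with
#' element ids assigned in (chromosome, start) order.
#'
#' @inheritParams scan_inverted_repeats
#' @param tsd_min,tsd_max,tsd_max_mismatch TSD verification parameters
#' @param require_tsd drop candidates without a TSD, default TRUE
#' @param refine apply TSD-guided boundary refinement, default TRUE
#' @return a data.frame of class `mite_catalog` (BED-like 0-based half-open
#'   coordinates plus structural evidence columns and an `element` id)
#' @export
detect_mites <- function(genome, min_tir = 10L, min_len = 50L,
                         max_len = 800L, max_tir_mismatch = 0L,
                         tsd_min = 2L, tsd_max = 10L, tsd_max_mismatch = 0L,
                         require_tsd = TRUE, refine = TRUE,
                         seed_len = DEFAULT_SEED_LEN) {
  seqs <- load_genome(genome)
  cand <- scan_inverted_repeats(seqs, min_tir, min_len, max_len,
                                max_tir_mismatch, seed_len)
  if (refine) {
    cand <- refine_boundaries(cand, seqs, min_tir = min_tir,
                              min_len = min_len, tsd_min = tsd_min,
                              tsd_max = tsd_max,
                              tsd_max_mismatch = tsd_max_mismatch)
  }
  cand <- verify_tsd(cand, seqs, tsd_min, tsd_max, tsd_max_mismatch)
  cand <- filter_candidates(cand, require_tsd = require_tsd)
  cand <- cand[order(cand$chrom, cand$start, cand$end), , drop = FALSE]
  rownames(cand) <- NULL
  if (nrow(cand)) {
    cand$element <- sprintf("M%05d", seq_len(nrow(cand)))
  } else {
    cand$element <- character(0)
  }
  # structural bounds are a contract, not just a filter
  stopifnot(all(cand$total_length >= min_len),
            all(cand$total_length <= max_len),
            all(cand$tir_length >= min_tir),
            all(is.na(cand$tsd_length) |
                  (cand$tsd_length >= tsd_min & cand$tsd_length <= tsd_max)))
  class(cand) <- c("mite_catalog", "data.frame")
  cand
}

#' Extract element sequences from a catalog
#' @param catalog a `mite_catalog`
#' @param genome as in [scan_inverted_repeats()]
#' @return named character vector of element sequences
#' @export
element_sequences <- function(catalog, genome) {
  seqs <- load_genome(genome)
  out <- vapply(seq_len(nrow(catalog)), function(r) {
    substr(seqs[[catalog$chrom[r]]], catalog$start[r] + 1L, catalog$end[r])
  }, character(1))
  names(out) <- catalog$element
  out
}

#' @export
print.mite_catalog <- function(x, ...) {
  cat(sprintf("mite_catalog: %d element(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) {
    cat(sprintf("  length %d-%d bp (mean %.0f), TIR %d-%d bp, %d with TSD\n",
                min(x$total_length), max(x$total_length),
                mean(x$total_length), min(x$tir_length), max(x$tir_length),
                sum(!is.na(x$tsd))))
  }
  NextMethod()
}
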