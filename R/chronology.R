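# Insertion dating. MITEs are dated from Kimura 2-parameter (K2P) divergence
# between each family member and the family consensus, converted to age with
# T = k / (2 r) * 1e-6 Mya at a substitution rate r = 1.30e-8 per site per
# year. LTR retrotransposons are dated from the raw divergence d of the two
# LTR copies of one insertion, Jukes-Cantor corrected (K = -3/4 ln(1 - 4d/3))
# and converted with the same clock (mu = 1.3e-8).

#' Default substitution rate (substitutions / site / year)
#' @export
MITE_SUBSTITUTION_RATE <- 1.30e-8

#' Default neutral mutation rate for LTR-pair dating (per site per year)
#' @export
LTR_MUTATION_RATE <- 1.3e-8

# transition pairs: A<->G (0,2), C<->T (1,3); everything else among ACGT is a
# transversion
is_transition <- function(b1, b2) {
  abs(b1 - b2) == 2L
}

#' Kimura 2-parameter distance of a pairwise alignment
#'
#' Computes transition (P) and transversion (Q) proportions over columns where
#' both rows carry an unambiguous base (gap- and N-containing columns are
#' excluded, i.e. pairwise deletion), then
#' `k = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' @param row_a,row_b equal-length gapped rows (characters over A/C/G/T/N/-)
#' @return a list with `sites`, `transitions`, `transversions`, `P`, `Q`, `k`
#' @details When `1 - 2P - Q <= 0` or `1 - 2Q <= 0` the correction is
#'   undefined (saturation); a condition of class `mitekit_saturation` is
#'   raised and the caller is expected to exclude the pair from dating.
#' @export
#' @examples
#' k2p_distance("ACGTACGT", "ACGTACGT")$k  # 0
k2p_distance <- function(row_a, row_b) {
  if (nchar(row_a) != nchar(row_b)) {
    mk_error("aligned rows must have equal length", "mitekit_parameter_error")
  }
  a <- seq_to_int(gsub("-", "N", row_a, fixed = TRUE))
  b <- seq_to_int(gsub("-", "N", row_b, fixed = TRUE))
  ok <- !is.na(a) & !is.na(b)
  sites <- sum(ok)
  if (sites == 0L) {
    mk_error("no ungapped comparable columns", "mitekit_parameter_error")
  }
  a <- a[ok]; b <- b[ok]
  ts <- sum(is_transition(a, b))
  tv <- sum(a != b) - ts
  P <- ts / sites
  Q <- tv / sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop(errorCondition(
      sprintf("K2P saturated (P=%.3f, Q=%.3f); pair excluded from dating",
              P, Q),
      class = c("mitekit_saturation", "mitekit_error")))
  }
  k <- -0.5 * log(w1) - 0.25 * log(w2)
  list(sites = sites, transitions = ts, transversions = tv,
       P = P, Q = Q, k = k)
}

#' Convert a K2P divergence to an insertion age in Mya
#'
#' `T = k / (2 r) * 1e-6` with `r` in substitutions/site/year.
#' @param k substitutions per site (>= 0)
#' @param r substitution rate, default [MITE_SUBSTITUTION_RATE]
#' @return age in Mya
#' @export
#' @examples
#' mite_age(0.026)  # 1 Mya
mite_age <- function(k, r = MITE_SUBSTITUTION_RATE) {
  if (any(k < 0)) mk_error("k must be non-negative", "mitekit_parameter_error")
  k / (2 * r) * 1e-6
}

#' Jukes-Cantor correction and age for an LTR pair
#'
#' @param d raw mismatch fraction of the aligned LTR pair, `0 <= d < 0.75`
#' @param mu neutral mutation rate, default [LTR_MUTATION_RATE]
#' @return list with `K` (corrected divergence) and `T` (age, Mya)
#' @export
#' @examples
#' jc_age(0.1)$K  # ~0.1073
jc_age <- function(d, mu = LTR_MUTATION_RATE) {
  if (any(d < 0)) mk_error("d must be non-negative", "mitekit_parameter_error")
  if (any(d >= 0.75)) {
    stop(errorCondition("JC correction saturated at d >= 0.75",
                        class = c("mitekit_saturation", "mitekit_error")))
  }
  K <- -0.75 * log(1 - 4 * d / 3)
  list(K = K, T = K / (2 * mu) * 1e-6)
}

#' Date every family member against its family consensus
#'
#' Reuses the family alignment columns: for each member row, the columns kept
#' in the consensus are compared with the consensus symbol, K2P divergence is
#' estimated, and the age follows from [mite_age()]. Members whose divergence
#' saturates the K2P correction are reported separately, not truncated.
#'
#' @param families a `mite_families` object (see [build_families()])
#' @param r substitution rate
#' @return a data.frame of class `mite_ages` with one row per dated member
#'   (`element`, `family`, `superfamily`, `sites`, `P`, `Q`, `k`, `age_mya`);
#'   saturated members are attached as attribute `"saturated"`.
#' @export
date_catalog <- function(families, r = MITE_SUBSTITUTION_RATE) {
  if (!inherits(families, "mite_families")) {
    mk_error("families must be a mite_families object",
             "mitekit_parameter_error")
  }
  rows <- list()
  saturated <- character(0)
  for (fam in families$families) {
    if (is.null(fam$consensus) || !nzchar(fam$consensus)) {
      mk_error(sprintf("family %s has no consensus", fam$id),
               "mitekit_parameter_error")
    }
    keep <- fam$kept_columns
    cons_chars <- strsplit(fam$consensus, "", fixed = TRUE)[[1L]]
    for (m in seq_along(fam$alignment)) {
      member_row <- substring(fam$alignment[m],
                              keep, keep)  # member symbols at kept columns
      res <- tryCatch(
        k2p_distance(paste(member_row, collapse = ""),
                     paste(cons_chars, collapse = "")),
        mitekit_saturation = function(e) NULL)
      id <- names(fam$alignment)[m]
      if (is.null(res)) {
        saturated <- c(saturated, id)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        element = id, family = fam$id, superfamily = fam$superfamily,
        sites = res$sites, P = res$P, Q = res$Q, k = res$k,
        age_mya = mite_age(res$k, r), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element = character(0), family = character(0),
               superfamily = character(0), sites = integer(0),
               P = numeric(0), Q = numeric(0), k = numeric(0),
               age_mya = numeric(0))
  attr(out, "saturated") <- saturated
  class(out) <- c("mite_ages", "data.frame")
  out
}

#' Age histogram with amplification-burst detection
#'
#' Bins ages into half-open `[i*bin, (i+1)*bin)` intervals and flags peaks:
#' bins strictly greater than both neighbours (edge bins compare to their
#' single neighbour) with count at least `min_peak_count`.
#'
#' @param ages numeric vector of ages (Mya), all >= 0
#' @param bin bin width in Mya
#' @param min_peak_count minimum count for a bin to qualify as a peak
#' @return list with `histogram` (data.frame: `bin_start`, `bin_end`, `count`)
#'   and `peaks` (data.frame subset of peak bins)
#' @export
burst_histogram <- function(ages, bin = 1.0, min_peak_count = 1L) {
  if (length(ages) == 0L) {
    h <- data.frame(bin_start = numeric(0), bin_end = numeric(0),
                    count = integer(0))
    return(list(histogram = h, peaks = h))
  }
  if (any(ages < 0)) mk_error("ages must be >= 0", "mitekit_parameter_error")
  idx <- floor(ages / bin)
  nb <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = nb)
  h <- data.frame(bin_start = (seq_len(nb) - 1L) * bin,
                  bin_end = seq_len(nb) * bin,
                  count = counts)
  is_peak <- logical(nb)
  for (i in seq_len(nb)) {
    left_ok <- i == 1L || counts[i] > counts[i - 1L]
    right_ok <- i == nb || counts[i] > counts[i + 1L]
    is_peak[i] <- left_ok && right_ok && counts[i] >= min_peak_count
  }
  if (nb == 1L) is_peak[1L] <- counts[1L] >= min_peak_count
  list(histogram = h, peaks = h[is_peak, , drop = FALSE])
}

#' Date LTR retrotransposons from their LTR pairs
#'
#' Accepts either a data.frame with columns `id` and `d` (raw divergence) or
#' one with `id`, `ltr5`, `ltr3` (sequences; each pair is globally aligned and
#' `d` is the mismatch fraction over ungapped columns).
#'
#' @param pairs data.frame as described
#' @param mu neutral mutation rate
#' @return data.frame with `id`, `d`, `K`, `age_mya`; saturated pairs are
#'   attached as attribute `"saturated"`.
#' @export
date_ltr_pairs <- function(pairs, mu = LTR_MUTATION_RATE) {
  if (!all(c("id") %in% names(pairs))) {
    mk_error("pairs needs an 'id' column", "mitekit_parameter_error")
  }
  if (!"d" %in% names(pairs)) {
    if (!all(c("ltr5", "ltr3") %in% names(pairs))) {
      mk_error("pairs needs either 'd' or 'ltr5'/'ltr3' columns",
               "mitekit_parameter_error")
    }
    pairs$d <- vapply(seq_len(nrow(pairs)), function(i) {
      al <- nw_align(pairs$ltr5[i], pairs$ltr3[i])
      a <- seq_to_int(gsub("-", "N", al$a, fixed = TRUE))
      b <- seq_to_int(gsub("-", "N", al$b, fixed = TRUE))
      ok <- !is.na(a) & !is.na(b)
      sum(a[ok] != b[ok]) / sum(ok)
    }, numeric(1))
  }
  res <- lapply(pairs$d, function(d) {
    tryCatch(jc_age(d, mu), mitekit_saturation = function(e) NULL)
  })
  keep <- !vapply(res, is.null, logical(1))
  out <- data.frame(id = pairs$id[keep], d = pairs$d[keep],
                    K = vapply(res[keep], `[[`, numeric(1), "K"),
                    age_mya = vapply(res[keep], `[[`, numeric(1), "T"),
                    stringsAsFactors = FALSE)
  attr(out, "saturated") <- pairs$id[!keep]
  out
}
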