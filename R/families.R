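# Family building: greedy centroid clustering at a global-alignment identity
# threshold, center-star multiple alignment, majority-rule consensus, and
# TSD/TIR-signature superfamily classification. Family ids follow the HvX#
# convention where X encodes the superfamily (T, P, h, M, C, N).

SUPERFAMILY_LEVELS <- c("Tc1/Mariner-like", "PIF/Harbinger-like", "hAT-like",
                        "Mutator-like", "CACTA-like", "Unknown")
SUPERFAMILY_CODES <- c("Tc1/Mariner-like" = "T", "PIF/Harbinger-like" = "P",
                       "hAT-like" = "h", "Mutator-like" = "M",
                       "CACTA-like" = "C", "Unknown" = "N")

#' A/T fraction of a sequence
#'
#' `(count A + count T) / length`, with N symbols excluded from both the
#' numerator and the denominator.
#' @param x character scalar over A/C/G/T/N
#' @return fraction in `[0, 1]`
#' @export
#' @examples
#' at_fraction("GGCCTTGTTCGGTT")  # 6/14
at_fraction <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  validate_dna(x, allow_n = TRUE)
  b <- seq_to_int(x)
  n_informative <- sum(!is.na(b))
  if (n_informative == 0L) {
    mk_error("all-N sequence: A/T fraction undefined",
             "mitekit_parameter_error")
  }
  sum(b == 0L | b == 3L, na.rm = TRUE) / n_informative
}

#' Superfamily classification from TIR and TSD signatures
#'
#' Applies a rule table in order, first match wins:
#' 1. TSD `TA` -> Tc1/Mariner-like (Stowaway signature)
#' 2. TSD `TAA` or `TTA` -> PIF/Harbinger-like (Tourist signature)
#' 3. TSD length 8 -> hAT-like
#' 4. TSD length 9-10 -> Mutator-like
#' 5. TIR starting `CACT` with TSD length 2-3 -> CACTA-like
#' 6. otherwise Unknown (also when the TSD is absent)
#'
#' @param tir5 5' TIR sequence (length >= 10)
#' @param tsd TSD sequence, or `NA`/`NULL` when absent
#' @param rules optional replacement rule table: a list of functions
#'   `(tir5, tsd) -> label or NA`
#' @return superfamily label
#' @export
#' @examples
#' classify_superfamily("GGCCTTGTTCGGTT", "TAA")
classify_superfamily <- function(tir5, tsd, rules = NULL) {
  if (nchar(tir5) < 10L) {
    mk_error("tir5 must be at least 10 bp", "mitekit_parameter_error")
  }
  if (!is.null(rules)) {
    for (r in rules) {
      lab <- r(tir5, tsd)
      if (!is.na(lab)) return(lab)
    }
    return("Unknown")
  }
  no_tsd <- is.null(tsd) || length(tsd) == 0L || is.na(tsd) || !nzchar(tsd)
  if (!no_tsd) {
    tsd <- toupper(tsd)
    if (tsd == "TA") return("Tc1/Mariner-like")
    if (tsd %in% c("TAA", "TTA")) return("PIF/Harbinger-like")
    if (nchar(tsd) == 8L) return("hAT-like")
    if (nchar(tsd) %in% c(9L, 10L)) return("Mutator-like")
    if (startsWith(toupper(tir5), "CACT") && nchar(tsd) %in% c(2L, 3L)) {
      return("CACTA-like")
    }
  }
  "Unknown"
}

#' Greedy centroid clustering of element sequences
#'
#' Sequences are sorted by decreasing length; each joins the first existing
#' centroid whose global-alignment identity (end gaps included) reaches the
#' threshold, otherwise it founds a new cluster. Clusters smaller than
#' `min_family_size` are discarded and reported as singletons.
#'
#' @param sequences named character vector (names are element ids)
#' @param identity_threshold identity fraction, default 0.80
#' @param min_family_size minimum cluster size kept, default 3
#' @param prefilter skip alignments that cannot or almost surely will not
#'   reach the threshold: an exact length-ratio bound
#'   (`identity <= min(len)/max(len)`) plus a shared 12-mer screen against
#'   an inverted index (a centroid must share at least 3% of the query's
#'   12-mers to be aligned). The screen keeps clustering near-linear on
#'   catalogs dominated by unrelated singletons; disable for strict
#'   all-pairs behaviour.
#' @return list with `clusters` (list of character vectors of member ids,
#'   first member = centroid) and `singletons` (ids of discarded members)
#' @export
cluster_by_identity <- function(sequences, identity_threshold = 0.80,
                                min_family_size = 3L, prefilter = TRUE) {
  if (length(sequences) < 1L) {
    mk_error("at least one sequence required", "mitekit_parameter_error")
  }
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%04d", seq_along(sequences))
  }
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  lens <- nchar(sequences)
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < 12L) return(character(0))
    unique(substring(s, 1:(n - 11L), 12:n))
  }
  index <- new.env(hash = TRUE, parent = emptyenv())
  centroid_seq <- character(0)
  centroid_len <- integer(0)
  members <- list()
  for (i in seq_along(sequences)) {
    assigned <- FALSE
    kms <- if (prefilter) kmers_of(sequences[[i]]) else character(0)
    if (length(centroid_seq)) {
      # sequences come in decreasing length, so centroids are never shorter
      cand <- which(lens[i] / centroid_len >= identity_threshold)
      if (prefilter && length(cand) && length(kms)) {
        hits <- unlist(mget(kms, envir = index,
                            ifnotfound = list(integer(0))),
                       use.names = FALSE)
        shared <- tabulate(hits, nbins = length(centroid_seq))
        # a pair at the 0.8 identity floor shares ~0.8^12 = 7% of its
        # 12-mers in expectation; 3% is a safe screen with chance sharing
        # between unrelated sequences essentially zero
        need <- max(2L, ceiling(0.03 * length(kms)))
        cand <- cand[shared[cand] >= need]
      }
      if (length(cand)) {
        ids <- pairwise_identity_set(centroid_seq[cand], sequences[[i]])
        hit <- cand[ids >= identity_threshold]
        if (length(hit)) {
          hit <- min(hit)  # first centroid in founding order
          members[[hit]] <- c(members[[hit]], names(sequences)[i])
          assigned <- TRUE
        }
      }
    }
    if (!assigned) {
      centroid_seq <- c(centroid_seq, sequences[[i]])
      centroid_len <- c(centroid_len, lens[i])
      members[[length(members) + 1L]] <- names(sequences)[i]
      if (prefilter) {
        id <- length(centroid_seq)
        for (km in kms) {
          index[[km]] <- c(get0(km, envir = index, ifnotfound = NULL), id)
        }
      }
    }
  }
  sizes <- lengths(members)
  keep <- sizes >= min_family_size
  list(clusters = members[keep],
       singletons = unlist(members[!keep], use.names = FALSE))
}

#' Center-star multiple sequence alignment
#'
#' The center is the sequence minimising the summed pairwise distance
#' (alignment-length minus matches against every other sequence); all others
#' are pairwise-aligned to the center (match +1, mismatch -1, gap -2) and
#' merged by the once-a-gap-always-a-gap rule. Row order equals input order.
#'
#' @param sequences named character vector (>= 1)
#' @return named character vector of equal-length gapped rows
#' @export
center_star_msa <- function(sequences) {
  n <- length(sequences)
  if (n == 0L) mk_error("no sequences", "mitekit_parameter_error")
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%04d", seq_len(n))
  }
  if (n == 1L) return(sequences)
  # pick center: minimise summed pairwise distance to all others
  dist_sum <- numeric(n)
  for (i in seq_len(n)) {
    ids <- pairwise_identity_set(sequences[-i], sequences[[i]])
    dist_sum[i] <- sum(1 - ids)
  }
  c_idx <- which.min(dist_sum)
  center <- sequences[[c_idx]]
  others <- setdiff(seq_len(n), c_idx)
  Lc <- nchar(center)

  # Each pairwise alignment is decomposed into (i) the member char opposite
  # every center base and (ii) blocks of member chars inserted after each
  # center base (slot 0 = before the first base). The merged master carries,
  # after each center base, a gap block as wide as the widest insert there
  # (once a gap, always a gap); member inserts are left-aligned within it.
  parsed <- lapply(others, function(i) {
    al <- nw_align(center, sequences[[i]])
    a <- strsplit(al$a, "", fixed = TRUE)[[1L]]
    b <- strsplit(al$b, "", fixed = TRUE)[[1L]]
    is_base <- a != "-"
    slot <- cumsum(is_base)
    base_chars <- b[is_base]
    gpos <- which(!is_base)
    blocks <- split(b[gpos], factor(slot[gpos], levels = 0:Lc))
    list(base = base_chars, blocks = blocks)
  })
  G <- rep(0L, Lc + 1L)
  for (p in parsed) G <- pmax(G, lengths(p$blocks))

  assemble <- function(base_chars, blocks) {
    pieces <- character(2L * Lc + 1L)
    pieces[1L] <- paste0(paste(blocks[[1L]], collapse = ""),
                         strrep("-", G[1L] - length(blocks[[1L]])))
    if (Lc > 0L) {
      pieces[2L * seq_len(Lc)] <- base_chars
      pieces[2L * seq_len(Lc) + 1L] <- vapply(seq_len(Lc), function(s) {
        blk <- blocks[[s + 1L]]
        paste0(paste(blk, collapse = ""), strrep("-", G[s + 1L] - length(blk)))
      }, character(1))
    }
    paste(pieces, collapse = "")
  }
  empty_blocks <- split(character(0), factor(integer(0), levels = 0:Lc))
  out <- character(n)
  out[c_idx] <- assemble(strsplit(center, "", fixed = TRUE)[[1L]],
                         empty_blocks)
  for (j in seq_along(others)) {
    out[others[j]] <- assemble(parsed[[j]]$base, parsed[[j]]$blocks)
  }
  names(out) <- names(sequences)
  out
}

#' Majority-rule consensus of an alignment
#'
#' Per column the most frequent non-gap symbol wins; columns with gap
#' frequency above 50% are dropped; ties break by fixed alphabet order
#' A < C < G < T.
#'
#' @param alignment character vector of equal-length gapped rows
#' @return list with `consensus` (character scalar) and `kept_columns`
#'   (integer positions of the alignment retained in the consensus)
#' @export
#' @examples
#' build_consensus(c("ACGT", "ACGT", "ACTT"))$consensus  # "ACGT"
build_consensus <- function(alignment) {
  if (length(alignment) == 0L) {
    mk_error("empty alignment", "mitekit_parameter_error")
  }
  L <- unique(nchar(alignment))
  if (length(L) != 1L) {
    mk_error("alignment rows must have equal length",
             "mitekit_parameter_error")
  }
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  nrows <- nrow(mat)
  cons <- character(0)
  kept <- integer(0)
  for (j in seq_len(L)) {
    col <- mat[, j]
    gap_freq <- sum(col == "-") / nrows
    if (gap_freq > 0.5) next
    sym <- col[col != "-" & col != "N"]
    if (length(sym) == 0L) next  # effectively all-gap/N column
    counts <- table(factor(sym, levels = DNA_BASES))
    best <- DNA_BASES[which.max(counts)]  # which.max takes first: A<C<G<T tie
    cons <- c(cons, best)
    kept <- c(kept, j)
  }
  list(consensus = paste(cons, collapse = ""), kept_columns = kept)
}

#' Cluster, align, classify and name MITE families
#'
#' The end-to-end family stage: greedy centroid clustering
#' ([cluster_by_identity()]), center-star alignment ([center_star_msa()]),
#' majority consensus ([build_consensus()]), per-member superfamily
#' classification ([classify_superfamily()]) with a family-level majority
#' vote (ties -> Unknown), and HvX# naming in superfamily then size order.
#'
#' @param sequences named character vector of element sequences
#' @param tir5s named character vector of 5' TIRs (same names)
#' @param tsds named character vector of TSDs (`NA` = absent)
#' @param identity_threshold,min_family_size see [cluster_by_identity()]
#' @param prefix two-letter species prefix for family ids, default `"Hv"`
#' @return an object of class `mite_families`: list with `families` (each a
#'   list: `id`, `members`, `alignment`, `consensus`, `kept_columns`,
#'   `superfamily`) and `singletons`
#' @export
build_families <- function(sequences, tir5s = NULL, tsds = NULL,
                           identity_threshold = 0.80, min_family_size = 3L,
                           prefix = "Hv") {
  cl <- cluster_by_identity(sequences, identity_threshold, min_family_size)
  fams <- lapply(cl$clusters, function(ids) {
    aln <- center_star_msa(sequences[ids])
    cons <- build_consensus(aln)
    label <- "Unknown"
    if (!is.null(tir5s) && !is.null(tsds)) {
      votes <- vapply(ids, function(id) {
        t5 <- tir5s[[id]]
        if (is.null(t5) || is.na(t5) || nchar(t5) < 10L) return("Unknown")
        classify_superfamily(t5, tsds[[id]])
      }, character(1))
      tab <- table(factor(votes, levels = SUPERFAMILY_LEVELS))
      top <- which(tab == max(tab))
      label <- if (length(top) == 1L) names(tab)[top] else "Unknown"
    }
    list(members = ids, alignment = aln, consensus = cons$consensus,
         kept_columns = cons$kept_columns, superfamily = label)
  })
  # deterministic naming: by superfamily order, then decreasing size,
  # then centroid id
  if (length(fams)) {
    sf <- vapply(fams, `[[`, character(1), "superfamily")
    size <- vapply(fams, function(f) length(f$members), integer(1))
    first <- vapply(fams, function(f) f$members[1L], character(1))
    ord <- order(match(sf, SUPERFAMILY_LEVELS), -size, first)
    fams <- fams[ord]
    counter <- integer(length(SUPERFAMILY_LEVELS))
    names(counter) <- SUPERFAMILY_LEVELS
    for (i in seq_along(fams)) {
      lab <- fams[[i]]$superfamily
      counter[lab] <- counter[lab] + 1L
      fams[[i]]$id <- sprintf("%s%s%d", prefix, SUPERFAMILY_CODES[[lab]],
                              counter[lab])
    }
  }
  structure(list(families = fams, singletons = cl$singletons),
            class = "mite_families")
}

#' @export
print.mite_families <- function(x, ...) {
  cat(sprintf("mite_families: %d families, %d singleton(s)\n",
              length(x$families), length(x$singletons)))
  for (f in head(x$families, 10L)) {
    cat(sprintf("  %s  %-20s %3d members, consensus %d bp\n",
                f$id, f$superfamily, length(f$members), nchar(f$consensus)))
  }
  if (length(x$families) > 10L) cat("  ...\n")
  invisible(x)
}

#' Per-group composition statistics
#'
#' @param lengths numeric vector of element lengths (bp)
#' @param at_fracs numeric vector of per-element A/T fractions
#' @param group factor/character grouping (e.g. superfamily)
#' @return data.frame: `group`, `n`, `mean_length`, `cv_percent`
#'   (sd/mean x 100), `at_percent`
#' @export
composition_stats <- function(lengths, at_fracs, group) {
  stopifnot(length(lengths) == length(at_fracs),
            length(lengths) == length(group))
  groups <- unique(as.character(group))
  do.call(rbind, lapply(groups, function(g) {
    i <- group == g
    m <- mean(lengths[i])
    data.frame(group = g, n = sum(i), mean_length = m,
               cv_percent = if (sum(i) > 1L) sd(lengths[i]) / m * 100 else 0,
               at_percent = mean(at_fracs[i]) * 100,
               stringsAsFactors = FALSE)
  }))
}

#' Mann-Whitney rank-sum test
#'
#' U is computed from midranks; the two-sided p-value comes from exact
#' enumeration of all rank assignments when `n_a + n_b <= 12`, otherwise from
#' the normal approximation with tie and continuity corrections.
#'
#' @param a,b numeric vectors (both non-empty)
#' @return list with `U` (the U statistic of group a) and `p` (two-sided)
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
rank_sum_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) {
    mk_error("both groups must be non-empty", "mitekit_parameter_error")
  }
  n <- na + nb
  r <- rank(c(a, b))  # midranks
  Ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (n <= 12L) {
    combs <- utils::combn(n, na)
    us <- apply(combs, 2L, function(idx) {
      sum(r[idx]) - na * (na + 1) / 2
    })
    p_le <- mean(us <= Ua + 1e-9)
    p_ge <- mean(us >= Ua - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (Ua - mu - sign(Ua - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  list(U = Ua, p = p)
}
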