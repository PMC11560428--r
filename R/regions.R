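# Genomic context of elements: category flags (intergenic / genic / exon /
# intron / 5 kb flanks / 2 kb promoter), nearest-gene distances, 500 bp flank
# segmentation, 1-Mb window densities, and the chromosome length~count
# correlation. An element sets every flag whose region it overlaps by >= 1 bp
# and is counted once per category even when it spans several regions.

FLANK_BP <- 5000L
PROMOTER_BP <- 2000L

#' Assign genomic-context categories to elements
#'
#' Flags are strand-aware: the 5' flank is the 5 kb upstream of the TSS on
#' the gene's strand, the promoter is the 2 kb upstream of the gene's 5' end
#' (so promoter implies flank5), and intergenic means overlapping no gene
#' body and no +/- 5 kb flank. `flank5_dist`/`flank3_dist` give the gap in bp
#' between the element edge nearest the gene and the TSS (5' side) or gene
#' end (3' side), against the nearest flanked gene; elements touching the
#' gene itself get distance clamped to 1.
#'
#' @param elements data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and an `element` id column, or a BED path
#' @param genes a GFF3 path or the list returned by [read_gene_models()]
#' @param flank_bp flank width, default 5000
#' @param promoter_bp promoter width, default 2000
#' @return data.frame (class `region_assignment`) with logical flags
#'   `intergenic`, `genic`, `exon`, `intron`, `flank5`, `flank3`, `promoter`,
#'   plus `nearest_gene`, `nearest_dist` (signed; negative = upstream of the
#'   TSS), `promoter_gene`, `flank5_dist`, `flank3_dist`
#' @export
assign_regions <- function(elements, genes, flank_bp = FLANK_BP,
                           promoter_bp = PROMOTER_BP) {
  if (is.character(elements)) elements <- read_bed(elements)
  if (!"element" %in% names(elements)) {
    elements$element <- if ("name" %in% names(elements)) elements$name else
      sprintf("M%05d", seq_len(nrow(elements)))
  }
  gm <- if (is.list(genes) && !methods::is(genes, "GRanges")) genes else
    read_gene_models(genes)
  g <- gm$genes
  ex <- gm$exons
  el <- df_to_granges(elements)

  introns <- GenomicRanges::setdiff(g, ex, ignore.strand = TRUE)
  f5 <- GenomicRanges::flank(g, flank_bp, start = TRUE, ignore.strand = FALSE)
  f3 <- GenomicRanges::flank(g, flank_bp, start = FALSE,
                             ignore.strand = FALSE)
  pr <- GenomicRanges::flank(g, promoter_bp, start = TRUE,
                             ignore.strand = FALSE)
  f5 <- GenomicRanges::trim(f5); f3 <- GenomicRanges::trim(f3)
  pr <- GenomicRanges::trim(pr)

  ov <- function(x) GenomicRanges::countOverlaps(el, x,
                                                 ignore.strand = TRUE) > 0L
  out <- elements
  out$genic <- ov(g)
  out$exon <- ov(ex)
  out$intron <- ov(introns)
  out$flank5 <- ov(f5)
  out$flank3 <- ov(f3)
  out$promoter <- ov(pr)
  out$intergenic <- !(out$genic | out$flank5 | out$flank3)

  # nearest gene and signed distance to its TSS (negative = upstream)
  out$nearest_gene <- NA_character_
  out$nearest_dist <- NA_integer_
  out$promoter_gene <- NA_character_
  out$flank5_dist <- NA_integer_
  out$flank3_dist <- NA_integer_
  if (length(g)) {
    gid <- names(g)
    gstart <- GenomicRanges::start(g)  # 1-based
    gend <- GenomicRanges::end(g)
    gstrand <- as.character(GenomicRanges::strand(g))
    gchrom <- as.character(GenomicRanges::seqnames(g))
    es1 <- out$start + 1L  # 1-based element bounds
    ee1 <- out$end

    # gap between element and a gene's 5' (upstream) or 3' (downstream) end,
    # clamped to 1 when the element touches or overlaps the gene
    up_gap <- function(r, gi) {
      pmax(ifelse(gstrand[gi] == "-", es1[r] - gend[gi],
                  gstart[gi] - ee1[r]), 1L)
    }
    dn_gap <- function(r, gi) {
      pmax(ifelse(gstrand[gi] == "-", gstart[gi] - ee1[r],
                  es1[r] - gend[gi]), 1L)
    }
    pick <- function(r, gi, gaps) gi[order(gaps, gid[gi])[1L]]

    hit5 <- GenomicRanges::findOverlaps(el, f5, ignore.strand = TRUE)
    hit3 <- GenomicRanges::findOverlaps(el, f3, ignore.strand = TRUE)
    hitp <- GenomicRanges::findOverlaps(el, pr, ignore.strand = TRUE)
    by5 <- split(S4Vectors::subjectHits(hit5), S4Vectors::queryHits(hit5))
    by3 <- split(S4Vectors::subjectHits(hit3), S4Vectors::queryHits(hit3))
    byp <- split(S4Vectors::subjectHits(hitp), S4Vectors::queryHits(hitp))

    for (r in seq_len(nrow(out))) {
      on_chr <- which(gchrom == out$chrom[r])
      if (length(on_chr)) {
        gap <- pmax(gstart[on_chr] - ee1[r], es1[r] - gend[on_chr], 0L)
        best <- on_chr[order(gap, gid[on_chr])[1L]]
        out$nearest_gene[r] <- gid[best]
        # signed distance of the nearest element edge to that gene's TSS
        # (negative = upstream of the TSS on the gene's strand)
        if (gstrand[best] == "-") {
          tss <- gend[best]
          d <- if (es1[r] > tss) es1[r] - tss else ee1[r] - tss
          out$nearest_dist[r] <- -d
        } else {
          tss <- gstart[best]
          d <- if (ee1[r] < tss) ee1[r] - tss else es1[r] - tss
          out$nearest_dist[r] <- d
        }
      }
      key <- as.character(r)
      gi <- by5[[key]]
      if (!is.null(gi)) {
        gaps <- up_gap(r, gi)
        out$flank5_dist[r] <- min(gaps)
      }
      gi <- by3[[key]]
      if (!is.null(gi)) {
        gaps <- dn_gap(r, gi)
        out$flank3_dist[r] <- min(gaps)
      }
      gi <- byp[[key]]
      if (!is.null(gi)) {
        gaps <- up_gap(r, gi)
        out$promoter_gene[r] <- gid[pick(r, gi, gaps)]
      }
    }
  }
  stopifnot(all(!out$promoter | out$flank5),
            all(out$intergenic | out$genic | out$flank5 | out$flank3))
  class(out) <- c("region_assignment", "data.frame")
  out
}

#' Histogram of flank insertions over 10 x 500 bp segments
#'
#' Each element lying in a 5' or 3' flank increments bin
#' `ceiling(distance / seg_bp)` on that side, where the distance is measured
#' from the element edge nearest the gene; distances of 0 or less (elements
#' touching the gene) fall in bin 1.
#'
#' @param assignments data.frame from [assign_regions()]
#' @param n_segments number of bins per side, default 10
#' @param seg_bp segment width, default 500
#' @return data.frame: `side` ("5prime"/"3prime"), `bin` (1..n), `from_bp`,
#'   `to_bp`, `count`
#' @export
flank_segments <- function(assignments, n_segments = 10L, seg_bp = 500L) {
  bin_of <- function(d) pmin(pmax(ceiling(d / seg_bp), 1L), Inf)
  out <- list()
  for (side in c("5prime", "3prime")) {
    dists <- if (side == "5prime") assignments$flank5_dist else
      assignments$flank3_dist
    dists <- dists[!is.na(dists)]
    bins <- bin_of(dists)
    bins <- bins[bins <= n_segments]
    counts <- tabulate(bins, nbins = n_segments)
    out[[side]] <- data.frame(
      side = side, bin = seq_len(n_segments),
      from_bp = (seq_len(n_segments) - 1L) * seg_bp + 1L,
      to_bp = seq_len(n_segments) * seg_bp,
      count = counts, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Element counts in fixed genomic windows
#'
#' Half-open windows `[i*w, (i+1)*w)`; an element belongs to the window
#' containing its start; the final partial window is kept.
#'
#' @param elements data.frame with `chrom` and `start` (0-based)
#' @param chrom_lengths named numeric vector of chromosome lengths (bp)
#' @param window window size in bp, default 1e6
#' @return data.frame: `chrom`, `window_start`, `window_end`, `count`
#' @export
window_density <- function(elements, chrom_lengths, window = 1e6) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    nwin <- ceiling(chrom_lengths[[ch]] / window)
    starts <- elements$start[elements$chrom == ch]
    idx <- floor(starts / window) + 1L
    counts <- tabulate(idx, nbins = nwin)
    out[[ch]] <- data.frame(
      chrom = ch,
      window_start = (seq_len(nwin) - 1L) * window,
      window_end = pmin(seq_len(nwin) * window, chrom_lengths[[ch]]),
      count = counts, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Pearson correlation of per-chromosome element counts with lengths
#'
#' @param counts numeric vector of element counts (>= 3 chromosomes)
#' @param lengths numeric vector of chromosome lengths, same order
#' @return list with `r` and `p` (two-sided, t transform with n - 2 df)
#' @export
chrom_correlation <- function(counts, lengths) {
  if (length(counts) != length(lengths) || length(counts) < 3L) {
    mk_error("need matched counts and lengths for at least 3 chromosomes",
             "mitekit_parameter_error")
  }
  if (sd(counts) == 0 || sd(lengths) == 0) {
    mk_error("zero variance: correlation undefined",
             "mitekit_parameter_error")
  }
  ct <- cor.test(counts, lengths, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Per-category insertion counts
#'
#' Counts each element at most once per category; because one element can set
#' several flags, the column totals may exceed the element count.
#' @param assignments data.frame from [assign_regions()]
#' @return data.frame: `category`, `count`
#' @export
region_summary <- function(assignments) {
  cats <- c("intergenic", "genic", "exon", "intron", "flank5", "flank3",
            "promoter")
  data.frame(category = cats,
             count = vapply(cats, function(cc) sum(assignments[[cc]]),
                            integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
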