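# MITE-derived miRNA calls: a precursor locus is MITE-derived when it
# overlaps a MITE by >= 1 bp (MITE overlap wins over LTR overlap; the
# largest-overlap element is chosen within a class, ties to the lower element
# id). Mature-sequence composition is summarised per length class with T read
# as U.

#' Classify miRNA precursor origins by element overlap
#'
#' @param mirnas data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and a `mirna` (or `name`) id column, or a BED path
#' @param mites MITE intervals: data.frame/BED path with `chrom`, `start`,
#'   `end` and an id column (`element`/`name`); a `superfamily` column is
#'   carried through when present
#' @param ltrs LTR retrotransposon intervals in the same form (optional)
#' @return data.frame: `mirna`, `origin` (`MITE-derived` / `LTR-derived` /
#'   `none`), `source_id`, `superfamily`, `overlap_bp`; the MITE-derived
#'   fraction is attached as attribute `"derived_fraction"`
#' @export
call_origins <- function(mirnas, mites, ltrs = NULL) {
  as_df <- function(x) {
    if (is.character(x)) x <- read_bed(x)
    x
  }
  mirnas <- as_df(mirnas)
  if (!"mirna" %in% names(mirnas)) {
    mirnas$mirna <- if ("name" %in% names(mirnas)) mirnas$name else
      sprintf("miR%04d", seq_len(nrow(mirnas)))
  }
  mites <- as_df(mites)
  if (!is.null(ltrs)) ltrs <- as_df(ltrs)
  id_col <- function(x) {
    if ("element" %in% names(x)) x$element
    else if ("name" %in% names(x)) x$name
    else sprintf("E%05d", seq_len(nrow(x)))
  }

  out <- data.frame(mirna = mirnas$mirna, origin = "none",
                    source_id = NA_character_, superfamily = NA_character_,
                    overlap_bp = 0L, stringsAsFactors = FALSE)
  qry <- df_to_granges(mirnas)
  best_hits <- function(target) {
    tg <- df_to_granges(target)
    hits <- GenomicRanges::findOverlaps(qry, tg, minoverlap = 1L,
                                        ignore.strand = TRUE)
    if (!length(hits)) return(NULL)
    wid <- GenomicRanges::width(IRanges::pintersect(
      qry[S4Vectors::queryHits(hits)], tg[S4Vectors::subjectHits(hits)]))
    data.frame(q = S4Vectors::queryHits(hits),
               s = S4Vectors::subjectHits(hits), bp = wid)
  }
  apply_class <- function(target, label) {
    h <- best_hits(target)
    if (is.null(h)) return(invisible(NULL))
    ids <- id_col(target)
    h$id <- ids[h$s]
    h <- h[order(h$q, -h$bp, h$id), , drop = FALSE]
    h <- h[!duplicated(h$q), , drop = FALSE]
    # MITE-derived beats LTR-derived: only fill rows still unclassified
    fill <- h[out$origin[h$q] == "none", , drop = FALSE]
    out$origin[fill$q] <<- label
    out$source_id[fill$q] <<- fill$id
    out$overlap_bp[fill$q] <<- fill$bp
    if ("superfamily" %in% names(target)) {
      out$superfamily[fill$q] <<- target$superfamily[fill$s]
    }
    invisible(NULL)
  }
  if (nrow(mites)) apply_class(mites, "MITE-derived")
  if (!is.null(ltrs) && nrow(ltrs)) apply_class(ltrs, "LTR-derived")
  attr(out, "derived_fraction") <- mean(out$origin == "MITE-derived")
  out
}

#' Per-position base frequencies of mature miRNA sequences
#'
#' All sequences must share one length (group by length first); T is read as
#' U on ingest. Column frequencies sum to 1 at every position.
#'
#' @param mature character vector of mature sequences (18-30 nt)
#' @return matrix 4 x L with rows A, C, G, U
#' @export
positional_base_bias <- function(mature) {
  if (!length(mature)) mk_error("no sequences", "mitekit_parameter_error")
  lens <- unique(nchar(mature))
  if (length(lens) != 1L) {
    mk_error("mixed sequence lengths: group by length first",
             "mitekit_parameter_error")
  }
  if (lens < 18L || lens > 30L) {
    mk_error("mature sequences must be 18-30 nt", "mitekit_parameter_error")
  }
  mat <- do.call(rbind,
                 strsplit(chartr("tTuU", "UUUU",
                                 chartr("acg", "ACG", mature)), "",
                          fixed = TRUE))
  freq <- vapply(seq_len(lens), function(j) {
    tab <- table(factor(mat[, j], levels = c("A", "C", "G", "U")))
    as.numeric(tab) / nrow(mat)
  }, numeric(4))
  rownames(freq) <- c("A", "C", "G", "U")
  colnames(freq) <- seq_len(lens)
  freq
}
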