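# Pan-genome presence/absence of MITE loci. Locus orthology across
# accessions is established by flank anchoring: a reference locus is present
# in an accession when some accession locus matches both its 200 bp flanks at
# a global-alignment identity at or above the threshold, each accession locus
# consuming at most one reference locus (greedy by identity, ties leftmost).
# Domestication-inserted loci are present in every cultivar and absent from
# every wild accession; domestication-lost loci show the exact complement;
# landraces never constrain either call.

#' Match MITE loci across accession catalogs into a presence/absence matrix
#'
#' @param reference catalog data.frame: `locus`, `chrom`, `start`, `end`,
#'   `flank_up`, `flank_down` (200 bp flank sequences)
#' @param catalogs named list of accession catalogs in the same form
#'   (names = accession ids); the reference accession itself is added as the
#'   first column, all-present
#' @param flank_identity_min minimum identity of both flank alignments,
#'   default 0.9
#' @param reference_name column name for the reference accession
#' @param prefilter only align accession loci sharing at least 3% of a
#'   reference locus' upstream-flank 12-mers (inverted index screen, same
#'   rationale as in [cluster_by_identity()]); identical flanks
#'   short-circuit the aligner either way
#' @return object of class `presence_matrix`: a locus x accession 0/1 matrix
#'   with the reference catalog attached as attribute `"anchors"`
#' @export
match_loci <- function(reference, catalogs, flank_identity_min = 0.9,
                       reference_name = "reference", prefilter = TRUE) {
  need <- c("locus", "chrom", "flank_up", "flank_down")
  if (!all(need %in% names(reference))) {
    mk_error("reference catalog must carry locus ids and flank sequences",
             "mitekit_parameter_error")
  }
  for (nm in names(catalogs)) {
    if (!all(c("flank_up", "flank_down") %in% names(catalogs[[nm]]))) {
      mk_error(sprintf("catalog '%s' lacks flank sequences", nm),
               "mitekit_parameter_error")
    }
  }
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < 12L) return(character(0))
    unique(substring(s, 1:(n - 11L), 12:n))
  }
  pair_identity <- function(ref_row, acc_rows, cat_df) {
    up <- ifelse(cat_df$flank_up[acc_rows] == reference$flank_up[ref_row],
                 1, NA_real_)
    todo <- which(is.na(up))
    if (length(todo)) {
      up[todo] <- pairwise_identity_set(cat_df$flank_up[acc_rows[todo]],
                                        reference$flank_up[ref_row])
    }
    dn <- rep(NA_real_, length(acc_rows))
    ok <- which(up >= flank_identity_min)
    if (length(ok)) {
      dn[ok] <- ifelse(cat_df$flank_down[acc_rows[ok]] ==
                         reference$flank_down[ref_row], 1, NA_real_)
      todo <- ok[is.na(dn[ok])]
      if (length(todo)) {
        dn[todo] <- pairwise_identity_set(cat_df$flank_down[acc_rows[todo]],
                                          reference$flank_down[ref_row])
      }
    }
    pmin(up, dn)
  }
  nl <- nrow(reference)
  mat <- matrix(0L, nrow = nl, ncol = length(catalogs) + 1L,
                dimnames = list(reference$locus,
                                c(reference_name, names(catalogs))))
  mat[, 1L] <- 1L
  for (acc in names(catalogs)) {
    cat_df <- catalogs[[acc]]
    index <- NULL
    if (prefilter) {
      index <- new.env(hash = TRUE, parent = emptyenv())
      for (a in seq_len(nrow(cat_df))) {
        for (km in kmers_of(cat_df$flank_up[a])) {
          index[[km]] <- c(get0(km, envir = index, ifnotfound = NULL), a)
        }
      }
    }
    scored <- list(); sn <- 0L
    for (ri in seq_len(nl)) {
      ai <- which(cat_df$chrom == reference$chrom[ri])
      if (!length(ai)) next
      if (prefilter) {
        kms <- kmers_of(reference$flank_up[ri])
        hits <- unlist(mget(kms, envir = index,
                            ifnotfound = list(integer(0))),
                       use.names = FALSE)
        if (!length(hits)) next
        shared <- tabulate(hits, nbins = nrow(cat_df))
        need_k <- max(2L, ceiling(0.03 * length(kms)))
        ai <- ai[shared[ai] >= need_k]
        if (!length(ai)) next
      }
      score <- pair_identity(ri, ai, cat_df)
      ok <- which(!is.na(score) & score >= flank_identity_min)
      if (length(ok)) {
        sn <- sn + 1L
        scored[[sn]] <- data.frame(ref = ri, acc = ai[ok],
                                   score = score[ok])
      }
    }
    if (sn) {
      sc <- do.call(rbind, scored)
      sc <- sc[order(-sc$score, sc$ref, sc$acc), , drop = FALSE]
      used_acc <- logical(nrow(cat_df))
      used_ref <- logical(nl)
      for (r in seq_len(nrow(sc))) {
        if (used_acc[sc$acc[r]] || used_ref[sc$ref[r]]) next
        used_acc[sc$acc[r]] <- TRUE
        used_ref[sc$ref[r]] <- TRUE
        mat[sc$ref[r], acc] <- 1L
      }
    }
  }
  structure(mat, anchors = reference, class = c("presence_matrix", "matrix"))
}

#' Call domestication-inserted and domestication-lost loci
#'
#' @param matrix locus x accession 0/1 matrix ([match_loci()] output or any
#'   matrix with locus rownames)
#' @param classes named character vector mapping accession ids to classes
#'   (`wild`, `landrace`, `cultivar`)
#' @return list with `inserted` and `lost` locus id vectors
#' @export
call_domestication <- function(matrix, classes) {
  accs <- colnames(matrix)
  if (is.null(classes) || !all(accs %in% names(classes))) {
    mk_error("every accession column needs a class label",
             "mitekit_parameter_error")
  }
  cls <- classes[accs]
  wild <- which(cls == "wild")
  cult <- which(cls == "cultivar")
  if (!length(wild) || !length(cult)) {
    mk_error("need at least one wild and one cultivar accession",
             "mitekit_parameter_error")
  }
  all_cult <- rowSums(matrix[, cult, drop = FALSE] == 1L) == length(cult)
  no_cult <- rowSums(matrix[, cult, drop = FALSE] == 1L) == 0L
  all_wild <- rowSums(matrix[, wild, drop = FALSE] == 1L) == length(wild)
  no_wild <- rowSums(matrix[, wild, drop = FALSE] == 1L) == 0L
  inserted <- rownames(matrix)[all_cult & no_wild]
  lost <- rownames(matrix)[no_cult & all_wild]
  stopifnot(length(intersect(inserted, lost)) == 0L)
  list(inserted = inserted, lost = lost)
}

#' Split loci into conserved and non-conserved classes
#'
#' In cross-species mode a locus present in every species is conserved; all
#' others are non-conserved (a partition of the locus set).
#'
#' @param matrix locus x species 0/1 matrix
#' @param assignments optional [assign_regions()] output keyed by locus id in
#'   its `element` column; when given, per-class promoter fractions are
#'   attached
#' @return list with `conserved`, `non_conserved`, and (when `assignments`
#'   given) `summary` (per class: n, promoter fraction)
#' @export
conservation_classes <- function(matrix, assignments = NULL) {
  if (ncol(matrix) < 2L) {
    mk_error("need at least 2 species", "mitekit_parameter_error")
  }
  pres <- rowSums(matrix == 1L)
  conserved <- rownames(matrix)[pres == ncol(matrix)]
  non_conserved <- setdiff(rownames(matrix), conserved)
  out <- list(conserved = conserved, non_conserved = non_conserved)
  if (!is.null(assignments)) {
    frac <- function(ids) {
      sub <- assignments[assignments$element %in% ids, , drop = FALSE]
      if (!nrow(sub)) return(c(n = 0L, promoter_frac = NA_real_))
      c(n = nrow(sub), promoter_frac = mean(sub$promoter))
    }
    out$summary <- rbind(conserved = frac(conserved),
                         non_conserved = frac(non_conserved))
  }
  out
}
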