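# Tissue specificity. The tau index of an expression profile x_1..x_N is
# sum_i (1 - x_i / x_max) / (N - 1): 1 for absolute specificity to a single
# tissue, 0 for equal expression everywhere. Replicates are averaged to
# per-tissue means upstream; no pseudocount is applied.

#' Tissue-specificity index tau of one expression profile
#'
#' @param x numeric vector of per-tissue mean FPKM values (length >= 2,
#'   all >= 0)
#' @return tau in `[0, 1]`
#' @details Profiles with `max(x) == 0` have no defined tau; a
#'   `mitekit_parameter_error` is raised and callers such as [compute_tau()]
#'   skip the gene with a log entry instead.
#' @export
#' @examples
#' tau_index(c(0, 0, 7.3, 0))  # 1
#' tau_index(c(4, 4, 4, 4))    # 0
tau_index <- function(x) {
  if (length(x) < 2L) {
    mk_error("tau requires at least 2 tissues", "mitekit_parameter_error")
  }
  if (any(x < 0) || any(is.na(x))) {
    mk_error("FPKM values must be non-negative and non-missing",
             "mitekit_parameter_error")
  }
  xmax <- max(x)
  if (xmax == 0) {
    mk_error("all-zero profile: tau undefined", "mitekit_parameter_error")
  }
  sum(1 - x / xmax) / (length(x) - 1L)
}

#' Compute tau for every gene of an FPKM matrix
#'
#' @param fpkm numeric matrix or data.frame, genes in rows (rownames = gene
#'   ids or a `gene` first column), tissues in columns. A TSV path is also
#'   accepted (header row of tissue names, first column gene ids).
#' @return data.frame with `gene` and `tau`; genes with all-zero profiles are
#'   skipped and listed in attribute `"skipped"`.
#' @export
compute_tau <- function(fpkm) {
  if (is.character(fpkm) && length(fpkm) == 1L) {
    fpkm <- read.table(fpkm, header = TRUE, sep = "\t", row.names = 1L,
                       check.names = FALSE)
  }
  if (is.data.frame(fpkm)) {
    if ("gene" %in% names(fpkm)) {
      rn <- fpkm$gene
      fpkm <- as.matrix(fpkm[setdiff(names(fpkm), "gene")])
      rownames(fpkm) <- rn
    } else {
      fpkm <- as.matrix(fpkm)
    }
  }
  if (ncol(fpkm) < 2L) {
    mk_error("tau requires at least 2 tissues", "mitekit_parameter_error")
  }
  ok <- apply(fpkm, 1L, max) > 0
  taus <- apply(fpkm[ok, , drop = FALSE], 1L, tau_index)
  out <- data.frame(gene = rownames(fpkm)[ok], tau = unname(taus),
                    stringsAsFactors = FALSE)
  skipped <- rownames(fpkm)[!ok]
  if (length(skipped)) {
    message(sprintf("compute_tau: skipped %d all-zero gene(s)",
                    length(skipped)))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Link promoter MITE insertions to tissue-specific downstream genes
#'
#' Joins region assignments (see [assign_regions()]) with per-gene tau values
#' and keeps elements carrying the promoter flag whose nearest gene has
#' `tau >= tau_min`.
#'
#' @param assignments data.frame from [assign_regions()]
#' @param taus data.frame with `gene` and `tau` (from [compute_tau()])
#' @param tau_min minimum tau for a link, default 1.0 (absolute specificity)
#' @return data.frame sorted by gene id: `element`, `gene`, `tau`, and, when
#'   present in `assignments`, `total_length` and `superfamily`
#' @export
promoter_specific_links <- function(assignments, taus, tau_min = 1.0) {
  stopifnot(is.data.frame(assignments), is.data.frame(taus))
  prom <- assignments[assignments$promoter, , drop = FALSE]
  # the gene whose promoter is hit is the promoter gene recorded per element
  gene_col <- if ("promoter_gene" %in% names(prom)) "promoter_gene"
              else "nearest_gene"
  idx <- match(prom[[gene_col]], taus$gene)
  miss <- !is.na(prom[[gene_col]]) & is.na(idx)
  if (any(miss)) {
    warning(sprintf("%d promoter element(s) reference genes absent from the tau table; skipped",
                    sum(miss)))
  }
  keep <- !is.na(idx) & taus$tau[idx] >= tau_min
  out <- data.frame(element = prom$element[keep],
                    gene = prom[[gene_col]][keep],
                    tau = taus$tau[idx[keep]],
                    stringsAsFactors = FALSE)
  for (extra in c("total_length", "superfamily")) {
    if (extra %in% names(prom)) out[[extra]] <- prom[[extra]][keep]
  }
  out[order(out$gene, out$element), , drop = FALSE]
}
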