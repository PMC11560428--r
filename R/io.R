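# Format edges: FASTA via Biostrings, GFF3/BED via rtracklayer, tab-separated
# truth and result tables via base R. Internal coordinates are 0-based
# half-open; GFF3 is converted on ingest (1-based inclusive) and BED written
# as-is.

# Accepts a named character vector, a Biostrings::DNAStringSet, or a FASTA
# path; returns a named character vector of upper-case sequences.
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      names(genome) <- sprintf("chr%d", seq_along(genome))
    }
    return(toupper(genome))
  }
  mk_error("genome must be a named character vector, DNAStringSet, or FASTA path",
           "mitekit_parameter_error")
}

#' Write sequences as 60-column wrapped FASTA
#' @param seqs named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 60L)
  invisible(path)
}

#' Write a catalog as BED6
#'
#' 0-based half-open intervals, name = element id, score 0, strand `+`.
#' @param catalog data.frame with `chrom`, `start`, `end` and an id column
#'   (`element` or `name`)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed6 <- function(catalog, path) {
  id <- if ("element" %in% names(catalog)) catalog$element else catalog$name
  df <- data.frame(catalog$chrom, catalog$start, catalog$end, id, 0L, "+")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a 0-based half-open data.frame
#' @param path BED path (3+ columns)
#' @return data.frame with `chrom`, `start`, `end`, and `name` when present
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

# data.frame (0-based half-open) -> GRanges
df_to_granges <- function(df, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (is.null(strand)) "*" else strand)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 path (or a GRanges already holding `type` and `ID`
#'   metadata columns)
#' @return list with `genes` (GRanges, names = gene ids) and `exons`
#'   (GRanges with a `gene` metadata column)
#' @export
read_gene_models <- function(path) {
  gr <- if (methods::is(path, "GRanges")) path else
    rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  names(genes) <- genes$ID
  exons <- gr[gr$type == "exon"]
  # resolve exon -> gene through the Parent chain (exon -> mRNA -> gene)
  mrna <- gr[gr$type == "mRNA"]
  mrna_parent <- setNames(as.character(unlist(mrna$Parent)), mrna$ID)
  exon_parent <- as.character(unlist(exons$Parent))
  exons$gene <- ifelse(exon_parent %in% names(mrna_parent),
                       mrna_parent[exon_parent], exon_parent)
  if (any(GenomicRanges::start(exons) <
            GenomicRanges::start(genes[exons$gene]) |
          GenomicRanges::end(exons) >
            GenomicRanges::end(genes[exons$gene]))) {
    mk_error("malformed gene model: exon outside its gene",
             "mitekit_annotation_error")
  }
  list(genes = genes, exons = exons)
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon features (1-based inclusive) with ID/Parent links.
#' @param genes data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `gene` id, and a list-column `exon_starts`/`exon_ends`
#'   (0-based half-open, relative to the chromosome)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (r in seq_len(nrow(genes))) {
    g <- genes$gene[r]
    lines <- c(lines,
      sprintf("%s\tmitekit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              genes$chrom[r], genes$start[r] + 1L, genes$end[r],
              genes$strand[r], g),
      sprintf("%s\tmitekit\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              genes$chrom[r], genes$start[r] + 1L, genes$end[r],
              genes$strand[r], g, g))
    es <- genes$exon_starts[[r]]
    ee <- genes$exon_ends[[r]]
    for (k in seq_along(es)) {
      lines <- c(lines,
        sprintf("%s\tmitekit\texon\t%d\t%d\t.\t%s\t.\tID=%s.1.exon%d;Parent=%s.1",
                genes$chrom[r], es[k] + 1L, ee[k], genes$strand[r], g, k, g))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
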