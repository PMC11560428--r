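# Genomic context: category flags, flank segmentation, window densities,
# chromosome correlation.

# one '+' gene at [1000, 2000) with a single exon, on a 20 kb chromosome
simple_models <- function(strand = "+") {
  genes <- data.frame(gene = "G0001", chrom = "chr1", start = 1000L,
                      end = 2000L, strand = strand,
                      stringsAsFactors = FALSE)
  genes$exon_starts <- list(1000L)
  genes$exon_ends <- list(2000L)
  tmp <- tempfile(fileext = ".gff3")
  write_gff3(genes, tmp)
  read_gene_models(tmp)
}

test_that("region flags follow the worked examples", {
  gm <- simple_models()
  els <- data.frame(chrom = "chr1",
                    start = c(1100L, 400L, 8000L),
                    end = c(1200L, 450L, 8100L),
                    element = c("e1", "e2", "e3"),
                    stringsAsFactors = FALSE)
  asg <- assign_regions(els, gm)
  expect_true(asg$genic[1L] && asg$exon[1L])
  expect_false(asg$intergenic[1L])
  # 550-600 bp upstream of the TSS: flank5 and promoter
  expect_true(asg$flank5[2L] && asg$promoter[2L])
  expect_equal(asg$promoter_gene[2L], "G0001")
  expect_equal(asg$flank5_dist[2L], 551L)
  # > 5 kb from the gene: intergenic only
  expect_true(asg$intergenic[3L])
  expect_false(asg$genic[3L] || asg$flank5[3L] || asg$flank3[3L])
  # upstream elements carry a negative signed distance to the TSS
  expect_lt(asg$nearest_dist[2L], 0L)
})

test_that("introns are genic but not exonic", {
  genes <- data.frame(gene = "G0001", chrom = "chr1", start = 1000L,
                      end = 3000L, strand = "+", stringsAsFactors = FALSE)
  genes$exon_starts <- list(c(1000L, 2500L))
  genes$exon_ends <- list(c(1500L, 3000L))
  tmp <- tempfile(fileext = ".gff3")
  write_gff3(genes, tmp)
  gm <- read_gene_models(tmp)
  els <- data.frame(chrom = "chr1", start = 1700L, end = 1800L,
                    element = "e1", stringsAsFactors = FALSE)
  asg <- assign_regions(els, gm)
  expect_true(asg$genic && asg$intron)
  expect_false(asg$exon)
})

test_that("flank segmentation assigns the stated bins", {
  gm <- simple_models()
  els <- data.frame(chrom = "chr1",
                    start = c(350L, 2000L, 1000L - 5001L - 50L),
                    end = c(400L, 2050L, 1000L - 5001L),
                    element = c("up600", "dn1", "up5001"),
                    stringsAsFactors = FALSE)
  asg <- assign_regions(els, gm)
  seg <- flank_segments(asg)
  # 600 bp upstream -> 5' bin 2 (the 501-1000 bp segment)
  expect_equal(seg$count[seg$side == "5prime" & seg$bin == 2L], 1L)
  # 1 bp downstream of the gene end -> 3' bin 1
  expect_equal(seg$count[seg$side == "3prime" & seg$bin == 1L], 1L)
  # 5001 bp upstream lies outside the flank: contributes to no bin
  expect_equal(sum(seg$count), 2L)
})

test_that("reversing the gene strand swaps 5' and 3' flank assignments", {
  els <- data.frame(chrom = "chr1", start = c(400L, 2300L),
                    end = c(450L, 2350L), element = c("up", "dn"),
                    stringsAsFactors = FALSE)
  plus <- assign_regions(els, simple_models("+"))
  minus <- assign_regions(els, simple_models("-"))
  expect_identical(plus$flank5, minus$flank3)
  expect_identical(plus$flank3, minus$flank5)
  expect_identical(plus$flank5_dist, minus$flank3_dist)
})

test_that("promoter counts never exceed 5'-flank counts", {
  run <- aged_run()
  tmp <- tempfile(fileext = ".gff3")
  write_gff3(run$sim$genes, tmp)
  asg <- assign_regions(run$sim$elements[, c("chrom", "start", "end",
                                             "element")],
                        read_gene_models(tmp))
  expect_true(all(!asg$promoter | asg$flank5))
  s <- region_summary(asg)
  expect_lte(s$count[s$category == "promoter"],
             s$count[s$category == "flank5"])
  # every element carries at least one flag; multi-counting can exceed n
  expect_true(all(asg$intergenic | asg$genic | asg$flank5 | asg$flank3))
  expect_gte(sum(s$count), nrow(asg))
})

test_that("window densities use half-open windows and conserve totals", {
  els <- data.frame(chrom = "chr1",
                    start = c(0, 5e5, 999999, 1e6, 15e5),
                    end = c(100, 5e5 + 100, 1e6 + 50, 1e6 + 100, 15e5 + 80),
                    stringsAsFactors = FALSE)
  wd <- window_density(els, c(chr1 = 2e6))
  expect_equal(nrow(wd), 2L)
  expect_equal(wd$count, c(3L, 2L))  # start at exactly 1e6 -> window 2
  expect_equal(sum(wd$count), nrow(els))
  # partial final window is kept
  wd2 <- window_density(els[1L, ], c(chr1 = 1.5e6))
  expect_equal(nrow(wd2), 2L)
  expect_equal(wd2$window_end[2L], 1.5e6)
})

test_that("chromosome correlation handles the worked examples", {
  got <- chrom_correlation(c(10, 20, 30, 40), c(1e6, 2e6, 3e6, 4e6))
  expect_equal(got$r, 1)
  got <- chrom_correlation(c(40, 30, 20, 10), c(1e6, 2e6, 3e6, 4e6))
  expect_equal(got$r, -1)
  got <- chrom_correlation(c(2, 1, 4, 3), c(1, 2, 3, 4))
  expect_equal(got$r, 0.6)
  ref <- cor.test(c(2, 1, 4, 3), c(1, 2, 3, 4))
  expect_equal(got$p, ref$p.value)
  expect_error(chrom_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "mitekit_parameter_error")
  expect_error(chrom_correlation(c(1, 2), c(1, 2)),
               class = "mitekit_parameter_error")
})
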