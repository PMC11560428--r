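# mitekit

Genome-wide characterization of **miniature inverted-repeat transposable
elements (MITEs)** in R, at desk scale. MITEs are short (50–800 bp)
non-autonomous Class II transposons bounded by terminal inverted repeats
(TIRs ≥ 10 bp) and flanked by target site duplications (TSDs, 2–10 bp)
created at insertion. They are the most gene-associated repeat class in
plant genomes — inserting into promoters and introns, seeding miRNAs, and
segregating between wild and cultivated germplasm — which makes their
structural annotation, family classification and insertion dating a
recurring need for anyone studying cereal genome evolution.

mitekit implements that workflow as a set of composable, deterministic
stages:

1. **Detection** — seed-and-extend inverted-repeat scan with TSD-guided
   boundary refinement and brute-force TSD verification
   (`detect_mites()`, `scan_inverted_repeats()`, `verify_tsd()`).
2. **Families** — greedy centroid clustering at 80% global-alignment
   identity, center-star multiple alignment, majority-rule consensus, and
   TIR/TSD-signature superfamily classification with `HvX#` naming
   (`build_families()`, `classify_superfamily()`).
3. **Genomic context** — intergenic/genic/exon/intron/flank/promoter flags,
   500 bp flank segmentation, 1-Mb window densities
   (`assign_regions()`, `flank_segments()`, `window_density()`).
4. **Chronology** — each member is dated against its family consensus with
   the Kimura 2-parameter distance
   `k = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` and the molecular clock
   `T = k / (2r) x 1e-6` Mya at `r = 1.30e-8` substitutions/site/year;
   LTR retrotransposons are dated from LTR-pair divergence with the
   Jukes–Cantor correction `K = -3/4 ln(1 - 4d/3)` at `mu = 1.3e-8`
   (`date_catalog()`, `jc_age()`, `burst_histogram()`).
5. **Expression** — the tissue-specificity index
   `tau = sum_i (1 - x_i / x_max) / (N - 1)` over per-tissue mean FPKM, and
   promoter-insertion links to maximally specific genes
   (`tau_index()`, `promoter_specific_links()`).
6. **miRNA origins** — MITE-derived miRNA calls by precursor/element
   interval overlap (`call_origins()`, `positional_base_bias()`).
7. **Pan-genome** — flank-anchored locus matching across accessions into a
   presence/absence matrix, and domestication-inserted / -lost calls
   (present in all cultivars and no wild accession, or the reverse)
   (`match_loci()`, `call_domestication()`, `conservation_classes()`).
8. **Synthetic data** — a ground-truth simulator that plants MITE families
   with superfamily-specific TIR/TSD signatures and age-dependent
   substitution loads (`k = 2 r T`, the exact inverse of the dating model)
   into multi-chromosome genomes with gene models, LTR elements, FPKM
   matrices and pan-genome accessions (`simulate_genome()`,
   `simulate_expression()`, `simulate_pangenome()`).

A pipeline driver (`run_pipeline()`) chains the stages from one JSON config
and writes a reproducible run manifest; `inst/scripts/mitekit` exposes every
stage as a shell command.

## Worked example

```r
library(mitekit)

cfg <- simulation_config(seed = 42, n_chromosomes = 2, chrom_length = 120000,
                         n_genes = 16,
                         families = default_family_specs(copy_number = 12),
                         ltr_count = 4)
sim <- simulate_genome(cfg)
sim
#> mite_simulation: 2 chromosome(s) x 120000 bp, 16 genes, 96 MITEs (8 families), 4 LTR elements

catalog <- detect_mites(sim$genome, max_tir_mismatch = 2, tsd_max_mismatch = 1)
fams <- build_families(element_sequences(catalog, sim$genome),
                       setNames(catalog$tir5, catalog$element),
                       setNames(catalog$tsd, catalog$element))
fams
#> mite_families: 15 families, 1151 singleton(s)
#>   HvT1  Tc1/Mariner-like       9 members, consensus 180 bp
#>   HvT2  Tc1/Mariner-like       5 members, consensus 133 bp
#>   ...

ages <- date_catalog(fams)
head(as.data.frame(ages)[, c("element", "family", "k", "age_mya")], 3)
#>   element family          k  age_mya
#> 1  M00684   HvT1 0.06389293 2.457420
#> 2  M00812   HvT1 0.04027484 1.549032
#> 3  M01010   HvT1 0.05174465 1.990179

burst_histogram(ages$age_mya, min_peak_count = 3)$peaks
#>   bin_start bin_end count
#> 3         2       3    35
```

The 96 planted copies carry substitution loads drawn from a bimodal age
mixture centred on 2.5 Mya; dating the recovered families against their
consensus sequences returns the recent amplification burst as a peak in the
[2,3) Mya bin. The detector reports every structurally valid
inverted-repeat locus (here 1248 candidates); clustering separates the
planted families from chance structure, which remains as singletons. The
two index identities behave as defined: a single-tissue profile gives
`tau_index(c(0, 0, 7.3, 0)) = 1`, a uniform one gives
`tau_index(c(4, 4, 4, 4)) = 0`, and `mite_age(0.026) = 1` Mya under the
default clock.

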