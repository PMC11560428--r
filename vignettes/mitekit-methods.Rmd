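---
title: "Models and methods behind mitekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mitekit annotates miniature inverted-repeat transposable elements (MITEs)
and places them in evolutionary and regulatory context. This vignette is
the package's own account of the models it implements, the parameters that
matter, the numerical choices behind them, and what the synthetic-data
tests do and do not demonstrate.

# The element model

A MITE is modelled structurally: a 50–800 bp interval whose two ends are
reverse-complementary over at least 10 bp (the terminal inverted repeats,
TIRs) and which is flanked on both sides by a direct repeat of 2–10 bp (the
target site duplication, TSD) created by staggered-cut insertion. The TSD
is evidence *about* the element, not part of it: element intervals run
TIR…TIR, and TSD coordinates are reported separately. All internal
coordinates are 0-based half-open (BED convention); GFF3 is converted on
ingest.

## Detection

`scan_inverted_repeats()` finds candidate loci by seed-and-extend:

* every exact `seed_len`-mer (default 6 bp) is matched against its reverse
  complement within the maximal element span;
* the implied TIR is extended inward under a mismatch budget
  (`max_tir_mismatch`, default 0), with two rules — a TIR must end on a
  matching pair, and at least `min_tir` *matched* pairs are required, so a
  tolerated mismatch never substitutes for matched TIR;
* extension proceeds outward only on exact matches, keeping reported
  boundaries conservative;
* TIR arms may not overlap (at least 1 bp of interior), which rejects
  palindromic single-arm hits;
* candidates sharing a start keep the longest TIR (tie: leftmost end), and
  output order is (chromosome, start, end), so runs are byte-stable.

The 6 bp seed is a sensitivity choice: with an 8 bp seed, TIRs of realistic
length (14–22 bp) that have accumulated ~6% per-site divergence frequently
retain no intact 8 bp complementary run, and recall on such copies drops
well below the level the rest of the pipeline needs. The shorter seed
recovers them at the cost of more chance candidates; downstream family-size
filtering absorbs that cost (chance loci are mutually unrelated and remain
singletons).

`refine_boundaries()` then reconciles boundaries with TSD evidence. Partial
self-complementarity of real TSDs (e.g. `TA`, whose reverse complement is
itself) makes the maximal inverted-repeat extent overshoot the true element
by a few bases; trims are therefore tried outermost-first and the first
junction carrying an exact 2–10 bp direct repeat is adopted (a
mismatch-tolerant pass is a fallback). `verify_tsd()` applies the same
exact-first preference: a short exact duplication is stronger evidence than
a longer one carrying mismatches, because ≥4 bp near-duplications arise
frequently by chance.

Known limitation: on strongly diverged copies whose candidate starts inside
the TIR, refinement can settle on an internal micro-duplication (2 bp
self-reverse-complementary words such as `GC` inside a TIR mimic a TSD).
This truncates some old copies and weakens their TSD-based classification;
family-level majority voting absorbs most of it, and classification is most
reliable for recent elements.

# Families, consensus, classification

`cluster_by_identity()` is greedy centroid clustering: sequences sorted by
decreasing length; each joins the first centroid whose global-alignment
identity (match +1, mismatch −1, gap −2; end gaps included in the
denominator) reaches `identity_threshold` (default 0.80), else founds a
cluster; clusters under `min_family_size` (default 3) are reported as
singletons. Including end gaps is deliberate: MITEs are full-length
elements and boundary divergence should count against identity. Two exact
screens keep clustering near-linear — `identity <= min(len)/max(len)` (an
algebraic bound) and a shared 12-mer index (a pair at the 0.80 floor shares
~7% of its 12-mers in expectation; candidates under 3% are not aligned;
settable off via `prefilter = FALSE`).

`center_star_msa()` replaces an external multiple aligner: the center
minimizes summed pairwise distance, all others are pairwise-aligned to it
(same scoring), and gaps merge under once-a-gap-always-a-gap. Because the
mutation model used in validation introduces no indels, the center-star
approximation is exact there; on real data it is the usual center-star
2-approximation. `build_consensus()` takes the most frequent non-gap symbol
per column, drops gap-majority columns, and breaks ties by fixed alphabet
order A < C < G < T — determinism is preferred over randomized tie-breaks.

`classify_superfamily()` applies literature TSD/TIR signatures in order:
`TA` → Tc1/Mariner-like (Stowaway), `TAA`/`TTA` → PIF/Harbinger-like
(Tourist), 8 bp TSD → hAT-like, 9–10 bp → Mutator-like, `CACT` TIR prefix
with a 2–3 bp TSD → CACTA-like, otherwise Unknown. The table is
config-overridable (`rules` argument). Families take the majority label of
their members (ties → Unknown) and are named `HvX#` with X in
{T, P, h, M, C, N}.

# Dating

Member-versus-consensus divergence is measured by the Kimura 2-parameter
distance over the family alignment columns retained in the consensus, with
pairwise deletion of gap/N columns:

$$k = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q)$$

with transition proportion P (A↔G, C↔T) and transversion proportion Q.
Ages follow the molecular clock $T = k/(2r) \times 10^{-6}$ Mya with
$r = 1.30\times10^{-8}$ substitutions/site/year; the same clock dates LTR
retrotransposon insertions from LTR-pair raw divergence d via Jukes–Cantor,
$K = -\tfrac34\ln(1-4d/3)$, $T = K/(2\mu)\times10^{-6}$,
$\mu = 1.3\times10^{-8}$. Both rates are per site per year — the only
reading under which the outputs are Mya. Saturated comparisons
($1-2P-Q \le 0$, $1-2Q \le 0$, or $d \ge 0.75$) are excluded and reported,
never truncated to a maximum age, which would fabricate an age mode at the
cap.

`burst_histogram()` bins ages into half-open 1-Mya bins; a peak is a bin
strictly greater than both neighbours with at least `min_peak_count`
members (default 3 in the pipeline). The strict-maximum-plus-floor
definition is the package's own — amplification bursts are reported
narratively in the literature, and a fixed rule keeps the call
reproducible.

# Expression and miRNA links

The tissue-specificity index over per-tissue mean FPKM values is
$\tau = \sum_i (1 - x_i/x_{\max})/(N-1)$: 1 for single-tissue expression, 0
for uniform expression. Replicate averaging is arithmetic and happens
upstream; no pseudocount is applied, and all-zero genes are skipped rather
than assigned a value. `promoter_specific_links()` joins elements carrying
the promoter flag (2 kb upstream of the gene's 5' end, strand-aware) to the
τ of their promoter gene, keeping genes with τ ≥ `tau_min` (default 1.0,
absolute specificity).

miRNA origin calls use bare interval intersection with a documented 1 bp
minimum overlap, strand-agnostic; MITE overlap outranks LTR overlap and the
largest-overlap element wins within a class (ties to the lower element id).

# Pan-genome calls

Locus orthology across accessions is established by flank anchoring: a
reference locus is present in an accession when some accession locus
matches both of its 200 bp flanks at global-alignment identity ≥ 0.9, each
accession locus consuming at most one reference locus (greedy by identity).
This stands in for block-synteny mapping because the domestication call
needs locus orthology, not collinearity. Domestication-inserted loci are
present in every cultivar and absent from every wild accession;
domestication-lost loci show the exact complement; landraces are recorded
but never constrain either call. Cross-species conservation uses the same
matcher (a lower identity, 0.75, is exposed for that mode) and partitions
loci into conserved (present in all species) versus non-conserved.

# The synthetic-data generator

`simulate_genome()` produces the study conditions every stage is validated
against: 3 chromosomes × 200 kb of random background (A/T fraction 0.55,
a cereal-like intergenic composition), 36 non-overlapping gene models with
1–3 exons, eight planted MITE families (two Stowaway-like with `TA` TSDs,
two Tourist-like with `TAA`, one hAT-like with an 8 bp TSD, one
Mutator-like with 9 bp, one CACTA-like, one Unknown; TIRs 14–36 bp; totals
156–462 bp; 65 copies each = 520 elements), and 12 LTR retrotransposons.
Insertion ages are drawn from the bimodal mixture 0.7·N(2.5, 0.5) +
0.3·N(12.5, 1.0) Mya — a strong recent burst plus a smaller old one — and
each copy is mutated at `k = 2 r T`, the exact inverse of the dating model,
using the K2P single-site transition probabilities at divergence k (so the
K2P estimator is unbiased at the target by construction). The
transition:transversion rate ratio defaults to 2.0, a typical plant nuclear
value; it is a configurable guess, not a measured one. LTR elements carry
two copies that each diverge independently for half the pair divergence
under the 1:2 (Jukes–Cantor) substitution split.

Deliberate idealizations, and what they imply about the tests:

* **No indels.** Dating stays exact on the truth and alignments are
  trivial; real MITE copies accumulate indels, so real-data identity and
  dating carry extra noise the tests do not measure.
* **Elements are written over background, not inserted**, so coordinates
  never shift and the truth table stays exact.
* **Junction sanitation.** Background bases adjacent to each un-mutated
  planted element are resampled so the planted boundary is the unique
  structurally supported one (outward complementarity stops at the TSD; no
  chance exact direct repeat at an outer junction; default TSD strings are
  chosen so their last base does not complement their first). Real genomes
  contain genuinely ambiguous junctions; perfect boundary recovery at age 0
  is therefore a property of identifiable truth, not a claim about real
  data.
* **TSDs mutate with the locus**, so TSD evidence decays realistically with
  age and the detector's mismatch tolerance is actually exercised.
* **Uniform placement** (outside exons, with a 30 bp spacing margin) gives
  region statistics a known null; insertion-site preference near genes
  exists as a config option and is off by default.
* **Background presence/absence vectors** in the pan-genome simulator are
  resampled if they would realize a domestication pattern by chance — the
  call is pattern-defined, and at 2 wild + 2 cultivar accessions chance
  mimicry would otherwise be common.

# Validation scale and determinism

The test suite validates parameter recovery on one 600 kb genome with 520
planted elements (detection recall on recent copies, cluster purity against
truth labels, a dating slope of estimated versus true age within
[0.9, 1.1], burst bins at 2–3 and 12–13 Mya, and exact domestication
calls), sizes chosen so the full suite runs in minutes on one core while
keeping ≥ 150 elements per age mode. Every stochastic step runs under a
caller-supplied seed through an RNG-scoping helper, so identical configs
produce byte-identical outputs and the pipeline manifest reproduces row
counts across reruns.

# Known limitations

* The detector is structural only; it reports every qualifying
  inverted-repeat locus and relies on family-size filtering for
  specificity. Precision as such is not a validated quantity.
* Superfamily calls rest on TSD signatures plus one TIR prefix; TIR-profile
  similarity beyond that is not modelled, and heavily diverged copies may
  classify as Unknown.
* Center-star alignment is a 2-approximation on indel-rich real data; an
  external aligner can be substituted upstream of `build_consensus()`.
* The clock assumes a single substitution rate; rate variation across
  families or genomic context is not modelled.
* Flank anchoring assumes locus flanks are orthologous and alignable at
  ≥ 0.9 identity; structural variation in flanks will read as absence.
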