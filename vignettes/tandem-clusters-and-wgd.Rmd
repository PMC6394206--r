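---
title: "Methods: tandem gene clusters, repeat arrays, and Ks-based WGD inference"
author: "dupscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tandem gene clusters, repeat arrays, and Ks-based WGD inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupscan)
```

dupscan implements the downstream analyses that turn an annotated plant
genome assembly into statements about tandem gene duplication and
whole-genome duplication (WGD): physical gene-cluster detection for
specialized-metabolism families such as terpene synthases (TPS) and
cytochrome P450s (CYP), telomere and rDNA tandem-array detection, assembly
contiguity metrics, synonymous-rate (Ks) estimation for paralog pairs with
Gaussian-mixture and SiZer analysis, and expression-divergence
classification of duplicated gene copies.  This vignette records the models,
the parameters that matter, the numerical choices, and the design decisions
taken where the methods literature leaves the procedure open.

## Physical (tandem) gene clusters

A physical cluster is a run of same-family gene loci on one pseudomolecule
in which every pair of consecutive members satisfies two rules:

1. at most `max_intervening_genes` annotated loci lie strictly between the
   two members (default 10, inclusive bound), and
2. the distance between the two members is less than
   `max_pair_distance_bp` (default 100 kbp, strict bound).

Several readings of "pairwise gene distance" are possible; dupscan measures
the *inter-gene gap* between gene spans, `start(right) - end(left) - 1`,
floored at 0 for overlapping loci, and applies the rule to *consecutive*
members (single-linkage chaining).  The all-pairs reading would sit
awkwardly beside rule 1, which is inherently a consecutive-pair condition,
and chaining is the common operational choice in cluster surveys; a cluster
spanning more than 100 kbp through a chain of nearby genes is therefore
allowed.  The stricter all-pairs variant is available via
`detect_clusters(..., all_pairs = TRUE)`.

Clustering operates on gene *loci*, not mRNA isoforms (`read_gff3()` keeps
only the configured locus feature), strand is ignored, and unplaced
scaffolds participate like any other sequence.  Maximality is guaranteed by
construction: the chain breaks exactly where a rule fails, and the suite
checks detected clusters against an independent union-find oracle on random
annotations.  Two-family co-clusters (`co_clusters()`) are detected on the
union of both member sets, keeping clusters that contain at least one gene
of each family.

## Family candidate filtering

`assign_family()` applies the standard two-part candidate filter for
similarity-based family annotation: a peptide qualifies iff its length is at
least 350 amino acids *and* its best hit against the family reference set
has at least 30% identity.  Both rejection clauses are verbatim "shorter
than" / "less than" rules, so the boundaries (exactly 350 aa, exactly 30.0%)
are accepted.  "Best hit" is the bitscore-maximal hit, with ties broken by
lower e-value and then lexicographic subject id — identity of the
best-scoring alignment, not the maximum identity over all hits, which keeps
the call deterministic.  Families defined by a diagnostic domain rather than
a curated reference set (CYPs via Pfam PF00067) use
`assign_family_by_domain()` on an externally produced domain-hit list; the
similarity/domain searches themselves are out of scope and consumed as
tables.

## Telomere tracts and monomer arrays

`find_telomere_tracts()` scans for exact copies of the plant
(Arabidopsis-type) telomere repeat `TTTAGGG` — the motif is a parameter, as
telomere repeats differ between lineages — on both strands, chains
consecutive copies separated by at most `max_gap_bp` (default 21 bp, three
motif lengths, so isolated interstitial matches do not bridge), and reports
tracts of at least `min_copies` copies (default 10).  Tracts within
`end_window_bp` (default 100 kbp) of a sequence end are flagged `at_end`,
the signature of a complete chromosome arm.

`find_monomer_arrays()` is query-driven: the user supplies a monomer
consensus (e.g. a 5S rDNA unit) and the detector seeds candidate copies
with exact 15-mers taken every 15 bp along the monomer, scores each
candidate by ungapped percent identity (default threshold 80%), and chains
co-oriented copies whose start-to-start spacing is at most 1.5 monomer
lengths.  The reported period is the median start-to-start spacing, which
tolerates point mutations but not large indels; de novo period discovery
(a TRF-style tandem repeat finder) is deliberately out of scope.  With the
substitution-only mutation model of the simulator, every planted copy
carries at least one intact seed with overwhelming probability, so
zero-noise recovery is exact — a property the acceptance suite asserts.

## Assembly contiguity metrics

`nx()` uses the standard definition: the length at which the cumulative sum
of descending-sorted lengths first reaches x% of the assembly total, with
the crossing sequence included.  `assembly_summary()` reports count, total,
maximum, minimum, N50, N90 and the mean rounded half-up to an integer
(matching how such tables are printed); `size_class_table()` reports
cumulative size, percent (2 decimals) and count per threshold.

## Ks estimation (NG86) and paralog pairing

The paralog-age chain is a transparent, self-contained equivalent of the
established paralog-age pipelines: reciprocal protein self-hits
(`pair_paralogs()`, default e-value ≤ 1e-10, alignment ≥ 100 aa, self-hits
removed), one CDS per locus chosen as the longest isoform (ties by gene
id), global protein alignment under BLOSUM62 with affine gaps
(opening 10, extension 1), codon threading of the CDS onto the protein
alignment, and Nei–Gojobori (1986) counting with Jukes–Cantor correction:

* synonymous sites per codon are the fraction of the three possible changes
  at each position that preserve the amino acid (changes to stop codons
  count as nonsynonymous), averaged over the two sequences;
* differences in codons with 2–3 changes are averaged over all minimal
  substitution pathways, excluding pathways through stop codons (falling
  back to all pathways in the rare case every pathway is blocked);
* codons containing gaps, ambiguous bases, or stops are skipped;
* `ks = -3/4 log(1 - 4/3 ps)`; when `4/3 ps >= 1` (or `pn` likewise) the
  pair is flagged saturated and excluded from downstream fitting.

The per-codon site and pathway tables are precomputed once, so estimation
is a vector lookup; the suite checks the fast path against a literal
string-manipulation re-implementation and against a hand-counted example
(`ng86_ks("TTTGCTAAA", "TTCGCTAAA")`: S = 5/3, ps = 0.6, Ks ≈ 1.2071).
Codon-model maximum-likelihood estimators and among-site rate variation are
out of scope.

## Mixture modelling and SiZer corroboration

Ks values are analysed inside the window [0.01, 2.0] (configurable):
near-zero pairs are dominated by alleles and identical annotations, and
values approaching saturation carry little signal.  `fit_gmm()` fits
Gaussian mixtures by EM for K = 1..5, ten k-means++-initialized restarts
per K, convergence when the log-likelihood gain falls below 1e-8 (at most
500 iterations), a variance floor of 1e-6 against singular components, and
BIC for model selection (BIC rather than AIC: mixture order selection with
free variances overfits under AIC).  The window truncates the upper
component slightly (a truncated-normal mean shift of about −0.01 for a
component at 1.36 with sd 0.30), well inside the ±0.05 recovery tolerance
the suite demands.

Mixture components are descriptive; whether a peak is a real feature is
delegated to a SiZer map (`sizer()`): for a grid of locations and log-spaced
bandwidths (default 11 bandwidths spanning 1/5× to 5× the normal-reference
bandwidth), the Gaussian-kernel density-derivative estimate and its standard
error classify each cell as significantly increasing, decreasing, flat, or
sparse (effective sample size below 5).  Row-wise simultaneous confidence
intervals use the Chaudhuri–Marron independent-blocks quantile with
m(h) = range/(2h) blocks.  SiZer runs on raw (not log-transformed) Ks
values, matching how Ks histograms are usually displayed.  A mode
(`significant_modes()`) is an increase region followed in x by a decrease
region, supported over a contiguous bandwidth range; `modes_at_bandwidth()`
answers the common question "how many modes at the normal-reference
bandwidth".

## Expression QC and divergence classification

Replicate QC follows the conventional rule: Pearson correlation of raw FPKM
between biological replicates, pass when r exceeds 0.94; failing replicates
are replaced by a designated surviving replicate (a configuration choice,
never auto-selected).  The high-confidence gene set is the evidence OR
rule: FPKM > 0 in any library (strictly greater; this is an evidence rule,
distinct from the expression threshold below) or a Pfam match.

No printed criterion exists for "expression neofunctionalization" of tandem
copies, so the package states one explicitly: for each pair of cluster
members, Pearson correlation of log2(FPKM+1) across tissues, and the
expressed-tissue sets at FPKM ≥ 1; a pair is *diverged* iff r < 0.5 or the
expressed sets are disjoint.  A member is *constitutive* iff FPKM ≥ 1 in
every tissue.  Both thresholds are parameters of
`classify_cluster_expression()`.

## The synthetic-data generator

`simulate_genome()`, `simulate_ks_pairs()` and `simulate_expression()`
define the package's reference study conditions; they are first-class,
tested code, fully deterministic given their config seed.

**Genome** (`genome_sim_config()`): three 1-Mbp pseudomolecules, 240 gene
loci of 0.5–3 kbp, uniform base composition (25% each).  Planted content: a
five-copy TPS cluster (20 kbp gaps, 2 intervening genes), a two-copy TPS
cluster (50 kbp, 5), a three-copy CYP cluster (30 kbp, 3) and a mixed
TPS/CYP co-cluster (15 kbp, 1); telomere tracts at three pseudomolecule
ends (50, 50 and 30 copies; left ends carry the reverse-complement motif,
as a left assembly end is the reverse-complemented 3′ telomere); one
5S-like array of 135 copies of a random 496-bp monomer at 1% per-copy
substitution — the copy number and period mirror the scale of a real 5S
array resolved by long reads.  Planted clusters are placed with a 150-kbp
buffer so that distinct clusters can never chain under the default distance
rule; intervening background genes are laid out inside the configured gaps,
and all remaining genes are placed uniformly without overlap.

**Ks pairs** (`ks_sim_config()`): 3000 pairs; per pair the target Ks is
drawn from the mixture with weights (0.3, 0.5, 0.2), means (0.22, 0.60,
1.36) and sds (0.06, 0.15, 0.30); a random stop-free 240-codon ancestor is
duplicated and the copies accumulate substitutions — synonymous accepted
always, nonsynonymous with probability 0.2 (ka/ks = 0.2), stops rejected —
until the pair's NG86 Ks first crosses `target − 0.02`.  Targeting is
iterative with re-measurement because pathway averaging makes closed-form
forward calibration awkward.  Two resolution notes: 240 codons make the Ks
increment of one synonymous substitution (≈ 6/S near Ks = 1.4) smaller than
the targeting tolerance, and the first-crossing stop rule leaves a small
negative bias (median ≈ −0.015) with occasional overshoot past +0.02 where
a single substitution jumps further than the tolerance window; both effects
are far inside the ±0.05 recovery tolerance on component means.  The inner
mutate-and-update loop is implemented in C++ (each step is O(1) through
incremental bookkeeping of the same NG86 tables the R estimator uses).

**Expression** (`expression_sim_config()`): six tissues × two replicates,
200 background genes (log2 profiles: gene effect N(3, 1.5), tissue effect
N(0, 1)), 20 planted diverged pairs (complementary on/off tissue halves,
on ≈ 32 FPKM, off < 1 FPKM) and 20 planted conserved pairs (shared profile,
tissue sd 2), per-gene lognormal noise sd 0.3 shared by replicates.
Replicate noise is calibrated so the *raw-FPKM* correlation matches the
target (default 0.98): the required log-scale correlation is backed out
through the lognormal moment relation
`r_raw = (exp(rho_log * s2) − 1) / (exp(s2) − 1)`.

What the generator does *not* emulate: repeat landscapes and transposons,
intron structure, GC heterogeneity, alignment/annotation errors, isoform
mixtures, indel evolution in paralogs, and count-level expression noise.
Passing tests therefore demonstrate correctness of the detectors and
estimators under their stated models, not robustness to every artifact of
real assemblies.

## Problem sizes and runtime envelope

The test and acceptance workloads are sized for a desk run: 1000 random
length lists (up to 10⁴ sequences) for the contiguity oracle, 200 random
annotations (≤ 500 genes) for the cluster oracle, 20 seeds × 3000 pairs for
mixture recovery, 50 replicates of n = 500 for the SiZer mode checks, and
50 seeds × 40 planted pairs for the expression classifier.  The full suite
runs in a few minutes on one CPU.

## Known limitations

* The cluster rule is annotation-relative: a missed locus changes both the
  intervening count and, potentially, chaining.
* NG86 underestimates Ks at high divergence relative to ML codon models;
  the [0.01, 2] window limits, but does not remove, this.
* SiZer's independent-blocks quantile is an approximation; extremely small
  effective sample sizes are masked as sparse rather than tested.
* The monomer-array detector assumes the supplied consensus is close
  (≥ 80% identity) to the true monomer and does not model higher-order
  repeat structure.
* Expression divergence calls inherit the arbitrariness of the r < 0.5 and
  FPKM ≥ 1 thresholds; they are reported as explicit parameters rather than
  facts of nature.
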