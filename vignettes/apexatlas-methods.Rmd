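---
title: "Methods: models, parameters and design choices in apexatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in apexatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

apexatlas reimplements, as one tested toolkit, the analysis chain used to
dissect gene expression across the ten microdissected domains of the
maize shoot apex: the whole meristem, its stem-cell tip (the central
zone, CZ), the incipient leaf (P0) and successive leaf primordia
(P1–P3), the L1 and L2 clonal layers, the internode and the vasculature.
This vignette explains each statistical component, the tunable
parameters, what the bundled synthetic-data generator does and does not
emulate, and the choices made where the methods literature leaves the
design open.

## Normalization and expression filtering

Counts are normalized to reads per million (RPM),
`RPM = 1e6 * count / library_total`. No gene-length correction is
applied: the toolkit targets 3'-anchored, linearly amplified libraries
in which read yield is independent of transcript length, so RPKM-style
normalization would *introduce* a length bias rather than remove one.
Domain profiles are means of replicate RPM columns. A gene counts as
expressed when its mean reaches **2 RPM** (inclusive) in at least one
domain; the threshold is a conventional detection floor for amplified
micro-dissected material and is exposed as `min_rpm` everywhere it is
used. Pairwise relatedness between libraries or domains uses Pearson
correlation restricted, for each pair, to the genes expressed in at
least one member of that pair, so the large never-expressed fraction
cannot inflate similarity.

## Entropy-based domain specificity

For each gene the domain profile is converted to fractions
`p_t = x_t / sum(x)` and scored with Shannon entropy
`H = -sum p_t log2 p_t` (bits), with `0·log 0 = 0` and no pseudocount —
a perfectly specific gene therefore scores exactly 0, and a uniform gene
scores `log2(10) ≈ 3.32`. Genes with `H < 2.33` bits are called
domain-specific; the permissive cutoff reflects the partial physical
overlap of the captured domains (e.g. the meristem capture contains the
tip). The assigned domain is the argmax of the profile, with ties broken
by the canonical domain order and flagged. Entropy is computed on
replicate-mean profiles, not per replicate: the expression filter is
defined on means, and means are the quantity the specificity call should
describe; this is recorded as an assumption. `calibrate_se_cutoff()`
additionally fits a chi-square distribution to the score distribution by
moment matching (df = mean) with a Pearson goodness-of-fit test over
equal-probability bins, as a shape diagnostic before trusting a fixed
cutoff; it never moves the cutoff.

## Differential expression

The DE module implements the classic negative-binomial
exact-conditional test: median-of-ratios size factors (computed over
genes with nonzero counts in every library), method-of-moments
dispersion `alpha` in `Var = mu + alpha*mu^2` pooled within groups, and
a two-sided exact test on the split of the two group sums given their
total, summing the probabilities of all splits no more likely than the
observed one; BH correction with significance at `q < 0.01`. With two
replicates per group, per-gene dispersion estimates are extremely noisy,
so each gene's estimate is floored at a log-linear mean–dispersion trend
fitted across genes — deliberately conservative, in the spirit of
"maximum of fit and estimate" sharing. Two numerical notes: group-sum
distributions are NB with moment-matched size parameters and fall back
to Poisson when the matched variance does not exceed the mean; and
because the test conditions on a discrete total, multiplying one
library's counts by a constant changes the conditioning set, so p-values
under depth rescaling are reproduced to a tight numerical tolerance
rather than exactly (size factors absorb the rescaling; the tests check
rank agreement above 0.99 and call agreement above 98%).

## Dynamic genes and CAST clustering

Genes changing at least two-fold between any two of (meristem, Tip, P0,
P1, P2, P3) — after flooring profiles at 1 RPM to stabilize ratios
against zeros — are clustered with the Cluster Affinity Search Technique
over pairwise Spearman rank correlation, with affinity threshold
`t = 0.8` on the *correlation* scale (a 0.8 threshold is only meaningful
there, matching the common correlation-based CAST convention). The
original CAST leaves processing order open; for determinism this
implementation opens each cluster with the unassigned gene of maximal
total similarity to the remaining unassigned genes (ties to the
smallest identifier), alternates one-at-a-time ADD and REMOVE phases
with recomputation, and sorts gene identifiers up front so the output is
invariant to input row order. Cluster count is emergent, never forced.

Cluster composites are means of per-gene max-rescaled profiles — raw-RPM
means would let a handful of highly expressed members dictate the
shape. Composites are classified into archetypes by ordered rules on the
rescaled profile (peak domain plus low-expression constraints at 0.3,
a high-expression constraint at 0.8 for the meristem+Tip "core" class,
and Spearman ≥ 0.9 against ontogeny rank for monotone leaf gradients).
These thresholds formalize qualitative profile descriptions and are
exposed as arguments of `classify_cluster_archetype()`.

A structural caveat worth knowing: Spearman correlation over six
tissues is rank-coarse, so any gene whose profile merely shares a
cluster's rank order — however shallow its gradient — can legitimately
join that cluster. On simulated data this admits marginal two-fold
background genes into archetype clusters and dilutes their composites;
archetype recovery is therefore assessed on clusters of the planted
archetype genes, where the classifier's input matches its design.

## TF PCA and family correlation

Each expressed TF is standardized to zero mean, unit variance across the
ten domains (gene-wise standardization is the only choice that makes
family means comparable), and PCA is run with domains as observations.
The first three components are retained by default. Each PC is oriented
so its largest-magnitude domain score is positive, fixing the sign
convention across linear-algebra backends. A TF family's profile is the
per-domain mean of its members' *standardized* expression — raw-RPM
averaging (available via `raw_profiles=`) would let one abundant member
swamp the family signal — and is correlated (Pearson) with each PC's
domain scores; `|r| >= 0.6` flags a family as correlated, with
singletons reported but flagged rather than dropped. Cumulative signed
profiles simply sum member RPM per domain for the positively and
negatively correlated family sets. Family membership enrichment in any
gene set uses the two-sided Fisher exact test with BH correction.

## Promoter motifs and the GRN

Promoters are the 1,500-base window from 1 kb upstream to 500 bp
downstream of the TSS in transcribed orientation; since "downstream"
includes the TSS itself as its first base, the window is
`[TSS-1000, TSS+499]` on the plus strand and the mirror image on the
minus strand, truncated and flagged at chromosome ends. The TSS is the
annotated gene start on its strand. Neighbouring-gene overlap is not
masked.

PWMs are read from MEME minimal format with pseudocount mixing
`M <- (1-4e)M + e` (default `e = 0.01`) and scored as log2 odds against
the genome's mononucleotide background (uniform fallback). The match
threshold is calibrated *exactly*: the distribution of the window score
under the background is computed by dynamic programming over a
discretized score grid (10,000 bins; per-position contributions rounded
to the grid, so DP tails are exact at bin resolution and are verified
against exhaustive enumeration for short motifs), and the threshold is
the smallest score whose upper-tail probability is at most the
per-window p-value, default `1e-4`, minus half a grid bin so that exact
scores rounding into the boundary bin still pass. Scanning slides over
both strands; overlapping matches count separately; windows containing
ambiguous bases are skipped.

Motif enrichment is gene-level presence/absence (≥ 1 match) of the
foreground set against the full scanned background, with hit-rate fold
change, two-sided Fisher p and BH q per PWM, and per-family summaries as
the union of member-PWM hits. The GRN is the edge table family → gene
(plus TF → gene for designated foreground TFs), with the per-gene count
of distinct matched families as the combinatorial-regulation summary.

## Enrichment statistics

All gene-set summaries use divergence from expectation,
`D = (O - E)/sqrt(E)`, with significance from a chi-square test with
Yates' continuity correction (per-cell correction capped at `|O-E|` so
it never overshoots past zero; df = 1, upper tail). Entropy-binned
target enrichment partitions expressed genes into 20 equal-width bins on
`[0, log2 10]` (equal-count binning available via `scheme = "count"`;
the bin boundaries are an assumption since only the bin count is
conventional). Trait-associated SNP (TAS) proximity uses a 10-kb window
measured arithmetically from the SNP position to the gene-body interval
— a SNP 10,001 bp from a gene start is *not* near — with two ordered
deduplication rules: per trait, a gene with several SNPs counts once;
per category, a gene with several same-category traits counts once. The
expectation denominator is the expressed genes near any TAS of the
tested set, with `E = |nearTAS| * |set| / |expressed|`. Annotation-term
enrichment is the plain upper-tail hypergeometric test with BH
correction (no length-bias correction; that is out of scope). Note the
Yates correction makes all of these tests mildly conservative; the null
calibration tests measure the pooled type-I rate at 400-gene target sets
where the conservativeness is modest.

## Cross-species conservation rules

Domain-specific maize genes are checked against Arabidopsis reference
domain profiles (AtHB8, S17shoot, WUS, CLV3, FIL, HDG4, HMG, KAN1, LAS).
Each class rule optionally excludes domains (profiles are renormalized
afterwards), requires a defining domain strictly above 25% relative
expression, and requires named domains strictly below 20%. Orthologs are
tested first, then near-paralogs, both in identifier order with
first-success semantics so the call is order-independent; genes absent
from the ortholog map return "no-ortholog".

## The synthetic-data generator

`simulate_atlas()` draws counts from a negative binomial with
`Var = mu + alpha*mu^2` (default `alpha = 0.05`, a standard
overdispersion magnitude for RNA-seq; no published dispersion estimates
exist for amplified micro-dissection libraries, so this is a stand-in,
not a calibration). Baselines are log-normal (log2 mean 5, sd 2) for a
realistic dynamic range; expected library size is 1e6. Every gene gets
per-domain log-normal wobble (log2 sd 0.25) as mild biological
cross-domain variation; setting it to 0 together with zero planted
signal yields an exact DE null.

Planted structure defines the ground truth:

* **Specific genes** (25 per domain, 5% of the transcriptome — the
  proportion typical of entropy-based specificity screens at this
  domain count) are on/off: multiplier 10 in the defining domain, 0.2
  elsewhere. A flat 10-fold elevation over an otherwise uniform profile
  would give `H = 2.50 > 2.33` identically — no cutoff recovers such
  genes — so specificity is modelled as expression presence with 20%
  leakage, which matches how domain-specific genes actually look and
  keeps the planted defining-domain fold at or above the configured
  value.
* **Archetype genes** (40 per archetype) follow strictly graded
  templates whose six rank vectors are mutually well separated (maximum
  cross-archetype Spearman 0.43). Both properties are load-bearing:
  rank-tied "low" tissues would randomize within-archetype Spearman
  below the 0.8 affinity, and rank-coincident templates (e.g. a core
  template that is merely a damped CZ) would be indistinguishable to a
  rank-based similarity however different their magnitudes.
* **TF families**: 300 TFs in 20 families; three families are biased 5x
  high and three 0.2x low in meristem+Tip, giving the PCA a planted
  axis.
* **Promoter motifs**: one pseudo-chromosome per 500 genes with 20-kb
  gene spacing (so 10-kb SNP windows rarely straddle two genes), i.i.d.
  uniform nucleotides, and a width-9 consensus PWM planted into CZ
  promoters at rate 0.5 and background promoters at 0.05, in random
  orientation, with a never-planted decoy PWM of the same shape. Width
  9 is chosen so that at the default `1e-4` calibration the threshold
  admits only exact consensus matches and the genomic chance-hit rate
  per 1.5-kb promoter (~2%) is negligible against the planted rates;
  at width 8 chance hits alone would contribute a ~9% background rate
  and the planted/background contrast would no longer reflect the
  configured rates.
* **SNPs**: architectural-trait SNPs fall within 10 kb of a random
  planted-archetype ("dynamic-truth") gene with probability 0.8, else
  uniformly; non-architectural SNPs are uniform.
* **Targets**: a 400-gene set sampled with 4:1 weight toward planted
  specific/archetype genes, giving the low-entropy bin bias the binned
  enrichment should detect.

Determinism: one seed drives everything, with per-component sub-seeds
derived arithmetically so that, e.g., SNP placement does not shift when
count sampling changes.

What the generator does **not** emulate: amplification and 3'-coverage
bias, mappability, splice isoforms, correlated domain overlap (each
domain's counts are sampled independently given the multipliers), linkage
between SNPs, promoter sequence composition beyond i.i.d. nucleotides,
and realistic motif degeneracy (planted sites are exact consensus).
Passing the recovery tests therefore demonstrates that the algorithms
are implemented correctly and are well calibrated under a faithful
statistical cartoon of the study design — not that real tissue
dissections would yield these recovery rates.

## Problem sizes and runtime choices

The test suite runs the reference conditions at 5,000 genes x 20
libraries (specificity, DE, clustering, TAS), 2,000 genes for the motif
recovery study over 20 seeds, 600-gene atlases for unit fixtures, and
1,000 resamplings for the null-calibration study. These sizes keep each
simulation's Monte-Carlo error well below the margins being asserted
while the whole suite stays desk-scale.

## Known limitations

* The NB exact test enumerates all splits of a gene's pooled count; for
  very deep libraries (group totals in the millions) a normal
  approximation would be needed.
* CAST is O(n^2) in the dynamic-gene count; tens of thousands of genes
  would need a compiled similarity kernel.
* The DP threshold is exact only at grid resolution (10,000 bins);
  motifs with pathological score ranges could in principle need a finer
  grid.
* Conservation classification depends entirely on the supplied ortholog
  map and reference profiles; no sequence-level orthology is computed.
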