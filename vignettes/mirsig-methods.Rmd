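---
title: "Methods and design of the mirsig pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mirsig pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsig)
```

# Scope

`mirsig` implements the desk analysis behind a cross-study microRNA
deregulation synthesis for a tumor/normal design, with papillary thyroid
carcinoma (PTC) as the motivating system: identifier harmonization,
signature derivation, sequencing-cohort validation, vote-counting
meta-analysis, concordant multi-dataset intersection, and clustering with
enrichment testing. Everything runs on plain TSV/GFF-dialect inputs, and a
synthetic-data module generates all of them with planted ground truth.
This vignette records the models, the parameters that matter, the
numerical choices, and what the synthetic validation does and does not
establish.

# Identifier harmonization

miRNA names drift across registry releases: the star convention
(`miR-222*`) gave way to arm suffixes (`-5p`/`-3p`), letters were added as
paralogs appeared (`miR-451` → `miR-451a`), and species prefixes are used
inconsistently. A cross-study comparison on raw names systematically
under-counts concordance, so every name is mapped to the stable mature
accession (MIMAT identifier) of one reference release before any
synthesis.

The registry is loaded from a two-column aliases table (accession, then a
semicolon-terminated name list; the **last** name is the current one — the
aliases-file convention, which makes the parse deterministic without a
second file) and a GFF3-like coordinate table in which
`miRNA_primary_transcript` rows describe hairpins and `miRNA` rows link
mature accessions to hairpins via `Derives_from`. That linkage convention
was chosen because it is the standard one for miRNA genome annotation and
keeps the precursor table self-contained.

Matching normalizes case, treats `mir`/`miR` identically, and strips a
species prefix of the form `xxx-` only when a `mir`/`let` stem follows.
Two rules are deliberately conservative:

* **No arm guessing.** An arm-less legacy name resolves only if the
  registry records it as an alias of exactly one mature. If two matures
  both claim it, the query is *ambiguous* and is excluded from signatures
  (but always reported). Silently assigning the dominant arm would
  fabricate identifications precisely where the literature is noisiest.
* **Conflicts are surfaced.** Within one study, two raw names resolving
  to the same accession with opposite directions are excluded as an
  intra-study conflict rather than arbitrated.

Grouping partitions a set of matures three ways: shared family label,
shared hairpin (`-5p`/`-3p` duplexes), and genomic cluster — hairpins on
the same chromosome and strand chained transitively while consecutive
gaps stay within `cluster_window_bp`. The default window is 10 kb, the
common operational definition of a polycistronic miRNA cluster; the
window is a parameter because no single distance is canonical.

# Signature derivation

Input is a log2 expression matrix (miRNA × sample). Rows detected in
fewer than `min_samples` samples (default 15, suited to a 24-sample
discovery design) are removed first. The group test is the Wilcoxon
rank-sum; Welch's *t* is available as an option. Moderated-variance
array pipelines are intentionally out of scope: the rank-sum keeps the
stage assumption-light, matches the test used for sequencing-cohort
validation, and admits an exact small-sample implementation that can be
verified by enumeration.

Numerical contract of `rank_sum_test`:

* exact branch when the larger group has at most `exact_max_n`
  observations (default 10) **and** the pooled data are tie-free: the
  null distribution of the rank sum is built by dynamic programming over
  all C(n₁+n₂, n₁) rank assignments, and the two-sided p is
  2·min(P(W ≤ w), P(W ≥ w)) capped at 1;
* otherwise the normal approximation with tie-corrected variance and a
  0.5 continuity correction. Ties always force the approximation — the
  exact distribution under midranks is not defined by the tie pattern
  alone;
* identical pooled values give p = 1 rather than an error.

Fold-changes are computed on log2 means (a geometric-mean fold-change),
the convention for log-scale array data, and reported as signed linear
values with |FC| = 2^|log2FC| and FC = +1 at log2FC = 0. The signature
keeps rows with |FC| ≥ `fc_cut` (linear scale — the standard reading of
an "FC ≥ 1.5" rule; the threshold is inclusive) and FDR strictly below
`fdr_cut` (default 0.05), ordered by |log2FC| descending with accession
as the tie-break so output is reproducible. The Benjamini–Hochberg
step-up adjustment is implemented directly (sort, q(i) = p(i)·m/i,
enforce monotonicity downward, cap at 1) and cross-checked against both
a naive per-definition oracle and `stats::p.adjust` in the tests.

# Sequencing-cohort validation

Isoform quantification records (sample, mature accession, read count)
are summed per mature accession after reannotation through a release
map; records whose accession the map does not cover are excluded and
reported, never carried under stale identifiers. Reads-per-million are
recomputed from the aggregated mature counts — the file's own universe —
because an external "per million miRNA-mapped" denominator is not
re-derivable from aggregated input. Zeros are replaced by the minimum
non-zero value of the matrix before log2; the replacement minimum is
**global** by default (the simpler reading of "the minimum non-null
value") with a per-row option behind the `scope` flag, and the choice is
recorded in the function's documentation rather than hidden.

Two-group validation reuses the rank-sum test and BH adjustment over the
tested subset only (m = subset size), reporting the direction of the
median difference. Stratified comparisons use the Kruskal–Wallis H with
midranks and tie correction (p from χ² with k−1 degrees of freedom),
plus unadjusted pairwise Wilcoxon tests of each stratum against a
declared reference and of all non-reference pairs — the per-pair
p-values are deliberately unadjusted, matching the usual per-panel
reporting, with the global Kruskal–Wallis gating interpretation.

# Vote-counting meta-analysis

The study–miRNA matrix counts, for every harmonized accession, how many
studies report it up and how many down. Three design points were
genuinely open and are resolved as follows:

* **Multi-dataset studies count once.** Their datasets are collapsed by
  union: a miRNA reported by any dataset, always in one direction, takes
  that direction; opposing directions make the study's cell a *conflict*.
  Union maximizes sensitivity, and conflicts are surfaced rather than
  hidden (an intersection rule would silently discard partial evidence).
* **Conflict cells support neither direction** in the frequency scores.
* **No effect-size pooling.** Scores are unweighted study counts; the
  heterogeneity of platforms and cutoffs across a literature corpus makes
  vote counting the defensible synthesis, so fold-changes are never
  averaged across studies.

The reporting filter keeps miRNAs reported by at least `k = 2`
independent studies. Ranked per-direction lists sort by score descending
with accession as tie-break.

# Concordant intersection

Datasets entering the intersection carry their own thresholds (e.g. a
clinical signature at |FC| ≥ 1.5 and FDR < 0.05; cell models at
|FC| ≥ 2.5, one of them without a usable FDR — `fdr_cut = NULL` skips
that filter) and an explicit **orientation flag**: whether "up" in that
dataset corresponds to the tumor-active state. The flag exists because
an inhibition-model comparison (untreated oncogene-active cells versus
inhibitor-treated cells) points opposite to a naive treated-vs-control
reading; inferring orientation from column names would be fragile
exactly where it matters. A miRNA is returned iff present in every
dataset with an identical tumor-oriented direction.

# Clustering and enrichment

Samples are clustered on d = 1 − Pearson r between their profiles over
the signature miRNAs, with average (UPGMA) linkage implemented via the
Lance–Williams update. Ties in the minimum inter-cluster distance are
broken lexicographically on the smallest original sample index of each
cluster, making the merge history deterministic; the implementation is
required (and tested) to match a naive oracle that recomputes all-pairs
average distances at every step. Cutting at the (k−1)-th largest merge
yields exactly k clusters, numbered by first sample occurrence. k is a
parameter — no automatic selection is attempted, since the reference
use case reports a fixed small k chosen by inspection.

Per (cluster, label) pair, enrichment is the one-sided Fisher exact test
(hypergeometric upper tail P(X ≥ a), evaluated by direct summation of
`dhyper` terms) for over-representation only. P-values are unadjusted by
default to match per-cluster reporting conventions; a BH column is
available behind `adjust = TRUE`.

# Synthetic data: what it emulates

The generators emit exactly the file formats the pipeline reads and are
byte-deterministic given a seed; after writing, each generator re-reads
its files and checks them against the returned ground truth.

* `simulate_registry`: two nomenclature eras — legacy arm-less, star and
  letter-less aliases on a configurable fraction of matures; duplex
  (`-5p`/`-3p`) hairpins; hairpin pairs placed within the cluster
  window; optional planted alias collisions. The letter-less alias is
  only attached to one arm so that every non-collision name resolves
  uniquely by construction.
* `simulate_expression`: per-miRNA baselines uniform on 4–12 log2
  units, Gaussian noise (default σ = 0.5 log2 units), planted signed
  shifts (default |log2FC| = 2 on 18 of 500 miRNAs), group sizes 19/5 —
  the discovery-cohort design. Detection flags are false for the lowest
  2% of intensities.
* `simulate_isoforms`: per-sample multinomial reads (200,000 per sample)
  over log-normal abundances, split into 1–5 isoform records per mature;
  a configurable fraction keyed by old-release accessions so aggregation
  must exercise the release map; planted 4-fold depletions in tumors
  (and a further 2-fold in one tumor stratum, so stratified tests have a
  target). Group sizes default to 100/12, the validation-cohort design
  scaled down for runtime.
* `simulate_study_signatures`: 15 studies reporting a planted consensus
  (10 miRNAs, half per direction) minus independent dropouts at rate
  0.2, plus random per-study extras; half the studies write legacy-era
  names; one study is emitted as three datasets to exercise collapsing.
  The designated most-reported down-regulated miRNA — emulating the
  hallmark miRNA that nearly every study in a mature literature reports —
  is emitted by every study and assigned the smallest accession of the
  consensus, so "the planted most-frequent down-regulated miRNA" is
  well-defined for recovery checks even under dropout ties.

What the generators do **not** model: array probe effects and
normalization, batch structure, paired-sample correlation, sequence-level
miRNA biology, and realistic inter-study platform heterogeneity beyond
nomenclature era and dropout. Passing the planted-truth suite therefore
demonstrates that the pipeline's logic and statistics are correct under
its stated assumptions — not that any particular biological dataset will
meet those assumptions.

# Problem sizes and validation conditions

The test suite and the acceptance script use: 20 replicate seeds for
planted-recovery rates; 500 miRNAs × (19+5) samples for the
discovery-design checks; 300 miRNAs × (100+12) samples for the isoform
pipeline; registries of 120–160 hairpins (≥ 200 matures at rename
fraction 0.5) for round-trip resolution; 100 random instances for each
enumeration oracle (group sizes ≤ 7 for the exact Wilcoxon, every 2×2
table with total ≤ 40 for the Fisher tail, 1000 random vectors for BH,
100 random matrices with ≤ 8 samples for UPGMA). These sizes were chosen
so each property is measured with comfortable margins while a full run
stays fast on a laptop.

# Known limitations

* Vote counting weighs a 20-sample study and a 500-sample study equally;
  the matrix records the evidence but makes no attempt at effect-size
  synthesis.
* Harmonization is only as good as the alias table; a name absent from
  the registry is reported unknown rather than fuzzy-matched.
* The exact Wilcoxon branch is limited to small untied groups by design;
  midrank ties always use the approximation, which is slightly
  conservative at very small n.
* Cluster enrichment treats cluster membership as fixed when testing,
  as is conventional; p-values are descriptive, not selective-inference
  corrected.
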