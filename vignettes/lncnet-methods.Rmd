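---
title: "lncnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

# What the package does

`lncnet` is an integrative analysis pipeline for long noncoding RNAs
(lncRNAs) in staged bulk RNA-seq designs — the typical developmental
time-course in which an organ (the motivating case is chicken breast muscle
across late post-hatch development) is sampled at four ages, here labelled
W6, W14, W22 and W30, with three biological replicates each. Starting from
assembled transcript models, per-sample expression, and coding-potential
verdicts from external predictors, it:

1. identifies novel lncRNAs and transcripts of uncertain coding potential
   (TUCPs) by a five-step filter cascade;
2. calls differentially expressed (DE) features between every ordered pair
   of stages;
3. predicts *cis* target genes by genomic proximity and *trans* targets by
   expression correlation;
4. finds miRNA–lncRNA and miRNA–mRNA relations by seed matching, and
   lncRNAs that host pre-miRNA hairpins by exact sequence homology;
5. assembles lncRNA–miRNA–mRNA competing-endogenous-RNA (ceRNA) triads;
6. provides hypergeometric gene-set enrichment and STRING-score PPI
   filtering, and exports all networks as SIF/GraphML for Cytoscape.

A seeded synthetic-data generator with planted ground truth accompanies the
pipeline so that every stage can be validated by recovery rather than by
eyeballing.

# The identification cascade

The cascade applies five rules in order; each transcript's fate is recorded
in a per-transcript report.

| step | rule | boundary |
|------|------|----------|
| exon | keep transcripts with ≥ 2 exons | 1 exon removed |
| length | keep spliced length > 200 nt | exactly 200 removed |
| overlap | remove class codes {`=`, `c`, `j`, `e`, `o`} | annotated lncRNAs routed to output |
| expression | keep max FPKM across samples ≥ 0.5 | 0.5 itself kept |
| coding potential | all four predictors noncoding → lncRNA; ≥ 1 coding → TUCP | — |

Design notes:

* **Overlap by class code, not by interval arithmetic.** Whether a
  transcript shares exonic sequence with reference annotation is a question
  the upstream assembler/comparison tool (cuffcompare and its successors)
  already answered; the cascade trusts its single-character class code. The
  codes treated as "exonic overlap with reference" are `=` (complete
  match), `c` (contained), `j` (novel isoform sharing a junction), `e`
  (single-exon overlap) and `o` (other exonic overlap). Transcripts whose
  id appears in the annotated-lncRNA list are instead routed directly to
  the output as annotated lncRNAs — they are known lncRNAs, not novel
  candidates, and skip the expression and coding-potential steps.
* **The expression floor aggregates by maximum.** "Expressed at FPKM ≥
  0.5" is ambiguous in a 12-sample design: per-sample, per-stage-mean and
  max-over-samples all have defenders. The default is the maximum — a
  transcript convincingly expressed in any one sample is kept, which is
  the permissive, stage-aware reading — and the aggregate is configurable
  (`fpkm_aggregate = "mean"`).
* **Classification.** Surviving class code `u` (intergenic) → lincRNA;
  `x` (antisense exonic overlap) → antisense. Any other surviving code is
  an error rather than a silent bin: after the overlap step only `u`, `x`
  (and intronic `i`, which the cascade's code set deliberately does not
  remove) can survive, and an unexpected code means the inputs disagree
  with the cascade's assumptions. Flagging beats guessing.
* **ORF counting** (for the characterization panels) defines an ORF as any
  ATG whose first in-frame stop codon lies ≥ 30 codons downstream, scanned
  in the three forward frames of the spliced sequence. Thirty codons
  (90 nt) is a conventional floor for "could encode a peptide"; it is a
  parameter (`min_codons`). Every qualifying ATG counts, so nested starts
  give multiple ORFs — this matches the simple frame-scan definition used
  by assembly QC tools rather than any single-longest-ORF convention.

The cascade steps are pure per-transcript predicates, so the retained set
is independent of the order in which the exon, length and expression
filters are applied; the test suite asserts this by recomputing survivors
as an unordered conjunction.

# Differential expression

Fold change between two stages is the ratio of stage means of FPKM with a
small pseudocount:

$$\mathrm{FC} = \frac{\overline{\mathrm{FPKM}}_{\text{num}} + c}
                     {\overline{\mathrm{FPKM}}_{\text{den}} + c},
  \qquad c = 0.01$$

so features absent in one stage get a finite, direction-correct ratio and
features absent in both get FC = 1. Two calling grades are kept, because
the pipeline uses two different strictnesses downstream:

* `is_de`: q < 0.05 (strict) and FC ≥ 1.7 **or** ≤ 1/1.7 (boundary
  inclusive). "|FC| ≥ 1.7" is read direction-symmetrically — a linear fold
  change cannot be negative, so the only sensible reading of the absolute
  value is "1.7-fold in either direction".
* `is_cerna_grade`: q < 0.05 and |log2 FC| ≥ 1 (i.e. 2-fold), the stricter
  grade used to build ceRNA networks.

## The negative-binomial stand-in test

Count-based DE pipelines in this domain model counts as negative binomial
(NB). `lncnet` does not reimplement any particular tool; it provides a
transparent Wald-type stand-in with the same thresholding behaviour:

* per-feature dispersion by method of moments, pooled across the two
  groups: $\hat\phi = (s^2_{\text{pooled}} - \bar m)/\bar m^2$, floored at
  $10^{-8}$;
* delta-method variance of the log group mean,
  $\widehat{\mathrm{Var}}(\log \hat m) = (1/\hat m + \hat\phi)/n$, with
  group means floored at $1/n$ before logging so all-zero groups stay
  finite;
* statistic $W = (\log \hat m_1 - \log \hat m_2)/\mathrm{se}$, two-sided
  p-value from a **t reference with $n_1 + n_2 - 1$ degrees of freedom**.

The t reference is the one genuinely free choice. With three replicates
per group a standard-normal reference is badly anticonservative (the
plug-in variance ignores its own estimation error: null rejection near
0.12 at α = 0.05 in NB simulations), while $n_1+n_2-2$ overshoots slightly
in the other direction. $n_1+n_2-1$ degrees of freedom centres the null
rejection rate near nominal across dispersions 0.05–0.3 in simulations of
2,000 null features, which is the regime the test suite checks (empirical
size required to fall in [0.035, 0.065]). The test is documented as a
stand-in: it reproduces the *decisions* of NB-based callers at these
thresholds, not any tool's exact p-values.

Multiple testing uses Benjamini–Hochberg within each comparison group —
the de-facto meaning of "q-value" in this pipeline generation. DE miRNAs
(DEMs) are called on q < 0.05 alone, without a fold-change gate.

The six comparison groups are the ordered later-vs-earlier stage pairs
(W14vW6, W22vW14, W22vW6, W30vW6, W30vW14, W30vW22); Venn membership of DE
sets across all six is computed exactly over the 64 regions.

# Target prediction

**Cis.** A gene is a cis target of a lncRNA when both lie on the same
chromosome and the gap between their genomic spans (first exon start to
last exon end) is ≤ 100 kb, where the gap is the number of bases strictly
between the spans (overlapping or adjacent spans: gap 0). The window is an
inclusive hard cutoff at exactly 100,000 bp — "about 100 kb" is not
reproducible, a definite boundary is — and is configurable. Distance is
span-to-span rather than TSS-based because the pipeline deliberately makes
no promoter annotation assumptions; strand is ignored.

**Trans.** A gene is a trans target when the Pearson correlation of
expression across the 12 samples is **strictly greater** than 0.95, signed:
the selection rule is `r > 0.95`, not `|r| > 0.95`, so only positive
co-expression qualifies by default (`use_abs = TRUE` switches to
absolute-value mode). The stricter 0.98 sometimes used for pathway-focused
network views is the same parameter, and the 0.98 result is necessarily a
subset of the 0.95 result. Zero-variance features cannot have a defined
correlation and are skipped with a warning.

# miRNA interactions

No specific external target predictor is wrapped; instead the canonical
seed rule is implemented directly and transparently: a miRNA targets a
sequence when the reverse complement of mature positions 2–8 (the 7-mer
seed) occurs at least once in it. All site start positions (1-based) are
reported. Everything is normalized to the DNA alphabet on load (U→T), so
mature sequences supplied as RNA and transcripts supplied as DNA compare
directly, and results are invariant to the representation.

Pre-miRNA hosting is exact forward-strand substring homology: every
occurrence of a precursor sequence inside a lncRNA is reported with
1-based inclusive coordinates (a 66-nt precursor starting at position 309
spans 309..374). Exact matching is the point — the biological claim is
that the lncRNA *is* the precursor's host transcript — so no alignment
scoring is involved; a reverse-complement search mode exists but is off by
default. A precursor may hit several hosts.

# ceRNA triads

A triad (lncRNA *l*, miRNA *m*, mRNA *g*) for a comparison group is the
relational join: *m* is a DEM in the group, *m* targets both *l* and *g*,
and *l* and *g* are both ceRNA-grade DE in the group. The output is
deduplicated and lexicographically ordered, and the test suite verifies it
against a literal triple loop on every fixture.

* **Counting unit.** "How many ceRNA networks is gene *g* involved in" is
  counted as the number of distinct (lncRNA, miRNA) pairs among *g*'s
  triads. This is the only unit consistent with the arithmetic of typical
  reported examples (a gene with 2 miRNAs and 12 lncRNAs "in 13 networks"
  is possible only if the unit is the pair, not the product).
* **Direction.** The construction does not require the miRNA to move
  oppositely to its targets. An optional anticorrelation filter
  (`direction =` argument) enforces exactly that, but defaults off, and no
  lncRNA–mRNA co-expression requirement is imposed within a triad.

# Enrichment and PPI

Over-representation uses the plain hypergeometric upper tail
$p = P(X \ge k)$ for overlap *k* between the query and a term of size *K*
(after intersecting the term with the universe) in a universe of size *N*
with query size *n*, BH-adjusted within each namespace (GO biological
process / molecular function / cellular component, and pathways are
adjusted separately); significance is q < 0.05. The EASE-style correction
(testing *k* − 1) used by some web services is available behind a flag but
off by default: the plain tail is the textbook test and the difference is
documented rather than hidden. The default universe in the pipeline is the
expressed coding genes (max FPKM ≥ 0.5), configurable.

PPI edges come from a STRING-format table; edges with combined score
**strictly greater** than 700 (the conventional "high confidence" level)
are kept, deduplicated as unordered pairs, with weight = score/1000.

# The synthetic-data generator

`generate_dataset()` produces a fully specified toy study with planted
signal for every downstream stage, plus a truth object. The defaults *are*
the study conditions the test suite and acceptance script exercise:

* **Scale.** 2,000 transcripts: 1,200 mRNAs, 300 novel lncRNAs, 100
  TUCPs, 100 annotated lncRNAs, and 300 transcripts built to fail the
  cascade (equal thirds: single-exon, ≤ 200 nt, below the expression
  floor). 20 miRNAs. This is a desk-scale emulation of a transcriptome an
  order of magnitude larger; all counts are configurable.
* **Structure.** mRNAs draw 6–15 exons and 1.2–3.5 kb spliced length,
  lncRNA-class transcripts 2–4 exons and 0.3–1.5 kb, reproducing the
  qualitative length/exon-count contrast of real annotations. Novel
  lncRNAs are 79.7% intergenic (`u`) / 20.3% antisense (`x`) in
  expectation. lncRNA-class baseline FPKM is drawn lower than mRNA
  baseline (log-normal around 4 vs 20), reproducing the lower average
  abundance of lncRNAs.
* **Expression and noise.** FPKM = stage mean × log-normal noise with
  sdlog 0.1; counts are NB around stage mean × length(kb) × depth, with
  dispersion 0.02 and 30 M fragments. These defaults describe the
  low-biological-noise regime of closely related animals from a controlled
  line sequenced deeply — the regime in which planted 4-fold changes are
  expected to be essentially always recoverable, which is what the
  recovery tests require. Both knobs are parameters (`fpkm_sigma`,
  `nb_dispersion`, `lib_depth_m`).
* **Planted DE.** 10% of mRNA+lncRNA features get a stage-subset shift of
  |log2 FC| drawn uniform on [2, 4] (random sign). Truth is analytic: a
  feature is a true DE call for a group iff its planted stage-mean ratio
  differs from 1 — by construction at least 4-fold, keeping planted
  effects far from the 1.7-fold boundary so recovery measures the
  pipeline, not boundary luck.
* **Trans pairs** share a symmetric two-level stage profile (two stages
  16-fold above the other two) and carry only residual noise (sdlog 0.05,
  `trans_noise_sigma`). The balanced split matters: with multiplicative
  noise the linear-scale Pearson correlation of a skewed profile is capped
  well below 1 no matter how large the fold change, while the balanced
  profile keeps the population r near 0.99, comfortably above the 0.95
  rule. Their noiseless means are exactly proportional (r = 1).
* **Cis pairs** are planted on dedicated chromosomes at exact span-to-span
  gaps (defaults include 0, the 100,000 boundary, and 100,001 just beyond
  it), and both members are made DE in a cycling comparison group so the
  DE-driven pipeline can see them. Background transcripts sit in 1-Mb
  slots, so no accidental sub-100-kb pair exists.
* **miRNA signal.** Seed sites are written into target sequences by
  substring replacement at recorded positions, never overlapping each
  other or precursor spans; precursor sequences are copied verbatim into
  their host lncRNAs at configured positions (defaults include a 66-nt
  precursor at position 309 and one precursor shared by two hosts).
  Triads get DE lncRNA/mRNA partners, a DEM miRNA, and both seed sites.
* **Determinism.** The bundle is a pure function of the config (including
  its seed); the generator saves and restores the caller's RNG state.

What the generator does **not** emulate: real genome composition and
repeat structure (chance 7-mer seed matches occur in random background at
the expected ~1/16k rate, exactly as they would in shuffled real
sequence), isoform overlap, multi-mapping, GC or length bias, batch
effects, and library-size variation (size factors are 1, which is why the
pipeline applies no normalization step). Passing recovery tests on this
generator demonstrates the pipeline's logic is correct under its stated
model, not that the thresholds are well-chosen for any particular real
dataset.

# Numerical choices and degenerate inputs

* Coordinates are 1-based closed intervals everywhere (GTF convention);
  every reported position (cis distances, homology spans, seed sites)
  follows it.
* BH is `stats::p.adjust`; the hypergeometric tail is `stats::phyper` —
  standard library routines, with independent hand-rolled oracles in the
  test suite.
* Dispersion floor $10^{-8}$ and group-mean floor $1/n$ keep the NB
  statistic finite for degenerate (constant or all-zero) count vectors;
  identical groups give exactly p = 1.
* Ties and ordering: triads and target pairs are emitted in lexicographic
  order so outputs are byte-stable; network dedup uses unordered pair
  keys.
* Empty inputs (empty GTF, empty edge list, empty DE sets) produce empty,
  well-formed outputs rather than errors; violated preconditions (negative
  FPKM, non-integer counts, unknown class codes, query genes outside the
  universe, scores outside 0–1000) are errors naming the offender.

# Problem sizes used by the checks

The test suite and acceptance script run the full pipeline on the default
2,000-transcript bundle (seconds on one core), the null-calibration
simulation on 2,000 features, and oracle comparisons at n = 200 (cis
brute force), 50 (correlation formula), 30 features (triad triple loop),
64 regions (Venn), N ≤ 25 (exhaustive hypergeometric) — sizes chosen so
every oracle is an exact, literal enumeration.

# Known limitations

* The NB stand-in shares no code or estimation detail with DESeq-lineage
  tools; on real data its p-values will differ even where its calls agree.
* Seed matching is the canonical 7-mer rule with no thermodynamic or
  conservation scoring; it over-calls relative to modern predictors.
* The cascade delegates overlap decisions entirely to upstream class
  codes; misassigned codes propagate.
* Enrichment assumes an unstructured gene universe (no GO-graph
  propagation) and the gene-set input defines namespaces as given.
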