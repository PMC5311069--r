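---
title: "Methods: detecting and characterizing TCR clonal expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterizing TCR clonal expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonexpand)
```

## The experimental design and the data model

The package analyzes a paired design: one *ex vivo* blood TCR
repertoire and up to three 6-day *in vitro* cultures of the same cells
— medium only, carrier protein only, and antigen (hapten–carrier
conjugate). Each repertoire is a tibble of clonotypes keyed by
`(chain, v_call, j_call, junction)` — chain, V gene, J gene, and CDR3
nucleotide sequence — with a UMI-corrected `duplicate_count`.
Nucleotide-level identity is the most conservative key for a
UMI-counting pipeline: two clones with the same amino-acid CDR3 but
different nucleotide rearrangements are distinct clonal events, and
they are kept distinct all the way into the clustering stage. The
amino-acid junction is carried alongside for the similarity analysis.
α and β chains are analyzed separately throughout; only headline
counts are reported summed.

An unobserved clonotype is represented by absence: zero-count rows are
dropped on read, and duplicate keys are collapsed by summing counts
(idempotent, abundance-conserving). Files use AIRR-style column names
(`v_call`, `junction`, `junction_aa`, `duplicate_count`) so tables
interoperate with the wider repertoire-analysis ecosystem.

## The stimulation index

For each clonotype present after culture,

$$\mathrm{SI} = \log_2 \frac{n_\mathrm{culture}}{\max(n_\mathrm{ex\,vivo},\, v)}$$

with imputation value $v = 1$ for clones not seen ex vivo: a clone
observed after proliferation must have entered the culture with at
least one cell, and ex vivo abundances have median 1, so 1 is both a
floor and a typical value. SI is computed on raw counts, not
depth-normalized frequencies (a frequency mode exists but is off by
default); under comparable sequencing depths SI approximates the
number of cell doublings, ignoring death. Clonotypes seen only ex vivo
receive no SI — they have no in-culture abundance — and enter only the
background distribution of the enrichment test.

Thresholds are strict inequalities throughout: the expanded set is
SI > 3 (eightfold, three divisions); the specificity stage selects
SI > 8 in antigen among clones present with SI > 1 in carrier. Because
"fraction of TCRs detected" is ambiguous, `expansion_summary()`
reports all three denominators (distinct clonotypes in the cultured
sample, in the ex vivo sample, and in their union), labelled.

## Enrichment, usage skew, and their nulls

**Pre-expansion abundance enrichment.** The ex vivo abundances of the
expanded set are binned (default integer bins 0, 1, ..., 9 with an
overflow bin; expanded clones unseen ex vivo count as 0) and compared
bin-wise against all ex vivo clonotypes with the pooled two-proportion
z-test, two-sided, no continuity correction; $z^2$ equals the
uncorrected Pearson chi-square, which the tests verify exhaustively on
small tables. Bins are flagged at p < 0.01 per bin without
multiple-testing correction, matching the per-bin readout this class
of analysis reports; a Bonferroni switch exists. Degenerate tables
(pooled proportion 0 or 1) return z = 0, p = 1 by definition. The
scalar summary is the fraction of expanded clonotypes with ex vivo
abundance > 2.

**V/J usage skew.** Observed gene frequencies of the expanded set
(each distinct clonotype weighted once — a clonal expansion is one
receptor; abundance weighting is an option) are compared against a
resampling null: 100 equal-sized draws from the ex vivo repertoire,
abundance-weighted without replacement — i.e. drawing cells, the
closest analogue of sampling TCRs from blood. Whether such draws
should instead be clonotype-uniform is not decidable from the design
alone, so a uniform mode is provided; abundance weighting is the
default and the mode is recorded in the result's attributes. Genes
outside the null mean ± 2 SD are flagged over/under-represented, with
fold enrichment observed/mean (not estimable when the null mean is 0).
At k = 2 SDs a random draw leaves roughly 5% of genes outside the band;
the acceptance suite checks the empirical rate stays below 10%.
Allele suffixes (`*01`) are trimmed so usage is gene-level.

## CDR3 similarity

Distances are unit-cost Levenshtein edit distances between amino-acid
CDR3s (`utils::adist`; substitution, insertion, deletion each cost 1),
verified in the tests against the bare recursive definition,
exhaustively over all string pairs up to length 6 on a 4-letter
alphabet. Clustering is agglomerative with the Ward criterion; the
`ward.D2` variant is the default and `ward.D` is available, since
"Ward" alone underdetermines the variant. The labelled distance matrix
is sorted by label before `stats::hclust`, so the tree is a pure
function of the labelled distances, independent of input order;
remaining ties break as `hclust` resolves them on the sorted input,
which is deterministic. Duplicate amino-acid sequences stay separate
leaves.

Families are subtrees: `extract_family()` walks up from an anchor leaf
(typically the most abundant expanded clonotype) to the largest
enclosing subtree that respects a height cut or a size cap. The family
alignment is a center-star multiple alignment around the anchor:
unit-cost global pairwise alignments (Needleman–Wunsch with a fixed
tie-break: match/mismatch, then gap in the partner, then gap in the
center) merged through the center's gap pattern. Center-star is exact
for the pairwise alignments, deterministic, and adequate for
near-identical short peptides; it makes no claim of optimal sum-of-pairs
score. De-gapping any row recovers its input exactly, which the tests
assert. The logo matrix is the per-column residue frequency profile
over the 20 amino acids plus gap, with information content
$\log_2 21 - H$ bits per column.

Diversity of the expanded set is its mean pairwise distance compared
with the distribution of that statistic over 100 equal-sized uniform
draws of distinct clonotypes from the ex vivo repertoire (an
abundance-weighted mode exists). The z-score of the observed mean
against that distribution is the reported effect.

## The synthetic generator

The generator exists so that every stage above can be validated
against known ground truth. It emulates:

* **Clone sizes**: discrete Zipf, $P(k) \propto k^{-s}$, truncated at
  $10^5$. Only the mean (≈1.3) and median (1) of real ex vivo
  abundance distributions are constrained by the design, not the law
  itself; a power law is the standard model for clone-size
  distributions and $s = 3.1$ reproduces mean ≈ 1.32 at median 1. The
  exponent is a parameter.
* **V/J usage**: 15 V and 10 J synthetic segments per chain with
  geometrically decaying usage — non-uniform, as real repertoires are.
  The segment table is an explicit synthetic fixture (IMGT-style
  labels, stop-free codon prefixes/suffixes starting with the
  canonical CDR3 cysteine and ending with phenylalanine); real
  germline references are deliberately out of scope.
* **Junctions**: V-prefix + random stop-free codon insert + J-suffix,
  in frame by construction. Drawing insert codons uniformly from the
  61 sense codons is exactly equivalent to drawing uniformly from all
  64 and resampling any insert containing a stop. Default insert
  lengths give 10–16 aa CDR3s, the typical human range.
* **Responders**: `n_responders` clonotypes per chain, drawn
  abundance-weighted by default — a recall response comes from
  pre-expanded memory clones, which is what makes the enrichment
  analysis show signal. The default of 20 responders per 10,000
  clonotypes is a deliberately scaled-up rate so that a
  desk-scale simulation contains enough signal to measure recall and
  false-positive rates; the physiological rate of a few precursors per
  100,000 T cells is reproduced by running 100,000 clonotypes with 3
  responders, as the acceptance script does.
* **Growth**: in the antigen culture each responder multiplies by
  $2^d$, where $d$ is the largest integer with
  $24 + (d-1)\,t \le 144$ hours and $t$ is drawn per clone uniformly
  from 16–18 h — so $d \in \{7, 8\}$ under the defaults. Responders
  are not expanded in medium or carrier cultures. Non-responders die
  independently per cell at 5%/day (binomial thinning over 6 days);
  the rate is a parameter and only the qualitative behaviour (bulk SI
  at or slightly below 0) is asserted. An optional weak carrier
  expansion (≤ 3 divisions, off by default) emulates nonspecific
  carrier responses.
* **Families**: responder CDR3s are rewritten into `n_families`
  families of `family_size` members — a seed plus variants at ≤
  `family_max_edits` amino-acid edits applied in codon space, so
  nucleotide and amino-acid sequences stay consistent. Seeds are
  chosen greedily with pairwise distance ≥ 8, giving families that are
  tight within (pairwise ≤ 2 edits at the default max of 1) and well
  separated between.
* **Depth**: each condition is multinomially sampled to a fixed depth
  (default 10,000 — slightly undersampling the baseline, which keeps
  observed ex vivo counts at mean ≈ 1.3, median 1). `depth = NULL`
  disables sampling, which is what makes the exact SI-equals-divisions
  identity testable.

One master seed drives derived child seeds per chain and stage, so the
whole experiment is byte-reproducible and stages can be re-run
independently.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: PCR and sequencing error, UMI
collisions, amplification bias between samples, cross-sample
contamination, real germline segment sequences and trimming
distributions, biological sharing of CDR3s between individuals, or
depth differences between conditions. Results on synthetic data
validate the statistical machinery, not the wet-lab pipeline upstream
of it.

## Numerical and design choices

* Bins of the SI histogram and the enrichment test are half-open
  `[lo, hi)`; SI bins align to multiples of the bin width.
* The z-test is vectorized and pooled-variance; its degenerate cases
  are defined (z = 0, p = 1) rather than NaN.
* `run_analysis()` seeds once from the config and runs stages in a
  fixed order; two runs with identical inputs and seed produce
  byte-identical output files (the suite checks md5 sums).
* Problem sizes used in the validation suite: 10,000 clonotypes per
  chain for recovery and calibration runs (10 seeds), 2,000 for
  pipeline-level tests, 100,000 for the physiological-rate
  demonstration; these sizes give stable statistics while keeping a
  full run of suite plus acceptance script in the minutes range.
* Known limitations: SI on raw counts assumes comparable sequencing
  depth across conditions (use the frequency mode otherwise); the
  center-star alignment is not optimal sum-of-pairs for distant
  sequences; the usage null's SD from 100 resamples is itself noisy,
  so the ±2 SD band is indicative, not a calibrated test; and with
  very small expanded sets (< ~10) the per-bin z-tests are
  underpowered.
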