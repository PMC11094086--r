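---
title: "Methods: from phosphoproteomic and splicing measurements to candidate MHC-I neoantigens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from phosphoproteomic and splicing measurements to candidate MHC-I neoantigens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

spliceotope re-implements, as a tested and reusable pipeline, the
computational route by which a phosphatase-inhibitor perturbation of the
spliceosome is turned into candidate MHC class I neoantigens:

1. **Differential intensity statistics** (proteome, phosphoproteome,
   immunopeptidome): Perseus-style valid-value filtering, downshifted-normal
   imputation of missing-not-at-random dropouts, and a SAM-type moderated
   t statistic with permutation FDR.
2. **Splicing event analysis**: rMATS-dialect junction tables in, percent
   spliced-in (PSI) re-derivation, FDR/|ΔPSI| significance filtering,
   direction classification and family-level skew tests.
3. **Sequence features and motif maps**: exon/intron lengths, GC content,
   branch-point distance to the 3' splice site, and position-resolved
   RNA-binding-protein motif coverage maps around splice-site anchors.
4. **Neopeptide prediction**: reconstruction of altered transcripts from
   productive events, translation under canonical-START assumptions,
   digestion into unique 8–14mers, a novelty filter against the canonical
   proteome, and interfaces to MHC-I binding prediction.
5. **Set statistics**: exact hypergeometric overlaps and
   foreground-vs-background shift tests.

Everything is driven end-to-end on synthetic data with planted ground truth
(the `analysis/` scripts), so every stage is testable offline, without any
external download, and with known right answers.

# The differential-intensity model

Log2 intensities are modelled per feature as a group mean plus Gaussian
noise, with dropout concentrated at low intensities. The analysis chain is
fixed in the Perseus order: transform → filter → (normalise) → impute →
test.

**Valid-value filter.** A feature is kept when its fraction of observed
values reaches the threshold *in at least one* sample group — 0.75 for the
proteome preset, 1.0 for the phosphoproteome preset. This retains features
detected in only one condition (which carry the condition-specific signal)
while discarding features too sparse to test.

**Downshifted-normal imputation.** Each missing entry in sample $s$ is
replaced by a draw from

$$N\!\left(\mu_s - d\,\sigma_s,\ (w\,\sigma_s)^2\right)$$

with $\mu_s, \sigma_s$ the observed mean and standard deviation of that
sample, downshift $d$ and width $w$. Presets: proteome $w = 0.3, d = 2.4$;
phosphoproteome $w = 0.3, d = 1.8$. The downshift encodes the
missing-not-at-random assumption: missing values are censored low-abundance
measurements, so they are imputed below the observed distribution.
Imputation is per sample by default (`per = "sample"`); a whole-matrix mode
is available.

**SAM statistic and permutation FDR.** Per feature,

$$d = \frac{\bar{x}_T - \bar{x}_C}{s + s_0},$$

where $s$ is the pooled two-sample standard error of the mean difference
and $s_0$ a variance-stabilising offset (0.35 for the proteome preset, 0.1
for phospho). With $s_0 = 0$, $d$ is exactly the classical pooled-variance
Student t statistic — a regression guard the tests enforce to $10^{-9}$.
The offset penalises features whose tiny variance would otherwise produce
huge statistics from negligible fold changes, which is the reason the
"t-test with an S0 parameter" phrasing in proteomics software denotes this
moderated statistic rather than a plain t-test.

q-values follow the SAM convention: group labels are permuted (all distinct
assignments when at most `n_permutations = 250` exist — with 3+3 samples
that is all 20 — otherwise 250 random draws); at threshold $|d_i|$, the
estimated false-positive count is the median over permutations of
$\#\{|d^*| \ge |d_i|\}$, divided by the observed count $\#\{|d| \ge
|d_i|\}$; q-values are capped at 1 and made monotone non-decreasing as
$|d|$ decreases. $\pi_0$ is fixed at 1, which is conservative. Ties are
compared with $\ge$ throughout.

**Downstream classifications.** A phosphosite is regulated when significant
and $|\log_2 FC| > 0.58$; a protein is *hyper* (only up-regulated sites),
*hypo* (only down), *biphasic* (both), or *unchanged*. A feature is
*condition-specific* when the raw matrix shows at least one valid value in
one group and none in the other, and the post-imputation Welch t-test gives
$p < 0.05$.

# Splicing events

PSI is re-derived from junction counts exactly as the upstream caller
defines it,

$$\psi = \frac{I/l_I}{I/l_I + S/l_S},$$

with effective form lengths $l_I, l_S$; a replicate with $I = S = 0$ is
undefined and excluded from the group mean. Significance uses the strict
cut-offs FDR $< 0.05$ **and** $|\Delta\psi| > 0.1$, read literally from the
stated thresholds; events with undefined PSI in either group cannot be
evaluated and are dropped. ΔPSI is treated-minus-control; because the
upstream tool reports sample1-minus-sample2 without naming the groups, the
reader requires the caller to declare which sample is treated
(`treated_group`, default sample 1), preventing silent sign flips.

Family skew (are SE events more often UP than the pooled UP/DOWN ratio
suggests?) is a one-sided upper hypergeometric tail: draw the family's
events from the pooled UP+DOWN population and ask for at least the observed
number of UP. The implementation is `phyper`; the tests pin it to explicit
enumeration for all universes up to 12.

# Sequence features and the branch-point scorer

Features are computed on the annotated strand in transcript orientation:
exon length from the half-open-start coordinate convention
(`end − start_0base`), GC content of the target exon (SE) or retained
intron (RI), and the branch-point distance in the upstream intron.

The branch-point scorer replaces an external SVM-based tool with a
transparent position-weight model: every adenosine whose distance to the
intron's 3' end lies in the 15–100 nt window (standard for human branch
points; configurable) is scored by the 7-mer centred on it against a
yUnAy-consensus PWM shipped as a versioned fixture
(`inst/extdata/bp_pwm.tsv`, column 4 ≈ pure A); the best-scoring adenosine
wins, ties going to the one closest to the 3' splice site. Distance is the
number of intron bases 3' of the branch adenosine. The scorer is pluggable:
any matrix in the same format can be substituted.

Group comparisons use the Mann–Whitney U test: exact enumeration of all
group assignments when both groups have ≤ 8 observations (midranks handle
ties; two-sided extremeness is $|U - n_1 n_2/2|$, which equals the
doubled-tail definition by symmetry), and the tie- and continuity-corrected
normal approximation otherwise. On an $n = 8$ lattice the approximation
carries ≈ 0.01 absolute error against enumeration — the tests document
this at a 0.02 bound. No multiple-testing correction is applied across
features; each feature is reported per test, as in the figure-level
convention this mirrors.

The figure-legend wording "median exon number" conflicts with the running
text's "short length" for the same panel; this package reads it as exon
*length*.

# Motif RNA maps

A motif model is a PWM over A/C/G/U with log2-odds scoring against a
uniform 0.25 background; a hit is any window scoring at least a threshold
fraction (default 0.8) of the maximal attainable score. Coverage at a map
position is the fraction of the group's events with **at least one** hit
overlapping that position (presence/absence, the common RNA-map
convention; hit density would weight long U-rich stretches). Four
splice-site anchors are supported (upstream-exon donor, target-exon
acceptor and donor, downstream-exon acceptor); windows default to 300 nt
into the flank and 50 nt into the exon, with a 31-nt running mean for
display — rMAPS-style settings chosen because the mirrored tool documents
only "default settings". Position 0 is the first base 3' of the splice-site
boundary in transcript orientation.

Per-position significance is a label permutation test on the coverage
difference with Benjamini–Hochberg correction across positions. The
attainable minimum p is $1/(n_{\text{perm}}+1)$, so with ~350 positions a
few thousand permutations (default 5000) are required to resolve q < 0.05;
the permutation sums are computed in a single matrix product, which keeps
this cheap.

# Neopeptide prediction

Productive events are exactly the two classes whose *altered* isoform gains
abundance under treatment: skipped exons with decreased inclusion (the
exclusion isoform) and retained introns with increased retention. Other
families (MXE, A3SS, A5SS) are declared out of scope rather than
improvised.

Reconstruction removes the annotated internal exon (SE) or splices the
intron into the exon chain (RI), then translates with the standard code
from the annotated canonical START to the first stop codon — no
readthrough, no internal initiation. If the START-containing exon was
removed the product is empty with reason `start_lost`. Frameshift is
decided by the CDS-overlapping length change mod 3; premature stop by
whether the observed stop maps upstream of the canonical stop codon's
position in the altered transcript. Coordinates are GTF 1-based inclusive
at the interfaces and rMATS half-open starts in event tables, documented at
each function.

Proteins are digested into all substrings of length 8–14. "Unique" is
interpreted as de-duplication within the library **and** novelty against
the canonical background proteome (substring query against every canonical
protein); only novel peptides proceed to binding prediction. The binding
stage has two backends: a parser for NetMHCpan v4.1 tabular output (joined
on peptide sequence; strong/weak classes at %rank ≤ 0.5 / ≤ 2.0, the
tool's conventional thresholds), and a *toy scorer* — a 9-mer
anchor-position matrix with percent ranks computed against
proteome-sampled background peptides — which exists solely to make the
stage testable offline and makes no biological claims. The allele is a free
parameter throughout.

# The synthetic-data generators

The generators define the study conditions for all tests; they are not
tuning knobs.

**Toy genome.** One chromosome per gene; each gene is a single transcript
with 3–5 coding exons (8–30 codons each), 9-nt UTRs, GT..AG introns of
60–150 nt and 500 nt intergenic padding. Exon lengths are multiples of
three, so every intron sits at codon phase 0 — a deliberate simplification
that makes in-frame event planting exact; frameshift handling is covered by
hand-built fixtures instead. Strand is drawn at random and all generation
is bit-reproducible under a seed. Multi-isoform genes are a non-goal.

**Neoepitope planting.** RI: the intron is rewritten as a valine-leading
in-frame cassette encoding the peptide followed by a stop, so retention
appends `V<peptide>` to the canonical N-terminus; the canonical proteome is
unchanged. SE: the codons flanking an internal exon are rewritten so the
exclusion junction reads the peptide in frame; the canonical protein
contains the two halves separated by the exon but never the contiguous
peptide. Both modes verify the peptide is absent from the canonical
proteome and re-draw (or refuse, for user-supplied peptides) on collision.

**Junction tables.** Inclusion counts are binomial,
$I \sim \mathrm{Bin}(N, p)$ with
$p = \psi l_I / (\psi l_I + (1-\psi) l_S)$, so the length-normalised PSI
estimate is centred on the planted truth; $S = N - I$; two replicates per
group, treated as sample 1. A binomial (not negative-binomial) read model
is used deliberately: it is the simplest model whose expectation matches
the planted PSI, and overdispersion is out of scope. FDR is set to 0.001
for planted-significant rows and uniform on (0.2, 1) otherwise, so the
significance filter recovers the planted set exactly; significant rows are
re-drawn (bounded retries, then expectation counts) if sampling noise
pushed the observed |ΔPSI| below the cut-off. Default read depth is 2000
junction reads per replicate.

**Intensity matrices.** Log-normal baselines (log2 mean 25, sd 2), additive
treated-group effects, Gaussian noise, and logistic MNAR censoring:
$P(\text{missing}\mid x) = r \cdot \mathrm{plogis}((c - x)/s)$ with
per-feature maximal dropout $r$, half-maximal point $c$ (default baseline
mean − 1.5 sd) and scale $s$ (0.8). The logistic form makes
downshifted-normal imputation meaningfully testable.

**What the synthetic data does not emulate:** correlated features,
batch effects, peptide-to-protein roll-up, isoform-resolved quantification,
read-level alignment noise, overdispersed junction counts. Passing tests
demonstrate algorithmic correctness against planted truth, not performance
on real cohorts.

# Numerical choices and degenerate inputs

* Strict inequalities in the event filter (`< 0.05`, `> 0.1`), matching the
  stated cut-offs; significance filtering before direction classification
  guarantees ΔPSI ≠ 0 there (ΔPSI = 0 on a significant event is a contract
  error).
* PSI of a replicate with no reads is `NA` and propagates as missing rather
  than 0.
* The hypergeometric universe must be passed explicitly; there is no silent
  default to genome size, because overlap p-values are meaningless without
  a declared universe. Default orientation is enrichment (upper tail);
  depletion by flag.
* Zero-variance Mann–Whitney input (all values tied) returns p = 1 rather
  than NaN.
* Running-mean smoothing truncates at window edges (no padding), so
  boundary values average over shrinking windows.
* Permutation reproducibility: every stochastic routine takes a seed and is
  bit-reproducible; the RNG state of the caller is never disturbed
  (`withr::with_seed`).

# Problem sizes in the shipped analyses

The `analysis/` drivers and the acceptance script use: 5 toy genes with 5
planted neoepitopes; 1000 simulated junction-table rows (300 significant);
2000-feature intensity matrices with 3–4 samples per group, 20 simulation
seeds for SAM calibration; 10,000 imputation draws for the
Kolmogorov–Smirnov check; 200 events per group for RNA maps with 3000
permutations. These sizes give stable estimates (binomial standard errors
well under the tolerances checked) while keeping a full run in the order of
a minute; all scale linearly if enlarged.

# Known limitations

* Single-isoform gene models only; ASE-to-isoform matching on real
  annotation (which transcript hosts an event) is the caller's problem.
* The rMATS dialect writes transcript-orientation flanking-exon columns;
  files from real rMATS runs follow the same header but may order flanks
  genomically for some event types — coordinates should be checked before
  mixing sources.
* The binding toy scorer is a test harness, not a predictor; real use goes
  through the NetMHCpan output parser.
* The permutation FDR with 3+3 samples rests on 20 distinct relabelings;
  q-value granularity is correspondingly coarse and conservative under the
  null.
* A3SS/A5SS/MXE events are filtered, counted and skew-tested, but never
  translated into peptide libraries (by design, matching the productive-
  isoform argument for SE exclusion and RI inclusion).
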