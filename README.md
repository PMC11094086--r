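# spliceotope

Phosphatase inhibitors such as LB-100 rewire the phosphorylation of
spliceosome components, which changes alternative splicing genome-wide —
and mis-spliced transcripts can translate into peptides that the cell has
never shown to the immune system. Presented on MHC class I, such
splicing-derived neoantigens are candidate targets for combining
splicing-modulating drugs with immunotherapy.

`spliceotope` is an R package plus analysis workflow that implements the
computational route from raw measurements to candidate neoantigens, for
researchers who want to run, audit or extend each stage:

* **Differential intensity statistics** (proteome / phosphoproteome /
  immunopeptidome): valid-value filtering, median normalisation,
  downshifted-normal imputation of MNAR dropouts
  (`N(μ_s − d·σ_s, (w·σ_s)²)` per sample), and the SAM moderated statistic
  `d = Δm/(s + s0)` with permutation FDR — presets `proteome`
  (valid ≥ 75 %, w = 0.3, d = 2.4, S0 = 0.35) and `phospho`
  (valid = 100 %, w = 0.3, d = 1.8, S0 = 0.1, site probability ≥ 0.75),
  plus hyper/hypo/biphasic protein classification and condition-specific
  peptide detection.
* **Splicing events**: rMATS 4.1.2-dialect junction tables, PSI
  re-derivation `ψ = (I/lI)/((I/lI)+(S/lS))`, the significance filter
  FDR < 0.05 ∧ |ΔPSI| > 0.1, direction classification, family counts and
  hypergeometric skew tests.
* **Sequence features**: exon/intron lengths, GC content, branch-point
  distance to the 3' splice site via a transparent yUnAy-consensus PWM
  scorer; Mann–Whitney comparisons with an exact-enumeration path.
* **Motif RNA maps**: PWM scanning and position-resolved coverage around
  splice-site anchors with permutation significance bands.
* **Neopeptides**: reconstruction of SE-exclusion / RI-inclusion isoforms,
  canonical-START translation to the first stop, digestion into unique
  8–14mers, novelty filtering against the canonical proteome, and MHC-I
  binding via a NetMHCpan v4.1 output parser (or an offline toy scorer for
  testing).
* **Set statistics**: exact hypergeometric overlaps (explicit universe
  required) and foreground-vs-background shift tests.

A first-class synthetic-data module generates every input with planted
ground truth — a toy genome with neoepitope-encoding events, binomial
junction counts centred on planted PSI, and log-normal intensity matrices
with logistic MNAR censoring — so the entire pipeline is testable offline.

## Worked example

Plant a known neoepitope, simulate an rMATS table, and recover the peptide:

```r
library(spliceotope)

tg <- make_toy_genome(5, seed = 11)
p  <- plant_neoepitope(tg, "G001", "RI", peptide = "KLFERWNTLV", seed = 3)
tg <- p$genome

ps  <- plant_splice_events(tg, transform(p$truth, planted = TRUE), seed = 5)
dir <- tempfile(); write_rmats_tables(ps$tables, dir)

ev  <- read_rmats_dir(dir)
sig <- classify_direction(filter_significant(ev))
sig[, c("event_id", "event_type", "delta_psi", "fdr", "direction")]
#>   event_id event_type delta_psi   fdr direction
#> 1     RI_1         RI 0.4982438 0.001        UP

genome <- toy_chrom_sequences(tg)
model  <- toy_gene_models(tg)[["G001.t1"]]
alt <- reconstruct_transcript(select_productive_events(sig)[1, ], model, genome)
grepl("KLFERWNTLV", alt$protein, fixed = TRUE)
#> [1] TRUE

nov <- novelty_filter(digest_kmers(alt$protein), toy_proteome(tg))
c(total = nrow(nov), novel = sum(nov$novel),
  planted_is_novel = "KLFERWNTLV" %in% nov$peptide[nov$novel])
#>            total            novel planted_is_novel
#>               70               67                1
```

The retained intron gains inclusion on treatment (ΔPSI ≈ +0.50 at
FDR 0.001, direction UP), its read-through translation contains the
planted 10-mer, and of the 70 unique 8–14mers from the altered protein, 67
are absent from the canonical proteome — including the planted peptide.

The numbered drivers under `analysis/` run the whole study end to end on
simulated data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_inputs.R       # toy genome, rMATS tables, intensity matrices
Rscript analysis/02_differential_intensity.R
Rscript analysis/03_splicing_events.R
Rscript analysis/04_motif_maps.R
Rscript analysis/05_neopeptides.R
```

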