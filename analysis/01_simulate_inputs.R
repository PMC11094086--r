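#!/usr/bin/env Rscript
# Step 1: generate every input the downstream analyses consume, with
# planted ground truth: a 5-gene toy genome carrying 3 retained-intron and
# 2 skipped-exon neoepitopes, rMATS-dialect junction tables (300 planted
# significant events among 1000), and proteome/phospho/immunopeptide
# intensity matrices with planted group effects and MNAR dropout.

suppressPackageStartupMessages(library(spliceotope))
seed <- 20260927L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Building the toy genome and planting neoepitopes ...")
tg <- make_toy_genome(5, seed = seed)
plan <- list(c("G001", "RI"), c("G002", "RI"), c("G003", "RI"),
             c("G004", "SE"), c("G005", "SE"))
truth <- NULL
for (i in seq_along(plan)) {
  p <- plant_neoepitope(tg, plan[[i]][1], plan[[i]][2], seed = seed + i)
  tg <- p$genome
  truth <- rbind(truth, transform(p$truth, planted = TRUE))
}
message("  planted peptides: ", paste(truth$planted_peptide, collapse = ", "))

message("Simulating rMATS junction tables (1000 events, 300 significant) ...")
set.seed(seed + 10)
n <- 1000L
filler <- data.frame(
  event_id = NA_character_,
  event_type = sample(c("SE", "RI", "MXE", "A3SS", "A5SS"), n - 5L, TRUE),
  gene_id = sample(paste0("G00", 1:5), n - 5L, TRUE),
  true_psi_control = 0.5, true_psi_treated = 0.5,
  is_significant = rep(c(TRUE, FALSE), c(295L, n - 300L)),
  planted_peptide = NA_character_, planted = FALSE)
filler$true_psi_treated[filler$is_significant] <-
  0.5 + sample(c(-1, 1), 295, TRUE) * runif(295, 0.25, 0.45)
truths <- rbind(truth, filler)
ps <- plant_splice_events(tg, truths, seed = seed + 20)
write_rmats_tables(ps$tables, file.path(out, "rmats"))
suppressWarnings(write_toy_genome(tg, file.path(out, "ref")))
write.table(ps$truth, file.path(out, "event_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("Simulating intensity matrices ...")
# proteome: few changes (as seen for total protein abundance)
eff_prot <- rep(0, 2000); eff_prot[1:100] <- rep(c(1.5, -1.5), 50)
prot <- simulate_intensity_matrix(2000, 4, effects = eff_prot, noise_sd = 0.5,
                                  dropout_rate = 0.25, seed = seed + 30)
write_intensity_tsv(prot$matrix, file.path(out, "proteome.tsv"))
write.table(prot$truth, file.path(out, "proteome_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# phosphosites: widespread changes, hyper-biased (phosphatase inhibition),
# several sites per protein so hyper/hypo/biphasic classes exist
set.seed(seed + 40)
n_sites <- 3000
eff_ph <- rep(0, n_sites)
changed <- seq_len(900)
eff_ph[changed] <- sample(c(2, -2), 900, TRUE, prob = c(0.62, 0.38))
ph <- simulate_intensity_matrix(n_sites, 4, effects = eff_ph, noise_sd = 0.5,
                                dropout_rate = 0.15, seed = seed + 41)
ph$matrix$feature_meta <- data.frame(
  protein_id = paste0("P", sample(1:600, n_sites, TRUE)),
  localization_prob = pmin(1, rbeta(n_sites, 8, 1)),
  reverse = runif(n_sites) < 0.01,
  contaminant = runif(n_sites) < 0.01)
write_intensity_tsv(ph$matrix, file.path(out, "phospho.tsv"))
write.table(cbind(ph$truth, ph$matrix$feature_meta),
            file.path(out, "phospho_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# immunopeptides: a block detected only under treatment
set.seed(seed + 50)
imm <- simulate_intensity_matrix(800, 3, effects = 0, noise_sd = 0.5,
                                 dropout_rate = 0.2, seed = seed + 51)
treated_only <- 1:40
imm$matrix$values[treated_only, 1:3] <- NA          # absent in control
imm$matrix$values[treated_only, 4:6] <- rnorm(120, 26, 0.5)
write_intensity_tsv(imm$matrix, file.path(out, "immunopeptides.tsv"))
writeLines(rownames(imm$matrix$values)[treated_only],
           file.path(out, "immunopeptides_treated_only_truth.txt"))

message("Done; inputs under ", out)
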