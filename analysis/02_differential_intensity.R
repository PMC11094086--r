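#!/usr/bin/env Rscript
# Step 2: Perseus-style differential analysis of the simulated proteome and
# phosphoproteome, with the study's parameter presets, followed by the
# hyper/hypo/biphasic protein classification and the condition-specific
# immunopeptide detection.

suppressPackageStartupMessages(library(spliceotope))
seed <- 20260927L
sim <- "results/simulated"
out <- "results/differential"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## Proteome: valid >= 75% in one group, impute (0.3, 2.4), SAM S0 = 0.35
message("Proteome ...")
preset <- perseus_preset("proteome")
prot <- read_intensity_tsv(file.path(sim, "proteome.tsv"))
prot_f <- filter_valid_fraction(prot, preset$valid_fraction)
prot_i <- impute_downshifted_normal(prot_f, preset$width, preset$downshift,
                                    seed = seed)
res_p <- sam_test(prot_i, s0 = preset$s0, fdr_threshold = preset$fdr,
                  seed = seed)
write.table(res_p, file.path(out, "diff_proteome.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
truth_p <- read.delim(file.path(sim, "proteome_truth.tsv"))
hit <- merge(res_p, truth_p, by.x = "feature_id", by.y = "feature_id")
message(sprintf("  %d/%d features kept by the valid-value filter",
                nrow(prot_f$values), nrow(prot$values)))
message(sprintf("  %d significant; sensitivity %.2f, empirical FDR %.3f",
                sum(res_p$significant),
                sum(hit$significant & !hit$is_null) / sum(!hit$is_null),
                sum(hit$significant & hit$is_null) /
                  max(1, sum(hit$significant))))

## Phosphoproteome: site prob >= 0.75, valid 100%, median normalise,
## impute (0.3, 1.8), SAM S0 = 0.1; then per-protein classification
message("Phosphoproteome ...")
preset <- perseus_preset("phospho")
ph <- read_intensity_tsv(file.path(sim, "phospho.tsv"),
                         meta_cols = c("protein_id", "localization_prob",
                                       "reverse", "contaminant"))
ph_f <- filter_phosphosites(ph, preset$min_localization)
ph_f <- filter_valid_fraction(ph_f, preset$valid_fraction)
ph_n <- median_normalize(ph_f)
ph_i <- impute_downshifted_normal(ph_n, preset$width, preset$downshift,
                                  seed = seed)
res_s <- sam_test(ph_i, s0 = preset$s0, fdr_threshold = preset$fdr,
                  seed = seed)
res_s$protein_id <- ph_i$feature_meta$protein_id
write.table(res_s, file.path(out, "diff_phospho.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cls <- classify_protein_phospho(res_s)
write.table(cls, file.path(out, "phospho_protein_classes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
up_sites <- sum(res_s$significant & res_s$log2_fold_change > 0.58)
dn_sites <- sum(res_s$significant & res_s$log2_fold_change < -0.58)
message(sprintf("  %d sites kept; %d hyper / %d hypo site calls (%.0f%% hyper)",
                nrow(ph_i$values), up_sites, dn_sites,
                100 * up_sites / max(1, up_sites + dn_sites)))
message(sprintf("  protein classes: %s",
                paste(names(table(cls$class)), table(cls$class),
                      sep = "=", collapse = ", ")))

## Immunopeptides: detected only under treatment (t-test p < 0.05)
message("Condition-specific immunopeptides ...")
imm <- read_intensity_tsv(file.path(sim, "immunopeptides.tsv"))
imm_i <- impute_downshifted_normal(imm, 0.3, 1.8, seed = seed)
spec <- detect_condition_specific(imm, imm_i, p_threshold = 0.05)
write.table(spec, file.path(out, "condition_specific_peptides.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
truth_ids <- readLines(file.path(sim, "immunopeptides_treated_only_truth.txt"))
message(sprintf("  %d treated-only peptides (planted %d; recovered %.0f%%)",
                sum(spec$direction == "treated-only"), length(truth_ids),
                100 * mean(truth_ids %in% spec$feature_id)))
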