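#!/usr/bin/env Rscript
# Step 5: the immunoproteome prediction run end to end on the simulated
# inputs: select productive events (SE exclusion, RI inclusion),
# reconstruct and translate altered transcripts, digest into unique
# 8-14mers, keep peptides absent from the canonical proteome, score them
# with the offline toy MHC-I scorer, and check recovery of the planted
# neoepitopes. Also: overlap statistics between event-derived gene sets
# and a 9-mer sequence logo of the candidate set.

suppressPackageStartupMessages(library(spliceotope))
seed <- 20260927L
sim <- "results/simulated"
out <- "results/neopeptides"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- pipeline_config(
  rmats_dir = file.path(sim, "rmats"),
  genome_fasta = file.path(sim, "ref", "genome.fa"),
  gtf = file.path(sim, "ref", "annotation.gtf"),
  proteome_fasta = file.path(sim, "ref", "proteome.fa"),
  out_dir = out, seed = seed)
res <- run_pipeline(cfg)

truth <- read.delim(file.path(sim, "event_truth.tsv"))
planted <- truth$planted_peptide[truth$planted %in% TRUE]
message(sprintf("%d candidate peptides from %d productive events",
                nrow(res$candidates), length(unique(res$candidates$event_id))))
message(sprintf("planted neoepitopes recovered: %d/%d",
                sum(planted %in% res$candidates$peptide), length(planted)))

proteome <- read_proteome_fasta(file.path(sim, "ref", "proteome.fa"))
haystack <- paste(proteome, collapse = "#")
fp <- sum(vapply(res$candidates$peptide, function(p)
  grepl(p, haystack, fixed = TRUE), logical(1)))
message("canonical-substring false positives: ", fp)

binders <- table(res$candidates$binder_class)
message("toy binder classes: ",
        paste(names(binders), binders, sep = "=", collapse = ", "))

# 9-mer logo of the candidate set
nine <- res$candidates$peptide[nchar(res$candidates$peptide) == 9]
if (length(nine) >= 10) {
  logo <- peptide_logo_matrix(nine)
  write.table(
    data.frame(position = 1:9,
               information_bits = round(logo$information_content, 4)),
    file.path(out, "logo_information_content.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
}

# overlap of SE- and RI-regulated gene sets over all tested genes
message("SE/RI gene-set overlap:")
print(res$overlap, row.names = FALSE)
message("Outputs under ", out)
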