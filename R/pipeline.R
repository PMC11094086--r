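# End-to-end pipeline: rMATS tables + genome/annotation/proteome (and,
# optionally, intensity matrices) to significant events, sequence features,
# neopeptide candidates and overlap statistics.

#' Build a validated pipeline configuration
#'
#' @param rmats_dir Directory of `*.MATS.JC.txt` tables.
#' @param genome_fasta,gtf,proteome_fasta Reference file paths.
#' @param out_dir Output directory.
#' @param max_fdr,min_abs_dpsi Event significance cut-offs.
#' @param treated_group Which rMATS sample group is treated (1 or 2).
#' @param allele MHC-I allele label for the binding stage.
#' @param proteome_tsv,phospho_tsv Optional intensity matrices
#'   ([write_intensity_tsv()] format) for the differential stage.
#' @param run_binding Run the toy binding scorer over novel candidates.
#' @param seed Integer seed for every stochastic stage.
#' @return A validated config list.
#' @export
pipeline_config <- function(rmats_dir, genome_fasta, gtf, proteome_fasta,
                            out_dir, max_fdr = 0.05, min_abs_dpsi = 0.1,
                            treated_group = 1L, allele = "HLA-A*02:01",
                            proteome_tsv = NULL, phospho_tsv = NULL,
                            run_binding = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$max_fdr > 0, cfg$max_fdr < 1, cfg$min_abs_dpsi >= 0,
            cfg$treated_group %in% c(1L, 2L), is.numeric(cfg$seed))
  for (f in c("genome_fasta", "gtf", "proteome_fasta")) {
    if (!file.exists(cfg[[f]])) stop("missing input: ", f, " = ", cfg[[f]])
  }
  if (!dir.exists(cfg$rmats_dir)) stop("missing input: rmats_dir = ", cfg$rmats_dir)
  cfg
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

# flatten list columns for TSV output
flatten_events <- function(ev) {
  for (cc in names(ev)) {
    if (is.list(ev[[cc]])) {
      ev[[cc]] <- vapply(ev[[cc]], function(v) paste(v, collapse = ","), character(1))
    }
  }
  ev
}

#' Run the full analysis pipeline
#'
#' Stages, in order: read rMATS tables, apply the FDR/|dPSI| significance
#' filter, classify directions and count families; extract SE/RI sequence
#' features; select productive events (SE exclusion, RI inclusion),
#' reconstruct and translate altered transcripts, digest into unique
#' 8-14mers and keep those absent from the canonical proteome; optionally
#' score candidates with the toy MHC-I scorer; optionally run the
#' Perseus-style differential stage on supplied intensity matrices; test
#' the overlap between SE- and RI-regulated gene sets. Outputs are TSVs in
#' `out_dir` plus `run_metadata.tsv` recording every parameter and the
#' seed.
#'
#' @param cfg Config from [pipeline_config()].
#' @return Invisibly, a list with the main result tables (`events`,
#'   `counts`, `skew`, `features`, `candidates`, `overlap`, and `diff_*`
#'   when intensity matrices were supplied).
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome_fasta(cfg$genome_fasta)
  models <- read_gene_models(cfg$gtf)
  proteome <- read_proteome_fasta(cfg$proteome_fasta)

  events <- read_rmats_dir(cfg$rmats_dir, cfg$treated_group)
  sig <- filter_significant(events, cfg$max_fdr, cfg$min_abs_dpsi)
  sig <- classify_direction(sig)
  counts <- count_by_type(sig)
  skew <- family_skew_table(counts)
  write_tsv(flatten_events(sig), file.path(cfg$out_dir, "significant_events.tsv"))
  write_tsv(as.data.frame.table(counts, responseName = "count"),
            file.path(cfg$out_dir, "event_counts.tsv"))
  write_tsv(skew, file.path(cfg$out_dir, "family_skew.tsv"))

  feat_events <- sig[sig$event_type %in% c("SE", "RI"), , drop = FALSE]
  features <- if (nrow(feat_events) > 0) {
    extract_features(feat_events, genome)
  } else data.frame()
  write_tsv(features, file.path(cfg$out_dir, "features.tsv"))

  productive <- select_productive_events(sig)
  model_by_gene <- setNames(models, vapply(models, `[[`, character(1), "gene_id"))
  cand_rows <- list()
  for (i in seq_len(nrow(productive))) {
    ev <- productive[i, ]
    gm <- model_by_gene[[ev$gene_id]]
    if (is.null(gm)) stop("no gene model for ", ev$gene_id)
    alt <- reconstruct_transcript(ev, gm, genome)
    peps <- digest_kmers(alt$protein)
    if (length(peps) == 0L) next
    nov <- novelty_filter(peps, proteome)
    nov <- nov[nov$novel, , drop = FALSE]
    if (nrow(nov) > 0L) {
      cand_rows[[length(cand_rows) + 1L]] <- data.frame(
        peptide = nov$peptide, event_id = ev$event_id, gene_id = ev$gene_id,
        variant = alt$variant, frameshifted = alt$frameshifted,
        premature_stop = alt$premature_stop, novel = TRUE)
    }
  }
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(peptide = character(0), event_id = character(0),
               gene_id = character(0), variant = character(0),
               frameshifted = logical(0), premature_stop = logical(0),
               novel = logical(0))
  if (isTRUE(cfg$run_binding) && nrow(candidates) > 0L) {
    candidates <- predict_binding(candidates, allele = cfg$allele,
                                  backend = "toy_scorer", proteome = proteome,
                                  seed = cfg$seed)
  }
  write_tsv(candidates, file.path(cfg$out_dir, "candidates.tsv"))
  if (nrow(candidates) > 0L) {
    fa <- Biostrings::AAStringSet(candidates$peptide)
    names(fa) <- sprintf("%s|%s|%s", candidates$peptide, candidates$event_id,
                         candidates$variant)
    Biostrings::writeXStringSet(fa, file.path(cfg$out_dir, "candidates.fasta"))
  }

  # set overlap between SE- and RI-regulated genes over all tested genes
  universe <- unique(events$gene_id)
  se_genes <- unique(sig$gene_id[sig$event_type == "SE"])
  ri_genes <- unique(sig$gene_id[sig$event_type == "RI"])
  overlap <- if (length(se_genes) && length(ri_genes)) {
    ov <- hypergeometric_overlap(se_genes, ri_genes, universe)
    data.frame(set_a = "SE_genes", set_b = "RI_genes",
               as.data.frame(ov))
  } else data.frame()
  write_tsv(overlap, file.path(cfg$out_dir, "overlaps.tsv"))

  results <- list(events = sig, counts = counts, skew = skew,
                  features = features, candidates = candidates,
                  overlap = overlap)

  for (stage in c("proteome", "phospho")) {
    tsv <- cfg[[paste0(stage, "_tsv")]]
    if (is.null(tsv)) next
    preset <- perseus_preset(stage)
    meta_cols <- if (stage == "phospho")
      c("protein_id", "localization_prob") else NULL
    im <- read_intensity_tsv(tsv, meta_cols = meta_cols)
    if (stage == "phospho") im <- filter_phosphosites(im, preset$min_localization)
    im <- filter_valid_fraction(im, preset$valid_fraction)
    if (stage == "phospho") im <- median_normalize(im)
    imp <- impute_downshifted_normal(im, preset$width, preset$downshift,
                                     seed = cfg$seed)
    res <- sam_test(imp, s0 = preset$s0, fdr_threshold = preset$fdr,
                    seed = cfg$seed)
    write_tsv(res, file.path(cfg$out_dir, paste0("diff_", stage, ".tsv")))
    results[[paste0("diff_", stage)]] <- res
    if (stage == "phospho") {
      res$protein_id <- im$feature_meta$protein_id
      cls <- classify_protein_phospho(res)
      write_tsv(cls, file.path(cfg$out_dir, "phospho_classes.tsv"))
      results$phospho_classes <- cls
    }
  }

  meta <- data.frame(
    parameter = c("max_fdr", "min_abs_dpsi", "treated_group", "allele",
                  "seed", "package_version"),
    value = c(cfg$max_fdr, cfg$min_abs_dpsi, cfg$treated_group, cfg$allele,
              cfg$seed, as.character(utils::packageVersion("spliceotope"))))
  write_tsv(meta, file.path(cfg$out_dir, "run_metadata.tsv"))
  invisible(results)
}
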