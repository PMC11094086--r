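# Shared fixtures, all generated in code at test time.

# A 5-gene toy genome with 3 RI and 2 SE neoepitopes planted, plus the
# planted-event truth table (significant by construction).
planted_genome <- function(seed = 11, n_filler = 0) {
  tg <- make_toy_genome(5, seed = seed)
  plan <- list(c("G001", "RI"), c("G002", "RI"), c("G003", "RI"),
               c("G004", "SE"), c("G005", "SE"))
  truths <- NULL
  for (i in seq_along(plan)) {
    p <- plant_neoepitope(tg, plan[[i]][1], plan[[i]][2], seed = seed + i)
    tg <- p$genome
    truths <- rbind(truths, transform(p$truth, planted = TRUE))
  }
  if (n_filler > 0) {
    filler <- data.frame(
      event_id = NA_character_,
      event_type = rep(c("SE", "RI", "MXE", "A3SS", "A5SS"), length.out = n_filler),
      gene_id = rep(paste0("G00", 1:5), length.out = n_filler),
      true_psi_control = 0.5, true_psi_treated = 0.55,
      is_significant = FALSE, planted_peptide = NA_character_, planted = FALSE)
    truths <- rbind(truths, filler)
  }
  list(tg = tg, truths = truths)
}

# A hand-built single-gene genome for reconstruction edge cases: exon
# lengths and CDS placement fully controlled. Returns genome (named char),
# gene model, and the canonical protein.
manual_gene <- function(exon_seqs, intron_seqs, strand = "+",
                        utr5 = "GGGTTT", utr3 = "CCCAAA", pad = 30L,
                        chrom = "chrT") {
  stopifnot(length(intron_seqs) == length(exon_seqs) - 1)
  n <- length(exon_seqs)
  full_ex <- exon_seqs
  full_ex[1] <- paste0(utr5, full_ex[1])
  full_ex[n] <- paste0(full_ex[n], "TAA", utr3)
  pad5 <- strrep("T", pad); pad3 <- strrep("G", pad)
  pos <- nchar(pad5)
  exons <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    exons[i, ] <- c(pos + 1L, pos + nchar(full_ex[i]))
    pos <- pos + nchar(full_ex[i])
    if (i < n) pos <- pos + nchar(intron_seqs[i])
  }
  cds <- exons
  cds[1, 1] <- exons[1, 1] + nchar(utr5)
  cds[n, 2] <- exons[n, 2] - nchar(utr3) - 3L
  layout <- paste0(pad5, paste0(vapply(seq_len(n), function(i)
    paste0(full_ex[i], if (i < n) intron_seqs[i] else ""), character(1)),
    collapse = ""), pad3)
  L <- nchar(layout)
  if (strand == "+") {
    genome_seq <- layout
    ex <- exons; cd <- cds; start_codon <- cds[1, 1]
  } else {
    genome_seq <- revcomp(layout)
    flip <- function(m) cbind(L - m[, 2] + 1L, L - m[, 1] + 1L)
    ex <- flip(exons); cd <- flip(cds)
    start_codon <- L - cds[1, 1] + 1L
  }
  strip_attrs <- function(x) { attributes(x) <- NULL; x }
  model <- list(gene_id = "MANUAL", transcript_id = "MANUAL.t1", chrom = chrom,
                strand = strand,
                exons = data.frame(start = ex[, 1], end = ex[, 2]),
                cds = data.frame(start = cd[, 1], end = cd[, 2]),
                start_codon = start_codon)
  genome <- setNames(genome_seq, chrom)
  protein <- strip_attrs(translate_dna(paste(exon_seqs, collapse = "")))
  list(genome = genome, model = model, protein = protein, exons_tx = exons)
}

# rMATS-style SE event row for the j-th (transcript-order) exon of a model.
se_event_row <- function(model, j, event_id = "SE_man", delta_psi = -0.5) {
  ex <- model$exons
  data.frame(event_id = event_id, event_type = "SE", gene_id = model$gene_id,
             chrom = model$chrom, strand = model$strand,
             exonStart_0base = ex$start[j] - 1L, exonEnd = ex$end[j],
             upstreamES = ex$start[j - 1] - 1L, upstreamEE = ex$end[j - 1],
             downstreamES = ex$start[j + 1] - 1L, downstreamEE = ex$end[j + 1],
             delta_psi = delta_psi, fdr = 0.001, direction = "DOWN",
             variant = "SE_exclusion")
}

ri_event_row <- function(model, j, event_id = "RI_man", delta_psi = 0.5) {
  ex <- model$exons
  data.frame(event_id = event_id, event_type = "RI", gene_id = model$gene_id,
             chrom = model$chrom, strand = model$strand,
             riExonStart_0base = min(ex$start[j], ex$start[j + 1]) - 1L,
             riExonEnd = max(ex$end[j], ex$end[j + 1]),
             upstreamES = ex$start[j] - 1L, upstreamEE = ex$end[j],
             downstreamES = ex$start[j + 1] - 1L, downstreamEE = ex$end[j + 1],
             delta_psi = delta_psi, fdr = 0.001, direction = "UP",
             variant = "RI_inclusion")
}

# random codons for a protein without stops (independent of encode_peptide)
random_cds <- function(n_codons) {
  ct <- Biostrings::GENETIC_CODE
  codons <- names(ct)[ct != "*"]
  paste(c("ATG", sample(codons, n_codons - 1, replace = TRUE)), collapse = "")
}
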