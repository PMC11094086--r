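#' Generate a toy multi-gene genome with annotation and proteome
#'
#' Builds a small genome in which every gene is a single multi-exon
#' protein-coding transcript: a short 5' UTR, coding exons whose lengths are
#' multiples of three (every intron sits at codon phase 0, which makes
#' in-frame event planting straightforward), GT..AG introns, a stop codon and
#' a short 3' UTR, surrounded by intergenic padding. One chromosome per gene;
#' strand drawn at random. The emitted canonical protein is, by construction,
#' the translation of the concatenated CDS.
#'
#' @param n_genes Number of genes (one per chromosome), `>= 1`.
#' @param seed Integer seed; generation is bit-reproducible.
#' @param n_exons_range Integer range to draw the exon count from (min 3).
#' @param cds_codons_range Range of codons per coding exon segment.
#' @param intron_length_range Range of intron lengths (nt, made multiples of 3).
#' @param utr_length Length of each UTR (nt).
#' @param pad Intergenic padding on each side of the gene (nt); must exceed
#'   any RNA-map flank you intend to use.
#' @return An object of class `toy_genome`: a list with `genes` (internal
#'   per-gene layouts), and accessors [toy_chrom_sequences()],
#'   [toy_gene_models()], [toy_proteome()], [toy_gtf()].
#' @seealso [plant_neoepitope()], [plant_splice_events()], [write_toy_genome()]
#' @export
make_toy_genome <- function(n_genes, seed,
                            n_exons_range = c(3L, 5L),
                            cds_codons_range = c(8L, 30L),
                            intron_length_range = c(60L, 150L),
                            utr_length = 9L,
                            pad = 500L) {
  stopifnot(n_genes >= 1, n_exons_range[1] >= 2)
  withr::with_seed(seed, {
    genes <- lapply(seq_len(n_genes), function(g) {
      n_exons <- sample(seq(n_exons_range[1], n_exons_range[2]), 1L)
      n_codons <- sample(seq(cds_codons_range[1], cds_codons_range[2]),
                         n_exons, replace = TRUE)
      protein <- random_protein(sum(n_codons))
      # split the protein across exons and encode each segment independently
      bounds <- cumsum(c(0L, n_codons))
      cds_exons <- vapply(seq_len(n_exons), function(i) {
        seg <- substr(protein, bounds[i] + 1L, bounds[i + 1L])
        dna <- encode_peptide(seg)
        if (i == 1L) substr(dna, 1L, 3L) <- "ATG"
        dna
      }, character(1))
      introns <- vapply(seq_len(n_exons - 1L), function(i) {
        len <- sample(seq(intron_length_range[1], intron_length_range[2]), 1L)
        len <- len - (len %% 3L)   # phase-0 friendly; keeps RI arithmetic clean
        body <- random_dna(len - 4L)
        paste0("GT", body, "AG")
      }, character(1))
      list(
        gene_id = sprintf("G%03d", g),
        transcript_id = sprintf("G%03d.t1", g),
        chrom = sprintf("chr%d", g),
        strand = sample(c("+", "-"), 1L),
        pad5 = random_dna(pad),
        utr5 = random_dna(utr_length),
        cds_exons = cds_exons,
        introns = as.list(introns),
        stop_codon = sample(c("TAA", "TAG", "TGA"), 1L),
        utr3 = random_dna(utr_length),
        pad3 = random_dna(pad),
        planted = NULL
      )
    })
    structure(list(genes = genes, seed = seed), class = "toy_genome")
  })
}

#' @export
print.toy_genome <- function(x, ...) {
  n_planted <- sum(vapply(x$genes, function(g) !is.null(g$planted), logical(1)))
  cat(sprintf("toy_genome: %d genes, %d with planted neoepitopes (seed %d)\n",
              length(x$genes), n_planted, x$seed))
  invisible(x)
}

# ---- assembly ---------------------------------------------------------------

# Plus-strand layout of one gene: sequence plus 1-based inclusive coordinate
# tables. The layout is always in coding orientation; strand flipping happens
# at chromosome assembly.
gene_layout <- function(gene) {
  n <- length(gene$cds_exons)
  exon_seqs <- gene$cds_exons
  exon_seqs[1] <- paste0(gene$utr5, exon_seqs[1])
  exon_seqs[n] <- paste0(exon_seqs[n], gene$stop_codon, gene$utr3)
  seq_parts <- character(0)
  pos <- nchar(gene$pad5)
  exons <- matrix(NA_integer_, n, 2)
  introns <- if (n > 1) matrix(NA_integer_, n - 1, 2) else matrix(NA_integer_, 0, 2)
  for (i in seq_len(n)) {
    exons[i, ] <- c(pos + 1L, pos + nchar(exon_seqs[i]))
    pos <- pos + nchar(exon_seqs[i])
    if (i < n) {
      introns[i, ] <- c(pos + 1L, pos + nchar(gene$introns[[i]]))
      pos <- pos + nchar(gene$introns[[i]])
    }
  }
  cds <- exons
  cds[1, 1] <- exons[1, 1] + nchar(gene$utr5)
  cds[n, 2] <- exons[n, 1] + nchar(exon_seqs[n]) -
    nchar(gene$utr3) - 3L - 1L  # exclude stop codon and 3' UTR
  stop_iv <- c(cds[n, 2] + 1L, cds[n, 2] + 3L)
  seqall <- paste0(gene$pad5,
                   paste0(vapply(seq_len(n), function(i) {
                     paste0(exon_seqs[i],
                            if (i < n) gene$introns[[i]] else "")
                   }, character(1)), collapse = ""),
                   gene$pad3)
  list(seq = seqall, exons = exons, introns = introns, cds = cds,
       stop_codon = stop_iv, start_pos = cds[1, 1], length = nchar(seqall))
}

flip_iv <- function(iv, L) cbind(L - iv[, 2, drop = FALSE] + 1L,
                                 L - iv[, 1, drop = FALSE] + 1L)

# Full gene model in genomic coordinates (1-based inclusive), exons and CDS
# ordered 5'->3' in transcript orientation.
gene_model_of <- function(gene) {
  lay <- gene_layout(gene)
  L <- lay$length
  if (gene$strand == "+") {
    exons <- lay$exons; cds <- lay$cds
    start_codon <- lay$start_pos
    stop_iv <- lay$stop_codon
  } else {
    exons <- flip_iv(lay$exons, L)
    cds <- flip_iv(lay$cds, L)
    start_codon <- L - lay$start_pos + 1L
    stop_iv <- rev(L - lay$stop_codon + 1L)
  }
  list(gene_id = gene$gene_id, transcript_id = gene$transcript_id,
       chrom = gene$chrom, strand = gene$strand,
       exons = data.frame(start = exons[, 1], end = exons[, 2]),
       cds = data.frame(start = cds[, 1], end = cds[, 2]),
       start_codon = start_codon,
       stop_codon = data.frame(start = stop_iv[1], end = stop_iv[2]))
}

#' Chromosome sequences of a toy genome
#' @param tg A `toy_genome`.
#' @return Named character vector, one DNA string per chromosome.
#' @export
toy_chrom_sequences <- function(tg) {
  out <- vapply(tg$genes, function(g) {
    s <- gene_layout(g)$seq
    if (g$strand == "-") revcomp(s) else s
  }, character(1))
  names(out) <- vapply(tg$genes, `[[`, character(1), "chrom")
  out
}

#' Gene models of a toy genome
#' @param tg A `toy_genome`.
#' @return List of gene models (gene_id, transcript_id, chrom, strand,
#'   `exons`/`cds` data frames in transcript order, `start_codon`).
#' @export
toy_gene_models <- function(tg) {
  models <- lapply(tg$genes, gene_model_of)
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  models
}

#' Canonical proteome of a toy genome
#' @param tg A `toy_genome`.
#' @return Named character vector of protein sequences (one per gene).
#' @export
toy_proteome <- function(tg) {
  out <- vapply(tg$genes, function(g) {
    translate_dna(paste(g$cds_exons, collapse = ""))
  }, character(1))
  names(out) <- vapply(tg$genes, `[[`, character(1), "gene_id")
  out
}

#' GTF annotation of a toy genome
#' @param tg A `toy_genome`.
#' @return A [GenomicRanges::GRanges] with gene/transcript/exon/CDS/
#'   start_codon/stop_codon features, exportable via rtracklayer.
#' @export
toy_gtf <- function(tg) {
  rows <- list()
  for (g in tg$genes) {
    m <- gene_model_of(g)
    ex <- m$exons[order(m$exons$start), , drop = FALSE]
    cd <- m$cds[order(m$cds$start), , drop = FALSE]
    add <- function(type, start, end) {
      data.frame(chrom = m$chrom, start = start, end = end,
                 strand = m$strand, type = type,
                 gene_id = m$gene_id, transcript_id = m$transcript_id)
    }
    rows[[length(rows) + 1L]] <- rbind(
      add("gene", min(ex$start), max(ex$end)),
      add("transcript", min(ex$start), max(ex$end)),
      add("exon", ex$start, ex$end),
      add("CDS", cd$start, cd$end),
      add("start_codon", m$start_codon - if (m$strand == "-") 2L else 0L,
          m$start_codon + if (m$strand == "-") 0L else 2L),
      add("stop_codon", m$stop_codon$start, m$stop_codon$end)
    )
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "spliceotope", type = df$type,
    # exon lengths are multiples of 3, so every CDS segment is phase 0
    phase = ifelse(df$type == "CDS", 0L, NA_integer_),
    gene_id = df$gene_id, transcript_id = df$transcript_id)
  gr
}

#' Write a toy genome to FASTA/GTF files
#'
#' Emits `genome.fa`, `proteome.fa` (canonical proteins) and
#' `annotation.gtf` under `dir`.
#'
#' @param tg A `toy_genome`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_toy_genome <- function(tg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             proteome = file.path(dir, "proteome.fa"),
             gtf = file.path(dir, "annotation.gtf"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(toy_chrom_sequences(tg)), paths["genome"])
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(toy_proteome(tg)), paths["proteome"])
  rtracklayer::export(toy_gtf(tg), paths["gtf"], format = "gtf")
  invisible(paths)
}

#' Mirror a toy genome (reverse-complement every chromosome)
#'
#' Flips the strand of every gene; because chromosome assembly honours the
#' strand flag, the emitted chromosome sequences become exact reverse
#' complements and all annotation coordinates flip accordingly. Transcript
#' content -- and therefore all sequence features and peptides -- is
#' unchanged, which is the property the test-suite checks.
#'
#' @param tg A `toy_genome`.
#' @return The mirrored `toy_genome`.
#' @export
mirror_toy_genome <- function(tg) {
  tg$genes <- lapply(tg$genes, function(g) {
    g$strand <- if (g$strand == "+") "-" else "+"
    g
  })
  tg
}

#' Read a genome FASTA as a named character vector
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*", "", names(x))
  out
}

#' Read a proteome FASTA as a named character vector
#' @param path FASTA file path.
#' @return Named character vector of protein sequences.
#' @export
read_proteome_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*", "", names(x))
  out
}
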