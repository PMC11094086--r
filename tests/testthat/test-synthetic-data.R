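# Synthetic-data generators: determinism, construction guarantees, and
# recoverability of the planted truth.

test_that("toy genome generation is seeded and deterministic", {
  a <- make_toy_genome(5, seed = 7)
  b <- make_toy_genome(5, seed = 7)
  expect_identical(toy_chrom_sequences(a), toy_chrom_sequences(b))
  expect_identical(toy_proteome(a), toy_proteome(b))
  c <- make_toy_genome(5, seed = 8)
  expect_false(identical(toy_chrom_sequences(a), toy_chrom_sequences(c)))
})

test_that("emitted proteome equals codon-table translation of the genomic CDS", {
  tg <- make_toy_genome(6, seed = 3)
  genome <- toy_chrom_sequences(tg)
  prot <- toy_proteome(tg)
  for (m in toy_gene_models(tg)) {
    cds_seq <- paste(vapply(seq_len(nrow(m$cds)), function(i) {
      s <- substr(genome[[m$chrom]], m$cds$start[i], m$cds$end[i])
      if (m$strand == "-") revcomp(s) else s
    }, character(1)), collapse = "")
    # independent oracle: Biostrings translation
    ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq)))
    expect_false(grepl("\\*", ref))
    expect_identical(ref, unname(prot[m$gene_id]))
  }
})

test_that("toy genome round-trips through its own FASTA/GTF readers", {
  tg <- make_toy_genome(3, seed = 5)
  dir <- withr::local_tempdir()
  write_toy_genome(tg, dir)
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  expect_identical(genome, toy_chrom_sequences(tg))
  models <- read_gene_models(file.path(dir, "annotation.gtf"))
  orig <- toy_gene_models(tg)
  for (tx in names(orig)) {
    expect_equal(models[[tx]]$exons, orig[[tx]]$exons)
    expect_equal(models[[tx]]$cds, orig[[tx]]$cds)
    expect_identical(models[[tx]]$strand, orig[[tx]]$strand)
    expect_equal(models[[tx]]$start_codon, orig[[tx]]$start_codon)
  }
  prot <- read_proteome_fasta(file.path(dir, "proteome.fa"))
  expect_identical(prot, toy_proteome(tg))
})

test_that("planted rMATS tables are deterministic and obey the count model", {
  pg <- planted_genome(seed = 21, n_filler = 10)
  a <- plant_splice_events(pg$tg, pg$truths, seed = 9)
  b <- plant_splice_events(pg$tg, pg$truths, seed = 9)
  expect_identical(a, b)

  # symmetric PSI: expected IncLevelDifference ~ 0 over 200 events
  tg <- make_toy_genome(5, seed = 2)
  tr <- data.frame(event_type = "SE", gene_id = rep(paste0("G00", 1:5), 40),
                   true_psi_control = 0.5, true_psi_treated = 0.5,
                   is_significant = FALSE)
  ps <- plant_splice_events(tg, tr, reads_per_event = 500, seed = 4)
  expect_lt(abs(mean(ps$tables$SE$IncLevelDifference)), 0.02)

  # degenerate binomial: PSI 1 means zero skipping counts
  tr1 <- data.frame(event_type = "RI", gene_id = "G001",
                    true_psi_control = 1, true_psi_treated = 1,
                    is_significant = FALSE)
  ps1 <- plant_splice_events(tg, tr1, reads_per_event = 300, seed = 4)
  expect_identical(ps1$tables$RI$SJC_SAMPLE_1, "0,0")
  expect_identical(ps1$tables$RI$SJC_SAMPLE_2, "0,0")

  # truth-table invariant is enforced
  bad <- data.frame(event_type = "SE", gene_id = "G001",
                    true_psi_control = 0.5, true_psi_treated = 0.55,
                    is_significant = TRUE)
  expect_error(plant_splice_events(tg, bad, seed = 1), "is_significant")
})

test_that("downstream filter recovers exactly the planted significant set", {
  tg <- make_toy_genome(5, seed = 31)
  n <- 1000; n_sig <- 300
  set.seed(17)
  truths <- data.frame(
    event_type = sample(c("SE", "RI", "MXE", "A3SS", "A5SS"), n, replace = TRUE),
    gene_id = sample(paste0("G00", 1:5), n, replace = TRUE),
    true_psi_control = 0.5, true_psi_treated = 0.5,
    is_significant = rep(c(TRUE, FALSE), c(n_sig, n - n_sig)))
  truths$true_psi_treated[truths$is_significant] <-
    0.5 + sample(c(-1, 1), n_sig, replace = TRUE) * runif(n_sig, 0.25, 0.45)
  ps <- plant_splice_events(tg, truths, reads_per_event = 2000, seed = 8)
  dir <- withr::local_tempdir()
  write_rmats_tables(ps$tables, dir)
  ev <- read_rmats_dir(dir)
  sig <- filter_significant(ev)
  expect_setequal(sig$event_id, ps$truth$event_id[ps$truth$is_significant])
})

test_that("planted neoepitopes translate into the expected altered proteins", {
  tg <- make_toy_genome(4, seed = 41)
  # RI: retained-intron readthrough contains the requested peptide
  p <- plant_neoepitope(tg, "G001", "RI", peptide = "KLFERWNTLV", seed = 2)
  tg2 <- p$genome
  genome <- toy_chrom_sequences(tg2)
  models <- toy_gene_models(tg2)
  m <- models[[which(vapply(models, `[[`, "", "gene_id") == "G001")]]
  pl <- tg2$genes[[1]]$planted
  ev <- ri_event_row(m, pl$index, "RI_1")
  alt <- reconstruct_transcript(ev, m, genome)
  expect_true(grepl("KLFERWNTLV", alt$protein, fixed = TRUE))
  expect_true(alt$premature_stop)
  expect_false(alt$frameshifted)
  # peptide is guaranteed absent from the canonical proteome
  expect_false(any(grepl("KLFERWNTLV", toy_proteome(tg2), fixed = TRUE)))

  # SE: exclusion junction reads as the peptide; canonical does not contain it
  p2 <- plant_neoepitope(tg2, "G002", "SE", seed = 3)
  tg3 <- p2$genome
  pep <- p2$truth$planted_peptide
  genome3 <- toy_chrom_sequences(tg3)
  models3 <- toy_gene_models(tg3)
  m2 <- models3[[which(vapply(models3, `[[`, "", "gene_id") == "G002")]]
  pl2 <- tg3$genes[[2]]$planted
  ev2 <- se_event_row(m2, pl2$index, "SE_1")
  alt2 <- reconstruct_transcript(ev2, m2, genome3)
  expect_true(grepl(pep, alt2$protein, fixed = TRUE))
  expect_false(alt2$frameshifted)
  expect_false(any(grepl(pep, toy_proteome(tg3), fixed = TRUE)))
  # in-frame deletion: exclusion protein = canonical minus the exon residues
  canon <- toy_proteome(tg3)[["G002"]]
  exon_aa <- nchar(tg3$genes[[2]]$cds_exons[pl2$index]) / 3
  expect_equal(nchar(alt2$protein), nchar(canon) - exon_aa)

  # a user-supplied peptide already in the proteome is rejected
  canon1 <- toy_proteome(tg3)[["G003"]]
  clash <- substr(canon1, 3, 12)
  expect_error(plant_neoepitope(tg3, "G003", "RI", peptide = clash, seed = 5),
               "collides")
})

test_that("intensity simulation honours noise, effects and censoring switches", {
  # no censoring: complete matrix
  sim <- simulate_intensity_matrix(200, 3, effects = 0, noise_sd = 0.5,
                                   dropout_rate = 0, seed = 1)
  expect_false(anyNA(sim$matrix$values))
  expect_identical(sim$matrix$groups, rep(c("control", "treated"), each = 3))

  # zero noise, effect 2: every non-null feature separates perfectly
  eff <- rep(c(0, 2), c(150, 50))
  sim2 <- simulate_intensity_matrix(200, 3, effects = eff, noise_sd = 0,
                                    dropout_rate = 0, seed = 2)
  d <- rowMeans(sim2$matrix$values[, 4:6]) - rowMeans(sim2$matrix$values[, 1:3])
  expect_equal(unname(d), eff)
  expect_identical(sim2$truth$is_null, eff == 0)

  # MNAR censoring hits low intensities more often
  sim3 <- simulate_intensity_matrix(4000, 3, effects = 0, noise_sd = 0.5,
                                    dropout_rate = 0.6, seed = 3)
  vals <- sim3$matrix$values
  miss_rate_low <- mean(is.na(vals[rowMeans(vals, na.rm = TRUE) < 23, ]))
  miss_rate_high <- mean(is.na(vals[rowMeans(vals, na.rm = TRUE) > 27, ]))
  expect_gt(miss_rate_low, miss_rate_high + 0.05)

  # determinism
  sim4 <- simulate_intensity_matrix(4000, 3, effects = 0, noise_sd = 0.5,
                                    dropout_rate = 0.6, seed = 3)
  expect_identical(sim3, sim4)
})
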