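# Altered-transcript reconstruction, translation, digestion, novelty and
# binding-prediction interfaces.

test_that("productive-event selection keeps SE-down and RI-up only", {
  ev <- data.frame(event_id = paste0("E", 1:5),
                   event_type = c("SE", "SE", "RI", "RI", "MXE"),
                   direction = c("DOWN", "UP", "UP", "DOWN", "UP"))
  sel <- select_productive_events(ev)
  expect_identical(sel$event_id, c("E1", "E3"))
  expect_identical(sel$variant, c("SE_exclusion", "RI_inclusion"))
})

test_that("SE exclusion reconstructs an in-frame deletion or a frameshift", {
  set.seed(2)
  for (strand in c("+", "-")) {
    # 60-nt internal exon: in-frame deletion of 20 residues
    mg <- manual_gene(c(random_cds(6), substr(random_cds(21), 4, 63),
                        random_cds(8)),
                      c(strrep("C", 45), strrep("G", 45)), strand = strand)
    ev <- se_event_row(mg$model, 2)
    alt <- reconstruct_transcript(ev, mg$model, mg$genome)
    expect_false(alt$frameshifted)
    expect_false(alt$premature_stop)
    expect_identical(nchar(alt$protein), nchar(mg$protein) - 20L)
    # exclusion protein = canonical minus the exon residues
    expect_identical(as.character(alt$protein),
                     paste0(substr(mg$protein, 1, 6),
                            substr(mg$protein, 27, nchar(mg$protein))))
    # unaltered reconstruction (RI then SE of nothing) is impossible here,
    # but translating the full exon chain must give the canonical protein
    full <- list(sequence = spliceotope:::blocks_sequence(
                   mg$model$exons, strand, mg$genome, mg$model$chrom),
                 tx_start = spliceotope:::tx_offset_of(
                   mg$model$exons, strand, mg$model$start_codon))
    expect_identical(as.character(translate_canonical(full)), mg$protein)
  }

  # 61-nt exon: frameshift with a premature stop expected downstream
  mg61 <- manual_gene(c(random_cds(6), substr(random_cds(22), 4, 64),
                        random_cds(30)),
                      c(strrep("C", 45), strrep("G", 45)))
  ev61 <- se_event_row(mg61$model, 2)
  alt61 <- reconstruct_transcript(ev61, mg61$model, mg61$genome)
  expect_true(alt61$frameshifted)
  # event coordinates that match no annotated exon are an error
  bad <- ev61; bad$exonStart_0base <- bad$exonStart_0base + 1L
  expect_error(reconstruct_transcript(bad, mg61$model, mg61$genome),
               "reconciliation error")
})

test_that("RI inclusion splices the intron in and flags premature stops", {
  set.seed(3)
  for (strand in c("+", "-")) {
    # in-frame intron with an internal stop: readthrough truncates
    intron <- paste0("GTA", "TGA", strrep("C", 21))  # 27 nt, stop right away
    mg <- manual_gene(c(random_cds(8), substr(random_cds(10), 4, 30)),
                      intron, strand = strand)
    ev <- ri_event_row(mg$model, 1)
    alt <- reconstruct_transcript(ev, mg$model, mg$genome)
    expect_false(alt$frameshifted)
    expect_true(alt$premature_stop)
    # protein = canonical prefix (8 codons incl. start) + V from GTA
    expect_identical(as.character(alt$protein),
                     paste0(substr(mg$protein, 1, 8), "V"))
    # sequence is the exon chain with the intron retained, base by base
    ex_seqs <- vapply(seq_len(2), function(i) {
      s <- substr(mg$genome[[1]], mg$model$exons$start[i], mg$model$exons$end[i])
      if (strand == "-") revcomp(s) else s
    }, character(1))
    expect_identical(alt$sequence, paste0(ex_seqs[1], intron, ex_seqs[2]))
  }
})

test_that("a retained intron 5' of the START leaves the protein unchanged", {
  set.seed(4)
  e2 <- random_cds(9)
  # exon 1 is treated as pure UTR (model edited so CDS starts in exon 2)
  mg <- manual_gene(c("AAACCCTTT", e2), strrep("C", 30))
  model <- mg$model
  model$cds <- model$cds[2, , drop = FALSE]
  model$cds$start[1] <- model$exons$start[2]  # exon 2 opens with ATG
  model$start_codon <- model$cds$start[1]
  ev <- ri_event_row(model, 1)
  alt <- reconstruct_transcript(ev, model, mg$genome)
  expect_false(alt$premature_stop)
  expect_false(alt$frameshifted)
  expect_identical(substr(alt$sequence, alt$tx_start, alt$tx_start + 2), "ATG")
  # UTR-only change: the product equals the canonical protein
  expect_identical(as.character(alt$protein),
                   as.character(translate_dna(e2)))
})

test_that("removing the START-containing exon loses the product", {
  set.seed(5)
  mg <- manual_gene(c("GGGTTTAAA", "ATG", substr(random_cds(13), 4, 39)),
                    c(strrep("C", 30), strrep("G", 30)))
  model <- mg$model
  model$cds <- model$cds[-1, , drop = FALSE]
  model$start_codon <- model$cds$start[1]
  ev <- se_event_row(model, 2)
  alt <- reconstruct_transcript(ev, model, mg$genome)
  expect_true(alt$start_lost)
  expect_identical(as.character(alt$protein), "")
  expect_identical(attr(translate_canonical(alt), "reason"), "start_lost")
})

test_that("translation follows the standard code to the first stop", {
  expect_identical(as.character(translate_dna("ATGAAATAG")), "MK")
  expect_identical(attr(translate_dna("ATGAAATAG"), "stop_offset"), 7L)
  # 100 random CDS agree with the Biostrings oracle
  set.seed(6)
  for (i in 1:100) {
    cds <- random_cds(sample(10:60, 1))
    mine <- as.character(translate_dna(cds))
    oracle <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_identical(mine, oracle)
  }
})

test_that("k-mer digestion counts follow the closed form", {
  set.seed(7)
  # collision-free protein of length 20: sum_{k=8}^{14} (20 - k + 1) = 70
  prot <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 20), collapse = "")
  expect_identical(length(digest_kmers(prot)), 70L)
  for (L in c(15, 25, 40)) {
    p <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L, replace = TRUE),
               collapse = "")
    expect_lte(length(digest_kmers(p)), sum(pmax(0, L - 8:14 + 1)))
  }
  expect_identical(digest_kmers("AAAAAAAA"), "AAAAAAAA")  # de-duplication
  expect_identical(digest_kmers("AAAAAAA"), character(0)) # below k_min
  # digestion + novelty is idempotent and order-invariant
  peps <- digest_kmers(prot)
  expect_identical(sort(unique(c(peps, rev(peps)))), sort(peps))
})

test_that("novelty filter equals a naive all-pairs substring scan", {
  set.seed(8)
  proteome <- vapply(1:5, function(i)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 50, replace = TRUE),
          collapse = ""), character(1))
  names(proteome) <- paste0("P", 1:5)
  peptides <- c(substr(proteome[1], 5, 13),       # canonical substring
                substr(proteome[3], 20, 30),      # canonical substring
                "WWWWHHHHKK", "AVLDPQNMRF")       # almost surely novel
  got <- novelty_filter(peptides, proteome)
  oracle <- vapply(peptides, function(p) {
    !any(vapply(proteome, function(pr) grepl(p, pr, fixed = TRUE), logical(1)))
  }, logical(1))
  expect_identical(got$novel, unname(oracle))
  expect_false(got$novel[1])
  expect_false(got$novel[2])
})

test_that("binding backends score and classify candidates", {
  proteome <- setNames(vapply(1:4, function(i) {
    set.seed(i); paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                              120, replace = TRUE), collapse = "")
  }, character(1)), paste0("P", 1:4))
  # anchor-matching 9-mer scores as a strong binder under the toy matrix
  cand <- data.frame(peptide = c("YLDAAAAAV", "GGGGGGGGG", "SHORTPEP"))
  scored <- predict_binding(cand, backend = "toy_scorer", proteome = proteome,
                            seed = 2)
  expect_identical(scored$binder_class[1], "strong")
  expect_true(is.na(scored$percent_rank[3]))  # only 9-mers are scored
  # a background-typical peptide ranks near 50%
  psm <- load_toy_psm()
  pool <- unlist(lapply(proteome, function(p) {
    substring(p, 1:(nchar(p) - 8), 9:nchar(p))
  }), use.names = FALSE)
  sc <- sort(spliceotope:::toy_score_9mer(pool, psm))
  med_pep <- pool[which(spliceotope:::toy_score_9mer(pool, psm) ==
                          sc[ceiling(length(sc) / 2)])[1]]
  r_med <- predict_binding(data.frame(peptide = med_pep),
                           backend = "toy_scorer", proteome = proteome,
                           n_background = length(pool) * 2, seed = 3)
  expect_gt(r_med$percent_rank, 30)
  expect_lt(r_med$percent_rank, 70)

  # NetMHCpan-style parser round-trips a fixture file
  f <- tempfile()
  writeLines(c("Pos Peptide ID Score %Rank",
               "1 YLDAAAAAV cand1 0.88 0.21",
               "2 GGGGGGGGG cand2 0.02 35.5"), f)
  joined <- predict_binding(data.frame(peptide = c("GGGGGGGGG", "YLDAAAAAV")),
                            backend = "netmhcpan_output_parser",
                            netmhcpan_file = f)
  expect_equal(joined$percent_rank, c(35.5, 0.21))
  expect_identical(joined$binder_class, c("non-binder", "strong"))
  writeLines(c("Pos Peptide ID Score %Rank", "1 YLDAAAAAV cand1 0.88 oops"), f)
  expect_error(parse_netmhcpan(f), "format error")
})

test_that("peptide logo frequencies and information content behave", {
  logo <- peptide_logo_matrix(rep("KLFERWNTL", 25))
  expect_equal(unname(colSums(logo$freq)), rep(1, 9))
  expect_equal(unname(logo$information_content), rep(log2(20), 9))
  set.seed(9)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  unif <- vapply(1:4000, function(i)
    paste(sample(aa, 9, replace = TRUE), collapse = ""), character(1))
  logo_u <- peptide_logo_matrix(unif)
  expect_lt(max(logo_u$information_content), 0.2)
  expect_error(peptide_logo_matrix(c("AAAAAAAAA", "AAAA")), "9-mers")
})
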