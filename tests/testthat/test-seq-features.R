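# Sequence features: lengths, GC, branch-point scoring and the
# Mann-Whitney comparison machinery.

# independent branch-point oracle: score every eligible A explicitly
bp_oracle <- function(intron, pwm, window = c(15, 100)) {
  L <- nchar(intron)
  chars <- strsplit(intron, "")[[1]]
  lo <- log2(pwm / 0.25)
  best <- NULL
  for (p in seq_len(L)) {
    d <- L - p
    if (chars[p] != "A" || d < window[1] || d > window[2] ||
        p - 3 < 1 || p + 3 > L) next
    sc <- sum(vapply(1:7, function(j) lo[j, chars[p - 4 + j]], numeric(1)))
    if (is.null(best) || sc > best$score ||
        (sc == best$score && d < best$distance)) {
      best <- list(position = p, distance = d, score = sc)
    }
  }
  best
}

test_that("branch-point search matches an explicit scan and its tie rule", {
  pwm <- load_branchpoint_pwm()
  expect_equal(rowSums(pwm), rep(1, 7), ignore_attr = TRUE)
  # planted consensus box (branch A centred), poly-C elsewhere: box start
  # 30 nt from the 3' end puts the central A at distance 26
  box <- "TTAATCC"
  intron <- paste0(strrep("C", 80), box, strrep("C", 23))
  got <- find_branch_point(intron, pwm)
  expect_identical(got$distance, 26L)
  oracle <- bp_oracle(intron, pwm)
  expect_identical(got$position, oracle$position)
  expect_equal(got$score, oracle$score)

  # two identical boxes: the one closer to the 3' splice site wins
  intron2 <- paste0(strrep("C", 40), box, strrep("C", 23), box, strrep("C", 23))
  got2 <- find_branch_point(intron2, pwm)
  expect_identical(got2$distance, 26L)

  # random introns agree with the oracle
  set.seed(12)
  for (i in 1:25) {
    intr <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
    got <- find_branch_point(intr, pwm)
    oracle <- bp_oracle(intr, pwm)
    if (is.null(oracle)) {
      expect_true(is.na(got$position))
    } else {
      expect_identical(got$position, oracle$position)
    }
  }

  # no adenosine in the window, or an intron below the window start: missing
  expect_true(is.na(find_branch_point(strrep("C", 150), pwm)$position))
  expect_true(is.na(find_branch_point("TACTAAC", pwm)$position))
})

test_that("feature extraction gets lengths, GC and strand handling right", {
  # hand-built gene: exon2 60 nt with known GC, upstream intron 90 nt with
  # a planted branch-point box at distance 26
  exon2 <- paste0(strrep("GGCC", 9), strrep("AT", 12))  # 36 GC + 24 AT
  # length 90; box central A 26 nt from the intron 3' end
  intron1 <- paste0(strrep("C", 60), "TTAATCC", strrep("C", 23))
  for (strand in c("+", "-")) {
    mg <- manual_gene(
      exon_seqs = c("ATGAAACCCGGG", exon2, "TTTCCCGGGTAA"),
      intron_seqs = c(intron1, strrep("G", 60)), strand = strand)
    ev <- se_event_row(mg$model, 2)
    ft <- extract_features(ev, mg$genome)
    expect_identical(ft$exon_length, 60L)
    expect_identical(ft$upstream_intron_length, 90L)
    expect_equal(ft$gc_content, 36 / 60)
    expect_identical(ft$bp_to_3ss_distance, 26L)
    # RI features on the same gene
    ri <- ri_event_row(mg$model, 1)
    ftr <- extract_features(ri, mg$genome)
    expect_identical(ftr$intron_length, 90L)
    expect_equal(ftr$gc_content, 85 / 90, tolerance = 1e-9)  # 5 non-GC in the box
  }
  # out-of-chromosome coordinates are a coordinate error
  mg <- manual_gene(c("ATGAAACCCGGG", exon2, "TTTCCCGGGTAA"),
                    c(intron1, strrep("G", 60)))
  bad <- se_event_row(mg$model, 2)
  bad$exonEnd <- 10000L
  expect_error(extract_features(bad, mg$genome), "coordinate error")
})

test_that("Mann-Whitney exact path equals enumeration and handles the null", {
  # identical samples: p = 1
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 1)
  # fully separated small samples: U = 0, two-sided exact p = 2/20
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 0.1)
  expect_identical(r$method, "exact")
  # tie-free samples match wilcox.test's exact p
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    expect_equal(compare_groups(a, b)$p_two_sided,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
  # label symmetry: swapping groups preserves p, mirrors U
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(0.7, 2.9, 4.4)
  r1 <- compare_groups(a, b); r2 <- compare_groups(b, a)
  expect_equal(r1$p_two_sided, r2$p_two_sided)
  expect_equal(r1$U + r2$U, length(a) * length(b))
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney normal approximation tracks the exact path at n = 8", {
  # the continuity-corrected normal approximation carries ~0.01 absolute
  # error on an n = 8 lattice; check it stays within 0.02 of enumeration
  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    p_exact <- compare_groups(a, b)$p_two_sided
    p_norm <- compare_groups(a, b, exact_max = 4)$p_two_sided
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("planted feature contrasts are detected", {
  # UP exons drawn shorter than NO exons by construction
  set.seed(41)
  up <- sample(40:80, 200, replace = TRUE)
  no <- sample(100:200, 200, replace = TRUE)
  r <- compare_groups(up, no)
  expect_lt(r$p_two_sided, 0.01)
  expect_lt(r$median_a, r$median_b)
})
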