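# Position-resolved RNA-binding-protein motif coverage maps around splice
# sites of regulated vs unregulated exons.

#' Read a position-weight matrix motif model
#'
#' Shares the tab-separated `position` x `A C G U/T` format with the
#' branch-point fixture. Scores are log2 odds against a uniform 0.25
#' background; the hit threshold is a fraction of the maximal attainable
#' score.
#'
#' @param path PWM file; default is the toy RBP motif shipped with the
#'   package (consensus `UGCAUG`-like).
#' @param motif_id,rbp_name Identifiers carried through to outputs.
#' @param threshold Hit threshold as a fraction of the maximum score.
#' @return A `motif_model` list: `motif_id`, `rbp_name`, `pwm`,
#'   `threshold`.
#' @export
read_pwm <- function(path = NULL, motif_id = "toy_rbp", rbp_name = "TOY",
                     threshold = 0.8) {
  path <- path %||% system.file("extdata", "toy_rbp_pwm.tsv", package = "spliceotope")
  df <- read.delim(path, check.names = FALSE)
  bases <- intersect(c("A", "C", "G", "U", "T"), names(df))
  m <- as.matrix(df[, bases])
  colnames(m)[colnames(m) == "U"] <- "T"
  stopifnot(nrow(m) >= 2, all(abs(rowSums(m) - 1) < 1e-6))
  structure(list(motif_id = motif_id, rbp_name = rbp_name, pwm = m,
                 threshold = threshold), class = "motif_model")
}

#' Scan a sequence for motif hits
#'
#' Slides the PWM over the sequence and reports every start where the log2
#' odds score (uniform background) reaches `threshold * max_score`.
#' Overlapping hits are allowed; a sequence shorter than the motif yields
#' an empty result.
#'
#' @param sequence DNA/RNA string (`U` is treated as `T`).
#' @param motif A `motif_model` from [read_pwm()].
#' @return Data frame of hits: `start`, `end` (1-based inclusive), `score`.
#' @export
scan_motif <- function(sequence, motif) {
  pwm <- motif$pwm
  w <- nrow(pwm)
  seqc <- chartr("Uu", "Tt", toupper(sequence))
  L <- nchar(seqc)
  empty <- data.frame(start = integer(0), end = integer(0), score = numeric(0))
  if (L < w) return(empty)
  logodds <- log2(pwm / 0.25)
  idx <- match(strsplit(seqc, "")[[1]], colnames(pwm))
  n_pos <- L - w + 1L
  score <- numeric(n_pos)
  for (j in seq_len(w)) {
    lo <- logodds[j, ][idx[j:(j + n_pos - 1L)]]
    lo[is.na(lo)] <- min(logodds)    # non-ACGT characters score worst
    score <- score + lo
  }
  max_score <- sum(apply(logodds, 1, max))
  hit <- which(score >= motif$threshold * max_score)
  data.frame(start = hit, end = hit + w - 1L, score = score[hit])
}

# Genomic window and orientation for one anchor of one SE event.
# Returns c(start, end, upstream_len) where upstream_len is the number of
# window bases 5' (transcript orientation) of the splice-site boundary;
# relative position 0 is the first base 3' of the boundary.
anchor_window <- function(ev, anchor, flank, into_exon) {
  plus <- ev$strand == "+"
  # transcript-oriented boundaries of the target exon and flanking exons
  b <- switch(anchor,
    exon_3ss = if (plus) ev$exonStart_0base else ev$exonEnd,           # acceptor
    exon_5ss = if (plus) ev$exonEnd else ev$exonStart_0base,           # donor
    upstream_5ss = if (plus) ev$upstreamEE else ev$upstreamES,         # donor of upstream exon
    downstream_3ss = if (plus) ev$downstreamES else ev$downstreamEE,   # acceptor of downstream exon
    stop("unknown anchor: ", anchor))
  # bases 5' / 3' of the boundary in transcript orientation
  n5 <- switch(anchor,
    exon_3ss = flank, exon_5ss = into_exon,
    upstream_5ss = into_exon, downstream_3ss = flank)
  n3 <- switch(anchor,
    exon_3ss = into_exon, exon_5ss = flank,
    upstream_5ss = flank, downstream_3ss = into_exon)
  if (plus) c(b - n5 + 1L, b + n3, n5) else c(b - n3 + 1L, b + n5, n5)
}

#' Per-event motif coverage matrix around a splice-site anchor
#'
#' For each event, extracts the window around the anchor in transcript
#' orientation, scans it for motif hits, and marks each window position
#' covered by at least one hit. Events whose window leaves the chromosome
#' are skipped with a warning.
#'
#' @param events SE-layout event data frame (`chrom`, `strand`,
#'   `exonStart_0base`, `exonEnd`, flanking exon columns for the flanking
#'   anchors).
#' @param genome Named character vector of chromosome sequences.
#' @param motif A `motif_model`.
#' @param anchor One of `"exon_3ss"`, `"exon_5ss"`, `"upstream_5ss"`,
#'   `"downstream_3ss"`.
#' @param flank Window extent on the intron side (nt).
#' @param into_exon Window extent on the exon side (nt).
#' @return Binary matrix events x positions; column names are positions
#'   relative to the splice-site boundary (position 0 = first base 3' of
#'   the boundary, negative = 5' of it, transcript orientation).
#' @export
rna_map_matrix <- function(events, genome, motif, anchor = "exon_3ss",
                           flank = 300L, into_exon = 50L) {
  width <- flank + into_exon
  n5 <- switch(anchor, exon_3ss = , downstream_3ss = flank, into_exon)
  rel <- seq(-n5, width - n5 - 1L)
  out <- matrix(NA_real_, nrow(events), width,
                dimnames = list(events$event_id, rel))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    win <- anchor_window(ev, anchor, flank, into_exon)
    chrom_len <- nchar(genome[[ev$chrom]] %||% "")
    if (win[1] < 1L || win[2] > chrom_len) {
      warning("event ", ev$event_id, " too close to chromosome edge; skipped")
      next
    }
    s <- tx_subseq(genome, ev$chrom, win[1], win[2], ev$strand)
    hits <- scan_motif(s, motif)
    cov <- numeric(width)
    for (h in seq_len(nrow(hits))) {
      cov[hits$start[h]:hits$end[h]] <- 1
    }
    out[i, ] <- cov
  }
  out[!is.na(out[, 1]), , drop = FALSE]
}

#' Running-mean smoothing with truncated edges
#'
#' @param x Numeric vector.
#' @param width Odd window width (nt).
#' @return Smoothed vector of the same length; edge windows shrink.
#' @export
smooth_running_mean <- function(x, width = 31L) {
  stopifnot(width >= 1L)
  half <- width %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Motif RNA map: per-group positional coverage around an anchor
#'
#' Coverage at a position is the fraction of the group's events with at
#' least one motif hit overlapping it (presence/absence, the usual RNA-map
#' convention), then running-mean smoothed.
#'
#' @param event_groups Named list of event data frames (e.g. `UP`, `DOWN`,
#'   `NO`), all non-empty.
#' @param genome,motif,anchor,flank,into_exon As in [rna_map_matrix()].
#' @param smooth Smoothing window width (nt).
#' @return Data frame: `group`, `anchor`, `position`, `coverage`
#'   (unsmoothed), `coverage_smooth`.
#' @export
build_rna_map <- function(event_groups, genome, motif, anchor = "exon_3ss",
                          flank = 300L, into_exon = 50L, smooth = 31L) {
  stopifnot(length(event_groups) >= 1, all(vapply(event_groups, nrow, 1L) > 0))
  parts <- lapply(names(event_groups), function(g) {
    m <- rna_map_matrix(event_groups[[g]], genome, motif, anchor, flank, into_exon)
    cov <- colMeans(m)
    data.frame(group = g, anchor = anchor,
               position = as.integer(colnames(m)),
               coverage = cov,
               coverage_smooth = smooth_running_mean(cov, smooth),
               row.names = NULL)
  })
  do.call(rbind, parts)
}

#' Permutation significance of coverage differences between two groups
#'
#' Shuffles event-to-group labels, recomputes the per-position coverage
#' difference, and reports per-position permutation p-values
#' (`(1 + #{|diff*| >= |diff|}) / (n + 1)`) with Benjamini-Hochberg
#' correction across positions.
#'
#' @param mat_a,mat_b Binary coverage matrices from [rna_map_matrix()] for
#'   the two groups (same anchor/window); each needs `>= 5` events.
#' @param n_permutations Number of label permutations; the attainable
#'   minimum p is `1 / (n + 1)`, so with Benjamini-Hochberg correction over
#'   a few hundred positions a few thousand permutations are needed to
#'   resolve q-values near 0.05.
#' @param seed Integer seed.
#' @return Data frame: `position`, `diff` (a minus b), `p_value`, `q_value`.
#' @export
map_significance <- function(mat_a, mat_b, n_permutations = 5000L, seed = 1L) {
  if (nrow(mat_a) < 5L || nrow(mat_b) < 5L) {
    stop("groups too small for permutation testing (< 5 events)")
  }
  stopifnot(identical(colnames(mat_a), colnames(mat_b)))
  na <- nrow(mat_a); nb <- nrow(mat_b)
  pool <- rbind(mat_a, mat_b)
  obs <- colMeans(mat_a) - colMeans(mat_b)
  # indicator matrix of permuted group-a memberships; one BLAS product gives
  # the per-position group-a sums for every permutation at once
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(b)
      as.numeric(seq_len(na + nb) %in% sample.int(na + nb, na)),
      numeric(na + nb))
  })
  tot <- colSums(pool)
  s_a <- crossprod(pool, perm)                  # positions x permutations
  d_star <- s_a / na - (tot - s_a) / nb
  exceed <- rowSums(abs(d_star) >= abs(obs) - 1e-12)
  p <- (1 + exceed) / (n_permutations + 1)
  data.frame(position = as.integer(colnames(mat_a)), diff = obs,
             p_value = p, q_value = stats::p.adjust(p, "BH"),
             row.names = NULL)
}
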