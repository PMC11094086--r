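# Sequence features of regulated exons/introns (lengths, GC content,
# branch-point distance) and Mann-Whitney group comparisons.

#' Load the branch-point consensus position-weight matrix
#'
#' A transparent 7-column PWM over the yUnAy human branch-point consensus,
#' with the branch adenosine at the central position (column 4). Shipped as
#' a versioned tab-separated fixture (`position` x `A C G T` frequencies);
#' any matrix in the same format can be plugged in instead.
#'
#' @param path Optional path to an alternative PWM file.
#' @return Numeric matrix, positions x bases, rows summing to 1.
#' @export
load_branchpoint_pwm <- function(path = NULL) {
  path <- path %||% system.file("extdata", "bp_pwm.tsv", package = "spliceotope")
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, c("A", "C", "G", "T")])
  rownames(m) <- df$position
  stopifnot(all(abs(rowSums(m) - 1) < 1e-6))
  m
}

#' Locate the branch-point adenosine in an intron
#'
#' Scans every adenosine whose distance to the intron 3' end lies in the
#' search window (15-100 nt upstream of the 3' splice site by default),
#' scores the 7-mer centred on it against the branch-point PWM (log2
#' odds against a uniform background) and returns the best-scoring
#' candidate; ties go to the adenosine closest to the 3' splice site.
#' Distance is the number of intron bases 3' of the branch adenosine
#' (`length - position`).
#'
#' @param intron_seq Intron sequence, 5' to 3' (transcript orientation).
#' @param pwm Branch-point PWM, default [load_branchpoint_pwm()].
#' @param window Distance window `c(min, max)` in nt upstream of the 3' end.
#' @return List with `position` (1-based index of the branch A), `distance`
#'   (nt to the 3' end) and `score`; all `NA` when the intron is shorter
#'   than the window start or has no eligible adenosine.
#' @export
find_branch_point <- function(intron_seq, pwm = load_branchpoint_pwm(),
                              window = c(15L, 100L)) {
  L <- nchar(intron_seq)
  miss <- list(position = NA_integer_, distance = NA_integer_, score = NA_real_)
  if (L < window[1] + 3L) return(miss)
  chars <- strsplit(toupper(intron_seq), "")[[1]]
  pos <- which(chars == "A")
  dist <- L - pos
  pos <- pos[dist >= window[1] & dist <= window[2] & pos - 3L >= 1L & pos + 3L <= L]
  if (length(pos) == 0L) return(miss)
  logodds <- log2(pwm / 0.25)
  score <- vapply(pos, function(p) {
    heptamer <- chars[(p - 3L):(p + 3L)]
    sum(logodds[cbind(seq_len(7L), match(heptamer, colnames(pwm)))])
  }, numeric(1))
  best <- which(score == max(score))
  if (length(best) > 1L) best <- best[which.min(L - pos[best])]
  list(position = pos[best], distance = L - pos[best], score = score[best])
}

# 1-based inclusive genomic interval of the transcript-upstream intron of a
# skipped exon, and of the retained intron of an RI event.
upstream_intron_interval <- function(ev) {
  if (ev$strand == "+") c(ev$upstreamEE + 1L, ev$exonStart_0base)
  else c(ev$exonEnd + 1L, ev$upstreamES)
}
ri_intron_interval <- function(ev) {
  if (ev$strand == "+") c(ev$upstreamEE + 1L, ev$downstreamES)
  else c(ev$downstreamEE + 1L, ev$upstreamES)
}

# Extract a genomic interval in transcript orientation.
tx_subseq <- function(genome, chrom, start, end, strand) {
  seq <- genome[[chrom]]
  if (is.null(seq) || start < 1L || end > nchar(seq) || start > end) {
    stop("coordinate error: ", chrom, ":", start, "-", end)
  }
  s <- substr(seq, start, end)
  if (strand == "-") revcomp(s) else s
}

#' Sequence features of SE and RI events
#'
#' For skipped exons: exon length and GC content, upstream-intron length
#' and the branch-point distance to the 3' splice site in that intron. For
#' retained introns: intron length, GC content and branch-point distance.
#' All features are computed on the annotated strand (transcript
#' orientation); lengths come from the half-open-start rMATS coordinate
#' convention (`end - start_0base`).
#'
#' @param events Data frame of SE and/or RI events ([read_rmats_table()]
#'   layout) with an optional `direction`/`group` column.
#' @param genome Named character vector of chromosome sequences.
#' @param pwm Branch-point PWM.
#' @param bp_window Branch-point search window.
#' @return A feature table: `event_id`, `event_type`, `group`,
#'   `exon_length`, `upstream_intron_length`, `intron_length`,
#'   `gc_content`, `bp_to_3ss_distance`.
#' @export
extract_features <- function(events, genome, pwm = load_branchpoint_pwm(),
                             bp_window = c(15L, 100L)) {
  stopifnot(all(events$event_type %in% c("SE", "RI")))
  group <- events$group %||% events$direction %||% rep(NA_character_, nrow(events))
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    if (ev$event_type == "SE") {
      exon_len <- ev$exonEnd - ev$exonStart_0base
      exon_seq <- tx_subseq(genome, ev$chrom, ev$exonStart_0base + 1L,
                            ev$exonEnd, ev$strand)
      iv <- upstream_intron_interval(ev)
      intron_seq <- tx_subseq(genome, ev$chrom, iv[1], iv[2], ev$strand)
      bp <- find_branch_point(intron_seq, pwm, bp_window)
      data.frame(event_id = ev$event_id, event_type = "SE", group = group[i],
                 exon_length = exon_len,
                 upstream_intron_length = iv[2] - iv[1] + 1L,
                 intron_length = NA_integer_,
                 gc_content = gc_content(exon_seq),
                 bp_to_3ss_distance = bp$distance)
    } else {
      iv <- ri_intron_interval(ev)
      intron_seq <- tx_subseq(genome, ev$chrom, iv[1], iv[2], ev$strand)
      bp <- find_branch_point(intron_seq, pwm, bp_window)
      data.frame(event_id = ev$event_id, event_type = "RI", group = group[i],
                 exon_length = NA_integer_,
                 upstream_intron_length = NA_integer_,
                 intron_length = iv[2] - iv[1] + 1L,
                 gc_content = gc_content(intron_seq),
                 bp_to_3ss_distance = bp$distance)
    }
  })
  do.call(rbind, rows)
}

# Mann-Whitney U for group a vs b with ties counted 1/2, via midranks.
mw_u_stat <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Two-sided Mann-Whitney U comparison of two feature groups
#'
#' Uses exact enumeration of all group assignments when both groups have at
#' most `exact_max` observations (ties handled naturally through midranks,
#' two-sided extremeness measured as `|U - n1*n2/2|`), and the tie- and
#' continuity-corrected normal approximation otherwise.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param exact_max Largest group size for the exact path, default 8.
#' @return List: `median_a`, `median_b`, `U` (for group `a`), `p_two_sided`,
#'   `method`.
#' @export
compare_groups <- function(a, b, exact_max = 8L) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  u_obs <- mw_u_stat(a, b)
  mu <- n1 * n2 / 2
  if (max(n1, n2) <= exact_max) {
    pool <- c(a, b)
    assignments <- combn(N, n1)
    u_all <- apply(assignments, 2, function(idx) {
      mw_u_stat(pool[idx], pool[-idx])
    })
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
    method <- "exact"
  } else {
    ties <- table(c(a, b))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 == 0) return(list(median_a = median(a), median_b = median(b),
                                 U = u_obs, p_two_sided = 1, method = "normal"))
    z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)  # continuity-corrected
    p <- min(1, 2 * pnorm(-z))
    method <- "normal"
  }
  list(median_a = median(a), median_b = median(b), U = u_obs,
       p_two_sided = p, method = method)
}
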