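# Fixture builders for the motif-map tests.

write_onehot_pwm <- function(consensus, path = tempfile(fileext = ".tsv")) {
  bases <- c("A", "C", "G", "T")
  rows <- t(vapply(strsplit(consensus, "")[[1]], function(b) {
    out <- rep(0.01, 4); out[bases == b] <- 0.97; out
  }, numeric(4)))
  df <- data.frame(position = seq_len(nrow(rows)), rows)
  names(df)[-1] <- bases
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# One chromosome per event: 400 nt intron, 120 nt exon, 400 nt intron;
# optionally a motif planted in the upstream intron at a fixed distance
# upstream of the exon start (the 3' splice site): a hit at `offset` sits
# at relative position -offset on the exon_3ss anchor axis.
map_fixture <- function(n_events, motif_seq = NULL, offset = 40L, seed = 1,
                        prefix = "ev") {
  set.seed(seed)
  genome <- character(n_events)
  events <- NULL
  for (i in seq_len(n_events)) {
    up <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
    if (!is.null(motif_seq)) {
      s <- 400 - offset + 1
      substr(up, s, s + nchar(motif_seq) - 1) <- motif_seq
    }
    exon <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
    down <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
    genome[i] <- paste0(up, exon, down)
    events <- rbind(events, data.frame(
      event_id = paste0(prefix, i), event_type = "SE",
      chrom = paste0(prefix, "chr", i), strand = "+",
      exonStart_0base = 400L, exonEnd = 520L,
      upstreamES = 0L, upstreamEE = 0L,
      downstreamES = 920L, downstreamEE = 920L))
  }
  names(genome) <- paste0(prefix, "chr", seq_len(n_events))
  list(genome = genome, events = events)
}
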