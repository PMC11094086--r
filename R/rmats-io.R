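# Reader/writer for the rMATS 4.1.2 junction-count (JC) table dialect.

rmats_coord_cols <- list(
  SE   = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  RI   = c("riExonStart_0base", "riExonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  MXE  = c("1stExonStart_0base", "1stExonEnd", "2ndExonStart_0base",
           "2ndExonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
  A3SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  A5SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE")
)

#' rMATS 4.1.2 JC header for an event type
#'
#' @param event_type One of `"SE"`, `"RI"`, `"MXE"`, `"A3SS"`, `"A5SS"`.
#' @return Character vector of column names (the `ID` column appears twice,
#'   as in rMATS output).
#' @export
rmats_header <- function(event_type) {
  event_type <- match.arg(event_type, names(rmats_coord_cols))
  c("ID", "GeneID", "geneSymbol", "chr", "strand",
    rmats_coord_cols[[event_type]],
    "ID", "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
    "IncFormLen", "SkipFormLen", "PValue", "FDR",
    "IncLevel1", "IncLevel2", "IncLevelDifference")
}

# internal column names: duplicate ID becomes ID.1
rmats_internal_names <- function(event_type) {
  h <- rmats_header(event_type)
  h[duplicated(h)] <- paste0(h[duplicated(h)], ".1")
  h
}

#' Write an rMATS-dialect JC table
#'
#' @param tab Data frame with the internal rMATS columns (as produced by
#'   [plant_splice_events()]).
#' @param event_type Event type of the table.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_rmats_table <- function(tab, event_type, path) {
  internal <- rmats_internal_names(event_type)
  missing <- setdiff(internal, names(tab))
  if (length(missing) > 0L) {
    stop("table lacks rMATS columns: ", paste(missing, collapse = ", "))
  }
  tab <- tab[, internal, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rmats_header(event_type), collapse = "\t"), con)
  write.table(tab, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

parse_int_csv <- function(x) lapply(strsplit(x, ","), function(v) as.integer(v))
parse_num_csv <- function(x) lapply(strsplit(x, ","), function(v) {
  v[v == "NA"] <- NA
  as.numeric(v)
})

#' Read an rMATS-dialect JC table
#'
#' Validates the header against the rMATS 4.1.2 JC layout for the event
#' type (a mismatch is an error naming the missing/unexpected columns) and
#' the per-row field count (a malformed row is an error naming its line
#' number). Comma-separated replicate counts are parsed into list columns,
#' and PSI values are re-derived from the counts with [compute_psi()].
#'
#' Convention: `upstreamES/EE` and `downstreamES/EE` are the transcript-
#' orientation flanking exons; all start columns are 0-based, end columns
#' 1-based inclusive. Sample 1 is declared treated by default
#' (`treated_group = 1`), so `delta_psi = psi_treated - psi_control` matches
#' `IncLevelDifference`; pass `treated_group = 2` to flip.
#'
#' @param path File path.
#' @param event_type Event type the file should contain.
#' @param treated_group Which rMATS sample group (1 or 2) is the treated one.
#' @return Data frame with one row per event: `event_id`, `event_type`,
#'   `gene_id`, `chrom`, `strand`, the native coordinate columns, list
#'   columns `ijc_treated`/`sjc_treated`/`ijc_control`/`sjc_control` and
#'   `inc_level_treated`/`inc_level_control`, `inc_form_len`,
#'   `skip_form_len`, `p_value`, `fdr`, `psi_control`, `psi_treated`,
#'   `delta_psi`.
#' @export
read_rmats_table <- function(path, event_type, treated_group = 1L) {
  stopifnot(treated_group %in% c(1L, 2L))
  lines <- readLines(path)
  if (length(lines) == 0L) stop("format error: empty file ", path)
  expected <- rmats_header(event_type)
  got <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(got, expected)) {
    miss <- setdiff(expected, got)
    extra <- setdiff(got, expected)
    stop("format error: header does not match rMATS ", event_type, " JC layout",
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  }
  body <- lines[-1]
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  bad <- which(nf != length(expected))
  if (length(bad) > 0L) {
    stop("format error: line ", bad[1] + 1L, " has ", nf[bad[1]],
         " fields, expected ", length(expected))
  }
  internal <- rmats_internal_names(event_type)
  tab <- read.delim(text = body, header = FALSE, col.names = internal,
                    check.names = FALSE, colClasses = "character")
  t1 <- treated_group == 1L
  coord <- rmats_coord_cols[[event_type]]
  out <- data.frame(
    event_id = paste0(event_type, "_", tab$ID),
    event_type = event_type,
    gene_id = tab$GeneID, chrom = tab$chr, strand = tab$strand,
    stringsAsFactors = FALSE)
  for (cc in coord) out[[cc]] <- as.integer(tab[[cc]])
  out$ijc_treated <- parse_int_csv(if (t1) tab$IJC_SAMPLE_1 else tab$IJC_SAMPLE_2)
  out$sjc_treated <- parse_int_csv(if (t1) tab$SJC_SAMPLE_1 else tab$SJC_SAMPLE_2)
  out$ijc_control <- parse_int_csv(if (t1) tab$IJC_SAMPLE_2 else tab$IJC_SAMPLE_1)
  out$sjc_control <- parse_int_csv(if (t1) tab$SJC_SAMPLE_2 else tab$SJC_SAMPLE_1)
  out$inc_form_len <- as.numeric(tab$IncFormLen)
  out$skip_form_len <- as.numeric(tab$SkipFormLen)
  out$p_value <- as.numeric(tab$PValue)
  out$fdr <- as.numeric(tab$FDR)
  out$inc_level_treated <- parse_num_csv(if (t1) tab$IncLevel1 else tab$IncLevel2)
  out$inc_level_control <- parse_num_csv(if (t1) tab$IncLevel2 else tab$IncLevel1)
  psi_grp <- function(i_col, s_col) {
    vapply(seq_len(nrow(out)), function(r) {
      psi <- compute_psi(out[[i_col]][[r]], out[[s_col]][[r]],
                         out$inc_form_len[r], out$skip_form_len[r])
      if (all(is.na(psi))) NA_real_ else mean(psi, na.rm = TRUE)
    }, numeric(1))
  }
  out$psi_treated <- psi_grp("ijc_treated", "sjc_treated")
  out$psi_control <- psi_grp("ijc_control", "sjc_control")
  out$delta_psi <- out$psi_treated - out$psi_control
  out
}

#' Read every rMATS table in a directory
#'
#' @param dir Directory containing `<TYPE>.MATS.JC.txt` files.
#' @param treated_group Passed to [read_rmats_table()].
#' @return One data frame combining all event types (coordinate columns are
#'   type-specific and therefore `NA` where not applicable).
#' @export
read_rmats_dir <- function(dir, treated_group = 1L) {
  files <- list.files(dir, pattern = "\\.MATS\\.JC\\.txt$", full.names = TRUE)
  if (length(files) == 0L) stop("no *.MATS.JC.txt files under ", dir)
  parts <- lapply(files, function(f) {
    type <- sub("\\.MATS\\.JC\\.txt$", "", basename(f))
    read_rmats_table(f, type, treated_group)
  })
  all_cols <- unique(unlist(lapply(parts, names)))
  parts <- lapply(parts, function(p) {
    for (cc in setdiff(all_cols, names(p))) p[[cc]] <- NA
    p[, all_cols]
  })
  do.call(rbind, parts)
}
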