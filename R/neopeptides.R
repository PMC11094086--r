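# Reconstruction of altered transcripts from productive splicing events,
# translation under canonical-START assumptions, 8-14mer digestion, novelty
# filtering against the canonical proteome, and MHC-I binding interfaces.

#' Read single-isoform gene models from a GTF annotation
#'
#' Imports the GTF via rtracklayer and builds one model per transcript:
#' exons and CDS ordered 5' to 3' in transcript orientation, plus the
#' genomic coordinate of the canonical START (the first base of the
#' 5'-most CDS codon). Multi-isoform genes are not supported; each
#' transcript is treated independently.
#'
#' @param path GTF file (1-based inclusive coordinates).
#' @return Named list of gene models (`gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `exons`, `cds`, `start_codon`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  tx_ids <- unique(df$transcript_id[df$type == "exon"])
  models <- lapply(tx_ids, function(tx) {
    sub <- df[!is.na(df$transcript_id) & df$transcript_id == tx, ]
    strand <- as.character(sub$strand[1])
    order_tx <- function(d) d[order(d$start, decreasing = (strand == "-")), , drop = FALSE]
    ex <- order_tx(sub[sub$type == "exon", c("start", "end")])
    cd <- order_tx(sub[sub$type == "CDS", c("start", "end")])
    if (nrow(cd) == 0L) stop("transcript ", tx, " has no CDS")
    list(gene_id = sub$gene_id[1], transcript_id = tx,
         chrom = as.character(sub$seqnames[1]), strand = strand,
         exons = data.frame(start = ex$start, end = ex$end),
         cds = data.frame(start = cd$start, end = cd$end),
         start_codon = if (strand == "+") min(cd$start) else max(cd$end))
  })
  names(models) <- tx_ids
  models
}

#' Select events productive for neopeptide formation
#'
#' Keeps skipped exons with decreased inclusion (the exclusion isoform
#' gains abundance on treatment) and retained introns with increased
#' retention; all other types and directions are excluded.
#'
#' @param events Significant, direction-classified event data frame.
#' @return The productive subset with a `variant` column
#'   (`SE_exclusion` / `RI_inclusion`).
#' @export
select_productive_events <- function(events) {
  keep_se <- events$event_type == "SE" & events$direction == "DOWN"
  keep_ri <- events$event_type == "RI" & events$direction == "UP"
  out <- events[keep_se | keep_ri, , drop = FALSE]
  out$variant <- ifelse(out$event_type == "SE", "SE_exclusion", "RI_inclusion")
  out
}

# Map a genomic position into transcript coordinates over ordered blocks.
tx_offset_of <- function(blocks, strand, pos) {
  cum <- 0L
  for (i in seq_len(nrow(blocks))) {
    s <- blocks$start[i]; e <- blocks$end[i]
    if (pos >= s && pos <= e) {
      return(cum + if (strand == "+") pos - s + 1L else e - pos + 1L)
    }
    cum <- cum + (e - s + 1L)
  }
  NA_integer_
}

blocks_sequence <- function(blocks, strand, genome, chrom) {
  paste(vapply(seq_len(nrow(blocks)), function(i) {
    tx_subseq(genome, chrom, blocks$start[i], blocks$end[i], strand)
  }, character(1)), collapse = "")
}

#' Reconstruct the altered transcript of a productive splicing event
#'
#' `SE_exclusion`: the annotated internal exon matching the event
#' coordinates is removed from the exon chain. `RI_inclusion`: the intron
#' between the two matching consecutive exons is spliced in (the exons are
#' merged into one block). The sequence is reported 5' to 3' on the coding
#' strand; frameshift and premature-stop flags come from CDS arithmetic
#' (length change mod 3 within the CDS span; stop observed upstream of the
#' canonical stop codon's mapped position).
#'
#' @param event One event row (rMATS-layout columns) with a `variant`.
#' @param gene_model Matching gene model from [read_gene_models()] /
#'   [toy_gene_models()].
#' @param genome Named character vector of chromosome sequences.
#' @return An `altered_transcript` list: `event_id`, `variant`, `blocks`,
#'   `sequence`, `tx_start` (transcript offset of the canonical START, `NA`
#'   if lost), `protein`, `frameshifted`, `premature_stop`, `start_lost`.
#' @export
reconstruct_transcript <- function(event, gene_model, genome) {
  ex <- gene_model$exons
  variant <- event$variant
  coord_err <- function(msg) {
    stop("reconciliation error (", event$event_id, "): ", msg, " at ",
         event$chrom, ":", event$exonStart_0base %||% event$upstreamES)
  }
  if (variant == "SE_exclusion") {
    j <- which(ex$start == event$exonStart_0base + 1L & ex$end == event$exonEnd)
    if (length(j) != 1L) coord_err("skipped exon is not an annotated exon")
    if (j == 1L || j == nrow(ex)) coord_err("skipped exon is not internal")
    blocks <- ex[-j, , drop = FALSE]
    delta_cds <- sum(pmax(0L, pmin(gene_model$cds$end, ex$end[j]) -
                            pmax(gene_model$cds$start, ex$start[j]) + 1L))
    delta_cds <- -delta_cds
  } else if (variant == "RI_inclusion") {
    j <- which(ex$start == event$upstreamES + 1L & ex$end == event$upstreamEE)
    if (length(j) != 1L || j == nrow(ex)) coord_err("upstream exon not annotated")
    jn <- j + 1L
    if (!(ex$start[jn] == event$downstreamES + 1L && ex$end[jn] == event$downstreamEE)) {
      coord_err("downstream exon does not follow the upstream exon")
    }
    merged <- data.frame(start = min(ex$start[j], ex$start[jn]),
                         end = max(ex$end[j], ex$end[jn]))
    blocks <- rbind(ex[seq_len(j - 1L), , drop = FALSE], merged,
                    ex[setdiff(seq_len(nrow(ex)), seq_len(jn)), , drop = FALSE])
    intron_len <- (merged$end - merged$start + 1L) -
      (ex$end[j] - ex$start[j] + 1L) - (ex$end[jn] - ex$start[jn] + 1L)
    cds_span <- c(min(gene_model$cds$start), max(gene_model$cds$end))
    intron_lo <- min(ex$end[j], ex$end[jn]) + 1L
    intron_hi <- max(ex$start[j], ex$start[jn]) - 1L
    in_cds <- intron_lo > cds_span[1] && intron_hi < cds_span[2]
    delta_cds <- if (in_cds) intron_len else 0L
  } else {
    stop("unsupported variant: ", variant)
  }
  strand <- gene_model$strand
  seq <- blocks_sequence(blocks, strand, genome, gene_model$chrom)
  tx_start <- tx_offset_of(blocks, strand, gene_model$start_codon)
  alt <- structure(list(
    event_id = event$event_id, variant = variant, blocks = blocks,
    sequence = seq, tx_start = tx_start,
    gene_id = gene_model$gene_id,
    frameshifted = (delta_cds %% 3L) != 0L,
    start_lost = is.na(tx_start)), class = "altered_transcript")
  alt$protein <- translate_canonical(alt)
  # premature stop: the observed stop begins upstream of where the canonical
  # stop codon maps in the altered transcript (or that codon is gone)
  g_stop <- if (strand == "+") max(gene_model$cds$end) + 1L else min(gene_model$cds$start) - 1L
  stop_off <- attr(alt$protein, "stop_offset")
  if (alt$start_lost || is.na(stop_off)) {
    alt$premature_stop <- FALSE
  } else {
    canon_stop_tx <- tx_offset_of(blocks, strand, g_stop)
    obs_stop_tx <- tx_start + stop_off - 1L
    alt$premature_stop <- is.na(canon_stop_tx) || obs_stop_tx < canon_stop_tx
  }
  alt
}

#' Translate an altered transcript under canonical-START assumptions
#'
#' Standard-code translation from the annotated canonical START to the
#' first stop codon; no stop-codon readthrough and no internal initiation.
#' If the START-containing exon was removed the product is empty with
#' reason `"start_lost"`.
#'
#' @param altered An `altered_transcript` from [reconstruct_transcript()].
#' @return Protein string (possibly empty); attributes `stop_offset` (from
#'   [translate_dna()]) and, when empty, `reason`.
#' @export
translate_canonical <- function(altered) {
  if (is.na(altered$tx_start)) {
    out <- ""
    attr(out, "reason") <- "start_lost"
    attr(out, "stop_offset") <- NA_integer_
    return(out)
  }
  translate_dna(substr(altered$sequence, altered$tx_start, nchar(altered$sequence)))
}

#' Digest a protein into unique 8-14mer peptides
#'
#' @param protein Amino-acid string.
#' @param k_min,k_max Peptide length bounds (default 8 and 14).
#' @return Character vector of unique substrings of length `k_min..k_max`
#'   (empty if the protein is shorter than `k_min`).
#' @export
digest_kmers <- function(protein, k_min = 8L, k_max = 14L) {
  L <- nchar(protein)
  if (L < k_min) return(character(0))
  out <- unlist(lapply(seq(k_min, min(k_max, L)), function(k) {
    starts <- seq_len(L - k + 1L)
    substring(protein, starts, starts + k - 1L)
  }))
  unique(out)
}

#' Mark peptides absent from the canonical proteome
#'
#' A peptide is novel iff it is not a substring of any canonical protein.
#'
#' @param peptides Character vector of peptides.
#' @param proteome Named character vector of canonical protein sequences.
#' @return Data frame `peptide`, `novel` (input order preserved,
#'   duplicates removed).
#' @export
novelty_filter <- function(peptides, proteome) {
  peptides <- unique(peptides)
  haystack <- paste(proteome, collapse = "#")
  novel <- !vapply(peptides, function(p) grepl(p, haystack, fixed = TRUE),
                   logical(1))
  data.frame(peptide = peptides, novel = unname(novel), row.names = NULL)
}

#' Load the toy 9-mer MHC-I scoring matrix
#'
#' A position-specific score matrix with hydrophobic anchor preferences at
#' positions 2 and 9. It exists solely to make the binding stage testable
#' offline and makes no biological claims.
#'
#' @param path Optional alternative matrix file.
#' @return Numeric matrix, 9 positions x 20 residues.
#' @export
load_toy_psm <- function(path = NULL) {
  path <- path %||% system.file("extdata", "toy_a0201_psm.tsv", package = "spliceotope")
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$position
  m
}

toy_score_9mer <- function(peptides, psm) {
  vapply(peptides, function(p) {
    idx <- match(strsplit(p, "")[[1]], colnames(psm))
    if (anyNA(idx)) return(NA_real_)
    sum(psm[cbind(1:9, idx)])
  }, numeric(1))
}

#' Parse NetMHCpan v4.1 tabular output
#'
#' Reads a whitespace-delimited table whose header names (case-insensitive)
#' include `Peptide` and a percent-rank column (`%Rank`, `%Rank_EL`,
#' `EL_Rank` or `Rank`); an optional score column (`Score`, `EL-score`,
#' `Score_EL`) is carried through. Lines that do not parse are an error
#' naming the offending line.
#'
#' @param path File path.
#' @return Data frame `peptide`, `percent_rank`, `score` (NA if absent).
#' @export
parse_netmhcpan <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|-|$)", lines)]
  if (length(lines) == 0L) stop("format error: no content in ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  header <- tolower(toks[[1]])
  pep_col <- which(header == "peptide")
  rank_col <- which(header %in% c("%rank", "%rank_el", "el_rank", "rank"))
  score_col <- which(header %in% c("score", "el-score", "score_el"))
  if (length(pep_col) != 1L || length(rank_col) < 1L) {
    stop("format error: header lacks Peptide/%Rank columns: ", lines[1])
  }
  rank_col <- rank_col[1]
  body <- toks[-1]
  n <- length(header)
  rows <- lapply(seq_along(body), function(i) {
    t <- body[[i]]
    if (length(t) < max(pep_col, rank_col)) {
      stop("format error at line: ", lines[i + 1L])
    }
    rank <- suppressWarnings(as.numeric(t[rank_col]))
    if (is.na(rank)) stop("format error at line: ", lines[i + 1L])
    data.frame(peptide = t[pep_col], percent_rank = rank,
               score = if (length(score_col))
                 suppressWarnings(as.numeric(t[score_col[1]])) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Attach MHC-I binding predictions to peptide candidates
#'
#' Two backends: `"netmhcpan_output_parser"` joins a NetMHCpan v4.1 output
#' file on the peptide sequence; `"toy_scorer"` scores 9-mers against the
#' package's toy anchor matrix and converts scores to percent ranks against
#' a background of proteome-sampled 9-mers (non-9-mers get `NA` ranks in
#' toy mode). Binder classes follow the NetMHCpan conventions: strong
#' `%rank <= 0.5`, weak `%rank <= 2`.
#'
#' @param candidates Data frame with a `peptide` column.
#' @param allele Allele label carried into the output (e.g. `HLA-A*02:01`).
#' @param backend `"toy_scorer"` or `"netmhcpan_output_parser"`.
#' @param netmhcpan_file Output file to parse (parser backend).
#' @param proteome Canonical proteome (toy backend background).
#' @param n_background Number of background 9-mers (toy backend).
#' @param seed Seed for the background draw.
#' @param strong,weak Percent-rank class thresholds.
#' @return `candidates` with `allele`, `score`, `percent_rank`,
#'   `binder_class` (`strong`/`weak`/`non-binder`/`NA`).
#' @export
predict_binding <- function(candidates, allele = "HLA-A*02:01",
                            backend = c("toy_scorer", "netmhcpan_output_parser"),
                            netmhcpan_file = NULL, proteome = NULL,
                            n_background = 2000L, seed = 1L,
                            strong = 0.5, weak = 2.0) {
  backend <- match.arg(backend)
  candidates$allele <- allele
  if (backend == "netmhcpan_output_parser") {
    if (is.null(netmhcpan_file)) stop("netmhcpan_file is required for the parser backend")
    pred <- parse_netmhcpan(netmhcpan_file)
    idx <- match(candidates$peptide, pred$peptide)
    candidates$score <- pred$score[idx]
    candidates$percent_rank <- pred$percent_rank[idx]
  } else {
    if (is.null(proteome)) stop("proteome is required for the toy scorer background")
    psm <- load_toy_psm()
    bg <- withr::with_seed(seed, {
      pool <- unlist(lapply(proteome, function(p) {
        L <- nchar(p)
        if (L < 9L) return(character(0))
        starts <- seq_len(L - 8L)
        substring(p, starts, starts + 8L)
      }), use.names = FALSE)
      if (length(pool) > n_background) sample(pool, n_background) else pool
    })
    bg_scores <- sort(toy_score_9mer(bg, psm))
    is9 <- nchar(candidates$peptide) == 9L
    sc <- rep(NA_real_, nrow(candidates))
    sc[is9] <- toy_score_9mer(candidates$peptide[is9], psm)
    candidates$score <- sc
    # percent of background scoring at or above the candidate
    candidates$percent_rank <- vapply(sc, function(s) {
      if (is.na(s)) return(NA_real_)
      100 * (length(bg_scores) - findInterval(s, bg_scores, left.open = TRUE)) /
        length(bg_scores)
    }, numeric(1))
  }
  candidates$binder_class <- ifelse(is.na(candidates$percent_rank), NA_character_,
    ifelse(candidates$percent_rank <= strong, "strong",
    ifelse(candidates$percent_rank <= weak, "weak", "non-binder")))
  candidates
}

#' Position frequency and information content of 9-mer peptides
#'
#' @param peptides Character vector of 9-mers (mixed lengths are an error).
#' @return List with `freq` (20 residues x 9 positions, columns sum to 1)
#'   and `information_content` (bits per position,
#'   `log2(20) - Shannon entropy`).
#' @export
peptide_logo_matrix <- function(peptides) {
  if (length(peptides) == 0L) stop("no peptides")
  if (any(nchar(peptides) != 9L)) stop("all peptides must be 9-mers")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mat <- do.call(rbind, strsplit(peptides, ""))
  freq <- vapply(seq_len(9L), function(j) {
    tab <- table(factor(mat[, j], levels = aa))
    as.numeric(tab) / length(peptides)
  }, numeric(20L))
  rownames(freq) <- aa
  colnames(freq) <- seq_len(9L)
  ic <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    log2(20) + sum(f * log2(f))
  })
  list(freq = freq, information_content = ic)
}
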