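# Planting of ground-truth splicing events and neoepitopes into a toy genome.

default_truth_psi <- list(
  RI = c(control = 0.10, treated = 0.60),  # retention gained on treatment
  SE = c(control = 0.90, treated = 0.30)   # inclusion lost on treatment
)

#' Plant a neoepitope-encoding splicing event into a toy genome
#'
#' Rewrites one gene so that the altered isoform of a splicing event encodes
#' a known peptide absent from the canonical proteome:
#'
#' * `RI`: one intron is rewritten to `GT<n>` (a valine codon, preserving the
#'   GT donor), followed by in-frame codons for the peptide, a stop codon and
#'   filler ending in `AG`. Retaining the intron therefore appends
#'   `V<peptide>` to the canonical N-terminal sequence before terminating.
#' * `SE`: the codons flanking one internal exon are rewritten so that when
#'   that exon is skipped, the new exon-exon junction reads as the peptide in
#'   frame. The canonical protein changes too (the two halves appear in it,
#'   separated by the exon), but never contains the contiguous peptide.
#'
#' If `peptide` is `NULL` a random 8-14mer is drawn and re-drawn on any
#' collision with the canonical proteome; a user-supplied colliding peptide
#' is an error.
#'
#' @param tg A `toy_genome`.
#' @param gene_id Gene to modify (must not already carry a planted event).
#' @param event_type `"RI"` or `"SE"`.
#' @param peptide Amino-acid string, length 8-14, or `NULL` to draw one.
#' @param seed Integer seed.
#' @return List with `genome` (the modified `toy_genome`) and `truth`, a
#'   one-row data frame (event_id, event_type, gene_id, true PSI per group,
#'   is_significant, planted_peptide).
#' @export
plant_neoepitope <- function(tg, gene_id, event_type = c("RI", "SE"),
                             peptide = NULL, seed) {
  event_type <- match.arg(event_type)
  gi <- which(vapply(tg$genes, `[[`, character(1), "gene_id") == gene_id)
  if (length(gi) != 1L) stop("unknown gene_id: ", gene_id)
  gene <- tg$genes[[gi]]
  if (!is.null(gene$planted)) stop("gene ", gene_id, " already carries a planted event")
  n <- length(gene$cds_exons)
  if (n < 3L) stop("placement error: gene ", gene_id, " has fewer than 3 exons")

  proteome_wo <- toy_proteome(tg)
  collides <- function(pep, prot) any(vapply(prot, function(p) grepl(pep, p, fixed = TRUE), logical(1)))

  withr::with_seed(seed, {
    draw_peptide <- is.null(peptide)
    for (attempt in seq_len(200L)) {
      pep <- if (draw_peptide) {
        k <- sample(8:14, 1L)
        substr(random_protein(k + 1L), 2L, k + 1L)  # random residues, no leading-M constraint
      } else peptide
      if (nchar(pep) < 8L || nchar(pep) > 14L) {
        stop("peptide length must be in [8,14], got ", nchar(pep))
      }
      cand <- gene
      if (event_type == "RI") {
        idx <- sample(seq_len(n - 1L), 1L)
        lead <- paste0("GT", sample(DNA_BASES, 1L))      # GTN = valine, keeps the donor
        core <- paste0(lead, encode_peptide(pep), "TAA")
        total <- max(60L, nchar(core) + 24L)
        total <- total + (3L - total %% 3L) %% 3L        # multiple of 3: no frameshift flag
        filler <- random_dna(total - nchar(core) - 2L)
        cand$introns[[idx]] <- paste0(core, filler, "AG")
        cand$planted <- list(event_type = "RI", variant = "RI_inclusion",
                             index = idx, peptide = pep)
        new_prot <- proteome_wo     # RI planting leaves the canonical proteome unchanged
      } else {
        k <- nchar(pep)
        k1 <- ceiling(k / 2); k2 <- k - k1
        ok_j <- Filter(function(j) {
          m_prev <- nchar(cand$cds_exons[j - 1L]) / 3L
          m_next <- nchar(cand$cds_exons[j + 1L]) / 3L
          need_prev <- k1 + if (j - 1L == 1L) 1L else 0L  # keep the ATG codon
          m_prev >= need_prev && m_next >= k2 + 1L
        }, 2:(n - 1L))
        if (length(ok_j) == 0L) stop("placement error: no internal exon with room in ", gene_id)
        j <- if (length(ok_j) == 1L) ok_j[[1]] else sample(unlist(ok_j), 1L)
        prev <- cand$cds_exons[j - 1L]; nxt <- cand$cds_exons[j + 1L]
        half1 <- substr(pep, 1L, k1); half2 <- substr(pep, k1 + 1L, k)
        cand$cds_exons[j - 1L] <- paste0(
          substr(prev, 1L, nchar(prev) - 3L * k1), encode_peptide(half1))
        cand$cds_exons[j + 1L] <- paste0(
          encode_peptide(half2), substr(nxt, 3L * k2 + 1L, nchar(nxt)))
        cand$planted <- list(event_type = "SE", variant = "SE_exclusion",
                             index = j, peptide = pep)
        new_prot <- proteome_wo
        new_prot[gene_id] <- translate_dna(paste(cand$cds_exons, collapse = ""))
      }
      if (!collides(pep, new_prot)) {
        tg$genes[[gi]] <- cand
        psi <- default_truth_psi[[event_type]]
        truth <- data.frame(
          event_id = NA_character_, event_type = event_type, gene_id = gene_id,
          true_psi_control = psi[["control"]], true_psi_treated = psi[["treated"]],
          is_significant = TRUE, planted_peptide = pep,
          stringsAsFactors = FALSE)
        return(list(genome = tg, truth = truth))
      }
      if (!draw_peptide) {
        stop("peptide '", pep, "' collides with the canonical proteome")
      }
    }
    stop("could not place a collision-free peptide after 200 attempts")
  })
}

# rMATS-style coordinate columns for one event on a gene model.
# All *Start*/ES columns are 0-based, end columns 1-based inclusive, per the
# rMATS convention. upstream/downstream are in TRANSCRIPT orientation.
event_coords <- function(model, event_type, j, a_shift = 12L) {
  ex <- model$exons  # transcript order
  n <- nrow(ex)
  s0 <- function(i) ex$start[i] - 1L
  ee <- function(i) ex$end[i]
  switch(event_type,
    SE = data.frame(exonStart_0base = s0(j), exonEnd = ee(j),
                    upstreamES = s0(j - 1L), upstreamEE = ee(j - 1L),
                    downstreamES = s0(j + 1L), downstreamEE = ee(j + 1L)),
    RI = data.frame(riExonStart_0base = min(s0(j), s0(j + 1L)),
                    riExonEnd = max(ee(j), ee(j + 1L)),
                    upstreamES = s0(j), upstreamEE = ee(j),
                    downstreamES = s0(j + 1L), downstreamEE = ee(j + 1L)),
    MXE = data.frame(`1stExonStart_0base` = s0(j), `1stExonEnd` = ee(j),
                     `2ndExonStart_0base` = s0(j + 1L), `2ndExonEnd` = ee(j + 1L),
                     upstreamES = s0(j - 1L), upstreamEE = ee(j - 1L),
                     downstreamES = s0(j + 2L), downstreamEE = ee(j + 2L),
                     check.names = FALSE),
    A3SS = {
      plus <- model$strand == "+"
      data.frame(longExonStart_0base = if (plus) s0(j) - a_shift else s0(j),
                 longExonEnd = if (plus) ee(j) else ee(j) + a_shift,
                 shortES = s0(j), shortEE = ee(j),
                 flankingES = s0(j - 1L), flankingEE = ee(j - 1L))
    },
    A5SS = {
      plus <- model$strand == "+"
      data.frame(longExonStart_0base = if (plus) s0(j) else s0(j) - a_shift,
                 longExonEnd = if (plus) ee(j) + a_shift else ee(j),
                 shortES = s0(j), shortEE = ee(j),
                 flankingES = s0(j + 1L), flankingEE = ee(j + 1L))
    },
    stop("unknown event type: ", event_type))
}

# Pick a valid anchor exon index for an event type on a model with n exons.
valid_event_index <- function(event_type, n) {
  switch(event_type,
    SE = if (n >= 3L) 2:(n - 1L) else integer(0),
    RI = if (n >= 2L) seq_len(n - 1L) else integer(0),
    MXE = if (n >= 4L) 2:(n - 2L) else integer(0),
    A3SS = if (n >= 2L) 2:n else integer(0),
    A5SS = if (n >= 2L) seq_len(n - 1L) else integer(0))
}

# Effective junction-count form lengths per event type (JC counting).
form_lengths <- function(event_type, read_length) {
  jl <- read_length - 1L
  switch(event_type,
    SE = c(inc = 2L * jl, skip = jl),
    RI = c(inc = 2L * jl, skip = jl),
    MXE = c(inc = 2L * jl, skip = 2L * jl),
    A3SS = c(inc = jl, skip = jl),
    A5SS = c(inc = jl, skip = jl))
}

#' Simulate rMATS-dialect junction-count tables with planted truth
#'
#' For every truth row, inclusion counts are drawn per replicate as
#' `I ~ Binomial(reads_per_event, p)` with `p` chosen so that the
#' length-normalised PSI expectation equals the planted true PSI
#' (`p = psi * lI / (psi * lI + (1 - psi) * lS)`), and `S = reads - I`.
#' Sample 1 is the treated group, sample 2 the control, two replicates each.
#' FDR is set to 0.001 for planted-significant rows and drawn uniform on
#' (0.2, 1) otherwise, so the significance filter recovers the planted truth
#' exactly; significant rows are re-drawn (bounded retries, then expectation
#' counts) if sampling noise pushed the observed |IncLevelDifference| under
#' the 0.1 cut-off.
#'
#' @param tg A `toy_genome` (events are placed on its genes).
#' @param truths Data frame with columns `event_id` (optional; generated if
#'   absent), `event_type`, `gene_id`, `true_psi_control`, `true_psi_treated`,
#'   `is_significant`, and optional `planted` (logical: use the gene's
#'   planted neoepitope coordinates).
#' @param reads_per_event Junction reads per replicate (>= 1).
#' @param read_length Read length used for the effective form lengths.
#' @param seed Integer seed.
#' @return List with `tables` (named list of rMATS-dialect data frames, one
#'   per event type present) and `truth` (the input with `event_id` filled
#'   as `<type>_<ID>`).
#' @export
plant_splice_events <- function(tg, truths, reads_per_event = 2000L,
                                read_length = 100L, seed) {
  stopifnot(reads_per_event >= 1)
  bad <- truths$is_significant !=
    (abs(truths$true_psi_treated - truths$true_psi_control) > 0.1)
  if (any(bad)) {
    stop("truth table violates is_significant <=> |dPSI| > 0.1 at rows: ",
         paste(which(bad), collapse = ","))
  }
  models <- toy_gene_models(tg)
  by_gene <- setNames(models, vapply(models, `[[`, character(1), "gene_id"))
  planted_flag <- truths$planted %||% rep(FALSE, nrow(truths))
  if (is.null(truths$event_id)) truths$event_id <- NA_character_

  withr::with_seed(seed, {
    out <- list()
    for (type in intersect(c("SE", "RI", "MXE", "A3SS", "A5SS"),
                           unique(truths$event_type))) {
      rows_idx <- which(truths$event_type == type)
      fl <- form_lengths(type, read_length)
      recs <- lapply(seq_along(rows_idx), function(ii) {
        tr <- truths[rows_idx[ii], ]
        model <- by_gene[[tr$gene_id]]
        if (is.null(model)) stop("coordinate error: unknown gene ", tr$gene_id)
        n <- nrow(model$exons)
        if (isTRUE(planted_flag[rows_idx[ii]])) {
          gi <- which(vapply(tg$genes, `[[`, character(1), "gene_id") == tr$gene_id)
          pl <- tg$genes[[gi]]$planted
          if (is.null(pl) || pl$event_type != type) {
            stop("gene ", tr$gene_id, " has no planted ", type, " event")
          }
          j <- pl$index
        } else {
          cand <- valid_event_index(type, n)
          if (length(cand) == 0L) {
            # fall back to any gene that can host this event type
            ok <- Filter(function(m) length(valid_event_index(type, nrow(m$exons))) > 0,
                         models)
            if (length(ok) == 0L) stop("no gene can host a ", type, " event")
            model <- ok[[sample.int(length(ok), 1L)]]
            cand <- valid_event_index(type, nrow(model$exons))
          }
          j <- if (length(cand) == 1L) cand else sample(cand, 1L)
        }
        coords <- event_coords(model, type, j)
        p_of <- function(psi) psi * fl["inc"] / (psi * fl["inc"] + (1 - psi) * fl["skip"])
        draw <- function() {
          i1 <- rbinom(2L, reads_per_event, p_of(tr$true_psi_treated))
          i2 <- rbinom(2L, reads_per_event, p_of(tr$true_psi_control))
          list(i1 = i1, s1 = reads_per_event - i1,
               i2 = i2, s2 = reads_per_event - i2)
        }
        cc <- draw()
        obs_diff <- function(cc) {
          p1 <- compute_psi(cc$i1, cc$s1, fl["inc"], fl["skip"])
          p2 <- compute_psi(cc$i2, cc$s2, fl["inc"], fl["skip"])
          mean(p1, na.rm = TRUE) - mean(p2, na.rm = TRUE)
        }
        if (tr$is_significant) {
          tries <- 0L
          while (abs(obs_diff(cc)) <= 0.1 && tries < 50L) {
            cc <- draw(); tries <- tries + 1L
          }
          if (abs(obs_diff(cc)) <= 0.1) {  # deterministic expectation counts
            e1 <- round(reads_per_event * p_of(tr$true_psi_treated))
            e2 <- round(reads_per_event * p_of(tr$true_psi_control))
            cc <- list(i1 = rep(e1, 2L), s1 = rep(reads_per_event - e1, 2L),
                       i2 = rep(e2, 2L), s2 = rep(reads_per_event - e2, 2L))
          }
          pval <- 1e-5; fdr <- 0.001
        } else {
          fdr <- runif(1L, 0.2, 1); pval <- fdr
        }
        inc1 <- compute_psi(cc$i1, cc$s1, fl["inc"], fl["skip"])
        inc2 <- compute_psi(cc$i2, cc$s2, fl["inc"], fl["skip"])
        cbind(
          data.frame(ID = ii, GeneID = model$gene_id, geneSymbol = model$gene_id,
                     chr = model$chrom, strand = model$strand),
          coords,
          data.frame(ID.1 = ii,
                     IJC_SAMPLE_1 = paste(cc$i1, collapse = ","),
                     SJC_SAMPLE_1 = paste(cc$s1, collapse = ","),
                     IJC_SAMPLE_2 = paste(cc$i2, collapse = ","),
                     SJC_SAMPLE_2 = paste(cc$s2, collapse = ","),
                     IncFormLen = unname(fl["inc"]), SkipFormLen = unname(fl["skip"]),
                     PValue = pval, FDR = fdr,
                     IncLevel1 = paste(sprintf("%.9g", inc1), collapse = ","),
                     IncLevel2 = paste(sprintf("%.9g", inc2), collapse = ","),
                     IncLevelDifference = mean(inc1, na.rm = TRUE) - mean(inc2, na.rm = TRUE)))
      })
      tab <- do.call(rbind, recs)
      out[[type]] <- tab
      truths$event_id[rows_idx] <- paste0(type, "_", tab$ID)
    }
    list(tables = out, truth = truths)
  })
}

#' Write rMATS-dialect tables to a directory
#'
#' One `<TYPE>.MATS.JC.txt` file per event type, matching the rMATS 4.1.2
#' junction-count header for that type.
#'
#' @param tables Named list of data frames from [plant_splice_events()].
#' @param dir Output directory.
#' @return Invisibly, the named file paths.
#' @export
write_rmats_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(type) {
    path <- file.path(dir, paste0(type, ".MATS.JC.txt"))
    write_rmats_table(tables[[type]], type, path)
    path
  }, character(1))
  invisible(paths)
}
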