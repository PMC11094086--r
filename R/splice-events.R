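# PSI computation, significance filtering, direction classification and
# family-level skew statistics for alternative splicing events.

#' Percent spliced-in from junction counts
#'
#' The rMATS inclusion level, re-derived for verification:
#' `psi = (I/lI) / ((I/lI) + (S/lS))`, computed per replicate. Undefined
#' (`NA`) when a replicate has `I = S = 0`.
#'
#' @param I Inclusion junction counts (vector, one per replicate).
#' @param S Skipping junction counts (same length).
#' @param lI,lS Effective inclusion/skipping form lengths (`>= 1`).
#' @return Numeric vector of per-replicate PSI values in `[0, 1]`.
#' @export
compute_psi <- function(I, S, lI, lS) {
  stopifnot(length(I) == length(S), all(lI >= 1), all(lS >= 1),
            all(I >= 0, na.rm = TRUE), all(S >= 0, na.rm = TRUE))
  inc <- I / lI
  skp <- S / lS
  psi <- inc / (inc + skp)
  psi[I == 0 & S == 0] <- NA_real_
  psi
}

#' Significance filter for splicing events
#'
#' Retains events with `fdr < max_fdr` and `|delta_psi| > min_abs_dpsi`,
#' both strict, matching the study cut-offs FDR < 0.05 and |dPSI| > 0.1.
#' Events with undefined PSI in either group (hence undefined `delta_psi`)
#' cannot be evaluated and are dropped.
#'
#' @param events Data frame with `fdr` and `delta_psi` columns (from
#'   [read_rmats_table()]).
#' @param max_fdr FDR cut-off (strict `<`), default 0.05.
#' @param min_abs_dpsi |dPSI| cut-off (strict `>`), default 0.1.
#' @return The surviving rows, original order preserved.
#' @export
filter_significant <- function(events, max_fdr = 0.05, min_abs_dpsi = 0.1) {
  stopifnot(max_fdr > 0, max_fdr < 1, min_abs_dpsi >= 0)
  keep <- !is.na(events$fdr) & !is.na(events$delta_psi) &
    events$fdr < max_fdr & abs(events$delta_psi) > min_abs_dpsi
  events[keep, , drop = FALSE]
}

#' Classify event direction from the PSI change
#'
#' `UP` means increased inclusion/retention in the treated group
#' (`delta_psi > 0`), `DOWN` decreased. A significant event with
#' `delta_psi == 0` is a contract violation.
#'
#' @param events Data frame with a `delta_psi` column.
#' @return The data frame with a `direction` column added.
#' @export
classify_direction <- function(events) {
  if (any(events$delta_psi == 0 | is.na(events$delta_psi))) {
    stop("cannot classify events with delta_psi == 0 or NA; filter first")
  }
  events$direction <- ifelse(events$delta_psi > 0, "UP", "DOWN")
  events
}

#' Event counts by type and direction
#'
#' @param events Data frame with `event_type` and `direction` columns.
#' @return Complete zero-filled contingency table (rows: SE, RI, MXE, A3SS,
#'   A5SS; columns: UP, DOWN) as a matrix.
#' @export
count_by_type <- function(events) {
  types <- c("SE", "RI", "MXE", "A3SS", "A5SS")
  dirs <- c("UP", "DOWN")
  tab <- table(factor(events$event_type, levels = types),
               factor(events$direction, levels = dirs))
  m <- matrix(as.integer(tab), nrow = length(types),
              dimnames = list(event_type = types, direction = dirs))
  m
}

#' Hypergeometric test for directional skew within an event family
#'
#' Given the pooled numbers of UP and DOWN events across all families, tests
#' whether one family contains at least its observed number of UP events
#' when drawing `n_up + n_down` events from the pooled UP+DOWN population
#' (one-sided upper hypergeometric tail).
#'
#' @param n_up,n_down UP/DOWN counts in the family.
#' @param total_up,total_down Pooled UP/DOWN counts across families.
#' @return One-sided p-value, or `NA` for an empty family.
#' @export
family_skew_test <- function(n_up, n_down, total_up, total_down) {
  stopifnot(n_up >= 0, n_down >= 0, total_up >= n_up, total_down >= n_down)
  k <- n_up + n_down
  if (k == 0L) return(NA_real_)
  stats::phyper(n_up - 1, total_up, total_down, k, lower.tail = FALSE)
}

#' Family skew tests for a full type-by-direction count table
#'
#' @param counts Matrix from [count_by_type()].
#' @return Data frame with one row per event family: counts and the
#'   UP-enrichment and DOWN-enrichment hypergeometric p-values.
#' @export
family_skew_table <- function(counts) {
  tu <- sum(counts[, "UP"]); td <- sum(counts[, "DOWN"])
  data.frame(
    event_type = rownames(counts),
    n_up = counts[, "UP"], n_down = counts[, "DOWN"],
    p_up = vapply(rownames(counts), function(t)
      family_skew_test(counts[t, "UP"], counts[t, "DOWN"], tu, td), numeric(1)),
    p_down = vapply(rownames(counts), function(t)
      family_skew_test(counts[t, "DOWN"], counts[t, "UP"], td, tu), numeric(1)),
    row.names = NULL)
}

#' Mirror rMATS-dialect event coordinates onto a reverse-complemented genome
#'
#' Companion to [mirror_toy_genome()]: transforms every coordinate column
#' (0-based starts, 1-based ends) to the flipped chromosome and swaps the
#' strand, leaving transcript-orientation semantics intact.
#'
#' @param events Data frame from [read_rmats_table()] / [read_rmats_dir()].
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return The mirrored events data frame.
#' @export
mirror_events <- function(events, chrom_lengths) {
  L <- chrom_lengths[events$chrom]
  start_cols <- intersect(unique(unlist(lapply(rmats_coord_cols, function(x)
    grep("Start|ES$", x, value = TRUE)))), names(events))
  end_cols <- intersect(unique(unlist(lapply(rmats_coord_cols, function(x)
    grep("End|EE$", x, value = TRUE)))), names(events))
  old <- events
  for (sc in start_cols) {
    ec <- sub("Start_0base", "End", sub("ES$", "EE", sc))
    events[[sc]] <- as.integer(L - old[[ec]])
    events[[ec]] <- as.integer(L - old[[sc]])
  }
  events$strand <- ifelse(old$strand == "+", "-", "+")
  events
}
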