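# Perseus-style differential intensity analysis: valid-value filtering,
# median normalisation, downshifted-normal imputation, and the SAM/S0
# moderated t statistic with permutation FDR.

#' Parameter presets for the proteome and phosphoproteome workflows
#'
#' The two named parameter sets used throughout: proteome (valid fraction
#' 0.75, imputation width 0.3 / downshift 2.4, S0 = 0.35) and phospho
#' (valid fraction 1.0, width 0.3 / downshift 1.8, S0 = 0.1, site
#' localization probability >= 0.75), both at 5% FDR.
#'
#' @param which `"proteome"` or `"phospho"`.
#' @return Named list of parameters.
#' @export
perseus_preset <- function(which = c("proteome", "phospho")) {
  which <- match.arg(which)
  switch(which,
    proteome = list(valid_fraction = 0.75, width = 0.3, downshift = 2.4,
                    s0 = 0.35, fdr = 0.05, min_localization = NA),
    phospho  = list(valid_fraction = 1.00, width = 0.3, downshift = 1.8,
                    s0 = 0.10, fdr = 0.05, min_localization = 0.75))
}

#' Filter features on valid-value presence within at least one group
#'
#' Keeps a feature if its non-missing fraction is `>= min_fraction` in at
#' least one sample group (the "at least 75% valid values in at least one
#' group" rule; `min_fraction = 1` gives the 100% phospho rule).
#'
#' @param im An `intensity_matrix`.
#' @param min_fraction Required valid fraction, `0 < f <= 1`.
#' @return Filtered `intensity_matrix`; a warning (not an error) if empty.
#' @export
filter_valid_fraction <- function(im, min_fraction) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  ok_by_group <- vapply(unique(im$groups), function(g) {
    sub <- im$values[, im$groups == g, drop = FALSE]
    rowMeans(!is.na(sub)) >= min_fraction
  }, logical(nrow(im$values)))
  keep <- apply(matrix(ok_by_group, nrow = nrow(im$values)), 1, any)
  if (!any(keep)) warning("valid-value filter removed every feature")
  subset_features(im, keep)
}

#' Filter phosphosite rows on flags and localization probability
#'
#' Drops rows flagged as reverse-database or contaminant hits and rows with
#' localization probability below the cut-off (inclusive bound: 0.75 is
#' kept at the default).
#'
#' @param im An `intensity_matrix` whose `feature_meta` has
#'   `localization_prob` and optionally logical `reverse` / `contaminant`.
#' @param min_localization Minimum site localization probability.
#' @return Filtered `intensity_matrix`.
#' @export
filter_phosphosites <- function(im, min_localization = 0.75) {
  meta <- im$feature_meta
  if (is.null(meta) || is.null(meta$localization_prob)) {
    stop("phosphosite metadata (localization_prob) is required")
  }
  keep <- meta$localization_prob >= min_localization
  if (!is.null(meta$reverse)) keep <- keep & !meta$reverse
  if (!is.null(meta$contaminant)) keep <- keep & !meta$contaminant
  subset_features(im, keep)
}

#' Median normalisation
#'
#' Subtracts each sample's median of observed values, so that every
#' post-normalisation sample median is zero.
#'
#' @param im An `intensity_matrix`.
#' @return Normalised `intensity_matrix`.
#' @export
median_normalize <- function(im) {
  med <- apply(im$values, 2, median, na.rm = TRUE)
  im$values <- sweep(im$values, 2, med, "-")
  im
}

#' Downshifted-normal imputation of missing values
#'
#' Replaces each missing entry in sample `s` by a draw from
#' `N(mu_s - downshift * sd_s, (width * sd_s)^2)`, where `mu_s`, `sd_s` are
#' the mean and standard deviation of the observed values of that sample
#' (`per = "sample"`, the Perseus "each column" mode) or of the whole
#' matrix (`per = "matrix"`). Observed entries are untouched.
#'
#' @param im An `intensity_matrix`.
#' @param width Width of the imputation distribution relative to `sd_s`.
#' @param downshift Downshift in units of `sd_s`.
#' @param seed Integer seed; imputation is reproducible.
#' @param per `"sample"` (default) or `"matrix"`.
#' @return Imputed `intensity_matrix` (no missing entries).
#' @export
impute_downshifted_normal <- function(im, width, downshift, seed,
                                      per = c("sample", "matrix")) {
  stopifnot(width > 0, downshift >= 0)
  per <- match.arg(per)
  vals <- im$values
  withr::with_seed(seed, {
    if (per == "matrix") {
      obs <- vals[!is.na(vals)]
      if (length(obs) < 2L) stop("imputation error: fewer than 2 observed values")
      mu <- mean(obs); s <- sd(obs)
      miss <- is.na(vals)
      vals[miss] <- rnorm(sum(miss), mu - downshift * s, width * s)
    } else {
      for (j in seq_len(ncol(vals))) {
        obs <- vals[!is.na(vals[, j]), j]
        miss <- which(is.na(vals[, j]))
        if (length(miss) == 0L) next
        if (length(obs) < 2L) {
          stop("imputation error: sample ", colnames(vals)[j],
               " has fewer than 2 observed values")
        }
        mu <- mean(obs); s <- sd(obs)
        vals[miss, j] <- rnorm(length(miss), mu - downshift * s, width * s)
      }
    }
  })
  im$values <- vals
  im
}

# Moderated statistic d = (mean_t - mean_c) / (s + s0) with s the two-sample
# pooled standard error; returns d, the fold change and s per feature.
sam_d_stat <- function(vals, is_treated, s0) {
  n1 <- sum(is_treated); n2 <- sum(!is_treated)
  m1 <- rowMeans(vals[, is_treated, drop = FALSE])
  m2 <- rowMeans(vals[, !is_treated, drop = FALSE])
  v1 <- apply(vals[, is_treated, drop = FALSE], 1, var)
  v2 <- apply(vals[, !is_treated, drop = FALSE], 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  s <- sqrt(sp2 * (1 / n1 + 1 / n2))
  list(d = (m1 - m2) / (s + s0), log2fc = m1 - m2, s = s)
}

# All distinct ways to relabel n samples with n1 "treated", as a logical
# matrix (columns are assignments); subsampled when there are too many.
permutation_labels <- function(n, n1, n_max) {
  total <- choose(n, n1)
  if (total <= n_max) {
    idx <- combn(n, n1)
    apply(idx, 2, function(i) seq_len(n) %in% i)
  } else {
    vapply(seq_len(n_max), function(b) seq_len(n) %in% sample.int(n, n1),
           logical(n))
  }
}

#' SAM/S0 moderated two-sample test with permutation FDR
#'
#' Per feature, `d = (mean_treated - mean_control) / (s + s0)` with `s` the
#' pooled two-sample standard error of the mean difference; with `s0 = 0`
#' this is exactly the classical pooled-variance Student t statistic. False
#' discovery rates follow the SAM convention: group labels are permuted
#' (all distinct assignments when there are at most `n_permutations`,
#' otherwise that many random ones), and the q-value at threshold `|d_i|`
#' is the median, over permutations, of the number of permuted `|d*|`
#' values at or above the threshold, divided by the observed count at or
#' above it, capped at 1 and made monotone non-decreasing as `|d|`
#' decreases. Ties are handled with `>=` comparisons throughout.
#'
#' @param im A complete (post-imputation) `intensity_matrix`.
#' @param s0 Variance-stabilising offset added to the standard error.
#' @param fdr_threshold Significance cut-off on the q-value.
#' @param n_permutations Maximum number of label permutations (>= 10).
#' @param seed Integer seed for the permutation draw.
#' @param treated Name of the treated group label.
#' @return Data frame: `feature_id`, `log2_fold_change`, `se`, `d`,
#'   `q_value`, `significant`.
#' @export
sam_test <- function(im, s0, fdr_threshold = 0.05, n_permutations = 250L,
                     seed = 1L, treated = "treated") {
  vals <- im$values
  if (anyNA(vals)) stop("sam_test requires a complete matrix; impute first")
  if (!treated %in% im$groups) stop("no samples labelled '", treated, "'")
  is_treated <- im$groups == treated
  if (sum(is_treated) < 2L || sum(!is_treated) < 2L) {
    stop("each group needs >= 2 samples")
  }
  stopifnot(n_permutations >= 10L)
  obs <- sam_d_stat(vals, is_treated, s0)
  m <- nrow(vals)
  abs_d <- abs(obs$d)

  perms <- withr::with_seed(seed,
    permutation_labels(ncol(vals), sum(is_treated), n_permutations))
  # counts of permuted |d*| >= threshold, evaluated at each observed |d|
  ord <- order(abs_d, decreasing = TRUE)
  thresholds <- abs_d[ord]
  fp <- matrix(0, nrow = m, ncol = ncol(perms))
  for (b in seq_len(ncol(perms))) {
    d_star <- sort(abs(sam_d_stat(vals, perms[, b], s0)$d))
    # #{|d*| >= t} via position of t in the sorted permuted values
    fp[, b] <- length(d_star) - findInterval(thresholds, d_star,
                                             left.open = TRUE)
  }
  med_fp <- apply(fp, 1, median)
  observed_count <- seq_len(m)          # #{|d| >= thresholds[i]} = i
  q_sorted <- pmin(1, med_fp / observed_count)
  for (i in seq(m - 1L, 1L)) {          # monotone in decreasing |d|
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1L])
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  data.frame(feature_id = rownames(vals),
             log2_fold_change = obs$log2fc,
             se = obs$s, d = obs$d, q_value = q,
             significant = q <= fdr_threshold,
             row.names = NULL)
}

#' Classify proteins as hyper-, hypo- or biphasically phosphorylated
#'
#' Sites are called regulated when significant and `|log2FC|` exceeds the
#' fold-change cut-off. Per protein: `hyper` if it has only up-regulated
#' sites, `hypo` only down-regulated, `biphasic` at least one of each,
#' `unchanged` when no site passes.
#'
#' @param site_results Data frame with `protein_id`, `log2_fold_change`,
#'   `significant` (e.g. [sam_test()] output joined with site metadata).
#' @param min_abs_log2fc Fold-change cut-off (strict `>`), default 0.58.
#' @return Data frame: `protein_id`, `class`, `n_sites_up`, `n_sites_down`.
#' @export
classify_protein_phospho <- function(site_results, min_abs_log2fc = 0.58) {
  stopifnot(!is.null(site_results$protein_id))
  reg <- site_results$significant &
    abs(site_results$log2_fold_change) > min_abs_log2fc
  up <- tapply(reg & site_results$log2_fold_change > 0,
               site_results$protein_id, sum)
  dn <- tapply(reg & site_results$log2_fold_change < 0,
               site_results$protein_id, sum)
  cls <- ifelse(up >= 1 & dn >= 1, "biphasic",
         ifelse(up >= 1, "hyper",
         ifelse(dn >= 1, "hypo", "unchanged")))
  data.frame(protein_id = names(up), class = unname(cls),
             n_sites_up = as.integer(up), n_sites_down = as.integer(dn),
             row.names = NULL)
}

#' Detect condition-specific features (detected in one group only)
#'
#' A feature qualifies when, in the raw (pre-imputation) matrix, it has at
#' least one valid value in one group and none in the other, and its
#' post-imputation two-sample t-test p-value is below the threshold.
#'
#' @param raw The pre-imputation `intensity_matrix` (missingness pattern).
#' @param imputed The matching post-imputation `intensity_matrix`.
#' @param p_threshold Welch t-test p-value cut-off, default 0.05.
#' @param treated Treated group label.
#' @return Data frame: `feature_id`, `direction`
#'   (`"treated-only"`/`"control-only"`), `p_value`.
#' @export
detect_condition_specific <- function(raw, imputed, p_threshold = 0.05,
                                      treated = "treated") {
  stopifnot(identical(rownames(raw$values), rownames(imputed$values)))
  is_treated <- raw$groups == treated
  n_valid_t <- rowSums(!is.na(raw$values[, is_treated, drop = FALSE]))
  n_valid_c <- rowSums(!is.na(raw$values[, !is_treated, drop = FALSE]))
  cand <- which((n_valid_t >= 1 & n_valid_c == 0) |
                (n_valid_c >= 1 & n_valid_t == 0))
  if (length(cand) == 0L) {
    return(data.frame(feature_id = character(0), direction = character(0),
                      p_value = numeric(0)))
  }
  p <- vapply(cand, function(i) {
    stats::t.test(imputed$values[i, is_treated],
                  imputed$values[i, !is_treated])$p.value
  }, numeric(1))
  out <- data.frame(
    feature_id = rownames(raw$values)[cand],
    direction = ifelse(n_valid_t[cand] > 0, "treated-only", "control-only"),
    p_value = p, row.names = NULL)
  out[out$p_value < p_threshold, , drop = FALSE]
}
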