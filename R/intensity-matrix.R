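# A light container for log2 intensity matrices with group labels and
# per-feature metadata (protein id, phosphosite, localization probability).

#' Construct an intensity matrix
#'
#' @param values Numeric matrix, features x samples, log2 intensities with
#'   `NA` for missing; rownames are feature ids, colnames sample ids.
#' @param groups Character vector (length `ncol(values)`) of group labels,
#'   e.g. `"control"`/`"treated"`; each group must have `>= 2` samples.
#' @param feature_meta Optional data frame of per-feature metadata
#'   (`nrow(values)` rows), e.g. `protein_id`, `site`,
#'   `localization_prob`, `reverse`, `contaminant`.
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, groups, feature_meta = NULL) {
  stopifnot(is.matrix(values), length(groups) == ncol(values))
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("f%05d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- make.unique(paste0(groups, "_", seq_along(groups)), sep = "r")
  }
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  if (any(!is.finite(values) & !is.na(values))) stop("values must be finite or NA")
  if (!is.null(feature_meta)) stopifnot(nrow(feature_meta) == nrow(values))
  structure(list(values = values, groups = as.character(groups),
                 feature_meta = feature_meta),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d features x %d samples (%s); %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s n=%d", names(table(x$groups)), table(x$groups)),
                    collapse = ", "),
              100 * mean(is.na(x$values))))
  invisible(x)
}

subset_features <- function(im, keep) {
  im$values <- im$values[keep, , drop = FALSE]
  if (!is.null(im$feature_meta)) {
    im$feature_meta <- im$feature_meta[keep, , drop = FALSE]
  }
  im
}

#' Write an intensity matrix as TSV
#'
#' First column `feature`, then one column per sample; missing entries are
#' empty cells. Group labels go in a `#groups:` comment on line one.
#'
#' @param im An `intensity_matrix`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_intensity_tsv <- function(im, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#groups: ", paste(im$groups, collapse = "\t")), con)
  df <- data.frame(feature = rownames(im$values), im$values,
                   check.names = FALSE)
  if (!is.null(im$feature_meta)) df <- cbind(df, im$feature_meta)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an intensity matrix TSV written by [write_intensity_tsv()]
#'
#' @param path File path.
#' @param meta_cols Names of trailing metadata columns, if any.
#' @return An `intensity_matrix`.
#' @export
read_intensity_tsv <- function(path, meta_cols = NULL) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#groups: ")) stop("missing #groups: header in ", path)
  groups <- strsplit(sub("^#groups: ", "", first), "\t", fixed = TRUE)[[1]]
  df <- read.delim(path, skip = 1L, check.names = FALSE, na.strings = "")
  meta <- NULL
  if (!is.null(meta_cols)) {
    meta <- df[, meta_cols, drop = FALSE]
    df <- df[, setdiff(names(df), meta_cols), drop = FALSE]
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$feature
  intensity_matrix(vals, groups, meta)
}

#' Simulate a log-normal intensity matrix with planted group effects
#'
#' Log2 intensities are `baseline + effect * treated + N(0, noise_sd^2)`;
#' the planted per-feature effect is the treated-minus-control log2 fold
#' change. Low-intensity values are censored to missing with a logistic
#' probability that increases as intensity decreases (missing-not-at-random
#' dropout): `P(missing | x) = dropout_rate * plogis((censor_at - x) /
#' censor_scale)`.
#'
#' @param n_features Number of features.
#' @param n_per_group Samples per group (`>= 2`).
#' @param effects Numeric vector (length `n_features`) of planted log2
#'   effects; 0 means null. Alternatively a single number recycled.
#' @param noise_sd Residual standard deviation (log2 units).
#' @param dropout_rate Per-feature maximal dropout probability in `[0, 1]`
#'   (scalar or vector); 0 disables censoring.
#' @param baseline_mean,baseline_sd Feature baseline distribution (log2).
#' @param censor_at Intensity at which dropout probability is half-maximal;
#'   default `baseline_mean - 1.5 * baseline_sd`.
#' @param censor_scale Logistic scale of the censoring curve (log2 units).
#' @param seed Integer seed.
#' @return List with `matrix` (an `intensity_matrix`, groups
#'   `control`/`treated`) and `truth` (feature_id, group_effect, is_null,
#'   dropout_rate).
#' @export
simulate_intensity_matrix <- function(n_features, n_per_group, effects = 0,
                                      noise_sd = 0.5, dropout_rate = 0,
                                      baseline_mean = 25, baseline_sd = 2,
                                      censor_at = baseline_mean - 1.5 * baseline_sd,
                                      censor_scale = 0.8, seed) {
  stopifnot(n_per_group >= 2)
  effects <- rep_len(effects, n_features)
  dropout_rate <- rep_len(dropout_rate, n_features)
  stopifnot(all(dropout_rate >= 0 & dropout_rate <= 1))
  withr::with_seed(seed, {
    groups <- rep(c("control", "treated"), each = n_per_group)
    baseline <- rnorm(n_features, baseline_mean, baseline_sd)
    mu <- outer(baseline, rep(1, 2 * n_per_group)) +
      outer(effects, as.numeric(groups == "treated"))
    vals <- mu + matrix(rnorm(length(mu), 0, noise_sd), nrow = n_features)
    p_miss <- dropout_rate * stats::plogis((censor_at - vals) / censor_scale)
    vals[matrix(runif(length(vals)), nrow = n_features) < p_miss] <- NA
    rownames(vals) <- sprintf("f%05d", seq_len(n_features))
    colnames(vals) <- paste0(groups, "_", rep(seq_len(n_per_group), 2))
    truth <- data.frame(feature_id = rownames(vals), group_effect = effects,
                        is_null = effects == 0, dropout_rate = dropout_rate)
    list(matrix = intensity_matrix(vals, groups), truth = truth)
  })
}
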