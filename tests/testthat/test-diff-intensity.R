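# Perseus-style differential stage: filtering, normalisation, imputation,
# the SAM/S0 statistic with permutation FDR, and downstream classification.

im_from <- function(vals, groups, meta = NULL) {
  intensity_matrix(matrix(vals, nrow = length(vals) / length(groups),
                          byrow = TRUE), groups, meta)
}

test_that("valid-value filter applies the at-least-one-group rule", {
  groups <- rep(c("control", "treated"), each = 4)
  vals <- rbind(
    c(1, 2, 3, NA, NA, NA, NA, NA),   # 3/4 in control, 0/4 treated -> kept at 0.75
    c(1, 2, NA, NA, 3, 4, NA, NA),    # 2/4 both -> dropped at 0.75
    c(1, 2, 3, 4, NA, 2, 3, 4))       # complete control -> kept even at 1.0
  im <- intensity_matrix(vals, groups)
  expect_identical(rownames(filter_valid_fraction(im, 0.75)$values),
                   rownames(vals <- im$values)[c(1, 3)])
  expect_identical(rownames(filter_valid_fraction(im, 1.0)$values),
                   rownames(im$values)[3])
  expect_warning(filter_valid_fraction(
    intensity_matrix(matrix(NA_real_, 1, 8), groups), 0.75), "every feature")
})

test_that("phosphosite filter honours flags and the inclusive 0.75 bound", {
  groups <- rep(c("control", "treated"), each = 2)
  meta <- data.frame(protein_id = paste0("P", 1:4),
                     localization_prob = c(0.75, 0.99, 0.74, 0.80),
                     reverse = c(FALSE, TRUE, FALSE, FALSE),
                     contaminant = c(FALSE, FALSE, FALSE, TRUE))
  im <- intensity_matrix(matrix(1, 4, 4), groups, meta)
  kept <- filter_phosphosites(im)
  expect_identical(kept$feature_meta$protein_id, "P1")  # 0.75 kept inclusively
  expect_error(filter_phosphosites(intensity_matrix(matrix(1, 2, 4), groups)),
               "localization_prob")
})

test_that("median normalisation zeroes every sample median and is idempotent", {
  groups <- rep(c("control", "treated"), each = 2)
  im <- intensity_matrix(matrix(c(1, 2, 3, 0, 0, 0, 5, 5, 6, -1, 0, 1), 3, 4),
                         groups)
  norm <- median_normalize(im)
  expect_equal(unname(norm$values[, 1]), c(-1, 0, 1))
  expect_equal(unname(apply(norm$values, 2, median)), rep(0, 4))
  expect_equal(median_normalize(norm)$values, norm$values)
  set.seed(1)
  imr <- intensity_matrix(matrix(rnorm(400), 50, 8), rep(c("a", "b"), each = 4))
  expect_equal(unname(apply(median_normalize(imr)$values, 2, median)),
               rep(0, 8))
})

test_that("downshifted-normal imputation draws from the stated distribution", {
  groups <- c("control", "control", "treated", "treated")
  # complete matrix is returned unchanged
  full <- intensity_matrix(matrix(rnorm(40, 25), 10, 4), groups)
  expect_identical(impute_downshifted_normal(full, 0.3, 2.4, seed = 1), full)

  # distributional oracle: observed values standardised to mean 25, sd 1
  # exactly, so imputed draws must follow N(25 - 2.4, 0.3^2) = N(22.6, 0.09)
  set.seed(5)
  n_obs <- 5000; n_miss <- 10000
  obs <- rnorm(n_obs); obs <- (obs - mean(obs)) / sd(obs) + 25
  col1 <- c(obs, rep(NA, n_miss))
  vals <- cbind(col1, matrix(rnorm(3 * (n_obs + n_miss), 25), ncol = 3))
  im <- intensity_matrix(vals, groups)
  imp <- impute_downshifted_normal(im, width = 0.3, downshift = 2.4, seed = 42)
  drawn <- imp$values[is.na(im$values[, 1]), 1]
  ks <- suppressWarnings(stats::ks.test(drawn, "pnorm", 22.6, 0.3))
  expect_gt(ks$p.value, 0.01)

  # seeded determinism; observed entries untouched
  imp2 <- impute_downshifted_normal(im, width = 0.3, downshift = 2.4, seed = 42)
  expect_identical(imp$values, imp2$values)
  expect_identical(imp$values[!is.na(im$values)], im$values[!is.na(im$values)])

  # a sample with < 2 observed values cannot be imputed
  bad <- intensity_matrix(cbind(c(1, rep(NA, 9)), matrix(1, 10, 3)), groups)
  expect_error(impute_downshifted_normal(bad, 0.3, 2.4, seed = 1),
               "imputation error")
})

test_that("with s0 = 0 the SAM statistic is the classical pooled t statistic", {
  sim <- simulate_intensity_matrix(1000, 3, effects = 0, noise_sd = 1, seed = 2)
  res <- sam_test(sim$matrix, s0 = 0, seed = 3)
  tstat <- apply(sim$matrix$values, 1, function(v) {
    unname(stats::t.test(v[4:6], v[1:3], var.equal = TRUE)$statistic)
  })
  expect_lt(max(abs(res$d - tstat)), 1e-9)
})

test_that("SAM null behaviour, s0 monotonicity and q-value ordering hold", {
  groups <- rep(c("control", "treated"), each = 3)
  # identical group means, no variance: all d = 0, nothing significant
  flat <- intensity_matrix(matrix(rep(c(20, 21, 22), each = 6), 3, 6,
                                  byrow = TRUE), groups)
  res0 <- sam_test(flat, s0 = 0.35, seed = 1)
  expect_equal(res0$d, rep(0, 3))
  expect_false(any(res0$significant))

  sim <- simulate_intensity_matrix(300, 3, effects = 0, noise_sd = 0.6, seed = 4)
  r_a <- sam_test(sim$matrix, s0 = 0.35, seed = 5)
  r_b <- sam_test(sim$matrix, s0 = 0.05, seed = 5)
  expect_true(all(sign(r_a$d) == sign(r_b$d)))
  # q-values non-decreasing as |d| decreases
  ord <- order(abs(r_a$d), decreasing = TRUE)
  expect_true(all(diff(r_a$q_value[ord]) >= 0))
  # determinism
  expect_identical(r_a, sam_test(sim$matrix, s0 = 0.35, seed = 5))
})

test_that("SAM recovers planted effects with controlled error", {
  eff <- rep(c(2, 0), c(30, 270))
  hits <- 0; fps <- 0
  for (s in 1:5) {
    sim <- simulate_intensity_matrix(300, 3, effects = eff, noise_sd = 0.5,
                                     seed = 50 + s)
    r <- sam_test(sim$matrix, s0 = 0.35, fdr_threshold = 0.05, seed = s)
    hits <- hits + sum(r$significant & !sim$truth$is_null)
    fps <- fps + sum(r$significant & sim$truth$is_null)
  }
  expect_gt(hits / (5 * 30), 0.9)
  expect_lt(fps / max(1, hits + fps), 0.10)
})

test_that("protein phospho classification follows the site-direction rules", {
  sites <- data.frame(
    protein_id = c("A", "A", "B", "B", "C", "D"),
    log2_fold_change = c(1.2, 0.9, 1.2, -0.8, 0.3, -1.5),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  cls <- classify_protein_phospho(sites)
  got <- setNames(cls$class, cls$protein_id)
  expect_identical(unname(got[c("A", "B", "C", "D")]),
                   c("hyper", "biphasic", "unchanged", "unchanged"))
  # classes partition the proteins
  expect_identical(sort(cls$protein_id), c("A", "B", "C", "D"))
  expect_true(all((cls$class == "biphasic") ==
                  (cls$n_sites_up >= 1 & cls$n_sites_down >= 1)))
})

test_that("condition-specific detection needs one-group-only missingness", {
  groups <- rep(c("control", "treated"), each = 3)
  set.seed(9)
  background <- matrix(rnorm(40 * 6, 25, 0.3), 40, 6)
  raw_vals <- rbind(
    c(NA, NA, NA, 25.1, 25.0, 24.9),   # treated-only, well separated from
    c(25.0, 24.9, 25.1, NA, NA, NA),   # the downshifted imputed values
    c(20, 20, 20, 24, 24, 24),         # detected in both -> never reported
    background)
  raw <- intensity_matrix(raw_vals, groups)
  imp <- impute_downshifted_normal(raw, 0.3, 1.8, seed = 7)
  hits <- detect_condition_specific(raw, imp, p_threshold = 0.05)
  ids <- rownames(raw$values)
  expect_true(all(hits$feature_id %in% ids[1:2]))
  expect_false(ids[3] %in% hits$feature_id)
  expect_identical(hits$direction[hits$feature_id == ids[1]], "treated-only")
  expect_identical(hits$direction[hits$feature_id == ids[2]], "control-only")
})
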