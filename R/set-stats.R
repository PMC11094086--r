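# Hypergeometric overlap tests between gene/transcript sets and
# foreground-vs-background location-shift tests.

#' Hypergeometric overlap test between two sets
#'
#' Exact upper-tail probability of observing at least the given overlap
#' when drawing `|B|` elements from a universe containing `|A|` marked
#' elements (enrichment orientation; `alternative = "depletion"` gives the
#' lower tail). The universe must be passed explicitly: overlap p-values
#' are meaningless without a declared universe.
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @param universe Character vector containing both sets.
#' @param alternative `"enrichment"` (default) or `"depletion"`.
#' @return List: `set_a_size`, `set_b_size`, `universe_size`,
#'   `overlap_size`, `expected_overlap`, `p_value`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe,
                                   alternative = c("enrichment", "depletion")) {
  alternative <- match.arg(alternative)
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b)) {
    stop("element(s) outside the declared universe: ",
         paste(head(c(out_a, out_b), 5), collapse = ", "))
  }
  k <- length(intersect(set_a, set_b))
  m <- length(set_a); n <- length(universe) - m; b <- length(set_b)
  p <- if (alternative == "enrichment") {
    stats::phyper(k - 1, m, n, b, lower.tail = FALSE)
  } else {
    stats::phyper(k, m, n, b, lower.tail = TRUE)
  }
  list(set_a_size = m, set_b_size = b, universe_size = m + n,
       overlap_size = k, expected_overlap = m * b / (m + n), p_value = p)
}

#' Foreground-vs-background location shift test
#'
#' Two-sided test of a location shift of the foreground values against the
#' background, as a Welch t-test or a Mann-Whitney U test; direction is
#' reported as foreground minus background.
#'
#' @param fg_values,bg_values Numeric vectors.
#' @param test `"t"` or `"mann_whitney"`.
#' @return List: `mean_fg`, `mean_bg`, `median_fg`, `median_bg`, `shift`
#'   (fg - bg, mean for t / median for Mann-Whitney), `p_value`, `test`.
#' @export
foreground_background_shift <- function(fg_values, bg_values,
                                        test = c("t", "mann_whitney")) {
  test <- match.arg(test)
  stopifnot(length(fg_values) > 0, length(bg_values) > 0)
  if (test == "t") {
    p <- if (isTRUE(all.equal(var(c(fg_values, bg_values)), 0))) 1
         else stats::t.test(fg_values, bg_values)$p.value
    shift <- mean(fg_values) - mean(bg_values)
  } else {
    p <- compare_groups(fg_values, bg_values)$p_two_sided
    shift <- median(fg_values) - median(bg_values)
  }
  list(mean_fg = mean(fg_values), mean_bg = mean(bg_values),
       median_fg = median(fg_values), median_bg = median(bg_values),
       shift = shift, p_value = p, test = test)
}

#' Exclusive intersection region counts for several sets
#'
#' Venn-style partition: every element of the union is assigned to exactly
#' one membership pattern, so region counts sum to the union size.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return Data frame: `region` (set names joined by `&`, or per-set
#'   exclusive regions), `count`.
#' @export
multiset_intersections <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(NULL, names(sets)))
  pattern <- apply(membership, 1, function(r) paste(names(sets)[r], collapse = "&"))
  tab <- table(pattern)
  data.frame(region = names(tab), count = as.integer(tab), row.names = NULL)
}
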