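#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test for association in a 2x2 contingency table
#' (rows: factor level, columns: diversification present/absent). The
#' two-sided p follows the minimum-likelihood convention (sum of the
#' probabilities of all tables with fixed margins at most as probable
#' as the observed one). The reported odds ratio is the sample odds
#' ratio `a*d / (b*c)` (infinite when `b*c = 0` with `a*d > 0`), not
#' the conditional maximum-likelihood estimate.
#'
#' @param t 2x2 integer matrix, or the four counts `a, b, c, d` in
#'   row-major order.
#' @param alternative `"two_sided"` (default), `"less"` or `"greater"`.
#' @return list with `odds_ratio`, `p`, and `degenerate` (TRUE when a
#'   margin is zero, in which case `p = 1` and the odds ratio is NA).
#' @examples
#' fisher_exact_2x2(matrix(c(40, 236, 60, 123), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(t, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!is.matrix(t)) t <- matrix(as.numeric(t), 2L, 2L, byrow = TRUE)
  stopifnot(dim(t) == c(2L, 2L))
  if (any(t < 0) || any(t != round(t)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(t) == 0) stop("table is empty", call. = FALSE)
  a <- t[1, 1]; b <- t[1, 2]; cc <- t[2, 1]; d <- t[2, 2]
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    return(list(odds_ratio = NA_real_, p = 1, degenerate = TRUE))
  or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
  alt <- switch(alternative, two_sided = "two.sided", less = "less",
                greater = "greater")
  p <- stats::fisher.test(t, alternative = alt)$p.value
  list(odds_ratio = or, p = min(p, 1), degenerate = FALSE)
}

#' Kruskal-Wallis rank test
#'
#' Compares two or more groups of continuous values by ranks, with tie
#' correction; p from the chi-squared approximation with k - 1 degrees
#' of freedom. Completely tied data (all values identical) give
#' `H = 0, p = 1` rather than an error.
#'
#' @param groups list of numeric vectors, each non-empty.
#' @return list with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(!vapply(groups, length, integer(1))))
    stop("each group must be non-empty", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  if (length(unique(values)) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Microenvironmental subtype calls
#'
#' Classifies slides by the abundance of lymphocytes and stromal cells
#' among all cells: Lymphocyte-high slides combine high lymphocyte with
#' low stromal abundance, Stromal-high the reverse, everything else is
#' Other. In `"percentile"` mode (default) the high/low thresholds are
#' the cohort's 75th/25th percentiles of each variable; in
#' `"absolute"` mode they are fixed percentages (defaults 75 and 25).
#'
#' @param lymphocyte_pct,stromal_pct per-slide percentages (0-100).
#' @param mode `"percentile"` or `"absolute"`.
#' @param hi,lo thresholds for absolute mode, in `[0, 100]`.
#' @return character vector of labels (`"Lymphocyte-high"`,
#'   `"Stromal-high"`, `"Other"`).
#' @export
microenv_subtype <- function(lymphocyte_pct, stromal_pct,
                             mode = c("percentile", "absolute"),
                             hi = 75, lo = 25) {
  mode <- match.arg(mode)
  stopifnot(length(lymphocyte_pct) == length(stromal_pct))
  if (mode == "percentile") {
    if (length(lymphocyte_pct) < 4L)
      stop("percentile mode needs a cohort of at least 4 slides",
           call. = FALSE)
    l_hi <- stats::quantile(lymphocyte_pct, 0.75, names = FALSE)
    l_lo <- stats::quantile(lymphocyte_pct, 0.25, names = FALSE)
    s_hi <- stats::quantile(stromal_pct, 0.75, names = FALSE)
    s_lo <- stats::quantile(stromal_pct, 0.25, names = FALSE)
  } else {
    if (hi < 0 || hi > 100 || lo < 0 || lo > 100)
      stop("absolute thresholds must lie in [0, 100]", call. = FALSE)
    l_hi <- hi; s_hi <- hi; l_lo <- lo; s_lo <- lo
  }
  lymph_high <- lymphocyte_pct >= l_hi & stromal_pct <= s_lo
  strom_high <- stromal_pct >= s_hi & lymphocyte_pct <= l_lo
  out <- rep("Other", length(lymphocyte_pct))
  out[lymph_high & !strom_high] <- "Lymphocyte-high"
  out[strom_high & !lymph_high] <- "Stromal-high"
  out
}

#' Build a 2x2 contingency table of label vs diversification
#'
#' Cross-tabulates a per-slide categorical label against the
#' present/absent diversification call: `a` = positive level and
#' present, `b` = other and present, `c` = positive and absent, `d` =
#' other and absent. Slides with a missing label (NA or `"Unknown"`)
#' are excluded from all four cells before testing, mirroring the usual
#' handling of unannotated samples.
#'
#' @param present logical vector of per-slide present/absent calls.
#' @param labels per-slide categorical labels, aligned with `present`.
#' @param positive_level the label level forming the first row.
#' @param drop_levels labels treated as missing (default `"Unknown"`).
#' @return 2x2 integer matrix (rows: present/absent; columns: positive
#'   level/other).
#' @export
build_contingency <- function(present, labels, positive_level,
                              drop_levels = "Unknown") {
  stopifnot(length(present) == length(labels))
  keep <- !is.na(labels) & !labels %in% drop_levels & !is.na(present)
  if (!any(keep)) stop("no slides with both label and call", call. = FALSE)
  pos <- labels[keep] == positive_level
  pr <- present[keep]
  matrix(c(sum(pos & pr), sum(!pos & pr),
           sum(pos & !pr), sum(!pos & !pr)),
         2L, 2L, byrow = TRUE,
         dimnames = list(c("present", "absent"),
                         c(positive_level, "other")))
}
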