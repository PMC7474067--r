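# ---------------------------------------------------------------------------
# Outlier flagging, prevalence, global deviation ratios
# ---------------------------------------------------------------------------

#' Flag region-wise statistical outliers
#'
#' A cell is flagged when `|w| > threshold` (strict inequality: a w of
#' exactly the threshold is not an outlier and falls in the gW denominator).
#' Missing w-scores are never flagged; their count is reported.
#'
#' @param w `wscore_matrix` (subjects x regions).
#' @param threshold positive cutoff in SD units (default 2).
#' @return logical matrix with `attr(x, "n_missing")`.
#' @export
flag_outliers <- function(w, threshold = 2.0) {
  stopifnot(threshold > 0)
  flags <- !is.na(w) & abs(w) > threshold
  dimnames(flags) <- dimnames(w)
  attr(flags, "n_missing") <- sum(is.na(w))
  flags
}

#' Per-region outlier prevalence
#'
#' Proportion of the case group flagged per region, plus the across-region
#' distribution (the prevalence map's histogram analogue).
#'
#' @param flags logical matrix from [flag_outliers()].
#' @param group_n denominator; defaults to `nrow(flags)`.
#' @return list with `prevalence` (named numeric per region), `counts`,
#'   `median_prevalence`, and `distribution` (sorted prevalences).
#' @export
region_prevalence <- function(flags, group_n = nrow(flags)) {
  stopifnot(group_n > 0)
  counts <- colSums(flags)
  prev <- counts / group_n
  list(prevalence = prev, counts = counts,
       median_prevalence = median(prev),
       distribution = sort(prev))
}

#' One-sample proportion chi-square test
#'
#' Tests an observed proportion against an expected one:
#' `X^2 = n * (|p_obs - p0| - c)^2 / (p0 * (1 - p0))` with Yates continuity
#' correction `c = 1/(2n)` (capped so the corrected difference is never
#' negative) or `c = 0`; p-value from the chi-square distribution with 1 df.
#' `n` is an explicit argument: published prevalence tests are sensitive to
#' whether the region count or the subject count is used.
#'
#' @param p_obs observed proportion.
#' @param p0 expected proportion, in (0, 1).
#' @param n count the proportion is based on.
#' @param yates apply the continuity correction (default TRUE).
#' @return list with `statistic` (X^2), `p_value`, `df = 1`.
#' @export
prevalence_chisq <- function(p_obs, p0, n, yates = TRUE) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must be strictly inside (0, 1)")
  stopifnot(n > 0, p_obs >= 0, p_obs <= 1)
  cc <- if (yates) 1 / (2 * n) else 0
  diff <- max(abs(p_obs - p0) - cc, 0)
  x2 <- n * diff^2 / (p0 * (1 - p0))
  list(statistic = x2, p_value = pchisq(x2, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Global w-score ratio for one subject
#'
#' `gW = #(|w| > threshold) / #(|w| <= threshold)`: the count of outlier
#' regions over the count of non-outlier regions. `gW+` restricts the
#' numerator to `w > threshold`, `gW-` to `w < -threshold` (disjoint sets
#' partitioning the gW numerator); both share the gW denominator. Missing
#' cells are excluded from numerator and denominator. A zero denominator
#' (every region an outlier) returns `Inf` with `degenerate = TRUE`.
#'
#' @param w_row numeric vector of one subject's w-scores.
#' @param threshold cutoff (default 2).
#' @return list with `gW`, `gW_pos`, `gW_neg`, `n_outlier`, `n_typical`,
#'   `degenerate`.
#' @export
global_w_ratio <- function(w_row, threshold = 2.0) {
  w <- w_row[!is.na(w_row)]
  if (length(w) == 0L) stop("all w-scores missing for subject")
  n_out <- sum(abs(w) > threshold)
  n_pos <- sum(w > threshold)
  n_neg <- sum(w < -threshold)
  n_typ <- sum(abs(w) <= threshold)
  degenerate <- n_typ == 0L
  ratio <- function(num) if (degenerate) Inf else num / n_typ
  list(gW = ratio(n_out), gW_pos = ratio(n_pos), gW_neg = ratio(n_neg),
       n_outlier = n_out, n_typical = n_typ, degenerate = degenerate)
}

#' Global w-score ratios for all subjects
#'
#' Applies [global_w_ratio()] row-wise and adds the global-thin flag:
#' subjects whose negative-deviation ratio `gW-` exceeds `thin_ratio`
#' (default 0.5, i.e. a globally thinner cortex across a large share of
#' regions). Subjects with no scored region get `NA` ratios and are never
#' flagged.
#'
#' @param w `wscore_matrix`.
#' @param threshold outlier cutoff.
#' @param thin_ratio gW- cutoff for the global-thin flag.
#' @return data.frame: subject_id, gW, gW_pos, gW_neg, n_outlier,
#'   n_typical, degenerate, global_thin.
#' @export
global_w_table <- function(w, threshold = 2.0, thin_ratio = 0.5) {
  na_row <- list(gW = NA_real_, gW_pos = NA_real_, gW_neg = NA_real_,
                 n_outlier = NA_real_, n_typical = NA_real_,
                 degenerate = FALSE)
  rows <- lapply(seq_len(nrow(w)), function(i) {
    if (all(is.na(w[i, ]))) na_row else global_w_ratio(w[i, ], threshold)
  })
  out <- data.frame(
    subject_id = rownames(w),
    gW = vapply(rows, `[[`, numeric(1), "gW"),
    gW_pos = vapply(rows, `[[`, numeric(1), "gW_pos"),
    gW_neg = vapply(rows, `[[`, numeric(1), "gW_neg"),
    n_outlier = vapply(rows, `[[`, numeric(1), "n_outlier"),
    n_typical = vapply(rows, `[[`, numeric(1), "n_typical"),
    degenerate = vapply(rows, `[[`, logical(1), "degenerate"),
    stringsAsFactors = FALSE)
  out$global_thin <- !is.na(out$gW_neg) & out$gW_neg > thin_ratio
  out
}

#' Ages of flagged outliers, per region and pooled
#'
#' @param flags logical matrix from [flag_outliers()].
#' @param cohort `cohort_table` covering the flagged subjects.
#' @return list with `median_age` (named numeric per region, `NA` where a
#'   region has no outliers), `pooled` (the non-missing medians), and
#'   `range` of the pooled distribution.
#' @export
outlier_age_summary <- function(flags, cohort) {
  ages <- cohort$age[match(rownames(flags), cohort$subject_id)]
  med <- apply(flags, 2L, function(f)
    if (any(f)) median(ages[f]) else NA_real_)
  pooled <- med[!is.na(med)]
  list(median_age = med, pooled = pooled,
       range = if (length(pooled)) range(pooled) else c(NA_real_, NA_real_))
}
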