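# ---------------------------------------------------------------------------
# Normative model: age-bin norms, w-scores, centiles, bootstrap reliability
# ---------------------------------------------------------------------------

# integer one-year bin index for an age, [k, k+1) half-open from bin_origin
age_bin <- function(age, bin_origin) floor(age - bin_origin) + bin_origin

#' Build per-region age norms from a control group
#'
#' For each region: (1) selects the LOESS span on (age, value) of the
#' reference (control) subjects via [optimize_span()]; (2) evaluates the
#' LOESS mean at each control's age; (3) tabulates one-year age bins
#' `[k, k+1)` (integer years, starting at the floor of the minimum control
#' age): bin normative mean `mu` = median of fitted means in the bin, bin
#' normative SD `sigma` = SD of residuals (observed - fitted) in the bin.
#' Bins with fewer than `min_bin_count` controls, or with `sigma` below
#' `sigma_floor` (an essentially-zero SD makes the deviation score
#' undefined), are dropped.
#'
#' @param cohort `cohort_table` of reference subjects (controls, one sex
#'   stratum; rows with group != "control" are refused unless
#'   `allow_any_group`).
#' @param morph `morph_matrix` covering the cohort's subjects.
#' @param regions regions to model; default all columns of `morph`.
#' @param min_bin_count minimum controls per retained bin (default 5).
#' @param span_bounds,degree,sse_mode passed to [optimize_span()] /
#'   [fit_loess()].
#' @param sigma_floor minimum usable bin SD (mm).
#' @param allow_any_group set TRUE to build norms from a mixed table
#'   (e.g. for resampling internals).
#' @return object of class `normative_model`: list with `spans` (named
#'   numeric), `bins` (data.frame: region, bin, mu, sigma, n, retained),
#'   `bin_origin`, `regions`, and the call parameters.
#' @export
build_norms <- function(cohort, morph, regions = colnames(morph),
                        min_bin_count = 5L, span_bounds = c(0.05, 1),
                        degree = 1L, sse_mode = "cv", sigma_floor = 1e-6,
                        allow_any_group = FALSE) {
  if (!allow_any_group && any(cohort$group != "control"))
    stop("norms must be built on the control group only")
  morph <- align_morph(morph, cohort)
  cohort <- cohort[match(rownames(morph), cohort$subject_id), , drop = FALSE]
  if (nrow(cohort) < 10L) stop("too few reference subjects")
  ages <- cohort$age
  bin_origin <- floor(min(ages))
  spans <- setNames(numeric(length(regions)), regions)
  bins_list <- vector("list", length(regions))
  for (r in seq_along(regions)) {
    y <- morph[, regions[r]]
    spans[r] <- optimize_span(ages, y, bounds = span_bounds, degree = degree,
                              sse_mode = sse_mode)
    fitted <- fit_loess(ages, y, spans[r], degree)
    bins_list[[r]] <- bin_table(ages, y, fitted, bin_origin,
                                min_bin_count, sigma_floor, regions[r])
  }
  bins <- do.call(rbind, bins_list)
  if (!any(bins$retained)) stop("no retained bins in any region")
  structure(list(spans = spans, bins = bins, bin_origin = bin_origin,
                 regions = regions, min_bin_count = min_bin_count,
                 degree = degree, span_bounds = span_bounds,
                 sse_mode = sse_mode, sigma_floor = sigma_floor,
                 n_reference = nrow(cohort)),
            class = "normative_model")
}

bin_table <- function(ages, y, fitted, bin_origin, min_bin_count,
                      sigma_floor, region) {
  b <- age_bin(ages, bin_origin)
  ub <- sort(unique(b))
  resid <- y - fitted
  out <- data.frame(
    region = region, bin = ub,
    mu = vapply(ub, function(k) median(fitted[b == k]), numeric(1)),
    sigma = vapply(ub, function(k) {
      v <- resid[b == k]
      if (length(v) >= 2L) sd(v) else 0
    }, numeric(1)),
    n = vapply(ub, function(k) sum(b == k), integer(1)),
    stringsAsFactors = FALSE)
  out$retained <- out$n >= min_bin_count & out$sigma > sigma_floor
  out
}

#' @export
print.normative_model <- function(x, ...) {
  cat("normative_model:", length(x$regions), "regions,",
      "reference n =", x$n_reference, "\n")
  cat("  spans: [", round(min(x$spans), 3), ",", round(max(x$spans), 3),
      "] (", x$sse_mode, "objective )\n")
  cat("  bins retained:", sum(x$bins$retained), "/", nrow(x$bins), "\n")
  invisible(x)
}

#' Age-normed deviation scores (w-scores)
#'
#' For each subject and region, `w = (value - mu_bin) / sigma_bin` using the
#' normative bin containing the subject's age. Analogous to a z-score: how
#' far the subject's value lies from the age norm, in SD units. Cells whose
#' age bin was dropped (or whose age falls outside all modelled bins) are
#' `NA`, never zero; the count of such cells is reported in
#' `attr(w, "n_missing")`.
#'
#' @param morph `morph_matrix` (any group).
#' @param model a `normative_model`.
#' @param cohort `cohort_table` providing ages for the subjects of `morph`.
#' @return subjects x regions numeric matrix of class `wscore_matrix`.
#' @export
compute_wscores <- function(morph, model, cohort) {
  morph <- align_morph(morph, cohort)
  cohort <- cohort[match(rownames(morph), cohort$subject_id), , drop = FALSE]
  regions <- intersect(model$regions, colnames(morph))
  if (length(regions) == 0L) stop("model and morphometry share no regions")
  b <- age_bin(cohort$age, model$bin_origin)
  w <- matrix(NA_real_, nrow(morph), length(regions),
              dimnames = list(rownames(morph), regions))
  bins <- model$bins[model$bins$retained, , drop = FALSE]
  for (r in regions) {
    br <- bins[bins$region == r, , drop = FALSE]
    idx <- match(b, br$bin)
    hit <- !is.na(idx)
    w[hit, r] <- (morph[hit, r] - br$mu[idx[hit]]) / br$sigma[idx[hit]]
  }
  n_missing <- sum(is.na(w))
  structure(w, class = c("wscore_matrix", "matrix", "array"),
            n_missing = n_missing)
}

#' Empirical centile scores against control age bins
#'
#' For each case value, the empirical percentile within the control
#' distribution of the same one-year age bin, under the Hazen mid-rank
#' convention: `centile = 100 * (#less + 0.5 * #equal) / n`, clamped to
#' `[100/(2n), 100 * (n - 0.5)/n]` so values beyond the control range get
#' the plotting position of the extreme control rather than 0/100.
#' Optionally mapped to normal-deviate scale with [stats::qnorm].
#'
#' @param morph `morph_matrix` of the subjects to score.
#' @param controls_cohort,controls_morph the reference group.
#' @param cohort `cohort_table` for the scored subjects.
#' @param min_bin_count bins with fewer controls are dropped (`NA` scores).
#' @param as_normal if TRUE return `qnorm(centile/100)` instead of 0-100.
#' @return subjects x regions matrix of centiles (or normal deviates).
#' @export
centile_scores <- function(morph, controls_cohort, controls_morph, cohort,
                           min_bin_count = 5L, as_normal = FALSE) {
  morph <- align_morph(morph, cohort)
  cohort <- cohort[match(rownames(morph), cohort$subject_id), , drop = FALSE]
  controls_morph <- align_morph(controls_morph, controls_cohort)
  controls_cohort <- controls_cohort[
    match(rownames(controls_morph), controls_cohort$subject_id), , drop = FALSE]
  bin_origin <- floor(min(controls_cohort$age))
  cb <- age_bin(controls_cohort$age, bin_origin)
  sb <- age_bin(cohort$age, bin_origin)
  regions <- intersect(colnames(morph), colnames(controls_morph))
  out <- matrix(NA_real_, nrow(morph), length(regions),
                dimnames = list(rownames(morph), regions))
  for (k in unique(sb)) {
    ctl <- which(cb == k)
    if (length(ctl) < min_bin_count) next
    n <- length(ctl)
    rows <- which(sb == k)
    for (r in regions) {
      ref <- controls_morph[ctl, r]
      v <- morph[rows, r]
      p <- (colSums(outer(ref, v, "<")) + 0.5 * colSums(outer(ref, v, "=="))) / n
      out[rows, r] <- 100 * pmin(pmax(p, 0.5 / n), (n - 0.5) / n)
    }
  }
  if (as_normal) qnorm(out / 100) else out
}

#' Bootstrap reliability of w-scores
#'
#' Resamples the reference group with replacement `B` times; each resample
#' refits the LOESS mean (holding each region's span fixed at its
#' full-sample optimum) and rebuilds the bin norms, giving a bootstrap
#' w-score `w*` per scored subject x region. The two-sided empirical
#' p-value is the position of the real w in its bootstrap distribution,
#' `p = min(1, 2 * min(1 + #(w* <= w), 1 + #(w* >= w)) / (B + 1))`
#' (add-one smoothed, so p is never 0; w at the bootstrap median gives
#' p ~ 1). Resamples in which a subject's bin falls below the model's
#' `min_bin_count` (or has ~zero SD) contribute missing and shrink that
#' cell's effective B. p-values are BH-FDR corrected across regions within
#' each subject.
#'
#' @param controls_cohort,controls_morph reference group.
#' @param cohort,morph subjects to score (e.g. the case group).
#' @param model optional prebuilt `normative_model` (built if NULL).
#' @param B number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @param ... passed to [build_norms()] when `model` is NULL.
#' @return list with `p` (raw empirical p matrix), `q` (per-subject BH-FDR
#'   across regions), `w` (real w-scores), `B`.
#' @export
bootstrap_reliability <- function(controls_cohort, controls_morph,
                                  cohort, morph, model = NULL,
                                  B = 1000L, seed = 1L, ...) {
  stopifnot(B >= 100L)
  if (is.null(model))
    model <- build_norms(controls_cohort, controls_morph, ...)
  controls_morph <- align_morph(controls_morph, controls_cohort)
  controls_cohort <- controls_cohort[
    match(rownames(controls_morph), controls_cohort$subject_id), , drop = FALSE]
  w_real <- compute_wscores(morph, model, cohort)
  regions <- colnames(w_real)
  scored_cohort <- cohort[match(rownames(w_real), cohort$subject_id), ,
                          drop = FALSE]
  sb <- age_bin(scored_cohort$age, model$bin_origin)
  ages <- controls_cohort$age
  n <- length(ages)

  lower <- matrix(0L, nrow(w_real), length(regions))  # #(w* <= w)
  upper <- matrix(0L, nrow(w_real), length(regions))  # #(w* >= w)
  used <- matrix(0L, nrow(w_real), length(regions))   # non-missing resamples
  set.seed(stream_seed(seed, 42L))
  draws <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  vals <- morph[rownames(w_real), regions, drop = FALSE]
  for (bidx in seq_len(B)) {
    take <- draws[, bidx]
    a <- ages[take]
    bo <- model$bin_origin
    bb <- age_bin(a, bo)
    for (ri in seq_along(regions)) {
      r <- regions[ri]
      y <- controls_morph[take, r]
      fitted <- fit_loess(a, y, model$spans[[r]], model$degree)
      bt <- bin_table(a, y, fitted, bo, model$min_bin_count,
                      model$sigma_floor, r)
      bt <- bt[bt$retained, , drop = FALSE]
      idx <- match(sb, bt$bin)
      hit <- which(!is.na(idx) & !is.na(w_real[, ri]))
      if (length(hit) == 0L) next
      wstar <- (vals[hit, ri] - bt$mu[idx[hit]]) / bt$sigma[idx[hit]]
      lower[cbind(hit, ri)] <- lower[cbind(hit, ri)] +
        (wstar <= w_real[cbind(hit, ri)])
      upper[cbind(hit, ri)] <- upper[cbind(hit, ri)] +
        (wstar >= w_real[cbind(hit, ri)])
      used[cbind(hit, ri)] <- used[cbind(hit, ri)] + 1L
    }
  }
  p <- pmin(2 * pmin(lower + 1, upper + 1) / (used + 1), 1)
  p[used == 0L | is.na(w_real)] <- NA_real_
  dimnames(p) <- dimnames(w_real)
  q <- t(apply(p, 1L, function(pr) {
    out <- rep(NA_real_, length(pr))
    ok <- !is.na(pr)
    if (any(ok)) out[ok] <- bh_fdr(pr[ok])$q
    out
  }))
  dimnames(q) <- dimnames(p)
  list(p = p, q = q, w = w_real, B = B)
}
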