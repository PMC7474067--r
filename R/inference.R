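# ---------------------------------------------------------------------------
# Mass-univariate inference: mixed models, FDR, brain-behaviour maps, power
# ---------------------------------------------------------------------------

#' Benjamini-Hochberg step-up FDR
#'
#' Computes q-values as `min_{j >= i} p_(j) * m / j` (step-up with enforced
#' monotonicity) and rejection flags at level `q`.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list with `q` (q-values, input order) and `reject` (logical).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  o <- order(pvals)
  qv <- pvals[o] * m / seq_len(m)
  qv <- rev(cummin(rev(qv)))
  qv <- pmin(qv, 1)
  out <- numeric(m)
  out[o] <- qv
  list(q = out, reject = out < q)
}

# residual-df Wald p with a guard for degenerate (zero-variance) fits
wald_p <- function(est, se, dfree) {
  if (se == 0) return(if (abs(est) < 1e-12) 1 else 0)
  2 * pt(-abs(est / se), df = dfree)
}

# build the model frame for one region; drops rows missing a used covariate
lme_frame <- function(values, cohort, covariates) {
  df <- data.frame(value = values,
                   group = factor(cohort$group, levels = c("control", "case")),
                   age = cohort$age,
                   sex = cohort$sex,
                   motion_fd = cohort$motion_fd,
                   euler = cohort$euler,
                   site = cohort$site,
                   stringsAsFactors = FALSE)
  covariates <- intersect(covariates, c("age", "sex", "motion_fd", "euler"))
  if ("sex" %in% covariates && length(unique(df$sex)) < 2L)
    covariates <- setdiff(covariates, "sex")
  keep <- !is.na(df$value)
  for (cv in covariates) keep <- keep & !is.na(df[[cv]])
  list(df = df[keep, , drop = FALSE], covariates = covariates,
       n_dropped = sum(!keep))
}

#' Case-control contrast for one region via a site-random-intercept model
#'
#' Fits `value ~ group + covariates + (1 | site)` with [lme4::lmer()] and
#' returns the group (case - control) coefficient, its Wald p-value using
#' the residual-df t approximation, and Cohen's d as coefficient / residual
#' SD (reduces to the classical pooled-SD d with no covariates and a single
#' site). With a single site the model falls back to ordinary least squares
#' (then, with no covariates, the p-value is exactly the pooled-variance
#' two-sample t-test).
#'
#' @param values numeric vector (one region, aligned to `cohort` rows).
#' @param cohort `cohort_table` with both groups.
#' @param covariates subset of `c("age", "sex", "motion_fd", "euler")`;
#'   subjects missing a used covariate are dropped for this model only.
#' @return list: `estimate`, `se`, `p`, `d`, `n`, `n_dropped`, `singular`,
#'   `method` ("lmer" or "ols").
#' @export
fit_region_lme <- function(values, cohort,
                           covariates = c("age", "sex", "motion_fd", "euler")) {
  fr <- lme_frame(values, cohort, covariates)
  df <- fr$df
  if (length(unique(df$group)) < 2L) stop("both groups must be present")
  rhs <- paste(c("group", fr$covariates), collapse = " + ")
  n_sites <- length(unique(df$site))
  singular <- FALSE
  if (n_sites >= 2L) {
    fml <- stats::as.formula(paste("value ~", rhs, "+ (1 | site)"))
    fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE,
                                       control = lme4::lmerControl(
                                         check.conv.singular = "ignore")))
    singular <- lme4::isSingular(fit)
    co <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    sigma_res <- stats::sigma(fit)
    p_fixed <- length(co)
  } else {
    fml <- stats::as.formula(paste("value ~", rhs))
    fit <- lm(fml, data = df)
    co <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    sigma_res <- stats::sigma(fit)
    p_fixed <- length(co)
  }
  i <- grep("^groupcase$", names(co))
  est <- unname(co[i]); s <- unname(se[i])
  dfree <- nrow(df) - p_fixed
  p <- wald_p(est, s, dfree)
  list(estimate = est, se = s, p = p,
       d = if (sigma_res == 0) ifelse(est == 0, 0, Inf) else est / sigma_res,
       n = nrow(df), n_dropped = fr$n_dropped, singular = singular,
       method = if (n_sites >= 2L) "lmer" else "ols")
}

#' Region-wise case-control map
#'
#' Applies [fit_region_lme()] to every region and BH-FDR corrects across
#' regions (single whole-brain family).
#'
#' @param morph subjects x regions matrix.
#' @param cohort `cohort_table`.
#' @param covariates as in [fit_region_lme()].
#' @param fdr_q FDR level.
#' @param label analysis label stored in the table.
#' @return `region_stats` data.frame: region, estimate, se, d, p, q,
#'   significant, n, singular, analysis.
#' @export
case_control_map <- function(morph, cohort,
                             covariates = c("age", "sex", "motion_fd", "euler"),
                             fdr_q = 0.05, label = "case_control") {
  morph <- align_morph(morph, cohort)
  cohort <- cohort[match(rownames(morph), cohort$subject_id), , drop = FALSE]
  res <- lapply(colnames(morph), function(r)
    fit_region_lme(morph[, r], cohort, covariates))
  stats_table(res, colnames(morph), fdr_q, label)
}

stats_table <- function(res, regions, fdr_q, label) {
  out <- data.frame(
    region = regions,
    estimate = vapply(res, `[[`, numeric(1), "estimate"),
    se = vapply(res, `[[`, numeric(1), "se"),
    d = vapply(res, `[[`, numeric(1), "d"),
    p = vapply(res, `[[`, numeric(1), "p"),
    n = vapply(res, `[[`, numeric(1), "n"),
    singular = vapply(res, `[[`, logical(1), "singular"),
    stringsAsFactors = FALSE)
  out$q <- NA_real_
  out$significant <- FALSE
  ok <- is.finite(out$p)
  if (any(ok)) {
    fdr <- bh_fdr(out$p[ok], q = fdr_q)
    out$q[ok] <- fdr$q
    out$significant[ok] <- fdr$reject
  }
  out$analysis <- label
  class(out) <- c("region_stats", "data.frame")
  out
}

#' Case-control map after region-wise outlier removal
#'
#' For each region, case subjects whose |w| exceeds `threshold` in that
#' region are dropped (region-wise, not listwise; controls are never
#' dropped) and the model is refit. Reports the number of FDR-significant
#' regions before and after removal and their ratio — the headline check of
#' whether small on-average differences are carried by a few highly
#' age-atypical cases.
#'
#' @param morph,cohort,covariates,fdr_q as in [case_control_map()].
#' @param w `wscore_matrix` covering the case subjects.
#' @param threshold outlier cutoff in SD units.
#' @param min_cases regions left with fewer cases are flagged unstable.
#' @return list: `before`, `after` (`region_stats`), `n_sig_before`,
#'   `n_sig_after`, `fold_change`, `unstable_regions`,
#'   `n_removed` (named per-region count of dropped cases).
#' @export
remove_region_outliers_and_refit <- function(morph, w, cohort,
                                             covariates = c("age", "sex",
                                                            "motion_fd", "euler"),
                                             threshold = 2.0, fdr_q = 0.05,
                                             min_cases = 10L) {
  morph <- align_morph(morph, cohort)
  cohort <- cohort[match(rownames(morph), cohort$subject_id), , drop = FALSE]
  before <- case_control_map(morph, cohort, covariates, fdr_q)
  case_ids <- cohort$subject_id[cohort$group == "case"]
  res <- vector("list", ncol(morph))
  n_removed <- setNames(integer(ncol(morph)), colnames(morph))
  unstable <- character(0)
  for (ri in seq_len(ncol(morph))) {
    r <- colnames(morph)[ri]
    drop_ids <- character(0)
    if (r %in% colnames(w)) {
      wr <- w[intersect(rownames(w), case_ids), r]
      drop_ids <- names(wr)[!is.na(wr) & abs(wr) > threshold]
    }
    n_removed[ri] <- length(drop_ids)
    keep <- !cohort$subject_id %in% drop_ids
    sub <- cohort[keep, , drop = FALSE]
    if (sum(sub$group == "case") < min_cases) unstable <- c(unstable, r)
    res[[ri]] <- fit_region_lme(morph[keep, r], sub, covariates)
  }
  after <- stats_table(res, colnames(morph), fdr_q,
                       "case_control_outlier_removed")
  nb <- sum(before$significant); na_ <- sum(after$significant)
  list(before = before, after = after,
       n_sig_before = nb, n_sig_after = na_,
       fold_change = if (na_ > 0) nb / na_ else Inf,
       unstable_regions = unstable, n_removed = n_removed)
}

#' One-sample tests of w-scores against zero
#'
#' Per region, fits `w ~ 1 + (1 | site)` on the supplied (case-group)
#' w-scores — does the group deviate on average from its age norms? Single
#' site falls back to the one-sample t-test (via OLS intercept). BH-FDR
#' across regions.
#'
#' @param w `wscore_matrix` (case group).
#' @param cohort `cohort_table` providing site labels.
#' @param fdr_q FDR level.
#' @return `region_stats` data.frame (estimate = mean w, d = mean w /
#'   residual SD).
#' @export
wscore_one_sample <- function(w, cohort, fdr_q = 0.05) {
  cohort <- cohort[match(rownames(w), cohort$subject_id), , drop = FALSE]
  res <- lapply(colnames(w), function(r) {
    wr <- w[, r]
    ok <- !is.na(wr)
    if (sum(ok) < 3L) {
      return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                  d = NA_real_, n = sum(ok), n_dropped = sum(!ok),
                  singular = FALSE))
    }
    df <- data.frame(w = wr[ok], site = cohort$site[ok])
    n_sites <- length(unique(df$site))
    singular <- FALSE
    if (n_sites >= 2L) {
      fit <- suppressMessages(lme4::lmer(w ~ 1 + (1 | site), data = df,
                                         control = lme4::lmerControl(
                                           check.conv.singular = "ignore")))
      singular <- lme4::isSingular(fit)
      est <- unname(lme4::fixef(fit)[1]); s <- sqrt(vcov(fit)[1, 1])
      sig <- stats::sigma(fit); pf <- 1L
    } else {
      fit <- lm(w ~ 1, data = df)
      est <- unname(coef(fit)[1]); s <- sqrt(vcov(fit)[1, 1])
      sig <- stats::sigma(fit); pf <- 1L
    }
    p <- wald_p(est, s, nrow(df) - pf)
    list(estimate = est, se = s, p = p,
         d = if (sig == 0) ifelse(est == 0, 0, Inf) else est / sig,
         n = nrow(df), n_dropped = sum(!ok), singular = singular)
  })
  stats_table(res, colnames(w), fdr_q, "wscore_one_sample")
}

#' Spearman brain-behaviour correlation maps
#'
#' Correlates each region's w-scores with each phenotype
#' (pairwise-complete), then applies a single BH-FDR family jointly across
#' all phenotype x region tests. p-values use the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` for n > 30 and a seeded
#' permutation test (20,000 draws) for smaller n.
#'
#' @param w `wscore_matrix`.
#' @param phenotypes data.frame with `subject_id` plus one numeric column
#'   per phenotype.
#' @param min_pairs minimum complete pairs per test (default 10); tests
#'   with fewer, or with a constant phenotype/w vector, are reported `NA`
#'   and excluded from the FDR family.
#' @param fdr_q FDR level.
#' @param seed seed for small-n permutation p-values.
#' @return data.frame: phenotype, region, rho, n, p, q, significant.
#' @export
spearman_phenotype_map <- function(w, phenotypes, min_pairs = 10L,
                                   fdr_q = 0.05, seed = 1L) {
  ph_names <- setdiff(names(phenotypes), "subject_id")
  idx <- match(rownames(w), phenotypes$subject_id)
  grid <- expand.grid(phenotype = ph_names, region = colnames(w),
                      stringsAsFactors = FALSE)
  set.seed(stream_seed(seed, 77L))
  res <- mapply(function(ph, r) {
    x <- phenotypes[[ph]][idx]
    y <- w[, r]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_pairs) return(c(NA_real_, n, NA_real_))
    x <- x[ok]; y <- y[ok]
    if (length(unique(x)) < 2L || length(unique(y)) < 2L)
      return(c(NA_real_, n, NA_real_))
    rho <- cor(rank(x), rank(y))
    p <- spearman_p(rho, rank(x), rank(y))
    c(rho, n, p)
  }, grid$phenotype, grid$region)
  grid$rho <- res[1, ]
  grid$n <- as.integer(res[2, ])
  grid$p <- res[3, ]
  grid$q <- NA_real_
  grid$significant <- NA
  ok <- !is.na(grid$p)
  if (any(ok)) {
    fdr <- bh_fdr(grid$p[ok], q = fdr_q)
    grid$q[ok] <- fdr$q
    grid$significant[ok] <- fdr$reject
  }
  grid
}

spearman_p <- function(rho, rx, ry, n_perm = 20000L) {
  n <- length(rx)
  if (n > 30L) {
    if (abs(rho) >= 1) return(0)
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    return(2 * pt(-abs(tt), df = n - 2))
  }
  perm <- replicate(n_perm, cor(rx, sample(ry)))
  (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
}

# ---------------------------------------------------------------------------
# A-priori power
# ---------------------------------------------------------------------------

two_sample_power <- function(d, n, alpha) {
  dfree <- 2 * n - 2
  tc <- qt(1 - alpha / 2, dfree)
  ncp <- d * sqrt(n / 2)
  1 - pt(tc, dfree, ncp) + pt(-tc, dfree, ncp)
}

#' Minimum detectable effect size for a two-sample t-test
#'
#' Solves the two-sided two-sample t-test power equation (noncentral t,
#' df = 2n - 2, ncp = d * sqrt(n/2)) for Cohen's d.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return the smallest detectable d.
#' @export
min_detectable_d <- function(n_per_group, alpha = 0.005, power = 0.80) {
  stopifnot(n_per_group >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  if (two_sample_power(10, n_per_group, alpha) < power)
    stop("unsolvable power configuration")
  uniroot(function(d) two_sample_power(d, n_per_group, alpha) - power,
          interval = c(1e-8, 10), tol = 1e-10)$root
}

correlation_power <- function(r, n, alpha) {
  dfree <- n - 2
  tc <- qt(1 - alpha / 2, dfree)
  ncp <- r * sqrt(dfree) / sqrt(1 - r^2)
  1 - pt(tc, dfree, ncp) + pt(-tc, dfree, ncp)
}

#' Minimum detectable correlation
#'
#' Solves the two-sided correlation-test power equation for r, using the t
#' statistic `r * sqrt((n - 2) / (1 - r^2))` with n - 2 df and noncentral-t
#' power (default), or the Fisher-z approximation
#' `tanh((z_{1-alpha/2} + z_power) / sqrt(n - 3))`.
#'
#' @param n sample size (>= 4).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param method `"nct"` (noncentral t, default) or `"fisher"`.
#' @return the smallest detectable r.
#' @export
min_detectable_r <- function(n, alpha = 0.005, power = 0.80,
                             method = c("nct", "fisher")) {
  method <- match.arg(method)
  stopifnot(n >= 4, alpha > 0, alpha < 1, power > 0, power < 1)
  if (method == "fisher")
    return(tanh((qnorm(1 - alpha / 2) + qnorm(power)) / sqrt(n - 3)))
  if (correlation_power(0.9999, n, alpha) < power)
    stop("unsolvable power configuration")
  uniroot(function(r) correlation_power(r, n, alpha) - power,
          interval = c(1e-8, 0.9999), tol = 1e-10)$root
}

# ---------------------------------------------------------------------------
# Sensitivity to QC covariate exclusions
# ---------------------------------------------------------------------------

#' Spatial consistency of effect-size maps under top-covariate exclusion
#'
#' Recomputes the per-region case-control effect-size (Cohen's d) map after
#' excluding the top fraction of subjects ranked by a QC covariate, and
#' reports the Pearson correlation of each reduced map with the full map.
#'
#' @param morph,cohort,covariates as in [case_control_map()].
#' @param rank_covariate `"motion_fd"` or `"euler"`.
#' @param top_fractions fractions to exclude (each < 0.5).
#' @return data.frame: fraction, n_excluded, map_correlation.
#' @export
sensitivity_exclusion_maps <- function(morph, cohort,
                                       rank_covariate = c("motion_fd", "euler"),
                                       top_fractions = c(0.05, 0.10),
                                       covariates = c("age", "sex")) {
  rank_covariate <- match.arg(rank_covariate)
  if (any(top_fractions >= 0.5)) stop("fractions >= 0.5 are degenerate")
  cv <- cohort[[rank_covariate]]
  if (all(is.na(cv))) stop("covariate entirely missing")
  full <- case_control_map(morph, cohort, covariates)$d
  out <- lapply(top_fractions, function(f) {
    if (f == 0) return(data.frame(fraction = 0, n_excluded = 0L,
                                  map_correlation = 1.0))
    k <- floor(nrow(cohort) * f)
    thr <- sort(cv)[length(cv) - k]
    keep <- is.na(cv) | cv <= thr
    sub <- cohort[keep, , drop = FALSE]
    red <- case_control_map(align_morph(morph, sub), sub, covariates)$d
    data.frame(fraction = f, n_excluded = sum(!keep),
               map_correlation = cor(full, red))
  })
  do.call(rbind, out)
}
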