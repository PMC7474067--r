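# age-bin norms, w-scores, centiles, bootstrap

test_that("w-score arithmetic follows the deviation equation exactly", {
  model <- manual_norm_model("rA", bins = 10:12, mu = 2.50, sigma = 0.10)
  co <- make_cohort_df(3, "case", age = c(10.5, 11.2, 12.9))
  vals <- morph_matrix(matrix(c(2.50, 2.70, 2.27), 3,
                              dimnames = list(co$subject_id, "rA")))
  w <- compute_wscores(vals, model, cohort_table(co))
  expect_equal(unname(w[, "rA"]), c(0, 2.0, -2.3))

  # subject outside all bins -> missing with logged count
  co2 <- make_cohort_df(1, "case", age = 30)
  v2 <- morph_matrix(matrix(2.5, 1, dimnames = list(co2$subject_id, "rA")))
  w2 <- compute_wscores(v2, model, cohort_table(co2))
  expect_true(is.na(w2[1, 1]))
  expect_equal(attr(w2, "n_missing"), 1L)
})

test_that("bins below the minimum count or with zero SD are dropped", {
  set.seed(31)
  # 40 controls at ages 10-12, only 4 in bin [12,13)
  ages <- c(runif(18, 10, 11), runif(18, 11, 12), runif(4, 12, 13))
  co <- cohort_table(make_cohort_df(40, "control", age = ages))
  vals <- matrix(2.5 + 0.01 * ages + rnorm(40, 0, 0.1), 40,
                 dimnames = list(co$subject_id, "rA"))
  m <- build_norms(co, morph_matrix(vals), span_bounds = c(0.5, 0.5))
  b12 <- m$bins[m$bins$bin == 12, ]
  expect_false(b12$retained)
  expect_equal(b12$n, 4L)
  expect_true(all(m$bins$retained[m$bins$bin %in% 10:11]))

  # noise-free region trips the zero-SD guard; noisy region survives
  vals2 <- cbind(rA = 2.5 + 0.01 * ages,
                 rB = 2.5 + 0.01 * ages + rnorm(40, 0, 0.1))
  rownames(vals2) <- co$subject_id
  m2 <- build_norms(co, morph_matrix(vals2), span_bounds = c(0.5, 0.5))
  expect_false(any(m2$bins$retained[m2$bins$region == "rA"]))
  expect_true(any(m2$bins$retained[m2$bins$region == "rB"]))

  # norms refuse non-control input
  co_bad <- co; co_bad$group <- "case"
  expect_error(build_norms(co_bad, morph_matrix(vals)), "control")
})

test_that("bin residual SD recovers the generating noise level", {
  set.seed(17)
  n <- 2000
  ages <- runif(n, 6, 30)
  truth <- 2.4 + 0.5 * exp(-(ages - 5) / 10)
  co <- cohort_table(make_cohort_df(n, "control", age = ages))
  vals <- matrix(truth + rnorm(n, 0, 0.1), n,
                 dimnames = list(co$subject_id, "rA"))
  m <- build_norms(co, morph_matrix(vals), span_bounds = c(0.25, 0.25))
  kept <- m$bins[m$bins$retained, ]
  expect_true(all(kept$sigma > 0.08 & kept$sigma < 0.12))
  # and the bin means track the trajectory closely
  mid_truth <- 2.4 + 0.5 * exp(-(kept$bin + 0.5 - 5) / 10)
  expect_lt(max(abs(kept$mu - mid_truth)), 0.05)
})

test_that("in-sample control w-scores are centred per bin", {
  # iid-noise world (no site/subject random effects) and many regions: the
  # smoother does not absorb bin-level noise averages, so the per-bin mean
  # concentrates only through region pooling (~N(0, 1/sqrt(n_bin * R))).
  # Fixed span: span selection is not under test here.
  set.seed(23)
  cfg <- sim_config(n_control = 500, n_case = 1, n_regions = 60,
                    site_sd = 0, subject_sd = 0,
                    n_global_thin = 0, outlier_prevalence = 0, seed = 23)
  gen <- generate_cohort(cfg)
  ctl <- gen$cohort[gen$cohort$group == "control", ]
  m <- build_norms(ctl, gen$morph, span_bounds = c(0.3, 0.3))
  w <- compute_wscores(gen$morph, m, ctl)
  bins <- floor(ctl$age)
  for (k in unique(bins)) {
    rows <- bins == k
    if (sum(rows) >= 20) {
      expect_lt(abs(mean(w[rows, ], na.rm = TRUE)), 0.1)
    }
  }
})

test_that("region shift equivariance: +c shifts mu by c, w unchanged", {
  set.seed(29)
  cfg <- sim_config(n_control = 250, n_case = 60, n_regions = 2,
                    n_global_thin = 0, seed = 29)
  gen <- generate_cohort(cfg)
  ctl <- gen$cohort[gen$cohort$group == "control", ]
  cas <- gen$cohort[gen$cohort$group == "case", ]
  m1 <- build_norms(ctl, gen$morph)
  w1 <- compute_wscores(gen$morph, m1, cas)
  shifted <- unclass(gen$morph)
  shifted[, 1] <- shifted[, 1] + 0.7
  m2 <- build_norms(ctl, morph_matrix(shifted))
  w2 <- compute_wscores(morph_matrix(shifted), m2, cas)
  mu1 <- m1$bins$mu[m1$bins$region == colnames(shifted)[1]]
  mu2 <- m2$bins$mu[m2$bins$region == colnames(shifted)[1]]
  expect_equal(mu2, mu1 + 0.7, tolerance = 1e-8)
  expect_equal(w2, w1, tolerance = 1e-6)
})

test_that("centile scores follow the mid-rank convention", {
  # 9 controls in one bin with distinct values 1..9
  ctl <- cohort_table(make_cohort_df(9, "control", age = rep(10.5, 9)))
  ctl_vals <- morph_matrix(matrix(as.numeric(1:9), 9,
                                  dimnames = list(ctl$subject_id, "rA")))
  cas <- cohort_table(make_cohort_df(3, "case", age = rep(10.2, 3)))
  cas_vals <- morph_matrix(matrix(c(5, 0.5, 20), 3,
                                  dimnames = list(cas$subject_id, "rA")))
  ce <- centile_scores(cas_vals, ctl, ctl_vals, cas)
  expect_equal(unname(ce[1, "rA"]), 50)            # at the control median
  expect_equal(unname(ce[2, "rA"]), 100 / 18)      # below all controls
  expect_equal(unname(ce[3, "rA"]), 100 * 8.5 / 9) # above all controls
  # dropped (sparse) bin -> missing
  cas2 <- cohort_table(make_cohort_df(1, "case", age = 25))
  v2 <- morph_matrix(matrix(5, 1, dimnames = list(cas2$subject_id, "rA")))
  expect_true(is.na(centile_scores(v2, ctl, ctl_vals, cas2)[1, 1]))
})

test_that("centile-derived and w-derived global ratios agree (r > 0.8)", {
  cfg <- sim_config(n_control = 800, n_case = 250, n_regions = 16,
                    outlier_prevalence = 0.06, outlier_magnitude = 3.5,
                    n_global_thin = 6, seed = 37)
  gen <- generate_cohort(cfg)
  ctl <- gen$cohort[gen$cohort$group == "control", ]
  cas <- gen$cohort[gen$cohort$group == "case", ]
  m <- build_norms(ctl, gen$morph, span_bounds = c(0.3, 0.3))
  w <- compute_wscores(gen$morph, m, cas)
  gw <- global_w_table(w)
  ce <- centile_scores(gen$morph, ctl, gen$morph, cas, min_bin_count = 22L)
  # centile analogue of |w| > 2: beyond the two-sided normal 2 SD tails
  tail_p <- 100 * pnorm(-2)
  ce_flag <- !is.na(ce) & (ce < tail_p | ce > 100 - tail_p)
  ce_ratio <- rowSums(ce_flag) / pmax(rowSums(!is.na(ce) & !ce_flag), 1)
  keep <- rowSums(!is.na(ce)) > 0 & is.finite(gw$gW)
  expect_gt(cor(gw$gW[keep], ce_ratio[keep]), 0.8)
})

test_that("bootstrap reliability is deterministic and centred w get p ~ 1", {
  cfg <- sim_config(n_control = 150, n_case = 15, n_regions = 6,
                    n_global_thin = 0, outlier_prevalence = 0, seed = 41)
  gen <- generate_cohort(cfg)
  ctl <- gen$cohort[gen$cohort$group == "control", ]
  cas <- gen$cohort[gen$cohort$group == "case", ]
  m <- build_norms(ctl, gen$morph, span_bounds = c(0.4, 0.4))
  br1 <- bootstrap_reliability(ctl, gen$morph, cas, gen$morph, model = m,
                               B = 100L, seed = 5)
  br2 <- bootstrap_reliability(ctl, gen$morph, cas, gen$morph, model = m,
                               B = 100L, seed = 5)
  expect_identical(br1$p, br2$p)
  expect_true(all(br1$p > 0 & br1$p <= 1, na.rm = TRUE))
  expect_error(bootstrap_reliability(ctl, gen$morph, cas, gen$morph,
                                     model = m, B = 50L), "B >= 100")

  # a case value pinned at the full-sample norm mean (w = 0) sits centrally
  # in its bootstrap distribution
  bins <- m$bins[m$bins$retained & m$bins$region == "region_001", ]
  target_bin <- bins$bin[which.max(bins$n)]
  cas1 <- cohort_table(make_cohort_df(1, "case", age = target_bin + 0.5))
  v <- matrix(rep(bins$mu[bins$bin == target_bin], 6), 1,
              dimnames = list(cas1$subject_id, colnames(gen$morph)))
  br3 <- bootstrap_reliability(ctl, gen$morph, cas1, morph_matrix(v),
                               model = m, B = 200L, seed = 6)
  expect_gt(br3$p[1, "region_001"], 0.5)
})
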