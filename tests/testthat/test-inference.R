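# mixed-model contrasts, FDR, behaviour maps, power

test_that("bh_fdr matches hand computation and the brute-force definition", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$q, rep(0.04, 4))
  expect_true(all(r$reject))

  r1 <- bh_fdr(rep(1, 5))
  expect_false(any(r1$reject))

  r2 <- bh_fdr(0.04)
  expect_equal(r2$q, 0.04)
  expect_true(r2$reject)

  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    mine <- bh_fdr(p)
    oracle <- bh_oracle(p)
    expect_equal(mine$q, oracle$q, tolerance = 1e-12)
    expect_identical(mine$reject, oracle$reject)
    expect_equal(mine$q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(mine$q >= p - 1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("single-site covariate-free model equals the pooled t-test", {
  set.seed(11)
  co <- cohort_table(rbind(make_cohort_df(40, "case", seed = 1),
                           make_cohort_df(40, "control", seed = 2)))
  y <- rnorm(80, ifelse(co$group == "case", 2.55, 2.5), 0.1)
  fit <- fit_region_lme(y, co, covariates = character(0))
  tt <- t.test(y[co$group == "case"], y[co$group == "control"],
               var.equal = TRUE)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-6)
  expect_equal(fit$estimate, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  expect_equal(fit$method, "ols")
  # d reduces to classical pooled-SD d here
  sp <- sqrt(((40 - 1) * var(y[co$group == "case"]) +
              (40 - 1) * var(y[co$group == "control"])) / 78)
  expect_equal(fit$d, fit$estimate / sp, tolerance = 1e-10)
})

test_that("null simulations give nominal type-I error", {
  set.seed(13)
  co <- cohort_table(rbind(make_cohort_df(100, "case", seed = 5),
                           make_cohort_df(100, "control", seed = 6)))
  nrep <- 400
  p <- replicate(nrep, fit_region_lme(rnorm(200), co,
                                      covariates = character(0))$p)
  rate <- mean(p < 0.05)
  half99 <- 2.576 * sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(rate - 0.05), half99)
})

test_that("planted group effects are recovered on the d scale", {
  set.seed(17)
  co <- cohort_table(rbind(make_cohort_df(400, "case", seed = 7),
                           make_cohort_df(400, "control", seed = 8)))
  d_hat <- replicate(60, {
    y <- rnorm(800, sd = 1) + ifelse(co$group == "case", 0.3, 0)
    fit_region_lme(y, co, covariates = character(0))$d
  })
  expect_lt(abs(median(d_hat) - 0.3), 0.1)
})

test_that("multi-site model uses the site random intercept", {
  set.seed(19)
  co <- rbind(make_cohort_df(90, "case", seed = 9),
              make_cohort_df(90, "control", seed = 10))
  co$site <- rep(sprintf("site_%d", 1:3), length.out = 180)
  co <- cohort_table(co)
  site_off <- c(site_1 = 0.3, site_2 = -0.2, site_3 = 0)[co$site]
  y <- 2.5 + site_off + rnorm(180, 0, 0.1)
  fit <- fit_region_lme(y, co, covariates = c("age"))
  expect_equal(fit$method, "lmer")
  expect_true(is.finite(fit$p) && is.finite(fit$d))
  # site variance largely leaves the residual: d uses residual SD ~ 0.1
  expect_lt(abs(fit$d), abs(fit$estimate) / 0.05)
  # subjects missing the ranked covariate are dropped for this model only
  co2 <- co; co2$motion_fd[1:10] <- NA
  fit2 <- fit_region_lme(y, cohort_table(co2),
                         covariates = c("age", "motion_fd"))
  expect_equal(fit2$n_dropped, 10L)
  expect_equal(fit2$n, 170L)
})

test_that("region-wise outlier removal is a no-op without outliers and
           ignores control outliers", {
  set.seed(23)
  co <- rbind(make_cohort_df(60, "case", seed = 11),
              make_cohort_df(60, "control", seed = 12))
  co$site <- rep(sprintf("site_%d", 1:2), length.out = 120)
  co <- cohort_table(co)
  m <- matrix(rnorm(120 * 8, 2.5, 0.1), 120,
              dimnames = list(co$subject_id, paste0("r", 1:8)))
  w0 <- matrix(0, 60, 8, dimnames = list(co$subject_id[co$group == "case"],
                                         paste0("r", 1:8)))
  rr <- remove_region_outliers_and_refit(morph_matrix(m), w0, co,
                                         covariates = "age")
  expect_equal(rr$after$estimate, rr$before$estimate, tolerance = 1e-10)
  expect_equal(sum(rr$n_removed), 0L)

  # huge w for controls must not change anything: removal targets cases only
  w_ctl <- matrix(9, 120, 8, dimnames = list(co$subject_id, paste0("r", 1:8)))
  w_ctl[co$subject_id[co$group == "case"], ] <- 0
  rr2 <- remove_region_outliers_and_refit(morph_matrix(m), w_ctl, co,
                                          covariates = "age")
  expect_equal(sum(rr2$n_removed), 0L)
  expect_equal(rr2$after$n, rr2$before$n)
})

test_that("one-sample w tests behave at the null and recover a shift", {
  co <- cohort_table(make_cohort_df(500, "case", seed = 13))
  w0 <- matrix(0, 500, 3, dimnames = list(co$subject_id, paste0("r", 1:3)))
  r0 <- wscore_one_sample(w0, co)
  expect_equal(r0$estimate, rep(0, 3))
  expect_equal(r0$p, rep(1, 3))

  set.seed(29)
  w1 <- matrix(rnorm(500 * 3, 0.5, 1), 500,
               dimnames = dimnames(w0))
  r1 <- wscore_one_sample(w1, co)
  expect_true(all(abs(r1$estimate - 0.5) < 0.15))
  expect_true(all(r1$significant))

  wn <- matrix(rnorm(500 * 20), 500,
               dimnames = list(co$subject_id, paste0("r", 1:20)))
  rn <- wscore_one_sample(wn, co)
  expect_lte(sum(rn$significant), 1)
})

test_that("spearman maps hit exact ranks and control the joint family", {
  co_ids <- paste0("s", 1:40)
  set.seed(31)
  w <- matrix(rnorm(40 * 4), 40, dimnames = list(co_ids, paste0("r", 1:4)))
  ph <- data.frame(subject_id = co_ids,
                   inc = rank(w[, 1]),              # strictly increasing in w
                   dec = -rank(w[, 2]),
                   flat = rep(1, 40))
  sp <- spearman_phenotype_map(w, ph, fdr_q = 0.05, seed = 2)
  expect_equal(sp$rho[sp$phenotype == "inc" & sp$region == "r1"], 1)
  expect_equal(sp$rho[sp$phenotype == "dec" & sp$region == "r2"], -1)
  expect_true(all(is.na(sp$rho[sp$phenotype == "flat"])))

  # tiny-n exact ranks
  w3 <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2,
               dimnames = list(paste0("t", 1:3), c("rX", "rY")))
  ph3 <- data.frame(subject_id = paste0("t", 1:3), v = c(3, 2, 1))
  sp3 <- spearman_phenotype_map(w3, ph3, min_pairs = 3L, seed = 3)
  expect_equal(sp3$rho, c(-1, -1))

  # independent phenotypes across a 6 x 100 family -> no FDR rejections
  set.seed(37)
  wbig <- matrix(rnorm(120 * 100), 120,
                 dimnames = list(paste0("u", 1:120), paste0("r", 1:100)))
  phbig <- data.frame(subject_id = paste0("u", 1:120),
                      matrix(rnorm(120 * 6), 120,
                             dimnames = list(NULL, paste0("ph", 1:6))))
  spbig <- spearman_phenotype_map(wbig, phbig, seed = 5)
  expect_equal(nrow(spbig), 600L)
  expect_lte(sum(spbig$significant, na.rm = TRUE), 1)
})

test_that("power solvers reproduce published minima and closed forms", {
  expect_lt(abs(min_detectable_d(870, 0.005, 0.80) - 0.1752), 0.0005)
  expect_lt(abs(min_detectable_r(421, 0.005, 0.80) - 0.1765), 0.001)

  # normal-approximation cross-checks
  d100 <- min_detectable_d(100, 0.05, 0.80)
  approx_d <- (qnorm(0.975) + qnorm(0.80)) * sqrt(2 / 100)
  expect_lt(abs(d100 - approx_d) / approx_d, 0.01)
  r421_f <- min_detectable_r(421, 0.005, 0.80, method = "fisher")
  expect_lt(abs(r421_f - min_detectable_r(421, 0.005, 0.80)), 0.002)

  # monotone in n and alpha; vanishing in the large-n limit
  ns <- c(50, 100, 400, 2000)
  ds <- sapply(ns, min_detectable_d, alpha = 0.005, power = 0.8)
  expect_true(all(diff(ds) < 0))
  expect_lt(min_detectable_d(870, 0.05, 0.8),
            min_detectable_d(870, 0.005, 0.8))
  expect_lt(min_detectable_r(20000, 0.005, 0.8), 0.03)
  expect_error(min_detectable_d(2, 1e-12, 0.999999), "unsolvable|power")
})

test_that("exclusion sensitivity maps stay consistent when the covariate is
           benign and degrade when confounded", {
  set.seed(41)
  n <- 150
  co <- rbind(make_cohort_df(n, "case", seed = 14),
              make_cohort_df(n, "control", seed = 15))
  co <- cohort_table(co)
  eff <- rep(c(0.15, 0), each = n)
  m <- matrix(rnorm(2 * n * 25, 2.5, 0.15), 2 * n,
              dimnames = list(co$subject_id, paste0("r", 1:25)))
  m <- m + outer(eff, runif(25, 0.5, 1))
  sens <- sensitivity_exclusion_maps(morph_matrix(m), co, "motion_fd",
                                     top_fractions = c(0, 0.1),
                                     covariates = "age")
  expect_equal(sens$map_correlation[sens$fraction == 0], 1.0)
  expect_gt(sens$map_correlation[sens$fraction == 0.1], 0.9)

  # covariate aligned with group: excluding by it guts the case group
  co2 <- co
  co2$motion_fd <- ifelse(co2$group == "case",
                          0.5 + runif(2 * n, 0, 0.01), runif(2 * n, 0, 0.1))
  co2 <- cohort_table(co2)
  sens2 <- sensitivity_exclusion_maps(morph_matrix(m), co2, "motion_fd",
                                      top_fractions = 0.4,
                                      covariates = "age")
  expect_lt(sens2$map_correlation, sens$map_correlation[sens$fraction == 0.1])
  expect_error(sensitivity_exclusion_maps(morph_matrix(m), co, "motion_fd",
                                          top_fractions = 0.5), "degenerate")
})
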