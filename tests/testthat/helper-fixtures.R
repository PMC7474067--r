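# shared fixture builders; everything is generated in code at test time

make_cohort_df <- function(n, group = "control", seed = 1,
                           age = NULL, site = "site_01", sex = "male") {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("%s-%03d", substr(group[1], 1, 3), seq_len(n)),
    group = group, sex = sex,
    age = if (is.null(age)) runif(n, 6, 39) else age,
    site = site,
    motion_fd = round(runif(n, 0.01, 0.3), 3),
    euler = sample(10:200, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

write_temp_csv <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  path
}

# hand-built normative model with known bin statistics
manual_norm_model <- function(regions, bins, mu, sigma, n = 100L,
                              bin_origin = min(bins)) {
  grid <- expand.grid(bin = bins, region = regions,
                      stringsAsFactors = FALSE)[, c("region", "bin")]
  grid$mu <- mu
  grid$sigma <- sigma
  grid$n <- n
  grid$retained <- grid$n >= 5 & grid$sigma > 1e-6
  structure(list(spans = stats::setNames(rep(0.5, length(regions)), regions),
                 bins = grid, bin_origin = bin_origin, regions = regions,
                 min_bin_count = 5L, degree = 1L, span_bounds = c(0.05, 1),
                 sse_mode = "cv", sigma_floor = 1e-6,
                 n_reference = n),
            class = "normative_model")
}

# brute-force LOESS oracle: same window convention, independent solver (lm)
loess_oracle <- function(x, y, span, degree = 1, xout = x) {
  n <- length(x)
  k <- min(max(ceiling(span * n), degree + 2), n)
  sapply(xout, function(x0) {
    d <- abs(x - x0)
    dmax <- sort(d)[k]
    if (dmax == 0) dmax <- min(d[d > 0])
    w <- (1 - pmin(d / dmax, 1)^3)^3
    if (sum(w > 0) < degree + 1) w <- as.numeric(d <= dmax)
    dat <- data.frame(x = x, y = y)
    fml <- if (degree == 1) y ~ x else y ~ x + I(x^2)
    unname(predict(lm(fml, data = dat, weights = w),
                   newdata = data.frame(x = x0)))
  })
}

# brute-force BH step-up from the definition: largest k with
# p_(k) <= k q / m rejected; q-value = min over j >= i of p_(j) m / j
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qv <- sapply(seq_len(m), function(i) min(ps[i:m] * m / (i:m)))
  qv <- pmin(qv, 1)
  out <- numeric(m)
  out[o] <- qv
  list(q = out, reject = out < q)
}

quiet_pipeline <- function(cfg) suppressMessages(run_pipeline(cfg))
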