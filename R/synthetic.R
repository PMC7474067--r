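# ---------------------------------------------------------------------------
# Synthetic cohort generator
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Defines the stated world the generator draws from: a two-group,
#' multi-site cohort aged (by default) 5-40 years with region-specific
#' nonlinear age trajectories, site offsets, per-subject global offsets,
#' (optionally age-dependent) residual noise, a planted subgroup of
#' region-wise case outliers, and a few globally-thin case subjects.
#'
#' Trajectories follow a monotone exponential decay toward an adult
#' asymptote: `thickness(age) = asymptote + offset * exp(-(age - age_min) / tau)`,
#' the qualitative shape cortical thickness follows through development.
#' Default group sizes mirror the post-QC male sample the analysis targets
#' (699 cases, 624 controls); default noise scales are typical for regional
#' mean thickness in mm.
#'
#' @param n_control,n_case group sizes.
#' @param n_regions number of regions (default 308).
#' @param age_range numeric length-2, years.
#' @param age_skew Beta shape pair used to sample ages on `age_range`
#'   (right-skewed by default: more children than adults).
#' @param n_sites number of acquisition sites.
#' @param site_sd SD (mm) of site offsets.
#' @param subject_sd SD (mm) of per-subject global thickness offsets.
#' @param asymptote_range,offset_range,tau_range per-region trajectory
#'   parameter ranges: adult asymptote (mm), childhood offset above the
#'   asymptote (mm), decay timescale (years).
#' @param residual_sd residual noise SD (mm) at the lower age bound.
#' @param residual_sd_slope linear change of residual SD per year (mm/yr);
#'   0 = homoscedastic.
#' @param outlier_prevalence per-region probability that a case cell is a
#'   planted outlier.
#' @param outlier_magnitude planted shift in units of the total local SD
#'   (site + subject + residual); default 3.
#' @param outlier_neg_prob probability a planted outlier is a *thinning*
#'   (negative) shift; 0.5 = unbiased signs, 1 = all thinner (the mechanism
#'   by which an outlier subgroup drags down a group mean).
#' @param n_global_thin number of case subjects shifted downward in a
#'   majority (`global_thin_frac`) of regions.
#' @param global_thin_frac fraction of regions affected per global-thin
#'   subject (> 0.5).
#' @param global_thin_magnitude downward shift (local SD units).
#' @param seed integer master seed; expanded into independent substreams
#'   (parameters, ages, noise, planting, phenotypes) so adding a stream
#'   never perturbs earlier ones.
#' @param world_seed seed for the population-level draws (region trajectory
#'   parameters and site offsets). Defaults to `seed`. Two configs sharing
#'   `world_seed` but differing in `seed` describe independent cohorts
#'   sampled from the same population — what a reference-vs-replication
#'   calibration needs.
#' @return object of class `sim_config` (a list).
#' @export
sim_config <- function(n_control = 624, n_case = 699, n_regions = 308,
                       age_range = c(5, 40), age_skew = c(1.5, 3.5),
                       n_sites = 20, site_sd = 0.05, subject_sd = 0.05,
                       asymptote_range = c(2.2, 3.0),
                       offset_range = c(0.3, 0.7),
                       tau_range = c(8, 15),
                       residual_sd = 0.10, residual_sd_slope = 0,
                       outlier_prevalence = 0.05, outlier_magnitude = 3,
                       outlier_neg_prob = 0.5,
                       n_global_thin = 5, global_thin_frac = 0.6,
                       global_thin_magnitude = 2.5,
                       seed = 1L, world_seed = seed) {
  cfg <- list(n_control = n_control, n_case = n_case, n_regions = n_regions,
              age_range = age_range, age_skew = age_skew,
              n_sites = n_sites, site_sd = site_sd, subject_sd = subject_sd,
              asymptote_range = asymptote_range, offset_range = offset_range,
              tau_range = tau_range,
              residual_sd = residual_sd,
              residual_sd_slope = residual_sd_slope,
              outlier_prevalence = outlier_prevalence,
              outlier_magnitude = outlier_magnitude,
              outlier_neg_prob = outlier_neg_prob,
              n_global_thin = n_global_thin,
              global_thin_frac = global_thin_frac,
              global_thin_magnitude = global_thin_magnitude,
              seed = as.integer(seed), world_seed = as.integer(world_seed))
  stopifnot(cfg$n_control >= 1, cfg$n_case >= 0, cfg$n_regions >= 1,
            cfg$age_range[1] < cfg$age_range[2],
            cfg$site_sd >= 0, cfg$subject_sd >= 0, cfg$residual_sd >= 0,
            cfg$outlier_prevalence >= 0, cfg$outlier_prevalence <= 1,
            cfg$outlier_neg_prob >= 0, cfg$outlier_neg_prob <= 1,
            cfg$global_thin_frac > 0.5, cfg$global_thin_frac <= 1)
  if (cfg$n_global_thin > cfg$n_case)
    stop("infeasible config: n_global_thin > n_case")
  class(cfg) <- "sim_config"
  cfg
}

# independent deterministic substream: derive a 32-bit-safe seed per stream
stream_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + stream * 104729) %% 2147483647
}
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}

local_total_sd <- function(cfg, age) {
  res <- cfg$residual_sd + cfg$residual_sd_slope * (age - cfg$age_range[1])
  sqrt(cfg$site_sd^2 + cfg$subject_sd^2 + pmax(res, 0)^2)
}

#' Generate a synthetic two-group cohort with ground truth
#'
#' Draws region trajectory parameters, subject demographics, and a
#' subjects x regions thickness matrix:
#' `value = trajectory(age) + site_offset + subject_offset + noise`,
#' then plants region-wise case outliers (shift of
#' `outlier_magnitude x total local SD`, random sign) and globally-thin
#' case subjects (downward shift in a majority of regions). Identical
#' config (including seed) gives bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (cohort_table), `morph` (morph_matrix),
#'   `truth` (list: `outlier` logical matrix cases-only x regions,
#'   `global_thin` character ids, `trajectory` matrix of noise-free
#'   pre-shift values, `region_params` data.frame).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_control + cfg$n_case
  ids <- sprintf("sub-%04d", seq_len(n))
  group <- c(rep("control", cfg$n_control), rep("case", cfg$n_case))
  regions <- sprintf("region_%03d", seq_len(cfg$n_regions))

  rp <- with_stream(cfg$world_seed, 1L, data.frame(
    region = regions,
    asymptote = runif(cfg$n_regions, cfg$asymptote_range[1], cfg$asymptote_range[2]),
    offset = runif(cfg$n_regions, cfg$offset_range[1], cfg$offset_range[2]),
    tau = runif(cfg$n_regions, cfg$tau_range[1], cfg$tau_range[2]),
    stringsAsFactors = FALSE))

  demo <- with_stream(cfg$seed, 2L, {
    age <- cfg$age_range[1] +
      diff(cfg$age_range) * rbeta(n, cfg$age_skew[1], cfg$age_skew[2])
    site <- sprintf("site_%02d", sample.int(cfg$n_sites, n, replace = TRUE))
    fd <- round(pmax(rgamma_fd(n), 0.01), 4)
    euler <- rpois_euler(n)
    list(age = age, site = site, fd = fd, euler = euler)
  })
  site_offsets <- with_stream(cfg$world_seed, 3L,
                              rnorm(cfg$n_sites, 0, cfg$site_sd))
  names(site_offsets) <- sprintf("site_%02d", seq_len(cfg$n_sites))
  subj_offsets <- with_stream(cfg$seed, 4L, rnorm(n, 0, cfg$subject_sd))

  # noise-free trajectory values per subject x region
  a <- demo$age - cfg$age_range[1]
  traj <- outer(seq_len(n), seq_len(cfg$n_regions), function(i, j)
    rp$asymptote[j] + rp$offset[j] * exp(-a[i] / rp$tau[j]))
  dimnames(traj) <- list(ids, regions)

  res_sd <- pmax(cfg$residual_sd + cfg$residual_sd_slope * a, 0)
  noise <- with_stream(cfg$seed, 5L,
                       matrix(rnorm(n * cfg$n_regions), n) * res_sd)

  base <- traj + site_offsets[demo$site] + subj_offsets + noise

  # plant region-wise outliers in cases only
  case_idx <- which(group == "case")
  tot_sd <- local_total_sd(cfg, demo$age)
  outlier <- matrix(FALSE, length(case_idx), cfg$n_regions,
                    dimnames = list(ids[case_idx], regions))
  shift <- matrix(0, n, cfg$n_regions, dimnames = list(ids, regions))
  if (cfg$outlier_prevalence > 0 && length(case_idx) > 0) {
    pl <- with_stream(cfg$seed, 6L, {
      flags <- matrix(runif(length(case_idx) * cfg$n_regions) <
                        cfg$outlier_prevalence,
                      length(case_idx))
      signs <- matrix(ifelse(runif(length(case_idx) * cfg$n_regions) <
                               cfg$outlier_neg_prob, -1, 1),
                      length(case_idx))
      list(flags = flags, signs = signs)
    })
    outlier[] <- pl$flags
    shift[case_idx, ] <- pl$flags * pl$signs *
      cfg$outlier_magnitude * tot_sd[case_idx]
  }

  global_thin <- character(0)
  if (cfg$n_global_thin > 0 && length(case_idx) > 0) {
    gt <- with_stream(cfg$seed, 7L, {
      subj <- sample(case_idx, cfg$n_global_thin)
      regs <- lapply(subj, function(i)
        sample.int(cfg$n_regions, round(cfg$global_thin_frac * cfg$n_regions)))
      list(subj = subj, regs = regs)
    })
    global_thin <- ids[gt$subj]
    for (k in seq_along(gt$subj)) {
      i <- gt$subj[k]
      shift[i, gt$regs[[k]]] <- shift[i, gt$regs[[k]]] -
        cfg$global_thin_magnitude * tot_sd[i]
    }
  }

  values <- base + shift
  cohort <- cohort_table(data.frame(
    subject_id = ids, group = group, sex = "male",
    age = demo$age, site = demo$site,
    motion_fd = demo$fd, euler = demo$euler,
    stringsAsFactors = FALSE), age_range = cfg$age_range)
  list(cohort = cohort,
       morph = morph_matrix(values),
       truth = list(outlier = outlier, global_thin = global_thin,
                    trajectory = traj, region_params = rp,
                    shift = shift, config = cfg))
}

# QC covariate marginals: plausible FD (mm) and Euler-count distributions
rgamma_fd <- function(n) stats::rgamma(n, shape = 2, rate = 15)
rpois_euler <- function(n) stats::rpois(n, lambda = 60)

#' Generate phenotype scores coupled to planted deviations
#'
#' For each phenotype, `score = baseline + slope * mean(true deviation in
#' target regions) + N(0, noise_sd)`, where the true deviation is the
#' planted shift expressed in local-SD units; controls get baseline + noise
#' scaled the same way. A missing-at-random mask emulates incompletely
#' collected instruments.
#'
#' @param cohort a `cohort_table` from [generate_cohort()].
#' @param truth the `truth` element from [generate_cohort()].
#' @param coupling named list; each element a list with fields `baseline`,
#'   `slope`, `noise_sd`, `regions` (character, targets of the coupling),
#'   `missing_rate` (proportion MCAR).
#' @param seed integer.
#' @return data.frame with `subject_id` and one column per phenotype.
#' @export
generate_phenotypes <- function(cohort, truth, coupling, seed = 1L) {
  regions <- colnames(truth$shift)
  ph <- data.frame(subject_id = cohort$subject_id, stringsAsFactors = FALSE)
  tot_sd <- local_total_sd(truth$config, cohort$age)
  # deviation in SD units per subject over target regions
  for (k in seq_along(coupling)) {
    cp <- coupling[[k]]
    unknown <- setdiff(cp$regions, regions)
    if (length(unknown) > 0L)
      stop("unknown region in coupling: ", paste(unknown, collapse = ", "))
    idx <- match(cohort$subject_id, rownames(truth$shift))
    dev <- rowMeans(truth$shift[idx, cp$regions, drop = FALSE] / tot_sd)
    val <- with_stream(seed, 100L + k, {
      v <- cp$baseline + cp$slope * dev + rnorm(nrow(cohort), 0, cp$noise_sd)
      if ((cp$missing_rate %||% 0) > 0)
        v[runif(nrow(cohort)) < cp$missing_rate] <- NA_real_
      v
    })
    ph[[names(coupling)[k]]] <- val
  }
  ph
}
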