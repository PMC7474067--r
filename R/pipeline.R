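# ---------------------------------------------------------------------------
# End-to-end pipeline and command-line front-end
# ---------------------------------------------------------------------------

#' Default run configuration
#'
#' @param simulate if TRUE, generate the cohort from `sim` instead of
#'   reading `cohort_path` / `morph_path`.
#' @param sim a [sim_config()] (used when `simulate`).
#' @param cohort_path,morph_path,phenotype_path input tables when not
#'   simulating.
#' @param sex_stratum sex the normative model is estimated on.
#' @param outlier_threshold |w| cutoff for region-wise outliers.
#' @param fdr_q FDR level.
#' @param min_bin_count minimum controls per retained age bin.
#' @param span_bounds,sse_mode LOESS span selection settings.
#' @param euler_top_fraction QC exclusion fraction (0 disables).
#' @param bootstrap_B bootstrap resamples (0 disables the stage).
#' @param seed master seed.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(simulate = TRUE, sim = sim_config(),
                       cohort_path = NULL, morph_path = NULL,
                       phenotype_path = NULL,
                       sex_stratum = "male", outlier_threshold = 2.0,
                       fdr_q = 0.05, min_bin_count = 5L,
                       span_bounds = c(0.05, 1), sse_mode = "cv",
                       euler_top_fraction = 0.10, bootstrap_B = 0L,
                       seed = 1L, out_dir = tempfile("normdev_run_")) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

stage_msg <- function(...) message("[normdev] ", ...)

#' Run the full pipeline
#'
#' Stages, in dependency order: simulate (or load) -> sex stratum filter ->
#' Euler QC exclusion -> age matching -> normative fit (controls) ->
#' w-scoring (cases) -> atypicality summaries -> inference (case-control,
#' outlier-stripped rerun, one-sample w tests, optional behaviour maps) ->
#' optional bootstrap reliability. All stage outputs are plain CSV/JSON
#' files under `config$out_dir`; a manifest records the resolved config,
#' seed, exclusion counts and stage timings. Outputs are a pure function of
#' (inputs, config, seed).
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly; side effect: files in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, started = format(Sys.time()),
                   stages = list(), counts = list())
  t0 <- proc.time()[["elapsed"]]
  tick <- function(name) {
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    t0 <<- proc.time()[["elapsed"]]
    stage_msg("stage complete: ", name)
  }
  echo_config(config, file.path(config$out_dir, "config_echo.json"))

  # -- input ----------------------------------------------------------------
  phenotypes <- NULL
  if (isTRUE(config$simulate)) {
    gen <- generate_cohort(config$sim)
    cohort <- gen$cohort; morph <- gen$morph
  } else {
    if (is.null(config$cohort_path) || !file.exists(config$cohort_path))
      stop("pipeline abort at stage 'load': missing cohort path: ",
           config$cohort_path %||% "<NULL>")
    if (is.null(config$morph_path) || !file.exists(config$morph_path))
      stop("pipeline abort at stage 'load': missing morphometry path: ",
           config$morph_path %||% "<NULL>")
    cohort <- load_cohort(config$cohort_path)
    morph <- load_morphometry(config$morph_path)
    if (!is.null(config$phenotype_path)) {
      phenotypes <- read.csv(config$phenotype_path, stringsAsFactors = FALSE)
    }
  }
  tick("input")

  # -- stratify + QC --------------------------------------------------------
  fs <- filter_sex(cohort, config$sex_stratum, morph)
  cohort <- fs$cohort; morph <- fs$morph
  manifest$counts$after_sex_filter <- nrow(cohort)
  if (config$euler_top_fraction > 0 && !all(is.na(cohort$euler))) {
    qc <- qc_exclude_euler(cohort, config$euler_top_fraction)
    manifest$counts$euler_excluded <- length(qc$excluded_ids)
    write.csv(data.frame(subject_id = qc$excluded_ids),
              file.path(config$out_dir, "qc_excluded.csv"), row.names = FALSE)
    cohort <- qc$kept
    morph <- align_morph(morph, cohort)
  }
  tick("qc")

  # -- match ----------------------------------------------------------------
  cases <- cohort[cohort$group == "case", , drop = FALSE]
  controls <- cohort[cohort$group == "control", , drop = FALSE]
  mt <- match_groups_by_age(cases, controls)
  manifest$counts$matched_pairs <- nrow(mt$pairs)
  manifest$counts$mean_abs_age_diff <- mt$mean_abs_age_diff
  cases <- mt$cases; controls <- mt$controls
  cohort_m <- rbind(cases, controls)
  class(cohort_m) <- class(cohort)
  write.csv(mt$pairs, file.path(config$out_dir, "matched_pairs.csv"),
            row.names = FALSE)
  tick("match")

  # -- normative fit + scoring ---------------------------------------------
  model <- build_norms(controls, morph, min_bin_count = config$min_bin_count,
                       span_bounds = config$span_bounds,
                       sse_mode = config$sse_mode)
  write_normative_model(model, config$out_dir)
  w_case <- compute_wscores(morph, model, cases)
  write_morphometry(w_case, file.path(config$out_dir, "wscores_case.csv"))
  manifest$counts$wscore_missing_cells <- attr(w_case, "n_missing")
  tick("norms")

  # -- atypicality ----------------------------------------------------------
  flags <- flag_outliers(w_case, config$outlier_threshold)
  prev <- region_prevalence(flags, group_n = nrow(flags))
  gw <- global_w_table(w_case, config$outlier_threshold)
  ages <- outlier_age_summary(flags, cases)
  write.csv(data.frame(region = names(prev$prevalence),
                       prevalence = prev$prevalence,
                       count = prev$counts,
                       median_outlier_age = ages$median_age),
            file.path(config$out_dir, "region_prevalence.csv"),
            row.names = FALSE)
  write.csv(gw, file.path(config$out_dir, "global_w_ratio.csv"),
            row.names = FALSE)
  chi <- prevalence_chisq(prev$median_prevalence, 0.05,
                          n = ncol(w_case), yates = TRUE)
  tick("atypicality")

  # -- inference ------------------------------------------------------------
  rr <- remove_region_outliers_and_refit(morph, w_case, cohort_m,
                                         threshold = config$outlier_threshold,
                                         fdr_q = config$fdr_q)
  ws <- wscore_one_sample(w_case, cases, fdr_q = config$fdr_q)
  results <- rbind(rr$before, rr$after, ws)
  write.csv(results, file.path(config$out_dir, "region_stats.csv"),
            row.names = FALSE)
  manifest$counts$n_sig_case_control <- rr$n_sig_before
  manifest$counts$n_sig_outlier_removed <- rr$n_sig_after
  manifest$counts$n_sig_wscore <- sum(ws$significant)
  tick("inference")

  # -- behaviour maps (optional) -------------------------------------------
  if (!is.null(phenotypes)) {
    sp <- spearman_phenotype_map(w_case, phenotypes, fdr_q = config$fdr_q,
                                 seed = config$seed)
    write.csv(sp, file.path(config$out_dir, "behaviour_map.csv"),
              row.names = FALSE)
    manifest$counts$n_sig_behaviour <- sum(sp$significant, na.rm = TRUE)
    tick("behaviour")
  }

  # -- bootstrap (optional) -------------------------------------------------
  if (config$bootstrap_B >= 100L) {
    br <- bootstrap_reliability(controls, morph, cases, morph, model = model,
                                B = config$bootstrap_B, seed = config$seed)
    write_morphometry(br$p, file.path(config$out_dir, "bootstrap_p.csv"))
    n_sig <- apply(br$q, 1L, function(qq) sum(qq < config$fdr_q, na.rm = TRUE))
    manifest$counts$bootstrap_median_sig_regions <- median(n_sig)
    tick("bootstrap")
  }

  summary_json <- list(
    median_prevalence = prev$median_prevalence,
    prevalence_chisq_yates = chi$statistic,
    prevalence_chisq_p = chi$p_value,
    n_global_thin = sum(gw$global_thin),
    n_sig_case_control = rr$n_sig_before,
    n_sig_outlier_removed = rr$n_sig_after,
    fold_change = rr$fold_change,
    n_sig_wscore_one_sample = sum(ws$significant),
    outlier_age_range = ages$range)
  jsonlite::write_json(summary_json, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

echo_config <- function(config, path) {
  flat <- lapply(unclass(config), function(x)
    if (inherits(x, "sim_config")) unclass(x) else x)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  # YAML echo too when the yaml package is available
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml_path <- sub("\\.json$", ".yaml", path)
    writeLines(yaml::as.yaml(flat), yaml_path)
  }
  invisible(path)
}

#' Serialize a normative model to a CSV bundle
#' @param model `normative_model`.
#' @param dir output directory.
#' @export
write_normative_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(region = names(model$spans), span = model$spans),
            file.path(dir, "norm_spans.csv"), row.names = FALSE)
  write.csv(model$bins, file.path(dir, "norm_bins.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a normative model from a CSV bundle
#' @param dir directory written by [write_normative_model()].
#' @param ... overrides for metadata fields (`degree`, `min_bin_count`, ...).
#' @export
read_normative_model <- function(dir, ...) {
  spans_df <- read.csv(file.path(dir, "norm_spans.csv"),
                       stringsAsFactors = FALSE)
  bins <- read.csv(file.path(dir, "norm_bins.csv"), stringsAsFactors = FALSE)
  meta <- modifyList(list(degree = 1L, min_bin_count = 5L,
                          sigma_floor = 1e-6, sse_mode = "cv",
                          span_bounds = c(0.05, 1),
                          n_reference = NA_integer_), list(...))
  structure(c(list(spans = setNames(spans_df$span, spans_df$region),
                   bins = bins,
                   bin_origin = min(bins$bin),
                   regions = spans_df$region), meta),
            class = "normative_model")
}

# ---------------------------------------------------------------------------
# CLI
# ---------------------------------------------------------------------------

#' Command-line entry point
#'
#' Subcommands: `simulate`, `fit-norms`, `score`, `atypicality`,
#' `case-control`, `behaviour`, `power`, `run`. Invoked by the
#' `inst/cli/normdev` Rscript wrapper; callable directly with a character
#' vector of arguments for testing.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
normdev_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: normdev <simulate|fit-norms|score|atypicality|run|power> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[[1]]; rest <- args[-1]
  opts <- parse_cli_opts(rest)
  seed <- as.integer(opts$seed %||% 1L)
  out <- opts$out %||% "normdev_out"
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  switch(cmd,
    simulate = {
      cfg <- sim_config(n_control = as.integer(opts$`n-control` %||% 624),
                        n_case = as.integer(opts$`n-case` %||% 699),
                        n_regions = as.integer(opts$`n-regions` %||% 308),
                        seed = seed)
      gen <- generate_cohort(cfg)
      write_cohort(gen$cohort, file.path(out, "cohort.csv"))
      write_morphometry(gen$morph, file.path(out, "morphometry.csv"))
      echo_config(structure(list(sim = cfg), class = "run_config"),
                  file.path(out, "config_echo.json"))
      stage_msg("simulated cohort written to ", out)
    },
    `fit-norms` = {
      cohort <- load_cohort(opts$cohort)
      morph <- load_morphometry(opts$morph)
      fs <- filter_sex(cohort, opts$sex %||% "male", morph)
      controls <- fs$cohort[fs$cohort$group == "control", , drop = FALSE]
      model <- build_norms(controls, fs$morph,
                           min_bin_count = as.integer(opts$`min-bin-count` %||% 5),
                           span_bounds = parse_bounds(opts$`span-bounds`),
                           sse_mode = opts$`sse-mode` %||% "cv")
      write_normative_model(model, out)
      stage_msg("normative model written to ", out)
    },
    score = {
      cohort <- load_cohort(opts$cohort)
      morph <- load_morphometry(opts$morph)
      model <- read_normative_model(opts$model %||% out)
      w <- compute_wscores(morph, model, cohort)
      write_morphometry(w, file.path(out, "wscores.csv"))
      stage_msg("w-scores written to ", out)
    },
    atypicality = {
      cohort <- load_cohort(opts$cohort)
      w <- as.matrix(read.csv(opts$wscores, row.names = 1,
                              check.names = FALSE))
      flags <- flag_outliers(w, as.numeric(opts$threshold %||% 2))
      prev <- region_prevalence(flags)
      gw <- global_w_table(w, as.numeric(opts$threshold %||% 2))
      write.csv(data.frame(region = names(prev$prevalence),
                           prevalence = prev$prevalence),
                file.path(out, "region_prevalence.csv"), row.names = FALSE)
      write.csv(gw, file.path(out, "global_w_ratio.csv"), row.names = FALSE)
      stage_msg("atypicality tables written to ", out)
    },
    power = {
      d <- min_detectable_d(as.integer(opts$n %||% 870),
                            as.numeric(opts$alpha %||% 0.005),
                            as.numeric(opts$power %||% 0.80))
      cat(sprintf("minimum detectable d: %.4f\n", d))
    },
    run = {
      cfg <- run_config(simulate = is.null(opts$cohort),
                        sim = sim_config(
                          n_control = as.integer(opts$`n-control` %||% 200),
                          n_case = as.integer(opts$`n-case` %||% 200),
                          n_regions = as.integer(opts$`n-regions` %||% 30),
                          seed = seed),
                        cohort_path = opts$cohort, morph_path = opts$morph,
                        bootstrap_B = as.integer(opts$`bootstrap-B` %||% 0),
                        sse_mode = opts$`sse-mode` %||% "cv",
                        seed = seed, out_dir = out)
      run_pipeline(cfg)
      stage_msg("pipeline outputs in ", out)
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (grepl("=", key)) {
        kv <- strsplit(key, "=", fixed = TRUE)[[1]]
        opts[[kv[1]]] <- paste(kv[-1], collapse = "=")
      } else if (i < length(args) && !grepl("^--", args[[i + 1L]])) {
        opts[[key]] <- args[[i + 1L]]
        i <- i + 1L
      } else {
        opts[[key]] <- TRUE
      }
    }
    i <- i + 1L
  }
  opts
}

parse_bounds <- function(x) {
  if (is.null(x)) return(c(0.05, 1))
  as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
}
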