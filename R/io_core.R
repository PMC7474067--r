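#' @keywords internal
"_PACKAGE"

#' @importFrom stats median sd quantile qt pt qnorm pnorm pchisq uniroot
#'   optimize rnorm runif rbinom rbeta complete.cases cor setNames lm coef
#'   vcov aggregate p.adjust
#' @importFrom utils read.csv write.csv head modifyList
NULL

# ---------------------------------------------------------------------------
# Cohort table
# ---------------------------------------------------------------------------

#' Construct a validated cohort table
#'
#' A cohort table holds one row per subject with demographics and
#' quality-control covariates: `subject_id` (unique), `group`
#' (`"case"`/`"control"`), `sex` (`"male"`/`"female"`), `age` (years),
#' `site` (factor-like label), and optionally `motion_fd` (mean framewise
#' displacement, mm) and `euler` (surface-reconstruction Euler index;
#' higher is worse quality). Both QC covariates may be missing per subject;
#' subjects with a missing covariate are retained for normative scoring but
#' dropped from models that use that covariate.
#'
#' @param df data.frame with at least `subject_id`, `group`, `sex`, `age`,
#'   `site` columns.
#' @param age_range numeric length-2; declared plausible study age range.
#'   Rows outside it fail validation.
#' @return object of class `cohort_table` (a data.frame). Rows failing
#'   validation are removed and reported in `attr(x, "rejections")`.
#' @export
cohort_table <- function(df, age_range = c(5, 65)) {
  required <- c("subject_id", "group", "sex", "age", "site")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup) > 0L) {
    stop("cohort validation error: duplicated subject_id: ",
         paste(unique(dup), collapse = ", "))
  }
  df$group <- as.character(df$group)
  df$sex <- as.character(df$sex)
  df$site <- as.character(df$site)
  age <- strict_numeric(df$age)
  fd <- if ("motion_fd" %in% names(df)) strict_numeric(df$motion_fd) else
    rep(NA_real_, nrow(df))
  eul <- if ("euler" %in% names(df)) strict_numeric(df$euler) else
    rep(NA_real_, nrow(df))

  reasons <- character(nrow(df))
  bad <- function(idx, why) {
    reasons[idx] <<- ifelse(reasons[idx] == "", why,
                            paste(reasons[idx], why, sep = "; "))
  }
  bad(which(!df$group %in% c("case", "control")), "group not case/control")
  bad(which(!df$sex %in% c("male", "female")), "sex not male/female")
  bad(which(is.na(age) | !is.finite(age)), "age not a valid number")
  ok_age <- !is.na(age) & is.finite(age)
  bad(which(ok_age & (age < age_range[1] | age > age_range[2])),
      sprintf("age outside declared range [%g, %g]", age_range[1], age_range[2]))
  bad(which(is.na(df$site) | df$site == ""), "missing site label")
  # motion_fd / euler: missing is allowed, but a present-but-unparseable or
  # negative value is a rejection
  if ("motion_fd" %in% names(df)) {
    raw_present <- !is.na(df$motion_fd) & trimws(as.character(df$motion_fd)) != ""
    bad(which(raw_present & is.na(fd)), "motion_fd not a valid number")
    bad(which(!is.na(fd) & fd < 0), "motion_fd negative")
  }
  if ("euler" %in% names(df)) {
    raw_present <- !is.na(df$euler) & trimws(as.character(df$euler)) != ""
    bad(which(raw_present & is.na(eul)), "euler not a valid number")
    bad(which(!is.na(eul) & eul < 0), "euler negative")
  }

  keep <- reasons == ""
  rejections <- data.frame(row = which(!keep),
                           subject_id = df$subject_id[!keep],
                           reason = reasons[!keep],
                           stringsAsFactors = FALSE)
  out <- data.frame(subject_id = df$subject_id[keep],
                    group = df$group[keep],
                    sex = df$sex[keep],
                    age = age[keep],
                    site = df$site[keep],
                    motion_fd = fd[keep],
                    euler = eul[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "age_range") <- age_range
  attr(out, "rejections") <- rejections
  out
}

# strict numeric parse: period decimal separator only; anything else -> NA
strict_numeric <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  s <- trimws(as.character(x))
  out <- rep(NA_real_, length(s))
  ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", s)
  out[ok] <- as.numeric(s[ok])
  out
}

#' Load a cohort table from delimited text
#'
#' Reads a UTF-8 comma- or tab-delimited file with a header row, maps
#' columns via `schema`, and validates per [cohort_table()]. Decimal
#' separator is the period only; values like `"14,2"` are rejected with the
#' offending row listed in the rejection report.
#'
#' @param path file path.
#' @param schema named character vector mapping canonical field names
#'   (`subject_id`, `group`, `sex`, `age`, `site`, `motion_fd`, `euler`) to
#'   column names in the file. Defaults to identity.
#' @param sep field separator; `NULL` sniffs comma vs tab from the header.
#' @param age_range passed to [cohort_table()].
#' @return a `cohort_table`; inspect `attr(x, "rejections")`.
#' @export
load_cohort <- function(path, schema = NULL, sep = NULL, age_range = c(5, 65)) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% sniff_sep(path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  canonical <- c("subject_id", "group", "sex", "age", "site",
                 "motion_fd", "euler")
  schema <- schema %||% setNames(canonical, canonical)
  required <- c("subject_id", "group", "sex", "age", "site")
  need <- schema[names(schema) %in% required]
  absent <- need[!need %in% names(raw)]
  if (length(absent) > 0L) {
    stop("cohort schema error: missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(schema)) {
    col <- schema[[canon]]
    if (col %in% names(raw)) df[[canon]] <- raw[[col]]
  }
  cohort_table(df, age_range = age_range)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Write a cohort table to CSV
#'
#' Full double precision is preserved (values are written with
#' `format(..., digits = 17)`), so write-then-load round-trips bit-exactly.
#'
#' @param cohort a `cohort_table`.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (col in c("age", "motion_fd", "euler")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        format(df[[col]], digits = 17, trim = TRUE,
                               scientific = FALSE))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Morphometry matrix
# ---------------------------------------------------------------------------

#' Construct a morphometry matrix
#'
#' Subjects x regions matrix of a regional morphometric (cortical thickness
#' in mm by default). All cells must be finite and strictly positive; rows
#' violating this are rejected with a report.
#'
#' @param values numeric matrix with subject ids as rownames and region
#'   labels as colnames.
#' @return object of class `morph_matrix` with `attr(x, "rejections")`.
#' @export
morph_matrix <- function(values) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("morphometry matrix needs subject rownames and region colnames")
  storage.mode(values) <- "double"
  bad_row <- apply(values, 1L, function(r) any(!is.finite(r) | r <= 0))
  rejections <- data.frame(
    subject_id = rownames(values)[bad_row],
    reason = rep("non-finite or non-positive cell", sum(bad_row)),
    stringsAsFactors = FALSE)
  out <- values[!bad_row, , drop = FALSE]
  class(out) <- c("morph_matrix", "matrix", "array")
  attr(out, "rejections") <- rejections
  out
}

#' Load a morphometry matrix from delimited text
#'
#' Expects a `subject_id` column plus one numeric column per region. Columns
#' not in `region_list` are dropped with a warning; regions in `region_list`
#' absent from the file are an error. Rows with any non-numeric,
#' non-positive or missing cell are rejected and reported.
#'
#' @param path file path.
#' @param region_list character vector of region labels defining column
#'   order; `NULL` takes all non-id columns in file order.
#' @param sep separator, sniffed if `NULL`.
#' @return a `morph_matrix` aligned to `region_list` order.
#' @export
load_morphometry <- function(path, region_list = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% sniff_sep(path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  if (!"subject_id" %in% names(raw))
    stop("morphometry schema error: missing subject_id column")
  regions_in_file <- setdiff(names(raw), "subject_id")
  region_list <- region_list %||% regions_in_file
  unknown <- setdiff(regions_in_file, region_list)
  if (length(unknown) > 0L) {
    warning("dropping ", length(unknown),
            " region column(s) not in region_list: ",
            paste(head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ..." else "")
  }
  absent <- setdiff(region_list, regions_in_file)
  if (length(absent) > 0L) {
    stop("morphometry error: region_list region(s) missing from file: ",
         paste(head(absent, 5L), collapse = ", "))
  }
  vals <- vapply(region_list, function(r) strict_numeric(raw[[r]]),
                 numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(raw$subject_id, region_list))
  morph_matrix(vals)
}

#' Write a morphometry matrix (or any subjects x regions matrix) to CSV
#' @param m matrix with subject rownames and region colnames.
#' @param path output path.
#' @export
write_morphometry <- function(m, path) {
  df <- data.frame(subject_id = rownames(m), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (j in colnames(m)) {
    df[[j]] <- ifelse(is.na(m[, j]), "",
                      format(m[, j], digits = 17, trim = TRUE,
                             scientific = FALSE))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a plain-text region list (one label per line)
#' @param path file path.
#' @export
load_region_list <- function(path) {
  x <- trimws(readLines(path))
  x[x != ""]
}

# ---------------------------------------------------------------------------
# Matching and QC
# ---------------------------------------------------------------------------

#' Greedy 1:1 nearest-neighbour age matching
#'
#' Matches each case to its nearest-age control without replacement,
#' traversing cases in descending age order (oldest first; sparse adult
#' tail gets first pick). Ties in |age difference| break toward the younger
#' control. When there are more cases than controls, the unmatched youngest
#' cases are dropped; output groups have equal size.
#'
#' @param cases,controls `cohort_table`s (or data.frames with `subject_id`,
#'   `age`).
#' @return list with `cases`, `controls` (matched, equal size, in matched
#'   pair order), `pairs` (data.frame of ids and age difference) and
#'   `mean_abs_age_diff`.
#' @export
match_groups_by_age <- function(cases, controls) {
  if (nrow(cases) == 0L || nrow(controls) == 0L)
    stop("matching error: empty group")
  ord <- order(cases$age, decreasing = TRUE)
  avail <- rep(TRUE, nrow(controls))
  ctl_age <- controls$age
  pick_case <- integer(0); pick_ctl <- integer(0)
  for (i in ord) {
    if (!any(avail)) break
    idx <- which(avail)
    d <- abs(ctl_age[idx] - cases$age[i])
    best <- d == min(d)
    cand <- idx[best]
    # tie-break toward the younger control, then stable by position
    j <- cand[order(ctl_age[cand])][1L]
    avail[j] <- FALSE
    pick_case <- c(pick_case, i)
    pick_ctl <- c(pick_ctl, j)
  }
  pairs <- data.frame(case_id = cases$subject_id[pick_case],
                      control_id = controls$subject_id[pick_ctl],
                      age_diff = abs(cases$age[pick_case] - ctl_age[pick_ctl]),
                      stringsAsFactors = FALSE)
  list(cases = cases[pick_case, , drop = FALSE],
       controls = controls[pick_ctl, , drop = FALSE],
       pairs = pairs,
       mean_abs_age_diff = mean(pairs$age_diff))
}

#' Exclude subjects with the worst surface-reconstruction quality
#'
#' Removes the top `top_fraction` of subjects by Euler index (higher index =
#' worse reconstruction). The threshold is the (n - floor(n * top_fraction))-th
#' order statistic of the Euler values; subjects strictly above it are
#' excluded, so ties at the threshold are conservatively retained (with
#' distinct values exactly floor(n * top_fraction) subjects are removed).
#'
#' @param cohort a `cohort_table` with non-missing `euler` for subjects
#'   considered.
#' @param top_fraction proportion in [0, 1) to remove.
#' @return list with `kept` (cohort_table), `excluded_ids`, `threshold`,
#'   and `ties_at_threshold` (ids equal to the threshold, retained).
#' @export
qc_exclude_euler <- function(cohort, top_fraction = 0.10) {
  if (top_fraction < 0 || top_fraction >= 1)
    stop("top_fraction must be in [0, 1)")
  eul <- cohort$euler
  if (all(is.na(eul))) stop("qc error: all euler values missing")
  if (any(is.na(eul)))
    stop("qc error: euler missing for ", sum(is.na(eul)), " subject(s)")
  n <- length(eul)
  k <- floor(n * top_fraction)
  if (k == 0L) {
    return(list(kept = cohort, excluded_ids = character(0),
                threshold = max(eul), ties_at_threshold = character(0)))
  }
  thr <- sort(eul)[n - k]
  drop <- eul > thr
  list(kept = cohort[!drop, , drop = FALSE],
       excluded_ids = cohort$subject_id[drop],
       threshold = thr,
       ties_at_threshold = cohort$subject_id[eul == thr])
}

#' Restrict a cohort (and optionally a morphometry matrix) to one sex
#' @param cohort a `cohort_table`.
#' @param sex `"male"` or `"female"`.
#' @param morph optional `morph_matrix` filtered to the same subjects.
#' @return cohort (or `list(cohort, morph)` if `morph` given).
#' @export
filter_sex <- function(cohort, sex = "male", morph = NULL) {
  stopifnot(sex %in% c("male", "female"))
  keep <- cohort$sex == sex
  out <- cohort[keep, , drop = FALSE]
  if (is.null(morph)) return(out)
  m <- morph[rownames(morph) %in% out$subject_id, , drop = FALSE]
  list(cohort = out, morph = m)
}

# align a morph matrix's rows to a cohort's subjects (subset + order)
align_morph <- function(morph, cohort) {
  ids <- intersect(cohort$subject_id, rownames(morph))
  morph[ids, , drop = FALSE]
}
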