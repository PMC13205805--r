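# Canonical column set of a cohort table (wide format: one row per patient,
# both crossover periods on the row, matching the paired unit of analysis).
COHORT_COLUMNS <- c(
  "patient_id", "sequence",
  "area_es_start", "area_es_end", "area_pl_start", "area_pl_end",
  "design_r_total", "depth"
)

SEQUENCE_LEVELS <- c("ES_first", "placebo_first")
DEPTH_LEVELS <- c("superficial", "deep")

#' Construct a pressure-injury crossover cohort
#'
#' A `pi_cohort` holds one row per participant of a 2x2 crossover trial of
#' electrical stimulation (ES) versus placebo, with the wound area (cm^2) at
#' the start and end of each 14-day period, the DESIGN-R total score and the
#' wound depth class.
#'
#' @param records A data frame with columns `patient_id`, `sequence`
#'   (`"ES_first"` or `"placebo_first"`), `area_es_start`, `area_es_end`,
#'   `area_pl_start`, `area_pl_end` (wound areas in cm^2, all >= 0),
#'   `design_r_total` (non-negative integer) and `depth` (`"superficial"` or
#'   `"deep"`).
#' @param period_length_days Length of each treatment period in days
#'   (default 14).
#'
#' @return An object of class `pi_cohort`: a list with elements `records`
#'   (validated data frame) and `period_length_days`.
#' @export
#' @examples
#' coh <- generate_cohort(generator_spec(seed = 1))
#' coh
pi_cohort <- function(records, period_length_days = 14) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  obj <- structure(
    list(records = records, period_length_days = period_length_days),
    class = "pi_cohort"
  )
  validate_pi_cohort(obj)
}

#' Validate a pi_cohort object
#'
#' Checks the schema and invariants: all required columns present, wound areas
#' non-negative, DESIGN-R totals non-negative integers, depth and sequence
#' restricted to their two levels, patient ids unique, positive period length.
#'
#' @param x A `pi_cohort`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_pi_cohort <- function(x) {
  stopifnot(inherits(x, "pi_cohort"))
  rec <- x$records
  missing_cols <- setdiff(COHORT_COLUMNS, names(rec))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(x$period_length_days) || length(x$period_length_days) != 1 ||
      !is.finite(x$period_length_days) || x$period_length_days <= 0) {
    stop("period_length_days must be a single positive number", call. = FALSE)
  }
  if (nrow(rec) == 0) {
    return(invisible(x))
  }
  if (anyDuplicated(rec$patient_id)) {
    dup <- unique(rec$patient_id[duplicated(rec$patient_id)])
    stop("cohort validation error: duplicate patient_id: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  area_cols <- c("area_es_start", "area_es_end", "area_pl_start", "area_pl_end")
  for (col in area_cols) {
    bad <- !is.na(rec[[col]]) & rec[[col]] < 0
    if (any(bad)) {
      stop("cohort validation error: negative ", col, " for patient_id ",
           paste(rec$patient_id[bad], collapse = ", "), call. = FALSE)
    }
    if (any(is.na(rec[[col]]))) {
      stop("cohort validation error: missing ", col, call. = FALSE)
    }
  }
  dr <- rec$design_r_total
  if (any(is.na(dr)) || any(dr < 0) || any(dr != round(dr))) {
    stop("cohort validation error: design_r_total must be non-negative integers",
         call. = FALSE)
  }
  if (!all(rec$sequence %in% SEQUENCE_LEVELS)) {
    stop("cohort validation error: sequence must be one of ",
         paste(SEQUENCE_LEVELS, collapse = "/"), call. = FALSE)
  }
  if (!all(rec$depth %in% DEPTH_LEVELS)) {
    stop("cohort validation error: depth must be one of ",
         paste(DEPTH_LEVELS, collapse = "/"), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.pi_cohort <- function(x, ...) {
  rec <- x$records
  cat(sprintf("<pi_cohort> %d patient(s), %g-day periods\n",
              nrow(rec), x$period_length_days))
  if (nrow(rec) > 0) {
    tab <- table(depth = rec$depth,
                 category = design_r_category(rec$design_r_total))
    cat("strata (depth x DESIGN-R category):\n")
    print(tab)
    nf <- attr(x, "n_floored")
    if (!is.null(nf) && nf > 0) {
      cat(sprintf("note: %d synthetic end area(s) floored at 0 cm^2\n", nf))
    }
  }
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort A `pi_cohort`.
#' @return Integer count of records.
#' @export
n_patients <- function(cohort) {
  stopifnot(inherits(cohort, "pi_cohort"))
  nrow(cohort$records)
}

#' Read a cohort from a CSV file
#'
#' Reads a comma-separated, dot-decimal, UTF-8 file with a header row and one
#' row per patient, and returns a validated [pi_cohort]. Non-canonical column
#' names can be mapped via `dialect`.
#'
#' @param path Path to the CSV file.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(patient_id = "id", depth = "wound_depth")`.
#' @param period_length_days Period length in days (default 14).
#' @return A validated [pi_cohort]; row order is preserved.
#' @export
read_cohort <- function(path, dialect = NULL, period_length_days = 14) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(dialect)) {
    for (canonical in names(dialect)) {
      src <- dialect[[canonical]]
      if (!src %in% names(df)) {
        stop("cohort schema error: mapped column not in file: ", src,
             call. = FALSE)
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$patient_id <- as.character(df$patient_id)
  pi_cohort(df[, COHORT_COLUMNS], period_length_days = period_length_days)
}

#' Write a cohort to a CSV file
#'
#' Writes the canonical wide-format cohort CSV (header
#' `patient_id,sequence,area_es_start,area_es_end,area_pl_start,area_pl_end,design_r_total,depth`)
#' with numbers at full precision, so that [read_cohort()] recovers the cohort
#' field-by-field.
#'
#' @param cohort A valid [pi_cohort].
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  validate_pi_cohort(cohort)
  rec <- cohort$records[, COHORT_COLUMNS, drop = FALSE]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  # format() at 17 significant digits keeps doubles round-trip exact
  out <- rec
  for (col in c("area_es_start", "area_es_end", "area_pl_start", "area_pl_end")) {
    out[[col]] <- format(rec[[col]], digits = 17, scientific = FALSE, trim = TRUE)
  }
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Specification for the synthetic cohort generator
#'
#' Parameters of the seeded synthetic 2x2 crossover cohort. The defaults
#' emulate the 12-patient deep-pressure-injury cohort of the source trial:
#' 5 patients in DESIGN-R category 10-18 and 7 in >=19 (all deep), with cohort
#' means of daily wound-area reduction of exactly 0.179 cm^2/day under ES and
#' 0.051 cm^2/day under placebo.
#'
#' @param n_patients Number of patients (default 12).
#' @param target_mean_red_es,target_mean_red_pl Cohort means of daily
#'   wound-area reduction (cm^2/day) in the ES and placebo periods; the
#'   generator matches them exactly by affine recentring.
#' @param sd_red_es,sd_red_pl Between-patient standard deviations of the
#'   per-period daily reductions (cm^2/day). Defaults 0.15 and 0.08.
#' @param cor_red Correlation between a patient's ES and placebo reductions
#'   (default 0.5).
#' @param baseline_area_log_mean,baseline_area_log_sd Log-scale mean and sd of
#'   the lognormal period start areas; defaults `log(8)` cm^2 and 0.5.
#' @param strata Data frame with columns `category` (`"<=9"`, `"10-18"`,
#'   `">=19"`), `depth` and `count`; counts must sum to `n_patients`.
#' @param seed Integer seed making generation deterministic.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_patients = 12,
                           target_mean_red_es = 0.179,
                           target_mean_red_pl = 0.051,
                           sd_red_es = 0.15,
                           sd_red_pl = 0.08,
                           cor_red = 0.5,
                           baseline_area_log_mean = log(8),
                           baseline_area_log_sd = 0.5,
                           strata = data.frame(
                             category = c("10-18", ">=19"),
                             depth = c("deep", "deep"),
                             count = c(5L, 7L)
                           ),
                           seed = 1L) {
  spec <- structure(
    list(n_patients = as.integer(n_patients),
         target_mean_red_es = target_mean_red_es,
         target_mean_red_pl = target_mean_red_pl,
         sd_red_es = sd_red_es, sd_red_pl = sd_red_pl, cor_red = cor_red,
         baseline_area_log_mean = baseline_area_log_mean,
         baseline_area_log_sd = baseline_area_log_sd,
         strata = strata, seed = as.integer(seed)),
    class = "generator_spec"
  )
  if (spec$n_patients < 1) stop("n_patients must be positive", call. = FALSE)
  if (!all(is.finite(c(spec$target_mean_red_es, spec$target_mean_red_pl)))) {
    stop("target means must be finite", call. = FALSE)
  }
  if (spec$sd_red_es < 0 || spec$sd_red_pl < 0) {
    stop("reduction sds must be >= 0", call. = FALSE)
  }
  if (abs(spec$cor_red) > 1) stop("cor_red must lie in [-1, 1]", call. = FALSE)
  if (!all(c("category", "depth", "count") %in% names(strata))) {
    stop("strata needs columns category, depth, count", call. = FALSE)
  }
  if (sum(strata$count) != spec$n_patients) {
    stop("strata counts must sum to n_patients", call. = FALSE)
  }
  if (!all(strata$category %in% DESIGN_R_CATEGORIES)) {
    stop("unknown DESIGN-R category in strata; use ",
         paste(DESIGN_R_CATEGORIES, collapse = ", "), call. = FALSE)
  }
  if (!all(strata$depth %in% DEPTH_LEVELS)) {
    stop("unknown depth in strata", call. = FALSE)
  }
  spec
}

# Integer DESIGN-R score range sampled within each category.
category_score_range <- function(category) {
  switch(category,
    "<=9"   = 0:9,
    "10-18" = 10:18,
    ">=19"  = 19:28,
    stop("unknown DESIGN-R category: ", category, call. = FALSE)
  )
}

#' Generate a seeded synthetic crossover cohort
#'
#' Draws per-patient (ES, placebo) daily wound-area reductions from a
#' bivariate normal with the spec's dispersions and correlation, then
#' recentres each arm affinely so the cohort means equal the targets exactly
#' (for every seed). Period start areas are lognormal; end areas are
#' `start - period_length * reduction`. An end area that would fall below
#' 0 cm^2 is floored at 0 by raising that period's start area to
#' `period_length * reduction`, preserving the patient's reduction; the number
#' of floor events is recorded in the `n_floored` attribute. Treatment
#' sequence is assigned alternately and then shuffled by the seed; DESIGN-R
#' totals are drawn uniformly within each assigned category's integer range.
#'
#' @param spec A [generator_spec()].
#' @param period_length_days Period length in days (default 14).
#' @param calibrate Recentre the drawn reductions so the cohort means hit the
#'   targets exactly (default `TRUE`). Set `FALSE` for population-sampling
#'   simulation studies (e.g. interval-coverage experiments), where the
#'   targets act as population means and cohort means must be allowed to
#'   vary.
#' @return A [pi_cohort] with attribute `n_floored`.
#' @export
#' @examples
#' coh <- generate_cohort(generator_spec(seed = 42))
#' reds <- daily_reductions(coh)
#' mean(reds$red_es)  # exactly 0.179
generate_cohort <- function(spec, period_length_days = 14, calibrate = TRUE) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_patients
  L <- period_length_days

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  Sigma <- matrix(c(spec$sd_red_es^2,
                    spec$cor_red * spec$sd_red_es * spec$sd_red_pl,
                    spec$cor_red * spec$sd_red_es * spec$sd_red_pl,
                    spec$sd_red_pl^2), 2, 2)
  red <- MASS::mvrnorm(n, mu = c(spec$target_mean_red_es,
                                 spec$target_mean_red_pl),
                       Sigma = Sigma)
  red <- matrix(red, ncol = 2)
  if (calibrate) {
    # exact moment calibration: shift each arm onto its target mean
    red[, 1] <- red[, 1] - mean(red[, 1]) + spec$target_mean_red_es
    red[, 2] <- red[, 2] - mean(red[, 2]) + spec$target_mean_red_pl
  }

  start_es <- stats::rlnorm(n, spec$baseline_area_log_mean,
                            spec$baseline_area_log_sd)
  start_pl <- stats::rlnorm(n, spec$baseline_area_log_mean,
                            spec$baseline_area_log_sd)
  end_es <- start_es - L * red[, 1]
  end_pl <- start_pl - L * red[, 2]
  n_floored <- sum(end_es < 0) + sum(end_pl < 0)
  # floor at 0 cm^2 by raising the start area, so the reduction (and hence the
  # exact mean calibration) is preserved
  floor_es <- end_es < 0
  start_es[floor_es] <- L * red[floor_es, 1]
  end_es[floor_es] <- 0
  floor_pl <- end_pl < 0
  start_pl[floor_pl] <- L * red[floor_pl, 2]
  end_pl[floor_pl] <- 0
  if (any(start_es < 0) || any(start_pl < 0)) {
    stop("generation error: calibrated reductions force a negative start ",
         "area; increase baseline_area_log_mean", call. = FALSE)
  }

  seq_assign <- rep(SEQUENCE_LEVELS, length.out = n)[sample.int(n)]

  strata <- spec$strata
  category <- rep(strata$category, strata$count)
  depth <- rep(strata$depth, strata$count)
  design_r <- vapply(category, function(cat) {
    rng <- category_score_range(cat)
    rng[sample.int(length(rng), 1)]
  }, integer(1))

  rec <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    sequence = seq_assign,
    area_es_start = start_es, area_es_end = end_es,
    area_pl_start = start_pl, area_pl_end = end_pl,
    design_r_total = design_r,
    depth = depth,
    stringsAsFactors = FALSE
  )
  out <- pi_cohort(rec, period_length_days = L)
  attr(out, "n_floored") <- n_floored
  out
}
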