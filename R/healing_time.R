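DESIGN_R_CATEGORIES <- c("<=9", "10-18", ">=19")

#' DESIGN-R severity category
#'
#' Maps integer DESIGN-R total scores to the three severity categories used
#' for stratified median imputation: `<=9`, `10-18`, `>=19` (inclusive
#' integer boundaries).
#'
#' @param design_r_total Vector of non-negative integer scores.
#' @return Factor with levels `"<=9"`, `"10-18"`, `">=19"`.
#' @export
#' @examples
#' design_r_category(c(9, 10, 18, 19))
design_r_category <- function(design_r_total) {
  if (any(design_r_total < 0)) stop("design_r_total must be >= 0", call. = FALSE)
  cat <- ifelse(design_r_total <= 9, "<=9",
                ifelse(design_r_total <= 18, "10-18", ">=19"))
  factor(cat, levels = DESIGN_R_CATEGORIES)
}

#' Severity-stratified median healing-time table
#'
#' A depth x DESIGN-R-category matrix of published median days to heal under
#' usual care, used to impute each patient's baseline time to heal
#' (T_placebo). The defaults are the published medians for pressure injuries:
#' superficial 15/33/140 days and deep 26/63/259 days for DESIGN-R <=9,
#' 10-18 and >=19 respectively.
#'
#' @param superficial,deep Numeric length-3 vectors of median days for
#'   categories `<=9`, `10-18`, `>=19`. All entries must be positive and
#'   non-decreasing across categories within each depth.
#' @return An object of class `healing_time_table` (a 2x3 numeric matrix with
#'   dimnames `depth` x `category`).
#' @export
#' @examples
#' healing_time_table()
healing_time_table <- function(superficial = c(15, 33, 140),
                               deep = c(26, 63, 259)) {
  m <- rbind(superficial = superficial, deep = deep)
  colnames(m) <- DESIGN_R_CATEGORIES
  names(dimnames(m)) <- c("depth", "category")
  tab <- structure(m, class = c("healing_time_table", "matrix"))
  validate_healing_time_table(tab)
}

#' Validate a healing-time table
#' @param tab A `healing_time_table`.
#' @return `tab` invisibly if valid, else an error.
#' @export
validate_healing_time_table <- function(tab) {
  if (!inherits(tab, "healing_time_table")) {
    stop("not a healing_time_table", call. = FALSE)
  }
  if (any(!is.finite(tab)) || any(tab <= 0)) {
    stop("healing-time table entries must be positive finite days",
         call. = FALSE)
  }
  for (depth in rownames(tab)) {
    if (is.unsorted(tab[depth, ])) {
      stop("healing-time medians must be non-decreasing across DESIGN-R ",
           "categories <=9 -> 10-18 -> >=19 (depth ", depth, ")",
           call. = FALSE)
    }
  }
  invisible(tab)
}

#' @export
print.healing_time_table <- function(x, ...) {
  cat("<healing_time_table>  median days to heal (usual care)\n")
  print(unclass(x))
  invisible(x)
}

#' Read a healing-time table from CSV or JSON
#'
#' Accepts a long-format file with columns/fields `depth`
#' (`superficial`/`deep`), `category` (`<=9`, `10-18`, `>=19`) and
#' `median_days`. The format is inferred from the file extension.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A validated [healing_time_table()].
#' @export
read_healing_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  needed <- c("depth", "category", "median_days")
  if (!all(needed %in% names(df))) {
    stop("healing-time table file needs columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  tab <- healing_time_table()  # template for shape; overwritten below
  m <- unclass(tab)
  m[] <- NA_real_
  for (i in seq_len(nrow(df))) {
    if (!df$depth[i] %in% rownames(m) || !df$category[i] %in% colnames(m)) {
      stop("unknown depth/category in table file: ",
           df$depth[i], " / ", df$category[i], call. = FALSE)
    }
    m[df$depth[i], df$category[i]] <- df$median_days[i]
  }
  if (any(is.na(m))) {
    stop("configuration error: healing-time table is missing cells",
         call. = FALSE)
  }
  healing_time_table(superficial = m["superficial", ], deep = m["deep", ])
}

#' Impute baseline time to heal for a patient
#'
#' Stratified median imputation: each patient's baseline time to heal under
#' placebo/usual care is the published median for their DESIGN-R category and
#' wound depth.
#'
#' @param design_r_total Integer DESIGN-R total score(s), >= 0.
#' @param depth `"superficial"` or `"deep"` (recycled to match scores).
#' @param table A [healing_time_table()].
#' @return Numeric vector of imputed baseline days.
#' @export
#' @examples
#' impute_baseline(15, "deep")        # 63
#' impute_baseline(19, "deep")        # 259
impute_baseline <- function(design_r_total, depth,
                            table = healing_time_table()) {
  validate_healing_time_table(table)
  if (!all(depth %in% rownames(table))) {
    stop("configuration error: depth not in table: ",
         paste(setdiff(depth, rownames(table)), collapse = ", "),
         call. = FALSE)
  }
  cat <- as.character(design_r_category(design_r_total))
  n <- max(length(cat), length(depth))
  depth <- rep_len(depth, n)
  cat <- rep_len(cat, n)
  table[cbind(depth, cat)]
}

#' Cohort mean imputed baseline time to heal
#'
#' Arithmetic mean of the per-patient imputed baselines, the cohort-level
#' T_placebo input of the economic model.
#'
#' @param cohort A non-empty [pi_cohort].
#' @param table A [healing_time_table()].
#' @return Mean baseline days (full precision).
#' @export
mean_baseline <- function(cohort, table = healing_time_table()) {
  validate_pi_cohort(cohort)
  if (n_patients(cohort) == 0) stop("empty cohort", call. = FALSE)
  rec <- cohort$records
  mean(impute_baseline(rec$design_r_total, rec$depth, table))
}

#' Translation rule from baseline to under-treatment time to heal
#'
#' Defines how the short-term healing acceleration ratio r maps baseline time
#' to heal onto time to heal under ES. `constant_ratio` applies
#' `T_ES = T_placebo / r` over the whole trajectory. `diminishing` is the
#' conservative variant: healing progress accrues at rate r (relative to
#' usual care) only for the first `accel_window_days` (the treatment window
#' over which the acceleration was actually observed), after which the
#' acceleration attenuates to `r_late = 1 + kappa * (r - 1)`. `kappa = 1`
#' recovers the constant-ratio rule; `kappa = 0` assumes no late benefit.
#'
#' @param mode `"constant_ratio"` or `"diminishing"`.
#' @param r Acceleration ratio, > 0. Default [base_case_ratio()].
#' @param kappa Attenuation fraction in `[0, 1]` (diminishing mode only).
#' @param accel_window_days Days of full acceleration (default 14).
#' @return An object of class `translation_spec`.
#' @export
translation_spec <- function(mode = c("constant_ratio", "diminishing"),
                             r = base_case_ratio(),
                             kappa = 0.5,
                             accel_window_days = 14) {
  mode <- match.arg(mode)
  if (!is.finite(r) || r <= 0) stop("r must be > 0", call. = FALSE)
  if (kappa < 0 || kappa > 1) stop("kappa must lie in [0, 1]", call. = FALSE)
  if (accel_window_days < 0) stop("accel_window_days must be >= 0", call. = FALSE)
  structure(list(mode = mode, r = r, kappa = kappa,
                 accel_window_days = accel_window_days),
            class = "translation_spec")
}

#' Base-case healing acceleration ratio
#'
#' The headline acceleration ratio carried as the base-case constant, 3.52.
#' The ratio of the rounded period means (0.179/0.051 = 3.51) differs in the
#' third digit because the headline value arises from unrounded patient-level
#' means; the constant is configurable wherever it is used.
#'
#' @return The number 3.52.
#' @export
base_case_ratio <- function() 3.52

#' Translate baseline time to heal to time to heal under ES
#'
#' Applies a [translation_spec()]. Constant-ratio mode: `t_placebo / r`.
#' Diminishing mode (closed form): with window `w = accel_window_days` and
#' late rate `r_late = 1 + kappa * (r - 1)`, the result is `t_placebo / r`
#' if `t_placebo <= r * w`, else `w + (t_placebo - r * w) / r_late`.
#'
#' @param t_placebo Baseline time(s) to heal in days, > 0. Vectorized.
#' @param spec A [translation_spec()].
#' @return Estimated day(s) to heal under ES; always > 0, and <= `t_placebo`
#'   exactly when `r >= 1`.
#' @export
#' @examples
#' translate_time(259, translation_spec(r = 3.52))  # 73.58
translate_time <- function(t_placebo, spec = translation_spec()) {
  stopifnot(inherits(spec, "translation_spec"))
  if (any(t_placebo <= 0)) stop("t_placebo must be > 0", call. = FALSE)
  r <- spec$r
  if (spec$mode == "constant_ratio") {
    return(t_placebo / r)
  }
  w <- spec$accel_window_days
  r_late <- 1 + spec$kappa * (r - 1)
  ifelse(t_placebo <= r * w,
         t_placebo / r,
         w + (t_placebo - r * w) / r_late)
}

#' Days of healing saved
#'
#' `t_placebo - t_es`; negative when the translation lengthens healing
#' (r < 1), which is reported rather than clipped so downside scenarios stay
#' visible.
#'
#' @param t_placebo,t_es Times to heal in days, both > 0. Vectorized.
#' @return Days saved.
#' @export
days_saved <- function(t_placebo, t_es) {
  if (any(t_placebo <= 0) || any(t_es <= 0)) {
    stop("healing times must be > 0", call. = FALSE)
  }
  t_placebo - t_es
}
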