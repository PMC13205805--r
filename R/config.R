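#' Read a model configuration file
#'
#' Parses a YAML or JSON configuration into the package's parameter objects.
#' Recognised top-level blocks, all optional: `cost_parameters` (fields of
#' [cost_parameters()]), `healing_time_table` (`superficial` and `deep`
#' length-3 vectors), `generator_spec` (fields of [generator_spec()];
#' `strata` as a list of `{category, depth, count}`), and `scenarios` (a list
#' of [scenario_spec()] field sets). Unspecified fields keep the package
#' defaults. An example lives at
#' `system.file("extdata", "example_config.yaml", package = "picost")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `cost_parameters`, `healing_time_table`,
#'   `generator_spec`, `scenarios` (those present in the file; the first
#'   three fall back to defaults).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  out <- list()

  cp <- raw$cost_parameters
  out$cost_parameters <- if (is.null(cp)) cost_parameters() else {
    args <- cp[intersect(names(cp),
                         names(formals(cost_parameters)))]
    if (!is.null(args$per_day_components)) {
      args$per_day_components <- unlist(args$per_day_components)
    }
    do.call(cost_parameters, args)
  }

  ht <- raw$healing_time_table
  out$healing_time_table <- if (is.null(ht)) healing_time_table() else {
    healing_time_table(superficial = as.numeric(unlist(ht$superficial)),
                       deep = as.numeric(unlist(ht$deep)))
  }

  gs <- raw$generator_spec
  out$generator_spec <- if (is.null(gs)) generator_spec() else {
    args <- gs[intersect(names(gs), names(formals(generator_spec)))]
    if (!is.null(args$strata)) {
      st <- args$strata
      if (is.data.frame(st)) {
        args$strata <- st
      } else {
        args$strata <- do.call(rbind, lapply(st, function(s) {
          data.frame(category = s$category, depth = s$depth,
                     count = as.integer(s$count), stringsAsFactors = FALSE)
        }))
      }
    }
    do.call(generator_spec, args)
  }

  if (!is.null(raw$scenarios)) {
    out$scenarios <- lapply(raw$scenarios, function(s) {
      args <- s[intersect(names(s), names(formals(scenario_spec)))]
      do.call(scenario_spec, args)
    })
    names(out$scenarios) <- vapply(out$scenarios, `[[`, character(1), "name")
  }
  out
}
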