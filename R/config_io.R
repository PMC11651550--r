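#' Read or write a generator configuration as YAML
#'
#' The file mirrors the arguments of [generator_config()] as nested
#' key-value sections; admission-type mixtures are stored as per-cell
#' records. Unknown keys raise a named error.
#'
#' @param path YAML file path.
#' @param config A [generator_config()].
#' @return A validated [generator_config()] (read); `path` invisibly
#'   (write).
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("Unknown generator config field(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "fairaudit_error_config")
  }
  for (nm in c("ethnicity", "risk", "death")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  for (nm in c("admission_mixture", "death_mixture")) {
    if (!is.null(raw[[nm]])) {
      raw[[nm]] <- dplyr::bind_rows(lapply(raw[[nm]], tibble::as_tibble))
    }
  }
  do.call(generator_config, raw)
}

#' @rdname read_generator_config
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  x <- unclass(config)
  for (nm in c("ethnicity", "risk", "death")) x[[nm]] <- as.list(x[[nm]])
  for (nm in c("admission_mixture", "death_mixture")) {
    df <- x[[nm]]
    x[[nm]] <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

#' Read an audit configuration from YAML
#'
#' Scalar fields mirror [audit_config()]; `specs` is a vector of built-in
#' comparison names (default all six); a nested `generator` section is
#' passed to [generator_config()].
#'
#' @param path YAML file path.
#' @return An [audit_config()].
#' @export
read_audit_config <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- builtin_group_specs()
  if (!is.null(raw$specs)) {
    unknown <- setdiff(raw$specs, names(specs))
    if (length(unknown)) {
      abort(sprintf("Unknown group variable(s) in config: %s.",
                    paste(unknown, collapse = ", ")),
            class = "fairaudit_error_config")
    }
    specs <- specs[raw$specs]
  }
  gen <- NULL
  if (!is.null(raw$generator)) {
    g <- raw$generator
    for (nm in c("ethnicity", "risk", "death")) {
      if (!is.null(g[[nm]])) g[[nm]] <- unlist(g[[nm]])
    }
    gen <- do.call(generator_config, g)
  }
  grid <- if (!is.null(raw$grid)) {
    do.call(cutoff_grid, raw$grid)
  } else cutoff_grid()
  audit_config(
    output_dir = raw$output_dir %||% "audit_bundle",
    cohort_path = raw$cohort_path,
    generator = gen,
    specs = specs,
    grid = grid,
    age_bands = raw$age_bands %||% default_age_bands(),
    calibration_bins = raw$calibration_bins %||% 20,
    calibration_scheme = raw$calibration_scheme %||% "width",
    calibration_min_count = raw$calibration_min_count %||% 50,
    n_boot = raw$n_boot %||% 1000,
    seed = raw$seed %||% 1L,
    fn_threshold = raw$fn_threshold %||% 0.1,
    reference = raw$reference %||% "pooled_pair",
    render_figures = raw$render_figures %||% TRUE
  )
}
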