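#' Configuration for a full audit run
#'
#' Bundles everything [run_audit()] needs: the input cohort (a file path or
#' a [generator_config()] for synthetic runs), the comparisons to make, the
#' cutoff grid, stratification and calibration settings, bootstrap
#' replicates, the false-negative threshold, the reference distribution for
#' standardised curves, and the output directory. A single root seed drives
#' every stochastic stage, expanded per (comparison, stage) by a
#' deterministic scheme, so a re-run with the same config reproduces the
#' bundle bit-for-bit.
#'
#' @param output_dir Directory for the report bundle (created if needed).
#' @param cohort_path Path of a cohort file, or NULL to use `generator`.
#' @param generator A [generator_config()] for synthetic runs.
#' @param specs Named list of [group_spec()]s; default all built-ins.
#' @param grid Cutoff grid.
#' @param age_bands Age band edges for stratification.
#' @param calibration_bins,calibration_scheme,calibration_min_count
#'   Calibration binning settings, see [calibration_curve()].
#' @param n_boot Bootstrap replicates for all bootstrap intervals.
#' @param seed Root seed (mandatory: every bootstrap stage draws from it).
#' @param fn_threshold Score threshold for the false-negative decomposition.
#' @param reference Reference distribution for adjusted curves, see
#'   [adjusted_rate_curve()].
#' @param type_map Admission-type map, see [admission_type_map()].
#' @param render_figures Write PDF figures alongside the data files.
#' @return An `audit_config` object.
#' @export
audit_config <- function(output_dir,
                         cohort_path = NULL, generator = NULL,
                         specs = builtin_group_specs(),
                         grid = cutoff_grid(),
                         age_bands = default_age_bands(),
                         calibration_bins = 20,
                         calibration_scheme = "width",
                         calibration_min_count = 50,
                         n_boot = 1000, seed = 1L,
                         fn_threshold = 0.1,
                         reference = "pooled_pair",
                         type_map = admission_type_map(),
                         render_figures = TRUE) {
  if (is.null(cohort_path) && is.null(generator)) {
    abort("Provide either `cohort_path` or `generator`.",
          class = "fairaudit_error_config")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("A single integer `seed` is mandatory.",
          class = "fairaudit_error_config")
  }
  for (i in seq_along(specs)) {
    if (!inherits(specs[[i]], "group_spec")) {
      abort("`specs` must be a list of group_spec objects.",
            class = "fairaudit_error_config")
    }
  }
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- vapply(specs, function(s) s$variable, character(1))
  }
  check_grid(grid)
  structure(
    list(output_dir = output_dir, cohort_path = cohort_path,
         generator = generator, specs = specs, grid = grid,
         age_bands = age_bands,
         calibration_bins = calibration_bins,
         calibration_scheme = calibration_scheme,
         calibration_min_count = calibration_min_count,
         n_boot = n_boot, seed = as.integer(seed),
         fn_threshold = fn_threshold, reference = reference,
         type_map = type_map, render_figures = render_figures),
    class = "audit_config"
  )
}

save_figure <- function(plot, path, width = 7, height = 5) {
  grDevices::pdf(path, width = width, height = height, compress = FALSE)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}

# Replace the volatile date entries of an uncompressed PDF so identical runs
# produce byte-identical figures. Byte-wise: PDFs contain non-UTF-8 bytes.
strip_pdf_dates <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "bytes"
  txt <- gsub("/(CreationDate|ModDate) \\(D:[^)]*\\)",
              "/\\1 (D:19700101000000)", txt, useBytes = TRUE)
  writeBin(charToRaw(txt), path)
  invisible(path)
}

#' Run the full fairness audit
#'
#' For every configured comparison, computes and writes: the two parity
#' (score CDF) curves and the two counterfactual curves with their
#' difference curves; ROC points, AUROC with standard error and calibration
#' curves per group; raw and standardised FOR and FDR curves with
#' differences; and the false-negative decomposition per group. A
#' Table-1-style cohort summary and a run manifest (config echo, package
#' version, seed, per-stage warnings and errors) complete the bundle.
#' Failures are isolated per (comparison, stage): the failing stage is
#' recorded in the manifest and the remaining stages still run.
#'
#' @param config An [audit_config()].
#' @return The manifest, invisibly; the bundle is written to
#'   `config$output_dir`.
#' @export
run_audit <- function(config) {
  if (!inherits(config, "audit_config")) {
    abort("`config` must be an audit_config object.",
          class = "fairaudit_error_config")
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  fig_dir <- file.path(config$output_dir, "figures")
  if (config$render_figures) {
    dir.create(fig_dir, showWarnings = FALSE)
  }

  cohort <- if (!is.null(config$cohort_path)) {
    read_cohort(config$cohort_path)
  } else {
    generate_cohort(config$generator)$cohort
  }

  manifest <- list(
    package = "fairaudit",
    version = as.character(utils::packageVersion("fairaudit")),
    seed = config$seed,
    n_boot = config$n_boot,
    n_rows = nrow(cohort),
    fn_threshold = config$fn_threshold,
    reference = config$reference,
    auroc_se_method = "placement (DeLong)",
    comparisons = names(config$specs),
    files = character(), warnings = character(), errors = character()
  )
  note_file <- function(path) {
    manifest$files <<- c(manifest$files, basename(path))
  }
  run_stage <- function(comparison, stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        manifest$errors <<- c(
          manifest$errors,
          sprintf("%s/%s: %s", comparison, stage, conditionMessage(e)))
        NULL
      }),
      warning = function(w) {
        manifest$warnings <<- c(
          manifest$warnings,
          sprintf("%s/%s: %s", comparison, stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        manifest$warnings <<- c(
          manifest$warnings,
          sprintf("%s/%s: %s", comparison, stage,
                  trimws(conditionMessage(m))))
        invokeRestart("muffleMessage")
      }
    )
  }
  out_csv <- function(obj, name) {
    path <- file.path(config$output_dir, paste0(name, ".csv"))
    readr::write_delim(obj, path, delim = ",", na = "NA")
    note_file(path)
    path
  }
  out_fig <- function(plot, name, ...) {
    if (!config$render_figures || is.null(plot)) return(invisible(NULL))
    path <- file.path(fig_dir, paste0(name, ".pdf"))
    save_figure(plot, path, ...)
    strip_pdf_dates(path)
    note_file(file.path("figures", basename(path)))
  }

  run_stage("all", "summary", {
    out_csv(summarize_cohort(cohort, config$specs), "summary")
  })

  auroc_rows <- list()
  for (ci in seq_along(config$specs)) {
    comp <- names(config$specs)[ci]
    spec <- config$specs[[ci]]
    g <- assign_group(cohort, spec)
    labels <- c(spec$label_a, spec$label_b)
    masks <- list(g == spec$label_a, g == spec$label_b)
    sseed <- function(j) derive_seed(config$seed, ci, j)
    # drop the comparison's own dimension from the stratification
    strata_vars <- setdiff(c("age", "sex", "simd"),
                           switch(spec$variable, age = "age", sex = "sex",
                                  deprivation = "simd", character()))

    parity <- list()
    for (k in 1:2) {
      parity[k] <- list(run_stage(comp, paste0("parity_", labels[k]), {
        cv <- score_cdf(cohort$score[masks[[k]]], config$grid,
                        group_label = labels[k])
        out_csv(cv, sprintf("parity_%s_%s", comp, labels[k]))
        cv
      }))
    }
    if (!is.null(parity[[1]]) && !is.null(parity[[2]])) {
      run_stage(comp, "parity_difference", {
        d <- curve_difference(parity[[1]], parity[[2]])
        out_csv(d, sprintf("parity_%s_difference", comp))
        out_fig(plot_curve_pair(parity[[1]], parity[[2]], d,
                                title = sprintf("Score CDF: %s", comp)),
                sprintf("parity_%s", comp))
      })
    }

    cf <- list()
    for (k in 1:2) {
      other <- 3L - k
      cf[k] <- list(run_stage(comp, paste0("counterfactual_", labels[k]), {
        cv <- counterfactual_cdf(
          cohort, target = masks[[k]], source = masks[[other]],
          grid = config$grid, age_bands = config$age_bands,
          strata_vars = strata_vars,
          n_boot = config$n_boot, seed = sseed(10 + k),
          group_label = sprintf("%s_from_%s", labels[k], labels[other]))
        out_csv(cv, sprintf("counterfactual_%s_%s", comp, labels[k]))
        cv
      }))
      if (!is.null(cf[[k]]) && !is.null(parity[[k]])) {
        run_stage(comp, paste0("counterfactual_diff_", labels[k]), {
          d <- curve_difference(parity[[k]], cf[[k]])
          out_csv(d, sprintf("counterfactual_%s_%s_vs_raw", comp,
                             labels[k]))
          out_fig(plot_curve_pair(parity[[k]], cf[[k]], d,
                                  title = sprintf(
                                    "Raw vs counterfactual CDF: %s (%s)",
                                    comp, labels[k])),
                  sprintf("counterfactual_%s_%s", comp, labels[k]))
        })
      }
    }

    rocs <- list(); cals <- list(); aurocs <- list()
    for (k in 1:2) {
      run_stage(comp, paste0("discrimination_", labels[k]), {
        sc <- cohort$score[masks[[k]]]
        yy <- cohort$outcome[masks[[k]]]
        rp <- roc_points(sc, yy, config$grid)
        au <- auroc_with_se(sc, yy)
        out_csv(rp, sprintf("roc_%s_%s", comp, labels[k]))
        rocs[[labels[k]]] <- rp
        aurocs[[labels[k]]] <- au
        auroc_rows[[length(auroc_rows) + 1L]] <- tibble::tibble(
          comparison = comp, group = labels[k],
          auroc = au$estimate, se = au$se,
          n_event = au$n_event, n_nonevent = au$n_nonevent)
      })
      run_stage(comp, paste0("calibration_", labels[k]), {
        cc <- calibration_curve(
          cohort$score[masks[[k]]], cohort$outcome[masks[[k]]],
          bins = config$calibration_bins,
          scheme = config$calibration_scheme,
          min_count = config$calibration_min_count)
        out_csv(cc, sprintf("calibration_%s_%s", comp, labels[k]))
        cals[[labels[k]]] <- cc
      })
    }
    if (length(rocs) == 2) {
      run_stage(comp, "roc_figure", {
        out_fig(plot_roc(rocs, aurocs, title = sprintf("ROC: %s", comp)),
                sprintf("roc_%s", comp))
      })
    }
    if (length(cals) == 2) {
      run_stage(comp, "calibration_figure", {
        out_fig(plot_calibration(cals,
                                 title = sprintf("Calibration: %s", comp)),
                sprintf("calibration_%s", comp))
      })
    }

    for (metric in c("for", "fdr")) {
      raw <- list(); adj <- list()
      fn <- if (metric == "for") for_curve else fdr_curve
      for (k in 1:2) {
        raw[k] <- list(run_stage(comp, sprintf("%s_%s", metric, labels[k]), {
          cv <- fn(cohort$score[masks[[k]]], cohort$outcome[masks[[k]]],
                   config$grid, group_label = labels[k])
          out_csv(cv, sprintf("%s_%s_%s", metric, comp, labels[k]))
          cv
        }))
        adj[k] <- list(run_stage(comp,
                              sprintf("%s_adjusted_%s", metric, labels[k]), {
          cv <- adjusted_rate_curve(
            cohort, masks[[k]], metric = metric, grid = config$grid,
            reference = config$reference, other_rows = masks[[3L - k]],
            age_bands = config$age_bands, strata_vars = strata_vars,
            n_boot = config$n_boot,
            seed = sseed(20 + k + 2 * (metric == "fdr")),
            group_label = labels[k])
          out_csv(cv, sprintf("%s_adjusted_%s_%s", metric, comp,
                              labels[k]))
          cv
        }))
      }
      if (!is.null(raw[[1]]) && !is.null(raw[[2]])) {
        run_stage(comp, paste0(metric, "_difference"), {
          d <- curve_difference(raw[[1]], raw[[2]])
          out_csv(d, sprintf("%s_%s_difference", metric, comp))
          out_fig(plot_curve_pair(raw[[1]], raw[[2]], d,
                                  title = sprintf("%s: %s",
                                                  toupper(metric), comp)),
                  sprintf("%s_%s", metric, comp))
        })
      }
      if (!is.null(adj[[1]]) && !is.null(adj[[2]])) {
        run_stage(comp, paste0(metric, "_adjusted_difference"), {
          d <- curve_difference(adj[[1]], adj[[2]])
          out_csv(d, sprintf("%s_adjusted_%s_difference", metric, comp))
          out_fig(plot_curve_pair(adj[[1]], adj[[2]], d,
                                  title = sprintf("Adjusted %s: %s",
                                                  toupper(metric), comp)),
                  sprintf("%s_adjusted_%s", metric, comp))
        })
      }
    }

    for (k in 1:2) {
      run_stage(comp, paste0("decomposition_", labels[k]), {
        dt <- decomposition_table(
          cohort, masks[[k]], threshold = config$fn_threshold,
          map = config$type_map, n_boot = config$n_boot,
          seed = sseed(30 + k))
        out_csv(dt, sprintf("decomposition_%s_%s", comp, labels[k]))
        out_fig(plot_decomposition(
          dt, title = sprintf("False-negative decomposition: %s (%s)",
                              comp, labels[k])),
          sprintf("decomposition_%s_%s", comp, labels[k]))
      })
    }
  }

  if (length(auroc_rows)) {
    auroc_tbl <- dplyr::bind_rows(auroc_rows)
    out_csv(auroc_tbl, "auroc")
  }

  manifest$files <- sort(unique(manifest$files))
  yaml::write_yaml(manifest,
                   file.path(config$output_dir, "manifest.yaml"))
  invisible(manifest)
}

md_table <- function(df, digits = 4) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = digits, format = "g") else
      as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  c(header, sep, body)
}

#' Render a static report from an audit bundle
#'
#' Collates the bundle written by [run_audit()] into a single navigable
#' markdown document: one section per comparison, with curve tables,
#' figures (difference sub-panels beneath each paired curve panel), the
#' AUROC table, the cohort summary, and every warning recorded in the
#' manifest. Missing bundle members render as a placeholder with a warning.
#'
#' @param bundle_dir Directory containing a `manifest.yaml` from
#'   [run_audit()].
#' @param out_file Output file, default `report.md` inside the bundle.
#' @return The report path, invisibly.
#' @export
render_report <- function(bundle_dir,
                          out_file = file.path(bundle_dir, "report.md")) {
  manifest_path <- file.path(bundle_dir, "manifest.yaml")
  if (!file.exists(manifest_path)) {
    abort("No manifest.yaml in bundle directory.",
          class = "fairaudit_error_bundle")
  }
  manifest <- yaml::read_yaml(manifest_path)
  lines <- c(
    "# Risk score fairness audit report", "",
    sprintf("Package fairaudit %s; seed %s; %s bootstrap replicates; %s rows.",
            manifest$version, manifest$seed, manifest$n_boot,
            manifest$n_rows), ""
  )
  add_csv <- function(lines, name, heading, max_rows = 12) {
    path <- file.path(bundle_dir, paste0(name, ".csv"))
    lines <- c(lines, paste0("### ", heading), "")
    if (!file.exists(path)) {
      warn(sprintf("Bundle member '%s.csv' missing; rendering placeholder.",
                   name),
           class = "fairaudit_warning_missing_member")
      return(c(lines, "*[missing bundle member]*", ""))
    }
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    shown <- head(df, max_rows)
    c(lines, md_table(shown),
      if (nrow(df) > max_rows)
        sprintf("*(%d of %d rows shown; full table in %s.csv)*",
                max_rows, nrow(df), name),
      "")
  }
  add_fig <- function(lines, name) {
    rel <- file.path("figures", paste0(name, ".pdf"))
    if (file.exists(file.path(bundle_dir, rel))) {
      c(lines, sprintf("![%s](%s)", name, rel), "")
    } else lines
  }
  lines <- add_csv(lines, "summary", "Cohort summary", max_rows = 20)
  lines <- add_csv(lines, "auroc", "AUROC by group", max_rows = 24)
  for (comp in manifest$comparisons) {
    lines <- c(lines, paste0("## Comparison: ", comp), "")
    for (fig in c(sprintf("parity_%s", comp),
                  sprintf("for_%s", comp), sprintf("for_adjusted_%s", comp),
                  sprintf("fdr_%s", comp),
                  sprintf("fdr_adjusted_%s", comp),
                  sprintf("roc_%s", comp), sprintf("calibration_%s", comp))) {
      lines <- add_fig(lines, fig)
    }
    csvs <- grep("\\.csv$", unlist(manifest$files), value = TRUE)
    members <- grep(sprintf("^(decomposition)_%s_", comp),
                    sub("\\.csv$", "", csvs), value = TRUE)
    for (m in unique(members)) {
      lines <- add_csv(lines, m, paste0("Decomposition: ", m))
      lines <- add_fig(lines, m)
    }
  }
  if (length(manifest$warnings)) {
    lines <- c(lines, "## Warnings", "",
               paste0("- ", unlist(manifest$warnings)), "")
  }
  if (length(manifest$errors)) {
    lines <- c(lines, "## Stage errors", "",
               paste0("- ", unlist(manifest$errors)), "")
  }
  writeLines(lines, out_file)
  invisible(out_file)
}
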