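small_audit_config <- function(dir, seed = 5, render_figures = TRUE) {
  audit_config(
    output_dir = dir,
    generator = generator_config(n = 4000, seed = 77),
    specs = builtin_group_specs()[c("sex", "deprivation")],
    grid = cutoff_grid(0.02, 0.30, 0.02),
    n_boot = 50, seed = seed,
    calibration_min_count = 30,
    render_figures = render_figures
  )
}

test_that("two audit runs with the same config and seed are byte-identical", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- run_audit(small_audit_config(d1))
  m2 <- run_audit(small_audit_config(d2))
  expect_equal(m1$files, m2$files)
  expect_gt(length(m1$files), 10)
  for (f in m1$files) {
    h1 <- unname(tools::md5sum(file.path(d1, f)))
    h2 <- unname(tools::md5sum(file.path(d2, f)))
    expect_identical(h1, h2, label = sprintf("md5(%s)", f))
  }
  # manifests identical too
  expect_identical(readLines(file.path(d1, "manifest.yaml")),
                   readLines(file.path(d2, "manifest.yaml")))
})

test_that("a different seed changes the bootstrap-dependent outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_audit(small_audit_config(d1, seed = 5))
  run_audit(small_audit_config(d2, seed = 6))
  f <- "counterfactual_sex_M.csv"
  expect_false(identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f))))
})

test_that("the bundle contains the full metric menu per comparison", {
  d <- withr::local_tempdir()
  m <- run_audit(small_audit_config(d, render_figures = FALSE))
  files <- m$files
  for (comp in c("sex", "deprivation")) {
    labs <- if (comp == "sex") c("M", "F") else
      c("most_deprived", "least_deprived")
    for (lab in labs) {
      for (stem in c("parity_%s_%s", "counterfactual_%s_%s", "roc_%s_%s",
                     "calibration_%s_%s", "for_%s_%s", "for_adjusted_%s_%s",
                     "fdr_%s_%s", "fdr_adjusted_%s_%s",
                     "decomposition_%s_%s")) {
        expect_true(sprintf(paste0(stem, ".csv"), comp, lab) %in% files,
                    label = sprintf(stem, comp, lab))
      }
    }
  }
  expect_true("summary.csv" %in% files)
  expect_true("auroc.csv" %in% files)
  expect_length(m$errors, 0)
})

test_that("unknown group variables fail before any computation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(output_dir = "x", specs = c("sex", "height"),
                        generator = list(n = 100)), path)
  expect_error(read_audit_config(path), regexp = "height",
               class = "fairaudit_error_config")
  expect_error(audit_config(output_dir = "x"),
               class = "fairaudit_error_config")
  expect_error(audit_config(output_dir = "x", generator = generator_config(),
                            specs = list(1)),
               class = "fairaudit_error_config")
})

test_that("stage failures are isolated and recorded in the manifest", {
  d <- withr::local_tempdir()
  cfg <- small_audit_config(d, render_figures = FALSE)
  # an ethnicity comparison on a cohort with ethnicity wiped: that stage
  # fails, the others still run
  co <- generate_cohort(generator_config(n = 2000, seed = 78))$cohort
  co$ethnicity <- NA_character_
  path <- file.path(d, "cohort.csv")
  write_cohort(co, path)
  cfg2 <- audit_config(
    output_dir = file.path(d, "bundle"), cohort_path = path,
    specs = builtin_group_specs()[c("sex", "ethnicity")],
    grid = cutoff_grid(0.02, 0.30, 0.02), n_boot = 20, seed = 1,
    calibration_min_count = 30, render_figures = FALSE
  )
  m <- run_audit(cfg2)
  expect_gt(length(m$errors), 0)
  expect_true(any(grepl("ethnicity", m$errors)))
  expect_true("parity_sex_M.csv" %in% m$files)
})

test_that("warnings raised by stages are captured in the manifest", {
  d <- withr::local_tempdir()
  cfg <- small_audit_config(d, render_figures = FALSE)
  cfg$calibration_min_count <- 1000  # forces omitted-bin messages
  m <- run_audit(cfg)
  expect_gt(length(m$warnings) + length(m$errors), 0)
})

test_that("render_report produces one section per comparison and flags missing members", {
  d <- withr::local_tempdir()
  run_audit(small_audit_config(d, render_figures = FALSE))
  report <- render_report(d)
  lines <- readLines(report)
  expect_true(any(grepl("^## Comparison: sex$", lines)))
  expect_true(any(grepl("^## Comparison: deprivation$", lines)))
  # re-render is byte-identical
  txt1 <- readLines(report)
  render_report(d)
  expect_identical(readLines(report), txt1)
  # remove a member: placeholder plus warning
  file.remove(file.path(d, "summary.csv"))
  expect_warning(render_report(d),
                 class = "fairaudit_warning_missing_member")
  expect_true(any(grepl("missing bundle member",
                        readLines(report))))
})
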