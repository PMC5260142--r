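# Canonical sample-table column schema (units: mm, mm, ..., MPa, -, -, -)
sample_table_columns <- function() {
  c("W1", "W2", "W3", "W4", "W5", "T", "L", "P", "DR_32ms", "DR_42ms", "RER")
}

#' Read a sample table of evaluated stent designs
#'
#' Reads a CSV archive with one evaluated design per row: the seven design
#' variables (mm), the calibrated inflation pressure `P` (MPa), the
#' dogboning ratios at full expansion and post-recoil, and the radial
#' elastic recoil.  `#`-prefixed lines are metadata comments.  Rows whose
#' design falls outside the stent constraint box are loaded but flagged in
#' the logical column `in_bounds`.
#'
#' @param path CSV file path.
#' @return A data frame with the schema columns plus `in_bounds`.
#' @seealso [write_sample_table()], [table1_samples()].
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", check.names = FALSE),
    error = function(e) {
      stop(sprintf("cannot parse sample table '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
  want <- sample_table_columns()
  missing <- setdiff(want, names(df))
  if (length(missing)) {
    stop(sprintf("sample table is missing column(s) %s; expected header: %s",
                 paste(missing, collapse = ", "),
                 paste(want, collapse = ",")), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("sample table has no rows", call. = FALSE)
  df <- df[, want]
  space <- stent_design_space()
  df$in_bounds <- in_box(as.matrix(df[, space$names]), space)
  df
}

#' Write a sample table of evaluated stent designs
#'
#' Writes the canonical CSV schema of [read_sample_table()], with optional
#' `#`-prefixed metadata lines (e.g. seed) at the top.  Values are written
#' at full precision so a write/read round trip is lossless.
#'
#' @param df Data frame carrying at least the schema columns.
#' @param path Output path.
#' @param metadata Named character/numeric vector written as `# name: value`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(df, path, metadata = NULL) {
  want <- sample_table_columns()
  missing <- setdiff(want, names(df))
  if (length(missing)) {
    stop(sprintf("data frame lacks column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata)) {
    writeLines(sprintf("# %s: %s", names(metadata), as.character(metadata)), con)
  }
  out <- df[, want]
  writeLines(paste(want, collapse = ","), con)
  lines <- apply(out, 1L, function(r)
    paste(vapply(r, function(v) format(as.numeric(v), digits = 17), ""),
          collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

#' The bundled 30-design initial sample archive
#'
#' The thirty MRG-selected designs with their calibrated pressures,
#' dogboning ratios (full expansion and post-recoil) and radial elastic
#' recoils that seed the reference optimization run.
#'
#' @return A data frame in the [read_sample_table()] schema.
#' @export
table1_samples <- function() {
  read_sample_table(system.file("extdata", "table1_mrg_samples.csv",
                                package = "stentkrig", mustWork = TRUE))
}

#' Reference original-versus-optimal comparison values
#'
#' The reported geometries and expansion metrics of the original and the
#' optimized stent, plus the maximum transient dogboning ratios of the two
#' designs over the whole dilation, used for arithmetic verification of the
#' reported reduction percentages.
#'
#' @return A list with `designs` (two-row data frame, original and optimal)
#'   and `max_dr` (named vector of peak transient dogboning ratios).
#' @export
table2_results <- function() {
  designs <- data.frame(
    stent = c("original", "optimal"),
    W1 = c(0.28, 0.235), W2 = c(0.28, 0.22), W3 = c(0.28, 0.22),
    W4 = c(0.28, 0.22), W5 = c(0.249, 0.3), T = c(0.12, 0.1),
    L = c(5.8, 5.63), P = c(1.8654, 1.9077),
    DR_32ms = c(0.0622, 0.0036), DR_42ms = c(0.0634, 0.0067),
    RER = c(0.0178, 0.0151)
  )
  list(designs = designs, max_dr = c(original = 13.9, optimal = 8.78))
}

#' Recompute the reference reduction percentages
#'
#' Applies [percent_reduction()] to the bundled original/optimal comparison
#' values of [table2_results()]: dogboning at full expansion and post-recoil,
#' radial elastic recoil, and the peak transient dogboning ratio.
#'
#' @return A data frame with columns `metric`, `original`, `optimized` and
#'   `reduction_pct`.
#' @export
verify_table2 <- function() {
  t2 <- table2_results()
  d <- t2$designs
  orig <- d[d$stent == "original", ]
  opt <- d[d$stent == "optimal", ]
  data.frame(
    metric = c("abs_DR_32ms", "abs_DR_42ms", "RER", "max_DR_trace"),
    original = c(orig$DR_32ms, orig$DR_42ms, orig$RER, t2$max_dr[["original"]]),
    optimized = c(opt$DR_32ms, opt$DR_42ms, opt$RER, t2$max_dr[["optimal"]]),
    reduction_pct = c(
      percent_reduction(orig$DR_32ms, opt$DR_32ms),
      percent_reduction(orig$DR_42ms, opt$DR_42ms),
      percent_reduction(orig$RER, opt$RER),
      percent_reduction(t2$max_dr[["original"]], t2$max_dr[["optimal"]]))
  )
}

#' Write the report files of an optimization run
#'
#' Emits three artifacts into a directory: `evaluations.csv` (the archive in
#' the sample-table schema plus objective/EI/iteration/provenance columns),
#' `summary.json` (configuration echo, seeds, convergence residual trace and
#' incumbent) and `comparison.csv` — an original-versus-incumbent comparison
#' with [percent_reduction()] values for `|DR|` at full expansion, `|DR|`
#' post-recoil and `RER`.
#'
#' @param state An [ego()] result from a stent-type run.
#' @param dir Output directory (created if needed).
#' @param original A one-row data frame or named vector with the reference
#'   design's `DR_32ms`, `DR_42ms` and `RER`; defaults to the evaluation of
#'   [original_stent_design()] found in (or added to) the archive via the
#'   bundled simulator.
#' @param config The [stent_sim_config()] used (echoed in the summary, and
#'   used to evaluate the reference design when it is not supplied).
#' @return Invisibly, the paths written.
#' @export
write_run_report <- function(state, dir, original = NULL,
                             config = stent_sim_config()) {
  stopifnot(inherits(state, "ego"))
  if (!isTRUE(state$config$metric_mode)) {
    stop("run reports require a stent-type run (expansion metrics)", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  arch <- state$archive
  names(arch)[names(arch) == "pressure"] <- "P"
  names(arch)[names(arch) == "dr"] <- "DR_32ms"
  names(arch)[names(arch) == "dr_post"] <- "DR_42ms"
  names(arch)[names(arch) == "rer"] <- "RER"
  eval_path <- file.path(dir, "evaluations.csv")
  keep <- c(sample_table_columns(), "objective", "ei", "yhat", "iteration",
            "provenance")
  meta <- c(seed = if (is.null(state$config$seed)) "none" else state$config$seed,
            omega = state$config$omega, n_initial = state$config$n_initial)
  con <- file(eval_path, "w");
  writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  close(con)
  suppressWarnings(utils::write.table(
    arch[, keep], eval_path, sep = ",", row.names = FALSE, qmethod = "double",
    append = TRUE))

  if (is.null(original)) {
    rec <- evaluate_design(original_stent_design(), config)
    original <- c(DR_32ms = rec$metrics$dr, DR_42ms = rec$metrics$dr_post,
                  RER = rec$metrics$rer)
  }
  original <- as.list(original)
  inc <- incumbent(state)
  comparison <- data.frame(
    metric = c("abs_DR_32ms", "abs_DR_42ms", "RER"),
    original = abs(c(original$DR_32ms, original$DR_42ms, original$RER)),
    incumbent = abs(c(inc$dr, inc$dr_post, inc$rer))
  )
  comparison$reduction_pct <-
    percent_reduction(comparison$original, comparison$incumbent)
  comp_path <- file.path(dir, "comparison.csv")
  utils::write.csv(comparison, comp_path, row.names = FALSE)

  summary_path <- file.path(dir, "summary.json")
  summ <- list(
    config = list(n_initial = state$config$n_initial,
                  omega = state$config$omega,
                  seed = state$config$seed,
                  tolerances = unclass(state$config$tolerances),
                  target_diameter = config$target_diameter,
                  pressure_bracket = config$pressure_bracket),
    converged = state$converged,
    n_evaluations = nrow(state$archive),
    n_infill = state$n_infill,
    n_failures = length(state$failures),
    normalization_bounds = unclass(state$bounds),
    trace = state$trace,
    incumbent = as.list(inc),
    comparison = comparison
  )
  jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(evaluations = eval_path, comparison = comp_path,
              summary = summary_path))
}
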