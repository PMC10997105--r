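#' Regression of species-level resolution on log mean amplicon length
#'
#' Ordinary least squares of species-level taxonomic resolution on the
#' natural-log-transformed mean metabarcode length, one point per primer
#' pair. R-squared, F and p are invariant to the log base. For a simple
#' regression `f_stat = r_squared * (n - 2) / (1 - r_squared)`.
#'
#' @param reports Data frame with columns `mean_len` (bp, > 0) and
#'   `resolution_species`; rows with missing values are dropped. At least 3
#'   complete rows are required.
#' @return Object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `f_stat`, `df` (`c(1, n - 2)`), `p_value`,
#'   `n`.
#' @export
resolution_length_regression <- function(reports) {
  dat <- data.frame(len = reports$mean_len, res = reports$resolution_species)
  dat <- dat[is.finite(dat$len) & dat$len > 0 & is.finite(dat$res), ,
             drop = FALSE]
  n <- nrow(dat)
  if (n < 3L) stop("need at least 3 primer pairs with finite mean length ",
                   "and species resolution (got ", n, ")")
  fit <- stats::lm(res ~ log(len), data = dat)
  sm <- summary(fit)
  fstat <- unname(sm$fstatistic["value"])
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    f_stat = fstat,
    df = c(1L, n - 2L),
    p_value = stats::pf(fstat, 1, n - 2, lower.tail = FALSE),
    n = n
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> resolution ~ log(length): R2 = %.2f, F(%d,%d) = %.1f, P = %.3f (n = %d)\n",
              x$r_squared, x$df[1], x$df[2], x$f_stat, x$p_value, x$n))
  invisible(x)
}

#' Packaged published evaluation of the 18S primer set
#'
#' The published per-primer summary (coverage, mean/min/max metabarcode
#' length in bp excluding primers, and species/genus/family resolution) for
#' the 15 packaged 18S primer pairs, as printed (fractions to 2 decimals,
#' lengths to 1). Ships so the resolution-length regression can be exercised
#' without any database download.
#'
#' @return Data frame with one row per primer pair.
#' @export
published_primer_evaluation <- function() {
  read.delim(system.file("extdata", "published_evaluation_18S.tsv",
                         package = "primerscreen", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Build a run manifest
#'
#' Records everything needed to re-run an analysis bit-identically: package
#' version, parameters, seeds and input checksums.
#'
#' @param parameters Named list of run parameters (mismatch budget, length
#'   bounds, flags).
#' @param seeds Named list or vector of seeds used.
#' @param inputs Character vector of input file paths to checksum (md5).
#' @return Named list (class `run_manifest`).
#' @export
run_manifest <- function(parameters = list(), seeds = list(),
                         inputs = character(0)) {
  checks <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  structure(list(
    tool = "primerscreen",
    version = as.character(utils::packageVersion("primerscreen")),
    parameters = parameters,
    seeds = as.list(seeds),
    input_checksums = checks,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' Assemble and write a run bundle
#'
#' Writes the full evaluation into a directory: `report.tsv` (one row per
#' primer), `specificity.tsv`, `regression.json` and `manifest.json`.
#' [read_run_report()] round-trips the bundle.
#'
#' @param reports Data frame of [build_report()] rows.
#' @param specificities Data frame `primer, fraction, n_target_species`
#'   (or `NULL`).
#' @param regression A `regression_result` (or `NULL`).
#' @param manifest A [run_manifest()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
assemble_run_report <- function(reports, specificities, regression,
                                manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(reports, file.path(dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(specificities)) {
    write.table(specificities, file.path(dir, "specificity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(regression)) {
    jsonlite::write_json(unclass(regression),
                         file.path(dir, "regression.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(unclass(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a run bundle back
#'
#' @param dir Directory written by [assemble_run_report()].
#' @return List with `reports`, `specificities`, `regression`, `manifest`
#'   (missing pieces are `NULL`).
#' @export
read_run_report <- function(dir) {
  pick <- function(name, reader) {
    p <- file.path(dir, name)
    if (file.exists(p)) reader(p) else NULL
  }
  list(
    reports = pick("report.tsv",
                   function(p) read.delim(p, stringsAsFactors = FALSE)),
    specificities = pick("specificity.tsv",
                         function(p) read.delim(p, stringsAsFactors = FALSE)),
    regression = pick("regression.json", jsonlite::read_json),
    manifest = pick("manifest.json", jsonlite::read_json)
  )
}
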