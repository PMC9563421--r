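fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "roavcurves")
  assert_that(nzchar(p), "fixture %s not found; is the package installed?", file)
  p
}

#' Packaged study tables
#'
#' Loaders for the plain-text fixtures shipped with the package: the
#' GC-O/AEDA flavor-dilution table (`mrp_fd()`), the relative-content table
#' with replicate SDs (`mrp_content()`), the compound identities with
#' retention indices, odor thresholds and descriptors (`mrp_compounds()`),
#' the published ROAV scores (`mrp_roav_printed()`), the hold-out verification
#' table of actual and model-predicted ROAVs at the fifth hour
#' (`mrp_validation()`), and the measured degree-of-hydrolysis series over
#' 0-8 h (`mrp_dh_series()`). Samples A-E are Maillard reaction products of
#' a beef tallow residue hydrolysate after 0, 2, 4, 6 and 8 h of hydrolysis.
#'
#' @return `mrp_fd()` an [fd_matrix()]; `mrp_content()` a [content_matrix()];
#'   `mrp_compounds()` a [compound_table()]; `mrp_roav_printed()` a numeric
#'   samples x compounds matrix; `mrp_validation()` a `data.frame`;
#'   `mrp_dh_series()` a `data.frame` with columns `time_h`, `dh`, `sd`.
#' @name mrp_fixtures
NULL

#' @rdname mrp_fixtures
#' @export
mrp_fd <- function() read_fd_matrix(fixture_path("table1_fd.tsv"))

#' @rdname mrp_fixtures
#' @export
mrp_content <- function() {
  raw <- utils::read.delim(fixture_path("table2_content.tsv"), sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", colClasses = "character")
  keep <- setdiff(names(raw), "ions")
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(raw[keep], tmp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  read_content_matrix(tmp)
}

#' @rdname mrp_fixtures
#' @export
mrp_compounds <- function() {
  t3 <- utils::read.delim(fixture_path("table3_thresholds_roav.tsv"),
                          sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  t1 <- utils::read.delim(fixture_path("table1_fd.tsv"), sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  t2 <- utils::read.delim(fixture_path("table2_content.tsv"), sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  key3 <- name_key(t3$compound)
  desc <- strsplit(t1$flavor[match(key3, name_key(t1$compound))], ";")
  desc <- lapply(desc, trimws)
  ions <- strsplit(t2$ions[match(key3, name_key(t2$compound))], ",")
  ions <- lapply(ions, function(x) as.integer(trimws(x)))
  compound_table(t3$compound, t3$threshold_ugkg, chem_class = t3$class,
                 retention_index = t3$ri, descriptors = desc,
                 quant_ions = ions)
}

#' @rdname mrp_fixtures
#' @export
mrp_roav_printed <- function() {
  t3 <- utils::read.delim(fixture_path("table3_thresholds_roav.tsv"),
                          sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  samples <- grep("^MRPs ", names(t3), value = TRUE)
  m <- t(as.matrix(t3[samples]))
  colnames(m) <- canonical_compound_name(t3$compound)
  m
}

#' @rdname mrp_fixtures
#' @export
mrp_validation <- function() {
  v <- utils::read.delim(fixture_path("table4_validation.tsv"), sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE,
                         quote = "")
  v$compound <- canonical_compound_name(v$compound)
  v
}

#' @rdname mrp_fixtures
#' @export
mrp_dh_series <- function() {
  utils::read.delim(fixture_path("dh_series.tsv"), sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Published ROAV trajectories of the key volatiles as fit-ready series
#'
#' Builds one [trajectory_series()] per hold-out verification compound from
#' the published per-sample ROAV scores, with the abscissa either hydrolysis
#' time (0, 2, 4, 6, 8 h) or the measured degree of hydrolysis at those
#' times.
#'
#' @param x_axis `"time"` (hours, default) or `"dh"` (percent).
#' @return named list of [trajectory_series()] in verification-table row
#'   order.
#' @export
mrp_key_trajectories <- function(x_axis = c("time", "dh")) {
  x_axis <- match.arg(x_axis)
  roav <- mrp_roav_printed()
  keys <- mrp_validation()$compound
  x <- if (x_axis == "time") mrp_dh_series()$time_h else mrp_dh_series()$dh
  out <- lapply(keys, function(k) trajectory_series(x, roav[, k], x_axis))
  names(out) <- keys
  out
}
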