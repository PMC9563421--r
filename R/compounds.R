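#' Chemical classes recognised for aroma-active volatiles
#'
#' @format character vector of class labels.
#' @export
chem_classes <- c("aldehyde", "acid", "alcohol", "pyrazine", "furan",
                  "ketone", "phenol", "ester", "sulfur", "other")

#' Assign a chemical class from a compound name
#'
#' Deterministic, ordered suffix/substring rules on the canonicalized name.
#' The order matters: acids before everything ("hexanoic acid"), pyrazines and
#' furans before the aldehyde suffix, the aldehyde suffix before the thioether
#' substring (so 3-(methylthio)propanal counts as an aldehyde, matching the
#' conventional GC-O class tallies), and phenols before the generic "-ol"
#' alcohol suffix (p-cresol is a phenol, not an alcohol). Names matching no
#' rule fall through to `"other"`.
#'
#' @param name character vector of compound names; must be non-empty strings.
#' @return character vector of classes, one of [chem_classes].
#' @examples
#' classify_compound(c("Octanal", "p-Cresol", "2-Ethyl-3,5-dimethylpyrazine"))
#' @export
classify_compound <- function(name) {
  assert_that(is.character(name) && length(name) > 0, "name must be character")
  assert_that(all(nzchar(trimws(name))), "compound name must be non-empty")
  key <- name_key(name)
  cls <- rep("other", length(key))
  rule <- function(pattern) grepl(pattern, key) & cls == "other"
  cls[rule("acid")] <- "acid"
  cls[rule("pyrazine")] <- "pyrazine"
  cls[rule("furan")] <- "furan"
  cls[rule("al$|aldehyde")] <- "aldehyde"
  cls[rule("phenol|cresol")] <- "phenol"
  cls[rule("ol$")] <- "alcohol"
  cls[rule("one$|ketone")] <- "ketone"
  cls[rule("ate$|ester")] <- "ester"
  cls[rule("thio|sulf")] <- "sulfur"
  cls
}

#' Build a compound table
#'
#' One row per volatile: identity, chemical class, retention index on the
#' DB-WAX scale, odor (detection) threshold in water, free-text descriptors
#' and optional quantifier ions. When `chem_class` is missing it is derived
#' from the name by [classify_compound()].
#'
#' @param name compound names (made canonical; must be unique).
#' @param odor_threshold detection thresholds in ug/kg water; strictly > 0.
#' @param chem_class optional classes; `NA` entries are auto-classified.
#' @param retention_index optional integer retention indices.
#' @param descriptors optional list of character vectors of odor descriptors.
#' @param quant_ions optional list of integer m/z vectors.
#' @return a `data.frame` of class `"compound_table"`.
#' @export
compound_table <- function(name, odor_threshold, chem_class = NULL,
                           retention_index = NA_integer_, descriptors = NULL,
                           quant_ions = NULL) {
  name <- canonical_compound_name(name)
  n <- length(name)
  dup <- duplicated(name_key(name))
  assert_that(!any(dup), "duplicate compound name: %s",
              paste(unique(name[dup]), collapse = ", "))
  assert_that(is.numeric(odor_threshold) && length(odor_threshold) == n,
              "odor_threshold must be numeric, one per compound")
  bad <- !is.finite(odor_threshold) | odor_threshold <= 0
  assert_that(!any(bad), "odor_threshold must be > 0 (offending: %s)",
              paste(name[bad], collapse = ", "))
  if (is.null(chem_class)) chem_class <- rep(NA_character_, n)
  chem_class <- rep_len(as.character(chem_class), n)
  retention_index <- rep_len(retention_index, n)
  miss <- is.na(chem_class)
  if (any(miss)) chem_class[miss] <- classify_compound(name[miss])
  unknown <- setdiff(unique(chem_class), chem_classes)
  assert_that(length(unknown) == 0, "unknown chem_class: %s",
              paste(unknown, collapse = ", "))
  if (is.null(descriptors)) descriptors <- vector("list", n)
  if (is.null(quant_ions)) quant_ions <- vector("list", n)
  out <- data.frame(name = name, chem_class = chem_class,
                    retention_index = as.integer(retention_index),
                    odor_threshold = as.numeric(odor_threshold),
                    stringsAsFactors = FALSE)
  out$descriptors <- descriptors
  out$quant_ions <- quant_ions
  class(out) <- c("compound_table", class(out))
  out
}

#' Read a compound table from delimited text
#'
#' Expects columns `name`, `threshold_ugkg`, and optionally `class`, `ri` and
#' `descriptors` (descriptors separated by `";"`). Rows with no class are
#' classified by [classify_compound()].
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return a [compound_table()].
#' @export
read_compound_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "file not found: %s", path)
  raw <- utils::read.delim(path, sep = if (dialect == "tsv") "\t" else ",",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", colClasses = "character")
  assert_that(all(c("name", "threshold_ugkg") %in% names(raw)),
              "header must contain 'name' and 'threshold_ugkg' (got: %s)",
              paste(names(raw), collapse = ", "))
  if (nrow(raw) == 0) {
    return(compound_table(character(0), numeric(0)))
  }
  thr <- parse_number(raw$threshold_ugkg, seq_len(nrow(raw)), "threshold_ugkg")
  cls <- if ("class" %in% names(raw)) {
    ifelse(nzchar(trimws(raw$class)), trimws(raw$class), NA_character_)
  } else NULL
  ri <- if ("ri" %in% names(raw)) {
    as.integer(parse_number(raw$ri, seq_len(nrow(raw)), "ri"))
  } else NA_integer_
  desc <- if ("descriptors" %in% names(raw)) {
    lapply(strsplit(raw$descriptors, ";"), trimws)
  } else NULL
  compound_table(raw$name, thr, chem_class = cls, retention_index = ri,
                 descriptors = desc)
}

#' Write a compound table to delimited text
#'
#' Inverse of [read_compound_table()]; descriptors are joined with `"; "`.
#'
#' @param x a [compound_table()].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_compound_table <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "compound_table"))
  out <- data.frame(
    name = x$name, class = x$chem_class, ri = x$retention_index,
    threshold_ugkg = format(x$odor_threshold, scientific = FALSE, trim = TRUE),
    descriptors = vapply(x$descriptors, function(d) {
      paste(d, collapse = "; ")
    }, character(1)),
    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = if (dialect == "tsv") "\t" else ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tally compounds by chemical class
#'
#' @param records a [compound_table()].
#' @return named integer vector of counts; sums to `nrow(records)`. Classes
#'   with no members are dropped.
#' @export
tally_classes <- function(records) {
  stopifnot(inherits(records, "compound_table"))
  if (nrow(records) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(factor(records$chem_class, levels = chem_classes))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[out > 0]
}

#' @export
print.compound_table <- function(x, ...) {
  cat(sprintf("<compound_table> %d compounds\n", nrow(x)))
  NextMethod()
  invisible(x)
}
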