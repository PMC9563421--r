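#' Build a relative-content matrix
#'
#' Samples by compounds matrix of relative content, expressed as percent of
#' total chromatogram peak area (a share, so each sample's row sum cannot
#' exceed 100). A value of exactly 0 means the compound was not detected in
#' that sample. Optional per-cell standard deviations from replicate
#' injections.
#'
#' @param values numeric matrix, samples x compounds, with dimnames; all
#'   entries >= 0 and each row sum <= 100.
#' @param sds optional matrix of the same shape, entries >= 0.
#' @return an object of class `"content_matrix"` with fields `values`, `sds`,
#'   `sample_ids`, `compounds`.
#' @export
content_matrix <- function(values, sds = NULL) {
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values must carry sample row names and compound column names")
  colnames(values) <- canonical_compound_name(colnames(values))
  assert_that(all(is.finite(values)), "content values must be finite")
  assert_that(all(values >= 0), "content values must be >= 0")
  rs <- rowSums(values)
  over <- rs > 100 + 1e-9
  assert_that(!any(over),
              "relative content is a share of total peak area: sample %s sums to %.2f%% (> 100%%)",
              paste(rownames(values)[over], collapse = ", "), max(rs))
  if (!is.null(sds)) {
    assert_that(is.matrix(sds) && all(dim(sds) == dim(values)),
                "sds must match the shape of values")
    assert_that(all(is.finite(sds)) && all(sds >= 0), "sds must be >= 0")
    dimnames(sds) <- dimnames(values)
  }
  structure(list(values = values, sds = sds,
                 sample_ids = rownames(values),
                 compounds = colnames(values)),
            class = "content_matrix")
}

# Parse "v +/- s" cells; plain "v" gives sd NA.
parse_pm <- function(x, row, col) {
  parts <- strsplit(x, "±|\\+/-")
  v <- vapply(parts, function(p) trimws(p[1]), character(1))
  s <- vapply(parts, function(p) {
    if (length(p) > 1) trimws(p[2]) else NA_character_
  }, character(1))
  list(value = parse_number(v, row, col), sd = suppressWarnings(as.numeric(s)))
}

#' Read a relative-content matrix from delimited text
#'
#' File layout: one row per compound, first column `compound`, then one column
#' per sample. Cells may be plain numbers (`"2.16"`) or carry replicate
#' standard deviations in `"value ± sd"` notation. Alternatively an
#' explicit `<sample>_sd` column may follow each sample column.
#'
#' @inheritParams read_compound_table
#' @return a [content_matrix()].
#' @export
read_content_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "file not found: %s", path)
  raw <- utils::read.delim(path, sep = if (dialect == "tsv") "\t" else ",",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", colClasses = "character")
  assert_that(names(raw)[1] == "compound",
              "first column must be 'compound' (got %s)", names(raw)[1])
  cols <- names(raw)[-1]
  sd_cols <- grep("_sd$", cols, value = TRUE)
  sample_cols <- setdiff(cols, sd_cols)
  compounds <- canonical_compound_name(raw$compound)
  vals <- matrix(NA_real_, length(sample_cols), nrow(raw),
                 dimnames = list(sample_cols, compounds))
  sds <- matrix(NA_real_, length(sample_cols), nrow(raw),
                dimnames = list(sample_cols, compounds))
  for (s in sample_cols) {
    p <- parse_pm(raw[[s]], compounds, s)
    vals[s, ] <- p$value
    sds[s, ] <- p$sd
    sdc <- paste0(s, "_sd")
    if (sdc %in% sd_cols) sds[s, ] <- parse_number(raw[[sdc]], compounds, sdc)
  }
  if (all(is.na(sds))) sds <- NULL else sds[is.na(sds)] <- 0
  content_matrix(vals, sds)
}

#' Write a relative-content matrix to delimited text
#'
#' Writes the transposed layout read by [read_content_matrix()] (rows are
#' compounds); when SDs are present cells use `"value ± sd"` notation.
#' Values are written at full precision so a write/read round trip reproduces
#' the matrix exactly.
#'
#' @param x a [content_matrix()].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_content_matrix <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "content_matrix"))
  fmt <- function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE)
  cells <- if (is.null(x$sds)) {
    apply(x$values, c(1, 2), fmt)
  } else {
    matrix(paste(fmt(x$values), "±", fmt(x$sds)),
           nrow(x$values), ncol(x$values), dimnames = dimnames(x$values))
  }
  out <- data.frame(compound = x$compounds, t(cells),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = if (dialect == "tsv") "\t" else ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

is_power_of_3 <- function(x) {
  k <- round(log(x) / log(3))
  is.finite(x) & x > 0 & abs(3^k - x) < 1e-9
}

#' Build a flavor-dilution (FD) factor matrix
#'
#' FD factors from aroma extract dilution analysis with a 1:3 dilution step:
#' every detected entry must be a non-negative integer power of 3, and `NA`
#' encodes "not detected" (ND). ND is deliberately distinct from a content of
#' zero; the two are not reconciled across tables.
#'
#' @param fd numeric matrix, samples x compounds, dimnames required; entries
#'   `NA` (ND) or powers of 3.
#' @return an object of class `"fd_matrix"`.
#' @export
fd_matrix <- function(fd) {
  assert_that(is.matrix(fd) && is.numeric(fd), "fd must be a numeric matrix")
  assert_that(!is.null(rownames(fd)) && !is.null(colnames(fd)),
              "fd must carry sample row names and compound column names")
  colnames(fd) <- canonical_compound_name(colnames(fd))
  det <- fd[!is.na(fd)]
  assert_that(all(is_power_of_3(det)),
              "every detected FD factor must be a power of 3 (offending: %s)",
              paste(unique(det[!is_power_of_3(det)]), collapse = ", "))
  structure(list(fd = fd, sample_ids = rownames(fd),
                 compounds = colnames(fd)),
            class = "fd_matrix")
}

#' Read an FD-factor matrix from delimited text
#'
#' Layout: one row per compound, first column `compound`, one column per
#' sample; `ND` marks "not detected". Extra non-sample columns (e.g. odor
#' descriptors) are ignored here and read by the fixture loaders instead.
#'
#' @inheritParams read_compound_table
#' @param ignore columns to skip (default `"flavor"`).
#' @return an [fd_matrix()].
#' @export
read_fd_matrix <- function(path, dialect = c("tsv", "csv"),
                           ignore = "flavor") {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "file not found: %s", path)
  raw <- utils::read.delim(path, sep = if (dialect == "tsv") "\t" else ",",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", colClasses = "character")
  assert_that(names(raw)[1] == "compound",
              "first column must be 'compound' (got %s)", names(raw)[1])
  sample_cols <- setdiff(names(raw)[-1], ignore)
  compounds <- canonical_compound_name(raw$compound)
  m <- matrix(NA_real_, length(sample_cols), nrow(raw),
              dimnames = list(sample_cols, compounds))
  for (s in sample_cols) {
    cell <- trimws(raw[[s]])
    nd <- toupper(cell) == "ND"
    m[s, !nd] <- parse_number(cell[!nd], compounds[!nd], s)
  }
  fd_matrix(m)
}

#' A single sensory-evaluation record
#'
#' Plain data container for descriptive panel scores (linear 0-10 scale per
#' attribute) and hedonic overall acceptability (1-5). The package performs no
#' sensory statistics; the record exists so panel data can travel alongside
#' the volatile tables.
#'
#' @param sample_id sample identifier.
#' @param green,rancid,fatty,fruity,stale,roasty attribute scores in `[0, 10]`.
#' @param overall_acceptability hedonic score in `[1, 5]`.
#' @return an object of class `"sensory_record"`.
#' @export
sensory_record <- function(sample_id, green, rancid, fatty, fruity, stale,
                           roasty, overall_acceptability) {
  scores <- c(green = green, rancid = rancid, fatty = fatty, fruity = fruity,
              stale = stale, roasty = roasty)
  assert_that(all(is.finite(scores)) && all(scores >= 0 & scores <= 10),
              "attribute scores must lie in [0, 10]")
  assert_that(is_number(overall_acceptability) &&
                overall_acceptability >= 1 && overall_acceptability <= 5,
              "overall_acceptability must lie in [1, 5]")
  structure(list(sample_id = sample_id, scores = scores,
                 overall_acceptability = overall_acceptability),
            class = "sensory_record")
}

#' @export
print.content_matrix <- function(x, ...) {
  cat(sprintf("<content_matrix> %d samples x %d compounds (%s SDs)\n",
              length(x$sample_ids), length(x$compounds),
              if (is.null(x$sds)) "without" else "with"))
  invisible(x)
}

#' @export
print.fd_matrix <- function(x, ...) {
  cat(sprintf("<fd_matrix> %d samples x %d compounds, %d ND cells\n",
              length(x$sample_ids), length(x$compounds), sum(is.na(x$fd))))
  invisible(x)
}
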