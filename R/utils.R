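#' @keywords internal
"_PACKAGE"

# Stop with a message assembled sprintf-style; keeps call noise out of errors.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) abort(fmt, ...)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Normalize a compound name for display and matching
#'
#' Trims leading/trailing whitespace, collapses internal runs of whitespace,
#' and removes stray spaces around hyphens (a frequent artifact of table
#' extraction, e.g. `"2-Pentyl- furan"`). Known alternate spellings are mapped
#' to a single canonical form.
#'
#' @param x character vector of compound names.
#' @return character vector of canonical names, same length as `x`.
#' @examples
#' canonical_compound_name(c("2-Pentyl- furan", "  Octanal "))
#' @export
canonical_compound_name <- function(x) {
  assert_that(is.character(x), "compound names must be character")
  out <- trimws(gsub("[[:space:]]+", " ", x))
  out <- gsub("- ", "-", out, fixed = TRUE)
  out <- gsub(" -", "-", out, fixed = TRUE)
  key <- tolower(out)
  hit <- match(key, names(.compound_aliases))
  out[!is.na(hit)] <- .compound_aliases[hit[!is.na(hit)]]
  out
}

# Alternate spellings seen in source tables -> canonical form.
.compound_aliases <- c(
  "(e)-2-nonanal"   = "(E)-2-Nonenal",
  "2-pentyl-furan"  = "2-Pentylfuran",
  "(e)-2-nonnal"    = "(E)-2-Nonenal",
  "2-pentylfuran"   = "2-Pentylfuran",
  "1-octene-3-ol"   = "1-Octen-3-ol",
  "butyric acid"    = "Butanoic acid",
  "2-ethyl-6-methylpyrazine" = "2-Ethyl-6-methylpyrazine"
)

# Case-insensitive matching key.
name_key <- function(x) tolower(canonical_compound_name(x))

# Evaluate `expr` with the RNG seeded to `seed`, then restore the caller's
# RNG state so seeded fits do not disturb enclosing simulations.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Numeric parser that names the offending row/column on failure.
parse_number <- function(x, row, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad)) {
    abort("malformed number %s in row %s, column %s",
          dQuote(x[bad[1]]), row[bad[1]], col)
  }
  v
}
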