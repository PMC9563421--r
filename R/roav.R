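#' Relative odor activity values from contents and thresholds
#'
#' For each sample the ROAV of compound *i* is
#' `(C_i / C_ref) * (T_ref / T_i) * 100`, where the reference compound is the
#' one contributing most to the overall flavor — by default the compound
#' maximising the content-to-threshold ratio `C/T` in that sample, which by
#' construction scores exactly 100 and bounds all other scores by 100.
#' Compounds with zero content (not detected) score 0.
#'
#' @param contents a [content_matrix()].
#' @param thresholds odor thresholds in ug/kg: a named numeric vector or a
#'   [compound_table()]; every compound detected in `contents` needs one.
#' @param reference optional compound name forced as reference for all
#'   samples; it must be detected in every sample. With a manual reference
#'   ROAVs above 100 are possible and raise a warning.
#' @return an object of class `"roav_matrix"`: fields `roav` (samples x
#'   compounds), `reference` (named character, per sample), `sample_ids`,
#'   `compounds`.
#' @export
compute_roav <- function(contents, thresholds, reference = NULL) {
  stopifnot(inherits(contents, "content_matrix"))
  if (inherits(thresholds, "compound_table")) {
    thresholds <- stats::setNames(thresholds$odor_threshold, thresholds$name)
  }
  assert_that(is.numeric(thresholds) && !is.null(names(thresholds)),
              "thresholds must be a named numeric vector or compound_table")
  names(thresholds) <- canonical_compound_name(names(thresholds))
  vals <- contents$values
  detected <- colnames(vals)[colSums(vals > 0) > 0]
  missing <- setdiff(name_key(detected), name_key(names(thresholds)))
  assert_that(length(missing) == 0,
              "no odor threshold for detected compound(s): %s",
              paste(detected[name_key(detected) %in% missing], collapse = ", "))
  thr <- thresholds[match(name_key(colnames(vals)), name_key(names(thresholds)))]
  assert_that(all(is.finite(thr[colnames(vals) %in% detected]) &
                    thr[colnames(vals) %in% detected] > 0),
              "odor thresholds must be > 0")
  if (!is.null(reference)) {
    reference <- canonical_compound_name(reference)
    assert_that(reference %in% colnames(vals),
                "reference compound %s not present", reference)
  }
  roav <- matrix(0, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  refs <- character(nrow(vals))
  for (s in seq_len(nrow(vals))) {
    ci <- stats::setNames(vals[s, ], colnames(vals))
    assert_that(any(ci > 0), "sample %s has no detected compounds",
                rownames(vals)[s])
    ref <- if (is.null(reference)) {
      ratio <- ifelse(ci > 0, ci / thr, -Inf)
      colnames(vals)[which.max(ratio)]
    } else {
      assert_that(ci[reference] > 0,
                  "reference %s not detected in sample %s", reference,
                  rownames(vals)[s])
      reference
    }
    refs[s] <- ref
    roav[s, ] <- (ci / ci[ref]) * (thr[ref] / thr) * 100
    roav[s, ci == 0] <- 0
  }
  if (any(roav > 100 + 1e-9)) {
    warning("ROAV above 100: the chosen reference does not maximise C/T",
            call. = FALSE)
  }
  structure(list(roav = roav, reference = stats::setNames(refs, rownames(vals)),
                 sample_ids = rownames(vals), compounds = colnames(vals)),
            class = "roav_matrix")
}

#' Classify compounds by flavor contribution tier
#'
#' Three-way partition of each sample's ROAV scores: `key` for ROAV >= 1
#' (main flavor contributors), `modifier` for 0.1 <= ROAV < 1 (compounds with
#' an essential modifying effect on the overall flavor), `weak` below 0.1.
#' The boundaries are assigned upward: a score of exactly 1 is `key`, exactly
#' 0.1 is `modifier`.
#'
#' @param roav a `roav_matrix` from [compute_roav()], or a plain numeric
#'   samples x compounds matrix.
#' @return `data.frame` with columns `sample`, `compound`, `roav`, `tier`
#'   (factor key/modifier/weak).
#' @export
classify_roav <- function(roav) {
  m <- if (inherits(roav, "roav_matrix")) roav$roav else roav
  assert_that(is.matrix(m) && is.numeric(m), "roav must be a numeric matrix")
  long <- expand.grid(sample = rownames(m), compound = colnames(m),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$roav <- as.vector(m)
  long$tier <- factor(ifelse(long$roav >= 1, "key",
                             ifelse(long$roav >= 0.1, "modifier", "weak")),
                      levels = c("key", "modifier", "weak"))
  long[order(match(long$sample, rownames(m)), -long$roav), , drop = FALSE]
}

#' Select the key volatile compounds of a baseline sample
#'
#' Compounds scoring ROAV >= 1 in the baseline sample, in the column order of
#' the ROAV matrix. The per-sample reference compound scores a constant 100
#' at every time point, so its trajectory carries no curve information; by
#' default it is excluded from the selection used for curve fitting.
#'
#' @param roav a `roav_matrix` from [compute_roav()].
#' @param baseline_sample sample id the selection is anchored to.
#' @param exclude_reference drop the reference compound (default `TRUE`).
#' @return character vector of compound names (possibly empty).
#' @export
select_key_compounds <- function(roav, baseline_sample,
                                 exclude_reference = TRUE) {
  stopifnot(inherits(roav, "roav_matrix"))
  assert_that(baseline_sample %in% roav$sample_ids,
              "unknown sample: %s", baseline_sample)
  keys <- roav$compounds[roav$roav[baseline_sample, ] >= 1]
  if (exclude_reference) {
    keys <- setdiff(keys, roav$reference[[baseline_sample]])
  }
  keys
}

#' Most robust aroma contributor by flavor-dilution factor
#'
#' Returns the compound maximising the per-compound minimum FD factor across
#' samples — the odorant still perceived at the highest dilution in every
#' sample — together with that minimum and the compound's maximum FD. "Not
#' detected" counts as dilution 0 for the minimum. Ties are broken by lower
#' retention index when indices are supplied, otherwise by column order.
#'
#' @param fd an [fd_matrix()].
#' @param retention_index optional named numeric vector of retention indices
#'   used for tie-breaking.
#' @return list with `compound`, `min_fd`, `max_fd`.
#' @export
max_fd_query <- function(fd, retention_index = NULL) {
  stopifnot(inherits(fd, "fd_matrix"))
  m <- fd$fd
  assert_that(any(!is.na(m)), "FD matrix has no detected entries")
  m0 <- m
  m0[is.na(m0)] <- 0
  mins <- apply(m0, 2, min)
  best <- which(mins == max(mins))
  if (length(best) > 1 && !is.null(retention_index)) {
    names(retention_index) <- canonical_compound_name(names(retention_index))
    ri <- retention_index[match(name_key(fd$compounds[best]),
                                name_key(names(retention_index)))]
    best <- best[order(ri)]
  }
  pick <- best[1]
  list(compound = fd$compounds[pick], min_fd = unname(mins[pick]),
       max_fd = max(m[, pick], na.rm = TRUE))
}

#' @export
print.roav_matrix <- function(x, ...) {
  cat(sprintf("<roav_matrix> %d samples x %d compounds\n",
              length(x$sample_ids), length(x$compounds)))
  for (s in x$sample_ids) {
    cat(sprintf("  %s: reference %s, %d key compounds (ROAV >= 1)\n", s,
                x$reference[[s]], sum(x$roav[s, ] >= 1)))
  }
  invisible(x)
}
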