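test_that("ROAV recomputation from the fixtures matches the published table", {
  r <- compute_roav(mrp_content(), mrp_compounds())
  printed <- mrp_roav_printed()
  expect_identical(dim(r$roav), dim(printed[, colnames(r$roav)]))
  # the trace pyrazine maximises C/T in every sample and scores exactly 100
  expect_true(all(r$reference == "2-Ethyl-3,5-dimethylpyrazine"))
  for (s in r$sample_ids) {
    expect_equal(r$roav[s, r$reference[[s]]], 100)
  }
  printed <- printed[r$sample_ids, r$compounds]
  big <- printed >= 0.1
  rel <- abs(r$roav - printed) / pmax(printed, .Machine$double.eps)
  # agreement is bounded by the two-decimal rounding of the content inputs;
  # the worst cell has a content with only two significant figures
  expect_lt(max(rel[big]), 0.03)
  expect_equal(sum(rel[big] > 0.02), 2)
  expect_lt(max(abs(r$roav - printed)[!big]), 0.01)
  # undetected compounds score 0
  expect_identical(r$roav["MRPs A", "p-Cresol"], 0)
})

test_that("ROAV is scale invariant and bounded by the reference score", {
  cont <- tiny_content()
  r1 <- compute_roav(cont, tiny_thresholds())
  scaled <- content_matrix(cont$values * 0.37)
  r2 <- compute_roav(scaled, tiny_thresholds())
  expect_equal(r1$roav, r2$roav, tolerance = 1e-12)
  expect_true(all(r1$roav <= 100 + 1e-12))
  expect_true(all(r1$roav >= 0))
  # single-compound matrix: that compound is its own reference at 100
  one <- content_matrix(matrix(2, 1, 1, dimnames = list("s", "solo")))
  r3 <- compute_roav(one, c(solo = 0.01))
  expect_equal(unname(r3$roav[1, 1]), 100)
  expect_identical(unname(r3$reference), "solo")
})

test_that("ROAV input contracts are enforced", {
  cont <- tiny_content()
  expect_error(compute_roav(cont, c(alpha = 0.001, beta = 0.01)), "gamma")
  zero <- matrix(c(0, 0, 1, 1), 2, 2,
                 dimnames = list(c("s1", "s2"), c("a", "b")))
  zero["s1", ] <- 0
  expect_error(compute_roav(content_matrix(zero), c(a = 1, b = 1)),
               "no detected")
  # forcing a non-maximal reference pushes scores past 100 and warns
  expect_warning(compute_roav(cont, tiny_thresholds(), reference = "gamma"),
                 "above 100")
})

test_that("flavor tiers partition scores with boundaries assigned upward", {
  m <- matrix(c(1.0, 0.999, 0.1, 0.05, 0, 100), 1, 6,
              dimnames = list("s", paste0("c", 1:6)))
  cls <- classify_roav(m)
  tier_of <- function(cmp) as.character(cls$tier[cls$compound == cmp])
  expect_identical(tier_of("c1"), "key")
  expect_identical(tier_of("c2"), "modifier")
  expect_identical(tier_of("c3"), "modifier")
  expect_identical(tier_of("c4"), "weak")
  expect_identical(tier_of("c5"), "weak")
  expect_identical(tier_of("c6"), "key")
  expect_false(any(is.na(cls$tier)))
  expect_equal(nrow(cls), 6)
})

test_that("key-compound selection reproduces the published nine-compound set", {
  r <- compute_roav(mrp_content(), mrp_compounds())
  with_ref <- select_key_compounds(r, "MRPs A", exclude_reference = FALSE)
  expect_length(with_ref, 10)
  keys <- select_key_compounds(r, "MRPs A")
  expect_identical(keys, mrp_validation()$compound)
  expect_error(select_key_compounds(r, "MRPs Z"), "unknown sample")
  # a matrix with no key compounds yields an empty selection
  low <- compute_roav(tiny_content(), c(alpha = 1, beta = 1, gamma = 1))
  low$roav[] <- pmin(low$roav, 0.5)
  expect_length(select_key_compounds(low, "s1", exclude_reference = FALSE), 0)
})

test_that("class tallies sum to the record count and handle empties", {
  expect_length(tally_classes(compound_table(character(0), numeric(0))), 0)
  tab <- compound_table(c("Hexanal", "Hexanoic acid", "Phenol"), c(1, 1, 1))
  tal <- tally_classes(tab)
  expect_equal(sum(tal), 3)
  expect_equal(unname(tal["aldehyde"]), 1L)
})

test_that("the max-FD query finds the most dilution-robust odorant", {
  cmps <- mrp_compounds()
  q <- max_fd_query(mrp_fd(), stats::setNames(cmps$retention_index, cmps$name))
  expect_identical(q$compound, "2-Ethyl-3,5-dimethylpyrazine")
  expect_equal(q$min_fd, 81)
  expect_equal(q$max_fd, 243)

  one <- fd_matrix(matrix(3, 1, 1, dimnames = list("s", "solo")))
  expect_equal(max_fd_query(one), list(compound = "solo", min_fd = 3,
                                       max_fd = 3))
  allnd <- fd_matrix(matrix(NA_real_, 1, 2,
                            dimnames = list("s", c("a", "b"))))
  expect_error(max_fd_query(allnd), "no detected")
})

test_that("max-FD ties break toward the lower retention index", {
  # brute-force oracle over a permuted two-way tie
  m <- matrix(c(9, 9, 9, 9, 3, 3), 2, 3,
              dimnames = list(c("s1", "s2"), c("late", "early", "weak")))
  ri <- c(late = 1500, early = 1200, weak = 1000)
  for (perm in list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))) {
    q <- max_fd_query(fd_matrix(m[, perm]), ri)
    # oracle: among argmax of column minima, smallest retention index
    mins <- apply(m[, perm], 2, min)
    tied <- names(mins)[mins == max(mins)]
    expect_identical(q$compound, tied[which.min(ri[tied])])
    expect_identical(q$compound, "early")
  }
})
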