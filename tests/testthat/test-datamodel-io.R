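test_that("packaged tables load with the documented shapes and spot values", {
  cmps <- mrp_compounds()
  expect_s3_class(cmps, "compound_table")
  expect_equal(nrow(cmps), 30)
  expect_equal(cmps$odor_threshold[cmps$name == "Octanal"], 0.0004)
  expect_equal(cmps$retention_index[cmps$name == "Octanal"], 1291L)
  expect_true(all(cmps$odor_threshold > 0))

  cont <- mrp_content()
  expect_equal(dim(cont$values), c(5, 30))
  expect_equal(cont$values["MRPs C", "(E)-2-Octenal"], 6.38)
  expect_equal(cont$sds["MRPs C", "(E)-2-Octenal"], 0.05)
  expect_true(all(cont$values >= 0))
  expect_true(all(rowSums(cont$values) <= 100))
  # a cell printed as "0.00 ± 0.00" reads as a clean zero (not detected)
  expect_identical(cont$values["MRPs A", "Butanoic acid"], 0)

  fd <- mrp_fd()
  det <- fd$fd[!is.na(fd$fd)]
  expect_true(all(det %in% 3^(0:5)))
  expect_true(is.na(fd$fd["MRPs A", "Butanoic acid"]))

  dh <- mrp_dh_series()
  expect_equal(dh$time_h, c(0, 2, 4, 6, 8))
  expect_equal(dh$dh, c(0, 9.40, 11.93, 14.32, 14.77))
})

test_that("suffix rules classify the fixture compounds to the published tallies", {
  cmps <- mrp_compounds()
  derived <- classify_compound(cmps$name)
  # stored classes are exactly what the rules derive
  expect_identical(derived, cmps$chem_class)
  tal <- tally_classes(cmps)
  expect_equal(sum(tal), 30)
  expect_equal(unname(tal[c("aldehyde", "acid", "alcohol", "pyrazine")]),
               c(13L, 6L, 3L, 3L))
  expect_equal(unname(tal[c("furan", "ketone", "phenol", "ester")]),
               c(1L, 1L, 2L, 1L))
  # the phenol/alcohol and aldehyde/sulfur rule orderings that make the
  # tallies come out right
  expect_identical(classify_compound("p-Cresol"), "phenol")
  expect_identical(classify_compound("3-(Methylthio)propanal"), "aldehyde")
  expect_identical(classify_compound("Benzene acetaldehyde"), "aldehyde")
  expect_identical(classify_compound("unobtainium"), "other")
  expect_error(classify_compound("  "), "non-empty")
})

test_that("compound-table reader enforces schema and parses thresholds", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tclass\tri\tthreshold_ugkg\tdescriptors",
               "Octanal\t\t1291\t0.0004\tfatty",
               "Hexanal\taldehyde\t1087\t0.0011\tgreen; grassy"), path)
  tab <- read_compound_table(path)
  expect_equal(nrow(tab), 2)
  expect_identical(tab$chem_class, c("aldehyde", "aldehyde"))
  expect_equal(tab$odor_threshold, c(0.0004, 0.0011))
  expect_identical(tab$descriptors[[2]], c("green", "grassy"))

  writeLines("name\tthreshold_ugkg", path)
  expect_equal(nrow(read_compound_table(path)), 0)

  writeLines(c("name\tthreshold_ugkg", "Octanal\t0"), path)
  expect_error(read_compound_table(path), "> 0")
  writeLines(c("name\tthreshold_ugkg", "Octanal\tabc"), path)
  expect_error(read_compound_table(path), "threshold_ugkg")
  writeLines(c("name\tthreshold_ugkg", "Octanal\t0.1", "octanal\t0.2"), path)
  expect_error(read_compound_table(path), "duplicate")
})

test_that("content matrices round-trip through disk exactly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  v <- matrix(c(1.234567, 0, 3.14159, 2.5), 2, 2,
              dimnames = list(c("a", "b"), c("c1", "c2")))
  s <- matrix(c(0.1, 0, 0.25, 0.125), 2, 2, dimnames = dimnames(v))
  cm <- content_matrix(v, s)
  write_content_matrix(cm, path)
  back <- read_content_matrix(path)
  expect_identical(back$values, cm$values)
  expect_identical(back$sds, cm$sds)

  cm2 <- content_matrix(v)
  write_content_matrix(cm2, path)
  expect_identical(read_content_matrix(path)$values, v)
  expect_null(read_content_matrix(path)$sds)

  # the full fixture also survives a round trip
  cont <- mrp_content()
  write_content_matrix(cont, path)
  expect_identical(read_content_matrix(path)$values, cont$values)
})

test_that("content validation refuses negatives and over-100% shares", {
  v <- matrix(c(-1, 2), 1, 2, dimnames = list("s", c("a", "b")))
  expect_error(content_matrix(v), ">= 0")
  v2 <- matrix(c(60, 43), 1, 2, dimnames = list("s", c("a", "b")))
  expect_error(content_matrix(v2), "100")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound\ts1", "a\t1.0x"), path)
  expect_error(read_content_matrix(path), "malformed number.*row a.*column s1")
})

test_that("FD matrices accept ND and powers of three only", {
  m <- matrix(c(1, 3, NA, 81), 2, 2,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_s3_class(fd_matrix(m), "fd_matrix")
  m[1, 1] <- 5
  expect_error(fd_matrix(m), "power of 3")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound\ts1\ts2", "a\tND\t9", "b\t27\tnd"), path)
  fd <- read_fd_matrix(path)
  expect_identical(is.na(fd$fd["s1", "a"]), TRUE)
  expect_identical(is.na(fd$fd["s2", "b"]), TRUE)
  expect_equal(fd$fd["s2", "a"], 9)
})

test_that("compound names are canonicalized across spelling variants", {
  expect_identical(canonical_compound_name("2-Pentyl- furan"), "2-Pentylfuran")
  expect_identical(canonical_compound_name("(E)-2-nonanal"), "(E)-2-Nonenal")
  expect_identical(canonical_compound_name("  Benzene   acetaldehyde "),
                   "Benzene acetaldehyde")
})

test_that("sensory records enforce their scales", {
  r <- sensory_record("MRPs C", 2, 1, 3, 2, 1, 8, overall_acceptability = 4.2)
  expect_s3_class(r, "sensory_record")
  expect_error(sensory_record("x", 11, 1, 1, 1, 1, 1, 3), "\\[0, 10\\]")
  expect_error(sensory_record("x", 1, 1, 1, 1, 1, 1, 0.5), "\\[1, 5\\]")
})
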