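test_that("XML records parse with missing values and T->U normalization", {
  path <- writeFixtureXML(list(
    list(id = "tx1", sequence = "ACGU", reactivity = "0.1,NaN,2.3,0.0"),
    list(id = "tx2", sequence = "ACGT", reactivity = "0.0,0.1,0.2,0.3")))
  profiles <- readRNAFrameworkXML(path)
  expect_length(profiles, 2L)
  expect_identical(length(profiles[[1L]]), 4L)
  expect_identical(reactivity(profiles[[1L]]), c(0.1, NA, 2.3, 0))
  expect_identical(profileSequence(profiles[[2L]]), "ACGU")
})

test_that("XML whitespace inside sequence/reactivity blocks is ignored", {
  path <- writeFixtureXML(list(
    list(id = "tx1", sequence = "AC\nGU", reactivity = "0.1, 0.2,\n0.3,0.4")))
  p <- readRNAFrameworkXML(path)[[1L]]
  expect_identical(profileSequence(p), "ACGU")
  expect_identical(reactivity(p), c(0.1, 0.2, 0.3, 0.4))
})

test_that("malformed records fail loudly, naming the record", {
  path <- writeFixtureXML(list(
    list(id = "bad1", sequence = "ACGUA", reactivity = "0.1,0.2,0.3,0.4")))
  expect_error(readRNAFrameworkXML(path), "bad1")
  path <- writeFixtureXML(list(
    list(id = "bad2", sequence = "ACGU", reactivity = "0.1,-0.2,0.3,0.4")))
  expect_error(readRNAFrameworkXML(path), "negative")
  path <- writeFixtureXML(list(
    list(id = "bad3", sequence = "ACGU", reactivity = "0.1,oops,0.3,0.4")))
  expect_error(readRNAFrameworkXML(path), "position 2")
})

test_that("profiles reject ambiguity codes other than N", {
  expect_error(reactivityProfile("x", "ACGR", c(1, 1, 1, 1)), "invalid base")
  expect_silent(validObject(reactivityProfile("x", "ACGN", c(1, 1, 1, 1))))
})

test_that("TSV fallback parses the same content as XML", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "tx1\tACGT\t0.1,NaN,2.3,0.0"), tsv)
  p <- readReactivityTSV(tsv)[[1L]]
  expect_identical(profileSequence(p), "ACGU")
  expect_identical(reactivity(p), c(0.1, NA, 2.3, 0))
})

test_that("capping clamps values, preserves missing, and is idempotent", {
  expect_identical(capReactivity(c(0.2, 1.7, NA), 1), c(0.2, 1, NA))
  expect_identical(capReactivity(c(0, 0.5), 1.5), c(0, 0.5))
  expect_identical(capReactivity(c(3, 3, 3), 1), c(1, 1, 1))
  p <- reactivityProfile("x", "ACG", c(0.2, 5, NA))
  capped <- capReactivity(p, 1)
  expect_identical(reactivity(capped), c(0.2, 1, NA))
  expect_identical(reactivity(p), c(0.2, 5, NA))  # input unmodified
  expect_identical(reactivity(capReactivity(capped, 1)),
                   reactivity(capped))
})

test_that("database round trip is bit-exact including missing values", {
  p1 <- reactivityProfile("a", "ACGUN", c(0.123456789012345, NA, 1/3, 0, 2))
  p2 <- reactivityProfile("b", "GGCC", c(0.5, 0.6, 0.7, 0.8))
  db <- profileDatabase(list(p1, p2))
  path <- tempfile()
  writeProfileDb(db, path)
  back <- loadProfileDb(path)
  expect_identical(length(back), 2L)
  expect_identical(dbKind(back), dbKind(db))
  for (i in 1:2) {
    expect_identical(profileID(back[[i]]), profileID(db[[i]]))
    expect_identical(profileSequence(back[[i]]), profileSequence(db[[i]]))
    expect_identical(reactivity(back[[i]]), reactivity(db[[i]]))
  }
  expect_identical(totalLength(back), totalLength(db))
})

test_that("empty databases round trip and invalid files are rejected", {
  path <- tempfile()
  writeProfileDb(profileDatabase(list()), path)
  expect_identical(length(loadProfileDb(path)), 0L)
  writeLines("not a database", path)
  expect_error(loadProfileDb(path), "shapesearchdb")
  writeLines("#shapesearchdb v999 kind=shape-reactivity", path)
  expect_error(loadProfileDb(path), "version")
})

test_that("duplicated entry ids are rejected", {
  p <- reactivityProfile("dup", "ACGU", c(1, 1, 1, 1))
  expect_error(profileDatabase(list(p, p)), "duplicated")
  path <- tempfile()
  writeLines(c("#shapesearchdb v1 kind=shape-reactivity",
               ">dup", "ACGU", "1,1,1,1", ">dup", "ACGU", "1,1,1,1"), path)
  expect_error(loadProfileDb(path), "duplicated")
})

test_that("base-pairing-probability databases must stay within [0,1]", {
  p <- reactivityProfile("x", "ACGU", c(0.1, 0.9, 1.2, 0))
  expect_error(profileDatabase(list(p), kind = "base-pairing-probability"),
               "<= 1")
  expect_silent(validObject(profileDatabase(
    list(reactivityProfile("x", "ACGU", c(0.1, 0.9, 1, NA))),
    kind = "base-pairing-probability")))
})

test_that("shuffled-database provenance survives the round trip", {
  db <- profileDatabase(list(structuredProfile(60, "e1")))
  sh <- buildShuffledDb(db, shuffleParams(n_shuffles = 3L), seed = 9L)
  path <- tempfile()
  writeProfileDb(sh, path)
  back <- loadProfileDb(path)
  expect_true(back@shuffled)
  expect_identical(back@seed, 9L)
})
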