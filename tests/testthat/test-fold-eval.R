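.toyAlignment <- function() {
  profileAlignment(
    ids = c("q", "t"),
    sequences = c("GGGAAACCC", "GGAAAAACC"),
    reactivities = list(c(0.1, 0.1, 0.2, 0.9, 1.0, 0.8, 0.1, 0.2, 0.1),
                        c(0.2, 0.1, 0.1, 0.8, 0.9, 0.9, 0.2, 0.1, 0.1)))
}

test_that("the injected engine's structure and energy are carried verbatim", {
  aln <- .toyAlignment()
  engine <- mockFoldEngine("(((...)))", -10)
  fe <- withr::with_seed(1, evaluateFold(aln, engine, n_shuffles = 10L))
  expect_identical(fe@structure, "(((...)))")
  expect_equal(fe@energy, -10)
})

test_that("all-gap alignments are rejected as degenerate", {
  aln <- profileAlignment(c("a", "b"), c("---", "AC-"),
                          list(rep(NA_real_, 3), c(0.1, 0.2, NA)))
  engine <- mockFoldEngine("...", -1)
  expect_error(engine(aln), "degenerate")
})

test_that("column-block shuffling preserves columns and degapped rows", {
  aln <- .toyAlignment()
  withr::with_seed(2, {
    sh <- shuffleAlignment(aln, block = 3L)
    colkey <- function(a) {
      chars <- strsplit(a@sequences, "")
      sort(vapply(seq_len(ncol(a)), function(j)
        paste(c(vapply(chars, `[`, character(1), j),
                vapply(a@reactivities, `[`, numeric(1), j)),
              collapse = "|"), character(1)))
    }
    expect_identical(colkey(sh), colkey(aln))
  })
  # gapped rows stay synchronized: degapping reproduces original content
  gappy <- profileAlignment(c("a", "b"), c("AC-GU", "A-CGU"),
                            list(c(0.1, 0.2, NA, 0.3, 0.4),
                                 c(0.5, NA, 0.6, 0.7, 0.8)))
  withr::with_seed(3, {
    sh <- shuffleAlignment(gappy, block = 2L)
    degap <- function(a, i) {
      b <- strsplit(a@sequences[[i]], "")[[1]]
      paste(sort(paste(b[b != "-"], a@reactivities[[i]][b != "-"])),
            collapse = ";")
    }
    expect_identical(degap(sh, 1), degap(gappy, 1))
    expect_identical(degap(sh, 2), degap(gappy, 2))
  })
  # a 3-column alignment is a single block: output is a permutation
  three <- profileAlignment(c("a", "b"), c("ACG", "ACG"),
                            list(c(1, 2, 3), c(4, 5, 6)))
  withr::with_seed(4, {
    sh <- shuffleAlignment(three, block = 3L)
    expect_setequal(sh@reactivities[[1]], c(1, 2, 3))
  })
  # determinism
  s1 <- withr::with_seed(5, shuffleAlignment(aln))
  s2 <- withr::with_seed(5, shuffleAlignment(aln))
  expect_identical(s1@sequences, s2@sequences)
})

test_that("energy Z-scores and p-values match the closed forms", {
  aln <- .toyAlignment()
  # true energy -20; deterministic alternating null energies chosen so the
  # sample mean is exactly -10 and the sample sd exactly 2 over 100 draws
  a <- sqrt(4 * 99 / 100)
  null_pool <- c(-10 - a, -10 + a)
  mkEngine <- function(true_energy, counter) {
    mockFoldEngine("(((...)))", energy_fn = function(x) {
      counter$i <- counter$i + 1L
      if (counter$i == 1L) true_energy
      else null_pool[(counter$i %% 2L) + 1L]
    })
  }
  c1 <- new.env(); c1$i <- 0L
  fe <- withr::with_seed(6, evaluateFold(aln, mkEngine(-20, c1),
                                         n_shuffles = 100L))
  expect_equal(mean(fe@null_energies), -10)
  expect_equal(sd(fe@null_energies), 2, tolerance = 1e-12)
  expect_equal(fe@z, -5, tolerance = 1e-12)
  expect_equal(fe@p_value, 2.866516e-07, tolerance = 1e-6)
  expect_equal(fe@p_value, pnorm(-5))
  # true energy equal to the null mean: z = 0, p = 0.5
  c2 <- new.env(); c2$i <- 0L
  fe2 <- withr::with_seed(7, evaluateFold(aln, mkEngine(-10, c2),
                                          n_shuffles = 100L))
  expect_equal(fe2@z, 0, tolerance = 1e-12)
  expect_equal(fe2@p_value, 0.5, tolerance = 1e-12)
  # zero-variance null is degenerate: p = 1
  fe3 <- withr::with_seed(8, evaluateFold(aln, mockFoldEngine("..(...)..", -5),
                                          n_shuffles = 20L))
  expect_equal(fe3@p_value, 1)
  # z is invariant to shifting all energies by a constant
  c3 <- new.env(); c3$i <- 0L
  shift <- 7.5
  eng_shift <- mockFoldEngine("(((...)))", energy_fn = function(x) {
    c3$i <- c3$i + 1L
    (if (c3$i == 1L) -20 else null_pool[(c3$i %% 2L) + 1L]) + shift
  })
  fe4 <- withr::with_seed(6, evaluateFold(aln, eng_shift, n_shuffles = 100L))
  expect_equal(fe4@z, fe@z, tolerance = 1e-9)
})

test_that("base-pair support counts canonical pairs per row", {
  aln <- .toyAlignment()  # rows GGGAAACCC / GGCAAAGCC
  sup <- bpSupport("(((...)))", aln)
  expect_equal(sup[[1]], 1)     # GC, GC, GC all canonical
  expect_equal(sup[[2]], 2 / 3) # GC, GC ok; (3,7) = A-A breaks
  expect_equal(bpSupport("(((...)))",
                         profileAlignment(c("a", "b"),
                                          c("GGGAAACCC", "GGGAAACCC"),
                                          list(rep(0.5, 9), rep(0.5, 9)))),
               c(1, 1))
  # a row breaking 2 of 4 pairs has support 0.5
  a4 <- profileAlignment(c("a", "b"),
                         c("GGGGAAAACCCC", "GGAAAAAAAACC"),
                         list(rep(0.5, 12), rep(0.5, 12)))
  expect_equal(bpSupport("((((....))))", a4), c(1, 0.5))
  # gaps and N are never canonical
  an <- profileAlignment(c("a", "b"), c("GAC", "N-C"),
                         list(rep(0.5, 3), c(0.5, NA, 0.5)))
  expect_equal(bpSupport("(.)", an), c(1, 0))
  # zero-pair structures have undefined support
  expect_true(all(is.nan(bpSupport("...", an))))
})

test_that("the retention gate enforces p < 0.05 and support >= 0.75 exactly", {
  mk <- function(p, sup) new("FoldEvaluation", structure = "((..))",
                             energy = -5, null_energies = numeric(0),
                             z = 0, p_value = p, bp_support = sup)
  expect_true(retainFold(mk(0.049, c(1, 0.75))))
  expect_false(retainFold(mk(0.05, c(1, 1))))       # p gate is strict
  expect_false(retainFold(mk(0.2, c(1, 1))))        # perfect support, bad p
  expect_false(retainFold(mk(0.01, c(1, 0.74))))    # min over rows
  expect_true(retainFold(mk(0.01, c(0.8, 0.74)), aggregate = "mean"))
  expect_false(retainFold(mk(0.01, c(NaN, NaN))))   # no pairs: never retained
  # monotone: lowering p or raising support never flips retained -> rejected
  expect_true(retainFold(mk(0.001, c(1, 0.9))))
  expect_true(retainFold(mk(0.0001, c(1, 1))))
})

test_that("fold evaluations round-trip into Stockholm with SS_cons", {
  aln <- .toyAlignment()
  path <- tempfile(fileext = ".stk")
  writeStockholm(aln, path, structure = "(((...)))")
  lines <- readLines(path)
  expect_identical(lines[[1]], "# STOCKHOLM 1.0")
  expect_match(lines[grepl("SS_cons", lines)], "\\(\\(\\(\\.\\.\\.\\)\\)\\)")
  expect_identical(lines[[length(lines)]], "//")
})

test_that("the RNAalifold adapter folds a perfect hairpin", {
  # both rows support a 4-bp stem with a 4-nt loop
  aln <- profileAlignment(
    ids = c("q", "t"),
    sequences = c("GGGGAAAACCCC", "GGGGAAAACCCC"),
    reactivities = list(c(rep(0.05, 4), rep(0.9, 4), rep(0.05, 4)),
                        c(rep(0.1, 4), rep(0.8, 4), rep(0.1, 4))))
  engine <- rnaalifoldEngine(slope = 1.0, intercept = -0.4)
  res <- engine(aln)
  expect_identical(nchar(res$structure), 12L)
  pairs <- shapesearch:::.parsePairs(res$structure)
  expect_gte(nrow(pairs), 1L)
  expect_true(is.finite(res$energy))
  expect_lt(res$energy, 0)
})

test_that("search alignments render into foldable profile alignments", {
  withr::with_seed(81, {
    q <- randomProfile(120, "q")
    copy <- reactivityProfile("copy", profileSequence(q), reactivity(q))
    hsg <- list(query_start = 20L, query_end = 60L, db_start = 20L,
                db_end = 60L)
    r <- extendHSG(q, copy, hsg)
    pa <- alignmentToProfileAlignment(r, q, copy)
    expect_identical(ncol(pa), 120L)
    expect_identical(gsub("-", "", pa@sequences[[1]]),
                     profileSequence(q))
    fe <- evaluateFold(pa, mockFoldEngine(strrep(".", 120), -3),
                       n_shuffles = 5L)
    expect_s4_class(fe, "FoldEvaluation")
  })
})
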