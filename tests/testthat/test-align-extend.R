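test_that("column scores reproduce the printed endpoints and interpolation", {
  p <- alignParams()  # SHAPE defaults: match (-0.5, 2), mismatch (-6, -0.5)
  expect_equal(scoreColumn(0.4, 0.4, params = p), 2)       # d = 0
  expect_equal(scoreColumn(0, 1, params = p), -6)          # d = max_reactivity
  expect_equal(scoreColumn(0.5, 0.25, params = p), 0.75)   # 2 - 0.5*2.5
  expect_equal(scoreColumn(0.5, 0, params = p), -0.5)      # boundary d = t
  expect_equal(scoreColumn(NA, 0.3, params = p), 0)
  expect_equal(scoreColumn(0.3, NA, params = p), 0)
})

test_that("sequence scoring adds the identity bonus and penalty", {
  p <- alignParams(seq_scoring = TRUE)
  expect_equal(scoreColumn(0.4, 0.4, "A", "A", p), 2.5)
  expect_equal(scoreColumn(0.4, 0.4, "A", "C", p), 0)
  expect_equal(scoreColumn(0.4, 0.4, "N", "N", p), 0)  # N never matches
})

test_that("self-alignment saturates the match score over the full length", {
  q <- structuredProfile(60, "q", seed = 51)
  hsg <- list(query_start = 10L, query_end = 40L, db_start = 10L,
              db_end = 40L)
  r <- extendHSG(q, q, hsg)
  expect_equal(r@score, 60 * 2)
  expect_identical(c(r@query_start, r@query_end), c(0L, 60L))
  expect_identical(c(r@db_start, r@db_end), c(0L, 60L))
  expect_true(all(r@columns$state == "pair"))
  expect_equal(alignmentScore(r, q, q), r@score)
})

test_that("an insertion in the database copy yields one affine gap run", {
  withr::with_seed(52, {
    # 20 matched columns past the insertion out-earn the gap penalty
    # (gap_open + gap_ext = -19 < 20 * match_max), so the optimal path
    # crosses the insertion with exactly one two-column gap run
    q <- randomProfile(30, "q")
    qseq <- strsplit(profileSequence(q), "")[[1]]
    eseq <- c(qseq[1:10], "A", "C", qseq[11:30])
    ere <- c(reactivity(q)[1:10], 0.1, 0.9, reactivity(q)[11:30])
    e <- reactivityProfile("e", paste(eseq, collapse = ""), ere)
    hsg <- list(query_start = 0L, query_end = 4L, db_start = 0L,
                db_end = 4L)
    params <- alignParams(band_fraction = 1)
    r <- extendHSG(q, e, hsg, params, disable_dropoff = TRUE)
    gaps <- r@columns$state[r@columns$state != "pair"]
    expect_identical(gaps, c("gap_query", "gap_query"))
    expect_equal(alignmentScore(r, q, e, params), r@score)
    expect_equal(r@score, extendOracle(q, e, hsg, params))
  })
})

test_that("full-band extension equals the exhaustive unbanded DP oracle", {
  withr::with_seed(53, {
    params <- alignParams(band_fraction = 1)
    for (i in 1:20) {
      n <- sample(8:14, 1)
      q <- randomProfile(n, "q")
      e <- randomProfile(sample(8:14, 1), "e")
      hsg <- list(query_start = 0L, query_end = 3L, db_start = 0L,
                  db_end = 3L)
      r <- extendHSG(q, e, hsg, params, disable_dropoff = TRUE)
      expect_equal(r@score, extendOracle(q, e, hsg, params),
                   tolerance = 1e-12)
      expect_equal(alignmentScore(r, q, e, params), r@score,
                   tolerance = 1e-12)
    }
  })
})

test_that("score is symmetric under swapping query and database", {
  withr::with_seed(54, {
    for (i in 1:10) {
      q <- randomProfile(30, "q")
      e <- randomProfile(34, "e")
      hsg <- list(query_start = 5L, query_end = 15L, db_start = 7L,
                  db_end = 17L)
      swapped <- list(query_start = 7L, query_end = 17L, db_start = 5L,
                      db_end = 15L)
      expect_equal(extendHSG(q, e, hsg)@score,
                   extendHSG(e, q, swapped)@score, tolerance = 1e-12)
    }
  })
})

test_that("sequence scoring never lowers the score of identical sequences", {
  withr::with_seed(55, {
    q <- randomProfile(50, "q")
    e <- reactivityProfile("e", profileSequence(q),
                           pmax(reactivity(q) + rnorm(50, 0, 0.1), 0))
    hsg <- list(query_start = 10L, query_end = 30L, db_start = 10L,
                db_end = 30L)
    plain <- extendHSG(q, e, hsg, alignParams())@score
    seq <- extendHSG(q, e, hsg, alignParams(seq_scoring = TRUE))@score
    expect_gte(seq, plain)
  })
})

test_that("missing-only flanks contribute 0 and are excluded from the interval", {
  withr::with_seed(56, {
    core <- randomProfile(40, "core")
    naflank <- function(n) rep(NA_real_, n)
    q <- reactivityProfile("q", paste0(strrep("A", 15),
                                       profileSequence(core),
                                       strrep("A", 15)),
                           c(naflank(15), reactivity(core), naflank(15)))
    e <- reactivityProfile("e", profileSequence(q), reactivity(q))
    hsg <- list(query_start = 25L, query_end = 45L, db_start = 25L,
                db_end = 45L)
    r <- extendHSG(q, e, hsg)
    # the reported interval stops at the real signal's edge on both sides
    expect_identical(c(r@query_start, r@query_end), c(15L, 55L))
    expect_equal(r@score, 40 * 2)
  })
})

test_that("extension stops near the homology boundary against anti-correlated noise", {
  withr::with_seed(57, {
    q <- randomProfile(80, "q")
    # db copy of the first 40 bases, then a tail anti-correlated with q
    tail_re <- capReactivity(1 - capReactivity(reactivity(q)[41:80], 1), 1)
    e <- reactivityProfile("e", profileSequence(q),
                           c(reactivity(q)[1:40], tail_re))
    hsg <- list(query_start = 5L, query_end = 25L, db_start = 5L,
                db_end = 25L)
    params <- alignParams()
    r <- extendHSG(q, e, hsg, params)
    margin <- params@max_dropoff_bases + 10L  # drop-off window + band floor
    expect_lte(r@query_end, 40L + margin)
    expect_gte(r@query_end, 38L)  # reaches (about) the boundary
  })
})

test_that("degenerate HSGs are rejected", {
  q <- structuredProfile(30, "q", seed = 58)
  expect_error(extendHSG(q, q, list(query_start = 5L, query_end = 5L,
                                    db_start = 5L, db_end = 5L)),
               "degenerate")
  expect_error(extendHSG(q, q, list(query_start = 0L, query_end = 4L,
                                    db_start = 0L, db_end = 5L)),
               "equal length")
})

test_that("overlapping alignments from different seeds are deduplicated", {
  q <- structuredProfile(80, "q", seed = 59)
  db <- profileDatabase(list(reactivityProfile(
    "copy", profileSequence(q), reactivity(q))))
  m <- matchKmers(q, db)
  h <- groupHSGs(m)
  expect_gt(nrow(h), 0L)
  alns <- lapply(seq_len(nrow(h)), function(r)
    extendHSG(q, db[[1L]], h[r, ]))
  kept <- shapesearch:::.dedupAlignments(alns)
  expect_lte(length(kept), length(alns))
  # the best-scoring full-length self-alignment survives
  expect_equal(max(vapply(kept, function(a) a@score, numeric(1))), 80 * 2)
})
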