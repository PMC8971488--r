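test_that("gini matches closed forms and the pairwise oracle", {
  expect_equal(giniCoefficient(rep(1, 4)), 0)
  expect_equal(giniCoefficient(c(0, 0, 0, 1)), 0.75)  # one-hot: (n-1)/n
  withr::with_seed(11, {
    for (i in 1:50) {
      x <- runif(15)
      expect_equal(giniCoefficient(x), giniOracle(x), tolerance = 1e-12)
    }
  })
})

test_that("gini is scale-invariant and flags uncomputable input", {
  withr::with_seed(12, {
    x <- runif(10)
    for (c in c(0.01, 3, 1e6))
      expect_equal(giniCoefficient(c * x), giniCoefficient(x),
                   tolerance = 1e-12)
  })
  expect_true(is.na(giniCoefficient(c(0, 0, 0))))
  expect_true(is.na(giniCoefficient(c(1, NA, 2))))
})

test_that("kmer enumeration applies complexity, variance and missingness rules", {
  params <- seedParams()
  flat <- reactivityProfile("flat", strrep("A", 30), rep(0.5, 30))
  expect_length(enumerateQueryKmers(flat, params)$starts, 0L)
  alt <- reactivityProfile("alt", strrep("A", 30), rep(c(0, 1), 15))
  # Gini of every alternating 15-window exceeds the 0.3 cutoff
  expect_true(giniOracle(rep(c(0, 1), length.out = 15)) > 0.3)
  expect_identical(enumerateQueryKmers(alt, params)$starts, 0:15)
  vals <- rep(c(0, 1), 15)
  vals[8] <- NA  # 0-based index 7
  miss <- reactivityProfile("miss", strrep("A", 30), vals)
  expect_identical(enumerateQueryKmers(miss, params)$starts, 8:15)
  short <- reactivityProfile("short", strrep("A", 10), rep(c(0, 1), 5))
  expect_length(enumerateQueryKmers(short, params)$starts, 0L)
})

test_that("MASS distances match the naive z-normalization oracle", {
  withr::with_seed(21, {
    for (i in 1:25) {
      k <- sample(5:12, 1)
      m <- sample(20:60, 1)
      kmer <- runif(k)
      entry <- runif(m)
      expect_equal(massDistanceProfile(kmer, entry), massOracle(kmer, entry),
                   tolerance = 1e-9)
    }
  })
})

test_that("MASS distance is zero at planted and affine-transformed offsets", {
  withr::with_seed(22, {
    kmer <- runif(10)
    entry <- c(runif(5), kmer, runif(5), 2 * kmer + 0.3, runif(3))
    d <- massDistanceProfile(kmer, entry)
    expect_lt(d[6], 1e-6)   # verbatim copy
    expect_lt(d[21], 1e-6)  # z-normalization is affine-invariant
  })
})

test_that("MASS handles unmatchable windows and degenerate kmers", {
  kmer <- c(0, 1, 0, 1)
  entry <- c(0, 1, 0, 1, NA, 1, 0.5, 0.5, 0.5, 0.5, 0, 1)
  d <- massDistanceProfile(kmer, entry)
  expect_lt(d[1], 1e-6)
  expect_true(all(is.infinite(d[2:5])))          # windows covering the NA
  expect_true(is.finite(d[6]))
  expect_true(is.infinite(d[7]))                 # zero-variance window
  expect_error(massDistanceProfile(rep(0.5, 4), entry), "variance")
})

test_that("a verbatim planted kmer is found exactly once", {
  withr::with_seed(31, {
    q <- randomProfile(40, "q")
    entry <- randomProfile(400, "t1")
    # plant the query's first valid kmer at db offset 100
    qk <- enumerateQueryKmers(q)$starts[1]
    seqs <- strsplit(c(profileSequence(q), profileSequence(entry)), "")
    eb <- seqs[[2]]
    eb[101:115] <- seqs[[1]][(qk + 1):(qk + 15)]
    er <- reactivity(entry)
    er[101:115] <- reactivity(q)[(qk + 1):(qk + 15)]
    entry <- reactivityProfile("t1", paste(eb, collapse = ""), er)
    db <- profileDatabase(list(entry))
    m <- matchKmers(q, db)
    planted <- m[m$query_start == qk & m$db_start == 100, ]
    expect_identical(nrow(planted), 1L)
    expect_lt(planted$znorm_distance, 1e-6)
    expect_equal(planted$gc_diff, 0)
  })
})

test_that("every reported match satisfies the distance and GC bounds", {
  withr::with_seed(32, {
    q <- randomProfile(100, "q")
    db <- profileDatabase(list(randomProfile(800, "t1"),
                               randomProfile(500, "t2")))
    params <- seedParams()
    m <- matchKmers(q, db, params)
    expect_gt(nrow(m), 0L)
    expect_true(all(m$znorm_distance <=
                      params@dist_coeff * sqrt(params@kmer_len)))
    expect_true(all(m$gc_diff <= params@max_gc_diff))
  })
})

test_that("matches with deviating GC content are discarded", {
  # same reactivities (distance 0) but GC 60% vs 20% in the matched window
  re <- rep(c(0, 1), length.out = 15)
  q <- reactivityProfile("q", "GCGCGCGCGAUAUAU", re)       # GC 60%
  t <- reactivityProfile("t", "AUAUAUAUAUAUGCG", re)       # GC 20%
  m <- matchKmers(q, profileDatabase(list(t)),
                  seedParams(max_gc_diff = 10))
  expect_identical(nrow(m), 0L)
  m2 <- matchKmers(q, profileDatabase(list(t)),
                   seedParams(max_gc_diff = NA))
  expect_identical(nrow(m2), 1L)
})

test_that("promiscuous kmers are discarded entirely", {
  withr::with_seed(33, {
    q <- randomProfile(20, "q")
    qk <- enumerateQueryKmers(q)$starts[1]
    kseq <- substr(profileSequence(q), qk + 1, qk + 15)
    kre <- reactivity(q)[(qk + 1):(qk + 15)]
    # db of ~4000 nt carrying 30 copies of the kmer: limit is 4000/200 = 20
    pad <- function(n, id) randomProfile(n, id)
    blocks <- list()
    for (i in 1:30) {
      blocks[[i]] <- list(seq = kseq, re = kre)
    }
    spacer <- pad(4000 - 30 * 15, "sp")
    sseq <- profileSequence(spacer)
    sre <- reactivity(spacer)
    seqcat <- character(0); recat <- numeric(0)
    off <- 0
    gap <- floor((4000 - 30 * 15) / 30)
    for (i in 1:30) {
      seqcat <- c(seqcat, substr(sseq, off + 1, off + gap), kseq)
      recat <- c(recat, sre[(off + 1):(off + gap)], kre)
      off <- off + gap
    }
    entry <- reactivityProfile("t", paste(seqcat, collapse = ""), recat)
    db <- profileDatabase(list(entry))
    m <- matchKmers(q, db, seedParams(max_gc_diff = NA))
    expect_false(qk %in% m$query_start)
  })
})

test_that("HSG chaining follows the distance and membership rules", {
  params <- seedParams()  # max_kmer_dist 30, min_kmers 2
  mk <- function(qs, ds) data.frame(
    query_start = qs, db_entry_id = "t", db_start = ds,
    znorm_distance = 0, gc_diff = 0, stringsAsFactors = FALSE)
  h <- groupHSGs(mk(c(0L, 20L), c(5L, 25L)), params)
  expect_identical(nrow(h), 1L)
  expect_identical(h$n_kmers, 2L)
  expect_identical(h$query_start, 0L)
  expect_identical(h$query_end, 35L)
  expect_identical(h$db_start, 5L)
  expect_identical(h$db_end, 40L)
  # a 40-nt gap breaks the chain; two singletons fail min_kmers = 2
  expect_identical(nrow(groupHSGs(mk(c(0L, 40L), c(5L, 45L)), params)), 0L)
})

test_that("HSG grouping equals the exhaustive chaining oracle", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      n <- 50
      diag <- sample(c(-7L, 3L, 12L), n, replace = TRUE)
      qs <- sample(0L:300L, n, replace = TRUE)
      m <- data.frame(query_start = qs, db_entry_id = "t",
                      db_start = qs + diag, znorm_distance = 0, gc_diff = 0,
                      stringsAsFactors = FALSE)
      m <- m[!duplicated(m[c("query_start", "db_start")]), ]
      params <- seedParams()
      got <- groupHSGs(m, params)
      want <- chainOracle(m, params@max_kmer_dist, params@min_kmers,
                          params@kmer_len)
      got$members <- NULL
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  })
})

test_that("HSG memberships partition a subset of the input matches", {
  withr::with_seed(42, {
    q <- randomProfile(120, "q")
    db <- profileDatabase(list(randomProfile(1000, "t1")))
    m <- matchKmers(q, db)
    h <- groupHSGs(m)
    members <- unlist(h$members)
    expect_false(anyDuplicated(members) > 0)
    expect_true(all(members %in% seq_len(nrow(m))))
  })
})

test_that("self-search always seeds an HSG on diagonal zero", {
  withr::with_seed(43, {
    q <- randomProfile(150, "q")
    db <- profileDatabase(list(reactivityProfile(
      "copy", profileSequence(q), reactivity(q))))
    h <- groupHSGs(matchKmers(q, db))
    expect_true(any(h$diagonal == 0))
  })
})
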