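## Empirical extreme-value null: block-shuffled databases, null score
## collection, Gumbel fitting, p-values and E-values.

.EULER_GAMMA <- 0.57721566490153286

#' Block-shuffle a reactivity profile
#'
#' Partitions the profile into consecutive blocks of `block_size` bases (the
#' last block possibly shorter), permutes the block order uniformly at
#' random, and concatenates. Within-block order and the pairing of each base
#' with its reactivity are preserved, so local structural context survives
#' while long-range arrangement is destroyed — yielding a realistic null.
#'
#' @param profile a [ReactivityProfile-class].
#' @param block_size block size in nt (>= 1).
#' @return A shuffled [ReactivityProfile-class] (same id).
#' @export
blockShuffle <- function(profile, block_size = 10L) {
  stopifnot(block_size >= 1L)
  n <- length(profile)
  starts <- seq.int(1L, n, by = block_size)
  blocks <- lapply(starts, function(s) s:min(s + block_size - 1L, n))
  idx <- unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
  bases <- strsplit(profileSequence(profile), "", fixed = TRUE)[[1L]]
  reactivityProfile(profileID(profile), paste(bases[idx], collapse = ""),
                    reactivity(profile)[idx])
}

#' Build a shuffled (null) database
#'
#' For each entry and each of `n_shuffles` rounds: block-shuffle the entry,
#' then extract one uniformly placed contiguous chunk of length
#' `min(chunk_size, entry length)`. The output database carries
#' `n_shuffles * length(db)` entries with provenance-encoding ids
#' (`<id>|shuffle<i>`), is marked shuffled, and records the seed.
#'
#' @param db a [ProfileDatabase-class].
#' @param params a [ShuffleParams-class].
#' @param seed integer RNG seed (recorded in the output database header).
#' @return A shuffled [ProfileDatabase-class].
#' @export
buildShuffledDb <- function(db, params = shuffleParams(), seed = 1L) {
  stopifnot(length(db) > 0L)
  seed <- as.integer(seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- vector("list", length(db) * params@n_shuffles)
  pos <- 0L
  for (entry in db@entries) {
    for (i in seq_len(params@n_shuffles)) {
      sh <- blockShuffle(entry, params@block_size)
      len <- length(sh)
      cl <- min(params@chunk_size, len)
      start <- sample.int(len - cl + 1L, 1L)
      bases <- substr(profileSequence(sh), start, start + cl - 1L)
      pos <- pos + 1L
      out[[pos]] <- reactivityProfile(
        sprintf("%s|shuffle%d", profileID(sh), i), bases,
        reactivity(sh)[start:(start + cl - 1L)])
    }
  }
  profileDatabase(out, kind = db@kind, shuffled = TRUE, seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Batch score-only extension of the HSGs hitting one cached entry.
# Returns a data.frame with the total score and extended intervals per HSG.
.extendBatch <- function(qd, ce, hsgs, rows, params) {
  res <- .extendHSGsScore(
    qd$acap, ce$acap, qd$codes, ce$codes,
    hsgs$query_start[rows], hsgs$query_end[rows],
    hsgs$db_start[rows], hsgs$db_end[rows],
    params@match_min, params@match_max, params@mismatch_min,
    params@mismatch_max, params@gap_open, params@gap_ext,
    params@max_reactivity, params@seq_scoring, params@seq_match,
    params@seq_mismatch, params@max_dropoff_rate, params@max_dropoff_bases,
    params@band_fraction)
  data.frame(hsg_row = rows, score = res$score,
             query_start = res$query_start, query_end = res$query_end,
             db_start = res$db_start, db_end = res$db_end)
}

.collectNullScoresCached <- function(qd, cache, seed_params, align_params) {
  n_entries <- length(cache$entries)
  if (n_entries == 0L)
    stop("insufficient null trials: shuffled database is empty")
  scores <- rep(0, n_entries)
  matches <- .matchKmersCached(qd, cache, seed_params)
  if (nrow(matches) == 0L) return(scores)
  hsgs <- groupHSGs(matches, seed_params)
  if (nrow(hsgs) == 0L) return(scores)
  ei <- match(hsgs$db_entry_id, cache$ids)
  for (e in unique(ei)) {
    rows <- which(ei == e)
    ext <- .extendBatch(qd, cache$entries[[e]], hsgs, rows, align_params)
    scores[[e]] <- max(0, ext$score)
  }
  scores
}

#' Collect null alignment scores for a query window
#'
#' Runs the identical seed-and-extend stages (kmer matching, HSG grouping,
#' extension) for the query against every entry of a shuffled database and
#' records the best alignment score per shuffled entry; entries yielding no
#' HSG contribute the floor score 0 (skipping them would bias the null
#' upward).
#'
#' @param query a [ReactivityProfile-class] (typically one search window).
#' @param shuffled_db a shuffled [ProfileDatabase-class] built from the
#'   search database.
#' @param seed_params a [SeedParams-class].
#' @param align_params an [AlignParams-class].
#' @return Numeric vector of `length(shuffled_db)` best scores.
#' @export
collectNullScores <- function(query, shuffled_db,
                              seed_params = seedParams(),
                              align_params = alignParams()) {
  if (length(shuffled_db) == 0L)
    stop("insufficient null trials: shuffled database is empty")
  qd <- .querySeedData(query, seed_params, align_params@max_reactivity)
  cache <- .dbSeedCache(shuffled_db, seed_params,
                        align_params@max_reactivity)
  .collectNullScoresCached(qd, cache, seed_params, align_params)
}

#' Fit a Gumbel (type-I extreme value) distribution
#'
#' Alignment best scores over many independent shuffled targets follow an
#' extreme value distribution. The default estimator is the method of
#' moments — `beta = sd(scores) * sqrt(6) / pi`,
#' `mu = mean(scores) - gamma * beta` (gamma = Euler–Mascheroni constant) —
#' which is closed-form, deterministic and adequate at the 100–1000 trials
#' used here. `method = "ml"` refines the moment estimate by maximum
#' likelihood (Nelder–Mead on the Gumbel log-likelihood).
#'
#' @param scores numeric vector of null scores.
#' @param min_trials minimum number of scores required (default 50).
#' @param method `"moments"` (default) or `"ml"`.
#' @return A [NullDistribution-class].
#' @export
fitEVD <- function(scores, min_trials = 50L,
                   method = c("moments", "ml")) {
  method <- match.arg(method)
  scores <- as.numeric(scores)
  if (length(scores) < min_trials)
    stop(sprintf("insufficient null trials: %d < %d", length(scores),
                 min_trials))
  if (any(!is.finite(scores))) stop("null scores must be finite")
  s <- sd(scores)
  if (s == 0) stop("degenerate null: zero-variance scores")
  beta <- s * sqrt(6) / pi
  mu <- mean(scores) - .EULER_GAMMA * beta
  if (method == "ml") {
    nll <- function(par) {
      if (par[[2L]] <= 0) return(Inf)
      z <- (scores - par[[1L]]) / par[[2L]]
      length(scores) * log(par[[2L]]) + sum(z) + sum(exp(-z))
    }
    opt <- stats::optim(c(mu, beta), nll)
    mu <- opt$par[[1L]]
    beta <- opt$par[[2L]]
  }
  new("NullDistribution", scores = scores, mu = mu, beta = beta,
      n_trials = length(scores))
}

#' Gumbel survival p-value and E-value
#'
#' `evdPValue()` is the probability of a null score at least as large as
#' `S`: `p = 1 - exp(-exp(-(S - mu)/beta))`. `eValue()` converts a p-value
#' into the expected number of chance matches over the searched database:
#' `E = p * n_db_entries`.
#'
#' @param S observed alignment score(s).
#' @param null a [NullDistribution-class], or `mu =`/`beta =` given
#'   directly.
#' @param mu,beta Gumbel parameters (used when `null` is missing).
#' @return `evdPValue()`: p-value(s) in (0, 1); `eValue()`: `p * n`.
#' @examples
#' evdPValue(5, mu = 5, beta = 2)  # 1 - exp(-1) = 0.632...
#' eValue(0.005, 2)                # 0.01
#' @export
evdPValue <- function(S, null = NULL, mu = null@mu, beta = null@beta) {
  stopifnot(beta > 0)
  -expm1(-exp(-(S - mu) / beta))
}

#' @rdname evdPValue
#' @param p p-value(s).
#' @param n_db_entries number of (real) database entries searched.
#' @export
eValue <- function(p, n_db_entries) {
  stopifnot(n_db_entries >= 0)
  p * n_db_entries
}
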