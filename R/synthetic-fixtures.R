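## Synthetic fixtures: reactivity profiles and databases with planted
## homologous regions and known ground truth, so every pipeline stage is
## testable without external data.

#' Generate a random reactivity profile
#'
#' Sequence bases are uniform over A/C/G/U. Reactivities are drawn from a
#' bimodal mixture emulating probing data — a low mode for paired bases and
#' a high mode for unpaired/flexible ones — truncated at 0, so that
#' complexity filtering behaves as on real profiles (the median Gini of
#' 15-nt windows comfortably exceeds the 0.3 cutoff).
#'
#' @param length profile length (nt).
#' @param id profile identifier.
#' @param p_low fraction of bases in the low (paired) mode (default 0.6).
#' @param low_mean,low_sd low-mode normal parameters (default 0.05/0.08).
#' @param high_mean,high_sd high-mode normal parameters (default 0.9/0.4).
#' @return A [ReactivityProfile-class].
#' @export
randomProfile <- function(length, id = "synthetic", p_low = 0.6,
                          low_mean = 0.05, low_sd = 0.08,
                          high_mean = 0.9, high_sd = 0.4) {
  stopifnot(length >= 1L)
  bases <- sample(c("A", "C", "G", "U"), length, replace = TRUE)
  low <- runif(length) < p_low
  vals <- ifelse(low, rnorm(length, low_mean, low_sd),
                 rnorm(length, high_mean, high_sd))
  reactivityProfile(id, paste(bases, collapse = ""), pmax(vals, 0))
}

#' Plant a homologous region from a query into a database entry
#'
#' Copies `region_len` bases of `query` starting at `query_start` into
#' `db_entry` at `db_start`, perturbing the copy with Gaussian reactivity
#' noise (sd `noise_sd`, re-truncated at 0) and with random base
#' substitutions so that the planted region's sequence identity is
#' `identity` (substituted positions get a different base uniformly).
#'
#' @param query,db_entry [ReactivityProfile-class] objects.
#' @param query_start,db_start 0-based region starts.
#' @param region_len region length (nt).
#' @param noise_sd per-base Gaussian reactivity noise sd.
#' @param identity target fraction of identical bases in the planted copy.
#' @return A list: `db_entry` (modified), and `truth` — a one-row
#'   data.frame recording both 0-based half-open intervals.
#' @export
plantHomology <- function(query, db_entry, query_start, db_start,
                          region_len, noise_sd = 0.15, identity = 0.8) {
  stopifnot(query_start >= 0L, db_start >= 0L,
            query_start + region_len <= length(query),
            db_start + region_len <= length(db_entry),
            noise_sd >= 0, identity >= 0, identity <= 1)
  qidx <- query_start + seq_len(region_len)
  re <- pmax(reactivity(query)[qidx] + rnorm(region_len, 0, noise_sd), 0)
  qb <- strsplit(profileSequence(query), "", fixed = TRUE)[[1L]][qidx]
  n_sub <- round((1 - identity) * region_len)
  if (n_sub > 0L) {
    at <- sample.int(region_len, n_sub)
    qb[at] <- vapply(qb[at], function(b)
      sample(setdiff(c("A", "C", "G", "U"), b), 1L), character(1L))
  }
  eb <- strsplit(profileSequence(db_entry), "", fixed = TRUE)[[1L]]
  er <- reactivity(db_entry)
  didx <- db_start + seq_len(region_len)
  eb[didx] <- qb
  er[didx] <- re
  list(db_entry = reactivityProfile(profileID(db_entry),
                                    paste(eb, collapse = ""), er),
       truth = data.frame(
         query_id = profileID(query), query_start = as.integer(query_start),
         query_end = as.integer(query_start + region_len),
         db_id = profileID(db_entry), db_start = as.integer(db_start),
         db_end = as.integer(db_start + region_len),
         stringsAsFactors = FALSE))
}

#' Simulate a planted-homology benchmark
#'
#' Builds `n_queries` random query profiles and a database of `n_entries`
#' random profiles, then plants one region of each query into a database
#' entry at a random position, with reactivity noise `noise_sd` and
#' sequence identity `identity`. Returns the queries, the database and the
#' ground-truth table.
#'
#' @param n_queries number of query profiles (default 50).
#' @param query_len query length (default 200 nt).
#' @param n_entries database entries (default 10).
#' @param entry_len database entry length (default 5000 nt; 10 x 5000 =
#'   a 50 kb database).
#' @param region_len planted region length (default 150 nt).
#' @param noise_sd reactivity noise sd on planted copies (default 0.15).
#' @param identity planted sequence identity (default 0.8).
#' @param seed RNG seed.
#' @return list(queries, db, truth): a list of profiles, a
#'   [ProfileDatabase-class] and the truth data.frame.
#' @export
simulateBenchmark <- function(n_queries = 50L, query_len = 200L,
                              n_entries = 10L, entry_len = 5000L,
                              region_len = 150L, noise_sd = 0.15,
                              identity = 0.8, seed = 1L) {
  stopifnot(region_len <= query_len, region_len <= entry_len)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  queries <- lapply(seq_len(n_queries), function(i)
    randomProfile(query_len, sprintf("query%02d", i)))
  entries <- lapply(seq_len(n_entries), function(i)
    randomProfile(entry_len, sprintf("target%02d", i)))
  truth <- vector("list", n_queries)
  for (i in seq_len(n_queries)) {
    ei <- sample.int(n_entries, 1L)
    qs <- sample.int(query_len - region_len + 1L, 1L) - 1L
    ds <- sample.int(entry_len - region_len + 1L, 1L) - 1L
    planted <- plantHomology(queries[[i]], entries[[ei]], qs, ds, region_len,
                             noise_sd, identity)
    entries[[ei]] <- planted$db_entry
    truth[[i]] <- planted$truth
  }
  list(queries = queries,
       db = profileDatabase(entries, kind = "shape-reactivity"),
       truth = do.call(rbind, truth))
}

#' Label benchmark hits against the planted ground truth
#'
#' A hit is true when it falls at the planted position: it is on the planted
#' database entry for its query and its query and database intervals both
#' overlap the recorded planted intervals by at least `min_overlap` bases
#' (default 1 nt — a match touching the expected position counts, partial
#' recoveries included; anything elsewhere is a false positive).
#'
#' @param hits data.frame from [searchReactivityDb()].
#' @param truth truth table from [simulateBenchmark()].
#' @param min_overlap minimum overlap (nt) with the planted intervals.
#' @return `hits` with a logical `truth` column.
#' @export
labelPlanted <- function(hits, truth, min_overlap = 1L) {
  overlap <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))
  truthHit <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    t <- truth[truth$query_id == hits$query_id[[i]] &
                 truth$db_id == hits$db_id[[i]], , drop = FALSE]
    if (nrow(t) == 0L) next
    qov <- overlap(hits$query_start[[i]], hits$query_end[[i]],
                   t$query_start, t$query_end)
    dov <- overlap(hits$db_start[[i]], hits$db_end[[i]],
                   t$db_start, t$db_end)
    truthHit[[i]] <- any(qov >= min_overlap & dov >= min_overlap)
  }
  hits$truth <- truthHit
  hits
}

#' Run the planted-homology benchmark end to end
#'
#' Simulates the benchmark ([simulateBenchmark()]), builds one shuffled
#' database, searches every query ([searchReactivityDb()]), labels hits
#' against the planted truth ([labelPlanted()]) and computes sensitivity
#' (fraction of queries recovered) and FDR.
#'
#' @param ... passed to [simulateBenchmark()].
#' @param seed RNG seed (simulation and shuffled database).
#' @param seed_params,align_params,shuffle_params search parameters.
#' @param evalue_threshold reported E-value cutoff (default: mode default).
#' @return list(hits, labels, sensitivity, fdr, truth, fixture).
#' @export
runBenchmark <- function(..., seed = 1L, seed_params = seedParams(),
                         align_params = alignParams(),
                         shuffle_params = shuffleParams(),
                         evalue_threshold = NULL) {
  fixture <- simulateBenchmark(..., seed = seed)
  shuffled <- buildShuffledDb(fixture$db, shuffle_params, seed = seed + 1L)
  hits <- searchReactivityDb(fixture$queries, fixture$db, shuffled,
                             seed_params = seed_params,
                             align_params = align_params,
                             evalue_threshold = evalue_threshold)
  labels <- labelPlanted(hits, fixture$truth)
  list(hits = hits, labels = labels,
       sensitivity = sensitivityFromLabels(labels,
                                           length(fixture$queries)),
       fdr = fdrFromLabels(labels), truth = fixture$truth,
       fixture = fixture)
}
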