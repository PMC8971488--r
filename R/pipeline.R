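## Full search orchestration: query windowing, per-window seed -> extend ->
## significance, window merging, benchmark labelling and metrics.

#' Split a profile into overlapping search windows
#'
#' Window starts begin at 0 and advance by `window_len - overlap` while
#' `start < L - overlap`; the final window is truncated at the profile end,
#' so every base is covered. Profiles shorter than `window_len` yield a
#' single window.
#'
#' @param x a [ReactivityProfile-class] or an integer length.
#' @param window_len window length in nt (default 200).
#' @param overlap overlap between consecutive windows (default 100;
#'   must be < `window_len`).
#' @return data.frame with 0-based half-open `start`, `end`.
#' @examples
#' nrow(splitWindows(1542L))  # 15 windows for a 16S-sized transcript
#' @export
splitWindows <- function(x, window_len = 200L, overlap = 100L) {
  L <- if (is(x, "ReactivityProfile")) length(x) else as.integer(x)
  stopifnot(window_len > overlap, overlap >= 0L, L >= 1L)
  if (L <= window_len) return(data.frame(start = 0L, end = L))
  step <- window_len - overlap
  starts <- seq.int(0L, L - overlap - 1L, by = step)
  data.frame(start = as.integer(starts),
             end = as.integer(pmin(starts + window_len, L)))
}

.windowProfile <- function(profile, start, end) {
  reactivityProfile(profileID(profile),
                    substr(profileSequence(profile), start + 1L, end),
                    reactivity(profile)[(start + 1L):end])
}

# Seed -> group -> score-only extend for one query window. Only HSGs whose
# extended score reaches `min_score` (the score at the E-value threshold
# under the window's null) are traced back into full alignments.
.searchWindow <- function(wprof, qd, db, db_cache, seed_params,
                          align_params, min_score) {
  matches <- .matchKmersCached(qd, db_cache, seed_params)
  if (nrow(matches) == 0L) return(list())
  hsgs <- groupHSGs(matches, seed_params)
  if (nrow(hsgs) == 0L) return(list())
  ei <- match(hsgs$db_entry_id, db_cache$ids)
  results <- list()
  for (e in unique(ei)) {
    rows <- which(ei == e)
    ext <- .extendBatch(qd, db_cache$entries[[e]], hsgs, rows, align_params)
    for (r in ext$hsg_row[ext$score >= min_score]) {
      results[[length(results) + 1L]] <-
        extendHSG(wprof, db[[hsgs$db_entry_id[[r]]]], list(
          query_start = hsgs$query_start[[r]],
          query_end = hsgs$query_end[[r]],
          db_start = hsgs$db_start[[r]],
          db_end = hsgs$db_end[[r]]), align_params)
    }
  }
  .dedupAlignments(results)
}

#' Search query profiles against a reactivity database
#'
#' The full pipeline: each query is split into overlapping windows
#' ([splitWindows()]); each window is seeded ([matchKmers()],
#' [groupHSGs()]), extended ([extendHSG()]) and deduplicated; a per-window
#' empirical null is collected from the shuffled database
#' ([collectNullScores()]) and fitted ([fitEVD()]); alignments with
#' E-value at most `evalue_threshold` are reported, sorted by E-value.
#'
#' @param queries a [ProfileDatabase-class], a list of
#'   [ReactivityProfile-class], or a single profile.
#' @param db the searched [ProfileDatabase-class].
#' @param shuffled_db optional pre-built shuffled database (must match
#'   `db`'s kind); built on the fly with `shuffle_params` when `NULL`.
#' @param seed_params a [SeedParams-class].
#' @param align_params an [AlignParams-class]; its `seq_scoring` flag
#'   selects the search mode.
#' @param shuffle_params a [ShuffleParams-class] (used when `shuffled_db`
#'   is `NULL`).
#' @param evalue_threshold maximum reported E-value; defaults to 0.01 for
#'   reactivity-only searches and 0.005 when sequence scoring is active.
#' @param window_len,overlap query windowing (defaults 200/100 nt).
#' @param min_null_trials minimum shuffled targets required to fit the null.
#' @param evalue_units how the p-to-E search-space multiplier is counted:
#'   `"chunks"` (default) uses the number of null-chunk-sized pieces the
#'   database contains, so a p-value calibrated on chunk-length targets
#'   scales to the full search space; `"entries"` uses the raw entry count
#'   (equivalent when entries are no longer than the null chunk).
#' @param seed RNG seed used when building the shuffled database.
#' @return data.frame with one row per significant match: `query_id`,
#'   `window_start`, `window_end`, `query_start`, `query_end`, `db_id`,
#'   `db_start`, `db_end` (0-based half-open), `score`, `p_value`,
#'   `e_value`, `mode`, plus a list-column `alignment` of
#'   [AlignmentResult-class] objects in absolute query coordinates. The
#'   attribute `n_db_entries` records the E-value multiplier.
#' @export
searchReactivityDb <- function(queries, db, shuffled_db = NULL,
                               seed_params = seedParams(),
                               align_params = alignParams(),
                               shuffle_params = shuffleParams(),
                               evalue_threshold = NULL,
                               window_len = 200L, overlap = 100L,
                               min_null_trials = 50L,
                               evalue_units = c("chunks", "entries"),
                               seed = 1L) {
  evalue_units <- match.arg(evalue_units)
  if (is(queries, "ProfileDatabase")) {
    if (!identical(dbKind(queries), dbKind(db)))
      stop(sprintf("query kind (%s) does not match database kind (%s)",
                   dbKind(queries), dbKind(db)))
    queries <- dbEntries(queries)
  } else if (is(queries, "ReactivityProfile")) {
    queries <- list(queries)
  }
  if (is.null(shuffled_db)) {
    shuffled_db <- buildShuffledDb(db, shuffle_params, seed = seed)
  } else if (!identical(dbKind(shuffled_db), dbKind(db))) {
    stop("shuffled database kind does not match database kind")
  }
  if (is.null(evalue_threshold))
    evalue_threshold <- if (align_params@seq_scoring) 0.005 else 0.01
  mode <- if (align_params@seq_scoring) "shape+sequence" else "shape-only"
  entry_lens <- vapply(dbEntries(db), length, integer(1L))
  n_units <- if (evalue_units == "entries") length(db) else {
    chunk_len <- max(vapply(dbEntries(shuffled_db), length, integer(1L)))
    sum(pmax(1, ceiling(entry_lens / chunk_len)))
  }
  db_cache <- .dbSeedCache(db, seed_params, align_params@max_reactivity)
  sh_cache <- .dbSeedCache(shuffled_db, seed_params,
                           align_params@max_reactivity)
  rows <- list()
  for (q in queries) {
    wins <- splitWindows(q, window_len, overlap)
    for (w in seq_len(nrow(wins))) {
      ws <- wins$start[[w]]; we <- wins$end[[w]]
      wprof <- .windowProfile(q, ws, we)
      qd <- .querySeedData(wprof, seed_params, align_params@max_reactivity)
      if (!any(qd$retained)) next
      null_scores <- .collectNullScoresCached(qd, sh_cache, seed_params,
                                              align_params)
      null <- fitEVD(null_scores, min_trials = min_null_trials)
      # score needed to reach the E-value threshold under this null
      p_thr <- min(1, evalue_threshold / max(n_units, 1L))
      min_score <- null@mu - null@beta * log(-log1p(-p_thr))
      alns <- .searchWindow(wprof, qd, db, db_cache, seed_params,
                            align_params, min_score)
      if (length(alns) == 0L) next
      for (a in alns) {
        p <- evdPValue(a@score, null)
        e <- eValue(p, n_units)
        if (e > evalue_threshold) next
        # shift to absolute query coordinates
        a@query_start <- a@query_start + ws
        a@query_end <- a@query_end + ws
        if (nrow(a@columns)) a@columns$qi <- a@columns$qi + ws
        a@seed$query_start <- a@seed$query_start + ws
        a@seed$query_end <- a@seed$query_end + ws
        a@p_value <- p
        a@e_value <- e
        rows[[length(rows) + 1L]] <- list(
          query_id = profileID(q), window_start = ws, window_end = we,
          query_start = a@query_start, query_end = a@query_end,
          db_id = a@db_entry_id, db_start = a@db_start, db_end = a@db_end,
          score = a@score, p_value = p, e_value = e, mode = mode,
          alignment = a)
      }
    }
  }
  out <- if (length(rows)) {
    df <- do.call(rbind, lapply(rows, function(r)
      data.frame(r[setdiff(names(r), "alignment")],
                 stringsAsFactors = FALSE)))
    df$alignment <- lapply(rows, `[[`, "alignment")
    ord <- order(df$e_value, -df$score, df$query_id, df$window_start,
                 df$db_id, df$db_start)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    df
  } else {
    df <- data.frame(query_id = character(0), window_start = integer(0),
                     window_end = integer(0), query_start = integer(0),
                     query_end = integer(0), db_id = character(0),
                     db_start = integer(0), db_end = integer(0),
                     score = numeric(0), p_value = numeric(0),
                     e_value = numeric(0), mode = character(0),
                     stringsAsFactors = FALSE)
    df$alignment <- list()
    df
  }
  attr(out, "n_db_entries") <- length(db)
  attr(out, "n_search_units") <- n_units
  out
}

#' Merge consecutive matching windows into regions
#'
#' Hits on the same database entry whose query intervals are consecutive or
#' overlapping, and whose diagonals (`db_start - query_start`) agree within
#' `diag_tolerance` bases, are fused into one region spanning
#' `[min start, max end)` on both axes. The merged region keeps the best
#' (lowest) E-value and best score of its members. Idempotent.
#'
#' @param hits data.frame from [searchReactivityDb()] (or a previous merge)
#'   with columns `query_id`, `db_id`, `query_start`, `query_end`,
#'   `db_start`, `db_end`, `score`, `e_value`.
#' @param diag_tolerance maximum diagonal drift between merged hits
#'   (default 20 nt, accounting for indels introduced by extension).
#' @param check_diagonal set `FALSE` to merge on query/db entry adjacency
#'   alone.
#' @param max_query_gap maximum gap (nt) between consecutive query
#'   intervals for them to still merge (default 0: overlap/adjacency
#'   required).
#' @return data.frame of merged regions with `n_windows` member counts.
#' @export
mergeWindows <- function(hits, diag_tolerance = 20L, check_diagonal = TRUE,
                         max_query_gap = 0L) {
  cols <- c("query_id", "db_id", "query_start", "query_end", "db_start",
            "db_end", "score", "e_value")
  stopifnot(all(cols %in% names(hits)))
  empty <- data.frame(query_id = character(0), db_id = character(0),
                      query_start = integer(0), query_end = integer(0),
                      db_start = integer(0), db_end = integer(0),
                      score = numeric(0), e_value = numeric(0),
                      n_windows = integer(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  n_win <- if ("n_windows" %in% names(hits)) hits$n_windows
           else rep(1L, nrow(hits))
  regions <- list()
  for (grp in split(seq_len(nrow(hits)),
                    list(hits$query_id, hits$db_id), drop = TRUE)) {
    grp <- grp[order(hits$query_start[grp], hits$db_start[grp])]
    cur <- NULL
    flush <- function(cur) {
      regions[[length(regions) + 1L]] <<- cur
    }
    for (i in grp) {
      row <- list(query_id = hits$query_id[[i]], db_id = hits$db_id[[i]],
                  query_start = hits$query_start[[i]],
                  query_end = hits$query_end[[i]],
                  db_start = hits$db_start[[i]], db_end = hits$db_end[[i]],
                  score = hits$score[[i]], e_value = hits$e_value[[i]],
                  n_windows = n_win[[i]])
      if (is.null(cur)) { cur <- row; next }
      diag_ok <- !check_diagonal ||
        abs((row$db_start - row$query_start) -
              (cur$db_start - cur$query_start)) <= diag_tolerance
      if (row$query_start <= cur$query_end + max_query_gap && diag_ok) {
        cur$query_end <- max(cur$query_end, row$query_end)
        cur$db_start <- min(cur$db_start, row$db_start)
        cur$db_end <- max(cur$db_end, row$db_end)
        cur$score <- max(cur$score, row$score)
        cur$e_value <- min(cur$e_value, row$e_value)
        cur$n_windows <- cur$n_windows + row$n_windows
      } else {
        flush(cur); cur <- row
      }
    }
    if (!is.null(cur)) flush(cur)
  }
  out <- do.call(rbind, lapply(regions, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  out <- out[order(out$query_id, out$db_id, out$query_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label matches by the relative-genomic-position rule
#'
#' A match is considered true when its query and database intervals fall at
#' the same relative position within their respective genomes, within
#' `tolerance` (a fraction of genome length; default 0.02 = +/- 2%).
#' Positions are interval midpoints scaled by genome length. Set
#' `tolerance = 0` to require the exact relative position.
#'
#' @param hits data.frame with `query_start`, `query_end`, `db_start`,
#'   `db_end`.
#' @param query_len,db_len genome lengths of the query and database
#'   molecules.
#' @param tolerance allowed relative-position difference.
#' @return `hits` with added `relative_position_delta` and logical `truth`.
#' @export
labelMatches <- function(hits, query_len, db_len, tolerance = 0.02) {
  qmid <- (hits$query_start + hits$query_end) / 2
  dmid <- (hits$db_start + hits$db_end) / 2
  delta <- abs(qmid / query_len - dmid / db_len)
  hits$relative_position_delta <- delta
  hits$truth <- delta <= tolerance
  hits
}

#' Benchmark metrics from labelled matches
#'
#' `fdrFromLabels()` is the fraction of reported matches that are false;
#' with zero reported matches the FDR is undefined and `NA` is returned.
#' `sensitivityFromLabels()` is the fraction of expected query windows
#' recovered: windows (identified by `query_id` + `window_start`, falling
#' back to `query_id` alone) with at least one true match, divided by
#' `n_expected`.
#'
#' @param labels data.frame with a logical `truth` column (see
#'   [labelMatches()]).
#' @param n_expected number of query windows that should be recovered.
#' @return A single numeric value.
#' @export
fdrFromLabels <- function(labels) {
  if (nrow(labels) == 0L) {
    message("no reported matches: FDR undefined")
    return(NA_real_)
  }
  mean(!labels$truth)
}

#' @rdname fdrFromLabels
#' @export
sensitivityFromLabels <- function(labels, n_expected) {
  stopifnot(n_expected >= 1L)
  if (nrow(labels) == 0L) return(0)
  true <- labels[labels$truth, , drop = FALSE]
  if (nrow(true) == 0L) return(0)
  key <- if ("window_start" %in% names(true))
    paste(true$query_id, true$window_start) else true$query_id
  length(unique(key)) / n_expected
}

#' Fraction of windows in one result set recovered by another
#'
#' For two sets of correctly matched query windows over the same query
#' genome, computes the fraction of windows in `a` having at least one
#' window in `b` that overlaps it by at least `min_overlap` of the smaller
#' window.
#'
#' @param a,b data.frames with `query_start`, `query_end` intervals.
#' @param min_overlap minimum overlap fraction, relative to the smaller
#'   window (default 0.25).
#' @return Fraction in \[0,1\], or `NA` when `a` is empty.
#' @export
windowOverlapAnalysis <- function(a, b, min_overlap = 0.25) {
  if (nrow(a) == 0L) {
    message("empty reference set: overlap fraction undefined")
    return(NA_real_)
  }
  if (nrow(b) == 0L) return(0)
  hit <- vapply(seq_len(nrow(a)), function(i) {
    ov <- pmin(a$query_end[[i]], b$query_end) -
      pmax(a$query_start[[i]], b$query_start)
    need <- min_overlap * pmin(a$query_end[[i]] - a$query_start[[i]],
                               b$query_end - b$query_start)
    any(ov >= need & ov > 0)
  }, logical(1L))
  mean(hit)
}

#' Write search hits as a TSV report
#'
#' Coordinates are converted to 1-based inclusive. Numeric columns use a
#' fixed format so identical searches produce byte-identical files.
#'
#' @param hits data.frame from [searchReactivityDb()] or [mergeWindows()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHitsTSV <- function(hits, path) {
  df <- hits[setdiff(names(hits), "alignment")]
  for (col in intersect(c("window_start", "query_start", "db_start"),
                        names(df)))
    df[[col]] <- df[[col]] + 1L  # 1-based inclusive in reports
  for (col in intersect(c("score", "p_value", "e_value"), names(df)))
    df[[col]] <- sprintf("%.6g", df[[col]])
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}
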