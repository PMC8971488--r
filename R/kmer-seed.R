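## Kmer seeding: complexity filter, z-normalized lookup, GC/promiscuity
## filters, and grouping of co-diagonal matches into high scoring groups.

#' Gini coefficient of a reactivity window
#'
#' Inequality measure used as a structure-complexity filter: windows falling
#' entirely inside a paired (all-low) or unpaired (all-high) region show
#' little disparity and carry no searchable signal.
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, 0 for uniform input,
#' approaching 1 with extreme inequality; scale-invariant.
#'
#' @param values numeric vector (>= 2 non-negative values).
#' @return The Gini coefficient, or `NA` if it is uncomputable (any missing
#'   value, or an all-zero window).
#' @examples
#' giniCoefficient(c(1, 1, 1, 1))  # 0
#' giniCoefficient(c(0, 0, 0, 1))  # 0.75
#' @export
giniCoefficient <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values")
  if (anyNA(values)) return(NA_real_)
  if (any(values < 0)) stop("values must be non-negative")
  total <- sum(values)
  if (total == 0) return(NA_real_)
  n <- length(values)
  xs <- sort(values)
  2 * sum(seq_len(n) * xs) / (n * total) - (n + 1) / n
}

#' Enumerate complexity-passing query kmers
#'
#' Slides a window of `kmer_len` along the query (stride 1) and retains
#' every offset whose window, after capping at `max_reactivity`, contains no
#' missing value, has nonzero variance, and has a Gini coefficient of at
#' least `kmer_min_complexity`.
#'
#' @param query a [ReactivityProfile-class].
#' @param params a [SeedParams-class].
#' @return A list with `starts` (0-based offsets, possibly empty) and
#'   `kmers` (list of capped value vectors, one per retained offset).
#' @export
enumerateQueryKmers <- function(query, params = seedParams()) {
  qd <- .querySeedData(query, params)
  keep <- which(qd$retained)
  list(starts = keep - 1L,
       kmers = lapply(keep, function(i) qd$qcap[i:(i + params@kmer_len - 1L)]))
}

# Everything the seeding and extension stages need from a query profile,
# computed once per search window.
.querySeedData <- function(query, params, align_max_reactivity = NULL) {
  k <- params@kmer_len
  qcap <- capReactivity(reactivity(query), params@max_reactivity)
  n <- length(qcap)
  retained <- logical(max(n - k + 1L, 0L))
  qws <- NULL
  if (n >= k) {
    qws <- .windowStats(qcap, k)
    keep <- which(qws$valid)
    if (length(keep)) {
      g <- vapply(keep, function(i) giniCoefficient(qcap[i:(i + k - 1L)]),
                  numeric(1L))
      keep <- keep[!is.na(g) & g >= params@kmer_min_complexity]
    }
    retained[keep] <- TRUE
  }
  q0 <- qcap
  q0[is.na(q0)] <- 0
  bases <- strsplit(profileSequence(query), "", fixed = TRUE)[[1L]]
  out <- list(id = profileID(query), n = n, qcap = qcap, q0 = q0,
              qws = qws, retained = retained,
              gcq = .gcPercentWindows(profileSequence(query), k),
              bases = bases, codes = unname(.BASE_CODES[bases]))
  if (!is.null(align_max_reactivity))
    out$acap <- capReactivity(reactivity(query), align_max_reactivity)
  out
}

# Per-entry precomputation for a searched database: seed-stage arrays
# (zero-filled capped values, window stats, GC windows) plus the capped
# NA-preserving values and base codes used by alignment extension.
.dbSeedCache <- function(db, params, align_max_reactivity = NULL) {
  k <- params@kmer_len
  entries <- lapply(db@entries, function(entry) {
    ecap <- capReactivity(reactivity(entry), params@max_reactivity)
    e0 <- ecap
    e0[is.na(e0)] <- 0
    bases <- strsplit(profileSequence(entry), "", fixed = TRUE)[[1L]]
    out <- list(id = profileID(entry), n = length(ecap), e0 = e0,
                ews = if (length(ecap) >= k) .windowStats(ecap, k) else NULL,
                gce = .gcPercentWindows(profileSequence(entry), k),
                codes = unname(.BASE_CODES[bases]))
    if (!is.null(align_max_reactivity))
      out$acap <- capReactivity(reactivity(entry), align_max_reactivity)
    out
  })
  list(entries = entries, ids = dbIDs(db), total_length = totalLength(db),
       kind = dbKind(db))
}

.matchKmersCached <- function(qd, cache, params) {
  k <- params@kmer_len
  empty <- data.frame(query_start = integer(0), db_entry_id = character(0),
                      db_start = integer(0), znorm_distance = numeric(0),
                      gc_diff = numeric(0), stringsAsFactors = FALSE)
  if (!any(qd$retained)) return(empty)
  thr <- params@dist_coeff * sqrt(k)
  ne <- length(cache$entries)
  acc_qs <- acc_ds <- acc_ei <- vector("list", ne)
  acc_dist <- acc_gc <- vector("list", ne)
  for (ei in seq_len(ne)) {
    ce <- cache$entries[[ei]]
    if (is.null(ce$ews)) next
    hits <- .kmerMatchEntry(qd$q0, ce$e0, k, qd$retained, qd$qws$mu,
                            qd$qws$sd, ce$ews$valid, ce$ews$mu, ce$ews$sd,
                            thr)
    if (length(hits$query_start) == 0L) next
    gc_diff <- abs(qd$gcq[hits$query_start + 1L] - ce$gce[hits$db_start + 1L])
    keep <- if (is.na(params@max_gc_diff)) seq_along(gc_diff)
            else which(gc_diff <= params@max_gc_diff)
    acc_qs[[ei]] <- hits$query_start[keep]
    acc_ds[[ei]] <- hits$db_start[keep]
    acc_dist[[ei]] <- hits$dist[keep]
    acc_gc[[ei]] <- gc_diff[keep]
    acc_ei[[ei]] <- rep.int(ei, length(keep))
  }
  qs <- unlist(acc_qs, use.names = FALSE)
  if (is.null(qs) || length(qs) == 0L) return(empty)
  res <- data.frame(
    query_start = qs,
    db_entry_id = cache$ids[unlist(acc_ei, use.names = FALSE)],
    db_start = unlist(acc_ds, use.names = FALSE),
    znorm_distance = unlist(acc_dist, use.names = FALSE),
    gc_diff = unlist(acc_gc, use.names = FALSE), stringsAsFactors = FALSE)
  # promiscuity filter: drop kmers matching more than once every
  # kmer_max_match_every_nt database bases (floored at one allowed match so
  # short databases keep their planted seeds)
  limit <- max(1, cache$total_length / params@kmer_max_match_every_nt)
  counts <- tabulate(res$query_start + 1L)
  promiscuous <- counts[res$query_start + 1L] > limit
  res <- res[!promiscuous, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Z-normalized sliding distance profile (MASS)
#'
#' Computes, for every offset of `entry`, the Euclidean distance between the
#' z-normalized kmer and the z-normalized window `entry[i..i+k)`, using
#' FFT-based sliding dot products (Mueen's algorithm for similarity search).
#' Windows containing missing values or with zero variance are unmatchable
#' and get distance `Inf`. The distance is invariant to positive affine
#' transforms of either operand.
#'
#' @param kmer numeric vector of length `k` (no missing values, nonzero
#'   variance).
#' @param entry numeric vector of length `m >= k` (missing values allowed).
#' @return Numeric vector of `m - k + 1` distances.
#' @export
massDistanceProfile <- function(kmer, entry) {
  k <- length(kmer)
  m <- length(entry)
  if (m < k) stop("entry shorter than kmer")
  if (anyNA(kmer)) stop("kmer contains missing values")
  muq <- mean(kmer)
  sdq <- sqrt(mean((kmer - muq)^2))
  if (sdq < 1e-12)
    stop("kmer has zero variance (should have been complexity-filtered)")
  x <- entry
  x[is.na(x)] <- 0
  # sliding dot products by FFT convolution with the reversed kmer
  y <- c(rev(kmer), rep(0, m - k))
  dots <- Re(fft(fft(x) * fft(y), inverse = TRUE)) / m
  dots <- dots[k:m]  # dots[i] = sum(kmer * entry[i..i+k-1])
  ws <- .windowStats(entry, k)
  corr <- (dots - k * muq * ws$mu) / (k * sdq * ws$sd)
  d <- sqrt(pmax(0, 2 * k * (1 - corr)))
  d[!ws$valid] <- Inf
  d
}

.gcPercentWindows <- function(sequence, k) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(bases)
  if (n < k) return(numeric(0))
  gc <- cumsum(bases %in% c("G", "C"))
  nonN <- cumsum(bases != "N")
  i <- seq_len(n - k + 1L)
  gcw <- gc[i + k - 1L] - c(0, gc)[i]
  nnw <- nonN[i + k - 1L] - c(0, nonN)[i]
  ifelse(nnw > 0, 100 * gcw / nnw, 0)
}

#' Match query kmers against a profile database
#'
#' For each complexity-passing query kmer, database offsets whose
#' z-normalized distance is at most `dist_coeff * sqrt(kmer_len)` are
#' collected across all entries. Matches whose window GC% deviates from the
#' query kmer's GC% by more than `max_gc_diff` percentage points are
#' discarded (N bases count toward neither GC nor the denominator). Finally,
#' a kmer whose surviving match count exceeds
#' `totalLength(db) / kmer_max_match_every_nt` is considered promiscuous and
#' discarded with all its matches.
#'
#' @param query a [ReactivityProfile-class].
#' @param db a [ProfileDatabase-class].
#' @param params a [SeedParams-class].
#' @return A data.frame with columns `query_start`, `db_entry_id`,
#'   `db_start` (0-based), `znorm_distance`, `gc_diff`.
#' @export
matchKmers <- function(query, db, params = seedParams()) {
  .matchKmersCached(.querySeedData(query, params),
                    .dbSeedCache(db, params), params)
}

#' Group co-diagonal kmer matches into high scoring groups
#'
#' Within each (database entry, diagonal) stratum — diagonal being
#' `db_start - query_start` — matches sorted by `query_start` are chained
#' while the gap between consecutive kmer starts is at most `max_kmer_dist`
#' bases; chains with at least `min_kmers` members become HSGs, the
#' ungapped seeds of alignment extension.
#'
#' @param matches data.frame from [matchKmers()] (single query).
#' @param params a [SeedParams-class].
#' @return A data.frame with one row per HSG: `db_entry_id`, `diagonal`,
#'   `n_kmers`, `query_start`, `query_end`, `db_start`, `db_end` (0-based
#'   half-open spans), and a list-column `members` of row indices into
#'   `matches`.
#' @export
groupHSGs <- function(matches, params = seedParams()) {
  k <- params@kmer_len
  empty <- data.frame(db_entry_id = character(0), diagonal = integer(0),
                      n_kmers = integer(0), query_start = integer(0),
                      query_end = integer(0), db_start = integer(0),
                      db_end = integer(0), stringsAsFactors = FALSE)
  empty$members <- list()
  if (nrow(matches) == 0L) return(empty)
  diagonal <- matches$db_start - matches$query_start
  eid <- match(matches$db_entry_id, unique(matches$db_entry_id))
  ord <- order(eid, diagonal, matches$query_start)
  qs <- matches$query_start[ord]
  # a new chain starts at a new (entry, diagonal) stratum or at a gap
  new_stratum <- c(TRUE, diff(eid[ord]) != 0L | diff(diagonal[ord]) != 0L)
  gap <- c(TRUE, diff(qs) > params@max_kmer_dist)
  chain_id <- cumsum(new_stratum | gap)
  size <- tabulate(chain_id)
  keep_chain <- which(size >= params@min_kmers)
  if (length(keep_chain) == 0L) return(empty)
  members <- split(ord, chain_id)[keep_chain]
  first <- vapply(members, `[`, integer(1L), 1L)  # smallest query_start
  last <- vapply(members, function(m) m[length(m)], integer(1L))
  out <- data.frame(
    db_entry_id = matches$db_entry_id[first],
    diagonal = diagonal[first],
    n_kmers = lengths(members),
    query_start = matches$query_start[first],
    query_end = matches$query_start[last] + k,
    db_start = matches$db_start[first],
    db_end = matches$db_start[last] + k,
    stringsAsFactors = FALSE)
  out$members <- unname(members)
  out <- out[order(out$db_entry_id, out$diagonal, out$query_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
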