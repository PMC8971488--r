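# Independent brute-force oracles used to validate the optimized
# implementations, plus small fixture builders.

# O(n^2) pairwise-sum Gini
giniOracle <- function(x) {
  n <- length(x)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) tot <- tot + abs(x[i] - x[j])
  tot / (2 * n^2 * mean(x))
}

# per-offset z-normalize-and-subtract distance profile
massOracle <- function(kmer, entry) {
  k <- length(kmer)
  m <- length(entry)
  znorm <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  vapply(seq_len(m - k + 1L), function(i) {
    w <- entry[i:(i + k - 1L)]
    if (anyNA(w) || sqrt(mean((w - mean(w))^2)) < 1e-12) return(Inf)
    sqrt(sum((znorm(kmer) - znorm(w))^2))
  }, numeric(1L))
}

# exhaustive chain construction: for each (entry, diagonal) stratum walk the
# sorted starts and cut where the gap exceeds max_kmer_dist
chainOracle <- function(matches, max_kmer_dist, min_kmers, k) {
  out <- list()
  diag <- matches$db_start - matches$query_start
  for (id in unique(matches$db_entry_id)) {
    for (d in unique(diag[matches$db_entry_id == id])) {
      idx <- which(matches$db_entry_id == id & diag == d)
      idx <- idx[order(matches$query_start[idx])]
      chain <- idx[1L]
      flush <- function(chain) {
        if (length(chain) >= min_kmers) {
          qs <- matches$query_start[chain]
          ds <- matches$db_start[chain]
          out[[length(out) + 1L]] <<- data.frame(
            db_entry_id = id, diagonal = d, n_kmers = length(chain),
            query_start = min(qs), query_end = max(qs) + k,
            db_start = min(ds), db_end = max(ds) + k,
            stringsAsFactors = FALSE)
        }
      }
      for (i in idx[-1L]) {
        if (matches$query_start[i] -
              matches$query_start[chain[length(chain)]] <= max_kmer_dist) {
          chain <- c(chain, i)
        } else {
          flush(chain)
          chain <- i
        }
      }
      flush(chain)
    }
  }
  if (length(out) == 0L) return(NULL)
  out <- do.call(rbind, out)
  out[order(out$db_entry_id, out$diagonal, out$query_start), , drop = FALSE]
}

# full unbanded three-state affine-gap DP from the seed boundary; returns
# the best cumulative score over pair cells (>= 0 for the empty extension)
armOracle <- function(qr, er, qb, eb, params) {
  n <- length(qr); m <- length(er)
  NEG <- -1e30
  M <- matrix(NEG, n + 1L, m + 1L)
  GD <- matrix(NEG, n + 1L, m + 1L)
  GQ <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  col <- function(i, j) scoreColumn(qr[i], er[j], qb[i], eb[j], params)
  for (s in seq_len(n + m)) {
    for (i in max(0L, s - m):min(n, s)) {
      j <- s - i
      if (i >= 1L && j >= 1L) {
        prev <- max(M[i, j], GD[i, j], GQ[i, j])
        if (prev > NEG / 2) M[i + 1L, j + 1L] <- prev + col(i, j)
      }
      if (i >= 1L) {
        vo <- if (M[i, j + 1L] > NEG / 2) M[i, j + 1L] + params@gap_open
              else NEG
        ve <- if (GD[i, j + 1L] > NEG / 2) GD[i, j + 1L] + params@gap_ext
              else NEG
        GD[i + 1L, j + 1L] <- max(vo, ve)
      }
      if (j >= 1L) {
        vo <- if (M[i + 1L, j] > NEG / 2) M[i + 1L, j] + params@gap_open
              else NEG
        ve <- if (GQ[i + 1L, j] > NEG / 2) GQ[i + 1L, j] + params@gap_ext
              else NEG
        GQ[i + 1L, j + 1L] <- max(vo, ve)
      }
    }
  }
  max(M, 0)
}

# full-alignment oracle: seed columns plus both unbanded extension arms
extendOracle <- function(query, entry, hsg, params) {
  qcap <- capReactivity(reactivity(query), params@max_reactivity)
  ecap <- capReactivity(reactivity(entry), params@max_reactivity)
  qb <- strsplit(profileSequence(query), "")[[1L]]
  eb <- strsplit(profileSequence(entry), "")[[1L]]
  qs <- hsg$query_start; qe <- hsg$query_end
  ds <- hsg$db_start; de <- hsg$db_end
  span <- seq_len(qe - qs)
  seed <- sum(scoreColumn(qcap[qs + span], ecap[ds + span],
                          qb[qs + span], eb[ds + span], params))
  n <- length(qcap); m <- length(ecap)
  down <- armOracle(qcap[seq_len(n - qe) + qe], ecap[seq_len(m - de) + de],
                    qb[seq_len(n - qe) + qe], eb[seq_len(m - de) + de],
                    params)
  up <- armOracle(rev(qcap[seq_len(qs)]), rev(ecap[seq_len(ds)]),
                  rev(qb[seq_len(qs)]), rev(eb[seq_len(ds)]), params)
  seed + down + up
}

rgumbel <- function(n, mu, beta) mu - beta * log(-log(runif(n)))

# tiny RNA Framework-style XML fixture
writeFixtureXML <- function(records, path = tempfile(fileext = ".xml")) {
  body <- vapply(records, function(r) {
    sprintf(paste0('<transcript id="%s" length="%d">\n',
                   "<sequence>\n%s\n</sequence>\n",
                   "<reactivity>\n%s\n</reactivity>\n</transcript>"),
            r$id, nchar(gsub("[[:space:]]", "", r$sequence)), r$sequence,
            r$reactivity)
  }, character(1L))
  writeLines(c("<data>", body, "</data>"), path)
  path
}

# a profile whose reactivities pass the complexity filter everywhere
structuredProfile <- function(n, id = "fix", seed = 1L) {
  withr::with_seed(seed, randomProfile(n, id))
}
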