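## HSG extension: banded affine-gap semi-global DP over the reactivity
## signal, with drop-off termination and deterministic traceback.

.BASE_CODES <- c(A = 0L, C = 1L, G = 2L, U = 3L, N = 4L)

.encodeBases <- function(sequence) {
  unname(.BASE_CODES[strsplit(sequence, "", fixed = TRUE)[[1L]]])
}

#' AlignmentResult: an extended, scored alignment between profile regions
#'
#' Intervals are 0-based half-open. `columns` holds one row per alignment
#' column with `state` (`"pair"`, `"gap_db"` = query base against a gap in
#' the database, `"gap_query"` = database base against a gap in the query)
#' and the 0-based positions `qi`, `di` (`NA` at gaps). The score is
#' recomputable from the columns under the same [AlignParams-class].
#'
#' @slot query_id,db_entry_id profile identifiers.
#' @slot query_start,query_end,db_start,db_end 0-based half-open intervals.
#' @slot score total alignment score (seed + both extensions).
#' @slot columns data.frame of aligned columns (see above).
#' @slot seed list with the seeding HSG's spans (provenance).
#' @slot p_value,e_value filled by the null model (`NA` until then).
#'
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  slots = c(query_id = "character", db_entry_id = "character",
            query_start = "integer", query_end = "integer",
            db_start = "integer", db_end = "integer", score = "numeric",
            columns = "data.frame", seed = "list", p_value = "numeric",
            e_value = "numeric")
)

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(
    "AlignmentResult %s[%d,%d) ~ %s[%d,%d): score %.2f, %d columns%s\n",
    object@query_id, object@query_start, object@query_end,
    object@db_entry_id, object@db_start, object@db_end, object@score,
    nrow(object@columns),
    if (!is.na(object@e_value)) sprintf(", E = %.3g", object@e_value) else ""))
})

#' Column substitution score
#'
#' Piecewise-linear score of pairing two capped reactivities: with
#' `d = |rq - rd|` and boundary `t = max_reactivity/2`, similar values
#' (`d <= t`) interpolate from `match_max` at d = 0 to `match_min` at d = t;
#' dissimilar values interpolate from `mismatch_max` just past t to
#' `mismatch_min` at d = max_reactivity. A column with a missing reactivity
#' on either side scores 0. When `seq_scoring` is enabled, `seq_match` is
#' added for identical A/C/G/U bases and `seq_mismatch` otherwise (N never
#' matches).
#'
#' @param rq,rd capped reactivities (may be `NA`); vectorized.
#' @param bq,bd bases (single characters), used only with `seq_scoring`.
#' @param params an [AlignParams-class].
#' @return Numeric score(s).
#' @examples
#' scoreColumn(0.3, 0.3, params = alignParams())   # 2 (perfect match)
#' scoreColumn(0, 1, params = alignParams())       # -6 (maximal difference)
#' @export
scoreColumn <- function(rq, rd, bq = "N", bd = "N", params = alignParams()) {
  t <- params@max_reactivity / 2
  d <- abs(rq - rd)
  lo <- params@mismatch_max -
    ((d - t) / (params@max_reactivity - t)) *
      (params@mismatch_max - params@mismatch_min)
  sc <- ifelse(d <= t,
               params@match_max - (d / t) * (params@match_max - params@match_min),
               pmax(lo, params@mismatch_min))
  sc[is.na(sc)] <- 0  # missing reactivity on either side
  if (params@seq_scoring) {
    bq <- rep_len(toupper(bq), length(sc))
    bd <- rep_len(toupper(bd), length(sc))
    hit <- bq == bd & bq %in% c("A", "C", "G", "U")
    sc <- sc + ifelse(hit, params@seq_match, params@seq_mismatch)
  }
  sc
}

.armExtend <- function(qr, er, qb, eb, params, disable_dropoff = FALSE) {
  dropoff_bases <- if (disable_dropoff) length(qr) + length(er) + 1L
                   else params@max_dropoff_bases
  .extendArm(qr, er, qb, eb,
             params@match_min, params@match_max,
             params@mismatch_min, params@mismatch_max,
             params@gap_open, params@gap_ext, params@max_reactivity,
             params@seq_scoring, params@seq_match, params@seq_mismatch,
             params@max_dropoff_rate, dropoff_bases, params@band_fraction)
}

#' Extend a high scoring group into a full alignment
#'
#' The ungapped HSG span is scored column-by-column (the seed score), then
#' extended independently downstream and upstream with a three-state
#' affine-gap DP confined to a band around the seed diagonal, terminating on
#' score drop-off (see [alignParams()]). Each direction's reported extension
#' is the traceback to its best-scoring anti-diagonal cell; the total score
#' is seed plus both extensions.
#'
#' @param query,entry [ReactivityProfile-class] objects.
#' @param hsg one row of [groupHSGs()] output (or any list with
#'   `query_start`, `query_end`, `db_start`, `db_end`, 0-based half-open,
#'   spans of equal length).
#' @param params an [AlignParams-class].
#' @param disable_dropoff internal/testing switch: run the DP to the profile
#'   ends regardless of score drop-off.
#' @param score_only skip traceback column assembly (used when only the
#'   score matters, e.g. null-score collection).
#' @return An [AlignmentResult-class].
#' @export
extendHSG <- function(query, entry, hsg, params = alignParams(),
                      disable_dropoff = FALSE, score_only = FALSE) {
  qs <- as.integer(hsg$query_start); qe <- as.integer(hsg$query_end)
  ds <- as.integer(hsg$db_start); de <- as.integer(hsg$db_end)
  if (qe <= qs || de <= ds) stop("degenerate HSG: empty span")
  if (qe - qs != de - ds) stop("HSG spans must have equal length (ungapped)")
  qcap <- capReactivity(reactivity(query), params@max_reactivity)
  ecap <- capReactivity(reactivity(entry), params@max_reactivity)
  if (qe > length(qcap) || de > length(ecap))
    stop("HSG span exceeds profile length")
  qb <- .encodeBases(profileSequence(query))
  eb <- .encodeBases(profileSequence(entry))
  qbase <- strsplit(profileSequence(query), "", fixed = TRUE)[[1L]]
  ebase <- strsplit(profileSequence(entry), "", fixed = TRUE)[[1L]]
  span <- seq_len(qe - qs)
  seed_score <- sum(scoreColumn(qcap[qs + span], ecap[ds + span],
                                qbase[qs + span], ebase[ds + span], params))
  n <- length(qcap); m <- length(ecap)
  down <- .armExtend(qcap[seq_len(n - qe) + qe], ecap[seq_len(m - de) + de],
                     qb[seq_len(n - qe) + qe], eb[seq_len(m - de) + de],
                     params, disable_dropoff)
  up <- .armExtend(rev(qcap[seq_len(qs)]), rev(ecap[seq_len(ds)]),
                   rev(qb[seq_len(qs)]), rev(eb[seq_len(ds)]),
                   params, disable_dropoff)
  if (score_only) {
    return(new("AlignmentResult",
               query_id = profileID(query), db_entry_id = profileID(entry),
               query_start = qs - up$qlen, query_end = qe + down$qlen,
               db_start = ds - up$elen, db_end = de + down$elen,
               score = seed_score + up$score + down$score,
               columns = data.frame(), seed = list(
                 query_start = qs, query_end = qe, db_start = ds,
                 db_end = de),
               p_value = NA_real_, e_value = NA_real_))
  }
  # seed columns
  cols <- data.frame(state = rep("pair", qe - qs),
                     qi = qs + span - 1L, di = ds + span - 1L,
                     stringsAsFactors = FALSE)
  walk <- function(states, qi0, di0, step) {
    qadv <- as.integer(states %in% c(1L, 2L))
    dadv <- as.integer(states %in% c(1L, 3L))
    qi <- ifelse(qadv == 1L, qi0 + step * (cumsum(qadv) - 1L), NA_integer_)
    di <- ifelse(dadv == 1L, di0 + step * (cumsum(dadv) - 1L), NA_integer_)
    data.frame(state = c("pair", "gap_db", "gap_query")[states],
               qi = as.integer(qi), di = as.integer(di),
               stringsAsFactors = FALSE)
  }
  dcols <- walk(down$states, qe, de, 1L)
  ucols <- walk(up$states, qs - 1L, ds - 1L, -1L)
  ucols <- ucols[rev(seq_len(nrow(ucols))), , drop = FALSE]
  cols <- rbind(ucols, cols, dcols)
  rownames(cols) <- NULL
  new("AlignmentResult",
      query_id = profileID(query), db_entry_id = profileID(entry),
      query_start = qs - up$qlen, query_end = qe + down$qlen,
      db_start = ds - up$elen, db_end = de + down$elen,
      score = seed_score + up$score + down$score,
      columns = cols,
      seed = list(query_start = qs, query_end = qe, db_start = ds,
                  db_end = de),
      p_value = NA_real_, e_value = NA_real_)
}

#' Recompute an alignment score from its columns
#'
#' Sums the column scores of an [AlignmentResult-class] under the given
#' parameters: pair columns score via [scoreColumn()], and each maximal run
#' of gap columns costs `gap_open + (run length - 1) * gap_ext`. Used as a
#' hard consistency check on the DP traceback.
#'
#' @param result an [AlignmentResult-class].
#' @param query,entry the profiles it aligns.
#' @param params an [AlignParams-class].
#' @return The recomputed score.
#' @export
alignmentScore <- function(result, query, entry, params = alignParams()) {
  qcap <- capReactivity(reactivity(query), params@max_reactivity)
  ecap <- capReactivity(reactivity(entry), params@max_reactivity)
  qbase <- strsplit(profileSequence(query), "", fixed = TRUE)[[1L]]
  ebase <- strsplit(profileSequence(entry), "", fixed = TRUE)[[1L]]
  cols <- result@columns
  total <- 0
  prev_state <- "pair"
  for (i in seq_len(nrow(cols))) {
    st <- cols$state[[i]]
    if (st == "pair") {
      total <- total + scoreColumn(qcap[cols$qi[[i]] + 1L],
                                   ecap[cols$di[[i]] + 1L],
                                   qbase[cols$qi[[i]] + 1L],
                                   ebase[cols$di[[i]] + 1L], params)
    } else {
      total <- total + if (st == prev_state) params@gap_ext
                       else params@gap_open
    }
    prev_state <- st
  }
  total
}

# Deduplicate alignments seeded by different HSGs: for the same database
# entry, results overlapping by more than `min_frac` of the shorter interval
# on BOTH axes are redundant; the best-scoring one is kept.
.dedupAlignments <- function(results, min_frac = 0.5) {
  if (length(results) <= 1L) return(results)
  ord <- order(vapply(results, function(r) r@score, numeric(1L)),
               decreasing = TRUE)
  results <- results[ord]
  kept <- list()
  overlap_frac <- function(s1, e1, s2, e2) {
    ov <- min(e1, e2) - max(s1, s2)
    if (ov <= 0) return(0)
    ov / min(e1 - s1, e2 - s2)
  }
  for (r in results) {
    dup <- FALSE
    for (k in kept) {
      if (r@db_entry_id != k@db_entry_id) next
      if (overlap_frac(r@query_start, r@query_end,
                       k@query_start, k@query_end) > min_frac &&
          overlap_frac(r@db_start, r@db_end, k@db_start, k@db_end) > min_frac) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept[[length(kept) + 1L]] <- r
  }
  kept
}

#' Render an alignment as a two-row gapped profile alignment
#'
#' Produces a [ProfileAlignment-class] (gapped sequences plus parallel
#' reactivity tracks) from an [AlignmentResult-class], suitable for
#' consensus-structure evaluation or Stockholm/FASTA output.
#'
#' @param result an [AlignmentResult-class].
#' @param query,entry the aligned profiles.
#' @return A [ProfileAlignment-class] with the query as first row.
#' @export
alignmentToProfileAlignment <- function(result, query, entry) {
  cols <- result@columns
  qbase <- strsplit(profileSequence(query), "", fixed = TRUE)[[1L]]
  ebase <- strsplit(profileSequence(entry), "", fixed = TRUE)[[1L]]
  qseq <- ifelse(is.na(cols$qi), "-", qbase[cols$qi + 1L])
  eseq <- ifelse(is.na(cols$di), "-", ebase[cols$di + 1L])
  qre <- ifelse(is.na(cols$qi), NA_real_, reactivity(query)[cols$qi + 1L])
  ere <- ifelse(is.na(cols$di), NA_real_, reactivity(entry)[cols$di + 1L])
  profileAlignment(
    ids = c(profileID(query), profileID(entry)),
    sequences = c(paste(qseq, collapse = ""), paste(eseq, collapse = "")),
    reactivities = list(qre, ere))
}

#' Write alignments as gapped FASTA with parallel reactivity rows
#'
#' Each alignment row is emitted as a FASTA record followed by a `#react:`
#' comment line carrying the comma-separated gapped reactivities (`-` at gap
#' columns, `NaN` for missing measurements).
#'
#' @param aln a [ProfileAlignment-class].
#' @param path output file; use `""` for stdout.
#' @return `path`, invisibly.
#' @export
writeAlignedFasta <- function(aln, path = "") {
  out <- character(0)
  gaps <- strsplit(aln@sequences, "", fixed = TRUE)
  for (i in seq_len(nrow(aln))) {
    re <- aln@reactivities[[i]]
    tok <- ifelse(gaps[[i]] == "-", "-",
                  ifelse(is.na(re), "NaN", sprintf("%.3f", re)))
    out <- c(out, paste0(">", aln@ids[[i]]), aln@sequences[[i]],
             paste0("#react:", paste(tok, collapse = ",")))
  }
  if (identical(path, "")) writeLines(out) else {
    con <- file(path, "wb"); on.exit(close(con)); writeLines(out, con)
  }
  invisible(path)
}
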