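## Search parameter containers. Defaults are the optimized parameter sets for
## SHAPE reactivities and for base-pairing probabilities; see the methods
## vignette for how each knob acts.

#' SeedParams: kmer enumeration, lookup and grouping parameters
#'
#' @slot kmer_len kmer length (nt).
#' @slot min_kmers minimum co-diagonal kmer matches per high scoring group.
#' @slot max_kmer_dist maximum gap (nt) between consecutive kmer starts on a
#'   diagonal for them to be chained into one group.
#' @slot kmer_min_complexity minimum Gini coefficient of a query kmer's
#'   (capped) reactivities; low-complexity kmers are skipped.
#' @slot kmer_max_match_every_nt promiscuity limit: a kmer matching more than
#'   once every this many database nucleotides (i.e. more than
#'   `totalLength(db) / kmer_max_match_every_nt` times) is discarded.
#' @slot max_gc_diff maximum absolute GC% difference (percentage points)
#'   between a query kmer and a database window; `NA` disables the filter.
#' @slot max_reactivity reactivities are capped at this value before any
#'   comparison.
#' @slot dist_coeff kmer match threshold: an offset matches when its
#'   z-normalized Euclidean distance is `<= dist_coeff * sqrt(kmer_len)`.
#'
#' @exportClass SeedParams
setClass("SeedParams",
  slots = c(kmer_len = "integer", min_kmers = "integer",
            max_kmer_dist = "integer", kmer_min_complexity = "numeric",
            kmer_max_match_every_nt = "integer", max_gc_diff = "numeric",
            max_reactivity = "numeric", dist_coeff = "numeric")
)

setValidity("SeedParams", function(object) {
  msgs <- character()
  if (object@kmer_len < 2L) msgs <- c(msgs, "kmer_len must be >= 2")
  if (object@min_kmers < 1L) msgs <- c(msgs, "min_kmers must be >= 1")
  if (object@max_kmer_dist < 0L) msgs <- c(msgs, "max_kmer_dist must be >= 0")
  if (object@kmer_min_complexity < 0 || object@kmer_min_complexity >= 1)
    msgs <- c(msgs, "kmer_min_complexity must be in [0,1)")
  if (object@kmer_max_match_every_nt < 1L)
    msgs <- c(msgs, "kmer_max_match_every_nt must be >= 1")
  if (object@max_reactivity <= 0) msgs <- c(msgs, "max_reactivity must be > 0")
  if (object@dist_coeff <= 0) msgs <- c(msgs, "dist_coeff must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Seed-stage parameters
#'
#' Returns the optimized defaults for the given profile kind. For SHAPE
#' reactivities: kmer_len 15, min_kmers 2, max_kmer_dist 30,
#' kmer_min_complexity 0.3, kmer_max_match_every_nt 200, max_reactivity 1.
#' For base-pairing probabilities: min_kmers 3, max_kmer_dist 10,
#' kmer_min_complexity 0.4. `max_gc_diff` defaults to 10 percentage points
#' (local GC of structurally related RNAs varies little at kmer length 15);
#' set it to `NA` to disable. `dist_coeff` (default 0.75) sets the match
#' cutoff at `dist_coeff * sqrt(kmer_len)` z-normalized distance units,
#' equivalent to requiring Pearson correlation `>= 1 - dist_coeff^2/2`.
#'
#' @param kind `"shape"`/`"shape-reactivity"` or
#'   `"bpp"`/`"base-pairing-probability"`.
#' @param ... override any [SeedParams-class] slot by name.
#' @return A [SeedParams-class].
#' @examples
#' seedParams()                 # SHAPE defaults
#' seedParams("bpp")            # base-pairing probability defaults
#' seedParams(kmer_len = 10, max_gc_diff = NA)
#' @export
seedParams <- function(kind = c("shape", "bpp", "shape-reactivity",
                                "base-pairing-probability"), ...) {
  kind <- match.arg(kind)
  bpp <- kind %in% c("bpp", "base-pairing-probability")
  defaults <- list(
    kmer_len = 15L, min_kmers = if (bpp) 3L else 2L,
    max_kmer_dist = if (bpp) 10L else 30L,
    kmer_min_complexity = if (bpp) 0.4 else 0.3,
    kmer_max_match_every_nt = 200L, max_gc_diff = 10,
    max_reactivity = 1, dist_coeff = 0.75)
  args <- modifyList(defaults, list(...))
  new("SeedParams",
      kmer_len = as.integer(args$kmer_len),
      min_kmers = as.integer(args$min_kmers),
      max_kmer_dist = as.integer(args$max_kmer_dist),
      kmer_min_complexity = as.numeric(args$kmer_min_complexity),
      kmer_max_match_every_nt = as.integer(args$kmer_max_match_every_nt),
      max_gc_diff = as.numeric(args$max_gc_diff),
      max_reactivity = as.numeric(args$max_reactivity),
      dist_coeff = as.numeric(args$dist_coeff))
}

#' AlignParams: extension scoring and termination parameters
#'
#' The substitution score of a column pairing capped reactivities `rq`, `rd`
#' is a piecewise-linear function of `d = |rq - rd|` with boundary
#' `t = max_reactivity / 2`: for `d <= t` it interpolates from `match_max`
#' (at d = 0) down to `match_min` (at d = t); for `d > t` from
#' `mismatch_max` down to `mismatch_min` (at d = max_reactivity). A column
#' where either value is missing scores 0. With `seq_scoring`, `seq_match`
#' (identical A/C/G/U bases) or `seq_mismatch` is added; N never matches.
#'
#' @slot match_min,match_max reactivity score range for similar values.
#' @slot mismatch_min,mismatch_max score range for dissimilar values.
#' @slot gap_open,gap_ext affine gap penalties (negative).
#' @slot max_dropoff_rate extension in a direction stops once the best score
#'   on the current anti-diagonal stays below `max_dropoff_rate` times the
#'   running best of that direction for more than `max_dropoff_bases`
#'   consecutive anti-diagonals.
#' @slot max_dropoff_bases see above.
#' @slot max_reactivity cap applied before scoring.
#' @slot seq_scoring logical; add sequence identity scoring.
#' @slot seq_match,seq_mismatch sequence bonus/penalty when `seq_scoring`.
#' @slot band_fraction the banded DP half-width at anti-diagonal `s` is
#'   `max(10, ceiling(band_fraction * s))` cells around the seed diagonal.
#'
#' @exportClass AlignParams
setClass("AlignParams",
  slots = c(match_min = "numeric", match_max = "numeric",
            mismatch_min = "numeric", mismatch_max = "numeric",
            gap_open = "numeric", gap_ext = "numeric",
            max_dropoff_rate = "numeric", max_dropoff_bases = "integer",
            max_reactivity = "numeric", seq_scoring = "logical",
            seq_match = "numeric", seq_mismatch = "numeric",
            band_fraction = "numeric")
)

setValidity("AlignParams", function(object) {
  msgs <- character()
  if (object@match_max < object@match_min)
    msgs <- c(msgs, "match_max must be >= match_min")
  if (object@mismatch_max < object@mismatch_min)
    msgs <- c(msgs, "mismatch_max must be >= mismatch_min")
  if (object@gap_open > 0 || object@gap_ext > 0)
    msgs <- c(msgs, "gap penalties must be <= 0")
  if (object@max_dropoff_rate <= 0 || object@max_dropoff_rate > 1)
    msgs <- c(msgs, "max_dropoff_rate must be in (0,1]")
  if (object@max_dropoff_bases < 1L)
    msgs <- c(msgs, "max_dropoff_bases must be >= 1")
  if (object@max_reactivity <= 0)
    msgs <- c(msgs, "max_reactivity must be > 0")
  if (object@band_fraction <= 0 || object@band_fraction > 1)
    msgs <- c(msgs, "band_fraction must be in (0,1]")
  if (length(msgs)) msgs else TRUE
})

#' Alignment extension parameters
#'
#' Optimized defaults for SHAPE reactivities: match score (-0.5, 2),
#' mismatch score (-6, -0.5), gap open -14, gap extend -5, drop-off rate 0.8
#' over 8 bases, max_reactivity 1. For base-pairing probabilities: match
#' (0, 3), mismatch (-7, 0), gap open -12, gap extend -9, drop-off 0.7 over
#' 6 bases. Sequence scoring (off by default) adds +0.5 for a base match and
#' -2 for a mismatch.
#'
#' @param kind `"shape"` or `"bpp"` (long forms accepted).
#' @param seq_scoring enable combined reactivity + sequence scoring.
#' @param ... override any [AlignParams-class] slot by name.
#' @return An [AlignParams-class].
#' @export
alignParams <- function(kind = c("shape", "bpp", "shape-reactivity",
                                 "base-pairing-probability"),
                        seq_scoring = FALSE, ...) {
  kind <- match.arg(kind)
  bpp <- kind %in% c("bpp", "base-pairing-probability")
  defaults <- if (bpp) {
    list(match_min = 0, match_max = 3, mismatch_min = -7, mismatch_max = 0,
         gap_open = -12, gap_ext = -9, max_dropoff_rate = 0.7,
         max_dropoff_bases = 6L, max_reactivity = 1)
  } else {
    list(match_min = -0.5, match_max = 2, mismatch_min = -6,
         mismatch_max = -0.5, gap_open = -14, gap_ext = -5,
         max_dropoff_rate = 0.8, max_dropoff_bases = 8L, max_reactivity = 1)
  }
  defaults <- c(defaults, list(seq_scoring = isTRUE(seq_scoring),
                               seq_match = 0.5, seq_mismatch = -2,
                               band_fraction = 0.25))
  args <- modifyList(defaults, list(...))
  new("AlignParams",
      match_min = as.numeric(args$match_min),
      match_max = as.numeric(args$match_max),
      mismatch_min = as.numeric(args$mismatch_min),
      mismatch_max = as.numeric(args$mismatch_max),
      gap_open = as.numeric(args$gap_open),
      gap_ext = as.numeric(args$gap_ext),
      max_dropoff_rate = as.numeric(args$max_dropoff_rate),
      max_dropoff_bases = as.integer(args$max_dropoff_bases),
      max_reactivity = as.numeric(args$max_reactivity),
      seq_scoring = isTRUE(args$seq_scoring),
      seq_match = as.numeric(args$seq_match),
      seq_mismatch = as.numeric(args$seq_mismatch),
      band_fraction = as.numeric(args$band_fraction))
}

#' ShuffleParams: null-database construction parameters
#'
#' @slot block_size shuffling block size in bases (default 10): profiles are
#'   cut into consecutive blocks whose order is permuted, preserving local
#'   structural context within blocks.
#' @slot n_shuffles shuffles per database entry (default 100).
#' @slot chunk_size maximum length of the chunk extracted from each shuffled
#'   entry (default 1000; must be at least the query window length for an
#'   unbiased null).
#'
#' @exportClass ShuffleParams
setClass("ShuffleParams",
  slots = c(block_size = "integer", n_shuffles = "integer",
            chunk_size = "integer")
)

setValidity("ShuffleParams", function(object) {
  msgs <- character()
  if (object@block_size < 1L) msgs <- c(msgs, "block_size must be >= 1")
  if (object@n_shuffles < 1L) msgs <- c(msgs, "n_shuffles must be >= 1")
  if (object@chunk_size < 1L) msgs <- c(msgs, "chunk_size must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Null-database shuffling parameters
#'
#' @param block_size block size in nt (default 10).
#' @param n_shuffles shuffles per entry (default 100).
#' @param chunk_size maximum chunk length extracted per shuffle
#'   (default 1000).
#' @return A [ShuffleParams-class].
#' @export
shuffleParams <- function(block_size = 10L, n_shuffles = 100L,
                          chunk_size = 1000L) {
  new("ShuffleParams", block_size = as.integer(block_size),
      n_shuffles = as.integer(n_shuffles), chunk_size = as.integer(chunk_size))
}
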