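## Core S4 containers. Sequences are stored as plain character strings over
## {A,C,G,U,N}; reactivities as numeric vectors with NA for missing values.
## Coordinates are 0-based half-open internally, 1-based inclusive in reports.

.VALID_BASES <- c("A", "C", "G", "U", "N")
.DB_KINDS <- c("shape-reactivity", "base-pairing-probability")

#' ReactivityProfile: one transcript's probing signal
#'
#' Holds a transcript identifier, its RNA sequence (alphabet A/C/G/U/N; T is
#' normalized to U on construction) and the per-base reactivity track, with
#' `NA` marking nucleotides without a measurement.
#'
#' @slot id transcript identifier (non-empty string).
#' @slot sequence RNA sequence as a single string, same length as the
#'   reactivity track.
#' @slot reactivity numeric vector of non-negative reactivities; `NA` =
#'   missing.
#'
#' @exportClass ReactivityProfile
setClass("ReactivityProfile",
  slots = c(id = "character", sequence = "character", reactivity = "numeric")
)

setValidity("ReactivityProfile", function(object) {
  msgs <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msgs <- c(msgs, "'id' must be a single non-empty string")
  if (length(object@sequence) != 1L || is.na(object@sequence))
    msgs <- c(msgs, "'sequence' must be a single string")
  else {
    bases <- strsplit(object@sequence, "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(bases), .VALID_BASES)
    if (length(bad))
      msgs <- c(msgs, sprintf("invalid bases in sequence of '%s': %s",
                              object@id, paste(bad, collapse = ",")))
    if (length(bases) != length(object@reactivity))
      msgs <- c(msgs, sprintf(
        "record '%s': sequence length (%d) != reactivity length (%d)",
        object@id, length(bases), length(object@reactivity)))
  }
  if (any(object@reactivity < 0, na.rm = TRUE))
    msgs <- c(msgs, sprintf("record '%s': negative reactivity", object@id))
  if (length(msgs)) msgs else TRUE
})

#' Construct a ReactivityProfile
#'
#' @param id transcript identifier.
#' @param sequence RNA (or DNA) sequence; `T`/`t` are converted to `U`, and
#'   lowercase to uppercase. Only A/C/G/U/N are accepted after conversion.
#' @param reactivity numeric vector of per-base reactivities (`NA` or `NaN`
#'   for missing values); must be non-negative and match the sequence length.
#'
#' @return A [ReactivityProfile-class] object.
#' @examples
#' p <- reactivityProfile("tx1", "ACGT", c(0.1, NA, 2.3, 0))
#' profileSequence(p)  # "ACGU"
#' @export
reactivityProfile <- function(id, sequence, reactivity) {
  sequence <- toupper(sequence)
  sequence <- gsub("T", "U", sequence, fixed = TRUE)
  reactivity <- as.numeric(reactivity)
  reactivity[is.nan(reactivity)] <- NA_real_
  new("ReactivityProfile", id = as.character(id), sequence = sequence,
      reactivity = reactivity)
}

#' @describeIn reactivityProfile transcript identifier accessor.
#' @param x a `ReactivityProfile`.
#' @export
profileID <- function(x) x@id

#' @describeIn reactivityProfile sequence accessor (single string).
#' @export
profileSequence <- function(x) x@sequence

#' @describeIn reactivityProfile reactivity track accessor.
#' @export
reactivity <- function(x) x@reactivity

#' @export
setMethod("length", "ReactivityProfile", function(x) length(x@reactivity))

setMethod("show", "ReactivityProfile", function(object) {
  n <- length(object)
  nmiss <- sum(is.na(object@reactivity))
  cat(sprintf("ReactivityProfile '%s': %d nt, %d missing\n",
              object@id, n, nmiss))
})

#' ProfileDatabase: an ordered collection of reactivity profiles
#'
#' A searchable database of [ReactivityProfile-class] entries, all of one
#' kind: SHAPE-like reactivities (unbounded above) or base-pairing
#' probabilities (values in \[0,1\]). Entry ids must be unique.
#'
#' @slot entries list of `ReactivityProfile`.
#' @slot kind `"shape-reactivity"` or `"base-pairing-probability"`.
#' @slot shuffled logical; `TRUE` for null databases built by block
#'   shuffling.
#' @slot seed integer seed recorded for shuffled databases (`NA` otherwise).
#'
#' @exportClass ProfileDatabase
setClass("ProfileDatabase",
  slots = c(entries = "list", kind = "character", shuffled = "logical",
            seed = "integer")
)

setValidity("ProfileDatabase", function(object) {
  msgs <- character()
  if (!all(vapply(object@entries, is, logical(1L), "ReactivityProfile")))
    msgs <- c(msgs, "all entries must be ReactivityProfile objects")
  else {
    ids <- vapply(object@entries, profileID, character(1L))
    if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("duplicated entry id(s): %s",
                              paste(unique(ids[duplicated(ids)]), collapse = ",")))
    if (object@kind == "base-pairing-probability") {
      over <- vapply(object@entries,
                     function(p) any(p@reactivity > 1, na.rm = TRUE),
                     logical(1L))
      if (any(over))
        msgs <- c(msgs, "base-pairing probabilities must be <= 1")
    }
  }
  if (length(object@kind) != 1L || !object@kind %in% .DB_KINDS)
    msgs <- c(msgs, sprintf("kind must be one of: %s",
                            paste(.DB_KINDS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a ProfileDatabase
#'
#' @param entries list of [ReactivityProfile-class] objects with unique ids.
#' @param kind `"shape-reactivity"` (default) or
#'   `"base-pairing-probability"`.
#' @param shuffled marks a block-shuffled null database.
#' @param seed RNG seed recorded for shuffled databases.
#'
#' @return A [ProfileDatabase-class].
#' @export
profileDatabase <- function(entries, kind = "shape-reactivity",
                            shuffled = FALSE, seed = NA_integer_) {
  kind <- match.arg(kind, .DB_KINDS)
  new("ProfileDatabase", entries = unname(entries), kind = kind,
      shuffled = shuffled, seed = as.integer(seed))
}

#' @export
setMethod("length", "ProfileDatabase", function(x) length(x@entries))

#' @export
setMethod("[[", "ProfileDatabase", function(x, i) {
  if (is.character(i)) {
    hit <- match(i, dbIDs(x))
    if (is.na(hit)) stop("no entry with id '", i, "'")
    i <- hit
  }
  x@entries[[i]]
})

#' Database accessors
#'
#' `totalLength()` is the summed length of all entries (bases); `dbIDs()` the
#' entry identifiers in order; `dbKind()` the database kind; `dbEntries()`
#' the list of profiles.
#'
#' @param db a [ProfileDatabase-class].
#' @return `totalLength()`: integer; `dbIDs()`: character vector;
#'   `dbKind()`: string; `dbEntries()`: list of profiles.
#' @export
totalLength <- function(db) {
  sum(vapply(db@entries, length, integer(1L)))
}

#' @rdname totalLength
#' @export
dbIDs <- function(db) vapply(db@entries, profileID, character(1L))

#' @rdname totalLength
#' @export
dbKind <- function(db) db@kind

#' @rdname totalLength
#' @export
dbEntries <- function(db) db@entries

setMethod("show", "ProfileDatabase", function(object) {
  cat(sprintf("ProfileDatabase: %d entries, %d bases total (%s%s)\n",
              length(object), totalLength(object), object@kind,
              if (isTRUE(object@shuffled)) ", shuffled" else ""))
})

#' NullDistribution: empirical extreme-value null for alignment scores
#'
#' Best alignment score per shuffled database entry, with Gumbel (type-I EVD)
#' location/scale fitted by the method of moments (see [fitEVD()]).
#'
#' @slot scores numeric vector, one best score per shuffled target searched.
#' @slot mu Gumbel location.
#' @slot beta Gumbel scale (> 0).
#' @slot n_trials number of shuffled targets searched.
#'
#' @exportClass NullDistribution
setClass("NullDistribution",
  slots = c(scores = "numeric", mu = "numeric", beta = "numeric",
            n_trials = "integer")
)

setValidity("NullDistribution", function(object) {
  msgs <- character()
  if (length(object@beta) == 1L && !is.na(object@beta) && object@beta <= 0)
    msgs <- c(msgs, "beta must be > 0")
  if (object@n_trials != length(object@scores))
    msgs <- c(msgs, "n_trials must equal length(scores)")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution: %d trials, Gumbel(mu=%.4g, beta=%.4g)\n",
              object@n_trials, object@mu, object@beta))
})

#' FoldEvaluation: consensus-structure significance for an alignment
#'
#' @slot structure consensus dot-bracket over alignment columns.
#' @slot energy consensus free energy of the true alignment (kcal/mol, as
#'   reported by the folding engine).
#' @slot null_energies energies of the shuffled alignments.
#' @slot z energy Z-score against the null.
#' @slot p_value lower-tail normal p-value.
#' @slot bp_support per-row fraction of consensus pairs that are canonical
#'   (AU/GC/GU) in that row.
#'
#' @exportClass FoldEvaluation
setClass("FoldEvaluation",
  slots = c(structure = "character", energy = "numeric",
            null_energies = "numeric", z = "numeric", p_value = "numeric",
            bp_support = "numeric")
)

setMethod("show", "FoldEvaluation", function(object) {
  cat(sprintf(
    "FoldEvaluation: energy %.2f, z = %.3g, p = %.3g, min support %.3g\n",
    object@energy, object@z, object@p_value,
    if (length(object@bp_support)) min(object@bp_support) else NA_real_))
})

#' ProfileAlignment: gapped alignment rows with parallel reactivity tracks
#'
#' Two or more aligned entries; each row carries a gapped sequence (gap
#' symbol `-`) and a gapped reactivity track of identical column count (`NA`
#' at gap columns and at missing measurements). Degapping a row reproduces
#' the original subsequence and reactivity run exactly.
#'
#' @slot ids row identifiers.
#' @slot sequences gapped sequences (equal `nchar`).
#' @slot reactivities list of numeric vectors, one per row, length =
#'   column count.
#'
#' @exportClass ProfileAlignment
setClass("ProfileAlignment",
  slots = c(ids = "character", sequences = "character", reactivities = "list")
)

setValidity("ProfileAlignment", function(object) {
  msgs <- character()
  nc <- unique(nchar(object@sequences))
  if (length(object@sequences) < 2L)
    msgs <- c(msgs, "alignment needs >= 2 rows")
  if (length(nc) > 1L)
    msgs <- c(msgs, "rows must have equal column counts")
  if (length(object@reactivities) != length(object@sequences))
    msgs <- c(msgs, "one reactivity track per row required")
  else if (length(nc) == 1L &&
           !all(lengths(object@reactivities) == nc))
    msgs <- c(msgs, "reactivity tracks must match the column count")
  if (length(object@ids) != length(object@sequences))
    msgs <- c(msgs, "one id per row required")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ProfileAlignment
#'
#' @param ids row identifiers.
#' @param sequences gapped sequences (`-` for gaps), equal lengths.
#' @param reactivities list of per-row gapped reactivity tracks (`NA` at gap
#'   columns).
#' @return A [ProfileAlignment-class].
#' @export
profileAlignment <- function(ids, sequences, reactivities) {
  new("ProfileAlignment", ids = as.character(ids),
      sequences = toupper(as.character(sequences)),
      reactivities = lapply(reactivities, as.numeric))
}

#' @export
setMethod("ncol", "ProfileAlignment",
          function(x) nchar(x@sequences[[1L]]))

#' @export
setMethod("nrow", "ProfileAlignment", function(x) length(x@sequences))

setMethod("show", "ProfileAlignment", function(object) {
  cat(sprintf("ProfileAlignment: %d rows x %d columns (%s)\n",
              nrow(object), ncol(object),
              paste(object@ids, collapse = ", ")))
})
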