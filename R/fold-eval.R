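## Consensus-structure significance: pluggable folding engine, column-block
## alignment shuffling, energy Z-score p-value, per-row base-pair support.

#' Folding engines
#'
#' A folding engine is any function taking a [ProfileAlignment-class] and
#' returning `list(structure = <dot-bracket>, energy = <kcal/mol>)`.
#' `mockFoldEngine()` returns a deterministic engine for testing: a fixed
#' structure and either a fixed energy or one computed by `energy_fn` from
#' the alignment. `rnaalifoldEngine()` returns an adapter that shells out
#' to an RNAalifold-compatible executable, passing each row's reactivities
#' as SHAPE constraint files with Deigan slope/intercept pseudo-energies
#' (probe-specific pairs: 2A3 1.0/-0.4, NAI 1.1/0.0, NAI-N3 2.4/-0.6).
#'
#' @param structure dot-bracket returned by the mock engine.
#' @param energy fixed energy returned by the mock engine.
#' @param energy_fn optional `function(alignment)` overriding `energy`.
#' @return A function: the engine.
#' @export
mockFoldEngine <- function(structure, energy = -10, energy_fn = NULL) {
  force(structure); force(energy); force(energy_fn)
  function(alignment) {
    if (all(strsplit(alignment@sequences[[1L]], "")[[1L]] == "-"))
      stop("degenerate alignment: all-gap row")
    e <- if (is.null(energy_fn)) energy else energy_fn(alignment)
    list(structure = structure, energy = e)
  }
}

#' @rdname mockFoldEngine
#' @param slope,intercept Deigan pseudo-energy parameters for the probing
#'   reagent used (defaults: the 2A3 pair 1.0/-0.4).
#' @param use_reactivities pass the reactivity tracks to the engine
#'   (disable to fold on sequence alone).
#' @param executable name/path of the RNAalifold-compatible binary.
#' @export
rnaalifoldEngine <- function(slope = 1.0, intercept = -0.4,
                             use_reactivities = TRUE,
                             executable = "RNAalifold") {
  force(slope); force(intercept); force(use_reactivities); force(executable)
  function(alignment) {
    if (Sys.which(executable) == "")
      stop("folding engine unavailable: '", executable, "' not on PATH")
    nonGap <- vapply(strsplit(alignment@sequences, "", fixed = TRUE),
                     function(b) any(b != "-"), logical(1L))
    if (!all(nonGap)) stop("degenerate alignment: all-gap row")
    dir <- tempfile("alifold")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    aln_file <- file.path(dir, "aln.clustal")
    ids <- sprintf("row%d", seq_len(nrow(alignment)))
    writeLines(c("CLUSTAL W (shapesearch)", "",
                 sprintf("%-10s %s", ids, alignment@sequences)), aln_file)
    args <- c("--noPS", "-q")
    if (use_reactivities) {
      shape_files <- character(nrow(alignment))
      for (i in seq_len(nrow(alignment))) {
        bases <- strsplit(alignment@sequences[[i]], "", fixed = TRUE)[[1L]]
        re <- alignment@reactivities[[i]][bases != "-"]
        keep <- which(!is.na(re))
        shape_files[[i]] <- file.path(dir, sprintf("row%d.shape", i))
        writeLines(sprintf("%d %.4f", keep, re[keep]), shape_files[[i]])
      }
      args <- c(args,
                paste0("--shape=", paste(shape_files, collapse = ",")),
                sprintf("--shapeMethod=Dm%gb%g", slope, intercept))
    }
    out <- suppressWarnings(
      system2(executable, c(args, shQuote(aln_file)), stdout = TRUE,
              stderr = FALSE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0)
      stop("folding engine failed (exit ", status, ")")
    # output: sequence line, then "structure (energy = ...)"
    struct_line <- grep("^[.()]+", out, value = TRUE)[1]
    if (is.na(struct_line)) stop("could not parse folding engine output")
    structure <- sub("^([.()]+).*$", "\\1", struct_line)
    energy <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*=.*", "\\1",
                             struct_line))
    if (is.na(energy))
      stop("could not parse consensus energy from engine output")
    list(structure = structure, energy = energy)
  }
}

#' Shuffle alignment columns in blocks
#'
#' Columns are partitioned into consecutive blocks of `block` (last block
#' possibly shorter); the block order is permuted and then the columns
#' within each block are permuted. A column moves as a unit across all rows
#' and both tracks, so per-row degapped (base, reactivity) multisets are
#' preserved.
#'
#' @param alignment a [ProfileAlignment-class] (>= 2 columns).
#' @param block block size in columns (default 3).
#' @return A shuffled [ProfileAlignment-class].
#' @export
shuffleAlignment <- function(alignment, block = 3L) {
  nc <- ncol(alignment)
  stopifnot(nc >= 2L)
  starts <- seq.int(1L, nc, by = block)
  blocks <- lapply(starts, function(s) s:min(s + block - 1L, nc))
  blocks <- blocks[sample.int(length(blocks))]
  idx <- unlist(lapply(blocks, function(b)
    if (length(b) > 1L) b[sample.int(length(b))] else b), use.names = FALSE)
  chars <- strsplit(alignment@sequences, "", fixed = TRUE)
  profileAlignment(
    ids = alignment@ids,
    sequences = vapply(chars, function(b) paste(b[idx], collapse = ""),
                       character(1L)),
    reactivities = lapply(alignment@reactivities, `[`, idx))
}

#' Evaluate an alignment for a significant consensus structure
#'
#' Folds the true alignment once, then folds `n_shuffles` column-block
#' shuffles of it ([shuffleAlignment()]) to build a null energy
#' distribution. The true energy is converted into
#' `z = (energy - mean(null)) / sd(null)` and a lower-tail normal p-value
#' `p = pnorm(z)`: a consensus structure markedly more stable than those of
#' shuffled alignments is significant. A zero-variance null is degenerate
#' and reported as `p = 1`.
#'
#' @param alignment a [ProfileAlignment-class].
#' @param engine a folding engine (see [mockFoldEngine()]).
#' @param n_shuffles shuffled alignments to fold (default 100).
#' @param block shuffle block size in columns (default 3).
#' @return A [FoldEvaluation-class] (base-pair support filled via
#'   [bpSupport()]).
#' @export
evaluateFold <- function(alignment, engine, n_shuffles = 100L, block = 3L) {
  true <- engine(alignment)
  null_e <- vapply(seq_len(n_shuffles), function(i)
    engine(shuffleAlignment(alignment, block))$energy, numeric(1L))
  s <- sd(null_e)
  if (is.na(s) || s == 0) {
    z <- 0; p <- 1  # degenerate null
  } else {
    z <- (true$energy - mean(null_e)) / s
    p <- pnorm(z)
  }
  new("FoldEvaluation", structure = true$structure, energy = true$energy,
      null_energies = null_e, z = z, p_value = p,
      bp_support = bpSupport(true$structure, alignment))
}

.parsePairs <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1L]]
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(chars)) {
    if (chars[[i]] == "(") {
      stack <- c(stack, i)
    } else if (chars[[i]] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket structure")
      pairs <- rbind(pairs, c(stack[[length(stack)]], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket structure")
  pairs
}

.CANONICAL <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Per-row base-pair support of a consensus structure
#'
#' For each alignment row, the fraction of the structure's base pairs whose
#' two bases in that row form a canonical pair (AU, GC or GU, either
#' orientation, case-insensitive). A pair touching a gap or N in a row is
#' non-canonical for that row. With zero pairs the support is undefined
#' (`NaN` per row).
#'
#' @param structure dot-bracket over the alignment columns.
#' @param alignment a [ProfileAlignment-class].
#' @return Numeric vector of per-row fractions.
#' @export
bpSupport <- function(structure, alignment) {
  if (nchar(structure) != ncol(alignment))
    stop("structure length does not match alignment columns")
  pairs <- .parsePairs(structure)
  chars <- strsplit(toupper(alignment@sequences), "", fixed = TRUE)
  vapply(chars, function(b) {
    if (nrow(pairs) == 0L) return(NaN)
    mean(paste0(b[pairs[, 1L]], b[pairs[, 2L]]) %in% .CANONICAL)
  }, numeric(1L))
}

#' Retention gate for fold evaluations
#'
#' A structure is retained when its energy p-value is below `p_cut` and
#' every row's base-pair support reaches `support_cut`. Structures with no
#' base pairs (undefined support) are never retained.
#'
#' @param fold_eval a [FoldEvaluation-class].
#' @param p_cut p-value cutoff (default 0.05).
#' @param support_cut minimum per-row support (default 0.75).
#' @param aggregate `"min"` (default: every row must reach the cutoff) or
#'   `"mean"` (average support across rows).
#' @return Logical flag.
#' @export
retainFold <- function(fold_eval, p_cut = 0.05, support_cut = 0.75,
                       aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  sup <- fold_eval@bp_support
  if (length(sup) == 0L || anyNA(sup) || any(is.nan(sup))) return(FALSE)
  agg <- if (aggregate == "min") min(sup) else mean(sup)
  isTRUE(fold_eval@p_value < p_cut && agg >= support_cut)
}

#' Write a profile alignment as Stockholm
#'
#' Emits Stockholm 1.0 with the aligned rows and, when a structure is
#' given, a `#=GC SS_cons` consensus-structure line.
#'
#' @param alignment a [ProfileAlignment-class].
#' @param path output file.
#' @param structure optional consensus dot-bracket.
#' @return `path`, invisibly.
#' @export
writeStockholm <- function(alignment, path, structure = NULL) {
  width <- max(nchar(alignment@ids), nchar("#=GC SS_cons"))
  lines <- c("# STOCKHOLM 1.0", "",
             sprintf("%-*s %s", width, alignment@ids, alignment@sequences))
  if (!is.null(structure))
    lines <- c(lines, sprintf("%-*s %s", width, "#=GC SS_cons", structure))
  lines <- c(lines, "//")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
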