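## Reading, capping and persisting reactivity-profile databases.

.parseReactivityTokens <- function(tokens, id) {
  tokens <- trimws(tokens)
  vals <- suppressWarnings(as.numeric(tokens))
  missing <- toupper(tokens) %in% c("NAN", "NA")
  bad <- which(is.na(vals) & !missing)
  if (length(bad))
    stop(sprintf("record '%s': unparseable reactivity token '%s' at position %d",
                 id, tokens[bad[1L]], bad[1L]))
  vals[missing] <- NA_real_
  if (any(vals < 0, na.rm = TRUE))
    stop(sprintf("record '%s': negative reactivity", id))
  vals
}

.makeProfileChecked <- function(id, sequence, reactivity_string) {
  sequence <- gsub("[[:space:]]", "", sequence)
  tokens <- strsplit(gsub("[[:space:]]", "", reactivity_string), ",",
                     fixed = TRUE)[[1L]]
  vals <- .parseReactivityTokens(tokens, id)
  if (nchar(sequence) != length(vals))
    stop(sprintf("record '%s': sequence length (%d) != reactivity length (%d)",
                 id, nchar(sequence), length(vals)))
  reactivityProfile(id, sequence, vals)
}

#' Read reactivity profiles from RNA Framework-style XML
#'
#' Parses normalized reactivity XML as produced by probing-data analysis
#' pipelines: each transcript record carries an `id`, a nucleotide sequence,
#' and a comma-separated reactivity string of equal length, with `NaN`
#' marking unmeasured positions. `T` is normalized to `U`; whitespace and
#' newlines inside the sequence and reactivity blocks are ignored. Records
#' are any XML nodes that contain both a `<sequence>` and a `<reactivity>`
#' child; the id is taken from the node's `id` attribute.
#'
#' @param path XML file path.
#' @return A list of [ReactivityProfile-class] objects.
#' @examples
#' xml <- paste0('<data><transcript id="tx1" length="4">',
#'               "<sequence>ACGT</sequence>",
#'               "<reactivity>0.1,NaN,2.3,0.0</reactivity>",
#'               "</transcript></data>")
#' f <- tempfile(fileext = ".xml"); writeLines(xml, f)
#' readRNAFrameworkXML(f)
#' @export
readRNAFrameworkXML <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//*[sequence and reactivity]")
  if (length(nodes) == 0L)
    stop("no transcript records (nodes with <sequence> and <reactivity>) in ",
         path)
  lapply(nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    if (is.na(id) || !nzchar(id))
      stop("transcript record without an 'id' attribute in ", path)
    .makeProfileChecked(
      id,
      xml2::xml_text(xml2::xml_find_first(node, "./sequence")),
      xml2::xml_text(xml2::xml_find_first(node, "./reactivity")))
  })
}

#' Read reactivity profiles from a TSV
#'
#' Plain-text fallback input: three tab-separated columns per line
#' (id, sequence, comma-separated reactivities with `NaN` for missing).
#' Lines starting with `#` are skipped.
#'
#' @param path TSV file path.
#' @return A list of [ReactivityProfile-class] objects.
#' @export
readReactivityTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 3L)
      stop("TSV line must have 3 tab-separated fields: ", substr(ln, 1, 50))
    .makeProfileChecked(parts[[1L]], parts[[2L]], parts[[3L]])
  })
}

#' Cap reactivities at a maximum value
#'
#' Replaces each non-missing value `v` by `min(v, max_reactivity)`; missing
#' values are preserved. Idempotent; the input object is not modified.
#'
#' @param x a [ReactivityProfile-class] or a numeric vector.
#' @param max_reactivity positive cap.
#' @return Same type as `x` with capped values.
#' @export
capReactivity <- function(x, max_reactivity) {
  stopifnot(is.numeric(max_reactivity), length(max_reactivity) == 1L,
            max_reactivity > 0)
  if (is(x, "ReactivityProfile")) {
    x@reactivity <- pmin(x@reactivity, max_reactivity)
    x
  } else {
    pmin(as.numeric(x), max_reactivity)
  }
}

.DB_FORMAT_VERSION <- 1L

#' Persist and load profile databases
#'
#' The on-disk format is versioned plain text: a header line
#' `#shapesearchdb v<version> kind=<kind> [shuffled=1 seed=<seed>]`, then
#' three lines per entry: `>id`, the sequence, and the comma-separated
#' reactivities (`NaN` for missing, full double precision). The round trip
#' `loadProfileDb(writeProfileDb(db, path))` reproduces ids, sequences and
#' reactivities bit-exactly.
#'
#' @param db a [ProfileDatabase-class].
#' @param path file path.
#' @return `writeProfileDb()`: `path`, invisibly. `loadProfileDb()`: a
#'   [ProfileDatabase-class].
#' @export
writeProfileDb <- function(db, path) {
  stopifnot(is(db, "ProfileDatabase"))
  validObject(db)
  header <- sprintf("#shapesearchdb v%d kind=%s", .DB_FORMAT_VERSION, db@kind)
  if (isTRUE(db@shuffled)) {
    header <- paste0(header, " shuffled=1")
    if (!is.na(db@seed)) header <- paste0(header, sprintf(" seed=%d", db@seed))
  }
  con <- file(path, "wb")  # binary mode: byte-identical output across platforms
  on.exit(close(con))
  writeLines(header, con)
  for (p in db@entries) {
    vals <- ifelse(is.na(p@reactivity), "NaN", sprintf("%.17g", p@reactivity))
    writeLines(c(paste0(">", p@id), p@sequence, paste(vals, collapse = ",")),
               con)
  }
  invisible(path)
}

#' @rdname writeProfileDb
#' @export
loadProfileDb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[[1L]], "#shapesearchdb "))
    stop("not a shapesearch database (missing '#shapesearchdb' header): ",
         path)
  header <- strsplit(lines[[1L]], " ", fixed = TRUE)[[1L]]
  version <- sub("^v", "", header[[2L]])
  if (!identical(version, as.character(.DB_FORMAT_VERSION)))
    stop(sprintf("unsupported database format version '%s' (this build reads v%d)",
                 version, .DB_FORMAT_VERSION))
  fields <- header[-(1:2)]
  kv <- strsplit(fields, "=", fixed = TRUE)
  opts <- stats::setNames(vapply(kv, `[`, character(1L), 2L),
                          vapply(kv, `[`, character(1L), 1L))
  kind <- opts[["kind"]]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) %% 3L != 0L)
    stop("corrupt database file (entry lines not a multiple of 3): ", path)
  n <- length(body) %/% 3L
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    idline <- body[[3L * i - 2L]]
    if (!startsWith(idline, ">"))
      stop(sprintf("corrupt database file at entry %d: expected '>id' line", i))
    entries[[i]] <- .makeProfileChecked(sub("^>", "", idline),
                                        body[[3L * i - 1L]], body[[3L * i]])
  }
  profileDatabase(entries, kind = kind,
                  shuffled = identical(unname(opts["shuffled"]), "1"),
                  seed = if ("seed" %in% names(opts))
                    as.integer(opts[["seed"]]) else NA_integer_)
}
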