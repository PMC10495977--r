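#' Read a span-annotated corpus from JSON
#'
#' The JSON dialect (UTF-8) is
#' \code{\{"schema": [labels...], "sentences": [\{"id", "text", "entities":
#' [\{"label", "start", "end", "surface"\}]\}]\}} with 0-based half-open
#' character offsets.  Every span is validated against its sentence;
#' validation failures name the offending sentence and span.
#'
#' @param path Path to a JSON corpus file.
#' @param schema Optional schema overriding the one stored in the file.
#' @return A validated \code{\linkS4class{SpanCorpus}}.
#' @seealso \code{\link{writeJsonCorpus}}
#' @export
readJsonCorpus <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$sentences))
    stop("malformed corpus JSON: missing 'sentences' field in ", path)
  if (is.null(schema)) {
    schema <- vapply(doc$schema, as.character, character(1))
    if (length(schema) == 0L) stop("corpus JSON has no schema and none was supplied")
  }
  ids <- character(0); texts <- character(0); rows <- list()
  for (s in doc$sentences) {
    if (is.null(s$id) || is.null(s$text))
      stop("malformed corpus JSON: sentence missing 'id' or 'text'")
    ids <- c(ids, as.character(s$id))
    texts <- c(texts, as.character(s$text))
    for (e in s$entities) {
      rows[[length(rows) + 1L]] <- data.frame(
        sentence_id = as.character(s$id), label = as.character(e$label),
        start = as.integer(e$start), end = as.integer(e$end),
        surface = as.character(e$surface),
        source = if (is.null(e$source)) "manual" else as.character(e$source),
        stringsAsFactors = FALSE)
    }
  }
  ent <- if (length(rows)) do.call(rbind, rows) else NULL
  SpanCorpus(ids = ids, texts = texts, entities = ent, schema = schema)
}

#' Write a corpus to the JSON dialect
#'
#' Output is deterministic (byte-stable for a given corpus) and round-trips
#' exactly through \code{\link{readJsonCorpus}}, including nested spans.
#'
#' @param corpus A \code{\linkS4class{SpanCorpus}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeJsonCorpus <- function(corpus, path) {
  ent <- corpus@entities
  sentences <- lapply(seq_along(corpus@ids), function(i) {
    sid <- corpus@ids[i]
    rows <- ent[ent$sentence_id == sid, , drop = FALSE]
    list(id = sid, text = corpus@texts[i],
         entities = lapply(seq_len(nrow(rows)), function(r) {
           list(label = rows$label[r], start = rows$start[r],
                end = rows$end[r], surface = rows$surface[r],
                source = rows$source[r])
         }))
  })
  json <- jsonlite::toJSON(list(schema = corpus@schema, sentences = sentences),
                           auto_unbox = TRUE, pretty = 2, digits = NA)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

#' Convert annotated sentences to per-character BIO tags
#'
#' BIO tagging assigns one tag per character: \code{B-<label>} at an entity
#' start, \code{I-<label>} inside, \code{O} outside.  BIO cannot express
#' nesting, so when spans nest or overlap only a maximal non-overlapping
#' subset is encoded: candidates are taken outermost-first (earlier start,
#' then longer span) and every dropped span raises a warning naming it.
#'
#' @param corpus A \code{\linkS4class{SpanCorpus}}.
#' @param ids Sentence ids to convert (default all).
#' @return Named list (by sentence id) of character vectors of tags, one tag
#'   per character.
#' @export
toBIO <- function(corpus, ids = sentenceIds(corpus)) {
  ent <- corpus@entities
  out <- list()
  for (sid in ids) {
    text <- corpus@texts[match(sid, corpus@ids)]
    n <- nchar(text)
    tags <- rep("O", n)
    rows <- ent[ent$sentence_id == sid, , drop = FALSE]
    if (nrow(rows)) {
      rows <- rows[order(rows$start, -(rows$end - rows$start)), , drop = FALSE]
      covered <- rep(FALSE, n)
      for (r in seq_len(nrow(rows))) {
        idx <- (rows$start[r] + 1L):rows$end[r]
        if (any(covered[idx])) {
          warning(sprintf("BIO cannot encode span [%d,%d) '%s' in sentence '%s'; dropped",
                          rows$start[r], rows$end[r], rows$label[r], sid),
                  call. = FALSE)
          next
        }
        covered[idx] <- TRUE
        tags[idx[1L]] <- paste0("B-", rows$label[r])
        if (length(idx) > 1L) tags[idx[-1L]] <- paste0("I-", rows$label[r])
      }
    }
    out[[sid]] <- tags
  }
  out
}

#' Recover entity spans from a BIO tag sequence
#'
#' Inverse of \code{\link{toBIO}} for flat (non-nested) annotation.  An
#' orphan \code{I-} tag (no preceding \code{B-}/\code{I-} of the same label)
#' is repaired to \code{B-} with a warning, so third-party BIO files with
#' minor defects still import.
#'
#' @param chars Character vector, one element per character of the sentence.
#' @param tags Character vector of BIO tags, same length as \code{chars}.
#' @param schema Entity-type schema the labels must belong to.
#' @param id Sentence id for the result (default \code{"s1"}).
#' @return A one-sentence \code{\linkS4class{SpanCorpus}}.
#' @export
fromBIO <- function(chars, tags, schema = rehabSchema(), id = "s1") {
  if (length(chars) != length(tags))
    stop("chars and tags must have equal length (", length(chars),
         " vs ", length(tags), ")")
  n <- length(tags)
  # repair orphan I- tags
  prevLabel <- NA_character_
  for (i in seq_len(n)) {
    t <- tags[i]
    if (startsWith(t, "I-")) {
      lb <- substring(t, 3L)
      if (is.na(prevLabel) || prevLabel != lb) {
        warning(sprintf("orphan tag '%s' at position %d repaired to 'B-%s'",
                        t, i - 1L, lb), call. = FALSE)
        tags[i] <- paste0("B-", lb)
      }
      prevLabel <- lb
    } else if (startsWith(t, "B-")) {
      prevLabel <- substring(t, 3L)
    } else prevLabel <- NA_character_
  }
  text <- paste(chars, collapse = "")
  rows <- list()
  i <- 1L
  while (i <= n) {
    if (startsWith(tags[i], "B-")) {
      lb <- substring(tags[i], 3L)
      j <- i
      while (j < n && identical(tags[j + 1L], paste0("I-", lb))) j <- j + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        sentence_id = id, label = lb, start = i - 1L, end = j,
        surface = sliceText(text, i - 1L, j), source = "manual",
        stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  SpanCorpus(ids = id, texts = text,
             entities = if (length(rows)) do.call(rbind, rows) else NULL,
             schema = schema)
}

#' Read / write BIO-tagged text files
#'
#' File format: one character, a tab, and its tag per line; sentences
#' separated by a blank line.
#'
#' @param path File path.
#' @param schema Entity-type schema (read).
#' @return \code{readBioCorpus}: a \code{\linkS4class{SpanCorpus}} with
#'   sentence ids \code{s1, s2, ...}.
#' @export
readBioCorpus <- function(path, schema = rehabSchema()) {
  lines <- readLines(path, encoding = "UTF-8")
  blocks <- split(lines, cumsum(!nzchar(lines)))
  corpus <- NULL
  k <- 0L
  for (bl in blocks) {
    bl <- bl[nzchar(bl)]
    if (!length(bl)) next
    k <- k + 1L
    parts <- strsplit(bl, "\t", fixed = TRUE)
    chars <- vapply(parts, `[`, character(1), 1L)
    tags <- vapply(parts, `[`, character(1), 2L)
    one <- fromBIO(chars, tags, schema = schema, id = paste0("s", k))
    corpus <- if (is.null(corpus)) one else bindCorpora(corpus, one)
  }
  if (is.null(corpus)) SpanCorpus(character(0), character(0), schema = schema)
  else corpus
}

#' @rdname readBioCorpus
#' @param corpus A \code{\linkS4class{SpanCorpus}} to write.
#' @export
writeBioCorpus <- function(corpus, path) {
  tags <- toBIO(corpus)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(corpus@ids)) {
    chars <- splitChars(corpus@texts[i])
    writeLines(paste(chars, tags[[corpus@ids[i]]], sep = "\t"), con,
               useBytes = TRUE)
    if (i < length(corpus@ids)) writeLines("", con)
  }
  invisible(path)
}

#' Deterministic train/test split
#'
#' Partitions the sentences into a training and a test corpus.  The training
#' set has \code{round(n * trainFraction)} sentences; the split is a
#' disjoint, exhaustive partition and is identical for identical seeds.
#'
#' @param corpus A \code{\linkS4class{SpanCorpus}} with at least 2 sentences.
#' @param trainFraction Fraction in (0, 1); the conventional evaluation setup
#'   uses 0.9 (a 9:1 train:test ratio).
#' @param seed Integer RNG seed.
#' @return List with elements \code{train} and \code{test}.
#' @export
splitCorpus <- function(corpus, trainFraction = 0.9, seed = 1L) {
  n <- length(corpus)
  if (n < 2L) stop("need at least 2 sentences to split")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  nTrain <- as.integer(round(n * trainFraction))
  nTrain <- max(1L, min(n - 1L, nTrain))
  perm <- withSeed(seed, sample.int(n))
  list(train = subsetCorpus(corpus, corpus@ids[sort(perm[seq_len(nTrain)])]),
       test = subsetCorpus(corpus, corpus@ids[sort(perm[(nTrain + 1L):n])]))
}

#' Deterministic k-fold partition
#'
#' Assigns every sentence to exactly one test fold; fold sizes differ by at
#' most one (larger folds first).
#'
#' @param corpus A \code{\linkS4class{SpanCorpus}}.
#' @param k Number of folds (>= 2, <= number of sentences); 5 is the
#'   conventional choice for small corpora.
#' @param seed Integer RNG seed.
#' @return List of \code{k} lists, each with elements \code{train} and
#'   \code{test}.
#' @export
kfoldSplit <- function(corpus, k = 5L, seed = 1L) {
  n <- length(corpus)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of sentences (", n, ")")
  perm <- withSeed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  lapply(seq_len(k), function(f) {
    testIdx <- perm[starts[f]:stops[f]]
    list(train = subsetCorpus(corpus, corpus@ids[sort(setdiff(perm, testIdx))]),
         test = subsetCorpus(corpus, corpus@ids[sort(testIdx)]))
  })
}

#' Annotation-rule checks beyond structural validity
#'
#' Structural invariants (offsets in range, surface/slice agreement, labels
#' in schema) are enforced by the \code{SpanCorpus} constructor.  This
#' validator adds the corpus-construction rule checks as warnings:
#' overlapping annotation within a sentence, and entity surfaces consisting
#' entirely of Latin script (full foreign-language vocabulary is not meant
#' to be annotated).  Warnings, not errors, because nested annotation is a
#' deliberate feature of span-based corpora.
#'
#' @param corpus A \code{\linkS4class{SpanCorpus}}.
#' @param warnOverlap Check for overlapping/nested spans (default TRUE).
#' @param warnLatin Check for all-Latin-script surfaces (default TRUE).
#' @return Invisibly, a character vector of warning messages (empty if clean).
#' @export
validateCorpus <- function(corpus, warnOverlap = TRUE, warnLatin = TRUE) {
  msgs <- character(0)
  ent <- corpus@entities
  if (warnOverlap && nrow(ent) > 1L) {
    for (sid in unique(ent$sentence_id)) {
      rows <- ent[ent$sentence_id == sid, , drop = FALSE]
      if (nrow(rows) < 2L) next
      for (a in seq_len(nrow(rows) - 1L)) for (b in (a + 1L):nrow(rows)) {
        if (rows$start[a] < rows$end[b] && rows$start[b] < rows$end[a])
          msgs <- c(msgs, sprintf(
            "sentence '%s': spans [%d,%d) '%s' and [%d,%d) '%s' overlap",
            sid, rows$start[a], rows$end[a], rows$label[a],
            rows$start[b], rows$end[b], rows$label[b]))
      }
    }
  }
  if (warnLatin && nrow(ent)) {
    latin <- grepl("^[A-Za-z]+$", ent$surface)
    for (r in which(latin))
      msgs <- c(msgs, sprintf(
        "sentence '%s': surface '%s' is entirely Latin script",
        ent$sentence_id[r], ent$surface[r]))
  }
  for (m in msgs) warning(m, call. = FALSE)
  invisible(msgs)
}
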