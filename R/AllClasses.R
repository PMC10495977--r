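#' @import methods
NULL

#' Default entity-type schema for rehabilitation-medicine text
#'
#' The six entity categories used throughout the package: dysfunctions and
#' clinical performances, rehabilitation assessments, rehabilitation methods,
#' rehabilitation equipment, body parts, and drugs.  Schemas are ordered
#' character vectors of unique, non-empty labels; the order is stable across
#' save/load.
#'
#' @return Character vector of six entity-type labels.
#' @export
#' @examples
#' rehabSchema()
rehabSchema <- function() {
  c("dysfunction and performance", "rehabilitation assessment",
    "rehabilitation methods", "rehabilitation equipment", "body", "drugs")
}

checkSchema <- function(labels) {
  if (length(labels) == 0L) return("schema must contain at least one label")
  if (anyDuplicated(labels)) return("schema labels must be unique")
  if (any(!nzchar(labels))) return("schema labels must be non-empty")
  TRUE
}

#' SpanCorpus: a span-annotated sentence collection
#'
#' An S4 container holding sentences with typed character-offset entity
#' mentions.  Coordinates are 0-based half-open offsets on the raw sentence
#' string, so an entity \code{(start, end)} covers
#' \code{substr(text, start + 1, end)} and nesting/overlap is representable.
#'
#' @slot ids Character vector of unique sentence identifiers.
#' @slot texts Character vector of sentence strings, parallel to \code{ids}.
#' @slot entities data.frame with columns \code{sentence_id}, \code{label},
#'   \code{start}, \code{end}, \code{surface}, \code{source} (provenance,
#'   \code{"manual"} or \code{"model"}).
#' @slot schema Ordered character vector of entity-type labels.
#'
#' @section Validity:
#' Sentence ids unique; every entity references a known sentence; every label
#' is in the schema; \code{0 <= start < end <= nchar(text)}; \code{surface}
#' equals the text slice \code{[start, end)}.
#'
#' @name SpanCorpus-class
#' @rdname SpanCorpus-class
#' @exportClass SpanCorpus
setClass("SpanCorpus",
  representation(ids = "character", texts = "character",
                 entities = "data.frame", schema = "character"))

setValidity("SpanCorpus", function(object) {
  msgs <- character(0)
  sc <- checkSchema(object@schema)
  if (!isTRUE(sc)) msgs <- c(msgs, sc)
  if (length(object@ids) != length(object@texts))
    msgs <- c(msgs, "ids and texts must have equal length")
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, sprintf("duplicate sentence ids: %s",
                            paste(unique(object@ids[duplicated(object@ids)]),
                                  collapse = ", ")))
  ent <- object@entities
  need <- c("sentence_id", "label", "start", "end", "surface", "source")
  if (!all(need %in% names(ent))) {
    msgs <- c(msgs, sprintf("entities must have columns %s",
                            paste(need, collapse = ", ")))
  } else if (nrow(ent) > 0L) {
    nch <- setNames(nchar(object@texts), object@ids)
    for (r in seq_len(nrow(ent))) {
      sid <- ent$sentence_id[r]
      tag <- sprintf("sentence '%s' span [%s,%s) '%s'",
                     sid, ent$start[r], ent$end[r], ent$label[r])
      if (!sid %in% object@ids) {
        msgs <- c(msgs, sprintf("%s: unknown sentence id", tag)); next
      }
      if (!ent$label[r] %in% object@schema)
        msgs <- c(msgs, sprintf("%s: label not in schema", tag))
      if (is.na(ent$start[r]) || is.na(ent$end[r]) ||
          ent$start[r] < 0L || ent$start[r] >= ent$end[r] ||
          ent$end[r] > nch[[sid]]) {
        msgs <- c(msgs, sprintf("%s: offsets out of range for sentence of length %d",
                                tag, nch[[sid]]))
        next
      }
      text <- object@texts[match(sid, object@ids)]
      slice <- sliceText(text, ent$start[r], ent$end[r])
      if (!identical(slice, ent$surface[r]))
        msgs <- c(msgs, sprintf("%s: surface '%s' does not match text slice '%s'",
                                tag, ent$surface[r], slice))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpanCorpus
#'
#' @param ids Character vector of unique sentence identifiers.
#' @param texts Character vector of sentence strings (UTF-8), parallel to
#'   \code{ids}.
#' @param entities data.frame of entity spans with columns
#'   \code{sentence_id}, \code{label}, \code{start}, \code{end},
#'   \code{surface} and optionally \code{source}; 0-based half-open
#'   character offsets.  May be \code{NULL} for an unannotated corpus.
#' @param schema Ordered character vector of entity-type labels
#'   (default \code{\link{rehabSchema}()}).
#' @return A validated \code{\linkS4class{SpanCorpus}}.
#' @export
#' @examples
#' SpanCorpus(ids = "s1", texts = "patient limb numbness",
#'            entities = data.frame(sentence_id = "s1", label = "body",
#'                                  start = 8, end = 12, surface = "limb"))
SpanCorpus <- function(ids, texts, entities = NULL, schema = rehabSchema()) {
  new("SpanCorpus", ids = as.character(ids), texts = as.character(texts),
      entities = asEntityFrame(entities), schema = as.character(schema))
}

#' @describeIn SpanCorpus-class Number of sentences.
#' @param x A \code{SpanCorpus}.
#' @export
setMethod("length", "SpanCorpus", function(x) length(x@ids))

#' Accessors for SpanCorpus
#'
#' \code{sentenceIds}, \code{sentenceTexts}, \code{entities} and
#' \code{schema} extract the corresponding slots; \code{entityCount} returns
#' the total number of entity mentions.
#'
#' @param x A \code{\linkS4class{SpanCorpus}}.
#' @return \code{sentenceIds}/\code{sentenceTexts}: character vectors;
#'   \code{entities}: a data.frame of spans; \code{schema}: character vector
#'   of labels; \code{entityCount}: integer.
#' @name corpus-accessors
NULL

#' @rdname corpus-accessors
#' @export
sentenceIds <- function(x) x@ids

#' @rdname corpus-accessors
#' @export
sentenceTexts <- function(x) setNames(x@texts, x@ids)

#' @rdname corpus-accessors
#' @export
entities <- function(x) x@entities

#' @rdname corpus-accessors
#' @export
schema <- function(x) x@schema

#' @rdname corpus-accessors
#' @export
entityCount <- function(x) nrow(x@entities)

#' Subset a corpus by sentence ids
#'
#' Keeps the given sentences (in the given order) and their entities.
#'
#' @param x A \code{\linkS4class{SpanCorpus}}.
#' @param ids Character vector of sentence ids to keep.
#' @return A \code{SpanCorpus}.
#' @export
subsetCorpus <- function(x, ids) {
  stopifnot(all(ids %in% x@ids))
  keep <- match(ids, x@ids)
  ent <- x@entities[x@entities$sentence_id %in% ids, , drop = FALSE]
  ent <- ent[order(match(ent$sentence_id, ids)), , drop = FALSE]
  rownames(ent) <- NULL
  new("SpanCorpus", ids = x@ids[keep], texts = x@texts[keep],
      entities = ent, schema = x@schema)
}

#' Concatenate two corpora sharing a schema
#'
#' @param x,y \code{\linkS4class{SpanCorpus}} objects with identical schemas
#'   and disjoint sentence ids.
#' @return A \code{SpanCorpus}.
#' @export
bindCorpora <- function(x, y) {
  stopifnot(identical(x@schema, y@schema))
  new("SpanCorpus", ids = c(x@ids, y@ids), texts = c(x@texts, y@texts),
      entities = asEntityFrame(rbind(x@entities, y@entities)),
      schema = x@schema)
}

setMethod("show", "SpanCorpus", function(object) {
  cat(sprintf("SpanCorpus with %d sentences, %d entity mentions, %d entity types\n",
              length(object@ids), nrow(object@entities),
              length(object@schema)))
  if (nrow(object@entities)) {
    tab <- table(factor(object@entities$label, levels = object@schema))
    for (lb in names(tab)) cat(sprintf("  %-28s %d\n", lb, tab[[lb]]))
  }
})
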