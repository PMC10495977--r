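#' SpanNERModel: boundary prediction + pair matching over an encoder
#'
#' The span head predicts, independently for each entity category, a
#' per-position probability of being an entity start and of being an entity
#' end, extracts the candidate indices by row argmax, and matches start/end
#' candidates with a sigmoid binary classifier over the concatenated
#' position representations.  Because every admissible (start, end) pair is
#' scored independently, overlapping and nested entities are decodable — the
#' capability BIO sequence tagging lacks.
#'
#' Formally, with representation matrix E (n x d) and per-category weights
#' \eqn{T_{start}, T_{end} \in R^{d \times 2}}, indicator embedding
#' \eqn{U \in R^{2 \times d}} and matching vector \eqn{m \in R^{2d}}:
#' \deqn{P_{start} = softmax_{row}(E T_{start})}
#' \deqn{P_{end} = softmax_{row}((E + H U) T_{end})}
#' where H is the n x 2 one-hot start-indicator matrix (gold starts during
#' training — teacher forcing; row argmax of \eqn{P_{start}} at inference),
#' and for candidate start i and end j
#' \deqn{P_{i,j} = \sigma(m \cdot [E_i ; E_j]).}
#' The printed formulation adds the one-hot matrix to E directly, which is
#' dimensionally inconsistent; the learned 2-to-d indicator embedding U
#' realizes the intended injection of start information into the end
#' sequence.
#'
#' @slot encoder Any encoder honouring the \code{\link{encodeText}} contract.
#' @slot heads Named list (one per schema label) of head parameter lists
#'   with elements \code{Ts} (d x 2), \code{Te} (d x 2), \code{U} (2 x d)
#'   and \code{m} (length 2d).
#' @slot schema Entity-type schema.
#' @slot threshold Matching-probability acceptance threshold (default 0.5,
#'   the sigmoid midpoint).
#' @slot maxSpanLen Maximum decoded span length in characters (default 30,
#'   generous enough for long rehabilitation-medicine terms).
#'
#' @name SpanNERModel-class
#' @rdname SpanNERModel-class
#' @exportClass SpanNERModel
setClass("SpanNERModel",
  representation(encoder = "ANY", heads = "list", schema = "character",
                 threshold = "numeric", maxSpanLen = "integer"))

setValidity("SpanNERModel", function(object) {
  msgs <- character(0)
  if (!identical(sort(names(object@heads)), sort(object@schema)))
    msgs <- c(msgs, "one head parameter set required per schema label")
  for (lb in names(object@heads)) {
    h <- object@heads[[lb]]
    d <- nrow(h$Ts)
    if (ncol(h$Ts) != 2L || !identical(dim(h$Te), dim(h$Ts)) ||
        !identical(dim(h$U), c(2L, d)) || length(h$m) != 2L * d)
      msgs <- c(msgs, sprintf("head '%s' has inconsistent shapes", lb))
  }
  if (object@threshold <= 0 || object@threshold >= 1)
    msgs <- c(msgs, "threshold must be in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

newSpanHead <- function(d, seed) {
  withSeed(seed, list(
    Ts = matrix(rnorm(2 * d, sd = 1 / sqrt(d)), ncol = 2),
    Te = matrix(rnorm(2 * d, sd = 1 / sqrt(d)), ncol = 2),
    U = matrix(rnorm(2 * d, sd = 0.1), nrow = 2),
    m = rnorm(2 * d, sd = 1 / sqrt(2 * d))))
}

#' Construct an untrained span model
#'
#' @param encoder Encoder honouring the \code{\link{encodeText}} contract.
#' @param schemaLabels Entity-type schema (one head per label).
#' @param seed Integer seed for head initialization.
#' @param threshold Matching acceptance threshold in (0, 1).
#' @param maxSpanLen Maximum span length in characters.
#' @return A \code{\linkS4class{SpanNERModel}}.
#' @export
spanNERModel <- function(encoder, schemaLabels = rehabSchema(), seed = 1L,
                         threshold = 0.5, maxSpanLen = 30L) {
  d <- encoder@d
  heads <- lapply(seq_along(schemaLabels),
                  function(i) newSpanHead(d, seed + i))
  names(heads) <- schemaLabels
  new("SpanNERModel", encoder = encoder, heads = heads,
      schema = schemaLabels, threshold = threshold,
      maxSpanLen = as.integer(maxSpanLen))
}

setMethod("show", "SpanNERModel", function(object) {
  d <- nrow(object@heads[[1L]]$Ts)
  cat(sprintf("SpanNERModel: %d categories, d = %d, threshold = %g, maxSpanLen = %d\n",
              length(object@schema), d, object@threshold, object@maxSpanLen))
  show(object@encoder)
})

#' Per-position start probabilities
#'
#' Row-wise softmax of \code{E \%*\% Ts}: an n x 2 row-stochastic matrix
#' whose second column is the probability that the position starts an entity
#' of the head's category.
#'
#' @param E n x d representation matrix.
#' @param head Head parameter list (element \code{Ts}).
#' @return n x 2 row-stochastic matrix.
#' @export
predictStart <- function(E, head) {
  if (any(!is.finite(E))) stop("non-finite encoder output")
  softmaxRows(E %*% head$Ts)
}

#' Per-position end probabilities
#'
#' The n x 2 one-hot start indicator is embedded into representation space
#' (via the learned 2 x d matrix \code{U}) and added to E before the end
#' projection, injecting start-position information into the end sequence:
#' row-wise softmax of \code{(E + indicator \%*\% U) \%*\% Te}.
#'
#' @param E n x d representation matrix.
#' @param indicator n x 2 one-hot matrix: gold start labels during training
#'   (teacher forcing), row argmax of \code{\link{predictStart}} at inference.
#' @param head Head parameter list (elements \code{Te}, \code{U}).
#' @return n x 2 row-stochastic matrix.
#' @export
predictEnd <- function(E, indicator, head) {
  if (!is.matrix(indicator) || !identical(dim(indicator), c(nrow(E), 2L)))
    stop("indicator must be an n x 2 one-hot matrix")
  softmaxRows((E + indicator %*% head$U) %*% head$Te)
}

#' One-hot start indicator from predicted probabilities
#'
#' @param P n x 2 row-stochastic matrix (or a 0/1 label vector).
#' @return n x 2 one-hot matrix; ties resolve to the non-entity class.
#' @export
startIndicator <- function(P) {
  if (is.matrix(P)) pos <- as.integer(P[, 2L] > P[, 1L])
  else pos <- as.integer(P)
  cbind(1 - pos, pos)
}

#' Candidate boundary indices by row argmax
#'
#' Position i (0-based) is a candidate iff its entity-class probability
#' strictly exceeds the non-entity probability; an exact tie resolves to
#' non-entity (conservative, deterministic).
#'
#' @param P n x 2 row-stochastic matrix.
#' @return Integer vector of 0-based positions.
#' @export
extractIndices <- function(P) {
  which(P[, 2L] > P[, 1L]) - 1L
}

#' Start/end pair matching probability
#'
#' \code{sigmoid(m . [E_i ; E_j])} for a candidate start i and end j
#' (0-based positions, i <= j).
#'
#' @param E n x d representation matrix.
#' @param i,j 0-based start and end positions with \code{i <= j}.
#' @param m Length-2d matching weight vector.
#' @return Matching probability in (0, 1).
#' @export
matchPair <- function(E, i, j, m) {
  if (i > j) stop("start index ", i, " exceeds end index ", j)
  if (i < 0L || j >= nrow(E)) stop("pair indices out of range")
  sigmoid(sum(m * c(E[i + 1L, ], E[j + 1L, ])))
}

#' Decode spans of one category from boundary probabilities
#'
#' Enumerates candidate pairs (i, j) with i in the start set, j in the end
#' set, i <= j and j - i < \code{maxSpanLen}, and accepts a pair iff its
#' matching probability strictly exceeds \code{threshold}.  All accepted
#' spans are retained, so nested and overlapping spans survive decoding.
#'
#' @param Pstart,Pend n x 2 row-stochastic boundary matrices.
#' @param pairProb Function \code{(i, j) -> probability} over 0-based
#'   positions (e.g. a closure over \code{\link{matchPair}}).
#' @param threshold Acceptance threshold.
#' @param maxSpanLen Maximum span length in characters.
#' @param label Category label attached to the spans.
#' @return data.frame with columns \code{label}, \code{start}, \code{end}
#'   (0-based half-open), \code{prob}.
#' @export
decodeSpans <- function(Pstart, Pend, pairProb, threshold = 0.5,
                        maxSpanLen = 30L, label = "entity") {
  starts <- extractIndices(Pstart)
  ends <- extractIndices(Pend)
  out <- list()
  for (i in starts) for (j in ends) {
    if (j < i || j - i >= maxSpanLen) next
    p <- pairProb(i, j)
    if (p > threshold)
      out[[length(out) + 1L]] <- data.frame(
        label = label, start = i, end = j + 1L, prob = p,
        stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(label = character(0), start = integer(0),
                  end = integer(0), prob = numeric(0),
                  stringsAsFactors = FALSE)
}

#' Decode all entities of a sentence
#'
#' Runs one encoder pass, then per-category boundary prediction (inference
#' indicators from the predicted start argmax), candidate extraction and
#' pair matching.
#'
#' @param model A \code{\linkS4class{SpanNERModel}}.
#' @param text Sentence string.
#' @return data.frame with columns \code{label}, \code{start}, \code{end},
#'   \code{surface}, \code{prob} (0-based half-open offsets).
#' @export
decodeEntities <- function(model, text) {
  E <- encodeText(model@encoder, text)
  out <- list()
  for (lb in model@schema) {
    h <- model@heads[[lb]]
    if (nrow(E) == 0L) next
    Ps <- predictStart(E, h)
    Pe <- predictEnd(E, startIndicator(Ps), h)
    spans <- decodeSpans(Ps, Pe, function(i, j) matchPair(E, i, j, h$m),
                         threshold = model@threshold,
                         maxSpanLen = model@maxSpanLen, label = lb)
    if (nrow(spans)) out[[length(out) + 1L]] <- spans
  }
  spans <- if (length(out)) do.call(rbind, out)
           else data.frame(label = character(0), start = integer(0),
                           end = integer(0), prob = numeric(0),
                           stringsAsFactors = FALSE)
  spans$surface <- vapply(seq_len(nrow(spans)), function(r)
    sliceText(text, spans$start[r], spans$end[r]), character(1))
  spans[, c("label", "start", "end", "surface", "prob")]
}

#' Annotate a corpus with model predictions
#'
#' @param model A \code{\linkS4class{SpanNERModel}}.
#' @param corpus A \code{\linkS4class{SpanCorpus}} (its gold entities, if
#'   any, are ignored).
#' @param source Provenance tag for the predicted spans (default
#'   \code{"model"}).
#' @return A \code{SpanCorpus} over the same sentences containing the
#'   predicted entities.
#' @export
predictCorpus <- function(model, corpus, source = "model") {
  rows <- list()
  for (i in seq_along(corpus@ids)) {
    spans <- decodeEntities(model, corpus@texts[i])
    if (nrow(spans)) {
      spans$sentence_id <- corpus@ids[i]
      spans$source <- source
      rows[[length(rows) + 1L]] <-
        spans[, c("sentence_id", "label", "start", "end", "surface", "source")]
    }
  }
  SpanCorpus(ids = corpus@ids, texts = corpus@texts,
             entities = if (length(rows)) do.call(rbind, rows) else NULL,
             schema = model@schema)
}

binaryRowCE <- function(P, y) {
  # mean cross-entropy of n x 2 row-stochastic P against 0/1 labels y
  if (length(y) == 0L) return(0)
  -mean(log(pmax(P[cbind(seq_along(y), y + 1L)], 1e-12)))
}

#' Composite span loss
#'
#' \deqn{L = \alpha L_{start} + \beta L_{end} + \gamma L_{span}} where
#' \eqn{L_{start}} and \eqn{L_{end}} are mean cross-entropies of the
#' boundary predictions over positions (averaged over categories) and
#' \eqn{L_{span}} is the mean binary cross-entropy of the matching
#' probabilities over the sampled candidate pairs.  The loss is
#' non-negative and zero exactly when every prediction puts probability 1
#' on its label; the total is linear in the weights.
#'
#' @param predictions List per category: \code{list(Pstart, Pend,
#'   pairProbs)} with the boundary matrices and the matching probabilities
#'   of the sampled pairs.
#' @param targets List per category: \code{list(yStart, yEnd, pairLabels)}
#'   with 0/1 labels aligned to the predictions.
#' @param weights Numeric \code{c(alpha, beta, gamma)}, non-negative, not
#'   all zero (default all 1; values unstated in the method's description).
#' @return List with \code{total}, \code{lStart}, \code{lEnd}, \code{lSpan}.
#' @export
computeLoss <- function(predictions, targets, weights = c(1, 1, 1)) {
  stopifnot(length(predictions) == length(targets),
            length(weights) == 3L, all(weights >= 0), any(weights > 0))
  lStart <- lEnd <- lSpan <- 0
  nPairs <- 0L
  C <- length(predictions)
  for (c in seq_len(C)) {
    p <- predictions[[c]]; t <- targets[[c]]
    lStart <- lStart + binaryRowCE(p$Pstart, t$yStart) / C
    lEnd <- lEnd + binaryRowCE(p$Pend, t$yEnd) / C
    if (length(t$pairLabels)) {
      pr <- pmin(pmax(p$pairProbs, 1e-12), 1 - 1e-12)
      lSpan <- lSpan +
        -mean(t$pairLabels * log(pr) + (1 - t$pairLabels) * log(1 - pr)) / C
      nPairs <- nPairs + length(t$pairLabels)
    }
  }
  if (nPairs == 0L)
    warning("empty candidate-pair sample; L_span = 0", call. = FALSE)
  list(total = weights[1] * lStart + weights[2] * lEnd + weights[3] * lSpan,
       lStart = lStart, lEnd = lEnd, lSpan = lSpan)
}
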