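#' TinyEncoder: a small trainable character encoder
#'
#' The span head consumes an n x d representation matrix from a pluggable
#' token encoder.  In production deployments that encoder is a Chinese
#' BERT-family model; this class is a small trainable stand-in that runs on
#' a CPU in seconds: a character embedding table plus a position-wise mixing
#' layer over a 3-character window with a tanh nonlinearity, so each row
#' sees its immediate left and right context (enough to learn boundary
#' cues).  Any object implementing \code{\link{encodeText}} with the same
#' contract (text window in, n x d matrix out, trainable parameters) can
#' replace it.
#'
#' @slot vocab Character vector of known characters; unknown characters map
#'   to a shared UNK row, out-of-sentence window positions to a PAD row.
#' @slot emb (|vocab| + 2) x dEmb embedding matrix (rows: PAD, UNK, vocab).
#' @slot W 3 dEmb x d mixing weights.
#' @slot b Length-d bias.
#' @slot d Output representation width.
#'
#' @name TinyEncoder-class
#' @rdname TinyEncoder-class
#' @exportClass TinyEncoder
setClass("TinyEncoder",
  representation(vocab = "character", emb = "matrix", W = "matrix",
                 b = "numeric", d = "integer"))

setValidity("TinyEncoder", function(object) {
  msgs <- character(0)
  if (nrow(object@emb) != length(object@vocab) + 2L)
    msgs <- c(msgs, "embedding table must have |vocab| + 2 rows")
  if (nrow(object@W) != 3L * ncol(object@emb))
    msgs <- c(msgs, "mixing weights must have 3 * dEmb rows")
  if (ncol(object@W) != object@d || length(object@b) != object@d)
    msgs <- c(msgs, "output width inconsistent")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TinyEncoder
#'
#' @param vocab Character vector of characters the encoder should know
#'   (e.g. \code{corpusVocabulary(corpus)}).
#' @param dEmb Embedding width (default 16).
#' @param d Output representation width (default 32; keep <= 64 for
#'   desk-scale training).
#' @param seed Integer seed for the initialization stream.
#' @return A \code{\linkS4class{TinyEncoder}}.
#' @export
tinyEncoder <- function(vocab, dEmb = 16L, d = 32L, seed = 1L) {
  vocab <- unique(vocab)
  withSeed(seed, {
    emb <- matrix(rnorm((length(vocab) + 2L) * dEmb, sd = 0.5),
                  ncol = dEmb)
    W <- matrix(rnorm(3L * dEmb * d, sd = 1 / sqrt(3 * dEmb)), ncol = d)
  })
  new("TinyEncoder", vocab = vocab, emb = emb, W = W,
      b = numeric(d), d = as.integer(d))
}

#' Character vocabulary of a corpus
#'
#' @param corpus A \code{\linkS4class{SpanCorpus}}.
#' @return Sorted character vector of distinct characters.
#' @export
corpusVocabulary <- function(corpus) {
  sort(unique(unlist(lapply(corpus@texts, splitChars))))
}

#' Encode a text window into an n x d representation matrix
#'
#' @param encoder A \code{\linkS4class{TinyEncoder}} (or compatible object).
#' @param text Character string of n characters.
#' @param withCache Keep forward intermediates for a backward pass.
#' @return The n x d matrix \code{E} (rows finite); with
#'   \code{withCache = TRUE}, a list \code{(E, cache)}.
#' @export
encodeText <- function(encoder, text, withCache = FALSE) {
  chars <- splitChars(text)
  n <- length(chars)
  idx <- match(chars, encoder@vocab) + 2L
  idx[is.na(idx)] <- 2L                      # UNK
  idxL <- c(1L, head(idx, -1L))              # PAD at the left edge
  idxR <- c(idx[-1L], 1L)                    # PAD at the right edge
  if (n == 0L) {
    E <- matrix(0, 0L, encoder@d)
    return(if (withCache) list(E = E, cache = NULL) else E)
  }
  X <- cbind(encoder@emb[idxL, , drop = FALSE],
             encoder@emb[idx, , drop = FALSE],
             encoder@emb[idxR, , drop = FALSE])
  E <- tanh(sweep(X %*% encoder@W, 2L, encoder@b, `+`))
  if (withCache) list(E = E, cache = list(idx = idx, idxL = idxL,
                                          idxR = idxR, X = X, E = E))
  else E
}

# Backward pass: gradient of the loss w.r.t. encoder parameters given dL/dE.
encoderBackward <- function(encoder, cache, dE) {
  dZ <- dE * (1 - cache$E^2)
  dW <- crossprod(cache$X, dZ)
  db <- colSums(dZ)
  dX <- dZ %*% t(encoder@W)
  de <- ncol(encoder@emb)
  dEmb <- matrix(0, nrow(encoder@emb), de)
  scatter <- function(rows, block) {
    for (r in seq_along(rows))
      dEmb[rows[r], ] <<- dEmb[rows[r], ] + block[r, ]
  }
  scatter(cache$idxL, dX[, 1:de, drop = FALSE])
  scatter(cache$idx, dX[, (de + 1):(2 * de), drop = FALSE])
  scatter(cache$idxR, dX[, (2 * de + 1):(3 * de), drop = FALSE])
  list(emb = dEmb, W = dW, b = db)
}

setMethod("show", "TinyEncoder", function(object) {
  cat(sprintf("TinyEncoder: |vocab| = %d, dEmb = %d, d = %d (%d parameters)\n",
              length(object@vocab), ncol(object@emb), object@d,
              length(object@emb) + length(object@W) + length(object@b)))
})
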