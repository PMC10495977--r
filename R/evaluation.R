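#' Entity-level TP/FP/FN counts
#'
#' Exact-match scoring: a predicted span counts as a true positive iff a
#' gold span with the same sentence, label, start and end exists (multiset
#' matching, so duplicated spans are not double-credited).  Unmatched
#' predictions are false positives; unmatched gold spans false negatives.
#' Counts are permutation-invariant in sentence order.
#'
#' @param gold,predicted \code{\linkS4class{SpanCorpus}} objects over the
#'   same sentence ids.
#' @return data.frame with one row per schema label plus an \code{"overall"}
#'   row, columns \code{label}, \code{tp}, \code{fp}, \code{fn}; the overall
#'   row is the per-type column sum.
#' @export
scoreEntities <- function(gold, predicted) {
  missing <- setdiff(gold@ids, predicted@ids)
  extra <- setdiff(predicted@ids, gold@ids)
  if (length(missing) || length(extra))
    stop("gold and predicted corpora cover different sentences; missing: ",
         paste(missing, collapse = ", "), "; extra: ",
         paste(extra, collapse = ", "))
  key <- function(df) paste(df$sentence_id, df$label, df$start, df$end,
                            sep = "\r")
  g <- gold@entities; p <- predicted@entities
  gk <- key(g); pk <- key(p)
  labs <- gold@schema
  out <- data.frame(label = c(labs, "overall"), tp = 0L, fp = 0L, fn = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(labs)) {
    gi <- table(gk[g$label == labs[i]])
    pi <- table(pk[p$label == labs[i]])
    shared <- intersect(names(gi), names(pi))
    tp <- sum(pmin(gi[shared], pi[shared]))
    out$tp[i] <- tp
    out$fp[i] <- sum(pi) - tp
    out$fn[i] <- sum(gi) - tp
  }
  k <- nrow(out)
  out$tp[k] <- sum(out$tp[-k]); out$fp[k] <- sum(out$fp[-k])
  out$fn[k] <- sum(out$fn[-k])
  out
}

#' Precision, recall and F1 from match counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R), reported as percentages.
#' Conventions for empty denominators: a precision (or recall) whose
#' denominator is zero is 0 when the opposite error count is nonzero; when
#' gold and prediction are both empty, P = R = F1 = 100 (perfect agreement
#' on the absence of entities); F1 = 0 when P + R = 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector \code{c(P, R, F1)} in percent, full
#'   precision (round for display).
#' @export
#' @examples
#' prf(1, 1, 1)            # P = R = F1 = 50
#' round(prfFromPR(88.80, 85.38), 2)  # harmonic mean: 87.06
prf <- function(tp, fp, fn) {
  if (tp + fp + fn == 0L) return(c(P = 100, R = 100, F1 = 100))
  P <- if (tp + fp == 0L) 0 else 100 * tp / (tp + fp)
  R <- if (tp + fn == 0L) 0 else 100 * tp / (tp + fn)
  F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  c(P = P, R = R, F1 = F1)
}

#' @rdname prf
#' @param P,R Precision and recall in percent.
#' @export
prfFromPR <- function(P, R) {
  if (P + R == 0) 0 else 2 * P * R / (P + R)
}

#' Per-type and micro-averaged metric report
#'
#' Expands TP/FP/FN counts into percentages.  The \code{"overall"} row is
#' micro-averaged: counts are pooled across types before computing P/R/F1.
#' Percentages are carried at full precision; use \code{digits} to round for
#' display (tables conventionally print two decimals).
#'
#' @param counts Count table from \code{\link{scoreEntities}}.
#' @param digits Rounding for the returned percentages (default NULL = none).
#' @return data.frame with columns \code{label}, \code{tp}, \code{fp},
#'   \code{fn}, \code{P}, \code{R}, \code{F1}.
#' @export
metricReport <- function(counts, digits = NULL) {
  m <- t(vapply(seq_len(nrow(counts)),
                function(i) prf(counts$tp[i], counts$fp[i], counts$fn[i]),
                numeric(3)))
  out <- cbind(counts, as.data.frame(m))
  if (!is.null(digits))
    out[, c("P", "R", "F1")] <- roundHalfUp(out[, c("P", "R", "F1")], digits)
  out
}

#' Softmax BIO baseline decoding
#'
#' The conventional per-position baseline head: each character position gets
#' a \code{2 * |schema| + 1}-way distribution over \code{\{O\} + \{B-, I-\} x
#' schema}; decoding takes the row argmax and converts the BIO tag sequence
#' to spans.  By construction this head cannot emit nested or overlapping
#' spans — the structural limitation that motivates span-based decoding.
#'
#' @param logits n x (2L+1) matrix of per-position label scores, columns
#'   ordered \code{O, B-l1, I-l1, B-l2, I-l2, ...} for schema labels
#'   \code{l1..lL}.
#' @param chars Character vector of the n sentence characters.
#' @param schemaLabels Entity-type schema.
#' @param id Sentence id for the result.
#' @return A one-sentence \code{\linkS4class{SpanCorpus}}.
#' @seealso \code{\link{bioLabelSet}} for the column order.
#' @export
softmaxBaselineDecode <- function(logits, chars, schemaLabels = rehabSchema(),
                                  id = "s1") {
  labels <- bioLabelSet(schemaLabels)
  stopifnot(ncol(logits) == length(labels), nrow(logits) == length(chars))
  tags <- labels[apply(logits, 1L, which.max)]
  suppressWarnings(fromBIO(chars, tags, schema = schemaLabels, id = id))
}

#' BIO label set for a schema
#'
#' @param schemaLabels Entity-type schema.
#' @return Character vector \code{c("O", "B-l1", "I-l1", ...)}.
#' @export
bioLabelSet <- function(schemaLabels) {
  c("O", as.vector(rbind(paste0("B-", schemaLabels),
                         paste0("I-", schemaLabels))))
}

#' k-fold cross-validation of the span model
#'
#' Trains one model per fold on the deterministic \code{\link{kfoldSplit}}
#' partition and scores it on the held-out fold with exact-match entity-level
#' metrics.
#'
#' @param corpus Annotated \code{\linkS4class{SpanCorpus}}.
#' @param k Number of folds.
#' @param encoderFactory Zero-argument function returning a fresh encoder
#'   (each fold must start from its own initialization).
#' @param cfg A \code{\link{trainConfig}}.
#' @param seed Integer seed controlling the fold assignment.
#' @return List with \code{folds} (per-fold micro metric rows), \code{mean}
#'   and \code{sd} of the micro F1, and \code{reports} (full per-fold
#'   MetricReports).
#' @export
crossValidate <- function(corpus, k, encoderFactory, cfg, seed = 1L) {
  folds <- kfoldSplit(corpus, k = k, seed = seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    fit <- tryCatch(
      trainSpanModel(folds[[f]]$train, encoderFactory(), cfg),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e)))
    pred <- predictCorpus(fit$model, folds[[f]]$test)
    reports[[f]] <- metricReport(scoreEntities(folds[[f]]$test, pred))
  }
  micro <- do.call(rbind, lapply(seq_len(k), function(f) {
    row <- reports[[f]][reports[[f]]$label == "overall", , drop = FALSE]
    cbind(fold = f, row)
  }))
  list(folds = micro, mean = mean(micro$F1), sd = sd(micro$F1),
       reports = reports)
}
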