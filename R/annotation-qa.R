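#' Entity mention counts per type
#'
#' @param corpus A \code{\linkS4class{SpanCorpus}}.
#' @return Named integer vector over the schema (zero for unused types);
#'   counts sum to the total number of entity mentions.
#' @export
entityCounts <- function(corpus) {
  tab <- table(factor(corpus@entities$label, levels = corpus@schema))
  setNames(as.integer(tab), corpus@schema)
}

#' Low-frequency entity analysis
#'
#' A low-frequency entity is a surface form occurring exactly once within
#' its entity type.  For each type the function reports the number of such
#' singleton surfaces, the total number of mentions, and the proportion
#' \code{low / total} as a whole percent rounded half away from zero.  Types
#' with zero mentions get an \code{NA} proportion (undefined, not 0).
#'
#' @param corpus A \code{\linkS4class{SpanCorpus}}.
#' @return data.frame with columns \code{label}, \code{low}, \code{total},
#'   \code{proportion} (integer percent or NA).
#' @seealso \code{\link{lowFrequencyProportion}} for the bare proportion rule.
#' @export
lowFrequencyAnalysis <- function(corpus) {
  ent <- corpus@entities
  out <- data.frame(label = corpus@schema, low = 0L, total = 0L,
                    proportion = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(corpus@schema)) {
    surf <- ent$surface[ent$label == corpus@schema[i]]
    out$total[i] <- length(surf)
    if (length(surf)) {
      freq <- table(surf)
      out$low[i] <- sum(freq == 1L)
      out$proportion[i] <- lowFrequencyProportion(out$low[i], out$total[i])
    }
  }
  out
}

#' Proportion rule for low-frequency entities
#'
#' \code{low / total} expressed as a whole percent, rounded half away from
#' zero — the convention used in corpus frequency tables.
#'
#' @param low Number of singleton surface forms.
#' @param total Total mentions of the type.
#' @return Integer percent, or NA if \code{total} is zero.
#' @export
#' @examples
#' lowFrequencyProportion(666, 3881)  # 17
#' lowFrequencyProportion(144, 445)   # 32
lowFrequencyProportion <- function(low, total) {
  if (total == 0L) return(NA_integer_)
  as.integer(roundHalfUp(100 * low / total))
}

#' Inter-annotator agreement as entity-level F1
#'
#' Compares two independent annotations of the same sentences under the
#' exact-match criterion (identical label, start and end).  Treating one
#' corpus as reference and the other as candidate, agreement is reported as
#' micro-averaged precision/recall/F1 plus per-type rows.  F1 is symmetric
#' under swapping the annotators (TP is symmetric; FP and FN exchange).
#'
#' @param ref,other \code{\linkS4class{SpanCorpus}} objects covering the
#'   same sentence ids.
#' @return A \code{MetricReport} data.frame as from \code{\link{metricReport}}.
#' @export
computeIaa <- function(ref, other) {
  missing <- setdiff(ref@ids, other@ids)
  extra <- setdiff(other@ids, ref@ids)
  if (length(missing) || length(extra))
    stop("annotator corpora cover different sentences; missing: ",
         paste(missing, collapse = ", "), "; extra: ",
         paste(extra, collapse = ", "))
  metricReport(scoreEntities(ref, other))
}
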