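#' @importFrom stats runif rnorm uniroot sd setNames
#' @importFrom utils head modifyList
NULL

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream.  All randomised operations in the package route through this.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero; base round() is banker's rounding, which does
# not reproduce whole-percent tables.
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable row-wise softmax of an n x k matrix.
softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Character-wise split of a UTF-8 string.
splitChars <- function(text) {
  if (nchar(text) == 0L) character(0) else strsplit(text, "", fixed = FALSE)[[1L]]
}

# Slice by 0-based half-open character offsets.
sliceText <- function(text, start, end) {
  if (end <= start) return("")
  substr(text, start + 1L, end)
}

emptyEntityFrame <- function() {
  data.frame(sentence_id = character(0), label = character(0),
             start = integer(0), end = integer(0),
             surface = character(0), source = character(0),
             stringsAsFactors = FALSE)
}

asEntityFrame <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(emptyEntityFrame())
  if (is.null(df$source)) df$source <- "manual"
  df <- df[, c("sentence_id", "label", "start", "end", "surface", "source")]
  df$sentence_id <- as.character(df$sentence_id)
  df$label <- as.character(df$label)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$surface <- as.character(df$surface)
  df$source <- as.character(df$source)
  rownames(df) <- NULL
  df
}
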