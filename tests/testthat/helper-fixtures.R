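# Fixtures are built in code; no data files.

miniSchema <- c("body", "drugs")

# A two-sentence corpus with hand-placed spans (0-based half-open offsets).
tinyCorpus <- function() {
  SpanCorpus(
    ids = c("s1", "s2"),
    texts = c("患者肢体麻木",   # 患者肢体麻木
              "口服阿司匹林"),  # 口服阿司匹林
    entities = data.frame(
      sentence_id = c("s1", "s2"),
      label = c("body", "drugs"),
      start = c(2L, 2L), end = c(4L, 6L),
      surface = c("肢体", "阿司匹林"),
      stringsAsFactors = FALSE),
    schema = miniSchema)
}

# Seed-deterministic flat synthetic corpus (no nesting).
flatCorpus <- function(n = 30, seed = 1, ...) {
  generateCorpus(synthConfig(nSentences = n, nestingRate = 0, seed = seed,
                             sentenceLengthRange = c(12, 25),
                             mentionsRange = c(1, 2), ...))$corpus
}

# A corpus whose only sentence holds a nested gold pair: outer "body"
# span [0, 5) strictly containing inner "drugs" span [1, 3).
nestedFixture <- function() {
  text <- "一二三四五六"   # 6 characters
  SpanCorpus(
    ids = "n1", texts = text,
    entities = data.frame(
      sentence_id = c("n1", "n1"),
      label = c("body", "drugs"),
      start = c(0L, 1L), end = c(5L, 3L),
      surface = c(substr(text, 1, 5), substr(text, 2, 3)),
      stringsAsFactors = FALSE),
    schema = miniSchema)
}

# Independent brute-force span decoder: enumerates every (category, i, j)
# triple from first principles (raw softmax / sigmoid arithmetic, no calls
# into the package's prediction path).
oracleDecode <- function(E, heads, schemaLabels, threshold, maxSpanLen) {
  rawSoftmax <- function(Z) {
    t(apply(Z, 1, function(z) { e <- exp(z - max(z)); e / sum(e) }))
  }
  n <- nrow(E)
  out <- list()
  for (lb in schemaLabels) {
    h <- heads[[lb]]
    Ps <- rawSoftmax(E %*% h$Ts)
    hot <- cbind(as.numeric(!(Ps[, 2] > Ps[, 1])),
                 as.numeric(Ps[, 2] > Ps[, 1]))
    Pe <- rawSoftmax((E + hot %*% h$U) %*% h$Te)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j < i || j - i >= maxSpanLen) next
      if (!(Ps[i, 2] > Ps[i, 1])) next
      if (!(Pe[j, 2] > Pe[j, 1])) next
      z <- sum(h$m * c(E[i, ], E[j, ]))
      if (1 / (1 + exp(-z)) > threshold)
        out[[length(out) + 1L]] <- c(lb, i - 1L, j)   # 0-based half-open
    }
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, paste, character(1), collapse = ":"))
}

spanKeys <- function(df) {
  sort(paste(df$label, df$start, df$end, sep = ":"))
}

randomModel <- function(seed, n = 8, d = 6) {
  vocab <- strsplit("abcdefgh", "")[[1]]
  enc <- tinyEncoder(vocab, dEmb = 4, d = d, seed = seed)
  spanNERModel(enc, schemaLabels = miniSchema, seed = seed + 100,
               maxSpanLen = 30L)
}

randomText <- function(seed, n) {
  set.seed(seed)
  paste(sample(strsplit("abcdefgh", "")[[1]], n, replace = TRUE),
        collapse = "")
}
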