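#' Training configuration
#'
#' Defaults follow the reference fine-tuning recipe for the production
#' (BERT-family) encoder: Adam with initial learning rate 2e-5, warmup
#' proportion 0.15, batch size 8, 20 epochs.  Desk-scale runs with the
#' \code{\linkS4class{TinyEncoder}} train from scratch and want a larger
#' learning rate (around 0.05) and fewer epochs; see the package vignette.
#' The committed defaults file \code{system.file("extdata",
#' "default-train.yaml", package = "rehabspan")} records the full default
#' set so "default values" is reproducible.
#'
#' @param learningRate Positive initial learning rate.
#' @param warmupProportion Fraction of total steps in [0, 1) over which the
#'   learning-rate multiplier rises linearly from 0 to 1; linear decay to 0
#'   afterwards.
#' @param batchSize Sentences per optimizer step (>= 1).
#' @param epochs Training epochs (>= 1).
#' @param maxSeqLen Maximum sentence window in characters; longer sentences
#'   are truncated and entities crossing the boundary dropped with a warning.
#' @param seed Integer seed controlling initialization-free randomness
#'   (batch order, pair subsampling).
#' @param lossWeights Numeric \code{c(alpha, beta, gamma)} weighting the
#'   start, end and span loss terms (default all 1).
#' @param optimizer Only \code{"adam"} is implemented.
#' @param maxPairsPerSentence Cap on the candidate-pair sample per sentence
#'   and category (gold pairs always kept; negative pairs subsampled
#'   seed-deterministically).
#' @return A validated list of class \code{trainConfig}.
#' @export
trainConfig <- function(learningRate = 2e-5, warmupProportion = 0.15,
                        batchSize = 8L, epochs = 20L, maxSeqLen = 128L,
                        seed = 42L, lossWeights = c(1, 1, 1),
                        optimizer = "adam", maxPairsPerSentence = 50L) {
  stopifnot(learningRate > 0, warmupProportion >= 0, warmupProportion < 1,
            batchSize >= 1L, epochs >= 1L, maxSeqLen >= 1L,
            length(lossWeights) == 3L, all(lossWeights >= 0),
            any(lossWeights > 0))
  if (!identical(optimizer, "adam"))
    stop("unsupported optimizer: ", optimizer)
  structure(list(learningRate = learningRate,
                 warmupProportion = warmupProportion,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 maxSeqLen = as.integer(maxSeqLen), seed = as.integer(seed),
                 lossWeights = lossWeights, optimizer = optimizer,
                 maxPairsPerSentence = as.integer(maxPairsPerSentence)),
            class = "trainConfig")
}

#' Learning-rate multiplier with linear warmup and decay
#'
#' Rises linearly from 0 to 1 over the first \code{floor(warmupProportion *
#' totalSteps)} steps, then decays linearly to 0 at the final step.
#'
#' @param step Current step (1-based).
#' @param totalSteps Total optimizer steps of the run.
#' @param warmupProportion Warmup fraction in [0, 1).
#' @return Multiplier in [0, 1].
#' @export
lrMultiplier <- function(step, totalSteps, warmupProportion) {
  ws <- floor(warmupProportion * totalSteps)
  if (ws > 0 && step <= ws) return(step / ws)
  if (totalSteps - ws <= 0) return(1)
  (totalSteps - step) / (totalSteps - ws)
}

# ---- parameter plumbing -----------------------------------------------------

getParams <- function(model) {
  p <- list(enc.emb = model@encoder@emb, enc.W = model@encoder@W,
            enc.b = model@encoder@b)
  for (lb in model@schema) {
    h <- model@heads[[lb]]
    p[[paste0("head.", lb, ".Ts")]] <- h$Ts
    p[[paste0("head.", lb, ".Te")]] <- h$Te
    p[[paste0("head.", lb, ".U")]] <- h$U
    p[[paste0("head.", lb, ".m")]] <- h$m
  }
  p
}

setParams <- function(model, p) {
  model@encoder@emb <- p$enc.emb
  model@encoder@W <- p$enc.W
  model@encoder@b <- p$enc.b
  for (lb in model@schema) {
    model@heads[[lb]]$Ts <- p[[paste0("head.", lb, ".Ts")]]
    model@heads[[lb]]$Te <- p[[paste0("head.", lb, ".Te")]]
    model@heads[[lb]]$U <- p[[paste0("head.", lb, ".U")]]
    model@heads[[lb]]$m <- p[[paste0("head.", lb, ".m")]]
  }
  model
}

zeroLike <- function(p) lapply(p, function(x) x * 0)

adamInit <- function(p) list(m = zeroLike(p), v = zeroLike(p), t = 0L)

adamStep <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(p)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    p[[k]] <- p[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, state = state)
}

# ---- training instances -----------------------------------------------------

# Truncate a sentence to the window and build per-category boundary labels
# and the candidate-pair sample.  Gold (start, end) pairs are positives; all
# i <= j combinations of gold starts with gold ends that are not gold pairs
# are negatives, subsampled to the per-sentence cap.
buildInstance <- function(text, ents, schemaLabels, maxSeqLen, maxPairs,
                          seed) {
  n <- nchar(text)
  if (n > maxSeqLen) {
    dropped <- ents[ents$end > maxSeqLen, , drop = FALSE]
    if (nrow(dropped))
      warning(sprintf("%d entity span(s) beyond the %d-character window dropped",
                      nrow(dropped), maxSeqLen), call. = FALSE)
    text <- sliceText(text, 0L, maxSeqLen)
    ents <- ents[ents$end <= maxSeqLen, , drop = FALSE]
    n <- maxSeqLen
  }
  cats <- vector("list", length(schemaLabels))
  names(cats) <- schemaLabels
  for (lb in schemaLabels) {
    rows <- ents[ents$label == lb, , drop = FALSE]
    yS <- integer(n); yE <- integer(n)
    goldPairs <- character(0)
    if (nrow(rows)) {
      yS[rows$start + 1L] <- 1L
      yE[rows$end] <- 1L
      goldPairs <- paste(rows$start, rows$end - 1L)
    }
    starts <- which(yS == 1L) - 1L
    ends <- which(yE == 1L) - 1L
    pi <- integer(0); pj <- integer(0); py <- integer(0)
    for (i in starts) for (j in ends) {
      if (j < i) next
      pi <- c(pi, i); pj <- c(pj, j)
      py <- c(py, as.integer(paste(i, j) %in% goldPairs))
    }
    if (length(py) > maxPairs) {
      pos <- which(py == 1L)
      neg <- which(py == 0L)
      keepNeg <- withSeed(seed, sample(neg, max(0L, maxPairs - length(pos))))
      keep <- sort(c(pos, keepNeg))
      pi <- pi[keep]; pj <- pj[keep]; py <- py[keep]
    }
    cats[[lb]] <- list(yStart = yS, yEnd = yE,
                       pairI = pi, pairJ = pj, pairY = py)
  }
  list(text = text, n = n, cats = cats)
}

# Forward + backward for one sentence; returns loss components and gradients.
sentenceGrad <- function(model, inst, weights) {
  enc <- encodeText(model@encoder, inst$text, withCache = TRUE)
  E <- enc$E
  n <- nrow(E); d <- ncol(E)
  C <- length(model@schema)
  dE <- matrix(0, n, d)
  g <- list()
  lStart <- lEnd <- lSpan <- 0
  for (lb in model@schema) {
    h <- model@heads[[lb]]
    t <- inst$cats[[lb]]
    Ys <- cbind(1 - t$yStart, t$yStart)
    Ps <- softmaxRows(E %*% h$Ts)
    lStart <- lStart + binaryRowCE(Ps, t$yStart) / C
    dS <- (Ps - Ys) / n * (weights[1] / C)
    gTs <- crossprod(E, dS)
    dE <- dE + dS %*% t(h$Ts)

    H <- cbind(1 - t$yStart, t$yStart)        # teacher forcing: gold starts
    E2 <- E + H %*% h$U
    Ye <- cbind(1 - t$yEnd, t$yEnd)
    Pe <- softmaxRows(E2 %*% h$Te)
    lEnd <- lEnd + binaryRowCE(Pe, t$yEnd) / C
    dS2 <- (Pe - Ye) / n * (weights[2] / C)
    gTe <- crossprod(E2, dS2)
    dE2 <- dS2 %*% t(h$Te)
    dE <- dE + dE2
    gU <- crossprod(H, dE2)

    gm <- numeric(2 * d)
    np <- length(t$pairY)
    if (np) {
      for (q in seq_len(np)) {
        i <- t$pairI[q] + 1L; j <- t$pairJ[q] + 1L
        feat <- c(E[i, ], E[j, ])
        p <- sigmoid(sum(h$m * feat))
        p <- min(max(p, 1e-12), 1 - 1e-12)
        lSpan <- lSpan - (t$pairY[q] * log(p) +
                          (1 - t$pairY[q]) * log(1 - p)) / (np * C)
        dz <- (p - t$pairY[q]) * weights[3] / (np * C)
        gm <- gm + dz * feat
        dE[i, ] <- dE[i, ] + dz * h$m[1:d]
        dE[j, ] <- dE[j, ] + dz * h$m[(d + 1):(2 * d)]
      }
    }
    g[[paste0("head.", lb, ".Ts")]] <- gTs
    g[[paste0("head.", lb, ".Te")]] <- gTe
    g[[paste0("head.", lb, ".U")]] <- gU
    g[[paste0("head.", lb, ".m")]] <- gm
  }
  ge <- encoderBackward(model@encoder, enc$cache, dE)
  g$enc.emb <- ge$emb; g$enc.W <- ge$W; g$enc.b <- ge$b
  list(grads = g,
       loss = list(total = weights[1] * lStart + weights[2] * lEnd +
                     weights[3] * lSpan,
                   lStart = lStart, lEnd = lEnd, lSpan = lSpan))
}

#' Train the span model
#'
#' Mini-batch Adam over the composite loss with linear warmup/decay
#' scheduling.  Teacher forcing is used for the end head (gold start
#' indicators); the candidate-pair sample per sentence is built once,
#' seed-deterministically.  For a fixed seed, data and platform the run is
#' reproducible (same initialization stream, same batch order).
#'
#' @param corpus Annotated training \code{\linkS4class{SpanCorpus}}.
#' @param encoder Encoder honouring the \code{\link{encodeText}} contract,
#'   e.g. \code{\link{tinyEncoder}}.
#' @param cfg A \code{\link{trainConfig}}.
#' @param threshold,maxSpanLen Decoding settings stored in the returned
#'   model.
#' @return List with \code{model} (a trained
#'   \code{\linkS4class{SpanNERModel}}) and \code{log} (data.frame of
#'   per-epoch mean loss components and the last learning rate).
#' @export
trainSpanModel <- function(corpus, encoder, cfg = trainConfig(),
                           threshold = 0.5, maxSpanLen = 30L) {
  if (length(corpus) == 0L) stop("empty training corpus")
  model <- spanNERModel(encoder, schemaLabels = corpus@schema,
                        seed = cfg$seed, threshold = threshold,
                        maxSpanLen = maxSpanLen)
  ent <- corpus@entities
  insts <- lapply(seq_along(corpus@ids), function(i)
    buildInstance(corpus@texts[i],
                  ent[ent$sentence_id == corpus@ids[i], , drop = FALSE],
                  corpus@schema, cfg$maxSeqLen, cfg$maxPairsPerSentence,
                  seed = cfg$seed + i))
  nS <- length(insts)
  stepsPerEpoch <- ceiling(nS / cfg$batchSize)
  totalSteps <- cfg$epochs * stepsPerEpoch
  params <- getParams(model)
  state <- adamInit(params)
  logRows <- vector("list", cfg$epochs)
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    order <- withSeed(cfg$seed * 1000L + epoch, sample.int(nS))
    epochLoss <- c(total = 0, lStart = 0, lEnd = 0, lSpan = 0)
    lrLast <- 0
    for (bStart in seq(1L, nS, by = cfg$batchSize)) {
      batch <- order[bStart:min(bStart + cfg$batchSize - 1L, nS)]
      acc <- NULL
      for (si in batch) {
        r <- sentenceGrad(model, insts[[si]], cfg$lossWeights)
        acc <- if (is.null(acc)) r$grads
               else Map(`+`, acc, r$grads[names(acc)])
        epochLoss <- epochLoss + unlist(r$loss)
      }
      acc <- lapply(acc, function(x) x / length(batch))
      step <- step + 1L
      lrLast <- cfg$learningRate * lrMultiplier(step, totalSteps,
                                                cfg$warmupProportion)
      upd <- adamStep(params, acc, state, lrLast)
      params <- upd$p; state <- upd$state
      model <- setParams(model, params)
    }
    logRows[[epoch]] <- data.frame(
      epoch = epoch, loss = epochLoss[["total"]] / nS,
      lStart = epochLoss[["lStart"]] / nS, lEnd = epochLoss[["lEnd"]] / nS,
      lSpan = epochLoss[["lSpan"]] / nS, lr = lrLast)
  }
  list(model = model, log = do.call(rbind, logRows))
}

#' Self-training augmentation
#'
#' Annotates unlabeled sentences with a trained model and appends them to a
#' manually annotated base corpus.  Provenance is recorded per span
#' (\code{source = "model"} vs \code{"manual"}) so downstream reports can
#' separate the two.  No confidence filter is applied by default; set
#' \code{minProb} to keep only spans whose matching probability reaches it.
#'
#' @param model Trained \code{\linkS4class{SpanNERModel}}.
#' @param texts Character vector of unlabeled sentences.
#' @param base Manually annotated \code{\linkS4class{SpanCorpus}}.
#' @param idPrefix Prefix for the generated sentence ids (default
#'   \code{"auto"}).
#' @param minProb Optional minimum matching probability (default
#'   \code{NULL} = keep all).
#' @return The augmented \code{SpanCorpus}: base sentences followed by the
#'   model-annotated ones.
#' @export
selfTrainAugment <- function(model, texts, base, idPrefix = "auto",
                             minProb = NULL) {
  if (length(texts) == 0L) return(base)
  ids <- paste0(idPrefix, "_", seq_along(texts))
  if (any(ids %in% base@ids)) stop("idPrefix collides with base sentence ids")
  rows <- list()
  for (i in seq_along(texts)) {
    spans <- decodeEntities(model, texts[i])
    if (!is.null(minProb)) spans <- spans[spans$prob >= minProb, , drop = FALSE]
    if (nrow(spans)) {
      spans$sentence_id <- ids[i]
      spans$source <- "model"
      rows[[length(rows) + 1L]] <-
        spans[, c("sentence_id", "label", "start", "end", "surface", "source")]
    }
  }
  pseudo <- SpanCorpus(ids = ids, texts = texts,
                       entities = if (length(rows)) do.call(rbind, rows)
                                  else NULL,
                       schema = base@schema)
  bindCorpora(base, pseudo)
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory containing a self-describing JSON manifest
#' (\code{model.json}) with the schema, decoding settings, span-head
#' parameters and encoder weights.  Only the
#' \code{\linkS4class{TinyEncoder}} is serializable; deployments with an
#' external encoder should store its reference alongside.
#'
#' @param model A \code{\linkS4class{SpanNERModel}}.
#' @param dir Checkpoint directory (created if needed).
#' @return \code{saveCheckpoint}: invisibly, \code{dir};
#'   \code{loadCheckpoint}: the restored \code{SpanNERModel}.
#' @export
saveCheckpoint <- function(model, dir) {
  if (!is(model@encoder, "TinyEncoder"))
    stop("only TinyEncoder-backed models are serializable")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  doc <- list(
    format = "rehabspan-checkpoint", version = 1L,
    schema = model@schema, threshold = model@threshold,
    maxSpanLen = model@maxSpanLen,
    heads = lapply(model@heads, function(h)
      list(Ts = h$Ts, Te = h$Te, U = h$U, m = h$m)),
    encoder = list(class = "TinyEncoder", vocab = model@encoder@vocab,
                   emb = model@encoder@emb, W = model@encoder@W,
                   b = model@encoder@b, d = model@encoder@d))
  writeLines(jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE),
             file.path(dir, "model.json"), useBytes = TRUE)
  invisible(dir)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(dir) {
  path <- file.path(dir, "model.json")
  if (!file.exists(path)) stop("no model.json under ", dir)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "rehabspan-checkpoint"))
    stop("not a rehabspan checkpoint: ", path)
  enc <- new("TinyEncoder", vocab = doc$encoder$vocab,
             emb = doc$encoder$emb, W = doc$encoder$W,
             b = as.numeric(doc$encoder$b), d = as.integer(doc$encoder$d))
  heads <- lapply(doc$heads, function(h)
    list(Ts = h$Ts, Te = h$Te, U = h$U, m = as.numeric(h$m)))
  new("SpanNERModel", encoder = enc, heads = heads[doc$schema],
      schema = doc$schema, threshold = doc$threshold,
      maxSpanLen = as.integer(doc$maxSpanLen))
}

# ---- softmax BIO baseline ---------------------------------------------------

#' SoftmaxBaseline: per-position BIO classification head
#'
#' The standard sequence-labeling baseline: a linear projection of each
#' position's representation onto the \code{2L + 1} BIO labels, trained
#' with cross-entropy and decoded by row argmax.  Structurally limited to
#' flat (non-nested) spans.
#'
#' @slot encoder Encoder honouring the \code{\link{encodeText}} contract.
#' @slot W d x (2L+1) projection.
#' @slot b Length-(2L+1) bias.
#' @slot schema Entity-type schema.
#' @name SoftmaxBaseline-class
#' @rdname SoftmaxBaseline-class
#' @exportClass SoftmaxBaseline
setClass("SoftmaxBaseline",
  representation(encoder = "ANY", W = "matrix", b = "numeric",
                 schema = "character"))

#' Train the softmax BIO baseline
#'
#' @inheritParams trainSpanModel
#' @return List with \code{model} (a
#'   \code{\linkS4class{SoftmaxBaseline}}) and \code{log}.
#' @export
trainSoftmaxBaseline <- function(corpus, encoder, cfg = trainConfig()) {
  labels <- bioLabelSet(corpus@schema)
  L <- length(labels)
  tags <- suppressWarnings(toBIO(corpus))
  insts <- lapply(seq_along(corpus@ids), function(i) {
    text <- corpus@texts[i]
    y <- match(tags[[corpus@ids[i]]], labels)
    if (nchar(text) > cfg$maxSeqLen) {
      text <- sliceText(text, 0L, cfg$maxSeqLen)
      y <- y[seq_len(cfg$maxSeqLen)]
    }
    list(text = text, y = y)
  })
  d <- encoder@d
  W <- withSeed(cfg$seed, matrix(rnorm(d * L, sd = 1 / sqrt(d)), ncol = L))
  b <- numeric(L)
  params <- list(enc.emb = encoder@emb, enc.W = encoder@W,
                 enc.b = encoder@b, W = W, b = b)
  state <- adamInit(params)
  nS <- length(insts)
  stepsPerEpoch <- ceiling(nS / cfg$batchSize)
  totalSteps <- cfg$epochs * stepsPerEpoch
  step <- 0L
  logRows <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    order <- withSeed(cfg$seed * 1000L + epoch, sample.int(nS))
    epochLoss <- 0
    for (bStart in seq(1L, nS, by = cfg$batchSize)) {
      batch <- order[bStart:min(bStart + cfg$batchSize - 1L, nS)]
      acc <- NULL
      for (si in batch) {
        inst <- insts[[si]]
        enc <- encodeText(encoder, inst$text, withCache = TRUE)
        n <- nrow(enc$E)
        P <- softmaxRows(sweep(enc$E %*% params$W, 2L, params$b, `+`))
        epochLoss <- epochLoss -
          mean(log(pmax(P[cbind(seq_len(n), inst$y)], 1e-12)))
        Y <- matrix(0, n, L); Y[cbind(seq_len(n), inst$y)] <- 1
        dS <- (P - Y) / n
        gW <- crossprod(enc$E, dS)
        gb <- colSums(dS)
        dE <- dS %*% t(params$W)
        ge <- encoderBackward(encoder, enc$cache, dE)
        g <- list(enc.emb = ge$emb, enc.W = ge$W, enc.b = ge$b,
                  W = gW, b = gb)
        acc <- if (is.null(acc)) g else Map(`+`, acc, g[names(acc)])
      }
      acc <- lapply(acc, function(x) x / length(batch))
      step <- step + 1L
      lr <- cfg$learningRate * lrMultiplier(step, totalSteps,
                                            cfg$warmupProportion)
      upd <- adamStep(params, acc, state, lr)
      params <- upd$p; state <- upd$state
      encoder@emb <- params$enc.emb
      encoder@W <- params$enc.W
      encoder@b <- params$enc.b
    }
    logRows[[epoch]] <- data.frame(epoch = epoch, loss = epochLoss / nS)
  }
  model <- new("SoftmaxBaseline", encoder = encoder, W = params$W,
               b = params$b, schema = corpus@schema)
  list(model = model, log = do.call(rbind, logRows))
}

#' Annotate a corpus with the softmax baseline
#'
#' @param model A \code{\linkS4class{SoftmaxBaseline}}.
#' @param corpus A \code{\linkS4class{SpanCorpus}}.
#' @return A \code{SpanCorpus} of predictions (necessarily flat).
#' @export
predictBaselineCorpus <- function(model, corpus) {
  rows <- list()
  for (i in seq_along(corpus@ids)) {
    text <- corpus@texts[i]
    chars <- splitChars(text)
    if (!length(chars)) next
    E <- encodeText(model@encoder, text)
    logits <- sweep(E %*% model@W, 2L, model@b, `+`)
    one <- softmaxBaselineDecode(logits, chars, model@schema,
                                 id = corpus@ids[i])
    ent <- one@entities
    if (nrow(ent)) { ent$source <- "model"; rows[[length(rows) + 1L]] <- ent }
  }
  SpanCorpus(ids = corpus@ids, texts = corpus@texts,
             entities = if (length(rows)) do.call(rbind, rows) else NULL,
             schema = model@schema)
}
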