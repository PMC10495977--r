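#' Synthetic-corpus configuration
#'
#' The generator emulates the structural properties of a
#' rehabilitation-medicine span corpus at a controllable scale: six entity
#' categories, long entities, nested entity pairs, and a tunable proportion
#' of low-frequency (once-seen) entity surfaces per category.  Each category
#' draws its surfaces from a disjoint character alphabet (CJK code points),
#' which makes the surface-to-type mapping learnable by construction and
#' keeps generated corpora clean under the annotation-rule validator.
#'
#' @param nSentences Number of sentences (default 2500, the scale of a
#'   manually annotated corpus in this domain).
#' @param schemaLabels Entity-type schema.
#' @param vocabSizes Per-type vocabulary sizes; \code{NULL} (default) sizes
#'   each vocabulary at 1.5x the planned mention count so the low-frequency
#'   target is reachable.
#' @param entityLengthRange Entity surface length range in characters
#'   (default 2..12, covering long terms).
#' @param nestingRate Fraction of sentences carrying one nested pair (an
#'   outer span strictly containing an inner span of a different type).
#' @param lowFreqTarget Target proportion of mentions whose surface occurs
#'   exactly once within its type (default 0.25, the mid-range of observed
#'   corpora).
#' @param sentenceLengthRange Approximate sentence length range (characters).
#' @param mentionsRange Range of entity mentions per sentence; types within
#'   a sentence are distinct.
#' @param seed Integer seed; generation is byte-deterministic.
#' @return A validated list of class \code{synthConfig}.
#' @export
synthConfig <- function(nSentences = 2500L, schemaLabels = rehabSchema(),
                        vocabSizes = NULL, entityLengthRange = c(2L, 12L),
                        nestingRate = 0.1, lowFreqTarget = 0.25,
                        sentenceLengthRange = c(20L, 60L),
                        mentionsRange = c(1L, 4L), seed = 1L) {
  stopifnot(nSentences >= 1L, nestingRate >= 0, nestingRate <= 1,
            lowFreqTarget >= 0, lowFreqTarget <= 1,
            all(entityLengthRange >= 1L),
            entityLengthRange[1] <= entityLengthRange[2],
            all(sentenceLengthRange >= 1L),
            mentionsRange[1] >= 1L,
            mentionsRange[2] <= length(schemaLabels),
            is.null(vocabSizes) || all(vocabSizes >= 1L))
  if (entityLengthRange[2] + 2L > sentenceLengthRange[2])
    stop("infeasible config: entities longer than the sentence window")
  structure(list(nSentences = as.integer(nSentences),
                 schemaLabels = schemaLabels, vocabSizes = vocabSizes,
                 entityLengthRange = as.integer(entityLengthRange),
                 nestingRate = nestingRate, lowFreqTarget = lowFreqTarget,
                 sentenceLengthRange = as.integer(sentenceLengthRange),
                 mentionsRange = as.integer(mentionsRange),
                 seed = as.integer(seed)),
            class = "synthConfig")
}

typeAlphabet <- function(typeIndex, size = 100L) {
  vapply(0x4E00 + (typeIndex - 1L) * size + seq_len(size) - 1L,
         intToUtf8, character(1))
}

randomString <- function(alphabet, len) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Solve the truncated power-law exponent s (draw probability of vocabulary
# item k proportional to k^-s) so that the expected fraction of draws whose
# item is drawn exactly once among N draws hits the target:
#   E[singleton fraction] = sum_k p_k (1 - p_k)^(N - 1).
solveZipfExponent <- function(V, N, target) {
  singletonFraction <- function(s) {
    p <- (seq_len(V))^(-s)
    p <- p / sum(p)
    sum(p * (1 - p)^(N - 1))
  }
  lo <- singletonFraction(0)
  if (lo <= target) return(list(s = 0, expected = lo, attainable = lo >= target))
  hi <- singletonFraction(12)
  if (hi >= target) return(list(s = 12, expected = hi, attainable = FALSE))
  s <- uniroot(function(s) singletonFraction(s) - target, c(0, 12),
               tol = 1e-4)$root
  list(s = s, expected = singletonFraction(s), attainable = TRUE)
}

#' Generate a synthetic span-annotated corpus
#'
#' Sentences are built from per-type entity surfaces separated by filler
#' runs from a dedicated filler alphabet.  Surface draws follow a truncated
#' power law whose exponent is solved numerically so the expected realized
#' fraction of once-seen surfaces matches \code{lowFreqTarget}.  A
#' \code{nestingRate} fraction of sentences additionally carries one nested
#' pair: an outer span (surface built over the outer type's alphabet)
#' strictly containing an inner span of a different type.
#'
#' @param cfg A \code{\link{synthConfig}}.
#' @return List with \code{corpus} (a \code{\linkS4class{SpanCorpus}}) and
#'   \code{manifest} (realized statistics: per-type mention counts,
#'   singleton proportions and solved exponents, nested-sentence fraction).
#' @export
generateCorpus <- function(cfg) {
  labs <- cfg$schemaLabels
  Tn <- length(labs)
  alphabets <- lapply(seq_len(Tn), typeAlphabet)
  names(alphabets) <- labs
  filler <- typeAlphabet(Tn + 1L)
  withSeed(cfg$seed, {
    # ---- plan sentences ----
    nested <- runif(cfg$nSentences) < cfg$nestingRate
    plan <- lapply(seq_len(cfg$nSentences), function(i) {
      k <- sample(cfg$mentionsRange[1]:cfg$mentionsRange[2], 1L)
      if (nested[i]) k <- max(k, 2L)
      sample(labs, k)
    })
    # planned flat mentions per type (nested sentences: first planned type
    # becomes the outer ad-hoc surface, second the vocabulary-drawn inner)
    Nt <- setNames(integer(Tn), labs)
    for (i in seq_len(cfg$nSentences)) {
      tys <- plan[[i]]
      if (nested[i]) tys <- tys[-1L]          # outer span is ad hoc
      for (ty in tys) Nt[ty] <- Nt[ty] + 1L
    }
    # ---- vocabularies and draw distributions ----
    vocabs <- list(); exponents <- setNames(numeric(Tn), labs)
    attainable <- setNames(logical(Tn), labs)
    for (t in seq_len(Tn)) {
      V <- if (!is.null(cfg$vocabSizes)) cfg$vocabSizes[t]
           else max(30L, ceiling(1.5 * max(Nt[t], 1L)))
      surfs <- character(0)
      while (length(surfs) < V) {
        need <- V - length(surfs)
        cand <- vapply(seq_len(need), function(z)
          randomString(alphabets[[t]],
                       sample(cfg$entityLengthRange[1]:cfg$entityLengthRange[2],
                              1L)),
          character(1))
        surfs <- unique(c(surfs, cand))
      }
      sol <- solveZipfExponent(V, max(Nt[t], 2L), cfg$lowFreqTarget)
      exponents[t] <- sol$s
      attainable[t] <- sol$attainable
      p <- (seq_len(V))^(-sol$s); p <- p / sum(p)
      vocabs[[labs[t]]] <- list(surfaces = surfs, p = p)
    }
    drawSurface <- function(ty) {
      v <- vocabs[[ty]]
      sample(v$surfaces, 1L, prob = v$p)
    }
    # ---- assemble sentences ----
    ids <- paste0("s", seq_len(cfg$nSentences))
    texts <- character(cfg$nSentences)
    rows <- vector("list", cfg$nSentences)
    for (i in seq_len(cfg$nSentences)) {
      tys <- plan[[i]]
      pieces <- character(0)      # alternating filler / entity text
      ents <- list()
      targetLen <- sample(cfg$sentenceLengthRange[1]:cfg$sentenceLengthRange[2],
                          1L)
      segs <- list()
      if (nested[i]) {
        outerTy <- tys[1L]; innerTy <- tys[2L]
        inner <- drawSurface(innerTy)
        pre <- randomString(alphabets[[outerTy]], sample(1:3, 1L))
        suf <- randomString(alphabets[[outerTy]], sample(1:3, 1L))
        segs[[1L]] <- list(kind = "nested", outer = outerTy,
                           inner = innerTy, pre = pre, suf = suf,
                           innerSurf = inner)
        tys <- tys[-(1:2)]
      }
      for (ty in tys)
        segs[[length(segs) + 1L]] <- list(kind = "flat", ty = ty,
                                          surf = drawSurface(ty))
      segs <- segs[sample.int(length(segs))]
      entLen <- sum(vapply(segs, function(s)
        if (s$kind == "flat") nchar(s$surf)
        else nchar(s$pre) + nchar(s$innerSurf) + nchar(s$suf), numeric(1)))
      nGaps <- length(segs) + 1L
      spare <- max(0L, targetLen - entLen - nGaps)
      extra <- if (spare > 0L)
        tabulate(sample.int(nGaps, spare, replace = TRUE), nGaps)
        else integer(nGaps)
      gapLens <- 1L + extra
      text <- ""
      for (g in seq_along(segs)) {
        text <- paste0(text, randomString(filler, gapLens[g]))
        off <- nchar(text)
        s <- segs[[g]]
        if (s$kind == "flat") {
          ents[[length(ents) + 1L]] <- data.frame(
            sentence_id = ids[i], label = s$ty, start = off,
            end = off + nchar(s$surf), surface = s$surf, source = "manual",
            stringsAsFactors = FALSE)
          text <- paste0(text, s$surf)
        } else {
          outerSurf <- paste0(s$pre, s$innerSurf, s$suf)
          ents[[length(ents) + 1L]] <- data.frame(
            sentence_id = ids[i], label = s$outer, start = off,
            end = off + nchar(outerSurf), surface = outerSurf,
            source = "manual", stringsAsFactors = FALSE)
          ents[[length(ents) + 1L]] <- data.frame(
            sentence_id = ids[i], label = s$inner,
            start = off + nchar(s$pre),
            end = off + nchar(s$pre) + nchar(s$innerSurf),
            surface = s$innerSurf, source = "manual",
            stringsAsFactors = FALSE)
          text <- paste0(text, outerSurf)
        }
      }
      text <- paste0(text, randomString(filler, gapLens[nGaps]))
      texts[i] <- text
      rows[[i]] <- do.call(rbind, ents)
    }
    corpus <- SpanCorpus(ids = ids, texts = texts,
                         entities = do.call(rbind, rows),
                         schema = labs)
    lf <- lowFrequencyAnalysis(corpus)
    manifest <- list(
      nSentences = cfg$nSentences,
      nestedFraction = mean(nested),
      entityCounts = entityCounts(corpus),
      lowFrequency = lf,
      zipfExponents = exponents,
      lowFreqTargetAttainable = attainable,
      seed = cfg$seed)
    list(corpus = corpus, manifest = manifest)
  })
}

#' Simulate a second annotator
#'
#' Produces a perturbed copy of a gold corpus for agreement studies.  Each
#' span is independently perturbed with probability \code{rate}; the
#' perturbation is drawn uniformly from boundary shift (one character),
#' label swap, and deletion.  At \code{rate = 0} the copies are identical
#' (IAA F1 = 100); higher rates lower agreement predictably.
#'
#' @param corpus Gold \code{\linkS4class{SpanCorpus}}.
#' @param rate Per-span perturbation probability in [0, 1].
#' @param seed Integer seed.
#' @return List with \code{a} (the input) and \code{b} (the perturbed copy).
#' @export
makeAnnotatorPair <- function(corpus, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  ent <- corpus@entities
  nch <- setNames(nchar(corpus@texts), corpus@ids)
  withSeed(seed, {
    keep <- logical(nrow(ent))
    out <- ent
    for (r in seq_len(nrow(ent))) {
      keep[r] <- TRUE
      if (runif(1) >= rate) next
      kind <- sample(c("shift", "swap", "delete"), 1L)
      if (kind == "delete") { keep[r] <- FALSE; next }
      if (kind == "swap") {
        out$label[r] <- sample(setdiff(corpus@schema, ent$label[r]), 1L)
        next
      }
      s <- ent$start[r]; e <- ent$end[r]
      n <- nch[[ent$sentence_id[r]]]
      moves <- list()
      if (s > 0L) moves <- c(moves, list(c(s - 1L, e)))
      if (s + 1L < e) moves <- c(moves, list(c(s + 1L, e)))
      if (e < n) moves <- c(moves, list(c(s, e + 1L)))
      if (e - 1L > s) moves <- c(moves, list(c(s, e - 1L)))
      mv <- moves[[sample.int(length(moves), 1L)]]
      out$start[r] <- mv[1L]; out$end[r] <- mv[2L]
    }
    out <- out[keep, , drop = FALSE]
    for (r in seq_len(nrow(out))) {
      text <- corpus@texts[match(out$sentence_id[r], corpus@ids)]
      out$surface[r] <- sliceText(text, out$start[r], out$end[r])
    }
    list(a = corpus,
         b = SpanCorpus(ids = corpus@ids, texts = corpus@texts,
                        entities = out, schema = corpus@schema))
  })
}
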