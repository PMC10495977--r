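test_that("start prediction is a row-wise softmax of E %*% Ts", {
  E <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  headZero <- list(Ts = matrix(0, 2, 2))
  P <- predictStart(E, headZero)
  expect_equal(P, matrix(0.5, 2, 2))

  # logits (10, 0) in the first row: softmax = (0.9999546, 0.0000454)
  head10 <- list(Ts = matrix(c(10, 0, 0, 0), 2, 2))
  P <- predictStart(E, head10)
  expect_equal(P[1, ], c(1 / (1 + exp(-10)), exp(-10) / (1 + exp(-10))),
               tolerance = 1e-7)

  set.seed(1)
  E <- matrix(rnorm(40), 8, 5)
  head <- list(Ts = matrix(rnorm(10), 5, 2))
  expect_equal(rowSums(predictStart(E, head)), rep(1, 8), tolerance = 1e-6)
  expect_error(predictStart(matrix(c(1, NaN), 1, 2),
                            list(Ts = matrix(0, 2, 2))), "non-finite")
})

test_that("end prediction injects the start indicator row-locally", {
  set.seed(2)
  d <- 4; n <- 5
  E <- matrix(rnorm(n * d), n, d)
  head <- list(Te = matrix(rnorm(2 * d), d, 2), U = matrix(rnorm(2 * d), 2, d))

  zeroHead <- list(Te = matrix(0, d, 2), U = matrix(0, 2, d))
  expect_equal(predictEnd(E, startIndicator(rep(0, n)), zeroHead),
               matrix(0.5, n, 2))

  ind <- startIndicator(c(0, 1, 0, 0, 0))
  flipped <- startIndicator(c(0, 1, 1, 0, 0))
  P1 <- predictEnd(E, ind, head)
  P2 <- predictEnd(E, flipped, head)
  expect_equal(P1[-3, ], P2[-3, ])          # only the flipped row changes
  expect_false(isTRUE(all.equal(P1[3, ], P2[3, ])))

  # with a gold start indicator, the logits differ from the no-indicator
  # branch by exactly the projected embedding contribution
  base <- E %*% head$Te
  withInd <- (E + ind %*% head$U) %*% head$Te
  expect_equal(withInd - base, (ind %*% head$U) %*% head$Te)

  expect_error(predictEnd(E, matrix(1, 2, 2), head), "n x 2")
})

test_that("candidate extraction follows strict argmax with ties to non-entity", {
  expect_identical(extractIndices(matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2,
                                         byrow = TRUE)), 1L)
  expect_length(extractIndices(matrix(c(1, 0), 4, 2, byrow = TRUE)), 0)
  expect_length(extractIndices(matrix(0.5, 3, 2)), 0)   # ties excluded
})

test_that("pair matching is the sigmoid of m . concat and monotone", {
  E <- diag(2)
  expect_equal(matchPair(E, 0, 1, rep(0, 4)), 0.5)
  # m . concat = 2  ->  sigmoid(2) = 0.8807971
  expect_equal(matchPair(E, 0, 1, c(2, 0, 0, 0)), 0.8807971, tolerance = 1e-7)
  zs <- seq(-3, 3, by = 0.5)
  ps <- vapply(zs, function(z) matchPair(E, 0, 1, c(z, 0, 0, 0)), numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_error(matchPair(E, 1, 0, rep(0, 4)), "exceeds")
})

test_that("span decoding enumerates admissible pairs and keeps overlaps", {
  n <- 9
  Pfor <- function(pos) {   # probability matrix with class 1 at `pos` (0-based)
    P <- matrix(c(0.9, 0.1), n, 2, byrow = TRUE)
    for (p in pos) P[p + 1, ] <- c(0.1, 0.9)
    P
  }
  one <- decodeSpans(Pfor(1), Pfor(3), function(i, j) 0.9, threshold = 0.5)
  expect_identical(one$start, 1L)
  expect_identical(one$end, 4L)     # half-open

  multi <- decodeSpans(Pfor(c(1, 5)), Pfor(c(3, 7)), function(i, j) 0.9)
  expect_identical(spanKeys(multi),
                   sort(c("entity:1:4", "entity:1:8", "entity:5:8")))

  none <- decodeSpans(Pfor(5), Pfor(1), function(i, j) 0.9)
  expect_identical(nrow(none), 0L)
})

test_that("decoder agrees with a brute-force oracle on random instances", {
  for (seed in 1:60) {
    model <- randomModel(seed)
    n <- 3 + (seed %% 10)
    text <- randomText(seed + 500, n)
    got <- decodeEntities(model, text)
    E <- encodeText(model@encoder, text)
    want <- oracleDecode(E, model@heads, model@schema,
                         threshold = model@threshold,
                         maxSpanLen = model@maxSpanLen)
    expect_identical(spanKeys(got), as.character(want))
  }
})

test_that("nested gold spans are recovered under gold-forcing scores", {
  nf <- nestedFixture()
  n <- nchar(sentenceTexts(nf)[[1]])
  gold <- entities(nf)
  recovered <- list()
  for (lb in schema(nf)) {
    rows <- gold[gold$label == lb, , drop = FALSE]
    Ps <- matrix(c(0.9, 0.1), n, 2, byrow = TRUE)
    Pe <- matrix(c(0.9, 0.1), n, 2, byrow = TRUE)
    Ps[rows$start + 1, ] <- c(0.1, 0.9)
    Pe[rows$end, ] <- c(0.1, 0.9)
    goldPairs <- paste(rows$start, rows$end - 1L)
    recovered[[lb]] <- decodeSpans(
      Ps, Pe, function(i, j) as.numeric(paste(i, j) %in% goldPairs),
      threshold = 0.5, maxSpanLen = 30, label = lb)
  }
  got <- do.call(rbind, recovered)
  expect_identical(spanKeys(got), spanKeys(gold))
})

test_that("composite loss is zero at perfect prediction, ln 2 under uniform", {
  n <- 4
  y <- c(0L, 1L, 0L, 0L)
  perfect <- cbind(1 - y, y)
  pred <- list(list(Pstart = perfect, Pend = perfect, pairProbs = 1))
  targ <- list(list(yStart = y, yEnd = y, pairLabels = 1L))
  L <- computeLoss(pred, targ)
  expect_equal(L$total, 0)

  uniform <- matrix(0.5, n, 2)
  predU <- list(list(Pstart = uniform, Pend = uniform, pairProbs = 0.5))
  LU <- computeLoss(predU, targ, weights = c(1, 0, 0))
  expect_equal(LU$total, log(2), tolerance = 1e-12)
  expect_equal(LU$lStart, log(2), tolerance = 1e-12)

  # weight gamma = 0 makes the total blind to matching predictions
  predA <- list(list(Pstart = uniform, Pend = uniform, pairProbs = 0.99))
  predB <- list(list(Pstart = uniform, Pend = uniform, pairProbs = 0.01))
  expect_equal(computeLoss(predA, targ, c(1, 1, 0))$total,
               computeLoss(predB, targ, c(1, 1, 0))$total)

  # linearity in (alpha, beta, gamma)
  w <- c(0.3, 1.7, 2.2)
  L1 <- computeLoss(predU, targ, w)
  expect_equal(L1$total,
               w[1] * L1$lStart + w[2] * L1$lEnd + w[3] * L1$lSpan)

  expect_warning(
    computeLoss(list(list(Pstart = uniform, Pend = uniform,
                          pairProbs = numeric(0))),
                list(list(yStart = y, yEnd = y, pairLabels = integer(0)))),
    "empty candidate-pair")
})

test_that("analytic gradients match finite differences", {
  model <- randomModel(3, d = 5)
  corpus <- SpanCorpus(
    "s1", "abcdefg",
    data.frame(sentence_id = "s1", label = c("body", "drugs"),
               start = c(1L, 4L), end = c(3L, 6L),
               surface = c("bc", "ef"), stringsAsFactors = FALSE),
    schema = miniSchema)
  inst <- rehabspan:::buildInstance(sentenceTexts(corpus)[[1]],
                                    entities(corpus), miniSchema,
                                    maxSeqLen = 50L, maxPairs = 50L, seed = 1L)
  w <- c(1, 1, 1)
  res <- rehabspan:::sentenceGrad(model, inst, w)
  lossAt <- function(m) rehabspan:::sentenceGrad(m, inst, w)$loss$total
  eps <- 1e-5
  params <- rehabspan:::getParams(model)
  for (key in c("enc.emb", "enc.W", "enc.b", "head.body.Ts",
                "head.body.Te", "head.body.U", "head.drugs.m")) {
    idx <- if (length(params[[key]]) > 3) c(1L, 3L) else 1L
    for (i in idx) {
      pp <- params; pp[[key]][i] <- pp[[key]][i] + eps
      pm <- params; pm[[key]][i] <- pm[[key]][i] - eps
      num <- (lossAt(rehabspan:::setParams(model, pp)) -
              lossAt(rehabspan:::setParams(model, pm))) / (2 * eps)
      expect_equal(res$grads[[key]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("loss strictly decreases along one gradient step on a fixed example", {
  model <- randomModel(9, d = 5)
  inst <- rehabspan:::buildInstance("abcdefg",
    data.frame(sentence_id = "s1", label = "body", start = 1L, end = 3L,
               surface = "bc", source = "manual", stringsAsFactors = FALSE),
    miniSchema, maxSeqLen = 50L, maxPairs = 50L, seed = 1L)
  res <- rehabspan:::sentenceGrad(model, inst, c(1, 1, 1))
  params <- rehabspan:::getParams(model)
  stepped <- Map(function(p, g) p - 0.05 * g, params,
                 res$grads[names(params)])
  after <- rehabspan:::sentenceGrad(rehabspan:::setParams(model, stepped),
                                    inst, c(1, 1, 1))
  expect_lt(after$loss$total, res$loss$total)
})
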