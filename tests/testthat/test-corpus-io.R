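test_that("JSON corpus round-trips exactly, including nested spans", {
  tc <- tinyCorpus()
  f <- withr::local_tempfile(fileext = ".json")
  writeJsonCorpus(tc, f)
  back <- readJsonCorpus(f)
  expect_identical(sentenceTexts(back), sentenceTexts(tc))
  expect_identical(entities(back), entities(tc))
  expect_identical(schema(back), schema(tc))

  nf <- nestedFixture()
  writeJsonCorpus(nf, f)
  back <- readJsonCorpus(f)
  expect_identical(entities(back), entities(nf))
  expect_equal(nrow(entities(back)), 2L)

  empty <- SpanCorpus(character(0), character(0), schema = miniSchema)
  writeJsonCorpus(empty, f)
  expect_identical(length(readJsonCorpus(f)), 0L)
})

test_that("JSON output is byte-stable across repeated writes", {
  corpus <- flatCorpus(n = 3)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeJsonCorpus(corpus, f1)
  writeJsonCorpus(corpus, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("constructor rejects out-of-range, mismatched and unknown spans", {
  expect_error(
    SpanCorpus("s1", "患者肢体麻木",
               data.frame(sentence_id = "s1", label = "body",
                          start = 2L, end = 7L, surface = "肢体麻木x"),
               schema = miniSchema),
    "out of range")
  expect_error(
    SpanCorpus("s1", "患者肢体麻木",
               data.frame(sentence_id = "s1", label = "body",
                          start = 2L, end = 4L, surface = "肢"),
               schema = miniSchema),
    "does not match text slice")
  expect_error(
    SpanCorpus("s1", "患者肢体麻木",
               data.frame(sentence_id = "s1", label = "disease",
                          start = 2L, end = 4L, surface = "肢体"),
               schema = miniSchema),
    "not in schema")
})

test_that("BIO conversion encodes flat spans and drops nested ones with warning", {
  flat <- SpanCorpus("s1", "一二三四五",
                     data.frame(sentence_id = "s1", label = "body",
                                start = 1L, end = 3L, surface = "二三"),
                     schema = miniSchema)
  expect_identical(toBIO(flat)$s1, c("O", "B-body", "I-body", "O", "O"))

  nested <- nestedFixture()
  expect_warning(tags <- toBIO(nested), "dropped")
  # outer span (earlier start, longer) is kept; inner span vanishes
  expect_identical(tags$n1,
                   c("B-body", rep("I-body", 4), "O"))

  none <- SpanCorpus("s1", "一二三", NULL, schema = miniSchema)
  expect_identical(toBIO(none)$s1, c("O", "O", "O"))
})

test_that("fromBIO inverts toBIO and repairs orphan I- tags", {
  chars <- c("服", "阿", "司")
  got <- fromBIO(chars, c("O", "B-drugs", "I-drugs"), schema = miniSchema)
  expect_identical(entities(got)[, c("label", "start", "end", "surface")],
                   data.frame(label = "drugs", start = 1L, end = 3L,
                              surface = "阿司", stringsAsFactors = FALSE))

  expect_warning(rep <- fromBIO(c("肢", "体"), c("I-body", "I-body"),
                                schema = miniSchema),
                 "orphan")
  expect_identical(entities(rep)$start, 0L)
  expect_identical(entities(rep)$end, 2L)

  expect_identical(entityCount(fromBIO(chars, rep("O", 3), miniSchema)), 0L)
  expect_error(fromBIO(chars, c("O", "O")), "equal length")
})

test_that("BIO round-trip is the identity on random flat corpora", {
  for (seed in 1:5) {
    corpus <- flatCorpus(n = 10, seed = seed)
    tags <- toBIO(corpus)
    for (sid in sentenceIds(corpus)) {
      text <- sentenceTexts(corpus)[[sid]]
      back <- fromBIO(strsplit(text, "")[[1]], tags[[sid]],
                      schema = schema(corpus), id = sid)
      gold <- entities(corpus)[entities(corpus)$sentence_id == sid,
                               c("label", "start", "end", "surface")]
      gold <- gold[order(gold$start), ]
      rownames(gold) <- NULL
      expect_identical(entities(back)[, c("label", "start", "end", "surface")],
                       gold)
    }
  }
})

test_that("BIO files round-trip through the tab-separated format", {
  corpus <- flatCorpus(n = 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".bio")
  writeBioCorpus(corpus, f)
  back <- readBioCorpus(f, schema = schema(corpus))
  expect_identical(entities(back)[, c("label", "start", "end", "surface")],
                   entities(corpus)[, c("label", "start", "end", "surface")])
})

test_that("splitCorpus partitions deterministically with round(n * fraction)", {
  big <- SpanCorpus(paste0("s", 1:2500), rep("文", 2500),
                    schema = miniSchema)
  sp <- splitCorpus(big, 0.9, seed = 5)
  expect_identical(length(sp$train), 2250L)
  expect_identical(length(sp$test), 250L)

  sp2 <- splitCorpus(big, 0.9, seed = 5)
  expect_identical(sentenceIds(sp$train), sentenceIds(sp2$train))

  small <- SpanCorpus(paste0("s", 1:10), rep("文", 10), schema = miniSchema)
  sp <- splitCorpus(small, 0.5, seed = 3)
  expect_identical(sort(c(sentenceIds(sp$train), sentenceIds(sp$test))),
                   sort(sentenceIds(small)))
  expect_length(intersect(sentenceIds(sp$train), sentenceIds(sp$test)), 0)
  expect_error(splitCorpus(SpanCorpus("s1", "文", schema = miniSchema), 0.5),
               "at least 2")
})

test_that("kfoldSplit test folds are disjoint, exhaustive and balanced", {
  corpus <- SpanCorpus(paste0("s", 1:7), rep("文", 7), schema = miniSchema)
  folds <- kfoldSplit(corpus, k = 5, seed = 2)
  sizes <- sort(vapply(folds, function(f) length(f$test), integer(1)),
                decreasing = TRUE)
  expect_identical(sizes, c(2L, 2L, 1L, 1L, 1L))
  testIds <- unlist(lapply(folds, function(f) sentenceIds(f$test)))
  expect_identical(sort(testIds), sort(sentenceIds(corpus)))  # exhaustive
  expect_false(anyDuplicated(testIds) > 0)                    # disjoint
  for (f in folds)
    expect_length(intersect(sentenceIds(f$train), sentenceIds(f$test)), 0)
  expect_error(kfoldSplit(corpus, k = 8), "exceeds")
  expect_error(kfoldSplit(corpus, k = 1), "at least 2")

  folds2 <- kfoldSplit(corpus, k = 5, seed = 2)
  expect_identical(lapply(folds, function(f) sentenceIds(f$test)),
                   lapply(folds2, function(f) sentenceIds(f$test)))
})

test_that("annotation-rule validator flags overlap and Latin surfaces as warnings", {
  nested <- nestedFixture()
  expect_warning(msgs <- validateCorpus(nested), "overlap")
  expect_length(msgs, 1L)

  latin <- SpanCorpus("s1", "测试ABC结束",
                      data.frame(sentence_id = "s1", label = "drugs",
                                 start = 2L, end = 5L, surface = "ABC"),
                      schema = miniSchema)
  expect_warning(validateCorpus(latin), "Latin")

  clean <- flatCorpus(n = 5, seed = 4)
  expect_silent(msgs <- validateCorpus(clean))
  expect_length(msgs, 0L)
})
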