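test_that("lexicon loading casefolds, deduplicates and rejects long entries", {
  f <- withr::local_tempfile(lines = c("Lipitor", "lipitor", "Prednisone",
                                       "# a comment", ""))
  lex <- load_lexicon(f, "drug")
  expect_equal(length(lex$entries), 2L)
  expect_setequal(lex$entries, c("lipitor", "prednisone"))

  f2 <- withr::local_tempfile(lines = c("ok", "one two three four five six"))
  expect_warning(lex2 <- load_lexicon(f2, "side_effect"), "5 tokens")
  expect_equal(lex2$entries, "ok")

  f3 <- withr::local_tempfile(lines = c("# only a comment"))
  expect_error(load_lexicon(f3, "drug"), "empty")
})

test_that("the transcribed keyword lexicon has exactly 45 entries", {
  kw <- adr_keywords()
  expect_equal(length(kw$entries), 45L)
  expect_true(all(c("made me feel", "due to", "side effects", "i am having",
                    "was causing") %in% kw$entries))
  expect_true(all(lengths(strsplit(kw$entries, " ")) <= 5))
})

test_that("phrase matching is greedy leftmost-longest with class precedence", {
  lex <- tiny_lexset()
  m <- match_phrases(c("i", "developed", "hives", "after", "taking",
                       "prednisone"), lex)
  expect_equal(m$lexicon, c("keyword", "side_effect", "drug"))
  expect_equal(m$entry, c("developed", "hives", "prednisone"))
  expect_equal(m$start, c(2L, 3L, 6L))

  # leftmost-longest: "side effects" wins over the overlapping "effects of"
  m2 <- match_phrases(c("side", "effects", "of"), lex)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$entry, "side effects")
  expect_equal(c(m2$start, m2$end), c(1L, 2L))

  # multi-word side-effect terms match as one span
  m3 <- match_phrases(c("got", "acid", "reflux"), lex)
  expect_equal(m3$entry, "acid reflux")

  expect_equal(nrow(match_phrases(c("nothing", "to", "see"), lex)), 0L)

  # equal-length competition at the same start: drug beats side_effect
  amb <- lexicon_set(drug = lexicon("moon face", "drug"),
                     side_effect = lexicon("moon face", "side_effect"))
  m4 <- match_phrases(c("moon", "face"), amb)
  expect_equal(m4$lexicon, "drug")
})

test_that("matching is invariant to lexicon file line order", {
  entries <- c("hives", "acid reflux", "dry mouth", "headache", "moon face")
  toks <- c("i", "got", "acid", "reflux", "and", "dry", "mouth", "hives")
  withr::local_seed(5)
  base <- NULL
  for (i in 1:5) {
    lex <- lexicon_set(drug = lexicon("prednisone", "drug"),
                       side_effect = lexicon(sample(entries), "side_effect"))
    m <- match_phrases(toks, lex)
    if (is.null(base)) base <- m else expect_identical(m, base)
  }
})

test_that("matched spans never overlap and stay within bounds", {
  withr::local_seed(9)
  gen <- generate_corpus(generator_config(n_messages = 40, seed = 9))
  seqs <- preprocess_corpus(gen$corpus, gen$lexicons)
  for (msg in gen$corpus[1:15]) {
    toks <- tokenize_text(normalize_text(strip_html(msg$text)))
    m <- match_phrases(toks, gen$lexicons)
    if (!nrow(m)) next
    covered <- unlist(Map(seq.int, m$start, m$end))
    expect_equal(anyDuplicated(covered), 0L)
    expect_true(all(covered >= 1 & covered <= length(toks)))
  }
})

test_that("symbol substitution collapses matched spans to one observation", {
  lex <- tiny_lexset()
  toks <- c("she", "was", "starting", "to", "feel", "nausea", "zzzz")
  cfg <- pipeline_config(stopword_filter = FALSE)
  obs <- run_pipeline(adr_message("m", paste(toks, collapse = " ")), lex, cfg)
  # "starting to feel" (3 tokens) collapses to a single KW observation
  expect_equal(obs$tokens$surface,
               c("she", "was", "starting to feel", "nausea", "zzzz"))
  expect_equal(obs$tokens$symbol[3:5], c(3L, 2L, 4L))  # KW, SE, UNK
})

test_that("entry-level granularity emits per-entry symbols", {
  lex <- tiny_lexset(granularity = "entry_level")
  seqs <- preprocess_corpus(list(
    adr_message("a", "developed hives from prednisone"),
    adr_message("b", "developed nausea from prednisone")
  ), lex)
  vocab <- build_vocab(seqs, lex, min_count = 1)
  s1 <- symbolize_seq(seqs[[1]], vocab, lex)
  s2 <- symbolize_seq(seqs[[2]], vocab, lex)
  sym <- function(s, surface) s$tokens$symbol[s$tokens$surface == surface]
  expect_equal(sym(s1, "prednisone"), sym(s2, "prednisone"))
  expect_false(sym(s1, "hives") == sym(s2, "nausea"))
  expect_true(all(s1$tokens$symbol >= 1 & s1$tokens$symbol <= attr(vocab, "M")))
})

test_that("word symbols require min_count occurrences, rare words are unknown", {
  lex <- tiny_lexset()
  seqs <- preprocess_corpus(list(
    adr_message("a", "banana banana kumquat"),
    adr_message("b", "banana pear")
  ), lex)
  vocab <- build_vocab(seqs, lex, min_count = 2)
  expect_true("banana" %in% names(vocab))
  expect_false("kumquat" %in% names(vocab))
  s <- symbolize_seq(seqs[[1]], vocab, lex)
  expect_equal(s$tokens$symbol[3], 4L)  # <unk>
})

test_that("lexicon subsetting floors the size and is a seeded sub-multiset", {
  big <- lexicon(sprintf("drug%04d", 1:760), "drug")
  half <- subset_lexicon(big, 0.5, seed = 3)
  expect_equal(length(half$entries), 380L)
  se <- lexicon(sprintf("se%04d", 1:1390), "side_effect")
  expect_equal(length(subset_lexicon(se, 0.5, seed = 3)$entries), 695L)
  expect_identical(subset_lexicon(big, 1, seed = 1)$entries, big$entries)
  for (s in c(1, 7, 101)) {
    sub <- subset_lexicon(big, 0.5, seed = s)
    expect_true(all(sub$entries %in% big$entries))
    expect_identical(sub$entries, subset_lexicon(big, 0.5, seed = s)$entries)
  }
  tiny <- lexicon("only", "drug")
  expect_error(subset_lexicon(tiny, 0.5, seed = 1), "empty")
})

test_that("n-gram candidate mining matches a brute-force recount", {
  withr::local_seed(13)
  vocab <- c("made", "me", "feel", "sick", "the", "dog", "ran")
  corpus <- replicate(60, sample(vocab, sample(3:9, 1), replace = TRUE),
                      simplify = FALSE)
  got <- mine_keyword_candidates(corpus, 2, 5, min_count = 3)
  oracle <- brute_ngram_counts(corpus, 2, 5)
  oracle <- oracle[oracle > 3]
  expect_setequal(got$ngram, names(oracle))
  expect_equal(got$count, as.integer(oracle[got$ngram]))
  # sorted by count desc then lexicographically
  expect_true(all(diff(got$count) <= 0))
})

test_that("the candidate threshold is strictly greater-than", {
  corpus <- c(replicate(20, c("made", "me", "feel"), simplify = FALSE),
              replicate(21, c("was", "causing"), simplify = FALSE))
  got <- mine_keyword_candidates(corpus, 2, 5, min_count = 20)
  expect_equal(got$ngram, "was causing")  # exactly 20 occurrences excluded
  expect_equal(got$count, 21L)
  expect_equal(nrow(mine_keyword_candidates(list(), 2, 5, 20)), 0L)
  expect_error(mine_keyword_candidates(corpus, 5, 2), "n_min")
})
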