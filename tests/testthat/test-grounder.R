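test_that("normalize_label handles case, punctuation and typography", {
  expect_identical(normalize_label("Marfan Syndrome."), "marfan syndrome")
  expect_identical(normalize_label("Loeys–Dietz  syndrome"),
                   "loeys-dietz syndrome")
  expect_identical(normalize_label("  EHLERS—DANLOS  "), "ehlers-danlos")
  expect_identical(normalize_label("“Alpha” syndrome?"),
                   normalize_label("alpha” syndrome"))
  expect_identical(normalize_label("O’Brien disease"), "o'brien disease")
})

test_that("normalize_label is idempotent over a random corpus", {
  set.seed(101)
  alphabet <- c(letters, LETTERS, " ", ".", ",", "-", "–", "’",
                "(", ")", "  ", "é", "付", "1", "9")
  for (i in 1:200) {
    s <- paste(sample(alphabet, sample(1:30, 1), replace = TRUE),
               collapse = "")
    n1 <- normalize_label(s)
    expect_identical(normalize_label(n1), n1)
  }
})

test_that("the grounding index applies the documented collision policy", {
  g <- load_obograph(write_obograph_fixture(list(
    list(id = "MONDO:0000001", label = "Root"),
    list(id = "MONDO:0000002", label = "Alpha disease",
         synonyms = "shared name", parents = "MONDO:0000001"),
    list(id = "MONDO:0000003", label = "Shared Name",
         parents = "MONDO:0000001"),
    list(id = "MONDO:0000004", label = "Twin label",
         parents = "MONDO:0000001"),
    list(id = "MONDO:0000005", label = "twin LABEL",
         parents = "MONDO:0000001"),
    list(id = "MONDO:0000006", label = "Dead disease",
         parents = "MONDO:0000001", obsolete = TRUE))))
  idx <- build_grounding_index(g)
  # label beats synonym
  expect_identical(ground_candidates("shared name", idx)$grounded,
                   "MONDO:0000003")
  # equal kinds: lexicographically smallest id wins
  expect_identical(ground_candidates("Twin Label", idx)$grounded,
                   "MONDO:0000004")
  # obsolete terms are not indexed
  expect_true(ground_candidates("Dead disease", idx)$failure)
  expect_true(nrow(idx$collisions) > 0)
})

test_that("index size equals the brute-force count of unique strings", {
  g <- tiny_world()$onts$disease
  idx <- build_grounding_index(g)
  live <- Filter(function(t) !t$obsolete, g$terms)
  strings <- unlist(lapply(live, function(t)
    normalize_label(c(t$label, t$synonyms))))
  expect_identical(nrow(idx$entries), length(unique(strings[nzchar(strings)])))
})

# One entry per hand-written reply dialect with its expected extraction;
# NULL items mean refusal.
reply_dialects <- list(
  list(raw = "1. Marfan syndrome\n2. Loeys-Dietz syndrome",
       items = c("Marfan syndrome", "Loeys-Dietz syndrome")),
  list(raw = "1) Alpha syndrome\n2) Beta disorder",
       items = c("Alpha syndrome", "Beta disorder")),
  list(raw = "1: Alpha syndrome\n2: Beta disorder",
       items = c("Alpha syndrome", "Beta disorder")),
  list(raw = "1 - Alpha syndrome\n2 - Beta disorder",
       items = c("Alpha syndrome", "Beta disorder")),
  list(raw = "- Alpha syndrome\n- Beta disorder",
       items = c("Alpha syndrome", "Beta disorder")),
  list(raw = "* Alpha syndrome\n* Beta disorder",
       items = c("Alpha syndrome", "Beta disorder")),
  list(raw = "• Alpha syndrome\n• Beta disorder",
       items = c("Alpha syndrome", "Beta disorder")),
  list(raw = "Alpha syndrome\nBeta disorder\nGamma disease",
       items = c("Alpha syndrome", "Beta disorder", "Gamma disease")),
  list(raw = "Here are my top candidates:\n1. Alpha syndrome\n2. Beta disorder\nI hope this helps!",
       items = c("Alpha syndrome", "Beta disorder")),
  list(raw = "My differential:\n\n1. Alpha syndrome (FBN1)\n\n2. Beta disorder (OMIM 154700)",
       items = c("Alpha syndrome (FBN1)", "Beta disorder (OMIM 154700)")),
  list(raw = "1.  Alpha   syndrome  \n2.\tBeta disorder",
       items = c("Alpha   syndrome", "Beta disorder")),
  list(raw = "10. Alpha syndrome\n11. Beta disorder",
       items = c("Alpha syndrome", "Beta disorder")),
  list(raw = "I am sorry, I cannot determine a diagnosis from this description.",
       items = NULL),
  list(raw = "Sorry, there is not enough information to answer.",
       items = NULL),
  list(raw = "", items = NULL),
  list(raw = "   \n \n", items = NULL),
  list(raw = "As an assistant I would need more clinical detail to answer.",
       items = NULL),
  list(raw = "Unfortunately the phenotype is too unspecific for a single answer.",
       items = NULL),
  list(raw = "- Alpha syndrome",
       items = "Alpha syndrome"),
  list(raw = "Alpha syndrome",
       items = "Alpha syndrome"))

test_that("parse_differential handles the dialect corpus", {
  for (d in reply_dialects) {
    got <- parse_differential(d$raw)
    if (is.null(d$items)) {
      expect_true(got$refusal, info = d$raw)
      expect_length(got$candidates, 0)
    } else {
      expect_false(got$refusal, info = d$raw)
      expect_identical(got$candidates, d$items, info = d$raw)
    }
  }
})

test_that("grounding preserves rank and keeps failures in place", {
  idx <- build_grounding_index(six_subtype_graph())
  got <- ground_candidates(
    c("Alpha syndrome type 2", "acme nonexistosis", "Beta disorder"), idx)
  expect_identical(got$rank, 1:3)
  expect_identical(got$grounded,
                   c("MONDO:0000202", NA, "MONDO:0000300"))
  expect_identical(got$failure, c(FALSE, TRUE, FALSE))
})

test_that("terminal parentheticals are stripped, then retried verbatim", {
  g <- load_obograph(write_obograph_fixture(list(
    list(id = "MONDO:0000001", label = "Root"),
    list(id = "MONDO:0000002", label = "Alpha syndrome",
         parents = "MONDO:0000001"),
    list(id = "MONDO:0000003", label = "Xyzzy disease (atypical)",
         parents = "MONDO:0000001"))))
  idx <- build_grounding_index(g)
  expect_identical(ground_candidates("Alpha syndrome (FBN1)", idx)$grounded,
                   "MONDO:0000002")
  # stripping misses but the unstripped form matches a parenthetical label
  expect_identical(
    ground_candidates("Xyzzy disease (atypical)", idx)$grounded,
    "MONDO:0000003")
})

test_that("fuzzy fallback is off by default and conservative when on", {
  idx <- build_grounding_index(six_subtype_graph())
  # word-order scramble: exact match fails, token-set similarity is 1
  expect_true(ground_candidates("syndrome Alpha", idx)$failure)
  fz <- ground_candidates("syndrome Alpha", idx, fuzzy = TRUE)
  expect_identical(fz$grounded, "MONDO:0000100")
  # below threshold stays a failure
  expect_true(ground_candidates("Alpha", idx, fuzzy = TRUE)$failure)
  # exact matches are unaffected by the flag
  expect_identical(
    ground_candidates("Alpha syndrome type 3", idx, fuzzy = TRUE)$grounded,
    "MONDO:0000203")
})

test_that("refusal responses ground to empty differentials", {
  idx <- build_grounding_index(six_subtype_graph())
  resp <- list(case_id = "c1", language = "en",
               raw_text = "I am sorry, I cannot answer.", failed = FALSE)
  d <- ground_response(resp, idx)
  expect_true(d$refusal)
  expect_identical(nrow(d$candidates), 0L)
  failed <- list(case_id = "c2", language = "en",
                 raw_text = "ERROR: backend unreachable", failed = TRUE)
  expect_true(ground_response(failed, idx)$refusal)
})

test_that("every label and non-colliding synonym round-trips", {
  g <- tiny_world()$onts$disease
  idx <- build_grounding_index(g)
  colliding <- unique(idx$collisions$string)
  live <- Filter(function(t) !t$obsolete, g$terms)
  for (t in live) {
    if (!normalize_label(t$label) %in% colliding) {
      expect_identical(ground_candidates(t$label, idx)$grounded, t$id)
    }
    for (s in t$synonyms) {
      if (!normalize_label(s) %in% colliding) {
        expect_identical(ground_candidates(s, idx)$grounded, t$id)
      }
    }
  }
})
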