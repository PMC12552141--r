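# The mock backend and batch dispatcher.

mock_world <- function(n_cases = 12L) {
  w <- tiny_world()
  list(w = w,
       dx = corpus_diagnoses(w$cases)[seq_len(n_cases)],
       prompts = lapply(w$cases[seq_len(n_cases)], function(r)
         structure(list(case_id = r$id, language = "en",
                        text = paste("prompt for", r$id),
                        term_manifest = NULL), class = "prompt_text")))
}

test_that("run configurations validate their fields", {
  expect_error(run_config("m", temperature = -1), "temperature")
  expect_error(run_config("m", max_output_tokens = 0), "max_output_tokens")
  expect_identical(gpt_like_config()$temperature, 1)
  m <- meditron_like_config()
  expect_identical(m$seed, 1234L)
  expect_identical(m$max_output_tokens, 2048L)
})

test_that("accuracy profiles reject inconsistent probabilities", {
  expect_error(accuracy_profile(c(0.9, 0.2), refusal_probability = 0.2),
               "exceed 1")
  expect_error(accuracy_profile(c(0.5, -0.1)), "\\[0,1\\]")
  expect_error(accuracy_profile(rep(0.05, 12), n_candidates = 10),
               "n_candidates")
})

test_that("degenerate profiles behave as configured", {
  mw <- mock_world()
  w <- mw$w
  be1 <- mock_backend(accuracy_profile(c(1)), w$onts$disease, mw$dx, seed = 5)
  for (p in mw$prompts[1:5]) {
    reply <- be1(p, gpt_like_config())
    first <- strsplit(reply, "\n")[[1]][1]
    expect_identical(first,
                     paste0("1. ", term_label(w$onts$disease, mw$dx[[p$case_id]])))
  }
  be2 <- mock_backend(accuracy_profile(c(0), refusal_probability = 1),
                      w$onts$disease, mw$dx, seed = 5)
  for (p in mw$prompts[1:5]) {
    expect_identical(be2(p, gpt_like_config()), lingodx:::MOCK_REFUSAL_TEXT)
  }
})

test_that("the mock is a pure function of (profile, seed, case, language)", {
  mw <- mock_world()
  prof <- accuracy_profile(c(0.3, 0.1, 0.1), refusal_probability = 0.1)
  be_a <- mock_backend(prof, mw$w$onts$disease, mw$dx, seed = 9)
  be_b <- mock_backend(prof, mw$w$onts$disease, mw$dx, seed = 9)
  texts_a <- vapply(mw$prompts, be_a, character(1), config = gpt_like_config())
  # different instantiation, reversed dispatch order: byte-identical
  texts_b <- vapply(rev(mw$prompts), be_b, character(1),
                    config = gpt_like_config())
  expect_identical(texts_a, rev(texts_b))
  # a different seed changes the stream
  be_c <- mock_backend(prof, mw$w$onts$disease, mw$dx, seed = 10)
  texts_c <- vapply(mw$prompts, be_c, character(1), config = gpt_like_config())
  expect_false(all(texts_c == texts_a))
})

test_that("run_batch preserves order, count and hashes", {
  mw <- mock_world()
  prof <- accuracy_profile(c(0.5))
  be <- mock_backend(prof, mw$w$onts$disease, mw$dx, seed = 2)
  recs <- run_batch(mw$prompts, be, gpt_like_config())
  expect_length(recs, length(mw$prompts))
  expect_identical(vapply(recs, `[[`, character(1), "case_id"),
                   unname(vapply(mw$prompts, `[[`, character(1), "case_id")))
  for (i in seq_along(recs)) {
    expect_identical(recs[[i]]$prompt_sha256,
                     digest::digest(enc2utf8(mw$prompts[[i]]$text),
                                    algo = "sha256", serialize = FALSE))
  }
  dup <- c(mw$prompts, mw$prompts[1])
  expect_error(run_batch(dup, be, gpt_like_config()), "duplicate")
})

test_that("resume skips already-logged prompts", {
  mw <- mock_world(n_cases = 4L)
  prof <- accuracy_profile(c(0.5))
  be <- mock_backend(prof, mw$w$onts$disease, mw$dx, seed = 2)
  log1 <- tempfile(fileext = ".jsonl")
  run_batch(mw$prompts[1:2], be, gpt_like_config(), log_path = log1)

  calls <- new.env(); calls$ids <- character(0)
  counting_be <- function(p, config) {
    calls$ids <- c(calls$ids, p$case_id)
    be(p, config)
  }
  recs <- run_batch(mw$prompts, counting_be, gpt_like_config(),
                    log_path = log1)
  expect_length(recs, 4)
  # records 1-2 came from the log, 3-4 were dispatched
  expect_identical(calls$ids,
                   unname(vapply(mw$prompts[3:4], `[[`, character(1),
                                 "case_id")))
  expect_length(read_responses(log1), 4)
})

test_that("backend failures are recorded, never dropped", {
  mw <- mock_world(n_cases = 3L)
  flaky <- function(p, config) {
    if (p$case_id == mw$prompts[[2]]$case_id) stop("backend unreachable")
    "1. Beta disorder"
  }
  recs <- run_batch(mw$prompts, flaky, gpt_like_config(), retries = 2L)
  expect_length(recs, 3)
  expect_false(recs[[1]]$failed)
  expect_true(recs[[2]]$failed)
  expect_match(recs[[2]]$raw_text, "^ERROR: ")
  expect_false(recs[[3]]$failed)
})

test_that("ignore-English mode emits the prompt-language label", {
  w <- tiny_world()
  dx <- corpus_diagnoses(w$cases)[1]
  prompt <- structure(list(case_id = names(dx), language = "ja", text = "x"),
                      class = "prompt_text")
  be <- mock_backend(accuracy_profile(c(1), ignore_english_probability = 1),
                     w$onts$disease, dx, seed = 3,
                     translations = w$onts$translations)
  reply <- be(prompt, gpt_like_config())
  ja_label <- translate_term(w$onts$translations, dx, "ja", w$onts$disease)
  expect_identical(strsplit(reply, "\n")[[1]][1], paste0("1. ", ja_label))
})
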