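# Equivalence rollup and Top-N aggregation.

test_that("a disease without subtypes under a non-grouping parent is a singleton", {
  g <- six_subtype_graph()
  eq <- build_equivalence(g, "MONDO:0000300")  # "Beta disorder" under "disease"
  expect_identical(eq$members, "MONDO:0000300")
  expect_true(is.na(eq$grouping_anchor))
  expect_error(build_equivalence(g, "MONDO:9999999"), "unknown term")
})

test_that("a subtype rolls up to the grouping and all six siblings", {
  g <- six_subtype_graph()
  eq <- build_equivalence(g, "MONDO:0000201")  # subtype 1, via prefix rule
  expect_setequal(eq$members,
                  c("MONDO:0000100", sprintf("MONDO:00002%02d", 1:6)))
  expect_identical(eq$grouping_anchor, "MONDO:0000100")
  # explicit grouping list works with the prefix rule disabled
  eq2 <- build_equivalence(g, "MONDO:0000201",
                           grouping_terms = "MONDO:0000100",
                           prefix_rule = FALSE)
  expect_setequal(eq2$members, eq$members)
  # without either route, ancestors earn no credit
  eq3 <- build_equivalence(g, "MONDO:0000201", prefix_rule = FALSE)
  expect_identical(eq3$members, "MONDO:0000201")
})

# independent oracle: recursive DFS descendant closure + the stated rule
oracle_equivalence <- function(graph, dx, grouping_terms) {
  desc <- function(id) {
    out <- character(0)
    for (ch in graph$children[[id]]) out <- c(out, ch, desc(ch))
    out
  }
  members <- c(dx, desc(dx))
  for (p in graph$terms[[dx]]$parents) {
    if (p %in% grouping_terms ||
        startsWith(graph$terms[[dx]]$label, graph$terms[[p]]$label)) {
      members <- c(members, p, desc(p))
    }
  }
  sort(unique(members))
}

test_that("equivalence members equal the brute-force closure on a random world", {
  w <- tiny_world()
  g <- w$onts$disease
  for (dx in c(w$onts$subtypes, w$onts$distractors)) {
    eq <- build_equivalence(g, dx, grouping_terms = w$onts$grouping_terms)
    expect_identical(eq$members,
                     oracle_equivalence(g, dx, w$onts$grouping_terms),
                     info = dx)
  }
})

test_that("score_case takes the minimum credited rank", {
  g <- six_subtype_graph()
  eq <- build_equivalence(g, "MONDO:0000201")
  d1 <- make_diff("c1", "en", c("MONDO:0000201", "MONDO:0000300"))
  expect_identical(score_case(d1, eq)$correct_rank, 1L)
  # the grouping term at rank 2 is credited for a subtype diagnosis
  d2 <- make_diff("c2", "en", c("MONDO:0000300", "MONDO:0000100"))
  expect_identical(score_case(d2, eq)$correct_rank, 2L)
  # duplicate correct answers at ranks 4 and 9: min wins
  d3 <- make_diff("c3", "en",
                  c("MONDO:0000300", NA, NA, "MONDO:0000201",
                    NA, NA, NA, NA, "MONDO:0000201", NA))
  s3 <- score_case(d3, eq)
  expect_identical(s3$correct_rank, 4L)
  expect_identical(s3$n_grounding_failures, 7L)
  # refusal propagates
  d4 <- make_diff("c4", "en", character(0), refusal = TRUE)
  s4 <- score_case(d4, eq)
  expect_true(s4$refusal)
  expect_true(is.na(s4$correct_rank))
  expect_identical(s4$n_candidates, 0L)
})

test_that("equivalence symmetry: any member is as correct as any other", {
  g <- six_subtype_graph()
  eq <- build_equivalence(g, "MONDO:0000201")
  base <- make_diff("c", "en", c("MONDO:0000300", "MONDO:0000201"))
  for (m in eq$members) {
    alt <- make_diff("c", "en", c("MONDO:0000300", m))
    expect_identical(score_case(alt, eq)$correct_rank,
                     score_case(base, eq)$correct_rank, info = m)
  }
})

test_that("aggregation matches the hand-counted definitions", {
  scores <- data.frame(
    case_id = paste0("c", 1:5), language = "en",
    correct_rank = c(1L, 2L, 11L, NA, NA),
    refusal = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    n_candidates = c(10L, 10L, 12L, 10L, 0L),
    n_grounding_failures = 0L, stringsAsFactors = FALSE)
  s <- aggregate_language(scores)
  expect_identical(s$top1, 1L)
  expect_identical(s$top3, 2L)
  expect_identical(s$top10, 2L)
  expect_identical(s$beyond10, 1L)
  expect_identical(s$not_ranked, 1L)
  expect_identical(s$no_diagnosis, 1L)
  expect_identical(s$n_total, 5L)

  refusals <- data.frame(case_id = paste0("c", 1:4), language = "de",
                         correct_rank = NA_integer_, refusal = TRUE,
                         n_candidates = 0L, n_grounding_failures = 0L)
  s2 <- aggregate_language(refusals)
  expect_identical(s2$no_diagnosis, 4L)
  expect_identical(s2$top10 + s2$beyond10 + s2$not_ranked, 0L)

  expect_error(aggregate_language(rbind(scores, refusals)), "mix")
})

test_that("conservation and monotonicity hold across random aggregations", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    rk <- sample(c(1:12, NA), n, replace = TRUE)
    refusal <- is.na(rk) & runif(n) < 0.5
    scores <- data.frame(case_id = paste0("c", 1:n), language = "fr",
                         correct_rank = ifelse(refusal, NA, rk),
                         refusal = refusal,
                         n_candidates = ifelse(refusal, 0L, 10L),
                         n_grounding_failures = 0L)
    s <- aggregate_language(scores)
    expect_true(s$top1 <= s$top3 && s$top3 <= s$top10)
    expect_identical(s$top10 + s$beyond10 + s$not_ranked + s$no_diagnosis,
                     s$n_total)
    expect_identical(s$n_total, n)
  }
})

test_that("topn_frequency follows both denominator conventions", {
  s <- language_summary("en", top1 = 978, top3 = 1328, top10 = 1532,
                        not_ranked = 3384, no_diagnosis = 1)
  expect_identical(s$n_total, 4917L)
  expect_identical(topn_frequency(s, 1), 19.9)
  expect_identical(topn_frequency(s, 3), 27.0)
  expect_identical(topn_frequency(s, 10), 31.2)
  expect_identical(topn_frequency(s, 1, "all"), 19.9)

  m <- language_summary("nl", top1 = 782, top3 = 1118, top10 = 1379,
                        not_ranked = 3538)
  expect_identical(topn_frequency(m, 10), 28.0)

  zero <- language_summary("en", 0, 0, 0, not_ranked = 5)
  expect_identical(topn_frequency(zero, 10), 0)
  only_refusals <- language_summary("en", 0, 0, 0, not_ranked = 0,
                                    no_diagnosis = 3)
  expect_error(topn_frequency(only_refusals, 1), "zero denominator")
  expect_error(topn_frequency(s, 5), "must be 1, 3 or 10")
})

test_that("grounding failures aggregate as a per-candidate rate", {
  scores <- data.frame(case_id = paste0("c", 1:4),
                       language = c("en", "en", "de", "de"),
                       correct_rank = NA_integer_, refusal = FALSE,
                       n_candidates = c(10L, 10L, 10L, 6L),
                       n_grounding_failures = c(1L, 2L, 0L, 3L))
  r <- grounding_failure_rates(scores)
  expect_identical(r$failure_pct[r$language == "en"], 15.0)
  expect_identical(r$failure_pct[r$language == "de"],
                   round(100 * 3 / 16, 1))
})
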