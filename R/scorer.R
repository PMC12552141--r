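# Scorer: ontology-aware correctness with subtype-equivalence rollup, and
# per-language Top-N aggregation in the layout of the benchmark's count
# tables.

#' Build the equivalence class of a diagnosis
#'
#' The set of disease ids counted as "correct" for one diagnosis:
#' the diagnosis itself, all of its descendants (a more specific correct
#' answer is correct), and — for each parent satisfying the grouping
#' predicate — that parent and all of the parent's descendants. A parent
#' qualifies as a clinical grouping term when it is explicitly listed in
#' `grouping_terms`, or (with `prefix_rule = TRUE`) when its label is a
#' prefix of the diagnosis label, which captures subtype naming of the form
#' "X syndrome type 1" under "X syndrome". Ancestors never enter the class
#' through any other route, so vague superclasses earn no credit.
#'
#' @param graph disease `ontology_graph`.
#' @param diagnosis disease CURIE present in the graph.
#' @param grouping_terms character vector of CURIEs designated as clinical
#'   grouping terms.
#' @param prefix_rule also accept parents whose label prefixes the
#'   diagnosis label?
#' @return object of class `equivalence_class`: list with `diagnosis`,
#'   `members` (sorted character vector) and `grouping_anchor` (CURIE or
#'   `NA`).
#' @export
build_equivalence <- function(graph, diagnosis, grouping_terms = character(0),
                              prefix_rule = TRUE) {
  assert_in_graph(graph, diagnosis)
  members <- c(diagnosis, ontology_descendants(graph, diagnosis))
  anchor <- NA_character_
  dx_label <- term_label(graph, diagnosis)
  for (p in graph$terms[[diagnosis]]$parents) {
    qualifies <- p %in% grouping_terms ||
      (prefix_rule && startsWith(dx_label, term_label(graph, p)))
    if (qualifies) {
      members <- c(members, p, ontology_descendants(graph, p))
      if (is.na(anchor)) anchor <- p
    }
  }
  structure(list(diagnosis = diagnosis, members = sort(unique(members)),
                 grouping_anchor = anchor),
            class = "equivalence_class")
}

#' Score one grounded differential against an equivalence class
#'
#' `correct_rank` is the minimum rank whose grounded id belongs to the
#' equivalence class, `NA` when absent. Refusals propagate with zero
#' candidates. Grounding failures are counted per candidate.
#'
#' @param diff a `differential_result`.
#' @param eq an `equivalence_class`.
#' @return one-row data.frame: `case_id`, `language`, `correct_rank`,
#'   `refusal`, `n_candidates`, `n_grounding_failures`.
#' @export
score_case <- function(diff, eq) {
  hits <- which(!diff$candidates$failure &
                  diff$candidates$grounded %in% eq$members)
  correct_rank <- if (length(hits) == 0) NA_integer_
                  else min(diff$candidates$rank[hits])
  data.frame(case_id = diff$case_id, language = diff$language,
             correct_rank = correct_rank, refusal = diff$refusal,
             n_candidates = nrow(diff$candidates),
             n_grounding_failures = sum(diff$candidates$failure),
             stringsAsFactors = FALSE)
}

#' Score a batch of differentials
#'
#' @param diffs list of `differential_result`.
#' @param diagnoses named character vector: case_id -> diagnosis CURIE.
#' @param graph disease `ontology_graph`.
#' @inheritParams build_equivalence
#' @return data.frame with one row per differential (columns as in
#'   [score_case()]). Equivalence classes are built once per distinct
#'   diagnosis.
#' @export
score_differentials <- function(diffs, diagnoses, graph,
                                grouping_terms = character(0),
                                prefix_rule = TRUE) {
  eqs <- new.env(parent = emptyenv())
  rows <- lapply(diffs, function(d) {
    dx <- diagnoses[[d$case_id]]
    if (is.null(dx)) stop(sprintf("no diagnosis for case %s", d$case_id),
                          call. = FALSE)
    if (!exists(dx, envir = eqs, inherits = FALSE)) {
      assign(dx, build_equivalence(graph, dx, grouping_terms, prefix_rule),
             envir = eqs)
    }
    score_case(d, get(dx, envir = eqs))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Construct a per-language summary of counts
#'
#' @param language language code.
#' @param top1,top3,top10 cumulative counts of cases with the correct
#'   diagnosis at rank 1, within 3, within 10.
#' @param not_ranked cases whose reply contained no correct diagnosis
#'   (grounding failures included), excluding refusals.
#' @param no_diagnosis refusal count.
#' @param beyond10 cases correct only beyond rank 10 (kept separate
#'   internally; folded into "not ranked" when emitting paper-style tables).
#' @return object of class `language_summary` (a one-row data.frame).
#' @export
language_summary <- function(language, top1, top3, top10, not_ranked,
                             no_diagnosis = 0L, beyond10 = 0L) {
  if (!(top1 <= top3 && top3 <= top10)) {
    stop("cumulative counts must satisfy top1 <= top3 <= top10",
         call. = FALSE)
  }
  df <- data.frame(language = language, top1 = as.integer(top1),
                   top3 = as.integer(top3), top10 = as.integer(top10),
                   beyond10 = as.integer(beyond10),
                   not_ranked = as.integer(not_ranked),
                   no_diagnosis = as.integer(no_diagnosis),
                   n_total = as.integer(top10 + beyond10 + not_ranked +
                                          no_diagnosis),
                   stringsAsFactors = FALSE)
  class(df) <- c("language_summary", class(df))
  df
}

#' Aggregate case scores of one language
#'
#' @param scores data.frame of case scores sharing one language (from
#'   [score_differentials()]).
#' @return a `language_summary`. Conservation holds by construction:
#'   `top10 + beyond10 + not_ranked + no_diagnosis = n_total`.
#' @export
aggregate_language <- function(scores) {
  langs <- unique(scores$language)
  if (length(langs) != 1L) {
    stop(sprintf("scores mix languages: %s", paste(langs, collapse = ", ")),
         call. = FALSE)
  }
  r <- scores$correct_rank
  ranked <- !is.na(r)
  language_summary(
    language = langs,
    top1 = sum(ranked & r == 1L),
    top3 = sum(ranked & r <= 3L),
    top10 = sum(ranked & r <= 10L),
    beyond10 = sum(ranked & r > 10L),
    not_ranked = sum(!ranked & !scores$refusal),
    no_diagnosis = sum(scores$refusal))
}

#' Aggregate case scores of all languages
#' @param scores data.frame of case scores (any mix of languages).
#' @return data.frame of stacked `language_summary` rows, one per language,
#'   sorted by language code.
#' @export
summarize_languages <- function(scores) {
  parts <- lapply(split(scores, scores$language), aggregate_language)
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  out[order(out$language), , drop = FALSE]
}

#' Top-N frequency of a language summary
#'
#' The benchmark's headline percentages: `100 * topN / (n_total -
#' no_diagnosis)` with the default `exclude_refusals` denominator, or
#' `100 * topN / n_total` with `all`. Values are rounded half-up to one
#' decimal, the reporting precision.
#'
#' @param summary a `language_summary` (one row).
#' @param n 1, 3 or 10.
#' @param denominator `"exclude_refusals"` (default) or `"all"`.
#' @return a number (percentage, one decimal).
#' @export
topn_frequency <- function(summary, n,
                           denominator = c("exclude_refusals", "all")) {
  denominator <- match.arg(denominator)
  if (!n %in% c(1, 3, 10)) stop("n must be 1, 3 or 10", call. = FALSE)
  top <- summary[[paste0("top", n)]]
  den <- if (denominator == "exclude_refusals")
    summary$n_total - summary$no_diagnosis else summary$n_total
  if (den == 0) stop("zero denominator: no scoreable cases", call. = FALSE)
  round_half_up(100 * top / den, 1)
}

#' Per-language grounding-failure rate
#'
#' Failures are counted per candidate over all candidates of a language,
#' echoing the benchmark's reporting of grounding failures as a rate, not a
#' per-case category.
#'
#' @param scores data.frame of case scores.
#' @return data.frame with `language`, `n_candidates`, `n_failures`,
#'   `failure_pct` (half-up, one decimal).
#' @export
grounding_failure_rates <- function(scores) {
  parts <- lapply(split(scores, scores$language), function(s) {
    nc <- sum(s$n_candidates)
    nf <- sum(s$n_grounding_failures)
    data.frame(language = s$language[1], n_candidates = nc, n_failures = nf,
               failure_pct = if (nc > 0) round_half_up(100 * nf / nc, 1)
                             else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  out[order(out$language), , drop = FALSE]
}
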