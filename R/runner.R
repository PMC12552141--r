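# LLM runner: dispatches prompts to a pluggable backend, persists raw
# responses as JSONL with full run metadata, and supports crash-safe resume.
# The deterministic mock backend stands in for live models in every test.

#' Construct a run configuration
#'
#' @param model_name backend model identifier.
#' @param temperature sampling temperature, >= 0.
#' @param seed integer seed or `NA` (no fixed seed).
#' @param max_output_tokens positive integer cap or `NA` (no limit).
#' @param extra_params named character vector of backend-specific settings.
#' @return object of class `run_config`.
#' @export
run_config <- function(model_name, temperature = 1, seed = NA_integer_,
                       max_output_tokens = NA_integer_,
                       extra_params = character(0)) {
  if (temperature < 0) stop("temperature must be >= 0", call. = FALSE)
  if (!is.na(max_output_tokens) && max_output_tokens <= 0) {
    stop("max_output_tokens must be positive", call. = FALSE)
  }
  structure(list(model_name = model_name, temperature = temperature,
                 seed = seed, max_output_tokens = max_output_tokens,
                 extra_params = extra_params),
            class = "run_config")
}

#' Reproduction-style run configurations
#'
#' `gpt_like_config()` mirrors a default-parameter API run (temperature 1,
#' no token cap); `meditron_like_config()` mirrors a locally hosted
#' deterministic run (temperature 0, seed 1234, 2048-token cap).
#'
#' @return a `run_config`.
#' @export
gpt_like_config <- function() {
  run_config("gpt-like", temperature = 1)
}

#' @rdname gpt_like_config
#' @export
meditron_like_config <- function() {
  run_config("meditron-like", temperature = 0, seed = 1234L,
             max_output_tokens = 2048L,
             extra_params = c(task_type = "mcq"))
}

#' Construct an accuracy profile for the mock backend
#'
#' `rank_probabilities[r]` is the probability that the correct diagnosis is
#' emitted at rank r. With probability `refusal_probability` the reply is a
#' refusal sentence; with the residual mass the correct diagnosis is absent
#' from the list entirely. `garble_probability` independently replaces any
#' candidate line with an ungroundable nonsense string;
#' `subtype_swap_probability` replaces the correct diagnosis label with a
#' sibling subtype's label (exercising the scorer's equivalence rollup);
#' `ignore_english_probability` emits the correct label in the prompt
#' language instead of English (exercising grounding-failure accounting).
#'
#' @param rank_probabilities numeric vector p_1..p_R, each in `[0,1]`.
#' @param refusal_probability probability of a refusal reply.
#' @param garble_probability per-candidate nonsense substitution rate.
#' @param subtype_swap_probability sibling-label substitution rate.
#' @param ignore_english_probability prompt-language reply rate.
#' @param n_candidates number of lines in a non-refusal reply.
#' @return object of class `accuracy_profile`.
#' @export
accuracy_profile <- function(rank_probabilities,
                             refusal_probability = 0,
                             garble_probability = 0,
                             subtype_swap_probability = 0,
                             ignore_english_probability = 0,
                             n_candidates = 10L) {
  p <- c(rank_probabilities, refusal_probability, garble_probability,
         subtype_swap_probability, ignore_english_probability)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0,1]", call. = FALSE)
  if (sum(rank_probabilities) + refusal_probability > 1 + 1e-12) {
    stop("rank probabilities plus refusal probability exceed 1", call. = FALSE)
  }
  if (n_candidates < length(rank_probabilities)) {
    stop("n_candidates smaller than the rank probability vector", call. = FALSE)
  }
  structure(list(rank_probabilities = rank_probabilities,
                 refusal_probability = refusal_probability,
                 garble_probability = garble_probability,
                 subtype_swap_probability = subtype_swap_probability,
                 ignore_english_probability = ignore_english_probability,
                 n_candidates = as.integer(n_candidates)),
            class = "accuracy_profile")
}

MOCK_REFUSAL_TEXT <- paste(
  "I am sorry, but I cannot provide a confident differential diagnosis",
  "based on the information supplied.")

# Disease labels usable as distractors: non-obsolete disease terms outside
# the excluded set.
distractor_pool <- function(graph, exclude = character(0)) {
  ids <- names(graph$terms)
  keep <- vapply(graph$terms, function(t) !t$obsolete, logical(1))
  sort(setdiff(ids[keep], exclude))
}

#' Deterministic mock model backend
#'
#' Returns a backend function `(prompt, config) -> reply text` that samples
#' a numbered English differential list (or a refusal sentence) per the
#' accuracy profile. Each reply is a pure function of
#' `(profile, seed, case_id, language)`: the RNG stream is re-seeded per
#' prompt from a stable hash, so language subsets rerun identically and in
#' any order. The backend needs the case diagnoses (which never appear in
#' the prompt text) to be able to emit the correct label.
#'
#' @param profile an `accuracy_profile`.
#' @param graph disease `ontology_graph` (labels, siblings, distractors).
#' @param diagnoses named character vector: case_id -> diagnosis CURIE.
#' @param seed integer global seed for the run.
#' @param translations optional `translation_table` used by the
#'   ignore-English mode to emit the diagnosis in the prompt language.
#' @return a function with signature `(prompt, config)` returning a string.
#' @export
mock_backend <- function(profile, graph, diagnoses, seed,
                         translations = NULL) {
  stopifnot(inherits(profile, "accuracy_profile"))
  pool <- distractor_pool(graph)
  cum_refusal <- profile$refusal_probability
  p_rank <- profile$rank_probabilities

  function(prompt, config) {
    dx <- diagnoses[[prompt$case_id]]
    if (is.null(dx) || is.na(dx)) {
      stop(sprintf("mock backend: unknown case id '%s'", prompt$case_id),
           call. = FALSE)
    }
    stream <- stable_hash(seed, prompt$case_id, prompt$language)
    with_rng_stream(stream, {
      u <- stats::runif(1)
      if (u < cum_refusal) return(MOCK_REFUSAL_TEXT)
      # sample the rank of the correct diagnosis; residual mass = absent
      v <- stats::runif(1)
      rank <- match(TRUE, v < cumsum(p_rank))  # NA => absent
      # exclude everything the equivalence rollup could credit: the
      # diagnosis, its ancestors, its descendants, and all descendants of
      # its parents (sibling subtypes)
      exclude <- c(dx, ontology_ancestors(graph, dx),
                   ontology_descendants(graph, dx),
                   unlist(lapply(graph$terms[[dx]]$parents,
                                 function(p) ontology_descendants(graph, p))))
      distractors <- sample(setdiff(pool, exclude),
                            size = profile$n_candidates, replace = FALSE)
      lines <- vapply(distractors, function(id) term_label(graph, id),
                      character(1), USE.NAMES = FALSE)
      if (!is.na(rank)) {
        label <- term_label(graph, dx)
        if (profile$subtype_swap_probability > 0 &&
            stats::runif(1) < profile$subtype_swap_probability) {
          sib <- mock_sibling_subtype(graph, dx)
          if (!is.na(sib)) label <- term_label(graph, sib)
        }
        if (profile$ignore_english_probability > 0 &&
            !is.null(translations) && prompt$language != "en" &&
            stats::runif(1) < profile$ignore_english_probability) {
          label <- translate_term(translations, dx, prompt$language, graph,
                                  fallback = TRUE)
        }
        lines[rank] <- label
      }
      garbled <- stats::runif(length(lines)) < profile$garble_probability
      lines[garbled] <- sprintf("zxq-%08x syndrome",
                                floor(stats::runif(sum(garbled)) * 2^31))
      paste(sprintf("%d. %s", seq_along(lines), lines), collapse = "\n")
    })
  }
}

# A sibling genetic subtype: another child of the diagnosis's parent(s).
# NA when the diagnosis has no sibling.
mock_sibling_subtype <- function(graph, dx) {
  parents <- graph$terms[[dx]]$parents
  sibs <- setdiff(sort(unique(unlist(graph$children[parents]))), dx)
  if (length(sibs) == 0) return(NA_character_)
  sibs[sample.int(length(sibs), 1)]
}

#' Dispatch a batch of prompts to a backend
#'
#' One response record is produced per prompt, order preserved. Responses
#' are appended to a JSONL log as they arrive; if `log_path` already holds
#' records, prompts whose sha256 already appears are not re-dispatched
#' (crash-safe resume). Backend errors after `retries` attempts are
#' recorded with `failed = TRUE` and an error marker in `raw_text`, never
#' silently skipped.
#'
#' @param prompts list of `prompt_text` objects; (case_id, language) pairs
#'   must be unique.
#' @param backend function `(prompt, config) -> text`.
#' @param config a `run_config`.
#' @param log_path optional JSONL log for persistence and resume.
#' @param retries attempts per prompt before marking failure.
#' @return list of response records (named lists with case_id, language,
#'   prompt_sha256, raw_text, model_name, timestamp, failed, config).
#' @export
run_batch <- function(prompts, backend, config, log_path = NULL,
                      retries = 3L) {
  keys <- vapply(prompts, function(p) paste(p$case_id, p$language),
                 character(1))
  if (anyDuplicated(keys)) {
    stop(sprintf("duplicate case_id+language in batch: %s",
                 keys[duplicated(keys)][1]), call. = FALSE)
  }
  done <- character(0)
  existing <- list()
  if (!is.null(log_path) && file.exists(log_path)) {
    existing <- read_jsonl(log_path)
    done <- vapply(existing, `[[`, character(1), "prompt_sha256")
  }
  existing_by_sha <- stats::setNames(existing, done)

  out <- vector("list", length(prompts))
  for (i in seq_along(prompts)) {
    p <- prompts[[i]]
    sha <- sha256_hex(p$text)
    if (sha %in% done) {
      out[[i]] <- existing_by_sha[[sha]]
      next
    }
    raw <- NULL
    failed <- TRUE
    for (attempt in seq_len(retries)) {
      raw <- tryCatch(backend(p, config), error = function(e) e)
      if (!inherits(raw, "error")) { failed <- FALSE; break }
    }
    rec <- list(case_id = p$case_id, language = p$language,
                prompt_sha256 = sha,
                raw_text = if (failed)
                  paste0("ERROR: ", conditionMessage(raw)) else raw,
                model_name = config$model_name,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                   tz = "UTC"),
                failed = failed,
                config = unclass(config)[c("model_name", "temperature",
                                           "seed", "max_output_tokens")])
    if (!is.null(log_path)) append_jsonl(list(rec), log_path)
    out[[i]] <- rec
  }
  out
}

#' Read a responses JSONL log
#' @param path JSONL file written by [run_batch()].
#' @return list of response records.
#' @export
read_responses <- function(path) read_jsonl(path)
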