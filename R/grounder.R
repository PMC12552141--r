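# Grounder: parses raw LLM replies into ordered candidate lists and maps
# each free-text candidate to a disease-ontology identifier by
# exact-normalized label/synonym lookup. Grounding failures are first-class
# outcomes, not errors: the benchmark reports their rate.

#' Normalize a disease-name string for index lookup
#'
#' Pipeline: Unicode NFKC -> case fold -> map typographic dashes and
#' apostrophes to ASCII -> trim -> collapse internal whitespace -> strip
#' surrounding punctuation and trailing periods. Idempotent.
#'
#' @param s character vector.
#' @return character vector of normalized strings.
#' @export
normalize_label <- function(s) {
  out <- stringi::stri_trans_nfkc(s)
  out <- stringi::stri_trans_tolower(out)
  out <- gsub("[‒–—―−]", "-", out)
  out <- gsub("[‘’ʼ`´]", "'", out)
  out <- gsub("[“”„]", "\"", out)
  out <- gsub("\\s+", " ", out)
  out <- trimws(out)
  # strip surrounding punctuation (quotes, brackets, stray list markers) and
  # any trailing sentence periods
  out <- gsub("^[\"'()\\[\\]{}.,;:!?*\\s-]+|[\"'()\\[\\]{}.,;:!?*\\s]+$", "",
              out, perl = TRUE)
  trimws(out)
}

#' Build a grounding index from a disease ontology
#'
#' Inserts the normalized primary label and normalized synonyms of every
#' non-obsolete term. Collisions (one normalized string claimed by several
#' terms) are resolved deterministically: a primary label beats a synonym;
#' among equal kinds the lexicographically smallest term id wins. All
#' collisions are retained in a log.
#'
#' @param graph disease `ontology_graph`.
#' @return object of class `grounding_index` with `map` (environment:
#'   normalized string -> CURIE), `entries` (data.frame string / id / kind)
#'   and `collisions` (data.frame of every contested string).
#' @export
build_grounding_index <- function(graph) {
  terms <- Filter(function(t) !t$obsolete, graph$terms)
  rows <- lapply(terms, function(t) {
    strs <- c(t$label, t$synonyms)
    kinds <- c("label", rep("synonym", length(t$synonyms)))
    data.frame(string = normalize_label(strs), id = t$id, kind = kinds,
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  entries <- entries[nzchar(entries$string), , drop = FALSE]

  # resolution order: labels first, then synonyms; within a kind smallest id
  entries <- entries[order(entries$string,
                           match(entries$kind, c("label", "synonym")),
                           entries$id), , drop = FALSE]
  contested <- entries$string[duplicated(entries$string) |
                                duplicated(entries$string, fromLast = TRUE)]
  collisions <- entries[entries$string %in% contested &
                          vapply(split(entries$id, entries$string)[entries$string],
                                 function(x) length(unique(x)) > 1,
                                 logical(1)), , drop = FALSE]
  winners <- entries[!duplicated(entries$string), , drop = FALSE]

  map <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(winners))) {
    assign(winners$string[i], winners$id[i], envir = map)
  }
  structure(list(map = map, entries = winners, all_entries = entries,
                 collisions = collisions),
            class = "grounding_index")
}

#' @export
print.grounding_index <- function(x, ...) {
  cat(sprintf("<grounding_index> %d strings (%d collisions logged)\n",
              nrow(x$entries), length(unique(x$collisions$string))))
  invisible(x)
}

# Strip a single terminal parenthetical annotation: "Marfan syndrome (FBN1)"
# -> "Marfan syndrome". Returns the input unchanged when no terminal
# parenthetical exists.
strip_terminal_parenthetical <- function(s) {
  sub("\\s*\\([^()]*\\)\\s*$", "", s)
}

#' Parse a raw LLM reply into ordered candidate strings
#'
#' Recognizes numbered lists (`1.`, `1)`, `1 -`), bulleted lists (`-`, `*`,
#' `•`) and bare one-candidate-per-line blocks. Lines that carry no
#' list marker in a reply that does have markers are treated as surrounding
#' prose and dropped. An empty extraction is a refusal (a value, not an
#' error).
#'
#' @param raw reply text.
#' @return list with `candidates` (character vector, possibly empty) and
#'   `refusal` (logical).
#' @export
parse_differential <- function(raw) {
  if (is.null(raw) || is.na(raw) || !nzchar(trimws(raw))) {
    return(list(candidates = character(0), refusal = TRUE))
  }
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  num_re <- "^[0-9]+[.):]\\s+|^[0-9]+\\s+-\\s+"
  bullet_re <- "^[-*•]\\s+"
  numbered <- grepl(num_re, lines)
  bulleted <- grepl(bullet_re, lines)

  if (any(numbered)) {
    items <- sub(num_re, "", lines[numbered])
  } else if (any(bulleted)) {
    items <- sub(bullet_re, "", lines[bulleted])
  } else if (length(lines) > 1L ||
             (length(lines) == 1L && looks_like_name(lines))) {
    # bare block: every line is one candidate, unless it reads as prose
    items <- lines[vapply(lines, looks_like_name, logical(1))]
  } else {
    items <- character(0)
  }
  items <- trimws(items)
  items <- items[nzchar(items)]
  list(candidates = items, refusal = length(items) == 0L)
}

# Heuristic for bare-line replies: a candidate disease name is short and is
# not a full sentence (no sentence-final period followed by more prose, not
# starting with a refusal-style clause).
looks_like_name <- function(line) {
  words <- length(strsplit(trimws(line), "\\s+")[[1]])
  words >= 1 && words <= 12 && !grepl("^(i |i'|sorry|unfortunately|as an)",
                                      tolower(line))
}

#' Ground candidate strings against an index
#'
#' Each candidate is normalized and looked up by exact match. A single
#' terminal parenthetical (gene / OMIM annotation) is stripped first; if the
#' stripped form misses, the unstripped form is tried. Misses yield
#' `failure = TRUE` but keep their rank: failures still occupy positions in
#' the differential.
#'
#' Optional fuzzy matching (off by default) falls back to the index entry
#' with the highest token-set Jaccard similarity at or above
#' `fuzzy_threshold`; ties break to the entry kind (label first) and then
#' the smallest term id. The default pipeline stays exact-match only:
#' tolerating grounding failures is preferred over risking false grounding.
#'
#' @param raw_candidates character vector, in rank order.
#' @param index a `grounding_index`.
#' @param fuzzy enable the token-set similarity fallback?
#' @param fuzzy_threshold minimum Jaccard similarity in `(0, 1]`.
#' @return data.frame with columns `rank`, `raw_text`, `grounded`
#'   (CURIE or `NA`), `failure` (logical).
#' @export
ground_candidates <- function(raw_candidates, index, fuzzy = FALSE,
                              fuzzy_threshold = 0.85) {
  n <- length(raw_candidates)
  grounded <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    stripped <- normalize_label(strip_terminal_parenthetical(raw_candidates[i]))
    hit <- lookup_index(index, stripped)
    if (is.na(hit)) {
      hit <- lookup_index(index, normalize_label(raw_candidates[i]))
    }
    if (is.na(hit) && fuzzy) {
      hit <- lookup_fuzzy(index, stripped, fuzzy_threshold)
    }
    grounded[i] <- hit
  }
  data.frame(rank = seq_len(n), raw_text = raw_candidates,
             grounded = grounded, failure = is.na(grounded),
             stringsAsFactors = FALSE)
}

lookup_index <- function(index, key) {
  if (nzchar(key) && exists(key, envir = index$map, inherits = FALSE)) {
    get(key, envir = index$map)
  } else {
    NA_character_
  }
}

# Token-set Jaccard fallback over the resolved index entries. Entries are
# already sorted by (string, kind, id), so which.max on the similarity
# vector is a deterministic tie-break: label before synonym, then the
# smallest id.
lookup_fuzzy <- function(index, key, threshold) {
  if (!nzchar(key)) return(NA_character_)
  qt <- unique(strsplit(key, " ", fixed = TRUE)[[1]])
  sims <- vapply(index$entries$string, function(s) {
    st <- unique(strsplit(s, " ", fixed = TRUE)[[1]])
    length(intersect(qt, st)) / length(union(qt, st))
  }, numeric(1), USE.NAMES = FALSE)
  ord <- order(-sims,
               match(index$entries$kind, c("label", "synonym")),
               index$entries$id)
  best <- ord[1]
  if (sims[best] >= threshold) index$entries$id[best] else NA_character_
}

#' Parse and ground one response record
#'
#' @param response a response record from [run_batch()] /
#'   [read_responses()].
#' @param index a `grounding_index`.
#' @return object of class `differential_result`: list with `case_id`,
#'   `language`, `candidates` (data.frame as in [ground_candidates()]) and
#'   `refusal`. A failed dispatch is treated as a refusal.
#' @export
ground_response <- function(response, index) {
  parsed <- if (isTRUE(response$failed)) {
    list(candidates = character(0), refusal = TRUE)
  } else {
    parse_differential(response$raw_text)
  }
  candidates <- ground_candidates(parsed$candidates, index)
  structure(list(case_id = response$case_id, language = response$language,
                 candidates = candidates, refusal = parsed$refusal),
            class = "differential_result")
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf("<differential_result> case %s [%s]: %d candidates%s\n",
              x$case_id, x$language, nrow(x$candidates),
              if (x$refusal) " (refusal)" else ""))
  invisible(x)
}

#' Ground a full batch of responses
#' @param responses list of response records.
#' @param index a `grounding_index`.
#' @return list of `differential_result` objects.
#' @export
ground_responses <- function(responses, index) {
  lapply(responses, ground_response, index = index)
}

#' Write grounded differentials as JSONL
#'
#' One line per candidate (`case_id`, `language`, `rank`, `raw_text`,
#' `grounded` or `"FAIL"`, `refusal`); refusals emit a single line with
#' rank 0.
#'
#' @param diffs list of `differential_result`.
#' @param path output JSONL file.
#' @return `path`, invisibly.
#' @export
write_differentials <- function(diffs, path) {
  if (file.exists(path)) file.remove(path)
  for (d in diffs) {
    if (d$refusal) {
      append_jsonl(list(list(case_id = d$case_id, language = d$language,
                             rank = 0L, raw_text = "", grounded = "FAIL",
                             refusal = TRUE)), path)
    } else {
      recs <- lapply(seq_len(nrow(d$candidates)), function(i) {
        list(case_id = d$case_id, language = d$language,
             rank = d$candidates$rank[i],
             raw_text = d$candidates$raw_text[i],
             grounded = if (d$candidates$failure[i]) "FAIL"
                        else d$candidates$grounded[i],
             refusal = FALSE)
      })
      append_jsonl(recs, path)
    }
  }
  invisible(path)
}
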