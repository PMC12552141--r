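# Shared fixtures, built in code at test time.

# Write an OBO-Graph JSON file from a compact term spec:
# terms = list(list(id=, label=, parents=, synonyms=, obsolete=), ...)
write_obograph_fixture <- function(terms, path = tempfile(fileext = ".json"),
                                   version = "fixture-1") {
  nodes <- lapply(terms, function(t) {
    node <- list(id = t$id, lbl = t$label %||% "")
    meta <- list()
    if (!is.null(t$synonyms)) {
      meta$synonyms <- lapply(t$synonyms, function(s)
        list(pred = "hasExactSynonym", val = s))
    }
    if (isTRUE(t$obsolete)) meta$deprecated <- TRUE
    if (length(meta) > 0) node$meta <- meta
    node
  })
  edges <- list()
  for (t in terms) {
    for (p in t$parents %||% character(0)) {
      edges[[length(edges) + 1L]] <- list(sub = t$id, pred = "is_a", obj = p)
    }
  }
  doc <- list(graphs = list(list(id = "fixture",
                                 meta = list(version = version),
                                 nodes = nodes, edges = edges)))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), path, useBytes = TRUE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Chain A <- B <- C
chain_graph <- function() {
  load_obograph(write_obograph_fixture(list(
    list(id = "HP:0000001", label = "A"),
    list(id = "HP:0000002", label = "B", parents = "HP:0000001"),
    list(id = "HP:0000003", label = "C", parents = "HP:0000002"))))
}

# Diamond: D is_a B, D is_a C; B, C is_a A
diamond_graph <- function() {
  load_obograph(write_obograph_fixture(list(
    list(id = "HP:0000001", label = "A"),
    list(id = "HP:0000002", label = "B", parents = "HP:0000001"),
    list(id = "HP:0000003", label = "C", parents = "HP:0000001"),
    list(id = "HP:0000004", label = "D",
         parents = c("HP:0000002", "HP:0000003")))))
}

# Disease fixture mirroring a clinical grouping with six genetic subtypes,
# plus an unrelated singleton disease and an obsolete term.
six_subtype_graph <- function() {
  terms <- c(
    list(list(id = "MONDO:0000001", label = "disease"),
         list(id = "MONDO:0000100", label = "Alpha syndrome",
              parents = "MONDO:0000001",
              synonyms = c("inherited alpha syndrome"))),
    lapply(1:6, function(i)
      list(id = sprintf("MONDO:00002%02d", i),
           label = sprintf("Alpha syndrome type %d", i),
           parents = "MONDO:0000100",
           synonyms = sprintf("familial alpha syndrome %d", i))),
    list(list(id = "MONDO:0000300", label = "Beta disorder",
              parents = "MONDO:0000001"),
         list(id = "MONDO:0000400", label = "Old gamma disease",
              parents = "MONDO:0000001", obsolete = TRUE)))
  load_obograph(write_obograph_fixture(terms))
}

minimal_phenopacket_json <- function(path = tempfile(fileext = ".json")) {
  writeLines('{
    "id": "case-min",
    "subject": {"sex": "FEMALE"},
    "phenotypicFeatures": [{"type": {"id": "HP:0000003"}}],
    "diseases": [{"term": {"id": "MONDO:0000001", "label": "disease"}}]
  }', path)
  path
}

# Small synthetic world shared by several test files (built once per run).
tiny_spec <- function(seed = 42L, ...) {
  corpus_spec(n_cases = 20L, n_diseases = 4L, subtypes_min = 2L,
              subtypes_max = 3L, n_distractors = 6L,
              mean_features_per_case = 6, seed = seed, ...)
}

tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- tiny_spec()
      onts <- gen_mini_ontologies(spec)
      cache <<- list(spec = spec, onts = onts,
                     cases = gen_cases(spec, onts))
    }
    cache
  }
})

# A differential_result built directly (bypassing parsing) for scorer tests.
make_diff <- function(case_id, language, grounded, failure = NULL,
                      refusal = FALSE) {
  n <- length(grounded)
  if (is.null(failure)) failure <- is.na(grounded)
  structure(list(
    case_id = case_id, language = language,
    candidates = data.frame(rank = seq_len(n),
                            raw_text = if (n > 0) paste("cand", seq_len(n))
                                       else character(0),
                            grounded = as.character(grounded),
                            failure = failure,
                            stringsAsFactors = FALSE),
    refusal = refusal), class = "differential_result")
}
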