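# Ontology store: OBO-Graph JSON loading, is-a traversal, label/synonym
# lookup, and multilingual translation tables.

OBO_PURL <- "http://purl.obolibrary.org/obo/"

iri_to_curie <- function(x) {
  ifelse(startsWith(x, OBO_PURL),
         sub("_", ":", substring(x, nchar(OBO_PURL) + 1L), fixed = TRUE),
         x)
}

curie_to_iri <- function(x) paste0(OBO_PURL, sub(":", "_", x, fixed = TRUE))

#' Load an ontology from OBO-Graph JSON
#'
#' Reads the `nodes`/`edges` arrays of an OBO-Graph JSON document (as
#' published for HPO and Mondo). Node ids may be CURIEs or OBO PURL IRIs;
#' IRIs are converted to CURIEs. Only `is_a` edges are consumed; other edge
#' predicates are ignored. Deprecated nodes are kept but flagged obsolete.
#' The is-a closure is verified acyclic and all parents must resolve within
#' the graph.
#'
#' @param path path to an OBO-Graph JSON file.
#' @return an object of class `ontology_graph`: a list with `terms` (named
#'   list keyed by CURIE, each a list with `id`, `label`, `synonyms`,
#'   `parents`, `obsolete`), `children` (named list, inverse of `parents`),
#'   and `version`.
#' @export
load_obograph <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop(sprintf(
                    "cannot parse OBO-Graph JSON '%s': %s", path,
                    conditionMessage(e)), call. = FALSE))
  graphs <- doc[["graphs"]]
  if (is.null(graphs) || length(graphs) == 0L) {
    stop("OBO-Graph JSON has no 'graphs' array", call. = FALSE)
  }
  g <- graphs[[1]]
  version <- g[["meta"]][["version"]]
  if (is.null(version)) version <- "unversioned"

  terms <- list()
  for (node in g[["nodes"]]) {
    id <- iri_to_curie(node[["id"]])
    if (!is_curie(id)) next  # skip blank nodes / property nodes
    syns <- character(0)
    meta <- node[["meta"]]
    if (!is.null(meta[["synonyms"]])) {
      syns <- vapply(meta[["synonyms"]], function(s) s[["val"]], character(1))
    }
    obsolete <- isTRUE(meta[["deprecated"]])
    label <- node[["lbl"]]
    if (is.null(label)) label <- ""
    if (!nzchar(label) && !obsolete) {
      stop(sprintf("node %s has no label and is not obsolete", id),
           call. = FALSE)
    }
    terms[[id]] <- list(id = id, label = label, synonyms = syns,
                        parents = character(0), obsolete = obsolete)
  }

  for (edge in g[["edges"]]) {
    pred <- edge[["pred"]]
    if (!identical(pred, "is_a") && !identical(pred, "subClassOf")) next
    sub <- iri_to_curie(edge[["sub"]])
    obj <- iri_to_curie(edge[["obj"]])
    if (is.null(terms[[sub]]) || is.null(terms[[obj]])) {
      stop(sprintf("is_a edge references unknown term: %s -> %s", sub, obj),
           call. = FALSE)
    }
    if (identical(sub, obj)) {
      stop(sprintf("self-parenting edge on %s", sub), call. = FALSE)
    }
    terms[[sub]]$parents <- unique(c(terms[[sub]]$parents, obj))
  }

  graph <- new_ontology_graph(terms, version)
  check_acyclic(graph)
  graph
}

new_ontology_graph <- function(terms, version = "unversioned") {
  children <- list()
  for (t in terms) {
    for (p in t$parents) {
      children[[p]] <- c(children[[p]], t$id)
    }
  }
  structure(list(terms = terms, children = children, version = version),
            class = "ontology_graph")
}

# Kahn-style check; reports one member of a cycle on failure.
check_acyclic <- function(graph) {
  indeg <- vapply(graph$terms, function(t) length(t$parents), integer(1))
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    id <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in graph$children[[id]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(graph$terms)) {
    member <- names(indeg)[indeg > 0L][1L]
    stop(sprintf("is-a hierarchy contains a cycle (involving %s)", member),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d terms (%d obsolete), version %s\n",
              length(x$terms),
              sum(vapply(x$terms, `[[`, logical(1), "obsolete")),
              x$version))
  invisible(x)
}

assert_in_graph <- function(graph, id) {
  if (is.null(graph$terms[[id]])) {
    stop(sprintf("unknown term id: %s", id), call. = FALSE)
  }
  invisible(id)
}

#' Ancestors of a term
#'
#' Transitive closure over is-a edges, excluding the term itself.
#'
#' @param graph an `ontology_graph`.
#' @param id a term CURIE present in the graph.
#' @return character vector of ancestor CURIEs (sorted, possibly empty).
#' @export
ontology_ancestors <- function(graph, id) {
  assert_in_graph(graph, id)
  out <- character(0)
  frontier <- graph$terms[[id]]$parents
  while (length(frontier) > 0L) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(lapply(frontier,
                                     function(p) graph$terms[[p]]$parents)))
  }
  sort(unique(out))
}

#' Descendants of a term
#'
#' Transitive closure over inverse is-a edges, excluding the term itself.
#'
#' @inheritParams ontology_ancestors
#' @return character vector of descendant CURIEs (sorted, possibly empty).
#' @export
ontology_descendants <- function(graph, id) {
  assert_in_graph(graph, id)
  out <- character(0)
  frontier <- graph$children[[id]]
  while (length(frontier) > 0L) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(lapply(frontier,
                                     function(c) graph$children[[c]])))
  }
  sort(unique(out))
}

#' Primary English label of a term
#' @inheritParams ontology_ancestors
#' @return a string.
#' @export
term_label <- function(graph, id) {
  assert_in_graph(graph, id)
  graph$terms[[id]]$label
}

#' Leaf terms of an ontology graph
#' @param graph an `ontology_graph`.
#' @return character vector of CURIEs with no children.
#' @export
ontology_leaves <- function(graph) {
  ids <- names(graph$terms)
  sort(ids[!ids %in% names(graph$children)])
}

#' Serialize an ontology graph to OBO-Graph JSON
#'
#' Inverse of [load_obograph()] on the supported subset: node ids, labels,
#' synonyms, deprecation flags and the is_a edge multiset round-trip.
#'
#' @param graph an `ontology_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_obograph <- function(graph, path) {
  nodes <- unname(lapply(graph$terms, function(t) {
    node <- list(id = curie_to_iri(t$id), lbl = t$label)
    meta <- list()
    if (length(t$synonyms) > 0) {
      meta$synonyms <- lapply(t$synonyms, function(s)
        list(pred = "hasExactSynonym", val = s))
    }
    if (t$obsolete) meta$deprecated <- TRUE
    if (length(meta) > 0) node$meta <- meta
    node
  }))
  edges <- list()
  for (t in graph$terms) {
    for (p in t$parents) {
      edges[[length(edges) + 1L]] <- list(sub = curie_to_iri(t$id),
                                          pred = "is_a",
                                          obj = curie_to_iri(p))
    }
  }
  doc <- list(graphs = list(list(
    id = "lingodx-export",
    meta = list(version = graph$version),
    nodes = nodes,
    edges = edges)))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = FALSE), path,
             useBytes = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Translation tables

#' Load a translation table from TSV
#'
#' Dialect: UTF-8, tab-separated, no quoting, columns `term_id`, `language`,
#' `type` (`label` or `synonym`) and `text`, mirroring the simple
#' Babelon-style tables published by the HPO internationalisation effort.
#' At most one primary label is allowed per (term, language).
#'
#' @param path TSV file.
#' @param languages permitted ISO 639-1 codes; defaults to the ten study
#'   languages.
#' @return an object of class `translation_table`.
#' @export
load_translation_table <- function(path, languages = study_languages()) {
  df <- read_tsv(path)
  required <- c("term_id", "language", "type", "text")
  if (!all(required %in% names(df))) {
    stop(sprintf("translation TSV must have columns %s",
                 paste(required, collapse = ", ")), call. = FALSE)
  }
  new_translation_table(df, languages)
}

new_translation_table <- function(df, languages = study_languages()) {
  bad_lang <- setdiff(unique(df$language), languages)
  if (length(bad_lang) > 0) {
    stop(sprintf("language codes outside the configured set: %s",
                 paste(bad_lang, collapse = ", ")), call. = FALSE)
  }
  if (any(!nzchar(df$text))) stop("empty translation text", call. = FALSE)
  lab <- df[df$type == "label", , drop = FALSE]
  key <- paste(lab$term_id, lab$language)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate primary label for (term, language): %s",
                 key[duplicated(key)][1]), call. = FALSE)
  }
  index <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(lab))) {
    assign(paste0(lab$term_id[i], "|", lab$language[i]), lab$text[i],
           envir = index)
  }
  coverage <- table(lab$language)
  structure(list(entries = df, index = index,
                 coverage = stats::setNames(as.integer(coverage),
                                            names(coverage)),
                 languages = languages),
            class = "translation_table")
}

#' @export
print.translation_table <- function(x, ...) {
  cov <- paste(sprintf("%s:%d", names(x$coverage), x$coverage),
               collapse = " ")
  cat(sprintf("<translation_table> %d entries | %s\n", nrow(x$entries), cov))
  invisible(x)
}

#' Test whether a primary label translation exists
#' @param table a `translation_table`.
#' @param id term CURIE (vectorized).
#' @param language ISO 639-1 code.
#' @return logical vector.
#' @export
has_translation <- function(table, id, language) {
  vapply(id, function(i)
    exists(paste0(i, "|", language), envir = table$index, inherits = FALSE),
    logical(1), USE.NAMES = FALSE)
}

#' Translate a term's primary label
#'
#' Returns the translated primary label for `(id, language)`. If no entry
#' exists and `fallback` is `TRUE`, the English label from `graph` is
#' returned with a warning; with `fallback = FALSE` a missing translation is
#' an error. English never falls back: the English label itself is stored in
#' the table (the generator guarantees full `en` coverage), and if absent it
#' is taken from the graph silently only when `language == "en"`.
#'
#' @param table a `translation_table`.
#' @param id term CURIE.
#' @param language target ISO 639-1 code.
#' @param graph an `ontology_graph` supplying the English fallback label.
#' @param fallback logical; fall back to English on a missing translation?
#' @return a string.
#' @export
translate_term <- function(table, id, language, graph, fallback = TRUE) {
  assert_in_graph(graph, id)
  key <- paste0(id, "|", language)
  if (exists(key, envir = table$index, inherits = FALSE)) {
    return(get(key, envir = table$index))
  }
  if (language == "en") {
    return(term_label(graph, id))
  }
  if (!fallback) {
    stop(sprintf("no %s translation for %s", language, id), call. = FALSE)
  }
  warning(sprintf("no %s translation for %s; falling back to English",
                  language, id), call. = FALSE)
  term_label(graph, id)
}

#' Write a translation table to TSV
#' @param table a `translation_table`.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
save_translation_table <- function(table, path) {
  write_tsv(table$entries, path)
}
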