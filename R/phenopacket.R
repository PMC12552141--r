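# GA4GH Phenopacket (schema v2) I/O, restricted to the subset the pipeline
# consumes: subject sex and age, phenotypic features with excluded flags and
# onset ages, and the disease diagnosis. Genetic / variant information is
# deliberately dropped on read so that it can never leak into prompts.

PHENOPACKET_SEXES <- c("FEMALE", "MALE", "UNKNOWN")

#' Construct a case record
#'
#' One case record represents one patient: demographics, observed and
#' excluded phenotype terms (HP CURIEs) with optional onset ages, and
#' exactly one disease diagnosis.
#'
#' @param id case identifier, unique within a corpus.
#' @param sex one of `"FEMALE"`, `"MALE"`, `"UNKNOWN"`.
#' @param age ISO-8601 duration string (`"P4Y"`) or `NA`.
#' @param features data.frame with columns `term` (HP CURIE), `excluded`
#'   (logical), `onset` (ISO-8601 duration or `NA`).
#' @param diagnosis disease CURIE (e.g. MONDO).
#' @param diagnosis_label human-readable disease name.
#' @return object of class `case_record`.
#' @export
case_record <- function(id, sex, age, features, diagnosis, diagnosis_label) {
  stopifnot(is.character(id), nzchar(id))
  if (!sex %in% PHENOPACKET_SEXES) {
    stop(sprintf("case %s: invalid sex '%s'", id, sex), call. = FALSE)
  }
  if (!is.na(age)) parse_iso8601_duration(age)
  stopifnot(is.data.frame(features),
            all(c("term", "excluded", "onset") %in% names(features)))
  assert_curie(features$term, "feature term")
  if (any(curie_prefix(features$term) != "HP")) {
    stop(sprintf("case %s: non-HP feature id(s): %s", id,
                 paste(features$term[curie_prefix(features$term) != "HP"],
                       collapse = ", ")), call. = FALSE)
  }
  for (o in features$onset[!is.na(features$onset)]) parse_iso8601_duration(o)
  if (sum(!features$excluded) < 1L) {
    stop(sprintf("case %s: at least one observed (non-excluded) feature required",
                 id), call. = FALSE)
  }
  assert_curie(diagnosis, "diagnosis")
  structure(list(id = id, sex = sex, age = age,
                 features = features[, c("term", "excluded", "onset")],
                 diagnosis = diagnosis,
                 diagnosis_label = diagnosis_label),
            class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record> %s: %s, age %s; %d observed / %d excluded; dx %s (%s)\n",
              x$id, x$sex, ifelse(is.na(x$age), "?", x$age),
              sum(!x$features$excluded), sum(x$features$excluded),
              x$diagnosis, x$diagnosis_label))
  invisible(x)
}

#' Read a phenopacket JSON file into a case record
#'
#' Supports the v2 field layout: `subject` (sex,
#' `timeAtLastEncounter.age.iso8601duration`), `phenotypicFeatures`
#' (`type.id`, `excluded`, `onset.age.iso8601duration`) and the diagnosis
#' from the first `diseases` entry, falling back to
#' `interpretations[[1]].diagnosis.disease` when no `diseases` block exists.
#' Variant and gene information present in the file is dropped.
#'
#' @param path phenopacket JSON file.
#' @return a `case_record`.
#' @export
read_phenopacket <- function(path) {
  pp <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stop(sprintf(
                   "cannot parse phenopacket '%s': %s", path,
                   conditionMessage(e)), call. = FALSE))
  id <- pp[["id"]]
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))

  sex <- pp[["subject"]][["sex"]]
  if (is.null(sex) || !sex %in% PHENOPACKET_SEXES) sex <- "UNKNOWN"
  age <- pp[["subject"]][["timeAtLastEncounter"]][["age"]][["iso8601duration"]]
  if (is.null(age)) age <- NA_character_

  feats <- pp[["phenotypicFeatures"]]
  if (is.null(feats)) feats <- list()
  features <- data.frame(
    term = vapply(feats, function(f) {
      tid <- f[["type"]][["id"]]
      if (is.null(tid)) stop(sprintf("case %s: feature without type.id", id),
                             call. = FALSE)
      tid
    }, character(1)),
    excluded = vapply(feats, function(f) isTRUE(f[["excluded"]]), logical(1)),
    onset = vapply(feats, function(f) {
      o <- f[["onset"]][["age"]][["iso8601duration"]]
      if (is.null(o)) NA_character_ else o
    }, character(1)),
    stringsAsFactors = FALSE)

  disease <- NULL
  if (length(pp[["diseases"]]) > 0) {
    disease <- pp[["diseases"]][[1]][["term"]]
  } else if (length(pp[["interpretations"]]) > 0) {
    disease <- pp[["interpretations"]][[1]][["diagnosis"]][["disease"]]
  }
  if (is.null(disease) || is.null(disease[["id"]])) {
    stop(sprintf("case %s: no disease diagnosis entry", id), call. = FALSE)
  }
  dlabel <- disease[["label"]]
  if (is.null(dlabel)) dlabel <- ""

  case_record(id = id, sex = sex, age = age, features = features,
              diagnosis = disease[["id"]], diagnosis_label = dlabel)
}

#' Write a case record as phenopacket JSON
#'
#' Inverse of [read_phenopacket()] on the supported subset.
#'
#' @param record a `case_record`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_phenopacket <- function(record, path) {
  subject <- list(id = paste0(record$id, "-subject"), sex = record$sex)
  if (!is.na(record$age)) {
    subject$timeAtLastEncounter <- list(age = list(iso8601duration = record$age))
  }
  feats <- lapply(seq_len(nrow(record$features)), function(i) {
    f <- list(type = list(id = record$features$term[i]))
    if (record$features$excluded[i]) f$excluded <- TRUE
    if (!is.na(record$features$onset[i])) {
      f$onset <- list(age = list(iso8601duration = record$features$onset[i]))
    }
    f
  })
  pp <- list(
    id = record$id,
    subject = subject,
    phenotypicFeatures = feats,
    diseases = list(list(term = list(id = record$diagnosis,
                                     label = record$diagnosis_label))),
    metaData = list(created = "1970-01-01T00:00:00Z",
                    createdBy = "lingodx",
                    phenopacketSchemaVersion = "2.0"))
  writeLines(jsonlite::toJSON(pp, auto_unbox = TRUE, pretty = TRUE), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read every phenopacket in a directory
#'
#' @param dir directory containing `*.json` phenopackets.
#' @return named list of `case_record`s, keyed and sorted by case id.
#' @export
read_corpus <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  records <- lapply(paths, read_phenopacket)
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate case ids in corpus: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  stats::setNames(records, ids)[order(ids)]
}

#' Validate translation coverage of a corpus
#'
#' A record passes only if every feature term (observed or excluded) has a
#' primary-label translation in every requested language. This mirrors the
#' corpus restriction step of the benchmark: cases whose HPO terms are not
#' fully translated are excluded.
#'
#' @param records list of `case_record`s.
#' @param graph phenotype `ontology_graph` (terms must resolve).
#' @param table a `translation_table`.
#' @param languages character vector of language codes to require; an empty
#'   vector retains every record vacuously.
#' @return data.frame with one row per record: `id`, `pass`, and
#'   `missing` (comma-separated `term@lang` pairs); attributes `retained`
#'   and `excluded` carry the counts.
#' @export
validate_corpus <- function(records, graph, table, languages) {
  rows <- lapply(records, function(rec) {
    for (term in rec$features$term) assert_in_graph(graph, term)
    missing <- character(0)
    for (lang in languages) {
      ok <- has_translation(table, rec$features$term, lang)
      if (any(!ok)) {
        missing <- c(missing, paste0(rec$features$term[!ok], "@", lang))
      }
    }
    data.frame(id = rec$id, pass = length(missing) == 0L,
               missing = paste(missing, collapse = ","),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(report, "retained") <- sum(report$pass)
  attr(report, "excluded") <- sum(!report$pass)
  report
}
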