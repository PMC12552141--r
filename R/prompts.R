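# Prompt builder: renders a case record into a narrative zero-shot prompt in
# a target language using a data-driven template pack plus the ontology
# translation table. One pack per language ships under
# inst/extdata/packs/<lang>.json; adding a language requires no code.

PACK_REQUIRED_FIELDS <- c(
  "language", "header_text", "example_output_block",
  "english_reply_instruction", "subject_frames", "observed_frame",
  "excluded_frame", "onset_frame", "list_separator", "final_conjunction",
  "age_phrase_rules", "onset_phrase_rules")

#' Load and audit a template pack
#'
#' A template pack is a JSON document holding every language-specific string
#' needed to render prompts: the constant instruction header, sentence
#' frames for subject (by sex and age-class), observed features, excluded
#' features and onset groups, list punctuation, and age-phrase rules. The
#' example output block is always English; non-English packs must carry a
#' non-empty instruction to reply in English. Loading audits that every
#' frame contains exactly the placeholders its renderer fills.
#'
#' @param path pack JSON file.
#' @return object of class `template_pack`.
#' @export
load_template_pack <- function(path) {
  pack <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  missing <- setdiff(PACK_REQUIRED_FIELDS, names(pack))
  if (length(missing) > 0) {
    stop(sprintf("template pack '%s' missing field(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  audit_placeholder <- function(frame, field, placeholders) {
    for (ph in placeholders) {
      if (!grepl(ph, frame, fixed = TRUE)) {
        stop(sprintf("template pack '%s': field '%s' lacks placeholder %s",
                     path, field, ph), call. = FALSE)
      }
    }
  }
  for (sex in PHENOPACKET_SEXES) {
    frames <- pack$subject_frames[[sex]]
    if (is.null(frames) || is.null(frames[["with_age"]]) ||
        is.null(frames[["no_age"]])) {
      stop(sprintf("template pack '%s': subject_frames missing %s/with_age or no_age",
                   path, sex), call. = FALSE)
    }
    audit_placeholder(frames[["with_age"]], paste0("subject_frames.", sex),
                      "{age}")
  }
  audit_placeholder(pack$observed_frame, "observed_frame", "{features}")
  audit_placeholder(pack$excluded_frame, "excluded_frame", "{features}")
  audit_placeholder(pack$onset_frame, "onset_frame", c("{age}", "{features}"))
  for (rules in list(pack$age_phrase_rules, pack$onset_phrase_rules)) {
    if (!all(c("years", "months", "days") %in% names(rules))) {
      stop(sprintf("template pack '%s': phrase rules need years/months/days",
                   path), call. = FALSE)
    }
    for (r in rules) audit_placeholder(r, "phrase rule", "{n}")
  }
  if (pack$language != "en" && !nzchar(pack$english_reply_instruction)) {
    stop(sprintf("template pack '%s': non-English pack needs english_reply_instruction",
                 path), call. = FALSE)
  }
  if (!nzchar(pack$header_text) || !nzchar(pack$example_output_block)) {
    stop(sprintf("template pack '%s': header/example block must be non-empty",
                 path), call. = FALSE)
  }
  structure(pack, class = "template_pack")
}

#' Path to a shipped template pack
#' @param language ISO 639-1 code of one of the ten study languages.
#' @return file path inside the installed package.
#' @export
template_pack_path <- function(language) {
  p <- system.file("extdata", "packs", paste0(language, ".json"),
                   package = "lingodx")
  if (!nzchar(p)) stop(sprintf("no shipped pack for '%s'", language),
                       call. = FALSE)
  p
}

#' Load a shipped template pack by language code
#' @inheritParams template_pack_path
#' @return a `template_pack`.
#' @export
default_template_pack <- function(language) {
  load_template_pack(template_pack_path(language))
}

fill <- function(frame, ...) {
  subs <- list(...)
  for (nm in names(subs)) {
    frame <- gsub(paste0("{", nm, "}"), subs[[nm]], frame, fixed = TRUE)
  }
  frame
}

#' Render a localized age phrase from an ISO-8601 duration
#'
#' Mixed-unit durations truncate to the largest non-zero unit: years if the
#' age is at least one year, else months if at least one month, else days
#' (`"P2Y3M"` renders as the 2-year phrase). `style = "attributive"` uses
#' the pack's `age_phrase_rules` (for subject sentences, e.g. "4-year-old");
#' `style = "nominal"` uses `onset_phrase_rules` (for onset sentences, e.g.
#' "4 years").
#'
#' @param age ISO-8601 duration string.
#' @param pack a `template_pack`.
#' @param style `"attributive"` or `"nominal"`.
#' @return a string.
#' @export
render_age_phrase <- function(age, pack, style = c("attributive", "nominal")) {
  style <- match.arg(style)
  d <- parse_iso8601_duration(age)
  rules <- if (style == "attributive") pack$age_phrase_rules
           else pack$onset_phrase_rules
  if (d[["years"]] >= 1) {
    fill(rules[["years"]], n = format(d[["years"]]))
  } else if (d[["months"]] >= 1) {
    fill(rules[["months"]], n = format(d[["months"]]))
  } else {
    fill(rules[["days"]], n = format(d[["days"]]))
  }
}

join_list <- function(items, pack) {
  n <- length(items)
  if (n == 1L) return(items)
  paste0(paste(items[-n], collapse = pack$list_separator),
         pack$final_conjunction, items[n])
}

#' Render a case record into a narrative prompt
#'
#' Sentence order is: constant header; subject sentence (sex and age);
#' one onset sentence per distinct onset value among observed features (in
#' first-appearance order); a single sentence for observed features without
#' onset; one exclusion sentence if any features are excluded; the English
#' example output block; and, for non-English packs, the instruction to
#' reply in English. The diagnosis and any genetic information never enter
#' the text. Feature labels come from the translation table in the pack's
#' language (English fallback only if `fallback = TRUE`; otherwise a missing
#' translation is an error listing the terms).
#'
#' @param record a `case_record`.
#' @param pack a `template_pack`.
#' @param table a `translation_table`.
#' @param graph phenotype `ontology_graph` (labels + English fallback).
#' @param fallback allow English fallback for untranslated terms?
#' @return object of class `prompt_text`: list with `case_id`, `language`,
#'   `text` and `term_manifest` (data.frame term / label / status).
#' @export
render_prompt <- function(record, pack, table, graph, fallback = FALSE) {
  lang <- pack$language
  if (!fallback && lang != "en") {
    ok <- has_translation(table, record$features$term, lang)
    if (any(!ok)) {
      stop(sprintf("case %s: missing %s translation for: %s", record$id, lang,
                   paste(record$features$term[!ok], collapse = ", ")),
           call. = FALSE)
    }
  }
  labels <- vapply(record$features$term, function(tid)
    translate_term(table, tid, lang, graph, fallback = TRUE),
    character(1), USE.NAMES = FALSE)

  feats <- record$features
  obs <- which(!feats$excluded)
  exc <- which(feats$excluded)

  # subject sentence
  frames <- pack$subject_frames[[record$sex]]
  subject_sentence <- if (is.na(record$age)) {
    frames[["no_age"]]
  } else {
    fill(frames[["with_age"]],
         age = render_age_phrase(record$age, pack, "attributive"))
  }

  body <- subject_sentence
  # observed features grouped by onset (first-appearance order of onsets)
  obs_onset <- feats$onset[obs]
  for (ons in unique(obs_onset[!is.na(obs_onset)])) {
    grp <- obs[!is.na(obs_onset) & obs_onset == ons]
    body <- c(body, fill(pack$onset_frame,
                         age = render_age_phrase(ons, pack, "nominal"),
                         features = join_list(labels[grp], pack)))
  }
  plain <- obs[is.na(obs_onset)]
  if (length(plain) > 0) {
    body <- c(body, fill(pack$observed_frame,
                         features = join_list(labels[plain], pack)))
  }
  if (length(exc) > 0) {
    body <- c(body, fill(pack$excluded_frame,
                         features = join_list(labels[exc], pack)))
  }

  parts <- c(pack$header_text, paste(body, collapse = " "),
             pack$example_output_block)
  if (lang != "en") parts <- c(parts, pack$english_reply_instruction)
  text <- paste(parts, collapse = "\n\n")

  manifest <- data.frame(
    term = feats$term,
    label = labels,
    status = ifelse(feats$excluded, "excluded", "observed"),
    stringsAsFactors = FALSE)

  structure(list(case_id = record$id, language = lang, text = text,
                 term_manifest = manifest),
            class = "prompt_text")
}

#' @export
print.prompt_text <- function(x, ...) {
  cat(sprintf("<prompt_text> case %s [%s], %d terms, %d chars\n", x$case_id,
              x$language, nrow(x$term_manifest), nchar(x$text)))
  invisible(x)
}

#' Write prompts to disk with a manifest
#'
#' Writes one UTF-8 text file per prompt, named `<case_id>_<lang>.txt`, and
#' a `manifest.tsv` with columns case_id, language, n_terms, sha256.
#'
#' @param prompts list of `prompt_text` objects.
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
write_prompts <- function(prompts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(prompts, function(p) {
    path <- file.path(dir, paste0(p$case_id, "_", p$language, ".txt"))
    writeLines(p$text, path, useBytes = TRUE)
    data.frame(case_id = p$case_id, language = p$language,
               n_terms = nrow(p$term_manifest),
               sha256 = sha256_hex(p$text), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(file.path(dir, "manifest.tsv"))
}
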