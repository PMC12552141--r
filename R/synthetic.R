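# Synthetic fixtures: mini ontologies, translation tables, phenopacket
# corpora and mock accuracy profiles with the statistical shape of the
# study corpus (about 14 phenotype terms per case, observed and excluded
# features, onset ages, a female/male/unspecified sex mix, diseases with
# genetic subtypes under clinical grouping terms). Everything is a pure
# function of the spec's seed.

#' Specification of a synthetic corpus
#'
#' Defaults state the emulated world: mean of 14 phenotype terms per case,
#' sex mix proportional to the study's printed 1590/1826/1500
#' female/male/unspecified triple, a modest excluded-feature fraction and
#' onset recorded for half of the observed features, diseases organized as
#' clinical grouping terms with 2-6 genetic subtypes each.
#'
#' @param n_cases number of cases to generate.
#' @param n_diseases number of clinical grouping diseases.
#' @param subtypes_min,subtypes_max range of genetic subtypes per disease.
#' @param n_distractors additional subtype-free distractor diseases.
#' @param mean_features_per_case Poisson mean of phenotype terms per case.
#' @param excluded_feature_fraction probability a feature is excluded.
#' @param onset_fraction probability an observed feature carries an onset.
#' @param age_fraction probability the subject age is recorded.
#' @param sex_probabilities named numeric triple (FEMALE, MALE, UNKNOWN),
#'   normalized internally.
#' @param untranslated_term_fraction named numeric vector: per-language
#'   fraction of phenotype terms left untranslated (English is always
#'   fully covered).
#' @param pool_size phenotype terms owned by each disease.
#' @param pool_share fraction of a case's features drawn from its disease's
#'   pool (the rest is uniform noise).
#' @param seed integer; fixes every generated artifact byte-exactly.
#' @return object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_cases = 100L,
                        n_diseases = 10L,
                        subtypes_min = 2L,
                        subtypes_max = 6L,
                        n_distractors = 15L,
                        mean_features_per_case = 14,
                        excluded_feature_fraction = 0.15,
                        onset_fraction = 0.5,
                        age_fraction = 0.8,
                        sex_probabilities = c(FEMALE = 1590, MALE = 1826,
                                              UNKNOWN = 1500),
                        untranslated_term_fraction = numeric(0),
                        pool_size = 25L,
                        pool_share = 0.8,
                        seed = 42L) {
  stopifnot(n_cases >= 1, n_diseases >= 1, subtypes_min >= 1,
            subtypes_max >= subtypes_min)
  probs <- c(excluded_feature_fraction, onset_fraction, age_fraction,
             pool_share, untranslated_term_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("fractions must lie in [0,1]", call. = FALSE)
  }
  sex_probabilities <- sex_probabilities / sum(sex_probabilities)
  structure(list(n_cases = as.integer(n_cases),
                 n_diseases = as.integer(n_diseases),
                 subtypes_min = as.integer(subtypes_min),
                 subtypes_max = as.integer(subtypes_max),
                 n_distractors = as.integer(n_distractors),
                 mean_features_per_case = mean_features_per_case,
                 excluded_feature_fraction = excluded_feature_fraction,
                 onset_fraction = onset_fraction,
                 age_fraction = age_fraction,
                 sex_probabilities = sex_probabilities,
                 untranslated_term_fraction = untranslated_term_fraction,
                 pool_size = as.integer(pool_size),
                 pool_share = pool_share,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

SYLLABLES <- c("ba", "be", "bi", "bo", "da", "do", "ka", "ke", "ki", "ko",
               "la", "le", "li", "lo", "ma", "me", "mi", "mo", "na", "ne",
               "ni", "no", "ra", "re", "ri", "ro", "sa", "se", "si", "so",
               "ta", "te", "ti", "to", "va", "ve", "vi", "vo", "za", "zo")

pseudo_word <- function(used) {
  repeat {
    n <- sample(2:4, 1)
    w <- paste(sample(SYLLABLES, n, replace = TRUE), collapse = "")
    w <- paste0(toupper(substring(w, 1, 1)), substring(w, 2))
    if (!w %in% used) return(w)
  }
}

# Pseudo-localization tag per language; CJK languages get non-Latin tags so
# the pipeline is exercised on non-ASCII text.
LANG_TAGS <- c(en = "", zh = "拟:", cs = "cs:", nl = "nl:", fr = "fr:",
               de = "de:", it = "it:", ja = "仮:", es = "es:", tr = "tr:")

pseudo_translation <- function(label, lang) {
  if (lang == "en") label else paste0(LANG_TAGS[[lang]], label)
}

#' Generate the mini ontologies and translation table of a synthetic world
#'
#' Builds a rooted phenotype is-a tree whose leaf count is at least five
#' times the mean features per case, a disease ontology with
#' `n_diseases` clinical grouping terms each carrying sampled genetic
#' subtypes (labelled "<Disease> syndrome type k") plus subtype-free
#' distractor diseases, unique labels with 1-3 synonyms per disease term,
#' and a translation table covering all ten study languages with
#' per-language dropout on phenotype terms. Deterministic in `spec$seed`.
#'
#' @param spec a `corpus_spec`.
#' @return list with `phenotype` and `disease` (`ontology_graph`s),
#'   `translations` (`translation_table`), `disease_pools` (named list:
#'   subtype CURIE -> phenotype leaf pool), `grouping_terms`, `subtypes`,
#'   `distractors` (character vectors of CURIEs).
#' @export
gen_mini_ontologies <- function(spec) {
  with_rng_stream(stable_hash(spec$seed, "ontologies"), {
    n_leaves <- max(ceiling(5 * spec$mean_features_per_case), 80L,
                    spec$pool_size)
    n_branches <- 8L

    # phenotype tree: root -> branches -> leaves
    pterms <- list()
    root <- "HP:0000001"
    pterms[[root]] <- list(id = root, label = "Phenotypic abnormality",
                           synonyms = character(0), parents = character(0),
                           obsolete = FALSE)
    branches <- sprintf("HP:%07d", 100 + seq_len(n_branches))
    for (i in seq_len(n_branches)) {
      pterms[[branches[i]]] <- list(
        id = branches[i],
        label = sprintf("Abnormality of synthetic system %d", i),
        synonyms = character(0), parents = root, obsolete = FALSE)
    }
    leaves <- sprintf("HP:%07d", 1000 + seq_len(n_leaves))
    for (i in seq_len(n_leaves)) {
      pterms[[leaves[i]]] <- list(
        id = leaves[i],
        label = sprintf("Synthetic phenotype %03d", i),
        synonyms = character(0),
        parents = branches[((i - 1L) %% n_branches) + 1L],
        obsolete = FALSE)
    }
    phenotype <- new_ontology_graph(pterms, "synthetic-phenotype-1")

    # disease ontology: root -> groupings -> subtypes, plus distractors
    dterms <- list()
    droot <- "MONDO:0000001"
    dterms[[droot]] <- list(id = droot, label = "disease",
                            synonyms = character(0), parents = character(0),
                            obsolete = FALSE)
    used_words <- character(0)
    syn_prefixes <- c("inherited", "congenital", "familial")
    add_disease <- function(id, label, parents) {
      n_syn <- sample(1:3, 1)
      syns <- paste(syn_prefixes[seq_len(n_syn)], tolower(label))
      dterms[[id]] <<- list(id = id, label = label, synonyms = syns,
                            parents = parents, obsolete = FALSE)
    }
    groupings <- sprintf("MONDO:%07d", 100 + seq_len(spec$n_diseases))
    subtypes <- character(0)
    k <- 0L
    for (i in seq_len(spec$n_diseases)) {
      w <- pseudo_word(used_words); used_words <- c(used_words, w)
      glabel <- paste(w, "syndrome")
      add_disease(groupings[i], glabel, droot)
      sub_range <- seq(spec$subtypes_min, spec$subtypes_max)
      n_sub <- sub_range[sample.int(length(sub_range), 1)]
      for (j in seq_len(n_sub)) {
        k <- k + 1L
        sid <- sprintf("MONDO:%07d", 10000 + k)
        add_disease(sid, sprintf("%s type %d", glabel, j), groupings[i])
        subtypes <- c(subtypes, sid)
      }
    }
    distractors <- sprintf("MONDO:%07d", 50000 + seq_len(spec$n_distractors))
    for (i in seq_len(spec$n_distractors)) {
      w <- pseudo_word(used_words); used_words <- c(used_words, w)
      add_disease(distractors[i], paste(w, "disorder"), droot)
    }
    disease <- new_ontology_graph(dterms, "synthetic-disease-1")

    # disease-specific phenotype pools (subtype level; siblings share the
    # grouping's pool so swapped labels stay phenotypically coherent)
    grouping_pools <- stats::setNames(
      lapply(groupings, function(g) sample(leaves, spec$pool_size)),
      groupings)
    disease_pools <- stats::setNames(
      lapply(subtypes, function(s)
        grouping_pools[[disease$terms[[s]]$parents[1]]]),
      subtypes)

    # translation table: all phenotype + disease terms, ten languages,
    # per-language dropout on phenotype terms (never on English)
    all_terms <- c(names(pterms), names(dterms))
    en_labels <- c(vapply(pterms, `[[`, character(1), "label"),
                   vapply(dterms, `[[`, character(1), "label"))
    rows <- list()
    for (lang in study_languages()) {
      drop_frac <- spec$untranslated_term_fraction[lang]
      dropped <- character(0)
      if (lang != "en" && !is.na(drop_frac) && length(drop_frac) == 1 &&
          drop_frac > 0) {
        phen_ids <- names(pterms)
        dropped <- sample(phen_ids, floor(drop_frac * length(phen_ids)))
      }
      keep <- !all_terms %in% dropped
      rows[[lang]] <- data.frame(
        term_id = all_terms[keep], language = lang, type = "label",
        text = vapply(seq_along(all_terms)[keep], function(i)
          pseudo_translation(en_labels[i], lang), character(1)),
        stringsAsFactors = FALSE)
    }
    entries <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    translations <- new_translation_table(entries)

    list(phenotype = phenotype, disease = disease,
         translations = translations, disease_pools = disease_pools,
         grouping_terms = groupings, subtypes = subtypes,
         distractors = distractors)
  })
}

random_age <- function(max_years = 17L) {
  y <- sample(0:max_years, 1)
  if (y >= 1) sprintf("P%dY", y)
  else if (stats::runif(1) < 0.7) sprintf("P%dM", sample(1:11, 1))
  else sprintf("P%dD", sample(1:27, 1))
}

#' Generate a synthetic phenopacket corpus
#'
#' Each case samples a diagnosis at the genetic-subtype level, draws
#' Poisson(`mean_features_per_case`) phenotype terms (floored at one)
#' biased toward the disease's term pool plus uniform noise, marks a
#' fraction excluded (always keeping at least one observed), assigns onset
#' ages to a fraction of observed features, and samples sex and age.
#' Deterministic in `spec$seed`.
#'
#' @param spec a `corpus_spec`.
#' @param ontologies output of [gen_mini_ontologies()].
#' @param out_dir optional directory; when given, each case is written as
#'   `<id>.json` phenopacket.
#' @return named list of `case_record`s.
#' @export
gen_cases <- function(spec, ontologies, out_dir = NULL) {
  leaves <- ontology_leaves(ontologies$phenotype)
  subtypes <- ontologies$subtypes
  with_rng_stream(stable_hash(spec$seed, "cases"), {
    records <- lapply(seq_len(spec$n_cases), function(i) {
      id <- sprintf("case-%04d", i)
      dx <- subtypes[sample.int(length(subtypes), 1)]
      pool <- ontologies$disease_pools[[dx]]

      n_feat <- max(1L, stats::rpois(1, spec$mean_features_per_case))
      n_feat <- min(n_feat, length(leaves))
      n_pool <- min(stats::rbinom(1, n_feat, spec$pool_share), length(pool))
      terms <- c(sample(pool, n_pool),
                 sample(setdiff(leaves, pool), n_feat - n_pool))

      excluded <- stats::runif(n_feat) < spec$excluded_feature_fraction
      if (all(excluded)) excluded[1] <- FALSE
      onset <- rep(NA_character_, n_feat)
      has_onset <- !excluded & stats::runif(n_feat) < spec$onset_fraction
      onset[has_onset] <- vapply(which(has_onset), function(j) random_age(),
                                 character(1))

      sex <- sample(names(spec$sex_probabilities), 1,
                    prob = spec$sex_probabilities)
      age <- if (stats::runif(1) < spec$age_fraction) random_age() else
        NA_character_

      case_record(
        id = id, sex = sex, age = age,
        features = data.frame(term = terms, excluded = excluded,
                              onset = onset, stringsAsFactors = FALSE),
        diagnosis = dx,
        diagnosis_label = term_label(ontologies$disease, dx))
    })
    names(records) <- vapply(records, `[[`, character(1), "id")
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (rec in records) {
        write_phenopacket(rec, file.path(out_dir, paste0(rec$id, ".json")))
      }
    }
    records
  })
}

#' Diagnoses of a corpus as a named vector
#' @param records named list of `case_record`s.
#' @return named character vector: case id -> diagnosis CURIE.
#' @export
corpus_diagnoses <- function(records) {
  vapply(records, `[[`, character(1), "diagnosis")
}

#' Published per-language count tables shipped as regression fixtures
#'
#' The printed per-language Top-N count rows for the two benchmarked models
#' (a general-purpose API model and a medically fine-tuned open model),
#' shipped as TSV data and used only by reporting regression tests; they
#' are inputs, not recomputable outputs.
#'
#' @return list with elements `gpt4o` and `meditron`, each a data.frame of
#'   `language_summary` rows.
#' @export
gen_regression_fixture <- function() {
  list(gpt4o = read_count_table(regression_fixture_path("gpt4o")),
       meditron = read_count_table(regression_fixture_path("meditron")))
}

#' @rdname gen_regression_fixture
#' @param model `"gpt4o"` or `"meditron"`.
#' @export
regression_fixture_path <- function(model = c("gpt4o", "meditron")) {
  model <- match.arg(model)
  p <- system.file("extdata", "regression", paste0(model, "_counts.tsv"),
                   package = "lingodx")
  if (!nzchar(p)) stop("regression fixture not installed", call. = FALSE)
  p
}
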