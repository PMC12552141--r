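# Cross-language statistics and report emission.

#' Kruskal-Wallis H-test over k groups of ordinal values
#'
#' Rank-based k-group test of identical distributions. Pooled values get
#' mid-ranks; with rank-sum R_j of group j (size n_j, pooled size N),
#'
#'   H = \[ 12 / (N (N + 1)) * sum_j R_j^2 / n_j  -  3 (N + 1) \] / C,
#'
#' with tie correction C = 1 - sum_t (t^3 - t) / (N^3 - N) over tie groups.
#' The p-value is the upper chi-square tail with k - 1 degrees of freedom.
#' Authored here as a contract of this package; tests verify agreement with
#' an independent reference implementation to 1e-9.
#'
#' @param groups list of >= 2 non-empty numeric vectors of ordinal values
#'   (here: per-case correct ranks, see [kw_rank_coding()]).
#' @return object of class `kw_result`: list with `H`, `p_value`, `df`,
#'   `tie_corrected`, `group_sizes`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("groups must be non-empty", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("NA values not allowed", call. = FALSE)
  N <- length(x)
  g <- rep(seq_along(groups), sizes)
  rk <- rank(x)  # mid-ranks
  Rj <- tapply(rk, g, sum)
  H0 <- 12 / (N * (N + 1)) * sum(Rj^2 / sizes) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) {
    stop("degenerate input: all pooled values identical (H undefined)",
         call. = FALSE)
  }
  H <- H0 / C
  df <- length(groups) - 1L
  p <- stats::pchisq(H, df = df, lower.tail = FALSE)
  structure(list(H = H, p_value = p, df = df,
                 tie_corrected = any(ties > 1), group_sizes = as.integer(sizes)),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.1f, df = %d, p = %s (%d groups%s)\n",
              x$H, x$df, format_pvalue(x$p_value), length(x$group_sizes),
              if (x$tie_corrected) ", tie-corrected" else ""))
  invisible(x)
}

format_pvalue <- function(p) {
  if (p < 0.001) sprintf("%.1e", p) else sprintf("%.4f", p)
}

#' Ordinal coding of case scores for the Kruskal-Wallis test
#'
#' This package's documented convention (the source tables do not fix one):
#' the per-case value is `correct_rank`; cases with no correct diagnosis in
#' the reply (unranked, including grounding failures) are coded as rank 11,
#' one worse than the deepest rank credited; refusals are excluded.
#'
#' @param scores data.frame of case scores.
#' @return named list of numeric vectors, one per language.
#' @export
kw_rank_coding <- function(scores) {
  s <- scores[!scores$refusal, , drop = FALSE]
  r <- ifelse(is.na(s$correct_rank) | s$correct_rank > 10, 11, s$correct_rank)
  split(as.numeric(r), s$language)
}

# ---------------------------------------------------------------------------
# Count tables and report emission

#' Read a per-language count table
#'
#' TSV with columns `language`, `top1`, `top3`, `top10`, `not_ranked` and
#' optionally `no_diagnosis` (absent column means zero refusals, as for a
#' model that always answered).
#'
#' @param path TSV file (`#` comment lines allowed).
#' @return data.frame of stacked `language_summary` rows.
#' @export
read_count_table <- function(path) {
  df <- read_tsv(path)
  if (!"no_diagnosis" %in% names(df)) df$no_diagnosis <- 0L
  rows <- lapply(seq_len(nrow(df)), function(i) {
    language_summary(df$language[i], df$top1[i], df$top3[i], df$top10[i],
                     not_ranked = df$not_ranked[i],
                     no_diagnosis = df$no_diagnosis[i])
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Frequency table for a set of language summaries
#'
#' Top-1/3/10 percentages under both denominator conventions.
#'
#' @param summaries data.frame of `language_summary` rows.
#' @return data.frame with columns `language`, `top1_pct`, `top3_pct`,
#'   `top10_pct` (refusals excluded from the denominator) and `*_pct_all`
#'   (all cases in the denominator).
#' @export
frequency_table <- function(summaries) {
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, , drop = FALSE]
    data.frame(language = s$language,
               top1_pct = topn_frequency(s, 1),
               top3_pct = topn_frequency(s, 3),
               top10_pct = topn_frequency(s, 10),
               top1_pct_all = topn_frequency(s, 1, "all"),
               top3_pct_all = topn_frequency(s, 3, "all"),
               top10_pct_all = topn_frequency(s, 10, "all"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Emit the benchmark report
#'
#' Writes, per requested format: the count table in the benchmark's layout
#' (`beyond10` folded into `not_ranked`; the `no_diagnosis` column dropped
#' when all zero), the frequency table under both denominators, an optional
#' grounding-failure-rate table, an optional Kruskal-Wallis block, and a
#' JSON bundle with everything. Output is byte-stable for identical inputs.
#'
#' @param summaries data.frame of `language_summary` rows.
#' @param kw optional `kw_result`.
#' @param grounding optional data.frame from [grounding_failure_rates()].
#' @param dir output directory (created if needed).
#' @param formats subset of `c("tsv", "markdown")`.
#' @return named character vector of written file paths, invisibly.
#' @export
emit_report <- function(summaries, kw = NULL, grounding = NULL, dir,
                        formats = c("tsv", "markdown")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- data.frame(language = summaries$language,
                       top1 = summaries$top1, top3 = summaries$top3,
                       top10 = summaries$top10,
                       not_ranked = summaries$not_ranked + summaries$beyond10,
                       no_diagnosis = summaries$no_diagnosis,
                       stringsAsFactors = FALSE)
  if (all(counts$no_diagnosis == 0L)) counts$no_diagnosis <- NULL
  freqs <- frequency_table(summaries)

  paths <- character(0)
  if ("tsv" %in% formats) {
    paths["counts_tsv"] <- write_tsv(counts, file.path(dir, "counts.tsv"))
    paths["freqs_tsv"] <- write_tsv(freqs, file.path(dir, "frequencies.tsv"))
    if (!is.null(grounding)) {
      paths["grounding_tsv"] <- write_tsv(grounding,
                                          file.path(dir, "grounding.tsv"))
    }
  }
  if ("markdown" %in% formats) {
    md <- c("# Differential-diagnosis benchmark report", "",
            "## Counts by language", "", md_table(counts), "",
            "## Top-N frequencies (%)", "", md_table(freqs))
    if (!is.null(grounding)) {
      md <- c(md, "", "## Grounding failures", "", md_table(grounding))
    }
    if (!is.null(kw)) {
      md <- c(md, "", "## Cross-language Kruskal-Wallis test", "",
              sprintf("H = %.1f, df = %d, p = %s", kw$H, kw$df,
                      format_pvalue(kw$p_value)))
    }
    p <- file.path(dir, "report.md")
    writeLines(md, p, useBytes = TRUE)
    paths["markdown"] <- p
  }
  bundle <- list(counts = counts, frequencies = freqs)
  if (!is.null(grounding)) bundle$grounding <- grounding
  if (!is.null(kw)) {
    bundle$kruskal_wallis <- list(H = kw$H, p_value = kw$p_value, df = kw$df,
                                  group_sizes = kw$group_sizes)
  }
  p <- file.path(dir, "results.json")
  writeLines(jsonlite::toJSON(bundle, dataframe = "rows", auto_unbox = TRUE,
                              digits = NA, pretty = TRUE), p, useBytes = TRUE)
  paths["json"] <- p
  invisible(paths)
}

md_table <- function(df) {
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) format(x, nsmall = 1, trim = TRUE)
    else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  c(header, sep, body)
}
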