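# Internal utilities: CURIE handling, ISO-8601 durations, deterministic
# seeding, half-up rounding, JSONL I/O.

#' Test whether strings are well-formed CURIEs
#'
#' A CURIE has the form `PREFIX:LOCAL` with exactly one colon, a non-empty
#' uppercase alphanumeric prefix and a non-empty local part
#' (e.g. `HP:0000118`, `MONDO:0007947`).
#'
#' @param x character vector.
#' @return logical vector, one element per input.
#' @export
is_curie <- function(x) {
  !is.na(x) & grepl("^[A-Z0-9]+:[^:[:space:]]+$", x)
}

assert_curie <- function(x, what = "term id") {
  bad <- x[!is_curie(x)]
  if (length(bad) > 0) {
    stop(sprintf("invalid %s (not a CURIE): %s", what,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

curie_prefix <- function(x) sub(":.*$", "", x)

#' Parse an ISO-8601 duration of the form P<y>Y<m>M<d>D
#'
#' Only the date components used by phenopacket ages are supported; any of
#' the three parts may be absent. Week and time components are rejected.
#'
#' @param x a single duration string such as `"P4Y"`, `"P6M"`, `"P2Y3M10D"`.
#' @return named numeric vector with elements `years`, `months`, `days`.
#' @export
parse_iso8601_duration <- function(x) {
  if (length(x) != 1L || is.na(x) || !is.character(x)) {
    stop("duration must be a single string", call. = FALSE)
  }
  m <- regmatches(x, regexec("^P(?:([0-9]+)Y)?(?:([0-9]+)M)?(?:([0-9]+)D)?$", x))[[1]]
  if (length(m) == 0L || x == "P") {
    stop(sprintf("unparseable ISO-8601 duration: '%s'", x), call. = FALSE)
  }
  num <- function(s) if (s == "") 0 else as.numeric(s)
  out <- c(years = num(m[2]), months = num(m[3]), days = num(m[4]))
  if (all(out == 0) && !grepl("0", x)) {
    stop(sprintf("unparseable ISO-8601 duration: '%s'", x), call. = FALSE)
  }
  out
}

is_iso8601_duration <- function(x) {
  vapply(x, function(s) {
    ok <- TRUE
    tryCatch(parse_iso8601_duration(s), error = function(e) ok <<- FALSE)
    ok
  }, logical(1), USE.NAMES = FALSE)
}

#' Round half away from zero to a fixed number of decimals
#'
#' Base `round()` rounds half to even; reported percentages here follow the
#' half-up convention (27.45 -> 27.5). A tiny epsilon absorbs binary
#' representation error so that values printed as x.x5 round up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Deterministic 31-bit hash of strings (polynomial rolling hash over UTF-8
# bytes, modulus 2^31 - 1). Exact in double arithmetic: state < 2^31 and
# state*31 + 255 < 2^53. Used to derive independent per-case RNG streams.
stable_hash <- function(...) {
  s <- paste(c(...), collapse = "\x1f")
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  mod <- 2147483647
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% mod
  as.integer(h)
}

# Evaluate `expr` under a private RNG stream without disturbing the caller's
# .Random.seed.
with_rng_stream <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

sha256_hex <- function(text) {
  digest::digest(enc2utf8(text), algo = "sha256", serialize = FALSE)
}

#' Append records to a JSONL file
#'
#' @param records list of named lists; one JSON object is written per element.
#' @param path output file; created if absent.
#' @keywords internal
append_jsonl <- function(records, path) {
  con <- file(path, open = "a", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in records) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Read a JSONL file into a list of records
#'
#' @param path file with one JSON object per line; blank lines are skipped.
#' @return list of named lists.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, comment.char = "#") {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = comment.char, fileEncoding = "UTF-8",
                    check.names = FALSE)
}

#' Languages covered by the shipped template packs and fixtures
#'
#' ISO 639-1 codes of the ten study languages: English, Chinese, Czech,
#' Dutch, French, German, Italian, Japanese, Spanish, Turkish.
#'
#' @return character vector of ten two-letter codes.
#' @export
study_languages <- function() {
  c("en", "zh", "cs", "nl", "fr", "de", "it", "ja", "es", "tr")
}
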