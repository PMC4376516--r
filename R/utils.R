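# Internal utilities: condition classes, date dialects, keyed tokens, seeds.

#' @importFrom stats quantile rbinom rlnorm runif sd setNames
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# All package errors carry class c("caresr_<kind>", "caresr_error", ...) so
# callers and tests can distinguish authorisation failures from lookup
# failures from bad parameters.
cares_abort <- function(msg, kind, call = sys.call(-1)) {
  stop(errorCondition(msg,
                      class = c(paste0("caresr_", kind), "caresr_error"),
                      call = call))
}

assert_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    cares_abort(sprintf("%s must be a non-empty string", what), "invalid_parameter")
  invisible(x)
}

assert_date <- function(x, what) {
  if (!inherits(x, "Date") || length(x) != 1L || is.na(x))
    cares_abort(sprintf("%s must be a single Date", what), "invalid_parameter")
  invisible(x)
}

as_cares_date <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(d)) cares_abort(sprintf("%s is not a valid ISO date", what), "invalid_parameter")
  d
}

## ---- date dialects -------------------------------------------------------

# Supported input dialects for date fields in source collections. The first
# two are the classic heterogeneous pair seen across administrative
# collections; the third is the canonical ISO form used internally.
CARES_DIALECTS <- c("DD/MM/YYYY" = "%d/%m/%Y",
                    "YYYYMMDD"   = "%Y%m%d",
                    "YYYY-MM-DD" = "%Y-%m-%d")

#' Date dialects understood by the loader
#'
#' @return Character vector of dialect names.
#' @export
cares_dialects <- function() names(CARES_DIALECTS)

dialect_format <- function(dialect) {
  fmt <- CARES_DIALECTS[dialect]
  if (anyNA(fmt)) cares_abort(sprintf("unknown date dialect '%s'", dialect), "schema_error")
  unname(fmt)
}

# Parse character dates in a declared dialect; invalid calendar dates
# (e.g. "31/02/2010") become NA, which the loader turns into row rejections.
# A strict round-trip check guards against lenient parsing of malformed input.
parse_dialect_dates <- function(x, dialect) {
  fmt <- dialect_format(dialect)
  d <- as.Date(as.character(x), format = fmt)
  ok <- !is.na(d) & format(d, fmt) == as.character(x)
  d[!ok] <- NA
  d
}

render_dialect_dates <- function(d, dialect) {
  out <- format(d, dialect_format(dialect))
  out[is.na(d)] <- NA_character_
  out
}

## ---- keyed tokens --------------------------------------------------------

# Keyed pseudorandom one-way transformation (HMAC-SHA256), rendered as hex
# and truncated to a fixed width. Used for CARES IDs, project person keys
# and stored password verifiers.
hmac_token <- function(key, message, nchar_out = 32L) {
  full <- vapply(message, function(m)
    digest::hmac(key = key, object = m, algo = "sha256"),
    character(1L), USE.NAMES = FALSE)
  substr(full, 1L, nchar_out)
}

is_hex_token <- function(x, nchar_out = 32L) {
  grepl(sprintf("^[0-9a-f]{%d}$", nchar_out), x)
}

## ---- seeds ---------------------------------------------------------------

# Generators take one integer seed; independent sub-streams (inclusion draws,
# record counts, field content, ...) are derived from it by keyed hashing so
# each sub-stream can be replayed on its own. Kept below 2^31 - 1.
sub_seed <- function(seed, label) {
  hex <- substr(digest::hmac(key = as.character(seed), object = label,
                             algo = "sha256"), 1L, 7L)
  strtoi(hex, base = 16L) %% .Machine$integer.max
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

random_hex <- function(n, width = 8L) {
  chars <- c(0:9, letters[1:6])
  vapply(seq_len(n), function(i)
    paste(sample(chars, width, replace = TRUE), collapse = ""), character(1L))
}

## ---- misc ----------------------------------------------------------------

new_df <- function(...) data.frame(..., stringsAsFactors = FALSE)

# Stable, content-derived row order for researcher-facing files: sort by
# person_key then by the concatenation of all rendered field values.
order_standardised <- function(df) {
  if (nrow(df) == 0L) return(integer(0))
  tiebreak <- do.call(paste, c(lapply(df, as.character), sep = "\x1f"))
  if ("person_key" %in% names(df)) order(df$person_key, tiebreak) else order(tiebreak)
}
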