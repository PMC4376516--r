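# Module step 6: uniform output files, layout description files, and
# quality/validity checking summaries.
#
# The canonical researcher-facing format is RFC-4180 CSV, UTF-8, LF line
# endings, header row; all dates rendered YYYYMMDD; missing values as empty
# fields; rows sorted by (person_key, stable content tiebreak). Because
# hub-mode extracts are emitted in this form directly, post-extraction
# standardisation becomes a no-op for them; classical-mode files in any
# collection dialect normalise to byte-identical output.

format_plain_number <- function(x) {
  vapply(x, function(v) if (is.na(v)) NA_character_ else
    format(v, scientific = FALSE, trim = TRUE), character(1))
}

# Find the one dialect under which every non-empty value of a character
# date column parses; canonical YYYYMMDD is tried first so standardised
# input is recognised as already canonical.
detect_date_dialect <- function(x, field) {
  vals <- x[!is.na(x) & nzchar(x)]
  if (length(vals) == 0L) return("YYYYMMDD")
  for (d in c("YYYYMMDD", setdiff(cares_dialects(), "YYYYMMDD"))) {
    if (!anyNA(parse_dialect_dates(vals, d))) return(d)
  }
  bad <- which(is.na(parse_dialect_dates(x, "YYYYMMDD")) & nzchar(x) & !is.na(x))[1]
  cares_abort(sprintf("field '%s', row %d: value '%s' is not a date in any known dialect",
                      field, bad, x[bad]), "standardisation_error")
}

#' Standardise extracted records to the canonical output form
#'
#' Coerces a record set — hub-canonical or classical-dialect — to the single
#' uniform output convention: fixed field order (the order of `types`),
#' dates rendered `YYYYMMDD`, numbers plainly formatted, categories as
#' canonical level labels, missing values as empty strings, rows sorted by
#' `(person_key, content tiebreak)`. Idempotent: standardising standardised
#' records is the identity.
#'
#' @param records Data frame of extracted records (typed or character).
#' @param types Named list/vector giving each output field's semantic type
#'   (`text`, `integer`, `numeric`, `date`, `category`), in canonical field
#'   order.
#' @param sort Sort rows into the canonical order.
#' @return Character data frame in canonical form.
#' @export
standardise <- function(records, types, sort = TRUE) {
  types <- as.list(types)
  if (!setequal(names(records), names(types)))
    cares_abort(sprintf("record fields (%s) do not match declared output fields (%s)",
                        paste(names(records), collapse = ","),
                        paste(names(types), collapse = ",")), "standardisation_error")
  out <- records[names(types)]
  for (fld in names(out)) {
    col <- out[[fld]]
    ftype <- types[[fld]]
    if (identical(ftype, "date")) {
      if (inherits(col, "Date")) {
        col <- format(col, "%Y%m%d")
      } else {
        col <- as.character(col)
        dialect <- detect_date_dialect(col, fld)
        parsed <- parse_dialect_dates(col, dialect)
        bad <- which(!is.na(col) & nzchar(col) & is.na(parsed))
        if (length(bad))
          cares_abort(sprintf("field '%s', row %d: value '%s' is not a valid %s date",
                              fld, bad[1], col[bad[1]], dialect), "standardisation_error")
        col <- format(parsed, "%Y%m%d")
      }
    } else if (identical(ftype, "integer") || identical(ftype, "numeric")) {
      if (!is.numeric(col)) {
        chr <- as.character(col)
        chr[!is.na(chr) & chr == ""] <- NA
        num <- suppressWarnings(as.numeric(chr))
        bad <- which(!is.na(chr) & is.na(num))
        if (length(bad))
          cares_abort(sprintf("field '%s', row %d: value '%s' is not numeric",
                              fld, bad[1], chr[bad[1]]), "standardisation_error")
        col <- num
      }
      col <- format_plain_number(col)
    } else {
      col <- as.character(col)
    }
    col[is.na(col)] <- ""
    out[[fld]] <- col
  }
  if (sort) out <- out[order_standardised(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- layout files --------------------------------------------------------

#' Build the layout (data dictionary) file for an extract
#'
#' One entry per output field, in exactly the output header order:
#' name, semantic type, format (`YYYYMMDD` for dates), category levels
#' where applicable, and a description. Derived fields are documented with
#' their generating expression.
#'
#' @param schema The collection's [collection_schema()].
#' @param steps The task's transform steps.
#' @param keep_record_token Whether the CARES ID column is retained.
#' @return Data frame with columns `field`, `type`, `format`, `levels`,
#'   `description`.
#' @export
make_layout <- function(schema, steps = list(), keep_record_token = FALSE) {
  entry <- function(field, type, levels = "", description = "") {
    fmt <- switch(type, date = "YYYYMMDD", integer = "integer",
                  numeric = "number", category = "label", "free text")
    new_df(field = field, type = type, format = fmt, levels = levels,
           description = description)
  }
  entries <- list(entry("person_key", "text",
                        description = "project-scoped person linkage key"))
  if (keep_record_token)
    entries <- c(entries, list(entry("cares_id", "text",
                                     description = "encrypted record token (QA use only)")))
  for (fld in schema$approved_items) {
    ftype <- schema_field_types(schema, fld)[[fld]]
    lev <- if (ftype == "category")
      paste(schema_levels(schema, fld), collapse = "|") else ""
    entries <- c(entries, list(entry(fld, ftype, lev,
                                     sprintf("%s field of collection %s", ftype,
                                             schema$collection_id))))
  }
  layout <- do.call(rbind, entries)
  for (i in seq_along(steps)) {
    step <- steps[[i]]
    p <- step$parameters
    if (step$kind == "field_map") {
      for (old in names(p$renames))
        layout$field[layout$field == old] <- p$renames[[old]]
    } else if (step$kind == "derived_field") {
      dtype <- switch(p$expr_kind, arith = "numeric", date_diff = "integer",
                      recode = "category")
      lev <- if (p$expr_kind == "recode")
        paste(sort(unique(unname(p$map))), collapse = "|") else ""
      layout <- rbind(layout, entry(p$name, dtype, lev, step_description(step)))
    }
  }
  rownames(layout) <- NULL
  layout
}

#' Write or read a layout file
#'
#' Delimited text with columns (field, type, format, levels, description);
#' parsing a written layout reproduces it exactly.
#'
#' @param layout From [make_layout()].
#' @param path File path.
#' @export
write_layout <- function(layout, path) {
  write.csv(layout, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  read.csv(path, colClasses = "character")
}

## ---- QA reports ----------------------------------------------------------

#' Build the quality/validity checking summary for one extract
#'
#' All counts are recomputed from the emitted output records, not copied
#' from engine state: key rows in, records matched, rows out, unmatched
#' CARES IDs ("missing records"), per-date-field coverage against the
#' task's date window, per-category-field level counts ("field
#' groupings"), per-field missing-value counts, and a structural
#' content-correctness checksum.
#'
#' @param key_rows Imported linkage-key rows.
#' @param retrieved Records as retrieved from the hub (with `cares_id`).
#' @param output The standardised output records.
#' @param task The [extraction_task()].
#' @param types Output field types (see [standardise()]).
#' @param unmatched CARES IDs from the key file with no hub record.
#' @return A `cares_qa` list.
#' @export
qa_report <- function(key_rows, retrieved, output, task, types,
                      unmatched = character(0)) {
  types <- as.list(types)
  rows_in <- nrow(key_rows)
  n_unmatched <- length(unmatched)
  out_fields <- names(output)

  date_fields <- out_fields[vapply(out_fields, function(f)
    identical(types[[f]], "date"), logical(1))]
  date_summary <- lapply(setNames(date_fields, date_fields), function(f) {
    d <- parse_dialect_dates(output[[f]], "YYYYMMDD")
    present <- d[!is.na(d)]
    oor <- if (is.null(task$date_window)) 0L
           else sum(present < task$date_window[1] | present > task$date_window[2])
    list(min = if (length(present)) format(min(present), "%Y%m%d") else NA_character_,
         max = if (length(present)) format(max(present), "%Y%m%d") else NA_character_,
         out_of_range = as.integer(oor))
  })

  cat_fields <- out_fields[vapply(out_fields, function(f)
    identical(types[[f]], "category"), logical(1))]
  category_counts <- lapply(setNames(cat_fields, cat_fields), function(f) {
    vals <- output[[f]][nzchar(output[[f]])]
    as.list(table(vals))
  })

  missing_counts <- vapply(output, function(col) sum(!nzchar(col)), integer(1))

  structure(list(
    task_id = task$task_id,
    rows_in = rows_in,
    rows_matched = nrow(retrieved),
    matched_key_rows = rows_in - n_unmatched,
    unmatched = n_unmatched,
    rows_out = nrow(output),
    date_coverage = date_summary,
    category_counts = category_counts,
    missing_counts = as.list(missing_counts),
    checksum = list(rows = nrow(output), fields = length(out_fields),
                    cells = nrow(output) * length(out_fields),
                    non_null = as.list(vapply(output, function(col)
                      sum(nzchar(col)), integer(1))))
  ), class = "cares_qa")
}

#' @export
print.cares_qa <- function(x, ...) {
  cat(sprintf("<QA %s: %d key rows in, %d records matched, %d out, %d missing record(s)>\n",
              x$task_id, x$rows_in, x$rows_matched, x$rows_out, x$unmatched))
  invisible(x)
}

## ---- output files --------------------------------------------------------

# RFC-4180 CSV writer with LF endings and quoted-when-needed fields via
# write.csv; identical record sets produce byte-identical files.
write_canonical_csv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an extract's three output files
#'
#' Records (CSV), layout (CSV) and QA summary (YAML) under a shared name
#' prefix.
#'
#' @param records Standardised records.
#' @param layout From [make_layout()].
#' @param qa From [qa_report()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the written paths.
#' @export
write_extract <- function(records, layout, qa, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, paste0(prefix, "_records.csv")),
             layout = file.path(dir, paste0(prefix, "_layout.csv")),
             qa = file.path(dir, paste0(prefix, "_qa.yaml")))
  write_canonical_csv(records, paths[["records"]])
  write_canonical_csv(layout, paths[["layout"]])
  yaml::write_yaml(unclass(qa), paths[["qa"]])
  paths
}
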