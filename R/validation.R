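# Parallel-run validation: compare a hub-mode extract against an
# independently produced reference extract and account for every
# discrepancy. This replicates go-live testing, where each project ran a
# hub version alongside the collection's own version and the files were
# compared to confirm that both had extracted the same records.

#' Default comparison key fields
#'
#' The researcher-facing extract carries no record-level token, so records
#' are identified by the person key plus all date fields (columns whose
#' non-empty values are all `YYYYMMDD`).
#'
#' @param df A standardised extract.
#' @return Character vector of key field names.
#' @export
default_key_fields <- function(df) {
  is_datecol <- vapply(names(df), function(nm) {
    v <- df[[nm]][nzchar(df[[nm]])]
    length(v) > 0L && all(grepl("^[0-9]{8}$", v))
  }, logical(1))
  unique(c(intersect("person_key", names(df)), names(df)[is_datecol]))
}

join_keys <- function(df, key_fields) {
  if (length(key_fields) == 0L) return(as.character(seq_len(nrow(df))))
  do.call(paste, c(df[key_fields], sep = "|"))
}

#' Compare two standardised extracts
#'
#' Matches records on `key_fields`, then diffs every other field on the
#' matched records. Reports records present in only one input, all
#' field-level mismatches (deterministically ordered by key then field),
#' and an overall verdict: `identical` iff all three discrepancy counts
#' are zero.
#'
#' @param A,B Standardised extracts with identical column sets.
#' @param key_fields Fields identifying a record; must be duplicate-free
#'   within each input. Defaults to [default_key_fields()].
#' @return A `cares_comparison` with `n_only_in_A`, `n_only_in_B`,
#'   `n_matched`, `only_in_A`/`only_in_B` (the unmatched rows),
#'   `field_mismatches` (`key`, `field`, `value_A`, `value_B`) and
#'   `verdict`.
#' @export
compare_extracts <- function(A, B, key_fields = default_key_fields(A)) {
  if (!setequal(names(A), names(B)))
    cares_abort("extracts have different field sets", "comparison_error")
  B <- B[names(A)]
  miss <- setdiff(key_fields, names(A))
  if (length(miss))
    cares_abort(sprintf("key field(s) not present: %s", paste(miss, collapse = ", ")),
                "comparison_error")
  ka <- join_keys(A, key_fields)
  kb <- join_keys(B, key_fields)
  for (side in list(list("A", ka), list("B", kb))) {
    dup <- unique(side[[2]][duplicated(side[[2]])])
    if (length(dup))
      cares_abort(sprintf("duplicate key(s) in input %s: %s", side[[1]],
                          paste(head(dup, 5L), collapse = "; ")), "comparison_error")
  }
  only_a <- !(ka %in% kb)
  only_b <- !(kb %in% ka)
  matched_keys <- sort(intersect(ka, kb))
  ia <- match(matched_keys, ka)
  ib <- match(matched_keys, kb)

  value_fields <- setdiff(names(A), key_fields)
  mism <- list()
  for (fld in value_fields) {
    va <- A[[fld]][ia]
    vb <- B[[fld]][ib]
    d <- which(va != vb)
    if (length(d))
      mism[[fld]] <- new_df(key = matched_keys[d], field = fld,
                            value_A = va[d], value_B = vb[d])
  }
  field_mismatches <- if (length(mism)) do.call(rbind, mism)
    else new_df(key = character(0), field = character(0),
                value_A = character(0), value_B = character(0))
  field_mismatches <- field_mismatches[order(field_mismatches$key,
                                             field_mismatches$field), , drop = FALSE]
  rownames(field_mismatches) <- NULL

  out_a <- A[only_a, , drop = FALSE]; rownames(out_a) <- NULL
  out_b <- B[only_b, , drop = FALSE]; rownames(out_b) <- NULL
  n_only_a <- sum(only_a); n_only_b <- sum(only_b)
  structure(list(key_fields = key_fields,
                 n_only_in_A = n_only_a, n_only_in_B = n_only_b,
                 n_matched = length(matched_keys),
                 only_in_A = out_a, only_in_B = out_b,
                 keys_only_in_A = sort(ka[only_a]), keys_only_in_B = sort(kb[only_b]),
                 field_mismatches = field_mismatches,
                 verdict = if (n_only_a + n_only_b + nrow(field_mismatches) == 0L)
                   "identical" else "discrepant"),
            class = "cares_comparison")
}

#' @export
print.cares_comparison <- function(x, ...) {
  cat(sprintf("<comparison: %s; matched %d; only in A %d; only in B %d; field mismatches %d>\n",
              x$verdict, x$n_matched, x$n_only_in_A, x$n_only_in_B,
              nrow(x$field_mismatches)))
  invisible(x)
}

#' Classify discrepancies by likely cause
#'
#' Assigns every discrepancy in a comparison report to exactly one cause
#' bucket, mirroring the causes observed in parallel-run testing:
#' whole-record absences with a date outside the task window are
#' `cut-off dates`; other whole-record absences are `exclusion criteria`;
#' field mismatches where one side is empty are `missing data`; other
#' single-field deltas are `script bugs`; anything unclassifiable is
#' `other`.
#'
#' @param report A `cares_comparison` from [compare_extracts()].
#' @param date_window Optional length-2 Date vector (the task's cut-off
#'   window) used to recognise date-window edge drops.
#' @return Named integer vector of counts per bucket.
#' @export
classify_discrepancies <- function(report, date_window = NULL) {
  stopifnot(inherits(report, "cares_comparison"))
  buckets <- c("cut-off dates" = 0L, "exclusion criteria" = 0L,
               "missing data" = 0L, "script bugs" = 0L, other = 0L)
  outside_window <- function(rows) {
    if (is.null(date_window) || nrow(rows) == 0L) return(rep(FALSE, nrow(rows)))
    date_cols <- names(rows)[vapply(rows, function(v)
      any(grepl("^[0-9]{8}$", v)), logical(1))]
    if (length(date_cols) == 0L) return(rep(FALSE, nrow(rows)))
    apply(rows[date_cols], 1L, function(vals) {
      d <- parse_dialect_dates(vals, "YYYYMMDD")
      any(!is.na(d) & (d < date_window[1] | d > date_window[2]))
    })
  }
  for (side in c("only_in_A", "only_in_B")) {
    rows <- report[[side]]
    if (nrow(rows) == 0L) next
    oow <- outside_window(rows)
    buckets[["cut-off dates"]] <- buckets[["cut-off dates"]] + sum(oow)
    buckets[["exclusion criteria"]] <- buckets[["exclusion criteria"]] + sum(!oow)
  }
  fm <- report$field_mismatches
  if (nrow(fm)) {
    empty_side <- !nzchar(fm$value_A) | !nzchar(fm$value_B)
    buckets[["missing data"]] <- sum(empty_side)
    buckets[["script bugs"]] <- sum(!empty_side)
  }
  buckets
}
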