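# The hub: registration of collections, loading of de-identified partial
# copies keyed by CARES IDs, the sender/recipient-only transfer space, and
# governed record retrieval.
#
# The hub holds, for each collection, only the approved subset of fields —
# never source UIDs, never demographics — with dates normalised to ISO
# calendar dates at load. At rest the hub is isolated, unlinked,
# de-identified information: no hub operation joins records across
# collections at the person level.

#' Create an empty hub
#'
#' The in-memory store behind all hub, governance and extraction
#' operations: collection registry and tables, user registry, access
#' grants, task approvals, workspaces, transfer space, escrow and the
#' append-only audit log.
#'
#' @return A `cares_hub` environment.
#' @export
cares_hub <- function() {
  hub <- new.env(parent = emptyenv())
  hub$schemas <- list()
  hub$tables <- list()
  hub$load_batch <- list()
  hub$users <- list()
  hub$passwords <- list()          # keyed verifiers, never clear text
  hub$pepper <- paste(random_hex(1L, 32L), collapse = "")
  hub$custodians <- new_df(user_id = character(0), collection_id = character(0))
  hub$grants <- new_df(user_id = character(0), collection_id = character(0),
                       granted_by = character(0), granted_on = as.Date(character(0)),
                       expires_on = as.Date(character(0)))
  hub$approvals <- new_df(task_id = character(0), collection_id = character(0),
                          approved_by = character(0), evidence = character(0),
                          approved_on = as.Date(character(0)))
  hub$tasks <- list()
  hub$workspaces <- list()
  hub$transfer <- list()
  hub$escrow <- new_escrow()
  hub$audit <- list()
  class(hub) <- "cares_hub"
  hub
}

#' @export
print.cares_hub <- function(x, ...) {
  cat(sprintf("<hub: %d collections, %d users, %d audit events>\n",
              length(x$schemas), length(x$users), length(x$audit)))
  invisible(x)
}

#' Register a collection on the hub
#'
#' Records the schema agreed with the custodian (approved items and date
#' dialects) and initialises an empty hub table for the collection.
#'
#' @param hub A [cares_hub()].
#' @param schema A [collection_schema()].
#' @return The hub, invisibly.
#' @export
register_collection <- function(hub, schema) {
  stopifnot(inherits(hub, "cares_hub"), inherits(schema, "cares_schema"))
  cid <- schema$collection_id
  if (cid %in% names(hub$schemas))
    cares_abort(sprintf("collection '%s' is already registered", cid), "conflict_error")
  hub$schemas[[cid]] <- schema
  hub$tables[[cid]] <- empty_hub_table(schema)
  hub$load_batch[[cid]] <- 0L
  audit_append(hub, "system", "register_collection", cid, "ok")
  invisible(hub)
}

#' @rdname register_collection
#' @export
list_collections <- function(hub) names(hub$schemas)

empty_hub_table <- function(schema) {
  out <- new_df(cares_id = character(0), load_batch = integer(0))
  for (fld in schema$approved_items) {
    ftype <- schema_field_types(schema, fld)[[fld]]
    out[[fld]] <- switch(ftype,
                         date = as.Date(character(0)),
                         integer = integer(0),
                         character(0))
  }
  out
}

hub_schema <- function(hub, collection_id) {
  s <- hub$schemas[[collection_id]]
  if (is.null(s))
    cares_abort(sprintf("collection '%s' is not registered", collection_id), "lookup_error")
  s
}

#' Inspect a collection's hub table
#'
#' Custodian-level view of one collection's stored partial copy. Contains
#' CARES IDs and approved content fields only; there is deliberately no
#' cross-collection, person-level counterpart.
#'
#' @param hub A [cares_hub()].
#' @param collection_id Registered collection code.
#' @return Data frame of stored service records.
#' @export
hub_table <- function(hub, collection_id) {
  hub_schema(hub, collection_id)
  hub$tables[[collection_id]]
}

## ---- loading -------------------------------------------------------------

# Parse and validate one source table against its schema. Returns typed
# rows plus a rejection ledger; row-level rejection keeps good rows loading.
validate_source_rows <- function(rows, schema) {
  expected_cols <- c(schema$source_uid_field, "root_id", schema$fields$name)
  unknown <- setdiff(names(rows), expected_cols)
  if (length(unknown))
    cares_abort(sprintf("unknown field(s) in source table: %s",
                        paste(unknown, collapse = ", ")), "schema_error")
  n <- nrow(rows)
  reject_reason <- rep(NA_character_, n)
  typed <- new_df(.uid = as.character(rows[[schema$source_uid_field]]))
  for (fld in schema$approved_items) {
    ftype <- schema_field_types(schema, fld)[[fld]]
    raw <- as.character(rows[[fld]])
    raw[!is.na(raw) & raw == ""] <- NA
    if (ftype == "date") {
      dialect <- schema$fields$dialect[schema$fields$name == fld]
      parsed <- parse_dialect_dates(ifelse(is.na(raw), "", raw), dialect)
      bad <- !is.na(raw) & is.na(parsed)
      reject_reason[bad & is.na(reject_reason)] <-
        sprintf("unparseable date in field '%s'", fld)
      parsed[is.na(raw)] <- NA
      typed[[fld]] <- parsed
    } else if (ftype == "integer") {
      parsed <- suppressWarnings(as.integer(raw))
      bad <- !is.na(raw) & is.na(parsed)
      reject_reason[bad & is.na(reject_reason)] <-
        sprintf("invalid integer in field '%s'", fld)
      typed[[fld]] <- parsed
    } else if (ftype == "category") {
      levels <- schema_levels(schema, fld)
      bad <- !is.na(raw) & !(raw %in% levels)
      reject_reason[bad & is.na(reject_reason)] <-
        sprintf("unknown category level in field '%s'", fld)
      typed[[fld]] <- raw
    } else {
      typed[[fld]] <- raw
    }
  }
  list(typed = typed, reject_reason = reject_reason)
}

#' Load a source update into the hub
#'
#' Implements the in-house loading contract: every stored row gets
#' `cares_id = encrypt_id(source_uid)`; only approved items are retained;
#' dates are normalised to canonical ISO form; rows violating the schema
#' (unparseable dates, invalid integers, unknown category levels) are
#' rejected individually and reported, unless `strict = TRUE` aborts the
#' whole load. `mode = "full"` replaces the table; `mode = "append"`
#' upserts on `cares_id` with the new value winning.
#'
#' @param hub A [cares_hub()].
#' @param collection_id Registered collection.
#' @param source_table A `cares_source_table` (or its `rows` data frame).
#' @param key The collection's [collection_key()]; must match.
#' @param mode `"full"` or `"append"`.
#' @param strict Abort on the first rejected row instead of skipping it.
#' @return Load report: `rows_in`, `rows_stored`, `rows_rejected`,
#'   `rejections` (row numbers and reasons), `load_batch`.
#' @export
load_update <- function(hub, collection_id, source_table, key,
                        mode = c("full", "append"), strict = FALSE) {
  mode <- match.arg(mode)
  schema <- hub_schema(hub, collection_id)
  if (!inherits(key, "cares_collection_key") ||
      !identical(key$collection_id, collection_id)) {
    audit_append(hub, "loader", "load_update", collection_id, "deny")
    cares_abort(sprintf("key does not match collection '%s': nothing loaded",
                        collection_id), "authorisation_error")
  }
  rows <- if (inherits(source_table, "cares_source_table")) source_table$rows
          else source_table
  v <- validate_source_rows(rows, schema)
  rejected <- !is.na(v$reject_reason)
  if (strict && any(rejected))
    cares_abort(sprintf("strict load aborted: %s (row %d)",
                        v$reject_reason[which(rejected)[1]], which(rejected)[1]),
                "schema_error")
  good <- v$typed[!rejected, , drop = FALSE]
  batch <- hub$load_batch[[collection_id]] + 1L
  stored <- new_df(cares_id = if (nrow(good)) encrypt_id(collection_id, good$.uid, key)
                              else character(0),
                   load_batch = rep(batch, nrow(good)))
  for (fld in schema$approved_items) stored[[fld]] <- good[[fld]]
  if (nrow(stored))
    escrow_record(hub$escrow, collection_id, stored$cares_id, good$.uid)

  if (mode == "full") {
    new_tbl <- stored
  } else {
    old <- hub$tables[[collection_id]]
    keep <- !(old$cares_id %in% stored$cares_id)
    new_tbl <- rbind(old[keep, , drop = FALSE], stored)
  }
  # deterministic at-rest order and byte-identical reloads
  new_tbl$load_batch <- if (mode == "full") rep(1L, nrow(new_tbl)) else new_tbl$load_batch
  new_tbl <- new_tbl[order(new_tbl$cares_id), , drop = FALSE]
  rownames(new_tbl) <- NULL
  hub$tables[[collection_id]] <- new_tbl
  hub$load_batch[[collection_id]] <- if (mode == "full") 1L else batch

  report <- list(collection_id = collection_id, mode = mode,
                 rows_in = nrow(rows), rows_stored = nrow(stored),
                 rows_rejected = sum(rejected),
                 rejections = new_df(row = which(rejected),
                                     reason = v$reject_reason[rejected]),
                 load_batch = hub$load_batch[[collection_id]])
  audit_append(hub, "loader", "load_update",
               sprintf("%s in=%d stored=%d rejected=%d", collection_id,
                       report$rows_in, report$rows_stored, report$rows_rejected), "ok")
  report
}

## ---- transfer space ------------------------------------------------------

#' Deposit and read files in the transfer space
#'
#' Models the restricted transfer partition: a deposited item can be read
#' only by its sender and intended recipient, and every read is audited.
#'
#' @param hub A [cares_hub()].
#' @param sender,recipient,user Registered user ids.
#' @param name Item name.
#' @param payload Arbitrary R object (file contents).
#' @param receipt Value returned by `place_transfer()`.
#' @return `place_transfer()` a receipt id; `read_transfer()` the payload.
#' @export
place_transfer <- function(hub, sender, recipient, name, payload) {
  lookup_user(hub, sender); lookup_user(hub, recipient)
  receipt <- sprintf("T%05d", length(hub$transfer) + 1L)
  hub$transfer[[receipt]] <- list(sender = sender, recipient = recipient,
                                  name = name, payload = payload,
                                  deposited = Sys.time())
  audit_append(hub, sender, "place_transfer", sprintf("%s -> %s: %s", sender,
                                                      recipient, name), "ok")
  receipt
}

#' @rdname place_transfer
#' @export
read_transfer <- function(hub, user, receipt) {
  lookup_user(hub, user)
  item <- hub$transfer[[receipt]]
  if (is.null(item))
    cares_abort(sprintf("no transfer item '%s'", receipt), "lookup_error")
  if (!user %in% c(item$sender, item$recipient)) {
    audit_append(hub, user, "read_transfer", receipt, "deny")
    cares_abort(sprintf("transfer item '%s' is readable only by its sender and recipient",
                        receipt), "authorisation_error")
  }
  audit_append(hub, user, "read_transfer", receipt, "allow")
  item$payload
}

## ---- retrieval -----------------------------------------------------------

#' Retrieve service records by CARES ID
#'
#' Governed record retrieval: access is checked against all three tiers
#' (confidentiality, dataset grant, task approval) before any data is
#' touched. Returns exactly the stored records whose `cares_id` is in the
#' request, sorted by token; requested ids with no stored record are
#' reported separately, never silently dropped.
#'
#' @param hub A [cares_hub()].
#' @param user_id Requesting user.
#' @param collection_id Registered collection.
#' @param cares_ids Character vector of CARES ID tokens.
#' @param task_id The approved task under which records are requested.
#' @param on_date Date of the request (governance evaluation date).
#' @return List with `records` (data frame) and `unmatched` (character).
#' @export
query_records <- function(hub, user_id, collection_id, cares_ids, task_id,
                          on_date = Sys.Date()) {
  decision <- check_access(hub, user_id, collection_id, task_id, on_date)
  if (decision$decision != "allow")
    cares_abort(sprintf("access denied for user '%s' on collection '%s': %s",
                        user_id, collection_id, decision$reason),
                "authorisation_error")
  tbl <- hub_table(hub, collection_id)
  cares_ids <- unique(as.character(cares_ids))
  hit <- tbl[tbl$cares_id %in% cares_ids, , drop = FALSE]
  hit <- hit[order(hit$cares_id), , drop = FALSE]
  rownames(hit) <- NULL
  audit_append(hub, user_id, "query_records",
               sprintf("%s task=%s n=%d", collection_id, task_id, nrow(hit)), "ok")
  list(records = hit, unmatched = setdiff(cares_ids, tbl$cares_id))
}
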