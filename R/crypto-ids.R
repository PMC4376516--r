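# CARES ID scheme: keyed one-way encryption of collection source UIDs at
# load time, plus the separately-authorised decrypt-and-forward bridge.
#
# Loading software can encrypt but not decrypt: ordinary users hold no path
# from a CARES ID back to the source UID. Linkage officers can cross the
# bridge because loading escrows the forward mapping; decryption therefore
# requires BOTH the escrow store and the linkage-officer role.

CARES_ID_NCHAR <- 32L

#' Create a collection encryption key
#'
#' Key material is held by the collection's custodian authority and is used
#' only at load time to derive CARES IDs from source record identifiers.
#' Keys are never written into hub tables, extracts, QA reports or logs.
#'
#' @param collection_id Short collection code.
#' @param secret Key material (non-empty string). If `NULL`, random material
#'   is drawn from the current RNG stream.
#' @param holder Authority role holding the key.
#' @return A `cares_collection_key` object.
#' @export
collection_key <- function(collection_id, secret = NULL, holder = "custodian") {
  assert_scalar_chr(collection_id, "collection_id")
  if (is.null(secret)) secret <- paste(random_hex(1L, 48L), collapse = "")
  if (!is.character(secret) || length(secret) != 1L || !nzchar(secret))
    cares_abort("collection key material must be a non-empty string", "configuration_error")
  structure(list(collection_id = collection_id, secret = secret, holder = holder),
            class = "cares_collection_key")
}

#' @export
print.cares_collection_key <- function(x, ...) {
  cat(sprintf("<collection key: %s, holder: %s, material: <withheld>>\n",
              x$collection_id, x$holder))
  invisible(x)
}

#' @export
format.cares_collection_key <- function(x, ...) {
  sprintf("<collection key: %s (material withheld)>", x$collection_id)
}

#' Encrypt source record identifiers into CARES IDs
#'
#' Deterministic keyed one-way transformation: the same
#' (collection, source UID, key) always yields the same fixed-length token,
#' and no hub or extraction API maps a token back to its UID. Vectorised
#' over `source_uid`.
#'
#' @param collection_id Collection the UIDs belong to.
#' @param source_uid Character vector of source record identifiers.
#' @param key The collection's [collection_key()].
#' @return Character vector of 32-character lowercase hex tokens.
#' @export
encrypt_id <- function(collection_id, source_uid, key) {
  assert_scalar_chr(collection_id, "collection_id")
  if (!inherits(key, "cares_collection_key"))
    cares_abort("key must be a cares_collection_key", "invalid_parameter")
  if (!identical(key$collection_id, collection_id))
    cares_abort(sprintf("key for collection '%s' cannot encrypt IDs of collection '%s'",
                        key$collection_id, collection_id), "authorisation_error")
  source_uid <- as.character(source_uid)
  if (length(source_uid) == 0L) return(character(0))
  if (anyNA(source_uid) || any(!nzchar(source_uid)))
    cares_abort("source_uid values must be non-empty", "invalid_input")
  hmac_token(key$secret, paste0(collection_id, "\x1f", source_uid), CARES_ID_NCHAR)
}

## ---- escrow --------------------------------------------------------------

# Forward mapping CARES ID -> source UID, written at load time and retained
# by the bridge authority only. Implemented as one environment per
# collection so lookups are O(1) and the store can be detached wholesale.

new_escrow <- function() {
  e <- new.env(parent = emptyenv())
  class(e) <- "cares_escrow"
  e
}

escrow_record <- function(escrow, collection_id, cares_ids, source_uids) {
  stopifnot(inherits(escrow, "cares_escrow"))
  if (!exists(collection_id, envir = escrow, inherits = FALSE))
    assign(collection_id, new.env(parent = emptyenv()), envir = escrow)
  coll <- get(collection_id, envir = escrow, inherits = FALSE)
  for (i in seq_along(cares_ids)) assign(cares_ids[i], source_uids[i], envir = coll)
  invisible(escrow)
}

#' Decrypt CARES IDs through the linkage-officer bridge
#'
#' The only sanctioned path from CARES IDs back to source record
#' identifiers. The caller must hold the linkage-officer role and the
#' escrowed forward mapping must be available; removing either makes
#' decryption impossible. Every call is written to the audit log with the
#' caller's identity and the number of IDs decrypted.
#'
#' @param hub A [cares_hub()] (for the user registry and audit log).
#' @param user_id Identity of the caller.
#' @param cares_ids Character vector of CARES ID tokens to decrypt.
#' @param escrow The escrow store; defaults to the hub's own. Passing a
#'   detached or empty store models loss of the escrow.
#' @return Named character vector mapping CARES ID to source UID.
#' @export
bridge_decrypt <- function(hub, user_id, cares_ids, escrow = hub$escrow) {
  stopifnot(inherits(hub, "cares_hub"))
  user <- lookup_user(hub, user_id)
  if (!"linkage-officer" %in% user$roles) {
    audit_append(hub, user_id, "bridge_decrypt", sprintf("n=%d", length(cares_ids)), "deny")
    cares_abort(sprintf("user '%s' does not hold the linkage-officer role", user_id),
                "authorisation_error")
  }
  if (is.null(escrow) || !inherits(escrow, "cares_escrow")) {
    audit_append(hub, user_id, "bridge_decrypt", sprintf("n=%d", length(cares_ids)), "error")
    cares_abort("escrow store unavailable: CARES IDs cannot be decrypted",
                "configuration_error")
  }
  out <- character(length(cares_ids))
  found <- logical(length(cares_ids))
  colls <- ls(escrow, all.names = TRUE)
  for (i in seq_along(cares_ids)) {
    for (cid in colls) {
      coll <- get(cid, envir = escrow, inherits = FALSE)
      if (exists(cares_ids[i], envir = coll, inherits = FALSE)) {
        out[i] <- get(cares_ids[i], envir = coll, inherits = FALSE)
        found[i] <- TRUE
        break
      }
    }
  }
  if (any(!found)) {
    audit_append(hub, user_id, "bridge_decrypt", sprintf("n=%d", length(cares_ids)), "error")
    cares_abort(sprintf("no escrowed mapping for CARES ID(s): %s",
                        paste(cares_ids[!found], collapse = ", ")), "lookup_error")
  }
  audit_append(hub, user_id, "bridge_decrypt", sprintf("n=%d", length(cares_ids)), "allow")
  setNames(out, cares_ids)
}

## ---- key files -----------------------------------------------------------

#' Write or read a collection key file
#'
#' Structured text (YAML) holding the collection id and key material. Key
#' files belong with the custodian authority and must never be co-located
#' with hub tables or extract outputs.
#'
#' @param key A [collection_key()].
#' @param path File path.
#' @return `read_collection_key()` returns a `cares_collection_key`.
#' @export
write_collection_key <- function(key, path) {
  stopifnot(inherits(key, "cares_collection_key"))
  yaml::write_yaml(list(collection_id = key$collection_id,
                        holder = key$holder,
                        secret = key$secret), path)
  invisible(path)
}

#' @rdname write_collection_key
#' @export
read_collection_key <- function(path) {
  if (!file.exists(path)) cares_abort(sprintf("key file '%s' not found", path), "io_error")
  x <- yaml::read_yaml(path)
  collection_key(x$collection_id, x$secret, x$holder %||% "custodian")
}
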