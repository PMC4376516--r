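# Three-tier access governance, project workspaces, and the append-only
# audit log.
#
# Access to collection data requires all of: (1) a signed confidentiality
# agreement, (2) an unexpired custodian grant for the dataset, and
# (3) custodian approval of the specific task. Tiers are evaluated in that
# fixed order so deny reasons are deterministic; everything is audited.

## ---- users ---------------------------------------------------------------

CARES_ROLES <- c("cares-user", "linkage-officer", "custodian",
                 "client-services-analyst")

#' Register a hub user
#'
#' @param hub A [cares_hub()].
#' @param user_id Unique user id.
#' @param roles Subset of `cares-user`, `linkage-officer`, `custodian`,
#'   `client-services-analyst` (non-empty).
#' @param password Clear-text password, stored only as a keyed verifier.
#' @param confidentiality_signed Optional date the standard confidentiality
#'   agreement was signed.
#' @return The hub, invisibly.
#' @export
register_user <- function(hub, user_id, roles, password,
                          confidentiality_signed = NULL) {
  stopifnot(inherits(hub, "cares_hub"))
  assert_scalar_chr(user_id, "user_id")
  if (user_id %in% names(hub$users))
    cares_abort(sprintf("user '%s' already registered", user_id), "conflict_error")
  if (length(roles) == 0L || !all(roles %in% CARES_ROLES))
    cares_abort(sprintf("roles must be a non-empty subset of: %s",
                        paste(CARES_ROLES, collapse = ", ")), "invalid_parameter")
  assert_scalar_chr(password, "password")
  if (!is.null(confidentiality_signed))
    confidentiality_signed <- as_cares_date(confidentiality_signed)
  hub$users[[user_id]] <- list(user_id = user_id, roles = roles,
                               confidentiality_signed = confidentiality_signed)
  hub$passwords[[user_id]] <- hmac_token(hub$pepper, paste0(user_id, "\x1f", password))
  audit_append(hub, "system", "register_user", user_id, "ok")
  invisible(hub)
}

lookup_user <- function(hub, user_id) {
  u <- hub$users[[user_id]]
  if (is.null(u))
    cares_abort(sprintf("user '%s' is not registered", user_id), "lookup_error")
  u
}

#' Record a user's signed confidentiality agreement
#'
#' @inheritParams register_user
#' @param signed_on Date of signature.
#' @export
sign_confidentiality <- function(hub, user_id, signed_on) {
  u <- lookup_user(hub, user_id)
  u$confidentiality_signed <- as_cares_date(signed_on)
  hub$users[[user_id]] <- u
  audit_append(hub, user_id, "sign_confidentiality", format(u$confidentiality_signed), "ok")
  invisible(hub)
}

#' Assign a custodian to a collection
#'
#' Custodianship is per collection and shareable: a collection may have
#' several custodians, each able to issue grants and task approvals for it.
#'
#' @inheritParams register_user
#' @param collection_id Registered collection.
#' @export
assign_custodian <- function(hub, user_id, collection_id) {
  u <- lookup_user(hub, user_id)
  hub_schema(hub, collection_id)
  if (!"custodian" %in% u$roles)
    cares_abort(sprintf("user '%s' does not hold the custodian role", user_id),
                "authorisation_error")
  hub$custodians <- rbind(hub$custodians,
                          new_df(user_id = user_id, collection_id = collection_id))
  audit_append(hub, user_id, "assign_custodian", collection_id, "ok")
  invisible(hub)
}

is_custodian_of <- function(hub, user_id, collection_id) {
  any(hub$custodians$user_id == user_id &
        hub$custodians$collection_id == collection_id)
}

## ---- grants and approvals ------------------------------------------------

#' Grant a user access to a dataset
#'
#' Tier two of the access framework: per-user, per-collection approval by
#' the collection's custodian, with an optional expiry date. A grant is
#' valid from `granted_on` through `expires_on` inclusive.
#'
#' @inheritParams register_user
#' @param collection_id Registered collection.
#' @param granted_by Custodian of that collection.
#' @param granted_on Grant date.
#' @param expires_on Optional inclusive expiry date (`NA` = no expiry).
#' @export
grant_access <- function(hub, user_id, collection_id, granted_by,
                         granted_on, expires_on = NA) {
  lookup_user(hub, user_id)
  hub_schema(hub, collection_id)
  if (!is_custodian_of(hub, granted_by, collection_id))
    cares_abort(sprintf("'%s' is not a custodian of collection '%s'",
                        granted_by, collection_id), "authorisation_error")
  granted_on <- as_cares_date(granted_on)
  expires_on <- if (length(expires_on) == 1L && is.na(expires_on)) as.Date(NA)
                else as_cares_date(expires_on)
  hub$grants <- rbind(hub$grants,
                      new_df(user_id = user_id, collection_id = collection_id,
                             granted_by = granted_by, granted_on = granted_on,
                             expires_on = expires_on))
  audit_append(hub, granted_by, "grant_access",
               sprintf("%s on %s", user_id, collection_id), "ok")
  invisible(hub)
}

#' Revoke a user's dataset grants
#'
#' Takes effect immediately: the next access check re-evaluates the grant
#' table with no caching.
#'
#' @inheritParams grant_access
#' @export
revoke_access <- function(hub, user_id, collection_id) {
  keep <- !(hub$grants$user_id == user_id & hub$grants$collection_id == collection_id)
  hub$grants <- hub$grants[keep, , drop = FALSE]
  audit_append(hub, "system", "revoke_access",
               sprintf("%s on %s", user_id, collection_id), "ok")
  invisible(hub)
}

#' Register an extraction task with the hub
#'
#' @inheritParams register_user
#' @param task An [extraction_task()].
#' @export
register_task <- function(hub, task) {
  stopifnot(inherits(task, "cares_task"))
  hub$tasks[[task$task_id]] <- task
  audit_append(hub, "system", "register_task", task$task_id, "ok")
  invisible(hub)
}

#' Approve data use for one task and collection
#'
#' Tier three: per-task custodian approval of data use. The approval
#' evidence may be informal (e.g. a confirmation email) and is stored with
#' the task.
#'
#' @inheritParams register_user
#' @param task_id Registered task.
#' @param collection_id Collection being approved for the task.
#' @param approved_by Custodian of that collection.
#' @param evidence Free-text evidence reference.
#' @param approved_on Approval date.
#' @export
approve_task <- function(hub, task_id, collection_id, approved_by,
                         evidence = "email of confirmation",
                         approved_on = Sys.Date()) {
  if (is.null(hub$tasks[[task_id]]))
    cares_abort(sprintf("task '%s' is not registered", task_id), "lookup_error")
  hub_schema(hub, collection_id)
  if (!is_custodian_of(hub, approved_by, collection_id))
    cares_abort(sprintf("'%s' is not a custodian of collection '%s'",
                        approved_by, collection_id), "authorisation_error")
  hub$approvals <- rbind(hub$approvals,
                         new_df(task_id = task_id, collection_id = collection_id,
                                approved_by = approved_by, evidence = evidence,
                                approved_on = as_cares_date(approved_on)))
  audit_append(hub, approved_by, "approve_task",
               sprintf("%s on %s", task_id, collection_id), "ok")
  invisible(hub)
}

## ---- the access decision -------------------------------------------------

#' Evaluate the three-tier access decision
#'
#' Allows iff all of: the user signed the confidentiality agreement on or
#' before `on_date`; an unexpired dataset grant for (user, collection)
#' covers `on_date`; and a task approval exists for (task, collection).
#' Tiers are evaluated confidentiality, then grant, then approval, and the
#' first failing tier is the deny reason. Unknown users, collections or
#' tasks raise lookup errors, distinct from deny.
#'
#' @inheritParams register_user
#' @param collection_id Registered collection.
#' @param task_id Registered task.
#' @param on_date Evaluation date.
#' @return List with `decision` (`"allow"`/`"deny"`) and `reason` (`NULL`
#'   or one of `no-confidentiality`, `no-dataset-grant`, `grant-expired`,
#'   `no-task-approval`).
#' @export
check_access <- function(hub, user_id, collection_id, task_id,
                         on_date = Sys.Date()) {
  user <- lookup_user(hub, user_id)
  hub_schema(hub, collection_id)
  if (is.null(hub$tasks[[task_id]]))
    cares_abort(sprintf("task '%s' is not registered", task_id), "lookup_error")
  on_date <- as_cares_date(on_date)

  reason <- NULL
  if (is.null(user$confidentiality_signed) || user$confidentiality_signed > on_date) {
    reason <- "no-confidentiality"
  } else {
    g <- hub$grants[hub$grants$user_id == user_id &
                      hub$grants$collection_id == collection_id, , drop = FALSE]
    g <- g[g$granted_on <= on_date, , drop = FALSE]
    if (nrow(g) == 0L) {
      reason <- "no-dataset-grant"
    } else if (!any(is.na(g$expires_on) | g$expires_on >= on_date)) {
      reason <- "grant-expired"
    } else if (!any(hub$approvals$task_id == task_id &
                      hub$approvals$collection_id == collection_id)) {
      reason <- "no-task-approval"
    }
  }
  decision <- if (is.null(reason)) "allow" else "deny"
  audit_append(hub, user_id, "check_access",
               sprintf("%s task=%s", collection_id, task_id),
               if (is.null(reason)) "allow" else paste0("deny:", reason))
  list(decision = decision, reason = reason)
}

## ---- workspaces ----------------------------------------------------------

#' Create a project workspace
#'
#' Models the restricted project folder: only users approved for the task
#' may read or write its contents.
#'
#' @inheritParams register_user
#' @param task_id Registered task.
#' @param approved_users User ids approved by custodians for this project.
#' @export
create_workspace <- function(hub, task_id, approved_users) {
  if (is.null(hub$tasks[[task_id]]))
    cares_abort(sprintf("task '%s' is not registered", task_id), "lookup_error")
  for (u in approved_users) lookup_user(hub, u)
  hub$workspaces[[task_id]] <- list(approved_users = approved_users,
                                    contents = list())
  audit_append(hub, "system", "create_workspace", task_id, "ok")
  invisible(hub)
}

workspace_gate <- function(hub, user_id, task_id, action) {
  lookup_user(hub, user_id)
  ws <- hub$workspaces[[task_id]]
  if (is.null(ws))
    cares_abort(sprintf("no workspace for task '%s'", task_id), "lookup_error")
  if (!user_id %in% ws$approved_users) {
    audit_append(hub, user_id, action, task_id, "deny")
    cares_abort(sprintf("user '%s' is not approved for the workspace of task '%s'",
                        user_id, task_id), "authorisation_error")
  }
  ws
}

#' @rdname create_workspace
#' @param name Item name within the workspace.
#' @param value Item contents.
#' @export
workspace_write <- function(hub, user_id, task_id, name, value) {
  ws <- workspace_gate(hub, user_id, task_id, "workspace_write")
  ws$contents[[name]] <- value
  hub$workspaces[[task_id]] <- ws
  audit_append(hub, user_id, "workspace_write", sprintf("%s/%s", task_id, name), "allow")
  invisible(hub)
}

#' @rdname create_workspace
#' @export
workspace_read <- function(hub, user_id, task_id) {
  ws <- workspace_gate(hub, user_id, task_id, "workspace_read")
  audit_append(hub, user_id, "workspace_read", task_id, "allow")
  ws$contents
}

## ---- audit log -----------------------------------------------------------

#' Append to and verify the audit log
#'
#' The log is append-only with strictly increasing, gap-free sequence
#' numbers; `audit_verify()` detects any deletion or reordering and reports
#' the first broken position.
#'
#' @inheritParams register_user
#' @param actor,action,subject,outcome Event fields.
#' @export
audit_append <- function(hub, actor, action, subject, outcome) {
  stopifnot(inherits(hub, "cares_hub"))
  seq_no <- length(hub$audit) + 1L
  hub$audit[[seq_no]] <- list(seq = seq_no, timestamp = Sys.time(),
                              actor = actor, action = action,
                              subject = subject, outcome = outcome)
  invisible(hub)
}

#' @rdname audit_append
#' @export
audit_log <- function(hub) {
  if (length(hub$audit) == 0L)
    return(new_df(seq = integer(0), actor = character(0), action = character(0),
                  subject = character(0), outcome = character(0)))
  do.call(rbind, lapply(hub$audit, function(e)
    new_df(seq = e$seq, actor = e$actor, action = e$action,
           subject = e$subject, outcome = e$outcome)))
}

#' @rdname audit_append
#' @param log A data frame as returned by `audit_log()`.
#' @return `audit_verify()`: list with `ok` and, when broken, `position`
#'   (the first sequence position violated).
#' @export
audit_verify <- function(log) {
  expected <- seq_len(nrow(log))
  bad <- which(log$seq != expected)
  if (length(bad) == 0L) list(ok = TRUE, n = nrow(log))
  else list(ok = FALSE, position = expected[bad[1]])
}
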