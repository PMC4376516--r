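# The per-collection extraction "module" procedure:
#   1. authenticate the operator;
#   2. import the file of CARES IDs and project linkage keys;
#   3. retrieve the applicable records from the hub;
#   4. append the linkage keys to the retrieved records;
#   5. run optional field mapping, filtering, exclusions and derived fields;
#   6. emit the standardised file, layout file and QA summary.
#
# The same record path can run in classical mode, which renders each
# collection's output in that collection's own dialect (date format, field
# order, delimiter) with a simulated completion delay — the heterogeneous
# fan-out baseline that standardisation and the turnaround metrics are
# demonstrated against.

## ---- sessions ------------------------------------------------------------

#' Authenticate an operator against the hub registry
#'
#' Failures are audited and produce one indistinguishable message whether
#' the user is unknown or the password wrong (no account enumeration).
#'
#' @param hub A [cares_hub()].
#' @param user_id,password Credentials.
#' @return A `cares_session` bound to the user.
#' @export
authenticate <- function(hub, user_id, password) {
  stopifnot(inherits(hub, "cares_hub"))
  ok <- user_id %in% names(hub$users) &&
    identical(hub$passwords[[user_id]],
              hmac_token(hub$pepper, paste0(user_id, "\x1f", password)))
  if (!ok) {
    audit_append(hub, user_id, "authenticate", "login", "deny")
    cares_abort("invalid credentials", "authentication_error")
  }
  audit_append(hub, user_id, "authenticate", "login", "allow")
  structure(list(user_id = user_id, token = random_hex(1L, 16L),
                 created = Sys.time()),
            class = "cares_session")
}

## ---- tasks and transform steps ------------------------------------------

#' Define an extraction task
#'
#' A project's formal request: the collections to extract, the linkage-key
#' file per collection, the ordered optional transform steps, and request
#' metadata.
#'
#' @param task_id,project_id Identifiers.
#' @param collection_ids Collections to extract.
#' @param key_files Named list (by collection) of key-file paths or data
#'   frames with columns `cares_id`, `person_key`.
#' @param steps Ordered list of transform steps ([step_filter()] etc.).
#' @param requested_on Formal request date.
#' @param date_window Optional length-2 Date vector; the task's date
#'   coverage window used by QA reporting.
#' @param mode `"cares"` or `"classical"`.
#' @return A `cares_task`.
#' @export
extraction_task <- function(task_id, project_id, collection_ids, key_files,
                            steps = list(), requested_on = Sys.Date(),
                            date_window = NULL, mode = c("cares", "classical")) {
  assert_scalar_chr(task_id, "task_id")
  assert_scalar_chr(project_id, "project_id")
  mode <- match.arg(mode)
  if (!all(collection_ids %in% names(key_files)))
    cares_abort("every collection in the task needs a key file", "configuration_error")
  for (s in steps) stopifnot(inherits(s, "cares_step"))
  if (!is.null(date_window)) date_window <- as_cares_date(date_window, "date_window")
  structure(list(task_id = task_id, project_id = project_id,
                 collection_ids = collection_ids, key_files = key_files,
                 steps = steps, requested_on = as_cares_date(requested_on),
                 completed_on = NULL, date_window = date_window, mode = mode),
            class = "cares_task")
}

#' @export
print.cares_task <- function(x, ...) {
  cat(sprintf("<task %s (project %s): %s; %d step(s); requested %s>\n",
              x$task_id, x$project_id, paste(x$collection_ids, collapse = ", "),
              length(x$steps), format(x$requested_on)))
  invisible(x)
}

new_step <- function(kind, parameters) {
  structure(list(kind = kind, parameters = parameters), class = "cares_step")
}

CARES_COMPARATORS <- c("=", "!=", "<", "<=", ">", ">=", "in", "date-range")

check_comparator <- function(op, value) {
  if (!op %in% CARES_COMPARATORS)
    cares_abort(sprintf("comparator must be one of: %s",
                        paste(CARES_COMPARATORS, collapse = " ")), "invalid_parameter")
  if (op == "date-range" && length(value) != 2L)
    cares_abort("date-range requires a length-2 value (from, to)", "invalid_parameter")
}

#' Transform steps
#'
#' The closed, deterministic step set available to extraction tasks:
#' `step_field_map()` renames output fields and/or recodes values;
#' `step_filter()` keeps rows matching a predicate; `step_exclusion()`
#' removes them; `step_derived()` adds a field computed by restricted
#' arithmetic, a date difference in days or whole years, or a categorical
#' recode. Steps never see source UIDs or demographics — those are absent
#' by construction.
#'
#' @param renames Named character vector, old name -> new name.
#' @param recodes Named list: field -> named character map of value recodes.
#' @return A `cares_step`.
#' @export
step_field_map <- function(renames = NULL, recodes = NULL) {
  new_step("field_map", list(renames = as.list(renames %||% list()),
                             recodes = lapply(recodes %||% list(), unlist)))
}

#' @rdname step_field_map
#' @param field Field the predicate applies to.
#' @param op Comparator: one of `=`, `!=`, `<`, `<=`, `>`, `>=`, `in`,
#'   `date-range`.
#' @param value Literal (length 2 for `date-range`, any length for `in`).
#' @export
step_filter <- function(field, op, value) {
  check_comparator(op, value)
  new_step("filter", list(field = field, op = op, value = value))
}

#' @rdname step_field_map
#' @export
step_exclusion <- function(field, op, value) {
  check_comparator(op, value)
  new_step("exclusion", list(field = field, op = op, value = value))
}

# restricted arithmetic: only + - * / ( ) over field names and numbers
check_arith_expression <- function(expression) {
  expr <- tryCatch(parse(text = expression)[[1]],
                   error = function(e) cares_abort(
                     sprintf("cannot parse derived-field expression '%s'", expression),
                     "invalid_parameter"))
  walk <- function(e) {
    if (is.call(e)) {
      fn <- as.character(e[[1]])
      if (!fn %in% c("+", "-", "*", "/", "("))
        cares_abort(sprintf("derived-field expressions allow only + - * / ( ): found '%s'",
                            fn), "invalid_parameter")
      for (a in as.list(e)[-1]) walk(a)
    } else if (!is.name(e) && !is.numeric(e)) {
      cares_abort("derived-field expressions may contain only field names and numbers",
                  "invalid_parameter")
    }
  }
  walk(expr)
  all.vars(expr)
}

#' @rdname step_field_map
#' @param name Name of the new derived field.
#' @param kind `"arith"`, `"date_diff"` or `"recode"`.
#' @param expression Arithmetic expression over numeric fields
#'   (`kind = "arith"`).
#' @param field_a,field_b Date fields for `kind = "date_diff"`
#'   (computes `field_a - field_b`).
#' @param unit `"days"` or `"years"` (whole years, `floor(days / 365.25)`).
#' @param map Named character map for `kind = "recode"`.
#' @export
step_derived <- function(name, kind = c("arith", "date_diff", "recode"),
                         expression = NULL, field_a = NULL, field_b = NULL,
                         unit = c("days", "years"), field = NULL, map = NULL) {
  kind <- match.arg(kind)
  assert_scalar_chr(name, "derived field name")
  p <- switch(kind,
    arith = {
      vars <- check_arith_expression(expression)
      list(name = name, expr_kind = "arith", expression = expression, fields = vars)
    },
    date_diff = list(name = name, expr_kind = "date_diff", field_a = field_a,
                     field_b = field_b, unit = match.arg(unit)),
    recode = list(name = name, expr_kind = "recode", field = field, map = unlist(map)))
  new_step("derived_field", p)
}

step_description <- function(step) {
  p <- step$parameters
  switch(step$kind,
    field_map = sprintf("field map (%d rename(s), %d recode(s))",
                        length(p$renames), length(p$recodes)),
    filter = sprintf("keep rows where %s %s %s", p$field, p$op,
                     paste(p$value, collapse = ",")),
    exclusion = sprintf("exclude rows where %s %s %s", p$field, p$op,
                        paste(p$value, collapse = ",")),
    derived_field = switch(p$expr_kind,
      arith = sprintf("derived: %s = %s", p$name, p$expression),
      date_diff = sprintf("derived: %s = %s - %s (%s)", p$name, p$field_a,
                          p$field_b, p$unit),
      recode = sprintf("derived: %s = recode(%s)", p$name, p$field)))
}

## ---- key-file import -----------------------------------------------------

#' Import a project linkage-key file
#'
#' The documented two-column format: CSV with header `cares_id,person_key`.
#' Exact duplicate rows are dropped with a warning count; malformed rows
#' (ill-formed CARES ID token, empty person key) are rejected into the
#' report; one CARES ID mapped to two different person keys is an
#' ambiguous identity and aborts the import naming the id.
#'
#' @param x File path or data frame with columns `cares_id`, `person_key`.
#' @return List with `rows` (validated key rows) and `report`
#'   (`n_in`, `n_rows`, `n_duplicates`, `n_malformed`, `malformed`).
#' @export
import_keyfile <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x))
      cares_abort(sprintf("cannot read key file '%s'", x), "io_error")
    x <- read.csv(x, colClasses = "character")
  }
  if (!identical(sort(names(x)), c("cares_id", "person_key")))
    cares_abort("key file must have exactly the columns cares_id, person_key",
                "import_error")
  x <- new_df(cares_id = as.character(x$cares_id),
              person_key = as.character(x$person_key))
  n_in <- nrow(x)
  ok <- is_hex_token(x$cares_id, CARES_ID_NCHAR) &
    !is.na(x$person_key) & nzchar(x$person_key)
  malformed <- x[!ok, , drop = FALSE]
  x <- x[ok, , drop = FALSE]
  dup <- duplicated(x)
  n_dup <- sum(dup)
  x <- x[!dup, , drop = FALSE]
  ambiguous <- unique(x$cares_id[duplicated(x$cares_id)])
  if (length(ambiguous))
    cares_abort(sprintf("ambiguous identity: CARES ID(s) mapped to multiple person keys: %s",
                        paste(ambiguous, collapse = ", ")), "import_error")
  rownames(x) <- NULL
  list(rows = x,
       report = list(n_in = n_in, n_rows = nrow(x), n_duplicates = n_dup,
                     n_malformed = nrow(malformed), malformed = malformed))
}

## ---- engine transform application (vectorised) ---------------------------

engine_predicate <- function(col, op, literal, type) {
  if (identical(type, "date")) {
    col <- as.Date(col)
    literal <- as.Date(literal)
  } else if (type %in% c("integer", "numeric") || is.numeric(literal)) {
    col <- suppressWarnings(as.numeric(col))
    literal <- as.numeric(literal)
  } else {
    col <- as.character(col)
    literal <- as.character(literal)
  }
  res <- switch(op,
    "=" = col == literal[1],
    "!=" = col != literal[1],
    "<" = col < literal[1],
    "<=" = col <= literal[1],
    ">" = col > literal[1],
    ">=" = col >= literal[1],
    "in" = col %in% literal,
    "date-range" = col >= literal[1] & col <= literal[2])
  res & !is.na(res)
}

require_fields <- function(records, fields, step_index) {
  miss <- setdiff(fields, names(records))
  if (length(miss))
    cares_abort(sprintf("step %d references missing field(s): %s", step_index,
                        paste(miss, collapse = ", ")), "task_error")
}

apply_transform_steps <- function(records, steps, types) {
  for (i in seq_along(steps)) {
    step <- steps[[i]]
    p <- step$parameters
    if (step$kind == "field_map") {
      require_fields(records, c(names(p$renames), names(p$recodes)), i)
      for (old in names(p$renames)) {
        names(records)[names(records) == old] <- p$renames[[old]]
        names(types)[names(types) == old] <- p$renames[[old]]
      }
      for (fld in names(p$recodes)) {
        map <- p$recodes[[fld]]
        col <- as.character(records[[fld]])
        hit <- !is.na(col) & col %in% names(map)
        col[hit] <- unname(map[col[hit]])
        records[[fld]] <- col
      }
    } else if (step$kind %in% c("filter", "exclusion")) {
      require_fields(records, p$field, i)
      keep <- engine_predicate(records[[p$field]], p$op, p$value,
                               types[[p$field]] %||% "text")
      if (step$kind == "exclusion") keep <- !keep
      records <- records[keep, , drop = FALSE]
    } else if (step$kind == "derived_field") {
      if (p$expr_kind == "date_diff") {
        require_fields(records, c(p$field_a, p$field_b), i)
        days <- as.numeric(as.Date(records[[p$field_a]]) -
                             as.Date(records[[p$field_b]]))
        records[[p$name]] <- if (p$unit == "days") days else floor(days / 365.25)
        types[[p$name]] <- "integer"
      } else if (p$expr_kind == "arith") {
        require_fields(records, p$fields, i)
        env <- lapply(records[p$fields], function(v) suppressWarnings(as.numeric(v)))
        records[[p$name]] <- as.numeric(eval(parse(text = p$expression)[[1]],
                                             envir = env))
        types[[p$name]] <- "numeric"
      } else {
        require_fields(records, p$field, i)
        col <- as.character(records[[p$field]])
        out <- rep(NA_character_, length(col))
        hit <- !is.na(col) & col %in% names(p$map)
        out[hit] <- unname(p$map[col[hit]])
        records[[p$name]] <- out
        types[[p$name]] <- "category"
      }
    }
  }
  rownames(records) <- NULL
  list(records = records, types = types)
}

# Field types of the researcher-facing output: person_key, approved schema
# fields (possibly renamed), then derived fields.
output_field_types <- function(schema, steps) {
  types <- c(list(person_key = "text"),
             as.list(schema_field_types(schema, schema$approved_items)))
  probe <- as.data.frame(setNames(rep(list(character(0)), length(types)),
                                  names(types)), stringsAsFactors = FALSE)
  apply_transform_steps(probe, steps, types)$types
}

## ---- running a task ------------------------------------------------------

extract_one_collection <- function(hub, session, task, cid, on_date) {
  schema <- hub_schema(hub, cid)
  imported <- import_keyfile(task$key_files[[cid]])
  key_rows <- imported$rows
  q <- query_records(hub, session$user_id, cid, unique(key_rows$cares_id),
                     task$task_id, on_date)
  retrieved <- q$records
  # step 4: append the person key, drop hub-internal columns
  m <- match(retrieved$cares_id, key_rows$cares_id)
  retrieved$person_key <- key_rows$person_key[m]
  retrieved <- retrieved[c("person_key", "cares_id",
                           setdiff(names(retrieved),
                                   c("person_key", "cares_id", "load_batch")))]
  types <- c(list(person_key = "text", cares_id = "text"),
             as.list(schema_field_types(schema, schema$approved_items)))
  stepped <- apply_transform_steps(retrieved, task$steps, types)
  list(schema = schema, imported = imported, key_rows = key_rows,
       retrieved = retrieved, records = stepped$records, types = stepped$types,
       unmatched = q$unmatched)
}

#' Run the extraction module for a task
#'
#' Executes steps 2–6 of the module procedure for every collection in the
#' task under one operator session: key import, governed retrieval, key
#' appending, transform steps, then standardised output with layout file
#' and QA summary. Governance is checked for every collection before any
#' data is touched; a single failing collection refuses the whole task.
#' The CARES ID is dropped from researcher-facing output by default (see
#' `keep_record_token`).
#'
#' @param hub A [cares_hub()].
#' @param session From [authenticate()].
#' @param task An [extraction_task()], already registered and approved.
#' @param out_dir Optional directory; outputs are written as CSV + YAML.
#' @param keep_record_token Retain the CARES ID column (QA workflows only).
#' @param on_date Governance evaluation date (defaults to the request date).
#' @return A `cares_run`: per-collection `cares_extract` objects
#'   (standardised `records`, `layout`, `qa`, `files`) plus the completed
#'   task.
#' @export
run_module <- function(hub, session, task, out_dir = NULL,
                       keep_record_token = FALSE, on_date = task$requested_on) {
  stopifnot(inherits(session, "cares_session"), inherits(task, "cares_task"))
  lookup_user(hub, session$user_id)
  # fail closed: every collection must pass all three tiers first
  for (cid in task$collection_ids) {
    d <- check_access(hub, session$user_id, cid, task$task_id, on_date)
    if (d$decision != "allow") {
      audit_append(hub, session$user_id, "run_module", task$task_id, "refused")
      cares_abort(sprintf("task %s refused: access denied on collection '%s' (%s); no data touched",
                          task$task_id, cid, d$reason), "authorisation_error")
    }
  }
  outputs <- list()
  for (cid in task$collection_ids) {
    part <- extract_one_collection(hub, session, task, cid, on_date)
    records <- part$records
    if (!keep_record_token) {
      records$cares_id <- NULL
      part$types$cares_id <- NULL
    }
    std <- standardise(records, part$types)
    layout <- make_layout(part$schema, task$steps,
                          keep_record_token = keep_record_token)
    qa <- qa_report(part$key_rows, part$retrieved, std, task,
                    types = part$types, unmatched = part$unmatched)
    files <- if (!is.null(out_dir))
      write_extract(std, layout, qa, out_dir, sprintf("%s_%s", task$task_id, cid))
    outputs[[cid]] <- structure(list(collection_id = cid, records = std,
                                     layout = layout, qa = qa, files = files,
                                     mode = "cares"),
                                class = "cares_extract")
  }
  task$completed_on <- task$requested_on
  task$mode <- "cares"
  if (!is.null(hub$tasks[[task$task_id]])) hub$tasks[[task$task_id]] <- task
  audit_append(hub, session$user_id, "run_module", task$task_id, "ok")
  structure(list(outputs = outputs, task = task), class = "cares_run")
}

#' @export
print.cares_extract <- function(x, ...) {
  cat(sprintf("<%s extract %s: %d rows x %d fields>\n", x$mode, x$collection_id,
              nrow(x$records), ncol(x$records)))
  invisible(x)
}

## ---- classical fan-out baseline -----------------------------------------

#' Delay models for simulated completion times
#'
#' `delay_model("lognormal", ...)` draws elapsed days from a lognormal —
#' the long-right-tail shape of extraction queues with competing
#' priorities; `delay_model("constant", value)` is degenerate.
#' `classical_delay_model()` (median 18 days) and `cares_delay_model()`
#' (median 2 days) are the package's calibrated defaults.
#'
#' @param dist `"lognormal"` or `"constant"`.
#' @param meanlog,sdlog Lognormal parameters (days scale).
#' @param value Constant delay in days.
#' @return A `cares_delay_model`.
#' @export
delay_model <- function(dist = c("lognormal", "constant"),
                        meanlog = log(18), sdlog = 1, value = 0) {
  dist <- match.arg(dist)
  structure(list(dist = dist, meanlog = meanlog, sdlog = sdlog, value = value),
            class = "cares_delay_model")
}

#' @rdname delay_model
#' @export
classical_delay_model <- function() delay_model("lognormal", log(18), 1)

#' @rdname delay_model
#' @export
cares_delay_model <- function() delay_model("lognormal", log(2), 0.7)

draw_delays <- function(model, n) {
  stopifnot(inherits(model, "cares_delay_model"))
  switch(model$dist,
         lognormal = rlnorm(n, model$meanlog, model$sdlog),
         constant = rep(model$value, n))
}

# deterministic per-collection rendering quirks for classical mode
classical_dialect_of <- function(cid, schema) {
  list(sep = c(",", "\t", ";")[1L + sub_seed(cid, "sep") %% 3L],
       field_order_seed = sub_seed(cid, "order"))
}

#' Run a task in classical fan-out mode
#'
#' Produces the same record content as [run_module()], but as each source
#' collection would have delivered it: dates rendered in the collection's
#' own input dialect, a collection-specific field order and delimiter, and
#' a simulated per-collection completion delay drawn from `delay_model`.
#' These heterogeneous outputs are the baseline that [standardise()] and
#' the turnaround metrics are demonstrated against.
#'
#' @inheritParams run_module
#' @param delay_model A [delay_model()] for per-collection completion.
#' @param seed Integer seed for the delay draws.
#' @return A `cares_run` whose extracts carry raw dialect-rendered
#'   `records`, the rendering metadata, and `completed_on` dates.
#' @export
run_classical <- function(hub, session, task, delay_model = classical_delay_model(),
                          seed = 1L, on_date = task$requested_on) {
  stopifnot(inherits(session, "cares_session"), inherits(task, "cares_task"))
  for (cid in task$collection_ids) {
    d <- check_access(hub, session$user_id, cid, task$task_id, on_date)
    if (d$decision != "allow")
      cares_abort(sprintf("task %s refused: access denied on collection '%s' (%s)",
                          task$task_id, cid, d$reason), "authorisation_error")
  }
  delays <- with_seed(sub_seed(seed, paste0("classical-", task$task_id)),
                      draw_delays(delay_model, length(task$collection_ids)))
  outputs <- list()
  for (j in seq_along(task$collection_ids)) {
    cid <- task$collection_ids[j]
    part <- extract_one_collection(hub, session, task, cid, on_date)
    records <- part$records
    records$cares_id <- NULL
    types <- part$types
    types$cares_id <- NULL
    # render in the collection's own dialect
    raw <- records
    for (fld in names(raw)) {
      if (identical(types[[fld]], "date")) {
        dialect <- part$schema$fields$dialect[part$schema$fields$name == fld]
        if (length(dialect) == 0L || is.na(dialect)) dialect <- "DD/MM/YYYY"
        raw[[fld]] <- render_dialect_dates(as.Date(raw[[fld]]), dialect)
      } else {
        raw[[fld]] <- as.character(raw[[fld]])
      }
      raw[[fld]][is.na(raw[[fld]])] <- ""
    }
    quirks <- classical_dialect_of(cid, part$schema)
    raw <- raw[with_seed(quirks$field_order_seed, sample(names(raw)))]
    completed <- task$requested_on + as.integer(round(delays[j]))
    outputs[[cid]] <- structure(list(collection_id = cid, records = raw,
                                     types = types, sep = quirks$sep,
                                     completed_on = completed, mode = "classical"),
                                class = "cares_extract")
  }
  task$completed_on <- max(as.Date(vapply(outputs, function(o)
    format(o$completed_on), character(1))))
  task$mode <- "classical"
  if (!is.null(hub$tasks[[task$task_id]])) hub$tasks[[task$task_id]] <- task
  audit_append(hub, session$user_id, "run_classical", task$task_id, "ok")
  structure(list(outputs = outputs, task = task), class = "cares_run")
}
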