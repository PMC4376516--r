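# Synthetic study system: placeholder populations, source collections with
# collection-specific date dialects, project linkage keys, and project
# fixtures carrying brute-force ground-truth extracts.
#
# Person-level demographics (name, date of birth, address) exist only here
# and in the test suite: the hub and extraction modules never accept or
# return them. The fixture's expected output is computed by a literal
# row-by-row join/filter in this file, never by the extraction engine, so
# it can serve as an independent oracle for the engine.

#' Generate a synthetic person population
#'
#' Placeholder demographics only: opaque root identifiers, token names and
#' addresses, uniformly drawn birth dates. Deterministic for a fixed seed.
#'
#' @param n Number of persons (>= 1).
#' @param seed Integer seed; all randomness derives from it.
#' @return Data frame with columns `root_id`, `name`, `date_of_birth`,
#'   `address`.
#' @export
generate_population <- function(n, seed) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    cares_abort("n must be a positive integer", "invalid_parameter")
  n <- as.integer(n)
  with_seed(sub_seed(seed, "population"), {
    root_id <- paste0("R", sprintf("%06d", seq_len(n)), "-", random_hex(n, 6L))
    new_df(
      root_id = root_id,
      name = paste0("NAME_", random_hex(n, 8L)),
      date_of_birth = as.Date("1920-01-01") + sample.int(34000L, n, replace = TRUE),
      address = paste0(sample.int(999L, n, replace = TRUE), " STREET_",
                       random_hex(n, 6L))
    )
  })
}

## ---- collection schemas --------------------------------------------------

#' Define a source collection schema
#'
#' Describes the layout of a collection's service records: the collection's
#' own unique-identifier field, the content fields with semantic types, the
#' input date dialect of each date field, and the subset of fields approved
#' for provision to the hub. The source UID field is never among the
#' approved items: it is replaced by an encrypted CARES ID at load.
#'
#' @param collection_id Short code, e.g. `"HMDS"`.
#' @param name Human-readable collection name.
#' @param source_uid_field Name of the collection's own record identifier.
#' @param fields Data frame with columns `name`, `type` (one of `text`,
#'   `integer`, `date`, `category`), `dialect` (date fields only; see
#'   [cares_dialects()]), `levels` (`category` fields only; levels joined
#'   with `"|"`).
#' @param approved_items Field names provided to the hub; must exclude
#'   `source_uid_field`.
#' @param max_records_per_person Cap on per-person record multiplicity;
#'   `1` models registry-style collections (births, deaths), `Inf` models
#'   repeating service contacts.
#' @return A `cares_schema` object.
#' @export
collection_schema <- function(collection_id, name, source_uid_field, fields,
                              approved_items, max_records_per_person = Inf) {
  assert_scalar_chr(collection_id, "collection_id")
  assert_scalar_chr(source_uid_field, "source_uid_field")
  stopifnot(is.data.frame(fields), all(c("name", "type") %in% names(fields)))
  if (!"dialect" %in% names(fields)) fields$dialect <- NA_character_
  if (!"levels" %in% names(fields)) fields$levels <- NA_character_
  fields <- new_df(name = as.character(fields$name),
                   type = as.character(fields$type),
                   dialect = as.character(fields$dialect),
                   levels = as.character(fields$levels))
  if (anyDuplicated(fields$name))
    cares_abort("duplicate field names in schema", "schema_error")
  bad <- setdiff(fields$type, c("text", "integer", "date", "category"))
  if (length(bad))
    cares_abort(sprintf("unknown semantic type(s): %s", paste(bad, collapse = ", ")),
                "schema_error")
  for (i in which(fields$type == "date")) {
    if (is.na(fields$dialect[i]) || !fields$dialect[i] %in% cares_dialects())
      cares_abort(sprintf("date field '%s' must declare exactly one known dialect",
                          fields$name[i]), "schema_error")
  }
  for (i in which(fields$type == "category")) {
    if (is.na(fields$levels[i]) || !nzchar(fields$levels[i]))
      cares_abort(sprintf("category field '%s' must declare its levels",
                          fields$name[i]), "schema_error")
  }
  if (source_uid_field %in% fields$name)
    cares_abort("source_uid_field must not appear among content fields", "schema_error")
  approved_items <- as.character(approved_items)
  if (source_uid_field %in% approved_items)
    cares_abort("source UIDs are never stored in clear on the hub: source_uid_field cannot be an approved item",
                "schema_error")
  if (!all(approved_items %in% fields$name))
    cares_abort("approved_items must be a subset of schema field names", "schema_error")
  structure(list(collection_id = collection_id, name = name,
                 source_uid_field = source_uid_field, fields = fields,
                 approved_items = approved_items,
                 max_records_per_person = max_records_per_person),
            class = "cares_schema")
}

#' @export
print.cares_schema <- function(x, ...) {
  cat(sprintf("<collection schema %s ('%s'): %d fields, %d approved for hub>\n",
              x$collection_id, x$name, nrow(x$fields), length(x$approved_items)))
  invisible(x)
}

schema_levels <- function(schema, field) {
  lev <- schema$fields$levels[schema$fields$name == field]
  strsplit(lev, "|", fixed = TRUE)[[1]]
}

schema_field_types <- function(schema, fields = schema$fields$name) {
  setNames(schema$fields$type[match(fields, schema$fields$name)], fields)
}

## ---- source record tables ------------------------------------------------

# Per-person record counts follow a zero-truncated Poisson with rate
# `mean_records_per_person` (realised mean m/(1 - exp(-m))), capped at the
# schema's max_records_per_person; `count_model = "constant"` forces exactly
# round(mean) records per covered person.
rztpois <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  u <- runif(n, min = stats::dpois(0, lambda), max = 1)
  stats::qpois(u, lambda)
}

#' Generate a source collection's service-record table
#'
#' Simulates a collection's own data: roughly `coverage * nrow(population)`
#' persons receive records, multiplicity follows a zero-truncated Poisson
#' (or a degenerate constant), and every date field is rendered in the
#' schema's declared input dialect. Content fields carry a small missing
#' rate so downstream missing-value accounting is exercised.
#'
#' @param population From [generate_population()].
#' @param schema A [collection_schema()].
#' @param coverage Fraction of the population with at least one record.
#' @param mean_records_per_person Rate of the count distribution.
#' @param seed Integer seed.
#' @param count_model `"ztpois"` or `"constant"` (zero variance).
#' @param missing_rate Per-cell missing probability for non-date content
#'   fields (rendered as empty strings).
#' @return A `cares_source_table`: list with `collection_id` and `rows`
#'   (columns: the source UID field, `root_id`, then content fields, all
#'   character except integers).
#' @export
generate_collection <- function(population, schema, coverage = 0.6,
                                mean_records_per_person = 1.5, seed = 1L,
                                count_model = c("ztpois", "constant"),
                                missing_rate = 0.03) {
  count_model <- match.arg(count_model)
  if (!is.numeric(coverage) || coverage < 0 || coverage > 1)
    cares_abort("coverage must lie in [0, 1]", "invalid_parameter")
  if (mean_records_per_person <= 0)
    cares_abort("mean_records_per_person must be positive", "invalid_parameter")

  covered <- with_seed(sub_seed(seed, paste0("inclusion-", schema$collection_id)),
                       runif(nrow(population)) < coverage)
  owners <- population$root_id[covered]
  counts <- with_seed(sub_seed(seed, paste0("counts-", schema$collection_id)), {
    k <- switch(count_model,
                ztpois = rztpois(length(owners), mean_records_per_person),
                constant = rep(max(1L, as.integer(round(mean_records_per_person))),
                               length(owners)))
    pmin(k, schema$max_records_per_person)
  })
  owner_rep <- rep(owners, counts)
  n_rec <- length(owner_rep)

  rows <- with_seed(sub_seed(seed, paste0("content-", schema$collection_id)), {
    out <- new_df(uid = sprintf("%s%07d", schema$collection_id, seq_len(n_rec)),
                  root_id = owner_rep)
    names(out)[1] <- schema$source_uid_field
    for (i in seq_len(nrow(schema$fields))) {
      fname <- schema$fields$name[i]
      col <- switch(schema$fields$type[i],
        text = paste0("TXT_", random_hex(n_rec, 8L)),
        integer = as.character(sample.int(200L, n_rec, replace = TRUE) - 1L),
        date = render_dialect_dates(
          as.Date("1990-01-01") + sample.int(9100L, n_rec, replace = TRUE),
          schema$fields$dialect[i]),
        category = sample(schema_levels(schema, fname), n_rec, replace = TRUE))
      if (schema$fields$type[i] != "date" && missing_rate > 0 && n_rec > 0) {
        col[runif(n_rec) < missing_rate] <- ""
      }
      out[[fname]] <- col
    }
    out
  })
  structure(list(collection_id = schema$collection_id, rows = rows),
            class = "cares_source_table")
}

#' @export
print.cares_source_table <- function(x, ...) {
  cat(sprintf("<source table %s: %d records, %d persons>\n", x$collection_id,
              nrow(x$rows), length(unique(x$rows$root_id))))
  invisible(x)
}

## ---- project linkage keys ------------------------------------------------

#' Derive project-scoped person keys
#'
#' Keyed one-way transformation of (project, person): deterministic,
#' injective on a cohort, and unlinkable across projects without the
#' secret — the same person receives unrelated keys in different projects.
#'
#' @param cohort Character vector of person root identifiers (non-empty).
#' @param project_id Project code.
#' @param secret Linkage authority key material.
#' @return Named character vector, `root_id -> person_key` (17-char token).
#' @export
derive_project_keys <- function(cohort, project_id, secret) {
  if (length(cohort) == 0L)
    cares_abort("cohort must be non-empty", "invalid_parameter")
  assert_scalar_chr(project_id, "project_id")
  if (!is.character(secret) || length(secret) != 1L || !nzchar(secret))
    cares_abort("empty linkage secret", "configuration_error")
  keys <- paste0("K", hmac_token(secret, paste0(project_id, "\x1f", cohort), 16L))
  setNames(keys, cohort)
}

## ---- brute-force ground truth --------------------------------------------

# Literal, row-by-row application of transform steps. Deliberately naive and
# entirely separate from the extraction engine's vectorised path: fixtures
# built here remain a valid oracle for the engine.

bf_predicate <- function(value, op, literal, type) {
  if (type == "date") {
    value <- as.Date(value)
    literal <- as.Date(literal)
  } else if (type == "integer" || is.numeric(literal)) {
    value <- suppressWarnings(as.numeric(value))
    literal <- as.numeric(literal)
  }
  if (is.na(value)) return(FALSE)
  switch(op,
    "=" = value == literal[1],
    "!=" = value != literal[1],
    "<" = value < literal[1],
    "<=" = value <= literal[1],
    ">" = value > literal[1],
    ">=" = value >= literal[1],
    "in" = value %in% literal,
    "date-range" = value >= literal[1] & value <= literal[2],
    cares_abort(sprintf("unknown comparator '%s'", op), "task_error"))
}

bf_apply_steps <- function(records, steps, types) {
  for (step in steps) {
    p <- step$parameters
    if (step$kind == "field_map") {
      for (old in names(p$renames %||% list())) {
        names(records)[names(records) == old] <- p$renames[[old]]
        names(types)[names(types) == old] <- p$renames[[old]]
      }
      for (fld in names(p$recodes %||% list())) {
        map <- p$recodes[[fld]]
        for (r in seq_len(nrow(records))) {
          v <- as.character(records[[fld]][r])
          if (!is.na(v) && v %in% names(map)) records[[fld]][r] <- map[[v]]
        }
      }
    } else if (step$kind %in% c("filter", "exclusion")) {
      keep <- logical(nrow(records))
      for (r in seq_len(nrow(records))) {
        keep[r] <- bf_predicate(records[[p$field]][r], p$op, p$value,
                                types[[p$field]] %||% "text")
      }
      if (step$kind == "exclusion") keep <- !keep
      records <- records[keep, , drop = FALSE]
    } else if (step$kind == "derived_field") {
      vals <- vector("list", nrow(records))
      for (r in seq_len(nrow(records))) {
        vals[[r]] <- if (p$expr_kind == "date_diff") {
          a <- as.Date(records[[p$field_a]][r]); b <- as.Date(records[[p$field_b]][r])
          if (is.na(a) || is.na(b)) NA_real_
          else if (p$unit == "days") as.numeric(a - b)
          else floor(as.numeric(a - b) / 365.25)
        } else if (p$expr_kind == "arith") {
          env <- as.list(records[r, , drop = FALSE])
          env <- lapply(env, function(v) suppressWarnings(as.numeric(v)))
          val <- try(eval(parse(text = p$expression)[[1]], envir = env), silent = TRUE)
          if (inherits(val, "try-error")) NA_real_ else as.numeric(val)
        } else if (p$expr_kind == "recode") {
          v <- as.character(records[[p$field]][r])
          if (!is.na(v) && v %in% names(p$map)) p$map[[v]] else NA_character_
        }
      }
      records[[p$name]] <- if (length(vals)) unlist(vals)
        else if (p$expr_kind == "recode") character(0) else numeric(0)
      types[[p$name]] <- if (p$expr_kind == "recode") "category" else "integer"
    }
  }
  list(records = records, types = types)
}

# Literal standardisation used only for ground truth: character columns,
# dates as YYYYMMDD, numbers plainly formatted, NA -> "".
bf_standardise <- function(records, types) {
  out <- records
  for (nm in names(out)) {
    col <- out[[nm]]
    if (identical(types[[nm]], "date") || inherits(col, "Date")) {
      col <- format(as.Date(col), "%Y%m%d")
    } else if (is.numeric(col)) {
      col <- vapply(col, function(v) if (is.na(v)) NA_character_ else
        format(v, scientific = FALSE, trim = TRUE), character(1))
    } else {
      col <- as.character(col)
    }
    col[is.na(col)] <- ""
    out[[nm]] <- col
  }
  out <- out[order_standardised(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a project fixture with brute-force ground truth
#'
#' Assembles, for one project: per-collection linkage-key files (one row per
#' cohort record, pairing the record's CARES ID with the project person
#' key) and the expected researcher-facing extract per collection. The
#' expectation is computed by a literal filter-and-join in this module —
#' never by the extraction engine — so it is an independent oracle.
#'
#' @param population From [generate_population()].
#' @param collections Named list (by collection id), each element a list
#'   with `schema`, `table` (a `cares_source_table`) and `key`
#'   (a [collection_key()]).
#' @param cohort Character vector of root_ids, a subset of the population.
#' @param task An [extraction_task()] naming collections and steps.
#' @param project_secret Linkage secret for [derive_project_keys()].
#' @return A `cares_fixture`: `project_id`, `cohort`, `key_files`,
#'   `expected_output` (standardised data frames), `task`.
#' @export
build_fixture <- function(population, collections, cohort, task, project_secret) {
  stopifnot(inherits(task, "cares_task"))
  if (!all(cohort %in% population$root_id))
    cares_abort("cohort must be a subset of the population", "invalid_parameter")
  missing_coll <- setdiff(task$collection_ids, names(collections))
  if (length(missing_coll))
    cares_abort(sprintf("task references unregistered collection(s): %s",
                        paste(missing_coll, collapse = ", ")), "configuration_error")

  keys <- if (length(cohort)) derive_project_keys(cohort, task$project_id, project_secret)
          else setNames(character(0), character(0))

  key_files <- list()
  expected <- list()
  for (cid in task$collection_ids) {
    schema <- collections[[cid]]$schema
    tbl <- collections[[cid]]$table$rows
    ckey <- collections[[cid]]$key
    in_cohort <- tbl$root_id %in% cohort
    sub <- tbl[in_cohort, , drop = FALSE]
    cares_ids <- if (nrow(sub)) encrypt_id(cid, sub[[schema$source_uid_field]], ckey)
                 else character(0)
    key_files[[cid]] <- new_df(cares_id = cares_ids,
                               person_key = unname(keys[sub$root_id]))

    # typed content restricted to approved items
    rec <- new_df(person_key = unname(keys[sub$root_id]))
    types <- list(person_key = "text")
    for (fld in schema$approved_items) {
      ftype <- schema_field_types(schema, fld)[[fld]]
      col <- sub[[fld]]
      col[!is.na(col) & col == ""] <- NA
      if (ftype == "date") {
        col <- parse_dialect_dates(col, schema$fields$dialect[schema$fields$name == fld])
      } else if (ftype == "integer") {
        col <- suppressWarnings(as.integer(col))
      }
      rec[[fld]] <- col
      types[[fld]] <- ftype
    }
    stepped <- bf_apply_steps(rec, task$steps, types)
    expected[[cid]] <- bf_standardise(stepped$records, stepped$types)
  }
  structure(list(project_id = task$project_id, cohort = cohort,
                 key_files = key_files, expected_output = expected, task = task),
            class = "cares_fixture")
}

#' @export
print.cares_fixture <- function(x, ...) {
  cat(sprintf("<project fixture %s: cohort %d, collections: %s>\n", x$project_id,
              length(x$cohort), paste(names(x$key_files), collapse = ", ")))
  invisible(x)
}

## ---- discrepancy injection -----------------------------------------------

#' Inject known discrepancies into an extract
#'
#' Removes `n_drop` whole rows and alters exactly one non-key field in each
#' of `n_perturb` other rows, returning the perturbed table together with a
#' ledger of every change. Replaying the ledger against the original table
#' reproduces the perturbed one, and parallel-run comparison should recover
#' the ledger exactly.
#'
#' @param table A standardised extract data frame.
#' @param n_drop,n_perturb Numbers of rows to drop / perturb (disjoint).
#' @param seed Integer seed.
#' @param key_fields Columns treated as record identity (never perturbed);
#'   defaults to [default_key_fields()].
#' @return List with `table` (perturbed) and `ledger` (data frame with
#'   columns `type`, `row`, `key`, `field`, `old`, `new`).
#' @export
inject_discrepancies <- function(table, n_drop, n_perturb, seed,
                                 key_fields = default_key_fields(table)) {
  if (n_drop < 0 || n_perturb < 0 || n_drop + n_perturb > nrow(table))
    cares_abort("n_drop + n_perturb must not exceed the row count", "invalid_parameter")
  value_fields <- setdiff(names(table), key_fields)
  if (n_perturb > 0 && length(value_fields) == 0L)
    cares_abort("no non-key fields available to perturb", "invalid_parameter")
  keys <- if (length(key_fields))
    do.call(paste, c(table[key_fields], sep = "|")) else as.character(seq_len(nrow(table)))

  with_seed(sub_seed(seed, "discrepancies"), {
    idx <- sample.int(nrow(table), n_drop + n_perturb)
    drop_idx <- sort(idx[seq_len(n_drop)])
    pert_idx <- sort(idx[n_drop + seq_len(n_perturb)])
    ledger <- new_df(type = character(0), row = integer(0), key = character(0),
                     field = character(0), old = character(0), new = character(0))
    out <- table
    for (r in pert_idx) {
      fld <- sample(value_fields, 1L)
      old <- as.character(out[[fld]][r])
      new <- paste0(old, "#", random_hex(1L, 4L))
      out[[fld]][r] <- new
      ledger <- rbind(ledger, new_df(type = "perturb", row = r, key = keys[r],
                                     field = fld, old = old, new = new))
    }
    if (length(drop_idx)) {
      ledger <- rbind(ledger, new_df(type = "drop", row = drop_idx,
                                     key = keys[drop_idx], field = NA_character_,
                                     old = NA_character_, new = NA_character_))
    }
    out <- out[setdiff(seq_len(nrow(out)), drop_idx), , drop = FALSE]
    rownames(out) <- NULL
    ledger <- ledger[order(ledger$row), , drop = FALSE]
    rownames(ledger) <- NULL
    list(table = out, ledger = ledger)
  })
}

#' Replay an injection ledger against the original table
#'
#' @param table The original table passed to [inject_discrepancies()].
#' @param ledger The returned ledger.
#' @return The perturbed table.
#' @export
replay_ledger <- function(table, ledger) {
  out <- table
  for (i in which(ledger$type == "perturb")) {
    out[[ledger$field[i]]][ledger$row[i]] <- ledger$new[i]
  }
  drops <- ledger$row[ledger$type == "drop"]
  out <- out[setdiff(seq_len(nrow(out)), drops), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- fixture I/O ---------------------------------------------------------

#' Write or read a project fixture as delimited text
#'
#' Key files and expected outputs are written as RFC-4180 CSV (UTF-8, header
#' row) together with a YAML manifest recording the project, collections and
#' task parameters.
#'
#' @param fixture A `cares_fixture`.
#' @param dir Directory to write into (created if needed).
#' @return `read_fixture()` returns the key files and expected outputs.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cid in names(fixture$key_files)) {
    write.csv(fixture$key_files[[cid]],
              file.path(dir, paste0("keys_", cid, ".csv")), row.names = FALSE)
    write.csv(fixture$expected_output[[cid]],
              file.path(dir, paste0("expected_", cid, ".csv")), row.names = FALSE)
  }
  yaml::write_yaml(list(project_id = fixture$project_id,
                        collections = names(fixture$key_files),
                        cohort_size = length(fixture$cohort),
                        task_id = fixture$task$task_id,
                        n_steps = length(fixture$task$steps)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  key_files <- list()
  expected <- list()
  for (cid in manifest$collections) {
    key_files[[cid]] <- read.csv(file.path(dir, paste0("keys_", cid, ".csv")),
                                 colClasses = "character")
    expected[[cid]] <- read.csv(file.path(dir, paste0("expected_", cid, ".csv")),
                                colClasses = "character")
  }
  list(manifest = manifest, key_files = key_files, expected_output = expected)
}
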