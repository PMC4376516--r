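# Ready-made randomised study scenarios: a shared schema family, random
# project fixtures with brute-force ground truth, and a fully governed hub
# loaded from a fixture. Used throughout the tests, the vignette and the
# acceptance checks.

# All collections in a scenario share one content field family (service
# date(s), sex, a count, free text) so that one task's transform steps are
# meaningful for every collection; collections differ in their date
# dialect, record multiplicity (registry vs repeating service contacts)
# and approved subset.
scenario_schema <- function(collection_id, seed) {
  with_seed(sub_seed(seed, paste0("schema-", collection_id)), {
    dialect1 <- sample(cares_dialects(), 1L)
    dialect2 <- sample(cares_dialects(), 1L)
    registry <- runif(1) < 0.25
    drop_note <- runif(1) < 0.3
    fields <- new_df(
      name = c("event_date", "end_date", "sex", "units", "note"),
      type = c("date", "date", "category", "integer", "text"),
      dialect = c(dialect1, dialect2, NA, NA, NA),
      levels = c(NA, NA, "M|F|U", NA, NA))
    approved <- c("event_date", "end_date", "sex", "units",
                  if (!drop_note) "note")
    collection_schema(collection_id,
                      name = paste("Synthetic collection", collection_id),
                      source_uid_field = "src_uid",
                      fields = fields, approved_items = approved,
                      max_records_per_person = if (registry) 1 else Inf)
  })
}

# Draw 0..n_steps valid transform steps over the shared field family,
# tracking renames so later steps reference current names.
scenario_steps <- function(n_steps, seed) {
  fields <- c(event_date = "event_date", end_date = "end_date",
              sex = "sex", units = "units")
  steps <- list()
  with_seed(sub_seed(seed, "steps"), {
    derived_done <- FALSE
    renamed_done <- FALSE
    for (i in seq_len(n_steps)) {
      kind <- sample(c("filter", "exclusion", "derived", "map"), 1L)
      if (kind == "filter") {
        steps[[length(steps) + 1L]] <- if (runif(1) < 0.5)
          step_filter(fields[["units"]], ">=", sample(10:80, 1L))
        else step_filter(fields[["sex"]], "in", sample(c("M", "F"), 2L))
      } else if (kind == "exclusion") {
        cutoff <- as.Date("1990-01-01") + sample.int(9100L, 1L)
        steps[[length(steps) + 1L]] <-
          step_exclusion(fields[["event_date"]], "<", cutoff)
      } else if (kind == "derived" && !derived_done) {
        derived_done <- TRUE
        steps[[length(steps) + 1L]] <- if (runif(1) < 0.5)
          step_derived("duration_days", "date_diff",
                       field_a = fields[["end_date"]],
                       field_b = fields[["event_date"]], unit = "days")
        else step_derived("units_scaled", "arith",
                          expression = sprintf("%s * 2 + 1", fields[["units"]]))
      } else if (kind == "map" && !renamed_done) {
        renamed_done <- TRUE
        steps[[length(steps) + 1L]] <-
          step_field_map(renames = setNames("unit_count", fields[["units"]]),
                         recodes = setNames(list(c(M = "MALE", F = "FEMALE")),
                                            fields[["sex"]]))
        fields[["units"]] <- "unit_count"
      }
    }
  })
  steps
}

#' Generate a complete randomised project scenario
#'
#' One call produces everything needed to exercise an extraction end to
#' end: a population, 1–6 source collections (shared field family,
#' collection-specific date dialects and multiplicity), per-collection
#' encryption keys, a cohort, an extraction task with 0–4 random transform
#' steps, and the project fixture whose expected output was computed by
#' the brute-force oracle in [build_fixture()].
#'
#' @param seed Integer seed; the scenario is a pure function of it and the
#'   size parameters.
#' @param n_persons Population size.
#' @param n_collections Number of source collections (1–6).
#' @param cohort_size Cohort size (0 allowed).
#' @param n_steps Number of transform steps to draw (0–4).
#' @param date_window Optional QA date window for the task.
#' @return List with `population`, `collections` (schema/table/key per
#'   collection), `cohort`, `task`, `fixture`, `project_secret`.
#' @export
random_scenario <- function(seed, n_persons = 200L, n_collections = 2L,
                            cohort_size = 50L, n_steps = 1L,
                            date_window = NULL) {
  population <- generate_population(n_persons, seed)
  cids <- LETTERS[seq_len(n_collections)]
  collections <- list()
  for (cid in cids) {
    schema <- scenario_schema(cid, seed)
    key <- collection_key(cid, paste0("collection-secret-", cid, "-", seed))
    cov <- with_seed(sub_seed(seed, paste0("coverage-", cid)), runif(1, 0.4, 0.9))
    table <- generate_collection(population, schema, coverage = cov,
                                 mean_records_per_person = 1.6, seed = seed)
    collections[[cid]] <- list(schema = schema, table = table, key = key)
  }
  cohort <- with_seed(sub_seed(seed, "cohort"),
                      sample(population$root_id, min(cohort_size, n_persons)))
  steps <- scenario_steps(n_steps, seed)
  task <- extraction_task(task_id = sprintf("T%06d", seed %% 1000000L),
                          project_id = sprintf("PRJ%06d", seed %% 1000000L),
                          collection_ids = cids,
                          key_files = setNames(rep(list(NULL), length(cids)), cids),
                          steps = steps,
                          requested_on = as.Date("2013-06-01"),
                          date_window = date_window)
  secret <- paste0("project-secret-", seed)
  fixture <- build_fixture(population, collections, cohort, task, secret)
  task$key_files <- fixture$key_files
  fixture$task <- task
  list(population = population, collections = collections, cohort = cohort,
       task = task, fixture = fixture, project_secret = secret)
}

#' Stand up a governed hub from a scenario
#'
#' Registers and loads every collection, registers a standard cast of
#' users (an extraction analyst, a custodian over all collections, a
#' linkage officer, and an unprivileged user), issues the analyst's grants,
#' registers and approves the scenario task, and creates its workspace.
#'
#' @param scenario From [random_scenario()].
#' @param on_date Date grants/approvals/confidentiality are effective.
#' @return List with `hub`, `load_reports` and the standard `passwords`.
#' @export
scenario_hub <- function(scenario, on_date = as.Date("2012-01-01")) {
  hub <- cares_hub()
  passwords <- c(analyst = "pw-analyst", custodian = "pw-custodian",
                 lofficer = "pw-lofficer", outsider = "pw-outsider")
  register_user(hub, "analyst", "cares-user", passwords[["analyst"]],
                confidentiality_signed = on_date)
  register_user(hub, "custodian", c("custodian", "cares-user"),
                passwords[["custodian"]], confidentiality_signed = on_date)
  register_user(hub, "lofficer", "linkage-officer", passwords[["lofficer"]],
                confidentiality_signed = on_date)
  register_user(hub, "outsider", "cares-user", passwords[["outsider"]])
  load_reports <- list()
  for (cid in names(scenario$collections)) {
    coll <- scenario$collections[[cid]]
    register_collection(hub, coll$schema)
    assign_custodian(hub, "custodian", cid)
    grant_access(hub, "analyst", cid, granted_by = "custodian",
                 granted_on = on_date)
    load_reports[[cid]] <- load_update(hub, cid, coll$table, coll$key,
                                       mode = "full")
  }
  register_task(hub, scenario$task)
  for (cid in scenario$task$collection_ids)
    approve_task(hub, scenario$task$task_id, cid, approved_by = "custodian",
                 approved_on = on_date)
  create_workspace(hub, scenario$task$task_id, "analyst")
  list(hub = hub, load_reports = load_reports, passwords = passwords)
}
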