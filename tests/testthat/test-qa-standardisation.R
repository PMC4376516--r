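test_that("standardisation renders the canonical form and is idempotent", {
  rec <- data.frame(person_key = "Kx", d = as.Date("2010-03-01"), n = 7L,
                    stringsAsFactors = FALSE)
  std <- standardise(rec, list(person_key = "text", d = "date", n = "integer"))
  expect_identical(std$d, "20100301")
  expect_identical(std$n, "7")

  for (seed in c(71, 72)) {
    sc <- small_scenario(seed, n_steps = 2)
    run <- run_module(sc$hub, sc$session, sc$task)
    for (o in run$outputs) {
      types <- setNames(o$layout$type, o$layout$field)
      expect_identical(standardise(o$records, types), o$records)
      # all output dates are YYYYMMDD
      for (f in o$layout$field[o$layout$type == "date"])
        expect_true(all(grepl("^[0-9]{8}$", o$records[[f]]) |
                          o$records[[f]] == ""))
    }
  }
})

test_that("heterogeneous classical files normalise to byte-identical output", {
  sc <- small_scenario(73, n_collections = 2, n_steps = 1)
  run_c <- run_module(sc$hub, sc$session, sc$task)
  run_k <- run_classical(sc$hub, sc$session, sc$task, seed = 3)
  dir <- withr::local_tempdir()
  for (cid in names(run_c$outputs)) {
    fa <- file.path(dir, paste0(cid, "_cares.csv"))
    fb <- file.path(dir, paste0(cid, "_classical_standardised.csv"))
    caresr:::write_canonical_csv(run_c$outputs[[cid]]$records, fa)
    caresr:::write_canonical_csv(
      standardise(run_k$outputs[[cid]]$records, run_k$outputs[[cid]]$types), fb)
    expect_identical(readBin(fa, "raw", file.size(fa)),
                     readBin(fb, "raw", file.size(fb)))
  }
})

test_that("uncoercible values are named by row and field", {
  bad <- data.frame(person_key = "K1", d = "not-a-date", stringsAsFactors = FALSE)
  err <- tryCatch(standardise(bad, list(person_key = "text", d = "date")),
                  error = identity)
  expect_s3_class(err, "caresr_standardisation_error")
  expect_match(conditionMessage(err), "'d'")
  expect_cares_error(
    standardise(data.frame(person_key = "K1", n = "seven"),
                list(person_key = "text", n = "integer")),
    "standardisation_error")
})

test_that("layout files describe every output field in output order", {
  sc <- small_scenario(74, n_steps = 0)
  cid <- names(sc$collections)[1]
  schema <- sc$collections[[cid]]$schema
  steps <- list(step_derived("duration_days", "date_diff", field_a = "end_date",
                             field_b = "event_date", unit = "days"))
  layout <- make_layout(schema, steps)
  expect_equal(nrow(layout), 1L + length(schema$approved_items) + 1L)
  expect_match(layout$description[nrow(layout)], "end_date - event_date")

  task <- sc$task
  task$steps <- steps
  fx <- build_fixture(sc$population, sc$collections, sc$cohort, task,
                      sc$project_secret)
  task$key_files <- fx$key_files
  register_task(sc$hub, task)
  run <- run_module(sc$hub, sc$session, task)
  out <- run$outputs[[cid]]
  expect_identical(out$layout$field, names(out$records))

  path <- withr::local_tempfile(fileext = ".csv")
  write_layout(layout, path)
  expect_identical(read_layout(path), layout)
})

test_that("QA counts are recomputed from the data and conserve totals", {
  # all-miss: keys that match nothing in the hub
  sc <- small_scenario(75, n_steps = 0)
  cid <- names(sc$collections)[1]
  ghost_keys <- data.frame(
    cares_id = vapply(1:3, function(i) paste(rep(letters[i], 32), collapse = ""),
                      character(1)),
    person_key = paste0("K", 1:3), stringsAsFactors = FALSE)
  task2 <- extraction_task("TG", "PG", cid, setNames(list(ghost_keys), cid),
                           requested_on = sc$task$requested_on)
  register_task(sc$hub, task2)
  approve_task(sc$hub, "TG", cid, "custodian", approved_on = as.Date("2012-01-01"))
  run <- run_module(sc$hub, sc$session, task2,
                    on_date = sc$task$requested_on)
  qa <- run$outputs[[cid]]$qa
  expect_equal(qa$unmatched, 3L)
  expect_equal(qa$rows_out, 0L)
  expect_equal(qa$matched_key_rows + qa$unmatched, qa$rows_in)
})

test_that("date windows and category groupings are checked independently", {
  sc <- small_scenario(76, n_steps = 0,
                       date_window = as.Date(c("2000-01-01", "2010-12-31")))
  run <- run_module(sc$hub, sc$session, sc$task)
  for (o in run$outputs) {
    qa <- o$qa
    expect_equal(qa$matched_key_rows + qa$unmatched, qa$rows_in)
    # out-of-range counts match a direct recount on the emitted file
    for (f in names(qa$date_coverage)) {
      d <- as.Date(o$records[[f]], format = "%Y%m%d")
      d <- d[!is.na(d)]
      expect_equal(qa$date_coverage[[f]]$out_of_range,
                   sum(d < as.Date("2000-01-01") | d > as.Date("2010-12-31")))
    }
    # category level counts equal brute-force tabulation, and conserve rows
    for (f in names(qa$category_counts)) {
      tab <- table(o$records[[f]][nzchar(o$records[[f]])])
      expect_equal(unlist(qa$category_counts[[f]]),
                   setNames(as.integer(tab), names(tab)))
      expect_equal(sum(unlist(qa$category_counts[[f]])) +
                     qa$missing_counts[[f]], qa$rows_out)
    }
  }
})
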