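test_that("authentication gives no account enumeration", {
  sc <- small_scenario(51, n_steps = 0)
  expect_s3_class(authenticate(sc$hub, "analyst", "pw-analyst"), "cares_session")
  e1 <- tryCatch(authenticate(sc$hub, "analyst", "wrong"), error = identity)
  e2 <- tryCatch(authenticate(sc$hub, "who", "wrong"), error = identity)
  expect_s3_class(e1, "caresr_authentication_error")
  expect_identical(conditionMessage(e1), conditionMessage(e2))
})

test_that("key-file import validates, dedupes and refuses ambiguity", {
  ids <- vapply(1:5, function(i) paste(rep(letters[i], 32), collapse = ""),
                character(1))
  good <- data.frame(cares_id = ids, person_key = paste0("K", 1:5))
  imp <- import_keyfile(good)
  expect_equal(nrow(imp$rows), 5L)
  expect_equal(imp$report$n_duplicates, 0L)
  expect_equal(imp$report$n_malformed, 0L)

  withdup <- rbind(good, good[1:2, ])
  imp2 <- import_keyfile(withdup)
  expect_equal(nrow(imp2$rows), 5L)
  expect_equal(imp2$report$n_duplicates, 2L)

  ambig <- rbind(good, data.frame(cares_id = ids[1], person_key = "K-other"))
  err <- tryCatch(import_keyfile(ambig), error = identity)
  expect_s3_class(err, "caresr_import_error")
  expect_match(conditionMessage(err), ids[1])

  malformed <- rbind(good, data.frame(cares_id = "short", person_key = "K9"))
  imp3 <- import_keyfile(malformed)
  expect_equal(imp3$report$n_malformed, 1L)

  expect_cares_error(import_keyfile(data.frame(a = 1)), "import_error")
  expect_cares_error(import_keyfile("/nonexistent/file.csv"), "io_error")

  # file path round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(good, path, row.names = FALSE)
  expect_equal(import_keyfile(path)$rows, imp$rows)
})

test_that("module output equals the fixture oracle across random scenarios", {
  for (seed in c(61, 62, 63)) {
    sz <- withr::with_seed(seed, list(nc = sample(1:4, 1), cs = sample(0:80, 1),
                                      ns = sample(0:4, 1)))
    sc <- small_scenario(seed, n_persons = 150, n_collections = sz$nc,
                         cohort_size = sz$cs, n_steps = sz$ns)
    run <- run_module(sc$hub, sc$session, sc$task)
    for (cid in names(run$outputs))
      expect_identical(run$outputs[[cid]]$records,
                       sc$fixture$expected_output[[cid]],
                       label = sprintf("seed %d collection %s", seed, cid))
  }
})

test_that("an empty key file yields an empty, fully accounted output", {
  sc <- small_scenario(64, cohort_size = 0, n_steps = 0)
  run <- run_module(sc$hub, sc$session, sc$task)
  for (cid in names(run$outputs)) {
    o <- run$outputs[[cid]]
    expect_equal(nrow(o$records), 0L)
    expect_equal(o$qa$rows_in, 0L)
    expect_equal(o$qa$rows_out, 0L)
  }
})

test_that("a single failing collection refuses the whole task, fail-closed", {
  sc <- small_scenario(65, n_collections = 2, n_steps = 0)
  revoke_access(sc$hub, "analyst", names(sc$collections)[2])
  expect_cares_error(run_module(sc$hub, sc$session, sc$task),
                     "authorisation_error")
  log <- audit_log(sc$hub)
  expect_true(any(log$action == "run_module" & log$outcome == "refused"))
  # no retrieval happened for the still-permitted first collection either
  expect_false(any(log$action == "query_records" &
                     grepl(sc$task$task_id, log$subject)))
})

test_that("steps referencing missing fields name the failing step", {
  sc <- small_scenario(66, n_steps = 0)
  bad_task <- sc$task
  bad_task$steps <- list(step_filter("units", ">=", 1),
                         step_filter("no_such_field", "=", "x"))
  err <- tryCatch(run_module(sc$hub, sc$session, bad_task), error = identity)
  expect_s3_class(err, "caresr_task_error")
  expect_match(conditionMessage(err), "step 2")
})

test_that("step order sensitivity matches the oracle", {
  base <- random_scenario(67, n_persons = 150, n_collections = 1,
                          cohort_size = 60, n_steps = 0)
  s_filter <- step_filter("units", ">=", 50)
  s_derive <- step_derived("units_scaled", "arith", expression = "units * 2")
  for (steps in list(list(s_filter, s_derive), list(s_derive, s_filter))) {
    task <- extraction_task("TP", base$task$project_id, "A",
                            base$task$key_files, steps = steps,
                            requested_on = base$task$requested_on)
    fx <- build_fixture(base$population, base$collections, base$cohort, task,
                        base$project_secret)
    task$key_files <- fx$key_files
    base2 <- base
    base2$task <- task
    base2$fixture <- fx
    hb <- scenario_hub(base2)
    ses <- authenticate(hb$hub, "analyst", "pw-analyst")
    run <- run_module(hb$hub, ses, task)
    expect_identical(run$outputs[["A"]]$records, fx$expected_output[["A"]])
  }
})

test_that("researcher-facing output carries person keys but no record tokens", {
  sc <- small_scenario(68, n_steps = 1)
  run <- run_module(sc$hub, sc$session, sc$task)
  for (o in run$outputs) {
    expect_true("person_key" %in% names(o$records))
    expect_false("cares_id" %in% names(o$records))
  }
  run_qa <- run_module(sc$hub, sc$session, sc$task, keep_record_token = TRUE)
  expect_true(all(vapply(run_qa$outputs, function(o)
    "cares_id" %in% names(o$records), logical(1))))
})

test_that("classical mode reproduces the records in each collection's dialect", {
  sc <- small_scenario(69, n_collections = 3, n_steps = 1)
  run_c <- run_module(sc$hub, sc$session, sc$task)
  run_k <- run_classical(sc$hub, sc$session, sc$task, seed = 7)
  for (cid in names(run_k$outputs)) {
    o <- run_k$outputs[[cid]]
    expect_identical(standardise(o$records, o$types),
                     run_c$outputs[[cid]]$records)
    # date fields rendered in the schema's declared input dialect
    schema <- sc$collections[[cid]]$schema
    dialect <- schema$fields$dialect[schema$fields$name == "event_date"]
    if (dialect == "DD/MM/YYYY" && "event_date" %in% names(o$records)) {
      vals <- o$records$event_date[nzchar(o$records$event_date)]
      expect_true(all(grepl("^[0-9]{2}/[0-9]{2}/[0-9]{4}$", vals)))
    }
  }

  zero <- run_classical(sc$hub, sc$session, sc$task,
                        delay_model = delay_model("constant", value = 0), seed = 1)
  for (o in zero$outputs) expect_equal(o$completed_on, sc$task$requested_on)
})

test_that("one operator session serves a whole multi-collection task", {
  sc <- small_scenario(70, n_collections = 4, n_steps = 0)
  run <- run_module(sc$hub, sc$session, sc$task)
  expect_length(run$outputs, 4L)
  log <- audit_log(sc$hub)
  # one successful login only, reused across all collections
  expect_equal(sum(log$action == "authenticate" & log$outcome == "allow"), 1L)
})
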