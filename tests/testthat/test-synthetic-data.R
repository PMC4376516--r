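test_that("population generation is sized, deterministic and seed-sensitive", {
  expect_equal(nrow(generate_population(1, seed = 7)), 1L)
  p1 <- generate_population(100, seed = 7)
  p2 <- generate_population(100, seed = 7)
  expect_identical(p1, p2)
  expect_false(anyDuplicated(p1$root_id) > 0)
  p3 <- generate_population(100, seed = 8)
  expect_true(any(p1$name != p3$name | p1$root_id != p3$root_id))
  expect_cares_error(generate_population(0, seed = 1), "invalid_parameter")
})

test_that("collection generation honours coverage, counts and dialects", {
  pop <- generate_population(1000, seed = 3)
  schema <- collection_schema(
    "H", "toy hospital", "uid",
    data.frame(name = c("adm", "sex"), type = c("date", "category"),
               dialect = c("DD/MM/YYYY", NA), levels = c(NA, "M|F")),
    approved_items = c("adm", "sex"))

  empty <- generate_collection(pop, schema, coverage = 0, seed = 1)
  expect_equal(nrow(empty$rows), 0L)

  forced <- generate_collection(pop, schema, coverage = 1,
                                mean_records_per_person = 1,
                                count_model = "constant", seed = 1)
  expect_equal(nrow(forced$rows), 1000L)
  expect_true(all(grepl("^[0-9]{2}/[0-9]{2}/[0-9]{4}$", forced$rows$adm)))

  # recompute the inclusion draw from the same derived sub-stream
  tbl <- generate_collection(pop, schema, coverage = 0.5, seed = 42)
  covered <- withr::with_seed(caresr:::sub_seed(42, "inclusion-H"),
                              runif(1000) < 0.5)
  expect_setequal(unique(tbl$rows$root_id), pop$root_id[covered])
})

test_that("schema invariants are enforced", {
  flds <- data.frame(name = "d", type = "date", dialect = "DD-MM-YY")
  expect_cares_error(
    collection_schema("X", "x", "uid", flds, approved_items = "d"),
    "schema_error")
  flds2 <- data.frame(name = "f", type = "text")
  expect_cares_error(
    collection_schema("X", "x", "uid", flds2, approved_items = c("uid", "f")),
    "schema_error")
})

test_that("project person keys are deterministic, scoped and injective", {
  keys1 <- derive_project_keys(c("r1", "r2"), "P1", "s3cret")
  expect_identical(keys1, derive_project_keys(c("r1", "r2"), "P1", "s3cret"))
  keys2 <- derive_project_keys(c("r1", "r2"), "P2", "s3cret")
  expect_true(all(keys1 != keys2))
  expect_cares_error(derive_project_keys("r1", "P1", ""), "configuration_error")

  roots <- sprintf("r%05d", 1:10000)
  expect_equal(length(unique(derive_project_keys(roots, "P1", "s"))), 10000L)
})

test_that("fixture ground truth equals a brute-force join", {
  sc <- random_scenario(11, n_persons = 150, n_collections = 2,
                        cohort_size = 150, n_steps = 0)
  fx <- sc$fixture
  for (cid in names(sc$collections)) {
    tbl <- sc$collections[[cid]]$table$rows
    n_expected <- sum(tbl$root_id %in% sc$cohort)
    expect_equal(nrow(fx$expected_output[[cid]]), n_expected)
    expect_equal(nrow(fx$key_files[[cid]]), n_expected)
  }

  # empty cohort boundary
  sc0 <- random_scenario(12, n_persons = 50, cohort_size = 0, n_steps = 0)
  expect_true(all(vapply(sc0$fixture$key_files, nrow, integer(1)) == 0L))
  expect_true(all(vapply(sc0$fixture$expected_output, nrow, integer(1)) == 0L))

  # an exclusion step equals a literal date filter of the no-step expectation
  base <- random_scenario(13, n_persons = 150, cohort_size = 80, n_steps = 0)
  cutoff <- as.Date("2003-01-01")
  task2 <- extraction_task("T2", base$task$project_id,
                           base$task$collection_ids, base$task$key_files,
                           steps = list(step_exclusion("event_date", "<", cutoff)),
                           requested_on = base$task$requested_on)
  fx2 <- build_fixture(base$population, base$collections, base$cohort, task2,
                       base$project_secret)
  for (cid in names(fx2$expected_output)) {
    manual <- base$fixture$expected_output[[cid]]
    d <- as.Date(manual$event_date, format = "%Y%m%d")
    manual <- manual[!(d < cutoff), , drop = FALSE]
    rownames(manual) <- NULL
    expect_identical(fx2$expected_output[[cid]], manual)
  }
})

test_that("discrepancy injection is exact and replayable", {
  sc <- small_scenario(14, n_steps = 0)
  run <- run_module(sc$hub, sc$session, sc$task)
  tab <- dedup_on_keys(run$outputs[[1]]$records)
  tab <- head(tab, 10)

  same <- inject_discrepancies(tab, 0, 0, seed = 1)
  expect_identical(same$table, tab)
  expect_equal(nrow(same$ledger), 0L)

  inj <- inject_discrepancies(tab, 3, 2, seed = 1)
  expect_equal(nrow(inj$table), 7L)
  expect_equal(nrow(inj$ledger), 5L)
  expect_identical(replay_ledger(tab, inj$ledger), inj$table)
  expect_cares_error(inject_discrepancies(tab, 8, 5, seed = 1),
                     "invalid_parameter")
})

test_that("fixtures round-trip through delimited text", {
  sc <- random_scenario(15, n_persons = 60, cohort_size = 20, n_steps = 1)
  dir <- withr::local_tempdir()
  write_fixture(sc$fixture, dir)
  back <- read_fixture(dir)
  for (cid in names(sc$fixture$key_files)) {
    expect_equal(back$key_files[[cid]], sc$fixture$key_files[[cid]])
    got <- back$expected_output[[cid]]
    expect_equal(got, sc$fixture$expected_output[[cid]])
  }
})

test_that("ground truth is a pure function of its inputs, engine-free", {
  # no hub exists here: the fixture's expectation cannot come from the
  # extraction path, and recomputation is exact
  sc <- random_scenario(16, n_persons = 40, cohort_size = 10, n_steps = 2)
  expect_s3_class(sc$fixture, "cares_fixture")
  fx <- build_fixture(sc$population, sc$collections, sc$cohort, sc$task,
                      sc$project_secret)
  expect_identical(fx$expected_output, sc$fixture$expected_output)
})
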