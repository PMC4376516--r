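test_that("only the full three-tier conjunction allows access", {
  combos <- expand.grid(conf = c(FALSE, TRUE), grant = c(FALSE, TRUE),
                        approval = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    d <- access_case(combos$conf[i], combos$grant[i], combos$approval[i])$decision
    if (all(unlist(combos[i, ]))) {
      expect_equal(d$decision, "allow")
    } else {
      expect_equal(d$decision, "deny")
      # deny reason is the first failing tier in fixed evaluation order
      expected_reason <- if (!combos$conf[i]) "no-confidentiality"
        else if (!combos$grant[i]) "no-dataset-grant"
        else "no-task-approval"
      expect_equal(d$reason, expected_reason)
    }
  }
})

test_that("grants are valid through their expiry date inclusive", {
  on_date <- as.Date("2013-01-01")
  expired <- access_case(TRUE, TRUE, TRUE, on_date = on_date,
                         expires_on = on_date - 1)$decision
  expect_equal(expired$reason, "grant-expired")
  boundary <- access_case(TRUE, TRUE, TRUE, on_date = on_date,
                          expires_on = on_date)$decision
  expect_equal(boundary$decision, "allow")
})

test_that("unknown principals raise lookup errors, distinct from deny", {
  cs <- access_case(TRUE, TRUE, TRUE)
  expect_cares_error(check_access(cs$hub, "ghost", "Z", "TK"), "lookup_error")
  expect_cares_error(check_access(cs$hub, "u", "NOPE", "TK"), "lookup_error")
  expect_cares_error(check_access(cs$hub, "u", "Z", "NOPE"), "lookup_error")
})

test_that("revoking a grant takes effect on the next check, uncached", {
  cs <- access_case(TRUE, TRUE, TRUE)
  expect_equal(check_access(cs$hub, "u", "Z", "TK",
                            as.Date("2013-01-01"))$decision, "allow")
  revoke_access(cs$hub, "u", "Z")
  expect_equal(check_access(cs$hub, "u", "Z", "TK",
                            as.Date("2013-01-01"))$reason, "no-dataset-grant")
})

test_that("a fresh user with no grants is denied on every collection", {
  sc <- small_scenario(41, n_collections = 3, n_steps = 0)
  register_user(sc$hub, "fresh", "cares-user", "pw",
                confidentiality_signed = as.Date("2012-01-01"))
  for (cid in names(sc$collections)) {
    d <- check_access(sc$hub, "fresh", cid, sc$task$task_id,
                      sc$task$requested_on)
    expect_equal(d$decision, "deny")
  }
})

test_that("workspace access is per-task and audited", {
  sc <- small_scenario(42, n_steps = 0)
  hub <- sc$hub
  task_a <- sc$task$task_id
  workspace_write(hub, "analyst", task_a, "notes", "criteria v1")
  expect_identical(workspace_read(hub, "analyst", task_a)$notes, "criteria v1")
  expect_cares_error(workspace_read(hub, "outsider", task_a), "authorisation_error")

  # approval is scoped: approved on task A does not open task B
  task_b <- extraction_task("TB", "PB", names(sc$collections)[1],
                            setNames(list(NULL), names(sc$collections)[1]))
  register_task(hub, task_b)
  create_workspace(hub, "TB", "custodian")
  expect_cares_error(workspace_read(hub, "analyst", "TB"), "authorisation_error")
})

test_that("the audit log detects deletion and survives bulk appends", {
  hub <- cares_hub()
  for (i in 1:5) audit_append(hub, "a", "act", paste0("s", i), "ok")
  expect_true(audit_verify(audit_log(hub))$ok)

  broken <- audit_log(hub)[-3, ]
  v <- audit_verify(broken)
  expect_false(v$ok)
  expect_equal(v$position, 3L)

  hub2 <- cares_hub()
  for (i in 1:1000) audit_append(hub2, "a", "act", as.character(i), "ok")
  v2 <- audit_verify(audit_log(hub2))
  expect_true(v2$ok)
  expect_equal(v2$n, 1000L)
})

test_that("every governed action leaves an audit trace", {
  sc <- small_scenario(43, n_steps = 0)
  run_module(sc$hub, sc$session, sc$task)
  bridge_decrypt(sc$hub, "lofficer", hub_table(sc$hub, names(sc$collections)[1])$cares_id[1])
  log <- audit_log(sc$hub)
  for (act in c("authenticate", "check_access", "run_module", "bridge_decrypt",
                "load_update", "grant_access", "approve_task"))
    expect_true(any(log$action == act), label = paste("audit has", act))
  # one run_module completion per run
  expect_equal(sum(log$action == "run_module" & log$outcome == "ok"), 1L)
})
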