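# Shared fixtures and independent oracles for the suite.

# Small end-to-end scenario with governed hub and authenticated analyst.
small_scenario <- function(seed = 101L, n_persons = 120L, n_collections = 2L,
                           cohort_size = 30L, n_steps = 1L, date_window = NULL) {
  sc <- random_scenario(seed, n_persons = n_persons,
                        n_collections = n_collections,
                        cohort_size = cohort_size, n_steps = n_steps,
                        date_window = date_window)
  hb <- scenario_hub(sc)
  sc$hub <- hb$hub
  sc$load_reports <- hb$load_reports
  sc$session <- authenticate(hb$hub, "analyst", "pw-analyst")
  sc
}

# Minimal one-collection governance world with each access tier toggleable.
access_case <- function(confidentiality, grant, approval,
                        on_date = as.Date("2013-01-01"),
                        expires_on = NA) {
  hub <- cares_hub()
  schema <- collection_schema("Z", "toy", "uid",
                              data.frame(name = "f1", type = "text"),
                              approved_items = "f1")
  register_collection(hub, schema)
  register_user(hub, "cust", "custodian", "pw",
                confidentiality_signed = on_date - 30)
  assign_custodian(hub, "cust", "Z")
  register_user(hub, "u", "cares-user", "pw",
                confidentiality_signed = if (confidentiality) on_date - 10 else NULL)
  task <- extraction_task("TK", "PR", "Z", list(Z = NULL),
                          requested_on = on_date)
  register_task(hub, task)
  if (grant) grant_access(hub, "u", "Z", "cust", on_date - 10,
                          expires_on = expires_on)
  if (approval) approve_task(hub, "TK", "Z", "cust", approved_on = on_date - 5)
  list(hub = hub, decision = check_access(hub, "u", "Z", "TK", on_date))
}

# Independent type-7 quantile/mean/sd oracle: naive sort-and-index with
# explicit linear interpolation, no calls into the package or quantile().
naive_summary <- function(x) {
  s <- sort(x)
  n <- length(s)
  qq <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  m <- sum(s) / n
  list(mean = m, q1 = qq(0.25), median = qq(0.5), q3 = qq(0.75),
       sd = if (n > 1) sqrt(sum((s - m)^2) / (n - 1)) else NA_real_)
}

# Deduplicate a standardised extract on its comparison keys so the key
# fields identify records (the parallel-run comparison precondition).
dedup_on_keys <- function(df, key_fields = default_key_fields(df)) {
  keys <- do.call(paste, c(df[key_fields], sep = "|"))
  out <- df[!duplicated(keys), , drop = FALSE]
  rownames(out) <- NULL
  out
}

expect_cares_error <- function(expr, kind) {
  testthat::expect_error(expr, class = paste0("caresr_", kind))
}
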