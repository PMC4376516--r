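# Turnaround tracking and summary tables.
#
# Extraction-level turnaround is the number of elapsed calendar days
# between an extraction's formal request and the extracted file being
# returned; project-level turnaround runs from request to final dispatch
# to the researcher. Summaries report mean, quartiles (type-7 linear
# interpolation) and the n-1 sample standard deviation per group, the
# shape in which operational results are reported: per collection and
# method, and per project by the extent of hub usage (none / part / all).

#' Elapsed calendar days between request and return
#'
#' Plain calendar-day difference, no business-day adjustment. Vectorised.
#'
#' @param requested_on,returned_on Dates (or ISO strings).
#' @return Integer days.
#' @export
turnaround_days <- function(requested_on, returned_on) {
  requested_on <- as_cares_date(requested_on, "requested_on")
  returned_on <- as_cares_date(returned_on, "returned_on")
  d <- as.integer(returned_on - requested_on)
  if (any(d < 0))
    cares_abort("returned_on precedes requested_on", "invalid_record")
  d
}

summarise_group <- function(days) {
  q <- unname(quantile(days, c(0.25, 0.5, 0.75), type = 7))
  list(n = length(days), mean = mean(days), q1 = q[1], median = q[2], q3 = q[3],
       sd = if (length(days) > 1L) sd(days) else NA_real_)
}

#' Summarise turnaround times
#'
#' Groups turnaround records and reports, per group: n, arithmetic mean,
#' first quartile, median, third quartile and the sample (n-1) standard
#' deviation (undefined for singleton groups).
#'
#' @param records Data frame. For `group_by = "collection_method"`:
#'   columns `collection_id`, `method` (`"cares"`/`"classical"`) and
#'   either `days` or both `requested_on`/`returned_on`. For
#'   `group_by = "usage"`: columns `usage` (`none`/`part`/`all`) and
#'   `days` or `request_on`/`dispatched_on`.
#' @param group_by Grouping: `"collection_method"` or `"usage"`.
#' @return Data frame, one row per group, empty for empty input.
#' @export
summarise_turnaround <- function(records, group_by = c("collection_method", "usage")) {
  group_by <- match.arg(group_by)
  cols <- if (group_by == "collection_method") c("collection_id", "method") else "usage"
  if (nrow(records) == 0L)
    return(new_df(setNames(rep(list(character(0)), length(cols)), cols),
                  n = integer(0), mean = numeric(0), q1 = numeric(0),
                  median = numeric(0), q3 = numeric(0), sd = numeric(0)))
  if (!"days" %in% names(records)) {
    records$days <- if (group_by == "collection_method")
      turnaround_days(records$requested_on, records$returned_on)
    else turnaround_days(records$request_on, records$dispatched_on)
  }
  key <- do.call(paste, c(records[cols], sep = "\x1f"))
  out <- lapply(sort(unique(key)), function(k) {
    sub <- records[key == k, , drop = FALSE]
    s <- summarise_group(sub$days)
    cbind(sub[1L, cols, drop = FALSE],
          new_df(n = s$n, mean = s$mean, q1 = s$q1, median = s$median,
                 q3 = s$q3, sd = s$sd))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify a project's hub usage
#'
#' `all` if every extraction used the hub, `none` if none did, else
#' `part`.
#'
#' @param methods Character vector of extraction methods
#'   (`"cares"`/`"classical"`), one per extraction of the project.
#' @return `"all"`, `"part"` or `"none"`.
#' @export
classify_usage <- function(methods) {
  if (length(methods) == 0L)
    cares_abort("a project must have at least one extraction", "invalid_project")
  n_cares <- sum(methods == "cares")
  if (n_cares == length(methods)) "all" else if (n_cares == 0L) "none" else "part"
}

## ---- harvesting timings from runs ---------------------------------------

#' Harvest turnaround records from executed runs
#'
#' Builds the extraction- and project-level turnaround streams from a set
#' of completed `cares_run` objects: hub-mode extractions complete with
#' their actual (same-day) elapsed time, classical-mode ones with their
#' simulated per-collection delays; a project's dispatch date is the
#' latest completion of its extractions plus `dispatch_delay_days`.
#'
#' @param runs List of `cares_run` objects (from [run_module()] /
#'   [run_classical()]).
#' @param project_ids Optional project id per run (defaults to the tasks').
#' @param dispatch_delay_days Days from last extraction return to final
#'   dispatch (checking, documentation).
#' @return List with `extractions` (a TurnaroundRecord data frame) and
#'   `projects` (a ProjectRecord data frame with usage labels).
#' @export
end_to_end_timings <- function(runs, project_ids = NULL, dispatch_delay_days = 0L) {
  recs <- list()
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    task <- run$task
    pid <- project_ids[i] %||% task$project_id
    for (cid in names(run$outputs)) {
      o <- run$outputs[[cid]]
      returned <- if (identical(o$mode, "classical")) o$completed_on
                  else task$completed_on
      recs[[length(recs) + 1L]] <-
        new_df(extraction_id = sprintf("%s_%s", task$task_id, cid),
               project_id = pid, collection_id = cid, method = o$mode,
               requested_on = task$requested_on, returned_on = returned)
    }
  }
  extractions <- do.call(rbind, recs)
  projects <- do.call(rbind, lapply(split(extractions, extractions$project_id),
    function(e) {
      new_df(project_id = e$project_id[1],
             n_extractions = nrow(e),
             usage = classify_usage(e$method),
             request_on = min(e$requested_on),
             dispatched_on = max(e$returned_on) + dispatch_delay_days)
    }))
  rownames(projects) <- NULL
  list(extractions = extractions, projects = projects)
}

## ---- simulation of an operational log ------------------------------------

#' Simulate an operational turnaround log
#'
#' Draws an extraction log under the package's delay calibration: each
#' project comprises a few collections, each extraction is served either
#' by the hub or classically, and elapsed days come from the respective
#' delay model. Used to demonstrate the qualitative turnaround pattern
#' (lower mean and lower spread under the hub) without operational data.
#'
#' @param n_extractions Number of extractions to simulate.
#' @param p_cares Probability an extraction is served by the hub.
#' @param cares_delays,classical_delays [delay_model()]s.
#' @param collections_per_project Typical number of collections per
#'   project (records are grouped into projects of about this size).
#' @param start_date First request date.
#' @param seed Integer seed.
#' @return TurnaroundRecord data frame (`extraction_id`, `project_id`,
#'   `collection_id`, `method`, `requested_on`, `returned_on`, `days`).
#' @export
simulate_turnaround_log <- function(n_extractions, p_cares = 0.5,
                                    cares_delays = cares_delay_model(),
                                    classical_delays = classical_delay_model(),
                                    collections_per_project = 4L,
                                    start_date = as.Date("2012-01-01"),
                                    seed = 1L) {
  with_seed(sub_seed(seed, "turnaround-log"), {
    project <- rep(seq_len(ceiling(n_extractions / collections_per_project)),
                   each = collections_per_project)[seq_len(n_extractions)]
    method <- ifelse(runif(n_extractions) < p_cares, "cares", "classical")
    delays <- numeric(n_extractions)
    delays[method == "cares"] <- draw_delays(cares_delays, sum(method == "cares"))
    delays[method == "classical"] <- draw_delays(classical_delays,
                                                 sum(method == "classical"))
    days <- as.integer(round(delays))
    requested <- start_date + sample.int(900L, n_extractions, replace = TRUE)
    new_df(extraction_id = sprintf("X%05d", seq_len(n_extractions)),
           project_id = sprintf("PRJ%04d", project),
           collection_id = sample(LETTERS[1:6], n_extractions, replace = TRUE),
           method = method, requested_on = requested,
           returned_on = requested + days, days = days)
  })
}

#' Project-level turnaround from an extraction log
#'
#' A project's turnaround runs from its first extraction request to the
#' return of its slowest extraction plus a dispatch allowance: a single
#' slow external collection therefore bounds the whole project from
#' below.
#'
#' @param log From [simulate_turnaround_log()] (or equivalent columns).
#' @param dispatch_delay_days Days added after the last return.
#' @return ProjectRecord data frame with `usage` labels and `days`.
#' @export
project_turnarounds <- function(log, dispatch_delay_days = 0L) {
  out <- do.call(rbind, lapply(split(log, log$project_id), function(e) {
    request <- min(e$requested_on)
    dispatched <- max(e$returned_on) + dispatch_delay_days
    new_df(project_id = e$project_id[1], n_extractions = nrow(e),
           usage = classify_usage(e$method), request_on = request,
           dispatched_on = dispatched,
           days = as.integer(dispatched - request))
  }))
  rownames(out) <- NULL
  out
}
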