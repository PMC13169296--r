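#' @title Batch orchestration, caching and job monitoring
#' @name orchestrator
#' @description Run batches of compounds through the full pipeline with
#'   per-row isolation, cache results keyed on (canonical SMILES, radical)
#'   so repeated requests never recompute, allocate CPU resources by
#'   system size, and monitor/rescue asynchronous jobs.
NULL

#' Allocate CPUs for a calculation by system size
#'
#' Monotone non-decreasing in the heavy-atom count and clamped to
#' `[min_cpus, max_cpus]`. With the default policy (one breakpoint at 30
#' heavy atoms) compounds up to 30 heavy atoms get 16 CPUs and larger ones
#' 32, matching a 16-32 CPU dynamic allocation.
#'
#' @param mol a `Molecule3D` (or an integer heavy-atom count).
#' @param policy list with `min_cpus`, `max_cpus` and sorted
#'   `breakpoints` (heavy-atom thresholds).
#' @return Integer CPU count.
#' @export
allocate_resources <- function(mol, policy = list(min_cpus = 16L, max_cpus = 32L,
                                                  breakpoints = 30L)) {
  heavy <- if (inherits(mol, "Molecule3D")) mol$heavy_atom_count else as.integer(mol)
  stopifnot(policy$min_cpus >= 1, policy$max_cpus >= policy$min_cpus)
  bp <- sort(policy$breakpoints)
  levels <- round(seq(policy$min_cpus, policy$max_cpus, length.out = length(bp) + 1L))
  idx <- 1L + sum(heavy > bp)
  as.integer(min(max(levels[idx], policy$min_cpus), policy$max_cpus))
}

# ---------------------------------------------------------------------------
# Results store: single-file JSON database keyed on (canonical SMILES, radical)
# ---------------------------------------------------------------------------

#' Open (or create) a results store
#'
#' A single-file embedded database (JSON) holding one `SelectivityReport`
#' (plus per-site TS provenance) per (canonical SMILES, radical) key.
#' Lookups never trigger recomputation.
#'
#' @param path file path of the store.
#' @return A `ResultsStore`.
#' @export
results_store <- function(path = tempfile(fileext = ".json")) {
  env <- new.env(parent = emptyenv())
  env$path <- path
  env$data <- if (file.exists(path) && file.size(path) > 0) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    list()
  }
  structure(env, class = "ResultsStore")
}

store_key <- function(canonical_smiles, radical_name) {
  paste(canonical_smiles, radical_name, sep = "\r")
}

#' @rdname results_store
#' @param store a `ResultsStore`.
#' @param canonical_smiles,radical_name record key.
#' @export
store_get <- function(store, canonical_smiles, radical_name) {
  rec <- store$data[[store_key(canonical_smiles, radical_name)]]
  if (is.null(rec)) return(NULL)
  report_from_list(rec)
}

#' @rdname results_store
#' @param report a `SelectivityReport` to persist.
#' @export
store_put <- function(store, canonical_smiles, radical_name, report) {
  key <- store_key(canonical_smiles, radical_name)
  store$data[[key]] <- report_to_list(report)
  writeLines(jsonlite::toJSON(store$data, auto_unbox = TRUE, digits = NA, null = "null"),
             store$path)
  invisible(store)
}

report_to_list <- function(report) {
  list(
    compound_id = report$compound_id, radical_name = report$radical_name,
    sites = lapply(seq_len(nrow(report$sites)), function(i) as.list(report$sites[i, ])),
    predicted_major = report$predicted_major, temperature = report$temperature,
    failures = as.integer(report$failures), tie = report$tie
  )
}

report_from_list <- function(rec) {
  sites <- do.call(rbind, lapply(rec$sites, function(s) {
    data.frame(site_id = as.integer(s$site_id), atom_index = as.integer(s$atom_index),
               symmetry_class = as.integer(s$symmetry_class),
               activation_energy = if (is.null(s$activation_energy)) NA_real_ else as.numeric(s$activation_energy),
               degeneracy = as.integer(s$degeneracy),
               ratio_percent = if (is.null(s$ratio_percent)) NA_real_ else as.numeric(s$ratio_percent))
  }))
  structure(list(
    compound_id = rec$compound_id, radical_name = rec$radical_name,
    sites = sites, predicted_major = as.integer(rec$predicted_major),
    temperature = as.numeric(rec$temperature),
    failures = as.integer(unlist(rec$failures)), tie = isTRUE(rec$tie)
  ), class = "SelectivityReport")
}

#' Canonical JSON serialization of a selectivity report
#'
#' @param report a `SelectivityReport`.
#' @return A JSON string (stable across identical reports).
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

#' Number of engine invocations recorded on an engine spec
#'
#' The in-process engines count every attempt; used to verify the cache
#' contract (a second identical batch performs zero invocations).
#'
#' @param spec an `EngineSpec`.
#' @return Integer count.
#' @export
engine_invocations <- function(spec) {
  if (is.null(spec$counter)) 0L else spec$counter$n
}

# ---------------------------------------------------------------------------
# Batch runner
# ---------------------------------------------------------------------------

#' Run a batch of compounds through the full pipeline
#'
#' For every row of the request: on a cache hit the stored report is
#' returned without touching the engine; otherwise the full pipeline runs
#' (parse and embed, enumerate sites, one TS guess / clash resolution /
#' bond correction / rescued TS search per symmetry class, Boltzmann
#' report), and the new report is persisted. One row's failure never
#' aborts the batch; failures are recorded per row.
#'
#' @param request a `BatchRequest` from [read_batch_csv()] (or any
#'   data.frame with `smiles`, `name`, `radical`).
#' @param engine an `EngineSpec`.
#' @param store a `ResultsStore`.
#' @param config see [regiots_config()].
#' @return List with `reports` (one `SelectivityReport` per successful
#'   row), `failures` (data.frame row index, name, reason) and `summary`
#'   (status counts).
#' @export
run_batch <- function(request, engine, store = results_store(),
                      config = regiots_config()) {
  stopifnot(is.data.frame(request), inherits(engine, "EngineSpec"),
            inherits(store, "ResultsStore"))
  if (!all(c("smiles", "name", "radical") %in% names(request))) {
    stop("configuration error: request must have smiles/name/radical columns")
  }
  reports <- list()
  failures <- data.frame(row = integer(), name = character(), reason = character())
  statuses <- character()
  for (i in seq_len(nrow(request))) {
    row <- request[i, ]
    res <- tryCatch({
      key_smiles <- canonical_smiles(row$smiles, config = config)
      cached <- store_get(store, key_smiles, row$radical)
      if (!is.null(cached)) {
        list(report = cached, status = "cached")
      } else {
        rep_i <- run_compound(row$smiles, row$name, row$radical, engine, config)
        store_put(store, key_smiles, row$radical, rep_i)
        list(report = store_get(store, key_smiles, row$radical), status = "computed")
      }
    }, error = function(e) list(report = NULL, status = "failed",
                                reason = conditionMessage(e)))
    statuses <- c(statuses, res$status)
    if (is.null(res$report)) {
      failures <- rbind(failures, data.frame(row = i, name = row$name,
                                             reason = res$reason))
      message("row ", i, " (", row$name, ") failed: ", res$reason)
    } else {
      reports[[length(reports) + 1L]] <- res$report
    }
  }
  summary <- table(factor(statuses, levels = c("computed", "cached", "failed")))
  message("batch complete: ", paste(names(summary), as.integer(summary),
                                    sep = "=", collapse = ", "))
  list(reports = reports, failures = failures, summary = summary)
}

#' Run the full single-compound pipeline
#'
#' @param smiles SMILES string.
#' @param compound_id compound label.
#' @param radical radical name (see [radical_registry()]).
#' @param engine an `EngineSpec`.
#' @param config see [regiots_config()].
#' @return A `SelectivityReport`.
#' @export
run_compound <- function(smiles, compound_id, radical, engine = engine_spec("mock"),
                         config = regiots_config()) {
  mol <- parse_smiles(smiles, compound_id, config = config)
  sites <- enumerate_sites(mol, config = config)
  if (nrow(sites) == 0L) stop("no candidate reaction sites in ", compound_id)
  # one TS search per symmetry class (symmetry-equivalent sites share it)
  reps <- sites[!duplicated(sites$symmetry_class), , drop = FALSE]
  results <- lapply(seq_len(nrow(reps)), function(k) {
    g <- build_guess(mol, reps[k, ], radical, config = config)
    g <- resolve_clashes(g, config = config)
    g <- apply_bond_correction(g, config = config)
    run_ts_search(g, engine, config = config)
  })
  selectivity_report(compound_id, tolower(as.character(radical)), sites, results,
                     config = config)
}

# ---------------------------------------------------------------------------
# Job records and monitoring
# ---------------------------------------------------------------------------

job_transitions <- list(
  pending = "running",
  running = c("rescuing", "done", "failed", "running"),
  rescuing = "running",
  done = character(), failed = character()
)

#' Create job records for submitted TS searches
#'
#' @param compound_id,site_id,radical_name vectors (recycled) describing
#'   each job.
#' @param resource_cpus CPUs allocated per job.
#' @return Data.frame of `JobRecord` rows in state `"pending"`.
#' @export
job_records <- function(compound_id, site_id, radical_name, resource_cpus = 16L) {
  n <- max(length(compound_id), length(site_id), length(radical_name))
  df <- data.frame(
    job_id = sprintf("job%03d", seq_len(n)),
    compound_id = rep_len(compound_id, n),
    site_id = rep_len(site_id, n),
    radical_name = rep_len(radical_name, n),
    state = "pending",
    resource_cpus = rep_len(as.integer(resource_cpus), n),
    resubmissions = 0L,
    submitted_at = NA_character_, last_check = NA_character_,
    finished_at = NA_character_
  )
  class(df) <- c("JobRecord", "data.frame")
  df
}

advance_state <- function(from, to) {
  if (!to %in% job_transitions[[from]]) {
    stop("illegal job transition ", from, " -> ", to)
  }
  to
}

#' Poll running jobs, rescue drifters, collect finished results
#'
#' Each pending job is submitted (state `running`); each running job's
#' monitor snapshot is inspected: finished jobs advance to `done` or
#' `failed`; jobs whose intermediate trajectory is drifting to a minimum
#' are moved to `rescuing` and resubmitted with a modified geometry
#' (`resubmissions` incremented); `rescuing` jobs return to `running` on
#' the next poll. An unreachable monitor leaves the job `running` with a
#' warning (transient-failure tolerance). Polling with no engine progress
#' is idempotent.
#'
#' @param records a `JobRecord` data.frame.
#' @param engine an `EngineSpec` whose `monitor` field is a
#'   `function(job_id)` returning `list(finished, status, trajectory,
#'   guess_cc)`; absent monitor means "everything finished ok".
#' @param config see [regiots_config()].
#' @return The updated records.
#' @export
poll_jobs <- function(records, engine, config = regiots_config()) {
  stopifnot(is.data.frame(records))
  now <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  monitor <- engine$monitor %||% function(job_id) list(finished = TRUE, status = "done")
  for (i in seq_len(nrow(records))) {
    st <- records$state[i]
    if (st == "pending") {
      records$state[i] <- advance_state(st, "running")
      records$submitted_at[i] <- now
      next
    }
    if (st == "rescuing") {
      records$state[i] <- advance_state(st, "running")
      next
    }
    if (st != "running") next
    snap <- tryCatch(monitor(records$job_id[i]), error = function(e) e)
    records$last_check[i] <- now
    if (inherits(snap, "error")) {
      warning("monitor unreachable for ", records$job_id[i],
              "; leaving job running")
      next
    }
    if (isTRUE(snap$finished)) {
      to <- if (identical(snap$status, "failed")) "failed" else "done"
      records$state[i] <- advance_state(st, to)
      records$finished_at[i] <- now
      next
    }
    if (!is.null(snap$trajectory) && length(snap$trajectory)) {
      pseudo_guess <- list(cc_distance = snap$guess_cc %||% config$initial_cc_angstrom)
      traj <- classify_trajectory(
        stationary_report(FALSE, trajectory_summary = snap$trajectory),
        pseudo_guess, config)
      if (traj %in% c("drifting_to_product", "drifting_to_reactant")) {
        records$state[i] <- advance_state(st, "rescuing")
        records$resubmissions[i] <- records$resubmissions[i] + 1L
      }
    }
  }
  records
}
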