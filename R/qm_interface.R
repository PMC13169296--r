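#' @title Pluggable quantum-chemistry calculator layer
#' @name qm_interface
#' @description Write engine input decks, parse engine outputs, classify
#'   optimization trajectories, and drive the transition-state search /
#'   rescue state machine. A deterministic mock engine makes the whole
#'   workflow testable without any quantum-chemistry installation; the
#'   semiempirical (MOPAC-format) and ab-initio (NWChem-format) adapters
#'   emit and parse those engines' file formats but never run them.
NULL

#' Describe a calculation engine
#'
#' @param engine_name one of `"mock"`, `"scripted"`, `"semiempirical"`,
#'   `"hartree_fock"`.
#' @param method_label free-text method recorded in provenance (e.g.
#'   `"AM1"`, `"HF/6-31G*"`).
#' @param work_dir directory for input/output files.
#' @param cpu_count,wall_limit resource request recorded with each job.
#' @param surface mock-surface parameters (see [mock_surface()]); used by
#'   the mock engine.
#' @param script for `"scripted"`: list of `StationaryPointReport`s
#'   returned one per attempt (see [make_engine_script()]).
#' @return An `EngineSpec`.
#' @export
engine_spec <- function(engine_name = c("mock", "scripted", "semiempirical", "hartree_fock"),
                        method_label = NULL, work_dir = tempdir(),
                        cpu_count = 1L, wall_limit = "12:00:00",
                        surface = NULL, script = NULL) {
  engine_name <- match.arg(engine_name)
  stopifnot(cpu_count >= 1)
  if (is.null(method_label)) {
    method_label <- switch(engine_name,
                           mock = "mock-surface", scripted = "scripted",
                           semiempirical = "AM1", hartree_fock = "HF/6-31G*")
  }
  if (engine_name == "mock" && is.null(surface)) surface <- mock_surface()
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  spec <- list(engine_name = engine_name, method_label = method_label,
               work_dir = work_dir, cpu_count = as.integer(cpu_count),
               wall_limit = wall_limit, surface = surface, counter = counter)
  if (!is.null(script)) {
    spec$script <- script
    spec$script_pos <- new.env(parent = emptyenv())
    spec$script_pos$i <- 0L
  }
  structure(spec, class = "EngineSpec")
}

#' Construct a stationary-point report
#'
#' Normal result container for one engine attempt. Frequencies are signed
#' wavenumbers (negative = imaginary); the imaginary count and leading
#' imaginary magnitude are derived, never stored independently.
#'
#' @param converged logical.
#' @param energy electronic energy in hartree.
#' @param frequencies numeric vector of vibrational wavenumbers in cm^-1.
#' @param final_geometry optional n x 3 coordinate matrix (Å).
#' @param trajectory_summary per-step forming-bond distances (Å).
#' @param reference_energy optional reactant-asymptote energy in hartree
#'   (isolated substrate + isolated radical at the same level).
#' @param unreadable marks a structurally unreadable output (hard failure).
#' @return A `StationaryPointReport`.
#' @export
stationary_report <- function(converged, energy = NA_real_, frequencies = numeric(),
                              final_geometry = NULL, trajectory_summary = numeric(),
                              reference_energy = NA_real_, unreadable = FALSE) {
  imag <- sum(frequencies < 0)
  structure(list(
    converged = isTRUE(converged),
    energy = energy,
    frequencies = frequencies,
    imaginary_count = imag,
    leading_imaginary = if (imag >= 1) max(abs(frequencies[frequencies < 0])) else NA_real_,
    final_geometry = final_geometry,
    trajectory_summary = trajectory_summary,
    reference_energy = reference_energy,
    unreadable = isTRUE(unreadable)
  ), class = "StationaryPointReport")
}

deck_path <- function(guess, spec, ext) {
  file.path(spec$work_dir,
            sprintf("%s_site%s_%s%s", gsub("[^A-Za-z0-9_.-]", "_", guess$compound_id),
                    guess$site$site_id, guess$radical_name, ext))
}

#' Write an engine input deck for a TS guess
#'
#' For the mock engine a self-describing JSON job file is written; the
#' semiempirical adapter emits a MOPAC-format deck (AM1 TS search, then a
#' FORCE frequency job); the ab-initio adapter emits an NWChem-format deck
#' (saddle-point optimization plus frequency task at the configured
#' method). Decks are byte-stable given identical inputs.
#'
#' @param guess a `TSGuess`.
#' @param spec an `EngineSpec`.
#' @param tightened apply tightened convergence criteria (the configured
#'   `tighten_factor` on gradient/energy tolerances).
#' @param config see [regiots_config()].
#' @return The path of the written file.
#' @export
write_engine_input <- function(guess, spec, tightened = FALSE,
                               config = regiots_config()) {
  stopifnot(inherits(guess, "TSGuess"), inherits(spec, "EngineSpec"))
  el <- guess$geometry$elements
  xyz <- guess$geometry$coords
  tf <- if (tightened) config$tighten_factor else 1
  if (spec$engine_name %in% c("mock", "scripted")) {
    path <- deck_path(guess, spec, ".json")
    job <- list(
      engine = spec$engine_name, method_label = spec$method_label,
      compound_id = guess$compound_id, site_id = guess$site$site_id,
      radical = guess$radical_name,
      forming_bond = unname(guess$forming_bond),
      cc_distance = guess$cc_distance, tightened = tightened,
      geometry = list(elements = el, coords = apply(xyz, 1, function(r) round(r, 6),
                                                    simplify = FALSE))
    )
    writeLines(jsonlite::toJSON(job, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
    return(path)
  }
  if (spec$engine_name == "semiempirical") {
    path <- deck_path(guess, spec, ".mop")
    keywords <- sprintf("AM1 TS PRECISE GNORM=%.4f", 1.0 * tf)
    lines <- c(keywords,
               sprintf("regiots %s site %s + %s", guess$compound_id,
                       guess$site$site_id, guess$radical_name),
               "",
               sprintf("%-2s %12.6f 1 %12.6f 1 %12.6f 1",
                       el, xyz[, 1], xyz[, 2], xyz[, 3]),
               "",
               sub("TS PRECISE", "FORCE", keywords))
    writeLines(lines, path)
    return(path)
  }
  if (spec$engine_name == "hartree_fock") {
    path <- deck_path(guess, spec, ".nw")
    lines <- c(
      sprintf("start %s_site%s", gsub("[^A-Za-z0-9_]", "_", guess$compound_id),
              guess$site$site_id),
      sprintf("title \"regiots %s site %s + %s\"", guess$compound_id,
              guess$site$site_id, guess$radical_name),
      "geometry units angstroms noautosym noautoz",
      sprintf("  %-2s %14.6f %14.6f %14.6f", el, xyz[, 1], xyz[, 2], xyz[, 3]),
      "end",
      "basis", "  * library 6-31G*", "end",
      "scf", "  uhf", "  doublet",
      sprintf("  thresh %.2e", 1e-4 * tf), "end",
      "driver",
      sprintf("  gmax %.6f", 0.00045 * tf),
      sprintf("  grms %.6f", 0.00030 * tf),
      "end",
      "task scf saddle",
      "task scf freq")
    writeLines(lines, path)
    return(path)
  }
  stop("configuration error: unknown engine ", spec$engine_name)
}

#' Parse an engine output file into a stationary-point report
#'
#' Understands the mock engine's JSON results, MOPAC-format output (final
#' heat of formation, `ROOT NO.` frequency blocks, Cartesian coordinate
#' block) and NWChem-format output (`Total SCF energy`, `P.Frequency`
#' rows, `Output coordinates` block). Warnings in the file are tolerated;
#' only structurally unreadable files raise a parse error carrying the
#' last readable marker. Energies are returned in hartree.
#'
#' @param path output file path.
#' @param engine an `EngineSpec` (selects the dialect).
#' @return A `StationaryPointReport`.
#' @export
parse_engine_output <- function(path, engine) {
  if (!file.exists(path)) stop("parse error: no such output file: ", path)
  if (file.size(path) == 0) stop("parse error: empty output file (last marker: <none>)")
  if (engine$engine_name %in% c("mock", "scripted")) {
    res <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                    error = function(e) stop("parse error: unreadable JSON result (",
                                             conditionMessage(e), ")", call. = FALSE))
    geom <- if (!is.null(res$final_geometry)) as.matrix(res$final_geometry) else NULL
    return(stationary_report(
      converged = isTRUE(res$converged), energy = res$energy %||% NA_real_,
      frequencies = as.numeric(res$frequencies %||% numeric()),
      final_geometry = geom,
      trajectory_summary = as.numeric(res$trajectory_summary %||% numeric()),
      reference_energy = res$reference_energy %||% NA_real_))
  }
  lines <- readLines(path, warn = FALSE)
  if (engine$engine_name == "semiempirical") {
    parse_mopac_output(lines)
  } else if (engine$engine_name == "hartree_fock") {
    parse_nwchem_output(lines)
  } else {
    stop("configuration error: unknown engine ", engine$engine_name)
  }
}

numbers_in <- function(line) {
  m <- regmatches(line, gregexpr("[-+]?[0-9]*\\.?[0-9]+(?:[eEdD][-+]?[0-9]+)?", line))[[1]]
  as.numeric(gsub("[dD]", "e", m))
}

parse_mopac_output <- function(lines) {
  last_marker <- "<none>"
  hof <- grep("FINAL HEAT OF FORMATION", lines, value = TRUE)
  energy <- NA_real_
  converged <- FALSE
  if (length(hof)) {
    last_marker <- "FINAL HEAT OF FORMATION"
    kcal <- numbers_in(hof[length(hof)])[1]
    energy <- kcal / HARTREE_TO_KCAL
    converged <- TRUE
  }
  freqs <- numeric()
  root_rows <- grep("ROOT NO\\.", lines)
  for (i in root_rows) {
    j <- i + 1
    while (j <= length(lines) && !nzchar(trimws(lines[j]))) j <- j + 1
    if (j <= length(lines)) freqs <- c(freqs, numbers_in(lines[j]))
    last_marker <- "ROOT NO."
  }
  geom <- NULL
  gi <- grep("CARTESIAN COORDINATES", lines)
  if (length(gi)) {
    last_marker <- "CARTESIAN COORDINATES"
    j <- gi[length(gi)] + 1
    rows <- list()
    while (j <= length(lines)) {
      nums <- numbers_in(lines[j])
      if (length(nums) >= 4) {
        rows[[length(rows) + 1L]] <- utils::tail(nums, 3)
      } else if (length(rows) > 0) break
      j <- j + 1
    }
    if (length(rows)) geom <- do.call(rbind, rows)
  }
  if (!converged && !length(freqs)) {
    stop("parse error: no recognizable result in MOPAC output (last marker: ",
         last_marker, ")", call. = FALSE)
  }
  stationary_report(converged = converged, energy = energy, frequencies = freqs,
                    final_geometry = geom)
}

parse_nwchem_output <- function(lines) {
  last_marker <- "<none>"
  energy <- NA_real_
  converged <- any(grepl("Optimization converged", lines))
  en <- grep("Total SCF energy", lines, value = TRUE)
  if (length(en)) {
    last_marker <- "Total SCF energy"
    energy <- numbers_in(en[length(en)])[1]
  }
  freqs <- numeric()
  fr <- grep("P\\.Frequency", lines, value = TRUE)
  if (length(fr)) {
    last_marker <- "P.Frequency"
    freqs <- unlist(lapply(fr, numbers_in))
  }
  geom <- NULL
  gi <- grep("Output coordinates", lines)
  if (length(gi)) {
    last_marker <- "Output coordinates"
    j <- gi[length(gi)] + 1
    rows <- list()
    while (j <= length(lines)) {
      nums <- numbers_in(lines[j])
      if (length(nums) >= 4) {
        rows[[length(rows) + 1L]] <- utils::tail(nums, 3)
      } else if (length(rows) > 0) break
      j <- j + 1
    }
    if (length(rows)) geom <- do.call(rbind, rows)
  }
  if (is.na(energy) && !length(freqs)) {
    stop("parse error: no recognizable result in NWChem output (last marker: ",
         last_marker, ")", call. = FALSE)
  }
  stationary_report(converged = converged, energy = energy, frequencies = freqs,
                    final_geometry = geom)
}

#' Classify a TS-search trajectory
#'
#' Inspects the per-step forming-bond distances of an optimization and
#' decides whether the search is collapsing to the addition product
#' (monotone decrease below the product threshold), dissociating back to
#' reactants (monotone increase beyond the dissociation threshold),
#' holding in the saddle region (recent steps within a band around the
#' guess distance), or none of these.
#'
#' @param report a `StationaryPointReport` with non-empty
#'   `trajectory_summary`.
#' @param guess the `TSGuess` the search started from (supplies the band
#'   centre).
#' @param config thresholds: `product_threshold_angstrom`,
#'   `dissociation_threshold_angstrom`, `saddle_band_angstrom`.
#' @return One of `"on_saddle"`, `"drifting_to_product"`,
#'   `"drifting_to_reactant"`, `"indeterminate"`.
#' @export
classify_trajectory <- function(report, guess, config = regiots_config()) {
  d <- report$trajectory_summary
  stopifnot(length(d) >= 1)
  diffs <- diff(d)
  final <- d[length(d)]
  if (length(d) >= 2 && all(diffs <= 0) && final < config$product_threshold_angstrom) {
    return("drifting_to_product")
  }
  if (length(d) >= 2 && all(diffs >= 0) && final > config$dissociation_threshold_angstrom) {
    return("drifting_to_reactant")
  }
  recent <- utils::tail(d, 3L)
  if (all(abs(recent - guess$cc_distance) <= config$saddle_band_angstrom)) {
    return("on_saddle")
  }
  "indeterminate"
}

# ---------------------------------------------------------------------------
# Rescue state machine
# ---------------------------------------------------------------------------

# Decide the next rescue action from a report; NULL means success.
# Exported for transition-table testing via run_ts_search attempts.
next_rescue_action <- function(report, guess, tighten_used, config) {
  if (report$unreadable) return("abort")
  ok_ts <- report$converged && report$imaginary_count == 1 &&
    !is.na(report$leading_imaginary) &&
    report$leading_imaginary >= config$min_imaginary_cm
  if (ok_ts) return(NULL)
  traj <- if (length(report$trajectory_summary)) {
    classify_trajectory(report, guess, config)
  } else "indeterminate"
  if (traj %in% c("drifting_to_product", "drifting_to_reactant")) {
    return("restart_modified_geometry")
  }
  if (report$converged && report$imaginary_count == 0) {
    return("constrained_opt_research")
  }
  if (report$imaginary_count >= 2) {
    return("restart_from_final")
  }
  if (!tighten_used) return("tightened_convergence")
  "abort"
}

final_status <- function(report) {
  if (is.null(report) || report$unreadable) return("failed")
  if (report$imaginary_count >= 2) return("second_imaginary")
  if (report$converged && report$imaginary_count == 0) return("converged_to_minimum")
  "failed"
}

#' Run a transition-state search with automatic rescue
#'
#' Drives one site's TS search through the rescue state machine:
#' \enumerate{
#'   \item initial TS search plus frequency calculation;
#'   \item trajectory drifting to a minimum (product or reactant) ->
#'     restart from a modified geometry with the forming bond reset to the
#'     guess value;
#'   \item converged with zero imaginary frequencies -> constrained
#'     optimization with the forming bond frozen, then a fresh TS search;
#'   \item two or more imaginary frequencies -> restart from the final
#'     structure of the previous search;
#'   \item otherwise (including spurious small imaginaries) -> one retry
#'     with tightened convergence criteria.
#' }
#' The loop stops at the first validated transition state (exactly one
#' imaginary frequency of magnitude at least `min_imaginary_cm`) or when
#' the retry budget is exhausted, in which case the status reflects the
#' terminal failure mode (`second_imaginary`, `converged_to_minimum` or
#' `failed`). Engine-level errors yield status `failed`, never an uncaught
#' crash.
#'
#' @param guess a `TSGuess` (after clash resolution and bond correction).
#' @param spec an `EngineSpec` (`mock` and `scripted` run in-process).
#' @param policy optional overrides: `retry_budget`, `min_imaginary_cm`.
#' @param config see [regiots_config()].
#' @return A `TSResult`: `status` in `{true_ts, converged_to_minimum,
#'   second_imaginary, failed}`, `activation_energy` (kcal/mol, relative
#'   to separated reactants; present only for `true_ts`), and `attempts`,
#'   an ordered list of `(action, report)` pairs.
#' @export
run_ts_search <- function(guess, spec, policy = list(), config = regiots_config()) {
  stopifnot(inherits(guess, "TSGuess"), inherits(spec, "EngineSpec"))
  budget <- policy$retry_budget %||% config$retry_budget
  cfg <- config
  if (!is.null(policy$min_imaginary_cm)) cfg$min_imaginary_cm <- policy$min_imaginary_cm

  attempts <- list()
  action <- "initial"
  tighten_used <- FALSE
  state <- guess
  last_report <- NULL

  for (i in seq_len(budget)) {
    report <- tryCatch(
      engine_attempt(state, spec, tightened = identical(action, "tightened_convergence"),
                     constrained = identical(action, "constrained_opt_research"),
                     config = cfg),
      error = function(e) stationary_report(FALSE, unreadable = TRUE)
    )
    attempts[[i]] <- list(action = action, report = report)
    last_report <- report
    nxt <- next_rescue_action(report, guess, tighten_used, cfg)
    if (is.null(nxt)) {
      ref <- report$reference_energy
      if (is.na(ref) && !is.null(spec$surface)) ref <- spec$surface$reference_hartree
      ea <- if (!is.na(ref) && !is.na(report$energy)) {
        (report$energy - ref) * HARTREE_TO_KCAL
      } else NA_real_
      return(structure(list(site = guess$site, compound_id = guess$compound_id,
                            radical_name = guess$radical_name, status = "true_ts",
                            activation_energy = ea, attempts = attempts),
                       class = "TSResult"))
    }
    if (identical(nxt, "abort") || i == budget) break
    if (identical(nxt, "tightened_convergence")) tighten_used <- TRUE
    state <- apply_rescue(state, guess, report, nxt)
    action <- nxt
  }
  structure(list(site = guess$site, compound_id = guess$compound_id,
                 radical_name = guess$radical_name, status = final_status(last_report),
                 activation_energy = NA_real_, attempts = attempts),
            class = "TSResult")
}

# Geometry modification for each rescue action.
apply_rescue <- function(state, guess, report, action) {
  if (action == "restart_modified_geometry") {
    # reset the forming bond to the (corrected) guess value
    delta <- guess$cc_distance - state$cc_distance
    if (abs(delta) > 1e-12) state <- apply_bond_correction(state, delta)
    return(state)
  }
  if (action == "restart_from_final" && !is.null(report$final_geometry) &&
      nrow(report$final_geometry) == nrow(state$geometry$coords)) {
    state$geometry$coords <- report$final_geometry
    fb <- state$forming_bond
    state$cc_distance <- vnorm(state$geometry$coords[fb[["radical"]], ] -
                               state$geometry$coords[fb[["substrate"]], ])
  }
  state
}

# Dispatch one engine attempt.
engine_attempt <- function(state, spec, tightened, constrained, config) {
  if (!is.null(spec$counter)) spec$counter$n <- spec$counter$n + 1L
  if (spec$engine_name == "mock") {
    return(mock_energy(state, spec$surface))
  }
  if (spec$engine_name == "scripted") {
    pos <- spec$script_pos
    pos$i <- pos$i + 1L
    if (pos$i > length(spec$script)) stop("scripted engine exhausted")
    rep <- spec$script[[pos$i]]
    if (isTRUE(rep$unreadable)) stop("unreadable engine output")
    return(rep)
  }
  # Real engines: write the deck; an external runner must execute it.
  path <- write_engine_input(state, spec, tightened = tightened, config = config)
  out <- sub("\\.(mop|nw)$", ".out", path)
  if (!file.exists(out)) {
    stop("engine output not found for ", basename(path),
         " (no external runner configured)")
  }
  parse_engine_output(out, spec)
}

#' @export
print.TSResult <- function(x, ...) {
  cat("<TSResult> ", x$compound_id, " site ", x$site$site_id, " + ",
      x$radical_name, ": ", x$status, sep = "")
  if (!is.na(x$activation_energy)) {
    cat(sprintf(" (Ea = %.2f kcal/mol)", x$activation_energy))
  }
  cat(" [", length(x$attempts), " attempt(s): ",
      paste(vapply(x$attempts, `[[`, "", "action"), collapse = " -> "),
      "]\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Mock engine
# ---------------------------------------------------------------------------

#' Parameters of the deterministic mock energy surface
#'
#' The mock engine assigns each site a synthetic activation barrier:
#' a base value, plus an electronic term keyed on the site's topological
#' symmetry class (a seeded hash, so symmetry-equivalent sites always get
#' identical energies), plus a steric term proportional to the number of
#' substituted ortho ring neighbours. Identical inputs give identical
#' outputs.
#'
#' @param seed integer noise seed.
#' @param base_kcal base barrier (kcal/mol).
#' @param class_spread_kcal amplitude of the per-class electronic term.
#' @param steric_kcal penalty per substituted ortho neighbour.
#' @param reference_hartree reactant-asymptote energy used as the
#'   activation-energy reference.
#' @param class_offsets optional named numeric vector of explicit
#'   per-class offsets (names = symmetry-class labels), overriding the
#'   hashed term.
#' @return Parameter list for [mock_energy()].
#' @export
mock_surface <- function(seed = 1L, base_kcal = 8.0, class_spread_kcal = 4.0,
                         steric_kcal = 0.8, reference_hartree = -100.0,
                         class_offsets = NULL) {
  list(seed = as.integer(seed), base_kcal = base_kcal,
       class_spread_kcal = class_spread_kcal, steric_kcal = steric_kcal,
       reference_hartree = reference_hartree, class_offsets = class_offsets)
}

# Deterministic string hash -> [0, 1). Two passes so that a change in the
# final character still diffuses through the whole accumulator.
hash01 <- function(s) {
  h <- 0
  codes <- utf8ToInt(s)
  for (code in c(codes, codes)) h <- (h * 31 + code) %% 2147483647
  h / 2147483647
}

#' Evaluate the mock energy surface for a TS guess
#'
#' @param guess a `TSGuess`.
#' @param params see [mock_surface()].
#' @return A `StationaryPointReport` with `imaginary_count = 1`, a stable
#'   trajectory around the guess distance, and `reference_energy` set so
#'   activation energies can be formed.
#' @export
mock_energy <- function(guess, params = mock_surface()) {
  stopifnot(inherits(guess, "TSGuess"))
  cls <- as.character(guess$symmetry_class)
  elec <- if (!is.null(params$class_offsets) && cls %in% names(params$class_offsets)) {
    params$class_offsets[[cls]]
  } else {
    params$class_spread_kcal * hash01(paste(params$seed, guess$compound_id, cls))
  }
  barrier_kcal <- params$base_kcal + elec + params$steric_kcal * guess$ortho_substituted
  energy <- params$reference_hartree + barrier_kcal / HARTREE_TO_KCAL
  d <- guess$cc_distance
  stationary_report(
    converged = TRUE,
    energy = energy,
    frequencies = c(-520.4, 38.2, 77.5, 401.9, 1180.3),
    final_geometry = guess$geometry$coords,
    trajectory_summary = c(d, d - 0.01, d + 0.008, d),
    reference_energy = params$reference_hartree
  )
}
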