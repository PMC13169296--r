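# Hand-written transition table for the rescue state machine: scenario ->
# (action sequence, terminal status). Kept independent of the generator in
# R/fixtures.R so the machine is checked against a second source of truth.
rescue_oracle <- list(
  immediate_ts = list(actions = "initial", status = "true_ts"),
  drift_product_then_ts = list(actions = c("initial", "restart_modified_geometry"),
                               status = "true_ts"),
  drift_reactant_then_ts = list(actions = c("initial", "restart_modified_geometry"),
                                status = "true_ts"),
  zero_imaginary_then_ts = list(actions = c("initial", "constrained_opt_research"),
                                status = "true_ts"),
  double_imaginary_persistent = list(actions = c("initial", "restart_from_final",
                                                 "restart_from_final"),
                                     status = "second_imaginary"),
  hard_failure = list(actions = "initial", status = "failed")
)

make_test_guess <- function(radical = "trifluoromethyl", correct = TRUE) {
  pyr <- fixture_mol("pyridine", embed = TRUE)
  g <- build_guess(pyr, enumerate_sites(pyr)[1, ], radical)
  g <- resolve_clashes(g)
  if (correct) g <- apply_bond_correction(g)
  g
}

test_that("input decks are well-formed and byte-stable", {
  g <- make_test_guess()
  dir <- withr::local_tempdir()

  mock <- engine_spec("mock", work_dir = dir)
  p <- write_engine_input(g, mock)
  job <- jsonlite::fromJSON(p)
  expect_equal(job$engine, "mock")
  expect_equal(job$forming_bond, g$forming_bond, ignore_attr = TRUE)
  expect_length(job$geometry$elements, 15)
  expect_equal(job$cc_distance, g$cc_distance, tolerance = 1e-9)

  am1 <- engine_spec("semiempirical", work_dir = dir)
  pm <- write_engine_input(g, am1)
  lines <- readLines(pm)
  expect_match(lines[1], "^AM1 TS")
  geom_lines <- grep("^[A-Z][a-z]? +-?[0-9]", lines)
  expect_length(geom_lines, 15)

  hf <- engine_spec("hartree_fock", work_dir = dir)
  pn <- write_engine_input(g, hf)
  nw <- readLines(pn)
  expect_true(any(grepl("task scf saddle", nw)))
  expect_true(any(grepl("task scf freq", nw)))
  expect_true(any(grepl("6-31G\\*", nw)))

  # determinism
  expect_identical(readLines(write_engine_input(g, am1)), lines)
  expect_identical(readLines(write_engine_input(g, hf)), nw)

  # tightened convergence scales the thresholds by the configured factor
  tight <- readLines(write_engine_input(g, hf, tightened = TRUE))
  get_gmax <- function(l) as.numeric(sub(".*gmax ", "", grep("gmax", l, value = TRUE)))
  expect_equal(get_gmax(tight) / get_gmax(nw), 0.1, tolerance = 1e-6)
})

test_that("output parsing counts imaginary frequencies from synthetic engine files", {
  dir <- withr::local_tempdir()
  freqs <- c(-450.2, 35.1, 60.8, 210.5)
  paths <- make_engine_outputs(dir, frequencies = freqs, energy_hartree = -0.0371)

  rep_m <- parse_engine_output(paths[["semiempirical"]], engine_spec("semiempirical"))
  expect_equal(rep_m$imaginary_count, 1L)
  expect_equal(rep_m$leading_imaginary, 450.2)
  expect_equal(rep_m$energy, -0.0371, tolerance = 1e-6)  # kcal/mol -> hartree round trip
  expect_true(rep_m$converged)

  rep_n <- parse_engine_output(paths[["hartree_fock"]], engine_spec("hartree_fock"))
  expect_equal(rep_n$imaginary_count, 1L)
  expect_equal(rep_n$energy, -0.0371, tolerance = 1e-9)
  expect_equal(nrow(rep_n$final_geometry), 2L)

  all_pos <- make_engine_outputs(dir, frequencies = c(12.3, 88.1, 400.0))
  expect_equal(parse_engine_output(all_pos[["semiempirical"]],
                                   engine_spec("semiempirical"))$imaginary_count, 0L)

  two_im <- make_engine_outputs(dir, frequencies = c(-600.0, -120.5, 77.7))
  rep2 <- parse_engine_output(two_im[["hartree_fock"]], engine_spec("hartree_fock"))
  expect_equal(rep2$imaginary_count, 2L)
  expect_equal(rep2$leading_imaginary, 600.0)

  zb <- file.path(dir, "empty.out")
  file.create(zb)
  expect_error(parse_engine_output(zb, engine_spec("semiempirical")), "empty output")
  garbage <- file.path(dir, "garbage.out")
  writeLines(c("no results here", "just noise"), garbage)
  expect_error(parse_engine_output(garbage, engine_spec("semiempirical")),
               "parse error")
})

test_that("trajectory classification follows the documented thresholds", {
  g <- list(cc_distance = 2.25)
  mk <- function(d) stationary_report(FALSE, trajectory_summary = d)
  expect_equal(classify_trajectory(mk(c(2.25, 2.24, 2.26, 2.25)), g), "on_saddle")
  expect_equal(classify_trajectory(mk(c(2.25, 2.0, 1.8, 1.58)), g), "drifting_to_product")
  expect_equal(classify_trajectory(mk(c(2.25, 2.6, 3.1, 3.6)), g), "drifting_to_reactant")
  # non-monotone wandering far from the band
  expect_equal(classify_trajectory(mk(c(2.25, 2.8, 2.1, 2.9)), g), "indeterminate")
  # monotone decrease that has not yet crossed the product threshold
  expect_equal(classify_trajectory(mk(c(2.25, 2.1, 1.95)), g), "indeterminate")
})

test_that("the rescue state machine traverses exactly the documented action sequences", {
  for (sc in engine_scenarios()) {
    g <- make_test_guess()
    res <- run_ts_search(g, scripted_engine(sc, cc = g$cc_distance))
    expect_identical(vapply(res$attempts, `[[`, "", "action"),
                     rescue_oracle[[sc]]$actions, label = sc)
    expect_identical(res$status, rescue_oracle[[sc]]$status, label = sc)
    if (res$status == "true_ts") {
      final <- res$attempts[[length(res$attempts)]]$report
      expect_equal(final$imaginary_count, 1L, label = sc)
      expect_false(is.na(res$activation_energy))
    } else {
      expect_true(is.na(res$activation_energy))
    }
    expect_lte(length(res$attempts), regiots_config()$retry_budget)
  }
})

test_that("mock surface is deterministic, symmetry-keyed, and sterically monotone", {
  pyr <- fixture_mol("pyridine", embed = TRUE)
  sites <- enumerate_sites(pyr)
  params <- mock_surface(seed = 3)
  guesses <- lapply(seq_len(nrow(sites)), function(k) {
    build_guess(pyr, sites[k, ], "trifluoromethyl")
  })
  energies <- vapply(guesses, function(g) mock_energy(g, params)$energy, 0)
  cls <- sites$symmetry_class
  for (cl in unique(cls)) {
    expect_equal(length(unique(energies[cls == cl])), 1L)
  }
  # same seed -> identical, different seed -> different surface
  expect_identical(energies, vapply(guesses, function(g) mock_energy(g, params)$energy, 0))
  e2 <- vapply(guesses, function(g) mock_energy(g, mock_surface(seed = 4))$energy, 0)
  expect_false(isTRUE(all.equal(energies, e2)))

  # steric term: identical electronic class, more ortho substituents = higher barrier
  g0 <- guesses[[1]]
  g_hindered <- g0
  g_hindered$ortho_substituted <- 2L
  expect_gt(mock_energy(g_hindered, params)$energy, mock_energy(g0, params)$energy)
  expect_equal(mock_energy(g0, params)$imaginary_count, 1L)
})

test_that("energies convert to activation kcal/mol through the single central constant", {
  g <- make_test_guess()
  surface <- mock_surface(seed = 1, base_kcal = 10, class_spread_kcal = 0, steric_kcal = 0)
  res <- run_ts_search(g, engine_spec("mock", surface = surface))
  expect_identical(res$status, "true_ts")
  expect_equal(res$activation_energy, 10, tolerance = 1e-9)
  expect_equal(regiots_constants()$hartree_to_kcal, 627.509474)
})
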