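#' @title Fixture generators and independent brute-force oracles
#' @name fixtures
#' @description Generate every synthetic input the test suite needs: a
#'   heteroarene panel with hand-countable sites, scripted mock-engine
#'   behaviours driving each rescue path, synthetic engine-output files
#'   for the parsers, and a curation library with known filter outcomes.
#'   Every expected value is computed at generation time by an
#'   independent brute-force routine, so the fixtures double as a
#'   regression oracle for the implementation paths.
NULL

#' Brute-force reaction-site search (oracle)
#'
#' Independent of the SMARTS path: loops over the atom table and keeps
#' atoms that are aromatic carbons with exactly one attached hydrogen and
#' exactly two heavy neighbours, both in a ring.
#'
#' @param mol a `Molecule3D`.
#' @return Sorted integer vector of 1-based atom indices.
#' @export
brute_force_sites <- function(mol) {
  at <- mol$atoms
  keep <- integer()
  for (i in seq_len(nrow(at))) {
    if (at$element[i] != "C" || !at$aromatic[i] || at$n_h[i] != 1L) next
    nb <- bonded_atoms(mol, i)
    heavy_nb <- nb[at$element[nb] != "H"]
    if (length(heavy_nb) == 2L && all(at$in_ring[heavy_nb])) {
      keep <- c(keep, i)
    }
  }
  sort(keep)
}

#' Brute-force topological symmetry classes (oracle)
#'
#' Independent of canonical ranking: iterative neighbourhood-label
#' refinement (Morgan-style) over the heavy-atom graph, starting from
#' (element, aromaticity, charge, hydrogen count, heavy degree) and
#' refining with sorted neighbour labels until the partition stabilizes.
#'
#' @param mol a `Molecule3D`.
#' @return Integer vector of class ids, one per atom (`NA` for hydrogens).
#' @export
brute_force_classes <- function(mol) {
  at <- mol$atoms
  heavy <- which(at$element != "H")
  lab <- rep(NA_character_, nrow(at))
  deg <- vapply(heavy, function(i) {
    nb <- bonded_atoms(mol, i)
    sum(at$element[nb] != "H")
  }, 0L)
  lab[heavy] <- paste(at$element[heavy], at$aromatic[heavy], at$charge[heavy],
                      at$n_h[heavy], deg)
  repeat {
    k_before <- length(unique(lab[heavy]))
    newlab <- lab
    for (i in heavy) {
      nb <- bonded_atoms(mol, i)
      nb <- nb[at$element[nb] != "H"]
      newlab[i] <- paste(lab[i], paste(sort(lab[nb]), collapse = "|"), sep = "/")
    }
    # compress to keep labels bounded
    ids <- as.integer(factor(newlab[heavy]))
    lab[heavy] <- as.character(ids)
    if (length(unique(ids)) == k_before) break
  }
  out <- rep(NA_integer_, nrow(at))
  out[heavy] <- as.integer(lab[heavy])
  out
}

#' Generate the heteroarene test panel
#'
#' Sixteen molecules spanning 5- and 6-membered azines and azoles, fused
#' systems and 0-7 sites, each with expected site count and number of
#' symmetry classes computed by the brute-force oracles at generation
#' time (never hard-coded twice).
#'
#' @param config see [regiots_config()].
#' @param embed also embed 3D coordinates (slower; default `FALSE`).
#' @return Data.frame `name`, `smiles`, `expected_sites`,
#'   `expected_classes`, `expected_aromatic_n`, with the parsed molecules
#'   in attribute `molecules`.
#' @export
make_molecule_panel <- function(config = regiots_config(), embed = FALSE) {
  panel <- c(
    pyridine = "c1ccncc1",
    pyrimidine = "c1cncnc1",
    pyrazine = "c1cnccn1",
    pyridazine = "c1ccnnc1",
    furan = "c1ccoc1",
    thiophene = "c1ccsc1",
    pyrrole = "c1cc[nH]c1",
    imidazole = "c1cnc[nH]1",
    oxazole = "c1cnco1",
    thiazole = "c1cncs1",
    quinoline = "c1ccc2ncccc2c1",
    isoquinoline = "c1ccc2cnccc2c1",
    indole = "c1ccc2[nH]ccc2c1",
    `4-methylpyridine` = "Cc1ccncc1",
    benzene = "c1ccccc1",
    hexamethylbenzene = "Cc1c(C)c(C)c(C)c(C)c1C"
  )
  mols <- lapply(names(panel), function(nm) {
    parse_smiles(panel[[nm]], nm, embed = embed, config = config)
  })
  names(mols) <- names(panel)
  df <- data.frame(
    name = names(panel),
    smiles = unname(panel),
    expected_sites = vapply(mols, function(m) length(brute_force_sites(m)), 0L),
    expected_classes = vapply(mols, function(m) {
      s <- brute_force_sites(m)
      length(unique(brute_force_classes(m)[s]))
    }, 0L),
    expected_aromatic_n = vapply(mols, function(m) {
      any(m$atoms$element == "N" & m$atoms$aromatic)
    }, FALSE)
  )
  rownames(df) <- NULL
  attr(df, "molecules") <- mols
  df
}

#' Scripted mock-engine behaviours for the rescue state machine
#'
#' Each scenario is a per-attempt sequence of stationary-point reports
#' driving [run_ts_search()] down exactly one state-machine path, plus
#' the action sequence and terminal status that path is defined to take.
#'
#' @param name one of `"immediate_ts"`, `"drift_product_then_ts"`,
#'   `"drift_reactant_then_ts"`, `"zero_imaginary_then_ts"`,
#'   `"double_imaginary_persistent"`, `"hard_failure"`.
#' @param cc forming-bond distance of the guess the script is played
#'   against (trajectories are constructed relative to it).
#' @return List with `reports`, `expected_actions`, `expected_status`.
#' @export
make_engine_script <- function(name, cc = 2.35) {
  good <- stationary_report(TRUE, energy = -99.98, frequencies = c(-512.7, 45.1, 88.0),
                            trajectory_summary = c(cc, cc - 0.01, cc + 0.005, cc),
                            reference_energy = -100.0)
  stable <- c(cc, cc - 0.01, cc + 0.01, cc)
  switch(name,
    immediate_ts = list(
      reports = list(good),
      expected_actions = "initial",
      expected_status = "true_ts"),
    drift_product_then_ts = list(
      reports = list(
        stationary_report(TRUE, energy = -100.05, frequencies = c(40, 90, 300),
                          trajectory_summary = c(cc, 2.0, 1.8, 1.58),
                          reference_energy = -100.0),
        good),
      expected_actions = c("initial", "restart_modified_geometry"),
      expected_status = "true_ts"),
    drift_reactant_then_ts = list(
      reports = list(
        stationary_report(TRUE, energy = -100.01, frequencies = c(35, 80, 250),
                          trajectory_summary = c(cc, 2.6, 3.1, 3.6),
                          reference_energy = -100.0),
        good),
      expected_actions = c("initial", "restart_modified_geometry"),
      expected_status = "true_ts"),
    zero_imaginary_then_ts = list(
      reports = list(
        stationary_report(TRUE, energy = -100.02, frequencies = c(55, 120, 410),
                          trajectory_summary = stable, reference_energy = -100.0),
        good),
      expected_actions = c("initial", "constrained_opt_research"),
      expected_status = "true_ts"),
    double_imaginary_persistent = list(
      reports = rep(list(
        stationary_report(TRUE, energy = -99.97, frequencies = c(-601.2, -118.4, 66.0),
                          trajectory_summary = stable, reference_energy = -100.0)), 3),
      expected_actions = c("initial", "restart_from_final", "restart_from_final"),
      expected_status = "second_imaginary"),
    hard_failure = list(
      reports = list(stationary_report(FALSE, unreadable = TRUE)),
      expected_actions = "initial",
      expected_status = "failed"),
    stop("argument error: unknown scenario ", dQuote(name))
  )
}

#' All scripted scenario names
#' @return Character vector of the six scenario labels.
#' @export
engine_scenarios <- function() {
  c("immediate_ts", "drift_product_then_ts", "drift_reactant_then_ts",
    "zero_imaginary_then_ts", "double_imaginary_persistent", "hard_failure")
}

#' Write synthetic engine-output files for parser tests
#'
#' Emits text files mimicking the essential markers of MOPAC-format and
#' NWChem-format outputs, with known frequency lists and energies so the
#' parsers can be validated round-trip. Files are prefixed `synthetic_`
#' to mark that no quantum-chemistry engine produced them.
#'
#' @param dir output directory.
#' @param frequencies signed wavenumbers written into both files.
#' @param energy_hartree final energy (hartree; converted to kcal/mol for
#'   the MOPAC-format heat of formation).
#' @return Named character vector of the written paths.
#' @export
make_engine_outputs <- function(dir = tempdir(),
                                frequencies = c(-450.2, 35.1, 60.8, 210.5),
                                energy_hartree = -0.0371) {
  fmt_rows <- function(freqs) {
    blocks <- split(freqs, ceiling(seq_along(freqs) / 3))
    unlist(lapply(seq_along(blocks), function(b) {
      c(sprintf("          ROOT NO.  %s",
                paste(sprintf("%4d", (b - 1) * 3 + seq_along(blocks[[b]])), collapse = "      ")),
        "",
        paste0("           ", paste(sprintf("%12.2f", blocks[[b]]), collapse = "")),
        "")
    }))
  }
  mopac <- c(
    " MOPAC-FORMAT OUTPUT (synthetic fixture; no engine was run)",
    " AM1 CALCULATION",
    sprintf(" FINAL HEAT OF FORMATION = %16.5f KCAL/MOL",
            energy_hartree * HARTREE_TO_KCAL),
    "",
    "          CARTESIAN COORDINATES",
    "     1    C    0.000000    0.000000    0.000000",
    "     2    H    1.089000    0.000000    0.000000",
    "",
    " NORMAL COORDINATE ANALYSIS",
    fmt_rows(frequencies))
  nwchem <- c(
    " NWChem-format output (synthetic fixture; no engine was run)",
    "      Optimization converged",
    sprintf("         Total SCF energy = %18.9f", energy_hartree),
    "",
    "  Output coordinates in angstroms",
    "  No.       Tag          Charge          X              Y              Z",
    " ---- ---------------- ---------- -------------- -------------- --------------",
    "    1 C                    6.0000     0.00000000     0.00000000     0.00000000",
    "    2 H                    1.0000     1.08900000     0.00000000     0.00000000",
    "",
    paste0(" P.Frequency  ", paste(sprintf("%10.2f", frequencies), collapse = "")))
  p1 <- file.path(dir, "synthetic_mopac.out")
  p2 <- file.path(dir, "synthetic_nwchem.out")
  writeLines(mopac, p1)
  writeLines(nwchem, p2)
  c(semiempirical = p1, hartree_fock = p2)
}

#' Generate a synthetic curation library with known filter outcomes
#'
#' Synthesizes a SMILES library hitting every curation filter at least
#' twice (permanently charged, multi-molecule formulation, oversized,
#' nitrogen-free, too few sites) plus survivors, each entry tagged with
#' the filter expected to remove it. Expected verdicts are computed at
#' generation time by fixture-local rule application (fragment counts,
#' heavy-atom counts, atom-table charge scan, brute-force site search) --
#' independent of [apply_filters()]'s code path.
#'
#' @param n library size (>= 10; the base set is padded with decorated
#'   azine survivors).
#' @param seed integer seed controlling the padding.
#' @param config see [regiots_config()].
#' @return Data.frame `smiles`, `category`, `expected_removed_by` (`NA`
#'   for survivors).
#' @export
make_curation_library <- function(n = 50L, seed = 1L, config = regiots_config()) {
  stopifnot(n >= 10)
  base <- rbind(
    data.frame(smiles = c("C[N+](C)(C)C", "C[n+]1ccccc1",
                          "C[N+](C)(C)Cc1ccncc1", "OCC[N+](C)(C)C"),
               category = "charged"),
    data.frame(smiles = c("Cc1ccncc1.OCc1ccccc1", "c1ccncc1.c1ccc2ncccc2c1",
                          "CC(=O)Nc1ccncc1.OC(=O)c1ccccc1"),
               category = "formulation"),
    data.frame(smiles = c(paste0(strrep("C", 50), "c1ccncc1"),
                          paste0(strrep("C", 46), "c1ccc2ncccc2c1")),
               category = "oversized"),
    data.frame(smiles = c("c1ccccc1", "Cc1ccccc1", "c1ccoc1", "CC(=O)Nc1ccc(O)cc1"),
               category = "no_aromatic_N"),
    data.frame(smiles = c("Cc1nc(C)c(C)cc1C", "Cc1nc(C)nc(C)c1",
                          "Cc1c(C)c(C)nc(C)c1C"),
               category = "single_site"),
    data.frame(smiles = c("c1ccncc1", "c1cncnc1", "c1ccc2ncccc2c1",
                          "c1ccc2cnccc2c1", "Cc1cccnc1", "c1cnccn1",
                          "c1ccnnc1", "c1cnc[nH]1"),
               category = "survivor")
  )
  decorations <- c("C", "CC", "OC", "N", "F", "Cl", "C(C)C", "OCC", "CO", "CN")
  cores <- c("c1ccnc(%s)c1", "c1cc(%s)ncc1", "c1ncc(%s)cn1", "c1cc(%s)c2ncccc2c1")
  set.seed(seed)
  extra <- character()
  while (nrow(base) + length(extra) < n) {
    sm <- sprintf(sample(cores, 1L), sample(decorations, 1L))
    extra <- unique(c(extra, sm))
  }
  lib <- rbind(base, if (length(extra)) data.frame(smiles = extra, category = "survivor"))
  lib <- lib[seq_len(max(n, nrow(base))), , drop = FALSE]

  facts <- curation_facts(lib$smiles, config)
  lib$expected_removed_by <- vapply(facts, function(f) {
    if (!isTRUE(f$ok)) return("unparsable")
    mol <- f$mol
    at <- mol$atoms
    # fixture-local rule application, in filter order
    deg <- vapply(seq_len(nrow(at)), function(i) {
      sum(mol$bonds$a == i | mol$bonds$b == i)
    }, 0L)
    keep <- at$charge != 0 & deg > 0         # detached counter-ions drop out
    chg <- at$charge[keep]
    neut <- (chg > 0 & at$n_h[keep] >= 1) |
            (chg < 0 & at$element[keep] %in% c("O", "S", "N"))
    stuck <- sum(chg[!neut])
    can_zero <- (stuck == 0) ||
      (stuck > 0 && -sum(chg[neut & chg < 0]) >= stuck) ||
      (stuck < 0 && sum(chg[neut & chg > 0]) >= -stuck)
    if (!can_zero) return("charged")
    if (f$n_nontrivial_frags > 1) return("formulation")
    if (f$n_heavy > config$max_heavy_atoms) return("size")
    if (!any(at$element == "N" & at$aromatic)) return("no_aromatic_N")
    if (length(brute_force_sites(mol)) < config$min_sites) return("too_few_sites")
    NA_character_
  }, "")
  rownames(lib) <- NULL
  lib
}
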