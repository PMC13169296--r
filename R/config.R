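#' Default workflow configuration
#'
#' Central registry of the tunable parameters of the workflow, with the
#' defaults used throughout the package. Any subset can be overridden.
#'
#' Key parameters:
#' \describe{
#'   \item{site_smarts}{SMARTS pattern defining a candidate reaction site:
#'     an aromatic carbon whose only non-ring substituent is one hydrogen.
#'     Exposed so the workflow can be retargeted to new reaction systems.}
#'   \item{clash_threshold_angstrom}{Radical-substrate contact below this
#'     distance counts as a steric clash (default 1.0 Å).}
#'   \item{rotation_step_degrees}{Dihedral increment used to relieve
#'     clashes by rotation about the forming C-C bond (default 5°).}
#'   \item{initial_cc_angstrom}{Forming C-C distance of the initial
#'     transition-state guess (default 2.25 Å, typical for an early
#'     radical-addition saddle point).}
#'   \item{bond_correction_angstrom}{Rigid lengthening applied to the
#'     forming C-C bond before ab-initio refinement, compensating the
#'     systematic underestimation of that distance by the semiempirical
#'     level (default 0.10 Å; a tunable assumption).}
#'   \item{product_threshold_angstrom, dissociation_threshold_angstrom,
#'     saddle_band_angstrom}{Trajectory classification thresholds: a
#'     forming-bond distance collapsing monotonically below 1.7 Å signals
#'     drift to the addition product, growing monotonically beyond 3.2 Å
#'     signals dissociation to reactants, staying within ±0.15 Å of the
#'     guess distance signals a saddle-region search.}
#'   \item{min_imaginary_cm}{Smallest imaginary-frequency magnitude
#'     accepted as a genuine transition-state mode (default 50 cm^-1);
#'     smaller imaginaries are treated as spurious.}
#'   \item{retry_budget}{Maximum number of engine attempts (initial search
#'     plus rescues) per site (default 3).}
#'   \item{tighten_factor}{Multiplier applied to convergence tolerances in
#'     the tightened-convergence retry (default 0.1).}
#'   \item{temperature_k}{Temperature for Boltzmann ratios (default
#'     298.15 K).}
#'   \item{fp_radius, fp_bits}{Morgan fingerprint parameters for curation
#'     (radius 2, 2048 bits).}
#'   \item{cluster_threshold}{Tanimoto similarity threshold for leader
#'     clustering (default 0.7).}
#'   \item{max_heavy_atoms}{Drug-likeness size filter (default 50).}
#'   \item{min_sites}{Minimum candidate site count for curation
#'     (default 2).}
#'   \item{embed_seed}{Random seed for 3D embedding (default 2025).}
#' }
#'
#' @param ... name-value overrides of the defaults.
#' @return Named list of configuration values.
#' @examples
#' cfg <- regiots_config(rotation_step_degrees = 10)
#' cfg$clash_threshold_angstrom
#' @export
regiots_config <- function(...) {
  cfg <- list(
    site_smarts = "[cH1]",
    clash_threshold_angstrom = 1.0,
    rotation_step_degrees = 5,
    initial_cc_angstrom = 2.25,
    bond_correction_angstrom = 0.10,
    product_threshold_angstrom = 1.7,
    dissociation_threshold_angstrom = 3.2,
    saddle_band_angstrom = 0.15,
    min_imaginary_cm = 50,
    retry_budget = 3L,
    tighten_factor = 0.1,
    temperature_k = 298.15,
    reactive_ratio_percent = 25,
    fp_radius = 2L,
    fp_bits = 2048L,
    cluster_threshold = 0.7,
    max_heavy_atoms = 50L,
    min_sites = 2L,
    embed_seed = 2025L,
    embed_retries = 3L,
    optimize_maxiters = 2000L,
    min_cpus = 16L,
    max_cpus = 32L,
    cpu_breakpoints = 30L,
    exclude_zwitterions = FALSE
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}
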