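---
title: "Predicting radical C–H functionalization regioselectivity with regiots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting radical C-H functionalization regioselectivity with regiots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regiots)
```

## The model

Sulfinate-mediated C–H functionalization proceeds through a radical chain
whose rate-limiting, selectivity-determining step is the addition of a
carbon-centred radical (CF₃•, CF₂H•) to the heteroarene. Because the
regiochemistry is set by relative barrier heights rather than product
stabilities — kinetic control — the product distribution over candidate
sites follows from the per-site activation energies ΔE‡ᵢ by Boltzmann
weighting:

$$ r_i \;=\; 100\,\frac{g_i\,e^{-\Delta E^{\ddagger}_i/RT}}
                      {\sum_j g_j\,e^{-\Delta E^{\ddagger}_j/RT}} $$

where $g_i$ is the degeneracy of symmetry class $i$ (the number of
topologically equivalent sites sharing one barrier) and
$R = 1.98720\times10^{-3}$ kcal mol⁻¹ K⁻¹. The functional form is our
interpretive choice: nothing stronger than kinetic control (a
Curtin–Hammett-type argument over competing irreversible additions) is
assumed, and the resulting percentages should be read as a qualitative
ranking of sites, not as quantitative isomer ratios. The temperature
default is 298.15 K; since all sites of a compound share the reactant
asymptote, any common energy reference leaves the ratios unchanged.

A *candidate site* is an aromatic carbon whose only non-ring substituent
is a single hydrogen (SMARTS `[cH1]`, exposed in
`regiots_config()$site_smarts` so the workflow can be retargeted).
Fused-ring junction carbons carry no hydrogen and are excluded
automatically; five-membered-ring CH positions adjacent to heteroatoms are
included deliberately — indole-type five-ring sites can be the observed
major product, and it is the energetics, not the pattern, that should
decide. Symmetry classes come from graph-canonical atom ranks (topological
equivalence), not 3D symmetry: selectivity is defined per topological
site, and one transition-state search per class suffices.

## Transition-state guess construction

The guess geometry is built in internal-coordinate terms, with the forming
C–C distance and the approach axis as explicit degrees of freedom:

* the radical's attack carbon is placed along the local normal of the
  aromatic plane (defined by the site carbon and its two ring neighbours)
  at `initial_cc_angstrom` (default **2.25 Å**, a typical forming-bond
  distance for an early radical-addition saddle point), on the face
  pointing away from the substrate's heavy-atom centroid;
* substituents of the radical point away from the ring, at 104° from the
  approach axis — a partially pyramidalized radical carbon, as in an early
  addition transition state; out-of-plane pyramidalization of the *site*
  carbon is left to the TS optimizer rather than pre-imposed;
* steric clashes are resolved by rotating the radical about the forming
  C–C axis in `rotation_step_degrees` (default **5°**) increments until no
  radical–substrate contact (excluding the forming-bond pair) is shorter
  than `clash_threshold_angstrom` (default **1.0 Å**); if a full turn
  fails, the rotation maximizing the minimum contact is kept and flagged,
  letting the optimizer decide rather than aborting the site;
* semiempirical TS searches systematically underestimate the forming C–C
  distance, so `apply_bond_correction()` rigidly lengthens it by
  `bond_correction_angstrom` before ab-initio refinement. The magnitude is
  not well pinned down; the default **0.10 Å** is a deliberately visible,
  tunable assumption.

Facial selectivity (syn/anti approach relative to bulky out-of-plane
substituents) is decided only by the centroid rule and clash resolution;
no conformational search over substrate rotamers is attempted (single
starting geometry policy, one embedded conformer).

## Engine layer and the rescue state machine

`write_engine_input()` emits MOPAC-format decks (AM1 TS search + FORCE
frequency job) and NWChem-format decks (UHF doublet saddle optimization +
frequency at HF/6-31G*), and `parse_engine_output()` reads the
corresponding output markers (final heat of formation / `ROOT NO.`
frequency blocks; `Total SCF energy` / `P.Frequency` rows). No
electronic-structure code is executed by this package; correctness of the
engines themselves is out of scope, and every execution path is exercised
through the deterministic mock engine and scripted report sequences.

`run_ts_search()` drives each site through the rescue machine. After every
attempt the report is classified and exactly one action follows:

| observation | action |
|---|---|
| converged, 1 imaginary ≥ `min_imaginary_cm` | accept (`true_ts`) |
| forming bond collapsing monotonically below 1.7 Å, or growing monotonically beyond 3.2 Å | `restart_modified_geometry` (forming bond reset to the corrected guess value) |
| converged, 0 imaginaries | `constrained_opt_research` (forming bond frozen, then fresh search) |
| ≥ 2 imaginaries | `restart_from_final` |
| anything else (incl. spurious imaginaries < 50 cm⁻¹) | `tightened_convergence`, once (tolerances × `tighten_factor` = 0.1) |

The trajectory thresholds (product < **1.7 Å**, dissociation > **3.2 Å**,
saddle band ± **0.15 Å** about the guess distance) and the retry budget
(default **3** attempts per site) are configuration values; the numbers
are our operational choices for where "drifting to a minimum" becomes
unambiguous for a forming C–C bond. Exhausting the budget yields a status
describing the terminal failure mode (`second_imaginary`,
`converged_to_minimum`, `failed`); a failed site is excluded from the
ratios and listed in the report's `failures`. Engine energies are kept in
hartree and converted to kcal/mol exactly once, through the single
constant 627.509474.

The minimum imaginary-frequency magnitude (50 cm⁻¹) rejects spurious
shallow modes; a mode-projection check onto the forming-bond stretch would
further harden validation but requires normal-mode vectors, which the
shipped parsers do not extract — a known limitation.

## Molecule perception and reproducibility

Parsing, canonicalization, aromaticity, canonical ranks, SMARTS matching,
formal charges, Morgan fingerprints and seeded 3D embedding are delegated
to RDKit through a bundled Python worker invoked in batches (results are
memoised per session). Embedding uses distance geometry with a fixed,
configurable seed (`embed_seed`, default 2025) followed by MMFF94
relaxation, falling back to UFF when MMFF94 parameters are missing (the
force field actually used is recorded on the molecule). Identical inputs
and seed give bit-identical coordinates, which makes every downstream
geometry operation — and therefore the whole test surface — exactly
reproducible. Aromaticity follows the toolkit's default perception model;
ambiguous tautomer/protonation questions are out of scope (the curation
filters deliberately remove the permanently charged species where they
bite hardest).

## Orchestration

Batches run with per-row isolation: one unparsable SMILES or failed
compound never aborts the batch. Results are persisted in a single-file
JSON store keyed on (canonical SMILES, radical); a cache hit returns the
stored report without touching the engine, and `run_batch()` always
returns the store's serialized representation, so repeated runs are
byte-identical. Only fully completed compound reports are persisted, so a
crash mid-compound recomputes that compound and nothing else. CPU
allocation is a monotone step function of heavy-atom count (16 CPUs up to
30 heavy atoms, 32 above, configurable breakpoints). Job monitoring
classifies intermediate trajectories with the same thresholds as the
rescue machine and resubmits drifting jobs (`pending → running ⇄ rescuing
→ done/failed`); the local synchronous backend is the default and the one
used in tests.

## Dataset curation

`apply_filters()` applies, in order: permanent charge, formulation, heavy
atoms ≤ 50, aromatic nitrogen required, ≥ 2 candidate sites. Each
compound is attributed to the first filter it fails, but every filter is a
pure per-compound predicate, so the surviving *set* is order-invariant
(a property the tests assert). "Permanently charged" is operationalized
as: after dropping detached counter-ions, no choice of chemically
plausible neutralizations (deprotonating a cation that bears hydrogen,
protonating an O/S/N-centred anion) reaches net charge zero — quaternary
ammonium-type centres are the canonical stuck case. Net-neutral
zwitterions are kept by default (`exclude_zwitterions` flips this), since
the motivating concern is unpredictable protonation of parent cations.
Survivors are clustered Taylor–Butina-style on Morgan fingerprints
(radius 2, 2048 bits — the bit length is our choice) at Tanimoto 0.7, and
sampled round-robin over clusters in decreasing size order, one seeded
random member per cluster per round.

## What the synthetic fixtures do and do not show

The mock surface assigns each site a barrier = base (8 kcal/mol) +
an electronic term keyed on the site's symmetry class (seeded hash,
0–4 kcal/mol) + 0.8 kcal/mol per substituted ortho ring neighbour. It is
deterministic, symmetry-consistent and sterically monotone — exactly the
invariants the pipeline must preserve — but it has no chemistry in it:
passing tests demonstrate that sites are found correctly, geometry
operations are rigid and exhaustive-search-equivalent, the rescue machine
takes the documented paths, ratios are computed and normalized correctly,
and caching/isolation contracts hold. They say nothing about the accuracy
of any particular quantum-chemistry level on real compounds; reproducing
experimental benchmark accuracies requires an ab-initio engine and the
corresponding structure sets, which the package treats as external
inputs. The fixture panel (16 heteroarenes, 68 sites) and the synthetic
curation library (40 compounds) are sized so the whole suite runs in
seconds on one CPU; expected values are derived at generation time by
independent brute-force routines (atom-loop site search, Morgan-style
refinement for symmetry classes, exhaustive rotation scans), never
hard-coded twice.

## Numerical notes

* Boltzmann weights are evaluated after subtracting the minimum energy,
  so one large barrier cannot underflow the ratios of the others; ratios
  of surviving classes always sum to 100 within 10⁻⁹.
* Exact ratio ties across *distinct* symmetry classes break to the lowest
  site id and set a `tie` flag; equivalent sites of one class sharing a
  ratio are not a tie.
* Per-site ratios are the class ratio divided by the class degeneracy, so
  a plain sum over sites is 100 and equivalent sites display equal
  shares.
* `score_accuracy()` counts a site as predicted-reactive when it is the
  predicted major site or its ratio ≥ 25 % (configurable); each labelled
  site then scores by binary agreement. The convention credits strong
  secondary predictions without rewarding diffuse ones; it is one of
  several defensible readings of per-site accuracy and is therefore a
  configuration value, not a constant.
* Degenerate inputs are first-class: zero-site molecules produce empty
  site tables (and a clear error only when a selectivity report is
  requested), empty batches return empty results, and all-failed
  compounds raise an "empty report" error rather than NaN ratios.

## Limitations

* Electronic energies only: no zero-point, thermal or solvent
  corrections, and no spin-contamination diagnostics.
* Single conformer, single TS template per radical; facial selectivity is
  handled only sterically.
* The imaginary-mode identity check is magnitude-based (no normal-mode
  projection).
* The scheduler adapter emits job arrays abstractly; only the local
  synchronous backend is exercised in tests.
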