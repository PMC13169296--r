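# regiots

Automated transition-state search for predicting the regioselectivity of
radical C–H functionalization of nitrogen heteroarenes.

## The problem

Sulfinate-mediated radical reactions (e.g. trifluoromethylation with CF₃•
released from Langlois-type reagents) are a workhorse of late-stage
functionalization in medicinal chemistry, but a drug-like heteroarene
usually offers several aromatic C–H positions, each with its own steric
and electronic environment. Ground-state descriptors (charges, Fukui
indices, chemical shifts) miss the steric component; what actually decides
the product distribution under kinetic control is the set of activation
barriers for radical addition at each site.

`regiots` automates that calculation end to end, for computational and
medicinal chemists who want per-site barrier-based predictions at scale:

1. **Input** — SMILES (single compound or batch CSV), radical identity.
2. **Site enumeration** — SMARTS matching of aromatic C–H carbons whose
   only non-ring substituent is hydrogen, grouped into topological
   symmetry classes so equivalent sites are computed once.
3. **TS guess construction** — internal-coordinate placement of the
   radical along the local normal of the aromatic plane at a forming C–C
   distance of 2.25 Å; steric clashes (contacts < 1 Å) are relieved by 5°
   rotations about the forming bond; a configurable bond-length correction
   (default +0.10 Å) compensates the semiempirical underestimation of the
   forming C–C distance before ab-initio refinement.
4. **TS search with rescue** — a pluggable engine layer (MOPAC-format and
   NWChem-format deck writers and output parsers, plus a deterministic
   mock engine) drives each search through an automatic rescue state
   machine: restart from a modified geometry when the optimization drifts
   to reactants or products, constrained re-search when it lands on a
   minimum, restart from the final structure on a second imaginary
   frequency, and one tightened-convergence retry. A validated transition
   state has exactly one imaginary frequency (≥ 50 cm⁻¹).
5. **Selectivity** — activation energies ΔE‡ᵢ (kcal/mol) become
   regioisomeric ratios by Boltzmann weighting under kinetic control:

   ```
   rᵢ = 100 · gᵢ exp(−ΔE‡ᵢ / RT) / Σⱼ gⱼ exp(−ΔE‡ⱼ / RT)
   ```

   with gᵢ the symmetry degeneracy of site class i, R = 1.9872 × 10⁻³
   kcal mol⁻¹ K⁻¹, T = 298.15 K by default. Ratios are a qualitative
   ranking metric; `score_accuracy()` tallies per-site agreement with
   experimental labels.
6. **Orchestration & curation** — batch runs with per-row isolation and a
   (canonical SMILES, radical)-keyed result cache; CPU allocation by
   heavy-atom count (16–32); library curation by charge / formulation /
   size / aromatic-nitrogen / site-count filters followed by Butina
   clustering of Morgan fingerprints (radius 2, 2048 bits, Tanimoto 0.7)
   and round-robin diversity sampling.

No quantum-chemistry installation is required to use, test, or extend the
workflow: the engine layer ships a deterministic mock surface and scripted
engines, and all fixtures are generated programmatically. Molecule
perception and seeded 3D embedding (MMFF94, UFF fallback) are delegated to
RDKit through a bundled Python worker (`python` with `rdkit` must be on
the PATH).

## Worked example

```r
library(regiots)
rep <- run_compound("c1cncnc1", "pyrimidine", "trifluoromethyl")
print(rep)
#> <SelectivityReport> pyrimidine + trifluoromethyl @ 298.15 K
#>  site_id atom_index symmetry_class activation_energy degeneracy ratio_percent
#>        1          2              7              8.83          2          42.6
#>        3          6              7              8.83          2          42.6
#>        2          4              6              9.47          1          14.3
#>        0          1              9             11.53          1           0.4
#> predicted major site: 1
```

Pyrimidine has four candidate C–H sites in three symmetry classes: C4/C6
(equivalent, degeneracy 2), C5, and C2 between the two nitrogens. With the
default mock surface the C4/C6 class has the lowest barrier (8.83
kcal/mol), so each of its two sites carries 42.6 % of the predicted
product (85.2 % for the class); C5 gets 14.3 % and the doubly
nitrogen-flanked C2 only 0.4 %. The per-site percentages always sum to
100, and the first row is the predicted major site. With a real engine
configured the same report is produced from parsed ab-initio energies.

The Boltzmann arithmetic is easy to sanity-check: a barrier difference of
RT ln 2 (0.411 kcal/mol at 298.15 K) gives a 2:1 ratio:

```r
boltzmann_ratios(c(0, 0.411))
#> [1] 66.6787 33.3213
```

A command-line front end is installed with the package
(`system.file("scripts", "regiots", package = "regiots")`), with
subcommands `run`, `batch`, `curate` and `fixtures`.

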