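#' @title Reaction-site enumeration
#' @name site_enumeration
#' @description Identify candidate reaction sites for radical addition --
#'   aromatic carbons whose only non-ring substituent is a single hydrogen
#'   -- and group them into topological symmetry-equivalence classes.
NULL

#' Enumerate candidate reaction sites of a molecule
#'
#' Sites are the atoms matching the configurable site SMARTS pattern
#' (default `[cH1]`: aromatic carbon bearing exactly one hydrogen; its two
#' remaining connections are necessarily ring bonds, so fused-ring junction
#' carbons and substituted carbons are excluded automatically). Each site
#' carries a `symmetry_class` label derived from canonical atom ranking,
#' so topologically equivalent sites (e.g. the two ortho positions of
#' pyridine) share a label and need only one transition-state search.
#'
#' @param mol a `Molecule3D` from [parse_smiles()].
#' @param site_smarts optional SMARTS override; when it differs from the
#'   pattern used at parse time the molecule is re-matched.
#' @param config see [regiots_config()].
#' @return Data.frame of class `ReactionSite` rows: `site_id` (contiguous
#'   from 0, in ascending atom order), `atom_index` (1-based index into
#'   `mol$atoms`), `symmetry_class`.
#' @examples
#' \dontrun{
#' enumerate_sites(parse_smiles("c1ccncc1", "pyridine"))  # 5 sites, 3 classes
#' }
#' @export
enumerate_sites <- function(mol, site_smarts = NULL, config = regiots_config()) {
  stopifnot(inherits(mol, "Molecule3D"))
  idx <- mol$site_atom_idx
  if (!is.null(site_smarts) && !identical(site_smarts, config$site_smarts)) {
    cfg <- config
    cfg$site_smarts <- site_smarts
    opts <- worker_opts(cfg, embed = FALSE)
    rec <- worker_perceive(list(list(id = mol$compound_id, smiles = mol$smiles_input)),
                           opts)[[1]]
    if (!isTRUE(rec$ok)) stop("site matching failed: ", rec$error %||% "unknown")
    idx <- unlist(rec$sites) + 1L
  }
  idx <- sort(as.integer(idx))
  out <- data.frame(
    site_id = seq_along(idx) - 1L,
    atom_index = idx,
    symmetry_class = if (length(idx)) mol$ranks[idx] else integer()
  )
  class(out) <- c("ReactionSite", "data.frame")
  out
}

#' Count candidate reaction sites
#'
#' @inheritParams enumerate_sites
#' @return Integer site count (equals `nrow(enumerate_sites(mol))`).
#' @export
count_sites <- function(mol, config = regiots_config()) {
  nrow(enumerate_sites(mol, config = config))
}

#' Does the molecule contain an aromatic nitrogen?
#'
#' Exocyclic nitrogens (e.g. the aniline NH2) are not aromatic under the
#' perception model and do not count.
#'
#' @inheritParams enumerate_sites
#' @return Logical.
#' @export
has_aromatic_nitrogen <- function(mol) {
  stopifnot(inherits(mol, "Molecule3D"))
  any(mol$atoms$element == "N" & mol$atoms$aromatic)
}

# Count of ring neighbours of `atom_index` that carry a non-hydrogen
# substituent outside the ring (used by the mock engine's steric term).
substituted_ortho_count <- function(mol, atom_index) {
  nb <- ring_neighbors(mol, atom_index)
  sum(vapply(nb, function(j) {
    kj <- bonded_atoms(mol, j)
    any(mol$atoms$element[kj] != "H" & !mol$atoms$in_ring[kj])
  }, FALSE))
}

bonded_atoms <- function(mol, i) {
  c(mol$bonds$b[mol$bonds$a == i], mol$bonds$a[mol$bonds$b == i])
}

ring_neighbors <- function(mol, i) {
  nb <- bonded_atoms(mol, i)
  nb[mol$atoms$in_ring[nb]]
}
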