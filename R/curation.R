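#' @title Dataset curation: filtering, clustering, diversity sampling
#' @name curation
#' @description Reduce a raw compound library to reaction-relevant,
#'   drug-like molecules (charge, formulation, size, aromatic-nitrogen and
#'   site-count filters), cluster the survivors by Morgan-fingerprint
#'   Tanimoto similarity, and sample the clusters for a diverse panel.
NULL

# Fragment triviality: counter-ions and small salts. A fragment is trivial
# when it has <= 5 heavy atoms or contains no carbon.
is_trivial_fragment <- function(frag_smiles, frag_n_heavy) {
  frag_n_heavy <= 5 | !grepl("c|C(?!l)", frag_smiles, perl = TRUE)
}

# Per-compound curation facts computed from one perception pass.
curation_facts <- function(smiles_vec, config) {
  opts <- worker_opts(config, embed = FALSE, want_fp = TRUE)
  recs <- worker_perceive(lapply(seq_along(smiles_vec), function(i) {
    list(id = as.character(i), smiles = smiles_vec[i])
  }), opts)
  lapply(seq_along(recs), function(i) {
    rec <- recs[[i]]
    if (!isTRUE(rec$ok)) return(list(ok = FALSE, smiles = smiles_vec[i]))
    mol <- mol_from_worker(rec, as.character(i), smiles_vec[i], NA_integer_)
    fs <- unlist(rec$frag_smiles)
    fh <- unlist(rec$frag_n_heavy)
    trivial <- is_trivial_fragment(fs, fh)
    parent <- if (any(!trivial)) {
      nt <- which(!trivial)
      fs[nt[which.max(fh[nt])]]
    } else {
      rec$canonical_smiles
    }
    list(ok = TRUE, smiles = smiles_vec[i], mol = mol,
         parent = parent,
         canonical = rec$canonical_smiles,
         fp = unlist(rec$fp) + 1L,
         n_heavy = rec$n_heavy,
         n_nontrivial_frags = sum(!trivial),
         salt_stripped = any(trivial) && sum(!trivial) >= 1,
         n_sites = length(mol$site_atom_idx),
         has_arN = any(mol$atoms$element == "N" & mol$atoms$aromatic))
  })
}

# Permanent-charge verdict on the atom table. Detached monatomic ions
# (counter-ions: charged atoms with no bonds) leave with salt stripping and
# are ignored. Of the remaining charges, one is neutralizable iff it is a
# cation bearing at least one hydrogen (deprotonatable) or an anion centred
# on O, S or N (protonatable); quaternary-type N+ with no hydrogen is the
# canonical non-neutralizable case. The compound is permanently charged when
# no choice of neutralizations reaches net charge zero -- which keeps
# net-neutral zwitterions (e.g. betaines) unless `exclude_zwitterions`.
permanently_charged <- function(mol, exclude_zwitterions = FALSE) {
  at <- mol$atoms
  bonded <- unique(c(mol$bonds$a, mol$bonds$b))
  charged <- which(at$charge != 0 & seq_len(nrow(at)) %in% bonded)
  if (!length(charged)) return(FALSE)
  q <- at$charge[charged]
  neut <- (q > 0 & at$n_h[charged] >= 1) |
          (q < 0 & at$element[charged] %in% c("O", "S", "N"))
  stuck <- sum(q[!neut])
  neut_pos <- sum(q[neut & q > 0])
  neut_neg <- -sum(q[neut & q < 0])
  unreachable <- (stuck > 0 && neut_neg < stuck) ||
                 (stuck < 0 && neut_pos < -stuck)
  if (unreachable) return(TRUE)
  if (exclude_zwitterions && any(q > 0) && any(q < 0)) return(TRUE)
  FALSE
}

#' Apply the dataset-curation filters to a compound library
#'
#' Filters are applied in a fixed order, each compound being removed by
#' the first filter it fails:
#' \enumerate{
#'   \item `charged` -- permanently charged species (non-neutralizable
#'     residual formal charge after salt stripping, or a quaternary-type
#'     N+ with no hydrogen);
#'   \item `formulation` -- records containing more than one non-trivial
#'     organic fragment (trivial counter-ions are stripped and logged);
#'   \item `size` -- more than `max_heavy_atoms` (default 50) heavy atoms;
#'   \item `no_aromatic_N` -- no aromatic nitrogen;
#'   \item `too_few_sites` -- fewer than `min_sites` (default 2) candidate
#'     reaction sites.
#' }
#' The surviving *set* is order-independent (each filter is a pure
#' per-compound predicate); only the removal attribution depends on the
#' order.
#'
#' @param library character vector of SMILES (unparsable entries are
#'   logged and dropped before filtering).
#' @param config see [regiots_config()].
#' @param order optional permutation of the filter names (attribution
#'   changes, the surviving set does not).
#' @return A `FilterTrace`: `input_count`, `removed` (named counts),
#'   `surviving` (canonical SMILES), `verdicts` (per-compound data.frame),
#'   `salt_stripped` (canonical SMILES logged as stripped salts),
#'   `unparsable`.
#' @export
apply_filters <- function(library, config = regiots_config(),
                          order = c("charged", "formulation", "size",
                                    "no_aromatic_N", "too_few_sites")) {
  stopifnot(is.character(library))
  canonical_order <- c("charged", "formulation", "size", "no_aromatic_N",
                       "too_few_sites")
  stopifnot(setequal(order, canonical_order))
  if (length(library) == 0L) {
    return(structure(list(input_count = 0L,
                          removed = stats::setNames(integer(5), canonical_order),
                          surviving = character(), verdicts = NULL,
                          salt_stripped = character(), unparsable = character()),
                     class = "FilterTrace"))
  }
  facts <- curation_facts(library, config)
  ok <- vapply(facts, `[[`, TRUE, "ok")
  unparsable <- library[!ok]
  if (length(unparsable)) {
    message(length(unparsable), " unparsable entr(ies) dropped before filtering")
  }
  facts <- facts[ok]

  fails <- function(f, filter) {
    switch(filter,
      charged = permanently_charged(f$mol, config$exclude_zwitterions),
      formulation = f$n_nontrivial_frags > 1,
      size = f$n_heavy > config$max_heavy_atoms,
      no_aromatic_N = !f$has_arN,
      too_few_sites = f$n_sites < config$min_sites)
  }
  removed_by <- vapply(facts, function(f) {
    for (filter in order) if (fails(f, filter)) return(filter)
    NA_character_
  }, "")
  verdicts <- data.frame(
    smiles = vapply(facts, `[[`, "", "smiles"),
    canonical = vapply(facts, `[[`, "", "canonical"),
    parent = vapply(facts, `[[`, "", "parent"),
    removed_by = removed_by
  )
  surviving <- verdicts$parent[is.na(removed_by)]
  stripped <- vapply(facts, function(f) isTRUE(f$salt_stripped) &&
                       f$n_nontrivial_frags == 1, FALSE)
  removed <- vapply(canonical_order, function(fl) sum(removed_by == fl, na.rm = TRUE),
                    0L)
  structure(list(
    input_count = length(facts),
    removed = removed,
    surviving = surviving,
    verdicts = verdicts,
    salt_stripped = verdicts$parent[stripped & is.na(removed_by)],
    unparsable = unparsable
  ), class = "FilterTrace")
}

#' @export
print.FilterTrace <- function(x, ...) {
  cat("<FilterTrace> ", x$input_count, " parseable compounds\n", sep = "")
  for (nm in names(x$removed)) cat(sprintf("  removed by %-15s %d\n", nm, x$removed[[nm]]))
  cat("  surviving: ", length(x$surviving), "\n", sep = "")
  invisible(x)
}

#' Morgan fingerprints for a set of SMILES
#'
#' Circular (Morgan) fingerprints of the configured radius (default 2)
#' folded to `fp_bits` bits (default 2048).
#'
#' @param smiles_vec character vector of SMILES.
#' @param config see [regiots_config()].
#' @return List of integer vectors of 1-based on-bit positions, with
#'   attribute `nbits`.
#' @export
morgan_fingerprints <- function(smiles_vec, config = regiots_config()) {
  opts <- worker_opts(config, embed = FALSE, want_fp = TRUE)
  recs <- worker_perceive(lapply(seq_along(smiles_vec), function(i) {
    list(id = as.character(i), smiles = smiles_vec[i])
  }), opts)
  out <- lapply(recs, function(rec) {
    if (!isTRUE(rec$ok)) stop("input error: unparsable SMILES in fingerprint input")
    sort(unlist(rec$fp) + 1L)
  })
  attr(out, "nbits") <- config$fp_bits
  out
}

#' Tanimoto similarity of two bit-set fingerprints
#'
#' \eqn{|a \cap b| / |a \cup b|}; defined as 1 when both fingerprints are
#' empty.
#'
#' @param fp_a,fp_b integer vectors of on-bit positions (as returned by
#'   [morgan_fingerprints()]). When both carry a `nbits` attribute it must
#'   agree.
#' @return Similarity in [0, 1].
#' @export
tanimoto <- function(fp_a, fp_b) {
  na <- attr(fp_a, "nbits")
  nb <- attr(fp_b, "nbits")
  if (!is.null(na) && !is.null(nb) && na != nb) {
    stop("contract violation: fingerprint bit lengths differ (", na, " vs ", nb, ")")
  }
  i <- length(intersect(fp_a, fp_b))
  u <- length(union(fp_a, fp_b))
  if (u == 0L) return(1.0)
  i / u
}

#' Leader-style (Taylor-Butina) clustering of fingerprints
#'
#' Repeatedly picks the unassigned compound with the most unassigned
#' neighbours at Tanimoto >= `threshold` as a cluster centroid and assigns
#' those neighbours to it (centroid-exclusion clustering). Every member
#' has similarity >= threshold to its cluster centroid.
#'
#' @param fps list of fingerprints (see [morgan_fingerprints()]).
#' @param threshold Tanimoto similarity threshold.
#' @return A `ClusterAssignment`: list with `clusters` (list of member
#'   index vectors, centroid first, sorted by decreasing size),
#'   `centroids`, `threshold`.
#' @export
butina_clusters <- function(fps, threshold) {
  n <- length(fps)
  if (n == 0L) {
    return(structure(list(clusters = list(), centroids = integer(),
                          threshold = threshold), class = "ClusterAssignment"))
  }
  sim <- matrix(1, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- tanimoto(fps[[i]], fps[[j]])
        sim[i, j] <- s
        sim[j, i] <- s
      }
    }
  }
  neighbor <- sim >= threshold
  assigned <- rep(FALSE, n)
  clusters <- list()
  centroids <- integer()
  repeat {
    counts <- vapply(seq_len(n), function(i) {
      if (assigned[i]) -1L else sum(neighbor[i, ] & !assigned)
    }, 0L)
    if (max(counts) < 0L) break
    c0 <- which.max(counts)  # ties: lowest index
    members <- which(neighbor[c0, ] & !assigned)
    members <- c(c0, setdiff(members, c0))
    assigned[members] <- TRUE
    clusters[[length(clusters) + 1L]] <- members
    centroids <- c(centroids, c0)
  }
  ord <- order(-vapply(clusters, length, 0L), centroids)
  structure(list(clusters = clusters[ord], centroids = centroids[ord],
                 threshold = threshold), class = "ClusterAssignment")
}

#' Cluster survivors and sample a diverse panel
#'
#' Clusters the compounds with [butina_clusters()] at the given threshold,
#' then samples without replacement, round-robin over clusters in
#' decreasing size order (one random member per cluster per round, seeded)
#' until `n_target` compounds are drawn.
#'
#' @param survivors character vector of SMILES (e.g.
#'   `apply_filters(...)$surviving`).
#' @param threshold Tanimoto similarity threshold (default from config:
#'   0.7).
#' @param n_target number of compounds to sample.
#' @param seed integer RNG seed for reproducibility.
#' @param config see [regiots_config()].
#' @return Character vector of `n_target` sampled SMILES, with the
#'   `ClusterAssignment` as attribute `clusters`.
#' @export
cluster_and_sample <- function(survivors, threshold = NULL, n_target, seed = 1L,
                               config = regiots_config()) {
  threshold <- threshold %||% config$cluster_threshold
  if (n_target > length(survivors)) {
    stop("argument error: n_target (", n_target, ") exceeds number of survivors (",
         length(survivors), ")")
  }
  fps <- morgan_fingerprints(survivors, config)
  cl <- butina_clusters(fps, threshold)
  picked <- integer()
  remaining <- lapply(cl$clusters, identity)
  set.seed(seed)
  while (length(picked) < n_target && any(lengths(remaining) > 0)) {
    for (k in seq_along(remaining)) {
      if (length(picked) >= n_target) break
      pool <- remaining[[k]]
      if (!length(pool)) next
      take <- if (length(pool) == 1L) pool else sample(pool, 1L)
      picked <- c(picked, take)
      remaining[[k]] <- setdiff(pool, take)
    }
  }
  out <- survivors[picked]
  attr(out, "clusters") <- cl
  out
}
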