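#' @title Molecule input, 3D embedding and serialization
#' @name molecule_io
#' @description Parse and canonicalize SMILES, embed a single force-field
#'   relaxed 3D conformer, read batch CSV requests and write XYZ geometry
#'   files.
NULL

new_molecule3d <- function(compound_id, smiles_input, canonical_smiles, atoms,
                           coords, bonds, ranks = NULL, site_atom_idx = integer(),
                           ff = NA_character_, n_frags = 1L,
                           frag_n_heavy = integer(), frag_smiles = character(),
                           embed_seed = NA_integer_) {
  stopifnot(is.data.frame(atoms))
  heavy <- sum(atoms$element != "H")
  structure(list(
    compound_id = compound_id,
    smiles_input = smiles_input,
    canonical_smiles = canonical_smiles,
    atoms = atoms,
    coords = coords,
    bonds = bonds,
    heavy_atom_count = heavy,
    ranks = ranks,
    site_atom_idx = as.integer(site_atom_idx),
    ff = ff,
    n_frags = n_frags,
    frag_n_heavy = frag_n_heavy,
    frag_smiles = frag_smiles,
    embed_seed = embed_seed
  ), class = "Molecule3D")
}

mol_from_worker <- function(rec, compound_id, smiles, seed) {
  atoms <- data.frame(
    element = vapply(rec$atoms, `[[`, "", "el"),
    charge = vapply(rec$atoms, `[[`, 0L, "chg"),
    aromatic = vapply(rec$atoms, `[[`, FALSE, "arom"),
    n_h = vapply(rec$atoms, `[[`, 0L, "nh"),
    in_ring = vapply(rec$atoms, `[[`, FALSE, "ring"),
    stringsAsFactors = FALSE
  )
  bonds <- if (length(rec$bonds)) {
    data.frame(
      a = vapply(rec$bonds, function(b) b[[1]], 0) + 1L,
      b = vapply(rec$bonds, function(b) b[[2]], 0) + 1L,
      order = vapply(rec$bonds, function(b) b[[3]], 0),
      aromatic = vapply(rec$bonds, function(b) isTRUE(b[[4]]), FALSE)
    )
  } else {
    data.frame(a = integer(), b = integer(), order = numeric(), aromatic = logical())
  }
  coords <- NULL
  if (!is.null(rec$coords)) {
    coords <- do.call(rbind, lapply(rec$coords, unlist))
    colnames(coords) <- c("x", "y", "z")
  }
  new_molecule3d(
    compound_id = compound_id,
    smiles_input = smiles,
    canonical_smiles = rec$canonical_smiles,
    atoms = atoms,
    coords = coords,
    bonds = bonds,
    ranks = unlist(rec$ranks),
    site_atom_idx = unlist(rec$sites) + 1L,
    ff = if (is.null(rec$ff)) NA_character_ else rec$ff,
    n_frags = rec$n_frags,
    frag_n_heavy = unlist(rec$frag_n_heavy),
    frag_smiles = unlist(rec$frag_smiles),
    embed_seed = seed
  )
}

#' Parse a SMILES string into an embedded 3D molecule
#'
#' The SMILES is parsed and canonicalized, explicit hydrogens are added,
#' one 3D conformer is embedded with a seeded distance-geometry method and
#' relaxed with the MMFF94 force field (falling back to UFF when MMFF94
#' parameters are missing; the force field actually used is recorded in
#' `$ff`). Aromaticity is perceived with the toolkit's default model.
#'
#' @param smiles SMILES string.
#' @param compound_id label carried through reports and file comments.
#' @param embed embed and relax a 3D conformer (set `FALSE` for fast
#'   topology-only parsing, e.g. during library curation).
#' @param seed integer random seed for the embedding (default from config);
#'   identical inputs and seed give identical coordinates.
#' @param config see [regiots_config()].
#' @return A `Molecule3D` object: list with `compound_id`,
#'   `canonical_smiles`, `atoms` (element, formal charge, aromatic flag,
#'   hydrogen count, ring membership; explicit hydrogens appended after the
#'   heavy atoms), `coords` (n x 3 matrix, Å), `bonds`,
#'   `heavy_atom_count`, canonical symmetry `ranks` and candidate
#'   `site_atom_idx`.
#' @examples
#' \dontrun{
#' pyr <- parse_smiles("c1ccncc1", "pyridine")
#' pyr$heavy_atom_count  # 6
#' }
#' @export
parse_smiles <- function(smiles, compound_id = smiles, embed = TRUE,
                         seed = NULL, config = regiots_config()) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  opts <- worker_opts(config, embed = embed, seed = seed)
  rec <- worker_perceive(list(list(id = compound_id, smiles = smiles)), opts)[[1]]
  if (!isTRUE(rec$ok)) {
    if (grepl("unparsable", rec$error %||% "")) {
      stop("input error: unparsable SMILES ", dQuote(smiles), call. = FALSE)
    }
    stop("embedding error for ", dQuote(smiles), ": ", rec$error %||% "unknown",
         call. = FALSE)
  }
  mol_from_worker(rec, compound_id, smiles, opts$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.Molecule3D <- function(x, ...) {
  cat("<Molecule3D> ", x$compound_id, "\n",
      "  SMILES (canonical): ", x$canonical_smiles, "\n",
      "  atoms: ", nrow(x$atoms), " (", x$heavy_atom_count, " heavy), ",
      sum(x$atoms$aromatic), " aromatic\n",
      "  3D: ", if (is.null(x$coords)) "not embedded" else
        paste0("embedded (", x$ff, ", seed ", x$embed_seed, ")"), "\n",
      "  candidate sites: ", length(x$site_atom_idx), "\n", sep = "")
  invisible(x)
}

#' Read a batch request CSV
#'
#' Expects a comma-separated UTF-8 file with a header row naming (case-
#' insensitively) the columns `smiles`, `name` and `radical`. Fields are
#' whitespace-trimmed; rows with a blank SMILES are dropped with a warning;
#' duplicate (SMILES, radical) rows are retained but flagged so the result
#' cache can skip recomputation downstream.
#'
#' @param path CSV file path.
#' @return A `BatchRequest`: data.frame with columns `smiles`, `name`,
#'   `radical`, `duplicate` plus attribute `skipped` (rows dropped).
#' @export
read_batch_csv <- function(path) {
  if (!file.exists(path)) stop("batch file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8"),
                 error = function(e) stop("format error: unreadable CSV (", conditionMessage(e), ")",
                                          call. = FALSE))
  if (nrow(df) == 0L && ncol(df) == 0L) stop("format error: empty batch file")
  names(df) <- tolower(trimws(names(df)))
  need <- c("smiles", "name", "radical")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         "; expected header \"smiles,name,radical\"", call. = FALSE)
  }
  df <- df[, need]
  for (cn in need) df[[cn]] <- trimws(as.character(df[[cn]]))
  blank <- !nzchar(df$smiles)
  skipped <- df[blank, , drop = FALSE]
  if (any(blank)) {
    warning(sum(blank), " row(s) with blank SMILES skipped")
    df <- df[!blank, , drop = FALSE]
  }
  known <- names(radical_registry())
  bad <- !(tolower(df$radical) %in% known)
  if (any(bad)) {
    stop("input error: unknown radical(s): ",
         paste(unique(df$radical[bad]), collapse = ", "),
         " (supported: ", paste(known, collapse = ", "), ")", call. = FALSE)
  }
  df$radical <- tolower(df$radical)
  df$duplicate <- duplicated(paste(df$smiles, df$radical, sep = "\r"))
  rownames(df) <- NULL
  attr(df, "skipped") <- skipped
  class(df) <- c("BatchRequest", "data.frame")
  df
}

#' Write a molecule or TS guess to an XYZ file
#'
#' Standard XYZ: atom-count line, comment line carrying the compound id
#' (and, for TS guesses, site / radical / forming-distance provenance),
#' then one `element x y z` line per atom with fixed 6-decimal precision.
#'
#' @param mol a `Molecule3D` with coordinates, or a `TSGuess`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_xyz <- function(mol, path) {
  if (inherits(mol, "TSGuess")) {
    elements <- mol$geometry$elements
    coords <- mol$geometry$coords
    comment <- sprintf("%s site=%d radical=%s cc=%.4f",
                       mol$compound_id, mol$site$site_id, mol$radical_name,
                       mol$cc_distance)
  } else {
    stopifnot(inherits(mol, "Molecule3D"))
    if (is.null(mol$coords)) stop("molecule has no coordinates (parse with embed = TRUE)")
    elements <- mol$atoms$element
    coords <- mol$coords
    comment <- mol$compound_id
  }
  if (length(elements) == 0L) stop("cannot write XYZ for an empty molecule")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(length(elements)), comment), con)
  writeLines(sprintf("%-3s %14.6f %14.6f %14.6f",
                     elements, coords[, 1], coords[, 2], coords[, 3]), con)
  invisible(path)
}

#' Read an XYZ file
#'
#' @param path XYZ file path.
#' @return List with `elements`, `coords` (n x 3 matrix) and `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("parse error: truncated XYZ file")
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < 2L + n) stop("parse error: bad XYZ atom count")
  body <- lines[3:(2 + n)]
  parts <- strsplit(trimws(body), "\\s+")
  list(
    elements = vapply(parts, `[[`, "", 1L),
    coords = matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                    ncol = 3, byrow = TRUE, dimnames = list(NULL, c("x", "y", "z"))),
    comment = lines[2]
  )
}

#' Canonicalize a SMILES string
#'
#' @param smiles SMILES string.
#' @param config see [regiots_config()].
#' @return Canonical SMILES.
#' @export
canonical_smiles <- function(smiles, config = regiots_config()) {
  opts <- worker_opts(config, embed = FALSE)
  rec <- worker_perceive(list(list(id = "canon", smiles = smiles)), opts)[[1]]
  if (!isTRUE(rec$ok)) stop("input error: unparsable SMILES ", dQuote(smiles), call. = FALSE)
  rec$canonical_smiles
}
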