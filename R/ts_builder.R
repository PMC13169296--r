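#' @title Transition-state guess construction
#' @name ts_builder
#' @description Build per-site pseudo-transition-state geometries for
#'   radical addition: place the attacking radical along the local normal
#'   of the aromatic plane at the site carbon, relieve steric clashes by
#'   stepwise rotation about the forming C-C bond, and apply the forming
#'   C-C bond-length correction before ab-initio refinement.
NULL

# Radical fragment templates in a local frame whose +z axis points from the
# radical carbon toward the substrate site. theta is the angle (degrees)
# between a substituent bond and +z: > 90 puts substituents on the far side
# of the partially pyramidalized radical carbon, as in an early addition TS.
radical_template <- function(bonds) {
  do.call(rbind, lapply(bonds, function(b) {
    th <- b$theta * pi / 180
    ph <- b$phi * pi / 180
    c(b$r * sin(th) * cos(ph), b$r * sin(th) * sin(ph), b$r * cos(th))
  }))
}

#' Registry of supported attacking radicals
#'
#' Ships with trifluoromethyl (CF3) and difluoromethyl (CF2H); new radicals
#' are added by supplying the same structure: the attack atom is always the
#' first (carbon) atom, and `fragment` holds internal-coordinate bond
#' specifications (length r in Å, polar angle theta from the attack axis,
#' azimuth phi) from which the template geometry is built.
#'
#' @return Named list of `RadicalSpec` objects with fields `name`,
#'   `attack_atom` (index within the fragment), `elements`, `coords`
#'   (template geometry, attack axis = +z), `default_cc_distance` (Å).
#' @export
radical_registry <- function() {
  make <- function(name, elements, bonds, cc) {
    coords <- rbind(c(0, 0, 0), radical_template(bonds))
    structure(list(name = name, attack_atom = 1L, elements = elements,
                   coords = coords, default_cc_distance = cc),
              class = "RadicalSpec")
  }
  list(
    trifluoromethyl = make(
      "trifluoromethyl", c("C", "F", "F", "F"),
      list(list(r = 1.33, theta = 104, phi = 90),
           list(r = 1.33, theta = 104, phi = 210),
           list(r = 1.33, theta = 104, phi = 330)),
      cc = 2.25),
    difluoromethyl = make(
      "difluoromethyl", c("C", "F", "F", "H"),
      list(list(r = 1.34, theta = 104, phi = 90),
           list(r = 1.34, theta = 104, phi = 210),
           list(r = 1.09, theta = 104, phi = 330)),
      cc = 2.25)
  )
}

get_radical <- function(radical) {
  if (inherits(radical, "RadicalSpec")) return(radical)
  reg <- radical_registry()
  key <- tolower(as.character(radical))
  if (!key %in% names(reg)) {
    stop("unknown radical ", dQuote(radical), "; registry has: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[key]]
}

as_site_row <- function(site) {
  if (is.data.frame(site)) {
    stopifnot(nrow(site) == 1L)
    site <- as.list(site)
  }
  stopifnot(!is.null(site$atom_index))
  if (is.null(site$site_id)) site$site_id <- 0L
  site
}

# Minimum radical-substrate distance excluding the forming-bond pair.
min_contact <- function(sub_coords, rad_coords, site_row_in_sub, attack_row_in_rad) {
  d <- cross_distances(rad_coords, sub_coords)
  d[attack_row_in_rad, site_row_in_sub] <- Inf
  min(d)
}

#' Build an initial transition-state guess for one site
#'
#' The radical's attack carbon is placed along the local normal of the
#' aromatic plane at the site carbon (the plane defined by the site atom
#' and its two ring neighbours), at the radical's default forming C-C
#' distance, on the face pointing away from the substrate's heavy-atom
#' centroid. The construction is internal-coordinate based: the forming
#' C-C distance and the approach axis are explicit degrees of freedom that
#' later operations ([resolve_clashes()], [apply_bond_correction()])
#' manipulate directly. Construction is fully deterministic.
#'
#' @param mol a `Molecule3D` with coordinates.
#' @param site one row of [enumerate_sites()] output (or an equivalent
#'   list with `atom_index` and `site_id`).
#' @param radical radical name or `RadicalSpec` (see [radical_registry()]).
#' @param cc_distance forming C-C distance in Å (default: the radical's
#'   registry value).
#' @param config see [regiots_config()].
#' @return A `TSGuess`: combined substrate+radical geometry (substrate
#'   atoms first), `forming_bond` (substrate atom index, radical attack
#'   atom index into the combined geometry), `cc_distance`,
#'   `rotation_applied` (0 for a fresh guess) and `clash_free`.
#' @export
build_guess <- function(mol, site, radical, cc_distance = NULL,
                        config = regiots_config()) {
  stopifnot(inherits(mol, "Molecule3D"))
  if (is.null(mol$coords)) stop("molecule has no 3D coordinates")
  site <- as_site_row(site)
  rad <- get_radical(radical)
  i <- site$atom_index
  if (!(mol$atoms$element[i] == "C" && mol$atoms$aromatic[i])) {
    stop("contract violation: site atom ", i, " is not an aromatic carbon")
  }
  d0 <- if (is.null(cc_distance)) rad$default_cc_distance else cc_distance
  stopifnot(d0 > 0)

  s <- mol$coords[i, ]
  nb <- ring_neighbors(mol, i)
  if (length(nb) < 2L) stop("site atom has fewer than two ring neighbours")
  v1 <- mol$coords[nb[1], ] - s
  v2 <- mol$coords[nb[2], ] - s
  n <- unit(cross3(v1, v2))
  heavy <- mol$atoms$element != "H"
  centroid <- colMeans(mol$coords[heavy, , drop = FALSE])
  # approach from the less crowded face
  if (sum((s + n - centroid)^2) < sum((s - n - centroid)^2)) n <- -n

  zl <- -n                      # from radical carbon toward the site
  xl <- v1 - sum(v1 * zl) * zl
  xl <- unit(xl)
  yl <- cross3(zl, xl)
  M <- cbind(xl, yl, zl)
  pos <- s + d0 * n
  rad_coords <- t(M %*% t(rad$coords)) + matrix(pos, nrow(rad$coords), 3, byrow = TRUE)

  geometry <- list(
    elements = c(mol$atoms$element, rad$elements),
    coords = rbind(unname(mol$coords), rad_coords)
  )
  n_sub <- nrow(mol$coords)
  attack_combined <- n_sub + rad$attack_atom
  thr <- config$clash_threshold_angstrom
  clash_free <- min_contact(geometry$coords[seq_len(n_sub), , drop = FALSE],
                            geometry$coords[-seq_len(n_sub), , drop = FALSE],
                            i, rad$attack_atom) >= thr
  structure(list(
    compound_id = mol$compound_id,
    site = site,
    radical_name = rad$name,
    geometry = geometry,
    n_substrate_atoms = n_sub,
    forming_bond = c(substrate = i, radical = attack_combined),
    cc_distance = d0,
    rotation_applied = 0,
    clash_free = clash_free,
    clash_threshold = thr,
    symmetry_class = site$symmetry_class %||% NA_integer_,
    ortho_substituted = substituted_ortho_count(mol, i)
  ), class = "TSGuess")
}

#' @export
print.TSGuess <- function(x, ...) {
  cat("<TSGuess> ", x$compound_id, " site ", x$site$site_id,
      " + ", x$radical_name, "\n",
      "  atoms: ", length(x$geometry$elements),
      " (", x$n_substrate_atoms, " substrate)\n",
      "  forming C-C: ", sprintf("%.4f", x$cc_distance), " A, rotation ",
      x$rotation_applied, " deg, clash_free = ", x$clash_free, "\n", sep = "")
  invisible(x)
}

guess_split <- function(guess) {
  ns <- guess$n_substrate_atoms
  list(sub = guess$geometry$coords[seq_len(ns), , drop = FALSE],
       rad = guess$geometry$coords[-seq_len(ns), , drop = FALSE])
}

set_radical_coords <- function(guess, rad_coords) {
  ns <- guess$n_substrate_atoms
  guess$geometry$coords[(ns + 1):nrow(guess$geometry$coords), ] <- rad_coords
  guess$cc_distance <- vnorm(guess$geometry$coords[guess$forming_bond[["radical"]], ] -
                             guess$geometry$coords[guess$forming_bond[["substrate"]], ])
  guess
}

#' Relieve steric clashes by rotation about the forming C-C bond
#'
#' Tries rotations in increments of `step` degrees (starting from 0) about
#' the forming C-C axis and returns the first whose minimum
#' radical-substrate contact (excluding the forming-bond atom pair) is at
#' least `threshold`. If no rotation in a full turn succeeds, returns the
#' rotation maximizing that minimum contact with `clash_free = FALSE` and
#' a warning.
#'
#' @param guess a `TSGuess`.
#' @param threshold clash distance in Å (default from config: 1.0 Å).
#' @param step rotation increment in degrees (default 5°).
#' @param config see [regiots_config()].
#' @return The rotated `TSGuess` with `rotation_applied` and `clash_free`
#'   updated.
#' @export
resolve_clashes <- function(guess, threshold = NULL, step = NULL,
                            config = regiots_config()) {
  stopifnot(inherits(guess, "TSGuess"))
  threshold <- threshold %||% config$clash_threshold_angstrom
  step <- step %||% config$rotation_step_degrees
  stopifnot(threshold > 0, step > 0, step < 360)
  parts <- guess_split(guess)
  i_sub <- guess$forming_bond[["substrate"]]
  i_rad <- guess$forming_bond[["radical"]] - guess$n_substrate_atoms
  origin <- parts$sub[i_sub, ]
  axis <- parts$rad[i_rad, ] - origin

  angles <- seq(0, 360 - step, by = step)
  best_angle <- 0
  best_min <- -Inf
  for (ang in angles) {
    rc <- if (ang == 0) parts$rad else
      rotate_about_axis(parts$rad, origin, axis, ang * pi / 180)
    m <- min_contact(parts$sub, rc, i_sub, i_rad)
    if (m >= threshold) {
      out <- set_radical_coords(guess, rc)
      out$rotation_applied <- ang
      out$clash_free <- TRUE
      out$clash_threshold <- threshold
      return(out)
    }
    if (m > best_min) {
      best_min <- m
      best_angle <- ang
    }
  }
  warning("no clash-free rotation found for ", guess$compound_id, " site ",
          guess$site$site_id, "; keeping best rotation ", best_angle,
          " deg (min contact ", sprintf("%.3f", best_min), " A)")
  rc <- if (best_angle == 0) parts$rad else
    rotate_about_axis(parts$rad, origin, axis, best_angle * pi / 180)
  out <- set_radical_coords(guess, rc)
  out$rotation_applied <- best_angle
  out$clash_free <- FALSE
  out$clash_threshold <- threshold
  out
}

#' Lengthen the forming C-C bond by a fixed correction
#'
#' Rigidly translates the radical fragment along the forming-bond axis so
#' the forming C-C distance increases by exactly `delta`, compensating the
#' systematic underestimation of that distance at the semiempirical level.
#' All intra-fragment distances are untouched.
#'
#' @param guess a `TSGuess`.
#' @param delta length increment in Å (default from config: 0.10 Å).
#' @param config see [regiots_config()].
#' @return The corrected `TSGuess`.
#' @export
apply_bond_correction <- function(guess, delta = NULL, config = regiots_config()) {
  stopifnot(inherits(guess, "TSGuess"))
  delta <- delta %||% config$bond_correction_angstrom
  if (guess$cc_distance + delta <= 0) {
    stop("contract violation: correction would make the forming C-C distance non-positive")
  }
  if (delta == 0) return(guess)
  parts <- guess_split(guess)
  i_sub <- guess$forming_bond[["substrate"]]
  i_rad <- guess$forming_bond[["radical"]] - guess$n_substrate_atoms
  axis <- unit(parts$rad[i_rad, ] - parts$sub[i_sub, ])
  rc <- parts$rad + matrix(delta * axis, nrow(parts$rad), 3, byrow = TRUE)
  out <- set_radical_coords(guess, rc)
  out$clash_free <- min_contact(parts$sub, rc, i_sub, i_rad) >= out$clash_threshold
  out
}
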