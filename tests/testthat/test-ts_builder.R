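# Independent rotation used as the brute-force oracle (Rodrigues formula,
# written without reference to the package's geometry helpers).
oracle_rotate <- function(pts, origin, axis, deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  t(apply(pts, 1, function(p) {
    v <- p - origin
    vr <- v * cos(th) + c(k[2] * v[3] - k[3] * v[2],
                          k[3] * v[1] - k[1] * v[3],
                          k[1] * v[2] - k[2] * v[1]) * sin(th) +
      k * sum(k * v) * (1 - cos(th))
    vr + origin
  }))
}

oracle_min_contact <- function(sub, rad, i_sub, i_rad) {
  d <- as.matrix(stats::dist(rbind(rad, sub)))[seq_len(nrow(rad)),
                                               nrow(rad) + seq_len(nrow(sub)),
                                               drop = FALSE]
  d[i_rad, i_sub] <- Inf
  min(d)
}

oracle_scan <- function(guess, step = 5) {
  ns <- guess$n_substrate_atoms
  sub <- guess$geometry$coords[seq_len(ns), , drop = FALSE]
  rad <- guess$geometry$coords[-seq_len(ns), , drop = FALSE]
  i_sub <- guess$forming_bond[["substrate"]]
  i_rad <- guess$forming_bond[["radical"]] - ns
  origin <- sub[i_sub, ]
  axis <- rad[i_rad, ] - origin
  angles <- seq(0, 360 - step, by = step)
  vapply(angles, function(a) {
    rc <- oracle_rotate(rad, origin, axis, a)
    oracle_min_contact(sub, rc, i_sub, i_rad)
  }, 0)
}

test_that("guess construction places the radical at the requested distance, deterministically", {
  pyr <- fixture_mol("pyridine", embed = TRUE)
  sites <- enumerate_sites(pyr)
  g <- build_guess(pyr, sites[1, ], "trifluoromethyl")
  expect_s3_class(g, "TSGuess")
  expect_length(g$geometry$elements, 11 + 4)   # pyridine + CF3
  expect_equal(g$cc_distance, 2.25, tolerance = 1e-9)
  fb <- g$forming_bond
  d <- sqrt(sum((g$geometry$coords[fb[["radical"]], ] -
                 g$geometry$coords[fb[["substrate"]], ])^2))
  expect_equal(d, g$cc_distance, tolerance = 1e-6)
  expect_equal(g$rotation_applied, 0)

  g2 <- build_guess(pyr, sites[1, ], "trifluoromethyl")
  expect_identical(g$geometry$coords, g2$geometry$coords)   # bit-identical

  benz <- fixture_mol("benzene", embed = TRUE)
  gb <- build_guess(benz, enumerate_sites(benz)[1, ], "trifluoromethyl")
  expect_length(gb$geometry$elements, 12 + 4)

  # difluoromethyl carries one H
  gd <- build_guess(pyr, sites[1, ], "difluoromethyl")
  expect_setequal(gd$geometry$elements[12:15], c("C", "F", "F", "H"))

  n_idx <- which(pyr$atoms$element == "N")
  expect_error(build_guess(pyr, list(atom_index = n_idx, site_id = 99L),
                           "trifluoromethyl"),
               "not an aromatic carbon")
})

test_that("clash resolution equals the exhaustive 72-rotation search on every panel guess", {
  panel <- fixture_panel(embed = TRUE)
  mols <- attr(panel, "molecules")
  checked <- 0L
  for (nm in c("pyridine", "quinoline", "indole", "4-methylpyridine", "imidazole")) {
    mol <- mols[[nm]]
    sites <- enumerate_sites(mol)
    for (k in seq_len(nrow(sites))) {
      g <- build_guess(mol, sites[k, ], "trifluoromethyl")
      scan <- oracle_scan(g, step = 5)
      angles <- seq(0, 355, by = 5)
      # feasible threshold strictly between attained values, away from ties
      thr <- if (diff(range(scan)) < 1e-9) min(scan) - 1e-6 else mean(range(scan))
      res <- resolve_clashes(g, threshold = thr, step = 5)
      feas <- which(scan >= thr)
      expect_true(res$clash_free, label = paste(nm, k))
      expect_equal(res$rotation_applied, angles[min(feas)], label = paste(nm, k))
      # infeasible threshold: returned rotation attains the oracle maximum
      suppressWarnings(res2 <- resolve_clashes(g, threshold = max(scan) + 0.5, step = 5))
      expect_false(res2$clash_free)
      expect_equal(scan[match(res2$rotation_applied, angles)], max(scan),
                   tolerance = 1e-9, label = paste(nm, k))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 10L)
})

test_that("already clash-free guesses are returned unchanged; impossible thresholds give argmax", {
  pyr <- fixture_mol("pyridine", embed = TRUE)
  g <- build_guess(pyr, enumerate_sites(pyr)[1, ], "trifluoromethyl")
  res <- resolve_clashes(g, threshold = 1.0, step = 5)
  expect_true(res$clash_free)
  expect_equal(res$rotation_applied, 0)
  expect_identical(res$geometry$coords, g$geometry$coords)

  expect_warning(res2 <- resolve_clashes(g, threshold = 50, step = 5),
                 "no clash-free rotation")
  expect_false(res2$clash_free)
  scan <- oracle_scan(g, step = 5)
  expect_equal(scan[match(res2$rotation_applied, seq(0, 355, by = 5))], max(scan),
               tolerance = 1e-9)
})

test_that("bond correction lengthens the forming bond rigidly", {
  pyr <- fixture_mol("pyridine", embed = TRUE)
  g <- build_guess(pyr, enumerate_sites(pyr)[1, ], "trifluoromethyl")
  ns <- g$n_substrate_atoms
  rad_before <- g$geometry$coords[-seq_len(ns), , drop = FALSE]

  g2 <- apply_bond_correction(g, 0.15)
  expect_equal(g2$cc_distance, 2.40, tolerance = 1e-9)
  rad_after <- g2$geometry$coords[-seq_len(ns), , drop = FALSE]
  expect_lt(max(abs(stats::dist(rad_before) - stats::dist(rad_after))), 1e-9)

  # substrate untouched by every builder operation
  expect_identical(g2$geometry$coords[seq_len(ns), ], g$geometry$coords[seq_len(ns), ])
  g3 <- resolve_clashes(g, threshold = 1.8, step = 5)
  expect_identical(g3$geometry$coords[seq_len(ns), ], g$geometry$coords[seq_len(ns), ])

  expect_identical(apply_bond_correction(g, 0), g)
  expect_error(apply_bond_correction(g, -5), "non-positive")
})

test_that("guesses at symmetry-equivalent sites superimpose after the symmetry permutation", {
  benz <- ideal_benzene()
  g1 <- build_guess(benz, list(atom_index = 1L, site_id = 0L), "trifluoromethyl")
  g2 <- build_guess(benz, list(atom_index = 2L, site_id = 1L), "trifluoromethyl")
  # rotate-by-one automorphism of the ring: atom i of g1 corresponds to i+1 of g2
  perm <- c(2:6, 1, 8:12, 7, 13:16)
  expect_lt(rmsd_aligned(g1$geometry$coords, g2$geometry$coords[perm, ]), 1e-3)
})

test_that("rigid alignment agrees with an independent structural-biology implementation", {
  skip_if_not_installed("bio3d")
  set.seed(42)
  a <- matrix(rnorm(30), ncol = 3)
  R <- regiots:::rotation_matrix(c(1, 2, 3), 0.7)
  b <- a %*% t(R) + matrix(c(1, -2, 0.5), 10, 3, byrow = TRUE)
  expect_lt(rmsd_aligned(a, b), 1e-10)

  b2 <- b + matrix(rnorm(30, sd = 0.05), ncol = 3)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(a)), mobile = as.numeric(t(b2))))
  ref <- bio3d::rmsd(as.numeric(t(a)), fitted)  # bio3d reports 3 decimals
  expect_equal(round(rmsd_aligned(a, b2), 3), ref)
})
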