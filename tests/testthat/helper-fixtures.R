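# Shared fixtures, parsed once per test session (perception results are
# memoised inside the package, so repeated helper calls are cheap).

fixture_panel <- local({
  cache <- NULL
  function(embed = FALSE) {
    key <- if (embed) "embedded" else "flat"
    if (is.null(cache[[key]])) {
      cache[[key]] <<- make_molecule_panel(embed = embed)
    }
    cache[[key]]
  }
})

fixture_mol <- function(name, embed = FALSE) {
  attr(fixture_panel(embed), "molecules")[[name]]
}

# An idealized planar six-ring (benzene) built without embedding, so exact
# symmetry properties can be asserted on constructed geometry.
ideal_benzene <- function() {
  rcc <- 1.39
  rch <- 1.09
  ang <- seq(0, by = pi / 3, length.out = 6)
  cc <- cbind(rcc * cos(ang) / (2 * sin(pi / 6)), rcc * sin(ang) / (2 * sin(pi / 6)), 0)
  # place ring carbons on a circle of the correct C-C distance
  rring <- rcc / (2 * sin(pi / 6))
  cc <- cbind(rring * cos(ang), rring * sin(ang), 0)
  hh <- cbind((rring + rch) * cos(ang), (rring + rch) * sin(ang), 0)
  atoms <- data.frame(
    element = c(rep("C", 6), rep("H", 6)),
    charge = 0L,
    aromatic = c(rep(TRUE, 6), rep(FALSE, 6)),
    n_h = c(rep(1L, 6), rep(0L, 6)),
    in_ring = c(rep(TRUE, 6), rep(FALSE, 6))
  )
  bonds <- data.frame(
    a = c(1:6, 1:6),
    b = c(2:6, 1, 7:12),
    order = c(rep(1.5, 6), rep(1, 6)),
    aromatic = c(rep(TRUE, 6), rep(FALSE, 6))
  )
  regiots:::new_molecule3d("ideal_benzene", "c1ccccc1", "c1ccccc1",
                           atoms, rbind(cc, hh), bonds,
                           ranks = c(rep(1L, 6), rep(0L, 6)),
                           site_atom_idx = 1:6)
}

scripted_engine <- function(scenario, ...) {
  sc <- make_engine_script(scenario, ...)
  engine_spec("scripted", script = sc$reports)
}
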