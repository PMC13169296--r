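# Independent direct evaluation of the Boltzmann weights (no max-shift),
# used as the high-precision oracle.
oracle_ratios <- function(e, g, T) {
  w <- g * exp(-e / (1.98720425864083e-3 * T))
  100 * w / sum(w)
}

test_that("Boltzmann ratios reproduce forced analytic cases", {
  expect_equal(boltzmann_ratios(c(0, 0)), c(50, 50), ignore_attr = TRUE)
  expect_equal(boltzmann_ratios(c(5.5, 5.5), temperature = 77), c(50, 50),
               ignore_attr = TRUE)

  rt_ln2 <- regiots_constants()$r_kcal_mol_k * 298.15 * log(2)
  expect_equal(boltzmann_ratios(c(0, rt_ln2)), c(200, 100) / 3,
               tolerance = 1e-12, ignore_attr = TRUE)

  r <- boltzmann_ratios(c(0, 1, 2), degeneracies = c(1, 2, 1), temperature = 298.15)
  expect_equal(as.numeric(r), oracle_ratios(c(0, 1, 2), c(1, 2, 1), 298.15),
               tolerance = 1e-10)
})

test_that("Boltzmann ratios are normalized, order-invariant, monotone, and T->0 concentrates", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    e <- runif(n, 0, 15)
    g <- sample(1:3, n, replace = TRUE)
    T <- runif(1, 100, 600)
    r <- boltzmann_ratios(e, g, T)
    expect_equal(sum(r), 100, tolerance = 1e-9)
    expect_equal(as.numeric(r), oracle_ratios(e, g, T), tolerance = 1e-10)
    p <- sample(n)
    expect_equal(as.numeric(boltzmann_ratios(e[p], g[p], T)), as.numeric(r)[p],
                 tolerance = 1e-12)
    # lowering one class's barrier strictly increases its share
    k <- sample(n, 1)
    e2 <- e; e2[k] <- e2[k] - 0.5
    expect_gt(boltzmann_ratios(e2, g, T)[k], r[k])
  }
  # T -> 0+ concentrates all weight on the minimum-energy class
  r0 <- boltzmann_ratios(c(3, 1, 8), temperature = 1)
  expect_equal(as.numeric(r0), c(0, 100, 0), tolerance = 1e-6)

  # numerical stability where the naive form would overflow/underflow
  r_big <- boltzmann_ratios(c(0, 5000), temperature = 298.15)
  expect_equal(sum(r_big), 100)
  expect_false(any(is.nan(r_big)))

  expect_error(boltzmann_ratios(c(NA_real_, NA_real_)), "empty-report")
})

test_that("selectivity reports distribute class ratios over degenerate sites and rank them", {
  pyr <- fixture_mol("pyridine", embed = TRUE)
  sites <- enumerate_sites(pyr)
  engine <- engine_spec("mock", surface = mock_surface(seed = 2))
  results <- lapply(seq_len(nrow(sites)), function(k) {
    g <- build_guess(pyr, sites[k, ], "trifluoromethyl")
    run_ts_search(g, engine)
  })
  repx <- selectivity_report("pyridine", "trifluoromethyl", sites, results)
  expect_equal(sum(repx$sites$ratio_percent), 100, tolerance = 1e-6)
  # symmetry-equivalent sites receive equal ratios (cross-module property)
  for (cl in unique(repx$sites$symmetry_class)) {
    rr <- repx$sites$ratio_percent[repx$sites$symmetry_class == cl]
    expect_equal(length(unique(rr)), 1L)
  }
  # ranking is by descending ratio; predicted major is the top entry
  expect_true(all(diff(repx$sites$ratio_percent) <= 1e-12))
  expect_equal(predict_major(repx), repx$sites$site_id[1])
  expect_equal(repx$sites$site_id[which.min(repx$sites$activation_energy)],
               predict_major(repx))
})

test_that("exact ties break to the lowest site id with a flag", {
  sites <- data.frame(site_id = 0:1, atom_index = 1:2, symmetry_class = c(7L, 9L))
  class(sites) <- c("ReactionSite", "data.frame")
  mk_res <- function(sid, cls, ea) {
    structure(list(site = list(site_id = sid, atom_index = sid + 1L,
                               symmetry_class = cls),
                   compound_id = "tie", radical_name = "trifluoromethyl",
                   status = "true_ts", activation_energy = ea,
                   attempts = list()), class = "TSResult")
  }
  expect_message(
    repx <- selectivity_report("tie", "trifluoromethyl", sites,
                               list(mk_res(0L, 7L, 5.0), mk_res(1L, 9L, 5.0))),
    "tie")
  expect_true(repx$tie)
  expect_equal(predict_major(repx), 0L)
  expect_equal(repx$sites$ratio_percent, c(50, 50), tolerance = 1e-12)

  # failed classes are excluded and reported
  repf <- selectivity_report("part", "trifluoromethyl", sites,
                             list(mk_res(0L, 7L, 5.0),
                                  structure(list(site = list(site_id = 1L, atom_index = 2L,
                                                             symmetry_class = 9L),
                                                 compound_id = "part",
                                                 radical_name = "trifluoromethyl",
                                                 status = "failed",
                                                 activation_energy = NA_real_,
                                                 attempts = list()),
                                            class = "TSResult")))
  expect_equal(repf$failures, 1L)
  expect_equal(repf$sites$ratio_percent[repf$sites$site_id == 0], 100)
})

test_that("accuracy scoring reproduces the per-site tally arithmetic", {
  # synthetic panel: 30 compounds, 139 labelled sites, exactly 2 disagreements
  mk_report <- function(cid, n_sites, major = 0L) {
    ratios <- rep(1, n_sites)
    ratios[major + 1] <- 100
    ratios <- 100 * ratios / sum(ratios)
    ord <- order(-ratios, seq_len(n_sites) - 1L)
    structure(list(compound_id = cid, radical_name = "trifluoromethyl",
                   sites = data.frame(site_id = (seq_len(n_sites) - 1L)[ord],
                                      atom_index = ord,
                                      symmetry_class = seq_len(n_sites)[ord],
                                      activation_energy = NA_real_,
                                      degeneracy = 1L,
                                      ratio_percent = ratios[ord]),
                   predicted_major = major, temperature = 298.15,
                   failures = integer(), tie = FALSE),
              class = "SelectivityReport")
  }
  sizes <- c(rep(5, 19), rep(4, 11))  # 19*5 + 11*4 = 139 sites
  stopifnot(sum(sizes) == 139)
  reports <- lapply(seq_along(sizes), function(i) {
    mk_report(sprintf("cmpd%02d", i), sizes[i], major = 0L)
  })
  labels <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    data.frame(compound_id = sprintf("cmpd%02d", i),
               site_id = seq_len(sizes[i]) - 1L,
               observed = as.integer(seq_len(sizes[i]) == 1))
  }))
  # introduce exactly two disagreements: flip observations at two sites
  labels$observed[labels$compound_id == "cmpd01" & labels$site_id == 0] <- 0L
  labels$observed[labels$compound_id == "cmpd02" & labels$site_id == 3] <- 1L

  tally <- score_accuracy(reports, labels)
  expect_equal(tally$n_sites_total, 139L)
  expect_equal(tally$n_sites_correct, 137L)
  expect_equal(round(tally$accuracy_percent, 1), 98.6)

  # perfect synthetic set scores 100
  lab10 <- data.frame(compound_id = "c", site_id = 0:9,
                      observed = as.integer(0:9 == 0))
  expect_equal(score_accuracy(list(mk_report("c", 10)), lab10)$accuracy_percent, 100)

  # labels for an unknown compound are a data error
  expect_error(score_accuracy(list(mk_report("c", 10)),
                              data.frame(compound_id = "zzz", site_id = 0, observed = 1)),
               "data error")
  expect_error(score_accuracy(list(mk_report("c", 10)),
                              data.frame(compound_id = "c", site_id = 0:3, observed = 0)),
               "site set mismatch")
})
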