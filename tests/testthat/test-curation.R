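test_that("filters remove the hand-checked examples for the right reasons", {
  tr <- apply_filters(c("c1ccncc1", "c1ccccc1", "C[N+](C)(C)C"))
  expect_s3_class(tr, "FilterTrace")
  expect_identical(tr$surviving, "c1ccncc1")
  v <- tr$verdicts
  expect_equal(v$removed_by[v$smiles == "c1ccccc1"], "no_aromatic_N")
  expect_equal(v$removed_by[v$smiles == "C[N+](C)(C)C"], "charged")
  expect_equal(tr$input_count - sum(tr$removed), length(tr$surviving))

  # salt stripping: pyridine hydrochloride survives as the parent
  tr2 <- apply_filters("c1ccncc1.Cl")
  expect_identical(tr2$surviving, "c1ccncc1")
  expect_identical(tr2$salt_stripped, "c1ccncc1")

  # two non-trivial organic fragments = formulation
  tr3 <- apply_filters("Cc1ccncc1.OCc1ccccc1")
  expect_equal(unname(tr3$removed[["formulation"]]), 1L)

  # oversized polyaromatic-like chain
  tr4 <- apply_filters(paste0(strrep("C", 50), "c1ccncc1"))
  expect_equal(unname(tr4$removed[["size"]]), 1L)

  # net-neutral zwitterion kept by default, removable by flag
  zwit <- "C[N+](C)(CC([O-])=O)C"  # betaine-like, no aromatic N anyway
  expect_equal(apply_filters(zwit)$removed[["charged"]], 0L, ignore_attr = TRUE)
  cfg <- regiots_config(exclude_zwitterions = TRUE)
  expect_equal(apply_filters(zwit, config = cfg)$removed[["charged"]], 1L,
               ignore_attr = TRUE)

  expect_equal(apply_filters(character())$input_count, 0L)
})

test_that("generated fixture library matches its ground-truth verdicts and is coverage-complete", {
  lib <- make_curation_library(n = 40, seed = 1)
  expect_gte(nrow(lib), 40L)
  tr <- apply_filters(lib$smiles)
  expect_identical(unname(tr$verdicts$removed_by), unname(lib$expected_removed_by))
  # every filter category exercised at least twice
  tab <- table(lib$expected_removed_by, useNA = "no")
  for (f in c("charged", "formulation", "size", "no_aromatic_N", "too_few_sites")) {
    expect_gte(unname(tab[f]), 2L)
  }
  expect_gte(sum(is.na(lib$expected_removed_by)), 2L)
  # regeneration with the same seed is identical
  expect_identical(make_curation_library(n = 40, seed = 1), lib)
})

test_that("the surviving set is invariant under filter reordering", {
  lib <- make_curation_library(n = 30, seed = 2)
  base <- sort(apply_filters(lib$smiles)$surviving)
  orders <- list(
    c("too_few_sites", "no_aromatic_N", "size", "formulation", "charged"),
    c("size", "charged", "too_few_sites", "formulation", "no_aromatic_N")
  )
  for (ord in orders) {
    expect_identical(sort(apply_filters(lib$smiles, order = ord)$surviving), base)
  }
})

test_that("tanimoto matches hand-computed and library-computed values", {
  expect_equal(tanimoto(c(1L, 2L, 3L), c(2L, 3L, 4L)), 0.5)
  expect_equal(tanimoto(c(5L, 9L), c(5L, 9L)), 1.0)
  expect_equal(tanimoto(c(1L, 2L), c(3L, 4L)), 0.0)
  expect_equal(tanimoto(integer(), integer()), 1.0)
  a <- structure(c(1L, 2L), nbits = 1024L)
  b <- structure(c(1L, 2L), nbits = 2048L)
  expect_error(tanimoto(a, b), "bit lengths differ")

  set.seed(99)
  for (i in 1:25) {
    fa <- sort(sample.int(2048, sample(5:60, 1)))
    fb <- sort(sample.int(2048, sample(5:60, 1)))
    s <- tanimoto(fa, fb)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, tanimoto(fb, fa))
    if (s == 1) expect_identical(fa, fb)
  }
})

test_that("tanimoto agrees with the ChemmineR fingerprint oracle on random bit vectors", {
  skip_if_not_installed("ChemmineR")
  set.seed(7)
  for (i in 1:10) {
    bits_a <- sort(sample.int(1024, 40))
    bits_b <- sort(sample.int(1024, 40))
    va <- integer(1024); va[bits_a] <- 1L
    vb <- integer(1024); vb[bits_b] <- 1L
    ref <- ChemmineR::fpSim(methods::as(va, "FP"), methods::as(vb, "FP"),
                            method = "Tanimoto", addone = 0)
    expect_equal(tanimoto(bits_a, bits_b), unname(ref), tolerance = 1e-12)
  }
})

test_that("clustering honours the threshold and its boundary cases", {
  smls <- c("c1ccncc1", "Cc1ccncc1", "c1ccc2ncccc2c1",
            "CCCCCCCC", "O=C(O)CCCCC", "c1cncnc1")
  fps <- morgan_fingerprints(smls)

  # threshold above 1 puts everything in singletons; threshold 0 merges all
  cl_hi <- butina_clusters(fps, threshold = 1 + 1e-9)
  expect_length(cl_hi$clusters, length(smls))
  cl_lo <- butina_clusters(fps, threshold = 0)
  expect_length(cl_lo$clusters, 1L)
  expect_setequal(cl_lo$clusters[[1]], seq_along(smls))

  # every member is within threshold of its centroid
  cl <- butina_clusters(fps, threshold = 0.35)
  for (k in seq_along(cl$clusters)) {
    cen <- cl$clusters[[k]][1]
    for (m in cl$clusters[[k]]) {
      expect_gte(tanimoto(fps[[cen]], fps[[m]]), 0.35)
    }
  }
  # clusters partition the set
  expect_setequal(unlist(cl$clusters), seq_along(smls))
})

test_that("cluster sampling is seeded, covers clusters round-robin, and validates n_target", {
  distinct <- c("c1ccncc1", "CCCCCCCCCC", "O=S(=O)(O)c1ccc2ncccc2c1")
  s3 <- cluster_and_sample(distinct, threshold = 0.7, n_target = 3, seed = 4)
  expect_setequal(as.character(s3), distinct)
  expect_length(attr(s3, "clusters")$clusters, 3L)

  dup <- c(rep("c1ccncc1", 5), "CCCCCCCCCC")
  s2 <- cluster_and_sample(dup, threshold = 0.7, n_target = 2, seed = 4)
  expect_setequal(as.character(s2), c("c1ccncc1", "CCCCCCCCCC"))

  a <- cluster_and_sample(dup, threshold = 0.7, n_target = 3, seed = 9)
  b <- cluster_and_sample(dup, threshold = 0.7, n_target = 3, seed = 9)
  expect_identical(as.character(a), as.character(b))

  expect_error(cluster_and_sample(distinct, n_target = 10, seed = 1),
               "argument error")
})
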