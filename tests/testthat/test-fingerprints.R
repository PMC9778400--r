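test_that("path fingerprint basics: no bonds, determinism, invariance", {
  expect_length(path_fingerprint(SMI$methane)$bits, 0L)

  f1 <- path_fingerprint(SMI$quercetin)
  f2 <- path_fingerprint(SMI$quercetin)
  expect_identical(f1$bits, f2$bits)

  # atom-order permutation does not change the fingerprint
  mol <- parse_smiles(SMI$quercetin)
  set.seed(1)
  for (rep in 1:3) {
    alt <- flavoqsar:::.write_smiles(mol, rank = sample(nrow(mol$atoms)))
    expect_identical(path_fingerprint(alt)$bits, f1$bits)
  }

  # linear mode is a subset-features variant and also deterministic
  fl <- path_fingerprint(SMI$quercetin, branched = FALSE)
  expect_identical(fl$bits, path_fingerprint(SMI$quercetin, branched = FALSE)$bits)
  expect_error(tanimoto(f1, fl), "mismatched")
})

test_that("circular fingerprint radius semantics", {
  expect_lte(length(circular_fingerprint("CCO", radius = 0)$bits), 3L)
  b0 <- circular_fingerprint(SMI$benzene_arom, radius = 0)$bits
  b1 <- circular_fingerprint(SMI$benzene_arom, radius = 1)$bits
  expect_lte(length(setdiff(b1, b0)), 2L)
  f <- circular_fingerprint(SMI$quercetin)
  expect_identical(tanimoto(f, circular_fingerprint(SMI$quercetin)), 1)
})

test_that("tanimoto matches set arithmetic and its conventions", {
  mk <- function(bits) flavoqsar:::.new_fingerprint(bits, 2048L, "path", list())
  expect_equal(tanimoto(mk(1:5), mk(1:5)), 1)
  expect_equal(tanimoto(mk(1:3), mk(4:6)), 0)
  expect_equal(tanimoto(mk(1:3), mk(2:4)), 0.5)
  expect_warning(s <- tanimoto(mk(integer(0)), mk(integer(0))), "empty")
  expect_equal(s, 1)
  # symmetry on arbitrary molecules
  fa <- path_fingerprint(SMI$ethanol); fb <- path_fingerprint(SMI$propane)
  expect_identical(tanimoto(fa, fb), tanimoto(fb, fa))
})

test_that("similarity_matrix equals brute-force pairwise tanimoto", {
  set <- compound_set(id = c("a", "b", "c"),
                      smiles = c(SMI$ethanol, SMI$quercetin, SMI$benzene_arom))
  m <- similarity_matrix(set, kind = "path")
  expect_identical(dim(m), c(3L, 3L))
  expect_identical(unname(diag(m)), rep(1, 3))
  expect_identical(m, t(m))
  fps <- lapply(set$smiles, path_fingerprint)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_identical(m[i, j], tanimoto(fps[[i]], fps[[j]]))
  }
  # duplicated compound: off-diagonal 1
  dup <- compound_set(id = c("x", "y"), smiles = c(SMI$ethanol, "OCC"))
  expect_equal(similarity_matrix(dup, kind = "path")[1, 2], 1)
  # single compound
  one <- compound_set(id = "solo", smiles = "CCO")
  expect_identical(unclass(similarity_matrix(one, "path"))[1, 1], 1)
})

test_that("single linkage clustering honours trivial cuts and known geometry", {
  set.seed(7)
  ids <- letters[1:4]
  # two tight pairs, far apart
  S <- matrix(0.05, 4, 4, dimnames = list(ids, ids))
  S[1, 2] <- S[2, 1] <- 0.95
  S[3, 4] <- S[4, 3] <- 0.9
  diag(S) <- 1
  cl <- single_linkage_cluster(S, 2)
  expect_identical(cl$labels[["a"]], cl$labels[["b"]])
  expect_identical(cl$labels[["c"]], cl$labels[["d"]])
  expect_false(cl$labels[["a"]] == cl$labels[["c"]])
  expect_false(is.unsorted(cl$merge_heights))

  expect_length(unique(single_linkage_cluster(S, 4)$labels), 4L)
  expect_length(unique(single_linkage_cluster(S, 1)$labels), 1L)
  expect_error(single_linkage_cluster(S, 0), "between")
  expect_error(single_linkage_cluster(S, 5), "between")

  # permutation invariance up to label renaming
  perm <- c(3, 1, 4, 2)
  cl2 <- single_linkage_cluster(S[perm, perm], 2)
  expect_identical(cl$labels[["a"]] == cl$labels[["b"]],
                   cl2$labels[["a"]] == cl2$labels[["b"]])
  expect_identical(cl$labels[["a"]] == cl$labels[["c"]],
                   cl2$labels[["a"]] == cl2$labels[["c"]])
})

test_that("cluster_mean_similarity averages off-diagonal entries", {
  ids <- c("u", "v", "w", "z")
  S <- diag(1, 4); dimnames(S) <- list(ids, ids)
  S[1, 2] <- S[2, 1] <- 0.8
  S[3, 4] <- S[4, 3] <- 0.6
  cl <- single_linkage_cluster(S, 2)
  ms <- cluster_mean_similarity(cl, S)
  expect_setequal(round(unname(ms), 10), c(0.8, 0.6))
  # three-way cluster with equal sims
  S3 <- matrix(0.9, 3, 3); diag(S3) <- 1
  dimnames(S3) <- list(letters[1:3], letters[1:3])
  cl3 <- single_linkage_cluster(S3, 1)
  expect_equal(unname(cluster_mean_similarity(cl3, S3)), 0.9)
  # singleton clusters are absent
  cl1 <- single_linkage_cluster(S, 4)
  expect_length(cluster_mean_similarity(cl1, S), 0L)
  # id mismatch is a configuration error
  bad <- S; rownames(bad) <- colnames(bad) <- c("u", "v", "w", "q")
  expect_error(cluster_mean_similarity(cl, bad), "ids")
})
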