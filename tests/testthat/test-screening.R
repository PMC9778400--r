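test_that("similarity enrichment retains seeds and respects the threshold", {
  ref <- reference_set()
  seeds <- ref[1:3, ]
  lib <- compound_set(id = c("seedcopy", "hexane", "benzene"),
                      smiles = c(seeds$smiles[1], "CCCCCC", "c1ccccc1"))
  enr <- enrich_by_similarity(lib, seeds)
  expect_identical(enr$id, "seedcopy")
  expect_equal(enr$best_similarity, 1)
  expect_identical(enr$best_seed_id, seeds$id[1])

  # alkanes vs flavonoid seeds: all far below 0.8
  alkanes <- compound_set(id = c("a1", "a2"), smiles = c("CCCCCC", "CCCC(C)C"))
  expect_equal(nrow(enrich_by_similarity(alkanes, seeds)), 0L)

  # threshold 0 retains the whole parseable library
  cfg0 <- screening_config(similarity_threshold = 0)
  expect_equal(nrow(enrich_by_similarity(lib, seeds, cfg0)), 3L)

  expect_error(enrich_by_similarity(lib, seeds[0, ]), "empty seed")
})

test_that("deduplicate merges canonical structures and is idempotent", {
  set <- compound_set(id = c("a", "b", "c"),
                      smiles = c("CCO", "OCC", "c1ccccc1"))
  dd <- deduplicate(set)
  expect_equal(nrow(dd), 2L)
  expect_identical(dd$id, c("a", "c"))  # first occurrence kept
  expect_identical(deduplicate(dd), dd)
})

test_that("qed and molecular weight behave physically", {
  ref <- reference_set()
  q <- vapply(ref$smiles, qed, 0, USE.NAMES = FALSE)
  expect_true(all(q >= 0 & q <= 1))
  expect_equal(molecular_weight("O"), 18.02, tolerance = 0.01)
  # adding a methylene: +14.03
  expect_equal(molecular_weight("CCCO") - molecular_weight("CCO"), 14.03,
               tolerance = 0.01)
  expect_equal(molecular_weight(ref$smiles[ref$id == "5280343"]), 302.24,
               tolerance = 0.05)  # quercetin
})

test_that("drug-likeness and element filters reject as configured", {
  ref <- reference_set()
  cfg <- screening_config()
  # rutin: MW 610 < 650 passes mw; make a tighter config to reject it
  tight <- screening_config(mw_max = 400)
  rutin <- ref[ref$id == "5280805", ]
  out <- druglike_filter(rutin, tight)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "rejections")[["mw"]], 1L)

  impossible <- screening_config(qed_min = 0.999)
  out2 <- druglike_filter(ref[1:2, ], impossible)
  expect_equal(nrow(out2), 0L)
  expect_equal(attr(out2, "rejections")[["qed"]], 2L)

  expect_equal(nrow(druglike_filter(ref[0, ], cfg)), 0L)

  chl <- compound_set(id = c("clb", "q"),
                      smiles = c(SMI$chlorobenzene, SMI$quercetin))
  expect_identical(element_filter(chl, c("C", "H", "O"))$id, "q")
  expect_equal(nrow(element_filter(chl, c("C", "H", "O", "Cl"))), 2L)
})

test_that("rank_candidates converts units and breaks ties by id", {
  ref <- reference_set()
  two <- compound_set(id = c("zz", "aa"),
                      smiles = rep(SMI$quercetin, 2))
  rk <- rank_candidates(two, seeds = ref)
  expect_identical(rk$id, c("aa", "zz"))  # equal predictions: id order
  expect_equal(rk$ic50_pre_um, 10^(6 - rk$pic50_pre), tolerance = 1e-9)
  # explicit numeric ic50 relation from the funnel contract
  expect_equal(ic50_from_pic50(5.0469, "micromolar"), 8.977, tolerance = 1e-3)
  # empty set
  empty <- rank_candidates(two[0, ], seeds = ref)
  expect_equal(nrow(empty), 0L)
})

test_that("funnel stages are subsets, commute and are deterministic", {
  ref <- reference_set()
  seeds <- ref[c(1, 5, 8), ]
  lib <- synth_library(n_molecules = 20, seeds = seeds, planted_per_seed = 1,
                       seed = 3)
  cfg <- screening_config()
  s1 <- enrich_by_similarity(lib, seeds, cfg)
  s2 <- deduplicate(s1)
  s3 <- druglike_filter(s2, cfg)
  s4 <- element_filter(s3)
  expect_true(all(s1$id %in% lib$id))
  expect_true(all(s2$id %in% s1$id))
  expect_true(all(s3$id %in% s2$id))
  expect_true(all(s4$id %in% s3$id))
  expect_true(nrow(lib) >= nrow(s1) && nrow(s1) >= nrow(s2) &&
              nrow(s2) >= nrow(s3) && nrow(s3) >= nrow(s4))

  # element and drug-likeness filters commute
  ab <- element_filter(druglike_filter(s2, cfg))
  ba <- druglike_filter(element_filter(s2), cfg)
  expect_identical(ab$id, ba$id)

  # re-running the whole funnel is bit-identical
  r1 <- screen_library(lib, seeds, config = cfg)
  r2 <- screen_library(lib, seeds, config = cfg)
  expect_identical(r1, r2)
})

test_that("planted duplicates are fully recalled at threshold 0.8", {
  ref <- reference_set()
  seeds <- ref[c(2, 9, 16, 21, 25), ]
  lib <- synth_library(n_molecules = 25, seeds = seeds, planted_per_seed = 1,
                       seed = 13)
  enr <- enrich_by_similarity(lib, seeds)
  expect_equal(sum(enr$planted), sum(lib$planted))  # 100% recall
  expect_true(all(enr$best_similarity[enr$planted] > 0.8))
})
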