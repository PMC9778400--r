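test_that("read_smiles_table constructs sets and reports parse failures", {
  tf <- write_tiny_table(data.frame(id = c("a", "b"), smiles = c("CCO", "c1ccccc1")))
  set <- read_smiles_table(tf, columns = list(id = "id", smiles = "smiles"))
  expect_s3_class(set, "compound_set")
  expect_equal(nrow(set), 2L)

  # unclosed ring must be reported, not dropped silently
  tf2 <- write_tiny_table(data.frame(id = c("ok", "bad"), smiles = c("CCO", "C1CC")))
  expect_warning(set2 <- read_smiles_table(tf2, columns = list(id = "id", smiles = "smiles")),
                 "unparseable")
  expect_equal(nrow(set2), 1L)
  fails <- attr(set2, "parse_failures")
  expect_equal(fails$id, "bad")
  expect_match(fails$error, "ring")

  # configuration / empty-file errors
  tf3 <- write_tiny_table(data.frame(id = "a", structure = "CCO"))
  expect_error(read_smiles_table(tf3), "smiles column")
  tf4 <- tempfile(); writeLines("id,smiles", tf4)
  expect_error(read_smiles_table(tf4), "empty")
})

test_that("round trip write -> read preserves canonical smiles and pic50", {
  set <- compound_set(id = c("q", "e"), smiles = c(SMI$quercetin, SMI$ethanol),
                      pic50 = c(3.939, NA))
  tf <- tempfile(fileext = ".csv")
  write_smiles_table(set, tf)
  back <- read_smiles_table(tf, columns = list(id = "id", smiles = "smiles",
                                               pic50 = "pic50"))
  expect_identical(vapply(back$smiles, canonicalize, ""),
                   vapply(set$smiles, canonicalize, ""))
  expect_identical(back$pic50, set$pic50)
})

test_that("smi and sdf readers work", {
  tf <- tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1 benzene"), tf)
  set <- read_smi(tf)
  expect_equal(set$id, c("ethanol", "benzene"))

  # minimal V2000 ethanol record
  sdf <- tempfile(fileext = ".sdf")
  writeLines(c(
    "ethanol", "", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0",
    "  2  3  1  0",
    "M  END",
    "$$$$"), sdf)
  sset <- read_sdf(sdf)
  expect_equal(sset$id, "ethanol")
  expect_identical(canonicalize(sset$smiles), canonicalize("CCO"))
})

test_that("canonicalize is permutation-invariant and idempotent", {
  expect_identical(canonicalize("OCC"), canonicalize("CCO"))
  expect_identical(canonicalize(SMI$benzene_kek), canonicalize(SMI$benzene_arom))
  cq <- canonicalize(SMI$quercetin)
  expect_identical(canonicalize(cq), cq)
  expect_error(canonicalize("C1CC"), "ring")
})

test_that("reference fixture matches the printed table", {
  ref <- reference_set()
  expect_equal(nrow(ref), 27L)
  expect_equal(ref$pic50[ref$id == "5280343"], 3.939)  # quercetin
  expect_equal(ref$pic50[ref$id == "9064"], 1.789)     # (+)-catechin
  expect_equal(sum(ref$pic50), 95.314, tolerance = 0.001 / 95)
  # CID 5281673 carries both printed and CID-implied names
  i <- ref$id == "5281673"
  expect_equal(ref$name[i], "Myricetin")
  expect_equal(ref$alt_name[i], "Myricitrin")
  # every fixture SMILES parses; element union is C/H/O
  expect_identical(sort(unique(unlist(lapply(ref$smiles, element_set)))),
                   c("C", "H", "O"))
})

test_that("pic50 conversions are exact and monotone", {
  expect_equal(pic50_from_ic50(100, "micromolar"), 4)
  expect_equal(pic50_from_ic50(1, "molar"), 0)
  expect_equal(pic50_from_ic50(8.977, "micromolar"), 5.0469, tolerance = 5e-5)
  # round trip
  x <- c(0.3, 8.977, 120)
  expect_equal(ic50_from_pic50(pic50_from_ic50(x, "micromolar"), "micromolar"),
               x, tolerance = 1e-12)
  # strictly decreasing
  xs <- sort(stats::runif(20, 0.1, 500))
  expect_true(all(diff(pic50_from_ic50(xs, "micromolar")) < 0))
  expect_error(pic50_from_ic50(0), "positive")
  expect_error(pic50_from_ic50(-2), "positive")
})

test_that("element_set includes hydrogen and propagates parse errors", {
  expect_identical(element_set(SMI$quercetin), c("C", "H", "O"))
  expect_identical(element_set("CCN"), c("C", "H", "N"))
  expect_identical(element_set(SMI$chlorobenzene), c("C", "Cl", "H"))
  expect_error(element_set("C1CC"))
})

test_that("compound_set enforces unique ids and pic50 range", {
  expect_error(compound_set(id = c("a", "a"), smiles = c("C", "CC")), "unique")
  expect_error(compound_set(id = "a", smiles = "C", pic50 = 16), "range")
})
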