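test_that("curation applies the organic, size and lipophilicity filters", {
  cur <- curate(c("CCO",                    # 3 heavy atoms: too small
                  "[Na+].[Cl-]",            # no organic fragment
                  "not_a_smiles",           # unparseable
                  "",                       # empty line: skipped
                  "CC(=O)Oc1ccccc1C(=O)O")) # aspirin: accepted
  expect_equal(unname(cur$report["input"]), 5L)
  expect_equal(unname(cur$report["skipped_empty"]), 1L)
  expect_equal(nrow(cur$accepted), 1L)
  expect_setequal(cur$rejected$reason,
                  c("heavy_atoms", "no_organic_fragment", "parse_error"))
  asp <- cur$accepted
  expect_equal(asp$canonical_smiles, "CC(=O)Oc1ccccc1C(=O)O")
  # toolkit oracle values, and the strict filter bounds
  expect_equal(asp$MolWt, 180.159, tolerance = 1e-4)
  expect_equal(asp$MolLogP, 1.3101, tolerance = 1e-4)
  expect_gt(asp$MolWt, 12); expect_lt(asp$MolWt, 600)
  expect_gt(asp$MolLogP, -7); expect_lt(asp$MolLogP, 5)
})

test_that("salts are stripped to the largest organic fragment", {
  cur <- curate(c("CCCO.[Na+].[Cl-]",      # counterions dropped
                  "CC(=O)[O-].[Na+]"))     # charged organic fragment kept
  expect_equal(nrow(cur$accepted), 2L)
  expect_equal(cur$accepted$canonical_smiles, c("CCCO", "CC(=O)[O-]"))
})

test_that("stereochemistry is removed and duplicates collapse to first seen", {
  cur <- curate(c("C[C@H](N)C(=O)O", "CC(N)C(=O)O", "CCCO", "OCCC"))
  # the stereo and flat alanine collapse; the two propanol spellings collapse
  expect_equal(nrow(cur$accepted), 2L)
  expect_equal(cur$accepted$raw_smiles, c("C[C@H](N)C(=O)O", "CCCO"))
  expect_false(any(grepl("@", cur$accepted$canonical_smiles)))
  expect_true(all(cur$rejected$reason == "duplicate"))
})

test_that("curation is idempotent and every record is accounted for", {
  raw <- c("CCCO", "CCO", "CCCCCCN", "c1ccccc1O", "bogus", "CC(C)(C)C")
  cur <- curate(raw)
  expect_equal(unname(cur$report["accepted"] + cur$report["rejected"] +
                        cur$report["skipped_empty"]),
               unname(cur$report["input"]))
  again <- curate(cur$accepted$canonical_smiles)
  expect_equal(again$accepted$canonical_smiles,
               cur$accepted$canonical_smiles)
  expect_equal(nrow(again$rejected), 0L)
  # canonicalization stability
  expect_equal(canonicalize_smiles(cur$accepted$canonical_smiles),
               cur$accepted$canonical_smiles)
})

test_that("property vectors have the 13 documented components", {
  props <- compute_properties(c("c1ccccc1", "CCCC"))
  expect_equal(colnames(props), property_names())
  expect_equal(ncol(props), 13L)
  expect_true(all(is.finite(as.matrix(props))))
  expect_equal(props$TPSA[1], 0)          # benzene has no polar atoms
  expect_equal(props$HeavyAtomCount[2], 4)
  counts <- c("HeavyAtomCount", "NumValenceElectrons", "NumHAcceptors",
              "NumHDonors")
  expect_true(all(as.matrix(props[, counts]) >= 0))
  expect_true(all(as.matrix(props[, counts]) ==
                    round(as.matrix(props[, counts]))))
  expect_identical(compute_properties("c1ccccc1"),
                   compute_properties("c1ccccc1"))
})

test_that("the property scaler standardizes and inverts", {
  set.seed(99)
  X <- matrix(rnorm(10000 * 3, mean = c(10, -2, 100), sd = c(5, 1, 30)),
              10000, 3, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  sc <- fit_scaler(X)
  Z <- scaler_transform(sc, X)
  expect_equal(unname(colMeans(Z)), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1, 1), tolerance = 1e-10)
  expect_equal(scaler_inverse(sc, Z), X, tolerance = 1e-9,
               ignore_attr = TRUE)
  X[, 2] <- 7
  expect_error(fit_scaler(X), "b")
})
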