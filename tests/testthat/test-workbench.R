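test_that(".smi files round-trip with ids and survive stray whitespace", {
  path <- withr::local_tempfile(fileext = ".smi")
  write_smi(c("CCO", "c1ccccc1"), path, id = c("mol1", "mol2"))
  df <- read_smi(path)
  expect_equal(df$smiles, c("CCO", "c1ccccc1"))
  expect_equal(df$id, c("mol1", "mol2"))
  writeLines(c("CCO  mol1  ", "", "  c1ccccc1", "CCN\t"), path)
  df2 <- read_smi(path)
  expect_equal(df2$smiles, c("CCO", "c1ccccc1", "CCN"))
  expect_equal(df2$id[1], "mol1")
  expect_true(is.na(df2$id[2]))
})

test_that("latent CSVs round-trip at double precision", {
  z <- matrix(rnorm(20 * 8), 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_latent_csv(z, path, id = paste0("m", 1:20))
  z2 <- read_latent_csv(path)
  expect_lt(max(abs(z - z2)), 1e-12)
  expect_equal(rownames(z2), paste0("m", 1:20))
})

test_that("seed derivation is deterministic, bounded and component-specific", {
  expect_identical(derive_seed(1L, "screen"), derive_seed(1L, "screen"))
  expect_false(derive_seed(1L, "screen") == derive_seed(1L, "train"))
  expect_false(derive_seed(1L, "screen") == derive_seed(2L, "screen"))
  s <- vapply(1:50, derive_seed, 1L, component = "x")
  expect_true(all(s >= 1 & s <= 2^31 - 1))
})

test_that("the CLI dispatches, reports usage and fails cleanly", {
  expect_output(code <- cli_main("--help"), "Commands:")
  expect_equal(code, 0L)
  expect_message(code2 <- cli_main("definitely-not-a-command"), "unknown")
  expect_equal(code2, 2L)
  # domain error: missing checkpoint
  expect_message(
    code3 <- cli_main(c("encode", "--checkpoint", "/nonexistent.rds",
                        "--in", "x.smi", "--out", "y.csv")),
    "checkpoint")
  expect_equal(code3, 1L)
})

test_that("the fixtures and screen subcommands produce working files", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "lib")
  code <- cli_main(c("fixtures", "--kind", "screening", "--n", "300",
                     "--seed", "4", "--out", prefix))
  expect_equal(code, 0L)
  lat <- paste0(prefix, "_latents.csv")
  lab <- paste0(prefix, "_labels.csv")
  expect_true(file.exists(lat) && file.exists(lab))
  out <- file.path(dir, "screen.csv")
  code2 <- cli_main(c("screen", "--latents", lat, "--labels", lab,
                      "--queries", "2", "--iterations", "5",
                      "--seed", "1", "--out", out))
  expect_equal(code2, 0L)
  expect_equal(nrow(read.csv(out)), 5L)
})

test_that("the corpus fixture subcommand writes n molecules", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "corpus")
  code <- cli_main(c("fixtures", "--kind", "corpus", "--n", "25",
                     "--seed", "2", "--out", prefix))
  expect_equal(code, 0L)
  expect_equal(nrow(read_smi(paste0(prefix, ".smi"))), 25L)
})

test_that("curate accepts CSV input with a named SMILES column", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "mols.csv")
  write.csv(data.frame(id = 1:3, smiles = c("CCCO", "CCO", "bad_smiles")),
            csv, row.names = FALSE)
  code <- cli_main(c("curate", "--in", csv, "--out-prefix",
                     file.path(dir, "out")))
  expect_equal(code, 0L)
  curated <- read_smi(file.path(dir, "out_curated.smi"))
  expect_equal(curated$smiles, "CCCO")
  rejected <- read.csv(file.path(dir, "out_rejected.csv"))
  expect_setequal(rejected$reason, c("heavy_atoms", "parse_error"))
})
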