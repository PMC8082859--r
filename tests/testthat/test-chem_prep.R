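test_that("standardisation strips salts, neutralises, and rejects with reasons", {
  r <- standardise_molecule("CC(=O)[O-].[Na+]")
  expect_equal(r$status, "ok")
  # the neutral acetic-acid parent survives, the counter-ion is gone
  expect_equal(r$inchi, standardise_molecule("CC(=O)O")$inchi)
  expect_equal(standardise_molecule("[Na+].[Cl-]")$status, "non_organic")
  expect_equal(standardise_molecule("CCC")$status, "too_small")
  expect_equal(standardise_molecule("not_a_smiles")$status, "unparseable")
  # quaternary ammonium keeps its charge (no H to remove)
  expect_match(standardise_molecule("C[N+](C)(C)C.[Cl-]")$inchi, "/q\\+1")
  # charge-separated nitro group is preserved, molecule stays neutral overall
  expect_false(grepl("/q", standardise_molecule("O=[N+]([O-])c1ccccc1")$inchi))
  # largest organic fragment wins over a bigger inorganic one
  r2 <- standardise_molecule("CCCCO.[Na+].[Na+].[Na+].[Na+].[Na+].[Na+]")
  expect_equal(r2$inchi, standardise_molecule("CCCCO")$inchi)
})

test_that("deduplication removes conflicts entirely and merges agreeing copies", {
  rec <- data.frame(source_id = paste0("r", 1:3),
                    inchi = c("A", "A", "B"), label = c(0L, 1L, 0L))
  out <- deduplicate(rec)
  expect_equal(out$inchi, "B")
  expect_equal(unname(attr(out, "removed")), c(2L, 0L))

  rec2 <- data.frame(source_id = c("x", "y"), inchi = c("A", "A"), label = c(1L, 1L))
  out2 <- deduplicate(rec2)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$source_id, "x")  # first-seen provenance kept

  rec3 <- data.frame(source_id = paste0("r", 1:5),
                     inchi = c("A", "A", "B", "C", "D"),
                     label = c(0L, 1L, 1L, 0L, 1L))
  expect_equal(nrow(deduplicate(rec3)), 3L)
})

test_that("the preprocessing pipeline accounts for every removal", {
  fx <- molecule_fixtures()
  pp <- preprocess_dataset(fx)
  expect_equal(nrow(fx), nrow(pp$records) + sum(pp$report))
  expect_false(anyDuplicated(pp$records$inchi) > 0)
  # the aspirin pair conflicts; salts/charged variants merged post-standardisation
  expect_equal(unname(pp$report["conflict_pre"] + pp$report["conflict_post"]), 2L)
  expect_gte(unname(pp$report["duplicate_post"]), 2L)
  expect_equal(unname(pp$report["non_organic"]), 1L)
  expect_equal(unname(pp$report["too_small"]), 3L)
  expect_gte(unname(pp$report["unparseable"]), 1L)
  expect_true(all(vapply(pp$records$inchi, nzchar, logical(1))))
})

test_that("preprocessing is idempotent and tolerates empty input", {
  fx <- molecule_fixtures()[1:12, ]
  pp <- preprocess_dataset(fx)
  pp2 <- preprocess_dataset(pp$records)
  expect_equal(pp2$records$inchi, pp$records$inchi)
  expect_equal(sum(pp2$report), 0L)
  ep <- preprocess_dataset(fx[0, ])
  expect_equal(nrow(ep$records), 0L)
  expect_equal(sum(ep$report), 0L)
})

test_that("parents collapsing to one InChI after standardisation are caught", {
  # distinct raw structures (acid vs sodium salt) with conflicting labels:
  # identical only after salt strip + neutralisation, so the conflict is
  # invisible pre-standardisation and must be caught post-standardisation
  raw <- data.frame(source_id = c("p1", "p2", "p3"),
                    smiles = c("CC(C)C(=O)O", "CC(C)C(=O)[O-].[Na+]", "CCCCC"),
                    label = c(0L, 1L, 0L))
  pp <- preprocess_dataset(raw)
  expect_equal(pp$records$source_id, "p3")
  expect_equal(unname(pp$report["conflict_post"]), 2L)
})

test_that("missing labels are set aside before structural processing", {
  raw <- data.frame(source_id = c("a", "b"), smiles = c("CCCC", "CCCCC"),
                    label = c(NA_integer_, 1L))
  pp <- preprocess_dataset(raw)
  expect_equal(pp$records$source_id, "b")
  expect_equal(unname(pp$report["missing_label"]), 1L)
})

test_that("CSV and SDF readers deliver 0/1/NA labels; writers round-trip", {
  csv <- file.path(tempdir(), "raw.csv")
  writeLines(c("smiles,ep1,ep2", "CCCC,0,X", "c1ccccc1,1,0"), csv)
  df <- read_smiles_csv(csv)
  expect_equal(df$ep1, c(0L, 1L))
  expect_true(is.na(df$ep2[1]))

  sdf_file <- file.path(tempdir(), "raw.sdf")
  sdfs <- suppressWarnings(ChemmineR::smiles2sdf(c("CCCC", "c1ccccc1")))
  txt <- unlist(lapply(1:2, function(i) {
    s <- sdfs[[i]]
    c(ChemmineR::sdf2str(s)[-length(ChemmineR::sdf2str(s))],
      "> <ep1>", c("1", "X")[i], "", "$$$$")
  }))
  writeLines(txt, sdf_file)
  sd <- read_sdf_dataset(sdf_file)
  expect_equal(nrow(sd), 2L)
  expect_equal(sd$ep1, c(1L, NA_integer_))
  expect_true(all(nzchar(sd$smiles)))

  pp <- preprocess_dataset(data.frame(source_id = "a", smiles = "CCCC", label = 1L))
  rp <- file.path(tempdir(), "rec.csv"); qp <- file.path(tempdir(), "rep.csv")
  write_clean_dataset(pp, rp, qp, batch = "train")
  rec <- utils::read.csv(rp)
  expect_equal(rec$batch, "train")
  expect_equal(rec$inchi, pp$records$inchi)
  rep_df <- utils::read.csv(qp)
  expect_equal(sum(rep_df$removed), 0L)
  unlink(c(csv, sdf_file, rp, qp))
})
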