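test_that("snapshots round-trip through write and read byte-identically", {
  bundle <- reference_examples()
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_snapshot(bundle$snapshot, f1)
  back <- read_snapshot(f1)
  expect_equal(
    as.data.frame(back), as.data.frame(bundle$snapshot),
    ignore_attr = TRUE
  )
  write_snapshot(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})

test_that("missing mandatory columns raise a schema error naming the column", {
  f <- withr::local_tempfile(fileext = ".tsv")
  broken <- reference_examples()$snapshot
  broken$copies <- NULL
  readr::write_tsv(broken, f)
  expect_error(read_snapshot(f), "copies")
  expect_error(as_snapshot(broken), "copies")
})

test_that("validation reports every seeded invariant violation", {
  good <- haemoglobin_components()
  defects <- dplyr::bind_rows(
    comp_row("TOOLONG11", 1, 1),                             # bad entry id
    comp_row("1bad", 0, 1),                                  # assembly_id < 1
    comp_row("2bad", 1, 1, copies = 0),                      # copies < 1
    comp_row("3bad", 1, 1, type = "DNA", uniprot = "P12345"), # uniprot on DNA
    comp_row("4bad", 1, 1, type = "DNA", antibody = TRUE),   # antibody on DNA
    comp_row("5bad", 1, 1, type = "RNA", rfam = "RFX"),      # malformed rfam
    comp_row("6bad", 1, 1, type = "protein", rfam = "RF00005") # rfam on protein
  )
  report <- validate_snapshot(as_snapshot(dplyr::bind_rows(good, defects)))
  expect_s3_class(report, "validation_report")
  expect_equal(nrow(report$errors), 7)

  clean <- validate_snapshot(as_snapshot(good))
  expect_equal(nrow(clean$errors), 0)
})

test_that("duplicate (entry, assembly, entity) records are flagged on both rows", {
  dup <- dplyr::bind_rows(
    comp_row("1abc", 1, 1, uniprot = "P11111"),
    comp_row("1abc", 1, 1, uniprot = "P22222")
  )
  report <- validate_snapshot(as_snapshot(dup))
  expect_equal(sum(grepl("duplicate", report$errors$rule)), 2)
})

test_that("rejected snapshots fail loudly at read time", {
  f <- withr::local_tempfile(fileext = ".tsv")
  bad <- as_snapshot(comp_row("1abc", 1, 1, type = "DNA", uniprot = "P12345"))
  write_snapshot(bad, f)
  expect_error(read_snapshot(f), "validation failed")
  expect_silent(read_snapshot(f, validate = FALSE))
})

test_that("portal catalogues parse participants with stoichiometry", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "complex_ac\trecommended_name\tparticipants",
    "CPX-3225\tCLOCK-Bmal1 transcription complex\tQ9WTL8(1)|O08785(1)"
  ), f)
  cat <- read_portal_catalog(f)
  expect_equal(nrow(cat), 1)
  expect_equal(cat$complex_ac, "CPX-3225")
  expect_equal(
    cat$participants[[1]],
    c(O08785 = 1L, Q9WTL8 = 1L)
  )
})

test_that("portal parsing rejects zero stoichiometry and malformed tokens", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "complex_ac\trecommended_name\tparticipants",
    "CPX-1\tbroken\tP11111(0)"
  ), f)
  expect_error(read_portal_catalog(f), "stoichiometry")
  writeLines(c(
    "complex_ac\trecommended_name\tparticipants",
    "CPX-1\tbroken\tP11111"
  ), f)
  expect_error(read_portal_catalog(f), "line 2")
})

test_that("the public complextab dialect is accepted and small molecules dropped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("#Complex ac", "Recommended name", "Taxonomy identifier",
      "Identifiers (and stoichiometry) of molecules in complex",
      sep = "\t"
    ),
    paste("CPX-42", "synthetic machine", "9606",
      "P11111(2)|CHEBI:15422(1)|P22222(1)",
      sep = "\t"
    )
  ), f)
  expect_warning(cat <- read_portal_catalog(f), "non-protein")
  expect_true(cat$partial_definition[[1]])
  expect_equal(cat$participants[[1]], c(P11111 = 2L, P22222 = 1L))
})

test_that("generated catalogues round-trip with participant multisets intact", {
  bundle <- generate_archive(fixture_config(seed = 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_portal_catalog(bundle$portal, f)
  back <- read_portal_catalog(f)
  expect_equal(nrow(back), nrow(bundle$portal))
  expect_equal(back$participants, bundle$portal$participants)
})

test_that("curated-name lists validate keys and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  curated <- stats::setNames(
    c("name A", "name B"),
    c(strrep("a", 32), strrep("b", 32))
  )
  write_curated_names(curated, f)
  expect_equal(read_curated_names(f), curated)
  writeLines(c("md5\tname", "nothex\tx"), f)
  expect_error(read_curated_names(f), "malformed")
})

test_that("go_cc cells parse into id -> name maps", {
  parsed <- parse_go_cc("GO:0000786=nucleosome|GO:0005833=haemoglobin complex")
  expect_equal(
    parsed,
    c("GO:0000786" = "nucleosome", "GO:0005833" = "haemoglobin complex")
  )
  expect_length(parse_go_cc(NA_character_), 0)
})
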