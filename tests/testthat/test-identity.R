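test_that("composition labels follow the grammar for every component type", {
  records <- dplyr::bind_rows(
    comp_row("6kat", 1, 1, "protein", 1, uniprot = "P68871"),
    comp_row("6bok", 1, 1, "RNA", 1, rfam = "RF00177"),
    comp_row("5mv4", 1, 1, "protein", 1, antibody = TRUE),
    comp_row("7rx0", 1, 2, "protein", 1),
    comp_row("1un6", 1, 2, "RNA", 1),
    comp_row("8b1t", 1, 4, "DNA", 1),
    comp_row("8e8j", 1, 3, "DNA/RNA", 1)
  )
  expect_identical(
    component_label(records),
    c(
      "P68871_1", "RF00177_1", "antibody_5mv4_1_1", "protein_7rx0_2_1",
      "RNA_1un6_2_1", "DNA_8b1t_4_1", "DNA/RNA_8e8j_3_1"
    )
  )
})

test_that("a label parser recovers type, mapping and stoichiometry", {
  labels <- c(
    "P68871_2", "RF00177_1", "antibody_5mv4_1_1", "protein_7rx0_2_1",
    "RNA_1un6_2_1", "DNA_8b1t_4_1", "DNA/RNA_8e8j_3_1"
  )
  grammar <- paste0(
    "^(",
    "[A-Z][A-Z0-9]+", "|",
    "RF\\d{5}", "|",
    "(antibody|protein|RNA|DNA|DNA/RNA)_[a-z0-9]{4}_\\d+",
    ")_\\d+$"
  )
  expect_true(all(grepl(grammar, labels)))
  stoich <- as.integer(sub("^.*_(\\d+)$", "\\1", labels))
  expect_equal(stoich, c(2L, 1L, 1L, 1L, 1L, 1L, 1L))
})

test_that("chimeric components cannot be labelled and make assemblies ineligible", {
  chim <- comp_row("1abc", 1, 1, uniprot = "P11111;P22222")
  expect_error(component_label(chim), "chimeric")
  elig <- eligibility(dplyr::bind_rows(haemoglobin_components(), chim))
  expect_false(elig$eligible)
  expect_match(elig$reason, "1abc/1")
  expect_true(eligibility(haemoglobin_components())$eligible)
})

test_that("the haemoglobin key is canonical and md5 matches a file-based oracle", {
  key <- canonical_key(haemoglobin_components())
  expect_identical(key$composition_string, "P68871_2,P69905_2")
  expect_identical(key$labels, c("P68871_2", "P69905_2"))
  expect_identical(key$md5_hex, md5_file_oracle("P68871_2,P69905_2"))

  reversed <- haemoglobin_components()[2:1, ]
  expect_identical(canonical_key(reversed), key)
})

test_that("mapped labels order before unmapped labels in the composition string", {
  comp <- dplyr::bind_rows(
    comp_row("1uty", 1, 2, "DNA", 1),
    comp_row("1uty", 1, 1, "protein", 1, uniprot = "P12345")
  )
  expect_identical(
    canonical_key(comp)$composition_string,
    "P12345_1,DNA_1uty_2_1"
  )
})

test_that("same-accession entities merge with summed stoichiometry", {
  split_entities <- dplyr::bind_rows(
    comp_row("1abc", 1, 1, "protein", 2, uniprot = "P68871"),
    comp_row("1abc", 1, 2, "protein", 1, uniprot = "P68871")
  )
  key <- canonical_key(split_entities)
  expect_identical(key$composition_string, "P68871_3")
  merged <- merge_components(split_entities)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_entities, 2L)
})

test_that("composition keys are permutation-invariant and separate distinct multisets", {
  withr::local_seed(42)
  acc_pool <- sprintf("UPT%05d", 1:40)
  n <- 300
  assemblies <- lapply(seq_len(n), function(i) {
    random_components(sample(1:5, 1), sprintf("t%03x", i), acc_pool)
  })
  signatures <- vapply(assemblies, multiset_signature, character(1))
  keys <- lapply(assemblies, canonical_key)
  strings <- vapply(keys, `[[`, character(1), "composition_string")
  md5s <- vapply(keys, `[[`, character(1), "md5_hex")

  # shuffling component rows never changes the key
  for (i in sample(n, 50)) {
    for (s in 1:3) {
      shuffled <- assemblies[[i]][sample(nrow(assemblies[[i]])), ]
      expect_identical(canonical_key(shuffled)$md5_hex, md5s[[i]])
    }
  }
  # equal keys exactly where the independent multiset signatures are equal
  expect_identical(
    tapply(strings, signatures, function(x) length(unique(x))) |> unname() |> as.integer(),
    rep(1L, length(unique(signatures)))
  )
  expect_equal(length(unique(strings)), length(unique(signatures)))
  expect_equal(length(unique(md5s)), length(unique(strings)))
})

test_that("identifier assignment is idempotent and strictly increasing", {
  reg <- new_registry(next_serial = 100487)
  a1 <- assign_identifier(reg, strrep("a", 32))
  expect_equal(a1$accession, "PDB-CPX-100487")
  a2 <- assign_identifier(a1$registry, strrep("b", 32))
  expect_equal(a2$accession, "PDB-CPX-100488")
  again <- assign_identifier(a2$registry, strrep("a", 32))
  expect_equal(again$accession, "PDB-CPX-100487")
  expect_equal(again$registry$next_serial, a2$registry$next_serial)
})

test_that("registries persist append-only and reject rewrites", {
  f <- withr::local_tempfile(fileext = ".tsv")
  reg <- assign_identifiers(new_registry(), c(strrep("a", 32), strrep("b", 32)))$registry
  save_registry(reg, f)
  back <- load_registry(f)
  expect_equal(back$assignments, reg$assignments)
  expect_equal(back$next_serial, reg$next_serial)

  # dropping an existing assignment must refuse to save
  mutant <- new_registry()
  mutant <- assign_identifier(mutant, strrep("c", 32))$registry
  expect_error(save_registry(mutant, f), "integrity")

  # corrupt file (duplicate md5) refuses to load
  writeLines(c(
    "md5\taccession",
    paste0(strrep("a", 32), "\tPDB-CPX-1"),
    paste0(strrep("a", 32), "\tPDB-CPX-2")
  ), f)
  expect_error(load_registry(f), "integrity")
})

test_that("preferred assembly is the smallest complete one", {
  # entry with complete hexamer and complete dodecamer forms
  protease <- dplyr::bind_rows(
    comp_row("1e94", 1, 1, "protein", 6, uniprot = "UPT90001"),
    comp_row("1e94", 2, 1, "protein", 12, uniprot = "UPT90001")
  )
  expect_equal(select_preferred_assembly(protease), 1L)

  # four assemblies, two complete with total sizes 6 and 8
  entry <- dplyr::bind_rows(
    comp_row("4asm", 1, 1, copies = 4, uniprot = "UPT1"),           # incomplete
    comp_row("4asm", 2, 1, copies = 4, uniprot = "UPT1"),
    comp_row("4asm", 2, 2, copies = 4, uniprot = "UPT2"),           # complete, 8
    comp_row("4asm", 3, 1, copies = 2, uniprot = "UPT1"),
    comp_row("4asm", 3, 2, copies = 4, uniprot = "UPT2"),           # complete, 6
    comp_row("4asm", 4, 2, copies = 1, uniprot = "UPT2")            # incomplete
  )
  expect_equal(select_preferred_assembly(entry), 3L)

  # no complete assembly: best coverage wins, ties to smallest
  partial <- dplyr::bind_rows(
    comp_row("5prt", 1, 1, copies = 2, uniprot = "UPT1"),
    comp_row("5prt", 2, 2, copies = 1, uniprot = "UPT2"),
    comp_row("5prt", 2, 3, copies = 1, uniprot = "UPT3")
  )
  expect_equal(select_preferred_assembly(partial), 2L)
  expect_error(select_preferred_assembly(partial[0, ]), "at least one")
})

test_that("preferred selection minimises chain count among complete assemblies", {
  bundle <- reference_examples()
  pref <- select_preferred(bundle$snapshot)
  chosen <- pref$assembly_id[pref$entry_id == "1e94"]
  expect_equal(chosen, 1L)
  entry <- bundle$snapshot[bundle$snapshot$entry_id == "1e94", ]
  complete_sizes <- tapply(entry$copies, entry$assembly_id, sum)
  expect_true(all(complete_sizes[as.character(chosen)] <= complete_sizes))
})

test_that("grouping deduplicates members and classifies compositions", {
  bundle <- reference_examples()
  gu <- group_unique(bundle$snapshot, new_registry())
  u <- gu$uniques
  hb <- u[u$composition_string == "P68871_2,P69905_2", ]
  expect_equal(hb$n_members, 2L)
  expect_setequal(hb$members[[1]]$entry_id, c("6kat", "7jy3"))

  # composition classes match an independent re-scan of the components
  for (i in seq_len(nrow(u))) {
    comp <- u$components[[i]]
    expect_equal(u$protein_only[[i]], all(comp$polymer_type == "protein"))
    expect_equal(u$nucleic_only[[i]], all(comp$polymer_type != "protein"))
    expect_equal(
      u$quaternary[[i]],
      if (nrow(comp) > 1) {
        "heteromeric"
      } else if (comp$copies[[1]] > 1) "homomeric" else "monomeric"
    )
  }

  # chimeric assemblies never form groups
  chim <- as_snapshot(comp_row("9chi", 1, 1, uniprot = "P1;P2"))
  expect_equal(nrow(group_unique(chim, new_registry())$uniques), 0)
})

test_that("accession assignment is independent of snapshot row order", {
  bundle <- generate_archive(fixture_config(seed = 11))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  shuffled <- as_snapshot(bundle$snapshot[sample(nrow(bundle$snapshot)), ])
  save_registry(group_unique(bundle$snapshot, new_registry())$registry, f1)
  save_registry(group_unique(shuffled, new_registry())$registry, f2)
  expect_identical(
    readBin(f1, "raw", file.size(f1)),
    readBin(f2, "raw", file.size(f2))
  )
})

test_that("stoichiometry variability counts distinct homomer stoichiometries", {
  bundle <- reference_examples()
  u <- group_unique(bundle$snapshot, new_registry())$uniques
  sv <- stoichiometry_variability(u)
  kat <- sv[sv$accession_mapped == "Q8N5Z0", ]
  expect_equal(kat$n_stoichiometries, 2L)
  expect_equal(kat$stoichiometries, "2,4")
})
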