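named_reference <- function() {
  bundle <- reference_examples()
  u <- group_unique(bundle$snapshot, new_registry())$uniques
  matches <- match_all_portal(u, bundle$portal)
  named <- name_uniques(u,
    matches = matches, curated = bundle$curated,
    catalog = bundle$portal, term_counts = go_term_counts(bundle$snapshot)
  )
  list(bundle = bundle, named = named)
}

name_of_entry <- function(named, entry) {
  hit <- vapply(named$members, function(m) entry %in% m$entry_id, logical(1))
  named[hit, ]
}

test_that("ribosomes are detected through Rfam rRNA plus ribosomal proteins", {
  bundle <- reference_examples()
  ribo <- bundle$snapshot[bundle$snapshot$entry_id == "6bok", ]
  call <- detect_ribosome(merge_components(ribo))
  expect_true(call$is_ribosome)
  expect_equal(call$route, "rfam")
  expect_setequal(call$subunits, c("SSU", "LSU"))
  expect_true(call$has_trna)
  expect_true(call$has_other_rna)
  expect_equal(call$kingdom_style, "prokaryotic-style")
})

test_that("the fallback route needs unmapped RNA and ribosomal proteins", {
  fallback <- merge_components(dplyr::bind_rows(
    comp_row("9rib", 1, 1, "RNA", 1, entity_name = "unassigned rRNA"),
    comp_row("9rib", 1, 2, "protein", 1,
      entity_name = "50S ribosomal protein L2",
      uniprot = "UPT99901", uniprot_name = "50S ribosomal protein L2"
    )
  ))
  call <- detect_ribosome(fallback)
  expect_true(call$is_ribosome)
  expect_equal(call$route, "fallback")
  expect_equal(call$subunits, "LSU")

  # no RNA at all -> never a ribosome
  no_rna <- merge_components(comp_row("9rib", 1, 2, "protein", 1,
    entity_name = "50S ribosomal protein L2", uniprot = "UPT99901"
  ))
  expect_false(detect_ribosome(no_rna)$is_ribosome)

  # the fallback never fires when any Rfam RNA mapping is present
  mixed <- merge_components(dplyr::bind_rows(
    comp_row("9rib", 1, 1, "RNA", 1, rfam = "RF00162"),
    comp_row("9rib", 1, 2, "RNA", 1, entity_name = "unassigned RNA"),
    comp_row("9rib", 1, 3, "protein", 1,
      entity_name = "50S ribosomal protein L2", uniprot = "UPT99901"
    )
  ))
  expect_false(detect_ribosome(mixed)$is_ribosome)
})

test_that("ribosome names combine subunits, tRNA and other RNA", {
  call <- function(subunits, trna = FALSE, other = FALSE, style = "prokaryotic-style") {
    structure(
      list(
        is_ribosome = TRUE, subunits = subunits, has_trna = trna,
        has_other_rna = other, kingdom_style = style, route = "rfam"
      ),
      class = "ribosome_call"
    )
  }
  expect_equal(
    ribosome_name(call(c("SSU", "LSU"), trna = TRUE, other = TRUE)),
    "70 S ribosome and tRNA and RNA"
  )
  expect_equal(ribosome_name(call(c("SSU", "LSU"))), "70 S ribosome")
  expect_equal(ribosome_name(call("SSU")), "30 S ribosomal subunit")
  expect_equal(ribosome_name(call("LSU")), "50 S ribosomal subunit")
  expect_equal(
    ribosome_name(call(c("SSU", "LSU"), style = "eukaryotic-style")),
    "80 S ribosome"
  )
  expect_equal(
    ribosome_name(call("SSU", style = "eukaryotic-style")),
    "40 S ribosomal subunit"
  )
  expect_error(
    ribosome_name(structure(list(is_ribosome = FALSE), class = "ribosome_call")),
    "non-ribosome"
  )
})

test_that("a shared allow-listed GO term names the complex", {
  pol2 <- merge_components(dplyr::bind_rows(
    comp_row("2c35", 1, 1, uniprot = "UPT90011",
      go = "GO:0005665=DNA-directed RNA Polymerase II"
    ),
    comp_row("2c35", 1, 2, uniprot = "UPT90012",
      go = "GO:0005665=DNA-directed RNA Polymerase II"
    )
  ))
  expect_equal(common_go_name(pol2)$name, "DNA-directed RNA Polymerase II")

  # one component with no GO terms blocks GO naming
  partial <- merge_components(dplyr::bind_rows(
    comp_row("2c35", 1, 1, uniprot = "UPT90011", go = "GO:0005665=x"),
    comp_row("2c35", 1, 2, uniprot = "UPT90012")
  ))
  expect_null(common_go_name(partial))

  # terms outside the allow-list (e.g. locations) never name
  cyto <- merge_components(dplyr::bind_rows(
    comp_row("2c35", 1, 1, uniprot = "UPT90011", go = "GO:0005737=cytoplasm"),
    comp_row("2c35", 1, 2, uniprot = "UPT90012", go = "GO:0005737=cytoplasm")
  ))
  expect_null(common_go_name(cyto))
})

test_that("the most specific shared GO term wins by archive-wide counts", {
  shared <- "GO:0000502=proteasome complex|GO:0005839=proteasome core complex"
  comp <- merge_components(dplyr::bind_rows(
    comp_row("1pro", 1, 1, uniprot = "UPT1", go = shared),
    comp_row("1pro", 1, 2, uniprot = "UPT2", go = shared)
  ))
  counts <- c("GO:0000502" = 50L, "GO:0005839" = 4L)
  expect_equal(
    common_go_name(comp, term_counts = counts)$go_id,
    "GO:0005839"
  )
  counts_flipped <- c("GO:0000502" = 2L, "GO:0005839" = 40L)
  expect_equal(
    common_go_name(comp, term_counts = counts_flipped)$go_id,
    "GO:0000502"
  )
})

test_that("printed reference names are reproduced verbatim", {
  rr <- named_reference()
  expected <- c(
    "4f3l" = "CLOCK-Bmal1 transcription complex",
    "2c35" = "DNA-directed RNA Polymerase II",
    "5hi4" = "Interleukin-17A, IG-heavy chain, IG-light lambda chain, peptide complex",
    "12e8" = "IG-heavy chain and IG-light kappa chain",
    "6bok" = "70 S ribosome and tRNA and RNA",
    "5j7l" = "70 S ribosome",
    "6v3e" = "30 S ribosomal subunit",
    "1h27" = "Cyclin A2-CK2 complex and Cyclin-dependent kinase inhibitor 1B",
    "1ivi" = "dihydrolipoamide dehydrogenase"
  )
  for (entry in names(expected)) {
    expect_identical(
      name_of_entry(rr$named, entry)$name, unname(expected[[entry]]),
      label = paste0("name for ", entry)
    )
  }
})

test_that("naming categories follow the decision-tree precedence", {
  rr <- named_reference()
  expect_equal(name_of_entry(rr$named, "1cur")$category, "curated")
  expect_equal(name_of_entry(rr$named, "4f3l")$category, "complex_portal")
  expect_equal(name_of_entry(rr$named, "6bok")$category, "ribosome")
  expect_equal(name_of_entry(rr$named, "2c35")$category, "go")
  expect_equal(name_of_entry(rr$named, "1e94")$category, "uniprot")
  expect_equal(name_of_entry(rr$named, "12e8")$category, "antibody")
  expect_equal(name_of_entry(rr$named, "2gis")$category, "rfam")
  expect_equal(name_of_entry(rr$named, "8b1t")$category, "nucleic_generic")
  expect_equal(name_of_entry(rr$named, "7pch")$category, "unnamed")
  expect_true(is.na(name_of_entry(rr$named, "7pch")$name))
})

test_that("a curated name overrides every automated rule", {
  rr <- named_reference()
  # give the CLOCK-BMAL1 composition a curated override: it must win
  clock_md5 <- name_of_entry(rr$named, "4f3l")$md5
  curated <- stats::setNames("Curator knows best", clock_md5)
  u <- group_unique(rr$bundle$snapshot, new_registry())$uniques
  matches <- match_all_portal(u, rr$bundle$portal)
  renamed <- name_uniques(u,
    matches = matches, curated = curated,
    catalog = rr$bundle$portal
  )
  row <- renamed[renamed$md5 == clock_md5, ]
  expect_equal(row$name, "Curator knows best")
  expect_equal(row$category, "curated")
})

test_that("homomers take the UniProt recommended name at any stoichiometry", {
  for (copies in c(1L, 2L, 24L)) {
    comp <- comp_row("1bcf", 1, 1, "protein", copies,
      uniprot = "P0ABD3", uniprot_name = "Bacterioferritin"
    )
    snap <- as_snapshot(comp)
    u <- group_unique(snap, new_registry())$uniques
    res <- name_assembly(as.list(u[1, ]))
    expect_equal(res$name, "Bacterioferritin")
    expect_equal(res$category, "uniprot")
  }
})

test_that("single-accession assemblies with non-generic extras stay unnamed", {
  snap <- as_snapshot(dplyr::bind_rows(
    comp_row("1xyz", 1, 1, uniprot = "UPT1", uniprot_name = "Known protein"),
    comp_row("1xyz", 1, 2, seq_length = 300)  # unmapped full-length protein
  ))
  u <- group_unique(snap, new_registry())$uniques
  res <- name_assembly(as.list(u[1, ]))
  expect_equal(res$category, "unnamed")
})

test_that("multi-component unmapped nucleic assemblies get generic names", {
  snap <- as_snapshot(dplyr::bind_rows(
    comp_row("1dnr", 1, 1, "DNA", 1),
    comp_row("1dnr", 1, 2, "RNA", 1)
  ))
  u <- group_unique(snap, new_registry())$uniques
  res <- name_assembly(as.list(u[1, ]))
  expect_equal(res$name, "DNA/RNA hybrid")
  expect_equal(res$category, "nucleic_generic")
})

test_that("categories are sound with respect to their evidence", {
  rr <- named_reference()
  for (i in seq_len(nrow(rr$named))) {
    row <- rr$named[i, ]
    ev <- row$evidence[[1]]
    if (row$category == "complex_portal") {
      expect_true(all(grepl("^complex_portal:CPX-", ev)))
    }
    if (row$category == "go") {
      expect_true(all(grepl("^go:GO:\\d{7}$", ev)))
    }
    if (row$category == "uniprot") {
      comp <- row$components[[1]]
      expect_equal(length(unique(comp$uniprot[comp$mapped])), 1)
    }
    expect_equal(row$category == "unnamed", is.na(row$name))
  }
})

test_that("naming statistics count categories and entries", {
  rr <- named_reference()
  stats <- naming_statistics(rr$named)
  expect_equal(sum(stats$by_category$n_unique), nrow(rr$named))
  expect_equal(stats$n_named, sum(rr$named$category != "unnamed"))
  expect_equal(
    stats$named_fraction, stats$n_named / nrow(rr$named)
  )
  # entry counts: the kinase dimer group spans 15 entries
  uniprot_entries <- stats$by_category$n_entries[
    stats$by_category$category == "uniprot"
  ]
  expect_gte(uniprot_entries, 15)
})
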