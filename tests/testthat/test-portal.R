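ref_uniques <- function() {
  bundle <- reference_examples()
  list(
    bundle = bundle,
    uniques = group_unique(bundle$snapshot, new_registry())$uniques
  )
}

test_that("the CLOCK-BMAL1 heterodimer matches its portal entry exactly", {
  rr <- ref_uniques()
  clock <- rr$uniques[rr$uniques$composition_string == "O08785_1,Q9WTL8_1", ]
  m <- match_exact(clock$components[[1]], rr$bundle$portal)
  expect_s3_class(m, "portal_match")
  expect_equal(m$kind, "exact")
  expect_equal(m$complex_acs, "CPX-3225")
  expect_equal(nrow(m$extra_components), 0)
})

test_that("exact matching demands identical multisets and no other components", {
  rr <- ref_uniques()
  clock <- rr$uniques[rr$uniques$composition_string == "O08785_1,Q9WTL8_1", ]
  empty_cat <- rr$bundle$portal[0, ]
  expect_null(match_exact(clock$components[[1]], empty_cat))
  # assembly missing one participant of the only catalogue complex
  half <- clock$components[[1]][1, ]
  expect_null(match_exact(half, rr$bundle$portal))
  expect_null(match_extended(half, rr$bundle$portal))
})

test_that("planted exact matches are found, and only those", {
  bundle <- generate_archive(fixture_config(seed = 21, portal_exact = 5))
  u <- group_unique(bundle$snapshot, new_registry())$uniques
  matches <- match_all_portal(u, bundle$portal)
  exact_md5 <- names(matches)[vapply(
    matches, function(m) !is.null(m) && m$kind == "exact", logical(1)
  )]
  first_entry <- vapply(u$members, function(m) m$entry_id[[1]], character(1))
  truth <- bundle$truth[match(first_entry, bundle$truth$entry_id), ]
  expect_setequal(
    exact_md5,
    u$md5[truth$archetype == "portal_exact"]
  )
})

test_that("extended matches categorise the extra components", {
  rr <- ref_uniques()
  cyclin <- rr$uniques[grepl("UPT90041", rr$uniques$composition_string), ]
  m <- match_portal(cyclin$components[[1]], rr$bundle$portal)
  expect_equal(m$kind, "exact_plus_extras")
  expect_equal(m$complex_acs, "CPX-2006")
  expect_equal(m$extra_components$category, "protein")
  expect_equal(
    m$extra_components$display_name,
    "Cyclin-dependent kinase inhibitor 1B"
  )
})

test_that("a nucleosome-DDB composition maps to two disjoint portal entries", {
  rr <- ref_uniques()
  nuc <- rr$uniques[grepl("UPT90051", rr$uniques$composition_string), ]
  m <- match_portal(nuc$components[[1]], rr$bundle$portal)
  expect_equal(m$kind, "multi_portal")
  # largest participant coverage first
  expect_equal(m$complex_acs, c("CPX-2556", "CPX-308"))
  expect_equal(m$extra_components$category, "DNA")
  # disjoint coverage: no participant shared between the two complexes
  p <- rr$bundle$portal
  expect_length(
    intersect(
      names(p$participants[[which(p$complex_ac == "CPX-2556")]]),
      names(p$participants[[which(p$complex_ac == "CPX-308")]])
    ),
    0
  )
})

test_that("extended matching never fires when an exact match exists", {
  bundle <- generate_archive(fixture_config(seed = 13))
  u <- group_unique(bundle$snapshot, new_registry())$uniques
  for (i in seq_len(nrow(u))) {
    exact <- match_exact(u$components[[i]], bundle$portal)
    m <- match_portal(u$components[[i]], bundle$portal)
    if (!is.null(exact)) {
      expect_equal(m$kind, "exact")
    }
    if (!is.null(m) && m$kind == "exact") {
      # symmetry of exact matches: participants == mapped components
      hit <- which(bundle$portal$complex_ac == m$complex_acs)
      comp <- u$components[[i]]
      mapped <- stats::setNames(
        comp$copies[comp$mapped], comp$uniprot[comp$mapped]
      )
      expect_mapequal(
        as.list(mapped),
        as.list(bundle$portal$participants[[hit]])
      )
    }
  }
})

test_that("extras partition the leftover components without loss", {
  rr <- ref_uniques()
  matched <- Filter(
    Negate(is.null),
    match_all_portal(rr$uniques, rr$bundle$portal)
  )
  for (md5 in names(matched)) {
    m <- matched[[md5]]
    comp <- rr$uniques$components[[which(rr$uniques$md5 == md5)]]
    covered <- unlist(lapply(m$complex_acs, function(ac) {
      names(rr$bundle$portal$participants[[
        which(rr$bundle$portal$complex_ac == ac)
      ]])
    }))
    leftover <- comp$label[!(comp$mapped & comp$polymer_type == "protein" &
      comp$uniprot %in% covered)]
    expect_setequal(m$extra_components$label, leftover)
    expect_false(anyDuplicated(m$extra_components$label) > 0)
  }
})

test_that("peptide categorisation follows the configured length threshold", {
  short <- comp_row("1pep", 1, 1, "protein", 1, seq_length = 12)
  long <- comp_row("1pep", 1, 2, "protein", 1, seq_length = 80)
  unknown <- comp_row("1pep", 1, 3, "protein", 1)
  merged <- merge_components(dplyr::bind_rows(short, long, unknown))
  cats <- categorize_component(merged[order(merged$entity_id), ])
  expect_equal(cats, c("peptide", "unmapped", "unmapped"))
})

test_that("mapping export is sorted, stable and re-export is byte-identical", {
  rr <- ref_uniques()
  matches <- match_all_portal(rr$uniques, rr$bundle$portal)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  mapping <- export_mapping(rr$uniques, matches, f1)
  expect_equal(mapping$accession, sort(mapping$accession))
  expect_equal(nrow(mapping), sum(!vapply(matches, is.null, logical(1))))
  expect_setequal(mapping$kind, c("exact", "exact_plus_extras", "multi_portal"))
  export_mapping(rr$uniques, matches, f2)
  expect_identical(
    readBin(f1, "raw", file.size(f1)),
    readBin(f2, "raw", file.size(f2))
  )
})
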