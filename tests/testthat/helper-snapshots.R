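# Shared builders for in-code fixtures.

comp_row <- function(entry = "1abc", assembly = 1L, entity = 1L,
                     type = "protein", copies = 1L, uniprot = NA,
                     rfam = NA, antibody = FALSE, entity_name = "subunit",
                     uniprot_name = NA, go = NA, tax = NA, symmetry = NA,
                     seq_length = NA) {
  tibble::tibble(
    entry_id = entry, assembly_id = as.integer(assembly),
    entity_id = as.integer(entity), polymer_type = type,
    uniprot = as.character(uniprot), rfam = as.character(rfam),
    is_antibody = antibody, entity_name = as.character(entity_name),
    uniprot_name = as.character(uniprot_name), go_cc = as.character(go),
    taxonomy_id = as.integer(tax), copies = as.integer(copies),
    symmetry = as.character(symmetry), seq_length = as.integer(seq_length)
  )
}

haemoglobin_components <- function(entry = "6kat") {
  dplyr::bind_rows(
    comp_row(entry, 1, 1, "protein", 2,
      uniprot = "P68871",
      entity_name = "Hemoglobin subunit beta",
      uniprot_name = "Hemoglobin subunit beta"
    ),
    comp_row(entry, 1, 2, "protein", 2,
      uniprot = "P69905",
      entity_name = "Hemoglobin subunit alpha",
      uniprot_name = "Hemoglobin subunit alpha"
    )
  )
}

# random assembly component tables over a shared accession pool; unmapped
# components get unique entry/entity coordinates so they only match
# themselves
random_components <- function(n_comp, entry, acc_pool) {
  rows <- lapply(seq_len(n_comp), function(j) {
    kind <- sample(c("uniprot", "rfam", "dna", "unmapped_protein"), 1,
      prob = c(0.5, 0.2, 0.15, 0.15)
    )
    switch(kind,
      uniprot = comp_row(entry, 1, j, "protein", sample(1:4, 1),
        uniprot = sample(acc_pool, 1)
      ),
      rfam = comp_row(entry, 1, j, "RNA", sample(1:2, 1),
        rfam = sprintf("RF9%04d", sample(1:20, 1))
      ),
      dna = comp_row(entry, 1, j, "DNA", sample(1:2, 1)),
      unmapped_protein = comp_row(entry, 1, j, "protein", sample(1:2, 1))
    )
  })
  dplyr::bind_rows(rows)
}

# independent multiset signature: sorted identity=copies pairs computed
# without the label/canonicalisation machinery
multiset_signature <- function(components) {
  ids <- component_identity(components)
  agg <- tapply(components$copies, ids, sum)
  paste(sort(paste0(names(agg), "=", agg)), collapse = ";")
}

# independent subset oracle used against build_relation_graph()
oracle_is_sub <- function(ca, cb, mode = "strict") {
  ids_a <- unique(ca$identity)
  ids_b <- unique(cb$identity)
  if (!all(ids_a %in% ids_b) || setequal(ids_a, ids_b)) {
    return(FALSE)
  }
  for (id in ids_a) {
    na <- sum(ca$copies[ca$identity == id])
    nb <- sum(cb$copies[cb$identity == id])
    if (mode == "strict" && na != nb) {
      return(FALSE)
    }
    if (mode == "relaxed" && na > nb) {
      return(FALSE)
    }
  }
  TRUE
}

# md5 oracle independent of digest: hash the string through a file
md5_file_oracle <- function(s) {
  f <- tempfile()
  con <- file(f, "wb")
  writeChar(s, con, eos = NULL)
  close(con)
  unname(tools::md5sum(f))
}
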