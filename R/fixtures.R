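# Synthetic archive generation. Every downstream module is testable
# against archives produced here, with machine-readable ground truth
# (intended unique group, name, category, portal match, relations,
# symmetry consistency) recorded per generated assembly.
#
# Synthetic accessions live in reserved fake namespaces (UPTnnnnn
# proteins, RF9nnnn RNA families, CPX-9nnnn portal complexes) so no
# real-database coupling is implied. The fixed reference bundle
# (reference_examples) is the one place well-known real accessions
# appear, encoding textbook complexes — haemoglobin, CLOCK-BMAL1, the
# bacterial 70S ribosome, an antibody Fab, a SAM riboswitch — with their
# expected pipeline outputs.

#' Fixture generator configuration
#'
#' Counts of unique compositions per archetype, the symmetry noise rate
#' (fraction of multi-member labelled groups whose members disagree) and
#' the seed fixing all randomness.
#'
#' @param homomer Single-accession groups (monomers and homomers; the
#'   only archetype carrying point-group labels, 2-4 members each).
#' @param heteromer Multi-accession protein complexes sharing a GO
#'   cellular-component term (named via GO).
#' @param portal_exact,portal_extended,multi_portal Complex Portal
#'   archetypes (exact composition match; match plus one extra protein;
#'   two disjoint portal complexes plus a DNA component).
#' @param ribosome_70S,ribosome_SSU Full ribosomes (alternating empty and
#'   tRNA+mRNA-bound) and small-subunit-only assemblies.
#' @param antibody_complex Unmapped heavy/light chain pairs.
#' @param nucleic_only Single-component unmapped nucleic assemblies
#'   (DNA, RNA, hybrid in rotation).
#' @param rfam_riboswitch Single-component Rfam-mapped RNA assemblies.
#' @param chimeric Assemblies with a chimeric chain (excluded from
#'   identification).
#' @param sub_super_pair Pairs of compositions where one strictly
#'   contains the other.
#' @param unnamed_heteromer Multi-accession complexes with no portal or
#'   GO evidence (the automated process cannot name these).
#' @param curated Compositions named through the curated override list.
#' @param symmetry_noise Fraction in `[0, 1]` of labelled multi-member
#'   groups receiving one discordant label.
#' @param seed Integer seed.
#' @return A validated list of class `fixture_config`.
#' @export
fixture_config <- function(homomer = 30, heteromer = 15, portal_exact = 8,
                           portal_extended = 5, multi_portal = 3,
                           ribosome_70S = 3, ribosome_SSU = 2,
                           antibody_complex = 5, nucleic_only = 6,
                           rfam_riboswitch = 3, chimeric = 3,
                           sub_super_pair = 5, unnamed_heteromer = 3,
                           curated = 2, symmetry_noise = 0.06, seed = 1L) {
  config <- list(
    homomer = homomer, heteromer = heteromer, portal_exact = portal_exact,
    portal_extended = portal_extended, multi_portal = multi_portal,
    ribosome_70S = ribosome_70S, ribosome_SSU = ribosome_SSU,
    antibody_complex = antibody_complex, nucleic_only = nucleic_only,
    rfam_riboswitch = rfam_riboswitch, chimeric = chimeric,
    sub_super_pair = sub_super_pair, unnamed_heteromer = unnamed_heteromer,
    curated = curated, symmetry_noise = symmetry_noise, seed = as.integer(seed)
  )
  counts <- unlist(config[setdiff(names(config), c("symmetry_noise", "seed"))])
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("fixture config error: archetype counts must be non-negative integers",
      call. = FALSE
    )
  }
  if (symmetry_noise < 0 || symmetry_noise > 1) {
    stop("fixture config error: symmetry_noise must be in [0, 1]", call. = FALSE)
  }
  structure(config, class = "fixture_config")
}

go_vocabulary <- function() {
  c(
    "GO:0000786" = "nucleosome",
    "GO:0005665" = "DNA-directed RNA Polymerase II",
    "GO:0016591" = "RNA polymerase II holoenzyme",
    "GO:0000502" = "proteasome complex",
    "GO:0005839" = "proteasome core complex",
    "GO:0009522" = "photosystem I",
    "GO:0009523" = "photosystem II",
    "GO:0005833" = "haemoglobin complex",
    "GO:0033178" = "ATP synthase catalytic core",
    "GO:0045259" = "ATP synthase complex"
  )
}

# run code with a private, restored RNG state
with_fixture_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  force(code)
}

#' Generate a synthetic archive snapshot with ground truth
#'
#' Emits a schema-valid snapshot, a matching Complex Portal catalogue, a
#' curated-name list and a truth table covering every generated assembly.
#' Rerunning with the same configuration (and seed) is byte-identical
#' after writing.
#'
#' @param config A [fixture_config()].
#' @return A list of class `fixture_bundle`: `snapshot`
#'   (`assembly_snapshot`), `portal` (catalogue tibble), `curated`
#'   (named character vector), `truth` (tibble: entry_id, assembly_id,
#'   group_id, archetype, eligible, intended_category, intended_name,
#'   intended_portal_acs, intended_sub_of, symmetry_perturbed) and
#'   `config`.
#' @export
generate_archive <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  with_fixture_seed(config$seed, {
    gen <- new.env(parent = emptyenv())
    gen$rows <- list()
    gen$truth <- list()
    gen$portal <- list()
    gen$curated <- character(0)
    gen$entry_n <- 0L
    gen$acc_n <- 0L
    gen$cpx_n <- 0L
    gen$rf_n <- 0L

    next_entry <- function() {
      gen$entry_n <- gen$entry_n + 1L
      paste0("t", sprintf("%03x", gen$entry_n))
    }
    next_acc <- function() {
      gen$acc_n <- gen$acc_n + 1L
      sprintf("UPT%05d", gen$acc_n)
    }
    next_cpx <- function() {
      gen$cpx_n <- gen$cpx_n + 1L
      sprintf("CPX-9%04d", gen$cpx_n)
    }
    next_rf <- function() {
      gen$rf_n <- gen$rf_n + 1L
      sprintf("RF9%04d", gen$rf_n)
    }
    comp <- function(entry, entity, type, copies, uniprot = NA, rfam = NA,
                     antibody = FALSE, entity_name = NA, uniprot_name = NA,
                     go = NA, tax = NA, symmetry = NA, seq_length = NA) {
      tibble::tibble(
        entry_id = entry, assembly_id = 1L, entity_id = as.integer(entity),
        polymer_type = type, uniprot = as.character(uniprot),
        rfam = as.character(rfam), is_antibody = antibody,
        entity_name = as.character(entity_name),
        uniprot_name = as.character(uniprot_name),
        go_cc = as.character(go), taxonomy_id = as.integer(tax),
        copies = as.integer(copies), symmetry = as.character(symmetry),
        seq_length = as.integer(seq_length)
      )
    }
    emit <- function(rows, group_id, archetype, category, name,
                     portal_acs = NA, sub_of = NA, eligible = TRUE) {
      gen$rows[[length(gen$rows) + 1]] <- rows
      gen$truth[[length(gen$truth) + 1]] <- tibble::tibble(
        entry_id = rows$entry_id[[1]], assembly_id = rows$assembly_id[[1]],
        group_id = group_id, archetype = archetype, eligible = eligible,
        intended_category = category, intended_name = name,
        intended_portal_acs = as.character(portal_acs),
        intended_sub_of = as.character(sub_of),
        symmetry_perturbed = FALSE
      )
    }
    add_portal <- function(ac, name, participants) {
      gen$portal[[length(gen$portal) + 1]] <- tibble::tibble(
        complex_ac = ac, recommended_name = name,
        participants = list(participants), partial_definition = FALSE
      )
    }

    go_vocab <- go_vocabulary()

    # --- homomers -------------------------------------------------------
    homomer_groups <- character(0)
    for (i in seq_len(config$homomer)) {
      acc <- next_acc()
      pname <- paste0("Synthetic protein H", i)
      stoich <- sample(c(1L, 2L, 2L, 3L, 4L, 6L), 1)
      label <- switch(as.character(stoich),
        "1" = "C1", "2" = "C2", "3" = "C3",
        "4" = sample(c("C4", "D2"), 1), "6" = sample(c("C6", "D3"), 1)
      )
      gid <- paste0("homomer_", i)
      homomer_groups <- c(homomer_groups, gid)
      for (m in seq_len(sample(2:4, 1))) {
        emit(
          comp(next_entry(), 1, "protein", stoich,
            uniprot = acc,
            entity_name = pname, uniprot_name = pname, symmetry = label,
            seq_length = 150L + i
          ),
          gid, "homomer", "uniprot", pname
        )
      }
    }

    # --- GO-named heteromers -------------------------------------------
    for (i in seq_len(config$heteromer)) {
      go_id <- names(go_vocab)[(i - 1) %% length(go_vocab) + 1]
      go_cell <- paste0(go_id, "=", go_vocab[[go_id]])
      k <- sample(2:4, 1)
      accs <- replicate(k, next_acc())
      stoich <- sample(1:2, k, replace = TRUE)
      gid <- paste0("heteromer_", i)
      for (m in seq_len(sample(1:2, 1))) {
        entry <- next_entry()
        rows <- dplyr::bind_rows(lapply(seq_len(k), function(j) {
          comp(entry, j, "protein", stoich[j],
            uniprot = accs[j],
            entity_name = paste0("Synthetic subunit ", accs[j]),
            uniprot_name = paste0("Synthetic subunit ", accs[j]),
            go = go_cell, seq_length = 200L
          )
        }))
        emit(rows, gid, "heteromer", "go", unname(go_vocab[[go_id]]))
      }
    }

    # --- Complex Portal: exact matches ---------------------------------
    for (i in seq_len(config$portal_exact)) {
      k <- sample(2:3, 1)
      accs <- replicate(k, next_acc())
      stoich <- sample(1:2, k, replace = TRUE)
      ac <- next_cpx()
      cname <- paste0("Synthetic complex P", i)
      add_portal(ac, cname, stats::setNames(stoich, accs))
      gid <- paste0("portal_exact_", i)
      for (m in seq_len(sample(1:2, 1))) {
        entry <- next_entry()
        rows <- dplyr::bind_rows(lapply(seq_len(k), function(j) {
          comp(entry, j, "protein", stoich[j],
            uniprot = accs[j],
            entity_name = paste0("Subunit ", accs[j]),
            uniprot_name = paste0("Subunit ", accs[j]), seq_length = 200L
          )
        }))
        emit(rows, gid, "portal_exact", "complex_portal", cname, portal_acs = ac)
      }
    }

    # --- Complex Portal: core plus one extra protein -------------------
    for (i in seq_len(config$portal_extended)) {
      accs <- c(next_acc(), next_acc())
      extra <- next_acc()
      ac <- next_cpx()
      cname <- paste0("Synthetic complex E", i)
      rname <- paste0("Synthetic regulator R", i)
      add_portal(ac, cname, stats::setNames(c(1L, 1L), accs))
      entry <- next_entry()
      rows <- dplyr::bind_rows(
        comp(entry, 1, "protein", 1,
          uniprot = accs[1],
          entity_name = paste0("Subunit ", accs[1]),
          uniprot_name = paste0("Subunit ", accs[1]), seq_length = 200L
        ),
        comp(entry, 2, "protein", 1,
          uniprot = accs[2],
          entity_name = paste0("Subunit ", accs[2]),
          uniprot_name = paste0("Subunit ", accs[2]), seq_length = 200L
        ),
        comp(entry, 3, "protein", 1,
          uniprot = extra,
          entity_name = rname, uniprot_name = rname, seq_length = 180L
        )
      )
      emit(rows, paste0("portal_extended_", i), "portal_extended",
        "complex_portal", paste0(cname, " and ", rname),
        portal_acs = ac
      )
    }

    # --- Complex Portal: two disjoint complexes plus DNA ---------------
    for (i in seq_len(config$multi_portal)) {
      accs_a <- c(next_acc(), next_acc())
      accs_b <- c(next_acc(), next_acc())
      ac_a <- next_cpx()
      ac_b <- next_cpx()
      name_a <- paste0("Synthetic machine A", i)
      name_b <- paste0("Synthetic machine B", i)
      add_portal(ac_a, name_a, stats::setNames(c(2L, 2L), accs_a))
      add_portal(ac_b, name_b, stats::setNames(c(1L, 1L), accs_b))
      entry <- next_entry()
      rows <- dplyr::bind_rows(
        dplyr::bind_rows(lapply(1:2, function(j) {
          comp(entry, j, "protein", 2,
            uniprot = accs_a[j],
            entity_name = paste0("Subunit ", accs_a[j]),
            uniprot_name = paste0("Subunit ", accs_a[j]), seq_length = 200L
          )
        })),
        dplyr::bind_rows(lapply(1:2, function(j) {
          comp(entry, j + 2, "protein", 1,
            uniprot = accs_b[j],
            entity_name = paste0("Subunit ", accs_b[j]),
            uniprot_name = paste0("Subunit ", accs_b[j]), seq_length = 200L
          )
        })),
        comp(entry, 5, "DNA", 2, entity_name = "DNA duplex")
      )
      emit(rows, paste0("multi_portal_", i), "multi_portal", "complex_portal",
        paste0(name_a, ", ", name_b, " and DNA"),
        portal_acs = paste(ac_a, ac_b, sep = "|")
      )
    }

    # --- ribosomes ------------------------------------------------------
    ribosome_rows <- function(entry, bound) {
      ssu_acc <- c(next_acc(), next_acc())
      lsu_acc <- c(next_acc(), next_acc())
      rows <- dplyr::bind_rows(
        comp(entry, 1, "RNA", 1,
          rfam = "RF00177",
          entity_name = "16S ribosomal RNA", tax = 562
        ),
        comp(entry, 2, "RNA", 1,
          rfam = "RF02541",
          entity_name = "23S ribosomal RNA", tax = 562
        ),
        comp(entry, 3, "RNA", 1,
          rfam = "RF00001",
          entity_name = "5S ribosomal RNA", tax = 562
        ),
        dplyr::bind_rows(lapply(1:2, function(j) {
          comp(entry, 3 + j, "protein", 1,
            uniprot = ssu_acc[j],
            entity_name = paste0("30S ribosomal protein S", j),
            uniprot_name = paste0("30S ribosomal protein S", j),
            tax = 562, seq_length = 120L
          )
        })),
        dplyr::bind_rows(lapply(1:2, function(j) {
          comp(entry, 5 + j, "protein", 1,
            uniprot = lsu_acc[j],
            entity_name = paste0("50S ribosomal protein L", j),
            uniprot_name = paste0("50S ribosomal protein L", j),
            tax = 562, seq_length = 130L
          )
        }))
      )
      if (bound) {
        rows <- dplyr::bind_rows(
          rows,
          comp(entry, 8, "RNA", 1,
            rfam = "RF00005", entity_name = "tRNA",
            tax = 562
          ),
          comp(entry, 9, "RNA", 1, entity_name = "mRNA", tax = 562)
        )
      }
      rows
    }
    for (i in seq_len(config$ribosome_70S)) {
      bound <- i %% 2 == 1
      emit(
        ribosome_rows(next_entry(), bound),
        paste0("ribosome_70S_", i), "ribosome_70S", "ribosome",
        if (bound) "70 S ribosome and tRNA and RNA" else "70 S ribosome"
      )
    }
    for (i in seq_len(config$ribosome_SSU)) {
      entry <- next_entry()
      accs <- c(next_acc(), next_acc())
      rows <- dplyr::bind_rows(
        comp(entry, 1, "RNA", 1,
          rfam = "RF00177",
          entity_name = "16S ribosomal RNA", tax = 562
        ),
        dplyr::bind_rows(lapply(1:2, function(j) {
          comp(entry, 1 + j, "protein", 1,
            uniprot = accs[j],
            entity_name = paste0("30S ribosomal protein S", j),
            uniprot_name = paste0("30S ribosomal protein S", j),
            tax = 562, seq_length = 120L
          )
        }))
      )
      emit(rows, paste0("ribosome_SSU_", i), "ribosome_SSU", "ribosome",
        "30 S ribosomal subunit")
    }

    # --- antibody complexes --------------------------------------------
    for (i in seq_len(config$antibody_complex)) {
      light <- if (i %% 2 == 1) "IG-light kappa chain" else "IG-light lambda chain"
      entry <- next_entry()
      rows <- dplyr::bind_rows(
        comp(entry, 1, "protein", 2,
          antibody = TRUE,
          entity_name = "IG-heavy chain", seq_length = 220L
        ),
        comp(entry, 2, "protein", 2,
          antibody = TRUE,
          entity_name = light, seq_length = 214L
        )
      )
      emit(rows, paste0("antibody_", i), "antibody_complex", "antibody",
        paste0("IG-heavy chain and ", light))
    }

    # --- nucleic-acid-only assemblies ----------------------------------
    nucleic_types <- c("DNA", "RNA", "DNA/RNA")
    nucleic_names <- c("DNA", "RNA", "DNA/RNA hybrid")
    for (i in seq_len(config$nucleic_only)) {
      j <- (i - 1) %% 3 + 1
      entry <- next_entry()
      emit(
        comp(entry, 1, nucleic_types[j], sample(1:2, 1),
          entity_name = paste0("Synthetic nucleic acid N", i)
        ),
        paste0("nucleic_", i), "nucleic_only", "nucleic_generic",
        nucleic_names[j]
      )
    }

    # --- Rfam-mapped small RNA assemblies ------------------------------
    for (i in seq_len(config$rfam_riboswitch)) {
      entry <- next_entry()
      rname <- paste0("Synthetic riboswitch W", i)
      emit(
        comp(entry, 1, "RNA", 1, rfam = next_rf(), entity_name = rname),
        paste0("rfam_", i), "rfam_riboswitch", "rfam", rname
      )
    }

    # --- chimeric assemblies (excluded from identification) ------------
    for (i in seq_len(config$chimeric)) {
      entry <- next_entry()
      rows <- comp(entry, 1, "protein", 2,
        uniprot = paste(next_acc(), next_acc(), sep = ";"),
        entity_name = paste0("Chimeric construct X", i), seq_length = 400L
      )
      emit(rows, paste0("chimeric_", i), "chimeric", NA_character_,
        NA_character_,
        eligible = FALSE
      )
    }

    # --- sub/super pairs (GO-named, shared term) -----------------------
    for (i in seq_len(config$sub_super_pair)) {
      go_id <- names(go_vocab)[(i - 1) %% length(go_vocab) + 1]
      go_cell <- paste0(go_id, "=", go_vocab[[go_id]])
      accs <- c(next_acc(), next_acc(), next_acc())
      sub_gid <- paste0("sub_", i)
      super_gid <- paste0("super_", i)
      entry <- next_entry()
      sub_rows <- dplyr::bind_rows(lapply(1:2, function(j) {
        comp(entry, j, "protein", 2,
          uniprot = accs[j],
          entity_name = paste0("Subunit ", accs[j]),
          uniprot_name = paste0("Subunit ", accs[j]),
          go = go_cell, seq_length = 200L
        )
      }))
      emit(sub_rows, sub_gid, "sub_super_pair", "go", unname(go_vocab[[go_id]]),
        sub_of = super_gid
      )
      entry <- next_entry()
      super_rows <- dplyr::bind_rows(lapply(1:3, function(j) {
        comp(entry, j, "protein", 2,
          uniprot = accs[j],
          entity_name = paste0("Subunit ", accs[j]),
          uniprot_name = paste0("Subunit ", accs[j]),
          go = go_cell, seq_length = 200L
        )
      }))
      emit(super_rows, super_gid, "sub_super_pair", "go",
        unname(go_vocab[[go_id]]))
    }

    # --- unnamable heteromers ------------------------------------------
    for (i in seq_len(config$unnamed_heteromer)) {
      entry <- next_entry()
      rows <- dplyr::bind_rows(
        comp(entry, 1, "protein", 1,
          uniprot = next_acc(),
          entity_name = "Uncharacterized subunit",
          uniprot_name = "Uncharacterized subunit", seq_length = 300L
        ),
        comp(entry, 2, "protein", 1,
          entity_name = NA, seq_length = 250L
        )
      )
      emit(rows, paste0("unnamed_", i), "unnamed_heteromer", "unnamed",
        NA_character_)
    }

    # --- curated overrides ---------------------------------------------
    for (i in seq_len(config$curated)) {
      acc <- next_acc()
      entry <- next_entry()
      rows <- comp(entry, 1, "protein", 6,
        uniprot = acc,
        entity_name = paste0("Synthetic curated protein ", i),
        uniprot_name = paste0("Synthetic curated protein ", i),
        seq_length = 320L
      )
      cname <- paste0("Curated synthetic machine ", i)
      key <- canonical_key(rows)
      gen$curated[key$md5_hex] <- cname
      emit(rows, paste0("curated_", i), "curated", "curated", cname)
    }

    snapshot <- as_snapshot(dplyr::bind_rows(gen$rows))
    truth <- dplyr::bind_rows(gen$truth)

    # --- symmetry noise -------------------------------------------------
    labelled_groups <- truth |>
      dplyr::filter(.data$archetype == "homomer") |>
      dplyr::count(.data$group_id) |>
      dplyr::filter(.data$n >= 2)
    n_perturb <- round(config$symmetry_noise * nrow(labelled_groups))
    if (n_perturb > 0) {
      victims <- sort(sample(labelled_groups$group_id, n_perturb))
      for (gid in victims) {
        entries <- truth$entry_id[truth$group_id == gid]
        target <- entries[[2]]
        idx <- which(snapshot$entry_id == target)
        old <- snapshot$symmetry[idx]
        snapshot$symmetry[idx] <- ifelse(old == "C1", "C2", "asymmetric")
        truth$symmetry_perturbed[truth$group_id == gid] <- TRUE
      }
    }

    portal <- if (length(gen$portal) > 0) {
      dplyr::bind_rows(gen$portal)
    } else {
      tibble::tibble(
        complex_ac = character(), recommended_name = character(),
        participants = list(), partial_definition = logical()
      )
    }
    structure(
      list(
        snapshot = snapshot, portal = portal, curated = gen$curated,
        truth = truth, config = config
      ),
      class = "fixture_bundle"
    )
  })
}

#' Write a fixture bundle to a directory
#'
#' @param bundle A `fixture_bundle` from [generate_archive()] or
#'   [reference_examples()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    snapshot = file.path(dir, "snapshot.tsv"),
    portal = file.path(dir, "portal_catalog.tsv"),
    curated = file.path(dir, "curated_names.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_snapshot(bundle$snapshot, paths[["snapshot"]])
  write_portal_catalog(bundle$portal, paths[["portal"]])
  write_curated_names(bundle$curated, paths[["curated"]])
  readr::write_tsv(bundle$truth, paths[["truth"]], na = "", progress = FALSE)
  invisible(paths)
}

#' Fixed reference bundle of well-known complexes
#'
#' A deterministic, non-random archive encoding textbook worked examples
#' with their expected outputs: adult haemoglobin and its IsdB-bound
#' super-assembly, the CLOCK-BMAL1 heterodimer with its Complex Portal
#' entry, an entry carrying both hexameric and dodecameric protease
#' assemblies (preferred-assembly selection), RNA polymerase II named via
#' a shared GO term, an interleukin-antibody-peptide complex, an
#' antibody-only Fab, ribosomes (bound 70S, empty 70S, 30S subunit), the
#' label-grammar exemplars for every unmapped component type, a
#' cyclin-kinase complex extending a portal definition, a
#' nucleosome-DDB1/DDB2 composition mapping to two portal entries,
#' symmetry-discordant histidine-kinase dimers, a kinase homomer group
#' with a discordant stoichiometry annotation, a SAM riboswitch and one
#' curated override.
#'
#' @return A `fixture_bundle` (see [generate_archive()]).
#' @export
reference_examples <- function() {
  r <- function(entry, assembly, entity, type, copies, uniprot = NA,
                rfam = NA, antibody = FALSE, entity_name = NA,
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
  hb_go <- "GO:0005833=haemoglobin complex"
  hbb <- function(entry) {
    r(entry, 1, 1, "protein", 2,
      uniprot = "P68871",
      entity_name = "Hemoglobin subunit beta",
      uniprot_name = "Hemoglobin subunit beta", go = hb_go, tax = 9606,
      seq_length = 147
    )
  }
  hba <- function(entry) {
    r(entry, 1, 2, "protein", 2,
      uniprot = "P69905",
      entity_name = "Hemoglobin subunit alpha",
      uniprot_name = "Hemoglobin subunit alpha", go = hb_go, tax = 9606,
      seq_length = 142
    )
  }
  pol2_go <- "GO:0005665=DNA-directed RNA Polymerase II"
  kat <- function(entry, copies, symmetry) {
    r(entry, 1, 1, "protein", copies,
      uniprot = "Q8N5Z0",
      entity_name = "Kynurenine--oxoglutarate transaminase 2",
      uniprot_name = "Kynurenine--oxoglutarate transaminase 2",
      tax = 9606, symmetry = symmetry, seq_length = 425
    )
  }
  hk <- function(entry, symmetry) {
    r(entry, 1, 1, "protein", 2,
      uniprot = "A0A0M3KKX3",
      entity_name = "Sensor histidine kinase",
      uniprot_name = "Sensor histidine kinase", symmetry = symmetry,
      seq_length = 480
    )
  }
  ribo_core <- function(entry) {
    dplyr::bind_rows(
      r(entry, 1, 1, "RNA", 1,
        rfam = "RF00177",
        entity_name = "16S ribosomal RNA", tax = 562
      ),
      r(entry, 1, 2, "RNA", 1,
        rfam = "RF02541",
        entity_name = "23S ribosomal RNA", tax = 562
      ),
      r(entry, 1, 3, "RNA", 1,
        rfam = "RF00001",
        entity_name = "5S ribosomal RNA", tax = 562
      ),
      r(entry, 1, 4, "protein", 1,
        uniprot = "UPT90031",
        entity_name = "30S ribosomal protein S3",
        uniprot_name = "30S ribosomal protein S3", tax = 562, seq_length = 233
      ),
      r(entry, 1, 5, "protein", 1,
        uniprot = "UPT90032",
        entity_name = "50S ribosomal protein L2",
        uniprot_name = "50S ribosomal protein L2", tax = 562, seq_length = 273
      )
    )
  }

  snapshot_rows <- dplyr::bind_rows(
    # adult haemoglobin, two instances
    hbb("6kat"), hba("6kat"),
    hbb("7jy3"), hba("7jy3"),
    # haemoglobin bound to the IsdB receptor (super-assembly)
    hbb("7pch"), hba("7pch"),
    r("7pch", 1, 3, "protein", 2,
      uniprot = "Q8NX66",
      entity_name = "Iron-regulated surface determinant protein B",
      uniprot_name = "Iron-regulated surface determinant protein B",
      tax = 1280, seq_length = 645
    ),
    # CLOCK-BMAL1 heterodimer (exact Complex Portal match)
    r("4f3l", 1, 1, "protein", 1,
      uniprot = "Q9WTL8",
      entity_name = "Aryl hydrocarbon receptor nuclear translocator-like protein 1",
      uniprot_name = "Aryl hydrocarbon receptor nuclear translocator-like protein 1",
      tax = 10090, seq_length = 626
    ),
    r("4f3l", 1, 2, "protein", 1,
      uniprot = "O08785",
      entity_name = "Circadian locomoter output cycles protein kaput",
      uniprot_name = "Circadian locomoter output cycles protein kaput",
      tax = 10090, seq_length = 855
    ),
    # protease entry with hexamer and dodecamer assemblies
    r("1e94", 1, 1, "protein", 6,
      uniprot = "UPT90001",
      entity_name = "ATP-dependent protease subunit HslV",
      uniprot_name = "ATP-dependent protease subunit HslV",
      tax = 562, symmetry = "C6", seq_length = 176
    ),
    r("1e94", 2, 1, "protein", 12,
      uniprot = "UPT90001",
      entity_name = "ATP-dependent protease subunit HslV",
      uniprot_name = "ATP-dependent protease subunit HslV",
      tax = 562, symmetry = "D6", seq_length = 176
    ),
    # RNA polymerase II, named via shared GO term
    r("2c35", 1, 1, "protein", 1,
      uniprot = "UPT90011",
      entity_name = "DNA-directed RNA polymerase II subunit RPB1",
      uniprot_name = "DNA-directed RNA polymerase II subunit RPB1",
      go = pol2_go, tax = 4932, seq_length = 1733
    ),
    r("2c35", 1, 2, "protein", 1,
      uniprot = "UPT90012",
      entity_name = "DNA-directed RNA polymerase II subunit RPB2",
      uniprot_name = "DNA-directed RNA polymerase II subunit RPB2",
      go = pol2_go, tax = 4932, seq_length = 1224
    ),
    # interleukin + antibody chains + peptide
    r("5hi4", 1, 1, "protein", 2,
      uniprot = "UPT90021",
      entity_name = "Interleukin-17A", uniprot_name = "Interleukin-17A",
      tax = 9606, seq_length = 155
    ),
    r("5hi4", 1, 2, "protein", 2,
      antibody = TRUE,
      entity_name = "IG-heavy chain", seq_length = 221
    ),
    r("5hi4", 1, 3, "protein", 2,
      antibody = TRUE,
      entity_name = "IG-light lambda chain", seq_length = 215
    ),
    r("5hi4", 1, 4, "protein", 2,
      entity_name = "antigen peptide", seq_length = 12
    ),
    # antibody-only Fab
    r("12e8", 1, 1, "protein", 2,
      antibody = TRUE,
      entity_name = "IG-heavy chain", seq_length = 222
    ),
    r("12e8", 1, 2, "protein", 2,
      antibody = TRUE,
      entity_name = "IG-light kappa chain", seq_length = 214
    ),
    # unmapped homodimer named from its entity name
    r("1ivi", 1, 1, "protein", 2,
      entity_name = "dihydrolipoamide dehydrogenase", seq_length = 470
    ),
    # ribosomes
    ribo_core("6bok"),
    r("6bok", 1, 6, "RNA", 1, rfam = "RF00005", entity_name = "tRNA", tax = 562),
    r("6bok", 1, 7, "RNA", 1, entity_name = "mRNA", tax = 562),
    ribo_core("5j7l"),
    r("6v3e", 1, 1, "RNA", 1,
      rfam = "RF00177",
      entity_name = "16S ribosomal RNA", tax = 562
    ),
    r("6v3e", 1, 2, "protein", 1,
      uniprot = "UPT90033",
      entity_name = "30S ribosomal protein S4",
      uniprot_name = "30S ribosomal protein S4", tax = 562, seq_length = 206
    ),
    # label-grammar exemplars for unmapped component types
    r("5mv4", 1, 1, "protein", 1,
      antibody = TRUE,
      entity_name = "IG-heavy chain", seq_length = 230
    ),
    r("7rx0", 1, 2, "protein", 1,
      entity_name = "uncharacterized protein", seq_length = 310
    ),
    r("1un6", 1, 2, "RNA", 1, entity_name = "5S ribosomal RNA mimic"),
    r("8b1t", 1, 4, "DNA", 1, entity_name = "DNA duplex"),
    r("8e8j", 1, 3, "DNA/RNA", 1, entity_name = "DNA/RNA hybrid strand"),
    # cyclin-kinase complex extending a portal definition
    r("1h27", 1, 1, "protein", 1,
      uniprot = "UPT90041",
      entity_name = "Cyclin-A2", uniprot_name = "Cyclin-A2",
      tax = 9606, seq_length = 432
    ),
    r("1h27", 1, 2, "protein", 1,
      uniprot = "UPT90042",
      entity_name = "Cyclin-dependent kinase 2",
      uniprot_name = "Cyclin-dependent kinase 2", tax = 9606, seq_length = 298
    ),
    r("1h27", 1, 3, "protein", 1,
      uniprot = "UPT90043",
      entity_name = "Cyclin-dependent kinase inhibitor 1B",
      uniprot_name = "Cyclin-dependent kinase inhibitor 1B",
      tax = 9606, seq_length = 198
    ),
    # nucleosome + DDB1-DDB2 with DNA (two portal accessions)
    r("6r8z", 1, 1, "protein", 2,
      uniprot = "UPT90051",
      entity_name = "Histone H3.1", uniprot_name = "Histone H3.1",
      tax = 9606, seq_length = 136
    ),
    r("6r8z", 1, 2, "protein", 2,
      uniprot = "UPT90052",
      entity_name = "Histone H4", uniprot_name = "Histone H4",
      tax = 9606, seq_length = 103
    ),
    r("6r8z", 1, 3, "protein", 2,
      uniprot = "UPT90053",
      entity_name = "Histone H2A.2", uniprot_name = "Histone H2A.2",
      tax = 9606, seq_length = 130
    ),
    r("6r8z", 1, 4, "protein", 2,
      uniprot = "UPT90054",
      entity_name = "Histone H2B.1", uniprot_name = "Histone H2B.1",
      tax = 9606, seq_length = 126
    ),
    r("6r8z", 1, 5, "protein", 1,
      uniprot = "UPT90055",
      entity_name = "DNA damage-binding protein 1",
      uniprot_name = "DNA damage-binding protein 1", tax = 9606,
      seq_length = 1140
    ),
    r("6r8z", 1, 6, "protein", 1,
      uniprot = "UPT90056",
      entity_name = "DNA damage-binding protein 2",
      uniprot_name = "DNA damage-binding protein 2", tax = 9606,
      seq_length = 427
    ),
    r("6r8z", 1, 7, "DNA", 2, entity_name = "damaged DNA duplex"),
    # histidine-kinase dimers with discordant symmetry labels
    hk("4u7n", "C2"), hk("4u7o", "asymmetric"), hk("4zki", "asymmetric"),
    # kinase homodimers plus one discordant homotetramer annotation
    kat("2r2n", 2, "C2"),
    dplyr::bind_rows(lapply(sprintf("q2%02d", 1:14), function(e) {
      kat(e, 2, "C2")
    })),
    kat("2qlr", 4, "D2"),
    # SAM riboswitch (Rfam-mapped, RNA-only)
    r("2gis", 1, 1, "RNA", 1,
      rfam = "RF00162",
      entity_name = "SAM riboswitch", seq_length = 94
    ),
    # curated override
    r("1cur", 1, 1, "protein", 6,
      uniprot = "UPT90061",
      entity_name = "Synthetic curated protein",
      uniprot_name = "Synthetic curated protein", seq_length = 320
    )
  )
  snapshot <- as_snapshot(snapshot_rows)

  portal <- tibble::tibble(
    complex_ac = c("CPX-3225", "CPX-2006", "CPX-2556", "CPX-308"),
    recommended_name = c(
      "CLOCK-Bmal1 transcription complex",
      "Cyclin A2-CK2 complex",
      "Nucleosome variant H3.1-H2A.2-H2B.1",
      "DDB1-DDB2 UV DNA damage recognition complex"
    ),
    participants = list(
      c(O08785 = 1L, Q9WTL8 = 1L),
      c(UPT90041 = 1L, UPT90042 = 1L),
      c(UPT90051 = 2L, UPT90052 = 2L, UPT90053 = 2L, UPT90054 = 2L),
      c(UPT90055 = 1L, UPT90056 = 1L)
    ),
    partial_definition = FALSE
  )

  curated_key <- canonical_key(snapshot[snapshot$entry_id == "1cur", ])
  curated <- stats::setNames("Curated protease particle", curated_key$md5_hex)

  truth <- tibble::tribble(
    ~entry_id, ~assembly_id, ~group_id, ~intended_category, ~intended_name,
    ~intended_portal_acs, ~intended_sub_of,
    "6kat", 1L, "hb", "go", "haemoglobin complex", NA, "hb_isdb",
    "7jy3", 1L, "hb", "go", "haemoglobin complex", NA, "hb_isdb",
    "7pch", 1L, "hb_isdb", "unnamed", NA, NA, NA,
    "4f3l", 1L, "clock_bmal1", "complex_portal",
    "CLOCK-Bmal1 transcription complex", "CPX-3225", NA,
    "1e94", 1L, "hslv", "uniprot", "ATP-dependent protease subunit HslV",
    NA, NA,
    "2c35", 1L, "rnapol2", "go", "DNA-directed RNA Polymerase II", NA, NA,
    "5hi4", 1L, "il17",
    "uniprot", "Interleukin-17A, IG-heavy chain, IG-light lambda chain, peptide complex",
    NA, NA,
    "12e8", 1L, "fab", "antibody", "IG-heavy chain and IG-light kappa chain",
    NA, NA,
    "1ivi", 1L, "dld", "unmapped_protein", "dihydrolipoamide dehydrogenase",
    NA, NA,
    "6bok", 1L, "ribo_bound", "ribosome", "70 S ribosome and tRNA and RNA",
    NA, NA,
    "5j7l", 1L, "ribo_empty", "ribosome", "70 S ribosome", NA, "ribo_bound",
    "6v3e", 1L, "ribo_ssu", "ribosome", "30 S ribosomal subunit", NA, NA,
    "5mv4", 1L, "ab_single", "antibody", "IG-heavy chain", NA, NA,
    "7rx0", 1L, "up_single", "unmapped_protein", "uncharacterized protein",
    NA, NA,
    "1un6", 1L, "rna_single", "nucleic_generic", "RNA", NA, NA,
    "8b1t", 1L, "dna_single", "nucleic_generic", "DNA", NA, NA,
    "8e8j", 1L, "hybrid_single", "nucleic_generic", "DNA/RNA hybrid", NA, NA,
    "1h27", 1L, "cyclin_cdk",
    "complex_portal", "Cyclin A2-CK2 complex and Cyclin-dependent kinase inhibitor 1B",
    "CPX-2006", NA,
    "6r8z", 1L, "nucleosome_ddb", "complex_portal",
    "Nucleosome variant H3.1-H2A.2-H2B.1, DDB1-DDB2 UV DNA damage recognition complex and DNA",
    "CPX-2556|CPX-308", NA,
    "4u7n", 1L, "hk", "uniprot", "Sensor histidine kinase", NA, NA,
    "4u7o", 1L, "hk", "uniprot", "Sensor histidine kinase", NA, NA,
    "4zki", 1L, "hk", "uniprot", "Sensor histidine kinase", NA, NA,
    "2r2n", 1L, "kat2_dimer", "uniprot",
    "Kynurenine--oxoglutarate transaminase 2", NA, NA,
    "2qlr", 1L, "kat2_tetramer", "uniprot",
    "Kynurenine--oxoglutarate transaminase 2", NA, NA,
    "2gis", 1L, "sam", "rfam", "SAM riboswitch", NA, NA,
    "1cur", 1L, "curated1", "curated", "Curated protease particle", NA, NA
  )
  truth <- dplyr::bind_rows(
    truth,
    tibble::tibble(
      entry_id = sprintf("q2%02d", 1:14), assembly_id = 1L,
      group_id = "kat2_dimer", intended_category = "uniprot",
      intended_name = "Kynurenine--oxoglutarate transaminase 2",
      intended_portal_acs = NA_character_, intended_sub_of = NA_character_
    )
  )
  truth$archetype <- "reference"
  truth$eligible <- TRUE
  truth$symmetry_perturbed <- truth$group_id == "hk"

  structure(
    list(
      snapshot = snapshot, portal = portal, curated = curated,
      truth = truth, config = NULL
    ),
    class = "fixture_bundle"
  )
}
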