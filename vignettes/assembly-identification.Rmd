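---
title: "Identifying and naming unique macromolecular assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and naming unique macromolecular assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdbassemblies)
```

## The problem

Structure archives hold many depositions of the same biological assembly:
the same complex solved under different conditions, at different
resolutions, with mutations, bound ligands or antibodies. Because entry
titles and entity names follow no naming convention, finding every
instance of, say, adult haemoglobin requires knowing every way its chains
have ever been described. `pdbassemblies` standardises this by reducing
every assembly to a *canonical composition* — its components, mapped to
reference accessions, with stoichiometry — and giving every distinct
composition a persistent identifier and, where the evidence supports one,
a human-readable name.

## The model

### Canonical composition keys

Each polymer component of an assembly is labelled by one production of a
small grammar: `<UniProt accession>_<copies>` for mapped proteins,
`<Rfam accession>_<copies>` for mapped RNA, and
`<type>_<entry>_<entity>_<copies>` for everything else (`antibody`,
`protein`, `RNA`, `DNA`, `DNA/RNA`). Two consequences follow directly
from the grammar:

* mapped components are identified by molecule, so the same protein in
  different entries contributes the same label, and components of the
  same accession split across deposition entities are merged with summed
  copy numbers before labelling;
* unmapped components embed their entry and entity, so they only ever
  match themselves — assemblies built from unannotated chains never
  collapse into one group by accident. Species scoping is implicit for
  the same reason: accessions are species-specific, and unmapped labels
  are entry-specific.

Labels are ordered canonically — mapped-accession labels before unmapped
labels, each block in bytewise lexicographic order — and joined with `","`
(no whitespace) into the composition string, whose md5 digest is the
composition key. The ordering makes the key a pure function of the
component *multiset*: any permutation of input rows yields the same
digest, which the test suite checks by property (hundreds of shuffled
random assemblies per run).

A flagged antibody chain that nevertheless carries a UniProt mapping is
labelled by its accession: the mapping is the stronger, more specific
evidence. The antibody flag still drives naming and extras
categorisation.

### Persistent identifiers

Digests map to accessions `PDB-CPX-<serial>` through an append-only
registry (serials start at 100001, unpadded, strictly increasing). Once
assigned, a pairing never changes; saving refuses to drop or rewrite an
existing pair, and loading rejects files with duplicate digests or
accessions. Within a run, new digests are minted in lexicographic order
of their composition strings, so the registry produced from a snapshot is
independent of its row order.

### Preferred assemblies and eligibility

One entry may declare several assemblies. The *preferred* assembly is the
smallest one (fewest polymer chains) containing all polymeric entities of
the entry, with ties broken to the lowest assembly id; when no assembly
is complete, the one covering the most entities wins. Only preferred
assemblies enter identification, and assemblies containing chimeric
chains — one entity mapped to more than one accession — are excluded
outright, since a chimera has no honest single-accession identity.

### Sub- and super-assemblies

Composition `a` is a sub-assembly of `b` when `a`'s component identities
form a strict subset of `b`'s. In the default *strict* mode every shared
identity must have equal stoichiometry (both worked examples that
motivate the feature — haemoglobin inside the haemoglobin–IsdB receptor
complex, and the empty versus factor-bound ribosome — preserve shared
stoichiometry); a *relaxed* mode allowing lower stoichiometry in the
sub-assembly is available as a flag because the underlying definition is
genuinely ambiguous on this point. The stored graph is the full direct
relation; `transitive_reduction()` provides the covering-relation view.

### Complex Portal matching

An *exact* match requires the assembly to consist solely of
UniProt-mapped proteins whose accession multiset (with stoichiometry)
equals a portal complex's participants. Failing that, an *extended* match
covers the assembly's mapped multiset greedily with portal complexes
(largest participant coverage first, ties to the lowest accession); one
covered complex plus leftovers is `exact_plus_extras`, two or more
disjointly covered complexes is `multi_portal`. Greedy cover without
backtracking is a deliberate simplification — the motivating cases need
at most two disjoint complexes — and is a known limitation for
pathological catalogues. Leftover components are categorised as
`protein`, `antibody`, `peptide`, `DNA`, `RNA` or `unmapped`; a peptide
is an unmapped protein of at most 19 residues when the snapshot carries
sequence lengths (the threshold is configurable; without a length the
component stays `unmapped`, never silently a peptide). Portal
definitions containing non-protein participants are matched on their
protein subset and flagged `partial_definition`.

### The naming decision tree

Rules apply in precedence order; the first hit names the assembly:

1. **curated** override (md5-keyed list) — curation exists to repair
   automation, so it outranks everything;
2. **Complex Portal exact** — the portal's recommended name;
3. **Complex Portal extended** — portal name(s), extras appended with
   `" and "` (e.g. `"Cyclin A2-CK2 complex and Cyclin-dependent kinase
   inhibitor 1B"`);
4. **ribosome** (below);
5. **GO** — a cellular-component term shared by *every* component and
   present on a configured allow-list of complex-describing terms (never
   locations like "cytoplasm"); among several qualifying terms the most
   specific wins, measured by fewest annotated components archive-wide,
   ties alphabetical;
6. **single UniProt accession** — the UniProt recommended name alone
   (monomers and homomers at any stoichiometry), or comma-joined with
   generic extras plus trailing `"complex"` when the only other
   components are antibodies, peptides or nucleic acids
   (`"Interleukin-17A, IG-heavy chain, IG-light lambda chain, peptide
   complex"`);
7. **all-unmapped protein** assemblies — antibody entity names joined
   with `" and "` (category `antibody` when every chain is an antibody),
   a single entity's name (`unmapped_protein`), or joined entity names
   (`entity_common_name`);
8. **Rfam-only nucleic** assemblies — entity names of the mapped
   families;
9. **generic nucleic** — `"DNA"`, `"RNA"` or `"DNA/RNA hybrid"`;
   multi-component unmapped nucleic assemblies receive the same generic
   names;
10. otherwise **unnamed**, a valid outcome tracked as its own category.

Curated-versus-portal precedence and the GO position were genuinely open
design choices; both are recorded here and the order is a pure function
of the configuration, so a re-run with a different precedence is a
configuration change, not a code change.

### Ribosome detection

Ribosomes are heterogeneous enough to defeat composition matching, so
they get a dedicated detector with two *ordered* routes. Primary: at
least one RNA component maps to a configured rRNA Rfam family (SSU:
RF00177/RF01959/RF01960; LSU: RF02541/RF02540/RF02543 plus the 5S and
5.8S families RF00001/RF00002) *and* at least one protein matches a
ribosomal-protein name pattern. Fallback, only when no RNA maps to Rfam
at all: unmapped RNA plus ribosomal proteins. Subunits come from the
families present; on the fallback route they are inferred from
30S/50S-style hints in protein names, defaulting to a full ribosome when
names carry no hint. Names are `"30 S ribosomal subunit"`, `"50 S
ribosomal subunit"` or `"70 S ribosome"` (`40 S`/`60 S`/`80 S` when a
eukaryotic rRNA family or configured taxon is seen), with `" and tRNA"`
appended when RF00005/RF01852 is present and `" and RNA"` when any RNA
is neither rRNA- nor tRNA-mapped. That last rule means fallback-route
ribosomes always carry `" and RNA"` — defensible, since unidentified RNA
genuinely is present.

### Symmetry consistency

Point-group detection is an input, not something this package computes:
assemblies may carry Schoenflies labels (from a tool such as AnAnaS run
on coordinates). Labels are normalised to uppercase and `asymmetric` is
identified with `C1`; missing labels are excluded rather than treated as
asymmetric (absence of evidence). A composition is assessed when at
least two members carry labels and is inconsistent when they disagree —
the classic signal of either genuine conformational variability or an
annotation error. Family frequencies (cyclic, dihedral, cubic) are
reported among symmetric assemblies.

## The synthetic archive generator

`generate_archive()` emulates an archive snapshot with known ground
truth, one archetype per naming route: homomer groups (the only
archetype carrying symmetry labels, 2–4 members each), GO-named
heteromers, the three Complex Portal match kinds, bound and empty 70S
ribosomes, 30S subunits, antibody pairs, generic nucleic assemblies,
Rfam-mapped small RNAs, chimeric chains, strict sub/super pairs,
unnamable heteromers and curated overrides. Defaults (about 95 unique
compositions over roughly 300 component rows) were chosen as a realistic
miniature of archive composition — every naming route exercised, a few
percent of assemblies unnamable, symmetry noise at 6% of labelled
multi-member groups — and the truth table records the intended group,
category, name, portal accessions and relations for every assembly, so
tests can demand a diagonal category confusion matrix rather than spot
checks. Synthetic accessions use reserved fake namespaces (`UPTnnnnn`,
`RF9nnnn`, `CPX-9nnnn`); the fixed `reference_examples()` bundle is the
one place real accessions appear, encoding textbook complexes with their
expected outputs.

What the generator does *not* emulate: sequence-level variation,
coordinates, experimental metadata, annotation coverage biases, and the
long tail of partially mapped heteromers that dominates real unnamed
assemblies. Passing tests therefore demonstrate that the rules are
implemented faithfully on well-posed inputs, not that real-archive
naming coverage would reach any particular fraction.

## Numerical and degenerate-input choices

* Sorting is bytewise (`method = "radix"`) everywhere a canonical order
  matters, so results do not depend on the session locale.
* md5 digests are computed over the composition string's bytes; the
  digest must be recomputable from the stored string, which a test
  checks against an independent file-based hash.
* Empty snapshots run to empty outputs with exit 0; validation failures
  abort before the registry is touched; outputs are written to temporary
  files and renamed, so interrupted runs leave no partial files.
* Ties: preferred assemblies break to the lowest assembly id, portal
  covers to the lowest accession, GO terms to alphabetical names.

## Known limitations

* Non-polymer components (ligands, ions) are outside composition
  identity entirely.
* Identity never merges across species or across unmapped components of
  different entries, by design of the label grammar.
* The registry has no file locking; concurrent writers are not
  supported (run the pipeline single-process, as in a release cycle).
* Greedy multi-portal covering can miss an optimal cover on catalogues
  with heavily overlapping definitions.
* Cross-species comparison of homologous assemblies is a non-goal.

## Problem sizes used in the test suite

The suite builds everything it tests in code: property tests run
hundreds of randomised assemblies per block (1000 in the hash
canonicalisation check), relation-graph oracle comparisons use archives
of up to ~200 compositions, and end-to-end determinism checks run the
full pipeline twice on the default synthetic archive. The whole suite
completes in well under a minute on one CPU.
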