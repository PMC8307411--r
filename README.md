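# metharmonize

Hierarchical harmonization of compounds and atom-resolved metabolic
reactions across metabolic pathway databases, in R.

Merging compound and reaction records from different pathway databases
(KEGG-style and BioCyc-style sources) is blocked by inconsistent atomistic
detail: missing or conflicting stereochemistry, generic structures with
R-group placeholders paired against concrete molecules, sugars drawn as
open chains in one source and as cyclic hemiacetals in the other, and atom
mappings recorded in incompatible conventions. `metharmonize` is for
metabolic-modeling and cheminformatics practitioners who need to build a
non-redundant, atom-resolved reaction network out of such sources — and to
quantify how well the sources agree.

## What it computes

* **Compound coloring identifiers.** Every heavy atom receives an
  iteratively refined neighborhood color (base invariant = element +
  charge + H-count, plus stereo descriptors in *detailed* mode); the
  sorted multiset of final colors is a canonical compound identifier,
  invariant under atom relabeling. The *loose* identifier ignores stereo,
  so it joins compounds whose drawings disagree only in chemical detail.
* **A three-tier relationship taxonomy.** Matched compounds are classified
  by their chemical details (atom parity, double-bond cis/trans) as an
  **equivalence**, a directed **generic–specific** relationship (general →
  specific), or a **loose** relationship; reactions inherit the
  classification from their compound pairs.
* **Chemically aware substructure search.** VF2-style subgraph
  isomorphism in which an R atom matches any heavy atom, plus an anchored
  maximum-common-subgraph search; used to validate generic pairs (each
  unmatched branch must instantiate an R group), tautomers (skeleton
  equality after collapsing double bonds + 1,3 H-shift checking) and
  ring–chain pairs (hemiacetal bond opening).
* **An iterative discovery loop.** Reactions are paired through shared EC
  numbers (with a 3-level relaxation tier) and fully matched participants;
  near-miss reaction pairs propose new compound candidates for validation,
  and the loop repeats to a fixpoint.
* **RCLASS RDM atom mappings.** KEGG R:D:M descriptions are parsed and
  compound-pair atom mappings derived by enumerating reaction-center
  assignments with an explicit combinatorial cap.
* **A mapping-consistency metric.** The fraction of mapped atoms whose
  one-bond atom color changes across a mapping, with resonance
  normalization (carboxylate/phosphate oxygen swaps are not
  inconsistencies).

## Worked example

Everything below runs on synthetic databases with planted ground truth —
no licensed database downloads are needed.

```r
library(metharmonize)

fx  <- gen_harmonization_fixture(seed = 42)   # 30 compounds, 12 reactions per side
res <- harmonization_loop(fx$db_a, fx$db_b, fx$rxns_a, fx$rxns_b, verbose = TRUE)
#> round 2: 5 new compound pairs
#> round 3: 1 new compound pairs
#> round 4: 0 new compound pairs

table(vapply(res$compound_pairs, function(p) p$relationship$kind, character(1)))
#>      equivalence generic_specific            loose
#>               11                5                3

res$compound_pairs[[15]]
#> <pair A_g2 ~ B_sp2: generic_specific a_to_b [generic_validation]>
res$reaction_pairs[[3]]
#> <reaction pair A_R3 ~ B_R3: generic_specific (full EC)>
```

Nineteen compound pairs are found: thirteen seeded by loose identifiers
(including the loose pairs with conflicting parity), five discovered
through near-miss reactions in round 2 (three generic R-group pairs, two
tautomers), and one ring–chain pair in round 3 — it only becomes reachable
after a tautomer pair has entered the list, which is exactly the iterative
behaviour the loop exists for. `A_g2 ~ B_sp2` reads: generic compound
`A_g2` generalizes (`a_to_b`) the specific compound `B_sp2`, validated by
R-group subgraph embedding; reaction pair `A_R3 ~ B_R3` inherits the
generic–specific tier from that compound pair.

Deriving an atom mapping from an RDM description:

```r
f  <- gen_reaction_with_mapping(seed = 7, n_center_edits = 1)
pm <- derive_pair_mapping(f$substrate, f$product, f$rdms)
pm
#> <mapping sub ~ prod: 8 atoms, 1 centers>
head(pm$pairs, 3)
#>   atom_a atom_b
#> 1      1      6
#> 2      2      3
#> 3      3      5
```

The recovered mapping is exactly the generator's ground truth (the product
was relabeled randomly; 8 of 9 substrate atoms map, the removed branch atom
does not). A command-line interface over the same functions lives in
`inst/cli/metharmonize.R` (`harmonize`, `quality-check`, `parse-rdm`,
`derive-mappings`, `evaluate-mappings`, `gen-fixtures`).

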