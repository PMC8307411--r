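---
title: "Harmonizing compounds and atom-resolved reactions across metabolic databases"
author: "metharmonize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing compounds and atom-resolved reactions across metabolic databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Building an atom-resolved metabolic network requires merging compound and
reaction records from several pathway databases, and those records rarely
agree on the details: one database draws a compound with stereo descriptors
the other omits, one writes a generic structure with an R-group placeholder
where the other writes a concrete molecule, sugars appear as open-chain
aldehydes in one source and as cyclic hemiacetals in the other, and the atom
mappings that describe which substrate atom becomes which product atom are
recorded in incompatible conventions (per-compound-pair RDM patterns versus
reaction-level index maps). A naive identifier join silently drops most of
these cases. `metharmonize` implements a hierarchy of machinery to pair such
records anyway and to say *how well* they agree.

## Molecular graphs

A compound is a labeled graph (`molecule()`): atoms carry element, charge,
2D coordinates, an atom-parity descriptor (`none`, `cw`, `ccw`, `unknown`)
and an optional KEGG atom-type label; bonds carry order (`1`, `2`, `3`,
aromatic `a`), a wedge code and a cis/trans label. Structures are read from
MDL molfile V2000 blocks and from KEGG KCF tables (`parse_molfile()`,
`parse_kcf()`); a deterministic writer (`write_molfile()`) closes the round
trip. Atom numbering is 1-based molfile order everywhere, because every
atom-mapping convention in this domain refers to those indices.

Explicit hydrogens are parsed but never matched on: all matching and
coloring operates on the hydrogen-suppressed graph with a per-heavy-atom
hydrogen count. Databases disagree on whether hydrogens are explicit, so
suppressing them (while keeping the count as an annotation) is the only
representation under which both sides of a pair look alike. R-group symbols
(`R`, `R#`, `*`, `A`, `X`, `Q` — molfile dialects differ) normalize to a
single `R` element with unit valence.

Stereo perception is geometric. Atom parity comes from wedge/hash bonds: the
wedged neighbor is lifted out of the drawing plane and the sign of the
resulting orientation determinant over the index-ordered neighbors gives
`cw`/`ccw`; candidates without wedge information become `unknown` (not
`none` — the distinction carries through the whole relationship taxonomy).
Double-bond geometry splits the plane along the line through the two
double-bond atoms and compares the sides of the prioritized substituents
(a lone substituent is prioritized outright; otherwise atomic number, then
local neighborhood). Because the rule never mentions the elements at the
double bond itself, heteroatom double bonds such as C=N are classified too.
Colinear substituents within a coordinate tolerance of `1e-6` are reported
`unresolved` rather than guessed.

## Coloring identifiers

Every heavy atom gets a neighborhood-specific color: the base invariant is
element + charge + hydrogen count (plus parity and incident cis/trans labels
in *detailed* mode), and each refinement round appends the sorted list of
(bond token, neighbor color) terms. Refinement stops when the number of
color classes is stable across a round, capped at the atom count. Sorting
the neighbor terms makes colors independent of input atom order, so
automorphic atoms receive identical strings, and the sorted multiset of
final colors prefixed by the molecular formula is the *compound coloring
identifier* (`compound_identifier()`): bit-identical for isomorphic inputs,
in loose mode blind to stereo, in detailed mode sensitive to any parity or
cis/trans change. Known limitation, accepted: class-counting refinement can
in principle merge non-automorphic atoms on pathological regular graphs;
the test suite bounds this against brute-force automorphism orbits on all
small random fixtures.

The *one-bond color* (`one_bond_color()`) is the single-iteration variant —
element plus sorted `(order:neighbor element)` terms, hydrogen counts and
charges excluded. It changes exactly when an incident bond is made, broken
or changes order, which makes it the right local probe for reaction
centers. Excluding hydrogen keeps the metric stable across databases that
disagree on explicit protons.

## The substructure engine

Generic-compound validation and RDM mapping both need subgraph search on
small labeled graphs. `subgraph_search()` is a VF2-style backtracking
enumeration of injective, label- and bond-preserving embeddings (an R
pattern atom matches any heavy atom); `graph_isomorphism()` is the
equal-size special case; `maximum_common_subgraph()` grows a connected
common subgraph by branch-and-bound extension, optionally seeded with
anchor pairs (reaction centers), with ties broken by more matched bonds and
then the lexicographically smallest mapping. Determinism matters more than
raw speed at metabolite scale (tens of heavy atoms): results are canonically
sorted and contain no randomness. With `order_strict = FALSE` bond orders
are ignored, the mode the tautomer validator uses after collapsing double
bonds. The whole engine is validated against brute-force enumeration and an
independent igraph isomorphism check on hundreds of random instances.

## The relationship taxonomy

Two structurally matched compounds are compared on their *chemical details*
— atom parities and double-bond cis/trans labels, compared site by site
across the mapping (`classify_chemical_details()`):

* equal detail sets → **equivalence**;
* one side's details a strict subset of the other's → **generic-specific**,
  directed from the less-specified (general) to the more-specified
  compound;
* any conflicting site, or extras on both sides → **loose**.

`unknown` stereo counts as absent, never as conflicting — otherwise the
dominant general-to-specific tier could not form at all, since databases
routinely leave stereocenters undeclared. Charges and hydrogen counts are
deliberately *not* details: they are structural and already separate
identifiers. Whether they should ever be relaxed is a curation question,
not a matching question.

Candidate pairs come from four origins:

1. **Identifier pairs** (`detect_pairs_by_identifier()`): equal loose
   identifiers across the two databases; the strongest relationship over
   the possible bijections is kept, and one compound may pair with several
   partners.
2. **Generic pairs** (`validate_generic_pair()`): the R- and H-suppressed
   graph of the generic compound must embed in the partner, and every
   connected unmatched branch of the partner must hang (by a single bond)
   off a matched atom that carries an unused R group. Each R absorbs
   exactly one branch and every R must absorb one — an R standing for
   nothing (i.e. for hydrogen) is disallowed. Branches may themselves
   contain R atoms, which is how two generic compounds of different
   formula pair.
3. **Tautomer pairs** (`validate_tautomer_pair()`): equal formula including
   hydrogen; skeletons must agree once every double bond is collapsed to a
   single bond; each surviving double-bond mismatch must be a 1,3-shift —
   the bond moved to an adjacent position with the far atoms gaining and
   losing exactly one hydrogen. Longer-range shifts are rejected; the
   common tautomerization is a hydrogen changing places with an adjacent
   double bond, and looser rules would start accepting rearrangements.
4. **Ring-chain pairs** (`validate_ring_chain_pair()`): for each ring C–O
   bond whose carbon also bears a hydroxyl (the hemiacetal/hemiketal
   motif), the bond is broken, the carbonyl C=O restored, and the hydroxyl
   hydrogen moved onto the freed ring oxygen — the reverse of the
   intramolecular addition that closed the ring. The pair is valid when the
   loose identifier of the opened form equals the linear partner's.
   Hydrogen bookkeeping is done explicitly because the identifiers carry
   hydrogen counts.

Validators return an `absent()` sentinel with a reason rather than throwing,
so the discovery loop can try many candidates cheaply.

## Reaction harmonization and the discovery loop

Reactions pair (`pair_reactions()`) when they share an EC number and their
participant multisets (stoichiometry-expanded) admit a perfect matching
under the compound-pair relation; the only entities allowed to remain
unmatched are configured ignorables (`H+` by default — water is *not*
ignored by default, since dropping it changes atom balance). Both
substrate/product orientations are tried and the stronger result wins.
Reaction pairs inherit a relationship from their compound pairs: all
equivalences → equivalence; equivalences plus generic-specific pairs all
pointing the same database direction → generic-specific; any loose pair or
direction conflict → loose. Because EC annotation is incomplete, a
relaxation tier accepts pairs agreeing only on the first three EC levels,
flagged `three_level` and only when no full match exists.

The discovery loop (`harmonization_loop()`) exploits the reactions to find
the pairs identifiers cannot see. Seeded with identifier pairs, each round
extracts *near-miss* reaction pairs — shared EC, at least one matched
compound pair, some unmatched participants — and generates candidates from
them: every R-containing compound against every compound of the partner
reaction (generic validation, both database directions), and same-formula
unmatched compounds through the tautomer and then the ring-chain validator.
Validated pairs join the list and the process repeats until no new pair
appears. The pair list grows monotonically inside a finite universe, so the
loop terminates; candidate validations are cached so no pair is examined
twice. A pair whose reaction has no other matched participant in round
*k* can become discoverable in round *k+1* — the planted test databases
contain exactly such a chain, where a ring-chain pair is reachable only
after a tautomer pair has been found.

`quality_check_reaction()` classifies atom-resolved reactions into
`complete`, `incomplete_reaction` (stoichiometry-weighted element counts
differ across the arrow), `incorrect_mapping` (a mapping joins atoms of
different elements) and `incomplete_mapping` (fewer atoms mapped than the
mappable heavy atoms). Hydrogen is excluded from the balance by default
(configurable), again because proton bookkeeping is the least consistent
part of the source data.

## RDM-based atom mappings

KEGG RCLASS describes a substrate→product transformation as R:D:M triples
of atom-type labels — reaction center, difference region, matched region.
`parse_rclass()` reads the flat-file grammar (`*` for empty regions, `+`
joining labels within a region; a `+` standing between complete triples
separates triples). `derive_pair_mapping()` then:

1. collects candidate atoms for every center label on both sides
   (`candidate_centers()`; element-prefix fallback with a warning when KEGG
   types are absent);
2. enumerates injective center assignments; if the combination count
   exceeds the cap (default `1e5`) it raises a `mh_combinatorial_limit`
   condition carrying the count — symmetric molecules with several
   identical centers genuinely explode combinatorially, and an explicit
   fast failure is more useful than an open-ended search;
3. for each assignment removes the bonds the difference region declares
   changed and runs the anchored maximum-common-subgraph search on the
   remainder;
4. returns the mapping with the most mapped atoms, ties broken by the
   least changed one-bond-color ratio and then canonical order.

Raising the cap never changes a successful result — it only converts
errors into results.

## Mapping consistency

`changed_color_fraction()` is the fraction of mapped atoms whose one-bond
color differs across the mapping — an estimate of the proportion of mapped
atoms sitting at a reaction center, and a useful score for deciding which
of two disagreeing mappings to trust. Two mappings of the same compounds
are compared (`compare_mappings()`) after *resonance normalization*
(`resonance_normalize()`): atoms that are chemically interchangeable — full
symmetry-class members plus terminal oxygens of carboxylate- and
phosphate-like groups with equal hydrogen counts — may be permuted freely,
so each mapping is replaced by the lexicographically smallest member of its
equivalence class before the pair sets are compared. A mapping that differs
from another only by swapping the two carboxylate oxygens is therefore
*same*, not *inconsistent*. Normalization is idempotent; note that
normalizing a mapping that actually contains a resonant swap can lower its
changed-color fraction — that correction is the point of the operation.
Nitro and guanidinium groups are not currently treated as resonance
groups; the terminal-oxygen rule covers the overwhelmingly common cases.

Compound-level mappings aggregate to reaction level by union
(`reaction_level_mapping()`); source atoms mapped to several targets are
kept and flagged as conflicts rather than dropped, because such conflicts
are themselves a data-quality signal worth reporting.

## The synthetic generators

All tests and the acceptance script run on synthetic data with known ground
truth (`gen_molecule()`, `gen_pair()`, `gen_non_pair()`,
`gen_reaction_with_mapping()`, `gen_harmonization_fixture()`). The
generator grows random valence-respecting trees (valences C 4, N 3, O 2,
S 2, P 5, H 1, R 1; element weights 0.65 C / 0.15 N / 0.15 O / 0.05 S;
double-bond attempt rate 0.15) with explicit hydrogens, then plants each
pair category by construction: relabeled copies, terminal branches replaced
by R, parity conflicts at a uniquely identifiable stereocenter, keto/enol
hydrogen shifts, hemiacetal ring closures. Negative controls perturb the
same constructions (skeleton rewiring at constant formula, 1,5-shifts,
anomeric hydroxyls moved away). Reaction fixtures remove terminal branches
from molecules whose symmetry classes are all singletons, so the optimal
RDM mapping is unique and recovery can be checked exactly. Planted
mini-databases hold 30 compounds and 12 reactions per side with every
category represented — small enough that each full loop runs in seconds,
large enough that every discovery path is exercised.

What the generator does **not** emulate — and what green tests therefore do
not certify about real databases: aromatic ring systems (bond label `a` is
parsed and matched but never generated), charged macromolecular cofactors,
stereo wedges in generated drawings (harmonizer fixtures plant parity
labels directly; wedge perception is tested on hand-drawn cases), real KEGG
atom-type assignments (the synthetic types encode element, heavy degree and
one-bond environment — enough to exercise the machinery, not KEGG's actual
68-type scheme), multi-step RDM descriptions, and database-scale volumes.

## Numerical and design choices

* Geometry tolerance `1e-6` in coordinate units for colinearity and
  degenerate-determinant checks; no other floating-point comparisons exist
  (colors and identifiers are exact strings).
* Refinement termination by stable class count, capped at the atom count.
* All tie-breaks (MCS, RDM optimum, validator embeddings) resolve to the
  lexicographically smallest mapping, so every result is reproducible
  across platforms.
* Combination cap `1e5` by default; failure is an explicit typed condition.
* Equal-formula generic pairs classify under the specific-compound rules;
  R=H instantiation is disallowed; one R absorbs exactly one branch.
* Stoichiometric coefficients must match after ignorable-entity removal;
  reaction orientation is chosen by the stronger resulting relationship.
* Degenerate inputs: empty databases and empty candidate sets yield empty
  results; zero mapped atoms make the changed-color fraction an error
  rather than a silent `NaN`; a wedge whose narrow end is elsewhere, or an
  unknown KEGG atom type, degrades with a warning instead of failing.

## Limitations

Color refinement is an approximation of automorphism orbits (exact on all
tested fixture classes, not in general). The identifiers include hydrogen
counts, so databases must either both include or both omit explicit
hydrogens for identifier joins; the validators that reason about hydrogen
positions (tautomer, ring-chain) require explicit hydrogens. The MCS is
connected-extension: common fragments disconnected from every anchor are
not mapped. Multi-step RDM lists and R-groups standing for hydrogen are out
of scope, as are aromaticity perception and protonation-state modeling —
bond labels and charges are taken as given.
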