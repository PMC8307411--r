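test_that("changed-color fraction counts exactly the affected endpoints", {
  # identity mapping on identical molecules
  m <- gen_molecule(6, seed = 1, add_h = FALSE, id = "m")
  idmap <- data.frame(compound_a = "m", atom_a = 1:6,
                      compound_b = "m", atom_b = 1:6)
  expect_equal(changed_color_fraction(idmap, list(m = m)), 0)

  # one planted bond edit among 5 mapped atoms changes both endpoints: 2/5
  fx <- gen_bond_edit_reaction(seed = 2, k = 1, size = 5)
  expect_equal(changed_color_fraction(fx$mapping, list(sub_a = fx$a, sub_b = fx$b)),
               2 / 5)

  # k non-adjacent edits among n atoms: exactly 2k/n
  for (seed in 1:8) {
    k <- 1L + seed %% 3L
    fx <- gen_bond_edit_reaction(seed = seed, k = k, size = 10)
    expect_equal(changed_color_fraction(fx$mapping, list(sub_a = fx$a, sub_b = fx$b)),
                 fx$expected_fraction)
  }

  # every neighborhood changed
  chain <- mk_mol(rep("C", 4), path_bonds(4), id = "chain")
  bare <- mk_mol(rep("C", 4), id = "bare")
  allmap <- data.frame(compound_a = "chain", atom_a = 1:4,
                       compound_b = "bare", atom_b = 1:4)
  expect_equal(changed_color_fraction(allmap, list(chain = chain, bare = bare)), 1)

  expect_error(changed_color_fraction(idmap[0, ], list(m = m)),
               class = "mh_precondition_error")
})

carb_pair <- function() {
  cb <- gen_carboxylate(n_chain = 2L, id = "ca")
  cb2 <- gen_carboxylate(n_chain = 2L, id = "cb")
  n <- nrow(cb$mol$atoms)
  idmap <- data.frame(compound_a = "ca", atom_a = seq_len(n),
                      compound_b = "cb", atom_b = seq_len(n))
  swapped <- idmap
  swapped$atom_b[cb$o_double] <- cb2$o_single
  swapped$atom_b[cb$o_single] <- cb2$o_double
  list(mols = list(ca = cb$mol, cb = cb2$mol), idmap = idmap, swapped = swapped)
}

test_that("resonance normalization canonicalizes interchangeable oxygens", {
  cp <- carb_pair()
  n1 <- resonance_normalize(cp$idmap, cp$mols)
  n2 <- resonance_normalize(cp$swapped, cp$mols)
  expect_equal(n1, n2)

  # mapping without resonant groups is untouched
  m <- mk_mol(c("C", "C", "N"), path_bonds(3), id = "amine")
  plain <- data.frame(compound_a = "amine", atom_a = 1:3,
                      compound_b = "amine", atom_b = 1:3)
  expect_equal(resonance_normalize(plain, list(amine = m)), plain)

  # all 6 permutations of three phosphate-like oxygens normalize identically
  phos <- fill_hydrogens(mk_mol(c("C", "P", "O", "O", "O"),
                                data.frame(a = c(1, 2, 2, 2), b = c(2, 3, 4, 5),
                                           order = c("1", "2", "1", "1")),
                                id = "phos", charge = c(0L, 0L, 0L, -1L, -1L)))
  canon <- NULL
  for (perm in list(3:5, c(3, 5, 4), c(4, 3, 5), c(4, 5, 3), c(5, 3, 4), c(5, 4, 3))) {
    mp <- data.frame(compound_a = "phos", atom_a = 1:5,
                     compound_b = "phos", atom_b = c(1L, 2L, perm))
    nm <- resonance_normalize(mp, list(phos = phos))
    if (is.null(canon)) canon <- nm else expect_equal(nm, canon)
  }
})

test_that("normalization is idempotent and leaves the fraction stable", {
  cp <- carb_pair()
  n1 <- resonance_normalize(cp$swapped, cp$mols)
  n2 <- resonance_normalize(n1, cp$mols)
  expect_equal(n1, n2)
  expect_equal(changed_color_fraction(n1, cp$mols),
               changed_color_fraction(n2, cp$mols))
})

test_that("mapping comparison reports resonance-corrected agreement", {
  cp <- carb_pair()
  same <- compare_mappings(cp$idmap, cp$idmap, cp$mols)
  expect_equal(same$verdict, "same")
  expect_false(same$resonance_corrected)
  expect_equal(same$fraction_a, same$fraction_b)

  rep2 <- compare_mappings(cp$idmap, cp$swapped, cp$mols)
  expect_equal(rep2$verdict, "same")
  expect_true(rep2$resonance_corrected)

  # symmetric in its arguments
  rep3 <- compare_mappings(cp$swapped, cp$idmap, cp$mols)
  expect_equal(rep3$verdict, rep2$verdict)

  # genuinely different center choices stay inconsistent
  other <- cp$idmap
  other$atom_b[1:2] <- c(2L, 1L)
  rep4 <- compare_mappings(cp$idmap, other, cp$mols)
  expect_equal(rep4$verdict, "inconsistent")
  expect_true(rep4$fraction_a >= 0 && rep4$fraction_b <= 1)

  bad <- cp$idmap; bad$compound_b <- "elsewhere"
  expect_error(compare_mappings(cp$idmap, bad, cp$mols),
               class = "mh_precondition_error")
})

test_that("reaction-level mappings union pair mappings and flag conflicts", {
  pm1 <- data.frame(compound_a = "c1", atom_a = 1:2, compound_b = "c2", atom_b = 1:2)
  pm2 <- data.frame(compound_a = "c1", atom_a = 3L, compound_b = "c3", atom_b = 1L)
  clean <- reaction_level_mapping(list(pm1, pm2))
  expect_equal(nrow(clean$pairs), 3L)
  expect_equal(nrow(clean$conflicts), 0L)

  # one substrate atom mapped into two different products
  pm3 <- data.frame(compound_a = "c1", atom_a = 1L, compound_b = "c3", atom_b = 1L)
  confl <- reaction_level_mapping(list(pm1, pm3))
  expect_equal(nrow(confl$conflicts), 2L)
  expect_setequal(confl$conflicts$compound_b, c("c2", "c3"))

  empty <- reaction_level_mapping(list())
  expect_equal(nrow(empty$pairs), 0L)
})

test_that("consistency reports serialize as a scatter TSV", {
  cp <- carb_pair()
  reports <- list(r1 = compare_mappings(cp$idmap, cp$swapped, cp$mols))
  tf <- withr::local_tempfile(fileext = ".tsv")
  rows <- write_consistency_tsv(reports, tf)
  expect_equal(rows$id, "r1")
  expect_true(file.exists(tf))
})
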