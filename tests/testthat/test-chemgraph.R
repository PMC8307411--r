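test_that("molfile parsing preserves order, elements, charges and R groups", {
  # minimal single-atom block
  ch4 <- parse_molfile(paste(c("methane", "", "",
    "  1  0  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0", "M  END"), collapse = "\n"))
  expect_equal(nrow(ch4$atoms), 1L)
  expect_equal(unname(mol_formula(ch4)["C"]), 1L)

  eth <- parse_molfile(ethanol_molfile)
  expect_equal(eth$atoms$element, c("C", "C", "O"))
  expect_equal(eth$bonds$a, c(1L, 2L))
  expect_equal(eth$bonds$b, c(2L, 3L))

  rg <- parse_molfile(paste(c("rtest", "", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    1.0000    0.0000    0.0000 R#  0  0",
    "  1  2  1  0", "M  END"), collapse = "\n"))
  expect_true(rg$atoms$is_r[2])
  expect_equal(rg$atoms$element[2], "R")
  expect_equal(unname(mol_formula(rg)[c("C", "R")]), c(1L, 1L))
})

test_that("molfile charge property block supersedes atom-line codes", {
  txt <- paste(c("chg", "", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 N   0  3",
    "    1.0000    0.0000    0.0000 O   0  0",
    "  1  2  1  0",
    "M  CHG  1   2  -1",
    "M  END"), collapse = "\n")
  m <- parse_molfile(txt)
  # atom-line code said +1 on N, but an M CHG line resets everything
  expect_equal(m$atoms$charge, c(0L, -1L))
})

test_that("malformed molfiles raise structured parse errors", {
  expect_error(parse_molfile("x\n\n\nnot a counts line\n"),
               class = "mh_parse_error")
  bad_bond <- paste(c("bb", "", "",
    "  1  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "  1  5  1  0", "M  END"), collapse = "\n")
  expect_error(parse_molfile(bad_bond), class = "mh_structural_error")
})

test_that("molfile round trip preserves the labeled graph", {
  for (seed in 1:25) {
    m <- gen_molecule(3L + seed %% 7L, seed = seed, n_r = seed %% 2L)
    m2 <- parse_molfile(write_molfile(m), id = m$id)
    expect_equal(m2$atoms$element, m$atoms$element)
    expect_equal(m2$atoms$charge, m$atoms$charge)
    expect_equal(m2$bonds[, c("a", "b", "order")], m$bonds[, c("a", "b", "order")])
  }
})

test_that("KCF parsing infers elements from KEGG atom types", {
  one <- parse_kcf(paste(c("ENTRY  X", "ATOM  1",
                           "  1  C1a  0.0 0.0", "///"), collapse = "\n"))
  expect_equal(one$atoms$element, "C")
  expect_equal(one$atoms$kegg_type, "C1a")

  k <- parse_kcf(ethanol_kcf)
  m <- parse_molfile(ethanol_molfile)
  expect_equal(k$atoms$element, m$atoms$element)
  expect_equal(k$bonds[, c("a", "b", "order")], m$bonds[, c("a", "b", "order")])
  expect_equal(k$atoms$kegg_type, c("C1a", "C1b", "O1a"))

  expect_warning(
    unk <- parse_kcf(paste(c("ATOM  1", "  1  Eq9  0.0 0.0"), collapse = "\n")),
    "unknown KEGG atom type"
  )
  expect_equal(unk$atoms$kegg_type, "Eq9")
  expect_error(parse_kcf("BOND  0"), class = "mh_parse_error")
})

test_that("atom parity follows the wedge and flips under reflection", {
  block <- function(sx) paste(c("bcf", "", "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    sprintf("%10.4f    0.0000    0.0000 C   0  0", 0),
    sprintf("%10.4f    0.0000    0.0000 F   0  0", sx * 1),
    sprintf("%10.4f    0.0000    0.0000 Cl  0  0", sx * -1),
    sprintf("%10.4f    1.0000    0.0000 Br  0  0", 0),
    sprintf("%10.4f   -1.0000    0.0000 H   0  0", 0),
    "  1  2  1  1", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
    "M  END"), collapse = "\n")
  m <- assign_atom_parity(parse_molfile(block(1)))
  m_ref <- assign_atom_parity(parse_molfile(block(-1)))
  expect_true(m$atoms$parity[1] %in% c("cw", "ccw"))
  expect_true(m_ref$atoms$parity[1] %in% c("cw", "ccw"))
  expect_false(m$atoms$parity[1] == m_ref$atoms$parity[1])
  # neighbors keep parity "none"
  expect_equal(m$atoms$parity[2], "none")
})

test_that("stereocenter candidates without wedges become unknown, not none", {
  m <- mk_mol(c("C", "F", "Cl", "Br"),
              data.frame(a = c(1, 1, 1), b = 2:4, order = "1"),
              x = c(0, 1, -1, 0), y = c(0, 0, 0, 1))
  m <- assign_atom_parity(m)
  expect_equal(m$atoms$parity[1], "unknown")
})

test_that("a wedge with its narrow end elsewhere warns and leaves unknown", {
  m <- mk_mol(c("C", "F", "Cl", "Br"),
              data.frame(a = c(2, 1, 1), b = c(1, 3, 4), order = "1",
                         wedge = c("up", "none", "none")),
              x = c(0, 1, -1, 0), y = c(0, 0, 0, 1))
  expect_warning(m <- assign_atom_parity(m), "narrow end")
  expect_equal(m$atoms$parity[1], "unknown")
})

test_that("double-bond geometry is classified from 2D coordinates", {
  butene <- function(y4) {
    mk_mol(rep("C", 4), path_bonds(4, order = c("1", "2", "1")),
           x = c(0, 1, 2, 3), y = c(1, 0, 0, y4))
  }
  expect_equal(classify_double_bond(butene(1), c(2, 3)), "cis")
  expect_equal(classify_double_bond(butene(-1), c(2, 3)), "trans")

  # terminal CH2= end: no stereoisomerism
  term <- mk_mol(c("C", "C", "C"),
                 data.frame(a = c(1, 2), b = c(2, 3), order = c("2", "1")),
                 x = c(0, 1, 2), y = c(0, 0, 1))
  expect_equal(classify_double_bond(term, c(1, 2)), "none")

  # heteroatom double bond C=N is labeled, not skipped
  cn <- mk_mol(c("C", "C", "N", "C"), path_bonds(4, c("1", "2", "1")),
               x = c(0, 1, 2, 3), y = c(1, 0, 0, 1))
  expect_equal(classify_double_bond(cn, c(2, 3)), "cis")
})

test_that("cis/trans classification is rigid-motion invariant, reflection flips it", {
  base <- mk_mol(rep("C", 4), path_bonds(4, c("1", "2", "1")),
                 x = c(0, 1, 2, 3), y = c(1, 0, 0, 1))
  lab <- classify_double_bond(base, c(2, 3))
  for (theta in c(0.3, 1.2, 2.9)) {
    rot <- base
    xy <- cbind(base$atoms$x, base$atoms$y) %*%
      matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    rot$atoms$x <- xy[, 1] + 5; rot$atoms$y <- xy[, 2] - 2
    expect_equal(classify_double_bond(rot, c(2, 3)), lab)
  }
  # reflecting the whole drawing preserves which substituents share a side,
  # so the label must not change; moving a single substituent across the
  # double-bond line must flip it
  ref <- base; ref$atoms$y <- -ref$atoms$y
  expect_equal(classify_double_bond(ref, c(2, 3)), lab)
  asym <- base; asym$atoms$y[4] <- -asym$atoms$y[4]
  expect_false(classify_double_bond(asym, c(2, 3)) == lab)
})

test_that("priority-equivalent substituents give none", {
  # 2-methylpropene-like: two identical methyls on one end
  m <- mk_mol(rep("C", 4),
              data.frame(a = c(1, 1, 1), b = 2:4, order = c("2", "1", "1")),
              x = c(0, -1, 1, 1), y = c(0, 0, 1, -1))
  expect_equal(classify_double_bond(m, c(1, 2)), "none")
})
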