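# Hand-constructed fixture molecules and connection-table text blocks.

mk_mol <- function(el, bonds = NULL, id = "m", charge = NULL, x = NULL, y = NULL,
                   parity = NULL) {
  atoms <- data.frame(element = el, stringsAsFactors = FALSE)
  if (!is.null(charge)) atoms$charge <- charge
  if (!is.null(x)) atoms$x <- x
  if (!is.null(y)) atoms$y <- y
  if (!is.null(parity)) atoms$parity <- parity
  molecule(id, atoms, bonds)
}

path_bonds <- function(n, order = "1") {
  data.frame(a = seq_len(n - 1L), b = 2:n, order = order,
             stringsAsFactors = FALSE)
}

fix_ethanol <- function() mk_mol(c("C", "C", "O"), path_bonds(3), id = "ethanol")
fix_butane <- function() mk_mol(rep("C", 4), path_bonds(4), id = "butane")
fix_isobutane <- function() {
  mk_mol(rep("C", 4), data.frame(a = c(1, 1, 1), b = 2:4, order = "1"),
         id = "isobutane")
}
fix_benzene <- function() {
  mk_mol(rep("C", 6), data.frame(a = 1:6, b = c(2:6, 1), order = "a"),
         id = "benzene")
}

ethanol_molfile <- paste(c(
  "ethanol", "", "",
  "  3  2  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    2.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0", "  2  3  1  0", "M  END"), collapse = "\n")

ethanol_kcf <- paste(c(
  "ENTRY       C_eth               Compound",
  "ATOM        3",
  "            1   C1a C    0.0000    0.0000",
  "            2   C1b C    1.0000    0.0000",
  "            3   O1a O    2.0000    0.0000",
  "BOND        2",
  "            1     1   2 1",
  "            2     2   3 1",
  "///"), collapse = "\n")

# propanone (keto) and prop-1-en-2-ol (enol), explicit hydrogens
fix_keto <- function() {
  fill_hydrogens(mk_mol(c("C", "C", "C", "O"),
                        data.frame(a = c(1, 2, 2), b = c(2, 3, 4),
                                   order = c("1", "1", "2")),
                        id = "propanone"))
}
fix_enol <- function() {
  fill_hydrogens(mk_mol(c("C", "C", "C", "O"),
                        data.frame(a = c(1, 2, 2), b = c(2, 3, 4),
                                   order = c("2", "1", "1")),
                        id = "propenol"))
}

# R-CH2-OH and CH3-CH2-OH (explicit H)
fix_generic_a <- function() {
  fill_hydrogens(mk_mol(c("R", "C", "O"), path_bonds(3), id = "R_ch2_oh"))
}
fix_generic_b <- function() {
  fill_hydrogens(mk_mol(c("C", "C", "O"), path_bonds(3), id = "ethanol_h"))
}
# CH3-CH2-O-CH3: an extra branch hangs off the ether oxygen, which carries
# no R in the pattern, so the pair must be rejected
fix_generic_bad <- function() {
  fill_hydrogens(mk_mol(c("C", "C", "O", "C"), path_bonds(4), id = "ether"))
}

random_small_mol <- function(size, id = "rnd", p_double = 0.2) {
  gen_molecule(size, id = id, p_double = p_double, add_h = FALSE,
               elements = c(C = 0.6, N = 0.2, O = 0.2))
}
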