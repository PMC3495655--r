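test_that("SMILES reader preserves token order and atom attributes", {
  g <- read_smiles("ClCC(=O)Br")
  expect_equal(mg_natoms(g), 5L)
  expect_equal(g$atoms$element, c("Cl", "C", "C", "O", "Br"))
  expect_equal(nrow(g$bonds), 4L)
  k <- g$bonds[g$bonds$a == 3 & g$bonds$b == 4, ]
  expect_equal(k$order, 2L)
  expect_equal(g$atoms$hcount, c(0L, 2L, 0L, 0L, 0L))

  g <- read_smiles("C([2H])O")
  expect_equal(g$atoms$element, c("C", "H", "O"))
  expect_equal(g$atoms$isotope, c(0L, 2L, 0L))

  g <- read_smiles("[H][H]")
  expect_equal(g$atoms$element, c("H", "H"))
  expect_equal(nrow(g$bonds), 1L)

  g <- read_smiles("[NH4+]")
  expect_equal(g$atoms$charge, 1L)
  expect_equal(g$atoms$hcount, 4L)

  g <- read_smiles("C%10CC%10")
  expect_equal(nrow(g$bonds), 3L)
})

test_that("SMILES reader rejects malformed input", {
  expect_error(read_smiles("C1CC"), "unclosed ring")
  expect_error(read_smiles("C(C"), "unclosed branch")
  expect_error(read_smiles("[Xx]"), "unknown element")
  expect_error(read_smiles("C(=O))C"), "unmatched")
  expect_error(read_smiles("[C@@@]"), "malformed bracket")
})

test_that("OpenSMILES implicit valence filling", {
  hc <- function(s) read_smiles(s)$atoms$hcount
  expect_equal(hc("C"), 4L)
  expect_equal(hc("N"), 3L)
  expect_equal(hc("P"), 3L)
  expect_equal(hc("S"), 2L)
  expect_equal(hc("Cl"), 1L)
  expect_equal(hc("CS(C)(=O)=O")[2], 0L)   # hypervalent S: valence 6
  expect_equal(hc("CN(=O)=O")[2], 0L)      # pentavalent N
  expect_equal(hc("B"), 3L)
})

test_that("permute_atoms is seeded, isomorphic and stereo-preserving", {
  g <- read_smiles("OCC")
  expect_identical(permute_atoms(g, 5), permute_atoms(g, 5))
  # single atom: only one ordering
  g1 <- read_smiles("C")
  expect_identical(permute_atoms(g1, 3), g1)
  # multiset of (element, charge, isotope, degree) is preserved
  g <- read_smiles("C[C@@H](N)C(=O)[O-]")
  sig <- function(g) {
    deg <- table(factor(c(g$bonds$a, g$bonds$b), levels = seq_len(mg_natoms(g))))
    sort(paste(g$atoms$element, g$atoms$charge, g$atoms$isotope, as.integer(deg)))
  }
  for (seed in 1:10) expect_identical(sig(permute_atoms(g, seed)), sig(g))
  # InChI (including the stereo layer) is invariant for every seed
  i0 <- to_inchi(g, opt_universal)$inchi
  for (seed in 1:10) {
    ip <- to_inchi(permute_atoms(g, seed), opt_universal)$inchi
    expect_identical(ip, i0)
  }
  expect_match(i0, "/t", fixed = TRUE)  # the oracle really covers stereo
})

test_that("connected components are stable under permutation", {
  g <- read_smiles("CCO.CC.[Na+]")
  sizes0 <- sort(as.integer(table(mg_components(g))))
  for (seed in 1:5) {
    sizes <- sort(as.integer(table(mg_components(permute_atoms(g, seed)))))
    expect_equal(sizes, sizes0)
  }
})

test_that("molfile reader handles V2000 basics", {
  g <- read_molfile(ethanol_molblock)
  expect_equal(g$atoms$element, c("O", "C", "C"))
  expect_equal(nrow(g$bonds), 2L)
  expect_equal(length(g$tet), 0L)
  expect_equal(length(g$db), 0L)
  expect_equal(g$atoms$hcount, c(1L, 2L, 3L))

  methane <- mk_molblock(data.frame(x = 0, y = 0, symbol = "C"),
                         data.frame(a = integer(), b = integer(),
                                    order = integer()))
  g <- read_molfile(methane)
  expect_equal(g$atoms$hcount, 4L)

  expect_error(read_molfile(c("", "", "")), "line 4")
  bad <- ethanol_molblock
  bad[6] <- "not an atom line"
  expect_error(read_molfile(bad), "line")
})

test_that("molfile charges and isotopes come from M CHG / M ISO", {
  blk <- mk_molblock(data.frame(x = c(0, 1), y = c(0, 0), symbol = c("N", "O")),
                     data.frame(a = 1, b = 2, order = 1))
  blk <- append(blk, c("M  CHG  2   1   1   2  -1", "M  ISO  1   2  18"),
                after = length(blk) - 1L)
  g <- read_molfile(blk)
  expect_equal(g$atoms$charge, c(1L, -1L))
  expect_equal(g$atoms$isotope, c(0L, 18L))
})

test_that("wedge bonds become tetrahedral stereo matching the toolkit oracle", {
  # bromochlorofluoromethane drawn 2D with one wedge; the InChI of the
  # perceived graph must match the InChI of the corresponding SMILES
  blk <- mk_molblock(
    data.frame(x = c(0, 1, 0.5, -1, -0.5), y = c(0, 0, 1, 0.3, -1),
               symbol = c("C", "F", "Cl", "Br", "H")),
    data.frame(a = c(1, 1, 1, 1), b = c(2, 3, 4, 5), order = 1,
               wedge = c(0, 0, 0, 1))
  )
  g <- read_molfile(blk)
  expect_equal(length(g$tet), 1L)
  i_mol <- to_inchi(g, opt_universal)$inchi
  expect_match(i_mol, "/t", fixed = TRUE)
  cand <- c("[C@H](F)(Cl)Br", "[C@@H](F)(Cl)Br")
  i_smi <- vapply(cand, function(s) to_inchi(read_smiles(s), opt_universal)$inchi, "")
  expect_true(i_mol %in% i_smi)
  # and flipping the wedge flips the descriptor
  blk2 <- sub("  1  5  1  1", "  1  5  1  6", blk, fixed = TRUE)
  g2 <- read_molfile(blk2)
  i2 <- to_inchi(g2, opt_universal)$inchi
  expect_false(identical(i2, i_mol))
  expect_true(i2 %in% i_smi)
})

test_that("2D geometry defines double-bond stereo", {
  # trans-1,2-dichloroethene drawn flat
  blk <- mk_molblock(
    data.frame(x = c(0, 1, -0.87, 1.87), y = c(0, 0.5, 0.5, 0),
               symbol = c("C", "C", "Cl", "Cl")),
    data.frame(a = c(1, 1, 2), b = c(2, 3, 4), order = c(2, 1, 1))
  )
  g <- read_molfile(blk)
  expect_equal(length(g$db), 1L)
  i_mol <- to_inchi(g, opt_universal)$inchi
  i_trans <- to_inchi(read_smiles("Cl/C=C/Cl"), opt_universal)$inchi
  expect_identical(i_mol, i_trans)
})

test_that("SDF files split into records", {
  sdf <- c(ethanol_molblock, "$$$$", mk_molblock(
    data.frame(x = 0, y = 0, symbol = "C"),
    data.frame(a = integer(), b = integer(), order = integer()),
    title = "methane"), "$$$$")
  recs <- split_sdf(sdf)
  expect_equal(length(recs), 2L)
  expect_equal(names(recs)[2], "methane")
})

test_that("reading back any written graph preserves the molecule", {
  cases <- c("CC(=O)Oc1ccccc1C(=O)O", "C[C@@H](N)C(=O)O", "F/C=C/C=C/F",
             "C1CC2(CC1)CC2", "c1cc[nH]c1", "[Na+].[Cl-]", "C([2H])([3H])Cl")
  for (s in cases) {
    g <- read_smiles(s)
    g2 <- read_smiles(write_smiles(g))
    expect_identical(to_inchi(g2, opt_universal)$inchi,
                     to_inchi(g, opt_universal)$inchi, label = s)
  }
})
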