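test_that("non-standard InChI and AuxInfo match the reference strings", {
  r <- to_inchi(read_smiles("OCC"), opt_universal)
  expect_identical(r$inchi, "InChI=1/C2H6O/c1-2-3/h3H,2H2,1H3")
  expect_identical(r$auxinfo, "AuxInfo=1/0/N:3,2,1/rA:3OCC/rB:s1;s2;/rC:;;;")

  r <- to_inchi(read_smiles("ClCC(=O)Br"), opt_universal)
  expect_identical(r$inchi, "InChI=1/C2H2BrClO/c3-2(5)1-4/h1H2")

  # FixedH adds the /f layer for the hydrogen-oxalate anion
  r <- to_inchi(read_smiles("C(=O)([O-])C(=O)O"), opt_universal)
  expect_match(r$inchi, "/p-1/fC2HO4/h3H/q-1$")

  # without FixedH the two drawings get different /F-less AuxInfo labels
  r1 <- to_inchi(read_smiles("C(=O)([O-])C(=O)O"), inchi_options())
  r2 <- to_inchi(read_smiles("C(=O)(O)C(=O)[O-]"), inchi_options())
  expect_identical(r1$inchi, r2$inchi)
  expect_false(grepl("/f", r1$inchi, fixed = TRUE))

  # methane: same InChI whatever the options
  expect_identical(to_inchi(read_smiles("C"), opt_universal)$inchi,
                   sub("1S/", "1/", to_inchi(read_smiles("C"), inchi_options())$inchi,
                       fixed = TRUE))
})

test_that("the InChI string is invariant under atom permutation, AuxInfo is not", {
  g <- read_smiles("CC(=O)Oc1ccccc1C(=O)O")
  r0 <- to_inchi(g, opt_universal)
  seen_aux <- character(0)
  for (seed in 1:5) {
    rp <- to_inchi(permute_atoms(g, seed), opt_universal)
    expect_identical(rp$inchi, r0$inchi)
    seen_aux <- union(seen_aux, rp$auxinfo)
  }
  expect_gt(length(seen_aux), 1L)
})

test_that("from_inchi returns the normalised graph in canonical order", {
  r <- to_inchi(read_smiles("OCC"), inchi_options())
  b <- from_inchi(r$inchi)[[1]]
  expect_true(is.na(b$error))
  g2 <- b$graph
  expect_equal(g2$atoms$element, c("C", "C", "O"))
  # regenerating the InChI from the returned graph reproduces the input,
  # and its canonical labels are the identity
  r2 <- to_inchi(g2, inchi_options())
  expect_identical(r2$inchi, r$inchi)
  lab <- extract_labels(parse_auxinfo(r2$auxinfo))
  amap <- r2$atom_map
  ranks <- rep(NA_integer_, mg_natoms(g2))
  ranks[amap[seq_along(lab$rank)]] <- lab$rank
  expect_equal(ranks, seq_len(mg_natoms(g2)))
})

test_that("InChI normalisations are reflected in the reconstructed graph", {
  # ion-pair nitro input comes back with expanded valence N(=O)=O
  r <- to_inchi(read_smiles("c1ccccc1[N+](=O)[O-]"), inchi_options())
  g <- from_inchi(r$inchi)[[1]]$graph
  np <- which(g$atoms$element == "N")
  expect_equal(g$atoms$charge[np], 0L)
  ks <- which(g$bonds$a == np | g$bonds$b == np)
  expect_equal(sort(g$bonds$order[ks]), c(1L, 2L, 2L))
})

test_that("normalisation is idempotent and round-trips fixed points", {
  for (s in c("OCC", "CC(=O)N", "c1ccccc1[N+](=O)[O-]", "C[C@@H](N)C(=O)O")) {
    i1 <- to_inchi(read_smiles(s), inchi_options())$inchi
    g1 <- from_inchi(i1)[[1]]$graph
    i2 <- to_inchi(g1, inchi_options())$inchi
    expect_identical(i2, i1, label = s)
    g2 <- from_inchi(i2)[[1]]$graph
    expect_identical(write_smiles(g2), write_smiles(g1), label = s)
  }
})

test_that("backend failures yield error records, not crashes", {
  b <- from_inchi("InChI=1S/nonsense")[[1]]
  expect_false(is.na(b$error))
  expect_null(b$graph)
})

test_that("backend warnings are surfaced", {
  r <- to_inchi(read_smiles("C(=O)([O-])C(=O)O"), inchi_options())
  expect_true(any(grepl("Proton", r$warnings)))
})
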