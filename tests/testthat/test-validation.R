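test_that("fixture generation is deterministic and spans the required classes", {
  f1 <- make_fixtures(seed = 11)
  f2 <- make_fixtures(seed = 11)
  expect_identical(f1, f2)
  f3 <- make_fixtures(seed = 12)
  expect_false(identical(f1, f3))
  expect_gte(nrow(f1), 200L)
  expect_true("Cl/C=C/I" %in% f1$smiles)          # rule example
  expect_true("I/C=C/Cl" %in% f1$smiles)          # and its reversed variant
  expect_true(any(!is.na(f1$expected_fail)))
  expect_setequal(unique(stats::na.omit(f1$expected_fail)),
                  c("delocalised-charge", "isotope-layer"))
  # a two-component duplicate pair differing only in atom order
  expect_true(any(grepl("-scr$", f1$id)))
  # every fixture parses
  for (s in f1$smiles) expect_s3_class(read_smiles(s), "molgraph")
})

test_that("shuffle test passes trivially for a single atom and for references", {
  r <- shuffle_test("C", n_reps = 5, base_seed = 3)
  expect_true(r$passed)
  expect_equal(r$distinct_outputs, "C")
  for (i in seq_len(nrow(table1_cases))) {
    r <- shuffle_test(table1_cases$smiles[i], n_reps = 10, base_seed = 17)
    expect_true(r$passed, label = table1_cases$smiles[i])
    expect_identical(r$distinct_outputs, table1_cases$universal[i])
  }
})

test_that("the delocalised-charge structure fails with exactly the two known forms", {
  outs <- character(0)
  for (seed in c(1, 100, 4242)) {
    r <- shuffle_test("C[n+]1ccn(C)c1", n_reps = 10, base_seed = seed)
    outs <- union(outs, r$distinct_outputs)
  }
  expect_setequal(outs, c("C[n+]1ccn(C)c1", "Cn1cc[n+](C)c1"))
})

test_that("expected-fail fixtures do fail and would trip if fixed", {
  # full enumeration of atom orders: the isotope-layer class gives exactly
  # two distinct strings (regression tripwire in both directions)
  for (s in c("CC[2H]", "CC[13CH3]")) {
    g <- read_smiles(s)
    P <- all_perms(mg_natoms(g))
    outs <- unique(as.character(universal_smiles(
      lapply(seq_len(nrow(P)), function(r) mg_relabel(g, P[r, ])))))
    expect_equal(length(outs), 2L, label = s)
  }
})

test_that("duplicate test groups byte-identical keys", {
  recs <- data.frame(
    id = c("a1", "a2", "nitro1", "nitro2", "other"),
    smiles = c("C(=O)([O-])C(=O)O", "C(=O)(O)C(=O)[O-]",
               "c1ccccc1[N+](=O)[O-]", "c1ccccc1N(=O)=O", "CCO"),
    stringsAsFactors = FALSE)
  rep_u <- duplicate_test(recs, "universal")
  expect_equal(length(rep_u$groups), 1L)
  expect_setequal(rep_u$groups[[1]], c("a1", "a2"))   # FixedH merges the pair
  rep_i <- duplicate_test(recs, "inchified")
  grps <- lapply(rep_i$groups, sort)
  expect_true(any(vapply(grps, identical, logical(1), c("nitro1", "nitro2"))))
  # the nitro pair is NOT a duplicate under the universal key
  expect_false(any(vapply(rep_u$groups, function(g) "nitro1" %in% g, logical(1))))
  # all-distinct set
  rep0 <- duplicate_test(data.frame(id = c("x", "y"),
                                    smiles = c("CC", "CCO"),
                                    stringsAsFactors = FALSE), "inchi")
  expect_equal(length(rep0$groups), 0L)
})

test_that("inchified duplicate groups contain the InChI duplicate groups", {
  fx <- make_fixtures()
  sub <- fx[fx$class %in% c("table", "normalisation", "acid", "aromatic",
                            "table-scrambled", "aromatic-scrambled",
                            "acid-scrambled"), ]
  rep_inchi <- duplicate_test(sub, "inchi")
  rep_inchd <- duplicate_test(sub, "inchified")
  for (grp in rep_inchi$groups) {
    hit <- any(vapply(rep_inchd$groups, function(g) all(grp %in% g), logical(1)))
    expect_true(hit, label = paste(grp, collapse = "+"))
  }
  # scrambled variants really are detected as duplicates
  expect_true(any(vapply(rep_inchi$groups,
                         function(g) any(grepl("-scr$", g)), logical(1))))
})

test_that("per-rep errors are reported, not thrown", {
  r <- shuffle_test("C", n_reps = 2, base_seed = 1)
  expect_length(r$errors, 0L)
  expect_s3_class(r, "shuffle_report")
})
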