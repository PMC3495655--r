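# AuxInfo strings for the worked examples, as emitted by the InChI software
aux_occ <- "AuxInfo=1/0/N:3,2,1/rA:3OCC/rB:s1;s2;/rC:;;;"
aux_cc <- "AuxInfo=1/0/N:1;2/rA:2CC/rB:;/rC:;;"
aux_clbr <- "AuxInfo=1/0/N:2,3,5,1,4/rA:5ClCCOBr/rB:s1;s2;d3;s3;/rC:;;;;;"
aux_fixedh <- "AuxInfo=1/1/N:1,4,2,3,5,6/E:(1,2)(3,4,5,6)/gE:(1,2)/F:4,1,6,5,2,3/E:(5,6)/rA:6COO-COO/rB:d1;s1;s1;d4;s4;/rC:;;;;;;"
# reconnected-metal example (platinum complex), with a nested /R: record
aux_recmet <- "AuxInfo=1/1/N:1,2,3;7;5;6;4/E:(2,3);;;;/F:5m/E:m;;;;/CRV:;;2*1-1;/rA:7COOPtNNCl/rB:d1;s1;s3;s4;s4;s4;/rC:;;;;;;;/R:/0/N:1,7,5,6,2,3,4/E:(3,4)"

test_that("AuxInfo layers parse into per-component label lists", {
  r <- parse_auxinfo(aux_occ)
  expect_equal(r$n_layer, list(c(3L, 2L, 1L)))
  expect_null(r$f_layer)

  r <- parse_auxinfo(aux_cc)
  expect_equal(r$n_layer, list(1L, 2L))       # two components

  r <- parse_auxinfo(aux_fixedh)
  expect_equal(r$n_layer, list(c(1L, 4L, 2L, 3L, 5L, 6L)))
  expect_equal(r$f_layer, list(c(4L, 1L, 6L, 5L, 2L, 3L)))
})

test_that("nested /R: records and m-abbreviations parse", {
  r <- parse_auxinfo(aux_recmet)
  expect_equal(length(r$n_layer), 5L)
  # /F:5m expands to five components identical to /N
  expect_equal(r$f_layer, r$n_layer)
  expect_false(is.null(r$r_record))
  expect_equal(r$r_record$n_layer, list(c(1L, 7L, 5L, 6L, 2L, 3L, 4L)))
  expect_null(r$r_record$f_layer)
})

test_that("parse errors are informative", {
  expect_error(parse_auxinfo("InChI=1S/CH4"), "not an AuxInfo")
  expect_error(parse_auxinfo("AuxInfo=1/0/9Q:1,2"), "unrecognised AuxInfo layer")
})

test_that("parse -> serialize -> parse round-trips", {
  for (a in c(aux_occ, aux_cc, aux_clbr, aux_fixedh, aux_recmet)) {
    r <- parse_auxinfo(a)
    expect_identical(serialize_auxinfo(r), a)
    r2 <- parse_auxinfo(serialize_auxinfo(r))
    expect_equal(r2$n_layer, r$n_layer)
    expect_equal(r2$f_layer, r$f_layer)
  }
})

test_that("label extraction follows the layer preference", {
  lab <- extract_labels(parse_auxinfo(aux_clbr))
  # canonical labels 1..5 correspond to input atoms 2, 3, 5, 1 and 4
  expect_equal(lab$rank, c(4L, 1L, 2L, 5L, 3L))
  expect_equal(lab$rank[5], 3L)   # canonical label 3 is input atom 5, the Br
  expect_equal(lab$source, "N")

  lab <- extract_labels(parse_auxinfo(aux_fixedh))
  expect_equal(lab$source, "F")
  expect_equal(lab$rank, c(2L, 5L, 6L, 1L, 4L, 3L))

  # a record with both /N and /F extracts exactly as an /F-only record
  both <- parse_auxinfo("AuxInfo=1/1/N:1,4,2,3,5,6/F:4,1,6,5,2,3/rA:6COOCOO/rB:;/rC:;")
  fonly <- parse_auxinfo("AuxInfo=1/1/F:4,1,6,5,2,3/rA:6COOCOO/rB:;/rC:;")
  expect_equal(extract_labels(both)$rank, extract_labels(fonly)$rank)

  # nested /R: wins over the top-level layers
  lab <- extract_labels(parse_auxinfo(aux_recmet))
  expect_equal(lab$source, "R_N")
  expect_equal(which(lab$rank == 1L), 1L)
  expect_equal(which(lab$rank == 2L), 7L)

  # trivial single atom
  lab <- extract_labels(parse_auxinfo("AuxInfo=1/0/N:1/rA:1C/rB:/rC:;"))
  expect_equal(lab$rank, 1L)
})

test_that("component offsets make labels globally unique and contiguous", {
  # C.CC: /N:2,3;1 -> ethane atoms labelled 1,2; methane atom labelled 3
  lab <- extract_labels(parse_auxinfo("AuxInfo=1/0/N:2,3;1/E:(1,2);/rA:3CCC/rB:;s2;/rC:;;;"))
  expect_equal(lab$rank, c(3L, 1L, 2L))
})

test_that("extraction is a bijection onto 1..n for every fixture", {
  fx <- make_fixtures()
  fx <- fx[!grepl("-scr$", fx$id), ]
  gs <- lapply(fx$smiles, read_smiles)
  res <- to_inchi(gs, opt_universal)
  for (i in seq_along(gs)) {
    r <- res[[i]]
    if (!is.na(r$error) || is.na(r$auxinfo)) next
    lab <- tryCatch(extract_labels(parse_auxinfo(r$auxinfo)),
                    error = function(e) NULL)
    if (is.null(lab)) next                     # e.g. bare proton: no /N layer
    rk <- lab$rank[!is.na(lab$rank)]
    expect_equal(sort(rk), seq_along(rk), label = fx$id[i])
  }
})

test_that("non-permutation label lists are rejected", {
  expect_error(extract_labels(parse_auxinfo("AuxInfo=1/0/N:1,1,2/rA:3CCC/rB:;/rC:;")),
               "not a permutation")
})

test_that("hydrogen ordering keys slot unlabelled hydrogens below all labels", {
  g <- read_smiles("C([2H])([3H])Cl")
  ranks <- c(1, NA, NA, 2)
  keys <- hydrogen_order_keys(g, ranks)
  expect_equal(keys[1], 1)
  expect_equal(keys[4], 2)
  expect_lt(keys[2], keys[3])     # deuterium before tritium
  expect_lt(keys[3], min(keys[c(1, 4)]))
  # unchanged when there are no explicit hydrogens
  g2 <- read_smiles("CCO")
  expect_equal(hydrogen_order_keys(g2, c(3, 2, 1)), c(3, 2, 1))
  # a bridging hydrogen must carry an InChI label
  gb <- molgraph(
    data.frame(element = c("B", "H", "B"), isotope = 0L, charge = 0L,
               hcount = c(2L, 0L, 2L), aromatic = FALSE),
    data.frame(a = c(1, 2), b = c(2, 3), order = 1L, aromatic = FALSE))
  expect_error(hydrogen_order_keys(gb, c(1, NA, 2)), "bridging hydrogen")
})
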