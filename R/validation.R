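#' @title Order-invariance (shuffle) and duplicate tests
#' @description
#' A canonical identifier must be invariant to the order in which atoms are
#' presented.  The shuffle test probes this directly: for each structure,
#' several "anti-canonical" SMILES strings (written under seeded random
#' labels) are re-read and re-canonicalised; the structure passes when every
#' repetition yields one identical string.  The duplicate test groups
#' records by byte-identical keys (InChI, Universal or Inchified SMILES) to
#' expose either true duplicates or normalisation effects.
#' @name validation
NULL

#' Shuffle test for one structure
#'
#' For each repetition `i`, the atoms are permuted with seed
#' `base_seed + i`, an anti-canonical SMILES is written with the same seed,
#' re-read, and canonicalised in the requested mode.  The structure passes
#' when all repetitions produce a single identical string and none errors.
#'
#' @param x a SMILES string or [molgraph()]
#' @param n_reps number of repetitions (default 10)
#' @param mode `"universal"` or `"inchified"`
#' @param base_seed integer seed
#' @param record_id identifier used in the report
#' @return a list of class `shuffle_report`: `record_id`, `n_reps`, `mode`,
#'   `distinct_outputs`, `passed`, `errors`
#' @export
shuffle_test <- function(x, n_reps = 10L, mode = c("universal", "inchified"),
                         base_seed = 1L, record_id = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_reps >= 1L)
  if (is.null(record_id))
    record_id <- if (is.character(x)) x else "molgraph"
  g <- if (inherits(x, "molgraph")) x else read_smiles(x)
  rep_graphs <- vector("list", n_reps)
  errs <- character(0)
  for (i in seq_len(n_reps)) {
    rep_graphs[[i]] <- tryCatch({
      gi <- permute_atoms(g, base_seed + i)
      anti <- anticanonical_smiles(list(gi), seed = base_seed + i)
      read_smiles(anti)
    }, error = function(e) conditionMessage(e))
  }
  bad <- vapply(rep_graphs, is.character, logical(1))
  errs <- c(errs, unlist(rep_graphs[bad]))
  outs <- character(0)
  if (any(!bad)) {
    o <- generate_smiles(rep_graphs[!bad], mode)
    oe <- attr(o, "errors")
    if (!is.null(oe) && nrow(oe)) errs <- c(errs, oe$message)
    outs <- o[!is.na(o)]
  }
  distinct <- unique(outs)
  structure(list(record_id = record_id, n_reps = n_reps, mode = mode,
                 distinct_outputs = distinct,
                 passed = length(errs) == 0L && length(distinct) == 1L,
                 errors = errs),
            class = "shuffle_report")
}

#' @export
print.shuffle_report <- function(x, ...) {
  cat(sprintf("<shuffle_report> %s [%s]: %s (%d distinct over %d reps%s)\n",
              x$record_id, x$mode, if (x$passed) "PASS" else "FAIL",
              length(x$distinct_outputs), x$n_reps,
              if (length(x$errors)) sprintf(", %d error(s)", length(x$errors)) else ""))
  invisible(x)
}

#' Shuffle test over a set of records
#'
#' Vectorised version of [shuffle_test()]: backend calls are batched per
#' repetition, so a whole fixture set runs in a handful of `obabel`
#' invocations.
#'
#' @param records data.frame with columns `id` and `smiles`
#' @param n_reps repetitions per record
#' @param mode `"universal"` or `"inchified"`
#' @param base_seed integer seed
#' @return data.frame with columns `id`, `passed`, `n_distinct`, `n_errors`;
#'   attribute `outputs` holds the per-record distinct output sets
#' @export
shuffle_suite <- function(records, n_reps = 10L,
                          mode = c("universal", "inchified"), base_seed = 1L) {
  mode <- match.arg(mode)
  nr <- nrow(records)
  base <- lapply(records$smiles, function(s)
    tryCatch(read_smiles(s), error = function(e) conditionMessage(e)))
  outs <- vector("list", nr)
  errs <- integer(nr)
  for (j in seq_len(nr)) outs[[j]] <- character(0)
  for (i in seq_len(n_reps)) {
    graphs <- vector("list", nr)
    for (j in seq_len(nr)) {
      if (is.character(base[[j]])) { errs[j] <- errs[j] + 1L; next }
      graphs[[j]] <- tryCatch({
        gi <- permute_atoms(base[[j]], base_seed + i)
        anti <- anticanonical_smiles(list(gi), seed = base_seed + i)
        read_smiles(anti)
      }, error = function(e) NULL)
      if (is.null(graphs[[j]])) errs[j] <- errs[j] + 1L
    }
    ok <- which(!vapply(graphs, is.null, logical(1)))
    if (length(ok)) {
      o <- generate_smiles(graphs[ok], mode)
      for (t in seq_along(ok)) {
        j <- ok[t]
        if (is.na(o[t])) errs[j] <- errs[j] + 1L
        else outs[[j]] <- union(outs[[j]], o[t])
      }
    }
  }
  res <- data.frame(id = records$id,
                    passed = vapply(seq_len(nr), function(j)
                      errs[j] == 0L && length(outs[[j]]) == 1L, logical(1)),
                    n_distinct = lengths(outs),
                    n_errors = errs,
                    stringsAsFactors = FALSE)
  attr(res, "outputs") <- stats::setNames(outs, records$id)
  res
}

#' Exhaustive order-invariance check
#'
#' Enumerates *every* atom ordering of a small molecule and collects the
#' distinct Universal SMILES strings they generate; a canonical method must
#' return exactly one.  Orderings that serialise to the same input string,
#' and label assignments that coincide, are deduplicated before writing, so
#' molecules with symmetry cost far less than n! full pipeline runs.
#'
#' @param x a SMILES string or [molgraph()]
#' @param max_atoms refuse molecules above this size (n! blow-up guard)
#' @return character vector of distinct Universal SMILES strings
#' @export
exhaustive_shuffle <- function(x, max_atoms = 8L) {
  g <- if (inherits(x, "molgraph")) x else read_smiles(x)
  n <- mg_natoms(g)
  if (n > max_atoms)
    stop(sprintf("molecule has %d atoms; enumeration is capped at %d", n, max_atoms))
  if (n <= 1L) return(as.character(universal_smiles(list(g))))
  perms <- .all_permutations(n)
  np <- nrow(perms)
  smis <- character(np)
  maps <- vector("list", np)
  for (r in seq_len(np)) {
    s <- write_smiles(g, ranks = perms[r, ], kekule = TRUE)
    smis[r] <- s
    maps[[r]] <- attr(s, "atom_order")
  }
  uq <- which(!duplicated(smis))
  res <- .inchi_from_smiles(smis[uq], inchi_options(fixed_h = TRUE, rec_met = TRUE))
  rank_keys <- character(0)
  outs <- character(0)
  for (t in seq_along(uq)) {
    r <- uq[t]
    rr <- res[[t]]
    if (!is.na(rr$error)) {
      outs <- union(outs, NA_character_)
      next
    }
    rr$atom_map <- maps[[r]]
    ranks <- .graph_ranks(g, rr)
    key <- paste(ranks, collapse = ",")
    if (key %in% rank_keys) next
    rank_keys <- c(rank_keys, key)
    outs <- union(outs, as.character(write_smiles(g, ranks)))
  }
  outs
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

#' Duplicate test
#'
#' Groups records whose canonical key is byte-identical.  Keys are exact
#' strings; no chemical fuzzy matching is performed.
#'
#' @param records data.frame with columns `id` and `smiles`
#' @param key_kind `"inchi"` (Standard InChI), `"universal"` or
#'   `"inchified"`
#' @return a list of class `duplicate_report`: `key_kind`, `groups` (named
#'   list, key -> ids, only groups of two or more), `n_errors`, `keys`
#' @export
duplicate_test <- function(records, key_kind = c("inchi", "universal", "inchified")) {
  key_kind <- match.arg(key_kind)
  gs <- lapply(records$smiles, function(s)
    tryCatch(read_smiles(s), error = function(e) NULL))
  ok <- !vapply(gs, is.null, logical(1))
  keys <- rep(NA_character_, nrow(records))
  if (any(ok)) {
    if (key_kind == "inchi") {
      res <- to_inchi(gs[ok], inchi_options())
      keys[ok] <- vapply(res, function(r) if (is.na(r$error)) r$inchi else NA_character_, "")
    } else {
      keys[ok] <- generate_smiles(gs[ok], key_kind)
    }
  }
  valid <- !is.na(keys)
  grp <- split(records$id[valid], keys[valid])
  grp <- grp[lengths(grp) >= 2L]
  structure(list(key_kind = key_kind, groups = grp,
                 n_errors = sum(!valid),
                 keys = stats::setNames(keys, records$id)),
            class = "duplicate_report")
}

#' @export
print.duplicate_report <- function(x, ...) {
  cat(sprintf("<duplicate_report> key=%s: %d group(s), %d record error(s)\n",
              x$key_kind, length(x$groups), x$n_errors))
  invisible(x)
}

#' Built-in fixture set
#'
#' A deterministic set of roughly 200 structures standing in, at desk
#' scale, for a structure database: the worked examples from the method's
#' derivation (simple chains, hydrogen handling, fixed-hydrogen salts),
#' cis/trans and tetrahedral stereochemistry in chains and rings,
#' isotopes, multi-component salts, fused/spiro ring systems exercising
#' ring-closure digit reuse, symmetric acids and anions exercising the
#' carbonyl start-atom rule, aromatic heterocycles, a sample of drug-like
#' molecules, plus scrambled-order duplicates generated with the given
#' seed.  Structures of the two known non-canonical classes are tagged
#' `expected_fail` (`"delocalised-charge"`: graph symmetry broken only by a
#' charge; `"isotope-layer"`: symmetry broken only by a hydrogen isotope,
#' unsupported pending an upstream fix in the isotopic-label section).
#'
#' @param seed seed for the scrambled-duplicate variants
#' @return data.frame with columns `id`, `smiles`, `class`, `expected_fail`
#'   (`NA` or the failure class)
#' @export
make_fixtures <- function(seed = 42L) {
  base <- list(
    # worked examples: simple chains and hydrogen handling
    c("t1-occ", "OCC", "table"),
    c("t1-clbr", "ClCC(=O)Br", "table"),
    c("t1-cc", "C.C", "table"),
    c("t1-ccc", "C.CC", "table"),
    c("t1-hexpl", "C([H])C", "table"),
    c("t1-d", "C([2H])O", "table"),
    c("t2-a", "C(=O)([O-])C(=O)O", "table"),
    c("t2-b", "C(=O)(O)C(=O)[O-]", "table"),
    # rule illustrations
    c("rule-d", "C([2H])([3H])Cl", "stereo"),
    c("rule-g", "Cl/C=C(\\Br)/I", "stereo"),
    c("rule-h", "Cl/C=C/I", "stereo"),
    c("rule-h-rev", "I/C=C/Cl", "stereo"),
    c("rule-i", "C/C=C\\1/NC1", "stereo"),
    # cis/trans chains and conjugation
    c("db-cis", "C/C=C\\C", "stereo"),
    c("db-trans", "C/C=C/C", "stereo"),
    c("db-f", "F/C=C/F", "stereo"),
    c("db-diene", "F/C=C/C=C/F", "stereo"),
    c("db-diene2", "C/C=C\\C=C\\C", "stereo"),
    c("db-triene", "C/C=C/C=C/C=C/C", "stereo"),
    c("db-trisub", "C/C(Cl)=C(\\Br)F", "stereo"),
    c("db-n", "C/C=N/O", "stereo"),
    c("db-ring8", "C1CCC/C=C/CC1", "stereo"),
    c("db-ring9", "C1CCCC/C=C/CC1", "stereo"),
    # tetrahedral stereo
    c("tet-ala-l", "C[C@@H](N)C(=O)O", "stereo"),
    c("tet-ala-d", "C[C@H](N)C(=O)O", "stereo"),
    c("tet-bcf", "[C@H](F)(Cl)Br", "stereo"),
    c("tet-quart", "N[C@](C)(F)C(=O)O", "stereo"),
    c("tet-thr", "C[C@@H](O)[C@@H](N)C(=O)O", "stereo"),
    c("tet-ring", "C[C@H]1CC[C@@H](C)CC1", "stereo"),
    c("tet-nicotine", "CN1CCC[C@H]1c1cccnc1", "stereo"),
    c("tet-h-start", "[C@@H](N)(C)O", "stereo"),
    c("tet-deep", "CC[C@H](C)[C@@H](C)CC", "stereo"),
    # isotopes (asymmetric environments: canonical)
    c("iso-meod", "[2H]OC", "isotope"),
    c("iso-13c", "[13CH4]", "isotope"),
    c("iso-d2o", "[2H]O[2H]", "isotope"),
    c("iso-cdcl3", "[2H]C(Cl)(Cl)Cl", "isotope"),
    c("iso-t", "[3H]OC(=O)C", "isotope"),
    # hydrogen species
    c("h-h2", "[H][H]", "hydrogen"),
    c("h-proton", "[H+]", "hydrogen"),
    c("h-hydride", "[H-]", "hydrogen"),
    # salts and multi-component
    c("salt-nacl", "[Na+].[Cl-]", "salt"),
    c("salt-naoac", "CC(=O)[O-].[Na+]", "salt"),
    c("salt-double", "[Mg+2].[Cl-].[Cl-]", "salt"),
    c("salt-ammonium", "[NH4+].[O-]S(=O)(=O)[O-].[NH4+]", "salt"),
    c("multi-mix", "CCO.OCC.O", "salt"),
    c("multi-sym", "C1CCCCC1.C1CCCCC1", "salt"),
    # symmetric acids / anions (start-atom rule)
    c("sym-acetate", "CC(=O)[O-]", "acid"),
    c("sym-formate", "[O-]C=O", "acid"),
    c("sym-oxalate", "[O-]C(=O)C(=O)[O-]", "acid"),
    c("sym-carbonate", "[O-]C([O-])=O", "acid"),
    c("sym-sulfonate", "CS(=O)(=O)[O-]", "acid"),
    c("sym-phosphate", "OP(=O)(O)O", "acid"),
    c("sym-nitrate", "[O-][N+](=O)O", "acid"),
    c("sym-malonate", "[O-]C(=O)CC(=O)[O-]", "acid"),
    # rings: fusion, spiro, bridges, digit reuse
    c("ring-cyclopropane", "C1CC1", "ring"),
    c("ring-cyclohexene", "C1=CCCCC1", "ring"),
    c("ring-decalin", "C1CCC2CCCCC2C1", "ring"),
    c("ring-spiro", "C1CC2(CC1)CC2", "ring"),
    c("ring-spiro55", "C1CCC2(C1)CCCC2", "ring"),
    c("ring-bicyclo222", "C1CC2CCC1CC2", "ring"),
    c("ring-norbornane", "C1CC2CC1CC2", "ring"),
    c("ring-adamantane", "C1C2CC3CC1CC(C2)C3", "ring"),
    c("ring-cubane", "C12C3C4C1C5C2C3C45", "ring"),
    c("ring-fused3", "C1CC2CC3CCCC3CC2C1", "ring"),
    c("ring-propellane", "C1CC2(CC1)CCC1(CC2)CC1", "ring"),
    c("ring-macro", "C1CCCCCCCCCCC1", "ring"),
    # aromatics and heteroaromatics
    c("ar-benzene", "c1ccccc1", "aromatic"),
    c("ar-kekule", "C1=CC=CC=C1", "aromatic"),
    c("ar-toluene", "Cc1ccccc1", "aromatic"),
    c("ar-naphthalene", "c1ccc2ccccc2c1", "aromatic"),
    c("ar-anthracene", "c1ccc2cc3ccccc3cc2c1", "aromatic"),
    c("ar-biphenyl", "c1ccccc1-c1ccccc1", "aromatic"),
    c("ar-styrene", "C=Cc1ccccc1", "aromatic"),
    c("ar-pyridine", "c1ccncc1", "aromatic"),
    c("ar-pyrrole", "c1cc[nH]c1", "aromatic"),
    c("ar-furan", "c1ccoc1", "aromatic"),
    c("ar-thiophene", "c1ccsc1", "aromatic"),
    c("ar-imidazole", "c1c[nH]cn1", "aromatic"),
    c("ar-pyrazole", "c1cc[nH]n1", "aromatic"),
    c("ar-oxazole", "c1cnco1", "aromatic"),
    c("ar-pyrimidine", "c1cncnc1", "aromatic"),
    c("ar-quinoline", "c1ccc2ncccc2c1", "aromatic"),
    c("ar-indole", "c1ccc2[nH]ccc2c1", "aromatic"),
    c("ar-pyridinium", "C[n+]1ccccc1", "aromatic"),
    c("ar-phenol", "Oc1ccccc1", "aromatic"),
    c("ar-aniline", "Nc1ccccc1", "aromatic"),
    c("ar-benzoate", "[O-]C(=O)c1ccccc1", "aromatic"),
    c("ar-fluorobenzene", "Fc1ccccc1", "aromatic"),
    c("ar-xylene", "Cc1ccccc1C", "aromatic"),
    c("ar-mesitylene", "Cc1cc(C)cc(C)c1", "aromatic"),
    # normalisation probes (universal != inchified)
    c("norm-nitro", "c1cc(/C=C/F)cc(c1)[N+](=O)[O-]", "normalisation"),
    c("norm-nitro2", "c1cc(/C=C/F)cc(c1)N(=O)=O", "normalisation"),
    c("norm-nitromethane", "C[N+](=O)[O-]", "normalisation"),
    c("norm-sulfoxide", "C[S+](C)[O-]", "normalisation"),
    c("norm-sulfoxide2", "CS(C)=O", "normalisation"),
    c("norm-amide", "CC(=O)N", "normalisation"),
    c("norm-imidic", "CC(O)=N", "normalisation"),
    c("norm-amide2", "CC(=O)NC", "normalisation"),
    # charged species
    c("chg-ammonium", "[NH4+]", "charge"),
    c("chg-tma", "C[N+](C)(C)C", "charge"),
    c("chg-carbanion", "[CH3-]", "charge"),
    c("chg-hydroxide", "[OH-]", "charge"),
    c("chg-hydronium", "[OH3+]", "charge"),
    c("chg-betaine", "C[N+](C)(C)CC(=O)[O-]", "charge"),
    # small drug-like molecules
    c("drug-aspirin", "CC(=O)Oc1ccccc1C(=O)O", "drug"),
    c("drug-paracetamol", "CC(=O)Nc1ccc(O)cc1", "drug"),
    c("drug-caffeine", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "drug"),
    c("drug-ibuprofen", "CC(C)Cc1ccc(cc1)[C@@H](C)C(=O)O", "drug"),
    c("drug-nicotinamide", "NC(=O)c1cccnc1", "drug"),
    c("drug-benzocaine", "CCOC(=O)c1ccc(N)cc1", "drug"),
    c("drug-salicylate", "OC(=O)c1ccccc1O", "drug"),
    c("drug-glucose", "OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O", "drug"),
    c("drug-citrate", "OC(=O)CC(O)(CC(=O)O)C(=O)O", "drug"),
    c("drug-glycine", "NCC(=O)O", "drug"),
    c("drug-serine", "OC[C@@H](N)C(=O)O", "drug"),
    c("drug-cysteine", "SC[C@@H](N)C(=O)O", "drug"),
    c("drug-proline", "O=C(O)[C@@H]1CCCN1", "drug"),
    c("drug-phenylalanine", "N[C@@H](Cc1ccccc1)C(=O)O", "drug"),
    c("drug-tryptophan", "N[C@@H](Cc1c[nH]c2ccccc12)C(=O)O", "drug"),
    c("drug-histidine", "N[C@@H](Cc1c[nH]cn1)C(=O)O", "drug"),
    c("drug-sorbate", "C/C=C/C=C/C(=O)O", "drug"),
    c("drug-fumarate", "OC(=O)/C=C/C(=O)O", "drug"),
    c("drug-maleate", "OC(=O)/C=C\\C(=O)O", "drug"),
    c("drug-retinoidish", "CC(=CC=O)/C=C/C", "drug"),
    c("drug-menthol", "CC1CCC(C(C)C)C(O)C1", "drug"),
    c("drug-camphorish", "CC1(C)C2CCC1(C)C(=O)C2", "drug"),
    c("drug-gaba", "NCCCC(=O)O", "drug"),
    c("drug-urea", "NC(=O)N", "drug"),
    c("drug-taurine", "NCCS(=O)(=O)O", "drug"),
    c("drug-lactide", "C[C@H]1OC(=O)[C@H](C)OC1=O", "drug"),
    # assorted functional groups
    c("fg-nitrile", "CC#N", "functional"),
    c("fg-alkyne", "C#CC", "functional"),
    c("fg-allene", "C=C=C", "functional"),
    c("fg-isocyanate", "CN=C=O", "functional"),
    c("fg-azide", "CCN=[N+]=[N-]", "functional"),
    c("fg-thiol", "CCS", "functional"),
    c("fg-disulfide", "CSSC", "functional"),
    c("fg-ether", "CCOCC", "functional"),
    c("fg-ester", "CCOC(C)=O", "functional"),
    c("fg-ketone", "CC(=O)CC", "functional"),
    c("fg-aldehyde", "CCC=O", "functional"),
    c("fg-epoxide", "CC1CO1", "functional"),
    c("fg-boronic", "OB(O)c1ccccc1", "functional"),
    c("fg-phosphine", "CP(C)C", "functional"),
    c("fg-phosphonate", "CP(=O)(OC)OC", "functional"),
    c("fg-silane-free", "C[Si](C)(C)C", "functional"),
    c("fg-bromoform", "BrC(Br)Br", "functional"),
    c("fg-freon", "FC(F)(Cl)Cl", "functional"),
    c("fg-perfluoro", "FC(F)(F)C(F)(F)F", "functional"),
    c("fg-guanidinium", "NC(=[NH2+])N", "functional"),
    # expected-fail: delocalised charge (charge-only symmetry breaking)
    c("chg-amidinium", "CC(N)=[NH2+]", "charge"),
    c("xf-chembl1229272", "C[n+]1ccn(C)c1", "delocalised", "delocalised-charge"),
    # expected-fail: isotope-only symmetry breaking (isotopic label layer)
    c("xf-ethane-d", "CC[2H]", "isotope-sym", "isotope-layer"),
    c("xf-propane-13c", "CC[13CH3]", "isotope-sym", "isotope-layer")
  )
  df <- data.frame(
    id = vapply(base, `[[`, "", 1),
    smiles = vapply(base, `[[`, "", 2),
    class = vapply(base, `[[`, "", 3),
    expected_fail = vapply(base, function(x)
      if (length(x) >= 4L) x[[4]] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
  # scrambled-order duplicate variants of canonical fixtures: same molecule,
  # different atom order / SMILES spelling
  scramble_of <- df$id[df$class %in% c("table", "stereo", "ring", "aromatic",
                                       "drug", "acid", "salt")]
  scramble_of <- scramble_of[!duplicated(df$smiles[match(scramble_of, df$id)])]
  extra <- lapply(seq_along(scramble_of), function(t) {
    id <- scramble_of[t]
    s <- df$smiles[df$id == id]
    g <- permute_atoms(read_smiles(s), seed + t)
    c(paste0(id, "-scr"), anticanonical_smiles(list(g), seed = seed + t),
      paste0(df$class[df$id == id], "-scrambled"),
      df$expected_fail[df$id == id])
  })
  df2 <- data.frame(
    id = vapply(extra, `[[`, "", 1),
    smiles = vapply(extra, `[[`, "", 2),
    class = vapply(extra, `[[`, "", 3),
    expected_fail = vapply(extra, function(x)
      if (!is.na(x[[4]])) x[[4]] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
  out <- rbind(df, df2)
  rownames(out) <- NULL
  out
}
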