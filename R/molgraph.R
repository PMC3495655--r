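#' @title Molecular graph objects
#' @description
#' A `molgraph` is the package's internal molecular data model: a set of
#' atoms, a set of bonds (with Kekule bond orders), and explicit stereo
#' descriptors for tetrahedral centres and double bonds.  Aromaticity is a
#' perceived annotation on top of the Kekule structure (see
#' [perceive_aromaticity()]); a valid Kekule assignment is always retained.
#'
#' Atom indices are 1-based; all external numberings (AuxInfo layers, molfile
#' atom blocks) are converted at the I/O boundary.
#'
#' @name molgraph
NULL

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ELEMENTS <- c("B", "C", "N", "O", "P", "S")

ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U"
)

#' Construct a molecular graph
#'
#' Low-level constructor; readers ([read_smiles()], [read_molfile()]) are the
#' usual entry points.
#'
#' @param atoms data.frame with columns `element` (chr), `isotope` (int, 0 =
#'   natural abundance), `charge` (int), `hcount` (int, implicit hydrogens),
#'   `aromatic` (lgl).
#' @param bonds data.frame with columns `a`, `b` (atom indices), `order`
#'   (1, 2 or 3) and `aromatic` (lgl).
#' @param tet list of tetrahedral stereo descriptors, each a list with
#'   `center` (atom index), `nbrs` (integer(4); 0 is the implicit-hydrogen
#'   placeholder) and `winding` (`"acw"` or `"cw"`: looking from the first
#'   neighbour, the remaining three wind anticlockwise/clockwise).
#' @param db list of double-bond stereo descriptors, each a list with `a`,
#'   `b` (the double-bond atoms), `ref_a`, `ref_b` (one substituent at each
#'   end) and `config` (`"together"` if the references are cis, `"opposite"`
#'   if trans).
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds, tet = list(), db = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(bonds) == 0L) {
    bonds <- data.frame(a = integer(), b = integer(), order = integer(),
                        aromatic = logical())
  }
  g <- structure(list(atoms = atoms, bonds = bonds, tet = tet, db = db),
                 class = "molgraph")
  mg_validate(g)
  g
}

mg_validate <- function(g) {
  at <- g$atoms; bd <- g$bonds
  n <- nrow(at)
  bad <- setdiff(at$element, ELEMENTS)
  if (length(bad)) stop("unknown element symbol: ", paste(bad, collapse = ", "))
  if (any(at$hcount < 0L)) stop("negative implicit hydrogen count")
  if (nrow(bd)) {
    if (any(bd$a == bd$b)) stop("bond with identical endpoints")
    if (any(bd$a < 1L | bd$a > n | bd$b < 1L | bd$b > n))
      stop("bond references a non-existent atom")
    key <- paste(pmin(bd$a, bd$b), pmax(bd$a, bd$b))
    if (anyDuplicated(key)) stop("duplicate bond between an atom pair")
    if (!all(bd$order %in% 1:3)) stop("bond order must be 1, 2 or 3")
  }
  for (t in g$tet) {
    if (length(t$nbrs) != 4L) stop("tetrahedral centre must list 4 neighbours")
    nb <- t$nbrs[t$nbrs != 0L]
    if (anyDuplicated(t$nbrs[t$nbrs != 0L]) || sum(t$nbrs == 0L) > 1L)
      stop("tetrahedral neighbours must be distinct")
    for (x in nb) if (is.na(mg_bond_between(g, t$center, x)))
      stop("tetrahedral neighbour not bonded to centre")
  }
  for (d in g$db) {
    bi <- mg_bond_between(g, d$a, d$b)
    if (is.na(bi) || g$bonds$order[bi] != 2L)
      stop("double-bond stereo must sit on an order-2 bond")
    for (side in list(c(d$ref_a, d$a), c(d$ref_b, d$b))) {
      ri <- mg_bond_between(g, side[1], side[2])
      if (is.na(ri) || g$bonds$order[ri] != 1L)
        stop("double-bond stereo reference must be single-bonded to the bond end")
    }
  }
  invisible(g)
}

#' Number of atoms in a molecular graph
#' @param g a `molgraph`
#' @return integer
#' @export
mg_natoms <- function(g) nrow(g$atoms)

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d atoms, %d bonds, %d tetrahedral, %d double-bond stereo\n",
              nrow(x$atoms), nrow(x$bonds), length(x$tet), length(x$db)))
  invisible(x)
}

# bond index between two atoms, NA if absent
mg_bond_between <- function(g, i, j) {
  bd <- g$bonds
  w <- which((bd$a == i & bd$b == j) | (bd$a == j & bd$b == i))
  if (length(w)) w[1] else NA_integer_
}

# adjacency: list over atoms of data.frame(nbr, bond)
mg_adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- rep(list(list(nbr = integer(), bond = integer())), n)
  bd <- g$bonds
  if (nrow(bd)) {
    for (k in seq_len(nrow(bd))) {
      a <- bd$a[k]; b <- bd$b[k]
      adj[[a]]$nbr <- c(adj[[a]]$nbr, b); adj[[a]]$bond <- c(adj[[a]]$bond, k)
      adj[[b]]$nbr <- c(adj[[b]]$nbr, a); adj[[b]]$bond <- c(adj[[b]]$bond, k)
    }
  }
  adj
}

#' Connected components of a molecular graph
#'
#' @param g a `molgraph`
#' @return integer vector mapping each atom to a component id (1-based, in
#'   order of first appearance by atom index).
#' @export
mg_components <- function(g) {
  n <- nrow(g$atoms)
  comp <- integer(n)
  adj <- mg_adjacency(g)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]$nbr) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

# degree including implicit hydrogens
mg_total_degree <- function(g) {
  deg <- integer(nrow(g$atoms))
  if (nrow(g$bonds)) {
    tb <- table(factor(c(g$bonds$a, g$bonds$b), levels = seq_len(nrow(g$atoms))))
    deg <- as.integer(tb)
  }
  deg + g$atoms$hcount
}

# explicit (graph) degree
mg_degree <- function(g) {
  if (!nrow(g$bonds)) return(integer(nrow(g$atoms)))
  as.integer(table(factor(c(g$bonds$a, g$bonds$b), levels = seq_len(nrow(g$atoms)))))
}

#' Relabel the atoms of a graph
#'
#' Applies a permutation to the atom indices: atom `i` of the input becomes
#' atom `perm[i]` of the output.  All bonds and stereo descriptors are
#' remapped; the chemistry (and hence the InChI) is unchanged.
#'
#' @param g a `molgraph`
#' @param perm integer permutation of `seq_len(mg_natoms(g))`
#' @return the relabelled `molgraph`
#' @export
mg_relabel <- function(g, perm) {
  n <- nrow(g$atoms)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- integer(n); inv[perm] <- seq_len(n)
  atoms <- g$atoms[inv, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- g$bonds
  if (nrow(bonds)) {
    bonds$a <- perm[bonds$a]; bonds$b <- perm[bonds$b]
    sw <- bonds$a > bonds$b
    tmp <- bonds$a[sw]; bonds$a[sw] <- bonds$b[sw]; bonds$b[sw] <- tmp
    bonds <- bonds[order(bonds$a, bonds$b), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  tet <- lapply(g$tet, function(t) {
    t$center <- perm[t$center]
    t$nbrs <- ifelse(t$nbrs == 0L, 0L, perm[pmax(t$nbrs, 1L)])
    t
  })
  db <- lapply(g$db, function(d) {
    d$a <- perm[d$a]; d$b <- perm[d$b]
    d$ref_a <- perm[d$ref_a]; d$ref_b <- perm[d$ref_b]
    d
  })
  structure(list(atoms = atoms, bonds = bonds, tet = tet, db = db),
            class = "molgraph")
}

#' Randomly permute the atom order of a graph
#'
#' Produces a graph isomorphic to the input with its atoms in a seeded
#' pseudo-random order.  Stereo descriptors are remapped so the chemistry is
#' unchanged; the same seed always yields the same permutation.  This is the
#' structure scrambler used by the shuffle test.
#'
#' @param g a `molgraph`
#' @param seed integer seed
#' @return a permuted `molgraph`
#' @export
permute_atoms <- function(g, seed) {
  n <- nrow(g$atoms)
  if (n <= 1L) return(g)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  mg_relabel(g, perm)
}

# smallest standard valence >= bondsum for implicit-H filling; NA when the
# element is outside the table (such atoms get hcount 0)
.default_valences <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L
)

implicit_h_for <- function(element, charge, bondsum) {
  vals <- .default_valences[[element]]
  if (is.null(vals)) return(0L)
  if (charge != 0L) {
    # isoelectronic shift: cationic N/P behave like C (valence 4) etc.
    if (element %in% c("N", "P")) {
      vals <- if (charge > 0L) vals + 1L else vals - 1L
    } else if (element %in% c("O", "S")) {
      vals <- if (charge > 0L) vals + 1L else pmax(vals - 1L, 0L)
    } else if (element == "C") {
      vals <- vals - abs(charge)
    } else if (element == "B") {
      vals <- vals + ifelse(charge < 0L, 1L, -1L)
    } else {
      # charged halogens / hydrogens: no implicit hydrogens
      return(0L)
    }
  }
  vals <- vals[vals >= bondsum]
  if (!length(vals)) return(0L)
  as.integer(min(vals) - bondsum)
}
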