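#' @title Aromaticity: kekulisation and perception
#' @description
#' The OpenSMILES standard form writes aromatic systems in lowercase, but no
#' community aromatic model exists yet.  This package therefore commits to a
#' single documented model, applied identically when reading and when
#' writing:
#'
#' A simple ring of size 3--7 is aromatic when every ring atom is
#' sp2-compatible (at most three sigma neighbours) and the ring's pi-electron
#' count satisfies the Hueckel 4n+2 rule.  An atom with a double bond into
#' the ring (or to another ring atom of the system) contributes one electron;
#' a carbon with an exocyclic double bond to a non-ring atom contributes
#' zero; otherwise N/P (and N+/P+ with three substituents could not occur
#' without a double bond and are rejected), O, S and negatively charged
#' carbon contribute a lone pair (two electrons) and positively charged
#' carbon contributes zero.  Fused systems are aromatic ring-by-ring.
#'
#' Divergence from other toolkits' models is expected; because the same model
#' is used on both sides of the pipeline, canonicality is unaffected.
#' @name aromaticity-model
NULL

# Kekulise aromatic input: assign alternating double bonds over the
# aromatic-flagged bonds so that every aromatic atom that needs a double bond
# gets exactly one.  Returns list(atoms, bonds) with orders resolved;
# raises a kekulisation error if no assignment exists.
kekulize <- function(at, bd) {
  arom_atoms <- which(at$aromatic)
  if (!length(arom_atoms)) return(list(atoms = at, bonds = bd))
  n <- nrow(at)

  bondsum_fixed <- integer(n)   # orders of non-aromatic bonds
  has_multiple <- logical(n)    # an explicit (non-aromatic) multiple bond
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    if (!bd$aromatic[k]) {
      bondsum_fixed[bd$a[k]] <- bondsum_fixed[bd$a[k]] + bd$order[k]
      bondsum_fixed[bd$b[k]] <- bondsum_fixed[bd$b[k]] + bd$order[k]
      if (bd$order[k] > 1L) { has_multiple[bd$a[k]] <- TRUE; has_multiple[bd$b[k]] <- TRUE }
    }
  }
  deg <- integer(n)
  if (nrow(bd)) {
    tb <- table(factor(c(bd$a, bd$b), levels = seq_len(n)))
    deg <- as.integer(tb)
  }

  needs_double <- function(v) {
    if (!at$aromatic[v] || has_multiple[v]) return(FALSE)
    el <- at$element[v]; chg <- at$charge[v]
    hc <- at$hcount[v]  # NA for bare organic-subset atoms
    if (el == "C") {
      if (chg != 0L) return(FALSE)                    # c- / c+ keep the charge site single
      if (!is.na(hc) && deg[v] + hc >= 4L) return(FALSE)
      return(TRUE)
    }
    if (el %in% c("N", "P")) {
      if (chg < 0L) return(FALSE)                     # [n-]
      if (!is.na(hc) && hc > 0L && chg == 0L) return(FALSE)  # [nH] pyrrole-type
      if (chg == 0L && deg[v] >= 3L) return(FALSE)    # n(R) pyrrole-type
      return(TRUE)                                    # pyridine-type, [n+](R), [nH+]
    }
    if (el %in% c("O", "S")) return(chg > 0L)         # pyrylium/thiopyrylium
    FALSE
  }
  needy <- arom_atoms[vapply(arom_atoms, needs_double, logical(1))]

  # candidate matching edges: aromatic bonds between two needy atoms
  arom_bonds <- which(bd$aromatic)
  cand <- lapply(seq_len(n), function(v) integer())
  for (k in arom_bonds) {
    a <- bd$a[k]; b <- bd$b[k]
    if (a %in% needy && b %in% needy) {
      cand[[a]] <- c(cand[[a]], k); cand[[b]] <- c(cand[[b]], k)
    }
  }

  matched <- integer(n)  # bond index covering each needy atom, 0 = uncovered
  assign_bond <- function(k, val) {
    a <- bd$a[k]; b <- bd$b[k]
    matched[a] <<- val; matched[b] <<- val
  }
  solve <- function(todo) {
    if (!length(todo)) return(TRUE)
    v <- todo[1]
    if (matched[v] != 0L) return(solve(todo[-1]))
    for (k in cand[[v]]) {
      w <- if (bd$a[k] == v) bd$b[k] else bd$a[k]
      if (matched[w] != 0L) next
      assign_bond(k, k)
      if (solve(todo[-1])) return(TRUE)
      assign_bond(k, 0L)
    }
    FALSE
  }
  if (!solve(needy)) {
    stop("kekulisation error: no alternating double-bond assignment exists for the aromatic system",
         call. = FALSE)
  }
  double_bonds <- unique(matched[matched != 0L])
  bd$order[double_bonds] <- 2L
  list(atoms = at, bonds = bd)
}

#' Perceive aromatic systems
#'
#' Applies the package's aromatic model (see [aromaticity-model]) to a
#' Kekule-assigned graph, setting the `aromatic` flags on atoms and bonds.
#' Existing flags are discarded first, so perception is a pure function of
#' the Kekule structure.
#'
#' @param g a [molgraph()] with Kekule bond orders
#' @return the graph with aromatic flags set
#' @export
perceive_aromaticity <- function(g) {
  n <- nrow(g$atoms)
  g$atoms$aromatic <- rep(FALSE, n)
  if (nrow(g$bonds)) g$bonds$aromatic <- FALSE else return(g)

  rings <- find_rings(g, max_size = 7L)
  if (!length(rings)) return(g)
  ring_atoms <- sort(unique(unlist(rings)))

  adj <- mg_adjacency(g)
  bd <- g$bonds
  at <- g$atoms
  deg <- mg_degree(g)

  # double-bond partner of each atom (0 = none); triple bonds disqualify
  dbl_partner <- integer(n); has_triple <- logical(n)
  for (k in seq_len(nrow(bd))) {
    if (bd$order[k] == 2L) { dbl_partner[bd$a[k]] <- bd$b[k]; dbl_partner[bd$b[k]] <- bd$a[k] }
    if (bd$order[k] == 3L) { has_triple[bd$a[k]] <- TRUE; has_triple[bd$b[k]] <- TRUE }
  }

  pi_contrib <- function(v, ring) {
    el <- at$element[v]; chg <- at$charge[v]
    if (!el %in% AROMATIC_ELEMENTS) return(NA_integer_)
    if (has_triple[v]) return(NA_integer_)
    if (deg[v] + at$hcount[v] > 3L) return(NA_integer_)
    p <- dbl_partner[v]
    if (p != 0L) {
      if (p %in% ring) return(1L)
      if (p %in% ring_atoms) return(1L)   # double bond into a fused ring
      # exocyclic double bond to a non-ring atom: sp2, contributes nothing
      if (el %in% c("C", "S")) return(0L)
      return(NA_integer_)
    }
    if (el == "C") {
      if (chg < 0L) return(2L)
      if (chg > 0L) return(0L)
      return(NA_integer_)                 # sp3 carbon
    }
    if (el %in% c("N", "P", "O", "S")) {
      if (chg > 0L) return(NA_integer_)   # onium without a double bond
      return(2L)                          # lone pair
    }
    NA_integer_                           # boron: empty p orbital, not handled
  }

  for (ring in rings) {
    contribs <- vapply(ring, pi_contrib, 0L, ring = ring)
    if (anyNA(contribs)) next
    total <- sum(contribs)
    if (total %% 4L != 2L) next
    at$aromatic[ring] <- TRUE
    m <- length(ring)
    for (t in seq_len(m)) {
      a <- ring[t]; b <- ring[if (t == m) 1L else t + 1L]
      bi <- mg_bond_between(g, a, b)
      bd$aromatic[bi] <- TRUE
    }
  }
  g$atoms <- at
  g$bonds <- bd
  g
}

# Enumerate simple cycles of size 3..max_size, each returned once as an
# ordered atom vector.  Small-molecule DFS enumeration: paths rooted at their
# smallest atom.
find_rings <- function(g, max_size = 7L) {
  n <- nrow(g$atoms)
  adj <- mg_adjacency(g)
  rings <- list()
  seen <- character()
  for (root in seq_len(n)) {
    path <- integer(0)
    dfs <- function(v) {
      path <<- c(path, v)
      for (w in adj[[v]]$nbr) {
        if (w == root && length(path) >= 3L) {
          key <- paste(sort(path), collapse = ",")
          if (!key %in% seen) { seen <<- c(seen, key); rings[[length(rings) + 1L]] <<- path }
        } else if (w > root && !w %in% path && length(path) < max_size) {
          dfs(w)
        }
      }
      path <<- path[-length(path)]
    }
    dfs(root)
  }
  rings
}
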