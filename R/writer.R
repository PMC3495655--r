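#' @title Canonical SMILES writer
#' @description
#' Writes a SMILES string for a molecular graph under a given atom labelling,
#' following a fixed set of traversal and notation rules so that one
#' labelling always yields one byte-identical string:
#'
#' * start each component at its lowest-labelled atom, components in order of
#'   their lowest label; if the start atom would be a negatively charged
#'   oxygen, start at a doubly-bonded oxygen on the same neighbour instead
#'   (the carbonyl/carboxylate interchange guard);
#' * at branch points prefer multiple bonds (triple before double), then
#'   unlabelled explicit hydrogens (deuterium before tritium), then lower
#'   labels;
#' * OpenSMILES standard form for atoms (bare organic subset where possible,
#'   lowercase aromatic symbols under the package's aromatic model);
#' * every explicit substituent of a configured double bond carries a
#'   direction symbol, the earliest symbol of each conjugated system is `/`,
#'   and at ring closures the symbol sits only on the digit attached to the
#'   double-bond atom;
#' * ring-closure digits take the lowest available value, are reused once
#'   freed, and on a shared atom bond openings (by ascending label of the
#'   distal atom) precede bond closings (by opening order).
#' @name canonical-writer
NULL

#' Hydrogen ordering keys for a labelling
#'
#' InChI leaves ordinary explicit hydrogens unlabelled.  This fills in
#' ordering keys that place such a hydrogen before every labelled branch of
#' its parent (deuterium before tritium before other hydrogens), so the
#' branch-ordering rule needs no special casing.  Labelled atoms keep their
#' ranks.
#'
#' @param g a [molgraph()]
#' @param ranks numeric vector of canonical labels (`NA` = unlabelled)
#' @return numeric vector of ordering keys (unlabelled hydrogens get keys
#'   below every label)
#' @export
hydrogen_order_keys <- function(g, ranks) {
  n <- mg_natoms(g)
  stopifnot(length(ranks) == n)
  unlab <- is.na(ranks)
  if (any(unlab & g$atoms$element != "H"))
    stop("labelling incomplete: unlabelled non-hydrogen atom(s): ",
         paste(which(unlab & g$atoms$element != "H"), collapse = ", "))
  if (any(unlab)) {
    heavy_deg <- integer(n)
    if (nrow(g$bonds)) for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[k]; b <- g$bonds$b[k]
      if (g$atoms$element[b] != "H") heavy_deg[a] <- heavy_deg[a] + 1L
      if (g$atoms$element[a] != "H") heavy_deg[b] <- heavy_deg[b] + 1L
    }
    if (any(unlab & heavy_deg > 1L))
      stop("bridging hydrogen without an InChI label")
  }
  keys <- as.numeric(ranks)
  iso <- g$atoms$isotope
  keys[unlab] <- ifelse(iso[unlab] == 2L, -3, ifelse(iso[unlab] == 3L, -2, -1))
  keys
}

#' Choose the start atom of a component
#'
#' The start atom is the component's lowest-labelled atom, unless that atom
#' is a negatively charged oxygen whose neighbour also bears a doubly-bonded
#' oxygen; then the lowest-labelled such doubly-bonded oxygen is used
#' instead.  (The InChI treats `-O-` and `=O` on the same atom as
#' equivalent, so their labels can interchange between inputs; starting at
#' the carbonyl oxygen restores a canonical choice.)
#'
#' @param g a [molgraph()]
#' @param ranks canonical labels (`NA` allowed on explicit hydrogens only)
#' @param component atom indices of one connected component (default: all)
#' @return the start atom index
#' @export
choose_start_atom <- function(g, ranks, component = seq_len(mg_natoms(g))) {
  cand <- component[!is.na(ranks[component])]
  if (!length(cand)) stop("component has no labelled atom")
  s <- cand[which.min(ranks[cand])]
  at <- g$atoms
  if (at$element[s] == "O" && at$charge[s] < 0L) {
    adj <- mg_adjacency(g)
    nb <- adj[[s]]$nbr
    kb <- adj[[s]]$bond
    if (length(nb) == 1L && g$bonds$order[kb[1]] == 1L) {
      x <- nb[1]
      carb <- integer()
      for (t in seq_along(adj[[x]]$nbr)) {
        w <- adj[[x]]$nbr[t]; k <- adj[[x]]$bond[t]
        if (at$element[w] == "O" && g$bonds$order[k] == 2L) carb <- c(carb, w)
      }
      if (length(carb)) s <- carb[which.min(ranks[carb])]
    }
  }
  s
}

# permutation sign over an index vector (1..n in some order)
.perm_sign <- function(p) {
  inv <- 0L
  n <- length(p)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) if (p[i] > p[j]) inv <- inv + 1L
  if (inv %% 2L == 0L) 1L else -1L
}

#' Tetrahedral stereo token for a written neighbour order
#'
#' Given the stored neighbour reference order and winding of a stereocentre,
#' and the order in which those neighbours are written in the output, returns
#' `"@"` (anticlockwise viewed from the first written neighbour) or `"@@"`.
#'
#' @param stored integer(4) stored neighbour references (0 = implicit H)
#' @param winding `"acw"` or `"cw"` for the stored order
#' @param written integer(4) the same references in written order
#' @return `"@"` or `"@@"`, or `NA_character_` if the references do not match
#' @export
tetrahedral_token <- function(stored, winding, written) {
  if (length(written) != 4L || !setequal(written, stored)) return(NA_character_)
  p <- match(written, stored)
  even <- .perm_sign(p) == 1L
  acw <- (winding == "acw") == even
  if (acw) "@" else "@@"
}

#' Write a canonical SMILES string
#'
#' The core writer: produces the SMILES string of `g` under the atom
#' labelling `ranks` following the traversal and notation rules of
#' [canonical-writer].  With the default identity labelling the output is an
#' input-order SMILES (used, for example, to hand a structure to the InChI
#' backend).
#'
#' @param g a [molgraph()]
#' @param ranks numeric canonical labels, `NA` for unlabelled explicit
#'   hydrogens; `NULL` (default) for the identity labelling over
#'   non-hydrogen atoms (over all atoms if the graph is hydrogen only)
#' @param kekule write uppercase Kekule form, ignoring aromatic flags
#' @return character scalar; attribute `atom_order` gives, for each written
#'   atom in output order, its index in `g` (suppressed hydrogens excluded)
#' @export
write_smiles <- function(g, ranks = NULL, kekule = FALSE) {
  n <- mg_natoms(g)
  if (n == 0L) return(structure("", atom_order = integer()))
  if (is.null(ranks)) {
    ranks <- rep(NA_real_, n)
    heavy <- which(g$atoms$element != "H")
    if (!length(heavy)) heavy <- seq_len(n)
    ranks[heavy] <- seq_along(heavy)
  }
  stopifnot(length(ranks) == n)
  lab <- ranks[!is.na(ranks)]
  if (anyDuplicated(lab)) stop("canonical labels must be distinct")

  sup <- .suppress_hydrogens(g, ranks)
  g2 <- sup$g; ranks2 <- sup$ranks
  eff <- hydrogen_order_keys(g2, ranks2)
  plan <- .build_plan(g2, ranks2, eff, kekule = kekule)
  sym <- .assign_direction_symbols(g2, plan, kekule = kekule)
  out <- .emit(g2, plan, sym, kekule = kekule)
  structure(out, atom_order = sup$keep[plan$order])
}

#' Build the depth-first traversal plan for a labelling
#'
#' Exposed mainly for inspection and testing; [write_smiles()] drives the
#' full pipeline.
#'
#' @param g a [molgraph()] (explicit plain hydrogens should already be
#'   suppressed)
#' @param ranks canonical labels
#' @return a list with the visit `order`, per-atom ordered `children`,
#'   `parent`/`parent_bond` vectors, `roots`, and ring `closures`
#'   (bond, open, close, digit, opening sequence)
#' @export
build_traversal <- function(g, ranks) {
  eff <- hydrogen_order_keys(g, ranks)
  .build_plan(g, ranks, eff, kekule = FALSE)
}

.build_plan <- function(g, ranks, eff, kekule = FALSE) {
  n <- mg_natoms(g)
  adj <- mg_adjacency(g)
  bd <- g$bonds
  bond_arom <- if (kekule) rep(FALSE, nrow(bd)) else bd$aromatic
  is_multiple <- bd$order >= 2L & !bond_arom

  comp <- mg_components(g)
  comp_ids <- unique(comp)
  comp_key <- vapply(comp_ids, function(cid)
    suppressWarnings(min(ranks[comp == cid], na.rm = TRUE)), 0)
  if (any(!is.finite(comp_key))) stop("component without a labelled atom")
  comp_ids <- comp_ids[order(comp_key)]

  visited <- logical(n)
  outpos <- integer(n)
  parent <- integer(n); parent_bond <- integer(n)
  children <- rep(list(list(bond = integer(), atom = integer())), n)
  order_out <- integer(n)
  closures <- list()
  closure_seen <- logical(nrow(bd))
  counter <- 0L

  ordered_nbrs <- function(v, pb) {
    ks <- adj[[v]]$bond; ws <- adj[[v]]$nbr
    if (!is.na(pb)) { keep <- ks != pb; ks <- ks[keep]; ws <- ws[keep] }
    if (!length(ks)) return(list(bond = integer(), atom = integer()))
    key1 <- ifelse(is_multiple[ks], -as.numeric(bd$order[ks]), 0)
    o <- order(key1, eff[ws])
    list(bond = ks[o], atom = ws[o])
  }

  visit <- function(v, pb) {
    visited[v] <<- TRUE
    counter <<- counter + 1L
    outpos[v] <<- counter
    order_out[counter] <<- v
    nb <- ordered_nbrs(v, pb)
    for (t in seq_along(nb$bond)) {
      k <- nb$bond[t]; w <- nb$atom[t]
      if (visited[w]) {
        if (!closure_seen[k]) {
          closure_seen[k] <<- TRUE
          closures[[length(closures) + 1L]] <<- list(bond = k, open = w, close = v)
        }
      } else {
        children[[v]]$bond <<- c(children[[v]]$bond, k)
        children[[v]]$atom <<- c(children[[v]]$atom, w)
        parent[w] <<- v; parent_bond[w] <<- k
        visit(w, k)
      }
    }
  }

  roots <- integer()
  for (cid in comp_ids) {
    s <- choose_start_atom(g, ranks, which(comp == cid))
    roots <- c(roots, s)
    visit(s, NA_integer_)
  }

  closures <- .assign_closure_digits(closures, outpos, ranks, eff)

  list(order = order_out, outpos = outpos, parent = parent,
       parent_bond = parent_bond, children = children, roots = roots,
       closures = closures, comp = comp)
}

# Rules J and K: lowest available digit, reuse after closing; openings on an
# atom ordered by the label of the distal atom, closings by opening order.
.assign_closure_digits <- function(closures, outpos, ranks, eff) {
  if (!length(closures)) return(closures)
  opens <- vapply(closures, `[[`, 0L, "open")
  closes <- vapply(closures, `[[`, 0L, "close")
  free <- rep(TRUE, 99L)
  open_seq <- 0L
  atoms_in_order <- unique(c(opens, closes)[order(c(outpos[opens], outpos[closes]))])
  for (v in atoms_in_order) {
    idx_open <- which(opens == v)
    idx_close <- which(closes == v)
    if (length(idx_open)) {
      distal_key <- eff[closes[idx_open]]
      for (i in idx_open[order(distal_key)]) {
        d <- which(free)[1]
        if (is.na(d)) stop("ring closure digits exhausted")
        free[d] <- FALSE
        open_seq <- open_seq + 1L
        closures[[i]]$digit <- d
        closures[[i]]$open_seq <- open_seq
      }
    }
    if (length(idx_close)) {
      for (i in idx_close) free[closures[[i]]$digit] <- TRUE
    }
  }
  closures
}

# Rules G, H, I: direction symbols for cis/trans systems.
# Returns list(char = named map bond-index -> "/" or "\\" as written in
# orientation a->b, pos = emission position), resolved per conjugated system
# so the earliest symbol is "/".
.assign_direction_symbols <- function(g, plan, kekule = FALSE) {
  bd <- g$bonds
  nb <- nrow(bd)
  empty <- list(updown = rep(NA, nb))
  cfg <- g$db
  cfg <- Filter(function(d) d$config %in% c("together", "opposite"), cfg)
  if (!length(cfg) || !nb) return(empty)
  adj <- mg_adjacency(g)
  bond_arom <- if (kekule) rep(FALSE, nb) else bd$aromatic

  # variable bonds: explicit single-bond substituents of configured doubles
  varb <- logical(nb)
  for (d in cfg) for (v in c(d$a, d$b)) {
    ks <- adj[[v]]$bond
    sel <- ks[bd$order[ks] == 1L & !bond_arom[ks]]
    varb[sel] <- TRUE
  }
  vidx <- which(varb)
  if (!length(vidx)) return(empty)

  # constraints: list of (k1, k2, equal) over "dir(a->b)" booleans (TRUE=up)
  view <- function(k, sub) {
    # returns c(flip): dir(sub -> other) == val XOR flip
    if (bd$a[k] == sub) FALSE else TRUE
  }
  cons <- list()
  # constraint "d1 REL d2" with d = val XOR flip translates to
  # "v1 == v2" iff !(f1 XOR f2 XOR !REL)
  add_con <- function(k1, f1, k2, f2, equal) {
    cons[[length(cons) + 1L]] <<- list(k1 = k1, k2 = k2,
                                       equal = !xor(xor(f1, f2), !equal))
  }
  for (d in cfg) {
    for (v in c(d$a, d$b)) {
      ks <- adj[[v]]$bond
      subs <- ks[bd$order[ks] == 1L & !bond_arom[ks]]
      if (length(subs) == 2L) {
        s1 <- subs[1]; s2 <- subs[2]
        o1 <- if (bd$a[s1] == v) bd$b[s1] else bd$a[s1]
        o2 <- if (bd$a[s2] == v) bd$b[s2] else bd$a[s2]
        add_con(s1, view(s1, o1), s2, view(s2, o2), equal = FALSE)
      }
    }
    ka <- mg_bond_between(g, d$ref_a, d$a)
    kb <- mg_bond_between(g, d$ref_b, d$b)
    add_con(ka, view(ka, d$ref_a), kb, view(kb, d$ref_b),
            equal = d$config == "together")
  }

  # 2-colouring
  val <- rep(NA, nb)
  compid <- rep(NA_integer_, nb)
  ncomp <- 0L
  neighbours <- vector("list", nb)
  for (cn in cons) {
    neighbours[[cn$k1]] <- c(neighbours[[cn$k1]], list(list(k = cn$k2, eq = cn$equal)))
    neighbours[[cn$k2]] <- c(neighbours[[cn$k2]], list(list(k = cn$k1, eq = cn$equal)))
  }
  for (s in vidx) {
    if (!is.na(val[s])) next
    ncomp <- ncomp + 1L
    val[s] <- TRUE; compid[s] <- ncomp
    queue <- s
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      for (e in neighbours[[u]]) {
        want <- if (e$eq) val[u] else !val[u]
        if (is.na(val[e$k])) {
          val[e$k] <- want; compid[e$k] <- ncomp; queue <- c(queue, e$k)
        } else if (val[e$k] != want) {
          stop("impossible cis/trans configuration: contradictory direction constraints")
        }
      }
    }
  }

  # emission position of each symbol (for Rule H)
  pos <- rep(NA_real_, nb)
  cl_bonds <- vapply(plan$closures, `[[`, 0L, "bond")
  db_atoms <- unique(unlist(lapply(cfg, function(d) c(d$a, d$b))))
  digit_end <- rep(NA_integer_, nb)   # atom whose digit carries the symbol
  for (k in vidx) {
    ci <- match(k, cl_bonds)
    if (!is.na(ci)) {
      cl <- plan$closures[[ci]]
      endv <- intersect(c(bd$a[k], bd$b[k]), db_atoms)
      if (!length(endv)) { val[k] <- NA; next }  # defensive
      endv <- endv[which.min(plan$outpos[endv])]
      digit_end[k] <- endv
      pos[k] <- plan$outpos[endv] + 0.01 * cl$digit
    } else {
      child <- if (plan$parent_bond[bd$a[k]] == k) bd$a[k] else bd$b[k]
      pos[k] <- plan$outpos[child]
    }
  }

  # Rule H: flip each system so its earliest symbol is "/"
  for (cc in seq_len(ncomp)) {
    ks <- vidx[compid[vidx] == cc & !is.na(val[vidx])]
    ks <- ks[!is.na(pos[ks])]
    if (!length(ks)) next
    first <- ks[which.min(pos[ks])]
    # the written char at `first`: "/" iff dir(written_from -> written_to)=up
    fr <- .sym_from_atom(g, plan, first, digit_end)
    to <- if (bd$a[first] == fr) bd$b[first] else bd$a[first]
    dir_up <- if (bd$a[first] == fr) val[first] else !val[first]
    if (!dir_up) {
      flip <- vidx[compid[vidx] == cc]
      val[flip] <- !val[flip]
    }
  }
  list(updown = val, digit_end = digit_end)
}

# the atom at which bond k's symbol is written (parent of the tree edge, or
# the double-bond end carrying the closure digit)
.sym_from_atom <- function(g, plan, k, digit_end) {
  if (!is.na(digit_end[k])) return(digit_end[k])
  bd <- g$bonds
  if (plan$parent_bond[bd$a[k]] == k) bd$b[k] else bd$a[k]
}

# merge plain explicit hydrogens into their parent's implicit count
.suppress_hydrogens <- function(g, ranks) {
  n <- mg_natoms(g)
  at <- g$atoms
  deg <- mg_degree(g)
  adj <- mg_adjacency(g)
  drop <- logical(n)
  for (v in seq_len(n)) {
    if (at$element[v] != "H" || at$isotope[v] != 0L || at$charge[v] != 0L) next
    if (!is.na(ranks[v])) next                       # InChI-labelled H stays
    if (deg[v] != 1L || at$hcount[v] != 0L) next
    w <- adj[[v]]$nbr[1]
    if (at$element[w] == "H") next                   # H-H stays explicit
    if (g$bonds$order[adj[[v]]$bond[1]] != 1L) next
    drop[v] <- TRUE
  }
  if (!any(drop)) return(list(g = g, ranks = ranks, keep = seq_len(n)))
  keep <- which(!drop)
  newid <- rep(NA_integer_, n); newid[keep] <- seq_along(keep)
  at2 <- at[keep, , drop = FALSE]; rownames(at2) <- NULL
  # credit each suppressed H to its parent
  for (v in which(drop)) {
    w <- newid[adj[[v]]$nbr[1]]
    at2$hcount[w] <- at2$hcount[w] + 1L
  }
  bd <- g$bonds
  bkeep <- !(drop[bd$a] | drop[bd$b])
  bd2 <- bd[bkeep, , drop = FALSE]
  bd2$a <- newid[bd2$a]; bd2$b <- newid[bd2$b]
  rownames(bd2) <- NULL
  tet2 <- list()
  for (t in g$tet) {
    t$center <- newid[t$center]
    if (is.na(t$center)) next
    nbrs <- t$nbrs
    for (i in seq_along(nbrs)) {
      if (nbrs[i] == 0L) next
      if (drop[nbrs[i]]) nbrs[i] <- 0L else nbrs[i] <- newid[nbrs[i]]
    }
    if (sum(nbrs == 0L) > 1L) {
      warning("stereocentre with more than one implicit hydrogen; stereo dropped")
      next
    }
    t$nbrs <- as.integer(nbrs)
    tet2[[length(tet2) + 1L]] <- t
  }
  db2 <- list()
  for (d in g$db) {
    d$a <- newid[d$a]; d$b <- newid[d$b]
    for (side in c("a", "b")) {
      ref <- paste0("ref_", side)
      v <- d[[ref]]
      if (!drop[v]) { d[[ref]] <- newid[v]; next }
      # re-point to another explicit substituent, flipping the configuration
      end <- d[[side]]
      alts <- setdiff(adj[[keep[end]]]$nbr, c(keep[d$a], keep[d$b]))
      # note: end is already renumbered; use original ids via keep
      alts <- Filter(function(x) !drop[x], alts)
      if (!length(alts)) { d$config <- "undefined"; break }
      d[[ref]] <- newid[alts[1]]
      d$config <- if (d$config == "together") "opposite" else "together"
    }
    if (d$config %in% c("together", "opposite"))
      db2[[length(db2) + 1L]] <- d
  }
  g2 <- structure(list(atoms = at2, bonds = bd2, tet = tet2, db = db2),
                  class = "molgraph")
  list(g = g2, ranks = ranks[keep], keep = keep)
}

# final token assembly
.emit <- function(g, plan, sym, kekule = FALSE) {
  at <- g$atoms; bd <- g$bonds
  n <- nrow(at)
  arom_atom <- if (kekule) rep(FALSE, n) else at$aromatic
  bond_arom <- if (kekule) rep(FALSE, nrow(bd)) else bd$aromatic
  updown <- sym$updown
  digit_end <- sym$digit_end
  if (is.null(digit_end)) digit_end <- rep(NA_integer_, nrow(bd))

  cl_by_open <- split(seq_along(plan$closures),
                      vapply(plan$closures, `[[`, 0L, "open"))
  cl_by_close <- split(seq_along(plan$closures),
                       vapply(plan$closures, `[[`, 0L, "close"))

  ring_tokens <- function(v) {
    toks <- character(); partners <- integer()
    io <- cl_by_open[[as.character(v)]]
    if (!is.null(io)) {
      io <- io[order(vapply(plan$closures[io], `[[`, 0L, "open_seq"))]
      for (i in io) {
        cl <- plan$closures[[i]]
        k <- cl$bond
        pre <- ""
        if (!bond_arom[k]) {
          if (bd$order[k] == 2L) pre <- "="
          else if (bd$order[k] == 3L) pre <- "#"
          else if (!is.na(updown[k]) && !is.na(digit_end[k]) && digit_end[k] == v) {
            up <- if (bd$a[k] == v) updown[k] else !updown[k]
            pre <- if (up) "/" else "\\"
          }
        }
        toks <- c(toks, paste0(pre, if (cl$digit > 9L) sprintf("%%%02d", cl$digit) else cl$digit))
        partners <- c(partners, cl$close)
      }
    }
    ic <- cl_by_close[[as.character(v)]]
    if (!is.null(ic)) {
      ic <- ic[order(vapply(plan$closures[ic], `[[`, 0L, "open_seq"))]
      for (i in ic) {
        cl <- plan$closures[[i]]
        k <- cl$bond
        pre <- ""
        if (!bond_arom[k] && bd$order[k] == 1L &&
            !is.na(updown[k]) && !is.na(digit_end[k]) && digit_end[k] == v) {
          up <- if (bd$a[k] == v) updown[k] else !updown[k]
          pre <- if (up) "/" else "\\"
        }
        toks <- c(toks, paste0(pre, if (cl$digit > 9L) sprintf("%%%02d", cl$digit) else cl$digit))
        partners <- c(partners, cl$open)
      }
    }
    list(toks = toks, partners = partners)
  }

  bondsum <- integer(n)
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    bondsum[bd$a[k]] <- bondsum[bd$a[k]] + bd$order[k]
    bondsum[bd$b[k]] <- bondsum[bd$b[k]] + bd$order[k]
  }
  adj <- mg_adjacency(g)
  tet_by_center <- list()
  for (t in g$tet) tet_by_center[[as.character(t$center)]] <- t

  atom_token <- function(v, ring_partners) {
    el <- at$element[v]; iso <- at$isotope[v]; chg <- at$charge[v]
    hc <- at$hcount[v]; arom <- arom_atom[v]
    stereo <- NA_character_
    t <- tet_by_center[[as.character(v)]]
    if (!is.null(t) && t$winding %in% c("acw", "cw")) {
      written <- integer()
      if (plan$parent[v] != 0L) written <- plan$parent[v]
      if (0L %in% t$nbrs) written <- c(written, 0L)
      written <- c(written, ring_partners, plan$children[[v]]$atom)
      stereo <- tetrahedral_token(t$nbrs, t$winding, written)
      if (is.na(stereo))
        warning(sprintf("atom %d: unresolvable stereocentre references; stereo omitted", v))
    }
    sym_txt <- if (arom) tolower(el) else el
    bracket <- el == "H" || iso > 0L || chg != 0L || !is.na(stereo) ||
      !(el %in% ORGANIC_SUBSET) || (arom && !el %in% AROMATIC_ELEMENTS)
    if (!bracket) {
      expected <- if (arom) .aromatic_bare_h(v, at, bd, adj, bond_arom)
      else implicit_h_for(el, 0L, bondsum[v])
      bracket <- hc != expected
    }
    if (!bracket) return(sym_txt)
    paste0("[",
           if (iso > 0L) iso else "",
           sym_txt,
           if (!is.na(stereo)) stereo else "",
           if (hc == 1L) "H" else if (hc > 1L) paste0("H", hc) else "",
           if (chg > 0L) paste0("+", if (chg > 1L) chg else "")
           else if (chg < 0L) paste0("-", if (chg < -1L) -chg else ""),
           "]")
  }

  bond_prefix <- function(k, from, to) {
    if (bond_arom[k]) return("")
    o <- bd$order[k]
    if (o == 2L) return("=")
    if (o == 3L) return("#")
    if (!is.na(updown[k]) && is.na(digit_end[k])) {
      up <- if (bd$a[k] == from) updown[k] else !updown[k]
      return(if (up) "/" else "\\")
    }
    if (arom_atom[from] && arom_atom[to]) return("-")
    ""
  }

  emit_atom <- function(v) {
    rt <- ring_tokens(v)
    out <- paste0(atom_token(v, rt$partners), paste0(rt$toks, collapse = ""))
    ch <- plan$children[[v]]
    m <- length(ch$atom)
    if (m) {
      parts <- vapply(seq_len(m), function(t) {
        w <- ch$atom[t]; k <- ch$bond[t]
        paste0(bond_prefix(k, v, w), emit_atom(w))
      }, "")
      out <- paste0(out,
                    if (m > 1L) paste0("(", parts[-m], ")", collapse = "") else "",
                    parts[m])
    }
    out
  }

  paste0(vapply(plan$roots, emit_atom, ""), collapse = ".")
}

.aromatic_bare_h <- function(v, at, bd, adj, bond_arom) {
  if (at$element[v] != "C") return(0L)
  ks <- adj[[v]]$bond
  na_ <- sum(bond_arom[ks])
  others <- ks[!bond_arom[ks]]
  so <- if (length(others)) sum(bd$order[others]) else 0L
  needy <- !length(others) || all(bd$order[others] <= 1L)
  max(4L - na_ - so - (if (needy) 1L else 0L), 0L)
}
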