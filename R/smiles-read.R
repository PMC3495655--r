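#' Read a SMILES string into a molecular graph
#'
#' Parses an OpenSMILES-conformant SMILES string.  Atom order in the returned
#' graph equals token order in the string.  Aromatic (lowercase) input is
#' kekulised immediately so the graph always carries a valid Kekule
#' assignment, after which aromaticity is re-perceived with the package's own
#' model (see [perceive_aromaticity()]); this keeps reading and writing on a
#' single aromatic model.
#'
#' Tetrahedral (`@`/`@@`) and double-bond (`/`, `\`) stereochemistry are
#' converted to explicit stereo descriptors.  Directional markers around
#' cumulated (allene-type) systems are dropped with a warning: only
#' tetrahedral and double-bond stereochemistry are supported.
#'
#' @param text a single SMILES string
#' @param perceive re-perceive aromaticity after kekulisation (default TRUE)
#' @return a [molgraph()]
#' @export
read_smiles <- function(text, perceive = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  if (nchar(s) == 0L) {
    return(molgraph(data.frame(element = character(), isotope = integer(),
                               charge = integer(), hcount = integer(),
                               aromatic = logical()),
                    data.frame()))
  }

  atoms <- list()     # list of lists: element, isotope, charge, hcount(NA=derive), aromatic, bracket, stereo
  bonds <- list()     # list of lists: a, b, order(NA=implicit), aromatic, dir ("none"/"up"/"down"), dirfirst
  nbr_seq <- list()   # per atom: ordered neighbour refs; >0 atom, 0 implicit-H slot, -d ring digit slot
  ring_open <- list() # digit -> list(atom, order, dir, seq_slot)

  prev <- NA_integer_
  stack <- integer()
  pend_order <- NA_integer_   # NA = unspecified
  pend_dir <- "none"
  pend_dot <- FALSE
  n <- 0L

  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- 1L; len <- length(chars)

  err <- function(msg, at = i) {
    stop(sprintf("SMILES parse error at position %d in %s: %s", at,
                 encodeString(s, quote = '"'), msg), call. = FALSE)
  }

  add_atom <- function(element, isotope = 0L, charge = 0L, hcount = NA_integer_,
                       aromatic = FALSE, bracket = FALSE, stereo = NA_character_) {
    n <<- n + 1L
    atoms[[n]] <<- list(element = element, isotope = isotope, charge = charge,
                        hcount = hcount, aromatic = aromatic, bracket = bracket,
                        stereo = stereo)
    nbr_seq[[n]] <<- integer()
    if (!is.na(prev)) {
      if (pend_dot) err("internal: dot with pending bond")
      bonds[[length(bonds) + 1L]] <<- list(
        a = prev, b = n, order = pend_order, dir = pend_dir)
      nbr_seq[[prev]] <<- c(nbr_seq[[prev]], n)
      nbr_seq[[n]] <<- c(nbr_seq[[n]], prev)
    }
    if (bracket && !is.na(stereo) && !is.na(hcount) && hcount >= 1L) {
      nbr_seq[[n]] <<- c(nbr_seq[[n]], 0L)   # implicit-H slot
    }
    prev <<- n
    pend_order <<- NA_integer_; pend_dir <<- "none"; pend_dot <<- FALSE
  }

  close_ring <- function(digit) {
    key <- as.character(digit)
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      if (op$atom == prev) err(sprintf("ring closure %d to the same atom", digit))
      ord <- op$order
      if (!is.na(pend_order)) {
        if (!is.na(ord) && ord != pend_order)
          err(sprintf("conflicting bond orders for ring closure %d", digit))
        ord <- pend_order
      }
      dir <- "none"; dirfirst <- NA_integer_
      if (op$dir != "none") { dir <- op$dir; dirfirst <- op$atom }
      if (pend_dir != "none") {
        if (dir != "none") {
          # both ends marked: must be mirrored (x/d ... y\d)
          if (pend_dir == dir)
            err(sprintf("inconsistent direction symbols on ring closure %d", digit))
        } else {
          dir <- pend_dir; dirfirst <- prev
        }
      }
      bonds[[length(bonds) + 1L]] <<- list(a = op$atom, b = prev, order = ord,
                                           dir = dir, dirfirst = dirfirst)
      # resolve the reserved neighbour slots
      nbr_seq[[op$atom]][op$seq_slot] <<- prev
      nbr_seq[[prev]] <<- c(nbr_seq[[prev]], op$atom)
    } else {
      slot <- length(nbr_seq[[prev]]) + 1L
      nbr_seq[[prev]][slot] <<- NA_integer_  # placeholder until closed
      ring_open[[key]] <<- list(atom = prev, order = pend_order, dir = pend_dir,
                                seq_slot = slot)
    }
    pend_order <<- NA_integer_; pend_dir <<- "none"
  }

  two_letter <- c("Cl", "Br")  # organic-subset two-character symbols

  while (i <= len) {
    ch <- chars[i]
    if (ch == " " || ch == "\t") break  # title separator
    if (ch == "(") {
      if (is.na(prev)) err("branch open with no current atom")
      stack <- c(stack, prev); i <- i + 1L; next
    }
    if (ch == ")") {
      if (!length(stack)) err("unmatched closing parenthesis")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch == ".") {
      if (!is.na(pend_order) || pend_dir != "none") err("bond symbol before dot")
      prev <- NA_integer_; pend_dot <- FALSE; i <- i + 1L; next
    }
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (is.na(prev)) err("bond symbol with no preceding atom")
      if (ch == "-") pend_order <- 1L
      else if (ch == "=") pend_order <- 2L
      else if (ch == "#") pend_order <- 3L
      else if (ch == ":") pend_order <- -1L  # explicit aromatic bond
      else { pend_order <- 1L; pend_dir <- if (ch == "/") "up" else "down" }
      i <- i + 1L; next
    }
    if (ch >= "0" && ch <= "9") {
      if (is.na(prev)) err("ring closure with no preceding atom")
      close_ring(as.integer(ch)); i <- i + 1L; next
    }
    if (ch == "%") {
      if (i + 2L > len || !all(chars[i + 1:2] >= "0" & chars[i + 1:2] <= "9"))
        err("%% must be followed by two digits")
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L; next
    }
    if (ch == "[") {
      j <- i + 1L
      while (j <= len && chars[j] != "]") j <- j + 1L
      if (j > len) err("unterminated bracket atom")
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@@|@(?:TH[12])?)?(H[0-9]*)?((?:\\+{1,2}|-{1,2})[0-9]*)?(?::[0-9]+)?$",
        body, perl = TRUE))[[1]]
      if (!length(m)) err(sprintf("malformed bracket atom [%s]", body))
      iso <- if (nzchar(m[2])) as.integer(m[2]) else 0L
      sym <- m[3]
      aromatic <- FALSE
      if (substr(sym, 1, 1) %in% letters) {
        aromatic <- TRUE
        sym <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      }
      if (!sym %in% ELEMENTS) err(sprintf("unknown element '%s'", m[3]))
      if (aromatic && !sym %in% AROMATIC_ELEMENTS)
        err(sprintf("element '%s' cannot be aromatic", m[3]))
      stereo <- NA_character_
      if (nzchar(m[4])) {
        stereo <- switch(m[4], "@" = "acw", "@TH1" = "acw",
                         "@@" = "cw", "@TH2" = "cw")
      }
      hc <- 0L
      if (nzchar(m[5])) hc <- if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
      chg <- 0L
      if (nzchar(m[6])) {
        sgn <- if (substr(m[6], 1, 1) == "+") 1L else -1L
        digits <- gsub("[+-]", "", m[6])
        reps <- nchar(gsub("[^+-]", "", m[6]))
        chg <- if (nzchar(digits)) sgn * as.integer(digits) else sgn * reps
      }
      add_atom(sym, iso, chg, hc, aromatic, bracket = TRUE, stereo = stereo)
      i <- j + 1L; next
    }
    # organic-subset atom
    sym <- ch
    if (i < len && paste0(ch, chars[i + 1L]) %in% two_letter) {
      sym <- paste0(ch, chars[i + 1L]); i <- i + 1L
    }
    if (sym %in% ORGANIC_SUBSET) {
      add_atom(sym, aromatic = FALSE, bracket = FALSE)
    } else if (sym %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(sym), aromatic = TRUE, bracket = FALSE)
    } else err(sprintf("unexpected character '%s'", ch))
    i <- i + 1L
  }

  open_digits <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_digits))
    err(sprintf("unclosed ring bond number(s): %s",
                paste(open_digits, collapse = ", ")), at = len)
  if (length(stack)) err("unclosed branch", at = len)

  .assemble_smiles_graph(atoms, bonds, nbr_seq, perceive = perceive)
}

# Build the molgraph from parser accumulators: resolve bond orders, kekulise,
# fill implicit hydrogens, convert stereo markers.
.assemble_smiles_graph <- function(atoms, bonds, nbr_seq, perceive = TRUE) {
  n <- length(atoms)
  at <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    isotope = vapply(atoms, `[[`, 0L, "isotope"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    hcount = vapply(atoms, `[[`, NA_integer_, "hcount"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    bracket = vapply(atoms, `[[`, FALSE, "bracket"),
    stringsAsFactors = FALSE
  )

  nb <- length(bonds)
  bd <- data.frame(
    a = vapply(bonds, `[[`, 0L, "a"),
    b = vapply(bonds, `[[`, 0L, "b"),
    order = vapply(bonds, function(x) as.integer(x$order), 0L),
    dir = vapply(bonds, `[[`, "", "dir"),
    stringsAsFactors = FALSE
  )
  bd$dirfirst <- vapply(bonds, function(x)
    if (!is.null(x$dirfirst) && !is.na(x$dirfirst)) x$dirfirst else x$a, 0L)

  # aromatic bonds: explicit ':' (order -1) or implicit bond between two
  # aromatic atoms
  bd$aromatic <- logical(nb)
  if (nb) {
    expl_arom <- !is.na(bd$order) & bd$order == -1L
    impl <- is.na(bd$order)
    both_arom <- at$aromatic[bd$a] & at$aromatic[bd$b]
    bd$aromatic <- expl_arom | (impl & both_arom)
    bd$order[expl_arom] <- 1L
    bd$order[is.na(bd$order)] <- 1L
  }

  kk <- kekulize(at, bd)
  bd <- kk$bonds; at <- kk$atoms

  # implicit hydrogen counts for non-bracket atoms
  bondsum <- integer(n)
  if (nb) for (k in seq_len(nb)) {
    bondsum[bd$a[k]] <- bondsum[bd$a[k]] + bd$order[k]
    bondsum[bd$b[k]] <- bondsum[bd$b[k]] + bd$order[k]
  }
  for (v in seq_len(n)) {
    if (!is.na(at$hcount[v])) next
    if (at$aromatic[v] && at$element[v] != "C") {
      # bare aromatic heteroatoms never receive implicit hydrogens
      at$hcount[v] <- 0L
    } else {
      at$hcount[v] <- implicit_h_for(at$element[v], at$charge[v], bondsum[v])
    }
  }

  # double-bond stereo from direction markers
  db <- .perceive_db_from_dirs(at, bd)

  # tetrahedral stereo from @/@@ and neighbour sequences
  tet <- list()
  for (v in seq_len(n)) {
    st <- atoms[[v]]$stereo
    if (is.na(st)) next
    refs <- nbr_seq[[v]]
    if (anyNA(refs)) stop("internal: unresolved ring slot in stereo neighbours")
    if (length(refs) == 3L && at$hcount[v] == 1L && !0L %in% refs) {
      # bracket without H-count but implicit H present cannot happen (bracket
      # hcount is explicit); defensive only
      refs <- c(refs[1], 0L, refs[-1])
    }
    if (length(refs) != 4L) {
      warning(sprintf(
        "atom %d: tetrahedral mark with %d neighbour references; stereo dropped",
        v, length(refs)))
      next
    }
    tet[[length(tet) + 1L]] <- list(center = v, nbrs = as.integer(refs),
                                    winding = st)
  }

  bd2 <- bd[, c("a", "b", "order", "aromatic")]
  sw <- bd2$a > bd2$b
  if (any(sw)) { tmp <- bd2$a[sw]; bd2$a[sw] <- bd2$b[sw]; bd2$b[sw] <- tmp }
  at$bracket <- NULL
  g <- molgraph(at, bd2, tet = tet, db = db)
  if (perceive) g <- perceive_aromaticity(g) else g$atoms$aromatic <- FALSE
  g
}

# Interpret '/'/'\' markers: for every non-aromatic double bond with marked
# single bonds at both ends, record a DoubleBondStereo descriptor.  Markers
# that only touch cumulated double-bond chains (axial stereo) are dropped
# with a warning.
.perceive_db_from_dirs <- function(at, bd) {
  db <- list()
  nb <- nrow(bd)
  if (!nb) return(db)
  marked <- which(bd$dir != "none" & bd$order == 1L)
  if (!length(marked)) return(db)
  # dir value as dir(first->second); we need per-atom view
  dir_from <- function(k, from) {
    # direction of bond k read from atom `from` towards the other end
    d <- bd$dir[k]
    if (bd$dirfirst[k] == from) d else c(up = "down", down = "up")[[d]]
  }
  doubles <- which(bd$order == 2L & !bd$aromatic)
  used <- logical(length(bd$a))
  for (k in doubles) {
    i <- bd$a[k]; j <- bd$b[k]
    subs_i <- marked[(bd$a[marked] == i | bd$b[marked] == i)]
    subs_j <- marked[(bd$a[marked] == j | bd$b[marked] == j)]
    if (!length(subs_i) || !length(subs_j)) next
    ki <- subs_i[1]; kj <- subs_j[1]
    ref_i <- if (bd$a[ki] == i) bd$b[ki] else bd$a[ki]
    ref_j <- if (bd$a[kj] == j) bd$b[kj] else bd$a[kj]
    di <- dir_from(ki, ref_i)   # dir(ref_i -> i)
    dj <- dir_from(kj, ref_j)   # dir(ref_j -> j)
    cfg <- if (di == dj) "together" else "opposite"
    db[[length(db) + 1L]] <- list(a = i, b = j, ref_a = ref_i, ref_b = ref_j,
                                  config = cfg)
    used[c(subs_i, subs_j)] <- TRUE
  }
  orphan <- setdiff(marked, which(used))
  if (length(orphan)) {
    # markers not interpretable as double-bond stereo (e.g. allene axial)
    touches_double <- vapply(orphan, function(k) {
      any(bd$order[bd$a == bd$a[k] | bd$b == bd$a[k]] == 2L) ||
        any(bd$order[bd$a == bd$b[k] | bd$b == bd$b[k]] == 2L)
    }, logical(1))
    if (any(touches_double))
      warning("directional bond markers on a cumulated or incomplete system dropped; only tetrahedral and double-bond stereochemistry are supported")
  }
  db
}
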