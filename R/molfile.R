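#' Read an MDL Mol block into a molecular graph
#'
#' Parses a V2000 connection table.  Wedge (1) and hash (6) bond codes are
#' converted to tetrahedral stereo descriptors and 2D/3D geometry is
#' converted to double-bond stereo descriptors.  Atom order is preserved from
#' file order.  Charges are taken from `M  CHG` lines (which override the
#' legacy atom-block charge column) and isotopes from `M  ISO`.  Implicit
#' hydrogens are filled from the OpenSMILES organic-subset valence table
#' unless the atom block carries an explicit valence field.
#'
#' Stereo perception from a drawing is local: a tetrahedral centre is
#' perceived only where a wedge/hash starts at it (2D) or from coordinates
#' (3D), and double-bond stereo only for bonds outside rings of size 7 or
#' less whose ends carry distinguishable substituents at depth one.
#' Whether a perceived centre is *canonically* stereogenic is ultimately
#' decided by the InChI downstream.
#'
#' @param text a character scalar (whole Mol block) or character vector of
#'   lines
#' @param perceive re-perceive aromaticity after reading (default TRUE)
#' @return a [molgraph()]
#' @export
read_molfile <- function(text, perceive = TRUE) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 4L) stop("Mol block too short (line 4 missing)")
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds))
    stop("malformed counts line (line 4): ", encodeString(counts, quote = '"'))

  num <- function(s) suppressWarnings(as.numeric(s))
  at <- data.frame(element = character(natoms), isotope = 0L, charge = 0L,
                   hcount = NA_integer_, aromatic = FALSE,
                   stringsAsFactors = FALSE)
  xyz <- matrix(0, max(natoms, 1L), 3)
  valence_field <- integer(natoms)
  for (i in seq_len(natoms)) {
    ln <- lines[4L + i]
    if (is.na(ln)) stop(sprintf("atom block truncated at line %d", 4L + i))
    xyz[i, ] <- c(num(substr(ln, 1, 10)), num(substr(ln, 11, 20)),
                  num(substr(ln, 21, 30)))
    sym <- trimws(substr(ln, 32, 34))
    if (sym == "D") { sym <- "H"; at$isotope[i] <- 2L }
    if (sym == "T") { sym <- "H"; at$isotope[i] <- 3L }
    if (!sym %in% ELEMENTS)
      stop(sprintf("unknown element '%s' in atom block line %d", sym, 4L + i))
    at$element[i] <- sym
    chg <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    if (!is.na(chg) && chg %in% c(1:3, 5:7))
      at$charge[i] <- c(3L, 2L, 1L, 0L, -1L, -2L, -3L)[chg]
    val <- suppressWarnings(as.integer(substr(ln, 49, 51)))
    if (!is.na(val)) valence_field[i] <- val
    if (anyNA(xyz[i, ]))
      stop(sprintf("malformed coordinates in atom block line %d", 4L + i))
  }
  bd <- data.frame(a = integer(nbonds), b = integer(nbonds),
                   order = integer(nbonds), aromatic = logical(nbonds),
                   wedge = integer(nbonds))
  for (k in seq_len(nbonds)) {
    ln <- lines[4L + natoms + k]
    if (is.na(ln)) stop(sprintf("bond block truncated at line %d", 4L + natoms + k))
    a <- suppressWarnings(as.integer(substr(ln, 1, 3)))
    b <- suppressWarnings(as.integer(substr(ln, 4, 6)))
    o <- suppressWarnings(as.integer(substr(ln, 7, 9)))
    w <- suppressWarnings(as.integer(substr(ln, 10, 12)))
    if (is.na(a) || is.na(b) || is.na(o))
      stop(sprintf("malformed bond block line %d", 4L + natoms + k))
    if (o == 4L) { bd$aromatic[k] <- TRUE; o <- 1L; at$aromatic[c(a, b)] <- TRUE }
    if (!o %in% 1:3)
      stop(sprintf("unsupported bond type %d at line %d", o, 4L + natoms + k))
    bd$a[k] <- a; bd$b[k] <- b; bd$order[k] <- o
    bd$wedge[k] <- if (!is.na(w)) w else 0L
  }
  # property block: M CHG/ISO; the presence of any M CHG resets legacy charges
  prop <- lines[-(seq_len(4L + natoms + nbonds))]
  if (any(startsWith(prop, "M  CHG"))) at$charge <- rep(0L, natoms)
  for (ln in prop) {
    tag <- substr(ln, 1, 6)
    if (tag == "M  END") break
    if (tag %in% c("M  CHG", "M  ISO")) {
      cnt <- as.integer(substr(ln, 7, 9))
      for (e in seq_len(cnt)) {
        off <- 10L + (e - 1L) * 8L
        idx <- as.integer(substr(ln, off, off + 3L))
        val <- as.integer(substr(ln, off + 4L, off + 7L))
        if (tag == "M  CHG") at$charge[idx] <- val else at$isotope[idx] <- val
      }
    }
  }

  if (any(at$aromatic)) {
    kk <- kekulize(at, bd)
    at <- kk$atoms; bd <- kk$bonds
  }

  bondsum <- integer(natoms)
  for (k in seq_len(nbonds)) {
    bondsum[bd$a[k]] <- bondsum[bd$a[k]] + bd$order[k]
    bondsum[bd$b[k]] <- bondsum[bd$b[k]] + bd$order[k]
  }
  for (i in seq_len(natoms)) {
    at$hcount[i] <- if (valence_field[i] == 15L) 0L
    else if (valence_field[i] > 0L) max(0L, valence_field[i] - bondsum[i])
    else implicit_h_for(at$element[i], at$charge[i], bondsum[i])
  }

  wedge_from <- bd$a  # narrow end of a wedge, before a<b normalisation
  bd2 <- bd[, c("a", "b", "order", "aromatic")]
  sw <- bd2$a > bd2$b
  if (any(sw)) { tmp <- bd2$a[sw]; bd2$a[sw] <- bd2$b[sw]; bd2$b[sw] <- tmp }
  g <- molgraph(at, bd2)

  dims <- if (all(abs(xyz[, 3]) < 1e-6)) 2L else 3L
  flat <- natoms == 0L || all(abs(xyz) < 1e-6)
  if (!flat) {
    g$tet <- .perceive_tet_from_geometry(g, xyz, bd$wedge, wedge_from, dims)
    g$db <- .perceive_db_from_geometry(g, xyz, dims)
  }
  if (perceive) g <- perceive_aromaticity(g)
  g
}

#' Split an SD file into Mol blocks
#'
#' @param text character scalar or vector of lines of an SD file
#' @return named list of character vectors (one Mol block per record,
#'   property data stripped); names are the record title lines
#' @export
split_sdf <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  recs <- list()
  take <- function(chunk) {
    end <- which(startsWith(chunk, "M  END"))
    if (!length(end)) return()
    chunk <- chunk[seq_len(end[1])]
    recs[[length(recs) + 1L]] <<- chunk
    names(recs)[length(recs)] <<- trimws(chunk[1])
  }
  start <- 1L
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], "$$$$")) { take(lines[start:(i - 1L)]); start <- i + 1L }
  }
  if (start <= length(lines)) take(lines[start:length(lines)])
  recs
}

# Tetrahedral centres from wedge/hash codes plus coordinates.  A wedge is
# honoured only when its first atom is the candidate centre (standard MDL
# interpretation).
.perceive_tet_from_geometry <- function(g, xyz, wedge, wedge_from, dims) {
  at <- g$atoms; bd <- g$bonds
  n <- nrow(at)
  adj <- mg_adjacency(g)
  tet <- list()
  for (v in seq_len(n)) {
    ks <- adj[[v]]$bond
    if (length(ks) < 3L || length(ks) > 4L) next
    if (any(bd$order[ks] != 1L)) next
    nbrs <- adj[[v]]$nbr
    nh <- at$hcount[v]
    if (!(length(nbrs) == 4L || (length(nbrs) == 3L && nh == 1L))) next
    # >= 2 equivalent plain hydrogens: certainly not stereogenic
    plain_h <- sum(at$element[nbrs] == "H" & at$isotope[nbrs] == 0L)
    if (plain_h + nh >= 2L) next
    wz <- numeric(length(ks))
    if (dims == 2L) {
      # wedge codes live on the original (unsorted) bond rows; match by pair
      for (t in seq_along(ks)) {
        k <- ks[t]
        if (wedge_from[k] != v) next
        if (wedge[k] == 1L) wz[t] <- 1
        if (wedge[k] == 6L) wz[t] <- -1
      }
      if (all(wz == 0)) next
    }
    vecs <- lapply(seq_along(nbrs), function(t) {
      w <- nbrs[t]
      c(xyz[w, 1] - xyz[v, 1], xyz[w, 2] - xyz[v, 2],
        if (dims == 2L) wz[t] else xyz[w, 3] - xyz[v, 3])
    })
    nb4 <- nbrs
    if (length(nbrs) == 3L) {
      vecs[[4]] <- -(vecs[[1]] + vecs[[2]] + vecs[[3]])
      nb4 <- c(nbrs, 0L)
    }
    m <- cbind(vecs[[2]] - vecs[[1]], vecs[[3]] - vecs[[1]], vecs[[4]] - vecs[[1]])
    d <- det(m)
    if (abs(d) < 1e-9) next
    winding <- if (d < 0) "acw" else "cw"
    tet[[length(tet) + 1L]] <- list(center = v, nbrs = as.integer(nb4),
                                    winding = winding)
  }
  tet
}

# Double-bond stereo from geometry.  Skips aromatic and small-ring (<= 7)
# bonds and ends whose substituents are indistinguishable at depth one.
.perceive_db_from_geometry <- function(g, xyz, dims) {
  at <- g$atoms; bd <- g$bonds
  db <- list()
  adj <- mg_adjacency(g)
  rings <- find_rings(g, max_size = 7L)
  small_ring_bond <- function(i, j)
    any(vapply(rings, function(r) i %in% r && j %in% r, logical(1)))
  sig <- function(v) paste(at$element[v], at$isotope[v], at$charge[v],
                           length(adj[[v]]$nbr))
  for (k in seq_len(nrow(bd))) {
    if (bd$order[k] != 2L || bd$aromatic[k]) next
    i <- bd$a[k]; j <- bd$b[k]
    if (!at$element[i] %in% c("C", "N") || !at$element[j] %in% c("C", "N")) next
    if (small_ring_bond(i, j)) next
    end_ok <- function(v) {
      subs <- setdiff(adj[[v]]$nbr, c(i, j))
      nh <- at$hcount[v]
      if (length(subs) + nh > 2L) return(NULL)          # not sp2
      if (length(subs) == 0L) return(NULL)              # =CH2 / =N-H only
      if (length(subs) == 2L && sig(subs[1]) == sig(subs[2])) return(NULL)
      subs
    }
    si <- end_ok(i); sj <- end_ok(j)
    if (is.null(si) || is.null(sj)) next
    ra <- si[1]; rb <- sj[1]
    if (dims == 2L) {
      axis <- xyz[j, 1:2] - xyz[i, 1:2]
      side <- function(p, origin) {
        v <- xyz[p, 1:2] - xyz[origin, 1:2]
        axis[1] * v[2] - axis[2] * v[1]
      }
      sa <- side(ra, i); sb <- side(rb, j)
      if (abs(sa) < 1e-6 || abs(sb) < 1e-6) next        # collinear: undefined
      cfg <- if (sign(sa) == sign(sb)) "together" else "opposite"
    } else {
      ax <- xyz[j, ] - xyz[i, ]
      ax <- ax / sqrt(sum(ax^2))
      u <- xyz[ra, ] - xyz[i, ]; w <- xyz[rb, ] - xyz[j, ]
      u <- u - sum(u * ax) * ax; w <- w - sum(w * ax) * ax
      nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
      if (nu < 1e-6 || nw < 1e-6) next
      cosang <- sum(u * w) / (nu * nw)
      if (abs(cosang) < 0.1) next                       # near-perpendicular
      cfg <- if (cosang > 0) "together" else "opposite"
    }
    db[[length(db) + 1L]] <- list(a = i, b = j, ref_a = ra, ref_b = rb,
                                  config = cfg)
  }
  db
}
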