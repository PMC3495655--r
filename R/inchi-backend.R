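#' @title InChI backend adapter
#' @description
#' The InChI canonicalisation algorithm has a single reference
#' implementation and is consumed here through the Open Babel command-line
#' program (`obabel`), never reimplemented.  The adapter isolates exactly
#' two operations -- structure to InChI+AuxInfo, and InChI back to a
#' normalised structure in canonical atom order -- so a different backend
#' could be swapped in.  Calls are batched (many records per `obabel`
#' invocation) and memoised within the session.
#' @name inchi_backend
NULL

.backend_env <- new.env(parent = emptyenv())

.obabel <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p))
    stop("the 'obabel' program (Open Babel with InChI support) is required but was not found on the PATH")
  p
}

.run_obabel <- function(args, input_lines) {
  inf <- tempfile(fileext = ".txt")
  ef <- tempfile(fileext = ".err")
  on.exit(unlink(c(inf, ef)), add = TRUE)
  writeLines(input_lines, inf)
  out <- suppressWarnings(
    system2(.obabel(), c(inf, args), stdout = TRUE, stderr = ef))
  errl <- tryCatch(readLines(ef, warn = FALSE), error = function(e) character(0))
  list(stdout = out, stderr = errl)
}

# warnings per record id from obabel stderr ("  <id> :<message>")
.parse_backend_warnings <- function(errlines) {
  m <- regmatches(errlines, regexec("^  (\\S+) :(.*)$", errlines))
  m <- Filter(length, m)
  if (!length(m)) return(list())
  ids <- vapply(m, `[[`, "", 2)
  msg <- trimws(vapply(m, `[[`, "", 3))
  split(msg, ids)
}

#' InChI generation options
#'
#' Universal SMILES uses the non-standard options FixedH (adds a
#' fixed-hydrogen layer so protonation-equivalent atoms keep distinct
#' labels) and RecMet (reconnects metal-ligand bonds); Inchified SMILES uses
#' the Standard InChI (both off).
#'
#' @param fixed_h include the fixed-hydrogen layer
#' @param rec_met reconnect disconnected metals
#' @return a list of class `inchi_options`
#' @export
inchi_options <- function(fixed_h = FALSE, rec_met = FALSE) {
  structure(list(fixed_h = isTRUE(fixed_h), rec_met = isTRUE(rec_met)),
            class = "inchi_options")
}

#' Generate InChI and auxiliary information for molecular graphs
#'
#' Hands each graph to the backend as a Kekule input-order SMILES and
#' returns the InChI, AuxInfo and backend warnings.  The element
#' `atom_map` of each result maps backend input atom numbers (used in the
#' AuxInfo `/N:` layer) back to atom indices of the graph.
#'
#' @param gs a `molgraph` or list of them
#' @param opts an [inchi_options()] object
#' @return a list of results, each a list with `inchi`, `auxinfo`,
#'   `warnings`, `atom_map` and `error` (`NA` unless generation failed)
#' @export
to_inchi <- function(gs, opts = inchi_options()) {
  single <- inherits(gs, "molgraph")
  if (single) gs <- list(gs)
  smis <- character(length(gs)); maps <- vector("list", length(gs))
  for (i in seq_along(gs)) {
    s <- write_smiles(gs[[i]], kekule = TRUE)
    smis[i] <- s
    maps[[i]] <- attr(s, "atom_order")
  }
  res <- .inchi_from_smiles(smis, opts)
  for (i in seq_along(res)) res[[i]]$atom_map <- maps[[i]]
  if (single) res[[1]] else res
}

# vectorised, cached SMILES -> InChI+AuxInfo
.inchi_from_smiles <- function(smis, opts) {
  key <- paste0(if (opts$fixed_h) "F" else "f", if (opts$rec_met) "R" else "r",
                "|", smis)
  res <- vector("list", length(smis))
  cached <- vapply(key, function(k) !is.null(.backend_env[[k]]), logical(1))
  for (i in which(cached)) res[[i]] <- .backend_env[[key[i]]]
  todo <- which(!cached)
  if (length(todo)) {
    ids <- sprintf("q%d", todo)
    xopts <- paste(c(if (opts$fixed_h) "FixedH", if (opts$rec_met) "RecMet"),
                   collapse = " ")
    args <- c("-ismi", "-oinchi", "-xa", "-xt")
    if (nzchar(xopts)) args <- c(args, "-xX", shQuote(xopts))
    run <- .run_obabel(args, paste(smis[todo], ids))
    warns <- .parse_backend_warnings(run$stderr)
    got <- list()
    lines <- run$stdout
    li <- 1L
    while (li <= length(lines)) {
      ln <- lines[li]
      if (startsWith(ln, "InChI=")) {
        toks <- strsplit(ln, "[ \t]+")[[1]]
        id <- toks[length(toks)]
        aux <- if (li < length(lines) && startsWith(lines[li + 1L], "AuxInfo="))
          lines[li + 1L] else NA_character_
        got[[id]] <- list(inchi = toks[1], auxinfo = aux)
        li <- li + if (is.na(aux)) 1L else 2L
      } else li <- li + 1L
    }
    for (i in todo) {
      id <- sprintf("q%d", i)
      w <- warns[[id]] %||% character(0)
      if (is.null(got[[id]])) {
        res[[i]] <- list(inchi = NA_character_, auxinfo = NA_character_,
                         warnings = w,
                         error = paste0("InChI generation failed",
                                        if (length(w)) paste0(": ", paste(w, collapse = "; "))))
      } else {
        res[[i]] <- list(inchi = got[[id]]$inchi, auxinfo = got[[id]]$auxinfo,
                         warnings = w, error = NA_character_)
        .backend_env[[key[i]]] <- res[[i]]
      }
    }
  }
  res
}

#' Convert InChI strings back to normalised molecular graphs
#'
#' The backend reconstructs the (InChI-normalised) structure, which is then
#' re-read and relabelled so that atom order equals the InChI canonical
#' order: the backend's structure is written out as SMILES, parsed, and the
#' canonical labels of a regenerated Standard InChI are applied as a
#' permutation.  Explicit hydrogens (e.g. isotopes) sort after the heavy
#' atoms.
#'
#' @param inchis character vector of InChI strings
#' @return a list of results, each a list with `graph` (a [molgraph()] in
#'   canonical atom order, or `NULL` on failure), `warnings` and `error`
#' @export
from_inchi <- function(inchis) {
  res <- vector("list", length(inchis))
  key <- paste0("I|", inchis)
  cached <- vapply(key, function(k) !is.null(.backend_env[[k]]), logical(1))
  for (i in which(cached)) res[[i]] <- .backend_env[[key[i]]]
  todo <- which(!cached)
  if (length(todo)) {
    ids <- sprintf("q%d", todo)
    run <- .run_obabel(c("-iinchi", "-an", "-osmi"),
                       paste(inchis[todo], ids))
    warns <- .parse_backend_warnings(run$stderr)
    smi_by_id <- list()
    for (ln in run$stdout) {
      toks <- strsplit(ln, "[ \t]+")[[1]]
      if (length(toks) >= 2L) smi_by_id[[toks[length(toks)]]] <- toks[1]
    }
    for (i in todo) {
      id <- sprintf("q%d", i)
      w <- warns[[id]] %||% character(0)
      smi <- smi_by_id[[id]]
      res[[i]] <- if (is.null(smi)) {
        list(graph = NULL, warnings = w,
             error = "InChI could not be converted back to a structure")
      } else {
        tryCatch({
          g <- read_smiles(smi)
          g <- .to_canonical_order(g)
          g <- .repair_db_from_inchi(g, inchis[i])
          list(graph = g, warnings = w, error = NA_character_)
        }, error = function(e) {
          list(graph = NULL, warnings = w, error = conditionMessage(e))
        })
      }
      if (is.na(res[[i]]$error)) .backend_env[[key[i]]] <- res[[i]]
    }
  }
  res
}

# permute a graph into Standard-InChI canonical atom order
.to_canonical_order <- function(g) {
  n <- mg_natoms(g)
  if (n <= 1L) return(g)
  r <- to_inchi(g, inchi_options())
  if (!is.na(r$error)) stop(r$error)
  ranks <- .graph_ranks(g, r)
  perm <- integer(n)
  lab <- !is.na(ranks)
  perm[lab] <- rank(ranks[lab], ties.method = "first")
  perm[!lab] <- sum(lab) + seq_len(sum(!lab))
  mg_relabel(g, perm)
}

# Recover double-bond stereo dropped by the backend's SMILES writer (for
# example, Open Babel suppresses stereo on double bonds in rings of size 8
# or less) directly from the InChI /b layer.  The graph is in canonical
# order, so /b atom numbers are graph indices (offset per component).  The
# parity references are the highest-canonically-numbered heavy neighbours
# at each end; '+' means they sit on opposite sides.
.repair_db_from_inchi <- function(g, inchi) {
  m <- regmatches(inchi, regexec("/b([^/]+)", inchi))[[1]]
  if (length(m) < 2L) return(g)
  content <- m[2]
  if (grepl("*", content, fixed = TRUE)) return(g)  # multiplied components
  comp <- mg_components(g)
  heavy <- g$atoms$element != "H"
  # canonical labels are contiguous per component in order of appearance
  comp_sizes <- vapply(unique(comp), function(cid) sum(comp == cid & heavy), 0L)
  offsets <- c(0L, cumsum(comp_sizes))
  adj <- mg_adjacency(g)
  comps <- strsplit(content, ";", fixed = TRUE)[[1]]
  for (ci in seq_along(comps)) {
    if (!nzchar(comps[ci]) || ci > length(offsets) - 1L) next
    for (ent in strsplit(comps[ci], ",", fixed = TRUE)[[1]]) {
      em <- regmatches(ent, regexec("^([0-9]+)-([0-9]+)([+?-])$", ent))[[1]]
      if (length(em) < 4L || em[4] == "?") next
      i <- as.integer(em[3]) + offsets[ci]
      j <- as.integer(em[2]) + offsets[ci]
      k <- mg_bond_between(g, i, j)
      if (is.na(k) || g$bonds$order[k] != 2L) next
      if (any(vapply(g$db, function(d)
        (d$a == i & d$b == j) | (d$a == j & d$b == i), logical(1)))) next
      ref_for <- function(v, other) {
        nb <- setdiff(adj[[v]]$nbr, other)
        nb <- nb[heavy[nb] & vapply(nb, function(w)
          g$bonds$order[mg_bond_between(g, v, w)] == 1L, logical(1))]
        if (!length(nb)) NA_integer_ else max(nb)
      }
      ri <- ref_for(i, j); rj <- ref_for(j, i)
      if (is.na(ri) || is.na(rj)) next
      g$db[[length(g$db) + 1L]] <- list(
        a = i, b = j, ref_a = ri, ref_b = rj,
        config = if (em[4] == "+") "opposite" else "together")
    }
  }
  g
}

# remap AuxInfo input-atom labels onto graph atom indices via atom_map
.graph_ranks <- function(g, inchi_result) {
  n <- mg_natoms(g)
  ranks <- rep(NA_real_, n)
  if (is.na(inchi_result$auxinfo)) {
    if (n == 1L) { ranks[1] <- 1; return(ranks) }
    stop("backend returned no auxiliary information")
  }
  lab <- tryCatch(extract_labels(parse_auxinfo(inchi_result$auxinfo)),
                  error = function(e) NULL)
  if (is.null(lab)) {
    if (n == 1L) { ranks[1] <- 1; return(ranks) }
    stop("could not extract canonical labels from auxiliary information")
  }
  amap <- inchi_result$atom_map
  for (p in seq_along(lab$rank)) {
    if (is.na(lab$rank[p])) next
    if (p > length(amap)) stop("AuxInfo refers to an atom beyond the input")
    ranks[amap[p]] <- lab$rank[p]
  }
  if (all(is.na(ranks)) && n == 1L) ranks[1] <- 1
  ranks
}
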