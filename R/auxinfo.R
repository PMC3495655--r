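#' Parse an InChI auxiliary-information string
#'
#' The auxiliary information emitted alongside an InChI contains, among other
#' layers, the correspondence between input atom numbers and canonical
#' labels: `/N:` for the base structure, `/F:` for the fixed-hydrogen
#' variant, and a nested `/R:` record (with its own `/N:` and `/F:`) when a
#' disconnected metal has been reconnected.  Components are separated by
#' semicolons; an `m` entry in `/F:` means "same as the corresponding `/N:`
#' component" and a `k*...` prefix repeats a component, both of which are
#' expanded here.
#'
#' Layers not needed for label extraction (`/E:`, `/gE:`, `/rA:` ...) are
#' retained verbatim for diagnostics.
#'
#' @param text an AuxInfo string (must begin with `"AuxInfo="`)
#' @return an object of class `auxinfo_record`: a list with `version`,
#'   `norm_type`, `n_layer` and `f_layer` (lists of integer vectors per
#'   component, `f_layer` may be `NULL`), `r_record` (nested
#'   `auxinfo_record` or `NULL`), `layers` (named character of raw layer
#'   contents in order) and `raw` (the input string)
#' @export
parse_auxinfo <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!startsWith(text, "AuxInfo="))
    stop("not an AuxInfo string: ", encodeString(substr(text, 1, 40), quote = '"'))
  body <- substring(text, nchar("AuxInfo=") + 1L)
  parts <- strsplit(body, "/", fixed = TRUE)[[1]]
  if (length(parts) < 2L) stop("AuxInfo too short: ", text)
  version <- parts[1]
  norm_type <- parts[2]
  rec <- .parse_auxinfo_layers(parts[-(1:2)], raw = text)
  rec$version <- version
  rec$norm_type <- norm_type
  rec
}

.parse_auxinfo_layers <- function(parts, raw = NULL) {
  layers <- character(0)
  n_layer <- NULL; f_layer_raw <- NULL
  r_record <- NULL
  norm_type <- NULL
  i <- 1L
  while (i <= length(parts)) {
    p <- parts[i]
    if (p == "") { i <- i + 1L; next }
    if (grepl("^[0-9]+$", p) && is.null(norm_type) && !length(layers)) {
      # nested records restate a normalisation-type segment (e.g. "/R:/0/N:")
      norm_type <- p; i <- i + 1L; next
    }
    m <- regmatches(p, regexec("^([A-Za-z]+)(?::(.*))?$", p, perl = TRUE))[[1]]
    if (!length(m))
      stop("unrecognised AuxInfo layer ", encodeString(p, quote = '"'),
           " in ", encodeString(raw %||% paste(parts, collapse = "/"), quote = '"'))
    prefix <- m[2]; content <- m[3]
    if (prefix == "R") {
      # the reconnected-metal record spans the remainder of the string
      rest <- c(content, parts[seq_along(parts) > i])
      r_record <- .parse_auxinfo_layers(rest, raw = raw)
      layers <- c(layers, stats::setNames(paste(rest, collapse = "/"), "R"))
      break
    }
    layers <- c(layers, stats::setNames(content, prefix))
    if (prefix == "N" && is.null(n_layer)) n_layer <- .parse_label_lists(content)
    if (prefix == "F" && is.null(f_layer_raw)) f_layer_raw <- content
    i <- i + 1L
  }
  f_layer <- if (!is.null(f_layer_raw))
    .parse_label_lists(f_layer_raw, fallback = n_layer) else NULL
  structure(list(version = NULL, norm_type = norm_type, n_layer = n_layer,
                 f_layer = f_layer, r_record = r_record, layers = layers,
                 raw = raw),
            class = "auxinfo_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# "2,3;1" -> list(c(2,3), 1); "m" components fall back to the /N component;
# "k*..." repeats a component k times
.parse_label_lists <- function(content, fallback = NULL) {
  comps <- strsplit(content, ";", fixed = TRUE)[[1]]
  if (content == "" || !length(comps)) return(list())
  out <- list()
  for (ci in seq_along(comps)) {
    c0 <- comps[ci]
    reps <- 1L
    mm <- regmatches(c0, regexec("^([0-9]+)\\*(.*)$", c0))[[1]]
    if (length(mm)) { reps <- as.integer(mm[2]); c0 <- mm[3] }
    mm <- regmatches(c0, regexec("^([0-9]+)m$", c0))[[1]]
    if (length(mm)) { reps <- reps * as.integer(mm[2]); c0 <- "m" }
    for (r in seq_len(reps)) {
      idx <- length(out) + 1L
      if (c0 == "m") {
        if (is.null(fallback) || idx > length(fallback))
          stop("AuxInfo 'm' component with no corresponding /N component")
        out[[idx]] <- fallback[[idx]]
      } else if (c0 == "") {
        out[[idx]] <- integer(0)
      } else {
        v <- suppressWarnings(as.integer(strsplit(c0, ",", fixed = TRUE)[[1]]))
        if (anyNA(v)) stop("malformed AuxInfo label list: ", c0)
        out[[idx]] <- v
      }
    }
  }
  out
}

#' @export
print.auxinfo_record <- function(x, ...) {
  cat("<auxinfo_record>",
      if (!is.null(x$n_layer)) sprintf("/N %d component(s)", length(x$n_layer)),
      if (!is.null(x$f_layer)) "/F present",
      if (!is.null(x$r_record)) "/R present", "\n")
  invisible(x)
}

#' Extract canonical labels from an AuxInfo record
#'
#' Labels are taken, in order of preference, from the reconnected-metal
#' record's fixed-hydrogen list, the reconnected-metal record's base list,
#' the top-level fixed-hydrogen list, and finally the top-level base list
#' (`/R:/F:` > `/R:/N:` > `/F:` > `/N:`).  Within the chosen list, the atom
#' listed at position *i* of a component receives label *i* plus the sizes
#' of all preceding components, so labels are globally unique and a
#' component's atoms are contiguous.
#'
#' @param rec an `auxinfo_record` from [parse_auxinfo()]
#' @return an object of class `canonical_labeling`: list with `rank` (integer
#'   vector indexed by input atom number; `NA` = no label), `source` (one of
#'   `"N"`, `"F"`, `"R_N"`, `"R_F"`) and `component_order` (component
#'   indices ordered by their lowest label, which is ascending by
#'   construction)
#' @export
extract_labels <- function(rec) {
  stopifnot(inherits(rec, "auxinfo_record"))
  src <- NULL; lists <- NULL
  if (!is.null(rec$r_record)) {
    if (!is.null(rec$r_record$f_layer)) { lists <- rec$r_record$f_layer; src <- "R_F" }
    else if (!is.null(rec$r_record$n_layer)) { lists <- rec$r_record$n_layer; src <- "R_N" }
  }
  if (is.null(lists)) {
    if (!is.null(rec$f_layer)) { lists <- rec$f_layer; src <- "F" }
    else if (!is.null(rec$n_layer)) { lists <- rec$n_layer; src <- "N" }
  }
  if (is.null(lists)) stop("AuxInfo record has no /N layer to extract labels from")
  all_atoms <- unlist(lists)
  if (length(all_atoms) == 0L) {
    return(structure(list(rank = integer(0), source = src,
                          component_order = integer(0)),
                     class = "canonical_labeling"))
  }
  if (anyDuplicated(all_atoms))
    stop("AuxInfo label list is not a permutation: duplicated atom number")
  rank <- rep(NA_integer_, max(all_atoms))
  offset <- 0L
  for (comp in lists) {
    rank[comp] <- offset + seq_along(comp)
    offset <- offset + length(comp)
  }
  structure(list(rank = rank, source = src,
                 component_order = seq_along(lists)),
            class = "canonical_labeling")
}

#' @export
print.canonical_labeling <- function(x, ...) {
  cat(sprintf("<canonical_labeling> %d labelled atom(s), source /%s\n",
              sum(!is.na(x$rank)), sub("_", ":/", x$source)))
  invisible(x)
}

#' Reassemble an AuxInfo record into its string form
#'
#' Inverse of [parse_auxinfo()] for round-trip checking.
#'
#' @param rec an `auxinfo_record`
#' @return character scalar
#' @export
serialize_auxinfo <- function(rec) {
  stopifnot(inherits(rec, "auxinfo_record"))
  body <- paste0(vapply(seq_along(rec$layers), function(i) {
    pre <- names(rec$layers)[i]
    ct <- rec$layers[[i]]
    if (pre == "R" || is.na(ct)) paste0(pre, ":", ct) else paste0(pre, ":", ct)
  }, ""), collapse = "/")
  paste0("AuxInfo=", rec$version, "/", rec$norm_type, "/", body)
}
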