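#' @title Universal and Inchified SMILES generation
#' @description
#' Two canonical SMILES forms built on the InChI canonicalisation:
#'
#' * **Universal SMILES** keeps the original structure (including its
#'   tautomeric state) and orders its atoms by the canonical labels parsed
#'   from the auxiliary information of a non-standard (FixedH + RecMet)
#'   InChI.
#' * **Inchified SMILES** round-trips the structure through the Standard
#'   InChI: the InChI is converted back to a (normalised) structure whose
#'   atoms arrive in canonical order, and that structure is written.  All
#'   Standard-InChI normalisations (nitro/sulfoxide expansion, tautomer
#'   collapse, metal disconnection) carry over.
#'
#' When no normalisation applies the two forms are identical.
#' @name pipeline
NULL

.as_graph_list <- function(x) {
  if (inherits(x, "molgraph")) return(list(x))
  if (is.character(x)) return(lapply(x, read_smiles))
  if (is.list(x)) {
    stopifnot(all(vapply(x, inherits, logical(1), "molgraph")))
    return(x)
  }
  stop("expected a SMILES character vector, a molgraph, or a list of molgraphs")
}

.with_errors <- function(out, errors) {
  attr(out, "errors") <- errors
  out
}

#' Generate Universal SMILES
#'
#' @param x a character vector of SMILES strings, a [molgraph()], or a list
#'   of molgraphs
#' @return character vector of Universal SMILES strings (`NA` where
#'   generation failed); attribute `errors` is a data.frame of failed
#'   records (index, stage, message)
#' @export
universal_smiles <- function(x) {
  gs <- .as_graph_list(x)
  out <- rep(NA_character_, length(gs))
  errors <- data.frame(index = integer(), stage = character(),
                       message = character(), stringsAsFactors = FALSE)
  res <- to_inchi(gs, inchi_options(fixed_h = TRUE, rec_met = TRUE))
  for (i in seq_along(gs)) {
    r <- res[[i]]
    if (!is.na(r$error)) {
      errors[nrow(errors) + 1L, ] <- list(i, "inchi", r$error)
      next
    }
    out[i] <- tryCatch({
      ranks <- .graph_ranks(gs[[i]], r)
      as.character(write_smiles(gs[[i]], ranks))
    }, error = function(e) {
      errors[nrow(errors) + 1L, ] <<- list(i, "write", conditionMessage(e))
      NA_character_
    })
  }
  .with_errors(out, errors)
}

#' Generate Inchified SMILES
#'
#' @inheritParams universal_smiles
#' @return character vector of Inchified SMILES strings (`NA` where
#'   generation failed); attribute `errors` as in [universal_smiles()]
#' @export
inchified_smiles <- function(x) {
  gs <- .as_graph_list(x)
  out <- rep(NA_character_, length(gs))
  errors <- data.frame(index = integer(), stage = character(),
                       message = character(), stringsAsFactors = FALSE)
  res <- to_inchi(gs, inchi_options())
  ok <- which(vapply(res, function(r) is.na(r$error), logical(1)))
  for (i in setdiff(seq_along(gs), ok))
    errors[nrow(errors) + 1L, ] <- list(i, "inchi", res[[i]]$error)
  if (length(ok)) {
    back <- from_inchi(vapply(res[ok], `[[`, "", "inchi"))
    for (t in seq_along(ok)) {
      i <- ok[t]
      b <- back[[t]]
      if (!is.na(b$error)) {
        errors[nrow(errors) + 1L, ] <- list(i, "from_inchi", b$error)
        next
      }
      out[i] <- tryCatch(as.character(write_smiles(b$graph)),
                         error = function(e) {
                           errors[nrow(errors) + 1L, ] <<- list(i, "write", conditionMessage(e))
                           NA_character_
                         })
    }
  }
  .with_errors(out, errors)
}

#' Generate anti-canonical SMILES
#'
#' Writes each structure under uniformly random canonical labels (seeded),
#' producing a deliberately arbitrary -- but reproducible -- output
#' ordering.  Used by the shuffle test to stress order invariance.
#'
#' @inheritParams universal_smiles
#' @param seed integer; record `i` of a vector input uses `seed + i - 1`
#' @return character vector of SMILES strings
#' @export
anticanonical_smiles <- function(x, seed = 1L) {
  gs <- .as_graph_list(x)
  out <- character(length(gs))
  for (i in seq_along(gs)) {
    g <- gs[[i]]
    n <- mg_natoms(g)
    heavy <- which(g$atoms$element != "H")
    if (!length(heavy)) heavy <- seq_len(n)
    ranks <- rep(NA_real_, n)
    ranks[heavy] <- withr::with_seed(as.integer(seed) + i - 1L,
                                     sample.int(length(heavy)))
    out[i] <- as.character(write_smiles(g, ranks))
  }
  out
}

#' Generate canonical SMILES in a given mode
#'
#' @inheritParams universal_smiles
#' @param mode `"universal"`, `"inchified"` or `"anticanonical"`
#' @param seed seed for anti-canonical labelling
#' @return character vector of SMILES strings
#' @export
generate_smiles <- function(x, mode = c("universal", "inchified", "anticanonical"),
                            seed = 1L) {
  mode <- match.arg(mode)
  switch(mode,
         universal = universal_smiles(x),
         inchified = inchified_smiles(x),
         anticanonical = anticanonical_smiles(x, seed))
}
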