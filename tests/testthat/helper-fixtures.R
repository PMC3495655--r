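# Shared helpers: tiny inline fixtures and oracles.

# non-standard (FixedH + RecMet) options used by Universal SMILES
opt_universal <- inchi_options(fixed_h = TRUE, rec_met = TRUE)

# Table-style worked examples: input, expected Universal SMILES
table1_cases <- data.frame(
  smiles = c("OCC", "ClCC(=O)Br", "C.C", "C.CC", "C([H])C", "C([2H])O"),
  universal = c("CCO", "C(C(=O)Br)Cl", "C.C", "CC.C", "CC", "C([2H])O"),
  stringsAsFactors = FALSE
)

# minimal V2000 Mol block builder (2D)
mk_molblock <- function(atoms, bonds, title = "test") {
  # atoms: data.frame(x, y, symbol); bonds: data.frame(a, b, order, wedge)
  hdr <- c(title, "  test  2D", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(atoms), nrow(bonds)))
  ab <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                atoms$x, atoms$y, 0, atoms$symbol)
  bb <- if (nrow(bonds))
    sprintf("%3d%3d%3d%3d  0  0  0", bonds$a, bonds$b, bonds$order,
            if (is.null(bonds$wedge)) rep(0L, nrow(bonds)) else bonds$wedge)
  else character(0)
  c(hdr, ab, bb, "M  END")
}

ethanol_molblock <- mk_molblock(
  data.frame(x = c(0, 1, 2), y = c(0, 0.5, 0), symbol = c("O", "C", "C")),
  data.frame(a = c(1, 2), b = c(2, 3), order = c(1, 1))
)

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

# independent greedy re-derivation of ring-closure digits from an emitted
# SMILES string: returns the digit sequence in order of appearance
rederive_digits <- function(s) {
  chars <- strsplit(s, "")[[1]]
  open <- integer(0)     # digits currently open
  seqd <- integer(0)
  i <- 1L
  in_bracket <- FALSE
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") in_bracket <- TRUE
    if (ch == "]") in_bracket <- FALSE
    d <- NA_integer_
    if (!in_bracket && ch >= "0" && ch <= "9") d <- as.integer(ch)
    if (!in_bracket && ch == "%") {
      d <- as.integer(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 2L
    }
    if (!is.na(d)) {
      seqd <- c(seqd, d)
      if (d %in% open) open <- setdiff(open, d) else open <- c(open, d)
    }
    i <- i + 1L
  }
  seqd
}

# greedy lowest-available digit assignment over the opening/closing pattern
# of an emitted digit sequence (openings take the smallest free digit)
greedy_digits <- function(seqd) {
  free <- rep(TRUE, 99L)
  open_map <- list()
  out <- integer(0)
  open <- integer(0)
  for (d in seqd) {
    key <- as.character(d)
    if (!is.null(open_map[[key]])) {
      out <- c(out, open_map[[key]])
      free[open_map[[key]]] <- TRUE
      open_map[[key]] <- NULL
    } else {
      nd <- which(free)[1]
      free[nd] <- FALSE
      open_map[[key]] <- nd
      out <- c(out, nd)
    }
  }
  out
}
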