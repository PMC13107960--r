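# SMILES -> molecular graph. The annotation layer always works on Open Babel
# canonical SMILES, so atom indices here (0-based, in order of appearance) are
# the reproducible position convention used throughout the package.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
DEFAULT_VALENCE <- list(B = 3, C = 4, N = 3, O = 2, P = c(3, 5),
                        S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

#' Parse a SMILES string into a molecular graph
#'
#' Supports the constructs Open Babel emits for canonical drug-like SMILES:
#' organic-subset atoms, aromatic lowercase atoms, bracket atoms with charge
#' and explicit H, branches, ring closures (incl. `%nn`), bond symbols
#' `- = # :` (`/` and `\\` are read as single bonds; stereo is not modelled),
#' and dot-separated components. Implicit hydrogens follow the standard
#' valence model (aromatic atoms contribute one extra unit to the bond-order
#' sum).
#'
#' @param smiles a single SMILES string
#' @return an object of class `molgraph`: list with `atoms` (data.frame:
#'   element, aromatic, charge, h_count, idx 0-based) and `bonds` (data.frame:
#'   i, j 0-based, order, aromatic)
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    nmg_stop("parse_error", "SMILES must be a non-empty string", smiles = smiles)
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  atoms <- list()   # element, aromatic, charge, h_explicit (NA = implicit)
  bonds <- list()
  stack <- integer(0)
  prev <- NA_integer_
  pending_bond <- NULL    # NULL = default
  rings <- list()         # ring digit -> list(atom, bond)

  add_atom <- function(element, aromatic, charge = 0L, h = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, aromatic = aromatic,
                                         charge = charge, h = h)
    length(atoms)
  }
  add_bond <- function(a, b, sym) {
    if (is.null(sym)) {
      arom <- atoms[[a]]$aromatic && atoms[[b]]$aromatic
      bonds[[length(bonds) + 1L]] <<- list(i = a, j = b,
                                           order = 1L, aromatic = arom)
    } else {
      order <- switch(sym, "-" = 1L, "/" = 1L, "\\" = 1L, "=" = 2L,
                      "#" = 3L, ":" = 1L)
      bonds[[length(bonds) + 1L]] <<- list(i = a, j = b, order = order,
                                           aromatic = identical(sym, ":"))
    }
  }
  link <- function(idx) {
    if (!is.na(prev)) add_bond(prev, idx, pending_bond)
    pending_bond <<- NULL
    prev <<- idx
  }
  ring_closure <- function(key) {
    if (!is.null(rings[[key]])) {
      open <- rings[[key]]
      b <- if (!is.null(pending_bond)) pending_bond else open$bond
      add_bond(open$atom, prev, b)
      rings[[key]] <<- NULL
      pending_bond <<- NULL
    } else {
      rings[[key]] <- list(atom = prev, bond = pending_bond)
      rings[[key]] <<- rings[[key]]
      pending_bond <<- NULL
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= n) { if (chars[j] == "]") { close <- j; break }; j <- j + 1L }
      if (is.na(close))
        nmg_stop("parse_error", "unclosed bracket atom", smiles = smiles)
      spec <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      at <- parse_bracket_atom(spec, smiles)
      idx <- add_atom(at$element, at$aromatic, at$charge, at$h)
      link(idx)
      i <- close + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      idx <- add_atom(paste0(ch, chars[i + 1L]), FALSE)
      link(idx); i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET) {
      idx <- add_atom(ch, FALSE)
      link(idx); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), TRUE)
      link(idx); i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) nmg_stop("parse_error", "branch before any atom", smiles = smiles)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L)
        nmg_stop("parse_error", "unbalanced parentheses", smiles = smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      ring_closure(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) nmg_stop("parse_error", "truncated %nn ring bond", smiles = smiles)
      ring_closure(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_; pending_bond <- NULL; i <- i + 1L
    } else {
      nmg_stop("parse_error", sprintf("unexpected character '%s' in SMILES", ch),
               smiles = smiles)
    }
  }
  if (length(stack) > 0L)
    nmg_stop("parse_error", "unbalanced parentheses", smiles = smiles)
  if (length(Filter(Negate(is.null), rings)) > 0L)
    nmg_stop("parse_error", "unmatched ring-closure digit", smiles = smiles)
  if (length(atoms) == 0L)
    nmg_stop("parse_error", "no atoms in SMILES", smiles = smiles)

  adf <- data.frame(
    element = vapply(atoms, `[[`, character(1), "element"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    h_explicit = vapply(atoms, `[[`, integer(1), "h"),
    stringsAsFactors = FALSE
  )
  bdf <- if (length(bonds)) data.frame(
    i = vapply(bonds, `[[`, integer(1), "i") - 1L,
    j = vapply(bonds, `[[`, integer(1), "j") - 1L,
    order = vapply(bonds, `[[`, integer(1), "order"),
    aromatic = vapply(bonds, `[[`, logical(1), "aromatic")
  ) else data.frame(i = integer(0), j = integer(0), order = integer(0),
                    aromatic = logical(0))

  adf$h_count <- implicit_h(adf, bdf)
  adf$idx <- seq_len(nrow(adf)) - 1L
  structure(list(atoms = adf, bonds = bdf, smiles = smiles), class = "molgraph")
}

parse_bracket_atom <- function(spec, smiles) {
  parts <- regmatches(spec, regexec(
    "^([0-9]*)(se|as|[A-Z][a-z]?|[bcnops])(@{0,2})(H([0-9]*))?([+-]+[0-9]*|)$", spec))[[1]]
  if (length(parts) == 0 || !nzchar(parts[3]))
    nmg_stop("parse_error", sprintf("cannot parse bracket atom [%s]", spec),
             smiles = smiles)
  sym <- parts[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  element <- if (aromatic) {
    paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
  } else sym
  h <- if (nzchar(parts[5])) {
    if (nzchar(parts[6])) as.integer(parts[6]) else 1L
  } else 0L  # bracket atoms: hydrogens are explicit only
  chg_s <- parts[7]
  charge <- if (!nzchar(chg_s)) 0L else {
    sign <- if (substr(chg_s, 1, 1) == "+") 1L else -1L
    digits <- gsub("[+-]", "", chg_s)
    if (nzchar(digits)) sign * as.integer(digits)
    else sign * nchar(chg_s)
  }
  list(element = element, aromatic = aromatic, charge = charge, h = h)
}

# Implicit hydrogen counts under the standard valence model.
implicit_h <- function(atoms, bonds) {
  n <- nrow(atoms)
  bsum <- numeric(n)
  if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    o <- if (bonds$aromatic[k]) 1 else bonds$order[k]
    bsum[bonds$i[k] + 1L] <- bsum[bonds$i[k] + 1L] + o
    bsum[bonds$j[k] + 1L] <- bsum[bonds$j[k] + 1L] + o
  }
  out <- integer(n)
  for (a in seq_len(n)) {
    if (!is.na(atoms$h_explicit[a])) { out[a] <- atoms$h_explicit[a]; next }
    el <- atoms$element[a]
    val <- DEFAULT_VALENCE[[el]]
    if (is.null(val)) { out[a] <- 0L; next }
    # aromatic B/C/N/P carry one valence unit in the pi system; aromatic O/S
    # contribute a lone pair instead, so no correction there
    eff <- bsum[a] + if (atoms$aromatic[a] && el %in% c("B", "C", "N", "P")) 1 else 0
    cand <- val[val >= eff]
    out[a] <- if (length(cand)) as.integer(cand[1] - eff) else 0L
  }
  out
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %s: %d atoms, %d bonds\n",
              x$smiles, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

# total connection count (heavy neighbours + hydrogens), SMARTS 'X' semantics
atom_connectivity <- function(mol) {
  n <- nrow(mol$atoms)
  deg <- integer(n)
  if (nrow(mol$bonds)) {
    tab <- table(factor(c(mol$bonds$i, mol$bonds$j), levels = 0:(n - 1L)))
    deg <- as.integer(tab)
  }
  deg + mol$atoms$h_count
}

# heavy-atom degree, SMARTS 'D' semantics
atom_degree <- function(mol) {
  n <- nrow(mol$atoms)
  if (!nrow(mol$bonds)) return(integer(n))
  as.integer(table(factor(c(mol$bonds$i, mol$bonds$j), levels = 0:(n - 1L))))
}

# logical vector: is each atom in a ring? (bond-in-cycle test via union-find
# on the graph with that bond removed would be O(m^2); molecules here are
# small, so a simple cycle-edge search per bond is fine)
ring_membership <- function(mol) {
  n <- nrow(mol$atoms)
  b <- mol$bonds
  in_ring_atom <- logical(n)
  if (!nrow(b)) return(in_ring_atom)
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k] + 1L]] <- c(adj[[b$i[k] + 1L]], k)
    adj[[b$j[k] + 1L]] <- c(adj[[b$j[k] + 1L]], k)
  }
  for (k in seq_len(nrow(b))) {
    # BFS from i to j avoiding bond k
    src <- b$i[k] + 1L; dst <- b$j[k] + 1L
    seen <- logical(n); seen[src] <- TRUE
    queue <- src; found <- FALSE
    while (length(queue) && !found) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (e == k) next
        w <- if (b$i[e] + 1L == v) b$j[e] + 1L else b$i[e] + 1L
        if (w == dst) { found <- TRUE; break }
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    if (found) { in_ring_atom[src] <- TRUE; in_ring_atom[dst] <- TRUE }
  }
  in_ring_atom
}

# bonds that lie on a cycle (same test as above, returned per bond)
ring_bonds <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(logical(0))
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k] + 1L]] <- c(adj[[b$i[k] + 1L]], k)
    adj[[b$j[k] + 1L]] <- c(adj[[b$j[k] + 1L]], k)
  }
  vapply(seq_len(nrow(b)), function(k) {
    src <- b$i[k] + 1L; dst <- b$j[k] + 1L
    seen <- logical(n); seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (e == k) next
        w <- if (b$i[e] + 1L == v) b$j[e] + 1L else b$i[e] + 1L
        if (w == dst) return(TRUE)
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    FALSE
  }, logical(1))
}
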