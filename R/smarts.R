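# A restricted SMARTS dialect: enough expressive power for the shipped
# functional-group vocabulary, with full access to match atom indices (which
# no installed toolkit binding exposes). Supported:
#   atoms : C, Cl, c (aromatic), a / A / * wildcards, and bracket expressions
#           of primitives joined by ';' (AND, lowest precedence) and ','
#           (OR), each optionally negated with '!':
#           element symbol (aliphatic), lowercase symbol (aromatic),
#           #<n> atomic number (aromaticity-agnostic), X<n> connectivity
#           (heavy + H), D<n> heavy degree, H<n> total hydrogens, R / R0
#           ring membership, +<n> / -<n> formal charge.
#   bonds : default (single-or-aromatic), - (single), = double, # triple,
#           : aromatic, ~ any.
#   plus branches and numeric ring closures.

ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                   Cl = 17, Se = 34, Br = 35, I = 53)

#' Parse a SMARTS-dialect pattern
#'
#' @param pattern pattern string
#' @return object of class `fg_pattern`: atom constraint list + bond list
#' @export
parse_smarts <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    nmg_stop("pattern_error", "pattern must be a non-empty string",
             pattern = pattern)
  chars <- strsplit(pattern, "")[[1]]
  n <- length(chars)
  patoms <- list(); pbonds <- list()
  stack <- integer(0); prev <- NA_integer_
  pending <- NULL; rings <- list()

  push_atom <- function(constr) {
    patoms[[length(patoms) + 1L]] <<- constr
    idx <- length(patoms)
    if (!is.na(prev))
      pbonds[[length(pbonds) + 1L]] <<- list(a = prev, b = idx,
                                             type = pending %||% "default")
    pending <<- NULL
    prev <<- idx
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L; close <- NA_integer_
      while (j <= n) { if (chars[j] == "]") { close <- j; break }; j <- j + 1L }
      if (is.na(close))
        nmg_stop("pattern_error", "unclosed '[' in pattern", pattern = pattern)
      push_atom(parse_atom_expr(paste(chars[(i + 1L):(close - 1L)],
                                      collapse = ""), pattern))
      i <- close + 1L
    } else if (ch %in% c("C", "B") && i < n &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      push_atom(prim_list(element = paste0(ch, chars[i + 1L]), aromatic = FALSE))
      i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET) {
      push_atom(prim_list(element = ch, aromatic = FALSE)); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      push_atom(prim_list(element = toupper(ch), aromatic = TRUE)); i <- i + 1L
    } else if (ch == "a") {
      push_atom(prim_list(aromatic = TRUE)); i <- i + 1L
    } else if (ch == "A") {
      push_atom(prim_list(aromatic = FALSE)); i <- i + 1L
    } else if (ch == "*") {
      push_atom(prim_list()); i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending <- ch; i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack))
        nmg_stop("pattern_error", "unbalanced ')' in pattern", pattern = pattern)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      key <- ch
      if (!is.null(rings[[key]])) {
        pbonds[[length(pbonds) + 1L]] <- list(a = rings[[key]], b = prev,
                                              type = pending %||% "default")
        rings[[key]] <- NULL
      } else rings[[key]] <- prev
      pending <- NULL; i <- i + 1L
    } else {
      nmg_stop("pattern_error",
               sprintf("unsupported pattern character '%s'", ch),
               pattern = pattern)
    }
  }
  if (length(Filter(Negate(is.null), rings)))
    nmg_stop("pattern_error", "unmatched ring closure in pattern",
             pattern = pattern)
  if (!length(patoms))
    nmg_stop("pattern_error", "pattern has no atoms", pattern = pattern)
  structure(list(atoms = patoms, bonds = pbonds, pattern = pattern),
            class = "fg_pattern")
}

# Normalized atom constraint: list of AND-clauses (';'), each a list of
# OR-alternatives (','), each a list of juxtaposed primitives (implicit AND).
prim_list <- function(...) list(list(list(c(list(...)))))

parse_atom_expr <- function(expr, pattern) {
  ands <- strsplit(expr, ";", fixed = TRUE)[[1]]
  if (!length(ands))
    nmg_stop("pattern_error", "empty bracket expression", pattern = pattern)
  lapply(ands, function(clause) {
    ors <- strsplit(clause, ",", fixed = TRUE)[[1]]
    lapply(ors, function(p) tokenize_primitives(p, pattern))
  })
}

# split a juxtaposed primitive run like "!OX2H" into its primitives
tokenize_primitives <- function(p, pattern) {
  prims <- list()
  s <- p
  pat <- paste0("^(!?)(#[0-9]+|X[0-9]+|D[0-9]+|H[0-9]*|R0|R|\\+[0-9]*|-[0-9]*|",
                "se|as|Cl|Br|[A-Z][a-z]|[BCNOPSFI]|[bcnops]|a|A|\\*|@{1,2})")
  while (nzchar(s)) {
    m <- regmatches(s, regexec(pat, s))[[1]]
    if (!length(m))
      nmg_stop("pattern_error",
               sprintf("unsupported primitive at '%s' in '%s'", s, p),
               pattern = pattern)
    prims[[length(prims) + 1L]] <- parse_primitive_token(m[3], m[2] == "!", pattern)
    s <- substr(s, nchar(m[1]) + 1L, nchar(s))
  }
  if (!length(prims))
    nmg_stop("pattern_error", "empty primitive run", pattern = pattern)
  Filter(Negate(is.null), prims)
}

parse_primitive_token <- function(p, neg, pattern) {
  out <- if (grepl("^#", p)) {
    list(atomic_number = as.integer(substr(p, 2, nchar(p))))
  } else if (grepl("^X", p)) {
    list(connectivity = as.integer(substr(p, 2, nchar(p))))
  } else if (grepl("^D", p)) {
    list(degree = as.integer(substr(p, 2, nchar(p))))
  } else if (grepl("^H", p)) {
    list(h_count = if (nchar(p) > 1) as.integer(substr(p, 2, nchar(p))) else 1L)
  } else if (p == "R") {
    list(in_ring = TRUE)
  } else if (p == "R0") {
    list(in_ring = FALSE)
  } else if (grepl("^\\+", p)) {
    list(charge = if (nchar(p) > 1) as.integer(substr(p, 2, nchar(p))) else 1L)
  } else if (grepl("^-", p)) {
    list(charge = -(if (nchar(p) > 1) as.integer(substr(p, 2, nchar(p))) else 1L))
  } else if (grepl("^(se|as|[A-Z][a-z]?)$", p)) {
    list(element = if (p %in% c("se", "as"))
      paste0(toupper(substr(p, 1, 1)), substr(p, 2, 2)) else p,
      aromatic = p %in% c("se", "as"))
  } else if (grepl("^[bcnops]$", p)) {
    list(element = toupper(p), aromatic = TRUE)
  } else if (p == "a") {
    list(aromatic = TRUE)
  } else if (p == "A") {
    list(aromatic = FALSE)
  } else if (grepl("^@", p)) {
    return(NULL)  # chirality markers are accepted and ignored
  } else if (p == "*") {
    list()
  } else {
    nmg_stop("pattern_error", sprintf("unsupported primitive '%s'", p),
             pattern = pattern)
  }
  out$negate <- neg
  out
}

# Precomputed per-atom features for fast constraint evaluation.
mol_features <- function(mol) {
  list(
    element = mol$atoms$element,
    aromatic = mol$atoms$aromatic,
    charge = mol$atoms$charge,
    h_count = mol$atoms$h_count,
    connectivity = atom_connectivity(mol),
    degree = atom_degree(mol),
    in_ring = ring_membership(mol),
    atomic_number = unname(ATOMIC_NUMBER[mol$atoms$element])
  )
}

prim_ok <- function(prim, feat, a) {
  ok <- TRUE
  if (!is.null(prim$element))
    ok <- ok && feat$element[a] == prim$element &&
      feat$aromatic[a] == prim$aromatic
  else if (!is.null(prim$aromatic))
    ok <- ok && feat$aromatic[a] == prim$aromatic
  if (!is.null(prim$atomic_number))
    ok <- ok && !is.na(feat$atomic_number[a]) &&
      feat$atomic_number[a] == prim$atomic_number
  if (!is.null(prim$connectivity)) ok <- ok && feat$connectivity[a] == prim$connectivity
  if (!is.null(prim$degree)) ok <- ok && feat$degree[a] == prim$degree
  if (!is.null(prim$h_count)) ok <- ok && feat$h_count[a] == prim$h_count
  if (!is.null(prim$in_ring)) ok <- ok && feat$in_ring[a] == prim$in_ring
  if (!is.null(prim$charge)) ok <- ok && feat$charge[a] == prim$charge
  if (isTRUE(prim$negate)) !ok else ok
}

atom_ok <- function(constr, feat, a) {
  for (clause in constr) {
    clause_ok <- FALSE
    for (orpart in clause) {
      if (all(vapply(orpart, prim_ok, logical(1), feat = feat, a = a))) {
        clause_ok <- TRUE; break
      }
    }
    if (!clause_ok) return(FALSE)
  }
  TRUE
}

bond_ok <- function(type, border, barom) {
  switch(type,
         default = (border == 1L && !barom) || barom,
         "-" = border == 1L && !barom,
         "=" = border == 2L,
         "#" = border == 3L,
         ":" = barom,
         "~" = TRUE,
         FALSE)
}

#' Find all matches of a pattern in a molecule
#'
#' Backtracking subgraph matching. Matches mapping the same molecule atom
#' *set* (symmetric/automorphic duplicates) are collapsed to one instance.
#'
#' @param mol a `molgraph`
#' @param pattern an `fg_pattern` (or pattern string)
#' @return list of integer vectors of 0-based atom indices, one per instance,
#'   in pattern-atom order
#' @export
match_pattern <- function(mol, pattern) {
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  stopifnot(inherits(mol, "molgraph"), inherits(pattern, "fg_pattern"))
  feat <- mol_features(mol)
  np <- length(pattern$atoms)
  nm <- nrow(mol$atoms)
  if (nm < np) return(list())

  # molecule adjacency with bond attributes
  key <- function(i, j) paste0(min(i, j), "_", max(i, j))
  badj <- new.env(parent = emptyenv())
  nbrs <- vector("list", nm)
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    assign(key(i, j), c(mol$bonds$order[k], mol$bonds$aromatic[k]), envir = badj)
    nbrs[[i + 1L]] <- c(nbrs[[i + 1L]], j)
    nbrs[[j + 1L]] <- c(nbrs[[j + 1L]], i)
  }

  # order pattern atoms so each (after the first) touches an earlier one
  pb <- pattern$bonds
  order <- 1L
  placed <- c(TRUE, rep(FALSE, np - 1L))
  anchors <- list(NULL)
  while (length(order) < np) {
    extended <- FALSE
    for (e in pb) {
      if (placed[e$a] && !placed[e$b]) {
        order <- c(order, e$b); placed[e$b] <- TRUE
        anchors[[length(order)]] <- e; extended <- TRUE
      } else if (placed[e$b] && !placed[e$a]) {
        order <- c(order, e$a); placed[e$a] <- TRUE
        anchors[[length(order)]] <- e; extended <- TRUE
      }
    }
    if (!extended)
      nmg_stop("pattern_error", "disconnected pattern not supported",
               pattern = pattern$pattern)
  }

  matches <- list()
  assign_vec <- rep(NA_integer_, np)  # pattern idx -> 0-based mol atom

  check_bonds <- function(pidx, a) {
    for (e in pb) {
      other <- if (e$a == pidx) e$b else if (e$b == pidx) e$a else next
      oa <- assign_vec[other]
      if (is.na(oa)) next
      kb <- get0(key(a, oa), envir = badj)
      if (is.null(kb)) return(FALSE)
      if (!bond_ok(e$type, kb[1], as.logical(kb[2]))) return(FALSE)
    }
    TRUE
  }

  recurse <- function(step) {
    if (step > np) {
      matches[[length(matches) + 1L]] <<- assign_vec
      return(invisible(NULL))
    }
    pidx <- order[step]
    cands <- if (step == 1L) 0:(nm - 1L) else {
      anc <- anchors[[step]]
      prev_p <- if (anc$a == pidx) anc$b else anc$a
      nbrs[[assign_vec[prev_p] + 1L]]
    }
    for (a in cands) {
      if (a %in% assign_vec) next
      if (!atom_ok(pattern$atoms[[pidx]], feat, a + 1L)) next  # feat is 1-based
      assign_vec[pidx] <<- a
      if (check_bonds(pidx, a)) recurse(step + 1L)
      assign_vec[pidx] <<- NA_integer_
    }
  }
  recurse(1L)

  if (!length(matches)) return(list())
  keysets <- vapply(matches, function(m) paste(sort(m), collapse = ","), character(1))
  matches[!duplicated(keysets)]
}
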