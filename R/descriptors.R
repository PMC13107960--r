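# Physicochemical descriptors and scores. Bulk properties (MW, logP, TPSA,
# H-bond donors/acceptors) come from Open Babel; graph descriptors
# (rotatable bonds, aromatic rings, fingerprints) are computed on the
# package's molecular graph.

#' Bulk physicochemical properties of molecules
#'
#' @param smiles character vector (canonicalized internally)
#' @return data.frame: smiles, mw, logp, tpsa, hbd, hba (NA rows where the
#'   descriptor engine fails)
#' @export
mol_properties <- function(smiles) {
  out <- data.frame(smiles = smiles, mw = NA_real_, logp = NA_real_,
                    tpsa = NA_real_, hbd = NA_real_, hba = NA_real_)
  for (k in seq_along(smiles)) {
    p <- tryCatch({
      m <- ChemmineOB::forEachMol("SMILES", smiles[k], identity)
      ChemmineOB::prop_OB(m[[1]])
    }, error = function(e) NULL)
    if (!is.null(p) && nrow(p) == 1) {
      out$mw[k] <- p$MW; out$logp[k] <- p$logP; out$tpsa[k] <- p$TPSA
      out$hbd[k] <- p$HBD; out$hba[k] <- p$HBA2
    }
  }
  out
}

#' Rotatable-bond count
#'
#' Acyclic single non-aromatic bonds whose endpoints both have heavy degree
#' >= 2 (a simple, documented convention).
#' @param mol a `molgraph` (or SMILES string)
#' @return integer
#' @export
rotatable_bonds <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(canonicalize_smiles(mol))
  b <- mol$bonds
  if (!nrow(b)) return(0L)
  deg <- atom_degree(mol)
  rb <- ring_bonds(mol)
  sum(b$order == 1L & !b$aromatic & !rb &
        deg[b$i + 1L] >= 2L & deg[b$j + 1L] >= 2L)
}

#' Aromatic-ring count (5- and 6-membered)
#' @param mol a `molgraph` (or SMILES string)
#' @return integer
#' @export
aromatic_rings <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(canonicalize_smiles(mol))
  length(match_pattern(mol, "a1aaaa1")) + length(match_pattern(mol, "a1aaaaa1"))
}

# small curated structural-alert set for the drug-likeness score
ALERT_PATTERNS <- c(
  nitro = "[NX3](=O)~[OX1]",
  aldehyde = "[CX3H1]=O",
  thiol = "[SX2H]",
  acyl_halide = "C(=O)Cl",
  peroxide = "[OX2][OX2]",
  hydrazine = "[NX3][NX3]"
)

structural_alerts <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(canonicalize_smiles(mol))
  sum(vapply(ALERT_PATTERNS, function(p) length(match_pattern(mol, p)) > 0,
             logical(1)))
}

## ---- QED-style drug-likeness ----

# Asymmetric desirability function parameters (a, b, c, d, e, f, dmax) and
# weights of the published QED parameterization over the eight descriptors.
QED_ADS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000000, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610),
  ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140)
)
QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

qed_ads <- function(x, p) {
  v <- p[1] + p[2] / (1 + exp(-(x - p[3] + p[4] / 2) / p[5])) *
    (1 - 1 / (1 + exp(-(x - p[3] - p[4] / 2) / p[6])))
  pmax(v / p[7], 1e-6)
}

#' Drug-likeness score (QED desirability composite)
#'
#' Weighted geometric mean of asymmetric desirability functions over eight
#' descriptors (MW, logP, H-bond acceptors/donors, polar surface area,
#' rotatable bonds, aromatic rings, structural alerts), on [0,1].
#'
#' @param smiles character vector
#' @return numeric vector in [0,1]; NA where descriptors fail
#' @export
qed_score <- function(smiles) {
  props <- mol_properties(smiles)
  out <- rep(NA_real_, length(smiles))
  for (k in seq_along(smiles)) {
    if (is.na(props$mw[k])) next
    mol <- tryCatch(parse_smiles(canonicalize_smiles(smiles[k])),
                    error = function(e) NULL)
    if (is.null(mol)) next
    x <- c(MW = props$mw[k], ALOGP = props$logp[k], HBA = props$hba[k],
           HBD = props$hbd[k], PSA = props$tpsa[k],
           ROTB = rotatable_bonds(mol), AROM = aromatic_rings(mol),
           ALERTS = structural_alerts(mol))
    d <- vapply(names(QED_ADS), function(nm) qed_ads(x[[nm]], QED_ADS[[nm]]),
                numeric(1))
    out[k] <- exp(sum(QED_WEIGHTS * log(d)) / sum(QED_WEIGHTS))
  }
  out
}

#' Synthetic-accessibility heuristic
#'
#' A complexity-based estimate on the conventional raw 1 (easy) to 10 (hard)
#' scale: penalties for size, ring systems, branching and heteroatom load.
#' Deterministic and smooth; it is a heuristic, not a fragment-contribution
#' score.
#'
#' @param smiles character vector
#' @param normalized return (10 - raw)/9 on [0,1] (higher = easier)
#' @return numeric vector
#' @export
sa_score <- function(smiles, normalized = FALSE) {
  out <- rep(NA_real_, length(smiles))
  for (k in seq_along(smiles)) {
    mol <- tryCatch(parse_smiles(canonicalize_smiles(smiles[k])),
                    error = function(e) NULL)
    if (is.null(mol)) next
    nha <- nrow(mol$atoms)
    n_rings <- max(0L, nrow(mol$bonds) - nha + 1L)   # cycle rank (connected)
    deg <- atom_degree(mol)
    branch <- sum(deg >= 3)
    hetero <- mean(!mol$atoms$element %in% c("C", "H"))
    raw <- 1 + 0.08 * max(0, nha - 12) + 0.35 * n_rings + 0.2 * branch +
      2.0 * abs(hetero - 0.15)
    out[k] <- min(10, max(1, raw))
  }
  if (normalized) (10 - out) / 9 else out
}

#' Lipinski rule profile
#'
#' The five rules as used here: MW <= 500, logP <= 5, H-bond donors <= 5,
#' H-bond acceptors <= 10, rotatable bonds <= 10.
#' @param smiles character vector
#' @return data.frame with one logical column per rule plus `n_rules`
#'   (0-5) and `all5`
#' @export
lipinski_profile <- function(smiles) {
  props <- mol_properties(smiles)
  rotb <- vapply(smiles, function(s) {
    m <- tryCatch(parse_smiles(canonicalize_smiles(s)), error = function(e) NULL)
    if (is.null(m)) NA_integer_ else rotatable_bonds(m)
  }, integer(1), USE.NAMES = FALSE)
  df <- data.frame(
    mw_ok = props$mw <= 500,
    logp_ok = props$logp <= 5,
    hbd_ok = props$hbd <= 5,
    hba_ok = props$hba <= 10,
    rotb_ok = rotb <= 10
  )
  df$n_rules <- rowSums(df)
  df$all5 <- df$n_rules == 5
  df
}

## ---- circular fingerprints & diversity ----

#' Circular (radius-2) binary fingerprint
#'
#' Iterative neighbourhood hashing of atom invariants (element, degree,
#' hydrogen count, charge, aromaticity, ring membership), folded to
#' `n_bits`.
#' @param mol a `molgraph` (or SMILES)
#' @param radius neighbourhood radius
#' @param n_bits fingerprint length
#' @return sorted integer vector of set bit positions (0-based)
#' @export
circular_fingerprint <- function(mol, radius = 2L, n_bits = 2048L) {
  if (is.character(mol)) mol <- parse_smiles(canonicalize_smiles(mol))
  n <- nrow(mol$atoms)
  feat <- mol_features(mol)
  inv <- vapply(seq_len(n), function(a)
    fnv1a_hash(paste(feat$element[a], feat$degree[a], feat$h_count[a],
                     feat$charge[a], feat$aromatic[a], feat$in_ring[a],
                     sep = "|")), numeric(1))
  nbr <- vector("list", n); bkey <- vector("list", n)
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k] + 1L; j <- mol$bonds$j[k] + 1L
    o <- if (mol$bonds$aromatic[k]) "a" else as.character(mol$bonds$order[k])
    nbr[[i]] <- c(nbr[[i]], j); bkey[[i]] <- c(bkey[[i]], o)
    nbr[[j]] <- c(nbr[[j]], i); bkey[[j]] <- c(bkey[[j]], o)
  }
  all_ids <- inv
  cur <- inv
  for (r in seq_len(radius)) {
    nxt <- numeric(n)
    for (a in seq_len(n)) {
      parts <- if (length(nbr[[a]]))
        sort(paste0(bkey[[a]], ":", format(cur[nbr[[a]]], scientific = FALSE)))
      else character(0)
      nxt[a] <- fnv1a_hash(paste(c(format(cur[a], scientific = FALSE), parts),
                                 collapse = "#"))
    }
    cur <- nxt
    all_ids <- c(all_ids, cur)
  }
  sort(unique(as.integer(all_ids %% n_bits)))
}

#' Tanimoto similarity between two bit sets
#' @param fp1,fp2 integer vectors of set bits
#' @return similarity in [0,1]
#' @export
tanimoto <- function(fp1, fp2) {
  if (!length(fp1) && !length(fp2)) return(1)
  i <- length(intersect(fp1, fp2))
  i / (length(fp1) + length(fp2) - i)
}
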