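# Deterministic synthetic fixtures: a scaffold-x-substituent SMILES corpus
# with controllable functional-group content, seeded pocket-embedding
# matrices, corpus splitting, and a deterministic surrogate docking scorer.
# Everything the pipeline consumes can be generated offline from a seed.

DEFAULT_SCAFFOLDS <- c(
  "c1ccc({A})cc1",
  "c1ccc({A})c({B})c1",
  "c1cc({A})ccc1{B}",
  "c1ccnc({A})c1",
  "C1CCC({A})CC1",
  "c1ccc2c(c1)cccc2{A}",
  "O=C({A})c1ccc({B})cc1",
  "c1csc({A})c1"
)

DEFAULT_SUBSTITUENTS <- c(
  "O", "N", "CO", "CN", "C(=O)O", "C(=O)N", "C(=O)C", "C#N", "Cl", "F",
  "Br", "CC", "CCC", "C(C)C", "OC", "OCC", "S", "SC", "C=C", "NC(=O)C",
  "CNC", "CCO", "N(C)C", "C(=O)OC"
)

#' Specification of a synthetic corpus
#'
#' @param n_molecules corpus size
#' @param scaffolds SMILES templates with `{A}`/`{B}` substitution slots
#' @param substituents SMILES fragments valid inside a branch
#' @param max_atoms reject molecules larger than this
#' @param seed corpus seed
#' @return object of class `corpus_spec`
#' @export
corpus_spec <- function(n_molecules = 200L, scaffolds = DEFAULT_SCAFFOLDS,
                        substituents = DEFAULT_SUBSTITUENTS,
                        max_atoms = 40L, seed = 0L) {
  if (!length(scaffolds) || !length(substituents))
    nmg_stop("config_error", "scaffold and substituent sets must be non-empty")
  structure(list(n_molecules = as.integer(n_molecules), scaffolds = scaffolds,
                 substituents = substituents, max_atoms = as.integer(max_atoms),
                 seed = as.integer(seed)), class = "corpus_spec")
}

#' Generate a deterministic synthetic SMILES corpus
#'
#' Enumerates scaffold x substituent combinations, canonicalizes,
#' deduplicates, and samples `n_molecules` with the spec seed. Every emitted
#' molecule is valid and within the atom cap by construction.
#'
#' @param spec a `corpus_spec`
#' @return character vector of canonical SMILES
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  stopifnot(inherits(spec, "corpus_spec"))
  cands <- character(0)
  for (sc in spec$scaffolds) {
    slots <- sum(gregexpr("\\{[AB]\\}", sc)[[1]] > 0)
    if (grepl("\\{A\\}", sc) && grepl("\\{B\\}", sc)) {
      for (a in spec$substituents) for (b in spec$substituents) {
        cands <- c(cands, sub("\\{B\\}", b, sub("\\{A\\}", a, sc)))
      }
    } else {
      for (a in spec$substituents)
        cands <- c(cands, sub("\\{A\\}", a, sc))
    }
  }
  can <- character(0)
  for (s in cands) {
    cs <- tryCatch(canonicalize_smiles(s), error = function(e) NA_character_)
    if (is.na(cs)) next
    mol <- tryCatch(parse_smiles(cs), error = function(e) NULL)
    if (is.null(mol) || nrow(mol$atoms) > spec$max_atoms) next
    can <- c(can, cs)
  }
  can <- unique(can)
  if (length(can) < spec$n_molecules)
    nmg_stop("shortfall",
             sprintf("spec yields only %d distinct molecules, %d requested",
                     length(can), spec$n_molecules))
  set.seed(spec$seed)
  sort(sample(can, spec$n_molecules))
}

#' The 100-molecule hand-built fixture set
#'
#' A curated list of known drug-like molecules (plus a few deliberately
#' awkward structures) used as the annotation-oracle fixture.
#' @return character vector of 100 SMILES
#' @export
fixture_smiles_100 <- function() {
  path <- system.file("extdata", "fixture_smiles_100.txt", package = "nummolgen",
                      mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Seeded pocket-embedding fixtures
#'
#' Stand-ins for precomputed protein-language-model embeddings: seeded
#' Gaussian matrices scaled to unit row variance (entries N(0, 1/sqrt(d_p))).
#' @param n_pockets number of pockets
#' @param L_p residues per pocket
#' @param d_p embedding width
#' @param seed seed
#' @return list of `protein_context`: list(embeddings, pocket_id)
#' @export
generate_pocket_fixtures <- function(n_pockets = 4L, L_p = 16L, d_p = 32L,
                                     seed = 0L) {
  stopifnot(n_pockets > 0, L_p > 0, d_p > 0)
  set.seed(as.integer(seed))
  lapply(seq_len(n_pockets), function(k) {
    structure(list(
      embeddings = matrix(stats::rnorm(L_p * d_p, sd = 1 / sqrt(d_p)), L_p, d_p),
      pocket_id = sprintf("pocket_%03d", k)), class = "protein_context")
  })
}

#' Write pocket fixtures as npy arrays with a manifest
#' @param contexts list of `protein_context`
#' @param dir output directory (created)
#' @return path of the manifest CSV
#' @export
write_pocket_fixtures <- function(contexts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(contexts, function(ctx) {
    f <- file.path(dir, paste0(ctx$pocket_id, ".npy"))
    write_npy(ctx$embeddings, f)
    data.frame(pocket_id = ctx$pocket_id, file = basename(f),
               L_p = nrow(ctx$embeddings), d_p = ncol(ctx$embeddings))
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  manifest
}

#' Read pocket fixtures back from a manifest directory
#' @param dir directory holding manifest.csv and the npy files
#' @return list of `protein_context`
#' @export
read_pocket_fixtures <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(k)
    structure(list(embeddings = read_npy(file.path(dir, manifest$file[k])),
                   pocket_id = manifest$pocket_id[k]),
              class = "protein_context"))
}

#' Split a corpus into train/validation/test
#'
#' Seeded shuffle; sizes are the rounded ratio shares; splits are disjoint
#' and exhaustive.
#' @param corpus character vector (or list)
#' @param ratios length-3 numeric summing to 1
#' @param seed seed
#' @return list with `train`, `val`, `test`
#' @export
split_corpus <- function(corpus, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  if (abs(sum(ratios) - 1) > 1e-9)
    nmg_stop("config_error", "split ratios must sum to 1")
  n <- length(corpus)
  sizes <- c(round(n * ratios[1]), round(n * ratios[2]))
  sizes <- c(sizes, n - sum(sizes))
  if (any(sizes <= 0))
    nmg_stop("config_error", "every split must be non-empty")
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  list(train = corpus[ord[seq_len(sizes[1])]],
       val = corpus[ord[sizes[1] + seq_len(sizes[2])]],
       test = corpus[ord[sizes[1] + sizes[2] + seq_len(sizes[3])]])
}

#' Deterministic surrogate property scorer
#'
#' Maps each molecule to a (pseudo-dock, qed-like, sa) triple through smooth
#' functions of graph descriptors: the pseudo-docking score strengthens with
#' heavy-atom count and ring count (bounded to a realistic kcal/mol range),
#' the drug-likeness proxy peaks near 25 heavy atoms, and SA is the
#' package's normalized synthetic-accessibility heuristic. Bitwise
#' deterministic given a molecule.
#'
#' @param smiles character vector of valid SMILES
#' @return data.frame: smiles, dock, qed, sa
#' @export
surrogate_scorer <- function(smiles) {
  out <- data.frame(smiles = smiles, dock = NA_real_, qed = NA_real_,
                    sa = NA_real_)
  for (k in seq_along(smiles)) {
    mol <- tryCatch(parse_smiles(canonicalize_smiles(smiles[k])),
                    error = function(e) NULL)
    if (is.null(mol)) next
    nha <- nrow(mol$atoms)
    nring <- max(0L, nrow(mol$bonds) - nha + 1L)
    out$dock[k] <- max(-12, min(-1, -(0.5 * nha^0.85 + 0.4 * nring)))
    out$qed[k] <- 0.1 + 0.8 * exp(-((nha - 25) / 14)^2)
    out$sa[k] <- sa_score(smiles[k], normalized = TRUE)
  }
  out
}
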