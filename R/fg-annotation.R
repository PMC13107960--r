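# Functional-group triplet annotation: for each molecule, the ordered set
# {(type, number, positions)} over a fixed 27-entry pattern vocabulary.
# Counts are numbers of distinct pattern instances after collapsing
# symmetric duplicate matches; absent groups carry count 0 (the [NONE] case)
# so every molecule is annotated in the same dense constraint space.

#' Canonicalize a SMILES string
#'
#' Wraps Open Babel canonicalization (via ChemmineOB). Idempotent by
#' construction of the canonical form.
#'
#' @param smiles a single SMILES string
#' @return the canonical SMILES
#' @export
canonicalize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    nmg_stop("parse_error", "SMILES must be a non-empty string", smiles = smiles)
  out <- suppressWarnings(ob_clean(ChemmineOB::convertFormat("SMI", "CAN", smiles)))
  if (!nzchar(out))
    nmg_stop("parse_error", sprintf("SMILES does not parse: '%s'", smiles),
             smiles = smiles)
  out
}

#' Is a SMILES string chemically valid?
#' @param smiles character vector
#' @return logical vector
#' @export
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (!is.character(s) || is.na(s) || !nzchar(s)) return(FALSE)
    !inherits(tryCatch(canonicalize_smiles(s), error = function(e) e), "error")
  }, logical(1), USE.NAMES = FALSE)
}

#' Build a functional-group vocabulary
#'
#' Reads a two-column (name, pattern) tab-separated definition file; `#`
#' lines are comments. The file order is the vocabulary order. The default
#' build ships 27 named patterns covering the common pharmacophoric groups.
#'
#' @param source `"default"` or a path to a definition file
#' @return object of class `fg_vocabulary`
#' @export
build_vocabulary <- function(source = "default") {
  path <- if (identical(source, "default")) {
    system.file("extdata", "fg_vocabulary_default.tsv", package = "nummolgen",
                mustWork = TRUE)
  } else source
  if (!file.exists(path))
    nmg_stop("config_error", sprintf("vocabulary file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines))
    nmg_stop("config_error", sprintf("vocabulary source is empty: %s", path))
  types <- lapply(seq_along(lines), function(k) {
    parts <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2]))
      nmg_stop("format_error",
               sprintf("line %d of %s is not 'name<TAB>pattern': '%s'",
                       k, path, lines[k]))
    compiled <- tryCatch(parse_smarts(parts[2]), error = function(e)
      nmg_stop("format_error",
               sprintf("line %d of %s: pattern '%s' does not parse (%s)",
                       k, path, parts[2], conditionMessage(e))))
    list(name = parts[1], pattern = parts[2], vocab_index = k - 1L,
         compiled = compiled)
  })
  names_ <- vapply(types, `[[`, character(1), "name")
  if (anyDuplicated(names_))
    nmg_stop("format_error", sprintf("duplicate vocabulary names: %s",
                                     paste(names_[duplicated(names_)], collapse = ", ")))
  structure(list(types = types, size = length(types)), class = "fg_vocabulary")
}

#' @export
print.fg_vocabulary <- function(x, ...) {
  cat(sprintf("<fg_vocabulary> %d functional-group types\n", x$size))
  for (t in x$types) cat(sprintf("  %2d %-16s %s\n", t$vocab_index, t$name, t$pattern))
  invisible(x)
}

#' Annotate a molecule with functional-group triplets
#'
#' Canonicalizes the molecule, then matches every vocabulary pattern against
#' it. Each triplet records the group's count and the atom sets of its
#' instances (0-based indices over the canonical-SMILES atom order, each
#' atom as an (element, index) pair).
#'
#' @param smiles SMILES string (canonicalized internally)
#' @param vocab an `fg_vocabulary`
#' @return object of class `molecule_annotation`
#' @export
annotate_molecule <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "fg_vocabulary"))
  can <- canonicalize_smiles(smiles)
  mol <- parse_smiles(can)
  triplets <- lapply(vocab$types, function(t) {
    hits <- match_pattern(mol, t$compiled)
    instances <- lapply(hits, function(h)
      lapply(h, function(a) list(element = mol$atoms$element[a + 1L], index = a)))
    list(fg_type = t$name, count = length(hits), instances = instances)
  })
  structure(list(canonical_smiles = can, triplets = triplets,
                 n_atoms = nrow(mol$atoms)),
            class = "molecule_annotation")
}

#' @export
print.molecule_annotation <- function(x, ...) {
  present <- Filter(function(t) t$count > 0, x$triplets)
  cat(sprintf("<molecule_annotation> %s\n", x$canonical_smiles))
  if (!length(present)) cat("  (no functional groups present)\n")
  for (t in present) cat(sprintf("  %-16s n=%d\n", t$fg_type, t$count))
  invisible(x)
}

#' Flatten an annotation into its count vector
#'
#' @param annotation a `molecule_annotation`
#' @return named integer vector, one entry per vocabulary type
#' @export
count_vector <- function(annotation) {
  stopifnot(inherits(annotation, "molecule_annotation"))
  stats::setNames(vapply(annotation$triplets, `[[`, integer(1), "count"),
                  vapply(annotation$triplets, `[[`, character(1), "fg_type"))
}

#' Annotate a batch of molecules
#'
#' @param smiles character vector
#' @param vocab an `fg_vocabulary`
#' @param skip_invalid drop unparseable SMILES (with a warning) instead of
#'   erroring
#' @return list of `molecule_annotation`
#' @export
annotate_molecules <- function(smiles, vocab, skip_invalid = FALSE) {
  out <- vector("list", length(smiles))
  keep <- logical(length(smiles))
  for (k in seq_along(smiles)) {
    ann <- tryCatch(annotate_molecule(smiles[k], vocab), error = function(e) e)
    if (inherits(ann, "error")) {
      if (!skip_invalid) stop(ann)
      keep[k] <- FALSE
    } else { out[[k]] <- ann; keep[k] <- TRUE }
  }
  if (any(!keep)) nmg_warn(sprintf("%d molecule(s) skipped as unparseable", sum(!keep)))
  out[keep]
}

#' Write annotations to JSONL
#' @param annotations list of `molecule_annotation`
#' @param path output file
#' @export
write_annotations <- function(annotations, path) {
  write_jsonl(lapply(annotations, function(a) list(
    canonical_smiles = a$canonical_smiles,
    triplets = lapply(a$triplets, function(t) list(
      type = t$fg_type, count = t$count,
      instances = lapply(t$instances, function(inst)
        lapply(inst, function(at) list(at$element, at$index)))))
  )), path)
}
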