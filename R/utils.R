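# Shared infrastructure: classed conditions, seeding, hashing, small-file IO.

#' Signal a classed nummolgen error
#'
#' All user-facing failures in the package are classed conditions so callers
#' (and tests) can distinguish, e.g., a SMILES parse error from a malformed
#' sequence. The class is always c("nummolgen_<class>", "nummolgen_error",
#' "error", "condition").
#'
#' @param class short error class suffix, e.g. "parse_error"
#' @param message human-readable message
#' @param ... named fields attached to the condition (e.g. smiles = "...")
#' @keywords internal
nmg_stop <- function(class, message, ...) {
  cond <- structure(
    class = c(paste0("nummolgen_", class), "nummolgen_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

nmg_warn <- function(message) warning(message, call. = FALSE)

#' Derive a child RNG seed from a master seed
#'
#' Deterministic stream splitting: every stage of the pipeline draws its own
#' seed from the run's master seed plus a stream label, so stages can be
#' re-run or re-ordered without perturbing one another. Kept below 2^31.
#'
#' @param seed master integer seed
#' @param stream character label of the consumer ("corpus", "init", ...)
#' @return an integer seed
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- fnv1a_hash(paste0(format(seed, scientific = FALSE), "/", stream))
  as.integer(h %% 2147483647)
}

# 32-bit FNV-1a over the raw bytes of a string, done in double arithmetic
# (exact: all intermediates stay below 2^53).
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256                      # xor touches the low byte only (b < 256)
    h <- h - lo + bitwXor(as.integer(lo), b)
    # h * 16777619 mod 2^32, split so every intermediate stays below 2^53
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  h
}

#' Content hash of a functional-group vocabulary
#'
#' Used to stamp checkpoints so a model is never resumed against a different
#' vocabulary than it was trained with.
#' @param vocab an `fg_vocabulary`
#' @return character hex digest
#' @export
fg_vocab_hash <- function(vocab) {
  stopifnot(inherits(vocab, "fg_vocabulary"))
  h <- fnv1a_hash(paste(vapply(vocab$types, function(t)
    paste0(t$name, "\t", t$pattern), character(1)), collapse = "\n"))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## ---- JSONL ----

write_jsonl <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"), con)
  invisible(path)
}

read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

## ---- minimal .npy reader/writer (v1.0, C-order float64) ----
## Pocket embeddings travel as .npy-compatible arrays so they interoperate
## with the (external) tooling that produces real protein embeddings.

write_npy <- function(mat, path) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(mat), ncol(mat))
  # pad with spaces so total header block length (incl. 10-byte preamble) % 64 == 0
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.raw(c(nchar(header) %% 256L, nchar(header) %/% 256L)), con)
  writeChar(header, con, eos = NULL)
  writeBin(as.double(t(mat)), con, size = 8, endian = "little")
  invisible(path)
}

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(as.integer(magic[1]), 0x93L) ||
      !identical(rawToChar(magic[2:6]), "NUMPY"))
    nmg_stop("format_error", sprintf("not an npy file: %s", path))
  readBin(con, "raw", 2)  # version
  hlen <- sum(as.integer(readBin(con, "raw", 2)) * c(1L, 256L))
  header <- rawToChar(readBin(con, "raw", hlen))
  shape <- regmatches(header, regexpr("\\(([0-9]+), ([0-9]+)\\)", header))
  dims <- as.integer(strsplit(gsub("[() ]", "", shape), ",")[[1]])
  if (grepl("fortran_order': True", header))
    nmg_stop("format_error", "fortran-order npy not supported")
  vals <- readBin(con, "double", prod(dims), size = 8, endian = "little")
  matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
}

## ---- misc ----

# strip openbabel's trailing "\t<title>\n"
ob_clean <- function(s) sub("[\t\n].*$", "", s)

`%||%` <- function(a, b) if (is.null(a)) b else a
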