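# Quality and constraint-compliance metrics for generated molecule sets.

metric_guard <- function(cond, what) {
  if (!cond) nmg_stop("metric_undefined", sprintf("%s is undefined here", what))
}

#' Validity: fraction of strings that are chemically valid SMILES
#' @param smiles character vector
#' @return fraction in [0,1]
#' @export
validity <- function(smiles) {
  metric_guard(length(smiles) > 0, "validity of an empty set")
  mean(is_valid_smiles(smiles))
}

#' Uniqueness: distinct canonical molecules among the valid ones
#' @param smiles character vector of *valid* SMILES
#' @return fraction in [0,1]
#' @export
uniqueness <- function(smiles) {
  metric_guard(length(smiles) > 0, "uniqueness of an empty set")
  can <- vapply(smiles, canonicalize_smiles, character(1), USE.NAMES = FALSE)
  length(unique(can)) / length(can)
}

#' Novelty: distinct valid molecules absent from a reference set
#' @param smiles character vector of valid SMILES
#' @param reference character vector of canonical SMILES (e.g. training set)
#' @return fraction in [0,1]
#' @export
novelty <- function(smiles, reference) {
  metric_guard(length(smiles) > 0, "novelty of an empty set")
  can <- unique(vapply(smiles, canonicalize_smiles, character(1), USE.NAMES = FALSE))
  mean(!can %in% reference)
}

#' Lipinski metrics of a molecule set
#'
#' Returns both conventions in use: the fraction passing all five rules and
#' the mean number of rules satisfied (0-5 scale).
#' @param smiles character vector of valid SMILES
#' @return list: `all5_fraction`, `mean_rules`
#' @export
lipinski_metrics <- function(smiles) {
  metric_guard(length(smiles) > 0, "Lipinski metrics of an empty set")
  prof <- lipinski_profile(smiles)
  ok <- !is.na(prof$n_rules)
  metric_guard(any(ok), "Lipinski metrics with no scorable molecules")
  list(all5_fraction = mean(prof$all5[ok]), mean_rules = mean(prof$n_rules[ok]),
       n_failed = sum(!ok))
}

#' Per-molecule QED and normalized SA
#'
#' @param smiles character vector of valid SMILES
#' @return data.frame: smiles, qed (0-1), sa_norm (0-1, higher = easier);
#'   attribute `n_failed` counts descriptor failures (rows kept as NA)
#' @export
qed_and_sa <- function(smiles) {
  metric_guard(length(smiles) > 0, "QED/SA of an empty set")
  q <- qed_score(smiles)
  s <- sa_score(smiles, normalized = TRUE)
  out <- data.frame(smiles = smiles, qed = q, sa_norm = s)
  attr(out, "n_failed") <- sum(is.na(q) | is.na(s))
  out
}

#' Internal diversity: mean pairwise Tanimoto distance
#'
#' @param smiles character vector (>= 2 valid molecules)
#' @param radius,n_bits fingerprint settings
#' @return diversity in [0,1]
#' @export
diversity <- function(smiles, radius = 2L, n_bits = 2048L) {
  metric_guard(length(smiles) >= 2, "diversity of fewer than two molecules")
  fps <- lapply(smiles, circular_fingerprint, radius = radius, n_bits = n_bits)
  total <- 0; np <- 0
  for (i in seq_len(length(fps) - 1L)) {
    for (j in (i + 1L):length(fps)) {
      total <- total + (1 - tanimoto(fps[[i]], fps[[j]]))
      np <- np + 1
    }
  }
  total / np
}

#' Success rate under the standard pocket-design thresholds
#'
#' Fraction of records with Vina dock < -8.18, QED > 0.25 and SA > 0.59
#' (all strict inequalities; boundary values do not count).
#' @param records data.frame with columns `vina_dock`, `qed`, `sa`
#' @return fraction in [0,1]
#' @export
success_rate <- function(records) {
  metric_guard(NROW(records) > 0, "success rate of an empty record set")
  need <- c("vina_dock", "qed", "sa")
  if (!all(need %in% names(records)) ||
      any(is.na(records[need])))
    nmg_stop("scoring_error", "success_rate requires complete vina_dock/qed/sa")
  mean(records$vina_dock < -8.18 & records$qed > 0.25 & records$sa > 0.59)
}

#' Constraint compliance of generated molecules
#'
#' For each generated molecule and its target count vector: MSE between
#' target and observed counts (mean over molecules and groups), exact-match
#' rate (all groups equal), and fuzzy-match rate (all groups within +/-3).
#' Invalid molecules count as failures for EMR/FMR and are excluded from the
#' MSE (their number is reported).
#'
#' @param target_vectors list of integer count vectors (or a matrix with one
#'   row per molecule)
#' @param smiles generated SMILES, one per target
#' @param vocab the `fg_vocabulary`
#' @return object of class `constraint_report`
#' @export
constraint_compliance <- function(target_vectors, smiles, vocab) {
  if (is.matrix(target_vectors))
    target_vectors <- lapply(seq_len(nrow(target_vectors)),
                             function(i) target_vectors[i, ])
  if (length(target_vectors) != length(smiles))
    nmg_stop("contract_violation", "one target vector per molecule required")
  metric_guard(length(smiles) > 0, "constraint compliance of an empty set")
  n_groups <- vocab$size
  n <- length(smiles)
  sq_err <- numeric(0)
  exact <- logical(n); fuzzy <- logical(n)
  n_invalid <- 0L
  obs_counts <- matrix(NA_integer_, n, n_groups)
  for (k in seq_len(n)) {
    tv <- as.integer(target_vectors[[k]])
    if (length(tv) != n_groups)
      nmg_stop("contract_violation",
               sprintf("target vector %d has length %d, vocabulary %d",
                       k, length(tv), n_groups))
    ann <- tryCatch(annotate_molecule(smiles[k], vocab), error = function(e) NULL)
    if (is.null(ann)) { n_invalid <- n_invalid + 1L; next }   # EMR/FMR failure
    cv <- unname(count_vector(ann))
    obs_counts[k, ] <- cv
    dev <- cv - tv
    sq_err <- c(sq_err, mean(dev^2))
    exact[k] <- all(dev == 0L)
    fuzzy[k] <- all(abs(dev) <= 3L)
  }
  structure(list(
    mse = if (length(sq_err)) mean(sq_err) else NA_real_,
    emr = mean(exact), fmr = mean(fuzzy),
    n_molecules = n, n_invalid = n_invalid,
    per_group_frequency_ratio = colMeans(obs_counts > 0, na.rm = TRUE),
    per_group_average_count = colMeans(obs_counts, na.rm = TRUE),
    group_names = vapply(vocab$types, `[[`, character(1), "name")
  ), class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  cat(sprintf("<constraint_report> n=%d (invalid %d)\n", x$n_molecules, x$n_invalid))
  cat(sprintf("  MSE=%.4f  EMR=%.3f  FMR=%.3f\n", x$mse, x$emr, x$fmr))
  invisible(x)
}

#' Functional-group profiles of molecule collections
#'
#' For each named collection: per-group frequency ratio (fraction of
#' molecules containing the group) and average count per molecule. Profile
#' MSEs between collections quantify distributional fidelity.
#'
#' @param collections named list of character vectors of valid SMILES
#' @param vocab the `fg_vocabulary`
#' @param groups optional subset of group names to report
#' @return object of class `fg_profiles`: per-collection matrices
#'   `frequency_ratio` and `average_count` (groups x collections)
#' @export
fg_profiles <- function(collections, vocab, groups = NULL) {
  stopifnot(is.list(collections), !is.null(names(collections)))
  for (nm in names(collections))
    metric_guard(length(collections[[nm]]) > 0,
                 sprintf("profile of empty collection '%s'", nm))
  gnames <- vapply(vocab$types, `[[`, character(1), "name")
  if (!is.null(groups)) {
    missing <- setdiff(groups, gnames)
    if (length(missing))
      nmg_stop("lookup_error", sprintf("unknown group name(s): %s",
                                       paste(missing, collapse = ", ")))
  } else groups <- gnames
  gi <- match(groups, gnames)
  freq <- matrix(NA_real_, length(groups), length(collections),
                 dimnames = list(groups, names(collections)))
  avg <- freq
  for (ci in seq_along(collections)) {
    anns <- annotate_molecules(collections[[ci]], vocab)
    counts <- do.call(rbind, lapply(anns, function(a) unname(count_vector(a))))
    freq[, ci] <- colMeans(counts[, gi, drop = FALSE] > 0)
    avg[, ci] <- colMeans(counts[, gi, drop = FALSE])
  }
  structure(list(frequency_ratio = freq, average_count = avg),
            class = "fg_profiles")
}

#' Mean squared difference between two collections' profiles
#' @param profiles an `fg_profiles`
#' @param a,b collection names
#' @param statistic `"frequency_ratio"` or `"average_count"`
#' @return non-negative scalar
#' @export
profile_mse <- function(profiles, a, b, statistic = c("frequency_ratio", "average_count")) {
  statistic <- match.arg(statistic)
  m <- profiles[[statistic]]
  if (!all(c(a, b) %in% colnames(m)))
    nmg_stop("lookup_error", "unknown collection name")
  mean((m[, a] - m[, b])^2)
}

#' @export
plot.fg_profiles <- function(x, statistic = "frequency_ratio", ...) {
  m <- t(x[[statistic]])
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = statistic, las = 2, ...)
  invisible(x)
}

#' Full quality report of a generated molecule set
#'
#' @param smiles generated SMILES (raw model output)
#' @param reference canonical SMILES of the training set (for novelty)
#' @param compute_diversity include the pairwise-fingerprint diversity
#' @return object of class `quality_report`
#' @export
quality_report <- function(smiles, reference = character(0),
                           compute_diversity = TRUE) {
  metric_guard(length(smiles) > 0, "quality report of an empty set")
  val <- validity(smiles)
  valid_smiles <- smiles[is_valid_smiles(smiles)]
  rep <- list(n_molecules = length(smiles), validity = val,
              uniqueness = NA_real_, novelty = NA_real_,
              lipinski_all5_fraction = NA_real_, lipinski_mean_rules = NA_real_,
              mean_qed = NA_real_, mean_sa_norm = NA_real_,
              diversity = NA_real_)
  if (length(valid_smiles)) {
    rep$uniqueness <- uniqueness(valid_smiles)
    if (length(reference)) rep$novelty <- novelty(valid_smiles, reference)
    lip <- lipinski_metrics(valid_smiles)
    rep$lipinski_all5_fraction <- lip$all5_fraction
    rep$lipinski_mean_rules <- lip$mean_rules
    qs <- qed_and_sa(valid_smiles)
    rep$mean_qed <- mean(qs$qed, na.rm = TRUE)
    rep$mean_sa_norm <- mean(qs$sa_norm, na.rm = TRUE)
    if (compute_diversity && length(valid_smiles) >= 2)
      rep$diversity <- diversity(valid_smiles)
  }
  structure(rep, class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> n=%d\n", x$n_molecules))
  cat(sprintf("  validity   %.3f   uniqueness %.3f   novelty %s\n",
              x$validity, x$uniqueness,
              ifelse(is.na(x$novelty), "-", sprintf("%.3f", x$novelty))))
  cat(sprintf("  Lipinski   all5=%.3f mean-rules=%.2f\n",
              x$lipinski_all5_fraction, x$lipinski_mean_rules))
  cat(sprintf("  QED %.3f   SA(norm) %.3f   diversity %s\n",
              x$mean_qed, x$mean_sa_norm,
              ifelse(is.na(x$diversity), "-", sprintf("%.3f", x$diversity))))
  invisible(x)
}
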