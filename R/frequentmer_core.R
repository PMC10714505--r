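#' Build the cohort recurrency index over a training split
#'
#' For every k-mer observed in at least one training sample, counts the number
#' of distinct control and patient samples whose k-mer set contains it (sample
#' recurrency, never read counts). The index is computed by a heap-based
#' multiway merge over the per-sample sorted k-mer vectors, so the result is
#' emitted in ascending k-mer order.
#'
#' @param ksets List of `kmer_set` objects (in-memory backend) or a character
#'   vector of `.kset` file paths (file backend, see [read_kmerset()]); both
#'   backends produce identical indices.
#' @param manifest An `fqm_manifest` resolving each sample to a cohort.
#' @param fold_id Integer fold label stored with the index.
#' @param sample_ids Restrict to these samples (e.g. a fold's training split).
#'   Default: all samples present in `ksets`.
#' @return A `cohort_index`: `k`, `fold_id`, cohort sizes `n_control_total` /
#'   `n_patient_total`, and parallel vectors `kmer`, `n_control`, `n_patient`.
#' @export
build_index <- function(ksets, manifest, fold_id = 0L, sample_ids = NULL) {
  if (is.character(ksets)) ksets <- lapply(ksets, read_kmerset)
  stopifnot(length(ksets) > 0 || is.null(sample_ids) || length(sample_ids) == 0)
  ids <- vapply(ksets, function(x) x$sample_id, character(1))
  if (anyNA(ids)) stop("every kmer_set needs a sample_id to build an index")
  names(ksets) <- ids
  if (!is.null(sample_ids)) {
    missing_ks <- setdiff(sample_ids, ids)
    if (length(missing_ks))
      stop("no kmer_set for sample(s): ", paste(missing_ks, collapse = ", "))
    ksets <- ksets[sample_ids]
    ids <- sample_ids
  }
  unknown <- setdiff(ids, manifest$sample_id)
  if (length(unknown))
    stop("sample(s) not in manifest: ", paste(unknown, collapse = ", "))
  ks <- vapply(ksets, function(x) x$k, integer(1))
  if (length(unique(ks)) > 1)
    stop("mixed k across kmer_sets: ", paste(unique(ks), collapse = ", "))
  cohort <- manifest$cohort[match(ids, manifest$sample_id)]
  is_patient <- cohort == "patient"
  merged <- cohort_index_cpp(lapply(ksets, `[[`, "kmers"), is_patient)
  structure(list(k = if (length(ks)) ks[[1]] else NA_integer_,
                 fold_id = as.integer(fold_id),
                 n_control_total = sum(!is_patient),
                 n_patient_total = sum(is_patient),
                 kmer = merged$kmer,
                 n_control = merged$n_control,
                 n_patient = merged$n_patient),
            class = "cohort_index")
}

#' @export
print.cohort_index <- function(x, ...) {
  cat("cohort_index (fold ", x$fold_id, "): ", length(x$kmer), " distinct ",
      x$k, "-mers over ", x$n_control_total, " controls + ",
      x$n_patient_total, " patients\n", sep = "")
  invisible(x)
}

#' Derive the frequentmer catalog at a recurrency threshold
#'
#' Control frequentmers are k-mers present in at least `r` control training
#' samples and absent from every patient training sample; patient
#' frequentmers symmetrically. The two sets are disjoint by construction
#' (each requires zero occurrences in the opposite cohort).
#'
#' @param index A `cohort_index` from [build_index()].
#' @param r Recurrency threshold (minimum distinct same-cohort samples),
#'   at least 1. Values of 1 or less are accepted but flagged with a warning:
#'   recurrency 1 degenerates to mere group-absence.
#' @return A `frequentmer_catalog`: `fold_id`, `r`, `k`, and ascending sorted
#'   encoded sets `control_fms` and `patient_fms`.
#' @export
derive_frequentmers <- function(index, r) {
  stopifnot(inherits(index, "cohort_index"), r >= 1)
  if (r <= 1)
    warning("recurrency r = ", r, " degenerates to group-absence only; ",
            "thresholds >= 2 are recommended")
  control_fms <- index$kmer[index$n_control >= r & index$n_patient == 0]
  patient_fms <- index$kmer[index$n_patient >= r & index$n_control == 0]
  structure(list(fold_id = index$fold_id, r = as.integer(r), k = index$k,
                 control_fms = control_fms, patient_fms = patient_fms),
            class = "frequentmer_catalog")
}

#' @export
print.frequentmer_catalog <- function(x, ...) {
  cat("frequentmer_catalog (fold ", x$fold_id, ", r = ", x$r, "): ",
      length(x$control_fms), " control + ", length(x$patient_fms),
      " patient frequentmers (k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' Frequentmer counts as a function of the recurrency threshold
#'
#' For each threshold in `r_values`, counts control and patient frequentmers
#' and their patient ratio `n_patient / (n_patient + n_control)` (reported as
#' `NA` when no frequentmers exist at that threshold). Counts are
#' non-increasing in `r` because the qualifying condition only tightens.
#'
#' @param index A `cohort_index`.
#' @param r_values Integer vector of thresholds (default `5:20`).
#' @return Data frame with columns `r`, `n_control_fms`, `n_patient_fms`,
#'   `patient_ratio`.
#' @export
recurrency_sweep <- function(index, r_values = 5:20) {
  stopifnot(length(r_values) > 0)
  rows <- lapply(sort(unique(as.integer(r_values))), function(r) {
    nc <- sum(index$n_control >= r & index$n_patient == 0)
    np <- sum(index$n_patient >= r & index$n_control == 0)
    data.frame(r = r, n_control_fms = nc, n_patient_fms = np,
               patient_ratio = if (nc + np > 0) np / (nc + np) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Test-set recovery of training-derived frequentmers
#'
#' Measures how much of a training split's frequentmer catalog reappears in
#' held-out test samples: (i) the fraction of catalog frequentmers present in
#' at least one test sample (overall and per side), (ii) per-test-sample
#' counts of control and patient frequentmers detected, (iii) a majority-vote
#' cohort assignment for every recovered frequentmer (control if found in
#' strictly more control test samples, patient if strictly more patient test
#' samples, tie = unassigned), and (iv) a Mann-Whitney U test comparing the
#' per-sample patient-frequentmer counts between the two test cohorts.
#'
#' @param catalog A `frequentmer_catalog` derived from the fold's training
#'   split only.
#' @param test_ksets List of `kmer_set` for the held-out samples.
#' @param manifest An `fqm_manifest` giving test-sample cohorts.
#' @return A list of class `recovery_report`: `recovery_fraction`,
#'   `recovery_fraction_control`, `recovery_fraction_patient`, `per_sample`
#'   (data frame sample_id, cohort, n_control_fms_detected,
#'   n_patient_fms_detected), `votes` (data frame kmer, side,
#'   n_control_samples, n_patient_samples, vote), and `mannwhitney_p`.
#' @export
test_recovery <- function(catalog, test_ksets, manifest) {
  stopifnot(inherits(catalog, "frequentmer_catalog"))
  if (length(test_ksets) == 0) stop("empty test set")
  ids <- vapply(test_ksets, function(x) x$sample_id, character(1))
  cohort <- manifest$cohort[match(ids, manifest$sample_id)]
  if (anyNA(cohort))
    stop("test sample(s) not in manifest: ",
         paste(ids[is.na(cohort)], collapse = ", "))

  all_fms <- c(catalog$control_fms, catalog$patient_fms)
  side <- rep(c("control", "patient"),
              c(length(catalog$control_fms), length(catalog$patient_fms)))
  n_c_samp <- integer(length(all_fms))
  n_p_samp <- integer(length(all_fms))
  per_sample <- data.frame(sample_id = ids, cohort = cohort,
                           n_control_fms_detected = 0L,
                           n_patient_fms_detected = 0L,
                           stringsAsFactors = FALSE)
  for (i in seq_along(test_ksets)) {
    present <- all_fms %in% test_ksets[[i]]$kmers
    per_sample$n_control_fms_detected[i] <- sum(present & side == "control")
    per_sample$n_patient_fms_detected[i] <- sum(present & side == "patient")
    if (cohort[i] == "patient") n_p_samp <- n_p_samp + present
    else n_c_samp <- n_c_samp + present
  }
  recovered <- (n_c_samp + n_p_samp) > 0
  vote <- ifelse(n_c_samp > n_p_samp, "control",
                 ifelse(n_p_samp > n_c_samp, "patient", "unassigned"))
  vote[!recovered] <- NA_character_
  votes <- data.frame(kmer = all_fms, side = side,
                      n_control_samples = n_c_samp,
                      n_patient_samples = n_p_samp,
                      vote = vote, stringsAsFactors = FALSE)

  frac <- function(keep) if (any(keep)) mean(recovered[keep]) else NA_real_
  mw <- if (length(unique(cohort)) == 2) {
    suppressWarnings(
      stats::wilcox.test(per_sample$n_patient_fms_detected[cohort == "patient"],
                         per_sample$n_patient_fms_detected[cohort == "control"],
                         alternative = "greater"))$p.value
  } else NA_real_

  structure(list(
    recovery_fraction = if (length(all_fms)) mean(recovered) else NA_real_,
    recovery_fraction_control = frac(side == "control"),
    recovery_fraction_patient = frac(side == "patient"),
    per_sample = per_sample,
    votes = votes,
    mannwhitney_p = mw), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: %.1f%% of frequentmers recovered in the test set\n",
              100 * x$recovery_fraction))
  cat(sprintf("  control side %.1f%%, patient side %.1f%%; Mann-Whitney p = %.3g\n",
              100 * x$recovery_fraction_control,
              100 * x$recovery_fraction_patient, x$mannwhitney_p))
  invisible(x)
}
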