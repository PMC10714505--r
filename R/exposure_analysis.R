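#' Frequentmers specific to an exposure-positive patient subset
#'
#' Among patient frequentmers (k-mers absent from every control sample),
#' selects those additionally present in at least `r` exposure-positive
#' patients and in zero exposure-negative patients. Patients with unknown
#' exposure status are excluded from both subsets with a warning (they are
#' not treated as negative). The per-frequentmer prevalence (fraction of
#' exposure-positive samples containing it) is reported for histogramming.
#'
#' @param ksets List of `kmer_set` for all samples considered.
#' @param manifest An `fqm_manifest` with the exposure covariate.
#' @param covariate Name of the exposure column (e.g. `"HBV"`).
#' @param r Recurrency threshold within the exposure-positive subset.
#' @return A list of class `exposure_report`: `covariate`, `r`,
#'   `subset_specific_fms` (sorted codes), `per_fm_prevalence` (named numeric,
#'   fraction of positive samples containing each fm), and the subset sizes.
#' @export
subset_specific_frequentmers <- function(ksets, manifest, covariate, r) {
  stopifnot(r >= 1)
  ids <- vapply(ksets, function(x) x$sample_id, character(1))
  names(ksets) <- ids
  mrow <- match(ids, manifest$sample_id)
  if (anyNA(mrow))
    stop("sample(s) not in manifest: ", paste(ids[is.na(mrow)], collapse = ", "))
  cohort <- manifest$cohort[mrow]
  expo_all <- unique(unlist(lapply(manifest$exposures, names)))
  if (!covariate %in% expo_all)
    stop("covariate '", covariate, "' not found in manifest (has: ",
         paste(expo_all, collapse = ", "), ")")
  status <- vapply(manifest$exposures[mrow], function(e) {
    if (covariate %in% names(e)) e[[covariate]] else NA
  }, logical(1))

  is_patient <- cohort == "patient"
  unknown <- is_patient & is.na(status)
  if (any(unknown))
    warning(sum(unknown), " patient sample(s) with unknown '", covariate,
            "' status excluded from the subset analysis")
  pos_ids <- ids[is_patient & !is.na(status) & status]
  neg_ids <- ids[is_patient & !is.na(status) & !status]
  ctl_ids <- ids[!is_patient]
  if (length(pos_ids) == 0)
    stop("no exposure-positive patient samples for covariate '", covariate, "'")

  # counts over the three strata via the same multiway merge used for the
  # cohort index (positives as "patients" vs negatives+controls pooled)
  used <- c(pos_ids, neg_ids, ctl_ids)
  merged <- cohort_index_cpp(lapply(ksets[used], `[[`, "kmers"),
                             used %in% pos_ids)
  # n_patient = count in exposure-positive patients; n_control = count in
  # exposure-negative patients plus controls, which must be zero
  keep <- merged$n_patient >= r & merged$n_control == 0
  fms <- merged$kmer[keep]
  prevalence <- merged$n_patient[keep] / length(pos_ids)
  names(prevalence) <- format_code(fms)

  structure(list(covariate = covariate, r = as.integer(r),
                 subset_specific_fms = fms,
                 per_fm_prevalence = prevalence,
                 n_positive = length(pos_ids), n_negative = length(neg_ids),
                 n_controls = length(ctl_ids)),
            class = "exposure_report")
}

format_code <- function(x) sprintf("%.0f", x)

#' @export
print.exposure_report <- function(x, ...) {
  cat("exposure_report (", x$covariate, ", r = ", x$r, "): ",
      length(x$subset_specific_fms), " subset-specific frequentmers over ",
      x$n_positive, " positive / ", x$n_negative, " negative patients\n",
      sep = "")
  invisible(x)
}

#' Prevalence histogram of subset-specific frequentmers
#'
#' Bins each frequentmer's prevalence (percentage of exposure-positive
#' samples containing it) into percentage bins, for bar-plot style reporting.
#'
#' @param report An `exposure_report`.
#' @param bin_width Bin width in percentage points (default 10).
#' @return Data frame with `bin_low`, `bin_high`, `n_fms`.
#' @export
prevalence_histogram <- function(report, bin_width = 10) {
  pct <- 100 * report$per_fm_prevalence
  breaks <- seq(0, 100, by = bin_width)
  cut_idx <- pmin(findInterval(pct, breaks, left.open = TRUE,
                               rightmost.closed = TRUE) , length(breaks) - 1)
  cut_idx[pct <= 0] <- 1
  counts <- tabulate(cut_idx, nbins = length(breaks) - 1)
  data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
             n_fms = counts)
}

#' Pairwise Jaccard comparison of per-sample frequentmer profiles
#'
#' Computes the Jaccard index `|A n B| / |A u B|` between every pair of
#' samples' detected-frequentmer sets, splits the pairs into within-group
#' (both samples in the flagged group, or both outside it) and cross-group,
#' and compares the two Jaccard distributions. Two empty sets have Jaccard 0
#' by convention (flagged in the output). The default comparison is Welch's
#' two-sample t-test; `paired = TRUE` requires `within` and `cross` pairings
#' of equal length supplied via an explicit matching and is only for callers
#' who can justify one.
#'
#' @param sample_fm_sets Named list: per sample, the vector of frequentmer
#'   codes detected in it.
#' @param group_mask Logical vector (same order/names) flagging the subgroup
#'   of interest (e.g. HBV-positive).
#' @param paired Use a paired t-test. The within- and cross-group distance
#'   vectors are then truncated to equal length in sorted pair order; default
#'   `FALSE` (Welch).
#' @return A list of class `jaccard_comparison`: `pairs` (data frame with
#'   sample_a, sample_b, jaccard, type), `within`, `cross` (numeric vectors),
#'   `t_statistic`, `p_value`, `method`, `empty_pair_count`.
#' @export
jaccard_profile_comparison <- function(sample_fm_sets, group_mask,
                                       paired = FALSE) {
  n <- length(sample_fm_sets)
  stopifnot(length(group_mask) == n)
  if (sum(group_mask) < 2 || sum(!group_mask) < 2)
    stop("need at least 2 samples in each group")
  ids <- names(sample_fm_sets)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  pairs <- utils::combn(n, 2)
  jac <- numeric(ncol(pairs))
  empty_pairs <- 0L
  for (j in seq_len(ncol(pairs))) {
    a <- sample_fm_sets[[pairs[1, j]]]
    b <- sample_fm_sets[[pairs[2, j]]]
    u <- length(union(a, b))
    if (u == 0) { jac[j] <- 0; empty_pairs <- empty_pairs + 1L }
    else jac[j] <- length(intersect(a, b)) / u
  }
  same <- group_mask[pairs[1, ]] == group_mask[pairs[2, ]]
  type <- ifelse(same, "within", "cross")
  within <- jac[same]
  cross <- jac[!same]
  if (paired) {
    m <- min(length(within), length(cross))
    tt <- stats::t.test(within[seq_len(m)], cross[seq_len(m)], paired = TRUE)
    method <- "paired t-test (pairs truncated to equal length in pair order)"
  } else {
    tt <- stats::t.test(within, cross)
    method <- "Welch two-sample t-test"
  }
  structure(list(
    pairs = data.frame(sample_a = ids[pairs[1, ]], sample_b = ids[pairs[2, ]],
                       jaccard = jac, type = type, stringsAsFactors = FALSE),
    within = within, cross = cross,
    t_statistic = unname(tt$statistic), p_value = tt$p.value,
    method = method, empty_pair_count = empty_pairs),
    class = "jaccard_comparison")
}

#' @export
print.jaccard_comparison <- function(x, ...) {
  cat(sprintf("jaccard_comparison: within mean %.3f (n=%d), cross mean %.3f (n=%d)\n",
              mean(x$within), length(x$within), mean(x$cross), length(x$cross)))
  cat(sprintf("  %s: t = %.3f, p = %.3g\n", x$method, x$t_statistic, x$p_value))
  if (x$empty_pair_count > 0)
    cat("  note:", x$empty_pair_count, "pair(s) with both sets empty (J = 0 by convention)\n")
  invisible(x)
}
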