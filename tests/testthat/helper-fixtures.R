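# Shared fixtures: in-memory manifests, toy cohorts and independent oracles.

# Build an fqm_manifest directly (no files on disk needed for indexing).
make_manifest <- function(sample_ids, cohorts, exposures = NULL,
                          read_paths = NULL) {
  n <- length(sample_ids)
  m <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  m$cohort <- factor(cohorts, levels = c("control", "patient"))
  m$read_paths <- if (is.null(read_paths))
    replicate(n, NA_character_, simplify = FALSE) else read_paths
  m$exposures <- if (is.null(exposures))
    replicate(n, stats::setNames(logical(0), character(0)), simplify = FALSE)
  else exposures
  class(m) <- c("fqm_manifest", "data.frame")
  m
}

# kmer_sets + manifest for the 5-sample toy cohort used across core tests:
# H1={AAA,CCC} H2={AAA,GGG} H3={CCC,TTT}  P1={AAA,TTT} P2={GGG,CCA}
toy_cohort <- function() {
  sets <- list(H1 = c("AAA", "CCC"), H2 = c("AAA", "GGG"),
               H3 = c("CCC", "TTT"), P1 = c("AAA", "TTT"),
               P2 = c("GGG", "CCA"))
  ksets <- lapply(names(sets), function(id)
    kmer_set(sets[[id]], k = 3, sample_id = id))
  names(ksets) <- names(sets)
  manifest <- make_manifest(names(sets),
                            c("control", "control", "control",
                              "patient", "patient"))
  list(ksets = ksets, manifest = manifest)
}

# Independent oracle: naive string-keyed window counting for extraction.
naive_kmer_counts <- function(reads, k, min_count = 2) {
  wins <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    substring(r, 1:(n - k + 1), k:n)
  }))
  wins <- wins[!grepl("[^ACGT]", wins)]
  tab <- table(wins)
  sort(names(tab)[tab >= min_count])
}

# Independent oracle: per-k-mer membership scans for frequentmer derivation.
brute_force_frequentmers <- function(kset_list, cohorts, r) {
  universe <- sort(unique(unlist(kset_list)))
  in_sample <- function(km, i) km %in% kset_list[[i]]
  ctl <- which(cohorts == "control")
  pat <- which(cohorts == "patient")
  control_fms <- patient_fms <- numeric(0)
  for (km in universe) {
    nc <- sum(vapply(ctl, function(i) in_sample(km, i), logical(1)))
    np <- sum(vapply(pat, function(i) in_sample(km, i), logical(1)))
    if (nc >= r && np == 0) control_fms <- c(control_fms, km)
    if (np >= r && nc == 0) patient_fms <- c(patient_fms, km)
  }
  list(control_fms = control_fms, patient_fms = patient_fms)
}

# Independent oracle: AUC by brute-force enumeration of all score thresholds
# (trapezoid over the full ROC step curve).
brute_force_auc <- function(labels, scores) {
  thresholds <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  fpr <- tpr <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred <- scores >= thresholds[i]
    tpr[i] <- sum(pred & labels == 1) / sum(labels == 1)
    fpr[i] <- sum(pred & labels == 0) / sum(labels == 0)
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

random_reads <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

write_fasta <- function(seqs, path, ids = paste0("r", seq_along(seqs))) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

write_fastq_plain <- function(seqs, path, ids = paste0("r", seq_along(seqs))) {
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    vapply(nchar(seqs), function(n)
                      paste(rep("F", n), collapse = ""), character(1))), path)
  path
}

# Feature matrix straight from vectors, for classifier unit tests.
make_fm <- function(X, y, sides = rep("patient", ncol(X)), fold_id = 1L,
                    feature_kmers = as.numeric(seq_len(ncol(X)))) {
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(nrow(X)))
  structure(list(fold_id = fold_id, feature_kmers = feature_kmers,
                 feature_side = sides, X = X,
                 y = stats::setNames(y, rownames(X))),
            class = "feature_matrix")
}
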