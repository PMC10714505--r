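#' Specify a planted-marker synthetic two-cohort metagenome
#'
#' The generator emulates the statistical structure the frequentmer method
#' exploits: both cohorts share a common background sequence pool (the shared
#' microbiome), while cohort-specific marker sequences are planted into a
#' random subset of one cohort's samples at a controlled prevalence. Marker
#' sequences are rejection-sampled to be k-mer-disjoint from the background
#' and from each other, so every marker k-mer is a ground-truth frequentmer
#' candidate. Optional exposure markers are planted only into
#' exposure-positive patients. Reads receive i.i.d. per-base substitution
#' errors (no indels).
#'
#' @param n_patients,n_controls Cohort sizes (default 30 each).
#' @param n_background_refs,background_len Shared background pool: number of
#'   reference sequences and their length in bases (default 1 x 5000).
#' @param n_patient_markers,n_control_markers Planted marker counts
#'   (default 10 patient, 0 control).
#' @param marker_len Marker length in bases, `>= k` (default 100, one read).
#' @param prevalence Probability that a marker-carrying cohort sample
#'   includes each marker (default 0.5).
#' @param reads_per_sample Background reads per sample (default 600).
#' @param read_len Read length in bases (default 100).
#' @param error_rate Per-base substitution probability (default 0.005).
#' @param coverage_per_included_marker Reads drawn from each included marker;
#'   must be `>= 2` for marker k-mers to survive the singleton filter
#'   (default 3).
#' @param exposure_fraction Fraction of patients flagged exposure-positive
#'   (default 0).
#' @param n_exposure_markers Markers planted only in exposure-positive
#'   patients (default 0).
#' @param covariate_name Manifest column name for the exposure flag.
#' @param k K-mer length used for marker/background disjointness (default 16).
#' @param seed Integer seed; every stage is reproducible from it.
#' @param inclusion Optional logical override matrix (markers x samples,
#'   dimnames required) forcing exact per-sample marker inclusion instead of
#'   Bernoulli draws; rows/samples not named in it keep their drawn value.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients = 30L, n_controls = 30L,
                           n_background_refs = 1L, background_len = 5000L,
                           n_patient_markers = 10L, n_control_markers = 0L,
                           marker_len = 100L, prevalence = 0.5,
                           reads_per_sample = 600L, read_len = 100L,
                           error_rate = 0.005,
                           coverage_per_included_marker = 3L,
                           exposure_fraction = 0, n_exposure_markers = 0L,
                           covariate_name = "exposure",
                           k = 16L, seed = 1L, inclusion = NULL) {
  stopifnot(prevalence >= 0, prevalence <= 1, error_rate >= 0, error_rate <= 1,
            exposure_fraction >= 0, exposure_fraction <= 1,
            marker_len >= k, read_len >= k,
            coverage_per_included_marker >= 1)
  spec <- list(n_patients = as.integer(n_patients),
               n_controls = as.integer(n_controls),
               n_background_refs = as.integer(n_background_refs),
               background_len = as.integer(background_len),
               n_patient_markers = as.integer(n_patient_markers),
               n_control_markers = as.integer(n_control_markers),
               marker_len = as.integer(marker_len),
               prevalence = prevalence,
               reads_per_sample = as.integer(reads_per_sample),
               read_len = as.integer(read_len),
               error_rate = error_rate,
               coverage_per_included_marker = as.integer(coverage_per_included_marker),
               exposure_fraction = exposure_fraction,
               n_exposure_markers = as.integer(n_exposure_markers),
               covariate_name = covariate_name,
               k = as.integer(k), seed = as.integer(seed),
               inclusion = inclusion)
  class(spec) <- "synthetic_spec"
  spec
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

seq_kmers <- function(seqs, k) extract_kmers_cpp(seqs, as.integer(k), 1L, FALSE)

#' Generate a synthetic two-cohort read set with ground truth
#'
#' Draws the background pool, rejection-samples k-mer-disjoint markers,
#' decides per-sample marker inclusion (Bernoulli at the spec's prevalence,
#' overridable via `spec$inclusion`), emits each sample's reads (uniform
#' background reads plus `coverage_per_included_marker` reads covering every
#' included marker), and applies substitution errors. Fully reproducible from
#' `spec$seed`, including the byte content of emitted FASTQ files.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir If non-NULL, write per-sample gzipped FASTQ, `manifest.csv`
#'   and `truth.json` there.
#' @return A list of class `synthetic_cohorts`: `manifest` (an
#'   `fqm_manifest`), `reads` (named list of `sample_reads`), and `truth`
#'   (class `ground_truth`: `markers` data frame with name/sequence/type,
#'   `marker_kmers` named list, `inclusion` logical matrix markers x samples,
#'   `expected_sample_kmers` pre-error per-sample marker k-mer sets, `k`).
#' @export
generate_cohorts <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_private_seed(spec$seed, generate_cohorts_impl(spec, out_dir))
}

generate_cohorts_impl <- function(spec, out_dir) {
  k <- spec$k
  background <- vapply(seq_len(spec$n_background_refs),
                       function(i) random_dna(spec$background_len), character(1))
  forbidden <- seq_kmers(background, k)

  n_markers <- spec$n_patient_markers + spec$n_control_markers +
    spec$n_exposure_markers
  marker_type <- rep(c("patient", "control", "exposure"),
                     c(spec$n_patient_markers, spec$n_control_markers,
                       spec$n_exposure_markers))
  markers <- character(n_markers)
  marker_kmers <- vector("list", n_markers)
  for (i in seq_len(n_markers)) {
    ok <- FALSE
    for (attempt in 1:100) {
      cand <- random_dna(spec$marker_len)
      km <- seq_kmers(cand, k)
      if (length(km) == spec$marker_len - k + 1 && # internally duplicate-free
          !any(km %in% forbidden)) {
        markers[i] <- cand
        marker_kmers[[i]] <- km
        forbidden <- sort(c(forbidden, km))
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("failed to rejection-sample a k-mer-disjoint marker after 100 ",
           "attempts; use a longer background or fewer/shorter markers")
  }
  if (n_markers)
    names(marker_kmers) <- sprintf("%s_marker_%02d", marker_type,
                                   stats::ave(seq_len(n_markers), marker_type,
                                              FUN = seq_along))

  sample_ids <- c(sprintf("P%03d", seq_len(spec$n_patients)),
                  sprintf("C%03d", seq_len(spec$n_controls)))
  cohort <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
  n_pos <- round(spec$exposure_fraction * spec$n_patients)
  exposure <- rep(NA, length(sample_ids))
  if (spec$exposure_fraction > 0) {
    pos <- sample(seq_len(spec$n_patients), n_pos)
    exposure[seq_len(spec$n_patients)] <- FALSE
    exposure[pos] <- TRUE
  }

  inclusion <- matrix(FALSE, nrow = n_markers, ncol = length(sample_ids),
                      dimnames = list(names(marker_kmers), sample_ids))
  for (i in seq_len(n_markers)) {
    eligible <- switch(marker_type[i],
                       patient = cohort == "patient",
                       control = cohort == "control",
                       exposure = cohort == "patient" & !is.na(exposure) & exposure)
    inclusion[i, eligible] <- stats::runif(sum(eligible)) < spec$prevalence
  }
  if (!is.null(spec$inclusion)) {
    ov <- spec$inclusion
    if (is.null(rownames(ov)) || is.null(colnames(ov)))
      stop("inclusion override must have marker row names and sample column names")
    bad <- setdiff(rownames(ov), rownames(inclusion))
    if (length(bad)) stop("unknown marker(s) in inclusion override: ",
                          paste(bad, collapse = ", "))
    inclusion[rownames(ov), colnames(ov)] <- ov
  }

  reads <- vector("list", length(sample_ids))
  names(reads) <- sample_ids
  for (s in seq_along(sample_ids)) {
    ref_idx <- sample.int(spec$n_background_refs, spec$reads_per_sample,
                          replace = TRUE)
    offs <- vapply(ref_idx, function(r)
      sample.int(spec$background_len - spec$read_len + 1L, 1L), integer(1))
    bg <- substring(background[ref_idx], offs, offs + spec$read_len - 1L)
    marker_reads <- character(0)
    for (i in which(inclusion[, s])) {
      mreads <- marker_reads_for(markers[i], spec$marker_len, spec$read_len, k)
      marker_reads <- c(marker_reads,
                        rep(mreads, spec$coverage_per_included_marker))
    }
    reads[[s]] <- inject_errors(c(bg, marker_reads), spec$error_rate)
  }

  exposures <- lapply(exposure, function(e) {
    v <- stats::setNames(logical(0), character(0))
    if (spec$exposure_fraction > 0) v <- stats::setNames(e, spec$covariate_name)
    v
  })

  read_paths <- as.list(rep(NA_character_, length(sample_ids)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in seq_along(sample_ids)) {
      fq <- file.path(out_dir, paste0(sample_ids[s], ".fastq.gz"))
      write_fastq(reads[[s]], sample_ids[s], fq)
      read_paths[[s]] <- fq
    }
  }

  manifest <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  manifest$cohort <- factor(cohort, levels = c("control", "patient"))
  manifest$read_paths <- read_paths
  manifest$exposures <- exposures
  class(manifest) <- c("fqm_manifest", "data.frame")

  expected <- lapply(seq_along(sample_ids), function(s) {
    inc <- which(inclusion[, s])
    if (length(inc)) sort(unique(unlist(marker_kmers[inc]))) else numeric(0)
  })
  names(expected) <- sample_ids

  truth <- structure(list(
    markers = data.frame(name = names(marker_kmers) %||% character(0),
                         sequence = markers, type = marker_type,
                         stringsAsFactors = FALSE),
    marker_kmers = marker_kmers,
    inclusion = inclusion,
    expected_sample_kmers = expected,
    background = background,
    k = k), class = "ground_truth")

  if (!is.null(out_dir)) {
    mdf <- data.frame(sample_id = sample_ids, cohort = cohort,
                      read_paths = basename(unlist(read_paths)),
                      stringsAsFactors = FALSE)
    if (spec$exposure_fraction > 0)
      mdf[[spec$covariate_name]] <- ifelse(is.na(exposure), NA,
                                           as.integer(exposure))
    utils::write.csv(mdf, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE, na = "NA")
    jsonlite::write_json(
      list(markers = truth$markers,
           inclusion = as.data.frame(inclusion),
           k = k, seed = spec$seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE)
  }

  structure(list(manifest = manifest, reads = reads, truth = truth,
                 spec = spec, out_dir = out_dir),
            class = "synthetic_cohorts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reads covering the full marker: the marker itself when it fits exactly in
# one read, otherwise tiles with k-1 overlap (plus a final read ending at the
# marker's last base) so every marker k-mer is covered by some read.
marker_reads_for <- function(marker, marker_len, read_len, k) {
  if (marker_len == read_len) return(marker)
  if (marker_len < read_len) {
    # embed at a random position, padded with random bases; junction k-mers
    # are sample-specific and cannot recur across samples
    pad_total <- read_len - marker_len
    left <- if (pad_total > 0) sample.int(pad_total + 1L, 1L) - 1L else 0L
    paste0(if (left > 0) random_dna(left) else "",
           marker,
           if (pad_total - left > 0) random_dna(pad_total - left) else "")
  } else {
    starts <- unique(c(seq(1L, marker_len - read_len + 1L,
                           by = read_len - k + 1L),
                       marker_len - read_len + 1L))
    substring(marker, starts, starts + read_len - 1L)
  }
}

# i.i.d. per-base substitutions: binomial error count per read, uniform
# positions, substitute with one of the three other bases.
inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  lens <- nchar(reads)
  n_err <- stats::rbinom(length(reads), lens, error_rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], n_err[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      alt <- bases[bases != chars[p]]
      chars[p] <- alt[sample.int(3L, 1L)]
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

write_fastq <- function(reads, sample_id, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  if (length(reads)) {
    qual <- vapply(nchar(reads), function(n)
      paste(rep("I", n), collapse = ""), character(1))
    block <- paste0("@", sample_id, "_read", seq_along(reads), "\n",
                    reads, "\n+\n", qual)
    writeLines(block, con)
  }
  invisible(path)
}

#' Precision / recall of marker k-mer recovery
#'
#' Scores a derived `frequentmer_catalog` against the generator's ground
#' truth. A marker k-mer is *eligible* on its side if it meets the
#' frequentmer condition over the scored samples: present in at least `r`
#' own-cohort samples and absent from every opposite-cohort sample. When the
#' actual post-error `ksets` are supplied, eligibility is evaluated on them
#' (i.e. after error injection and the singleton filter); otherwise the
#' pre-error inclusion matrix is used.
#'
#' @param catalog A `frequentmer_catalog`.
#' @param truth A `ground_truth` from [generate_cohorts()].
#' @param manifest The matching `fqm_manifest`.
#' @param ksets Optional named list of `kmer_set` (post-error truth basis).
#' @param sample_ids Samples over which eligibility is evaluated (e.g. the
#'   fold's training split); default all manifest samples.
#' @param r Recurrency threshold; default the catalog's.
#' @return A list of class `recovery_score`: `recall` / `precision` (overall)
#'   and per-side `recall_patient`, `recall_control`, `precision_patient`,
#'   `precision_control`, plus eligible counts.
#' @export
score_recovery <- function(catalog, truth, manifest, ksets = NULL,
                           sample_ids = NULL, r = catalog$r) {
  stopifnot(inherits(catalog, "frequentmer_catalog"),
            inherits(truth, "ground_truth"))
  if (truth$k != catalog$k) stop("catalog and truth use different k")
  if (is.null(sample_ids)) sample_ids <- manifest$sample_id
  cohort <- manifest$cohort[match(sample_ids, manifest$sample_id)]

  side_of <- ifelse(truth$markers$type == "control", "control", "patient")
  patient_mk <- sort(unique(unlist(truth$marker_kmers[side_of == "patient"])))
  control_mk <- sort(unique(unlist(truth$marker_kmers[side_of == "control"])))

  presence_counts <- function(kmers) {
    np <- numeric(length(kmers)); nc <- numeric(length(kmers))
    for (i in seq_along(sample_ids)) {
      present <- if (!is.null(ksets)) {
        kmers %in% ksets[[sample_ids[i]]]$kmers
      } else {
        sid <- sample_ids[i]
        inc <- truth$inclusion[, sid]
        kmers %in% unlist(truth$marker_kmers[inc], use.names = FALSE)
      }
      if (cohort[i] == "patient") np <- np + present else nc <- nc + present
    }
    list(np = np, nc = nc)
  }
  eligible <- function(kmers, side) {
    if (!length(kmers)) return(numeric(0))
    pc <- presence_counts(kmers)
    if (side == "patient") kmers[pc$np >= r & pc$nc == 0]
    else kmers[pc$nc >= r & pc$np == 0]
  }
  elig_p <- eligible(patient_mk, "patient")
  elig_c <- eligible(control_mk, "control")

  rec <- function(fms, elig) if (length(elig)) mean(elig %in% fms) else NA_real_
  prec <- function(fms, mk) if (length(fms)) mean(fms %in% mk) else NA_real_
  recall_p <- rec(catalog$patient_fms, elig_p)
  recall_c <- rec(catalog$control_fms, elig_c)
  prec_p <- prec(catalog$patient_fms, patient_mk)
  prec_c <- prec(catalog$control_fms, control_mk)
  n_elig <- length(elig_p) + length(elig_c)
  n_cat <- length(catalog$patient_fms) + length(catalog$control_fms)
  overall_recall <- if (n_elig)
    (sum(elig_p %in% catalog$patient_fms) +
       sum(elig_c %in% catalog$control_fms)) / n_elig else NA_real_
  overall_prec <- if (n_cat)
    (sum(catalog$patient_fms %in% patient_mk) +
       sum(catalog$control_fms %in% control_mk)) / n_cat else NA_real_

  structure(list(recall = overall_recall, precision = overall_prec,
                 recall_patient = recall_p, recall_control = recall_c,
                 precision_patient = prec_p, precision_control = prec_c,
                 n_eligible_patient = length(elig_p),
                 n_eligible_control = length(elig_c),
                 r = r), class = "recovery_score")
}

#' @export
print.recovery_score <- function(x, ...) {
  cat(sprintf("recovery_score (r = %d): recall %.3f, precision %.3f\n",
              x$r, x$recall, x$precision))
  invisible(x)
}
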