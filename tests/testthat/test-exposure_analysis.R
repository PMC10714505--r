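expo_fixture <- function(p3_kmers) {
  ids <- c("P1", "P2", "P3", "C1", "C2")
  ksets <- list(kmer_set("AAA", sample_id = "P1"),
                kmer_set("AAA", sample_id = "P2"),
                kmer_set(p3_kmers, k = 3, sample_id = "P3"),
                kmer_set("CCC", sample_id = "C1"),
                kmer_set("CCC", sample_id = "C2"))
  names(ksets) <- ids
  expo <- list(c(HBV = TRUE), c(HBV = TRUE), c(HBV = FALSE),
               c(HBV = NA), c(HBV = NA))
  man <- make_manifest(ids, c("patient", "patient", "patient",
                              "control", "control"), exposures = expo)
  list(ksets = ksets, manifest = man)
}

test_that("subset-specific frequentmers require absence from exposure-negative patients", {
  # AAA present in an HBV-negative patient: excluded
  f <- expo_fixture("AAA")
  rep <- subset_specific_frequentmers(f$ksets, f$manifest, "HBV", r = 2)
  expect_length(rep$subset_specific_fms, 0)

  # HBV-negative patient carries GGG instead: AAA qualifies at prevalence 1
  f2 <- expo_fixture("GGG")
  rep2 <- subset_specific_frequentmers(f2$ksets, f2$manifest, "HBV", r = 2)
  expect_equal(decode_kmer(rep2$subset_specific_fms, 3), "AAA")
  expect_equal(unname(rep2$per_fm_prevalence), 1.0)

  # r above the number of exposure-positive samples: empty
  rep3 <- subset_specific_frequentmers(f2$ksets, f2$manifest, "HBV", r = 3)
  expect_length(rep3$subset_specific_fms, 0)

  expect_error(subset_specific_frequentmers(f2$ksets, f2$manifest, "smoking", 2),
               "not found")
})

test_that("subset-specific frequentmers are a subset of the patient catalog", {
  set.seed(41)
  n_p <- 6; n_c <- 4
  ids <- c(paste0("P", 1:n_p), paste0("C", 1:n_c))
  cohorts <- rep(c("patient", "control"), c(n_p, n_c))
  expo <- c(lapply(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                   function(v) c(HBV = v)),
            replicate(n_c, c(HBV = NA), simplify = FALSE))
  man <- make_manifest(ids, cohorts, exposures = expo)
  ksets <- lapply(ids, function(id)
    kmer_set(sample(0:60, 25), k = 3, sample_id = id))
  names(ksets) <- ids
  rep <- subset_specific_frequentmers(ksets, man, "HBV", r = 2)
  idx <- build_index(ksets, man)
  cat2 <- derive_frequentmers(idx, 2)
  expect_true(all(rep$subset_specific_fms %in% cat2$patient_fms))
})

test_that("unknown exposure status excludes patients with a warning", {
  f <- expo_fixture("GGG")
  f$manifest$exposures[[3]] <- c(HBV = NA)
  expect_warning(
    rep <- subset_specific_frequentmers(f$ksets, f$manifest, "HBV", r = 2),
    "unknown")
  # P3 (unknown) no longer counts as negative: GGG in >=0 positives is not
  # enough, but AAA (2 positives, 0 known negatives, 0 controls) qualifies
  expect_equal(decode_kmer(rep$subset_specific_fms, 3), "AAA")
})

test_that("prevalence histogram bins fractions of positive samples", {
  f <- expo_fixture("GGG")
  rep <- subset_specific_frequentmers(f$ksets, f$manifest, "HBV", r = 2)
  h <- prevalence_histogram(rep, bin_width = 25)
  expect_equal(sum(h$n_fms), length(rep$subset_specific_fms))
  expect_equal(h$n_fms[h$bin_high == 100], 1L)
})

test_that("Jaccard index follows the set formula with the empty convention", {
  sets <- list(S1 = c(1, 2, 3), S2 = c(2, 3, 4), S3 = numeric(0),
               S4 = numeric(0), S5 = c(1, 2, 3))
  cmp <- jaccard_profile_comparison(sets, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  pj <- function(a, b) cmp$pairs$jaccard[cmp$pairs$sample_a == a &
                                           cmp$pairs$sample_b == b]
  expect_equal(pj("S1", "S2"), 0.5)  # {2,3} / {1,2,3,4}
  expect_equal(pj("S1", "S5"), 1.0)  # identical non-empty
  expect_equal(pj("S1", "S3"), 0.0)  # disjoint
  expect_equal(pj("S3", "S4"), 0.0)  # both empty, by convention
  expect_equal(cmp$empty_pair_count, 1L)
  expect_true(all(cmp$pairs$jaccard >= 0 & cmp$pairs$jaccard <= 1))
  expect_equal(cmp$method, "Welch two-sample t-test")
})

test_that("Jaccard comparison separates similar from dissimilar subgroups", {
  set.seed(42)
  # group A samples share a core set; group B samples are unrelated
  core <- 1:30
  sets <- c(lapply(1:5, function(i) c(core, sample(100:400, 10))),
            lapply(1:5, function(i) sample(500:2000, 40)))
  names(sets) <- paste0("S", 1:10)
  mask <- rep(c(TRUE, FALSE), each = 5)
  cmp <- jaccard_profile_comparison(sets, mask)
  expect_gt(mean(cmp$within), mean(cmp$cross))
  expect_lt(cmp$p_value, 0.05)
  expect_error(jaccard_profile_comparison(sets[1:3], c(TRUE, TRUE, FALSE)),
               "at least 2")
})

test_that("planted exposure markers are recovered from synthetic cohorts", {
  spec <- synthetic_spec(n_patients = 8, n_controls = 6,
                         background_len = 1500, reads_per_sample = 250,
                         read_len = 50, marker_len = 50, k = 12,
                         n_patient_markers = 1, n_exposure_markers = 2,
                         exposure_fraction = 0.5, prevalence = 1,
                         error_rate = 0, coverage_per_included_marker = 2,
                         seed = 77)
  syn <- generate_cohorts(spec)
  ksets <- lapply(names(syn$reads), function(id)
    extract_kmerset(syn$reads[[id]], k = 12, sample_id = id))
  names(ksets) <- names(syn$reads)
  rep <- subset_specific_frequentmers(ksets, syn$manifest, "exposure", r = 2)
  mk <- syn$truth$marker_kmers
  expo_kmers <- sort(unique(unlist(mk[syn$truth$markers$type == "exposure"])))
  # every exposure-marker k-mer is positive-specific at prevalence 1
  expect_true(all(expo_kmers %in% rep$subset_specific_fms))
  # the general patient marker is present in exposure-negative patients too
  pat_kmers <- unlist(mk[syn$truth$markers$type == "patient"])
  expect_false(any(pat_kmers %in% rep$subset_specific_fms))
})
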