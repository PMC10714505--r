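test_that("the cohort index counts distinct samples per cohort", {
  toy <- toy_cohort()
  idx <- build_index(toy$ksets, toy$manifest, fold_id = 1)
  tab <- data.frame(kmer = decode_kmer(idx$kmer, 3),
                    nc = idx$n_control, np = idx$n_patient)
  expect_equal(tab[order(tab$kmer), ],
               data.frame(kmer = c("AAA", "CCA", "CCC", "GGG", "TTT"),
                          nc = c(2L, 0L, 2L, 1L, 1L),
                          np = c(1L, 1L, 0L, 1L, 1L)),
               ignore_attr = TRUE)
  expect_equal(idx$n_control_total, 3L)
  expect_equal(idx$n_patient_total, 2L)

  single <- build_index(list(kmer_set("AAA", sample_id = "H1")),
                        toy$manifest, fold_id = 0)
  expect_equal(single$n_control, 1L)
  expect_equal(single$n_patient, 0L)

  empty <- build_index(list(), toy$manifest)
  expect_length(empty$kmer, 0)
})

test_that("index construction rejects mixed k and unknown samples", {
  toy <- toy_cohort()
  mixed <- c(toy$ksets, list(kmer_set("ACGT", sample_id = "H9")))
  expect_error(build_index(mixed, toy$manifest), "not in manifest")
  m2 <- rbind(toy$manifest, make_manifest("H9", "control"))
  class(m2) <- c("fqm_manifest", "data.frame")
  expect_error(build_index(mixed, m2), "mixed k")
})

test_that("file-backed and in-memory index backends agree exactly", {
  dir <- withr::local_tempdir()
  toy <- toy_cohort()
  paths <- vapply(toy$ksets, function(ks)
    write_kmerset(ks, file.path(dir, paste0(ks$sample_id, ".kset"))),
    character(1))
  idx_mem <- build_index(toy$ksets, toy$manifest, fold_id = 1)
  idx_file <- build_index(unname(paths), toy$manifest, fold_id = 1)
  expect_identical(idx_mem[c("kmer", "n_control", "n_patient")],
                   idx_file[c("kmer", "n_control", "n_patient")])
})

test_that("frequentmer derivation implements recurrent presence + total absence", {
  toy <- toy_cohort()
  idx <- build_index(toy$ksets, toy$manifest)

  c2 <- derive_frequentmers(idx, 2)
  expect_equal(decode_kmer(c2$control_fms, 3), "CCC")
  expect_length(c2$patient_fms, 0)

  expect_warning(c1 <- derive_frequentmers(idx, 1), "group-absence")
  expect_equal(decode_kmer(c1$control_fms, 3), "CCC")
  expect_equal(decode_kmer(c1$patient_fms, 3), "CCA")

  c9 <- derive_frequentmers(idx, 9) # exceeds both cohort sizes
  expect_length(c9$control_fms, 0)
  expect_length(c9$patient_fms, 0)
})

test_that("recurrency sweep reports counts and the patient ratio", {
  toy <- toy_cohort()
  idx <- build_index(toy$ksets, toy$manifest)
  sw <- suppressWarnings(recurrency_sweep(idx, c(1, 2)))
  expect_equal(sw$n_control_fms, c(1L, 1L))
  expect_equal(sw$n_patient_fms, c(1L, 0L))
  expect_equal(sw$patient_ratio, c(0.5, 0))

  empty <- build_index(list(), toy$manifest)
  sw0 <- recurrency_sweep(empty, c(2, 3))
  expect_equal(sw0$n_control_fms + sw0$n_patient_fms, c(0L, 0L))
  expect_true(all(is.na(sw0$patient_ratio)))
})

test_that("sweep counts are non-increasing in r (property)", {
  set.seed(31)
  for (trial in 1:10) {
    n <- sample(4:10, 1)
    cohorts <- sample(c("control", "patient"), n, replace = TRUE,
                      prob = c(0.5, 0.5))
    cohorts[1:2] <- c("control", "patient")
    ksets <- lapply(seq_len(n), function(i)
      kmer_set(sample(0:80, sample(5:40, 1)), k = 4,
               sample_id = paste0("S", i)))
    man <- make_manifest(paste0("S", seq_len(n)), cohorts)
    idx <- build_index(ksets, man)
    sw <- recurrency_sweep(idx, 1:6)
    expect_true(all(diff(sw$n_control_fms) <= 0))
    expect_true(all(diff(sw$n_patient_fms) <= 0))
  }
})

test_that("derivation matches the brute-force membership-scan oracle", {
  set.seed(32)
  for (trial in 1:25) {
    n <- sample(4:12, 1)
    cohorts <- c("control", "patient",
                 sample(c("control", "patient"), n - 2, replace = TRUE))
    k <- sample(3:16, 1)
    kset_list <- lapply(seq_len(n), function(i)
      sort(sample(0:199, sample(0:60, 1))))
    ksets <- lapply(seq_len(n), function(i)
      kmer_set(kset_list[[i]], k = k, sample_id = paste0("S", i)))
    man <- make_manifest(paste0("S", seq_len(n)), cohorts)
    idx <- build_index(ksets, man)
    for (r in c(1, 2, 3)) {
      got <- suppressWarnings(derive_frequentmers(idx, r))
      want <- brute_force_frequentmers(kset_list, cohorts, r)
      expect_equal(got$control_fms, want$control_fms, ignore_attr = TRUE)
      expect_equal(got$patient_fms, want$patient_fms, ignore_attr = TRUE)
    }
  }
})

test_that("catalogs are disjoint, nested in r, and leak-free (properties)", {
  set.seed(33)
  for (trial in 1:10) {
    n <- 10
    cohorts <- rep(c("control", "patient"), each = 5)
    kset_list <- lapply(seq_len(n), function(i) sort(sample(0:150, 40)))
    ksets <- lapply(seq_len(n), function(i)
      kmer_set(kset_list[[i]], k = 4, sample_id = paste0("S", i)))
    man <- make_manifest(paste0("S", seq_len(n)), cohorts)
    idx <- build_index(ksets, man)
    prev <- NULL
    for (r in 1:4) {
      cat_r <- suppressWarnings(derive_frequentmers(idx, r))
      expect_length(intersect(cat_r$control_fms, cat_r$patient_fms), 0)
      if (!is.null(prev)) {
        expect_true(all(cat_r$control_fms %in% prev$control_fms))
        expect_true(all(cat_r$patient_fms %in% prev$patient_fms))
      }
      prev <- cat_r
      # re-scan: no frequentmer occurs in any opposite-cohort sample
      for (i in which(cohorts == "patient"))
        expect_length(intersect(cat_r$control_fms, kset_list[[i]]), 0)
      for (i in which(cohorts == "control"))
        expect_length(intersect(cat_r$patient_fms, kset_list[[i]]), 0)
    }
  }
})

test_that("test-set recovery reports fractions, votes and per-sample counts", {
  man <- make_manifest(c("T1", "T2"), c("patient", "control"))
  catalog <- structure(list(fold_id = 1L, r = 2L, k = 3L,
                            control_fms = numeric(0),
                            patient_fms = encode_kmer("TTT", 3)),
                       class = "frequentmer_catalog")
  tks <- list(kmer_set("TTT", sample_id = "T1"),
              kmer_set("AAA", sample_id = "T2"))
  rep <- test_recovery(catalog, tks, man)
  expect_equal(rep$recovery_fraction, 1.0)
  expect_equal(rep$votes$vote, "patient")
  expect_equal(rep$per_sample$n_patient_fms_detected, c(1L, 0L))

  # tie -> unassigned; absent -> unrecovered, excluded from voting
  man2 <- make_manifest(paste0("T", 1:4),
                        c("control", "control", "patient", "patient"))
  catalog2 <- structure(list(fold_id = 1L, r = 2L, k = 3L,
                             control_fms = encode_kmer("GGG", 3),
                             patient_fms = encode_kmer("TTT", 3)),
                        class = "frequentmer_catalog")
  tks2 <- lapply(paste0("T", 1:4), function(id) kmer_set("TTT", sample_id = id))
  rep2 <- test_recovery(catalog2, tks2, man2)
  votes <- rep2$votes
  expect_equal(votes$vote[votes$side == "patient"], "unassigned")
  expect_true(is.na(votes$vote[votes$side == "control"])) # never seen
  expect_equal(rep2$recovery_fraction, 0.5)
  expect_error(test_recovery(catalog2, list(), man2), "empty test set")
})
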