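#' Pipeline run configuration
#'
#' Validates and freezes the parameters of an end-to-end run: either a
#' manifest of existing read files or a [synthetic_spec()] to simulate,
#' k-mer parameters, the recurrency threshold, the fold count, the model
#' kind and the seed. The configuration is serialized alongside all outputs
#' and its hash stamps every stage, so stale intermediates from a different
#' configuration are never mixed into a resumed run.
#'
#' @param out_dir Run directory (created if needed).
#' @param manifest_path Path to a manifest of real read files (exclusive with
#'   `synthetic`).
#' @param synthetic A `synthetic_spec` to simulate (exclusive with
#'   `manifest_path`).
#' @param k,min_count,canonical K-mer extraction parameters.
#' @param r Recurrency threshold for frequentmer derivation.
#' @param n_folds Cross-validation folds (default 10).
#' @param model `"logistic"` or `"boosted"`.
#' @param seed Integer seed for fold assignment and the booster.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, manifest_path = NULL, synthetic = NULL,
                       k = 16L, min_count = 2L, canonical = FALSE, r = 15L,
                       n_folds = 10L, model = c("logistic", "boosted"),
                       seed = 1L) {
  model <- match.arg(model)
  if (is.null(manifest_path) == is.null(synthetic))
    stop("provide exactly one of manifest_path or synthetic")
  if (!is.null(manifest_path) && !file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  stopifnot(k >= 1, min_count >= 1, r >= 1, n_folds >= 2)
  structure(list(out_dir = out_dir, manifest_path = manifest_path,
                 synthetic = synthetic, k = as.integer(k),
                 min_count = as.integer(min_count), canonical = canonical,
                 r = as.integer(r), n_folds = as.integer(n_folds),
                 model = model, seed = as.integer(seed)),
            class = "run_config")
}

# Hash of the scientific configuration (out_dir excluded: the same run in a
# different directory is the same run).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  fields <- unclass(config)[setdiff(names(config), "out_dir")]
  writeLines(jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

stage_done <- function(out_dir, stage, hash) {
  stamp <- file.path(out_dir, paste0(".stage_", stage, ".json"))
  file.exists(stamp) &&
    identical(jsonlite::read_json(stamp)$config_hash, unname(hash))
}

stamp_stage <- function(out_dir, stage, hash) {
  jsonlite::write_json(list(stage = stage, config_hash = unname(hash)),
                       file.path(out_dir, paste0(".stage_", stage, ".json")),
                       auto_unbox = TRUE)
}

#' Run the end-to-end frequentmer pipeline
#'
#' Executes simulate (if configured) -> extract -> fold -> derive (per fold)
#' -> features -> classify -> evaluate, persisting every intermediate under
#' `config$out_dir`. Each completed stage is stamped with the configuration
#' hash; a rerun with the same configuration skips stages whose stamped
#' outputs are present, so a run is resumable after deleting any stage's
#' outputs (and its stamp). Rerunning an unchanged configuration end-to-end
#' reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `summary` (classification summary, also in
#'   `summary.json`), `catalogs`, `results`, `folds`, and paths of the
#'   persisted outputs.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  jsonlite::write_json(c(unclass(config)[setdiff(names(config), "synthetic")],
                         list(config_hash = unname(hash))),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", force = TRUE)
  say <- function(...) if (!quiet) message("[fqm] ", ...)

  # -- stage: simulate ------------------------------------------------------
  manifest_path <- config$manifest_path
  if (!is.null(config$synthetic)) {
    data_dir <- file.path(out_dir, "data")
    manifest_path <- file.path(data_dir, "manifest.csv")
    if (!stage_done(out_dir, "simulate", hash)) {
      say("simulate: generating synthetic cohorts")
      generate_cohorts(config$synthetic, out_dir = data_dir)
      stamp_stage(out_dir, "simulate", hash)
    } else say("simulate: up to date, skipped")
  }
  manifest <- load_manifest(manifest_path)

  # -- stage: extract -------------------------------------------------------
  kset_dir <- file.path(out_dir, "ksets")
  if (!stage_done(out_dir, "extract", hash)) {
    say("extract: ", nrow(manifest), " samples, k = ", config$k)
    extract_all_kmersets(manifest, k = config$k, min_count = config$min_count,
                         canonical = config$canonical, out_dir = kset_dir)
    stamp_stage(out_dir, "extract", hash)
  } else say("extract: up to date, skipped")
  ksets <- lapply(manifest$sample_id, function(sid)
    read_kmerset(file.path(kset_dir, paste0(sid, ".kset"))))
  names(ksets) <- manifest$sample_id

  # -- stage: folds ---------------------------------------------------------
  folds_path <- file.path(out_dir, "folds.json")
  if (!stage_done(out_dir, "folds", hash)) {
    folds <- make_folds(manifest, n_folds = config$n_folds, seed = config$seed)
    jsonlite::write_json(list(n_folds = folds$n_folds, seed = folds$seed,
                              assignment = as.list(folds$assignment)),
                         folds_path, auto_unbox = TRUE)
    stamp_stage(out_dir, "folds", hash)
    say("folds: assigned ", folds$n_folds, " stratified folds")
  } else {
    say("folds: up to date, skipped")
    fj <- jsonlite::read_json(folds_path)
    folds <- structure(list(n_folds = as.integer(fj$n_folds),
                            seed = as.integer(fj$seed),
                            assignment = unlist(fj$assignment)),
                       class = "fold_assignment")
  }

  # -- stage: classify (derive + features + fit, per fold) ------------------
  summary_path <- file.path(out_dir, "summary.json")
  cv <- NULL
  if (!stage_done(out_dir, "classify", hash) || !file.exists(summary_path)) {
    say("classify: r = ", config$r, ", model = ", config$model)
    cv <- crossval_classify(ksets, manifest, folds = folds, r = config$r,
                            model = config$model, seed = config$seed)
    for (f in seq_along(cv$catalogs)) {
      cat_f <- cv$catalogs[[f]]
      utils::write.csv(
        data.frame(kmer = format_code(c(cat_f$control_fms, cat_f$patient_fms)),
                   side = rep(c("control", "patient"),
                              c(length(cat_f$control_fms),
                                length(cat_f$patient_fms)))),
        file.path(out_dir, sprintf("catalog_fold%02d.csv", f)),
        row.names = FALSE, quote = FALSE)
      if (config$model == "logistic") {
        rk <- coefficient_report(cv$results[[f]], cv$fm_pairs[[f]]$train)
        tab <- rk$table
        tab$kmer <- format_code(tab$kmer)
        utils::write.csv(tab,
                         file.path(out_dir, sprintf("coefficients_fold%02d.csv", f)),
                         row.names = FALSE, quote = FALSE)
      }
    }
    s <- cv$summary
    jsonlite::write_json(
      list(model = config$model, r = config$r, n_folds = folds$n_folds,
           seed = config$seed, config_hash = unname(hash),
           per_fold_auc = as.list(s$per_fold_auc),
           mean_auc = s$mean_auc, pooled_auc = s$pooled_auc,
           ci = as.list(s$ci),
           confusion_percent = as.data.frame(s$confusion_percent)),
      summary_path, auto_unbox = TRUE, digits = NA)
    utils::write.csv(s$mean_roc, file.path(out_dir, "mean_roc.csv"),
                     row.names = FALSE, quote = FALSE)
    stamp_stage(out_dir, "classify", hash)
  } else say("classify: up to date, skipped")

  summary_json <- jsonlite::read_json(summary_path)
  say(sprintf("done: mean AUC %.3f over %d folds",
              as.numeric(summary_json$mean_auc),
              as.integer(summary_json$n_folds)))
  invisible(list(summary = summary_json, crossval = cv, folds = folds,
                 manifest = manifest,
                 paths = list(out_dir = out_dir, summary = summary_path,
                              ksets = kset_dir)))
}
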