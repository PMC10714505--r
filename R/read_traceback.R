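#' Select the most informative frequentmers by averaged coefficient
#'
#' Averages each frequentmer's signed logistic coefficient over the folds in
#' which it was a feature, then returns the `n_each` k-mers with the highest
#' averaged coefficient and the `n_each` with the lowest. In the regime the
#' method targets the former are patient frequentmers and the latter control
#' frequentmers; this is asserted and reported, not assumed.
#'
#' @param rankings List of `ranked_features`, one per fold (see
#'   [coefficient_report()]).
#' @param n_each Number of k-mers to take from each extreme (default 100).
#' @return A list of class `extreme_features`: `top` / `bottom` (data frames
#'   kmer, side, coefficient), `kmers` (all selected codes, sorted),
#'   `top_all_patient`, `bottom_all_control` (logical assertions).
#' @export
select_extreme_frequentmers <- function(rankings, n_each = 100L) {
  agg <- average_coefficient_ranking(rankings)
  agg <- agg[order(-agg$coefficient, agg$kmer), ] # signed, descending
  if (nrow(agg) < 2 * n_each)
    warning("only ", nrow(agg), " distinct features across folds; ",
            "extremes of size ", n_each, " will overlap or be truncated")
  n_top <- min(n_each, nrow(agg))
  n_bot <- min(n_each, nrow(agg))
  top <- utils::head(agg, n_top)
  bottom <- utils::tail(agg, n_bot)
  bottom <- bottom[order(bottom$coefficient, bottom$kmer), ]
  structure(list(top = top, bottom = bottom,
                 kmers = sort(unique(c(top$kmer, bottom$kmer))),
                 top_all_patient = all(top$side == "patient"),
                 bottom_all_control = all(bottom$side == "control")),
            class = "extreme_features")
}

#' Trace frequentmers back to the reads that contain them
#'
#' Exact multi-pattern scan: every read of every supplied sample is slid over
#' with the same 2-bit window encoding used for extraction (windows with N
#' never match) and checked against the query set. A read matching several
#' queries is emitted once in the FASTA but tallied once per query it
#' contains. FASTA headers are `sample_id|read_index|code1+code2+...` with
#' the matched k-mer codes.
#'
#' @param queries Numeric vector of encoded query k-mers (all the same `k`),
#'   or an `extreme_features` object.
#' @param samples List of `sample_reads` (see [read_sample()]).
#' @param k K-mer length of the queries.
#' @param fasta_path If non-NULL, write matching reads there as FASTA.
#' @param query_side Optional `"control"`/`"patient"` label per query, used
#'   to split per-sample hit counts by frequentmer side.
#' @return A list of class `traceback_report`: `per_query` (data frame kmer,
#'   n_reads, and side if given), `per_sample` (data frame sample_id,
#'   n_reads_hit, and per-side counts if sides given), `n_reads_total`
#'   (distinct reads emitted), `fasta_path`.
#' @export
trace_reads <- function(queries, samples, k = 16L, fasta_path = NULL,
                        query_side = NULL) {
  if (inherits(queries, "extreme_features")) {
    qtab <- rbind(queries$top, queries$bottom)
    qtab <- qtab[!duplicated(qtab$kmer), ]
    query_side <- qtab$side[order(qtab$kmer)]
    queries <- sort(qtab$kmer)
  }
  queries <- as.numeric(queries)
  if (length(queries) == 0) stop("empty query set")
  if (is.unsorted(queries, strictly = TRUE)) queries <- sort(unique(queries))
  if (!is.null(query_side)) stopifnot(length(query_side) == length(queries))

  per_query_counts <- numeric(length(queries))
  per_sample <- list()
  fasta_con <- NULL
  if (!is.null(fasta_path)) {
    fasta_con <- file(fasta_path, "wt")
    on.exit(close(fasta_con))
  }
  n_reads_total <- 0L
  for (s in samples) {
    scan <- scan_reads_cpp(s$reads, queries, as.integer(k))
    per_query_counts <- per_query_counts + scan$query_read_counts
    hit_idx <- which(lengths(scan$per_read) > 0)
    n_reads_total <- n_reads_total + length(hit_idx)
    side_counts <- c(control = 0L, patient = 0L)
    if (!is.null(query_side)) {
      for (i in hit_idx) {
        sides <- unique(query_side[scan$per_read[[i]]])
        side_counts[sides] <- side_counts[sides] + 1L
      }
    }
    per_sample[[length(per_sample) + 1L]] <- data.frame(
      sample_id = s$sample_id, n_reads_hit = length(hit_idx),
      n_reads_control_fms = side_counts[["control"]],
      n_reads_patient_fms = side_counts[["patient"]],
      stringsAsFactors = FALSE)
    if (!is.null(fasta_con) && length(hit_idx)) {
      headers <- vapply(hit_idx, function(i)
        paste0(">", s$sample_id, "|", i, "|",
               paste(format_code(queries[scan$per_read[[i]]]), collapse = "+")),
        character(1))
      writeLines(paste(headers, s$reads[hit_idx], sep = "\n"), fasta_con)
    }
  }
  per_query <- data.frame(kmer = queries, n_reads = per_query_counts)
  if (!is.null(query_side)) per_query$side <- query_side
  structure(list(per_query = per_query,
                 per_sample = do.call(rbind, per_sample),
                 n_reads_total = n_reads_total,
                 fasta_path = fasta_path),
            class = "traceback_report")
}

#' @export
print.traceback_report <- function(x, ...) {
  cat("traceback_report:", x$n_reads_total, "reads matched",
      nrow(x$per_query), "query frequentmers",
      sprintf("(mean %.1f reads per frequentmer)\n", mean(x$per_query$n_reads)))
  if (!is.null(x$fasta_path)) cat("  FASTA:", x$fasta_path, "\n")
  invisible(x)
}
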