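#' Encode / decode k-mers as 2-bit integers
#'
#' Each base maps to two bits (A=00, C=01, G=10, T=11), leftmost base most
#' significant, so a length-k ACGT string maps bijectively onto an integer in
#' `[0, 4^k)`. Codes are returned as doubles because `4^16 = 2^32` exceeds R's
#' integer range; doubles are exact up to `k = 26`.
#'
#' @param seqs Character vector of ACGT strings, all of length `k`.
#' @param k K-mer length.
#' @return `encode_kmer`: numeric vector of codes. `decode_kmer`: character
#'   vector of ACGT strings.
#' @examples
#' encode_kmer("ACGT", 4) # 27
#' decode_kmer(0, 4)      # "AAAA"
#' @export
encode_kmer <- function(seqs, k = nchar(seqs[1])) {
  encode_kmers_cpp(as.character(seqs), as.integer(k))
}

#' @rdname encode_kmer
#' @param codes Numeric vector of encoded k-mers.
#' @export
decode_kmer <- function(codes, k) {
  decode_kmers_cpp(as.numeric(codes), as.integer(k))
}

#' Reverse-complement encoded k-mers
#'
#' @inheritParams decode_kmer
#' @return Numeric vector of codes of the reverse complements.
#' @export
revcomp_kmer <- function(codes, k) {
  revcomp_codes_cpp(as.numeric(codes), as.integer(k))
}

#' Construct a k-mer set from an explicit k-mer vector
#'
#' Mostly useful in tests and toy examples; [extract_kmerset()] is the normal
#' entry point. Accepts either encoded codes or ACGT strings.
#'
#' @param kmers Numeric codes or character k-mers (deduplicated and sorted).
#' @param k K-mer length (inferred from strings if omitted).
#' @param sample_id Optional sample identifier.
#' @return A `kmer_set`.
#' @export
kmer_set <- function(kmers, k = NULL, sample_id = NA_character_) {
  if (is.character(kmers)) {
    if (is.null(k)) k <- if (length(kmers)) nchar(kmers[1]) else stop("k required")
    kmers <- encode_kmer(kmers, k)
  }
  if (is.null(k)) stop("k required when kmers are codes")
  structure(list(sample_id = sample_id, k = as.integer(k),
                 kmers = sort(unique(as.numeric(kmers)))),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat("kmer_set:", length(x$kmers), "distinct", paste0(x$k, "-mers"),
      if (!is.na(x$sample_id)) paste0("(sample ", x$sample_id, ")"), "\n")
  invisible(x)
}

#' Extract a sample's k-mer presence set
#'
#' Slides a window of length `k` (step 1) over every read, skipping windows
#' that contain an N, and keeps the distinct k-mers whose total occurrence
#' count across all of the sample's reads is at least `min_count`. The
#' default `min_count = 2` is the singleton filter: a k-mer observed exactly
#' once in a sample is discarded as a likely sequencing error. Counting is
#' forward-orientation by default; with `canonical = TRUE` each window is
#' mapped to the smaller of its code and its reverse-complement code before
#' counting.
#'
#' @param reads A `sample_reads` object from [read_sample()], or a character
#'   vector of reads.
#' @param k K-mer length (default 16).
#' @param min_count Minimum within-sample occurrence count (default 2).
#' @param canonical Canonicalize k-mers with their reverse complements
#'   (default `FALSE`).
#' @param sample_id Sample identifier; taken from `reads` when it is a
#'   `sample_reads`.
#' @return A `kmer_set`: `sample_id`, `k`, and `kmers`, the ascending sorted
#'   distinct encoded k-mers passing the filter.
#' @examples
#' extract_kmerset(c("ACGTACGTA"), k = 4)$kmers |> decode_kmer(4)
#' @export
extract_kmerset <- function(reads, k = 16L, min_count = 2L, canonical = FALSE,
                            sample_id = NA_character_) {
  if (inherits(reads, "sample_reads")) {
    sample_id <- reads$sample_id
    reads <- reads$reads
  }
  stopifnot(k >= 1, min_count >= 1)
  kmers <- extract_kmers_cpp(as.character(reads), as.integer(k),
                             as.integer(min_count), isTRUE(canonical))
  structure(list(sample_id = sample_id, k = as.integer(k), kmers = kmers),
            class = "kmer_set")
}

#' Extract and persist k-mer sets for every sample of a manifest
#'
#' Runs [read_sample()] + [extract_kmerset()] per sample. When `out_dir` is
#' given, each set is written as `<sample_id>.kset` with a JSON sidecar
#' recording read, window and k-mer counts.
#'
#' @param manifest An `fqm_manifest`.
#' @inheritParams extract_kmerset
#' @param out_dir Optional output directory for `.kset` files.
#' @return Named list of `kmer_set`, one per sample.
#' @export
extract_all_kmersets <- function(manifest, k = 16L, min_count = 2L,
                                 canonical = FALSE, out_dir = NULL) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ksets <- lapply(seq_len(nrow(manifest)), function(i) {
    sr <- read_sample(manifest[i, ])
    ks <- extract_kmerset(sr, k = k, min_count = min_count, canonical = canonical)
    if (!is.null(out_dir)) {
      write_kmerset(ks, file.path(out_dir, paste0(ks$sample_id, ".kset")))
      n_bases <- sum(nchar(sr$reads))
      sidecar <- list(sample_id = ks$sample_id, k = k, min_count = min_count,
                      canonical = canonical,
                      n_reads = length(sr$reads),
                      n_windows = sum(pmax(nchar(sr$reads) - k + 1L, 0L)),
                      n_bases = n_bases,
                      n_kmers = length(ks$kmers))
      jsonlite::write_json(sidecar,
                           file.path(out_dir, paste0(ks$sample_id, ".kset.json")),
                           auto_unbox = TRUE)
    }
    ks
  })
  names(ksets) <- manifest$sample_id
  ksets
}
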