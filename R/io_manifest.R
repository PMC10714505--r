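#' Load a sample manifest
#'
#' Reads a tab- or comma-separated manifest with one row per sample. Required
#' columns: `sample_id`, `cohort` (`patient` or `control`, case-insensitive)
#' and `read_paths` (one or more FASTQ/FASTA paths separated by `;`). Any
#' additional column is treated as a binary exposure covariate with cells
#' `1/0/true/false/NA` (`NA` = unknown).
#'
#' Relative read paths are resolved against the manifest's directory.
#'
#' @param path Path to the manifest file. The separator is taken from the file
#'   extension (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is given.
#' @param sep Optional field separator override.
#' @param check_files If `TRUE` (default), a missing read file is an error at
#'   load time.
#' @return A data frame of class `fqm_manifest` with columns `sample_id`,
#'   `cohort` (factor with levels control, patient), `read_paths` (list of
#'   character vectors) and `exposures` (list of named logical vectors).
#' @export
load_manifest <- function(path, sep = NULL, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  required <- c("sample_id", "cohort", "read_paths")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in manifest: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))

  cohort <- tolower(trimws(df$cohort))
  bad <- setdiff(unique(cohort), c("patient", "control"))
  if (length(bad))
    stop("unknown cohort value(s): ", paste(bad, collapse = ", "),
         " (expected 'patient' or 'control')")

  base_dir <- dirname(normalizePath(path))
  read_paths <- lapply(strsplit(df$read_paths, ";", fixed = TRUE), function(p) {
    p <- trimws(p)
    p <- p[nzchar(p)]
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))
  })
  if (any(lengths(read_paths) == 0))
    stop("every sample must list at least one read path")
  if (check_files) {
    missing_files <- setdiff(unlist(read_paths),
                             unlist(read_paths)[file.exists(unlist(read_paths))])
    if (length(missing_files))
      stop("read file(s) not found: ", paste(missing_files, collapse = ", "))
  }

  exposure_cols <- setdiff(names(df), required)
  exposures <- lapply(seq_len(nrow(df)), function(i) {
    vals <- vapply(exposure_cols, function(cn) parse_exposure(df[[cn]][i], cn),
                   logical(1))
    names(vals) <- exposure_cols
    vals
  })

  out <- data.frame(sample_id = df$sample_id, stringsAsFactors = FALSE)
  out$cohort <- factor(cohort, levels = c("control", "patient"))
  out$read_paths <- read_paths
  out$exposures <- exposures
  class(out) <- c("fqm_manifest", "data.frame")
  out
}

parse_exposure <- function(x, col) {
  x <- tolower(trimws(x))
  if (is.na(x) || x %in% c("", "na", "nan")) return(NA)
  if (x %in% c("1", "true", "t", "yes")) return(TRUE)
  if (x %in% c("0", "false", "f", "no")) return(FALSE)
  stop("cannot parse exposure value '", x, "' in column '", col,
       "' (expected 1/0/true/false/NA)")
}

#' @export
print.fqm_manifest <- function(x, ...) {
  cat("Sample manifest:", nrow(x), "samples (",
      sum(x$cohort == "patient"), "patients,",
      sum(x$cohort == "control"), "controls)\n")
  expo <- unique(unlist(lapply(x$exposures, names)))
  if (length(expo)) cat("Exposure covariates:", paste(expo, collapse = ", "), "\n")
  invisible(x)
}

#' Read and merge a sample's sequencing reads
#'
#' Reads every file listed for a sample (FASTA or FASTQ, optionally
#' gzip-compressed; format auto-detected per file) and concatenates the reads
#' in listed-file order, preserving within-file order. All files are treated
#' as single-end: pairing information, if any, is ignored because k-mer
#' presence does not use it. Sequences are uppercased and any character other
#' than A/C/G/T/N is mapped to N; quality strings are discarded.
#'
#' @param manifest_row One row of an [load_manifest()] manifest (or any list
#'   with `sample_id` and `read_paths`).
#' @return A list of class `sample_reads` with `sample_id` and `reads`
#'   (character vector over A,C,G,T,N).
#' @export
read_sample <- function(manifest_row) {
  if (is.data.frame(manifest_row)) {
    stopifnot(nrow(manifest_row) == 1)
    sample_id <- manifest_row$sample_id[[1]]
    paths <- manifest_row$read_paths[[1]]
  } else {
    sample_id <- manifest_row$sample_id
    paths <- manifest_row$read_paths
  }
  reads <- unlist(lapply(paths, read_seq_file), use.names = FALSE)
  if (is.null(reads)) reads <- character(0)
  structure(list(sample_id = sample_id, reads = reads), class = "sample_reads")
}

# Detect FASTA vs FASTQ from the first non-empty character and parse with
# Biostrings; normalize to the A/C/G/T/N alphabet.
read_seq_file <- function(path) {
  if (!file.exists(path)) stop("read file not found: ", path)
  con <- gzfile(path, "rt")
  first <- tryCatch(readLines(con, n = 1L), finally = close(con))
  if (length(first) == 0)
    return(character(0))
  fmt <- if (startsWith(first, "@")) "fastq"
         else if (startsWith(first, ">")) "fasta"
         else stop("cannot detect FASTA/FASTQ format of ", path,
                   " (first character '", substr(first, 1, 1), "')")
  seqs <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt),
    error = function(e) stop("malformed ", toupper(fmt), " file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  reads <- toupper(as.character(seqs))
  names(reads) <- NULL
  empty <- which(!nzchar(reads))
  if (length(empty))
    stop("malformed ", toupper(fmt), " file ", path, ": empty sequence at record ",
         empty[1])
  gsub("[^ACGTN]", "N", reads)
}

#' Write / read a k-mer set in the sorted binary `.kset` format
#'
#' On-disk layout (little-endian): the 4-byte magic `KSET`, a 4-byte integer
#' codec version (1), a 4-byte integer k, an 8-byte double element count, then
#' the payload of encoded k-mers as 8-byte doubles in strictly ascending
#' order. Doubles are exact for encoded k-mers up to k = 26.
#'
#' @param kset A `kmer_set` (see [extract_kmerset()]).
#' @param path Output file path.
#' @return `write_kmerset` invisibly returns `path`; `read_kmerset` returns
#'   the `kmer_set`.
#' @export
write_kmerset <- function(kset, path) {
  stopifnot(inherits(kset, "kmer_set"))
  if (is.unsorted(kset$kmers, strictly = TRUE) && length(kset$kmers) > 1)
    stop("kmer_set must be strictly ascending before writing")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("KSET", con, nchars = 4, eos = NULL)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(as.integer(kset$k), con, size = 4, endian = "little")
  writeBin(as.double(length(kset$kmers)), con, size = 8, endian = "little")
  id <- if (is.null(kset$sample_id)) "" else kset$sample_id
  writeBin(charToRaw(id), con)
  writeBin(as.raw(0), con)
  writeBin(as.double(kset$kmers), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_kmerset
#' @export
read_kmerset <- function(path) {
  if (!file.exists(path)) stop(".kset file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "KSET")) stop(path, " is not a .kset file (bad magic)")
  version <- readBin(con, integer(), size = 4, endian = "little")
  if (!identical(version, 1L)) stop("unsupported .kset codec version ", version)
  k <- readBin(con, integer(), size = 4, endian = "little")
  n <- readBin(con, double(), size = 8, endian = "little")
  id_bytes <- raw(0)
  repeat {
    b <- readBin(con, raw(), n = 1)
    if (length(b) == 0) stop(path, ": truncated header")
    if (b == as.raw(0)) break
    id_bytes <- c(id_bytes, b)
  }
  sample_id <- rawToChar(id_bytes)
  kmers <- readBin(con, double(), n = n + 1, size = 8, endian = "little")
  if (length(kmers) != n)
    stop(path, ": payload has ", length(kmers), " k-mers but header declares ", n)
  structure(list(sample_id = if (nzchar(sample_id)) sample_id else NA_character_,
                 k = k, kmers = kmers),
            class = "kmer_set")
}
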