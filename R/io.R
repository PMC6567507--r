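#' Read a FASTA file
#'
#' Thin wrapper over Biostrings' FASTA reader with stricter up-front
#' validation (malformed headers and empty records are reported with
#' their line numbers). T/U are unified according to `alphabet`.
#'
#' @param path file path (plain or gzipped).
#' @param alphabet `"genomic"` (T) or `"rna"` (U).
#' @return named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path, alphabet = c("genomic", "rna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) stop("FASTA format error: empty file ", path,
                                  call. = FALSE)
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop("FASTA format error at line ", nonempty[1],
         ": expected '>' header", call. = FALSE)
  }
  hdr <- nonempty[startsWith(trimws(lines[nonempty]), ">")]
  ends <- c(hdr[-1] - 1L, length(lines))
  for (k in seq_along(hdr)) {
    body <- lines[setdiff(seq(hdr[k] + 1L, ends[k]), hdr)]
    if (hdr[k] >= ends[k] || !any(nzchar(trimws(body)))) {
      stop("FASTA format error at line ", hdr[k], ": record '",
           sub("^>", "", trimws(lines[hdr[k]])), "' has empty sequence",
           call. = FALSE)
    }
  }
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1)
  validate_alphabet(out, what = paste0("FASTA file ", path))
  if (alphabet == "rna") to_rna(out) else to_dna(out)
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output file path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  ss <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Gzip is handled transparently (R connections auto-detect compressed
#' input). Truncated records and sequence/quality length mismatches
#' raise a format error carrying the record index.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ format error in ", path, ": truncated record ",
         length(lines) %/% 4L + 1L, call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0) {
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0)))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0) {
    stop("FASTQ format error in ", path, " at record ", bad[1],
         ": malformed record markers", call. = FALSE)
  }
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad) > 0) {
    stop("FASTQ format error in ", path, " at record ", bad[1],
         ": quality length differs from sequence length", call. = FALSE)
  }
  data.frame(id = vapply(strsplit(sub("^@", "", hdr), "\\s+"), `[`, "", 1),
             sequence = toupper(seqs), quality = qual, row.names = NULL)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `id`, `sequence` and optionally `quality`
#'   (constant "I" is used when absent).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads)) reads$quality else
    strrep("I", nchar(reads$sequence))
  ss <- Biostrings::DNAStringSet(to_dna(reads$sequence))
  names(ss) <- reads$id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sheet is a TSV with columns `library_id`, `treatment`
#' (control/heat), `timepoint_days` (0, 1, 4), `replicate` and
#' `file_path`. Rows are returned in deterministic
#' (treatment, timepoint, replicate) order regardless of file order.
#'
#' @param path TSV path.
#' @return data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("sample sheet is empty: ", path, call. = FALSE)
  df <- validate_sample_sheet(df)
  # relative library paths are resolved against the sheet's directory
  rel <- !grepl("^(/|[A-Za-z]:)", df$file_path)
  df$file_path[rel] <- file.path(dirname(path), df$file_path[rel])
  df
}

validate_sample_sheet <- function(df) {
  req <- c("library_id", "treatment", "timepoint_days", "replicate", "file_path")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$library_id)) {
    stop("duplicate library_id: ",
         df$library_id[duplicated(df$library_id)][1], call. = FALSE)
  }
  bad <- setdiff(unique(df$treatment), c("control", "heat"))
  if (length(bad) > 0) stop("unknown treatment value: ", bad[1], call. = FALSE)
  df$treatment <- factor(df$treatment, levels = c("control", "heat"))
  df <- df[order(df$treatment, df$timepoint_days, df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a data frame as TSV
#'
#' All pipeline tables are written in this single, diff-friendly form:
#' tab-separated, no quoting, no row names.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Pipeline configuration
#'
#' `default_config()` returns the full default configuration as a nested
#' list; `read_config()` reads a YAML file and merges it over the
#' defaults (values in the file win; unknown keys are kept).
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    adapter = "TGGAATTCTCGGGTGCCAAGG",  # TruSeq small-RNA 3' adapter
    machine_length = 50L,
    srna = list(min_len = 18L, max_len = 24L, rpm_threshold = 10,
                min_overlap = 7L),
    simulate = list(
      n_precursors = 50L, n_decoys = 50L, depth = 200000L,
      dispersion = 0.1, background_fraction = 0.3,
      de_fraction = 0.2, de_log2fc = 2, spacer = 800L,
      n_transcripts = 20L, n_targets = 10L,
      pare_signal_mean = 50, pare_background_fraction = 0.5,
      star_read_fraction = 0.7, catalog_fraction = 0.6
    ),
    folding = list(engine = "builtin", threshold_per_nt = -0.2,
                   flanks = c(30L, 60L, 100L, 150L), minloop = 3L,
                   prefilter_duplex = TRUE),
    discovery = list(max_unpaired_in_duplex = 4L, cluster_gap = 50L,
                     catalog_max_mismatch = 2L, catalog_max_len_diff = 2L),
    de = list(fdr = 0.05, prior_n = 10, dispersion_grid = 25L),
    pare = list(min_len = 19L, max_len = 21L, score_threshold = 6,
                n_shuffles = 100L, p_threshold = 0.05, min_abundance = 4)
  )
}

#' @rdname default_config
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modifyList(cfg, user)
}

#' Run manifest: per-stage read-attrition counters
#'
#' @param manifest named list of counters (possibly nested).
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
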