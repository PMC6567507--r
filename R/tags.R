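#' Trim the 3' adapter from reads
#'
#' A read is trimmed at the leftmost occurrence of the longest matching
#' adapter prefix, requiring at least `min_overlap` adapter nucleotides
#' and exact matching. Reads with no adapter evidence are rejected (the
#' insert size is then unknown); rejection is an outcome, not an error.
#'
#' @param reads character vector of read sequences.
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum adapter prefix length that counts as
#'   evidence.
#' @return list with `insert` (character, trimmed inserts) and `rejected`
#'   (integer count of reads without adapter evidence).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 7L) {
  stopifnot(nchar(adapter) >= 1)
  adapter <- toupper(adapter)
  reads <- toupper(reads)
  kmax <- min(nchar(adapter), max(nchar(reads), 0L))
  cut <- rep(NA_integer_, length(reads))
  for (k in seq(from = kmax, to = min_overlap)) {
    if (k < min_overlap) break
    todo <- is.na(cut)
    if (!any(todo)) break
    hit <- regexpr(substr(adapter, 1L, k), reads[todo], fixed = TRUE)
    found <- hit > 0
    cut[which(todo)[found]] <- hit[found]
  }
  keep <- !is.na(cut)
  list(insert = substr(reads[keep], 1L, cut[keep] - 1L),
       rejected = sum(!keep))
}

#' Size-select sequences
#'
#' @param seqs character vector.
#' @param min_len,max_len inclusive length bounds.
#' @return the subset of `seqs` with lengths within bounds.
#' @export
size_select <- function(seqs, min_len, max_len) {
  stopifnot(min_len <= max_len)
  n <- nchar(seqs)
  seqs[n >= min_len & n <= max_len]
}

#' Collapse reads to distinct tags with per-library counts
#'
#' @param read_lists named list (one element per library) of character
#'   vectors of trimmed, size-selected read sequences.
#' @return data.frame of class `tag_table`: `sequence`, `length`, one
#'   integer count column per library, ordered by descending total count
#'   with lexicographic tie-break.
#' @export
collapse_tags <- function(read_lists) {
  stopifnot(is.list(read_lists), !is.null(names(read_lists)))
  libs <- names(read_lists)
  tabs <- lapply(read_lists, function(r) table(factor(r)))
  seqs <- sort(unique(unlist(lapply(tabs, names), use.names = FALSE)))
  if (length(seqs) == 0) {
    df <- data.frame(sequence = character(0), length = integer(0))
    for (l in libs) df[[l]] <- integer(0)
    class(df) <- c("tag_table", "data.frame")
    return(df)
  }
  counts <- vapply(tabs, function(tb) {
    out <- integer(length(seqs))
    out[match(names(tb), seqs)] <- as.integer(tb)
    out
  }, integer(length(seqs)))
  counts <- matrix(counts, nrow = length(seqs),
                   dimnames = list(NULL, libs))
  df <- data.frame(sequence = seqs, length = nchar(seqs),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(counts, check.names = FALSE))
  total <- rowSums(counts)
  df <- df[order(-total, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("tag_table", "data.frame")
  df
}

tag_count_matrix <- function(tags) {
  libs <- setdiff(names(tags), c("sequence", "length"))
  m <- as.matrix(tags[, libs, drop = FALSE])
  rownames(m) <- tags$sequence
  storage.mode(m) <- "double"
  m
}

#' Reads-per-million normalisation of a tag table
#'
#' @param tags a `tag_table` from [collapse_tags()].
#' @param library_totals optional named totals; defaults to the column
#'   sums of the tag table (retained reads per library).
#' @return matrix of RPM values, tags x libraries.
#' @export
compute_rpm <- function(tags, library_totals = NULL) {
  m <- tag_count_matrix(tags)
  if (is.null(library_totals)) library_totals <- colSums(m)
  if (any(library_totals == 0)) {
    stop("library with zero retained reads: ",
         names(library_totals)[library_totals == 0][1], call. = FALSE)
  }
  sweep(m, 2, library_totals, "/") * 1e6
}

#' Filter tags on maximum reads-per-million
#'
#' A tag is kept when it reaches `threshold` RPM in at least one library.
#'
#' @param tags a `tag_table`.
#' @param threshold RPM threshold (default 10).
#' @param library_totals see [compute_rpm()].
#' @return the filtered `tag_table`, with an `rpm` attribute holding the
#'   RPM matrix of the retained tags.
#' @export
rpm_filter <- function(tags, threshold = 10, library_totals = NULL) {
  rpm <- compute_rpm(tags, library_totals)
  keep <- apply(rpm, 1, max) >= threshold
  out <- tags[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rpm") <- rpm[keep, , drop = FALSE]
  out
}
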