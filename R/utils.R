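#' @useDynLib hairpin2pare, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Convert sequences between DNA and RNA alphabets
#'
#' @param x character vector of sequences.
#' @return `to_rna()` replaces T with U; `to_dna()` replaces U with T.
#'   Case is normalised to upper.
#' @export
to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname to_rna
#' @export
to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement
#'
#' @param x character vector (DNA or RNA; T/U handled either way).
#' @param alphabet output alphabet, `"dna"` or `"rna"`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(to_dna(x))))
  names(out) <- names(x)
  if (alphabet == "rna") to_rna(out) else out
}

validate_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTUN]", toupper(x))
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,U,N} (first offender: %s)",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

#' Render a genomic interval in 1-based inclusive notation
#'
#' Intervals are held 0-based half-open internally; reports use the
#' conventional 1-based inclusive style, e.g. `Chr5A:663320619-663320737`.
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @return character vector of formatted loci.
#' @export
format_locus <- function(chrom, start, end, strand = "+") {
  sprintf("%s:%d-%d(%s)", chrom, start + 1L, end, strand)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
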