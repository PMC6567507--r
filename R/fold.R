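#' Fold an RNA sequence under the simplified pair-energy model
#'
#' Predicts the minimum-energy nested secondary structure by dynamic
#' programming. The energy model is additive over base pairs: GC -3.0,
#' AU -2.0, GU -1.0 kcal/mol, with hairpin loops of at least `minloop`
#' unpaired nucleotides and no pseudoknots. The traceback is
#' deterministic: position i is paired, to its smallest admissible
#' partner, whenever pairing attains the optimum.
#'
#' @param sequence a single RNA (or DNA; T is read as U) string,
#'   10-500 nt, alphabet A/C/G/U/N. N never pairs.
#' @param minloop minimum number of unpaired bases in a hairpin loop.
#' @return an object of class `fold_result`: list with `sequence`
#'   (RNA-normalised), `dotbracket`, `pair_table` (1-based partner index,
#'   `NA` if unpaired), `energy_kcal` (<= 0) and `energy_per_nt`.
#' @examples
#' fold("GGGAAAACCC")
#' @export
fold <- function(sequence, minloop = 3L) {
  stopifnot(length(sequence) == 1L)
  seq <- to_rna(sequence)
  validate_alphabet(seq)
  n <- nchar(seq)
  if (n < 10L || n > 500L) {
    stop("fold() accepts sequences of length 10-500 nt, got ", n, call. = FALSE)
  }
  res <- .fold_dp(seq, as.integer(minloop))
  structure(list(
    sequence = seq,
    dotbracket = res$dotbracket,
    pair_table = res$pair_table,
    energy_kcal = res$energy,
    energy_per_nt = res$energy / n
  ), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "\n", sep = "")
  cat(sprintf("energy %.2f kcal/mol (%.3f kcal/mol/nt)\n",
              x$energy_kcal, x$energy_per_nt))
  invisible(x)
}

#' Terminal (hairpin) loops of a structure
#'
#' A terminal loop is the innermost pair of a stem: a pair (i, j) with no
#' paired base strictly inside.
#'
#' @param pair_table 1-based partner indices, `NA` for unpaired.
#' @return integer matrix with columns `i`, `j`, one row per terminal loop.
#' @export
terminal_loops <- function(pair_table) {
  paired <- which(!is.na(pair_table) & pair_table > seq_along(pair_table))
  keep <- vapply(paired, function(i) {
    j <- pair_table[i]
    inner <- if (j - i > 1) (i + 1):(j - 1) else integer(0)
    all(is.na(pair_table[inner]))
  }, logical(1))
  cbind(i = paired[keep], j = pair_table[paired[keep]])
}

# terminal loops lying strictly within the region [i, j]
loops_within <- function(loops, i, j) {
  if (nrow(loops) == 0) return(loops)
  loops[loops[, "i"] > i & loops[, "j"] < j, , drop = FALSE]
}

#' Hairpin test for a folded candidate precursor
#'
#' A fold qualifies as a miRNA-style hairpin when its energy density is
#' below `threshold_per_nt` (default -0.2 kcal/mol/nt) and it presents a
#' single terminal loop on the relevant path. With no mature span the
#' whole structure must contain exactly one terminal loop. With a
#' mature span, the span must sit on the stem of one hairpin: at least
#' `length - max_unpaired` of its bases must be paired such that each
#' pair encloses exactly one and the same terminal loop (this is the
#' duplex-grade evidence miRNA-annotation guidelines require; stray
#' pairs of a few edge bases into flanking structure are tolerated,
#' branched/multi-loop enclosures are not).
#'
#' @param fold_result a [fold()] result.
#' @param threshold_per_nt retention threshold on energy per nucleotide.
#' @param mature_span optional integer `c(start, end)`, 1-based inclusive
#'   positions of the candidate mature sequence on the folded sequence.
#' @param max_unpaired maximum mature bases allowed to be unpaired or
#'   inconsistently paired.
#' @return list with `pass` (logical) and diagnostics: `energy_per_nt`,
#'   `n_terminal_loops` (distinct loops seen from the span, or total
#'   loops without a span), `loop` (the dominant terminal loop, `c(i, j)`
#'   closing pair, or NULL), `consistent` (bases supporting it),
#'   `reason`.
#' @export
is_hairpin <- function(fold_result, threshold_per_nt = -0.2,
                       mature_span = NULL, max_unpaired = 4L) {
  pt <- fold_result$pair_table
  loops <- terminal_loops(pt)
  energy_ok <- fold_result$energy_per_nt < threshold_per_nt
  if (is.null(mature_span)) {
    nl <- nrow(loops)
    pass <- energy_ok && nl == 1L
    return(list(pass = pass, energy_per_nt = fold_result$energy_per_nt,
                n_terminal_loops = nl,
                loop = if (nl == 1L) loops[1, ] else NULL,
                consistent = NA_integer_,
                reason = if (!energy_ok) "energy per nt above threshold"
                else if (nl != 1L) sprintf("%d terminal loops", nl)
                else "ok"))
  }
  idx <- mature_span[1]:mature_span[2]
  mpaired <- idx[!is.na(pt[idx])]
  loop_key <- character(0)
  for (p in mpaired) {
    q <- pt[p]
    enc <- loops_within(loops, min(p, q) - 1L, max(p, q) + 1L)
    if (nrow(enc) == 1L) {
      loop_key <- c(loop_key, paste(enc[1, 1], enc[1, 2]))
    } else {
      loop_key <- c(loop_key, NA_character_)  # branched enclosure
    }
  }
  tab <- table(loop_key[!is.na(loop_key)])
  need <- length(idx) - max_unpaired
  if (length(tab) == 0) {
    return(list(pass = FALSE, energy_per_nt = fold_result$energy_per_nt,
                n_terminal_loops = 0L, loop = NULL, consistent = 0L,
                reason = "mature span not on a hairpin stem"))
  }
  best <- which.max(tab)
  consistent <- as.integer(tab[best])
  loop <- as.integer(strsplit(names(tab)[best], " ")[[1]])
  names(loop) <- c("i", "j")
  pass <- energy_ok && consistent >= need
  reason <- if (!energy_ok) "energy per nt above threshold"
  else if (consistent < need) {
    sprintf("only %d/%d mature bases pair consistently on one stem-loop",
            consistent, length(idx))
  } else "ok"
  list(pass = pass, energy_per_nt = fold_result$energy_per_nt,
       n_terminal_loops = length(tab), loop = loop,
       consistent = consistent, reason = reason)
}

#' Fold with an external thermodynamic folder (RNAfold)
#'
#' Adapter around an installed ViennaRNA `RNAfold` binary (full Turner
#' nearest-neighbour model). The sequence is passed on stdin; the
#' dot-bracket line and free energy are parsed into the same
#' `fold_result` structure as [fold()], so the two engines are
#' interchangeable downstream.
#'
#' @param sequence a single RNA string.
#' @param binary name/path of the external folder.
#' @return a `fold_result`.
#' @export
fold_external <- function(sequence, binary = "RNAfold") {
  seq <- to_rna(sequence)
  validate_alphabet(seq)
  if (Sys.which(binary) == "") {
    stop("external folding engine '", binary, "' not found; ",
         "set folding.engine to 'builtin' to use the internal model",
         call. = FALSE)
  }
  out <- suppressWarnings(system2(binary, args = c("--noPS"), input = seq,
                                  stdout = TRUE, stderr = FALSE))
  if (length(out) < 2) stop("unparseable output from ", binary, call. = FALSE)
  m <- regmatches(out[2], regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", out[2]))[[1]]
  if (length(m) != 3) stop("unparseable output from ", binary, ": ", out[2],
                           call. = FALSE)
  db <- m[2]
  if (nchar(db) != nchar(seq)) stop("unparseable output from ", binary,
                                    call. = FALSE)
  energy <- as.numeric(m[3])
  structure(list(
    sequence = seq,
    dotbracket = db,
    pair_table = dotbracket_to_pairs(db),
    energy_kcal = energy,
    energy_per_nt = energy / nchar(seq)
  ), class = "fold_result")
}

#' Convert dot-bracket notation to a pair table
#'
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @return integer vector of 1-based partner indices, `NA` if unpaired.
#' @export
dotbracket_to_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  pt <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket string", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket string", call. = FALSE)
  pt
}
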