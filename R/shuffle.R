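#' Dinucleotide-preserving sequence shuffle
#'
#' Uniformly samples a permutation of the sequence that preserves its
#' exact dinucleotide (and hence mononucleotide) composition, by drawing
#' a random Eulerian path through the dinucleotide transition multigraph
#' (Altschul-Erikson). Used both to place decoy pseudo-precursors in the
#' synthetic genome and as the null model for target-prediction
#' p-values.
#'
#' @param sequence a single sequence string (>= 3 distinct
#'   dinucleotides required for a meaningful shuffle).
#' @return a shuffled sequence with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  if (n < 4 || length(unique(paste0(ch[-n], ch[-1]))) < 3) {
    stop("sequence too short / too uniform to dinucleotide-shuffle",
         call. = FALSE)
  }
  first <- ch[1]
  last <- ch[n]
  succ <- split(ch[-1], factor(ch[-n], levels = unique(ch)))
  succ <- succ[vapply(succ, length, 0L) > 0]
  verts <- names(succ)
  inner <- setdiff(verts, last)
  repeat {
    # pick a tentative final out-edge for every non-terminal vertex and
    # keep the draw only if these edges form paths leading to `last`
    final <- vapply(inner, function(v) sample(succ[[v]], 1), "")
    ok <- TRUE
    for (v in inner) {
      cur <- v
      seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || !(cur %in% inner)) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- final[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  lists <- lapply(verts, function(v) {
    edges <- succ[[v]]
    if (v %in% inner) {
      k <- match(final[[v]], edges)
      rest <- edges[-k]
      c(rest[sample.int(length(rest))], final[[v]])
    } else {
      edges[sample.int(length(edges))]
    }
  })
  names(lists) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- first
  cur <- first
  for (i in 2:n) {
    nxt <- lists[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}
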