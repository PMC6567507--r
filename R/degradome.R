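# Degradome (PARE) validation of miRNA-guided cleavage: 5'-end profiles
# over coding sequences, plant target-site scoring, cleavage-site
# localisation at the position paired to miRNA position 10, peak
# categorisation, shuffle-based significance and t-plot tables.

#' Build per-transcript degradome 5'-end profiles
#'
#' Tags are matched exactly, full length, on the sense strand of every
#' transcript; each placement increments the abundance at the tag's
#' 5'-end position by the tag count. Multi-mapping tags count at every
#' placement.
#'
#' @param pare_tags data.frame with `sequence` and `count` (collapsed
#'   degradome tags, 19-21 nt).
#' @param transcripts named character vector of coding sequences (DNA).
#' @return named list of `degradome_profile` objects: `transcript_id`,
#'   `length`, `abundance` (integer vector, 0-based positions reported
#'   1-based in R indexing), `total`.
#' @export
build_profiles <- function(pare_tags, transcripts) {
  tx <- to_dna(transcripts)
  profiles <- lapply(names(tx), function(id) {
    structure(list(transcript_id = id, length = nchar(tx[[id]]),
                   abundance = integer(nchar(tx[[id]])), total = 0L),
              class = "degradome_profile")
  })
  names(profiles) <- names(tx)
  seqs <- to_dna(pare_tags$sequence)
  for (L in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == L)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
    for (id in names(tx)) {
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(tx[[id]]))
      starts <- Biostrings::startIndex(m)
      nh <- lengths(starts)
      if (sum(nh) == 0) next
      s1 <- unlist(starts[nh > 0], use.names = FALSE)
      cnt <- rep(pare_tags$count[idx][nh > 0], nh[nh > 0])
      acc <- tapply(cnt, s1, sum)
      pos <- as.integer(names(acc))
      profiles[[id]]$abundance[pos] <-
        profiles[[id]]$abundance[pos] + as.integer(acc)
    }
  }
  for (id in names(profiles)) {
    profiles[[id]]$total <- sum(profiles[[id]]$abundance)
  }
  profiles
}

#' Score a miRNA against one transcript window (plant targeting rules)
#'
#' Ungapped antiparallel alignment: per position, match scores 0, G:U
#' wobble 0.5, mismatch 1.0; penalties at miRNA positions 2-13 (1-based
#' from the 5' end) are doubled. Lower is better; sites at or below the
#' configured threshold are candidate targets.
#'
#' @param mirna mature miRNA sequence (RNA, 5'->3').
#' @param window transcript window of the same length (DNA or RNA,
#'   5'->3').
#' @return list with `score` and `alignment` (three-line paired-string
#'   representation).
#' @export
score_target <- function(mirna, window) {
  m <- to_rna(mirna)
  w <- to_rna(window)
  if (nchar(m) != nchar(w)) {
    stop("ungapped scoring needs window length equal to miRNA length",
         call. = FALSE)
  }
  hit <- .scan_target_sites(m, w, Inf)
  mch <- strsplit(m, "")[[1]]
  wch <- strsplit(w, "")[[1]]
  L <- length(mch)
  sym <- vapply(seq_len(L), function(i) {
    a <- mch[i]
    b <- wch[L - i + 1]
    if (paste0(a, b) %in% c("AU", "UA", "GC", "CG")) "|"
    else if (paste0(a, b) %in% c("GU", "UG")) "o"
    else " "
  }, "")
  alignment <- paste0("5' ", m, " 3' (miRNA)\n   ",
                      paste(sym, collapse = ""), "\n3' ",
                      paste(rev(wch), collapse = ""), " 5' (target)")
  list(score = hit$score[1], alignment = alignment)
}

#' Find candidate target sites of a miRNA across transcripts
#'
#' @param mirna mature miRNA sequence (RNA).
#' @param transcripts named character vector of coding sequences.
#' @param threshold maximum penalty score retained.
#' @return data.frame `transcript`, `site_start` (0-based), `score`,
#'   `cleavage_pos` (0-based).
#' @export
find_target_sites <- function(mirna, transcripts, threshold = 6) {
  m <- to_rna(mirna)
  L <- nchar(m)
  out <- lapply(names(transcripts), function(id) {
    h <- .scan_target_sites(m, to_rna(transcripts[[id]]), threshold)
    if (nrow(h) == 0) return(NULL)
    data.frame(transcript = id, site_start = h$start - 1L, score = h$score,
               cleavage_pos = h$start - 1L + L - 10L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(transcript = character(0), site_start = integer(0),
                      score = numeric(0), cleavage_pos = integer(0))
  }
  out
}

#' Locate the cleavage position implied by an alignment
#'
#' The slicing site of a miRNA-guided cleavage lies opposite miRNA
#' position 10: with miRNA position 1 paired to transcript position t
#' (antisense), the 3' cleavage fragment's 5' end is t - 9.
#'
#' @param pos1_partner 0-based transcript position paired to miRNA
#'   position 1 (= site_start + L - 1 for an ungapped site).
#' @param mirna_length alignment length (must be >= 10).
#' @return 0-based cleavage position.
#' @export
locate_cleavage <- function(pos1_partner, mirna_length) {
  if (mirna_length < 10) {
    stop("alignment shorter than 10 nt has no position-10 cleavage site",
         call. = FALSE)
  }
  pos1_partner - 9L
}

#' Categorise a cleavage-site peak against its transcript profile
#'
#' Standard degradome category ladder. With a the abundance at the
#' cleavage position: no hit when a = 0; category 4 when a = 1;
#' category 0 when a is the unique maximum of the profile; 1 when a
#' equals a non-unique maximum; 2 when a exceeds the median of the
#' nonzero positions; 3 otherwise.
#'
#' @param profile a `degradome_profile`.
#' @param cleavage_pos 0-based transcript position.
#' @return integer category 0-4, or NA when a = 0.
#' @export
categorize <- function(profile, cleavage_pos) {
  stopifnot(profile$total > 0)
  a <- profile$abundance[cleavage_pos + 1L]
  if (is.na(a) || a == 0) return(NA_integer_)
  if (a == 1) return(4L)
  mx <- max(profile$abundance)
  if (a == mx) {
    if (sum(profile$abundance == mx) == 1) return(0L) else return(1L)
  }
  nz <- profile$abundance[profile$abundance > 0]
  if (a > stats::median(nz)) return(2L)
  3L
}

#' Shuffle-based p-value for an observed target hit
#'
#' The miRNA is dinucleotide-shuffled `n_shuffles` times; each shuffle
#' is run through the identical site search over the whole
#' transcriptome, and a shuffle succeeds when it attains at least one
#' site with score <= the observed score whose cleavage-site category
#' is <= the observed category. p = (1 + successes) / (n_shuffles + 1).
#'
#' @param mirna mature miRNA sequence.
#' @param transcripts named character vector of coding sequences.
#' @param profiles list from [build_profiles()].
#' @param observed_score,observed_category the observed hit's score and
#'   category.
#' @param n_shuffles number of shuffles (>= 19).
#' @param threshold score threshold used by the search.
#' @return p-value in (0, 1\].
#' @export
target_pvalue <- function(mirna, transcripts, profiles, observed_score,
                          observed_category, n_shuffles = 100L,
                          threshold = 6) {
  stopifnot(n_shuffles >= 19)
  succ <- 0L
  for (b in seq_len(n_shuffles)) {
    shuf <- dinucleotide_shuffle(to_rna(mirna))
    sites <- find_target_sites(shuf, transcripts,
                               min(threshold, observed_score))
    if (nrow(sites) == 0) next
    sites <- sites[sites$score <= observed_score, , drop = FALSE]
    ok <- FALSE
    for (r in seq_len(nrow(sites))) {
      pr <- profiles[[sites$transcript[r]]]
      if (pr$total == 0) next
      cat_r <- categorize(pr, sites$cleavage_pos[r])
      if (!is.na(cat_r) && cat_r <= observed_category) {
        ok <- TRUE
        break
      }
    }
    if (ok) succ <- succ + 1L
  }
  (1 + succ) / (n_shuffles + 1)
}

#' Run the full degradome validation for a set of miRNAs
#'
#' For every miRNA: candidate sites with penalty score <= the
#' threshold are located, the degradome abundance at each implied
#' cleavage position is read off the profile, the peak is categorised,
#' and a shuffle p-value computed (once per miRNA, against its best
#' hit's score/category, then attached to all that miRNA's hits).
#'
#' @param mirnas named character vector: miRNA name -> sequence.
#' @param transcripts named character vector of coding sequences.
#' @param profiles list from [build_profiles()].
#' @param config configuration list.
#' @return data.frame of target hits (unfiltered), one row per
#'   (miRNA, site).
#' @export
predict_targets <- function(mirnas, transcripts, profiles,
                            config = default_config()) {
  pc <- config$pare
  rows <- list()
  for (nm in names(mirnas)) {
    sites <- find_target_sites(mirnas[[nm]], transcripts,
                               pc$score_threshold)
    if (nrow(sites) == 0) next
    sites$pare_abundance <- vapply(seq_len(nrow(sites)), function(r) {
      pr <- profiles[[sites$transcript[r]]]
      p <- sites$cleavage_pos[r]
      if (p < 0 || p >= pr$length) 0L else pr$abundance[p + 1L]
    }, 0L)
    sites$category <- vapply(seq_len(nrow(sites)), function(r) {
      pr <- profiles[[sites$transcript[r]]]
      if (pr$total == 0 || sites$pare_abundance[r] == 0) NA_integer_
      else categorize(pr, sites$cleavage_pos[r])
    }, NA_integer_)
    with_peak <- which(!is.na(sites$category))
    if (length(with_peak) == 0) next
    best <- with_peak[order(sites$score[with_peak],
                            sites$category[with_peak])][1]
    p <- target_pvalue(mirnas[[nm]], transcripts, profiles,
                       sites$score[best], sites$category[best],
                       n_shuffles = pc$n_shuffles,
                       threshold = pc$score_threshold)
    sites <- sites[with_peak, , drop = FALSE]
    sites$mirna <- nm
    sites$p_value <- p
    rows[[length(rows) + 1]] <- sites
  }
  if (length(rows) == 0) {
    return(data.frame(mirna = character(0), transcript = character(0),
                      site_start = integer(0), score = numeric(0),
                      cleavage_pos = integer(0), pare_abundance = integer(0),
                      category = integer(0), p_value = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[, c("mirna", "transcript", "site_start", "score", "cleavage_pos",
          "pare_abundance", "category", "p_value")]
}

#' Filter target hits and emit t-plot tables
#'
#' Hits are retained when p < `p_threshold` (strict) and the raw
#' degradome abundance at the cleavage site exceeds `min_abundance`
#' (strict). For every retained hit a t-plot table (position,
#' abundance, cleavage-site flag) is produced; positions are reported
#' 1-based.
#'
#' @param hits data.frame from [predict_targets()].
#' @param profiles list from [build_profiles()].
#' @param p_threshold,min_abundance retention thresholds.
#' @return list with `retained` (filtered hit table, cleavage positions
#'   reported 1-based in `cleavage_pos_1based`) and `tplots` (named list
#'   of per-hit data.frames).
#' @export
filter_and_report <- function(hits, profiles, p_threshold = 0.05,
                              min_abundance = 4) {
  keep <- !is.na(hits$p_value) & hits$p_value < p_threshold &
    hits$pare_abundance > min_abundance
  retained <- hits[keep, , drop = FALSE]
  retained$cleavage_pos_1based <- retained$cleavage_pos + 1L
  rownames(retained) <- NULL
  tplots <- list()
  for (r in seq_len(nrow(retained))) {
    pr <- profiles[[retained$transcript[r]]]
    nz <- which(pr$abundance > 0)
    tplots[[paste(retained$mirna[r], retained$transcript[r], sep = "@")]] <-
      data.frame(transcript = pr$transcript_id, position = nz,
                 abundance = pr$abundance[nz],
                 is_cleavage_site = nz == retained$cleavage_pos[r] + 1L,
                 stringsAsFactors = FALSE)
  }
  list(retained = retained, tplots = tplots)
}
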