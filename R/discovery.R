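# miRNA ascertainment: exact mapping of tags to the genome, hairpin
# window extraction, star prediction from duplex geometry, isomiR
# grouping, family assignment against a known-miRNA catalog, and naming.

#' Map tags to a genome by exact full-length matching
#'
#' All 0-mismatch, full-length placements on both strands are reported.
#' Tags containing N never match.
#'
#' @param tags character vector of tag sequences (DNA or RNA).
#' @param genome named character vector of chromosome sequences.
#' @return data.frame with columns `tag`, `chrom`, `start` (0-based),
#'   `end` (half-open), `strand`.
#' @export
map_tags_exact <- function(tags, genome) {
  tags_dna <- to_dna(tags)
  valid <- !grepl("N", tags_dna, fixed = TRUE)
  gen <- Biostrings::DNAStringSet(to_dna(genome))
  hits <- list()
  for (L in sort(unique(nchar(tags_dna[valid])))) {
    idx <- which(valid & nchar(tags_dna) == L)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(tags_dna[idx]))
    for (ci in seq_along(gen)) {
      n <- length(gen[[ci]])
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") gen[[ci]] else
          Biostrings::reverseComplement(gen[[ci]])
        m <- Biostrings::matchPDict(pd, subj)
        starts <- Biostrings::startIndex(m)
        nh <- lengths(starts)
        if (sum(nh) == 0) next
        s1 <- unlist(starts[nh > 0], use.names = FALSE)
        tagv <- rep(tags[idx][nh > 0], nh[nh > 0])
        start0 <- if (strand == "+") s1 - 1L else n - (s1 + L - 1L)
        hits[[length(hits) + 1]] <- data.frame(
          tag = tagv, chrom = names(genome)[ci], start = start0,
          end = start0 + L, strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(tag = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$chrom, out$start, out$strand, out$tag), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Fold the candidate windows around one seed placement and return the
# best (lowest energy-per-nt) window passing the hairpin test, or NULL.
seed_candidate <- function(seed, windows, chrom_seq, rc_seq, strand,
                           config) {
  fc <- config$folding
  dc <- config$discovery
  n <- nchar(chrom_seq)
  best <- NULL
  for (w in windows) {
    wseq_dna <- if (strand == "+") {
      substr(chrom_seq, w[1] + 1L, w[2])
    } else {
      substr(rc_seq, n - w[2] + 1L, n - w[1])
    }
    wseq <- to_rna(wseq_dna)
    mspan <- if (strand == "+") {
      c(seed$start - w[1] + 1L, seed$end - w[1])
    } else {
      c(w[2] - seed$end + 1L, w[2] - seed$start)
    }
    if (isTRUE(fc$prefilter_duplex)) {
      bd <- .best_duplex_match(to_rna(seed$tag), wseq,
                               mspan[1] - 1L, mspan[2] - 1L)
      if (bd[1] < nchar(seed$tag) - dc$max_unpaired_in_duplex) next
    }
    fr <- if (identical(fc$engine, "external")) {
      fold_external(wseq)
    } else {
      fold(wseq, minloop = fc$minloop)
    }
    hp <- is_hairpin(fr, fc$threshold_per_nt, mature_span = mspan,
                     max_unpaired = dc$max_unpaired_in_duplex)
    if (!hp$pass) next
    if (is.null(best) || fr$energy_per_nt < best$fold$energy_per_nt) {
      best <- structure(list(
        locus = list(chrom = seed$chrom, start = w[1], end = w[2],
                     strand = strand),
        sequence = wseq, fold = fr, tags = NULL,
        anchor = seed$tag, anchor_span = mspan,
        clipped = w[1] == 0L || w[2] == n), class = "precursor_candidate")
    }
  }
  best
}

#' Extract and fold candidate precursor windows around tag placements
#'
#' Placements are visited in order of decreasing tag abundance; each
#' placement not already covered by a retained candidate seeds a set of
#' windows (one per flank size), each window is folded, and the lowest
#' energy-per-nucleotide window that passes [is_hairpin()] (judged on
#' the stem carrying the seed tag) is retained as a precursor
#' candidate. Every placement falling inside a retained window becomes
#' a supporting tag of that candidate. With `loci` supplied (annotation
#' mode), those intervals are used verbatim instead of derived windows.
#' A cheap antisense-complementarity prescan (on by default) skips
#' folding windows in which the seed tag has no near-complementary
#' partner, since no duplex-supported miRNA could be ascertained there.
#'
#' @param placements mapping table from [map_tags_exact()].
#' @param genome named chromosome sequences.
#' @param tag_abundance named numeric: total count per tag sequence
#'   (sets the seeding order).
#' @param config configuration list.
#' @param loci optional data.frame `chrom`, `start`, `end`, `strand`
#'   (0-based half-open) of known precursor loci.
#' @return list of `precursor_candidate` objects: `locus`, `sequence`
#'   (RNA, 5'->3' on its strand), `fold`, `tags` (data.frame of
#'   supporting tags with 1-based spans on the candidate), `anchor`.
#' @export
extract_precursor_windows <- function(placements, genome, tag_abundance,
                                      config = default_config(),
                                      loci = NULL) {
  fc <- config$folding
  dc <- config$discovery
  if (nrow(placements) == 0) return(list())
  ord <- order(-tag_abundance[placements$tag], placements$chrom,
               placements$start)
  placements <- placements[ord, , drop = FALSE]
  p_tag <- placements$tag
  p_chrom <- placements$chrom
  p_start <- placements$start
  p_end <- placements$end
  p_strand <- placements$strand
  p_key <- paste0(p_chrom, p_strand)
  rc_genome <- vapply(genome, revcomp, "")
  candidates <- list()
  cw_key <- character(0)
  cw_start <- integer(0)
  cw_end <- integer(0)
  max_flank <- max(fc$flanks)
  for (i in seq_along(p_tag)) {
    if (any(cw_key == p_key[i] & cw_start <= p_start[i] &
            cw_end >= p_end[i])) next
    chrom_seq <- genome[[p_chrom[i]]]
    n <- nchar(chrom_seq)
    seed <- list(tag = p_tag[i], chrom = p_chrom[i], start = p_start[i],
                 end = p_end[i])
    if (is.null(loci)) {
      # one cheap duplex prescan on the widest window decides whether
      # folding is worth attempting at all
      if (isTRUE(fc$prefilter_duplex)) {
        w0 <- c(max(0L, p_start[i] - max_flank), min(n, p_end[i] + max_flank))
        wseq0 <- if (p_strand[i] == "+") {
          substr(chrom_seq, w0[1] + 1L, w0[2])
        } else {
          substr(rc_genome[[p_chrom[i]]], n - w0[2] + 1L, n - w0[1])
        }
        ms0 <- if (p_strand[i] == "+") {
          c(p_start[i] - w0[1] + 1L, p_end[i] - w0[1])
        } else {
          c(w0[2] - p_end[i] + 1L, w0[2] - p_start[i])
        }
        bd <- .best_duplex_match(to_rna(p_tag[i]), to_rna(wseq0),
                                 ms0[1] - 1L, ms0[2] - 1L)
        if (bd[1] < nchar(p_tag[i]) - dc$max_unpaired_in_duplex) next
      }
      windows <- unique(lapply(fc$flanks, function(f) {
        c(max(0L, p_start[i] - f), min(n, p_end[i] + f))
      }))
    } else {
      sel <- loci$chrom == p_chrom[i] & loci$strand == p_strand[i] &
        loci$start <= p_start[i] & loci$end >= p_end[i]
      if (!any(sel)) next
      windows <- lapply(which(sel), function(k) c(loci$start[k], loci$end[k]))
    }
    best <- seed_candidate(seed, windows, chrom_seq,
                           rc_genome[[p_chrom[i]]], p_strand[i], config)
    if (!is.null(best)) {
      candidates[[length(candidates) + 1]] <- best
      cw_key <- c(cw_key, p_key[i])
      cw_start <- c(cw_start, best$locus$start)
      cw_end <- c(cw_end, best$locus$end)
    }
  }
  # assign every placement inside a retained window as a supporting tag
  for (k in seq_along(candidates)) {
    loc <- candidates[[k]]$locus
    sel <- placements$chrom == loc$chrom & placements$strand == loc$strand &
      placements$start >= loc$start & placements$end <= loc$end
    pl <- placements[sel, , drop = FALSE]
    spans <- if (loc$strand == "+") {
      data.frame(tag = pl$tag, start = pl$start - loc$start + 1L,
                 end = pl$end - loc$start, stringsAsFactors = FALSE)
    } else {
      data.frame(tag = pl$tag, start = loc$end - pl$end + 1L,
                 end = loc$end - pl$start, stringsAsFactors = FALSE)
    }
    spans <- spans[!duplicated(spans), , drop = FALSE]
    candidates[[k]]$tags <- spans
  }
  candidates
}

#' Predict the miRNA* span from duplex geometry
#'
#' With p() the pairing partner, the star of a mature spanning
#' \[m5, m3\] starts at p(m3 - 2) and ends at p(m5) + 2, which yields
#' 2-nt 3' overhangs on both duplex ends. If the anchor positions are
#' unpaired, the nearest paired base up to 3 nt inward is used and the
#' scanned offset carried into the projection (helix extrapolation), so
#' the projected duplex still has exactly 2-nt 3' overhangs.
#' `overhang_ok` is FALSE when the projection leaves the precursor
#' (clamped), in which case the overhang geometry cannot hold.
#'
#' @param fold_result a [fold()] result for the precursor.
#' @param mature_span 1-based inclusive `c(start, end)` of the mature.
#' @param loop optional `c(i, j)` closing pair of the stem's terminal
#'   loop (e.g. from [is_hairpin()]); anchor pairs that do not enclose
#'   this loop (stray pairs into flanking structure) are then skipped
#'   by the inward scan.
#' @return list: `star_span`, `star_sequence`, `overhang_ok`, `clamped`
#'   (projection fell outside the precursor), `d5`, `d3` (inward scan
#'   offsets used at the two anchors), or `NULL` when no projection
#'   exists (mature unpaired or straddling the loop).
#' @export
predict_star <- function(fold_result, mature_span, loop = NULL) {
  pt <- fold_result$pair_table
  n <- length(pt)
  m5 <- mature_span[1]
  m3 <- mature_span[2]
  usable <- function(pos) {
    if (is.na(pt[pos])) return(FALSE)
    q <- pt[pos]
    if (q >= m5 && q <= m3) return(FALSE)  # pairs within the mature span
    if (is.null(loop)) return(TRUE)
    min(pos, q) <= loop[1] && max(pos, q) >= loop[2]
  }
  d3 <- NA_integer_
  for (d in 0:3) if (m3 - 2 - d >= m5 && usable(m3 - 2 - d)) {
    d3 <- d; break
  }
  d5 <- NA_integer_
  for (d in 0:3) if (m5 + d <= m3 && usable(m5 + d)) { d5 <- d; break }
  if (is.na(d3) || is.na(d5)) return(NULL)
  star5 <- pt[m3 - 2 - d3] - d3
  star3 <- pt[m5 + d5] + 2 + d5
  if (star3 < star5) return(NULL)  # mature straddles the terminal loop
  clamped <- star5 < 1 || star3 > n
  span <- c(max(1L, star5), min(n, star3))
  list(star_span = span,
       star_sequence = substr(fold_result$sequence, span[1], span[2]),
       overhang_ok = !clamped,
       clamped = clamped, d5 = d5, d3 = d3)
}

#' Ascertain mature miRNAs and isomiR groups from retained candidates
#'
#' A tag is ascertained as a mature miRNA when it (a) maps fully within
#' a retained hairpin candidate, (b) does not straddle the terminal
#' loop, and (c) shows duplex-grade pairing: at least
#' `length - max_unpaired_in_duplex` of its bases paired, all enclosing
#' a single terminal loop (the mature:star duplex evidence that
#' miRNA-annotation guidelines require). Star evidence is graded, not
#' filtered on: TRUE when the predicted star sequence is itself observed
#' among the tags, or when the duplex geometry is exact and the star is
#' in the catalog.
#'
#' @param candidates list from [extract_precursor_windows()].
#' @param tags filtered `tag_table` (from [rpm_filter()], with `rpm`
#'   attribute).
#' @param catalog named character vector of known mature/star sequences
#'   (miRBase-style names carrying `miRnnn` family tokens).
#' @param config configuration list.
#' @return list with `mirnas` (data.frame, one row per ascertained
#'   mature miRNA) and `isomir_groups` (data.frame of within-precursor
#'   end-shift relations).
#' @export
ascertain_mirnas <- function(candidates, tags, catalog = character(0),
                             config = default_config()) {
  dc <- config$discovery
  rpm <- attr(tags, "rpm")
  totals <- rowSums(tag_count_matrix(tags))
  tag_rna <- to_rna(tags$sequence)
  catalog_rna <- to_rna(catalog)
  rows <- list()
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    pt <- cand$fold$pair_table
    prec_id <- format_locus(cand$locus$chrom, cand$locus$start,
                            cand$locus$end, cand$locus$strand)
    for (t in seq_len(nrow(cand$tags))) {
      span <- c(cand$tags$start[t], cand$tags$end[t])
      tag_seq <- cand$tags$tag[t]
      len <- span[2] - span[1] + 1L
      hp <- is_hairpin(cand$fold, config$folding$threshold_per_nt,
                       mature_span = span,
                       max_unpaired = dc$max_unpaired_in_duplex)
      if (!hp$pass) next
      loop <- hp$loop
      if (span[1] < loop["i"] && span[2] > loop["j"]) next  # straddles loop
      arm <- if ((span[1] + span[2]) / 2 < (loop["i"] + loop["j"]) / 2)
        "5p" else "3p"
      star <- predict_star(cand$fold, span, loop = loop)
      # the tag and its projected star must form a near-ungapped duplex
      # (plant miRNA:miRNA* duplexes tolerate only a few mismatches)
      if (is.null(star) ||
          duplex_complementarity(to_rna(tag_seq), star$star_sequence) <
            len - 2L - dc$max_unpaired_in_duplex) next
      star_seq <- star$star_sequence
      star_evidence <- to_dna(star$star_sequence) %in% to_dna(tags$sequence) ||
        (star$overhang_ok && star$star_sequence %in% catalog_rna)
      ti <- match(tag_seq, tags$sequence)
      rows[[length(rows) + 1]] <- data.frame(
        sequence = to_rna(tag_seq), length = len, precursor_id = prec_id,
        chrom = cand$locus$chrom, locus_start = cand$locus$start,
        locus_end = cand$locus$end,
        arm = arm, start = span[1], end = span[2],
        star_sequence = star_seq, star_evidence = star_evidence,
        overhang_ok = !is.null(star) && star$overhang_ok,
        total_count = unname(totals[ti]),
        mean_rpm = mean(rpm[ti, ]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(list(mirnas = data.frame(), isomir_groups = data.frame()))
  }
  mir <- do.call(rbind, rows)
  # one row per distinct mature sequence; primary locus = first in
  # genomic order, multi_locus_count = number of candidate loci
  mir <- mir[order(mir$chrom, mir$locus_start), , drop = FALSE]
  nloci <- tapply(mir$precursor_id, mir$sequence,
                  function(x) length(unique(x)))
  mir <- mir[!duplicated(mir$sequence), , drop = FALSE]
  mir$multi_locus_count <- as.integer(nloci[mir$sequence])
  mir$family <- assign_family(mir$sequence, catalog,
                              max_mismatch = dc$catalog_max_mismatch,
                              max_len_diff = dc$catalog_max_len_diff)
  rownames(mir) <- NULL
  groups <- isomir_groups(mir)
  list(mirnas = mir, isomir_groups = groups)
}

# antiparallel complementarity (WC + G:U) between a mature and its star
# in the duplex register implied by 2-nt 3' overhangs:
# mature[i] faces star[k - i + 1] for i in 1..k, k = length - 2
duplex_complementarity <- function(mature, star) {
  k <- min(nchar(mature) - 2L, nchar(star) - 2L)
  if (k < 1) return(0L)
  m <- strsplit(mature, "")[[1]]
  s <- strsplit(star, "")[[1]]
  sum(paste0(m[1:k], s[k:1]) %in%
        c("AU", "UA", "GC", "CG", "GU", "UG"))
}

isomir_groups <- function(mir) {
  out <- list()
  for (p in unique(mir$precursor_id)) {
    sub <- mir[mir$precursor_id == p, , drop = FALSE]
    for (a in unique(sub$arm)) {
      arm_sub <- sub[sub$arm == a, , drop = FALSE]
      if (nrow(arm_sub) < 2) next
      ref <- arm_sub[which.max(arm_sub$total_count), ]
      out[[length(out) + 1]] <- data.frame(
        precursor_id = p, arm = a, sequence = arm_sub$sequence,
        ref_sequence = ref$sequence,
        shift5 = arm_sub$start - ref$start,
        shift3 = arm_sub$end - ref$end, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}

#' Assign miRNA family names by catalog matching
#'
#' Best ungapped alignment of each query against every catalog entry
#' within `max_len_diff` nt of its length, sliding the shorter sequence
#' within the longer; matches with more than `max_mismatch` mismatches
#' are discarded. The family is the `miRnnn` token of the best catalog
#' name (fewest mismatches; ties broken towards the lexicographically
#' smallest family). Queries without an admissible match are `"novel"`.
#'
#' @param sequences character vector of mature sequences.
#' @param catalog named character vector of catalog sequences.
#' @param max_mismatch,max_len_diff matching thresholds.
#' @return character vector of family names.
#' @export
assign_family <- function(sequences, catalog, max_mismatch = 2L,
                          max_len_diff = 2L) {
  if (length(catalog) == 0) return(rep("novel", length(sequences)))
  fam_of <- regmatches(names(catalog), regexpr("miR[0-9]+", names(catalog)))
  cat_rna <- to_rna(catalog)
  vapply(to_rna(sequences), function(q) {
    best_mm <- Inf
    best_fam <- "novel"
    for (ci in seq_along(cat_rna)) {
      s <- cat_rna[ci]
      if (abs(nchar(q) - nchar(s)) > max_len_diff) next
      shorter <- if (nchar(q) <= nchar(s)) q else s
      longer <- if (nchar(q) <= nchar(s)) s else q
      ls <- nchar(shorter)
      a <- strsplit(shorter, "")[[1]]
      for (off in 0:(nchar(longer) - ls)) {
        mm <- sum(a != strsplit(substr(longer, off + 1, off + ls), "")[[1]])
        if (mm > max_mismatch) next
        if (mm < best_mm ||
            (mm == best_mm && fam_of[ci] < best_fam)) {
          best_mm <- mm
          best_fam <- fam_of[ci]
        }
      }
    }
    best_fam
  }, "", USE.NAMES = FALSE)
}

#' Name ascertained miRNAs
#'
#' Within each family, precursors are numbered in genomic order;
#' variants within a precursor are numbered by descending total
#' abundance (the variant index is omitted for single-variant
#' precursors); the arm suffix is appended:
#' `family-precursor.variant-arm`.
#'
#' @param mirnas the `mirnas` data.frame from [ascertain_mirnas()].
#' @return the same data.frame with a `name` column, sorted by name.
#' @export
name_mirnas <- function(mirnas) {
  if (nrow(mirnas) == 0) return(mirnas)
  mirnas <- mirnas[order(mirnas$chrom, mirnas$locus_start,
                         -mirnas$total_count, mirnas$sequence), ,
                   drop = FALSE]
  mirnas$name <- NA_character_
  for (fam in unique(mirnas$family)) {
    fi <- mirnas$family == fam
    precs <- unique(mirnas$precursor_id[fi])  # already in genomic order
    for (pi in seq_along(precs)) {
      rows <- which(fi & mirnas$precursor_id == precs[pi])
      rows <- rows[order(-mirnas$total_count[rows], mirnas$sequence[rows])]
      for (vi in seq_along(rows)) {
        stem <- if (length(rows) == 1) sprintf("%s-%d", fam, pi) else
          sprintf("%s-%d.%d", fam, pi, vi)
        mirnas$name[rows[vi]] <- paste0(stem, "-", mirnas$arm[rows[vi]])
      }
    }
  }
  mirnas <- mirnas[order(mirnas$name), , drop = FALSE]
  rownames(mirnas) <- NULL
  mirnas
}
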