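# Synthetic sRNA-seq + degradome data with planted ground truth.
#
# The generator emulates the study design the pipeline targets: 24
# libraries (2 treatments x 3 timepoints x 4 replicates), 18-24 nt small
# RNA reads dominated by the 21- and 24-nt size classes, hairpin
# precursors carrying miRNA/miRNA* duplexes with 2-nt 3' overhangs and
# 1-3 nt isomiR end shifts, heat-responsive fold changes that attenuate
# during recovery, and degradome 5'-end peaks at the positions paired to
# miRNA position 10.

RNA_BASES <- c("A", "C", "G", "U")

random_seq <- function(n, bases = RNA_BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

comp_base <- function(b) c(A = "U", C = "G", G = "C", U = "A")[[b]]

#' Construct a planted miRNA hairpin precursor
#'
#' The precursor is a fully base-paired stem-loop: the mature sequence
#' plus a loop-proximal extension form one arm, the other arm is its
#' exact reverse complement, so every arm base is paired (as in a
#' near-perfect plant pre-miRNA stem). The star is the standard duplex
#' partner: it starts at the base paired to mature position
#' (length - 2) and ends two nucleotides past the base paired to the
#' mature 5' end, giving 2-nt 3' overhangs on both duplex ends. Up to
#' `stem_mismatches` interior stem positions are mutated. The precursor
#' is exactly the stem-loop (2 basal guard pairs, duplex, loop-proximal
#' extension, all-C loop), which makes the designed stem the unique
#' minimum-energy structure under the simplified pair-energy model.
#' Genomic sequence context around the stem-loop is supplied by the
#' genome assembler, not by this constructor.
#'
#' @param mature_length mature length, 19-24 nt.
#' @param stem_mismatches number of imperfections planted in the stem.
#' @param loop_length terminal loop length (>= 4).
#' @param arm `"5p"`, `"3p"`, or `"random"`.
#' @param ext_length loop-proximal stem extension beyond the mature.
#' @param id precursor identifier.
#' @return list of class `planted_precursor`: `id`, `sequence` (RNA),
#'   `mature_span`, `star_span` (1-based inclusive), `arm`, `mature`,
#'   `star`, `isomir_offsets` (filled by the dataset assembler).
#' @export
build_precursor <- function(mature_length = 21L, stem_mismatches = 1L,
                            loop_length = 8L, arm = "random",
                            ext_length = 8L, id = "prec") {
  if (mature_length < 19L || mature_length > 24L) {
    stop("mature_length must be in [19, 24]", call. = FALSE)
  }
  if (loop_length < 4L) {
    stop("loop_length < 4 cannot fold into a hairpin", call. = FALSE)
  }
  if (identical(arm, "random")) arm <- sample(c("5p", "3p"), 1)
  L <- as.integer(mature_length)
  e <- as.integer(ext_length)
  mature <- random_seq(L)
  guard <- random_seq(2L)  # 2 basal stem pairs outside the duplex
  arm_len <- L + e + 2L
  # the loop-proximal extension is an A:U homopolymer helix: any
  # alternative arrangement of identical letters is forced back to the
  # designed antiparallel matching by the nesting constraint
  if (arm == "5p") {
    left <- paste0(guard, mature, strrep("A", e))
    right <- revcomp(left, "rna")
    mature_span <- c(3L, L + 2L)
  } else {
    right <- paste0(strrep("U", e), mature, guard)
    left <- revcomp(right, "rna")
    mature_span <- c(arm_len + loop_length + e + 1L,
                     arm_len + loop_length + e + L)
  }
  n <- 2L * arm_len + loop_length
  # duplex geometry: star5 = p(m3 - 2), star3 = p(m5) + 2 under the
  # designed full pairing p(x) = n + 1 - x
  star_span <- c(n + 1L - (mature_span[2] - 2L),
                 n + 1L - mature_span[1] + 2L)
  # plant imperfections in the stem interior of the star-bearing arm,
  # >= 3 nt clear of the star ends and arm boundaries
  if (stem_mismatches > 0 && L > 12L) {
    arm_ch <- strsplit(if (arm == "5p") right else left, "")[[1]]
    rel0 <- star_span[1] - (if (arm == "5p") arm_len + loop_length else 0L)
    pos <- sample(4:(L - 7L), min(stem_mismatches, 3L))
    for (p in pos) {
      q <- rel0 + p - 1L
      arm_ch[q] <- sample(setdiff(RNA_BASES, arm_ch[q]), 1)
    }
    if (arm == "5p") right <- paste(arm_ch, collapse = "") else
      left <- paste(arm_ch, collapse = "")
  }
  # all-C loop: C pairs only G, and every stem G is locked into the
  # designed helix before the loop is reached, so the loop is inert
  loop <- strrep("C", loop_length)
  sequence <- paste0(left, loop, right)
  star <- substr(sequence, star_span[1], star_span[2])
  structure(list(id = id, sequence = sequence, mature_span = mature_span,
                 star_span = star_span, arm = arm, mature = mature,
                 star = star, isomir_offsets = list()),
            class = "planted_precursor")
}

PLANT_FAMILIES <- c("miR156", "miR159", "miR160", "miR164", "miR166",
                    "miR167", "miR169", "miR171", "miR172", "miR319",
                    "miR393", "miR395", "miR396", "miR399", "miR408",
                    "miR528", "miR1118", "miR1120", "miR1121", "miR1122",
                    "miR1135", "miR9662", "miR9772")

# Dirichlet draw via normalised gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

draw_isomir_offsets <- function(n, mature_len) {
  out <- list()
  tries <- 0
  while (length(out) < n && tries < 50) {
    tries <- tries + 1
    d5 <- sample(-2:2, 1)
    d3 <- sample(-2:2, 1)
    if (d5 == 0 && d3 == 0) next
    len <- mature_len - d5 + d3
    if (len < 18 || len > 24) next
    if (any(vapply(out, function(o) all(o == c(d5, d3)), logical(1)))) next
    out[[length(out) + 1]] <- c(d5, d3)
  }
  out
}

#' Assemble the full synthetic study (genome, truth, design)
#'
#' Plants `n_precursors` hairpin precursors (each with isomiRs and a
#' star) and `n_decoys` dinucleotide-shuffled pseudo-precursors into a
#' multi-chromosome genome, assigns families and catalog membership,
#' draws per-design-cell expression truth (a `de_fraction` subset gets a
#' heat-vs-control log2 fold change of +/- `de_log2fc` at 0 DAT,
#' attenuating by half at 1 DAT and to a quarter at 4 DAT), and builds a
#' transcriptome with planted cleavage targets plus shuffled decoy sites.
#'
#' @param config configuration list, see [default_config()].
#' @return list of class `synthetic_truth` with elements `genome` (named
#'   DNA strings), `precursors`, `decoy_placements`, `design` (sample
#'   sheet), `catalog` (named RNA strings), `expression` (per-variant
#'   truth data.frame), `transcripts`, `targets`, `decoy_targets`.
#' @export
simulate_dataset <- function(config = default_config()) {
  sim <- config$simulate
  n_prec <- sim$n_precursors
  precursors <- lapply(seq_len(n_prec), function(i) {
    p <- build_precursor(mature_length = sample(20:22, 1),
                         stem_mismatches = sample(0:1, 1),
                         loop_length = sample(6:12, 1),
                         id = sprintf("prec%03d", i))
    p$isomir_offsets <- draw_isomir_offsets(sample(0:3, 1),
                                            nchar(p$mature))
    p
  })
  families <- sample(PLANT_FAMILIES, n_prec, replace = TRUE)
  in_catalog <- stats::runif(n_prec) < sim$catalog_fraction

  # genome: precursors and shuffled decoys embedded in random spacers
  chroms <- c("Chr1A", "Chr2B", "Chr3D")
  pieces <- list()
  placements <- list()
  decoy_placements <- list()
  slots <- data.frame(
    kind = c(rep("prec", n_prec), rep("decoy", sim$n_decoys)),
    idx = c(seq_len(n_prec), seq_len(sim$n_decoys)))
  slots <- slots[sample(nrow(slots)), , drop = FALSE]
  slots$chrom <- sort(rep_len(chroms, nrow(slots)))
  for (ch in chroms) {
    cursor <- 0L
    frags <- character(0)
    rows <- which(slots$chrom == ch)
    for (r in rows) {
      spacer <- random_seq(sim$spacer, c("A", "C", "G", "T"))
      frags <- c(frags, spacer)
      cursor <- cursor + nchar(spacer)
      if (slots$kind[r] == "prec") {
        p <- precursors[[slots$idx[r]]]
        seq_dna <- to_dna(p$sequence)
      } else {
        src <- precursors[[sample(n_prec, 1)]]
        seq_dna <- to_dna(dinucleotide_shuffle(src$sequence))
      }
      strand <- sample(c("+", "-"), 1)
      emitted <- if (strand == "+") seq_dna else revcomp(seq_dna)
      frags <- c(frags, emitted)
      place <- list(chrom = ch, start = cursor,
                    end = cursor + nchar(emitted), strand = strand)
      cursor <- cursor + nchar(emitted)
      if (slots$kind[r] == "prec") {
        placements[[slots$idx[r]]] <- place
      } else {
        decoy_placements[[length(decoy_placements) + 1]] <- place
      }
    }
    frags <- c(frags, random_seq(sim$spacer, c("A", "C", "G", "T")))
    pieces[[ch]] <- paste(frags, collapse = "")
  }
  genome <- unlist(pieces)
  for (i in seq_len(n_prec)) {
    precursors[[i]]$genome_placement <- placements[[i]]
    precursors[[i]]$family <- if (in_catalog[i]) families[i] else "novel"
    precursors[[i]]$in_catalog <- in_catalog[i]
  }

  # catalog of previously annotated miRNAs (miRBase-style headers)
  catalog <- character(0)
  letters_used <- integer(0)
  for (i in which(in_catalog)) {
    fam <- families[i]
    letters_used[fam] <- (if (is.na(letters_used[fam])) 0L else
                          letters_used[fam]) + 1L
    nm <- sprintf("tae-%s%s-%s", fam, letters[letters_used[fam]],
                  precursors[[i]]$arm)
    catalog[nm] <- precursors[[i]]$mature
    if (stats::runif(1) < 0.5) {
      catalog[paste0(nm, "*")] <- precursors[[i]]$star
    }
  }

  design <- expand.grid(replicate = 1:4, timepoint_days = c(0L, 1L, 4L),
                        treatment = c("control", "heat"),
                        stringsAsFactors = FALSE)
  design$library_id <- sprintf("%s_%dDAT_r%d", substr(design$treatment, 1, 4),
                               design$timepoint_days, design$replicate)
  design$file_path <- paste0(design$library_id, ".fastq")
  design <- validate_sample_sheet(design)

  expression <- build_expression_truth(precursors, sim)

  tx <- simulate_transcriptome(precursors, expression, sim)

  structure(list(genome = genome, precursors = precursors,
                 decoy_placements = decoy_placements, design = design,
                 catalog = catalog, expression = expression,
                 transcripts = tx$transcripts, targets = tx$targets,
                 decoy_targets = tx$decoy_targets, config = config),
            class = "synthetic_truth")
}

# Per-variant expression truth. RPM values are expressed against the
# expected retained-read total (planted + in-range background), so that
# the RPM a low-dispersion library measures converges to truth.
build_expression_truth <- function(precursors, sim) {
  rows <- list()
  for (p in precursors) {
    n_var <- 1L + length(p$isomir_offsets)
    props <- rdirichlet1(c(8, rep(1, n_var - 1L)))
    is_de <- stats::runif(1) < sim$de_fraction
    lfc0 <- if (is_de) sample(c(-1, 1), 1) * sim$de_log2fc else 0
    star_frac <- if (stats::runif(1) < sim$star_read_fraction)
      stats::runif(1, 0.02, 0.15) else 0
    base <- 10^stats::runif(1, 1.2, 3.8)
    variants <- data.frame(
      variant = c("mature", if (n_var > 1)
        paste0("isomir", seq_len(n_var - 1L))),
      d5 = c(0L, vapply(p$isomir_offsets, `[`, integer(1), 1L)),
      d3 = c(0L, vapply(p$isomir_offsets, `[`, integer(1), 2L)),
      proportion = props, stringsAsFactors = FALSE)
    variants$sequence <- substr(rep(p$sequence, n_var),
                                p$mature_span[1] + variants$d5,
                                p$mature_span[2] + variants$d3)
    variants$role <- c("mature", rep("isomir", n_var - 1L))
    if (star_frac > 0) {
      variants <- rbind(variants, data.frame(
        variant = "star", d5 = 0L, d3 = 0L, proportion = star_frac,
        sequence = p$star, role = "star"))
    }
    variants$precursor_id <- p$id
    variants$star_sequenced <- star_frac > 0
    variants$is_de <- is_de
    variants$lfc0 <- lfc0
    variants$lfc1 <- lfc0 * 0.5
    variants$lfc4 <- lfc0 * 0.25
    variants$base_level <- base * variants$proportion
    rows[[length(rows) + 1]] <- variants
  }
  tr <- do.call(rbind, rows)
  tr$variant_id <- paste(tr$precursor_id, tr$variant, sep = ":")
  # scale so planted reads make up (1 - background_fraction) of each library
  target_planted <- 1e6 * (1 - sim$background_fraction)
  scale <- target_planted / sum(tr$base_level)
  tr$base_level <- tr$base_level * scale
  # expected retained total per million sequenced reads: all planted reads
  # plus the 18-24 nt share of the background
  p_in_range <- sum(bg_length_weights()[as.character(18:24)])
  retained_per_m <- target_planted +
    1e6 * sim$background_fraction * p_in_range
  for (cell in c("control_0", "control_1", "control_4",
                 "heat_0", "heat_1", "heat_4")) {
    tp <- sub(".*_", "", cell)
    fc <- if (startsWith(cell, "heat"))
      2^tr[[paste0("lfc", tp)]] else 1
    tr[[paste0("mean_", cell)]] <- tr$base_level * fc
    tr[[paste0("rpm_", cell)]] <- tr$base_level * fc * 1e6 / retained_per_m
  }
  rownames(tr) <- NULL
  tr
}

# background length profile: 18-30 nt, 24-nt mode with a secondary 21-nt
# class, mirroring the size distribution of plant sRNA libraries
bg_length_weights <- function() {
  w <- c(2, 2, 3, 8, 4, 3, 12, 3, 2, 1.5, 1, 1, 1)
  names(w) <- as.character(18:30)
  w / sum(w)
}

#' Simulate the sRNA-seq libraries of the full design
#'
#' Per-library counts for every planted variant are drawn
#' negative-binomially (variance mu + phi mu^2) around the cell mean in
#' the truth table; background reads are random genomic fragments of
#' 18-30 nt (24-nt mode). Reads carry the 3' adapter and are truncated
#' to the machine read length.
#'
#' @param truth a `synthetic_truth` from [simulate_dataset()].
#' @param out_dir directory for the per-library FASTQ files; `NULL`
#'   returns reads in memory.
#' @return named list (by library) of character vectors of reads, or
#'   (with `out_dir`) the design data.frame with `file_path` filled in.
#' @export
simulate_srna_libraries <- function(truth, out_dir = NULL) {
  cfg <- truth$config
  sim <- cfg$simulate
  depth <- sim$depth
  if (depth <= 0) stop("sequencing depth must be positive", call. = FALSE)
  tr <- truth$expression
  adapter <- cfg$adapter
  mlen <- cfg$machine_length
  out <- list()
  for (i in seq_len(nrow(truth$design))) {
    lib <- truth$design$library_id[i]
    cell <- paste(truth$design$treatment[i], truth$design$timepoint_days[i],
                  sep = "_")
    mu <- tr[[paste0("mean_", cell)]] * depth / 1e6
    counts <- if (sim$dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / sim$dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
    planted <- rep(to_dna(tr$sequence), counts)
    n_bg <- round(depth * sim$background_fraction)
    bg <- sample_genomic_fragments(truth$genome, n_bg)
    reads <- substr(paste0(c(planted, bg), adapter), 1L, mlen)
    reads <- reads[sample(length(reads))]
    if (is.null(out_dir)) {
      out[[lib]] <- reads
    } else {
      write_fastq(data.frame(id = sprintf("%s_%d", lib, seq_along(reads)),
                             sequence = reads),
                  file.path(out_dir, paste0(lib, ".fastq")))
      # paths are recorded relative to the sheet so outputs are portable
      truth$design$file_path[i] <- paste0(lib, ".fastq")
    }
  }
  if (is.null(out_dir)) out else truth$design
}

sample_genomic_fragments <- function(genome, n) {
  if (n <= 0) return(character(0))
  lens <- as.integer(sample(names(bg_length_weights()), n, replace = TRUE,
                            prob = bg_length_weights()))
  chrom <- sample(names(genome), n, replace = TRUE,
                  prob = nchar(genome))
  starts <- floor(stats::runif(n) *
                    (nchar(genome)[match(chrom, names(genome))] - lens)) + 1L
  frag <- substr(genome[match(chrom, names(genome))], starts,
                 starts + lens - 1L)
  minus <- stats::runif(n) < 0.5
  frag[minus] <- revcomp(frag[minus])
  unname(frag)
}

# Transcriptome with planted miRNA cleavage sites and shuffled decoy sites
simulate_transcriptome <- function(precursors, expression, sim) {
  n_tx <- sim$n_transcripts
  lens <- sample(600:1500, n_tx, replace = TRUE)
  tx <- vapply(lens, random_seq, "", bases = c("A", "C", "G", "T"))
  names(tx) <- sprintf("tx%03d", seq_len(n_tx))
  mats <- expression[expression$role == "mature", , drop = FALSE]
  pick <- sample(nrow(mats), min(sim$n_targets, nrow(mats)))
  targets <- data.frame()
  used <- integer(0)
  for (k in pick) {
    j <- sample(setdiff(seq_len(n_tx), used), 1)
    used <- c(used, j)
    mir <- mats$sequence[k]
    L <- nchar(mir)
    site <- revcomp(to_dna(mir))
    s0 <- sample(100:(lens[j] - 100 - L), 1)  # 0-based site start
    substr(tx[j], s0 + 1L, s0 + L) <- site
    targets <- rbind(targets, data.frame(
      mirna_variant = mats$variant_id[k], mirna_sequence = mir,
      transcript = names(tx)[j], site_start = s0,
      cleavage_pos = s0 + L - 10L, stringsAsFactors = FALSE))
  }
  # decoy sites: shuffled site sequences in otherwise untargeted transcripts
  decoys <- data.frame()
  free <- setdiff(seq_len(n_tx), used)
  for (j in utils::head(free, min(5, length(free)))) {
    k <- sample(pick, 1)
    site <- to_dna(dinucleotide_shuffle(revcomp(to_dna(
      mats$sequence[k]), "rna")))
    L <- nchar(site)
    s0 <- sample(100:(lens[j] - 100 - L), 1)
    substr(tx[j], s0 + 1L, s0 + L) <- site
    decoys <- rbind(decoys, data.frame(
      mirna_variant = mats$variant_id[k], transcript = names(tx)[j],
      site_start = s0, stringsAsFactors = FALSE))
  }
  list(transcripts = tx, targets = targets, decoy_targets = decoys)
}

#' Simulate a degradome (PARE) library
#'
#' Signal reads are 20-nt fragments whose 5' end sits exactly at each
#' planted cleavage position, with negative-binomial counts; background
#' 5' ends are uniform over the transcriptome with geometrically decaying
#' per-position abundance.
#'
#' @param truth a `synthetic_truth`.
#' @return character vector of degradome reads (DNA).
#' @export
simulate_pare_library <- function(truth) {
  sim <- truth$config$simulate
  tx <- truth$transcripts
  tg <- truth$targets
  if (nrow(tg) > 0 &&
      any(tg$cleavage_pos >= nchar(tx[tg$transcript]) |
          tg$cleavage_pos < 0)) {
    stop("planted cleavage position outside transcript", call. = FALSE)
  }
  sig_counts <- stats::rnbinom(nrow(tg), mu = sim$pare_signal_mean,
                               size = 1 / max(sim$dispersion, 1e-8))
  signal <- rep(substr(tx[tg$transcript], tg$cleavage_pos + 1L,
                       tg$cleavage_pos + 20L), sig_counts)
  bf <- sim$pare_background_fraction
  n_bg <- round(sum(sig_counts) * bf / max(1 - bf, 1e-9))
  bg <- character(0)
  if (n_bg > 0) {
    npos <- max(1L, round(n_bg / 2))
    chrom <- sample(names(tx), npos, replace = TRUE, prob = nchar(tx))
    lens <- sample(19:21, npos, replace = TRUE)
    starts <- floor(stats::runif(npos) *
                      (nchar(tx)[match(chrom, names(tx))] - lens)) + 1L
    cnt <- 1L + stats::rgeom(npos, 0.5)
    bg <- rep(substr(tx[match(chrom, names(tx))], starts,
                     starts + lens - 1L), cnt)
  }
  unname(c(signal, bg))
}

#' Write the truth tables of a synthetic dataset
#'
#' @param truth a `synthetic_truth`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_truth <- function(truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(truth$genome, file.path(out_dir, "genome.fa"))
  write_fasta(to_dna(truth$transcripts), file.path(out_dir, "transcripts.fa"))
  write_fasta(truth$catalog, file.path(out_dir, "catalog.fa"))
  prec <- do.call(rbind, lapply(truth$precursors, function(p) {
    data.frame(id = p$id, sequence = p$sequence, arm = p$arm,
               mature = p$mature, star = p$star,
               mature_start = p$mature_span[1], mature_end = p$mature_span[2],
               star_start = p$star_span[1], star_end = p$star_span[2],
               family = p$family,
               locus = format_locus(p$genome_placement$chrom,
                                    p$genome_placement$start,
                                    p$genome_placement$end,
                                    p$genome_placement$strand),
               stringsAsFactors = FALSE)
  }))
  write_tsv(prec, file.path(out_dir, "truth_precursors.tsv"))
  keep <- setdiff(names(truth$expression), "base_level")
  write_tsv(truth$expression[, keep], file.path(out_dir, "truth_expression.tsv"))
  write_tsv(truth$targets, file.path(out_dir, "truth_targets.tsv"))
  # precursor loci as BED6 (0-based half-open, for annotation mode)
  bed <- do.call(rbind, lapply(truth$precursors, function(p) {
    g <- p$genome_placement
    data.frame(chrom = g$chrom, start = g$start, end = g$end, name = p$id,
               score = 0L, strand = g$strand, stringsAsFactors = FALSE)
  }))
  utils::write.table(bed, file.path(out_dir, "truth_precursors.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(out_dir)
}
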