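test_that("exact mapping finds planted substrings with correct coordinates", {
  genome <- c(chr1 = "AAAACGTCAGGCTTAACTTACGGATAAA",
              chr2 = "TTTTTTTTTTGCATGCATGCAT")
  hit <- map_tags_exact("CGTCAGGC", genome)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 4L)      # 0-based
  expect_equal(hit$end, 12L)
  expect_equal(hit$strand, "+")

  # reverse-strand placement: revcomp of a plus-strand substring
  rc <- revcomp("CGTCAGGC")
  hit2 <- map_tags_exact(rc, genome)
  expect_equal(nrow(hit2), 1L)
  expect_true(hit2$strand == "-" && hit2$start == 4 && hit2$end == 12)

  # N never matches
  expect_equal(nrow(map_tags_exact("CGNCAGGC", genome)), 0L)

  # multi-placement tags report every location
  hit3 <- map_tags_exact("GCATGCAT", genome)
  expect_gte(sum(hit3$strand == "+"), 2L)
})

test_that("star prediction follows the 2-nt overhang pair-table arithmetic", {
  # perfect 24-nt hairpin: pairs (i, 25 - i) for i = 1..10 (1-based)
  db <- paste0(strrep("(", 10), "....", strrep(")", 10))
  fr <- structure(list(sequence = strrep("A", 24), dotbracket = db,
                       pair_table = dotbracket_to_pairs(db),
                       energy_kcal = -20, energy_per_nt = -20 / 24),
                  class = "fold_result")
  # mature at 1-based positions 3..12 -> star at 15..24
  st <- predict_star(fr, c(3, 12))
  expect_equal(st$star_span, c(15, 24))
  expect_true(st$overhang_ok)
  expect_equal(st$d5, 0L)
  expect_equal(st$d3, 0L)

  # mature at positions 1..10: star 3' projection exceeds the precursor
  st2 <- predict_star(fr, c(1, 10))
  expect_true(st2$clamped)
  expect_false(st2$overhang_ok)

  # mature straddling the loop has no star
  expect_null(predict_star(fr, c(8, 17)))
})

test_that("predicted stars equal planted stars on constructed precursors", {
  set.seed(41)
  for (i in 1:30) {
    p <- build_precursor(mature_length = sample(19:24, 1),
                         stem_mismatches = sample(0:1, 1),
                         loop_length = sample(4:12, 1))
    fr <- fold(p$sequence)
    st <- predict_star(fr, p$mature_span)
    expect_equal(unname(st$star_sequence), p$star, info = p$sequence)
    expect_true(st$overhang_ok)
    # the reciprocal projection from the star recovers the mature
    back <- predict_star(fr, p$star_span)
    expect_equal(unname(back$star_sequence), p$mature)
  }
})

test_that("family assignment respects mismatch, length and tie-break rules", {
  catalog <- c("tae-miR166a" = "UCGGACCAGGCUUCAUUCCCC",
               "tae-miR167b" = "UCGGACCAGGCUUCAUUCCAA",
               "tae-miR399a" = "GCCAAAGGAGAGUUGCCCUG")
  expect_equal(assign_family("UCGGACCAGGCUUCAUUCCCC", catalog), "miR166")
  # two mismatches still match; three -> novel
  two <- "UCGGACCAGGCUUCAUUCGGC"
  three <- "UCGGACCAGGCUUCAUACGGC"
  expect_equal(assign_family(two, catalog), "miR166")
  expect_equal(assign_family(three, catalog), "novel")
  # equal-quality hits in two families resolve to the smaller family id
  tie <- "UCGGACCAGGCUUCAUUCCCA"  # 1 mismatch to both 166a and 167b
  expect_equal(assign_family(tie, catalog), "miR166")
  # length difference beyond 2 nt never matches
  expect_equal(assign_family("UCGGACCAGGCUUCAUUCCCCAAAA", catalog), "novel")
  expect_equal(assign_family("ACGUACGUACGUACGUACGU", character(0)), "novel")
})

test_that("naming is deterministic and ordered by locus and abundance", {
  mir <- data.frame(
    sequence = c("AAA", "CCC", "GGG", "UUU"),
    length = 3L,
    precursor_id = c("p1", "p1", "p2", "p3"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    locus_start = c(100L, 100L, 900L, 50L),
    arm = c("5p", "5p", "3p", "5p"),
    start = 1L, end = 3L, star_sequence = NA, star_evidence = FALSE,
    overhang_ok = FALSE, total_count = c(10, 200, 5, 7),
    mean_rpm = 1, multi_locus_count = 1L,
    family = c("miR9662", "miR9662", "miR9662", "miR156"),
    stringsAsFactors = FALSE)
  named <- name_mirnas(mir)
  # precursor 1 (genomic order), variants by descending abundance
  expect_equal(named$name[named$sequence == "CCC"], "miR9662-1.1-5p")
  expect_equal(named$name[named$sequence == "AAA"], "miR9662-1.2-5p")
  # single-variant precursor omits the variant index
  expect_equal(named$name[named$sequence == "GGG"], "miR9662-2-3p")
  expect_equal(named$name[named$sequence == "UUU"], "miR156-1-5p")
  # permuting the input rows leaves the names unchanged
  named2 <- name_mirnas(mir[c(3, 1, 4, 2), ])
  expect_equal(named2[order(named2$sequence), "name"],
               named[order(named$sequence), "name"])
})

test_that("ascertainment grades star evidence from observed tags and catalog", {
  set.seed(43)
  cfg <- default_config()
  p <- build_precursor(mature_length = 21, stem_mismatches = 0,
                       loop_length = 8)
  spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
  genome <- c(chrT = paste0(spacer(120), to_dna(p$sequence), spacer(120)))

  run_asc <- function(tag_reads, catalog) {
    tags <- collapse_tags(list(l1 = tag_reads))
    kept <- rpm_filter(tags, 1)
    pl <- map_tags_exact(kept$sequence, genome)
    ab <- stats::setNames(rowSums(kept[, "l1", drop = FALSE]),
                          kept$sequence)
    cand <- extract_precursor_windows(pl, genome, ab, cfg)
    ascertain_mirnas(cand, kept, catalog, cfg)$mirnas
  }

  # star sequenced (any count) -> star_evidence TRUE
  mir <- run_asc(c(rep(to_dna(p$mature), 50), to_dna(p$star)), character(0))
  row <- mir[mir$sequence == p$mature, ]
  expect_equal(nrow(row), 1L)
  expect_true(row$star_evidence)

  # star unsequenced and not in catalog -> ascertained, evidence FALSE
  mir2 <- run_asc(rep(to_dna(p$mature), 50), character(0))
  row2 <- mir2[mir2$sequence == p$mature, ]
  expect_equal(nrow(row2), 1L)
  expect_false(row2$star_evidence)

  # star unsequenced but present in the catalog -> evidence TRUE
  mir3 <- run_asc(rep(to_dna(p$mature), 50),
                  c("tae-miR166a*" = p$star))
  expect_true(mir3[mir3$sequence == p$mature, "star_evidence"])

  # a tag straddling the terminal loop is not ascertained
  loop_tag <- substr(p$sequence, p$mature_span[2] + 2,
                     p$mature_span[2] + 22)
  mir4 <- run_asc(c(rep(to_dna(p$mature), 50), rep(to_dna(loop_tag), 50)),
                  character(0))
  expect_false(to_dna(loop_tag) %in% to_dna(mir4$sequence))
})

test_that("tags mapping only to shuffled decoys are not ascertained", {
  set.seed(44)
  cfg <- default_config()
  hits <- 0
  for (r in 1:15) {
    p <- build_precursor(mature_length = 21, stem_mismatches = 1,
                         loop_length = 8)
    dec <- to_dna(dinucleotide_shuffle(p$sequence))
    spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
    genome <- c(chrD = paste0(spacer(120), dec, spacer(120)))
    s <- sample(1:(nchar(dec) - 21), 1)
    tag <- substr(dec, s, s + 20)
    tags <- collapse_tags(list(l1 = rep(tag, 50)))
    kept <- rpm_filter(tags, 1)
    pl <- map_tags_exact(kept$sequence, genome)
    if (nrow(pl) == 0) next
    ab <- stats::setNames(rep(50, nrow(kept)), kept$sequence)
    cand <- extract_precursor_windows(pl, genome, ab, cfg)
    mir <- ascertain_mirnas(cand, kept, character(0), cfg)$mirnas
    if (nrow(mir) > 0) hits <- hits + 1
  }
  expect_equal(hits, 0)
})

test_that("arm assignment flips under reverse complementation", {
  set.seed(45)
  cfg <- default_config()
  for (i in 1:8) {
    p <- build_precursor(mature_length = 21, stem_mismatches = 0,
                         loop_length = 8)
    arm_of <- function(seq_rna, span) {
      fr <- fold(seq_rna)
      hp <- is_hairpin(fr, mature_span = span)
      expect_true(hp$pass)
      loop <- hp$loop
      if ((span[1] + span[2]) / 2 < (loop["i"] + loop["j"]) / 2) "5p" else "3p"
    }
    a1 <- arm_of(p$sequence, p$mature_span)
    expect_equal(a1, p$arm)
    n <- nchar(p$sequence)
    rc <- revcomp(p$sequence, "rna")
    rc_span <- c(n - p$mature_span[2] + 1, n - p$mature_span[1] + 1)
    a2 <- arm_of(rc, rc_span)
    expect_equal(a2, setdiff(c("5p", "3p"), a1))
  }
})

test_that("annotation mode restricts windows to the supplied intervals", {
  set.seed(46)
  cfg <- default_config()
  p <- build_precursor(mature_length = 21, stem_mismatches = 0,
                       loop_length = 8)
  spacer <- paste(rep("ACGT", 40), collapse = "")
  genome <- c(chrA = paste0(spacer, to_dna(p$sequence), spacer))
  off <- nchar(spacer)
  loci <- data.frame(chrom = "chrA", start = off,
                     end = off + nchar(p$sequence), strand = "+")
  tags <- collapse_tags(list(l1 = rep(to_dna(p$mature), 30)))
  kept <- rpm_filter(tags, 1)
  pl <- map_tags_exact(kept$sequence, genome)
  ab <- stats::setNames(30, kept$sequence)
  cand <- extract_precursor_windows(pl, genome, ab, cfg, loci = loci)
  expect_equal(length(cand), 1L)
  expect_equal(c(cand[[1]]$locus$start, cand[[1]]$locus$end),
               c(loci$start, loci$end))
  # a placement outside every locus yields no candidate
  tag_out <- substr(genome, 10, 30)
  kept2 <- rpm_filter(collapse_tags(list(l1 = rep(tag_out, 30))), 1)
  pl2 <- map_tags_exact(kept2$sequence, genome)
  cand2 <- extract_precursor_windows(pl2, genome,
                                     stats::setNames(30, kept2$sequence),
                                     cfg, loci = loci)
  expect_length(cand2, 0L)
})
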