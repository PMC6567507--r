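test_that("planted precursors have the designed geometry", {
  set.seed(1)
  for (i in 1:20) {
    L <- sample(19:24, 1)
    p <- build_precursor(mature_length = L, stem_mismatches = 0,
                         loop_length = sample(4:12, 1))
    expect_equal(nchar(p$mature), L)
    expect_equal(nchar(p$star), L)
    # mature and star occur verbatim at their recorded spans
    expect_equal(substr(p$sequence, p$mature_span[1], p$mature_span[2]),
                 p$mature)
    expect_equal(substr(p$sequence, p$star_span[1], p$star_span[2]),
                 p$star)
    # arms do not overlap
    expect_true(p$mature_span[2] < p$star_span[1] ||
                  p$star_span[2] < p$mature_span[1])
  }
})

test_that("precursor length scales with mature length by two arms", {
  set.seed(2)
  p19 <- build_precursor(mature_length = 19, loop_length = 8)
  p24 <- build_precursor(mature_length = 24, loop_length = 8)
  expect_equal(nchar(p24$sequence) - nchar(p19$sequence), 10L)
})

test_that("construction is deterministic under a fixed seed", {
  set.seed(33)
  a <- build_precursor()
  set.seed(33)
  b <- build_precursor()
  expect_identical(a, b)
})

test_that("folding a mismatch-free precursor recovers a long stem over the mature", {
  set.seed(4)
  p <- build_precursor(mature_length = 21, stem_mismatches = 0,
                       loop_length = 4)
  f <- fold(p$sequence)
  m <- p$mature_span[1]:p$mature_span[2]
  expect_gte(sum(!is.na(f$pair_table[m])), 19)
  expect_true(is_hairpin(f, mature_span = p$mature_span)$pass)
})

test_that("loop < 4 is rejected and mature lengths are bounded", {
  expect_error(build_precursor(loop_length = 3), "loop")
  expect_error(build_precursor(mature_length = 18), "19, 24")
})

test_that("every planted sequence occurs verbatim in the synthetic genome", {
  set.seed(11)
  truth <- small_truth()
  for (p in truth$precursors) {
    g <- p$genome_placement
    emitted <- substr(truth$genome[[g$chrom]], g$start + 1, g$end)
    if (g$strand == "-") emitted <- revcomp(emitted)
    expect_equal(to_rna(emitted), p$sequence)
  }
  # every expression-truth variant is a substring of its precursor
  tr <- truth$expression
  for (i in seq_len(nrow(tr))) {
    p <- truth$precursors[[match(tr$precursor_id[i],
                                 vapply(truth$precursors, `[[`, "", "id"))]]
    expect_true(grepl(tr$sequence[i], p$sequence, fixed = TRUE))
  }
  # isomiR end shifts stay within 3 nt
  expect_true(all(abs(tr$d5) <= 3 & abs(tr$d3) <= 3))
})

test_that("low-dispersion libraries reproduce the truth RPM within 5%", {
  set.seed(12)
  truth <- small_truth(n_prec = 5, depth = 1e6, dispersion = 1e-6,
                       de_fraction = 0)
  reads <- simulate_srna_libraries(truth)[1]  # one library suffices
  insert <- trim_adapter(reads[[1]], truth$config$adapter)$insert
  sized <- size_select(insert, 18, 24)
  tags <- collapse_tags(list(l = sized))
  rpm <- compute_rpm(tags)
  tr <- truth$expression
  big <- tr$rpm_control_0 > 2000   # high-abundance: relative error stable
  expect_gt(sum(big), 0)
  obs <- rpm[match(to_dna(tr$sequence[big]), rownames(rpm)), 1]
  rel <- abs(obs - tr$rpm_control_0[big]) / tr$rpm_control_0[big]
  expect_lt(max(rel), 0.05)
})

test_that("planted fold changes are recovered empirically within 0.3 log2 units", {
  set.seed(14)
  truth <- small_truth(n_prec = 10, depth = 2e5, dispersion = 0.1,
                       de_fraction = 0.5)
  reads <- simulate_srna_libraries(truth)
  lists <- lapply(reads, function(r) {
    size_select(trim_adapter(r, truth$config$adapter)$insert, 18, 24)
  })
  tags <- collapse_tags(lists)
  rpm <- compute_rpm(tags)
  sheet <- truth$design
  h0 <- sheet$library_id[sheet$treatment == "heat" & sheet$timepoint_days == 0]
  c0 <- sheet$library_id[sheet$treatment == "control" &
                           sheet$timepoint_days == 0]
  tr <- truth$expression
  de <- tr[tr$is_de & tr$rpm_control_0 > 500, ]
  expect_gt(nrow(de), 0)
  idx <- match(to_dna(de$sequence), rownames(rpm))
  emp <- log2(rowMeans(rpm[idx, h0, drop = FALSE]) /
                rowMeans(rpm[idx, c0, drop = FALSE]))
  # sampling noise at 4 replicates leaves individual estimates with a
  # standard error of ~0.3 log2 units, so the typical deviation is bounded
  expect_lt(stats::median(abs(emp - de$lfc0)), 0.3)
  expect_lt(max(abs(emp - de$lfc0)), 1)
})

test_that("zero planted miRNAs leaves only background reads", {
  set.seed(15)
  cfg <- default_config()
  cfg$simulate$n_precursors <- 2L
  cfg$simulate$n_decoys <- 2L
  cfg$simulate$depth <- 5000L
  cfg$simulate$spacer <- 300L
  truth <- simulate_dataset(cfg)
  truth$expression[, grep("^mean_", names(truth$expression))] <- 0
  reads <- simulate_srna_libraries(truth)
  expect_equal(length(reads[[1]]),
               round(cfg$simulate$depth * cfg$simulate$background_fraction))
})

test_that("different seeds give different reads but the same truth structure", {
  cfg <- default_config()
  cfg$simulate$n_precursors <- 3L
  cfg$simulate$n_decoys <- 2L
  cfg$simulate$depth <- 5000L
  cfg$simulate$spacer <- 200L
  set.seed(1)
  t1 <- simulate_dataset(cfg)
  set.seed(1)
  t2 <- simulate_dataset(cfg)
  expect_identical(t1$expression, t2$expression)
  r1 <- simulate_srna_libraries(t1)
  r2a <- simulate_srna_libraries(t1)  # RNG has advanced
  expect_false(identical(r1[[1]], r2a[[1]]))
})

test_that("degradome simulation concentrates signal at planted cleavage sites", {
  set.seed(16)
  truth <- small_truth(n_prec = 6)
  # background off: every signal read shares the planted 5' end
  t0 <- truth
  t0$config$simulate$pare_background_fraction <- 0
  reads <- simulate_pare_library(t0)
  starts <- vapply(truth$targets$transcript, function(tx) 0L, 0L)
  tg <- truth$targets
  for (i in seq_len(nrow(tg))) {
    frag <- substr(truth$transcripts[[tg$transcript[i]]],
                   tg$cleavage_pos[i] + 1, tg$cleavage_pos[i] + 20)
    expect_gt(sum(reads == frag), 0)
  }
  expect_equal(length(unique(reads)), nrow(tg))
})

test_that("the planted peak is the transcript mode in most seeded libraries", {
  set.seed(17)
  truth <- small_truth(n_prec = 6)
  hits <- 0
  n_rep <- 40
  for (r in 1:n_rep) {
    reads <- simulate_pare_library(truth)
    tags <- collapse_tags(list(p = size_select(reads, 19, 21)))
    prof <- build_profiles(data.frame(sequence = tags$sequence,
                                      count = tags$p), truth$transcripts)
    tg <- truth$targets[1, ]
    ab <- prof[[tg$transcript]]$abundance
    if (which.max(ab) == tg$cleavage_pos + 1) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("untargeted transcripts carry no dominant background position", {
  set.seed(18)
  truth <- small_truth(n_prec = 6)
  truth$config$simulate$pare_background_fraction <- 0.9
  frac <- c()
  # transcripts without planted signal (decoy-site transcripts receive
  # background reads only, so they qualify)
  bg_tx <- setdiff(names(truth$transcripts), truth$targets$transcript)
  for (r in 1:20) {
    reads <- simulate_pare_library(truth)
    tags <- collapse_tags(list(p = size_select(reads, 19, 21)))
    prof <- build_profiles(data.frame(sequence = tags$sequence,
                                      count = tags$p), truth$transcripts)
    for (tx in bg_tx) {
      pr <- prof[[tx]]
      if (pr$total >= 20) frac <- c(frac, max(pr$abundance) / pr$total)
    }
  }
  expect_gt(length(frac), 0)
  expect_lt(stats::median(frac), 0.5)
})

test_that("dinucleotide shuffling preserves composition and endpoints", {
  set.seed(19)
  for (i in 1:30) {
    s <- random_rna(sample(20:60, 1))
    sh <- dinucleotide_shuffle(s)
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, nchar(sh), nchar(sh)),
                 substr(s, nchar(s), nchar(s)))
  }
  expect_error(dinucleotide_shuffle("AAAAAA"), "shuffle")
})
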