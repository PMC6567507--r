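# Stage orchestrators behind the CLI subcommands. Every stage reads and
# writes plain TSV/FASTA/FASTQ/JSON, records read attrition in a run
# manifest, and is deterministic given (config, seed).

#' Simulate a full synthetic study to disk
#'
#' @param config configuration list.
#' @param seed integer seed.
#' @param out_dir output directory; files land in `out_dir/sim`.
#' @return the `synthetic_truth` object, invisibly.
#' @export
run_simulate <- function(config = default_config(), seed = 1L,
                         out_dir = ".") {
  set.seed(seed)
  sim_dir <- file.path(out_dir, "sim")
  dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_dataset(config)
  write_truth(truth, sim_dir)
  design <- simulate_srna_libraries(truth, out_dir = sim_dir)
  write_tsv(design, file.path(sim_dir, "sample_sheet.tsv"))
  pare <- simulate_pare_library(truth)
  write_fasta(stats::setNames(pare, sprintf("pare_%d", seq_along(pare))),
              file.path(sim_dir, "pare_reads.fa"))
  invisible(truth)
}

#' Trim, size-select and collapse the sRNA libraries
#'
#' @param sample_sheet sample sheet data.frame (or TSV path).
#' @param config configuration list.
#' @param out_dir output directory.
#' @return list with `tags` (tag table) and `manifest`.
#' @export
run_collapse <- function(sample_sheet, config = default_config(),
                         out_dir = ".") {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  sc <- config$srna
  reads_per_lib <- list()
  manifest <- list()
  for (i in seq_len(nrow(sample_sheet))) {
    lib <- sample_sheet$library_id[i]
    fq <- read_fastq(sample_sheet$file_path[i])
    tr <- trim_adapter(fq$sequence, config$adapter, sc$min_overlap)
    sized <- size_select(tr$insert, sc$min_len, sc$max_len)
    reads_per_lib[[lib]] <- sized
    manifest[[lib]] <- list(reads_in = nrow(fq),
                            adapter_rejected = tr$rejected,
                            after_trim = length(tr$insert),
                            retained = length(sized))
  }
  tags <- collapse_tags(reads_per_lib)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(tags, file.path(out_dir, "tags.tsv"))
  write_manifest(manifest, file.path(out_dir, "collapse_manifest.json"))
  list(tags = tags, manifest = manifest)
}

#' Ascertain miRNAs from collapsed tags and a genome
#'
#' @param tags tag table (or TSV path from [run_collapse()]).
#' @param genome named chromosome sequences (or FASTA path).
#' @param catalog named known-miRNA sequences (or FASTA path; may be
#'   empty).
#' @param config configuration list.
#' @param out_dir output directory.
#' @param loci optional precursor annotation (data.frame or BED path).
#' @return list with `mirnas`, `isomir_groups`, `candidates`, `tags_kept`.
#' @export
run_discover <- function(tags, genome, catalog = character(0),
                         config = default_config(), out_dir = ".",
                         loci = NULL) {
  if (is.character(tags) && length(tags) == 1 && file.exists(tags)) {
    tags <- read_tsv(tags)
    class(tags) <- c("tag_table", "data.frame")
  }
  if (is.character(genome) && length(genome) == 1) {
    genome <- read_fasta(genome)
  }
  if (is.character(catalog) && length(catalog) == 1 && file.exists(catalog)) {
    catalog <- read_fasta(catalog, alphabet = "rna")
  }
  if (is.character(loci) && length(loci) == 1) {
    bed <- utils::read.delim(loci, header = FALSE, stringsAsFactors = FALSE)
    loci <- data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
                       strand = bed[[6]], stringsAsFactors = FALSE)
  }
  kept <- rpm_filter(tags, config$srna$rpm_threshold)
  placements <- map_tags_exact(kept$sequence, genome)
  abundance <- stats::setNames(rowSums(tag_count_matrix(kept)),
                               kept$sequence)
  candidates <- extract_precursor_windows(placements, genome, abundance,
                                          config, loci = loci)
  asc <- ascertain_mirnas(candidates, kept, catalog, config)
  mirnas <- name_mirnas(asc$mirnas)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(mirnas) > 0) {
    tbl <- mirnas[, c("name", "sequence", "precursor_id", "arm",
                      "star_sequence", "star_evidence", "family",
                      "multi_locus_count", "total_count", "mean_rpm")]
    names(tbl)[3] <- "precursor_locus"
  } else {
    tbl <- mirnas
  }
  write_tsv(tbl, file.path(out_dir, "mirna_table.tsv"))
  write_tsv(asc$isomir_groups, file.path(out_dir, "isomir_groups.tsv"))
  prec_seqs <- vapply(candidates, function(cc) cc$sequence, "")
  prec_ids <- vapply(candidates, function(cc)
    format_locus(cc$locus$chrom, cc$locus$start, cc$locus$end,
                 cc$locus$strand), "")
  db <- vapply(candidates, function(cc) cc$fold$dotbracket, "")
  write_fasta(stats::setNames(prec_seqs, prec_ids),
              file.path(out_dir, "precursors.fa"))
  writeLines(paste0(">", prec_ids, "\n", prec_seqs, "\n", db),
             file.path(out_dir, "precursors.dotbracket"))
  write_manifest(list(tags_in = nrow(tags), tags_after_rpm = nrow(kept),
                      placements = nrow(placements),
                      candidates = length(candidates),
                      mirnas = nrow(mirnas)),
                 file.path(out_dir, "discover_manifest.json"))
  list(mirnas = mirnas, isomir_groups = asc$isomir_groups,
       candidates = candidates, tags_kept = kept)
}

#' Count matrix of ascertained miRNAs
#'
#' @param mirnas miRNA table (with `name`, `sequence`).
#' @param tags tag table carrying per-library counts.
#' @return integer matrix, miRNAs x libraries, rownames = miRNA names.
#' @export
mirna_count_matrix <- function(mirnas, tags) {
  m <- tag_count_matrix(tags)
  idx <- match(to_dna(mirnas$sequence), to_dna(tags$sequence))
  out <- m[idx, , drop = FALSE]
  rownames(out) <- mirnas$name
  out
}

#' Differential expression of miRNAs across the design
#'
#' @param counts miRNAs x libraries count matrix.
#' @param design sample sheet aligned with the columns.
#' @param config configuration list.
#' @param out_dir output directory.
#' @return list with `de` (all contrasts), `norm_factors`, `dispersion`,
#'   `mds`, `tree`.
#' @export
run_de <- function(counts, design, config = default_config(),
                   out_dir = ".") {
  nf <- tmm_norm_factors(counts)
  disp <- estimate_dispersion(counts, design, norm_factors = nf,
                              prior_n = config$de$prior_n,
                              grid_size = config$de$dispersion_grid)
  de <- glm_lrt(counts, design, norm_factors = nf,
                dispersion = disp$tagwise)
  logrpm <- log2(sweep(counts, 2, colSums(counts) * nf, "/") * 1e6 + 1)
  mds <- mds_embed(t(logrpm))
  tree <- if (ncol(counts) >= 2) hcluster(t(logrpm)) else NULL
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(as.data.frame(de), file.path(out_dir, "de_results.tsv"))
  write_tsv(data.frame(library = rownames(mds), dim1 = mds[, 1],
                       dim2 = mds[, 2]),
            file.path(out_dir, "mds_coordinates.tsv"))
  if (!is.null(tree)) {
    jsonlite::write_json(list(labels = tree$labels,
                              merge = apply(tree$merge, 1, identity,
                                            simplify = FALSE),
                              height = tree$height),
                         file.path(out_dir, "dendrogram.json"),
                         auto_unbox = FALSE, digits = 10)
  }
  list(de = de, norm_factors = nf, dispersion = disp, mds = mds,
       tree = tree)
}

#' Degradome validation of miRNA targets
#'
#' @param pare_reads character vector of degradome reads (or FASTA/FASTQ
#'   path).
#' @param transcripts named coding sequences (or FASTA path).
#' @param mirnas miRNA table from [run_discover()] (needs `name`,
#'   `sequence`), or a named character vector of sequences.
#' @param config configuration list.
#' @param out_dir output directory.
#' @return list with `hits`, `retained`, `tplots`, `profiles`.
#' @export
run_pare <- function(pare_reads, transcripts, mirnas,
                     config = default_config(), out_dir = ".") {
  if (is.character(transcripts) && length(transcripts) == 1 &&
      file.exists(transcripts)) {
    transcripts <- read_fasta(transcripts)
  }
  if (length(pare_reads) == 1 && file.exists(pare_reads)) {
    pare_reads <- if (grepl("\\.(fq|fastq)(\\.gz)?$", pare_reads)) {
      read_fastq(pare_reads)$sequence
    } else {
      unname(read_fasta(pare_reads))
    }
  }
  pc <- config$pare
  sized <- size_select(pare_reads, pc$min_len, pc$max_len)
  tags <- collapse_tags(list(pare = sized))
  pare_tags <- data.frame(sequence = tags$sequence, count = tags$pare,
                          stringsAsFactors = FALSE)
  profiles <- build_profiles(pare_tags, transcripts)
  query <- if (is.data.frame(mirnas)) {
    stats::setNames(to_rna(mirnas$sequence), mirnas$name)
  } else {
    stats::setNames(to_rna(mirnas), names(mirnas))
  }
  hits <- predict_targets(query, transcripts, profiles, config)
  rep <- filter_and_report(hits, profiles, pc$p_threshold,
                           pc$min_abundance)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(rep$retained, file.path(out_dir, "targets.tsv"))
  tdir <- file.path(out_dir, "tplots")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in names(rep$tplots)) {
    write_tsv(rep$tplots[[nm]],
              file.path(tdir, paste0(gsub("[^A-Za-z0-9._@-]", "_", nm),
                                     ".tsv")))
  }
  write_manifest(list(reads_in = length(pare_reads),
                      retained_19_21 = length(sized),
                      distinct_tags = nrow(pare_tags),
                      candidate_hits = nrow(hits),
                      retained_hits = nrow(rep$retained)),
                 file.path(out_dir, "pare_manifest.json"))
  list(hits = hits, retained = rep$retained, tplots = rep$tplots,
       profiles = profiles)
}

#' Run the complete pipeline end to end
#'
#' Simulation, tag processing, miRNA discovery, differential expression
#' and degradome validation, writing every stage's tables under
#' `out_dir`. Identical (config, seed) pairs produce byte-identical
#' outputs.
#'
#' @param config configuration list.
#' @param seed integer seed for all randomness.
#' @param out_dir output directory.
#' @return named list with each stage's results, invisibly.
#' @export
run_all <- function(config = default_config(), seed = 1L, out_dir = ".") {
  truth <- run_simulate(config, seed, out_dir)
  sheet <- read_sample_sheet(file.path(out_dir, "sim", "sample_sheet.tsv"))
  col <- run_collapse(sheet, config, file.path(out_dir, "tags"))
  disc <- run_discover(col$tags, truth$genome, truth$catalog, config,
                       file.path(out_dir, "mirnas"))
  results <- list(truth = truth, tags = col, discovery = disc)
  if (nrow(disc$mirnas) > 0) {
    counts <- mirna_count_matrix(disc$mirnas, col$tags)
    results$de <- run_de(counts, sheet, config, file.path(out_dir, "de"))
    pare_reads <- unname(read_fasta(file.path(out_dir, "sim",
                                              "pare_reads.fa")))
    results$pare <- run_pare(pare_reads, truth$transcripts, disc$mirnas,
                             config, file.path(out_dir, "pare"))
  }
  invisible(results)
}
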