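# Independent oracles used across tests. These deliberately use naive
# algorithms (exhaustive enumeration, O(n^3) scans, literal definitions)
# so they share no code with the implementation they check.

PAIR_ENERGY <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)

# exhaustive minimum energy over all nested structures with loop >= 3
brute_force_min_energy <- function(seq, minloop = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < minloop + 1) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1, j)
    for (k in (i + minloop + 1):j) {
      e <- PAIR_ENERGY[paste0(ch[i], ch[k])]
      if (is.na(e)) next
      best <- min(best, e + rec(i + 1, k - 1) +
                    if (k < j) rec(k + 1, j) else 0)
    }
    memo[[key]] <- best
    best
  }
  if (n < minloop + 2) 0 else unname(rec(1, n))
}

# literal Benjamini-Hochberg step-up definition:
# q(rank r) = min over ranks s >= r of p(s) * m / s, capped at 1
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (r in seq_len(m)) qs[r] <- min(1, min(ps[r:m] * m / (r:m)))
  q <- numeric(m)
  q[o] <- qs
  q
}

# O(n^3) complete-linkage agglomeration with Chebyshev distance,
# recording the partition after every merge (label-free comparison)
brute_force_complete_linkage <- function(x) {
  n <- nrow(x)
  D <- as.matrix(stats::dist(x, method = "maximum"))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    bestd <- Inf
    for (a in seq_along(clusters)[-length(clusters)]) {
      for (b in (a + 1):length(clusters)) {
        d <- max(D[clusters[[a]], clusters[[b]]])
        if (d < bestd - 1e-12) {
          bestd <- d
          best <- c(a, b)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
    heights <- c(heights, bestd)
    partitions[[length(partitions) + 1]] <-
      lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# partition of the leaves after each merge of an hclust-style tree
tree_partitions <- function(merge) {
  n <- nrow(merge) + 1
  members <- vector("list", nrow(merge))
  out <- list()
  active <- as.list(seq_len(n))
  names(active) <- paste0("s", seq_len(n))
  for (s in seq_len(nrow(merge))) {
    get <- function(id) if (id < 0) -id else members[[id]]
    members[[s]] <- sort(c(get(merge[s, 1]), get(merge[s, 2])))
    out[[s]] <- members[[s]]
  }
  out
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

dinuc_counts <- function(x) {
  ch <- strsplit(x, "")[[1]]
  sort(table(paste0(ch[-length(ch)], ch[-1])))
}

# a tiny synthetic truth for generator-level tests
small_truth <- function(n_prec = 6, depth = 50000, dispersion = 0.1,
                        de_fraction = 0.2, n_decoys = 4) {
  cfg <- default_config()
  cfg$simulate$n_precursors <- n_prec
  cfg$simulate$n_decoys <- n_decoys
  cfg$simulate$depth <- as.integer(depth)
  cfg$simulate$dispersion <- dispersion
  cfg$simulate$de_fraction <- de_fraction
  cfg$simulate$spacer <- 300L
  cfg$simulate$n_transcripts <- 8L
  cfg$simulate$n_targets <- 4L
  simulate_dataset(cfg)
}
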