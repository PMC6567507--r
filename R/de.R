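# Normalisation, dispersion estimation, negative-binomial GLM
# likelihood-ratio tests, FDR control and clustering/MDS summaries for
# the 2-treatment x 3-timepoint count matrix. All statistics are
# implemented from first principles (simplified relative to full
# empirical-Bayes machinery; see the methods vignette).

#' Trimmed mean of M-values normalisation factors
#'
#' Composition-correcting scale factors for count libraries. The
#' reference library is the one whose upper quartile of counts-per-
#' million is closest to the mean upper quartile. Per-gene M (log2
#' ratio of library-size-scaled proportions) and A (mean log2
#' proportion) statistics are computed against the reference, genes
#' with a zero in either library are excluded, the extreme 30% of M and
#' 5% of A are trimmed, and the factor is 2 to the precision-weighted
#' trimmed mean of M with delta-method weights
#' (N - x)/(N x) + (Nr - xr)/(Nr xr). Factors are rescaled to geometric
#' mean 1.
#'
#' @param counts non-negative integer matrix, genes x libraries.
#' @return numeric vector of normalisation factors, one per library.
#' @export
tmm_norm_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 libraries", call. = FALSE)
  N <- colSums(counts)
  if (any(N == 0)) {
    stop("library with all-zero counts: ",
         colnames(counts)[N == 0][1], call. = FALSE)
  }
  cpm <- sweep(counts, 2, N, "/") * 1e6
  uq <- apply(cpm, 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    if (i == ref) return(1)
    x <- counts[, i]
    xr <- counts[, ref]
    keep <- x > 0 & xr > 0
    x <- x[keep]
    xr <- xr[keep]
    M <- log2((x / N[i]) / (xr / N[ref]))
    A <- (log2(x / N[i]) + log2(xr / N[ref])) / 2
    w <- (N[i] - x) / (N[i] * x) + (N[ref] - xr) / (N[ref] * xr)
    # double trim: drop the 30% M tails and 5% A tails
    n <- length(M)
    loM <- floor(n * 0.3) + 1
    hiM <- n + 1 - floor(n * 0.3)
    loA <- floor(n * 0.05) + 1
    hiA <- n + 1 - floor(n * 0.05)
    keep2 <- rank(M, ties.method = "first") >= loM &
      rank(M, ties.method = "first") <= hiM &
      rank(A, ties.method = "first") >= loA &
      rank(A, ties.method = "first") <= hiA
    if (!any(keep2)) return(1)
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, 0.0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

nb_loglik <- function(y, mu, phi) {
  if (phi < 1e-10) sum(stats::dpois(y, mu, log = TRUE)) else
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# cell-mean fitted values under offsets: pooled-proportion estimate
cell_means <- function(y, eff_size, cell) {
  pooled <- tapply(y, cell, sum) / tapply(eff_size, cell, sum)
  as.numeric(pooled[cell]) * eff_size
}

#' Estimate negative-binomial dispersion
#'
#' Common dispersion maximises the summed adjusted profile likelihood
#' (Cox-Reid-style adjustment for the fitted cell means) over a
#' logarithmic grid on \[1e-4, 10\]; per-gene dispersions are shrunk
#' towards the common value by weighted likelihood with a prior weight
#' equivalent to `prior_n` observations. Variance model:
#' Var = mu + phi mu^2.
#'
#' @param counts genes x libraries matrix.
#' @param design data.frame with `treatment` and `timepoint_days`
#'   aligned to the columns of `counts`.
#' @param norm_factors TMM factors (default: computed).
#' @param prior_n prior weight, in observations, for shrinkage.
#' @param grid_size number of grid points.
#' @return list with `common` (scalar phi) and `tagwise` (per-gene phi).
#' @export
estimate_dispersion <- function(counts, design, norm_factors = NULL,
                                prior_n = 10, grid_size = 25L) {
  counts <- as.matrix(counts)
  cell <- interaction(design$treatment, design$timepoint_days, drop = TRUE)
  if (max(table(cell)) < 2) {
    stop("dispersion is unidentifiable without replication", call. = FALSE)
  }
  if (is.null(norm_factors)) norm_factors <- tmm_norm_factors(counts)
  eff <- colSums(counts) * norm_factors
  grid <- exp(seq(log(1e-4), log(10), length.out = grid_size))
  G <- nrow(counts)
  apl <- matrix(0, G, length(grid))
  mus <- t(apply(counts, 1, cell_means, eff_size = eff, cell = cell))
  for (j in seq_along(grid)) {
    phi <- grid[j]
    ll <- rowSums(stats::dnbinom(counts, size = 1 / phi, mu = pmax(mus, 1e-8),
                                 log = TRUE))
    # Cox-Reid adjustment: -0.5 log det of the per-cell information
    w <- mus / (1 + phi * mus)
    cr <- 0.5 * rowSums(log(pmax(
      t(apply(w, 1, function(z) tapply(z, cell, sum))), 1e-10)))
    apl[, j] <- ll - cr
  }
  common <- grid[which.max(colSums(apl))]
  prior_weight <- prior_n / ncol(counts)
  wl <- apl + prior_weight * matrix(colMeans(apl), G, length(grid),
                                    byrow = TRUE)
  tagwise <- grid[apply(wl, 1, which.max)]
  names(tagwise) <- rownames(counts)
  list(common = common, tagwise = tagwise, grid = grid)
}

# NB GLM fit with log link, offsets and fixed dispersion, by IRLS
nb_glm_fit <- function(y, X, offset, phi, max_iter = 50L, tol = 1e-8) {
  eta <- log(pmax(y, 0.5)) # init near the saturated fit
  mu <- exp(eta)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) break
    beta <- fit$coefficients
    eta <- drop(X %*% beta) + offset
    eta <- pmin(eta, 30)
    mu <- pmax(exp(eta), 1e-10)
    ll <- nb_loglik(y, mu, phi)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(beta = beta, mu = mu, loglik = ll_old, converged = converged)
}

#' Per-gene negative-binomial GLM likelihood-ratio tests
#'
#' Fits the full cell-means model (one coefficient per
#' treatment:timepoint cell, offset log effective library size) and,
#' per contrast, a reduced model in which the two contrasted cells are
#' merged; twice the log-likelihood difference is referred to
#' chi-square with 1 df. log2 fold changes come from the fitted full
#' coefficients. All-zero genes get p = 1 and log2FC = 0 by convention;
#' non-converged fits are flagged with p = NA.
#'
#' @param counts genes x libraries matrix.
#' @param design sample sheet rows aligned with columns.
#' @param norm_factors TMM factors.
#' @param dispersion per-gene dispersions (recycled if scalar).
#' @param contrasts named list; each element `c(cellA, cellB)` with cell
#'   labels `treatment_timepoint` (e.g. `c("heat_0", "control_0")`).
#'   Default: heat vs control at 0/1/4 DAT plus heat 0-vs-4 and
#'   control 0-vs-4.
#' @return data.frame of class `de_result`: `gene`, `contrast`,
#'   `log2fc`, `lr_stat`, `p_value`, `fdr` (BH within contrast).
#' @export
glm_lrt <- function(counts, design, norm_factors = NULL, dispersion = 0.1,
                    contrasts = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  }
  if (is.null(norm_factors)) norm_factors <- tmm_norm_factors(counts)
  cell <- paste(design$treatment, design$timepoint_days, sep = "_")
  cells <- unique(cell)
  X <- stats::model.matrix(~ 0 + factor(cell, levels = cells))
  colnames(X) <- cells
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient",
                                 call. = FALSE)
  offset <- log(colSums(counts) * norm_factors)
  phi <- rep_len(dispersion, nrow(counts))
  if (is.null(contrasts)) {
    contrasts <- list(
      heat_vs_control_0DAT = c("heat_0", "control_0"),
      heat_vs_control_1DAT = c("heat_1", "control_1"),
      heat_vs_control_4DAT = c("heat_4", "control_4"),
      heat_0_vs_4DAT = c("heat_0", "heat_4"),
      control_0_vs_4DAT = c("control_0", "control_4"))
  }
  out <- list()
  n_nonconverged <- 0L
  for (cname in names(contrasts)) {
    pair <- contrasts[[cname]]
    stopifnot(all(pair %in% cells))
    merged <- ifelse(cell %in% pair, "merged", cell)
    Xr <- stats::model.matrix(~ 0 + factor(merged))
    res <- matrix(NA_real_, nrow(counts), 3,
                  dimnames = list(rownames(counts),
                                  c("log2fc", "lr_stat", "p_value")))
    for (g in seq_len(nrow(counts))) {
      y <- counts[g, ]
      if (all(y == 0)) {
        res[g, ] <- c(0, 0, 1)
        next
      }
      ff <- nb_glm_fit(y, X, offset, phi[g])
      fr <- nb_glm_fit(y, Xr, offset, phi[g])
      if (!ff$converged || !fr$converged) {
        n_nonconverged <- n_nonconverged + 1L
        next
      }
      lr <- max(0, 2 * (ff$loglik - fr$loglik))
      lfc <- (ff$beta[pair[1]] - ff$beta[pair[2]]) / log(2)
      res[g, ] <- c(lfc, lr, stats::pchisq(lr, df = 1, lower.tail = FALSE))
    }
    out[[cname]] <- data.frame(gene = rownames(counts), contrast = cname,
                               log2fc = res[, 1], lr_stat = res[, 2],
                               p_value = res[, 3],
                               fdr = bh_fdr(res[, 3]),
                               row.names = NULL, stringsAsFactors = FALSE)
  }
  de <- do.call(rbind, out)
  rownames(de) <- NULL
  attr(de, "n_nonconverged") <- n_nonconverged
  class(de) <- c("de_result", "data.frame")
  de
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' q(i) = min over j >= i of p(j) m / j on the sorted p-values, capped
#' at 1. NA p-values propagate as NA and do not count towards m.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of FDR-adjusted values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  o <- order(p[ok])
  q <- p[ok][o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out[ok[o]] <- pmin(q, 1)
  out
}

#' Agglomerative complete-linkage clustering with Chebyshev distance
#'
#' Distance between items is the maximum coordinate difference;
#' cluster-cluster distance is the complete-linkage maximum. Ties are
#' broken by merging the pair whose (smallest-original-member) labels
#' are lexicographically smallest, making the tree deterministic.
#'
#' @param x numeric matrix, items in rows (e.g. log2(RPM + 1)).
#' @return list of class `hcluster` with `merge` (hclust encoding),
#'   `height`, `order`, `labels`.
#' @export
hcluster <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 items to cluster", call. = FALSE)
  labels <- rownames(x) %||% as.character(seq_len(n))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- max(abs(x[i, ] - x[j, ]))
    }
  }
  active <- seq_len(n)
  id <- -seq_len(n)            # hclust convention: negatives = singletons
  rep_member <- seq_len(n)     # smallest original member, for tie-breaks
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (ai in seq_along(active)[-length(active)]) {
      for (aj in (ai + 1):length(active)) {
        i <- active[ai]
        j <- active[aj]
        d <- D[i, j]
        key <- sort(c(rep_member[i], rep_member[j]))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = d, key = key)
        }
      }
    }
    i <- best$i
    j <- best$j
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best$d
    # complete linkage update onto slot i
    for (k in active) {
      if (k != i && k != j) D[i, k] <- D[k, i] <- max(D[i, k], D[j, k])
    }
    id[i] <- step
    rep_member[i] <- min(rep_member[i], rep_member[j])
    active <- setdiff(active, j)
  }
  ord <- dendrogram_order(merge)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "complete",
                 dist.method = "maximum"), class = "hcluster")
}

dendrogram_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' @export
print.hcluster <- function(x, ...) {
  cat("complete-linkage / Chebyshev clustering of", length(x$labels),
      "items\nmerge heights:", paste(signif(x$height, 4), collapse = " "),
      "\n")
  invisible(x)
}

#' Classical (Torgerson) multidimensional scaling to 2 dimensions
#'
#' Double-centres the squared Euclidean distance matrix of the rows and
#' returns the top-2 eigenvectors scaled by the square roots of their
#' eigenvalues. With effective rank < 2 the missing axis is zero and a
#' warning is raised.
#'
#' @param x numeric matrix, items (libraries) in rows.
#' @return items x 2 coordinate matrix.
#' @export
mds_embed <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("MDS needs at least 3 items", call. = FALSE)
  D2 <- as.matrix(stats::dist(x))^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- e$values[1:2]
  if (lam[2] <= 1e-12 * max(lam[1], 1)) {
    warning("configuration has rank < 2; second axis set to zero")
    lam[2] <- 0
  }
  coords <- e$vectors[, 1:2] %*% diag(sqrt(pmax(lam, 0)), 2)
  rownames(coords) <- rownames(x)
  colnames(coords) <- c("dim1", "dim2")
  coords
}
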