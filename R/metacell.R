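# Metacell aggregation: bootstrap co-clustering of cells on a mutual-kNN
# graph, partitioned by Ward clustering of the co-clustering matrix with a
# minimum metacell size, then aggregation by arithmetic means. Stabilizes
# co-expression estimation on sparse single-cell counts.

#' Metacell configuration
#'
#' Defaults follow common metacell practice for single-cell cohorts:
#' scaled-variance gene filter at 0.08, K = 100 nearest neighbors, 500
#' bootstrap iterations over 75% of cells, minimum metacell size 50.
#'
#' @param scaled_var_threshold Scaled-variance cutoff for gene selection.
#' @param knn_k Neighbors per cell in each bootstrap graph.
#' @param n_boot Bootstrap iterations.
#' @param boot_frac Fraction of cells resampled per iteration (in (0, 1]).
#' @param resolution Louvain resolution for the within-bootstrap community
#'   partition; the default (4) puts communities at the metacell size
#'   scale rather than the macro-cluster scale.
#' @param min_size Minimum cells per metacell.
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes,
#'   excluded before analysis.
#' @param seed Integer RNG seed.
#' @return List of class `MetacellConfig`.
#' @export
metacell_config <- function(scaled_var_threshold = 0.08, knn_k = 100,
                            n_boot = 500, boot_frac = 0.75, resolution = 4,
                            min_size = 50, mito_prefix = "MT-", seed = 1L) {
  if (boot_frac <= 0 || boot_frac > 1) stop("boot_frac must be in (0, 1]")
  if (knn_k < 1 || n_boot < 1 || min_size < 1) stop("invalid config")
  structure(list(scaled_var_threshold = scaled_var_threshold,
                 knn_k = as.integer(knn_k), n_boot = as.integer(n_boot),
                 boot_frac = boot_frac, resolution = resolution,
                 min_size = as.integer(min_size),
                 mito_prefix = mito_prefix, seed = as.integer(seed)),
            class = "MetacellConfig")
}

#' Select variable genes by scaled variance
#'
#' Keeps genes whose variance of log-normalized expression divided by its
#' mean exceeds `threshold`. Mitochondrial genes (name prefix
#' `mito_prefix`) are excluded first, as are genes with no expression.
#'
#' @param matrix ExpressionMatrix or genes x cells counts.
#' @param threshold Scaled-variance cutoff (default 0.08).
#' @param mito_prefix Mitochondrial gene-name prefix (default `"MT-"`).
#' @return Character vector of selected genes.
#' @export
select_variable_genes <- function(matrix, threshold = 0.08,
                                  mito_prefix = "MT-") {
  counts <- get_counts(matrix)
  if (ncol(counts) < 2) stop("need at least 2 cells")
  keep <- !startsWith(rownames(counts), mito_prefix)
  ln <- lognorm(counts)[keep, , drop = FALSE]
  mu <- Matrix::rowMeans(ln)
  # E[x^2] - E[x]^2 with n/(n-1) correction, sparse-friendly
  n <- ncol(ln)
  ex2 <- Matrix::rowMeans(ln^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  v[v < 1e-12] <- 0  # guard against catastrophic-cancellation residue
  ok <- mu > 0
  scaled <- rep(0, length(mu))
  scaled[ok] <- v[ok] / mu[ok]
  sel <- rownames(ln)[scaled > threshold & v > 0]
  if (length(sel) == 0)
    stop("no variable genes selected; lower the threshold")
  sel
}

#' Bootstrap co-clustering of cells
#'
#' For each of `n_boot` bootstrap iterations, a random `boot_frac` of the
#' cells is selected, a mutual-kNN graph is built on Pearson-correlation
#' distance over the selected variable genes' log-normalized expression,
#' and cells are partitioned into communities of the mutual graph (Louvain
#' modularity; connected components collapse into a single giant component
#' on continuous expression manifolds and carry no granularity).
#' `coclustering[i, j]` is the fraction of iterations containing
#' both cells in which they land in the same component (0 for pairs never
#' co-sampled); the matrix is symmetric with unit diagonal.
#'
#' @param matrix ExpressionMatrix or genes x cells counts.
#' @param config [metacell_config()].
#' @param genes Optional pre-selected gene set; defaults to
#'   [select_variable_genes()] at the config threshold.
#' @return cells x cells co-clustering frequency matrix.
#' @export
build_coclustering <- function(matrix, config = metacell_config(),
                               genes = NULL) {
  counts <- get_counts(matrix)
  n <- ncol(counts)
  if (n <= config$knn_k) stop("n_cells must exceed knn_k")
  n_sub <- max(2, round(config$boot_frac * n))
  if (config$knn_k >= n_sub)
    stop("knn_k must be smaller than the bootstrap subsample size")
  if (is.null(genes))
    genes <- select_variable_genes(counts, config$scaled_var_threshold,
                                   config$mito_prefix)
  X <- as.matrix(lognorm(counts)[genes, , drop = FALSE])
  set.seed(config$seed)
  cooc <- matrix(0, n, n)
  pres <- matrix(0, n, n)
  k <- config$knn_k
  for (b in seq_len(config$n_boot)) {
    sub <- sort(sample.int(n, n_sub))
    cc <- suppressWarnings(stats::cor(X[, sub, drop = FALSE]))
    cc[is.na(cc)] <- 0
    diag(cc) <- -Inf
    # kNN by smallest correlation distance = largest correlation
    nnidx <- apply(cc, 2, function(col)
      order(col, decreasing = TRUE)[seq_len(k)])
    adj <- matrix(FALSE, n_sub, n_sub)
    adj[cbind(as.vector(nnidx), rep(seq_len(n_sub), each = k))] <- TRUE
    mutual <- adj & t(adj)
    g <- igraph::graph_from_adjacency_matrix(mutual, mode = "undirected")
    memb <- igraph::membership(
      igraph::cluster_louvain(g, resolution = config$resolution))
    same <- outer(memb, memb, "==")
    cooc[sub, sub] <- cooc[sub, sub] + same
    pres[sub, sub] <- pres[sub, sub] + 1
  }
  out <- ifelse(pres > 0, cooc / pmax(pres, 1), 0)
  diag(out) <- 1
  out <- (out + t(out)) / 2
  dimnames(out) <- list(colnames(counts), colnames(counts))
  out
}

#' Partition cells into metacells from a co-clustering matrix
#'
#' Ward hierarchical clustering (`ward.D2`) on `1 - coclustering` (average
#' linkage chains on smooth co-clustering frequencies and collapses the
#' partition; Ward yields balanced metacells), cut at
#' the finest level compatible with the size floor
#' (`floor(n / min_size)` clusters), then clusters below `min_size` are
#' iteratively merged into the cluster with the highest average
#' co-clustering frequency. Metacell expression and traits are arithmetic
#' means over member cells.
#'
#' @param coclustering Square symmetric matrix from [build_coclustering()].
#' @param min_size Minimum cells per metacell (default 50).
#' @param matrix Optional ExpressionMatrix/counts to aggregate
#'   (log-normalized means per metacell).
#' @param trait Optional per-cell numeric trait (e.g. a stemness score) to
#'   average per metacell.
#' @return List of class `MetacellAssignment`: `membership` (per-cell
#'   metacell id, contiguous from 1), `sizes`, `members`, and, when
#'   supplied, `expression` (genes x metacells) and `trait`.
#' @export
partition_metacells <- function(coclustering, min_size = 50, matrix = NULL,
                                trait = NULL) {
  co <- as.matrix(coclustering)
  stopifnot(nrow(co) == ncol(co))
  if (max(abs(co - t(co))) > 1e-8) stop("coclustering must be symmetric")
  n <- nrow(co)
  if (n < min_size) {
    warning("fewer cells than min_size: single metacell")
    memb <- rep(1L, n)
  } else {
    hc <- stats::hclust(stats::as.dist(1 - co), method = "ward.D2")
    k0 <- max(1L, n %/% as.integer(min_size))
    memb <- stats::cutree(hc, k = k0)
    repeat {
      sizes <- table(memb)
      small <- names(sizes)[sizes < min_size]
      if (length(small) == 0 || length(sizes) == 1) break
      s <- small[which.min(sizes[small])]
      in_s <- memb == as.integer(s)
      others <- setdiff(unique(memb), as.integer(s))
      sim <- vapply(others, function(o)
        mean(co[in_s, memb == o, drop = FALSE]), numeric(1))
      memb[in_s] <- others[which.max(sim)]
    }
  }
  # contiguous ids ordered by first occurrence
  memb <- as.integer(factor(memb, levels = unique(memb)))
  names(memb) <- rownames(co)
  out <- list(membership = memb, sizes = as.vector(table(memb)),
              members = split(seq_len(n), memb))
  if (!is.null(matrix)) {
    ln <- lognorm(get_counts(matrix))
    stopifnot(ncol(ln) == n)
    expr <- vapply(out$members, function(ix)
      Matrix::rowMeans(ln[, ix, drop = FALSE]), numeric(nrow(ln)))
    colnames(expr) <- sprintf("MC%03d", seq_along(out$members))
    out$expression <- expr
  }
  if (!is.null(trait)) {
    stopifnot(length(trait) == n)
    out$trait <- vapply(out$members, function(ix) mean(trait[ix]),
                        numeric(1))
    names(out$trait) <- sprintf("MC%03d", seq_along(out$members))
  }
  class(out) <- "MetacellAssignment"
  out
}

#' @export
print.MetacellAssignment <- function(x, ...) {
  cat(sprintf("MetacellAssignment: %d cells in %d metacells (sizes %d-%d)\n",
              length(x$membership), length(x$members), min(x$sizes),
              max(x$sizes)))
  invisible(x)
}
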