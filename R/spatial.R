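# Malignant-spot identification in spatial sections: graph clustering of
# spots, immune-score reference selection, windowed CNV inference against
# the reference cluster, and malignant-cluster calling by elevated CNV
# score.

#' Default marker panel for reference selection and validation
#'
#' Pan-immune (PTPRC), T-cell (CD2, CD3D, CD3E, CD3G), B-cell (CD79A,
#' MS4A1, CD79B), myeloid (CD68, CD14) and epithelial (EPCAM, KRT8, KRT19)
#' marker sets.
#'
#' @return Named list of character vectors of class `MarkerPanel`.
#' @export
default_marker_panel <- function() {
  structure(list(pan_immune = "PTPRC",
                 t_cell = c("CD2", "CD3D", "CD3E", "CD3G"),
                 b_cell = c("CD79A", "MS4A1", "CD79B"),
                 myeloid = c("CD68", "CD14"),
                 epithelial = c("EPCAM", "KRT8", "KRT19")),
            class = "MarkerPanel")
}

#' Mean log-normalized expression of a marker set per spot
#'
#' @param grid SpotGrid, ExpressionMatrix or matrix.
#' @param genes Marker genes (at least one must be present).
#' @return Named per-spot score (0 for all-zero spots).
#' @export
marker_score <- function(grid, genes) {
  ln <- lognorm(grid, allow_zero = TRUE)
  gs <- intersect(genes, rownames(ln))
  if (length(gs) == 0)
    stop("none of the marker genes are present in the matrix")
  stats::setNames(Matrix::colMeans(ln[gs, , drop = FALSE]), colnames(ln))
}

#' Per-spot immune score
#'
#' Mean log-normalized expression over the union of the immune marker sets
#' (pan-immune, T, B, myeloid).
#'
#' @param grid SpotGrid or ExpressionMatrix.
#' @param panel Marker panel (default [default_marker_panel()]).
#' @return Named per-spot score.
#' @export
immune_score <- function(grid, panel = default_marker_panel()) {
  genes <- unique(unlist(panel[c("pan_immune", "t_cell", "b_cell",
                                 "myeloid")]))
  marker_score(grid, genes)
}

#' Select the immune reference cluster
#'
#' The cluster with the maximum mean immune score; ties are broken by the
#' lowest cluster id.
#'
#' @param scores Per-spot immune scores.
#' @param clusters Per-spot cluster labels (same order).
#' @return The selected cluster id (same type as `clusters`).
#' @export
select_reference <- function(scores, clusters) {
  stopifnot(length(scores) == length(clusters))
  ids <- sort(unique(clusters))
  means <- vapply(ids, function(cl) mean(scores[clusters == cl]),
                  numeric(1))
  ids[which.max(means)]  # which.max returns the first (lowest id) on ties
}

#' Cluster spatial spots
#'
#' Log-normalize, select the top variable genes, PCA, then Leiden
#' community detection on a kNN graph of the PC embedding. Deterministic
#' under `seed`.
#'
#' @param grid SpotGrid or ExpressionMatrix.
#' @param n_pcs Principal components (reduced with a warning when there
#'   are fewer spots).
#' @param resolution Leiden resolution parameter (0 gives one cluster).
#' @param n_var_genes Variable genes used (default 2000).
#' @param knn_k Graph neighbors (default 20).
#' @param seed RNG seed.
#' @return Named integer per-spot cluster labels (1-based).
#' @export
cluster_spots <- function(grid, n_pcs = 30, resolution = 1,
                          n_var_genes = 2000, knn_k = 20, seed = 1L) {
  counts <- get_counts(grid)
  if (ncol(counts) < 50) stop("need at least 50 spots")
  ln <- as.matrix(lognorm(counts, allow_zero = TRUE))
  v <- apply(ln, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_var_genes, sum(v > 0)))]
  X <- ln[keep, , drop = FALSE]
  X <- (X - rowMeans(X)) / apply(X, 1, stats::sd)
  if (n_pcs >= ncol(X)) {
    warning("fewer spots than n_pcs; reducing")
    n_pcs <- ncol(X) - 1
  }
  sv <- svd(t(X), nu = n_pcs, nv = 0)
  emb <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  k <- min(knn_k, ncol(X) - 1)
  d2 <- as.matrix(stats::dist(emb))
  diag(d2) <- Inf
  nn <- apply(d2, 1, function(row) order(row)[seq_len(k)])
  edges <- cbind(rep(seq_len(ncol(X)), each = k), as.vector(nn))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  stats::setNames(as.integer(igraph::membership(cl)), colnames(counts))
}

# centered running mean with shrinking window at the edges
.running_mean <- function(v, window) {
  n <- length(v)
  h <- (window - 1) %/% 2
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Infer windowed CNV profiles against a reference
#'
#' Pipeline: drop genes with mean expression below `cutoff`; `log2` of
#' library-size-normalized counts plus one; center each gene on its
#' reference-spot mean; order genes along the genome; moving average of
#' width `window` within each chromosome (window shrinks at chromosome
#' edges); subtract each spot's median (denoising); clamp to
#' `[-clamp, clamp]`. The per-spot CNV score is the mean of squared
#' profile values.
#'
#' @param grid SpotGrid or ExpressionMatrix.
#' @param annotation data.frame `gene`, `chrom`, `start`.
#' @param reference_spots Barcodes or column indices of reference spots
#'   (>= 20).
#' @param window Moving-average width in genes (default 101).
#' @param clamp Symmetric clamp on profile values (default 0.2).
#' @param cutoff Minimum mean raw expression per gene (default 0.1).
#' @return List of class `CnvProfile`: `profile` (spots x genes,
#'   genome-ordered), `cnv_score` (named, non-negative), `annotation`,
#'   `reference` (barcodes).
#' @export
infer_cnv <- function(grid, annotation, reference_spots, window = 101,
                      clamp = 0.2, cutoff = 0.1) {
  counts <- get_counts(grid)
  if (is.character(reference_spots))
    reference_spots <- match(reference_spots, colnames(counts))
  if (anyNA(reference_spots)) stop("unknown reference spot barcodes")
  if (length(reference_spots) < 20) stop("need at least 20 reference spots")
  ann <- annotation[!is.na(annotation$gene), ]
  shared <- intersect(rownames(counts), ann$gene)
  if (length(shared) < 0.5 * nrow(counts))
    stop("annotation missing for more than 50% of genes")
  mu <- Matrix::rowMeans(counts)
  keep <- intersect(names(mu)[mu >= cutoff], shared)
  if (length(keep) < 100) stop("fewer than 100 annotated genes retained")
  ann <- ann[match(keep, ann$gene), ]
  chrom_num <- suppressWarnings(as.numeric(sub("^chr", "", ann$chrom)))
  ord <- order(if (anyNA(chrom_num)) ann$chrom else chrom_num, ann$start)
  ann <- ann[ord, ]

  cs <- Matrix::colSums(counts)
  target <- stats::median(cs)
  norm <- counts[ann$gene, , drop = FALSE] %*%
    Matrix::Diagonal(x = target / pmax(cs, 1))
  lg <- log2(as.matrix(norm) + 1)
  dimnames(lg) <- list(ann$gene, colnames(counts))
  ref_mean <- rowMeans(lg[, reference_spots, drop = FALSE])
  centered <- lg - ref_mean

  smoothed <- centered
  for (ch in unique(ann$chrom)) {
    ix <- which(ann$chrom == ch)
    smoothed[ix, ] <- apply(centered[ix, , drop = FALSE], 2, .running_mean,
                            window = window)
  }
  dimnames(smoothed) <- dimnames(centered)
  smoothed <- sweep(smoothed, 2, apply(smoothed, 2, stats::median))
  smoothed <- pmin(pmax(smoothed, -clamp), clamp)
  profile <- t(smoothed)
  score <- rowMeans(profile^2)
  structure(list(profile = profile, cnv_score = score, annotation = ann,
                 reference = colnames(counts)[reference_spots]),
            class = "CnvProfile")
}

#' Call malignant spots from a CNV profile
#'
#' Non-reference spots are partitioned by Ward hierarchical clustering of
#' their CNV profiles into `n_clusters`; a cluster is called malignant
#' when its median CNV score exceeds the reference median plus three
#' reference MADs (falling back to the reference 95th percentile when the
#' MAD is zero).
#'
#' @param profile [infer_cnv()] result.
#' @param n_clusters Number of CNV clusters (default 8).
#' @return List: `labels` (named `"tumor"`/`"non_tumor"` per spot,
#'   reference spots always `"non_tumor"`), `cluster` (id per spot, 0 =
#'   reference), `threshold`, `summary` (per-cluster size, median score,
#'   malignant flag).
#' @export
call_malignant <- function(profile, n_clusters = 8) {
  stopifnot(inherits(profile, "CnvProfile"))
  spots <- rownames(profile$profile)
  is_ref <- spots %in% profile$reference
  ref_scores <- profile$cnv_score[is_ref]
  med <- stats::median(ref_scores)
  mad <- stats::mad(ref_scores)
  if (mad == 0) {
    warning("zero reference MAD; using 95th percentile threshold")
    thr <- stats::quantile(ref_scores, 0.95)
  } else thr <- med + 3 * mad
  other <- which(!is_ref)
  k <- min(n_clusters, length(other))
  hc <- stats::hclust(stats::dist(profile$profile[other, , drop = FALSE]),
                      method = "ward.D2")
  memb <- stats::cutree(hc, k = k)
  cluster <- integer(length(spots))
  cluster[other] <- memb
  names(cluster) <- spots
  summ <- do.call(rbind, lapply(seq_len(k), function(cl) {
    sc <- profile$cnv_score[other][memb == cl]
    data.frame(cluster = cl, n = length(sc),
               median_score = stats::median(sc),
               malignant = stats::median(sc) > thr)
  }))
  labels <- rep("non_tumor", length(spots))
  mal_clusters <- summ$cluster[summ$malignant]
  labels[cluster %in% mal_clusters & !is_ref] <- "tumor"
  names(labels) <- spots
  list(labels = labels, cluster = cluster, threshold = unname(thr),
       summary = summ)
}
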