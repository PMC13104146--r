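# Per-cell stemness scoring: a transcriptional-diversity score (the number
# of expressed genes, propagated through correlated genes and smoothed over
# a cell-similarity graph) and a signature ranking-AUC score (recovery of a
# gene set within each cell's top-ranked genes).

#' Transcriptional-diversity stemness score
#'
#' A simplified transcriptional-diversity score: (1) count genes detected
#' per cell; (2) correlate each gene's log-normalized expression with the
#' per-cell gene counts; (3) average the top `n_corr_genes` most
#' count-correlated genes per cell; (4) smooth over a kNN cell-similarity
#' graph (`score <- alpha * neighbor_mean + (1 - alpha) * initial`,
#' iterated); (5) rank-transform to `[0, 1]`. Higher values indicate lower
#' differentiation (more stem-like cells).
#'
#' @param matrix ExpressionMatrix or genes x cells counts.
#' @param n_corr_genes Genes averaged in step 3 (default 200).
#' @param knn_k Neighbors in the smoothing graph (default 30).
#' @param smooth_alpha Neighbor weight per smoothing iteration.
#' @param smooth_iters Smoothing iterations.
#' @return Named per-cell score in `[0, 1]` (min 0, max 1 unless tied).
#' @export
diversity_score <- function(matrix, n_corr_genes = 200, knn_k = 30,
                            smooth_alpha = 0.7, smooth_iters = 50) {
  counts <- get_counts(matrix)
  if (ncol(counts) < 2) stop("need at least 2 cells")
  ln <- lognorm(counts)  # errors on zero-count cells, naming them
  gene_counts <- Matrix::colSums(counts > 0)

  lnd <- as.matrix(ln)
  sds <- apply(lnd, 1, stats::sd)
  use <- sds > 0
  if (stats::sd(gene_counts) == 0) {
    cors <- rep(0, sum(use))
  } else {
    cors <- suppressWarnings(
      as.vector(stats::cor(t(lnd[use, , drop = FALSE]), gene_counts)))
  }
  names(cors) <- rownames(lnd)[use]
  top <- names(sort(cors, decreasing = TRUE))[
    seq_len(min(n_corr_genes, length(cors)))]
  init <- if (length(top) > 0) colMeans(lnd[top, , drop = FALSE])
          else rep(0, ncol(lnd))

  k <- min(knn_k, ncol(counts) - 1)
  score <- init
  if (k >= 1 && stats::sd(init) > 0) {
    cc <- suppressWarnings(stats::cor(lnd[use, , drop = FALSE]))
    cc[is.na(cc)] <- 0
    diag(cc) <- -Inf
    nn <- apply(cc, 2, function(col) order(col, decreasing = TRUE)[seq_len(k)])
    for (it in seq_len(smooth_iters)) {
      nb_mean <- colMeans(matrix(score[nn], nrow = k))
      score <- smooth_alpha * nb_mean + (1 - smooth_alpha) * init
    }
  }
  r <- rank(score, ties.method = "average")
  out <- (r - 1) / max(ncol(counts) - 1, 1)
  names(out) <- colnames(counts)
  out
}

#' Signature ranking-AUC score (AUCell-style)
#'
#' For each cell, genes are ranked by expression (descending, ties broken
#' by fixed gene order) and the recovery curve of signature genes within
#' the top `ceil(top_frac * n_genes)` ranks is integrated (trapezoidal
#' rule) and normalized by its maximum attainable value, so a signature
#' ranked perfectly at the top scores 1.
#'
#' @param matrix ExpressionMatrix or genes x cells matrix (any monotone
#'   per-cell transformation of expression gives identical scores).
#' @param signature Character vector of genes or a `Signature` object.
#' @param top_frac Fraction of top-ranked genes integrated (default 0.05).
#' @return Named per-cell score in `[0, 1]`.
#' @export
signature_auc <- function(matrix, signature, top_frac = 0.05) {
  counts <- get_counts(matrix)
  genes <- if (inherits(signature, "Signature")) signature$genes
           else as.character(signature)
  if (top_frac <= 0 || top_frac >= 1) stop("top_frac must be in (0, 1)")
  present <- intersect(genes, rownames(counts))
  if (length(present) == 0)
    stop("no signature gene present in matrix; missing: ",
         paste(utils::head(genes, 10), collapse = ", "))
  ng <- nrow(counts)
  thr <- ceiling(top_frac * ng)
  in_sig <- rownames(counts) %in% present
  n_sig <- length(present)
  # maximum trapezoidal area: recovery curve min(x, n_sig) over x = 0..thr
  x <- seq_len(thr)
  max_curve <- pmin(x, n_sig)
  max_area <- sum((c(0, max_curve[-thr]) + max_curve) / 2)
  dense <- as.matrix(counts)
  out <- vapply(seq_len(ncol(dense)), function(j) {
    ord <- order(-dense[, j], seq_len(ng))[x]
    hits <- cumsum(in_sig[ord])
    sum((c(0, hits[-thr]) + hits) / 2) / max_area
  }, numeric(1))
  names(out) <- colnames(counts)
  out
}
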