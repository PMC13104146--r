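# Weighted co-expression analysis on metacells: soft-threshold selection
# against scale-free topology, topological overlap, module detection by
# average-linkage clustering of 1 - TOM, module eigengenes, module-trait
# correlation, malignant-marker testing and signature derivation by
# intersection.

# module naming follows the conventional color order, largest module first
.module_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                    "grey60", "lightgreen", "lightyellow", "royalblue")

#' Co-expression network configuration
#'
#' @param n_top_genes Most-variable genes entering the network.
#' @param powers Candidate soft-threshold powers.
#' @param r2_target Scale-free fit target (default 0.8).
#' @param network_type `"unsigned"` (`|cor|^beta`) or `"signed"`
#'   (`((1+cor)/2)^beta`).
#' @param min_module_size Smallest retained module (default 30).
#' @param cut_height Static tree-cut height on the 1 - TOM dendrogram;
#'   `NULL` = 0.99 of the tree height.
#' @return List of class `NetworkConfig`.
#' @export
network_config <- function(n_top_genes = 5000, powers = 1:20,
                           r2_target = 0.8,
                           network_type = c("unsigned", "signed"),
                           min_module_size = 30, cut_height = NULL) {
  network_type <- match.arg(network_type)
  if (any(powers < 1)) stop("powers must be >= 1")
  structure(list(n_top_genes = as.integer(n_top_genes), powers = powers,
                 r2_target = r2_target, network_type = network_type,
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height),
            class = "NetworkConfig")
}

# adjacency from a gene-gene correlation matrix
.cor_adjacency <- function(C, power, network_type) {
  a <- if (network_type == "signed") ((1 + C) / 2)^power else abs(C)^power
  diag(a) <- 0
  a
}

.scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(c(r2 = NA_real_, slope = NA_real_))
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mk <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(c(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[ok]) ~ log10(mk[ok]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  c(r2 = unname(r2 * ifelse(slope > 0, -1, 1)), slope = unname(slope))
}

#' Pick the soft-thresholding power for scale-free topology
#'
#' For each candidate power, builds the adjacency, computes connectivities
#' `k_i = sum_j a_ij`, and regresses `log10` bin frequency on `log10` mean
#' bin connectivity; the signed fit index is the regression R-squared,
#' negated when the slope is positive. Returns the smallest power whose
#' fit reaches `r2_target`, otherwise the power with the best fit.
#'
#' @param matrix genes x metacells expression matrix (e.g. the
#'   `expression` element of [partition_metacells()]).
#' @param config [network_config()].
#' @return List: `power`, `fit` (one row per candidate power: `power`,
#'   `r2`, `slope`, `mean_k`, `median_k`, `max_k`), `genes` used.
#' @export
pick_soft_threshold <- function(matrix, config = network_config()) {
  X <- as.matrix(matrix)
  v <- apply(X, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant gene rows dropped")
    X <- X[v > 0, , drop = FALSE]
    v <- v[v > 0]
  }
  keep <- order(v, decreasing = TRUE)[seq_len(min(config$n_top_genes,
                                                  nrow(X)))]
  X <- X[sort(keep), , drop = FALSE]
  C <- suppressWarnings(stats::cor(t(X)))
  C[is.na(C)] <- 0
  fit <- do.call(rbind, lapply(config$powers, function(p) {
    a <- .cor_adjacency(C, p, config$network_type)
    k <- rowSums(a)
    sf <- .scale_free_fit(k)
    data.frame(power = p, r2 = sf["r2"], slope = sf["slope"],
               mean_k = mean(k), median_k = stats::median(k),
               max_k = max(k), row.names = NULL)
  }))
  ok <- which(!is.na(fit$r2) & fit$r2 >= config$r2_target)
  power <- if (length(ok) > 0) fit$power[ok[1]]
           else fit$power[which.max(fit$r2)]
  list(power = power, fit = fit, genes = rownames(X))
}

#' Build a soft-thresholded adjacency matrix
#'
#' @param matrix genes x metacells expression matrix.
#' @param power Soft-threshold power.
#' @param network_type `"unsigned"` or `"signed"`.
#' @return genes x genes adjacency in `[0, 1]`, zero diagonal.
#' @export
coexpression_adjacency <- function(matrix, power,
                                   network_type = c("unsigned", "signed")) {
  network_type <- match.arg(network_type)
  C <- suppressWarnings(stats::cor(t(as.matrix(matrix))))
  C[is.na(C)] <- 0
  a <- .cor_adjacency(C, power, network_type)
  dimnames(a) <- list(rownames(matrix), rownames(matrix))
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal: the similarity of two genes' network neighborhoods.
#'
#' @param adjacency Square symmetric matrix, entries in `[0, 1]`, zero
#'   diagonal.
#' @return TOM matrix of the same dimension.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-10)
    stop("adjacency must be square and symmetric")
  if (any(a < 0) || any(a > 1)) stop("adjacency entries must be in [0, 1]")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage clustering of `1 - TOM` with a static cut; clusters
#' below `min_module_size` are assigned to `grey` (unassigned). Modules
#' are named by size rank using the conventional color aliases (largest =
#' `turquoise`).
#'
#' @param tom TOM matrix from [tom_similarity()], with gene names.
#' @param min_module_size Minimum module size (default 30).
#' @param cut_height Static cut height; `NULL` = 0.99 of the dendrogram
#'   height (tuned on synthetic fixtures).
#' @return List of class `ModuleSet`: `labels` (named gene -> module),
#'   `module_genes` (list per module), `sizes`, `cut_height`.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = NULL) {
  tom <- as.matrix(tom)
  stopifnot(!is.null(rownames(tom)))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  if (is.null(cut_height)) cut_height <- 0.99 * max(hc$height)
  memb <- stats::cutree(hc, h = cut_height)
  sizes <- table(memb)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", nrow(tom))
  names(labels) <- rownames(tom)
  if (length(keep) == 0) {
    warning("all genes unassigned (grey); consider a higher cut or ",
            "smaller min_module_size")
  } else {
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    alias <- c(.module_colors,
               sprintf("module%d", seq_len(max(0, length(keep) -
                                                 length(.module_colors)))))
    for (i in seq_along(keep))
      labels[memb == as.integer(keep[i])] <- alias[i]
  }
  mods <- split(names(labels), labels)
  mods <- mods[order(-vapply(mods, length, 1L))]
  structure(list(labels = labels,
                 module_genes = mods[setdiff(names(mods), "grey")],
                 sizes = vapply(mods, length, 1L),
                 cut_height = cut_height),
            class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  cat(sprintf("ModuleSet: %d genes, %d modules (+%d grey)\n",
              length(x$labels), length(x$module_genes),
              sum(x$labels == "grey")))
  print(x$sizes)
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the standardized module expression across
#' metacells (unit norm), sign-oriented so its correlation with the mean
#' module expression is non-negative.
#'
#' @param matrix genes x metacells expression matrix.
#' @param genes Module gene names (>= 2, present in `matrix`).
#' @return Named per-metacell eigengene vector (unit norm).
#' @export
module_eigengene <- function(matrix, genes) {
  X <- as.matrix(matrix)[genes, , drop = FALSE]
  if (nrow(X) < 2) stop("module must have at least 2 genes")
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) stop("degenerate module: constant gene expression")
  Z <- (X - rowMeans(X)) / sds
  sv <- svd(t(Z), nu = 1, nv = 0)
  eig <- sv$u[, 1]
  m <- colMeans(Z)
  if (stats::cor(eig, m) < 0) eig <- -eig
  names(eig) <- colnames(X)
  eig
}

#' Eigengene matrix for all modules
#'
#' @param matrix genes x metacells expression matrix.
#' @param modules ModuleSet from [detect_modules()].
#' @return metacells x modules matrix of unit-norm eigengenes.
#' @export
module_eigengenes <- function(matrix, modules) {
  stopifnot(inherits(modules, "ModuleSet"))
  out <- vapply(names(modules$module_genes), function(m)
    module_eigengene(matrix, modules$module_genes[[m]]),
    numeric(ncol(matrix)))
  rownames(out) <- colnames(matrix)
  out
}

#' Correlate module eigengenes with a trait
#'
#' Pearson correlation of each eigengene with a per-metacell trait (e.g.
#' mean stemness score), with two-sided t-distribution p-values, sorted by
#' correlation descending.
#'
#' @param eigengenes metacells x modules matrix.
#' @param trait Per-metacell numeric trait.
#' @return data.frame: `module`, `r`, `p`, sorted by `r` descending.
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  E <- as.matrix(eigengenes)
  stopifnot(nrow(E) == length(trait))
  if (stats::sd(trait) == 0) stop("zero-variance trait")
  res <- do.call(rbind, lapply(colnames(E), function(m) {
    ct <- stats::cor.test(E[, m], trait)
    data.frame(module = m, r = unname(ct$estimate), p = ct$p.value)
  }))
  res[order(res$r, decreasing = TRUE), , drop = FALSE]
}

#' Malignant-vs-rest marker genes
#'
#' Per gene: average log fold change
#' `log((mean(expm1(x_malignant)) + 1) / (mean(expm1(x_rest)) + 1))` on
#' log-normalized expression (pseudocount 1), and a Wilcoxon rank-sum
#' p-value (raw by default, matching a plain `p < 0.05` criterion; BH
#' adjustment optional).
#'
#' @param matrix ExpressionMatrix or genes x cells counts.
#' @param labels Logical (TRUE = malignant) or character vector where
#'   `"malignant"` marks the test group.
#' @param lfc_min,p_max Selection thresholds (defaults 0.5 and 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List: `markers` (selected gene names), `table` (gene, lfc, p,
#'   p_adj).
#' @export
malignant_markers <- function(matrix, labels, lfc_min = 0.5, p_max = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  counts <- get_counts(matrix)
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "malignant"
  stopifnot(length(labels) == ncol(counts))
  if (!any(labels) || !any(!labels)) stop("both groups must be non-empty")
  ln <- as.matrix(lognorm(counts))
  g1 <- which(labels); g2 <- which(!labels)
  small <- length(g1) < 3 || length(g2) < 3
  if (small) warning("a group has fewer than 3 cells; p-values set to 1")
  m1 <- rowMeans(expm1(ln[, g1, drop = FALSE]))
  m2 <- rowMeans(expm1(ln[, g2, drop = FALSE]))
  lfc <- log((m1 + 1) / (m2 + 1))
  p <- vapply(seq_len(nrow(ln)), function(i) {
    if (small) return(1)
    mann_whitney(ln[i, g1], ln[i, g2])$p
  }, numeric(1))
  p_adj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  tab <- data.frame(gene = rownames(ln), lfc = lfc, p = p, p_adj = p_adj,
                    row.names = NULL)
  list(markers = tab$gene[tab$lfc > lfc_min & tab$p_adj < p_max],
       table = tab)
}

#' Derive a gene signature by module/marker intersection
#'
#' @param module_genes Genes of the trait-associated module.
#' @param marker_genes Malignant-marker genes.
#' @param name Signature name.
#' @return Object of class `Signature`: list with `name` and sorted unique
#'   `genes`.
#' @export
derive_signature <- function(module_genes, marker_genes, name = "CSC") {
  stopifnot(length(module_genes) > 0, length(marker_genes) > 0)
  genes <- sort(intersect(unique(module_genes), unique(marker_genes)))
  if (length(genes) == 0)
    stop("empty intersection between module and marker genes")
  structure(list(name = name, genes = genes), class = "Signature")
}

#' @export
print.Signature <- function(x, ...) {
  cat(sprintf("Signature '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Derive a CSC signature from a labeled single-cell cohort
#'
#' Convenience wrapper chaining the full discovery pipeline on malignant
#' cells: stemness scoring ([diversity_score()]), metacell aggregation
#' ([build_coclustering()] + [partition_metacells()]), co-expression
#' network and module detection ([pick_soft_threshold()],
#' [tom_similarity()], [detect_modules()]), module-trait correlation, and
#' intersection of the top stemness-correlated module with malignant
#' markers ([malignant_markers()], [derive_signature()]).
#'
#' @param em ExpressionMatrix with a `cell_type` label containing
#'   `"malignant"`.
#' @param mc_config [metacell_config()].
#' @param net_config [network_config()].
#' @param name Signature name.
#' @return List: `signature`, `modules`, `module_trait` (correlation
#'   table), `top_module`, `metacells`, `power`, `stemness` (per-malignant
#'   cell), `markers`.
#' @export
derive_csc_signature <- function(em, mc_config = metacell_config(),
                                 net_config = network_config(),
                                 name = "CSC") {
  stopifnot(inherits(em, "ExpressionMatrix"), !is.null(em$cell_type))
  mal <- em$cell_type == "malignant"
  if (!any(mal)) stop("no malignant cells in em$cell_type")
  mal_counts <- em$counts[, mal, drop = FALSE]
  stem <- diversity_score(mal_counts)
  co <- build_coclustering(mal_counts, mc_config)
  mc <- partition_metacells(co, mc_config$min_size, matrix = mal_counts,
                            trait = stem)
  ps <- pick_soft_threshold(mc$expression, net_config)
  adj <- coexpression_adjacency(mc$expression[ps$genes, , drop = FALSE],
                                ps$power, net_config$network_type)
  tom <- tom_similarity(adj)
  mods <- detect_modules(tom, net_config$min_module_size,
                         net_config$cut_height)
  eig <- module_eigengenes(mc$expression, mods)
  mt <- module_trait_correlation(eig, mc$trait)
  top <- mods$module_genes[[mt$module[1]]]
  mk <- malignant_markers(em, mal)
  sig <- derive_signature(top, mk$markers, name = name)
  list(signature = sig, modules = mods, module_trait = mt,
       top_module = top, metacells = mc, power = ps$power,
       stemness = stem, markers = mk$markers)
}
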