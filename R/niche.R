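# Boundary geometry on the spot lattice and niche statistics:
# core-vs-boundary testing, two-gene co-localization, reference-profile
# deconvolution (NNLS) and CAF-subtype scoring.

#' Build the spot-lattice neighbor graph
#'
#' Hex mode uses the 6-neighbor offset-coordinate rule (odd rows shifted
#' half a spot right, Visium-like); square mode uses 4-neighbor rook
#' adjacency. The graph is undirected.
#'
#' @param grid SpotGrid, or a data.frame with `barcode`, `row`, `col` (then
#'   `lattice` must be given).
#' @param lattice Overrides the grid's lattice type if supplied.
#' @return Object of class `SpotLatticeGraph`: list with `neighbors`
#'   (adjacency list of integer indices), `barcodes`, `lattice`.
#' @export
lattice_adjacency <- function(grid, lattice = NULL) {
  if (inherits(grid, "SpotGrid")) {
    coords <- grid$coords
    if (is.null(lattice)) lattice <- grid$lattice
  } else {
    coords <- grid
    stopifnot(!is.null(lattice))
  }
  lattice_adjacency_coords(coords, lattice)
}

lattice_adjacency_coords <- function(coords, lattice) {
  stopifnot(all(c("barcode", "row", "col") %in% names(coords)))
  if (anyDuplicated(coords[, c("row", "col")]))
    stop("duplicate spot coordinates")
  key <- paste(coords$row, coords$col)
  idx <- stats::setNames(seq_len(nrow(coords)), key)
  offs <- function(r) {
    if (lattice == "square") {
      cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
    } else if (r %% 2 == 0) {  # even row, shifted left
      cbind(dr = c(0, 0, -1, -1, 1, 1), dc = c(-1, 1, -1, 0, -1, 0))
    } else {                   # odd row, shifted right
      cbind(dr = c(0, 0, -1, -1, 1, 1), dc = c(-1, 1, 0, 1, 0, 1))
    }
  }
  neighbors <- vector("list", nrow(coords))
  for (i in seq_len(nrow(coords))) {
    o <- offs(coords$row[i])
    nk <- paste(coords$row[i] + o[, "dr"], coords$col[i] + o[, "dc"])
    neighbors[[i]] <- unname(idx[nk[nk %in% names(idx)]])
  }
  structure(list(neighbors = neighbors, barcodes = coords$barcode,
                 lattice = lattice),
            class = "SpotLatticeGraph")
}

# Multi-source BFS: graph distance from every node to the nearest target
# node. Inf where unreachable.
bfs_distance_to_set <- function(graph, targets) {
  n <- length(graph$neighbors)
  dist <- rep(Inf, n)
  if (length(targets) == 0) return(dist)
  dist[targets] <- 0
  frontier <- targets
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(graph$neighbors[frontier]))
    nxt <- nxt[dist[nxt] == Inf]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Split tumor spots into boundary ring and core
#'
#' The boundary is the set of tumor spots within `width` lattice steps
#' (BFS graph distance) of the nearest non-tumor spot; remaining tumor
#' spots form the core. Spots at the section edge are classified using
#' observed spots only: tissue beyond the capture area is unknown and the
#' edge is not treated as non-tumor.
#'
#' @param tumor_labels Logical vector (TRUE = tumor), one per spot, in
#'   graph node order; may be named by barcode.
#' @param graph [lattice_adjacency()] result.
#' @param width Ring width in lattice steps (default 2).
#' @return data.frame of class `NicheLabels`: `barcode`, `region`
#'   (`core` / `boundary` / `non_tumor`), `dist_to_nontumor`.
#' @export
extract_boundary <- function(tumor_labels, graph, width = 2) {
  stopifnot(inherits(graph, "SpotLatticeGraph"),
            length(tumor_labels) == length(graph$neighbors))
  tumor_labels <- as.logical(tumor_labels)
  if (!any(tumor_labels)) stop("no tumor spots")
  out <- data.frame(barcode = graph$barcodes,
                    region = ifelse(tumor_labels, "core", "non_tumor"),
                    dist_to_nontumor = NA_real_,
                    stringsAsFactors = FALSE)
  if (!any(!tumor_labels)) {
    warning("no non-tumor spots: boundary undefined")
    out$region[tumor_labels] <- "undefined"
    class(out) <- c("NicheLabels", "data.frame")
    return(out)
  }
  d <- bfs_distance_to_set(graph, targets = which(!tumor_labels))
  out$dist_to_nontumor <- ifelse(tumor_labels, d, 0)
  out$region[tumor_labels & d <= width] <- "boundary"
  class(out) <- c("NicheLabels", "data.frame")
  out
}

#' Compare expression between tumor boundary and core
#'
#' Two-sided Mann-Whitney U test of boundary vs core values (U oriented to
#' the boundary group), with the boundary-minus-core median difference.
#'
#' @param expr Per-spot numeric values, in the same order as `labels`.
#' @param labels [extract_boundary()] result, or a character vector of
#'   regions containing `"boundary"` and `"core"`.
#' @return List: `U`, `p`, `median_diff`, `n_boundary`, `n_core`.
#' @export
compare_regions <- function(expr, labels) {
  region <- if (is.data.frame(labels)) labels$region else as.character(labels)
  stopifnot(length(expr) == length(region))
  b <- expr[region == "boundary"]
  k <- expr[region == "core"]
  if (length(b) < 3 || length(k) < 3)
    stop("need at least 3 spots in both boundary and core")
  mw <- mann_whitney(b, k)
  list(U = mw$U, p = mw$p,
       median_diff = stats::median(b) - stats::median(k),
       n_boundary = length(b), n_core = length(k))
}

#' Two-gene co-localization classes and double-positive percentage
#'
#' Spots with `exprA > threshold` are A+, similarly B+. The co-localization
#' percentage is double-positive spots as a share of spots positive for
#' either gene: `100 * |A+ and B+| / |A+ or B+|`.
#'
#' @param exprA,exprB Per-spot expression of the two genes (equal length).
#' @param threshold Positivity threshold (default 0, i.e. any expression).
#' @return List: `class` (factor with levels `A+B+`, `A+only`, `B+only`,
#'   `negative`), `percent_AB`, counts `n_AB`, `n_A`, `n_B`.
#' @export
colocalization <- function(exprA, exprB, threshold = 0) {
  stopifnot(length(exprA) == length(exprB))
  a <- exprA > threshold
  b <- exprB > threshold
  if (!any(a | b)) stop("no spots express either gene above threshold")
  cls <- ifelse(a & b, "A+B+", ifelse(a, "A+only",
                                      ifelse(b, "B+only", "negative")))
  cls <- factor(cls, levels = c("A+B+", "A+only", "B+only", "negative"))
  list(class = cls, percent_AB = 100 * sum(a & b) / sum(a | b),
       n_AB = sum(a & b), n_A = sum(a), n_B = sum(b))
}

#' Spot-level correlation between a gene and a score
#'
#' @param exprA,scoreB Per-spot values (equal length, >= 10 spots).
#' @param method `"pearson"` or `"spearman"`.
#' @return List: `r`, `p` (two-sided), `method`, `n`.
#' @export
spot_correlation <- function(exprA, scoreB,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(exprA) == length(scoreB))
  if (length(exprA) < 10) stop("need at least 10 spots")
  if (stats::sd(exprA) == 0 || stats::sd(scoreB) == 0)
    stop("constant vector: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(exprA, scoreB, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, method = method,
       n = length(exprA))
}

# Lawson-Hanson non-negative least squares: minimize ||Ax - b|| s.t. x >= 0
nnls_fit <- function(A, b, tol = 1e-10, max_iter = 10 * ncol(A)) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- qr.coef(qr(Ap), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) break
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Deconvolve spots onto reference cell-type profiles
#'
#' Per-spot non-negative least squares of CPM-normalized spot expression on
#' CPM-normalized type profiles over the shared genes, with proportions
#' renormalized to sum to 1. A simplification of full spatial deconvolution
#' models: no spatial prior is used, and the returned proportions are
#' transcript shares (types with deeper per-cell libraries weigh
#' correspondingly more than their cell-number share).
#'
#' @param grid SpotGrid or ExpressionMatrix of spots.
#' @param profiles genes x types matrix (e.g. [reference_profiles()]).
#' @return spots x types matrix of proportions (rows sum to 1).
#' @export
deconvolve_spots <- function(grid, profiles) {
  counts <- get_counts(grid)
  if (ncol(profiles) < 2) stop("need at least 2 reference types")
  shared <- intersect(rownames(counts), rownames(profiles))
  if (length(shared) < 50)
    stop("profiles share fewer than 50 genes with the spot matrix")
  A <- apply(profiles[shared, , drop = FALSE], 2,
             function(p) p / sum(p) * 1e6)
  if (qr(A)$rank < ncol(A)) stop("rank-deficient profile matrix")
  B <- as.matrix(cpm(counts[shared, , drop = FALSE]))
  out <- t(apply(B, 2, function(b) {
    x <- nnls_fit(A, b)
    if (sum(x) == 0) rep(1 / ncol(A), ncol(A)) else x / sum(x)
  }))
  dimnames(out) <- list(colnames(counts), colnames(profiles))
  out
}

#' Score CAF subtypes per spot
#'
#' Mean log-normalized expression of each subtype's marker set per spot.
#'
#' @param grid SpotGrid or ExpressionMatrix.
#' @param caf_signatures Named list of gene sets (e.g.
#'   [default_caf_signatures()]).
#' @return spots x subtypes matrix of scores.
#' @export
caf_subtype_scores <- function(grid, caf_signatures) {
  ln <- lognorm(grid)
  stopifnot(length(caf_signatures) > 0, !is.null(names(caf_signatures)))
  out <- vapply(names(caf_signatures), function(nm) {
    gs <- intersect(caf_signatures[[nm]], rownames(ln))
    if (length(gs) == 0)
      stop("signature '", nm, "' has no genes present in the matrix")
    Matrix::colMeans(ln[gs, , drop = FALSE])
  }, numeric(ncol(ln)))
  rownames(out) <- colnames(ln)
  out
}
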