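# Ligand-receptor communication between annotated groups: trimmed group
# means, a saturating mass-action (Hill-type) interaction probability,
# a label-permutation null, and pathway / sender-receiver aggregation.

#' Trimmed group means of normalized expression
#'
#' @param matrix ExpressionMatrix or genes x cells counts.
#' @param labels Per-cell group labels.
#' @param trim Fraction trimmed from each tail (default 0.1; 0 gives the
#'   arithmetic mean).
#' @return groups x genes matrix; groups with fewer than 3 cells are
#'   excluded with a warning.
#' @export
group_mean <- function(matrix, labels, trim = 0.1) {
  counts <- get_counts(matrix)
  stopifnot(length(labels) == ncol(counts))
  ln <- as.matrix(lognorm(counts, allow_zero = TRUE))
  tab <- table(labels)
  small <- names(tab)[tab < 3]
  if (length(small) > 0)
    warning("groups with fewer than 3 cells excluded: ",
            paste(small, collapse = ", "))
  groups <- setdiff(names(tab), small)
  if (length(groups) == 0) stop("no group with at least 3 cells")
  out <- t(vapply(groups, function(g)
    apply(ln[, labels == g, drop = FALSE], 1, mean, trim = trim),
    numeric(nrow(ln))))
  rownames(out) <- groups
  out
}

#' Saturating ligand-receptor interaction probability
#'
#' `P = (L * R) / (kh + L * R)`: a Hill-type saturating function of the
#' sender's mean ligand expression and the receiver's mean receptor
#' expression. Multi-subunit complexes are combined upstream by the
#' geometric mean of subunit means, so one absent subunit gives P = 0.
#'
#' @param L,R Non-negative mean expression values (vectorized).
#' @param kh Half-saturation constant (default 0.5).
#' @return Probability in `[0, 1)`.
#' @export
lr_probability <- function(L, R, kh = 0.5) {
  if (any(L < 0) || any(R < 0)) stop("L and R must be non-negative")
  if (kh <= 0) stop("kh must be positive")
  (L * R) / (kh + L * R)
}

# geometric mean of subunit means; a missing gene contributes 0
.complex_value <- function(means_row, subunits) {
  v <- means_row[subunits]
  v[is.na(v)] <- 0
  if (any(v == 0)) return(0)
  exp(mean(log(v)))
}

.pair_probabilities <- function(gm, db, kh) {
  groups <- rownames(gm)
  out <- expand.grid(sender = groups, receiver = groups,
                     idx = seq_len(nrow(db)), stringsAsFactors = FALSE)
  L <- vapply(seq_len(nrow(out)), function(i)
    .complex_value(gm[out$sender[i], ], db$ligand_subunits[[out$idx[i]]]),
    numeric(1))
  R <- vapply(seq_len(nrow(out)), function(i)
    .complex_value(gm[out$receiver[i], ], db$receptor_subunits[[out$idx[i]]]),
    numeric(1))
  data.frame(sender = out$sender, receiver = out$receiver,
             pathway = db$pathway[out$idx], pair = db$pair[out$idx],
             prob = lr_probability(L, R, kh), stringsAsFactors = FALSE)
}

#' Score ligand-receptor communication with a permutation null
#'
#' Computes the Hill-type interaction probability for every
#' (sender, receiver, pair) combination from trimmed group means, then
#' permutes the group labels `n_perm` times; the p-value is the add-one
#' smoothed fraction of permuted probabilities at least as large as the
#' observed one.
#'
#' @param matrix ExpressionMatrix or genes x cells counts.
#' @param labels Per-cell group labels (at least 2 groups of >= 3 cells).
#' @param db `LRDatabase` (default [default_lr_database()]).
#' @param kh Half-saturation constant of [lr_probability()].
#' @param trim Trimmed-mean fraction of [group_mean()].
#' @param n_perm Label permutations (minimum 20).
#' @param seed RNG seed for the permutations.
#' @return List of class `CommResult`: `pairs` (sender, receiver,
#'   pathway, pair, prob, p), `groups`, `n_perm`.
#' @export
score_communication <- function(matrix, labels, db = default_lr_database(),
                                kh = 0.5, trim = 0.1, n_perm = 100,
                                seed = 1L) {
  if (n_perm < 20) stop("n_perm must be at least 20")
  counts <- get_counts(matrix)
  genes <- unique(unlist(c(db$ligand_subunits, db$receptor_subunits)))
  sub <- counts[intersect(rownames(counts), genes), , drop = FALSE]
  # normalize on the full matrix so library sizes are honest, then subset
  ln_full <- lognorm(counts, allow_zero = TRUE)
  ln <- as.matrix(ln_full[intersect(rownames(counts), genes), ,
                          drop = FALSE])
  gm_of <- function(lab) {
    groups <- names(which(table(lab) >= 3))
    t(vapply(groups, function(g)
      apply(ln[, lab == g, drop = FALSE], 1, mean, trim = trim),
      numeric(nrow(ln))))
  }
  gm <- gm_of(labels)
  if (nrow(gm) < 2) stop("need at least 2 groups with >= 3 cells")
  obs <- .pair_probabilities(gm, db, kh)
  set.seed(seed)
  exceed <- numeric(nrow(obs))
  for (b in seq_len(n_perm)) {
    perm <- sample(labels)
    pm <- gm_of(perm)
    pp <- .pair_probabilities(pm, db, kh)
    exceed <- exceed + (pp$prob >= obs$prob)
  }
  obs$p <- (1 + exceed) / (1 + n_perm)
  structure(list(pairs = obs, groups = rownames(gm), n_perm = n_perm),
            class = "CommResult")
}

#' Aggregate communication to pathways and group totals
#'
#' Pairs with permutation p >= `alpha` are zeroed. Pathway strength is the
#' sum of remaining probabilities per pathway; outgoing/incoming totals
#' sum over combinations where a group is sender/receiver.
#'
#' @param comm `CommResult` from [score_communication()].
#' @param alpha Significance threshold (default 0.05).
#' @return List: `pathway_strength` (data.frame sorted by strength),
#'   `outgoing`, `incoming` (named totals per group), `significant`
#'   (filtered pair table).
#' @export
aggregate_communication <- function(comm, alpha = 0.05) {
  stopifnot(inherits(comm, "CommResult"))
  df <- comm$pairs
  df$prob_sig <- ifelse(df$p < alpha, df$prob, 0)
  ps <- stats::aggregate(prob_sig ~ pathway, df, sum)
  names(ps)[2] <- "strength"
  ps <- ps[order(ps$strength, decreasing = TRUE), , drop = FALSE]
  rownames(ps) <- NULL
  outg <- vapply(comm$groups, function(g)
    sum(df$prob_sig[df$sender == g]), numeric(1))
  inc <- vapply(comm$groups, function(g)
    sum(df$prob_sig[df$receiver == g]), numeric(1))
  list(pathway_strength = ps, outgoing = outg, incoming = inc,
       significant = df[df$prob_sig > 0, setdiff(names(df), "prob_sig")])
}
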