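make_two_pop_grid <- function(n_per = 60, seed = 17) {
  set.seed(seed)
  mu1 <- c(rep(20, 25), rep(1, 25))
  mu2 <- c(rep(1, 25), rep(20, 25))
  m <- cbind(matrix(rpois(50 * n_per, mu1), 50),
             matrix(rpois(50 * n_per, mu2), 50))
  dimnames(m) <- list(sprintf("g%02d", 1:50),
                      sprintf("s%03d", seq_len(2 * n_per)))
  truth <- rep(1:2, each = n_per)
  list(em = expression_matrix(m), truth = truth)
}

test_that("cluster_spots recovers planted populations deterministically", {
  tp <- make_two_pop_grid()
  # low resolution: recover the two macro-populations rather than
  # sub-structure
  cl <- cluster_spots(tp$em, n_pcs = 10, knn_k = 10, resolution = 0.2,
                      seed = 4)
  expect_gte(length(unique(cl)), 2)
  expect_gte(adjusted_rand_index(cl, tp$truth), 0.9)
  expect_identical(cl, cluster_spots(tp$em, n_pcs = 10, knn_k = 10,
                                     resolution = 0.2, seed = 4))
  # resolution 0 collapses a connected graph to a single cluster
  one_pop <- expression_matrix(fx_toy_matrix(50, 60, seed = 44))
  cl0 <- cluster_spots(one_pop, n_pcs = 10, knn_k = 10, resolution = 0,
                       seed = 4)
  expect_equal(length(unique(cl0)), 1)
  expect_warning(cluster_spots(tp$em, n_pcs = 500, seed = 1), "reducing")
})

test_that("immune_score and select_reference follow the marker panel", {
  genes <- c("PTPRC", "CD3D", "EPCAM", "other")
  m <- matrix(0, 4, 6, dimnames = list(genes, sprintf("s%d", 1:6)))
  m["EPCAM", 1:3] <- 10
  m["other", ] <- 1
  m[c("PTPRC", "CD3D"), 4:6] <- 10
  sc <- immune_score(expression_matrix(m))
  expect_true(all(sc[4:6] > sc[1:3]))
  expect_equal(select_reference(sc, rep(c(1, 2), each = 3)), 2)
  # all-zero spot scores zero
  m0 <- m; m0[, 2] <- 0
  expect_equal(unname(immune_score(expression_matrix(m0))[2]), 0)
  # uniform expression: tie broken by lowest cluster id
  mu <- matrix(1, 4, 6, dimnames = dimnames(m))
  su <- immune_score(expression_matrix(mu))
  expect_equal(select_reference(su, rep(c(2, 1), each = 3)), 1)
  expect_error(marker_score(expression_matrix(m), c("ZZZ")), "present")
})

make_cnv_fixture <- function(gain = 2, seed = 23) {
  # gain on chr1 = a quarter of the genome, so the per-spot median stays
  # anchored on unaffected chromosomes
  set.seed(seed)
  ng <- 120; ns <- 60
  genes <- sprintf("g%03d", 1:ng)
  ann <- data.frame(gene = genes,
                    chrom = rep(sprintf("chr%d", 1:4), each = ng / 4),
                    start = rep(seq_len(ng / 4) * 1e6, 4))
  mu <- matrix(100, ng, ns)
  tumor <- seq_len(ns) > 30
  mu[ann$chrom == "chr1", tumor] <- 100 * gain
  m <- matrix(rpois(ng * ns, mu), ng,
              dimnames = list(genes, sprintf("s%03d", 1:ns)))
  list(m = m, ann = ann, tumor = tumor, ref = sprintf("s%03d", 1:25))
}

test_that("infer_cnv closed form at window 1 without clamp", {
  fxt <- make_cnv_fixture()
  cnv <- infer_cnv(fxt$m, fxt$ann, fxt$ref, window = 1, clamp = Inf,
                   cutoff = 0.1)
  # oracle: centered log2 ratio minus the per-spot median, no smoothing
  cs <- colSums(fxt$m)
  lg <- log2(t(t(fxt$m) * median(cs) / cs) + 1)
  centered <- lg - rowMeans(lg[, match(fxt$ref, colnames(fxt$m))])
  want <- t(centered) - apply(centered, 2, median)
  expect_equal(cnv$profile, want[rownames(cnv$profile),
                                 colnames(cnv$profile)],
               tolerance = 1e-12)
})

test_that("infer_cnv detects the planted gain and is order-invariant", {
  fxt <- make_cnv_fixture()
  cnv <- infer_cnv(fxt$m, fxt$ann, fxt$ref, window = 31)
  chr1 <- cnv$annotation$gene[cnv$annotation$chrom == "chr1"]
  chr2 <- cnv$annotation$gene[cnv$annotation$chrom == "chr2"]
  expect_gt(mean(cnv$profile[fxt$tumor, chr1]), 0.1)
  expect_lt(abs(mean(cnv$profile[fxt$tumor, chr2])), 0.08)
  expect_lt(mean(cnv$cnv_score[fxt$ref]),
            0.1 * mean(cnv$cnv_score[fxt$tumor]))
  expect_true(all(cnv$cnv_score >= 0))

  perm <- sample(nrow(fxt$m))
  cnv2 <- infer_cnv(fxt$m[perm, ], fxt$ann, fxt$ref, window = 31)
  expect_equal(cnv2$profile, cnv$profile)

  expect_error(infer_cnv(fxt$m, fxt$ann, fxt$ref[1:5]), "20 reference")
  bad_ann <- fxt$ann[1:30, ]
  expect_error(infer_cnv(fxt$m, bad_ann, fxt$ref), "50%")
})

test_that("cnv score grows with the planted gain multiplier", {
  scores <- vapply(c(1.5, 2, 3), function(g) {
    fxt <- make_cnv_fixture(gain = g)
    # clamp lifted: the default 0.2 saturates at a 1.5x gain and would
    # mask the monotone response
    cnv <- infer_cnv(fxt$m, fxt$ann, fxt$ref, window = 31, clamp = 2)
    mean(cnv$cnv_score[fxt$tumor])
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("call_malignant separates gain spots and handles null data", {
  fxt <- make_cnv_fixture()
  cnv <- infer_cnv(fxt$m, fxt$ann, fxt$ref, window = 31)
  call <- call_malignant(cnv, n_clusters = 4)
  got <- call$labels == "tumor"
  sens <- mean(got[fxt$tumor])
  spc <- mean(!got[!fxt$tumor])
  expect_gte((sens + spc) / 2, 0.9)

  # reference-like everywhere: no malignant clusters
  set.seed(3)
  m_null <- matrix(rpois(120 * 60, 100), 120,
                   dimnames = dimnames(fxt$m))
  cnv0 <- infer_cnv(m_null, fxt$ann, fxt$ref, window = 31)
  call0 <- call_malignant(cnv0, n_clusters = 4)
  expect_true(all(call0$labels == "non_tumor"))
})
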