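test_that("tom_similarity matches the triple-loop oracle and closed forms", {
  set.seed(7)
  for (rep in 1:10) {
    a <- matrix(runif(36), 6, 6)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    dimnames(a) <- list(letters[1:6], letters[1:6])
    expect_equal(unname(tom_similarity(a)), oracle_tom(a),
                 tolerance = 1e-12)
  }
  ones <- matrix(1, 5, 5) - diag(5)
  dimnames(ones) <- list(letters[1:5], letters[1:5])
  t1 <- tom_similarity(ones)
  expect_true(all(abs(t1[upper.tri(t1)] - 1) < 1e-12))
  zero <- matrix(0, 4, 4)
  expect_true(all(tom_similarity(zero)[upper.tri(zero)] == 0))
  expect_error(tom_similarity(matrix(2, 3, 3)), "\\[0, 1\\]")
})

test_that("adjacency is monotone decreasing in power for |cor| < 1", {
  set.seed(13)
  X <- matrix(rnorm(20 * 12), 20, dimnames = list(sprintf("g%d", 1:20),
                                                  NULL))
  a3 <- coexpression_adjacency(X, 3)
  a7 <- coexpression_adjacency(X, 7)
  off <- upper.tri(a3)
  expect_true(all(a7[off] <= a3[off] + 1e-12))
})

test_that("pick_soft_threshold applies the selection rule", {
  set.seed(21)
  # single-factor structure with heavy-tailed loadings: high connectivity
  # spread, enough for a finite fit table
  w <- (runif(200))^2
  f <- rnorm(40)
  X <- outer(w, f) + matrix(rnorm(200 * 40, sd = 0.3), 200)
  rownames(X) <- sprintf("g%03d", 1:200)
  cfg <- network_config(powers = 1:10)
  ps <- pick_soft_threshold(X, cfg)
  expect_equal(nrow(ps$fit), 10)
  expect_equal(ps$fit$power, 1:10)
  # mean connectivity decreases with power
  expect_true(all(diff(ps$fit$mean_k) < 0))
  # an always-met target selects the smallest power; an unattainable one
  # selects the argmax of the fit
  ps_low <- pick_soft_threshold(X, network_config(powers = 1:10,
                                                  r2_target = -2))
  expect_equal(ps_low$power, 1)
  ps_high <- pick_soft_threshold(X, network_config(powers = 1:10,
                                                   r2_target = 2))
  expect_equal(ps_high$power, ps$fit$power[which.max(ps$fit$r2)])
  # constant rows are dropped with a warning
  X2 <- rbind(X, const = rep(1, 40))
  expect_warning(pick_soft_threshold(X2, cfg), "constant")
})

test_that("detect_modules recovers planted correlated blocks", {
  set.seed(31)
  n_mc <- 30
  f1 <- rnorm(n_mc); f2 <- rnorm(n_mc)
  block <- function(f, n) t(vapply(seq_len(n), function(i)
    f + rnorm(n_mc, sd = 0.3), numeric(n_mc)))
  X <- rbind(block(f1, 50), block(f2, 50),
             matrix(rnorm(100 * n_mc), 100))
  rownames(X) <- c(sprintf("a%02d", 1:50), sprintf("b%02d", 1:50),
                   sprintf("n%03d", 1:100))
  adj <- coexpression_adjacency(X, 6)
  mods <- detect_modules(tom_similarity(adj), min_module_size = 30)
  expect_gte(length(mods$module_genes), 2)
  labs <- mods$labels
  jac <- function(planted, lab) {
    tab <- table(labs[planted])
    best <- names(which.max(tab))
    got <- names(labs)[labs == best]
    length(intersect(got, planted)) / length(union(got, planted))
  }
  expect_gte(jac(sprintf("a%02d", 1:50)), 0.8)
  expect_gte(jac(sprintf("b%02d", 1:50)), 0.8)
  # labels partition the gene set
  expect_setequal(names(labs), rownames(X))
  # impossible min size sends everything to grey
  expect_warning(all_grey <- detect_modules(tom_similarity(adj),
                                            min_module_size = 1000),
                 "grey")
  expect_true(all(all_grey$labels == "grey"))
})

test_that("module_eigengene matches an SVD oracle and is oriented", {
  set.seed(41)
  X <- matrix(rnorm(5 * 12), 5, dimnames = list(sprintf("g%d", 1:5),
                                                sprintf("m%02d", 1:12)))
  eig <- module_eigengene(X, rownames(X))
  Z <- t(scale(t(X)))
  sv <- svd(t(Z))
  want <- sv$u[, 1]
  if (cor(want, colMeans(Z)) < 0) want <- -want
  expect_equal(unname(eig), want, tolerance = 1e-9)
  expect_equal(sum(eig^2), 1, tolerance = 1e-9)
  expect_gte(cor(eig, colMeans(Z)), 0)

  # identical genes: eigengene proportional to the shared profile
  X2 <- rbind(a = X[1, ], b = X[1, ], c = X[1, ])
  eig2 <- module_eigengene(X2, c("a", "b", "c"))
  expect_equal(abs(cor(eig2, X[1, ])), 1, tolerance = 1e-9)
  expect_error(module_eigengene(X, "g1"), "2 genes")
  X3 <- X; X3[2, ] <- 5
  expect_error(module_eigengene(X3, rownames(X3)), "degenerate")
})

test_that("module_trait_correlation orders by r and flags degenerate traits", {
  set.seed(51)
  E <- matrix(rnorm(30 * 3), 30, dimnames = list(NULL, c("x", "y", "z")))
  mt <- module_trait_correlation(E, E[, "y"])
  expect_equal(mt$module[1], "y")
  expect_equal(mt$r[1], 1, tolerance = 1e-12)
  expect_lt(mt$p[1], 1e-20)
  expect_true(all(diff(mt$r) <= 0))
  expect_equal(unname(cor(c(1, 2, 3), c(3, 2, 1))), -1)
  expect_error(module_trait_correlation(E, rep(1, 30)), "zero-variance")

  # independent noise stays weak at n = 100
  E2 <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "m"))
  rs <- vapply(1:50, function(i) {
    set.seed(i)
    module_trait_correlation(E2, rnorm(100))$r[1]
  }, numeric(1))
  expect_lt(mean(abs(rs) >= 0.3), 0.05)
})

test_that("malignant_markers selects planted shifts and not flat genes", {
  set.seed(61)
  n <- 200
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  m <- matrix(rpois(6 * n, 2), 6, n,
              dimnames = list(c("up4x", "flat", "exclusive", "down",
                                "weak", "noise"),
                              sprintf("c%03d", 1:n)))
  m["up4x", lab] <- rpois(n / 2, 8)
  m["exclusive", ] <- ifelse(lab, rpois(n, 5), 0)
  m["down", lab] <- 0
  mk <- malignant_markers(m, lab)
  expect_true(all(c("up4x", "exclusive") %in% mk$markers))
  expect_false("flat" %in% mk$markers)
  expect_false("down" %in% mk$markers)
  expect_error(malignant_markers(m, rep(TRUE, n)), "non-empty")
  expect_warning(malignant_markers(m[, 1:5], c(TRUE, TRUE, rep(FALSE, 3))),
                 "fewer than 3")
})

test_that("derive_signature intersects and rejects disjoint sets", {
  sig <- derive_signature(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(sig$genes, c("B", "C"))
  expect_error(derive_signature(c("A"), c("B")), "empty intersection")
  expect_error(derive_signature(character(0), "B"))
})
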