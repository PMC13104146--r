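square_graph <- function(nr, nc) {
  co <- expand.grid(row = seq_len(nr) - 1, col = seq_len(nc) - 1)
  co$barcode <- sprintf("s%03d", seq_len(nrow(co)))
  lattice_adjacency(co, "square")
}

hex_graph <- function(nr, nc) {
  co <- expand.grid(row = seq_len(nr) - 1, col = seq_len(nc) - 1)
  co$barcode <- sprintf("s%03d", seq_len(nrow(co)))
  lattice_adjacency(co, "hex")
}

test_that("lattice adjacency has the right degrees and is symmetric", {
  gs <- square_graph(5, 5)
  deg <- lengths(gs$neighbors)
  expect_equal(sort(unique(deg)), c(2, 3, 4))
  expect_equal(sum(deg == 2), 4)             # corners
  gh <- hex_graph(7, 7)
  degh <- lengths(gh$neighbors)
  expect_equal(max(degh), 6)
  interior <- degh == 6
  expect_gt(sum(interior), 0)
  # symmetry: i in neighbors(j) <=> j in neighbors(i)
  for (g in list(gs, gh)) {
    for (i in seq_along(g$neighbors))
      for (j in g$neighbors[[i]])
        expect_true(i %in% g$neighbors[[j]])
  }
  co_dup <- data.frame(barcode = c("a", "b"), row = c(0, 0), col = c(0, 0))
  expect_error(lattice_adjacency(co_dup, "square"), "duplicate")
})

test_that("extract_boundary matches the brute-force BFS oracle", {
  set.seed(77)
  for (rep in 1:6) {
    nr <- sample(5:12, 1); nc <- sample(5:12, 1)
    lattice <- sample(c("square", "hex"), 1)
    g <- if (lattice == "square") square_graph(nr, nc) else hex_graph(nr, nc)
    tumor <- runif(nr * nc) < 0.4
    if (!any(tumor)) tumor[1] <- TRUE
    if (!any(!tumor)) tumor[2] <- FALSE
    w <- sample(0:3, 1)
    nl <- extract_boundary(tumor, g, width = w)
    expect_identical(nl$region, oracle_boundary(tumor, g, w))
  }
})

test_that("boundary geometry: 7x7 block, single spot, degenerate cases", {
  g <- square_graph(11, 11)
  co <- expand.grid(row = 0:10, col = 0:10)
  tumor <- co$row >= 2 & co$row <= 8 & co$col >= 2 & co$col <= 8
  nl <- extract_boundary(tumor, g, width = 2)
  expect_equal(sum(nl$region == "boundary"), 40)
  expect_equal(sum(nl$region == "core"), 9)
  nl0 <- extract_boundary(tumor, g, width = 0)
  expect_equal(sum(nl0$region == "boundary"), 0)

  single <- rep(FALSE, 121); single[60] <- TRUE
  nls <- extract_boundary(single, g, width = 2)
  expect_equal(sum(nls$region == "boundary"), 1)
  expect_equal(sum(nls$region == "core"), 0)

  expect_error(extract_boundary(rep(FALSE, 121), g), "no tumor")
  expect_warning(nlu <- extract_boundary(rep(TRUE, 121), g), "undefined")
  expect_true(all(nlu$region == "undefined"))
})

test_that("compare_regions tests boundary vs core with sign symmetry", {
  set.seed(5)
  region <- rep(c("boundary", "core"), each = 40)
  x <- c(rnorm(40, 3), rnorm(40, 0))
  cr <- compare_regions(x, region)
  expect_lt(cr$p, 0.01)
  expect_gt(cr$median_diff, 0)
  flipped <- ifelse(region == "boundary", "core", "boundary")
  cr2 <- compare_regions(x, flipped)
  expect_equal(cr2$median_diff, -cr$median_diff)
  expect_error(compare_regions(x[1:41], region[1:41]), "3 spots")
})

test_that("compare_regions holds its size under the null", {
  ps <- vapply(1:200, function(i) {
    set.seed(3000 + i)
    compare_regions(rnorm(60), rep(c("boundary", "core"), each = 30))$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.90)
})

test_that("colocalization counts classes and percent correctly", {
  a <- c(1, 1, 1, 1, 0, 0)
  b <- c(1, 1, 1, 0, 1, 0)
  cl <- colocalization(a, b)
  expect_equal(cl$percent_AB, 60)
  expect_equal(as.vector(table(cl$class)), c(3, 1, 1, 1))
  expect_equal(colocalization(a, a)$percent_AB, 100)
  expect_error(colocalization(c(0, 0), c(0, 0)), "no spots")
  # invariant to monotone positive rescaling at threshold 0
  expect_equal(colocalization(a * 7.3, b * 0.2)$percent_AB, 60)
})

test_that("colocalization recovers a planted fraction on 2000 spots", {
  set.seed(9)
  n <- 2000
  cls <- sample(c("AB", "A", "B"), n, replace = TRUE,
                prob = c(0.8, 0.1, 0.1))
  a <- ifelse(cls %in% c("AB", "A"), rpois(n, 2) + 1, 0)
  b <- ifelse(cls %in% c("AB", "B"), rpois(n, 2) + 1, 0)
  got <- colocalization(a, b)$percent_AB
  expect_lt(abs(got - 80), 5)
})

test_that("spot_correlation handles both methods and degenerate input", {
  x <- rnorm(50)
  expect_equal(spot_correlation(x, x)$r, 1, tolerance = 1e-12)
  expect_equal(spot_correlation(x, exp(x), "spearman")$r, 1,
               tolerance = 1e-12)
  expect_error(spot_correlation(x, rep(1, 50)), "constant")
  expect_error(spot_correlation(x[1:5], x[1:5]), "10 spots")
  rs <- vapply(1:100, function(i) {
    set.seed(4000 + i)
    spot_correlation(rnorm(500), rnorm(500))$r
  }, numeric(1))
  expect_lt(mean(abs(rs) >= 0.15), 0.01)
})

test_that("NNLS deconvolution recovers pure spots and mixtures", {
  set.seed(15)
  prof <- matrix(rlnorm(60 * 3, 1, 1), 60,
                 dimnames = list(sprintf("g%02d", 1:60), c("t1", "t2", "t3")))
  pure <- prof[, 2, drop = FALSE] * 17
  colnames(pure) <- "spot1"
  dec <- deconvolve_spots(pure, prof)
  expect_equal(unname(dec["spot1", "t2"]), 1, tolerance = 1e-6)
  expect_true(all(abs(rowSums(dec) - 1) < 1e-9))

  # 50/50 mixture of depth-matched profiles (proportions are transcript
  # shares; equal totals make transcript share equal cell share)
  eq <- sweep(prof, 2, colSums(prof), "/") * 1e4
  mix <- 0.5 * eq[, 1] + 0.5 * eq[, 3]
  mixm <- matrix(mix, ncol = 1, dimnames = list(rownames(prof), "mix"))
  dm <- deconvolve_spots(mixm, prof)
  expect_equal(unname(dm["mix", c("t1", "t3")]), c(0.5, 0.5),
               tolerance = 0.01)

  expect_error(deconvolve_spots(pure, prof[1:10, ]), "50 genes")
  bad <- cbind(prof, t4 = prof[, 1])
  expect_error(deconvolve_spots(pure, bad), "rank-deficient")
})

test_that("caf_subtype_scores scores shipped signatures per spot", {
  sigs <- default_caf_signatures()
  expect_setequal(names(sigs), c("myCAF", "iCAF", "apCAF", "vCAF",
                                 "mesCAF", "adipoCAF"))
  m <- fx_toy_matrix(10, 5)
  rownames(m)[1] <- "FAP"
  one <- caf_subtype_scores(m, list(solo = "FAP"))
  expect_equal(unname(one[, "solo"]),
               unname(as.vector(lognorm(m)["FAP", ])))
  expect_error(caf_subtype_scores(m, list(none = "ZZZ")), "present")
})
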