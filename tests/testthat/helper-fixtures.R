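# Shared fixtures, built once per test run and cached. Expensive
# simulations are scaled down relative to the generator defaults (fewer
# bootstrap iterations, smaller metacell floor) to stay inside the test
# budget; the scaling is noted where it happens.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) {
    t0 <- Sys.time()
    assign(name, builder(), envir = .fx_cache)
    tm <- get0(".timings", envir = .fx_cache, ifnotfound = numeric(0))
    tm[name] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    assign(".timings", tm, envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

fx_timings <- function() get0(".timings", envir = .fx_cache,
                              ifnotfound = numeric(0))

# default single-cell cohort (2000 cells, 1500 genes, 50-gene module)
fx_sc <- function() fx("sc", function() simulate_sc_cohort(sc_sim_config(seed = 1L)))

# run-scale metacell configuration for the 2000-cell cohort: n_boot 100
# (down from 500) and min_size 25 (down from 50) so that a 1000-cell
# malignant compartment yields enough metacells for network estimation
fx_mc_config <- function(seed = 1L)
  metacell_config(n_boot = 100, min_size = 25, seed = seed)

# full signature-discovery pipeline on the default cohort
fx_pipeline <- function() fx("pipeline", function() {
  derive_csc_signature(fx_sc()$em, mc_config = fx_mc_config())
})

# default spatial section built from the cohort's reference profiles
fx_spatial <- function() fx("spatial", function() {
  sc <- fx_sc()
  prof <- reference_profiles(sc$em)
  ann <- simulate_gene_annotation(rownames(prof), sc$truth$special_genes)
  sim <- simulate_visium_section(spatial_sim_config(seed = 1L), prof, ann)
  c(sim, list(profiles = prof))
})

# spatial malignancy calling chain on the default section
fx_cnv <- function() fx("cnv", function() {
  sp <- fx_spatial()
  cl <- cluster_spots(sp$grid, seed = 1L)
  isc <- immune_score(sp$grid)
  ref_cl <- select_reference(isc, cl)
  ref_spots <- names(cl)[cl == ref_cl]
  cnv <- infer_cnv(sp$grid, sp$annotation, ref_spots)
  call <- call_malignant(cnv)
  list(clusters = cl, reference = ref_spots, cnv = cnv, call = call)
})

# tiny deterministic counts matrix with named genes
fx_toy_matrix <- function(n_genes = 20, n_cells = 10, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 3), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_cells))))
  m
}

# brute-force trapezoidal recovery-curve AUC: the independent oracle for
# signature_auc, written as an explicit loop
oracle_signature_auc <- function(expr, gene_names, sig_genes, top_frac) {
  ng <- length(expr)
  thr <- ceiling(top_frac * ng)
  ord <- order(-expr, seq_len(ng))
  n_sig <- length(intersect(sig_genes, gene_names))
  curve <- numeric(thr + 1)  # curve[x + 1] = hits among top x
  for (x in seq_len(thr))
    curve[x + 1] <- sum(gene_names[ord[seq_len(x)]] %in% sig_genes)
  area <- 0
  for (x in seq_len(thr))
    area <- area + (curve[x] + curve[x + 1]) / 2
  max_area <- 0
  for (x in seq_len(thr))
    max_area <- max_area + (min(x - 1, n_sig) + min(x, n_sig)) / 2
  area / max_area
}

# brute-force TOM by explicit triple loop
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) s <- s + a[i, u] * a[u, j]
    out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# brute-force boundary labels: all-pairs BFS distances via repeated
# single-source searches over the adjacency list
oracle_boundary <- function(tumor, graph, width) {
  n <- length(tumor)
  region <- ifelse(tumor, "core", "non_tumor")
  for (i in which(tumor)) {
    # single-source BFS from spot i
    dist <- rep(Inf, n)
    dist[i] <- 0
    frontier <- i
    while (length(frontier) > 0 && !any(!tumor & is.finite(dist))) {
      nxt <- setdiff(unique(unlist(graph$neighbors[frontier])),
                     which(is.finite(dist)))
      dist[nxt] <- min(dist[frontier]) + 1
      frontier <- nxt
    }
    d <- min(dist[!tumor])
    if (is.finite(d) && d <= width) region[i] <- "boundary"
  }
  region
}

# adjusted Rand index for cluster-recovery checks
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
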