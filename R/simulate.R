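# Synthetic-data generators: single-cell cohorts with a planted continuous
# stemness trait and co-expressed stemness module, Visium-like spatial
# sections with a contiguous tumor region / chromosome gains / a planted
# boundary niche, and survival tables with a biomarker-dependent hazard.
# Every generator returns ground truth alongside the data and is
# deterministic under its seed.

# Canonical marker blocks used by the generator (standard NSCLC cell-type
# markers). Communication genes (MDK, NCL, ...) are planted so that the
# myCAF -> CSC MDK-NCL axis dominates ligand-receptor scoring.
.sim_markers <- list(
  epithelial  = c("EPCAM", "KRT8", "KRT19"),
  fibroblast  = c("COL1A1", "COL1A2", "DCN", "FAP", "ACTA2", "POSTN",
                  "MMP9", "MMP12"),
  endothelial = c("PLVAP", "VWF", "PECAM1"),
  t_cell      = c("CD3D", "CD3E", "TRAC", "CD2", "CD3G"),
  b_cell      = c("MS4A1", "CD79A", "CD79B"),
  myeloid     = c("CD14", "CD163", "CD68", "FCGR3A")
)
.sim_pan_immune <- "PTPRC"
# malignant-biased accessory genes: gene -> mean in malignant cells
.sim_malignant_extra <- c(NCL = 4, SPP1 = 3, CD44 = 2, ITGAV = 1.5,
                          ITGB1 = 1.5, SDC1 = 0.8, SDC2 = 0.8,
                          PTPRZ1 = 0.8, ITGA6 = 0.8)
.sim_mdk_fibroblast_mean <- 5
# non-myCAF CAF-subtype markers: present at background level so subtype
# scoring is exercised end-to-end (myCAF markers live in the fibroblast
# block)
.sim_caf_extra <- c("IL6", "CXCL12", "CXCL14", "PDGFRA", "CD74", "HLA-DRA",
                    "HLA-DRB1", "RGS5", "NOTCH3", "PDGFRB", "MSLN", "UPK3B",
                    "CALB2", "APOD", "CFD", "PLIN2")
.sim_marker_mean <- 3
.sim_background_mean <- 0.05
.sim_module_base <- 0.6

#' Single-cell simulation configuration
#'
#' @param n_cells,n_genes,n_samples Cohort dimensions.
#' @param frac_malignant Fraction of cells that are malignant (in `[0, 1)`).
#' @param module_size Number of planted stemness-module genes (the first is
#'   named `DSG2`).
#' @param stemness_effect Log-fold range of module-gene means across the
#'   stemness trait (means scale with `exp(stemness_effect * s)`).
#' @param diversity_effect Fractional drop in per-cell detection
#'   probability from the most stem-like (`s = 1`) to the most
#'   differentiated (`s = 0`) malignant cell.
#' @param sample_shift_sd SD of patient-specific log-normal expression
#'   shifts applied to malignant cells only.
#' @param nb_dispersion Negative-binomial size parameter.
#' @param seed Integer RNG seed.
#' @return List of class `ScSimConfig`.
#' @export
sc_sim_config <- function(n_cells = 2000, n_genes = 1500, n_samples = 5,
                          frac_malignant = 0.5, module_size = 50,
                          stemness_effect = 2, diversity_effect = 0.3,
                          sample_shift_sd = 0.3, nb_dispersion = 2,
                          seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              frac_malignant = frac_malignant, module_size = as.integer(module_size),
              stemness_effect = stemness_effect,
              diversity_effect = diversity_effect,
              sample_shift_sd = sample_shift_sd,
              nb_dispersion = nb_dispersion, seed = as.integer(seed))
  if (cfg$n_cells < 1 || cfg$n_genes < 1 || cfg$n_samples < 1)
    stop("invalid config: counts must be positive")
  if (cfg$frac_malignant < 0 || cfg$frac_malignant >= 1)
    stop("invalid config: frac_malignant must be in [0, 1)")
  if (cfg$diversity_effect < 0 || cfg$diversity_effect >= 1)
    stop("invalid config: diversity_effect must be in [0, 1)")
  if (cfg$module_size > cfg$n_genes)
    stop("invalid config: module_size > n_genes")
  if (cfg$stemness_effect < 0 || cfg$nb_dispersion <= 0)
    stop("invalid config: effects must be non-negative, dispersion positive")
  class(cfg) <- "ScSimConfig"
  cfg
}

.sim_gene_universe <- function(cfg) {
  module_genes <- c("DSG2",
                    if (cfg$module_size > 1)
                      sprintf("STM%03d", seq_len(cfg$module_size - 1) + 1))
  special <- unique(c(unlist(.sim_markers), .sim_pan_immune, "MDK",
                      names(.sim_malignant_extra), .sim_caf_extra,
                      module_genes))
  if (length(special) > cfg$n_genes)
    stop("invalid config: n_genes too small for marker blocks plus module ",
         "(need at least ", length(special), ")")
  n_fill <- cfg$n_genes - length(special)
  fillers <- if (n_fill > 0) sprintf("G%04d", seq_len(n_fill)) else character(0)
  list(genes = c(special, fillers), module_genes = module_genes,
       special = special, fillers = fillers)
}

#' Simulate a single-cell cohort with planted stemness structure
#'
#' Generates negative-binomial counts for a mixed cohort: malignant cells
#' carry a latent stemness trait `s ~ Uniform(0, 1)` that (i) scales the
#' means of a planted co-expressed gene module by
#' `exp(stemness_effect * s)` and (ii) raises per-cell detection
#' probability (binomial thinning with probability
#' `1 - diversity_effect * (1 - s)`), so stem-like cells express more
#' genes. Non-malignant cells fall into six types with fixed marker
#' blocks; malignant cells additionally receive patient-specific
#' log-normal expression shifts.
#'
#' @param config [sc_sim_config()].
#' @return List with elements `em` ([expression_matrix()]) and `truth`
#'   (class `GroundTruth`: `stemness` (named, malignant cells only),
#'   `module_genes`, `cell_type`, `sample_id`, `special_genes`, `config`).
#' @export
simulate_sc_cohort <- function(config) {
  stopifnot(inherits(config, "ScSimConfig"))
  cfg <- config
  set.seed(cfg$seed)
  uni <- .sim_gene_universe(cfg)
  genes <- uni$genes
  ng <- length(genes); nc <- cfg$n_cells

  n_mal <- round(cfg$frac_malignant * nc)
  types <- c("malignant", names(.sim_markers))
  other <- rep(names(.sim_markers), length.out = nc - n_mal)
  cell_type <- c(rep("malignant", n_mal), other)
  sample_id <- sprintf("P%02d", sample.int(cfg$n_samples, nc, replace = TRUE))
  stemness <- if (n_mal > 0) stats::runif(n_mal) else numeric(0)

  # gene-level baseline means, log-normal
  base <- stats::rlnorm(ng, meanlog = log(0.3), sdlog = 0.8)
  names(base) <- genes
  # type-specific mean matrix genes x types
  mu_type <- matrix(rep(base, length(types)), nrow = ng,
                    dimnames = list(genes, types))
  for (ty in names(.sim_markers)) {
    mu_type[.sim_markers[[ty]], ] <- .sim_background_mean
    mu_type[.sim_markers[[ty]], ty] <- .sim_marker_mean
  }
  mu_type[.sim_pan_immune, ] <- .sim_background_mean
  mu_type[.sim_pan_immune, c("t_cell", "b_cell", "myeloid")] <- .sim_marker_mean
  mu_type["MDK", ] <- 0.1
  mu_type["MDK", "fibroblast"] <- .sim_mdk_fibroblast_mean
  mu_type["MDK", "malignant"] <- 0.5
  mu_type[names(.sim_malignant_extra), ] <- 0.1
  mu_type[names(.sim_malignant_extra), "malignant"] <- .sim_malignant_extra
  # malignant cells are epithelial-derived
  mu_type[.sim_markers$epithelial, "malignant"] <- .sim_marker_mean
  # planted module: malignant-specific, scaled below per cell
  mu_type[uni$module_genes, ] <- 0.02
  mu_type[uni$module_genes, "malignant"] <- .sim_module_base

  mu <- mu_type[, cell_type, drop = FALSE]
  if (n_mal > 0) {
    # stemness scaling of the planted module
    mu[uni$module_genes, seq_len(n_mal)] <-
      mu[uni$module_genes, seq_len(n_mal), drop = FALSE] *
      rep(exp(cfg$stemness_effect * stemness), each = length(uni$module_genes))
    # patient-specific log-normal shifts, malignant cells only
    shifts <- matrix(stats::rnorm(ng * cfg$n_samples, 0, cfg$sample_shift_sd),
                     nrow = ng,
                     dimnames = list(genes, sprintf("P%02d", seq_len(cfg$n_samples))))
    mu[, seq_len(n_mal)] <- mu[, seq_len(n_mal), drop = FALSE] *
      exp(shifts[, sample_id[seq_len(n_mal)], drop = FALSE])
  }

  counts <- matrix(stats::rnbinom(ng * nc, size = cfg$nb_dispersion, mu = mu),
                   nrow = ng)
  if (n_mal > 0 && cfg$diversity_effect > 0) {
    # stem-like cells detect more of their transcripts
    p_det <- 1 - cfg$diversity_effect * (1 - stemness)
    block <- counts[, seq_len(n_mal), drop = FALSE]
    thinned <- stats::rbinom(length(block), size = as.vector(block),
                             prob = rep(p_det, each = ng))
    counts[, seq_len(n_mal)] <- thinned
  }
  barcodes <- sprintf("C%05d", seq_len(nc))
  dimnames(counts) <- list(genes, barcodes)
  names(cell_type) <- names(sample_id) <- barcodes
  if (n_mal > 0) names(stemness) <- barcodes[seq_len(n_mal)]

  em <- expression_matrix(counts, cell_type = cell_type,
                          sample_id = sample_id)
  truth <- structure(list(stemness = stemness,
                          module_genes = uni$module_genes,
                          cell_type = cell_type, sample_id = sample_id,
                          special_genes = uni$special, config = cfg),
                     class = "GroundTruth")
  list(em = em, truth = truth)
}

#' Mean expression profiles per cell type
#'
#' Arithmetic mean of raw counts per gene within each label group; the
#' reference profiles consumed by [simulate_visium_section()] and
#' [deconvolve_spots()].
#'
#' @param em ExpressionMatrix (or matrix).
#' @param labels Per-cell labels; defaults to `em$cell_type`.
#' @return genes x types dense matrix of per-cell mean counts.
#' @export
reference_profiles <- function(em, labels = NULL) {
  counts <- get_counts(em)
  if (is.null(labels) && inherits(em, "ExpressionMatrix"))
    labels <- em$cell_type
  stopifnot(!is.null(labels), length(labels) == ncol(counts))
  groups <- sort(unique(labels))
  out <- vapply(groups, function(g)
    Matrix::rowMeans(counts[, labels == g, drop = FALSE]),
    numeric(nrow(counts)))
  rownames(out) <- rownames(counts)
  out
}

#' Assign genes to synthetic genomic positions
#'
#' Splits the gene universe into `n_chrom` equal-size chromosomes in gene
#' order, except that genes listed in `spread_genes` (cell-type markers and
#' other genes with strong composition signal) are distributed evenly
#' across chromosomes 2..`n_chrom` so that no chromosome carries a
#' contiguous block of composition-driven expression differences;
#' chromosome 1 holds only unlisted (type-neutral) genes and is the
#' default target of planted copy-number gains.
#'
#' @param genes Character vector of gene names.
#' @param spread_genes Genes to interleave across chromosomes 2+.
#' @param n_chrom Number of chromosomes.
#' @return data.frame `gene`, `chrom` (`"chr1"`...), `start` (bp).
#' @export
simulate_gene_annotation <- function(genes, spread_genes = character(0),
                                     n_chrom = 10) {
  stopifnot(!anyDuplicated(genes), n_chrom >= 2)
  spread_genes <- intersect(spread_genes, genes)
  neutral <- setdiff(genes, spread_genes)
  sizes <- rep(length(genes) %/% n_chrom, n_chrom)
  sizes[seq_len(length(genes) %% n_chrom)] <-
    sizes[seq_len(length(genes) %% n_chrom)] + 1
  if (length(neutral) < sizes[1])
    stop("not enough type-neutral genes to fill chromosome 1")
  chr1 <- neutral[seq_len(sizes[1])]
  rest_neutral <- neutral[-seq_len(sizes[1])]
  n_rest <- length(genes) - sizes[1]
  order_rest <- character(n_rest)
  if (length(spread_genes) > 0) {
    slots <- unique(round(seq(1, n_rest, length.out = length(spread_genes))))
    # guard against collisions when spread genes outnumber slots
    while (length(slots) < length(spread_genes))
      slots <- sort(unique(c(slots, setdiff(seq_len(n_rest), slots)[1])))
    order_rest[slots] <- spread_genes
    order_rest[setdiff(seq_len(n_rest), slots)] <- rest_neutral
  } else order_rest <- rest_neutral
  full <- c(chr1, order_rest)
  chrom <- rep(sprintf("chr%d", seq_len(n_chrom)), times = sizes)
  # positions restart per chromosome, 1 Mb spacing
  start <- unlist(lapply(sizes, function(s) seq_len(s) * 1e6))
  validate_gene_annotation(
    data.frame(gene = full, chrom = chrom, start = start,
               stringsAsFactors = FALSE))
}

#' Spatial simulation configuration
#'
#' @param n_rows,n_cols Lattice dimensions.
#' @param lattice `"hex"` (6-neighbor, Visium-like) or `"square"`
#'   (4-neighbor).
#' @param tumor_radius Tumor disc radius in spot units (Euclidean on the
#'   hex lattice; Chebyshev on the square lattice, so radius r gives a
#'   (2r+1) x (2r+1) block).
#' @param boundary_width Tumor-boundary ring width in lattice steps.
#' @param gain_blocks data.frame with columns `chrom`, `multiplier`:
#'   chromosome-level expression gains applied to tumor spots.
#' @param csc_gene,fap_gene Planted boundary-enriched CSC marker and
#'   stroma/boundary fibroblast gene.
#' @param immune_genes,epithelial_genes Marker genes used by downstream
#'   scoring (must exist in the reference profiles).
#' @param boundary_enrichment Multiplier on the CSC-gene mean in the
#'   boundary ring relative to the tumor core.
#' @param cells_per_spot Integer range `c(lo, hi)` of cells mixed per spot.
#' @param coloc_frac Planted probability that a niche spot (boundary ring
#'   or adjacent stroma) is double-positive for `csc_gene` and `fap_gene`.
#' @param seed Integer RNG seed.
#' @return List of class `SpatialSimConfig`.
#' @export
spatial_sim_config <- function(n_rows = 40, n_cols = 40,
                               lattice = c("hex", "square"),
                               tumor_radius = 12, boundary_width = 2,
                               gain_blocks = data.frame(chrom = "chr1",
                                                        multiplier = 2),
                               csc_gene = "DSG2", fap_gene = "FAP",
                               immune_genes = c("PTPRC", "CD2", "CD3D",
                                                "CD3E", "CD3G", "CD79A",
                                                "MS4A1", "CD79B", "CD68",
                                                "CD14"),
                               epithelial_genes = c("EPCAM", "KRT8",
                                                    "KRT19"),
                               boundary_enrichment = 3,
                               cells_per_spot = c(1, 10),
                               coloc_frac = 0.85, seed = 1L) {
  lattice <- match.arg(lattice)
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              lattice = lattice, tumor_radius = tumor_radius,
              boundary_width = as.integer(boundary_width),
              gain_blocks = gain_blocks, csc_gene = csc_gene,
              fap_gene = fap_gene, immune_genes = immune_genes,
              epithelial_genes = epithelial_genes,
              boundary_enrichment = boundary_enrichment,
              cells_per_spot = as.integer(cells_per_spot),
              coloc_frac = coloc_frac, seed = as.integer(seed))
  if (cfg$tumor_radius < 0) stop("invalid config: tumor_radius must be >= 0")
  if (any(cfg$gain_blocks$multiplier <= 0))
    stop("invalid config: gain multipliers must be > 0")
  if (cfg$boundary_width < 0) stop("invalid config: boundary_width < 0")
  if (length(cfg$cells_per_spot) != 2 || cfg$cells_per_spot[1] < 1 ||
      cfg$cells_per_spot[2] < cfg$cells_per_spot[1])
    stop("invalid config: cells_per_spot must be an increasing pair >= 1")
  if (cfg$coloc_frac <= 0 || cfg$coloc_frac >= 1)
    stop("invalid config: coloc_frac must be in (0, 1)")
  class(cfg) <- "SpatialSimConfig"
  cfg
}

# cartesian coordinates of lattice spots (unit spacing between neighbors)
.lattice_xy <- function(coords, lattice) {
  if (lattice == "hex") {
    cbind(x = coords$col + 0.5 * (coords$row %% 2),
          y = coords$row * sqrt(3) / 2)
  } else cbind(x = coords$col, y = coords$row)
}

#' Simulate a Visium-like spatial section with a planted tumor niche
#'
#' Each spot mixes 1-10 sampled cells from the reference profiles, with
#' region-dependent composition: a centered tumor disc (malignant-rich,
#' carrying chromosome-block gains), an adjacent fibroblast-rich stroma
#' ring, an immune-rich pocket, and normal tissue elsewhere. The CSC gene
#' and fibroblast gene are planted on top: niche spots (boundary ring plus
#' adjacent stroma) are double-positive with probability `coloc_frac`, the
#' CSC-gene mean is multiplied by `boundary_enrichment` in the boundary
#' ring, and half of tumor-core spots are CSC-positive at baseline level.
#'
#' @param config [spatial_sim_config()].
#' @param profiles genes x types matrix from [reference_profiles()]; must
#'   contain a `malignant` column.
#' @param annotation Gene position data.frame (`gene`, `chrom`, `start`)
#'   as from [simulate_gene_annotation()]; needed for gain blocks.
#' @return List with `grid` ([spot_grid()]), `annotation`, and `truth`
#'   (class `GroundTruth`: per-spot `tumor`, `region`
#'   (core/boundary/non_tumor), `zone` (tumor/stroma/immune/normal),
#'   `coloc_class`, `coloc_percent`, `proportions`, `config`).
#' @export
simulate_visium_section <- function(config, profiles, annotation) {
  stopifnot(inherits(config, "SpatialSimConfig"),
            "malignant" %in% colnames(profiles))
  cfg <- config
  set.seed(cfg$seed)
  genes <- rownames(profiles)
  stopifnot(!is.null(genes))
  ann <- annotation[match(genes, annotation$gene), ]

  coords <- expand.grid(row = seq_len(cfg$n_rows) - 1L,
                        col = seq_len(cfg$n_cols) - 1L)
  coords <- coords[order(coords$row, coords$col), ]
  coords$barcode <- sprintf("S%05d", seq_len(nrow(coords)))
  coords <- coords[, c("barcode", "row", "col")]
  rownames(coords) <- NULL
  n_spots <- nrow(coords)
  xy <- .lattice_xy(coords, cfg$lattice)
  center <- c(mean(range(xy[, "x"])), mean(range(xy[, "y"])))

  if (cfg$lattice == "square") {
    d_center <- pmax(abs(coords$row - round(mean(range(coords$row)))),
                     abs(coords$col - round(mean(range(coords$col)))))
  } else {
    d_center <- sqrt((xy[, "x"] - center[1])^2 + (xy[, "y"] - center[2])^2)
  }
  tumor <- if (cfg$tumor_radius <= 0) rep(FALSE, n_spots) else
    d_center <= cfg$tumor_radius
  max_fit <- min(cfg$n_rows, cfg$n_cols) / 2 - 1
  if (cfg$tumor_radius > max_fit && cfg$tumor_radius > 0)
    warning("tumor disc exceeds lattice; clipped at section edge")

  graph <- lattice_adjacency_coords(coords, cfg$lattice)
  d_nontumor <- bfs_distance_to_set(graph, targets = which(!tumor))
  region <- rep("non_tumor", n_spots)
  if (any(tumor)) {
    region[tumor] <- ifelse(d_nontumor[tumor] <= cfg$boundary_width,
                            "boundary", "core")
  }
  d_tumor <- bfs_distance_to_set(graph, targets = which(tumor))
  stroma <- !tumor & d_tumor <= 2
  imm_center <- c(stats::quantile(xy[, "x"], 0.85),
                  stats::quantile(xy[, "y"], 0.85))
  d_imm <- sqrt((xy[, "x"] - imm_center[1])^2 + (xy[, "y"] - imm_center[2])^2)
  immune <- !tumor & !stroma & d_imm <= max(4, cfg$tumor_radius / 2)
  zone <- ifelse(tumor, "tumor",
                 ifelse(stroma, "stroma", ifelse(immune, "immune", "normal")))

  # fibroblasts predominate inside and around the tumor; normal tissue is
  # epithelial-rich with sparse stroma
  mixes <- list(
    tumor  = c(malignant = 0.65, fibroblast = 0.20, myeloid = 0.10,
               endothelial = 0.05),
    stroma = c(fibroblast = 0.60, endothelial = 0.15, myeloid = 0.15,
               epithelial = 0.10),
    immune = c(t_cell = 0.35, b_cell = 0.25, myeloid = 0.30,
               fibroblast = 0.10),
    normal = c(epithelial = 0.60, fibroblast = 0.08, endothelial = 0.15,
               myeloid = 0.12, t_cell = 0.05))
  types <- colnames(profiles)
  mixes <- lapply(mixes, function(m) {
    m <- m[names(m) %in% types]
    m / sum(m)
  })

  # planted CSC / fibroblast gene positivity
  plant <- profiles
  plant[cfg$csc_gene, ] <- 0
  plant[cfg$fap_gene, ] <- 0
  niche <- region == "boundary" | zone == "stroma"
  cls <- rep("negative", n_spots)
  if (any(niche)) {
    p <- c(cfg$coloc_frac, (1 - cfg$coloc_frac) / 2, (1 - cfg$coloc_frac) / 2)
    cls[niche] <- sample(c("A+B+", "A+only", "B+only"), sum(niche),
                         replace = TRUE, prob = p)
  }
  core_idx <- which(region == "core")
  if (length(core_idx) > 0)
    cls[core_idx] <- ifelse(stats::runif(length(core_idx)) < 0.5,
                            "A+only", "negative")
  a_pos <- cls %in% c("A+B+", "A+only")
  b_pos <- cls %in% c("A+B+", "B+only")
  csc_base <- 1.5
  fap_base <- 3
  csc_mean <- ifelse(region == "boundary", csc_base * cfg$boundary_enrichment,
                     csc_base)

  gain_mult <- rep(1, length(genes))
  for (i in seq_len(nrow(cfg$gain_blocks))) {
    on_chr <- !is.na(ann$chrom) & ann$chrom == cfg$gain_blocks$chrom[i]
    gain_mult[on_chr] <- gain_mult[on_chr] * cfg$gain_blocks$multiplier[i]
  }

  n_cells <- sample(seq(cfg$cells_per_spot[1], cfg$cells_per_spot[2]),
                    n_spots, replace = TRUE)
  prop <- matrix(0, n_spots, length(types), dimnames = list(coords$barcode,
                                                            types))
  counts <- matrix(0L, length(genes), n_spots,
                   dimnames = list(genes, coords$barcode))
  for (i in seq_len(n_spots)) {
    mix <- mixes[[zone[i]]]
    tc <- as.vector(stats::rmultinom(1, n_cells[i], prob = mix))
    names(tc) <- names(mix)
    prop[i, names(tc)] <- tc / n_cells[i]
    mu <- as.vector(plant[, names(tc), drop = FALSE] %*% tc)
    if (tumor[i]) mu <- mu * gain_mult
    counts[, i] <- stats::rpois(length(genes), mu)
  }
  # planted positivity: guaranteed >= 1 count when positive, 0 otherwise
  ci <- match(cfg$csc_gene, genes); fi <- match(cfg$fap_gene, genes)
  counts[ci, ] <- ifelse(a_pos, 1L + stats::rpois(n_spots,
                                                  pmax(csc_mean - 1, 0)), 0L)
  counts[fi, ] <- ifelse(b_pos, 1L + stats::rpois(n_spots,
                                                  pmax(fap_base - 1, 0)), 0L)

  union_ab <- sum(a_pos | b_pos)
  coloc_percent <- if (union_ab > 0) 100 * sum(a_pos & b_pos) / union_ab
                   else NA_real_
  em <- expression_matrix(counts)
  grid <- spot_grid(em, coords, cfg$lattice)
  truth <- structure(list(tumor = stats::setNames(tumor, coords$barcode),
                          region = stats::setNames(region, coords$barcode),
                          zone = stats::setNames(zone, coords$barcode),
                          coloc_class = stats::setNames(cls, coords$barcode),
                          coloc_percent = coloc_percent,
                          proportions = prop, config = cfg),
                     class = "GroundTruth")
  list(grid = grid, annotation = ann, truth = truth)
}

#' Simulate a survival table with a biomarker-dependent hazard
#'
#' Biomarker `z ~ Normal(0, 1)`; event times are exponential with hazard
#' `base_rate * exp(log_hr * z)`; censoring is independent exponential
#' calibrated so that the expected censored fraction equals `censor_rate`
#' when `log_hr = 0`.
#'
#' @param n Number of subjects (>= 10).
#' @param log_hr Log hazard ratio per biomarker SD.
#' @param censor_rate Expected censored fraction, in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @param base_rate Baseline hazard per month (default 0.05, median
#'   overall survival around 14 months).
#' @param response_effect If non-zero, adds a `response` column
#'   (`"R"`/`"NR"`) with `P(NR) = plogis(response_effect * z)`.
#' @return data.frame: `subject_id`, `time` (months), `event`,
#'   `biomarker`, optionally `response`.
#' @export
simulate_survival <- function(n, log_hr = 0, censor_rate = 0.2, seed = 1L,
                              base_rate = 0.05, response_effect = 0) {
  if (n < 10) stop("n must be >= 10")
  if (censor_rate >= 1 || censor_rate < 0)
    stop("censor_rate must be in [0, 1)")
  set.seed(as.integer(seed))
  z <- stats::rnorm(n)
  t_event <- stats::rexp(n, rate = base_rate * exp(log_hr * z))
  if (censor_rate > 0) {
    c_rate <- base_rate * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(n, rate = c_rate)
  } else t_cens <- rep(Inf, n)
  time <- pmin(t_event, t_cens)
  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    time = pmax(time, 1e-6),
                    event = as.integer(t_event <= t_cens),
                    biomarker = z, stringsAsFactors = FALSE)
  if (response_effect != 0)
    out$response <- ifelse(stats::runif(n) <
                             stats::plogis(response_effect * z), "NR", "R")
  out
}
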