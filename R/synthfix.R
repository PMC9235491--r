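# Synthetic IHC corpus + expression generator with planted structure.
#
# Emulates the structure of a single-antibody IHC screen: each gene is
# assigned a planted cell type; every image of that gene renders a brown
# stain pattern (on a blue counterstain background) whose spatial statistics
# -- blob radius, blob count, ring vs disc morphology -- are a deterministic
# function of the planted type. Donor identity contributes a global color
# shift and a low-frequency background texture drawn once per donor (the
# nuisance the donor-masked loss is designed to cancel), plus per-image
# pixel noise. A matching cells x genes expression matrix plants the same
# cell-type structure (optionally decoupled for a subset of genes, emulating
# genes whose transcriptomic and proteomic specificity disagree).

KIDNEY_CELL_TYPES <- c("podocyte", "mesangial_cell", "proximal_tubule_cell",
                       "distal_tubule_cell", "principal_cell",
                       "intercalated_cell")

KIDNEY_REGION_MAP <- c(
  podocyte = "glomerulus", mesangial_cell = "glomerulus",
  proximal_tubule_cell = "proximal_tubule",
  distal_tubule_cell = "distal_tubule",
  principal_cell = "collecting_duct", intercalated_cell = "collecting_duct"
)

# Deterministic morphology per planted type: blob radius (px), blob count
# per 64x64 tile, and ring vs filled-disc rendering.
stain_morphology <- function(cell_type, k = NULL) {
  shapes <- list(
    list(radius = 7, count = 6, ring = FALSE),
    list(radius = 7, count = 6, ring = TRUE),
    list(radius = 5, count = 12, ring = TRUE),
    list(radius = 5, count = 12, ring = FALSE),
    list(radius = 3, count = 28, ring = FALSE),
    list(radius = 3, count = 28, ring = TRUE)
  )
  if (is.null(k)) k <- match(cell_type, KIDNEY_CELL_TYPES)
  if (is.na(k)) k <- 1L + (sum(utf8ToInt(cell_type)) %% length(shapes))
  shapes[[1L + ((k - 1L) %% length(shapes))]]
}

#' Synthetic-data configuration
#'
#' Defaults define the desk-scale study conditions used throughout the
#' package: 24 genes over 6 kidney-like cell types mapped onto 4 anatomical
#' regions, 4 donors (each gene drawing from a 2-donor pool), 2 antibodies
#' per gene with 3 replicate images each (144 images of 64x64 pixels), and
#' 40 cells per type in the expression matrix with a 5x-baseline marker
#' effect under multiplicative log-normal noise.
#'
#' @param n_genes number of genes.
#' @param cell_types character vector of K cell-type names.
#' @param region_map named character vector `cell_type -> region`; defaults
#'   to the kidney-like 6-type / 4-region scheme.
#' @param n_donors number of tissue donors.
#' @param donors_per_gene size of the donor pool each gene's images are drawn
#'   from (a random subset of the donors, drawn per gene). Values below
#'   `n_donors` reproduce the donor/gene co-occurrence imbalance of real
#'   screens -- the property that biases uniform negative sampling toward
#'   donor-clustered embeddings.
#' @param antibodies_per_gene,images_per_antibody corpus layout; donors cycle
#'   across a gene's images within its pool, so positive pairs span donors.
#' @param image_size square image side in pixels (>= 16).
#' @param donor_color_shift_sd sd of the per-donor global RGB shift.
#' @param donor_texture_sd amplitude of the per-donor background texture.
#' @param stain_noise_sd sd of per-image pixel noise.
#' @param marker_strength added mean expression of a gene in its marker
#'   type's cells, in units of the baseline (1.0).
#' @param n_cells_per_type cells per type in the expression matrix.
#' @param expression_sdlog sdlog of the multiplicative log-normal expression
#'   noise.
#' @param n_decoupled_genes number of genes whose *expression* marker type is
#'   deliberately different from the planted (image) type -- emulating
#'   markers whose transcript poorly reflects protein staining.
#' @param seed master seed; all generation is a pure function of the config.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_genes = 24L, cell_types = KIDNEY_CELL_TYPES,
                         region_map = KIDNEY_REGION_MAP, n_donors = 4L,
                         donors_per_gene = 2L,
                         antibodies_per_gene = 2L, images_per_antibody = 3L,
                         image_size = 64L, donor_color_shift_sd = 0.08,
                         donor_texture_sd = 0.04, stain_noise_sd = 0.03,
                         marker_strength = 5, n_cells_per_type = 40L,
                         expression_sdlog = 0.4, n_decoupled_genes = 0L,
                         seed = 1L) {
  stopifnot(n_genes >= 1L, length(cell_types) >= 1L, n_donors >= 1L,
            donors_per_gene >= 1L, donors_per_gene <= n_donors,
            antibodies_per_gene >= 1L, images_per_antibody >= 1L,
            n_cells_per_type >= 1L, n_decoupled_genes >= 0L,
            n_decoupled_genes <= n_genes)
  if (image_size < 16L) {
    stopf("image_size %d too small for the largest blob scale", image_size)
  }
  structure(
    list(n_genes = as.integer(n_genes), cell_types = cell_types,
         region_map = region_map, n_donors = as.integer(n_donors),
         donors_per_gene = as.integer(donors_per_gene),
         antibodies_per_gene = as.integer(antibodies_per_gene),
         images_per_antibody = as.integer(images_per_antibody),
         image_size = as.integer(image_size),
         donor_color_shift_sd = donor_color_shift_sd,
         donor_texture_sd = donor_texture_sd,
         stain_noise_sd = stain_noise_sd,
         marker_strength = marker_strength,
         n_cells_per_type = as.integer(n_cells_per_type),
         expression_sdlog = expression_sdlog,
         n_decoupled_genes = as.integer(n_decoupled_genes),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Planted gene table: round-robin cell types (balanced classes); the first
# n_decoupled genes in a seeded random order get a shifted expression type.
synth_gene_truth <- function(config) {
  K <- length(config$cell_types)
  genes <- sprintf("gene%03d", seq_len(config$n_genes))
  ct_idx <- ((seq_len(config$n_genes) - 1L) %% K) + 1L
  expr_idx <- ct_idx
  if (config$n_decoupled_genes > 0L) {
    set.seed(derive_seed(config$seed, "decouple"))
    dec <- sample.int(config$n_genes, config$n_decoupled_genes)
    expr_idx[dec] <- (ct_idx[dec] %% K) + 1L
  }
  tibble(
    gene = genes,
    cell_type = config$cell_types[ct_idx],
    region = unname(config$region_map[config$cell_types[ct_idx]]),
    expression_type = config$cell_types[expr_idx],
    decoupled = expr_idx != ct_idx
  )
}

synth_donor_truth <- function(config) {
  set.seed(derive_seed(config$seed, "donors"))
  n <- config$n_donors
  tibble(
    donor = sprintf("donor%02d", seq_len(n)),
    shift_r = rnorm(n, sd = config$donor_color_shift_sd),
    shift_g = rnorm(n, sd = config$donor_color_shift_sd),
    shift_b = rnorm(n, sd = config$donor_color_shift_sd),
    tex_freq_x = runif(n, 1, 3), tex_freq_y = runif(n, 1, 3),
    tex_phase = runif(n, 0, 2 * pi),
    tex_amp = abs(rnorm(n, sd = config$donor_texture_sd))
  )
}

# Render one image: blue counterstain background + donor texture + brown
# stain blobs of the planted type's morphology + donor color shift +
# per-image noise. Values clipped to [0,1]. Draws from the current RNG.
render_synth_image <- function(cell_type, donor_row, config) {
  s <- config$image_size
  morph <- stain_morphology(cell_type)
  gx <- matrix(rep(seq_len(s), each = s), s)   # column coordinate
  gy <- matrix(rep(seq_len(s), times = s), s)  # row coordinate
  # counterstain background with donor-specific low-frequency texture
  tex <- donor_row$tex_amp *
    sin(2 * pi * (donor_row$tex_freq_x * gx / s +
                  donor_row$tex_freq_y * gy / s) + donor_row$tex_phase)
  base <- c(0.72, 0.72, 0.88)
  # stain mask: blobs scaled to image size (counts defined per 64x64 tile)
  n_blob <- max(1L, round(morph$count * (s / 64)^2))
  mask <- matrix(0, s, s)
  r <- morph$radius
  for (b in seq_len(n_blob)) {
    cx <- runif(1, 1 + r, s - r)
    cy <- runif(1, 1 + r, s - r)
    d <- sqrt((gx - cx)^2 + (gy - cy)^2)
    mask <- mask + if (morph$ring) {
      exp(-(d - r)^2 / (2 * 1.1^2))
    } else {
      exp(-d^2 / (2 * (0.6 * r)^2))
    }
  }
  mask <- pmin(mask, 1) * runif(1, 0.75, 1)   # per-image stain intensity
  brown <- c(0.45, 0.28, 0.12)
  shift <- c(donor_row$shift_r, donor_row$shift_g, donor_row$shift_b)
  img <- array(0, c(s, s, 3L))
  for (ch in 1:3) {
    bgc <- base[ch] + tex
    img[, , ch] <- bgc * (1 - mask) + brown[ch] * mask + shift[ch] +
      rnorm(s * s, sd = config$stain_noise_sd)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a synthetic IHC corpus
#'
#' Writes one PNG per image under `out_dir/images/` plus a `manifest.csv`
#' (intensity `high`, validation `enhanced`, one target gene per antibody --
#' i.e. every record passes [filter_corpus()]). The whole corpus is a pure
#' function of the config, including its seed.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `corpus` (an `ihc_corpus`), `truth` (list of `genes`,
#'   `donors`, `images` tibbles), `manifest_path`.
#' @export
generate_corpus <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  gene_truth <- synth_gene_truth(config)
  donor_truth <- synth_donor_truth(config)
  rows <- list()
  set.seed(derive_seed(config$seed, "images"))
  ii <- 0L
  for (g in seq_len(config$n_genes)) {
    # each gene's replicates come from a per-gene donor pool: the donor/gene
    # co-occurrence imbalance seen in real screens
    pool <- sample.int(config$n_donors, config$donors_per_gene)
    for (a in seq_len(config$antibodies_per_gene)) {
      for (im in seq_len(config$images_per_antibody)) {
        ii <- ii + 1L
        di <- pool[(((a - 1L) * config$images_per_antibody + (im - 1L)) %%
                      config$donors_per_gene) + 1L]
        fn <- sprintf("img%04d.png", ii)
        img <- render_synth_image(gene_truth$cell_type[g],
                                  donor_truth[di, ], config)
        png::writePNG(img, file.path(img_dir, fn))
        rows[[ii]] <- tibble(
          image_id = sprintf("img%04d", ii),
          gene = gene_truth$gene[g],
          antibody = sprintf("%s_ab%d", gene_truth$gene[g], a),
          donor = donor_truth$donor[di],
          staining_intensity = "high",
          validation_status = "enhanced",
          n_target_genes = 1L,
          path = file.path("images", fn)
        )
      }
    }
  }
  records <- bind_rows(rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  readr::write_csv(records, manifest_path)
  image_truth <- bind_rows(rows) |>
    left_join(gene_truth[, c("gene", "cell_type", "region")], by = "gene")
  list(corpus = new_corpus(records, image_root = out_dir),
       truth = list(genes = gene_truth, donors = donor_truth,
                    images = image_truth),
       manifest_path = manifest_path)
}

#' Generate a matching synthetic expression dataset
#'
#' Cells x genes matrix with `n_cells_per_type` cells per type: gene g has
#' mean `1 + marker_strength` in the cells of its expression marker type and
#' mean 1 elsewhere, under multiplicative log-normal noise (so values are
#' non-negative). With `marker_strength = 0` no gene is differentially
#' expressed. Gene names match the corpus manifest.
#'
#' @param config a [synth_config()].
#' @return list with `expr` (an [expression_dataset()]) and `truth` (the
#'   per-gene tibble, including the `expression_type` linkage).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  gene_truth <- synth_gene_truth(config)
  K <- length(config$cell_types)
  n_cells <- K * config$n_cells_per_type
  cell_types <- rep(config$cell_types, each = config$n_cells_per_type)
  set.seed(derive_seed(config$seed, "expression"))
  mu <- matrix(1, n_cells, config$n_genes)
  for (g in seq_len(config$n_genes)) {
    mu[cell_types == gene_truth$expression_type[g], g] <-
      1 + config$marker_strength
  }
  noise <- matrix(stats::rlnorm(n_cells * config$n_genes,
                                meanlog = -config$expression_sdlog^2 / 2,
                                sdlog = config$expression_sdlog),
                  n_cells, config$n_genes)
  X <- mu * noise
  list(expr = expression_dataset(X, cell_types, gene_truth$gene),
       truth = gene_truth)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits everything the rest of the pipeline consumes: image directory +
#' `manifest.csv`, an MTX expression triplet (`expr/matrix.mtx`,
#' `expr/genes.tsv`, `expr/barcodes.tsv`, `expr/cell_types.tsv`), a
#' `region_map.tsv`, a per-gene `truth.tsv` (gene, cell_type, region) and a
#' `truth.json` with donor nuisance parameters.
#'
#' The `tiny` profile (8 genes x 4 types, 32 images) completes in seconds
#' and backs the unit tests; `default` is the 96-image condition used for
#' the end-to-end evaluation.
#'
#' @param profile `"tiny"` or `"default"`.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param overrides named list of [synth_config()] arguments overriding the
#'   profile (e.g. `n_decoupled_genes`).
#' @return list with `config`, `corpus`, `expr`, `truth`, and the file paths.
#' @export
make_fixture <- function(profile = c("tiny", "default"), out_dir = tempfile(),
                         seed = 1L, overrides = list()) {
  profile <- match.arg(profile)
  args <- if (profile == "tiny") {
    list(n_genes = 8L, cell_types = KIDNEY_CELL_TYPES[1:4],
         region_map = KIDNEY_REGION_MAP[1:4], n_donors = 4L,
         donors_per_gene = 2L, antibodies_per_gene = 2L,
         images_per_antibody = 2L, seed = seed)
  } else {
    list(seed = seed)
  }
  config <- do.call(synth_config, modifyList(args, overrides))
  gc <- generate_corpus(config, out_dir)
  ge <- generate_expression(config)
  expr_dir <- file.path(out_dir, "expr")
  dir.create(expr_dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(ge$expr$matrix, sparse = TRUE),
                  file.path(expr_dir, "matrix.mtx"))
  writeLines(ge$expr$gene_names, file.path(expr_dir, "genes.tsv"))
  barcodes <- sprintf("cell%04d", seq_along(ge$expr$cell_types))
  writeLines(barcodes, file.path(expr_dir, "barcodes.tsv"))
  readr::write_tsv(tibble(barcode = barcodes, cell_type = ge$expr$cell_types),
                   file.path(expr_dir, "cell_types.tsv"), col_names = FALSE)
  map_path <- file.path(out_dir, "region_map.tsv")
  readr::write_tsv(tibble(cell_type = names(config$region_map),
                          region = unname(config$region_map)), map_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  readr::write_tsv(gc$truth$genes[, c("gene", "cell_type", "region")],
                   truth_path)
  json_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(donors = gc$truth$donors, genes = gc$truth$genes,
         profile = profile, seed = seed),
    json_path, auto_unbox = TRUE, digits = NA
  )
  list(config = config, corpus = gc$corpus, expr = ge$expr,
       truth = gc$truth,
       paths = list(dir = out_dir, manifest = gc$manifest_path,
                    expr = expr_dir, region_map = map_path,
                    truth = truth_path, truth_json = json_path))
}
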