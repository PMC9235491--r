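# Corpus data model: manifest IO, quality filtering, gene partitioning.
#
# An `ihc_corpus` bundles a tibble of image records with the gene partition
# ("equivalence classes" of images sharing a nominal target gene) that the
# contrastive sampler draws positive pairs from. Images are decoded lazily:
# loading a manifest never touches pixel data.

MANIFEST_COLUMNS <- c(
  "image_id", "gene", "antibody", "donor",
  "staining_intensity", "validation_status"
)

VALID_INTENSITY <- c("high", "medium", "low", "not_detected")
VALID_VALIDATION <- c("enhanced", "supported", "approved", "uncertain")

#' Construct an IHC image corpus from a records table
#'
#' Lower-level constructor used by [read_manifest()] and the synthetic
#' generator. Validates the record schema, normalizes the categorical fields
#' (case-insensitively), and builds the gene partition.
#'
#' @param records data frame with columns `image_id`, `gene`, `antibody`,
#'   `donor`, `staining_intensity`, `validation_status`, and optionally
#'   `n_target_genes` (derived by splitting semicolon-separated `gene` values
#'   when absent) and `path` (image file, relative paths resolved against
#'   `image_root`). Extra columns are preserved.
#' @param image_root directory against which relative image paths resolve.
#' @return an object of class `ihc_corpus`: a list with `records` (tibble),
#'   `gene_partition` (named list of integer row indices), `image_root`.
#' @export
new_corpus <- function(records, image_root = ".") {
  records <- as_tibble(records)
  missing <- setdiff(MANIFEST_COLUMNS, names(records))
  if (length(missing) > 0) {
    stopf("manifest is missing required column(s): %s",
          paste(missing, collapse = ", "))
  }
  if (anyDuplicated(records$image_id)) {
    dup <- unique(records$image_id[duplicated(records$image_id)])
    stopf("duplicate image_id in manifest: %s",
          paste(head(dup, 3L), collapse = ", "))
  }
  records$staining_intensity <- tolower(records$staining_intensity)
  records$validation_status <- tolower(records$validation_status)
  bad_int <- setdiff(unique(records$staining_intensity), VALID_INTENSITY)
  if (length(bad_int) > 0 && nrow(records) > 0) {
    stopf("unknown staining_intensity value(s): %s",
          paste(bad_int, collapse = ", "))
  }
  bad_val <- setdiff(unique(records$validation_status), VALID_VALIDATION)
  if (length(bad_val) > 0 && nrow(records) > 0) {
    stopf("unknown validation_status value(s): %s",
          paste(bad_val, collapse = ", "))
  }
  if (!"n_target_genes" %in% names(records)) {
    # HPA-style exports may encode multi-target antibodies as "GENE1;GENE2".
    records$n_target_genes <- lengths(strsplit(as.character(records$gene), ";",
                                               fixed = TRUE))
  }
  records$n_target_genes <- as.integer(records$n_target_genes)
  if (nrow(records) > 0 && any(records$n_target_genes < 1L)) {
    stopf("n_target_genes must be >= 1 for every record")
  }
  if (!"path" %in% names(records)) records$path <- NA_character_
  structure(
    list(
      records = records,
      gene_partition = partition_by_gene(records),
      image_root = image_root
    ),
    class = "ihc_corpus"
  )
}

#' Read an image manifest into a corpus
#'
#' The manifest is a UTF-8 delimited table with a header row; the delimiter is
#' auto-detected from the file extension (`.csv` comma, `.tsv`/`.txt` tab).
#' One record is created per row, preserving row order; the gene partition is
#' built immediately. Image files are not decoded (an unreadable `path` only
#' errors at first decode). Stored images are expected to already be at
#' working resolution; any downsampling of larger originals happens upstream
#' of this tool.
#'
#' @param manifest_path path to the CSV/TSV manifest.
#' @param image_root directory for relative image paths; defaults to the
#'   manifest's directory.
#' @return an [new_corpus()] object.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "image_id,gene,antibody,donor,staining_intensity,validation_status,path",
#'   "img1,AQP1,ab1,d1,high,enhanced,img1.png",
#'   "img2,AQP1,ab2,d2,medium,enhanced,img2.png",
#'   "img3,NPHS2,ab3,d1,high,enhanced,img3.png"
#' ), tf)
#' corp <- read_manifest(tf)
#' length(corp$gene_partition) # 2 genes
#' @export
read_manifest <- function(manifest_path, image_root = dirname(manifest_path)) {
  if (!file.exists(manifest_path)) {
    stopf("manifest file not found: %s", manifest_path)
  }
  delim <- if (grepl("\\.csv$", manifest_path, ignore.case = TRUE)) "," else "\t"
  records <- readr::read_delim(
    manifest_path, delim = delim, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if ("n_target_genes" %in% names(records)) {
    records$n_target_genes <- as.integer(records$n_target_genes)
  }
  new_corpus(records, image_root = image_root)
}

#' Partition records by nominal target gene
#'
#' Each gene maps to the indices of all its records, pooling across antibodies
#' and donors: this is the sampling unit ("observational unit") of the
#' contrastive objective.
#'
#' @param records a records tibble (see [new_corpus()]).
#' @return named list mapping gene to an integer vector of row indices; every
#'   record appears in exactly one class.
#' @export
partition_by_gene <- function(records) {
  if (nrow(records) == 0) return(structure(list(), names = character(0)))
  split(seq_len(nrow(records)), factor(records$gene,
                                       levels = unique(records$gene)))
}

#' Quality-filter a corpus
#'
#' Retains exactly the records with enhanced antibody validation, medium or
#' high staining intensity, and a single nominal target gene; rebuilds the
#' gene partition (genes left with no records disappear). Idempotent; may
#' return an empty corpus.
#'
#' @param corpus an `ihc_corpus`.
#' @return the filtered `ihc_corpus`.
#' @export
filter_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "ihc_corpus"))
  rec <- corpus$records
  keep <- rec$validation_status == "enhanced" &
    rec$staining_intensity %in% c("medium", "high") &
    rec$n_target_genes == 1L
  new_corpus(rec[keep, , drop = FALSE], image_root = corpus$image_root)
}

#' @export
print.ihc_corpus <- function(x, ...) {
  cat(sprintf(
    "<ihc_corpus> %d images, %d genes, %d donors\n",
    nrow(x$records), length(x$gene_partition),
    length(unique(x$records$donor))
  ))
  invisible(x)
}

# Decode one record's image as an H x W x 3 array in [0,1]. Decoding is lazy
# and memoised in `cache` (an environment keyed by record index) because the
# training loop revisits images many times.
load_corpus_image <- function(corpus, i, cache = NULL) {
  key <- as.character(i)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  path <- corpus$records$path[i]
  if (is.na(path)) stopf("record %d ('%s') has no image path",
                         i, corpus$records$image_id[i])
  if (!file.exists(path)) {
    path2 <- file.path(corpus$image_root, path)
    if (!file.exists(path2)) {
      stopf("image file not found for record '%s': %s",
            corpus$records$image_id[i], path)
    }
    path <- path2
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (!is.null(cache)) cache[[key]] <- img
  img
}
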