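# Shared fixtures, generated once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(profile = "tiny", seed = 1L, overrides = list()) {
  key <- paste(profile, seed, paste(names(overrides), unlist(overrides),
                                    collapse = "_"), sep = "|")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_fixture(
      profile, out_dir = file.path(tempdir(), gsub("[^a-z0-9]", "_", key)),
      seed = seed, overrides = overrides
    )
  }
  .fixture_cache[[key]]
}

# A small in-memory records table for corpus unit tests.
toy_records <- function() {
  tibble::tibble(
    image_id = paste0("img", 1:5),
    gene = c("A", "A", "B", "B", "C"),
    antibody = paste0("ab", 1:5),
    donor = c("d1", "d2", "d1", "d2", "d1"),
    staining_intensity = c("high", "medium", "high", "low", "high"),
    validation_status = c("enhanced", "enhanced", "approved", "enhanced",
                          "enhanced"),
    n_target_genes = c(1L, 1L, 1L, 1L, 2L),
    path = NA_character_
  )
}

write_manifest_file <- function(records, dir = tempfile(), ext = ".csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0("manifest", ext))
  if (ext == ".csv") readr::write_csv(records, path)
  else readr::write_tsv(records, path)
  path
}

# Random simplex rows.
random_simplex <- function(n, k) {
  Y <- matrix(stats::rexp(n * k), n, k)
  Y / rowSums(Y)
}
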