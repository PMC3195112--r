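# Readers and writers for the package's TSV dialects (tab-separated, header
# row, UTF-8, "." decimal) plus JSON/YAML run configuration. Structural
# metadata that the tibble attributes carry (fingerprint length, number of
# searches, ...) is stored in "#key=value" comment lines ahead of the header
# so every file round-trips losslessly.

.write_tsv_with_meta <- function(x, path, meta) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#%s=%s", names(meta), unlist(meta)), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

.read_tsv_with_meta <- function(path, col_types) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (file.size(path) == 0L) abort(sprintf("Empty input file: %s", path))
  lines <- readLines(path, n = 50L, encoding = "UTF-8")
  meta_lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#", "", ml), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[kv[1L]]] <- kv[2L]
  }
  body <- readr::read_tsv(path, comment = "#", col_types = col_types,
                          progress = FALSE)
  if (nrow(body) == 0L) abort(sprintf("No data rows in %s", path))
  prob <- readr::problems(body)
  if (nrow(prob) > 0L) {
    abort(sprintf("Malformed TSV %s at line %d: %s", path, prob$row[1L],
                  prob$expected[1L]))
  }
  list(meta = meta, body = body)
}

#' Write / read a fingerprint database as TSV
#'
#' Columns: `molecule_id`, `class_id`, `scaffold_id`, then one lowercase-hex
#' fingerprint column per view (`fp1..fpV`). The fingerprint bit length is
#' recorded in a `#n_bits=` comment line so trailing pad bits are
#' unambiguous.
#'
#' @param db An `"fp_database"`.
#' @param path File path.
#' @return `write_database` returns `path` invisibly; `read_database` returns
#'   the `"fp_database"` tibble.
#' @export
write_database <- function(db, path) {
  .write_tsv_with_meta(as.data.frame(db), path,
                       list(n_bits = n_bits(db), n_views = n_views(db)))
  invisible(path)
}

#' @rdname write_database
#' @export
read_database <- function(path) {
  parsed <- .read_tsv_with_meta(path, readr::cols(
    molecule_id = readr::col_integer(),
    class_id = readr::col_character(),
    scaffold_id = readr::col_integer(),
    .default = readr::col_character()
  ))
  if (is.null(parsed$meta$n_bits)) abort("Missing '#n_bits=' header line.")
  L <- as.integer(parsed$meta$n_bits)
  db <- parsed$body
  fp_cols <- grep("^fp[0-9]+$", names(db), value = TRUE)
  if (length(fp_cols) == 0L) abort("No fingerprint columns (fp1, fp2, ...) found.")
  for (col in fp_cols) {
    bad <- which(nchar(db[[col]]) != 2L * ceiling(L / 8) |
                   grepl("[^0-9a-f]", db[[col]]))
    if (length(bad) > 0L) {
      abort(sprintf("Bad hex fingerprint in column %s, data line %d of %s.",
                    col, bad[1L], path))
    }
  }
  new_fp_database(tibble::as_tibble(db), n_bits = L, n_views = length(fp_cols))
}

#' Write / read retrieval counts as TSV
#'
#' Columns `molecule_id`, `count`, with `#n_searches=` and `#cutoff_count=`
#' header lines. Per-search sets are not serialized; statistics needing them
#' (scaffold profiles, intersection tables) must be computed before writing.
#'
#' @param counts A `"retrieval_counts"`.
#' @param path File path.
#' @return `write_counts` returns `path` invisibly; `read_counts` the
#'   `"retrieval_counts"` tibble.
#' @export
write_counts <- function(counts, path) {
  .write_tsv_with_meta(
    as.data.frame(counts), path,
    list(n_searches = n_searches(counts), cutoff_count = cutoff_count(counts))
  )
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  parsed <- .read_tsv_with_meta(path, readr::cols(
    molecule_id = readr::col_integer(), count = readr::col_integer()
  ))
  if (is.null(parsed$meta$n_searches)) abort("Missing '#n_searches=' header line.")
  new_retrieval_counts(
    parsed$body$molecule_id, parsed$body$count,
    n_searches = as.integer(parsed$meta$n_searches),
    cutoff_count = as.integer(parsed$meta$cutoff_count)
  )
}

#' Write / read overlap, precision and null profiles as TSV
#'
#' The profile type and `n_searches` are recorded in comment lines; columns
#' are `s`, `O` (overlap), `s`, `n_molecules`, `n_active`, `P` (precision) or
#' `s`, `expected` (binomial null).
#'
#' @param profile An `"overlap_profile"`, `"precision_profile"` or
#'   `"binomial_null"`.
#' @param path File path.
#' @return `write_profile` returns `path` invisibly; `read_profile` the
#'   profile with its class restored.
#' @export
write_profile <- function(profile, path) {
  type <- intersect(class(profile),
                    c("overlap_profile", "precision_profile", "binomial_null"))[1L]
  if (is.na(type)) abort("`profile` is not a recognized profile object.")
  meta <- list(profile_type = type, n_searches = attr(profile, "n_searches"))
  if (type == "precision_profile") meta$target_class <- attr(profile, "target_class")
  if (type == "binomial_null") {
    meta$M <- attr(profile, "M"); meta$p <- attr(profile, "p")
  }
  .write_tsv_with_meta(as.data.frame(profile), path, meta)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  parsed <- .read_tsv_with_meta(path, readr::cols(s = readr::col_integer()))
  type <- parsed$meta$profile_type
  if (is.null(type)) abort("Missing '#profile_type=' header line.")
  n <- as.integer(parsed$meta$n_searches)
  body <- parsed$body
  switch(type,
    overlap_profile = new_overlap_profile(body$s, body$O, n),
    precision_profile = structure(
      body, class = c("precision_profile", class(tibble::tibble())),
      n_searches = n, target_class = parsed$meta$target_class
    ),
    binomial_null = structure(
      body, class = c("binomial_null", class(tibble::tibble())),
      M = as.numeric(parsed$meta$M), p = as.numeric(parsed$meta$p),
      n_searches = n
    ),
    abort(sprintf("Unknown profile type \"%s\" in %s.", type, path))
  )
}

#' Read a run configuration from JSON or YAML
#'
#' The configuration drives [run_screening_study()]; see that function for
#' the recognized fields. The format is chosen by file extension
#' (`.json` vs `.yml`/`.yaml`).
#'
#' @param path Configuration file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    abort("Config must be a .json, .yml or .yaml file.")
  }
}
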