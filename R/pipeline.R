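# End-to-end screening study: generate (or read) a database, run replicated
# SF/GF experiments per activity class, average the overlap and precision
# profiles, fit trends, compute the binomial null and the generative-model
# section, and write everything to an output directory. One master seed
# recorded in the summary determines every output.

.as_class_specs <- function(classes) {
  purrr::pmap_dfr(classes, function(class_id, n_actives, noise_rate,
                                    n_scaffolds = NULL,
                                    scaffold_spread = NULL, ...) {
    args <- list(class_id, n_actives, noise_rate)
    if (!is.null(n_scaffolds)) args$n_scaffolds <- n_scaffolds
    if (!is.null(scaffold_spread)) args$scaffold_spread <- scaffold_spread
    do.call(activity_class_spec, args)
  })
}

.config_to_spec <- function(config) {
  if (!is.null(config$database_path)) {
    return(NULL) # database will be read, not generated
  }
  dbc <- config$database %||% list()
  classes <- if (!is.null(dbc$classes)) .as_class_specs(tibble::as_tibble(dbc$classes))
  if (is.null(classes)) {
    default_database_spec(
      M = dbc$M %||% 20000L, L = dbc$L %||% 512L, V = dbc$V %||% 5L,
      view_correlation = dbc$view_correlation %||% 0.6,
      background_density = dbc$background_density %||% 0.1,
      seed = config$seed %||% 1L
    )
  } else {
    database_spec(
      M = dbc$M, L = dbc$L %||% 512L, V = dbc$V %||% 5L,
      view_correlation = dbc$view_correlation %||% 0.6, classes = classes,
      background_density = dbc$background_density %||% 0.1,
      seed = config$seed %||% 1L
    )
  }
}

.study_one_class <- function(db, class_id, mode, fraction, n_replicates, seed) {
  exp <- run_replicated_experiment(
    db, class_id, mode = mode, n_replicates = n_replicates,
    fraction = fraction, seed = seed
  )
  overlaps <- lapply(exp$counts, overlap_profile)
  precisions <- lapply(exp$counts, precision_profile, db = db,
                       target_class = class_id)
  scaffolds <- lapply(exp$counts, scaffold_overlap_profile, db = db)
  ov <- average_profiles(overlaps)
  pr <- average_profiles(precisions)
  sc <- average_profiles(scaffolds)
  fit <- loglog_fit(ov)
  list(
    class_id = class_id, mode = mode, fraction = fraction,
    overlap = ov, precision = pr, scaffold_overlap = sc,
    slope = unname(fit$coefficients[["slope"]]), r_squared = fit$r_squared,
    argmax_precision = argmax_precision(pr)
  )
}

#' Run a full multi-search screening study
#'
#' Drives the whole analysis from one configuration: database generation (or
#' loading), replicated SF/GF experiments over the requested activity classes
#' and cutoff fractions, profile averaging, power-law fits, per-class
#' homogeneity, the binomial null matched to each cutoff, and the
#' generative-model steady-state slopes. All outputs are deterministic given
#' the configuration and its seed.
#'
#' Recognized configuration fields (all optional unless noted):
#' `seed`; `database` (list: `M`, `L`, `V`, `view_correlation`,
#' `background_density`, `classes` as a data-frame-like list of
#' `class_id`/`n_actives`/`noise_rate`/`n_scaffolds`) or `database_path` (TSV
#' from [write_database()]); `modes` (default `c("SF", "GF")`); `fractions`
#' (default `c(0.01, 0.05)`); `classes` (class ids to study, default all);
#' `n_replicates` (default 10); `pa_gammas` (default `c(0.9, 0.99)`);
#' `write_database`, `write_counts` (logical, default `FALSE`).
#'
#' @param config Named list, or path to a JSON/YAML file understood by
#'   [read_run_config()].
#' @param out_dir Output directory, created if missing. Per class/mode/
#'   fraction the averaged profiles are written as TSV; fit and study
#'   summaries as JSON (`summary.json`).
#' @return Invisibly, the summary list (also written to
#'   `out_dir/summary.json`).
#' @export
run_screening_study <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L

  if (!is.null(config$database_path)) {
    db <- read_database(config$database_path)
  } else {
    db <- generate_database(.config_to_spec(config))
  }
  if (isTRUE(config$write_database)) {
    write_database(db, file.path(out_dir, "database.tsv"))
  }

  class_ids <- config$classes %||% sort(unique(db$class_id[!is.na(db$class_id)]))
  modes <- config$modes %||% c("SF", "GF")
  fractions <- config$fractions %||% c(0.01, 0.05)
  n_replicates <- config$n_replicates %||% 10L

  runs <- list()
  for (fraction in fractions) {
    for (mode in modes) {
      for (cl in class_ids) {
        run_seed <- .sub_seed(seed, 6000 + round(1e4 * fraction) +
                                100 * match(mode, c("SF", "GF")) +
                                match(cl, class_ids))
        res <- .study_one_class(db, cl, mode, fraction, n_replicates, run_seed)
        tag <- sprintf("%s_%s_top%g", mode, cl, 100 * fraction)
        write_profile(res$overlap, file.path(out_dir, paste0("overlap_", tag, ".tsv")))
        write_profile(res$precision, file.path(out_dir, paste0("precision_", tag, ".tsv")))
        write_profile(res$scaffold_overlap,
                      file.path(out_dir, paste0("scaffold_overlap_", tag, ".tsv")))
        runs[[tag]] <- res[c("class_id", "mode", "fraction", "slope",
                             "r_squared", "argmax_precision")]
      }
    }
  }

  homogeneity <- vapply(class_ids, function(cl) class_homogeneity(db, cl), 0)
  nulls <- lapply(fractions, function(f) {
    nul <- binomial_null(M = nrow(db), p = f, n = 25L)
    write_profile(nul, file.path(out_dir, sprintf("binomial_null_top%g.tsv", 100 * f)))
    list(fraction = f, expected_O1 = nul$expected[nul$s == 1L])
  })

  pa_gammas <- config$pa_gammas %||% c(0.9, 0.99)
  pa <- lapply(pa_gammas, function(g) {
    ss <- steady_state_overlap(g, 25L)
    write_profile(
      new_overlap_profile(ss$s, ss$O, 25L),
      file.path(out_dir, sprintf("pa_steady_state_gamma%g.tsv", g))
    )
    list(gamma = g, effective_slope = effective_slope(g, 25L),
         asymptotic_exponent = asymptotic_exponent(g))
  })

  summary <- list(
    seed = seed, M = nrow(db), n_bits = n_bits(db), n_views = n_views(db),
    classes = as.list(setNames(homogeneity, class_ids)),
    runs = runs, binomial_null = nulls, pa_model = pa
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
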