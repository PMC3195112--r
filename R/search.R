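# Ranked similarity searching with top-fraction cutoffs, and the similarity
# fusion (SF) / group fusion (GF) drivers that tally how many searches
# retrieved each molecule.

#' Build a battery of similarity measures
#'
#' A similarity measure is a (fingerprint view, coefficient) pair. The full
#' crossing of five views with the five coefficients gives the classical
#' 25-measure similarity-fusion battery.
#'
#' @param views Integer vector of view indices.
#' @param coefficients Character vector of coefficient names.
#' @return A tibble with columns `view` and `coefficient`, one row per measure.
#' @export
similarity_measures <- function(views = 1:5, coefficients = similarity_coefficients()) {
  coefficients <- vapply(coefficients, match.arg, "", choices = COEFFICIENTS)
  tidyr::expand_grid(view = as.integer(views), coefficient = unname(coefficients))
}

# similarities of every row of bit matrix B to a single reference bit vector
.similarities_to_ref <- function(B, ref, coefficient) {
  a <- as.numeric(B %*% ref)
  on <- rowSums(B)
  ref_on <- sum(ref)
  counts <- tibble::tibble(
    a = a, b = ref_on - a, c = on - a,
    d = ncol(B) - ref_on - on + a, n_bits = ncol(B)
  )
  similarity_from_counts(counts, coefficient)
}

.ref_bits <- function(db, reference, B = NULL, view = NULL) {
  if (length(reference) == 1L && reference %in% db$molecule_id) {
    i <- match(reference, db$molecule_id)
    if (!is.null(B)) return(B[i, ]) else return(.view_matrix(db, view)[i, ])
  }
  .check_bits(reference, "reference")
}

#' Rank a database against a reference structure
#'
#' Orders all molecules by decreasing similarity to the reference under one
#' similarity measure. Ties are broken by ascending `molecule_id`, which makes
#' the ranking a deterministic total order.
#'
#' @param db An `"fp_database"`.
#' @param reference A `molecule_id` present in `db`, or a raw 0/1 bit vector
#'   of length `n_bits(db)`.
#' @param view Fingerprint view to search.
#' @param coefficient Similarity coefficient.
#' @return A tibble `molecule_id`, `similarity`, `rank` sorted by rank.
#' @export
rank_database <- function(db, reference, view = 1L, coefficient = "tanimoto") {
  if (nrow(db) == 0L) abort("Cannot rank an empty database.")
  B <- .view_matrix(db, view)
  ref <- .ref_bits(db, reference, B = B)
  sim <- .similarities_to_ref(B, ref, coefficient)
  ord <- order(-sim, db$molecule_id)
  tibble::tibble(
    molecule_id = db$molecule_id[ord], similarity = sim[ord],
    rank = seq_along(ord)
  )
}

#' Retain the top fraction of a ranking
#'
#' Keeps the `floor(fraction * M)` highest-ranked molecules (at least one),
#' the nearest-neighbour set of the search.
#'
#' @param ranking A ranking tibble from [rank_database()].
#' @param fraction Fraction of the database to retain, in `(0, 1]`.
#' @return The retained rows; the number kept is also attached as attribute
#'   `cutoff_count`.
#' @export
top_fraction <- function(ranking, fraction) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  k <- max(1L, floor(fraction * nrow(ranking)))
  out <- ranking[seq_len(k), , drop = FALSE]
  attr(out, "cutoff_count") <- k
  out
}

new_retrieval_counts <- function(molecule_id, count, n_searches, cutoff_count,
                                 search_sets = NULL) {
  structure(
    tibble::tibble(molecule_id = molecule_id, count = as.integer(count)),
    class = c("retrieval_counts", class(tibble::tibble())),
    n_searches = as.integer(n_searches),
    cutoff_count = as.integer(cutoff_count),
    search_sets = search_sets
  )
}

#' Retrieval counts from explicit nearest-neighbour sets
#'
#' Builds the per-molecule tally "how many searches retrieved me" from a list
#' of search outputs. Useful for worked examples and for plugging externally
#' computed searches into the overlap statistics.
#'
#' @param sets List of vectors of molecule ids, one per search. All sets must
#'   have equal size (the cutoff count).
#' @param molecule_ids Universe of molecules; defaults to the union of the
#'   sets. Molecules never retrieved get count 0.
#' @return A `"retrieval_counts"` tibble: `molecule_id`, `count`, with
#'   attributes `n_searches`, `cutoff_count` and the `search_sets` themselves.
#' @examples
#' counts <- retrieval_counts_from_sets(list(c("A", "B", "C"), c("A", "C", "D")))
#' @export
retrieval_counts_from_sets <- function(sets, molecule_ids = NULL) {
  if (length(sets) == 0L) abort("Need at least one search set.")
  sizes <- lengths(sets)
  if (length(unique(sizes)) != 1L) abort("All search sets must have equal size.")
  if (any(vapply(sets, anyDuplicated, 0L) > 0L)) {
    abort("A search set may not contain duplicate molecule ids.")
  }
  molecule_ids <- molecule_ids %||% sort(unique(unlist(sets)))
  tallied <- table(factor(unlist(sets), levels = molecule_ids))
  new_retrieval_counts(
    molecule_id = molecule_ids, count = as.vector(tallied),
    n_searches = length(sets), cutoff_count = sizes[1L], search_sets = sets
  )
}

#' Number of searches behind a retrieval-counts object
#'
#' @param counts A `"retrieval_counts"` tibble.
#' @return Integer scalar.
#' @export
n_searches <- function(counts) attr(counts, "n_searches")

#' @rdname n_searches
#' @export
cutoff_count <- function(counts) attr(counts, "cutoff_count")

#' @rdname n_searches
#' @export
search_sets <- function(counts) attr(counts, "search_sets")

# run one battery of searches described by (view, coefficient, reference)
# triples; views are decoded once each
.run_battery <- function(db, refs, views, coefficients, fraction) {
  stopifnot(length(refs) == length(views), length(views) == length(coefficients))
  k <- max(1L, floor(fraction * nrow(db)))
  sets <- vector("list", length(views))
  for (v in unique(views)) {
    B <- .view_matrix(db, v)
    for (i in which(views == v)) {
      ref <- .ref_bits(db, refs[[i]], B = B)
      sim <- .similarities_to_ref(B, ref, coefficients[[i]])
      ord <- order(-sim, db$molecule_id)[seq_len(k)]
      sets[[i]] <- db$molecule_id[ord]
    }
  }
  tallied <- tabulate(match(unlist(sets), db$molecule_id), nbins = nrow(db))
  new_retrieval_counts(
    molecule_id = db$molecule_id, count = tallied,
    n_searches = length(sets), cutoff_count = k, search_sets = sets
  )
}

#' Run a similarity-fusion search battery
#'
#' One reference structure is searched with many similarity measures; each
#' search keeps its top fraction, and the per-molecule retrieval counts over
#' all searches are returned. Duplicate measures are allowed (they simply run
#' twice).
#'
#' @param db An `"fp_database"`.
#' @param reference A `molecule_id` in `db` or a bit vector.
#' @param measures Tibble of measures from [similarity_measures()].
#' @param fraction Top fraction retained per search.
#' @return A `"retrieval_counts"` tibble.
#' @export
run_similarity_fusion <- function(db, reference, measures = similarity_measures(),
                                  fraction = 0.01) {
  if (nrow(measures) < 1L) abort("Need at least one similarity measure.")
  if (any(measures$view > n_views(db))) abort("Measure refers to a missing view.")
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  .run_battery(
    db, refs = rep(list(reference), nrow(measures)),
    views = measures$view, coefficients = measures$coefficient, fraction = fraction
  )
}

#' Run a group-fusion search battery
#'
#' Many reference structures are each searched with the same similarity
#' measure; per-molecule retrieval counts over the searches are returned.
#'
#' @param db An `"fp_database"`.
#' @param references Vector of `molecule_id`s (or list of bit vectors).
#' @param view,coefficient The single similarity measure used for every search.
#' @param fraction Top fraction retained per search.
#' @return A `"retrieval_counts"` tibble.
#' @export
run_group_fusion <- function(db, references, view = n_views(db),
                             coefficient = "tanimoto", fraction = 0.01) {
  if (length(references) < 1L) abort("Need at least one reference structure.")
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  refs <- if (is.list(references)) references else as.list(references)
  .run_battery(
    db, refs = refs, views = rep(as.integer(view), length(refs)),
    coefficients = rep(coefficient, length(refs)), fraction = fraction
  )
}

#' Run a replicated SF or GF experiment on one activity class
#'
#' Replicates the classical protocol: in SF mode each replicate randomly picks
#' one reference from the class and searches it with every measure in the
#' battery; in GF mode each replicate randomly picks `n_references` class
#' members (without replacement within a replicate, independently across
#' replicates) and searches each with the single measure.
#'
#' @param db An `"fp_database"`.
#' @param class_id Activity class to draw references from.
#' @param mode `"SF"` or `"GF"`.
#' @param n_replicates Number of replicate reference draws.
#' @param fraction Top fraction retained per search.
#' @param measures SF battery (default the 5 views x 5 coefficients crossing).
#' @param view,coefficient GF measure (default: last view with Tanimoto).
#' @param n_references References per GF replicate.
#' @param seed Seed for the reference sampling.
#' @return A list of class `"replicated_experiment"`: `counts` (list of
#'   `"retrieval_counts"`, one per replicate), `references` (list of drawn
#'   ids), plus `mode`, `class_id`, `fraction`, `seed`.
#' @export
run_replicated_experiment <- function(db, class_id, mode = c("SF", "GF"),
                                      n_replicates = 10L, fraction = 0.01,
                                      measures = NULL, view = n_views(db),
                                      coefficient = "tanimoto",
                                      n_references = 25L, seed = 1L) {
  mode <- match.arg(mode)
  pool <- db$molecule_id[!is.na(db$class_id) & db$class_id == class_id]
  need <- if (mode == "SF") 1L else n_references
  if (length(pool) < need) {
    abort(sprintf(
      "Class \"%s\" has %d actives but %d references per replicate are needed.",
      class_id, length(pool), need
    ))
  }
  measures <- measures %||% similarity_measures(views = seq_len(n_views(db)))
  set.seed(seed)
  references <- lapply(seq_len(n_replicates), function(i) {
    pool[sample.int(length(pool), need)]
  })
  counts <- lapply(references, function(refs) {
    if (mode == "SF") {
      run_similarity_fusion(db, refs, measures, fraction)
    } else {
      run_group_fusion(db, refs, view = view, coefficient = coefficient,
                       fraction = fraction)
    }
  })
  structure(
    list(counts = counts, references = references, mode = mode,
         class_id = class_id, fraction = fraction, seed = seed),
    class = "replicated_experiment"
  )
}
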