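# Search overlap and search precision statistics, the binomial
# random-retrieval null, common-molecule tables and profile averaging.

new_overlap_profile <- function(s, O, n_searches) {
  structure(
    tibble::tibble(s = as.integer(s), O = O),
    class = c("overlap_profile", class(tibble::tibble())),
    n_searches = as.integer(n_searches)
  )
}

#' Search-overlap profile
#'
#' `O_s` is the number of distinct molecules retrieved by exactly `s` of the
#' `n` searches, for `s = 1..n`; molecules retrieved by no search are
#' excluded. Conservation holds by construction:
#' `sum(s * O_s) = n_searches * cutoff_count`.
#'
#' @param counts A `"retrieval_counts"` tibble.
#' @return An `"overlap_profile"` tibble with columns `s`, `O`.
#' @export
overlap_profile <- function(counts) {
  n <- n_searches(counts)
  O <- tabulate(counts$count[counts$count > 0L], nbins = n)
  new_overlap_profile(seq_len(n), O, n)
}

#' Scaffold-level search-overlap profile
#'
#' A scaffold's retrieval count is the number of searches that retrieved at
#' least one molecule bearing that scaffold; the overlap profile is then
#' taken over scaffolds instead of molecules.
#'
#' @param counts A `"retrieval_counts"` carrying its `search_sets`.
#' @param db The `"fp_database"` supplying `scaffold_id` per molecule.
#' @return An `"overlap_profile"` over scaffolds.
#' @export
scaffold_overlap_profile <- function(counts, db) {
  sets <- search_sets(counts)
  if (is.null(sets)) {
    abort("`counts` does not carry per-search sets; rerun the search drivers.")
  }
  scaffold_of <- setNames(db$scaffold_id, db$molecule_id)
  scaffold_sets <- lapply(sets, function(ids) unique(unname(scaffold_of[as.character(ids)])))
  tallied <- table(unlist(scaffold_sets))
  n <- length(sets)
  O <- tabulate(as.vector(tallied), nbins = n)
  new_overlap_profile(seq_len(n), O, n)
}

#' Search-precision profile
#'
#' `P_s` is the percentage of the molecules retrieved by exactly `s` searches
#' that belong to the target activity class. Buckets with no retrieved
#' molecules are masked (`NA`), not zero, so empty buckets never drag
#' averages.
#'
#' @param counts A `"retrieval_counts"` over a database.
#' @param db The `"fp_database"` supplying activity labels.
#' @param target_class The activity class counted as active.
#' @return A `"precision_profile"` tibble: `s`, `n_molecules`, `n_active`,
#'   `P` (percent, `NA` where undefined).
#' @export
precision_profile <- function(counts, db, target_class) {
  if (!target_class %in% db$class_id) {
    abort(sprintf("Unknown target class \"%s\".", target_class))
  }
  lab <- db$class_id[match(counts$molecule_id, db$molecule_id)]
  if (anyNA(match(counts$molecule_id, db$molecule_id))) {
    abort("Activity labels do not cover all molecules in `counts`.")
  }
  n <- n_searches(counts)
  active <- !is.na(lab) & lab == target_class
  keep <- counts$count > 0L
  n_mol <- tabulate(counts$count[keep], nbins = n)
  n_act <- tabulate(counts$count[keep & active], nbins = n)
  structure(
    tibble::tibble(
      s = seq_len(n), n_molecules = n_mol, n_active = n_act,
      P = ifelse(n_mol > 0L, 100 * n_act / n_mol, NA_real_)
    ),
    class = c("precision_profile", class(tibble::tibble())),
    n_searches = n, target_class = target_class
  )
}

#' Binomial random-retrieval null
#'
#' If each of `n` searches retrieved molecules completely at random with
#' per-molecule probability `p`, the expected number of molecules retrieved
#' exactly `s` times is `E[O_s] = M * choose(n, s) * p^s * (1-p)^(n-s)`. The
#' expectations over `s = 0..n` sum to `M` exactly.
#'
#' Two readings of a "top-x%" probability are supported: `p` as the nominal
#' fraction (e.g. 0.01), or `p = floor(x * M) / M`, the realized fraction
#' after the integer cutoff. Pass whichever the analysis used.
#'
#' @param M Database size.
#' @param p Per-search retrieval probability.
#' @param n Number of searches.
#' @return A `"binomial_null"` tibble: `s` (0..n), `expected`.
#' @export
binomial_null <- function(M, p, n) {
  if (p < 0 || p > 1) abort("`p` must be in [0, 1].")
  structure(
    tibble::tibble(s = 0:n, expected = M * dbinom(0:n, n, p)),
    class = c("binomial_null", class(tibble::tibble())),
    M = M, p = p, n_searches = as.integer(n)
  )
}

#' Numbers of molecules (or scaffolds) common to the first k searches
#'
#' For each requested `k`, reports the size of the intersection of the first
#' `k` search outputs taken in their declared order (`method =
#' "intersection"`, the default), or the number of molecules retrieved by at
#' least `k` of the searches (`method = "threshold"`). `k = 1` gives the
#' single-search set size (the cutoff count).
#'
#' @param counts A `"retrieval_counts"` carrying `search_sets`.
#' @param k Integer vector of search counts; all must be `<= n_searches`.
#' @param method `"intersection"` or `"threshold"`.
#' @param db Optional `"fp_database"`; when given, sets are mapped to
#'   scaffolds first and common scaffolds are counted.
#' @return A tibble `k`, `n_common`.
#' @export
common_molecules_table <- function(counts, k = c(1L, 5L, 10L, 15L, 20L, 25L),
                                   method = c("intersection", "threshold"),
                                   db = NULL) {
  method <- match.arg(method)
  n <- n_searches(counts)
  if (any(k > n) || any(k < 1L)) {
    abort(sprintf("`k` values must lie in 1..%d (the number of searches).", n))
  }
  if (method == "threshold" && is.null(db)) {
    n_common <- vapply(k, function(kk) sum(counts$count >= kk), 0L)
    return(tibble::tibble(k = as.integer(k), n_common = n_common))
  }
  sets <- search_sets(counts)
  if (is.null(sets)) abort("`counts` does not carry per-search sets.")
  if (!is.null(db)) {
    scaffold_of <- setNames(db$scaffold_id, db$molecule_id)
    sets <- lapply(sets, function(ids) unique(unname(scaffold_of[as.character(ids)])))
  }
  n_common <- vapply(k, function(kk) {
    if (method == "intersection") {
      length(Reduce(intersect, sets[seq_len(kk)]))
    } else {
      sum(table(unlist(sets)) >= kk)
    }
  }, 0L)
  tibble::tibble(k = as.integer(k), n_common = n_common)
}

#' Number of searches at which precision peaks
#'
#' Returns the smallest `s` attaining the maximum defined precision (ties are
#' broken toward smaller `s`).
#'
#' @param profile A `"precision_profile"`.
#' @return Integer `s`.
#' @export
argmax_precision <- function(profile) {
  if (all(is.na(profile$P))) abort("All precision buckets are undefined.")
  profile$s[which.max(profile$P)]
}

#' Average a list of overlap or precision profiles
#'
#' Element-wise arithmetic mean across replicates. Overlap counts are averaged
#' directly; precision is averaged only over the replicates where the bucket
#' is defined (a bucket undefined in every replicate stays `NA`).
#'
#' @param profiles Non-empty list of profiles of the same type and
#'   `n_searches`.
#' @return A profile of the same class.
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) == 0L) abort("Cannot average an empty list of profiles.")
  ns <- unique(vapply(profiles, function(p) attr(p, "n_searches"), 0L))
  if (length(ns) != 1L) abort("Profiles have differing `n_searches`.")
  first <- profiles[[1L]]
  if (inherits(first, "overlap_profile")) {
    O <- rowMeans(vapply(profiles, function(p) p$O, numeric(nrow(first))))
    return(new_overlap_profile(first$s, O, ns))
  }
  if (inherits(first, "precision_profile")) {
    Pmat <- vapply(profiles, function(p) p$P, numeric(nrow(first)))
    nm <- rowMeans(vapply(profiles, function(p) p$n_molecules, numeric(nrow(first))))
    na <- rowMeans(vapply(profiles, function(p) p$n_active, numeric(nrow(first))))
    P <- apply(as.matrix(Pmat), 1L, function(row) {
      if (all(is.na(row))) NA_real_ else mean(row, na.rm = TRUE)
    })
    return(structure(
      tibble::tibble(s = first$s, n_molecules = nm, n_active = na, P = P),
      class = class(first), n_searches = ns,
      target_class = attr(first, "target_class")
    ))
  }
  abort("`profiles` must be overlap or precision profiles.")
}
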