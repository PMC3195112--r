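# Synthetic fingerprint databases with the statistical structure the overlap
# analysis assumes: activity classes of controllable homogeneity, scaffold
# clusters inside each class, and several correlated fingerprint views per
# molecule standing in for distinct fingerprint types.

#' Specify one activity class
#'
#' @param class_id Class label (character scalar).
#' @param n_actives Number of active molecules in the class (>= 1).
#' @param noise_rate Per-bit corruption probability in `[0, 0.5]`: each bit of
#'   a class member is redrawn from the background bit distribution with this
#'   probability, which perturbs fingerprints around the class centroid while
#'   preserving their expected on-bit density. 0 gives a perfectly homogeneous
#'   class (all fingerprints identical), larger values give more heterogeneous
#'   classes.
#' @param n_scaffolds Number of scaffold clusters within the class
#'   (`1 <= n_scaffolds <= n_actives`). Each cluster shares a sub-centroid
#'   corrupted away from the class centroid by `scaffold_spread`, so scaffold
#'   structure is coarser than molecule structure.
#' @param scaffold_spread Corruption probability between the class centroid
#'   and each scaffold sub-centroid, in `[0, 1]`. The default, half the class
#'   noise rate, nests scaffolds tightly inside the class; values approaching
#'   1 make the scaffolds independent chemotypes with no common core, the
#'   structure of genuinely heterogeneous activity classes.
#' @return A one-row tibble.
#' @export
activity_class_spec <- function(class_id, n_actives, noise_rate,
                                n_scaffolds = max(1L, n_actives %/% 10L),
                                scaffold_spread = noise_rate / 2) {
  if (n_actives < 1L) abort("`n_actives` must be >= 1.")
  if (noise_rate < 0 || noise_rate > 0.5) abort("`noise_rate` must be in [0, 0.5].")
  if (n_scaffolds < 1L || n_scaffolds > n_actives) {
    abort("`n_scaffolds` must be between 1 and `n_actives`.")
  }
  if (scaffold_spread < 0 || scaffold_spread > 1) {
    abort("`scaffold_spread` must be in [0, 1].")
  }
  tibble::tibble(
    class_id = as.character(class_id), n_actives = as.integer(n_actives),
    noise_rate = noise_rate, n_scaffolds = as.integer(n_scaffolds),
    scaffold_spread = scaffold_spread
  )
}

#' Specify a synthetic fingerprint database
#'
#' @param M Total number of molecules.
#' @param L Bits per fingerprint view.
#' @param V Number of fingerprint views per molecule.
#' @param view_correlation Fraction of bit positions each view copies from the
#'   molecule's master fingerprint, in `[0, 1]`; the remaining positions are
#'   redrawn from the molecule's latent bit model under a per-view stream, so
#'   views are correlated but rank molecules genuinely differently.
#' @param classes Tibble of activity classes, rows as from
#'   [activity_class_spec()]; total actives must not exceed `M`.
#' @param background_density Expected on-bit fraction of inactive molecules
#'   and of class centroids, in `(0, 1)`.
#' @param background_concentration Concentration of the per-molecule on-bit
#'   density of inactives: each inactive draws its own density from a Beta
#'   distribution with mean `background_density` and this concentration
#'   (shape1 + shape2). Finite values give the database a realistic spread of
#'   fingerprint sizes — dense molecules are mildly similar to everything and
#'   act as promiscuous retrievers — while `Inf` fixes every inactive at the
#'   same density.
#' @param seed Master seed; all class, molecule and view randomness is derived
#'   from it.
#' @return A list of class `"db_spec"`.
#' @seealso [default_database_spec()], [generate_database()]
#' @export
database_spec <- function(M, L = 512L, V = 5L, view_correlation = 0.6,
                          classes = NULL, background_density = 0.1,
                          background_concentration = 40, seed = 1L) {
  classes <- classes %||% tibble::tibble(
    class_id = character(), n_actives = integer(),
    noise_rate = double(), n_scaffolds = integer(), scaffold_spread = double()
  )
  if (is.null(classes$scaffold_spread)) {
    classes$scaffold_spread <- classes$noise_rate / 2
  }
  if (sum(classes$n_actives) > M) {
    abort("Total actives across classes exceeds the database size `M`.")
  }
  if (V < 1L) abort("`V` must be >= 1.")
  if (background_density <= 0 || background_density >= 1) {
    abort("`background_density` must be strictly inside (0, 1).")
  }
  if (view_correlation < 0 || view_correlation > 1) {
    abort("`view_correlation` must be in [0, 1].")
  }
  if (anyDuplicated(classes$class_id)) abort("Duplicate `class_id` in `classes`.")
  if (background_concentration <= 0) {
    abort("`background_concentration` must be positive (or Inf).")
  }
  structure(
    list(
      M = as.integer(M), L = as.integer(L), V = as.integer(V),
      view_correlation = view_correlation, classes = classes,
      background_density = background_density,
      background_concentration = background_concentration,
      seed = as.integer(seed)
    ),
    class = "db_spec"
  )
}

#' Default desk-scale database specification
#'
#' 20,000 molecules, five 512-bit views at view correlation 0.6, and eleven
#' activity classes of 100-600 actives whose noise rates span 0.15-0.45 so
#' that class homogeneities range from tight (renin-like) to diffuse
#' (COX-like) while staying modestly above the background similarity level,
#' the regime in which searches retrieve classes partially rather than
#' wholesale. Each class contributes 0.5-3% of the database, preserving the
#' per-class active fraction regime of large screening files at tractable
#' size.
#'
#' @inheritParams database_spec
#' @return A `"db_spec"` object.
#' @export
default_database_spec <- function(M = 20000L, L = 512L, V = 5L,
                                  view_correlation = 0.6,
                                  background_density = 0.1,
                                  background_concentration = 40, seed = 1L) {
  sizes <- seq(600L, 100L, by = -50L)
  noise <- seq(0.15, 0.45, length.out = 11L)
  classes <- purrr::pmap_dfr(
    list(sprintf("class%02d", 1:11), sizes, noise),
    function(id, n, q) activity_class_spec(id, n, q)
  )
  database_spec(
    M = M, L = L, V = V, view_correlation = view_correlation,
    classes = classes, background_density = background_density,
    background_concentration = background_concentration, seed = seed
  )
}

# Substream seeding: one master seed, fixed integer offsets per stage / class
# rank / view. Classes are processed in sorted class_id order so the stream a
# class sees does not depend on the order classes were listed in the spec.
.sub_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + offset * 69621) %% 2147483647
}

.rbits <- function(n, L, p) {
  matrix(rbinom(n * L, 1L, p), nrow = n, ncol = L)
}

# corrupt bits of each row of `m`: with probability q a bit is redrawn from
# Bernoulli(p). Unlike a symmetric XOR flip this preserves the expected on-bit
# density at every noise level, so class homogeneity decreases monotonically
# in the noise rate instead of being confounded by a density shift.
.perturb <- function(m, q, p) {
  if (q == 0) return(m)
  mask <- .rbits(nrow(m), ncol(m), q)
  fresh <- .rbits(nrow(m), ncol(m), p)
  m * (1L - mask) + fresh * mask
}

#' Generate a synthetic fingerprint database
#'
#' Actives in a class are drawn around a random class centroid: each scaffold
#' cluster gets a sub-centroid corrupted at half the class noise rate, and
#' each molecule corrupts sub-centroid bits at the full noise rate (corrupted
#' bits are redrawn from the background density, so density is preserved;
#' this corruption defines the molecule's latent bit model). The master
#' fingerprint is one draw from that model; view `v` copies a
#' `view_correlation` fraction of positions from the master and redraws the
#' rest from the same latent model under a per-view stream. Inactives are
#' i.i.d. Bernoulli(`background_density`) and carry singleton scaffold ids.
#'
#' @param spec A `"db_spec"` from [database_spec()] or
#'   [default_database_spec()].
#' @return A tibble of class `"fp_database"`: `molecule_id`, `class_id` (`NA`
#'   for inactives), `scaffold_id`, and hex fingerprint columns `fp1..fpV`;
#'   attributes `n_bits`, `n_views`, `db_spec`.
#' @examples
#' spec <- database_spec(
#'   M = 200, L = 64, V = 2,
#'   classes = activity_class_spec("A", 20, 0.1, 4), seed = 7
#' )
#' db <- generate_database(spec)
#' @export
generate_database <- function(spec) {
  stopifnot(inherits(spec, "db_spec"))
  L <- spec$L; V <- spec$V; rho <- spec$view_correlation
  classes <- spec$classes[order(spec$classes$class_id), , drop = FALSE]
  n_active <- sum(classes$n_actives)
  n_inactive <- spec$M - n_active

  # shared-bit positions per view, fixed across the whole database
  n_shared <- round(rho * L)
  shared <- lapply(seq_len(V), function(v) {
    set.seed(.sub_seed(spec$seed, 1000 + v))
    sort(sample.int(L, n_shared))
  })

  make_views <- function(master, redraw_fun, stage_offset) {
    # master: n x L; redraw_fun(v) returns an independent n x L draw from the
    # same latent model, used outside the shared positions of view v
    lapply(seq_len(V), function(v) {
      set.seed(.sub_seed(spec$seed, stage_offset + v))
      fresh <- redraw_fun()
      keep <- shared[[v]]
      if (length(keep) > 0L) fresh[, keep] <- master[, keep, drop = FALSE]
      fresh
    })
  }

  rows <- list()
  next_scaffold <- 1L
  for (j in seq_len(nrow(classes))) {
    cl <- classes[j, ]
    set.seed(.sub_seed(spec$seed, 2000 + j))
    centroid <- .rbits(1L, L, spec$background_density)
    sub_centroids <- .perturb(centroid[rep(1L, cl$n_scaffolds), , drop = FALSE],
                              cl$scaffold_spread, spec$background_density)
    sc_of_mol <- sort(rep_len(seq_len(cl$n_scaffolds), cl$n_actives))
    latent <- sub_centroids[sc_of_mol, , drop = FALSE]
    master <- .perturb(latent, cl$noise_rate, spec$background_density)
    views <- make_views(
      master,
      function() .perturb(latent, cl$noise_rate, spec$background_density),
      3000 + 100 * j
    )
    rows[[j]] <- list(
      class_id = rep(cl$class_id, cl$n_actives),
      scaffold_id = next_scaffold - 1L + sc_of_mol,
      views = views
    )
    next_scaffold <- next_scaffold + cl$n_scaffolds
  }

  if (n_inactive > 0L) {
    set.seed(.sub_seed(spec$seed, 4000))
    dens <- if (is.finite(spec$background_concentration)) {
      stats::rbeta(n_inactive,
                   spec$background_density * spec$background_concentration,
                   (1 - spec$background_density) * spec$background_concentration)
    } else {
      rep(spec$background_density, n_inactive)
    }
    # rbinom recycles `dens` down each column, giving molecule i its density
    draw_bg <- function() {
      matrix(rbinom(n_inactive * L, 1L, dens), nrow = n_inactive, ncol = L)
    }
    master <- draw_bg()
    views <- make_views(master, draw_bg, 5000)
    rows[[length(rows) + 1L]] <- list(
      class_id = rep(NA_character_, n_inactive),
      scaffold_id = next_scaffold - 1L + seq_len(n_inactive),
      views = views
    )
  }

  class_id <- unlist(lapply(rows, `[[`, "class_id"))
  scaffold_id <- unlist(lapply(rows, `[[`, "scaffold_id"))
  fps <- lapply(seq_len(V), function(v) {
    fp_to_hex(do.call(rbind, lapply(rows, function(r) r$views[[v]])))
  })
  names(fps) <- paste0("fp", seq_len(V))

  db <- tibble::tibble(
    molecule_id = seq_len(spec$M),
    class_id = class_id, scaffold_id = as.integer(scaffold_id), !!!fps
  )
  new_fp_database(db, n_bits = L, n_views = V, db_spec = spec)
}

new_fp_database <- function(db, n_bits, n_views, db_spec = NULL) {
  structure(db,
    class = c("fp_database", class(tibble::tibble())),
    n_bits = as.integer(n_bits), n_views = as.integer(n_views),
    db_spec = db_spec
  )
}

#' Fingerprint length and view count of a database
#'
#' @param db An `"fp_database"` tibble.
#' @return An integer scalar.
#' @export
n_bits <- function(db) attr(db, "n_bits")

#' @rdname n_bits
#' @export
n_views <- function(db) attr(db, "n_views")

# decode one view of the database into an M x L integer bit matrix
.view_matrix <- function(db, view) {
  V <- n_views(db)
  if (view < 1L || view > V) abort(sprintf("`view` must be in 1..%d.", V))
  fp_from_hex(db[[paste0("fp", view)]], n_bits(db))
}

#' Mean pairwise similarity within an activity class
#'
#' The homogeneity of an activity class is its mean pairwise fingerprint
#' similarity over all unordered pairs of class members.
#'
#' @param db An `"fp_database"`.
#' @param class_id Class label; the class must have at least 2 members.
#' @param view Which fingerprint view to use.
#' @param coefficient Similarity coefficient, default Tanimoto.
#' @return Mean pairwise similarity (in `[0, 1]` for Tanimoto).
#' @export
class_homogeneity <- function(db, class_id, view = 1L, coefficient = "tanimoto") {
  idx <- which(!is.na(db$class_id) & db$class_id == class_id)
  if (length(idx) < 2L) {
    abort(sprintf("Class \"%s\" needs >= 2 members, found %d.", class_id, length(idx)))
  }
  B <- .view_matrix(db, view)[idx, , drop = FALSE]
  A <- tcrossprod(B)                     # pairwise `a` counts
  on <- rowSums(B)
  n <- length(idx); L <- ncol(B)
  pair <- which(upper.tri(A), arr.ind = TRUE)
  a <- A[pair]
  bi <- on[pair[, 1L]] - a
  ci <- on[pair[, 2L]] - a
  counts <- tibble::tibble(a = a, b = bi, c = ci, d = L - a - bi - ci, n_bits = L)
  mean(similarity_from_counts(counts, coefficient))
}
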