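test_that("the four-searches worked example gives profile (3, 3, 1, 0)", {
  counts <- table3_counts()
  op <- overlap_profile(counts)
  expect_equal(op$O, c(3L, 3L, 1L, 0L))
  # 6 instances held by twice-retrieved molecules, 3 by the thrice-retrieved
  expect_equal(2 * op$O[2], 6)
  expect_equal(3 * op$O[3], 3)
  expect_equal(sum(op$s * op$O), 12)
  expect_equal(sum(op$s * op$O), n_searches(counts) * cutoff_count(counts))
})

test_that("overlap profiles match the brute-force histogram", {
  set.seed(61)
  n <- 6
  counts <- retrieval_counts_from_sets(
    lapply(seq_len(n), function(i) sample(letters, 10))
  )
  op <- overlap_profile(counts)
  expect_equal(op$O, bf_overlap_histogram(counts$count, n))

  # all molecules at the same count concentrates the profile
  all_n <- retrieval_counts_from_sets(rep(list(c("a", "b", "c")), 4))
  op_n <- overlap_profile(all_n)
  expect_equal(op_n$O, c(0L, 0L, 0L, 3L))
})

test_that("precision masks empty buckets and matches brute force", {
  db <- tiny_db(M = 40, L = 64, V = 1, n_actives = 10, seed = 71)
  cnt <- run_similarity_fusion(
    db, db$molecule_id[1],
    similarity_measures(1, similarity_coefficients()), 0.1
  )
  pp <- precision_profile(cnt, db, "act")
  is_active <- !is.na(db$class_id) & db$class_id == "act"
  expect_equal(pp$P, bf_precision(cnt$count, is_active, n_searches(cnt)))
  expect_true(all(is.na(pp$P[pp$n_molecules == 0])))
  expect_true(all(pp$P[!is.na(pp$P)] >= 0 & pp$P[!is.na(pp$P)] <= 100))
  expect_error(precision_profile(cnt, db, "nope"), "Unknown target class")

  # 1 active among 4 molecules at s = 2 is 25%
  sets <- list(c(1, 2, 3, 4), c(1, 2, 3, 4), c(5, 6, 7, 8))
  cnt2 <- retrieval_counts_from_sets(sets, molecule_ids = 1:9)
  fake_db <- tiny_db(M = 9, L = 32, V = 1, n_actives = 1, n_scaffolds = 1, seed = 5)
  # molecule 1 is the active; counts of 1..4 are 2, others vary
  pp2 <- precision_profile(cnt2, fake_db, "act")
  expect_equal(pp2$P[2], 25)
})

test_that("scaffold-level overlap collapses molecules onto scaffolds", {
  db <- tiny_db(M = 30, L = 64, V = 1, n_actives = 12, n_scaffolds = 3,
                seed = 81)
  cnt <- run_similarity_fusion(
    db, db$molecule_id[1],
    similarity_measures(1, c("tanimoto", "cosine", "forbes")), 0.2
  )
  sp <- scaffold_overlap_profile(cnt, db)
  # brute force: a scaffold is hit by a search if any of its molecules is
  sets <- search_sets(cnt)
  scaffold_of <- setNames(db$scaffold_id, db$molecule_id)
  sc_sets <- lapply(sets, function(ids) unique(scaffold_of[as.character(ids)]))
  sc_counts <- table(unlist(sc_sets))
  expect_equal(sp$O, vapply(1:3, function(s) sum(sc_counts == s), 0L))

  # unique scaffolds per molecule make it identical to the molecule profile
  db_uni <- db
  db_uni$scaffold_id <- seq_len(nrow(db))
  expect_equal(scaffold_overlap_profile(cnt, db_uni)$O, overlap_profile(cnt)$O)

  # one shared scaffold collapses to a single count
  db_one <- db
  db_one$scaffold_id <- rep(1L, nrow(db))
  sp_one <- scaffold_overlap_profile(cnt, db_one)
  expect_equal(sum(sp_one$O), 1)
  expect_equal(sp_one$O[3], 1L)  # all three searches retrieve something
})

test_that("binomial null matches the closed form and sums to M", {
  # the worked large-database case: M = 138,127, top-1%, 25 searches
  nul <- binomial_null(M = 138127, p = 0.01, n = 25)
  expect_equal(nul$expected[nul$s == 1], 138127 * 25 * 0.01 * 0.99^24)
  expect_equal(nul$expected[nul$s == 1], 27130.84, tolerance = 1e-6)
  expect_lt(nul$expected[nul$s == 5], 1)
  expect_equal(sum(nul$expected), 138127, tolerance = 1e-9)

  # realized-fraction convention lands just below the nominal one
  p_floor <- floor(0.01 * 138127) / 138127
  nul2 <- binomial_null(M = 138127, p = p_floor, n = 25)
  expect_equal(nul2$expected[nul2$s == 1], 27126.82, tolerance = 1e-6)

  set.seed(5)
  spec <- list(M = 500, p = 0.03, n = 10)
  nul3 <- binomial_null(spec$M, spec$p, spec$n)
  expect_equal(sum(nul3$expected), spec$M, tolerance = 1e-9 * spec$M)
})

test_that("common-molecule tables match brute-force intersections", {
  sets <- list(c(1, 2, 3, 4), c(2, 3, 4, 5), c(3, 4, 5, 6), c(4, 5, 6, 7))
  cnt <- retrieval_counts_from_sets(sets)
  tab <- common_molecules_table(cnt, k = 1:4)
  expect_equal(tab$n_common[1], cutoff_count(cnt))
  expect_equal(tab$n_common,
               vapply(1:4, function(k) bf_intersection_size(sets, k), 0L))

  # identical searches keep the intersection constant
  same <- retrieval_counts_from_sets(rep(list(c(1, 2, 3)), 5))
  expect_true(all(common_molecules_table(same, k = 1:5)$n_common == 3))

  # threshold variant counts molecules with count >= k
  tab_thr <- common_molecules_table(cnt, k = 1:4, method = "threshold")
  expect_equal(tab_thr$n_common,
               vapply(1:4, function(k) sum(cnt$count >= k), 0L))
  expect_error(common_molecules_table(cnt, k = 9), "1..4")
})

test_that("argmax precision takes the smallest maximizing s", {
  mk <- function(P) {
    structure(
      tibble::tibble(s = seq_along(P), n_molecules = ifelse(is.na(P), 0L, 10L),
                     n_active = 0L, P = P),
      class = c("precision_profile", class(tibble::tibble())),
      n_searches = length(P), target_class = "x"
    )
  }
  expect_equal(argmax_precision(mk(c(10, 20, 30, 40))), 4)
  expect_equal(argmax_precision(mk(c(10, 80, 40))), 2)
  expect_equal(argmax_precision(mk(c(10, 80, 80))), 2)      # tie to smaller s
  expect_equal(argmax_precision(mk(c(NA, 50, NA))), 2)
  expect_error(argmax_precision(mk(c(NA_real_, NA_real_))), "undefined")
})

test_that("profile averaging is the element-wise mean over replicates", {
  p1 <- overlap_profile(retrieval_counts_from_sets(list(c(1, 2), c(2, 3))))
  p2 <- overlap_profile(retrieval_counts_from_sets(list(c(1, 2), c(1, 2))))
  avg <- average_profiles(list(p1, p2))
  expect_equal(avg$O, (p1$O + p2$O) / 2)
  expect_equal(average_profiles(list(p1, p1))$O, p1$O)

  # ten random overlap profiles match the direct mean
  set.seed(91)
  profs <- lapply(1:10, function(i) {
    retrieval_counts_from_sets(lapply(1:3, function(j) sample(1:20, 5))) |>
      overlap_profile()
  })
  avg10 <- average_profiles(profs)
  expect_equal(avg10$O, rowMeans(sapply(profs, function(p) p$O)))

  # precision is averaged only over replicates where defined
  mkp <- function(P, nm) {
    structure(
      tibble::tibble(s = seq_along(P), n_molecules = nm,
                     n_active = 0L, P = P),
      class = c("precision_profile", class(tibble::tibble())),
      n_searches = length(P), target_class = "x"
    )
  }
  pa <- mkp(c(50, NA), c(2L, 0L))
  pb <- mkp(c(70, 30), c(2L, 2L))
  avg_p <- average_profiles(list(pa, pb))
  expect_equal(avg_p$P, c(60, 30))
  expect_error(average_profiles(list()), "empty list")
})
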