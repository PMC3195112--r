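test_that("an exact copy of the reference ranks first", {
  db <- tiny_db(M = 40, L = 64, V = 1, seed = 2)
  ref <- db$molecule_id[5]
  rk <- rank_database(db, ref, 1, "tanimoto")
  expect_equal(rk$molecule_id[1], ref)
  expect_equal(rk$similarity[1], 1)
  expect_error(rank_database(db[0, ], ref), "empty database")
})

test_that("rankings equal the brute-force sort on small databases", {
  set.seed(7)
  db <- tiny_db(M = 5, L = 32, V = 2, n_actives = 2, seed = 8)
  for (view in 1:2) {
    fps <- db_bits_list(db, view)
    for (co in similarity_coefficients()) {
      rk <- rank_database(db, db$molecule_id[1], view, co)
      expect_equal(rk$molecule_id,
                   bf_rank(fps, db$molecule_id, fps[[1]], co),
                   info = paste(view, co))
    }
  }
})

test_that("Tanimoto and Cosine can order the same view differently", {
  # search small random databases for a discordant ordering
  found <- FALSE
  for (seed in 1:20) {
    db <- tiny_db(M = 12, L = 24, V = 1, n_actives = 3, noise = 0.4,
                  seed = seed)
    rt <- rank_database(db, db$molecule_id[1], 1, "tanimoto")$molecule_id
    rc <- rank_database(db, db$molecule_id[1], 1, "cosine")$molecule_id
    if (!identical(rt, rc)) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("top_fraction applies the floor rule with a minimum of one", {
  rk <- tibble::tibble(molecule_id = 1:1000, similarity = runif(1000),
                       rank = 1:1000)
  expect_equal(nrow(top_fraction(rk, 0.01)), 10)
  expect_equal(attr(top_fraction(rk, 0.01), "cutoff_count"), 10)
  rk_large <- tibble::tibble(molecule_id = seq_len(138127),
                             similarity = 0, rank = seq_len(138127))
  expect_equal(nrow(top_fraction(rk_large, 0.01)), 1381)
  rk_small <- rk[1:50, ]
  expect_equal(nrow(top_fraction(rk_small, 0.01)), 1)
  expect_error(top_fraction(rk, 0), "fraction")
})

test_that("similarity fusion counts behave in degenerate batteries", {
  db <- tiny_db(M = 50, L = 64, V = 1, seed = 13)
  same <- similarity_measures(views = 1, coefficients = "tanimoto")
  battery25 <- same[rep(1, 25), ]
  cnt <- run_similarity_fusion(db, db$molecule_id[1], battery25, 0.1)
  expect_true(all(cnt$count %in% c(0L, 25L)))
  op <- overlap_profile(cnt)
  expect_true(all(op$O[1:24] == 0))
  expect_equal(op$O[25], cutoff_count(cnt))

  single <- run_similarity_fusion(db, db$molecule_id[1], same, 0.1)
  expect_true(all(single$count %in% c(0L, 1L)))
  expect_equal(sum(single$count), cutoff_count(single))
})

test_that("fusion counts match the brute-force tally", {
  db <- tiny_db(M = 20, L = 48, V = 2, n_actives = 6, seed = 21)
  measures <- tibble::tibble(view = c(1L, 2L, 1L),
                             coefficient = c("tanimoto", "cosine", "forbes"))
  frac <- 0.2
  cnt <- run_similarity_fusion(db, db$molecule_id[3], measures, frac)
  sets <- lapply(seq_len(nrow(measures)), function(i) {
    fps <- db_bits_list(db, measures$view[i])
    bf_top_set(fps, db$molecule_id, fps[[3]], measures$coefficient[i], frac)
  })
  expect_equal(cnt$count, bf_counts(sets, db$molecule_id))

  # group fusion, 2 references on a 10-molecule toy
  db10 <- tiny_db(M = 10, L = 32, V = 1, n_actives = 4, seed = 22)
  refs <- db10$molecule_id[c(2, 7)]
  gf <- run_group_fusion(db10, refs, view = 1, coefficient = "tanimoto",
                         fraction = 0.3)
  fps <- db_bits_list(db10, 1)
  sets <- lapply(c(2, 7), function(i) {
    bf_top_set(fps, db10$molecule_id, fps[[i]], "tanimoto", 0.3)
  })
  expect_equal(gf$count, bf_counts(sets, db10$molecule_id))
})

test_that("identical group-fusion references give all-or-nothing counts", {
  db <- tiny_db(M = 30, L = 48, V = 1, seed = 31)
  refs <- rep(db$molecule_id[4], 25)
  cnt <- run_group_fusion(db, refs, view = 1, fraction = 0.1)
  expect_true(all(cnt$count %in% c(0L, 25L)))
  expect_error(run_group_fusion(db, integer(0)), "at least one reference")
})

test_that("counts conserve total retrieval instances and ignore search order", {
  db <- tiny_db(M = 60, L = 64, V = 2, seed = 41)
  measures <- similarity_measures(1:2)
  cnt <- run_similarity_fusion(db, db$molecule_id[2], measures, 0.05)
  expect_equal(sum(cnt$count), n_searches(cnt) * cutoff_count(cnt))

  perm <- measures[sample.int(nrow(measures)), ]
  cnt2 <- run_similarity_fusion(db, db$molecule_id[2], perm, 0.05)
  expect_equal(cnt$count, cnt2$count)
})

test_that("replicated experiments are seeded and sized correctly", {
  db <- tiny_db(M = 80, L = 64, V = 2, n_actives = 30, seed = 51)
  e1 <- run_replicated_experiment(db, "act", "SF", n_replicates = 3,
                                  fraction = 0.05,
                                  measures = similarity_measures(1:2),
                                  seed = 99)
  e2 <- run_replicated_experiment(db, "act", "SF", n_replicates = 3,
                                  fraction = 0.05,
                                  measures = similarity_measures(1:2),
                                  seed = 99)
  expect_identical(e1$counts, e2$counts)
  expect_identical(e1$references, e2$references)

  single <- run_replicated_experiment(db, "act", "GF", n_replicates = 1,
                                      n_references = 5, seed = 1)
  expect_length(single$counts, 1)
  expect_length(single$references[[1]], 5)
  expect_equal(anyDuplicated(single$references[[1]]), 0)

  for (cnt in e1$counts) {
    expect_equal(sum(cnt$count), n_searches(cnt) * cutoff_count(cnt))
  }
  expect_error(
    run_replicated_experiment(db, "act", "GF", n_references = 100, seed = 1),
    "references per replicate"
  )
})
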