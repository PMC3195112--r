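# Shared fixtures, all generated in code.

random_bits <- function(L, p = 0.3) rbinom(L, 1, p)

# the four-searches-of-three worked example: counts A=2, B=2, C=3, D=2,
# F=G=H=1, twelve retrieval instances in total
table3_counts <- function() {
  retrieval_counts_from_sets(list(
    c("A", "B", "C"), c("A", "C", "D"), c("B", "C", "D"), c("F", "G", "H")
  ))
}

tiny_db <- function(M = 60, L = 64, V = 2, n_actives = 12, noise = 0.1,
                    n_scaffolds = min(3L, n_actives), seed = 42) {
  generate_database(database_spec(
    M = M, L = L, V = V,
    classes = activity_class_spec("act", n_actives, noise, n_scaffolds),
    seed = seed
  ))
}

two_class_db <- function(M = 400, L = 128, V = 3, seed = 7,
                         noise = c(0.05, 0.3)) {
  generate_database(database_spec(
    M = M, L = L, V = V,
    classes = dplyr::bind_rows(
      activity_class_spec("tight", 40, noise[1], 8),
      activity_class_spec("loose", 40, noise[2], 8)
    ),
    seed = seed
  ))
}
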