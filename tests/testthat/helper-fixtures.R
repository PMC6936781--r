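# small in-code fixtures shared across test files

tiny_abundance <- function(counts = matrix(c(3, 1, 0, 4), 2, 2, byrow = TRUE),
                           ...) {
  abundance_table(counts, sample_ids = c("F1", "F2"),
                  taxon_ids = c("gA", "gB"), ...)
}

random_abundance <- function(n = 6, p = 10, seed = 1, max_count = 50) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda = 5), n, p,
              dimnames = list(paste0("F", seq_len(n)),
                              paste0("g", seq_len(p))))
  m[1, ] <- m[1, ] + 1  # guard against an all-zero sample
  abundance_table(m)
}

tiny_annotation <- function() {
  data.frame(
    component_id = c("v1", "v2", "v3", "a1", "a2"),
    kind = c("VF", "VF", "VF", "AA", "AA"),
    category = c("ester", "acid", "other", NA, NA),
    taste_class = c(NA, NA, NA, "umami", "bitter"),
    stringsAsFactors = FALSE)
}

tiny_flavor <- function(n = 4, seed = 2) {
  set.seed(seed)
  ann <- tiny_annotation()
  m <- matrix(runif(n * 5, 1, 10), n, 5,
              dimnames = list(paste0("F", seq_len(n)), ann$component_id))
  flavor_table(m, annotation = ann)
}

# all permutations of 1..n (tiny n), independent of the package internals
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# a network built directly from a hand-made correlation matrix
hand_network <- function(cutoff = 0.7) {
  r <- matrix(c(0.71, -0.75, 0.69,
                0.10,  0.95, -0.85),
              2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("v1", "a1", "v2")))
  threshold_network(r, cutoff)
}
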