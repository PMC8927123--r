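# Shared fixtures, all generated in code.

# The 50-node study network: 5 planted clusters of sizes 10, 4, 7, 20, 9.
study_sizes <- c(10L, 4L, 7L, 20L, 9L)

# Scaled-down 30-node variant with the same 5-cluster shape.
small_sizes <- c(6L, 3L, 4L, 12L, 5L)

planted_study_network <- function(seed = 1, sizes = study_sizes, ...) {
  planted_equitable_network(quotient_spec(sizes, ...), seed = seed)
}

# A tiny directed weighted network used across I/O tests.
tiny_net <- function() {
  a <- matrix(0, 3, 3)
  a[2, 1] <- 2.0   # a -> b
  a[3, 2] <- 1.0   # b -> c
  a[1, 3] <- 0.5   # c -> a
  weighted_network(a, labels = c("a", "b", "c"))
}

# Random partition of n nodes into exactly k non-empty clusters.
random_partition <- function(n, k) {
  repeat {
    x <- sample.int(k, n, replace = TRUE)
    if (length(unique(x)) == k) return(node_partition(x))
  }
}

expect_partition_equal <- function(p1, p2) {
  expect_true(same_partition(p1, p2))
}
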