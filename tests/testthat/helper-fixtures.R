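# Fixture builders shared across the test files. Everything is generated
# in code under fixed seeds; nothing is read from disk.

random_count_table <- function(n_samples = 6, n_taxa = 8, seed = 1,
                               depth = 500) {
  withr::with_seed(seed, {
    m <- t(sapply(seq_len(n_samples), function(i) {
      p <- rgamma(n_taxa, 1)
      as.integer(rmultinom(1, depth, p / sum(p)))
    }))
    dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)),
                        sprintf("t%02d", seq_len(n_taxa)))
    count_table(m)
  })
}

# Distances of two tight, well-separated point clouds in the plane.
two_cluster_dist <- function(n_per = 10, sep = 50, seed = 1) {
  withr::with_seed(seed, {
    pts <- rbind(matrix(rnorm(n_per * 2, 0, 0.5), ncol = 2),
                 matrix(rnorm(n_per * 2, sep, 0.5), ncol = 2))
    rownames(pts) <- sprintf("s%02d", seq_len(2 * n_per))
    dist(pts)
  })
}

write_tsv_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
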