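# Shared fixtures, all generated in code.

# Balanced set of synthetic fundus images resized for TinyCNN.
tiny_image_set <- function(n_per_grade, seed) {
  imgs <- vector("list", n_per_grade * 5L)
  k <- 0L
  for (g in 0:4) for (i in seq_len(n_per_grade)) {
    k <- k + 1L
    img <- gen_fundus_image(g, 64, seed = seed * 100000L + k)
    imgs[[k]] <- graded_image(resize_for_model(img$pixels, "TinyCNN"),
                              g, source_id = sprintf("t%04d", k))
  }
  imgs
}

# Random valid probability row(s).
random_prob_rows <- function(n) {
  m <- matrix(rgamma(n * 5, shape = 1), n, 5)
  m / rowSums(m)
}

# Published counts, hand-entered independently of the package fixture file.
table4_counts <- matrix(c(
  3565,  36,  68,  1,  3,
   204,  87,  54,  0,  1,
   140,  47, 540, 15, 10,
     7,   0,  55, 54,  7,
     4,   1,  18, 12, 71), 5, 5, byrow = TRUE)

# Expand a count matrix into label vectors realising it.
labels_from_counts <- function(counts) {
  truth <- integer(0); pred <- integer(0)
  for (i in 1:5) for (j in 1:5) {
    k <- counts[i, j]
    if (k > 0) {
      truth <- c(truth, rep(i - 1L, k))
      pred <- c(pred, rep(j - 1L, k))
    }
  }
  list(truth = truth, pred = pred)
}
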