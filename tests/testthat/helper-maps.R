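# fixture builders shared across the suite (all generated in code)

# homogeneous construction with a fraction of entries randomly reshuffled:
# frac = 0 is perfectly region-pure, frac = 1 is a full permutation
mixed_homogeneous_map <- function(shape = c(32, 32), region_size = 8,
                                  frac = 0.5, seed = 42) {
  m <- region_homogeneous_map(shape, region_size, 2)
  lab <- unclass(m)
  n <- length(lab)
  set.seed(seed)
  k <- round(frac * n)
  if (k > 1) {
    idx <- sample.int(n, k)
    lab[idx] <- lab[idx][sample.int(k)]
  }
  trait_matrix(lab, C = attr(m, "C"), decoding = attr(m, "decoding"))
}

# fully occupied random label matrix (every cell holds one of C labels)
random_label_matrix <- function(shape = c(32, 32), C = 3, seed = 1) {
  set.seed(seed)
  trait_matrix(array(sample.int(C, prod(shape), replace = TRUE),
                     dim = shape), C = C)
}

# small spot table with two anti-correlated traits on a 2x2 lattice
demo_spot_table <- function() {
  as_spot_table(data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
                           GATA3 = c(1, 2, 3, 4), ESR1 = c(4, 3, 2, 1)))
}
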