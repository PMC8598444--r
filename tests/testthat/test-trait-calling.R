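test_that("median binarization is strictly above-median, ties to absent", {
  tab <- as_spot_table(data.frame(x = 0:3, y = 0, g = c(1, 2, 3, 4)))
  tens <- binarize_traits(tab)
  expect_equal(as.vector(tens$presence[, 1, 1]), c(0, 0, 1, 1))

  const <- as_spot_table(data.frame(x = 0:3, y = 0, g = c(5, 5, 5, 5)))
  expect_equal(as.vector(binarize_traits(const)$presence[, 1, 1]),
               c(0, 0, 0, 0))

  two <- binarize_traits(demo_spot_table())
  expect_equal(as.vector(two$presence[, , 1]), c(0, 0, 1, 1))  # GATA3
  expect_equal(as.vector(two$presence[, , 2]), c(1, 1, 0, 0))  # ESR1
})

test_that("binarization is invariant to strictly monotone transforms", {
  set.seed(3)
  for (i in 1:10) {
    v <- rnorm(20)
    tab1 <- as_spot_table(data.frame(x = 0:19, y = 0, g = v))
    tab2 <- as_spot_table(data.frame(x = 0:19, y = 0, g = exp(v)))
    tab3 <- as_spot_table(data.frame(x = 0:19, y = 0, g = rank(v)))
    p1 <- binarize_traits(tab1)$presence
    expect_equal(binarize_traits(tab2)$presence, p1)
    expect_equal(binarize_traits(tab3)$presence, p1)
  }
})

test_that("fixed thresholds and input errors are handled", {
  tab <- as_spot_table(data.frame(x = 0:3, y = 0, g = c(1, 2, 3, 4)))
  expect_equal(as.vector(binarize_traits(tab, threshold = 3)$presence[, 1, 1]),
               c(0, 0, 0, 1))
  expect_error(as_spot_table(data.frame(x = 0:1, y = 0, g = c("a", "b"))),
               "not numeric")
  expect_error(as_spot_table(data.frame(x = 0:1, y = 0)), "no trait")
})

test_that("unmeasured lattice positions are distinguished from trait-free spots", {
  # 3 spots on a 2x2 lattice: position (2,2) carries no spot
  tab <- as_spot_table(data.frame(x = c(0, 1, 0), y = c(0, 0, 1),
                                  g = c(5, 1, 9)))
  tens <- binarize_traits(tab)
  expect_equal(tens$shape, c(2L, 2L))
  expect_false(tens$occupied[2, 2])
  expect_true(is.na(tens$presence[2, 2, 1]))
  m <- encode_combinations(tens)
  expect_true(is.na(unclass(m)[2, 2]))   # no spot -> None
  expect_true(is.na(unclass(m)[2, 1]))   # spot, no trait above -> None
})

test_that("combination encoding counts observed or full subsets", {
  # seven traits, full mode: C = 2^7 - 1 = 127
  set.seed(11)
  tab7 <- as_spot_table(cbind(data.frame(x = rep(0:9, 10),
                                         y = rep(0:9, each = 10)),
                              matrix(rnorm(700), 100, 7,
                                     dimnames = list(NULL, paste0("G", 1:7)))))
  m_full <- encode_combinations(binarize_traits(tab7), c_mode = "full")
  expect_identical(attr(m_full, "C"), 127L)

  # two traits with only {A} and {A,B} present -> observed C = 2
  tens <- structure(list(
    presence = array(c(1L, 1L, 1L, 1L, 0L, 1L, 0L, 1L), dim = c(2, 2, 2)),
    occupied = array(TRUE, c(2, 2)), shape = c(2L, 2L),
    trait_names = c("A", "B"), origin = c(0L, 0L),
    threshold = c(NA, NA)), class = "trait_tensor")
  m_obs <- encode_combinations(tens, c_mode = "observed")
  expect_identical(attr(m_obs, "C"), 2L)
  expect_setequal(vapply(attr(m_obs, "decoding"), paste, "", collapse = "+"),
                  c("A", "A+B"))

  # FOXA1/MKI67-style census: all three of {A}, {B}, {A,B} present -> C = 3
  tens3 <- structure(list(
    presence = array(c(1L, 0L, 1L, 0L, 0L, 1L, 1L, 0L), dim = c(2, 2, 2)),
    occupied = array(TRUE, c(2, 2)), shape = c(2L, 2L),
    trait_names = c("FOXA1", "MKI67"), origin = c(0L, 0L),
    threshold = c(NA, NA)), class = "trait_tensor")
  m3 <- encode_combinations(tens3, c_mode = "observed")
  expect_identical(attr(m3, "C"), 3L)
})

test_that("observed decoding equals the set of subsets in the tensor", {
  set.seed(21)
  for (i in 1:5) {
    t <- sample(2:4, 1)
    pres <- array(rbinom(36 * t, 1, 0.5), dim = c(6, 6, t))
    tens <- structure(list(presence = pres, occupied = array(TRUE, c(6, 6)),
                           shape = c(6L, 6L),
                           trait_names = LETTERS[seq_len(t)],
                           origin = c(0L, 0L), threshold = rep(NA_real_, t)),
                      class = "trait_tensor")
    m <- encode_combinations(tens, "observed")
    expect_lte(attr(m, "C"), 2^t - 1)
    # decode every occupied cell and compare with its presence row
    lab <- unclass(m)
    dec <- attr(m, "decoding")
    for (cell in which(!is.na(lab))) {
      pos <- arrayInd(cell, c(6, 6))
      subset <- LETTERS[seq_len(t)][pres[pos[1], pos[2], ] == 1]
      expect_identical(dec[[lab[cell]]], subset)
    }
  }
})

test_that("nearest-neighbour resize replicates, is identity-safe and closed", {
  m <- trait_matrix(matrix(c(1L, 3L, 2L, NA), 2, 2), C = 3)
  up <- resize_nearest(m, c(4, 4))
  expect_equal(unclass(up)[1:2, 1:2], matrix(1L, 2, 2))
  expect_equal(unclass(up)[3:4, 3:4], matrix(NA_integer_, 2, 2))
  expect_equal(dim(up), c(4L, 4L))

  same <- resize_nearest(m, dim(m))
  expect_identical(unclass(same), unclass(m))

  set.seed(5)
  big <- trait_matrix(matrix(sample(c(NA, 1:2), 120 * 80, replace = TRUE),
                             120, 80), C = 2)
  small <- resize_nearest(big, c(90, 90))
  expect_equal(dim(small), c(90L, 90L))
  expect_true(all(unclass(small)[!is.na(unclass(small))] %in% 1:2))
  expect_identical(attr(small, "C"), attr(big, "C"))
  expect_error(resize_nearest(big, c(90, 0)), "positive")
})

test_that("spot tables reject duplicate or missing coordinates", {
  expect_error(as_spot_table(data.frame(x = c(0, 0), y = c(1, 1),
                                        g = c(1, 2))),
               "duplicate")
  expect_error(as_spot_table(data.frame(a = 1, b = 2, g = 3)),
               "x and y")
})
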