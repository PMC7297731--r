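barcode_from <- function(dim, birth, death) {
  wphom:::new_barcode(dim, birth, death)
}

test_that("PBN counts bars over closed intervals, infinite bars forever", {
  bc <- barcode_from(c(0, 0, 0), c(0, 0, 0), c(1, 2, Inf))
  pbn <- persistent_betti_number(bc, 0, c(1, 1.5, 3))
  expect_equal(pbn$value, c(3, 2, 1))

  # dim-0 curve starts at the point count and never increases
  d <- withr::with_seed(61, rand_dist(12))
  bc2 <- betti0_union_find(d)
  curve <- persistent_betti_number(bc2, 0, seq(0, max(d), length.out = 50))
  expect_equal(curve$value[1], 12)
  expect_true(all(diff(curve$value) <= 0))
  expect_equal(curve$value[50], 1)   # connected: reduces to one
  expect_error(persistent_betti_number(bc, 0, c(2, 1)), "ascending")
})

test_that("largest finite death is found and absent bars are an error", {
  bc <- barcode_from(c(0, 0, 0, 0), c(0, 0, 0, 0), c(2, 2, 4, Inf))
  expect_equal(max_finite_death(bc, 0), 4)
  expect_equal(max_finite_death(barcode_from(0, 0, 1), 0), 1)
  withr::with_seed(67, {
    deaths <- runif(20, 0, 9)
    bcr <- barcode_from(rep(0, 20), rep(0, 20), deaths)
    expect_equal(max_finite_death(bcr, 0), max(deaths))
  })
  expect_error(max_finite_death(barcode_from(0, 0, Inf), 0), "finite")
})

test_that("persistent entropy matches direct evaluation and its bounds", {
  expect_equal(persistent_entropy(barcode_from(0, 0, 5), 0), 0)

  bc <- barcode_from(c(0, 0), c(0, 0), c(1, 3))
  expect_equal(persistent_entropy(bc, 0),
               -(0.25 * log(0.25) + 0.75 * log(0.75)))
  expect_equal(persistent_entropy(bc, 0), 0.5623, tolerance = 1e-4)

  # infinite bar included: probability 1 on it, entropy exactly 0
  bci <- barcode_from(c(0, 0, 0), c(0, 0, 0), c(1, 3, Inf))
  expect_identical(persistent_entropy(bci, 0, include_infinite = TRUE), 0)
  # excluded by default: only finite bars enter
  expect_equal(persistent_entropy(bci, 0), persistent_entropy(bc, 0))

  # empty barcode: 0 by definition
  expect_equal(persistent_entropy(barcode_from(integer(0), numeric(0),
                                               numeric(0)), 1), 0)

  withr::with_seed(71, {
    for (rep in 1:20) {
      n <- sample(2:12, 1)
      lens <- runif(n, 0.1, 5)
      bcr <- barcode_from(rep(1, n), rep(0, n), lens)
      s <- persistent_entropy(bcr, 1)
      expect_gte(s, 0)
      expect_lte(s, log(n) + 1e-12)
    }
    # equality iff all lengths equal
    expect_equal(persistent_entropy(
      barcode_from(rep(1, 6), rep(2, 6), rep(5, 6)), 1), log(6))
  })
})

test_that("Betti energy is alpha * (length/eta)^kappa with infinite limit", {
  p <- entropy_params()
  expect_equal(betti_energy(2, p), 4)
  expect_equal(betti_energy(0, p), 0)
  expect_identical(betti_energy(Inf, p), Inf)
  p2 <- entropy_params(alpha = 2, eta = 0.5, kappa = 3)
  expect_equal(betti_energy(1, p2), 2 * 2^3)
  expect_error(entropy_params(kappa = 0), "positive")
})

test_that("Boltzmann probabilities invert the length ordering and sum to 1", {
  bc <- barcode_from(c(0, 0), c(0, 0), c(1, 2))
  pr <- boltzmann_probabilities(bc, 0)
  w <- exp(-c(1, 4))
  expect_equal(pr$probability, w / sum(w))
  expect_equal(pr$probability, c(0.9526, 0.0474), tolerance = 1e-4)

  # equal lengths: uniform
  bce <- barcode_from(rep(0, 5), rep(0, 5), rep(2.5, 5))
  expect_equal(boltzmann_probabilities(bce, 0)$probability, rep(0.2, 5))

  # infinite bars get exactly zero probability
  bci <- barcode_from(c(0, 0, 0), c(0, 0, 0), c(1, 2, Inf))
  pri <- boltzmann_probabilities(bci, 0)
  expect_identical(pri$probability[3], 0)
  expect_equal(sum(pri$probability), 1, tolerance = 1e-12)

  withr::with_seed(73, {
    for (rep in 1:20) {
      lens <- sort(runif(sample(2:10, 1), 0, 4))
      bcr <- barcode_from(rep(0, length(lens)), rep(0, length(lens)), lens)
      p <- boltzmann_probabilities(bcr, 0)$probability
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(diff(p) <= 1e-15))  # longer bar, lower probability
    }
  })
  expect_error(boltzmann_probabilities(barcode_from(0, 0, Inf), 0), "finite")
})

test_that("Boltzmann persistent entropy matches direct evaluation", {
  bc4 <- barcode_from(rep(1, 4), rep(0, 4), rep(2, 4))
  expect_equal(boltzmann_persistent_entropy(bc4, 1), log(4))
  expect_equal(boltzmann_persistent_entropy(bc4, 1), 1.386, tolerance = 1e-3)

  bc <- barcode_from(c(0, 0), c(0, 0), c(1, 2))
  w <- exp(-c(1, 4)); p <- w / sum(w)
  expect_equal(boltzmann_persistent_entropy(bc, 0), -sum(p * log(p)))
  expect_equal(boltzmann_persistent_entropy(bc, 0), 0.191, tolerance = 1e-3)

  # sparse local regions: no finite bars of the dimension => 0
  expect_equal(boltzmann_persistent_entropy(
    barcode_from(integer(0), numeric(0), numeric(0)), 1), 0)
  expect_equal(boltzmann_persistent_entropy(barcode_from(0, 0, Inf), 0), 0)

  # long bars must not underflow the normalization
  bclong <- barcode_from(c(0, 0), c(0, 0), c(30, 30))
  expect_equal(boltzmann_persistent_entropy(bclong, 0), log(2))
})

test_that("PRDF bins deaths with the 4 pi r^2 shell normalization", {
  bc <- barcode_from(rep(0, 4), rep(0, 4), c(2, 2, 4, Inf))
  curve <- prdf_from_barcode(bc, bin_width = 1, rho = 0.01)
  expect_equal(curve$value[curve$r == 2], 2 / (4 * pi * 4 * 1 * 0.01))
  expect_equal(curve$value[curve$r == 2], 3.979, tolerance = 1e-3)
  expect_equal(curve$value[curve$r == 4], 1 / (4 * pi * 16 * 1 * 0.01))
  expect_equal(attr(curve, "x_t"), 4)
  expect_equal(attr(curve, "n0"), 4)

  # bins beyond the largest death are zero
  wide <- prdf_from_barcode(bc, bin_width = 1, rho = 0.01, r_max = 10)
  expect_true(all(wide$value[wide$r > 4.5] == 0))

  # literal mode carries the x_t / N_0 prefactor and no density division
  lit <- prdf_from_barcode(bc, bin_width = 1, mode = "literal_eq4")
  expect_equal(lit$value[lit$r == 2], (4 / 4) * 2 / (4 * pi * 4 * 1))
  expect_error(prdf_from_barcode(bc, bin_width = 0, rho = 1), "positive")
  expect_error(prdf_from_barcode(barcode_from(0, 0, Inf), rho = 1), "finite")
})
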