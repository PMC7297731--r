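test_that("filtration enumeration follows the Rips rule", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  f <- build_rips_filtration(tri, max_dim = 2, max_filt = 2)
  expect_equal(sum(f$dim == 0), 3)
  expect_equal(sum(f$dim == 1), 3)
  expect_equal(sum(f$dim == 2), 1)
  expect_equal(f$value[f$dim == 2], 1)

  far <- matrix(c(0, 3, 3, 0), 2, 2)
  f2 <- build_rips_filtration(far, max_dim = 2, max_filt = 2)
  expect_equal(nrow(f2), 2)
  expect_true(all(f2$dim == 0))

  iso <- matrix(Inf, 4, 4); diag(iso) <- 0
  f3 <- build_rips_filtration(iso, max_dim = 2, max_filt = Inf)
  expect_equal(nrow(f3), 4)
  expect_true(all(f3$dim == 0))
})

test_that("filtrations are face-closed with non-decreasing values", {
  d <- withr::with_seed(21, rand_dist(7))
  f <- build_rips_filtration(d, max_dim = 3, max_filt = Inf)
  expect_false(is.unsorted(f$value))
  keys <- vapply(f$vertices, paste, "", collapse = "-")
  for (i in which(f$dim > 0)) {
    v <- f$vertices[[i]]
    for (drop in seq_along(v)) {
      face_key <- paste(v[-drop], collapse = "-")
      expect_lt(match(face_key, keys), i)
    }
    # Rips rule: simplex value is the max pairwise entry
    pairs <- utils::combn(v, 2)
    expect_equal(f$value[i], max(d[t(pairs)]))
  }
  expect_error(build_rips_filtration(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
})

test_that("persistence of canonical configurations matches hand reduction", {
  pt <- compute_persistence(build_rips_filtration(matrix(0, 1, 1)))
  expect_equal(nrow(pt), 1)
  expect_equal(pt$death, Inf)

  sq <- matrix(c(0, 1, sqrt(2), 1,
                 1, 0, 1, sqrt(2),
                 sqrt(2), 1, 0, 1,
                 1, sqrt(2), 1, 0), 4, 4)
  bc <- compute_persistence(build_rips_filtration(sq, max_dim = 2))
  d1 <- bc[bc$dimension == 1, ]
  expect_equal(nrow(d1), 1)
  expect_equal(d1$birth, 1)
  expect_equal(d1$death, sqrt(2))

  eq <- matrix(1, 3, 3); diag(eq) <- 0
  bc2 <- compute_persistence(build_rips_filtration(eq, max_dim = 2))
  expect_equal(bc2$death[bc2$dimension == 0], c(1, 1, Inf))
  expect_equal(sum(bc2$dimension == 1), 0)
})

test_that("union-find dimension-0 path agrees with examples and reduction", {
  line <- as.matrix(stats::dist(cbind(c(0, 1, 3), 0, 0)))
  bc <- betti0_union_find(line)
  expect_equal(sort(bc$death[is.finite(bc$death)]), c(1, 2))

  iso <- matrix(Inf, 5, 5); diag(iso) <- 0
  expect_equal(betti0_union_find(iso)$death, rep(Inf, 5))

  withr::with_seed(31, {
    for (rep in 1:10) {
      d <- rand_dist(8)
      a <- betti0_union_find(d)
      b <- compute_persistence(build_rips_filtration(d, max_dim = 1))
      b0 <- b[b$dimension == 0, ]
      expect_bars_equal(a, b0)
    }
  })
})

test_that("matrix-level and filtration-level persistence routes agree", {
  withr::with_seed(17, {
    for (rep in 1:8) {
      d <- rand_dist(8)
      a <- rips_persistence(d, max_dim = 1, max_filt = Inf)
      b <- compute_persistence(build_rips_filtration(d, max_dim = 2,
                                                     max_filt = Inf))
      expect_bars_equal(a[a$dimension == 0, ], b[b$dimension == 0, ])
      expect_bars_equal(a[a$dimension == 1, ], b[b$dimension == 1, ])
    }
  })
})

test_that("dimension-0 deaths form the minimum spanning forest multiset", {
  withr::with_seed(41, {
    for (n in c(5, 12, 25)) {
      d <- rand_dist(n)
      bc <- betti0_union_find(d)
      expect_equal(sort(bc$death[is.finite(bc$death)]),
                   oracle_msf_weights(d), tolerance = 1e-12)
    }
  })
})

test_that("bars alive at t count the components of the t-thresholded graph", {
  withr::with_seed(43, {
    for (rep in 1:5) {
      d <- rand_dist(9)
      bc <- betti0_union_find(d)
      for (t in c(quantile(d[upper.tri(d)], c(.1, .5, .9)), max(d) + 1)) {
        # a component that merges exactly at t is already dead at t
        alive <- sum(bc$death > t)
        expect_equal(alive, oracle_components_at(d, t))
      }
    }
  })
})

test_that("simplex slices at a filtration value obey the Rips rule", {
  eq <- matrix(1, 3, 3); diag(eq) <- 0
  f <- build_rips_filtration(eq, max_dim = 2, max_filt = 2)
  expect_equal(nrow(simplices_at_filtration(f, 0.5, dims = 2)), 0)
  expect_equal(nrow(simplices_at_filtration(f, 1, dims = 2)), 1)
  sq <- matrix(c(0, 1, sqrt(2), 1,
                 1, 0, 1, sqrt(2),
                 sqrt(2), 1, 0, 1,
                 1, sqrt(2), 1, 0), 4, 4)
  fsq <- build_rips_filtration(sq, max_dim = 2, max_filt = 2)
  expect_equal(nrow(simplices_at_filtration(fsq, 1.2, dims = 2)), 0)
  expect_equal(nrow(simplices_at_filtration(fsq, sqrt(2), dims = 2)), 4)
  expect_error(simplices_at_filtration(fsq, 3), "max_filt")
})

test_that("bipartite-infinite matrices never fill their loops", {
  withr::with_seed(53, {
    for (rep in 1:5) {
      cfg <- fixture_mixed(n_osm = 3, n_wat = 5, box = 12, seed = rep)
      m <- build_local_iph_matrix(cfg)
      mf <- max(m[is.finite(m)])
      f <- build_rips_filtration(unclass(m), max_dim = 2, max_filt = mf)
      expect_equal(sum(f$dim == 2), 0)
      bc <- rips_persistence(unclass(m), max_dim = 1, max_filt = mf)
      d1 <- bc[bc$dimension == 1, ]
      expect_true(all(is.infinite(d1$death)))
    }
  })
})
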