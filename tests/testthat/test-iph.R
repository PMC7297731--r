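test_that("interactive matrices follow the cross-type distance rule", {
  cfg <- fixture_config(c(5, 5, 5,   6, 5, 5,   8, 5, 5), box = 20,
                        types = c("OSMOLYTE", "WATER", "WATER"))
  m <- build_global_iph_matrix(cfg, 1)
  expect_equal(dim(m), c(3, 3))
  expect_identical(m[2, 3], Inf)       # water-water never interacts
  expect_equal(m[1, 2], 1)
  expect_equal(m[1, 3], 3)
  expect_equal(diag(m), rep(0, 3))
  expect_error(build_global_iph_matrix(cfg, 2), "OSMOLYTE")

  mixed <- fixture_mixed(n_osm = 2, n_wat = 3, box = 15, seed = 8)
  ml <- build_local_iph_matrix(mixed)
  expect_equal(dim(ml), c(5, 5))
  expect_identical(ml[1, 2], Inf)      # osmolyte-osmolyte entry
  d <- pairwise_distance_matrix(mixed)
  cross <- outer(mixed$type, mixed$type, "!=")
  expect_equal(ml[cross], d[cross])
  expect_error(build_local_iph_matrix(
    mol_config(matrix(1, 2, 3), 15, types = "WATER")), "each type")

  # swapping type labels transposes the finite block pattern
  swapped <- mol_config(cbind(mixed$x, mixed$y, mixed$z), 15,
                        types = ifelse(mixed$type == "WATER", "OSMOLYTE",
                                       "WATER"))
  expect_equal(is.finite(build_local_iph_matrix(swapped)),
               is.finite(ml))
})

test_that("global-scale dimension-0 deaths are the osmolyte-water distances", {
  cfg <- fixture_config(c(5, 5, 5,  6, 5, 5,  5, 7.5, 5,  5, 5, 12.3),
                        box = 30,
                        types = c("OSMOLYTE", rep("WATER", 3)))
  bc <- iph_betti0(build_global_iph_matrix(cfg, 1))
  expect_equal(sort(bc$death[is.finite(bc$death)]), c(1.0, 2.5, 7.3))
  expect_equal(sum(is.infinite(bc$death)), 1)

  # single osmolyte + single water at distance d
  pair <- fixture_config(c(1, 1, 1, 1, 1, 4), box = 20,
                         types = c("OSMOLYTE", "WATER"))
  bcp <- iph_betti0(build_global_iph_matrix(pair, 1))
  expect_equal(bcp$death, c(3, Inf))

  # fast path equals the generic union-find on random instances
  withr::with_seed(83, {
    for (rep in 1:10) {
      cfg2 <- fixture_mixed(n_osm = 4, n_wat = 30, box = 18, seed = rep)
      m <- build_global_iph_matrix(cfg2, sample(which(cfg2$type == "OSMOLYTE"), 1))
      fast <- iph_betti0(m)
      slow <- betti0_union_find(wphom:::unclass_matrix(m))
      expect_bars_equal(fast, slow, tol = 1e-12)
    }
  })
})

test_that("local-scale dimension-0 deaths are bipartite MSF edge weights", {
  withr::with_seed(89, {
    for (nw in c(10, 60, 180)) {
      cfg <- fixture_mixed(n_osm = 20, n_wat = nw, box = 25,
                           seed = nw)
      m <- build_local_iph_matrix(cfg)
      bc <- iph_betti0(m)
      expect_equal(sort(bc$death[is.finite(bc$death)]),
                   oracle_msf_weights(wphom:::unclass_matrix(m)),
                   tolerance = 1e-12)
    }
  })
})

test_that("no interactive dimension-1 feature ever dies", {
  cfg <- fixture_mixed(n_osm = 4, n_wat = 8, box = 14, seed = 31)
  chk <- iph_betti1_check(build_local_iph_matrix(cfg))
  expect_true(chk$bipartite_infinite)
  expect_equal(chk$n_triangles, 0L)
  expect_equal(chk$n_finite_dim1_deaths, 0L)
  expect_true(chk$verified_by_reduction)

  # an alternating 4-cycle of finite edges carries one immortal loop
  ring <- fixture_config(c(0, 0, 0,  1, 0, 0,  1, 1, 0,  0, 1, 0) + 5,
                         box = 20,
                         types = c("OSMOLYTE", "WATER", "OSMOLYTE", "WATER"))
  mring <- build_local_iph_matrix(ring)
  bc <- rips_persistence(wphom:::unclass_matrix(mring), max_dim = 1,
                         max_filt = max(mring[is.finite(mring)]))
  d1 <- bc[bc$dimension == 1, ]
  expect_equal(nrow(d1), 1)
  expect_identical(d1$death, Inf)

  # a single finite edge has no loops at all
  pair <- fixture_config(c(1, 1, 1, 2, 1, 1), box = 10,
                         types = c("OSMOLYTE", "WATER"))
  chk2 <- iph_betti1_check(build_local_iph_matrix(pair))
  expect_equal(chk2$n_dim1_bars, 0L)
})

test_that("global PRDF pipeline reduces to per-barcode PRDF for one molecule", {
  cfg <- fixture_mixed(n_osm = 1, n_wat = 50, box = 16, seed = 41)
  traj <- mol_trajectory(list(cfg))
  curve <- global_prdf_pipeline(traj, bin_width = 0.5)
  bc <- iph_betti0(build_global_iph_matrix(cfg, 1))
  ref <- prdf_from_barcode(bc, bin_width = 0.5, rho = attr(curve, "rho"),
                           r_max = min(box_lengths(cfg)) / 2)
  expect_equal(curve$value, ref$value)
})

test_that("local PRDF vanishes beyond the largest death and is frame-exact", {
  cfg <- fixture_mixed(n_osm = 5, n_wat = 40, box = 20, seed = 43)
  traj <- mol_trajectory(list(cfg))
  curve <- local_prdf_pipeline(traj, bin_width = 0.25)
  top <- max_finite_death(iph_betti0(build_local_iph_matrix(cfg)), 0)
  expect_true(all(curve$value[curve$r > top + 0.25] == 0))
  expect_gt(sum(curve$value), 0)

  # denser osmolyte packing shortens the longest bipartite MST edge
  withr::with_seed(47, {
    sparse <- fixture_mixed(n_osm = 3, n_wat = 60, box = 24, seed = 1)
    dense <- fixture_mixed(n_osm = 30, n_wat = 60, box = 24, seed = 1)
    top_sparse <- max_finite_death(iph_betti0(build_local_iph_matrix(sparse)))
    top_dense <- max_finite_death(iph_betti0(build_local_iph_matrix(dense)))
    expect_lt(top_dense, top_sparse)
  })
})

test_that("local-scale PBN/BPE pipeline has the stated frame structure", {
  cfg <- fixture_mixed(n_osm = 4, n_wat = 20, box = 18, seed = 53)
  traj <- fixture_frozen_traj(cfg, n = 5)
  res <- iph_pbn_bpe_pipeline(traj)
  expect_equal(nrow(res$bpe), 5)
  expect_equal(var(res$bpe$bpe), 0)      # frozen frames: no variance
  expect_equal(res$pbn$value[res$pbn$x == 0], 24)  # N_w + N_s vertices
})
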