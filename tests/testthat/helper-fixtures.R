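# Small configuration fixtures built in code.

fixture_config <- function(coords, box = 20, types = "WATER") {
  mol_config(matrix(coords, ncol = 3, byrow = TRUE), box, types = types)
}

# Mixed two-type uniform configuration.
fixture_mixed <- function(n_osm = 5, n_wat = 20, box = 20, seed = 42) {
  withr::with_seed(seed, {
    pts <- matrix(runif(3 * (n_osm + n_wat), 0, box), ncol = 3)
    mol_config(pts, box,
               types = c(rep("OSMOLYTE", n_osm), rep("WATER", n_wat)))
  })
}

# A trajectory of identical copies of one configuration.
fixture_frozen_traj <- function(config, n = 3) {
  mol_trajectory(lapply(seq_len(n), function(i) {
    attr(config, "frame_index") <- i - 1L
    config
  }))
}
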