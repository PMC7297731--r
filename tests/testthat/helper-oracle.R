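# Independent reference implementations used as test oracles. These share
# no code with the package's reduction engine:
#  - dimension 0 via single-linkage clustering (stats::hclust) and, for
#    graphs, igraph's MST / component routines;
#  - dimension 1 via persistent Betti numbers computed from GF(2) ranks of
#    2-boundary matrices, converted to bar multiplicities by
#    inclusion-exclusion over pairs of critical values.

# Rank over GF(2) of all row-prefixes of a 0/1 matrix: ranks[k + 1] is the
# rank of the first k rows. Incremental row insertion into a pivot-indexed
# basis.
gf2_prefix_ranks <- function(M) {
  nr <- nrow(M)
  nc <- ncol(M)
  ranks <- integer(nr + 1L)
  if (nc == 0L) return(ranks)
  basis <- vector("list", nc)   # basis[[p]]: reduced row with pivot p
  r <- 0L
  for (k in seq_len(nr)) {
    row <- M[k, ] != 0
    while (any(row)) {
      p <- which(row)[1L]
      if (is.null(basis[[p]])) {
        basis[[p]] <- row
        r <- r + 1L
        break
      }
      row <- xor(row, basis[[p]])
    }
    ranks[k + 1L] <- r
  }
  ranks
}

# Dimension-1 persistent barcode of a finite distance matrix, full Rips
# filtration (threshold = diameter, so the final complex is a cone and all
# dimension-1 classes die).
oracle_dim1_bars <- function(d) {
  n <- nrow(d)
  if (n < 3L) return(data.frame(birth = numeric(0), death = numeric(0)))
  eij <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[eij]
  crit <- sort(unique(w))
  m <- length(crit)
  ne <- length(w)

  # Edge id lookup and the edge x triangle 2-boundary matrix.
  edge_id <- matrix(0L, n, n)
  edge_id[eij] <- seq_len(ne)
  edge_id <- edge_id + t(edge_id)
  tri <- utils::combn(n, 3L)
  tval <- apply(tri, 2L, function(tp) max(d[tp[1], tp[2]], d[tp[1], tp[3]],
                                          d[tp[2], tp[3]]))
  B <- matrix(0L, ne, ncol(tri))
  for (t in seq_len(ncol(tri))) {
    B[c(edge_id[tri[1, t], tri[2, t]], edge_id[tri[1, t], tri[3, t]],
        edge_id[tri[2, t], tri[3, t]]), t] <- 1L
  }

  # Rows sorted by descending weight: the edges NOT yet present at level s
  # form a prefix.
  row_ord <- order(-w)
  B <- B[row_ord, , drop = FALSE]
  w_desc <- w[row_ord]

  n_absent <- vapply(crit, function(v) sum(w_desc > v), integer(1))
  n_edges <- ne - n_absent

  # Cycle space dimension Z1(s) = E(s) - (n - components(s)), components
  # from igraph (independent of the package's union-find).
  comp <- vapply(crit, function(v) {
    keep <- w <= v
    g <- igraph::graph_from_edgelist(eij[keep, , drop = FALSE],
                                     directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    igraph::components(g)$no
  }, numeric(1))
  z1 <- n_edges - (n - comp)

  # beta[s, t] = Z1(s) - (rank B(t) - rank of B(t) restricted to edges
  # absent at s); B(t) keeps triangle columns with value <= crit[t].
  beta <- matrix(0, m, m)
  for (t in seq_len(m)) {
    Bt <- B[, tval <= crit[t], drop = FALSE]
    pr <- gf2_prefix_ranks(Bt)
    full <- pr[length(pr)]
    for (s in seq_len(t)) {
      beta[s, t] <- z1[s] - (full - pr[n_absent[s] + 1L])
    }
  }

  bget <- function(s, t) if (s < 1L || t < s) 0 else beta[s, t]
  births <- numeric(0)
  deaths <- numeric(0)
  for (i in seq_len(m)) {
    for (j in seq(i + 1L, length.out = m - i)) {
      mult <- bget(i, j - 1L) - bget(i, j) - bget(i - 1L, j - 1L) +
        bget(i - 1L, j)
      if (mult > 0) {
        births <- c(births, rep(crit[i], mult))
        deaths <- c(deaths, rep(crit[j], mult))
      }
    }
    mult_inf <- bget(i, m) - bget(i - 1L, m)
    if (mult_inf > 0) {
      births <- c(births, rep(crit[i], mult_inf))
      deaths <- c(deaths, rep(Inf, mult_inf))
    }
  }
  data.frame(birth = births, death = deaths)[order(births, deaths), ,
                                             drop = FALSE]
}

# Dimension-0 finite deaths via single-linkage merge heights.
oracle_dim0_deaths <- function(d) {
  if (nrow(d) < 2L) return(numeric(0))
  sort(stats::hclust(stats::as.dist(d), method = "single")$height)
}

# MST edge-weight multiset of the finite-edge graph, via igraph (Kruskal
# oracle); works for bipartite-infinite matrices too.
oracle_msf_weights <- function(d) {
  n <- nrow(d)
  eij <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[eij]
  keep <- is.finite(w)
  g <- igraph::graph_from_edgelist(eij[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w[keep]
  sort(igraph::E(igraph::mst(g))$weight)
}

# Number of connected components of the graph thresholded at t.
oracle_components_at <- function(d, t) {
  n <- nrow(d)
  eij <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[eij]
  keep <- is.finite(w) & w <= t
  g <- igraph::graph_from_edgelist(eij[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::components(g)$no
}

# Random Euclidean distance matrix fixture.
rand_dist <- function(n, scale = 1) {
  pts <- matrix(runif(3 * n, 0, scale), ncol = 3)
  as.matrix(stats::dist(pts))
}

expect_bars_equal <- function(got, want, tol = 1e-9) {
  expect_equal(nrow(got), nrow(want))
  if (nrow(got) == 0L) return(invisible())
  og <- order(got$birth, got$death)
  ow <- order(want$birth, want$death)
  expect_equal(got$birth[og], want$birth[ow], tolerance = tol)
  gi <- is.infinite(got$death[og])
  wi <- is.infinite(want$death[ow])
  expect_identical(gi, wi)
  expect_equal(got$death[og][!gi], want$death[ow][!wi], tolerance = tol)
}
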