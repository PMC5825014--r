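test_that("link lengths follow the half-sum membership rule", {
  mu <- array(1, c(3, 3, 3))
  o <- fuzzy_object(mu, c(1, 1, 1))
  expect_equal(link_length(c(1, 1, 1), c(1, 1, 2), o), 1.0)
  mu2 <- mu; mu2[1, 1, 2] <- 0
  o2 <- fuzzy_object(mu2, c(1, 1, 1))
  expect_equal(link_length(c(1, 1, 1), c(1, 1, 2), o2), 0.5)
  o3 <- fuzzy_object(mu, c(0.2, 0.07, 0.07))
  expect_equal(link_length(c(1, 1, 1), c(2, 2, 2), o3),
               sqrt(0.2^2 + 0.07^2 + 0.07^2))
  expect_error(link_length(c(1, 1, 1), c(1, 1, 3), o), "adjacent")
})

test_that("fuzzy_distance: trivial cases and the Dijkstra oracle", {
  mu <- array(0, c(1, 1, 7)); mu[1, 1, 1:6] <- 1
  o <- fuzzy_object(mu, c(1, 1, 1))
  expect_equal(fuzzy_distance(c(1, 1, 3), c(1, 1, 3), o), 0)
  expect_equal(fuzzy_distance(c(1, 1, 1), c(1, 1, 6), o), 5)

  set.seed(5)
  for (rep in 1:5) {
    mu <- rand_mu(c(5, 5, 5), p_zero = 0.25)
    src <- which(mu > 0, arr.ind = TRUE)[1, , drop = FALSE]
    o <- fuzzy_object(mu, c(0.2, 0.07, 0.07))
    want <- oracle_geodesic(mu, o$spacing, src)
    sup <- which(mu > 0, arr.ind = TRUE)
    for (j in seq(1, nrow(sup), by = 7)) {
      expect_equal(fuzzy_distance(src[1, ], sup[j, ], o),
                   want[ovox_idx(sup[j, , drop = FALSE], dim(mu))],
                   tolerance = 1e-9)
    }
  }
})

test_that("fuzzy_distance is a metric on each support component", {
  set.seed(6)
  mu <- rand_mu(c(4, 4, 4), p_zero = 0.2)
  o <- fuzzy_object(mu, c(1, 1, 1))
  sup <- which(mu > 0, arr.ind = TRUE)
  pick <- sup[sample(nrow(sup), 3), ]
  dpq <- fuzzy_distance(pick[1, ], pick[2, ], o)
  dqp <- fuzzy_distance(pick[2, ], pick[1, ], o)
  expect_equal(dpq, dqp, tolerance = 1e-10)           # symmetry
  dpr <- fuzzy_distance(pick[1, ], pick[3, ], o)
  dqr <- fuzzy_distance(pick[2, ], pick[3, ], o)
  if (is.finite(dpq) && is.finite(dqr) && is.finite(dpr))
    expect_lte(dpr, dpq + dqr + 1e-10)                # triangle inequality
})

test_that("FDT: isolated voxel, Lipschitz property, membership scaling", {
  mu <- array(0, c(3, 3, 3)); mu[2, 2, 2] <- 1
  f <- fuzzy_distance_transform(fuzzy_object(mu, c(1, 1, 1)))
  expect_equal(f[2, 2, 2], 0.5)   # half-link into the background
  expect_true(all(f[mu == 0] == 0))

  set.seed(7)
  mu <- rand_mu(c(6, 6, 6), p_zero = 0.3)
  sp <- c(0.2, 0.07, 0.07)
  o <- fuzzy_object(mu, sp)
  f <- fuzzy_distance_transform(o)
  # |Omega(p) - Omega(q)| <= link length for every adjacent pair
  pairs <- oracle_adjacency(dim(mu))
  w <- oracle_link_w(as.numeric(mu), pairs, sp)
  both <- mu[pairs[, 1]] > 0 & mu[pairs[, 2]] > 0
  expect_true(all(abs(f[pairs[both, 1]] - f[pairs[both, 2]]) <=
                    w[both] + 1e-9))
  # homogeneity: scaling memberships scales the transform
  f2 <- fuzzy_distance_transform(fuzzy_object(0.5 * mu, sp))
  expect_equal(array(f2, dim(mu)), array(0.5 * unclass(f), dim(mu)),
               tolerance = 1e-9)

  expect_warning(fuzzy_distance_transform(fuzzy_object(array(0, c(2, 2, 2)))),
                 "empty support")
})

test_that("FDT equals the exhaustive Dijkstra oracle on random fields", {
  set.seed(8)
  for (rep in 1:6) {
    mu <- rand_mu(c(6, 6, 6), p_zero = 0.3)
    sp <- if (rep %% 2) c(1, 1, 1) else c(0.2, 0.07, 0.07)
    got <- fuzzy_distance_transform(fuzzy_object(mu, sp))
    expect_equal(array(got, dim(mu)), oracle_fdt(mu, sp), tolerance = 1e-6)
  }
})

test_that("binary-ball FDT stays within a voxel diagonal of the EDT", {
  for (r in c(3, 5)) {
    n <- 2 * r + 3
    ctr <- (n + 1) / 2
    g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
    mask <- array((g$z - ctr)^2 + (g$y - ctr)^2 + (g$x - ctr)^2 <= r^2,
                  c(n, n, n))
    f <- fuzzy_distance_transform(fuzzy_object(array(as.numeric(mask),
                                                     dim(mask))))
    edt <- oracle_edt(mask, c(1, 1, 1))
    dev <- abs(f[mask] - edt[mask])
    expect_lt(max(dev), sqrt(3))
  }
})

test_that("membership ramps: endpoints, midpoint, complementarity, partition", {
  b <- intensity_bands(0, 100, 200, 255)
  expect_equal(membership_dendrite(100, b), 0)
  expect_equal(membership_dendrite(200, b), 1)
  expect_equal(membership_dendrite(150, b), 0.5)
  expect_equal(membership_dendrite(50, b), 0)
  expect_equal(membership_spine(150, b), 0.5)
  expect_equal(membership_spine(230, b), 0)
  expect_equal(membership_spine(50, b), 1)
  expect_equal(membership_spine(-5, b), 0)
  ii <- seq(100, 199.5, by = 0.5)
  expect_equal(membership_spine(ii, b) + membership_dendrite(ii, b),
               rep(1, length(ii)))
  # pure spine / shared / pure dendrite partition the intensity range
  all_i <- seq(0, 255, by = 1)
  pure_s <- all_i < b$i_spine
  pure_d <- all_i >= b$i_dendrite
  shared <- !pure_s & !pure_d
  expect_true(all(pure_s + pure_d + shared == 1))
  expect_error(intensity_bands(0, 200, 100, 255), "i_spine")
})

test_that("fuzzy_union is a voxelwise max with identity and idempotence", {
  set.seed(9)
  a <- fuzzy_object(rand_mu(c(3, 3, 3)), c(1, 1, 1))
  b <- fuzzy_object(rand_mu(c(3, 3, 3)), c(1, 1, 1))
  u <- fuzzy_union(a, b)
  expect_equal(u$mu, pmax(a$mu, b$mu))
  empty <- fuzzy_object(array(0, c(3, 3, 3)), c(1, 1, 1))
  expect_equal(fuzzy_union(a, empty)$mu, a$mu)
  expect_equal(fuzzy_union(a, a)$mu, a$mu)
  wrong <- fuzzy_object(array(0, c(2, 2, 2)), c(1, 1, 1))
  expect_error(fuzzy_union(a, wrong), "shape")
})

test_that("min_weight_path matches the node-weight Dijkstra oracle", {
  set.seed(10)
  for (rep in 1:4) {
    d <- c(6, 6, 6)
    w <- array(runif(prod(d)), d)
    attr(w, "spacing") <- c(1, 1, 1)
    region <- array(runif(prod(d)) > 0.2, d)
    sup <- which(region, arr.ind = TRUE)
    src <- sup[1, ]; dst <- sup[nrow(sup), ]
    want <- oracle_node_path_cost(w, region, src, dst)
    if (!is.finite(want)) {
      expect_error(min_weight_path(w, src, dst, region), "disconnected")
    } else {
      got <- min_weight_path(w, src, dst, region)
      expect_equal(got$cost, want, tolerance = 1e-9)
      expect_equal(got$cost, sum(w[got$path]), tolerance = 1e-9)
      # determinism
      again <- min_weight_path(w, src, dst, region)
      expect_identical(got$path, again$path)
    }
  }
  # degenerate and uniform cases
  w <- array(1, c(2, 2, 5)); attr(w, "spacing") <- c(1, 1, 1)
  region <- array(TRUE, dim(w))
  single <- min_weight_path(w, c(1, 1, 3), c(1, 1, 3), region)
  expect_equal(nrow(single$path), 1)
  expect_equal(single$cost, 1)
  straight <- min_weight_path(w, c(1, 1, 1), c(1, 1, 5), region)
  expect_equal(nrow(straight$path), 5)  # uniform weights -> fewest voxels
})

test_that("two-level Otsu recovers the modes of a trimodal sample", {
  set.seed(12)
  x <- c(rnorm(4000, 10, 3), rnorm(800, 120, 8), rnorm(800, 220, 8))
  t2 <- otsu_thresholds(x, k = 2)
  # lower threshold separates background from signal, upper one the modes
  expect_gt(t2[1], 15); expect_lt(t2[1], 110)
  expect_gt(t2[2], 125); expect_lt(t2[2], 215)
  b <- auto_bands(x[x > t2[1]])
  expect_s3_class(b, "intensity_bands")
})
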