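# binary volume with two balls fused through a shallow overlap; a
# one-voxel bridge guarantees fusion when the waist is empty
make_two_balls <- function(r1, r2, gap_frac) {
  sep <- (r1 + r2) * gap_frac
  n1 <- 2 * max(r1, r2) + round(sep) + 6
  d <- c(2 * max(r1, r2) + 5, 2 * max(r1, r2) + 5, n1)
  c1 <- c((d[1] + 1) / 2, (d[2] + 1) / 2, r1 + 3)
  c2 <- c1 + c(0, 0, sep)
  g <- expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3])
  m1 <- (g$z - c1[1])^2 + (g$y - c1[2])^2 + (g$x - c1[3])^2 <= r1^2
  m2 <- (g$z - c2[1])^2 + (g$y - c2[2])^2 + (g$x - c2[3])^2 <= r2^2
  br <- g$z == c1[1] & g$y == c1[2] & g$x >= c1[3] & g$x <= c2[3]
  list(mask = array(m1 | m2 | br, d), c1 = round(c1), c2 = round(c2), dim = d)
}

test_that("threshold_foreground keeps only large components", {
  v <- as_volume(array(5, c(4, 4, 4)))
  expect_error(threshold_foreground(v, theta = 10), "empty foreground")

  a <- array(0, c(6, 10, 10))
  a[2:5, 2:6, 2:6] <- 100    # 100 voxels
  a[1, 9, 9] <- 100; a[2, 9, 9] <- 100; a[3, 9, 9] <- 100  # 3 voxels
  fg <- threshold_foreground(as_volume(a), theta = 50, min_voxels = 10)
  expect_equal(sum(fg$mu > 0), 100)
  expect_true(all(fg$mu[a == 0] == 0))
})

test_that("opening of fused balls: partition, connectivity, seeds, oracle", {
  set.seed(21)
  agree <- numeric(0)
  for (rep in 1:6) {
    r1 <- sample(5:7, 1); r2 <- sample(5:7, 1)
    gf <- runif(1, 0.92, 1.02)
    tb <- make_two_balls(r1, r2, gap_frac = gf)
    obj <- fuzzy_object(array(as.numeric(tb$mask), tb$dim), c(1, 1, 1))
    seeds <- seed_set(spine = matrix(tb$c2, 1), dendrite = matrix(tb$c1, 1))
    seg <- multi_scale_opening(obj, seeds)
    lab <- seg$labels
    # partition of the support
    expect_true(all(lab[tb$mask] %in% c(1L, 2L)))
    expect_true(all(lab[!tb$mask] == 0L))
    # each label 26-connected and containing its seed
    for (v in 1:2) {
      comp <- array(spinemorph:::.cpp_label_components(as.logical(lab == v),
                                                       as.integer(tb$dim)),
                    tb$dim)
      expect_equal(max(comp), 1)
    }
    expect_equal(lab[rbind(tb$c1)], 1L)
    expect_equal(lab[rbind(tb$c2)], 2L)
    want <- oracle_two_object_split(tb$mask, tb$c1, tb$c2, c(1, 1, 1))
    agree <- c(agree, mean((lab == want)[tb$mask]))
  }
  expect_true(all(agree >= 0.95))
})

test_that("opening is deterministic and respects separators monotonically", {
  tb <- make_two_balls(6, 6, 0.95)
  obj <- fuzzy_object(array(as.numeric(tb$mask), tb$dim), c(1, 1, 1))
  seeds <- seed_set(spine = matrix(tb$c2, 1), dendrite = matrix(tb$c1, 1))
  a <- multi_scale_opening(obj, seeds)
  b <- multi_scale_opening(obj, seeds)
  expect_identical(a$labels, b$labels)

  # a separator voxel is never claimed by either object's own label
  mid <- round((tb$c1 + tb$c2) / 2)
  seeds_sep <- seed_set(spine = matrix(tb$c2, 1), dendrite = matrix(tb$c1, 1),
                        separator = matrix(mid, 1))
  s <- suppressMessages(multi_scale_opening(obj, seeds_sep))
  expect_true(s$n_forced >= 1)  # separator itself is force-assigned at the end

  expect_error(multi_scale_opening(obj, seed_set(spine = matrix(tb$c2, 1))),
               "non-empty")
  expect_error(multi_scale_opening(obj,
                                   seed_set(spine = matrix(c(1, 1, 1), 1),
                                            dendrite = matrix(tb$c1, 1))),
               "support")
})

test_that("shared voxels reachable only from one side go to that side", {
  # a pure-spine region with an attached shared-band corridor, and a far
  # pure-dendrite region that cannot reach the corridor
  d <- c(3, 5, 12)
  intens <- array(0, d)
  intens[2, 2:4, 2:4] <- 120     # region A: pure spine band
  intens[2, 3, 5:6] <- 170       # shared-band corridor touching A only
  intens[2, 2:4, 9:11] <- 220    # region B: pure dendrite band, detached
  vol <- as_volume(intens)
  b <- intensity_bands(0, 150, 200, 255)
  fg <- threshold_foreground(vol, theta = 50, min_voxels = 1, bands = b)
  seeds <- seed_set(spine = matrix(c(2, 3, 3), 1),
                    dendrite = matrix(c(2, 3, 10), 1))
  seg <- multi_scale_opening(fg, seeds, intensity = unclass(vol), bands = b)
  expect_true(all(seg$labels[2, 2:4, 2:4] == 2L))  # spine keeps its band
  expect_equal(seg$labels[2, 3, 6], 2L)   # corridor reachable only from spine
  expect_true(all(seg$labels[2, 2:4, 9:11] == 1L))
})

test_that("extract_spine_components: counting, stray merge, empty case", {
  tb <- make_two_balls(5, 5, 0.95)
  obj <- fuzzy_object(array(as.numeric(tb$mask), tb$dim), c(1, 1, 1))
  seeds <- seed_set(spine = matrix(tb$c2, 1), dendrite = matrix(tb$c1, 1))
  seg <- extract_spine_components(multi_scale_opening(obj, seeds))
  expect_equal(seg$K, 1)
  expect_equal(sort(unique(as.integer(seg$labels))), c(0L, 1L, 2L))

  # an unseeded stray spine component is merged into the dendrite
  seg2 <- multi_scale_opening(obj, seeds)
  stray <- which(seg2$labels == 0L, arr.ind = TRUE)[1, , drop = FALSE]
  seg2$labels[stray] <- 2L
  expect_message(seg3 <- extract_spine_components(seg2), "merged")
  expect_equal(seg3$K, 1)
  expect_equal(seg3$labels[stray], 1L)

  seg4 <- multi_scale_opening(obj, seeds)
  seg4$labels[seg4$labels == 2L] <- 1L
  seg4$seeds <- seed_set(dendrite = matrix(tb$c1, 1),
                         spine = matrix(tb$c1 + c(0, 1, 0), 1))
  expect_equal(extract_spine_components(seg4)$K, 0)
  expect_equal(length(extract_spine_components(seg4)$regions), 0)
})
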