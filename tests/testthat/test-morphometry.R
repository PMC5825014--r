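test_that("spine_base enumerates the 26-adjacent dendrite footprint", {
  d <- c(5, 5, 5)
  dend <- array(FALSE, d); dend[, , 1] <- TRUE    # flat slab at x = 1
  region <- matrix(c(3, 3, 2), 1, dimnames = list(NULL, c("z", "y", "x")))
  base <- spine_base(region, dend)
  expect_equal(nrow(base), 9)  # 3 x 3 patch of the slab under 26-adjacency
  expect_true(all(dend[base]))

  far <- matrix(c(3, 3, 4), 1)
  expect_equal(nrow(spine_base(far, dend)), 0)
})

test_that("central_base_point is the centroid with deterministic snapping", {
  base <- rbind(c(1, 1, 1), c(3, 1, 1))
  expect_equal(central_base_point(base), c(2, 1, 1))
  expect_equal(unname(snap_to_voxel(c(2, 1, 1), base, c(1, 1, 1))),
               c(1, 1, 1))  # tie -> lexicographically smallest
  single <- rbind(c(4, 2, 2))
  expect_equal(central_base_point(single), c(4, 2, 2))
  expect_error(central_base_point(base[0, , drop = FALSE]), "empty base")
})

test_that("locally deepest points: ball centre, filament plateau, dumbbell", {
  # ball: the unique depth maximum is its centre
  n <- 11; ctr <- 6
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  ball <- array((g$z - ctr)^2 + (g$y - ctr)^2 + (g$x - ctr)^2 <= 16, c(n, n, n))
  reg <- which(ball, arr.ind = TRUE)
  om <- unclass(fuzzy_distance_transform(fuzzy_object(array(as.numeric(ball),
                                                            dim(ball)))))
  hp <- reg[locally_deepest_points(reg, om, l = 2), , drop = FALSE]
  expect_equal(unname(hp), matrix(c(ctr, ctr, ctr), 1), ignore_attr = TRUE)

  # thin filament: constant depth, every voxel qualifies
  fil <- array(0, c(3, 3, 9)); fil[2, 2, ] <- 1
  regf <- which(fil > 0, arr.ind = TRUE)
  omf <- unclass(fuzzy_distance_transform(fuzzy_object(fil)))
  expect_true(all(locally_deepest_points(regf, omf, l = 2)))

  # dumbbell of two fused balls: exactly the two centres for l = 2
  d2 <- c(11, 11, 19)
  g2 <- expand.grid(z = 1:11, y = 1:11, x = 1:19)
  m <- (g2$z - 6)^2 + (g2$y - 6)^2 + (g2$x - 6)^2 <= 16 |
    (g2$z - 6)^2 + (g2$y - 6)^2 + (g2$x - 13)^2 <= 16
  dumb <- array(m, d2)
  regd <- which(dumb, arr.ind = TRUE)
  omd <- unclass(fuzzy_distance_transform(fuzzy_object(array(as.numeric(dumb), d2))))
  hpd <- regd[locally_deepest_points(regd, omd, l = 2), , drop = FALSE]
  expect_setequal(paste(hpd[, 1], hpd[, 2], hpd[, 3]),
                  c("6 6 6", "6 6 13"))
})

test_that("center_of_head and tie handling", {
  om <- array(0, c(3, 3, 5))
  om[2, 2, 2] <- 1; om[2, 2, 4] <- 1   # two symmetric maxima
  hp <- rbind(c(2, 2, 2), c(2, 2, 4))
  ch <- center_of_head(hp, om, c(1, 1, 1))
  expect_equal(unname(ch$point), c(2, 2, 3))
  expect_true(any(apply(hp, 1, function(v) all(v == ch$voxel))))
})

test_that("spine_tip: filament end and ball pole", {
  fil <- array(0, c(3, 3, 9)); fil[2, 2, 2:8] <- 1
  reg <- which(fil > 0, arr.ind = TRUE)
  tip <- spine_tip(reg, cbp_voxel = c(2, 2, 2), shape = dim(fil),
                   spacing = c(1, 1, 1))
  expect_equal(unname(tip$voxel), c(2, 2, 8))
  expect_equal(tip$distance_um, 6)
})

test_that("central paths: trivial adjacency, filament, oracle cost", {
  fil <- array(0, c(3, 3, 9)); fil[2, 2, 2:8] <- 1
  reg <- which(fil > 0, arr.ind = TRUE)
  om <- structure(unclass(fuzzy_distance_transform(fuzzy_object(fil))),
                  spacing = c(1, 1, 1))
  base <- matrix(c(2, 2, 2), 1)
  paths <- central_paths(reg, base, om, cbp_voxel = c(2, 2, 2),
                         ch_voxel = c(2, 2, 5), tip_voxel = c(2, 2, 8))
  expect_equal(nrow(paths$bh$path), 4)   # the filament itself
  expect_equal(nrow(paths$ht$path), 4)

  set.seed(31)
  w <- array(runif(5^3), c(5, 5, 5)); attr(w, "spacing") <- c(1, 1, 1)
  region <- array(TRUE, dim(w))
  got <- min_weight_path(w, c(1, 1, 1), c(5, 5, 5), region)
  expect_equal(got$cost,
               oracle_node_path_cost(w, region, c(1, 1, 1), c(5, 5, 5)),
               tolerance = 1e-9)
})

test_that("feature recovery on a clean rasterized sphere-on-neck spine", {
  sl <- make_slab_spine(head_r = 0.4, neck_r = 0.1, neck_len = 0.6)
  s <- measure_spine(sl$region, sl$dendrite, sl$spacing)
  vd <- sqrt(sum(sl$spacing^2))  # one voxel diagonal
  expect_false(s$detached)
  expect_lt(abs(s$head_depth_um - 0.4), vd)
  expect_lt(abs(s$avg_head_width_um - 0.8), 1.5 * vd)
  expect_lt(abs(s$min_neck_width_um - 0.2), 1.5 * vd)
  expect_lt(abs(s$neck_length_um - 0.6), 1.5 * vd)
  expect_equal(s$volume_um3, nrow(sl$region) * prod(sl$spacing))
  # invariants
  expect_true(all(c(s$neck_length_um, s$min_neck_width_um,
                    s$avg_head_width_um, s$spine_length_um) >= 0))
  expect_lte(s$min_neck_width_um, 2 * s$head_depth_um + 1e-9)
  expect_gte(s$spine_length_um, s$ht_length_um - 1e-9)
})

test_that("neckless dome measures a zero neck (clamp) and detached flag", {
  sl <- make_slab_spine(head_r = 0.35, neck_r = 0.1, neck_len = 0)
  s <- measure_spine(sl$region, sl$dendrite, sl$spacing)
  expect_lt(s$neck_length_um, 0.1)

  # a region nowhere adjacent to the dendrite reports neck features as NA
  det <- sl$region[sl$region[, 3] > min(sl$region[, 3]) + 3, , drop = FALSE]
  dend_far <- array(FALSE, sl$shape); dend_far[, , 1] <- TRUE
  s2 <- measure_spine(det, dend_far, sl$spacing)
  expect_true(s2$detached)
  expect_true(is.na(s2$neck_length_um))
  expect_true(is.na(s2$min_neck_width_um))
  expect_false(is.na(s2$volume_um3))
})

test_that("volume scales with voxel count and physical voxel volume", {
  d <- c(4, 5, 6)
  dend <- array(FALSE, d); dend[, , 1] <- TRUE
  blk <- array(FALSE, d); blk[, , 2:6] <- TRUE   # 4 x 5 x 5 = 100 voxels
  region <- which(blk, arr.ind = TRUE)
  colnames(region) <- c("z", "y", "x")
  s <- measure_spine(region, dend, c(0.2, 0.07, 0.07))
  expect_equal(s$volume_um3, 100 * 0.2 * 0.07 * 0.07)
})

test_that("features are invariant to a 90-degree in-plane rotation", {
  sl <- make_slab_spine(head_r = 0.35, neck_r = 0.12, neck_len = 0.45,
                        spacing = c(0.2, 0.07, 0.07))
  s <- measure_spine(sl$region, sl$dendrite, sl$spacing)
  # rotate (y, x) -> (x, ny + 1 - y): swap the two in-plane axes
  d <- sl$shape
  rot_mask <- function(m) aperm(m, c(1, 3, 2))[, , rev(seq_len(d[2]))]
  dend_r <- rot_mask(sl$dendrite)
  reg_mask <- array(FALSE, d); reg_mask[sl$region] <- TRUE
  reg_r <- which(rot_mask(reg_mask), arr.ind = TRUE)
  colnames(reg_r) <- c("z", "y", "x")
  s2 <- measure_spine(reg_r, dend_r, sl$spacing)
  for (f in c("volume_um3", "head_depth_um", "avg_head_width_um",
              "min_neck_width_um", "neck_length_um", "spine_length_um"))
    expect_equal(s2[[f]], s[[f]], tolerance = 1e-6, label = f)
})
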