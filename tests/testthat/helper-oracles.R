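# Independent brute-force oracles built on igraph shortest paths and
# exhaustive enumeration; deliberately separate from the package's own
# Dijkstra code paths.

ovox_idx <- function(m, d) {
  m <- rbind(m)
  as.integer(m[, 1] + d[1] * ((m[, 2] - 1) + d[2] * (m[, 3] - 1)))
}

# all 26-adjacent voxel pairs (as linear index matrix) within dim d
oracle_adjacency <- function(d) {
  vox <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                               x = seq_len(d[3])))
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  # keep each undirected pair once
  off <- off[off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
               (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0), , drop = FALSE]
  out <- NULL
  for (k in seq_len(nrow(off))) {
    nb <- sweep(vox, 2, -off[k, ])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    out <- rbind(out, cbind(ovox_idx(vox[ok, , drop = FALSE], d),
                            ovox_idx(nb[ok, , drop = FALSE], d),
                            matrix(rep(off[k, ], sum(ok)), ncol = 3, byrow = TRUE)))
  }
  out  # columns: idx_a, idx_b, dz, dy, dx
}

# fuzzy link length for pairs given memberships and spacing
oracle_link_w <- function(mu, pairs, spacing) {
  step <- sqrt((pairs[, 3] * spacing[1])^2 + (pairs[, 4] * spacing[2])^2 +
                 (pairs[, 5] * spacing[3])^2)
  0.5 * (mu[pairs[, 1]] + mu[pairs[, 2]]) * step
}

# exhaustive-Dijkstra FDT oracle: shortest fuzzy path to a virtual
# background node; voxels on the array border are also background-adjacent
oracle_fdt <- function(mu, spacing) {
  d <- dim(mu)
  n <- prod(d)
  pairs <- oracle_adjacency(d)
  support <- mu > 0
  w <- oracle_link_w(as.numeric(mu), pairs, spacing)
  inin <- support[pairs[, 1]] & support[pairs[, 2]]
  edges <- cbind(pairs[inin, 1:2, drop = FALSE])
  ew <- w[inin]
  # half-links into the background (in-array background voxels and the
  # virtual outside): support voxel -> bg node
  bg_node <- n + 1L
  vox <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                               x = seq_len(d[3])))
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  half <- rep(Inf, n)
  for (k in seq_len(nrow(off))) {
    step <- sqrt(sum((off[k, ] * spacing)^2))
    nb <- sweep(vox, 2, -off[k, ])
    outside <- nb[, 1] < 1 | nb[, 1] > d[1] | nb[, 2] < 1 | nb[, 2] > d[2] |
      nb[, 3] < 1 | nb[, 3] > d[3]
    isbg <- outside
    inb <- !outside
    isbg[inb] <- !support[ovox_idx(nb[inb, , drop = FALSE], d)]
    i <- ovox_idx(vox, d)
    cand <- ifelse(isbg, 0.5 * as.numeric(mu)[i] * step, Inf)
    half <- pmin(half, cand)
  }
  bi <- which(support & is.finite(half))
  edges <- rbind(edges, cbind(bi, rep(bg_node, length(bi))))
  ew <- c(ew, half[bi])
  g <- igraph::make_empty_graph(n = bg_node, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(edges)))
  igraph::E(g)$weight <- ew
  dist <- as.numeric(igraph::distances(g, v = bg_node)[1, ])
  dist[!support] <- 0
  array(dist[seq_len(n)], d)
}

# fuzzy geodesic distances from one source voxel over the support
oracle_geodesic <- function(mu, spacing, src) {
  d <- dim(mu)
  n <- prod(d)
  pairs <- oracle_adjacency(d)
  support <- mu > 0
  inin <- support[pairs[, 1]] & support[pairs[, 2]]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(pairs[inin, 1:2, drop = FALSE])))
  igraph::E(g)$weight <- oracle_link_w(as.numeric(mu), pairs, spacing)[inin]
  as.numeric(igraph::distances(g, v = ovox_idx(src, d))[1, ])
}

# minimum node-weight path cost oracle (node sums via half-edge weights)
oracle_node_path_cost <- function(w, region, src, dst) {
  d <- dim(w)
  n <- prod(d)
  pairs <- oracle_adjacency(d)
  keep <- region[pairs[, 1]] & region[pairs[, 2]]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(pairs[keep, 1:2, drop = FALSE])))
  igraph::E(g)$weight <- (as.numeric(w)[pairs[keep, 1]] +
                            as.numeric(w)[pairs[keep, 2]]) / 2
  i <- ovox_idx(src, d); j <- ovox_idx(dst, d)
  base <- as.numeric(igraph::distances(g, v = i, to = j))
  base + (as.numeric(w)[i] + as.numeric(w)[j]) / 2
}

# brute-force Euclidean distance transform (distance to the nearest
# background voxel centre), physical spacing; blockwise |a - b|^2 =
# |a|^2 + |b|^2 - 2 a.b keeps it exhaustive but vectorised
oracle_edt <- function(mask, spacing) {
  d <- dim(mask)
  vox <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                               x = seq_len(d[3])))
  phys <- sweep(vox, 2, c(1, 1, 1)) * rep(spacing, each = nrow(vox))
  fg <- which(mask)
  bg <- which(!mask)
  out <- array(0, d)
  pb <- phys[bg, , drop = FALSE]
  nb2 <- rowSums(pb^2)
  for (start in seq(1, length(fg), by = 400)) {
    idx <- fg[start:min(start + 399, length(fg))]
    pa <- phys[idx, , drop = FALSE]
    d2 <- outer(rowSums(pa^2), nb2, "+") - 2 * pa %*% t(pb)
    out[idx] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

# erosion-disconnection oracle for two fused binary objects: erode (by
# EDT level) until the seeds separate, then label by hop-geodesic
# dilation from the two eroded cores back over the full mask
oracle_two_object_split <- function(mask, seed_a, seed_b, spacing) {
  d <- dim(mask)
  edt <- oracle_edt(mask, spacing)
  pairs <- oracle_adjacency(d)
  keep_full <- mask[pairs[, 1]] & mask[pairs[, 2]]
  full_edges <- pairs[keep_full, 1:2, drop = FALSE]
  ia <- ovox_idx(seed_a, d); ib <- ovox_idx(seed_b, d)
  levels <- sort(unique(edt[mask]))
  comp_of <- function(sub) {
    keep <- sub[full_edges[, 1]] & sub[full_edges[, 2]]
    g <- igraph::make_empty_graph(n = prod(d), directed = FALSE)
    g <- igraph::add_edges(g, as.vector(t(full_edges[keep, , drop = FALSE])))
    igraph::components(g)$membership
  }
  lab_core <- NULL
  for (lv in levels) {
    sub <- edt >= lv
    if (!sub[ia] || !sub[ib]) break
    cm <- comp_of(sub)
    if (cm[ia] != cm[ib]) {
      lab_core <- integer(prod(d))
      lab_core[sub & cm == cm[ia]] <- 1L
      lab_core[sub & cm == cm[ib]] <- 2L
      break
    }
  }
  if (is.null(lab_core)) {
    # never disconnected (or a seed eroded away): fall back to seeds only
    lab_core <- integer(prod(d))
    lab_core[ia] <- 1L; lab_core[ib] <- 2L
  }
  g <- igraph::make_empty_graph(n = prod(d), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(full_edges)))
  da <- suppressWarnings(igraph::distances(g, v = which(lab_core == 1L)))
  db <- suppressWarnings(igraph::distances(g, v = which(lab_core == 2L)))
  mda <- apply(da, 2, min); mdb <- apply(db, 2, min)
  out <- array(0L, d)
  out[mask & mda <= mdb] <- 1L
  out[mask & mdb < mda] <- 2L
  out
}

# dense separable-equivalent 3-D Gaussian convolution oracle (direct
# triple loop over the kernel support, reflect padding)
oracle_gauss3 <- function(vol, sigma) {
  d <- dim(vol)
  kern <- lapply(1:3, function(a) {
    if (sigma[a] == 0) return(1)
    r <- max(1L, ceiling(4 * sigma[a]))
    k <- exp(-((-r:r)^2) / (2 * sigma[a]^2))
    k / sum(k)
  })
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 2 - i[i < 1]
      i[i > n] <- 2 * n - i[i > n]
    }
    i
  }
  out <- array(0, d)
  r <- vapply(kern, function(k) (length(k) - 1L) %/% 2L, integer(1))
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    acc <- 0
    for (a in -r[1]:r[1]) for (b in -r[2]:r[2]) for (c in -r[3]:r[3]) {
      acc <- acc + kern[[1]][a + r[1] + 1] * kern[[2]][b + r[2] + 1] *
        kern[[3]][c + r[3] + 1] *
        vol[refl(z + a, d[1]), refl(y + b, d[2]), refl(x + c, d[3])]
    }
    out[z, y, x] <- acc
  }
  out
}

# random fuzzy membership field with some exact zeros
rand_mu <- function(d, p_zero = 0.3) {
  mu <- array(stats::runif(prod(d)), d)
  mu[array(stats::runif(prod(d)) < p_zero, d)] <- 0
  mu
}

# a rasterised sphere-on-neck spine attached to a flat dendrite slab:
# exact solid-geometry region for morphometry tests without segmentation
make_slab_spine <- function(head_r = 0.4, neck_r = 0.1, neck_len = 0.6,
                            spacing = c(0.07, 0.07, 0.07), pad_um = 0.35) {
  ext <- neck_len + 2 * head_r + pad_um
  nx <- ceiling(ext / spacing[3]) + 4L
  half <- ceiling((head_r + pad_um) / spacing[2])
  ny <- 2L * half + 1L
  nz <- 2L * ceiling((head_r + pad_um) / spacing[1]) + 1L
  d <- c(nz, ny, nx)
  gz <- (seq_len(nz) - 1) * spacing[1]
  gy <- (seq_len(ny) - 1) * spacing[2]
  gx <- (seq_len(nx) - 1) * spacing[3]
  cz <- gz[(nz + 1) / 2]; cy <- gy[(ny + 1) / 2]
  slab_x <- 2 * spacing[3]                 # dendrite slab occupies x <= slab_x
  att <- c(cz, cy, slab_x)                 # attachment on the slab face
  Z <- array(rep(gz, times = ny * nx), d)
  Y <- array(rep(rep(gy, each = nz), times = nx), d)
  X <- array(rep(gx, each = nz * ny), d)
  dend <- X <= slab_x + 1e-9
  neck <- (Z - cz)^2 + (Y - cy)^2 <= neck_r^2 &
    X > slab_x & X <= slab_x + neck_len + 1e-9
  hc <- c(cz, cy, slab_x + neck_len + head_r)
  head <- (Z - hc[1])^2 + (Y - hc[2])^2 + (X - hc[3])^2 <= head_r^2
  region_mask <- (neck | head) & !dend
  region <- which(region_mask, arr.ind = TRUE)
  colnames(region) <- c("z", "y", "x")
  list(region = region, dendrite = dend, spacing = spacing, shape = d,
       head_center = hc, head_r = head_r, neck_r = neck_r,
       neck_len = neck_len)
}
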