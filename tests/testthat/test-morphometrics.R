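test_that("anisotropy closed forms: cube is 1/3, rod is 1, axes permute freely", {
  cube <- array(0L, dim = c(9, 9, 9))
  cube[, , ] <- 1L
  a_cube <- cell_anisotropy(labeled_volume(cube))
  expect_equal(a_cube$anisotropy, 1 / 3)
  expect_equal(a_cube$m1, a_cube$m3)  # three equal magnitudes by symmetry

  rod <- array(0L, dim = c(1, 1, 9))
  rod[, , ] <- 1L
  a_rod <- cell_anisotropy(labeled_volume(rod))
  # population variance of {0..8} is 60/9; the other magnitudes vanish
  expect_equal(a_rod$m1, sqrt(60 / 9))
  expect_equal(a_rod$m2, 0)
  expect_equal(a_rod$anisotropy, 1)

  # the same rod along each axis gives identical anisotropy
  for (d in list(c(9, 1, 1), c(1, 9, 1), c(1, 1, 9))) {
    r <- array(1L, dim = d)
    expect_equal(cell_anisotropy(labeled_volume(r))$anisotropy, 1)
  }
})

test_that("single-voxel cells report missing anisotropy with a warning", {
  arr <- array(0L, dim = c(3, 3, 3))
  arr[2, 2, 2] <- 1L
  expect_warning(a <- cell_anisotropy(labeled_volume(arr)), "degenerate")
  expect_true(is.na(a$anisotropy))
})

test_that("anisotropy respects voxel size and stays within its bounds", {
  # a 3x3x3 voxel cube at voxel size (1,1,3) is physically a 1:1:3 slab
  arr <- array(1L, dim = c(3, 3, 3))
  iso <- cell_anisotropy(labeled_volume(arr, voxel_size = c(1, 1, 1)))
  tall <- cell_anisotropy(labeled_volume(arr, voxel_size = c(1, 1, 3)))
  expect_equal(iso$anisotropy, 1 / 3)
  expect_gt(tall$anisotropy, 1 / 3)

  fix <- phantom_fixture(jitter = 0, seed = 0, spec = small_phantom_spec(jitter = 0))
  a <- suppressWarnings(cell_anisotropy(fix$volume))
  ok <- !is.na(a$anisotropy)
  expect_true(all(a$anisotropy[ok] >= 1 / 3 - 1e-12))
  expect_true(all(a$anisotropy[ok] <= 1 + 1e-12))
})

test_that("two touching blocks share one edge with the exact face area", {
  net <- build_cell_network(two_block_volume())
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$interface_area, 4)  # 4 unit faces
  expect_equal(sort(c(net$edges$from, net$edges$to)), c(1L, 2L))

  # anisotropic voxels: contact along x, face area = vy * vz = 2 per face
  net2 <- build_cell_network(two_block_volume(voxel_size = c(1, 1, 2)))
  expect_equal(net2$edges$interface_area, 8)

  # isolated single cell: one node, no edges
  arr <- array(0L, dim = c(3, 3, 3))
  arr[2, 2, 2] <- 7L
  net3 <- build_cell_network(labeled_volume(arr))
  expect_equal(net3$nodes$label, 7L)
  expect_equal(nrow(net3$edges), 0)
})

test_that("interface areas conserve each cell's total voxel-face area", {
  fix <- phantom_fixture(jitter = 0, seed = 0, spec = small_phantom_spec(jitter = 0))
  vol <- fix$volume
  net <- build_cell_network(vol)
  vs <- vol$voxel_size

  # independent accounting: per cell, total face area minus internal
  # same-label faces, via direct neighbour comparison per axis
  A <- vol$labels
  d <- dim(A)
  face <- c(vs["x"] * vs["y"], vs["x"] * vs["z"], vs["y"] * vs["z"])
  counts <- table(A[A != 0])
  total_area <- setNames(as.numeric(counts) * 2 * sum(face), names(counts))
  internal <- setNames(numeric(length(counts)), names(counts))
  for (ax in 1:3) {
    n_ax <- d[ax]
    a1 <- switch(ax, A[-n_ax, , ], A[, -n_ax, ], A[, , -n_ax])
    a2 <- switch(ax, A[-1, , ], A[, -1, ], A[, , -1])
    same <- a1 == a2 & a1 != 0
    if (any(same)) {
      t2 <- table(a1[same])
      internal[names(t2)] <- internal[names(t2)] + 2 * as.numeric(t2) * face[ax]
    }
  }
  boundary_area <- total_area - internal

  edge_sum <- setNames(numeric(nrow(net$nodes)), net$nodes$label)
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    edge_sum[as.character(e$from)] <- edge_sum[as.character(e$from)] + e$interface_area
    edge_sum[as.character(e$to)] <- edge_sum[as.character(e$to)] + e$interface_area
  }
  lhs <- edge_sum + setNames(net$nodes$exposed_area, net$nodes$label)
  expect_equal(lhs[names(boundary_area)], boundary_area)
})

test_that("interior cells have more contacts than epidermal cells on average", {
  fix <- phantom_fixture(jitter = 0, seed = 0)
  net <- build_cell_network(fix$volume)
  deg <- setNames(numeric(nrow(net$nodes)), net$nodes$label)
  t1 <- table(c(net$edges$from, net$edges$to))
  deg[names(t1)] <- as.numeric(t1)
  lay <- fix$layers$layer[match(as.integer(names(deg)), fix$layers$label)]
  expect_gt(mean(deg[lay == "L2"]), mean(deg[lay == "L1"]))
})

test_that("zone summaries reflect generator ground truth and edge classes", {
  spec <- phantom_spec(layer_volume_profile = "increasing", jitter = 0.1, seed = 3)
  fix <- phantom_fixture(spec = spec)
  net <- build_cell_network(fix$volume)
  zs <- zone_summaries(fix$cells, fix$layers, net = net)
  z <- zs$zones
  # deeper layers were generated with larger cells
  vm <- setNames(z$volume_mean, z$zone)
  expect_gt(vm[["L2"]], vm[["L1"]])
  expect_gt(vm[["L3"]], vm[["L2"]])

  # edge classification double-checked by brute-force lookup of both endpoints
  zmap <- setNames(fix$layers$zone, fix$layers$label)
  pairs <- apply(cbind(zmap[as.character(net$edges$from)],
                       zmap[as.character(net$edges$to)]), 1,
                 function(p) paste(sort(p), collapse = "|"))
  brute <- table(pairs)
  got <- setNames(zs$interfaces$n_interfaces, zs$interfaces$pair)
  expect_equal(got[names(brute)], setNames(as.numeric(brute), names(brute)))

  # single-zone input gives exactly one zone row
  one <- zone_summaries(fix$cells,
                        tibble::tibble(label = fix$cells$label, zone = "L1"))
  expect_equal(nrow(one$zones), 1)
})
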