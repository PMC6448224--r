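test_that("cell centroids, volumes and planar surface projection are exact", {
  arr <- array(0L, dim = c(2, 2, 4))
  arr[1, 1, 1] <- 1L  # voxels (z,y,x) = (0,0,0)
  arr[1, 1, 2] <- 1L  # and (0,0,1)
  vol <- labeled_volume(arr)
  # mesh well above the cell: flat plane z = 5 shifted so projection is planar
  v <- rbind(c(-10, -10, 5), c(10, -10, 5), c(10, 10, 5), c(-10, 10, 5))
  mesh <- surface_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4)))
  ct <- compute_cell_table(vol, mesh)
  expect_equal(nrow(ct), 1)
  expect_equal(c(ct$x, ct$y, ct$z), c(0.5, 0, 0))  # mean of the two voxel centres
  expect_equal(ct$volume, 2)
  expect_equal(c(ct$surf_x, ct$surf_y, ct$surf_z), c(0.5, 0, 5))
  expect_equal(c(ct$t_x, ct$t_y, ct$t_z), c(0, 0, -5))  # t = centroid - surface point
  expect_equal(ct$t_norm, 5)
})

test_that("nearest point on mesh matches an exhaustive per-triangle oracle", {
  fix <- phantom_fixture(jitter = 0, seed = 0, spec = small_phantom_spec(jitter = 0))
  mesh <- fix$mesh
  set.seed(42)
  pts <- fix$cells[sample(nrow(fix$cells), 12), ]
  for (i in seq_len(nrow(pts))) {
    p <- c(pts$x[i], pts$y[i], pts$z[i])
    oracle <- brute_nearest_on_mesh(p, mesh)
    got <- nearest_mesh_point(p, mesh)
    expect_equal(got$distance, oracle$distance, tolerance = 1e-9)
    expect_lt(sqrt(sum((got$point - oracle$point)^2)), 1e-6)
  }
})

test_that("surface distance is invariant under rigid rotation of mesh and points", {
  fix <- phantom_fixture(jitter = 0, seed = 0, spec = small_phantom_spec(jitter = 0))
  mesh <- fix$mesh
  pts <- as.matrix(fix$cells[1:20, c("x", "y", "z")])
  d0 <- nearest_mesh_point(pts, mesh)$distance
  # a random rotation matrix (QR of a fixed random matrix)
  set.seed(7)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  mesh_rot <- surface_mesh(mesh$vertices %*% t(Q), mesh$triangles)
  d1 <- nearest_mesh_point(pts %*% t(Q), mesh_rot)$distance
  expect_equal(d1, d0, tolerance = 1e-6)
})

test_that("sum of cell volumes equals foreground voxel count times voxel volume", {
  fix <- phantom_fixture(jitter = 0, seed = 0, spec = small_phantom_spec(jitter = 0))
  nfg <- sum(fix$volume$labels != 0)
  expect_equal(sum(fix$cells$volume), nfg * prod(fix$volume$voxel_size))
})

test_that("extracted surface encloses the right volume and keeps the largest blob", {
  # solid cube, no smoothing: enclosed volume within 15% of 10^3
  arr <- array(0L, dim = c(14, 14, 14))
  arr[3:12, 3:12, 3:12] <- 1L
  mesh <- extract_surface_mesh(labeled_volume(arr), sigma = 0)
  expect_equal(mesh_volume(mesh), 1000, tolerance = 0.15)

  # two disjoint blobs: only the larger one's surface is returned
  arr2 <- array(0L, dim = c(12, 12, 20))
  arr2[3:10, 3:10, 3:10] <- 1L   # large
  arr2[5:7, 5:7, 15:17] <- 2L    # small, disjoint
  m2 <- extract_surface_mesh(labeled_volume(arr2), sigma = 0)
  expect_lt(max(m2$vertices[, "x"]), 13)  # nothing from the far blob

  expect_error(extract_surface_mesh(labeled_volume(array(0L, c(3, 3, 3)))),
               "foreground")
})

test_that("every phantom cell centroid lies inside or within a voxel of the mesh", {
  fix <- phantom_fixture(jitter = 0, seed = 0, spec = small_phantom_spec(jitter = 0))
  # centroids are interior points: distance to the (cut) surface is bounded by
  # the dome radius, and no centroid should sit far outside the mesh
  centre <- fix$truth$centre
  rel <- sweep(as.matrix(fix$cells[, c("x", "y", "z")]), 2, centre)
  expect_true(all(sqrt(rowSums(rel^2)) <= 16 + 1))
})

test_that("cone membership matches direct substitution and the arccos oracle", {
  # on-axis point is inside, orthogonal point is outside, 45 degrees inside
  expect_true(cone_contains(c(0, 0, 0), c(0, 0, 1), 60, c(0, 0, 5)))
  expect_false(cone_contains(c(0, 0, 0), c(0, 0, 1), 60, c(1, 0, 0)))
  expect_true(cone_contains(c(0, 0, 0), c(0, 0, 1), 60, c(1, 0, 1)))

  expect_error(cone_contains(c(0, 0, 0), c(0, 0, 0), 60, c(1, 1, 1)), "degenerate")

  set.seed(11)
  n <- 2000
  apex <- matrix(rnorm(3 * n), ncol = 3)
  axis <- matrix(rnorm(3 * n), ncol = 3)
  query <- matrix(rnorm(3 * n, sd = 3), ncol = 3)
  theta <- runif(n, 1, 89)
  for (i in seq_len(n)) {
    got <- cone_contains(apex[i, ], axis[i, ], theta[i], query[i, ])
    d <- query[i, ] - apex[i, ]
    ang <- acos(sum(d * axis[i, ]) / sqrt(sum(d^2) * sum(axis[i, ]^2))) * 180 / pi
    expect_identical(got, ang < theta[i])
  }
})

test_that("the literal printed inequality selects the cone complement", {
  apex <- c(0, 0, 0); axis <- c(0, 0, 1)  # axis toward surface, t = -axis
  q_in <- c(0, 0, 5)
  expect_true(cone_contains(apex, axis, 60, q_in, convention = "described"))
  # literal: cos(angle to t) = -1 < cos60 -> "member", i.e. complement behaviour
  expect_true(cone_contains(apex, axis, 60, q_in, convention = "literal"))
  q_down <- c(0, 0, -5)  # along t: described says no, literal says no (cos=1)
  expect_false(cone_contains(apex, axis, 60, q_down, convention = "described"))
  expect_false(cone_contains(apex, axis, 60, q_down, convention = "literal"))
})
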