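# selection geometry used by the worked example:
# x_SAM = (0,0,0), x_p = (10,0,0), x_b = (6,0,0) => d_p = 4, d_SAM = 6, r = 2/3
worked_cells <- function(extra = NULL) {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(6, 0, 0))
  if (!is.null(extra)) pts <- rbind(pts, extra)
  tibble::tibble(label = seq_len(nrow(pts)),
                 x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 volume = 10)
}

test_that("worked weighted-Voronoi example classifies P, B and S by substitution", {
  cells <- worked_cells(rbind(c(8, 0, 0), c(2, 0, 0)))
  part <- mark_primordium(cells, sam_peak_cell = 1, primordium_peak_cell = 2,
                          saddle_cell = 3, delta = 0, absolute_distance = 100)
  reg <- setNames(part$region, part$label)
  expect_equal(unname(reg["4"]), "P")  # rho = 2/8 < 2/3
  expect_equal(unname(reg["3"]), "B")  # rho = 4/6 = r exactly, within the band
  expect_equal(unname(reg["5"]), "S")  # rho = 8/2 > 2/3
  # the selected peaks belong to their own zones
  expect_equal(unname(reg["1"]), "S")
  expect_equal(unname(reg["2"]), "P")
})

test_that("partition equals a brute-force evaluation of the three set inequalities", {
  set.seed(101)
  for (cfg in 1:8) {
    pts <- matrix(runif(3 * 120, -20, 20), ncol = 3)
    sel <- sample(120, 3)
    delta <- runif(1, 0, 0.3)
    absd <- runif(1, 5, 40)
    cells <- tibble::tibble(label = 1:120, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                            volume = 1)
    part <- mark_primordium(cells, sel[1], sel[2], sel[3],
                            delta = delta, absolute_distance = absd)

    x_sam <- pts[sel[1], ]; x_p <- pts[sel[2], ]; x_b <- pts[sel[3], ]
    r <- sqrt(sum((x_p - x_b)^2)) / sqrt(sum((x_sam - x_b)^2))
    expected <- vapply(1:120, function(i) {
      dp <- sqrt(sum((pts[i, ] - x_p)^2))
      ds <- sqrt(sum((pts[i, ] - x_sam)^2))
      db <- sqrt(sum((pts[i, ] - x_b)^2))
      rho <- if (ds == 0) Inf else if (dp == 0) 0 else dp / ds
      if (rho < r - delta) return("P")
      if (rho <= r + delta) {
        if (db <= absd) return("B")
        return(if (rho < r) "P" else "S")
      }
      "S"
    }, "")
    expect_identical(part$region, expected)
  }
})

test_that("zones form a partition and B grows monotonically with delta", {
  set.seed(5)
  pts <- matrix(runif(3 * 200, -15, 15), ncol = 3)
  cells <- tibble::tibble(label = 1:200, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                          volume = 1)
  parts <- lapply(c(0, 0.05, 0.1, 0.2), function(d) {
    mark_primordium(cells, 1, 2, 3, delta = d, absolute_distance = 1e6)
  })
  for (p in parts) {
    expect_equal(sort(p$label), 1:200)
    expect_true(all(p$region %in% c("P", "B", "S")))
  }
  bsets <- lapply(parts, function(p) p$label[p$region == "B"])
  for (i in 1:3) expect_true(all(bsets[[i]] %in% bsets[[i + 1]]))
})

test_that("swapping the two peaks mirrors P and S when delta is zero", {
  set.seed(17)
  pts <- matrix(runif(3 * 150, -10, 10), ncol = 3)
  cells <- tibble::tibble(label = 1:150, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                          volume = 1)
  a <- mark_primordium(cells, 1, 2, 3, delta = 0, absolute_distance = 1e6)
  b <- mark_primordium(cells, 2, 1, 3, delta = 0, absolute_distance = 1e6)
  expect_setequal(a$label[a$region == "P"], b$label[b$region == "S"])
  expect_setequal(a$label[a$region == "S"], b$label[b$region == "P"])
})

test_that("selection validation rejects coincident or missing cells", {
  cells <- worked_cells()
  expect_error(mark_primordium(cells, 1, 1, 3), "distinct")
  expect_error(mark_primordium(cells, 1, 2, 99), "not found")
  cells2 <- worked_cells(rbind(c(0, 0, 0)))  # label 4 coincides with the SAM peak
  expect_error(mark_primordium(cells2, 1, 2, 4), "coincide")
})

test_that("sequential primordia freeze earlier zones and honour same_label", {
  fix <- phantom_fixture(jitter = 0, seed = 0,
                         spec = phantom_spec(
                           jitter = 0, seed = 0,
                           primordia = tibble::tibble(
                             dir_x = c(0.8, -0.8), dir_y = c(0.2, -0.3),
                             dir_z = c(0.56, 0.52),
                             bump_radius = 12, bump_height = 8)))
  tr <- fix$truth
  sels <- tibble::tibble(
    sam_peak_cell = tr$apex_cell,
    primordium_peak_cell = tr$primordia$peak_cell,
    saddle_cell = tr$primordia$saddle_cell,
    delta = 0.05, absolute_distance = 15
  )
  ann <- mark_primordia(fix$cells, sels, fix$layers)
  expect_setequal(ann$label, fix$cells$label)
  expect_false(any(duplicated(ann$label)))

  p1 <- ann$label[!is.na(ann$primordium_index) & ann$primordium_index == 1]
  p2 <- ann$label[!is.na(ann$primordium_index) & ann$primordium_index == 2]
  expect_gt(length(p1), 0)
  expect_gt(length(p2), 0)
  expect_length(intersect(p1, p2), 0)

  # primordium cells keep their layer stratum in the zone name
  prim <- startsWith(ann$zone, "primordium")
  expect_equal(ann$zone[prim], paste0("primordium_", ann$layer[prim]))

  ann_same <- mark_primordia(fix$cells, sels, fix$layers, same_label = TRUE)
  idx <- ann_same$primordium_index[!is.na(ann_same$primordium_index)]
  expect_true(all(idx == 1L))

  # one selection is just mark_primordium plus relabelling
  one <- mark_primordia(fix$cells, sels[1, ], fix$layers)
  direct <- mark_primordium(fix$cells, sels$sam_peak_cell[1],
                            sels$primordium_peak_cell[1], sels$saddle_cell[1],
                            delta = 0.05, absolute_distance = 15)
  direct_p <- direct$label[direct$region == "P"]
  expect_setequal(one$label[!is.na(one$primordium_index) &
                              startsWith(one$zone, "primordium")], direct_p)

  # a selection cell inside a previously marked primordium is rejected
  bad <- sels
  bad$primordium_peak_cell[2] <- p1[1]
  expect_error(mark_primordia(fix$cells, bad, fix$layers), "previously marked")
})
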