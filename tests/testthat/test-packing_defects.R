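radii_c <- c(C = 0.17, BEAD = 0.17)

test_that("a fully covered leaflet yields zero defects", {
  fx <- defect_patch(expose = FALSE, window = 0) # no gap at all
  # (the deliberately sparse lower leaflet produces void-cell warnings)
  grids <- suppressWarnings(scan_defects(fx$frame, fx$topo, fx$ref,
                                         radii = radii_c))
  expect_equal(sum(grids$upper$flag != "none"), 0)
  s <- defect_summary(grids)
  expect_true(all(s$n_defects[s$leaflet == "upper"] == 0))
})

test_that("an exposed aliphatic 0.15 nm below glycerol is a deep defect of ~0.25 nm^2", {
  fx <- defect_patch(depth = 0.15, window = 0.5)
  grids <- suppressWarnings(scan_defects(fx$frame, fx$topo, fx$ref,
                                         radii = radii_c))
  g <- grids$upper
  expect_gt(sum(g$flag == "deep"), 0)
  expect_equal(sum(g$flag == "shallow"), 0)
  # measured depth equals the planted depth exactly (grid-aligned atoms)
  expect_equal(unique(round(g$depth[g$flag == "deep"], 9)), 0.15)

  s <- defect_summary(grids)
  area <- s$total_area[s$leaflet == "upper" & s$class == "deep"]
  # one grid-cell ring tolerance around the 0.5 x 0.5 nm window
  ring <- (0.7^2 - 0.5^2) # nm^2
  expect_lt(abs(area - 0.25), ring)
  expect_equal(s$n_defects[s$leaflet == "upper" & s$class == "deep"], 1)
})

test_that("the 1 Angstrom threshold separates shallow from deep, boundary shallow", {
  fx <- defect_patch(depth = 0.05)
  g <- suppressWarnings(scan_defects(fx$frame, fx$topo, fx$ref,
                                     radii = radii_c))$upper
  expect_gt(sum(g$flag == "shallow"), 0)
  expect_equal(sum(g$flag == "deep"), 0)

  # depth exactly 0.1 nm: classified shallow (<= boundary)
  fx2 <- defect_patch(depth = 0.1)
  g2 <- suppressWarnings(scan_defects(fx2$frame, fx2$topo, fx2$ref,
                                      radii = radii_c))$upper
  expect_equal(unique(round(g2$depth[g2$flag != "none"], 9)), 0.1)
  expect_equal(sum(g2$flag == "deep"), 0)
  expect_gt(sum(g2$flag == "shallow"), 0)
})

test_that("the scan is invariant under x-y translation modulo the box", {
  fx <- defect_patch(depth = 0.15)
  g0 <- suppressWarnings(scan_defects(fx$frame, fx$topo, fx$ref,
                                      radii = radii_c))
  shift <- c(0.4, 1.2) # multiples of the 0.1 nm grid spacing
  coords <- fx$frame$coords
  coords[, 1] <- (coords[, 1] + shift[1]) %% fx$frame$box[1]
  coords[, 2] <- (coords[, 2] + shift[2]) %% fx$frame$box[2]
  frame2 <- md_frame(coords, fx$frame$box)
  g1 <- suppressWarnings(scan_defects(frame2, fx$topo,
                                      membrane_reference(frame2, fx$topo),
                                      radii = radii_c))
  expect_equal(sum(g1$upper$flag == "deep"), sum(g0$upper$flag == "deep"))
  expect_equal(sum(g1$upper$flag == "shallow"), sum(g0$upper$flag == "shallow"))
})

test_that("covering an exposed defect removes it (monotone coverage)", {
  fx <- defect_patch(depth = 0.15)
  n_deep <- sum(suppressWarnings(
    scan_defects(fx$frame, fx$topo, fx$ref, radii = radii_c))$upper$flag == "deep")
  expect_gt(n_deep, 0)
  # put each exposed lipid's head back over its own tail: full coverage
  coords3 <- fx$frame$coords
  for (rr in fx$exposed_res) {
    rows_r <- which(fx$topo$atoms$residue_id == rr)
    hd <- rows_r[fx$topo$atoms$atom_name[rows_r] == "HD"]
    c1 <- rows_r[fx$topo$atoms$atom_name[rows_r] == "C1"]
    coords3[hd, ] <- c(coords3[c1, 1:2], 3.0)
  }
  frame3 <- md_frame(coords3, fx$frame$box)
  g3 <- suppressWarnings(scan_defects(frame3, fx$topo,
                                      membrane_reference(frame3, fx$topo),
                                      radii = radii_c))
  expect_lt(sum(g3$upper$flag == "deep"), n_deep)
})

test_that("defect merging: cell arithmetic, connectivity, empty grids", {
  mk_grid <- function(flag) {
    structure(list(leaflet = "upper", grid_spacing = 0.1,
                   nx = nrow(flag), ny = ncol(flag), box = c(1, 1, 5),
                   cell_area = 0.01, flag = flag,
                   depth = matrix(NA_real_, nrow(flag), ncol(flag)),
                   contact = matrix(NA_integer_, nrow(flag), ncol(flag)),
                   void = matrix(FALSE, nrow(flag), ncol(flag))),
              class = "defect_grid")
  }
  fl <- matrix("none", 10, 10)
  fl[3:7, 3:7] <- "deep" # single 25-cell patch at 0.1 nm spacing
  g <- structure(list(upper = mk_grid(fl), lower = mk_grid(matrix("none", 10, 10))),
                 class = "defect_grids")
  s <- defect_summary(g)
  expect_equal(s$n_defects[s$leaflet == "upper" & s$class == "deep"], 1)
  expect_equal(s$total_area[s$leaflet == "upper" & s$class == "deep"], 0.25)

  # two patches separated by a non-defect cell are two defects
  fl2 <- matrix("none", 10, 10)
  fl2[2:3, 2:3] <- "deep"
  fl2[6:7, 6:7] <- "deep"
  g2 <- structure(list(upper = mk_grid(fl2), lower = mk_grid(matrix("none", 10, 10))),
                  class = "defect_grids")
  s2 <- defect_summary(g2)
  expect_equal(s2$n_defects[s2$leaflet == "upper" & s2$class == "deep"], 2)

  # patches touching across the periodic boundary merge into one
  fl3 <- matrix("none", 10, 10)
  fl3[1, 4:6] <- "deep"
  fl3[10, 4:6] <- "deep"
  g3 <- structure(list(upper = mk_grid(fl3), lower = mk_grid(matrix("none", 10, 10))),
                  class = "defect_grids")
  s3 <- defect_summary(g3)
  expect_equal(s3$n_defects[s3$leaflet == "upper" & s3$class == "deep"], 1)

  # empty grids: zero counts
  s0 <- defect_summary(structure(list(upper = mk_grid(matrix("none", 10, 10)),
                                      lower = mk_grid(matrix("none", 10, 10))),
                                 class = "defect_grids"))
  expect_true(all(s0$n_defects == 0))

  # inconsistent shapes error
  gbad <- list(g, structure(list(upper = mk_grid(matrix("none", 5, 5)),
                                 lower = mk_grid(matrix("none", 5, 5))),
                            class = "defect_grids"))
  expect_error(defect_summary(gbad), "grid shapes")
})

test_that("halving the grid spacing converges the measured area", {
  fx <- defect_patch(depth = 0.15, window = 0.6)
  a1 <- defect_summary(suppressWarnings(
    scan_defects(fx$frame, fx$topo, fx$ref, grid_spacing = 0.1,
                 radii = radii_c)))
  a2 <- defect_summary(suppressWarnings(
    scan_defects(fx$frame, fx$topo, fx$ref, grid_spacing = 0.05,
                 radii = radii_c)))
  area1 <- a1$total_area[a1$leaflet == "upper" & a1$class == "deep"]
  area2 <- a2$total_area[a2$leaflet == "upper" & a2$class == "deep"]
  # converged to within one perimeter band of the coarser grid
  expect_lt(abs(area1 - area2), 4 * 0.6 * 0.1)
})
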