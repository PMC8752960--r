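test_that("coordinate fields satisfy their boundary conditions and ranges", {
  m <- coarse_hf_mesh()
  u <- coarse_hf_uvc()
  expect_true(all(u$z >= 0 & u$z <= 1))
  expect_true(all(u$rho >= 0 & u$rho <= 1, na.rm = TRUE))
  expect_true(all(u$z[u$base_nodes] == 1))
  expect_true(all(u$z[u$apex_nodes] == 0))
  endo <- quadlead:::nodes_on_label(m, "LV_ENDO")
  epi <- quadlead:::nodes_on_label(m, "EPI", "LV_WALL")
  expect_true(all(u$rho_lv[endo] == 0))
  expect_true(all(u$rho_lv[epi] == 1))
  expect_true(all(u$nu %in% c("LV", "RV")))
  expect_true(all(u$phi > -pi & u$phi <= pi))
})

test_that("apicobasal extrema sit on the boundary sets (no interior extrema)", {
  u <- coarse_hf_uvc()
  interior <- setdiff(seq_along(u$z), c(u$base_nodes, u$apex_nodes))
  expect_gt(min(u$z[interior]), 0)
  expect_lt(max(u$z[interior]), 1)
})

test_that("missing surface labels raise a labelling error", {
  m <- coarse_hf_mesh()
  m$boundary$label[m$boundary$label == "BASE"] <- "EPI"
  expect_error(compute_uvc(m), class = "quadlead_label_error")
})

test_that("equatorial apicobasal coordinate matches the meridian-arc oracle", {
  p <- hf_shape_defaults(6)
  m <- generate_biventricular_mesh(p, seed = 2)
  u <- compute_uvc(m)
  # oracle: normalized arc length along the endocardial meridian from apex
  cc <- p$lv_long_axis; a <- p$lv_endo_radius
  zb <- cc * (2 * p$base_truncation_fraction - 1)
  th_max <- acos(-zb / cc)
  arc_to <- function(th) {
    tt <- seq(0, th, length.out = 2001)
    f <- sqrt((a * cos(tt))^2 + (cc * sin(tt))^2)
    sum((f[-1] + f[-length(f)]) / 2) * diff(tt[1:2])
  }
  z_oracle <- arc_to(pi / 2) / arc_to(th_max)
  # free-wall endocardial nodes at the equator (z coordinate ~ 0)
  endo <- quadlead:::nodes_on_label(m, "LV_ENDO")
  sel <- endo[abs(m$nodes[endo, 3]) < 2 & u$phi[endo] > 0 & u$phi[endo] < pi]
  expect_gt(length(sel), 3)
  expect_lt(max(abs(u$z[sel] - z_oracle)), 0.05)
})

test_that("the AHA map partitions the LV into the 17 standard segments", {
  m <- generate_biventricular_mesh(hf_shape_defaults(6), seed = 1)
  u <- compute_uvc(m)
  aha <- map_aha17(u)
  lv <- u$nu == "LV"
  expect_true(all(!is.na(aha[lv])))
  expect_true(all(is.na(aha[!lv])))
  expect_setequal(sort(unique(aha[lv])), 1:17)
  # apex cap by construction
  expect_true(all(aha[lv & u$z <= 0.15] == 17))
  # basal inferolateral sector centre -> segment 5
  bas_il <- lv & u$z > 0.8 & u$z < 0.95 &
    abs(u$phi - 120 * pi / 180) < 10 * pi / 180
  expect_true(any(bas_il))
  expect_true(all(aha[bas_il] == 5))
  # mid band of the same sector -> segment 11 (standard numbering)
  mid_il <- lv & u$z > 0.5 & u$z < 0.7 &
    abs(u$phi - 120 * pi / 180) < 10 * pi / 180
  expect_true(all(aha[mid_il] == 11))
})

test_that("the AHA map is invariant under uniform scaling", {
  m <- coarse_hf_mesh()
  aha1 <- map_aha17(coarse_hf_uvc())
  m2 <- scale_mesh(m, 1.3)
  aha2 <- map_aha17(compute_uvc(m2))
  expect_equal(unclass(aha1), unclass(aha2))
})

test_that("wall thickness is exact on a uniform spherical shell", {
  # sphere limit: wall thickness exactly 10 mm along every normal
  p <- shape_parameters(lv_long_axis = 30, lv_endo_radius = 30,
                        lv_wall_thickness = 10, rv_wall_thickness = 4,
                        rv_lateral_extent = 16, target_edge_length = 5)
  m <- generate_biventricular_mesh(p, seed = 1)
  u <- compute_uvc(m)
  th <- compute_wall_thickness(m, u)
  lv <- which(m$region == "LV_WALL")
  expect_true(all(th[lv] > 0))
  expect_true(all(is.na(th[-lv])))
  # away from the basal rim the shell is uniform; at the rim both surfaces
  # are cut by the same plane and a corner wedge legitimately widens
  z_e <- rowMeans(matrix(u$z[m$tets], ncol = 4))
  core <- lv[z_e[lv] < 0.9]
  expect_lt(max(abs(th[core] - 10)), 0.5)
})

test_that("ellipsoid-shell thickness agrees with the analytic normal ray", {
  p <- hf_shape_defaults(6)
  m <- generate_biventricular_mesh(p, seed = 2)
  u <- compute_uvc(m)
  th <- compute_wall_thickness(m, u)
  lv <- which(m$region == "LV_WALL")
  cent <- quadlead:::element_centroids(m, lv)
  z_e <- rowMeans(matrix(u$z[m$tets], ncol = 4))[lv]
  phi_e <- atan2(cent[, 2], cent[, 1])
  # free-wall, mid-height elements (away from rim/attachment effects)
  sel <- which(z_e > 0.25 & z_e < 0.75 & phi_e > 0.3 & phi_e < pi - 0.3)
  sel <- sel[seq(1, length(sel), by = 7)]
  oracle <- vapply(sel, function(i) {
    ellipsoid_shell_thickness(cent[i, ], p$lv_endo_radius, p$lv_long_axis,
                              p$lv_wall_thickness)
  }, 0)
  expect_lt(max(abs(th[lv][sel] - oracle) / oracle), 0.10)
})
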