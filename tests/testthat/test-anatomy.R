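test_that("generated biventricular meshes satisfy all structural invariants", {
  m <- coarse_hf_mesh()
  expect_s3_class(m, "ventricular_mesh")
  expect_true(all(m$volume > 0))
  expect_setequal(unique(m$boundary$label), c("LV_ENDO", "RV_ENDO", "EPI", "BASE"))
  expect_lt(max(abs(sqrt(rowSums(m$fibre^2)) - 1)), 1e-9)
  expect_setequal(unique(m$region), c("LV_WALL", "RV_WALL"))
  expect_invisible(validate_ventricular_mesh(m))
})

test_that("LV cavity volume matches the closed-form truncated ellipsoid", {
  p <- hf_shape_defaults(target_edge_length = 2)
  m <- generate_biventricular_mesh(p, seed = 1)
  a <- p$lv_endo_radius; cc <- p$lv_long_axis
  zb <- cc * (2 * p$base_truncation_fraction - 1)
  v_exact <- pi * a^2 * ((zb + cc) - (zb^3 + cc^3) / (3 * cc^2))
  expect_lt(abs(lv_cavity_volume(m) - v_exact) / v_exact, 0.02)
})

test_that("mesh generation is bitwise deterministic in its inputs", {
  m1 <- generate_biventricular_mesh(hf_shape_defaults(10), seed = 5)
  m2 <- generate_biventricular_mesh(hf_shape_defaults(10), seed = 5)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
  expect_identical(m1$fibre, m2$fibre)
})

test_that("infeasible geometry is rejected up front", {
  expect_error(shape_parameters(lv_endo_radius = 10, lv_wall_thickness = 12),
               class = "quadlead_geometry_error")
  expect_error(shape_parameters(base_truncation_fraction = 1.2),
               class = "quadlead_argument_error")
})

test_that("cohort sampling returns the requested sizes deterministically", {
  spec_hf <- cohort_specification(24, "HF",
                                  shape_mean = hf_shape_defaults(12),
                                  random_seed = 3)
  spec_rr <- cohort_specification(20, "RR",
                                  shape_mean = rr_shape_defaults(12),
                                  random_seed = 3)
  hf <- sample_cohort(spec_hf)
  rr <- sample_cohort(spec_rr)
  expect_length(hf, 24)
  expect_length(rr, 20)
  hf2 <- sample_cohort(spec_hf)
  expect_identical(vapply(hf, function(m) nrow(m$tets), 0L),
                   vapply(hf2, function(m) nrow(m$tets), 0L))
  expect_identical(hf[[7]]$nodes, hf2[[7]]$nodes)
  expect_error(cohort_specification(0, "HF"), class = "quadlead_argument_error")
})

test_that("HF draws have larger cavities and thinner walls than RR draws", {
  hf <- sample_cohort(cohort_specification(10, "HF",
                                           shape_mean = hf_shape_defaults(12),
                                           random_seed = 9))
  rr <- sample_cohort(cohort_specification(10, "RR",
                                           shape_mean = rr_shape_defaults(12),
                                           random_seed = 9))
  expect_gt(mean(vapply(hf, lv_cavity_volume, 0)),
            mean(vapply(rr, lv_cavity_volume, 0)))
  expect_lt(mean(attr(hf, "manifest")$lv_wall_thickness),
            mean(attr(rr, "manifest")$lv_wall_thickness))
})

test_that("uniform scaling obeys the cube law and is invertible", {
  m <- coarse_hf_mesh()
  expect_equal(sum(scale_mesh(m, 1)$volume), sum(m$volume), tolerance = 1e-12)
  s <- scale_mesh(m, 0.75)
  expect_equal(sum(s$volume) / sum(m$volume), 0.421875, tolerance = 1e-6)
  expect_identical(s$fibre, m$fibre)
  expect_identical(s$boundary$label, m$boundary$label)
  back <- scale_mesh(scale_mesh(m, 2), 0.5)
  expect_lt(max(abs(back$nodes - m$nodes)), 1e-9)
  expect_error(scale_mesh(m, -1), class = "quadlead_argument_error")
})

test_that("rule-based fibres follow the linear transmural helix rule", {
  m <- coarse_hf_mesh()
  u <- coarse_hf_uvc()
  m2 <- assign_rule_based_fibres(m, u, 60, -60)
  ha <- fibre_helix_angles(m2, u)
  rho_node <- ifelse(!is.na(u$rho_lv), u$rho_lv, u$rho_rv)
  rho_e <- rowMeans(matrix(rho_node[m2$tets], ncol = 4))
  # linear rule: helix angle 60 -> -60 across the wall; 0 at mid-wall
  expect_lt(max(abs(ha - (60 - 120 * rho_e))), 1)
  mid <- abs(rho_e - 0.5) < 0.02
  expect_true(any(mid))
  expect_lt(max(abs(ha[mid])), 3.5)
  # tangency: orthogonal to the transmural gradient
  lv <- which(m2$region == "LV_WALL")
  g <- quadlead:::element_gradient(m2, u$rho_lv, elements = lv)
  g <- g / sqrt(rowSums(g^2))
  expect_lt(max(abs(rowSums(m2$fibre[lv, ] * g))), 0.05)
  # degenerate rule: equal angles give circumferential fibres everywhere
  m0 <- assign_rule_based_fibres(m, u, 0, 0)
  expect_lt(max(abs(fibre_helix_angles(m0, u))), 1)
})

test_that("degenerate transmural gradients are reported with element ids", {
  m <- coarse_hf_mesh()
  u <- coarse_hf_uvc()
  u_flat <- u
  u_flat$rho_lv[] <- 0.5
  u_flat$rho_rv[] <- 0.5
  expect_error(assign_rule_based_fibres(m, u_flat),
               class = "quadlead_numerical_error")
})

test_that("helix angle is monotone in the transmural coordinate per band", {
  m <- coarse_hf_mesh()
  u <- coarse_hf_uvc()
  m2 <- assign_rule_based_fibres(m, u)
  ha <- fibre_helix_angles(m2, u)
  rho_node <- ifelse(!is.na(u$rho_lv), u$rho_lv, u$rho_rv)
  rho_e <- rowMeans(matrix(rho_node[m2$tets], ncol = 4))
  z_e <- rowMeans(matrix(u$z[m2$tets], ncol = 4))
  lv <- m2$region == "LV_WALL"
  for (band in list(c(0.2, 0.4), c(0.4, 0.6), c(0.6, 0.8))) {
    sel <- lv & z_e > band[1] & z_e <= band[2]
    o <- order(rho_e[sel])
    expect_true(all(diff(ha[sel][o]) <= 1e-6))   # non-increasing within tol
  }
})
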