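iso_params <- function(cv = 0.5) conduction_parameters(cv_fibre = cv, k_xf = 1)

test_that("FEC layer marking is one element thick and band-limited", {
  m <- coarse_hf_mesh()
  u <- coarse_hf_uvc()
  expect_false(any(mark_fec_layer(m, u, 0)))
  full <- mark_fec_layer(m, u, 1)
  endo_adj <- rep(FALSE, nrow(m$tets))
  endo_adj[m$boundary$owner[m$boundary$label %in% c("LV_ENDO", "RV_ENDO")]] <- TRUE
  expect_identical(full, endo_adj)        # whole endocardium, nothing else
  third <- mark_fec_layer(m, u, 0.33)
  z_e <- rowMeans(matrix(u$z[m$tets], ncol = 4))
  expect_true(all(z_e[third] <= 0.33))
  expect_true(all(endo_adj[third]))
  expect_true(any(third) && sum(third) < sum(full))
  expect_error(mark_fec_layer(m, u, 1.2), class = "quadlead_argument_error")
})

test_that("thickness-based scar marking blocks thin LV wall only", {
  m <- coarse_hf_mesh()              # 8 mm wall
  th <- coarse_subjects()[[1]]$thickness
  expect_false(any(mark_scar(th, 5)))
  expect_true(all(mark_scar(th, 5) <= mark_scar(th, 6)))  # monotone nesting
  all_lv <- mark_scar(th, Inf)
  expect_identical(all_lv, !is.na(th))
  expect_false(any(all_lv[m$region == "RV_WALL"]))
  expect_error(mark_scar(th, -1), class = "quadlead_argument_error")
  thin <- thin_wall_subject()        # 5.5 mm wall: 6 mm threshold bites
  expect_gt(sum(mark_scar(thin$thickness, 6)), 0)
  expect_true(all(which(mark_scar(thin$thickness, 5)) %in%
                    which(mark_scar(thin$thickness, 6))))
})

test_that("velocity tensors have the prescribed eigenstructure", {
  box <- make_box_mesh(c(5, 5, 5), edge = 2.5, fibre = c(1, 0, 0))
  fld <- build_velocity_field(box, conduction_parameters())
  V1 <- matrix(fld$V[1, ], 3, 3, byrow = TRUE)
  # along-fibre speed 0.5 mm/ms, cross-fibre 0.6 * 0.5 = 0.3 mm/ms
  expect_equal(as.numeric(V1 %*% c(1, 0, 0)), c(0.25, 0, 0), tolerance = 1e-12)
  expect_equal(as.numeric(V1 %*% c(0, 1, 0)), c(0, 0.09, 0), tolerance = 1e-12)
  # FEC override: isotropic at k_fec * cv = 2.5 mm/ms
  fec <- rep(TRUE, nrow(box$tets))
  fld_fec <- build_velocity_field(box, conduction_parameters(), fec_mask = fec)
  expect_equal(matrix(fld_fec$V[1, ], 3, 3, byrow = TRUE), diag(2.5^2, 3),
               tolerance = 1e-12)
  # k_xf = 1 degenerates to isotropy at cv_fibre
  fld_iso <- build_velocity_field(box, iso_params())
  expect_equal(matrix(fld_iso$V[5, ], 3, 3, byrow = TRUE), diag(0.25, 3),
               tolerance = 1e-12)
  # scar elements are inactive
  scar <- seq_len(nrow(box$tets)) == 1
  fld_scar <- build_velocity_field(box, conduction_parameters(), scar_mask = scar)
  expect_false(fld_scar$active[1])
  expect_true(all(fld_scar$active[-1]))
  # non-unit fibres are a validation error
  bad <- box; bad$fibre[2, ] <- c(2, 0, 0)
  expect_error(build_velocity_field(bad, conduction_parameters()),
               class = "quadlead_validation_error")
})

test_that("isotropic point-source times match distance over speed", {
  box <- make_box_mesh(c(10, 10, 10), edge = 1)
  fld <- build_velocity_field(box, iso_params(0.5))
  src <- which(rowSums(abs(box$nodes)) < 1e-9)
  am <- solve_eikonal(box, fld, src)
  expect_equal(unname(am[src]), 0)         # source exactness
  d <- sqrt(rowSums(box$nodes^2))
  far <- d >= 10
  err <- abs(unclass(am)[far] - d[far] / 0.5) / (d[far] / 0.5)
  expect_lt(max(err), 0.05)
})

test_that("anisotropic travel times match the closed form sqrt(e' V^-1 e)", {
  box <- make_box_mesh(c(10, 10, 10), edge = 1, fibre = c(1, 0, 0))
  fld <- build_velocity_field(box, conduction_parameters(0.5, 0.6))
  src <- which(rowSums(abs(box$nodes)) < 1e-9)
  am <- solve_eikonal(box, fld, src)
  n1 <- which(box$nodes[, 1] == 0 & box$nodes[, 2] == 10 & box$nodes[, 3] == 0)
  n2 <- which(box$nodes[, 1] == 6 & box$nodes[, 2] == 8 & box$nodes[, 3] == 0)
  expect_equal(unname(am[n1]), 10 / 0.3, tolerance = 0.05)
  expect_equal(unname(am[n2]), sqrt(36 / 0.25 + 64 / 0.09), tolerance = 0.05)
})

test_that("multi-source solutions are pointwise minima of single sources", {
  m <- coarse_hf_mesh()
  u <- coarse_hf_uvc()
  fld <- build_velocity_field(m, conduction_parameters(),
                              mark_fec_layer(m, u, 0.33))
  set.seed(42)
  nodes <- sample(nrow(m$nodes), 6)
  for (k in 1:3) {
    a <- nodes[2 * k - 1]; b <- nodes[2 * k]
    tab <- solve_eikonal(m, fld, c(a, b))
    ta <- solve_eikonal(m, fld, a)
    tb <- solve_eikonal(m, fld, b)
    expect_lt(max(abs(unclass(tab) - pmin(unclass(ta), unclass(tb)))), 1e-3)
  }
})

test_that("causality holds along every active mesh edge", {
  m <- coarse_hf_mesh()
  u <- coarse_hf_uvc()
  fld <- build_velocity_field(m, conduction_parameters(),
                              mark_fec_layer(m, u, 0.33))
  rv <- place_rv_electrode(m, u, "APEX")
  am <- unclass(solve_eikonal(m, fld, rv))
  act <- which(fld$active)
  tets <- m$tets[act, ]
  Minv <- quadlead:::inv3_rows(fld$V[act, , drop = FALSE])
  for (pair in list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))) {
    i <- tets[, pair[1]]; j <- tets[, pair[2]]
    e <- m$nodes[j, ] - m$nodes[i, ]
    tt <- sqrt(Minv[, 1] * e[, 1]^2 + Minv[, 5] * e[, 2]^2 + Minv[, 9] * e[, 3]^2 +
                 2 * Minv[, 2] * e[, 1] * e[, 2] + 2 * Minv[, 3] * e[, 1] * e[, 3] +
                 2 * Minv[, 6] * e[, 2] * e[, 3])
    expect_true(all(abs(am[i] - am[j]) <= tt + 1e-6))
  }
})

test_that("activation times are monotone in conduction parameters", {
  m <- coarse_hf_mesh()
  u <- coarse_hf_uvc()
  fec <- mark_fec_layer(m, u, 0.33)
  rv <- place_rv_electrode(m, u, "APEX")
  t_ref <- unclass(solve_eikonal(m, build_velocity_field(
    m, conduction_parameters(k_fec = 5), fec), rv))
  t_kfec <- unclass(solve_eikonal(m, build_velocity_field(
    m, conduction_parameters(k_fec = 10), fec), rv))
  expect_true(all(t_kfec <= t_ref + 1e-6))
  t_cv <- unclass(solve_eikonal(m, build_velocity_field(
    m, conduction_parameters(cv_fibre = 0.8), fec), rv))
  expect_true(all(t_cv <= t_ref + 1e-6))
})

test_that("adding scar never speeds up activation", {
  s <- thin_wall_subject()
  m <- s$mesh; u <- s$coords
  fec <- mark_fec_layer(m, u, 0.33)
  rv <- s$rv_apex
  t0 <- unclass(solve_eikonal(m, build_velocity_field(
    m, conduction_parameters(), fec), rv))
  scar <- mark_scar(s$thickness, 6)
  fld_scar <- build_velocity_field(m, conduction_parameters(scar_threshold = 6),
                                   fec, scar)
  t1 <- unclass(solve_eikonal(m, fld_scar, rv))
  reached <- is.finite(t1)
  expect_true(all(t1[reached] >= t0[reached] - 1e-6))
})

test_that("the Dijkstra oracle upper-bounds the solver on refinements", {
  for (e in c(2.5, 5 / 3, 1.25)) {
    box <- make_box_mesh(c(10, 10, 10), edge = e, fibre = c(1, 0, 0))
    fld <- build_velocity_field(box, conduction_parameters(0.5, 0.6))
    src <- which(rowSums(abs(box$nodes)) < 1e-9)
    am <- solve_eikonal(box, fld, src)
    orc <- dijkstra_oracle(box, fld, src)
    expect_true(all(unclass(orc) >= unclass(am) - 1e-6))
  }
})

test_that("solver error against the closed form shrinks under refinement", {
  errs <- vapply(c(2.5, 5 / 3, 1.25), function(e) {
    box <- make_box_mesh(c(10, 10, 10), edge = e, fibre = c(1, 0, 0))
    fld <- build_velocity_field(box, conduction_parameters(0.5, 0.6))
    src <- which(rowSums(abs(box$nodes)) < 1e-9)
    am <- solve_eikonal(box, fld, src)
    exact <- sqrt(box$nodes[, 1]^2 / 0.25 +
                    (box$nodes[, 2]^2 + box$nodes[, 3]^2) / 0.09)
    max(abs(unclass(am) - exact))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("a straight fibre-aligned chain is solved exactly by the oracle", {
  box <- make_box_mesh(c(10, 1, 1), edge = 1, fibre = c(1, 0, 0))
  fld <- build_velocity_field(box, conduction_parameters(0.5, 0.6))
  src <- which(rowSums(abs(box$nodes)) < 1e-9)
  orc <- dijkstra_oracle(box, fld, src)
  on_axis <- which(box$nodes[, 2] == 0 & box$nodes[, 3] == 0)
  expect_equal(unname(unclass(orc)[on_axis]), box$nodes[on_axis, 1] / 0.5,
               tolerance = 1e-9)
})

test_that("source validation rejects bad inputs", {
  box <- make_box_mesh(c(5, 5, 5), edge = 2.5)
  fld <- build_velocity_field(box, iso_params())
  expect_error(solve_eikonal(box, fld, integer(0)),
               class = "quadlead_argument_error")
  expect_error(solve_eikonal(box, fld, data.frame(node = 1, onset = -2)),
               class = "quadlead_argument_error")
  scar <- rep(FALSE, nrow(box$tets))
  scar[quadlead:::boundary_faces(box$tets, nrow(box$nodes))$owner[1]] <- TRUE
  # a node incident only to inactive elements is an invalid source
  fld2 <- build_velocity_field(box, iso_params(), scar_mask = rep(TRUE, nrow(box$tets)))
  expect_error(solve_eikonal(box, fld2, 1), class = "quadlead_source_error")
})
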