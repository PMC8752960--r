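test_that("AT090 toy cases follow the volume-quantile definition", {
  # ten equal-volume elements activating at 1..10 ms: 90% reached at 9 ms
  expect_equal(quadlead:::at090_from_elements(1:10, rep(1, 10)), 9)
  expect_equal(quadlead:::at090_from_elements(rep(4.2, 7), rep(2, 7)), 4.2)
  # brute-force volume-accumulation scan oracle on random cases
  set.seed(1)
  for (rep in 1:20) {
    times <- runif(25, 0, 100)
    vols <- runif(25, 0.5, 2)
    # exhaustive scan oracle: walk sorted times accumulating volume
    o <- order(times)
    scan <- times[o][which(cumsum(vols[o]) >= 0.9 * sum(vols))[1]]
    expect_equal(quadlead:::at090_from_elements(times, vols), scan)
  }
})

test_that("TAT is the maximum over active-tissue nodes", {
  cam <- tiny_campaign()
  expect_true(all(cam$baselines$at090_ms <= cam$baselines$tat_ms))
  expect_true(all(cam$records$at090_ms <= cam$records$tat_ms))
})

test_that("reduction arithmetic and sign conventions", {
  b <- tibble::tibble(tat_ms = 100, at090_ms = 100)
  p <- tibble::tibble(tat_ms = 85, at090_ms = 85)
  r <- compute_reduction(b, p)
  expect_equal(r$at090_reduction_ms, 15)
  expect_equal(r$at090_reduction_pct, 15)
  same <- compute_reduction(b, b)
  expect_equal(same$tat_reduction_ms, 0)
  expect_equal(same$tat_reduction_pct, 0)
  worse <- compute_reduction(b, tibble::tibble(tat_ms = 120, at090_ms = 120))
  expect_equal(worse$at090_reduction_ms, -20)
  expect_equal(worse$at090_reduction_pct, -20)
  expect_error(compute_reduction(tibble::tibble(tat_ms = 0, at090_ms = 0), p),
               class = "quadlead_argument_error")
})

test_that("paced activation never exceeds the baseline anywhere", {
  s <- coarse_subjects()[[1]]
  fld <- quadlead:::subject_field(s, conduction_parameters())
  base <- run_baseline(s$mesh, fld, s$rv_apex)
  lead <- s$leads[["LA"]]
  paced <- solve_eikonal(s$mesh, fld,
                         c(lead$electrodes$node[c(1, 8)], s$rv_apex))
  expect_true(all(unclass(paced) <= unclass(base$map) + 1e-9))
  expect_gte(base$metrics$tat_ms, compute_tat(paced, s$mesh))
  # TAT invariant to re-adding an already-covered source
  dup <- solve_eikonal(s$mesh, fld, c(s$rv_apex, s$rv_apex))
  expect_equal(compute_tat(dup, s$mesh), base$metrics$tat_ms, tolerance = 1e-9)
})

test_that("the campaign grid is complete, non-negative and deterministic", {
  cam <- tiny_campaign()
  expect_equal(nrow(cam$records), 2 * 2 * 36)    # subjects x veins x configs
  expect_equal(nrow(cam$baselines), 2)
  expect_true(all(table(cam$records$subject, cam$records$vein) == 36))
  # min-superposition: paced is never worse than baseline
  expect_true(all(cam$records$at090_reduction_ms >= -1e-9))
  expect_true(all(cam$records$tat_reduction_ms >= -1e-9))
  cam2 <- run_campaign(coarse_subjects(), veins = c("LA", "AN"))
  expect_equal(cam$records, cam2$records)
  expect_equal(cam$baselines, cam2$baselines)
})

test_that("adding a second electrode never hurts the best response", {
  cam <- tiny_campaign()
  by_sv <- dplyr::group_by(cam$records, subject, vein)
  best <- dplyr::summarise(
    by_sv,
    best_single = max(at090_reduction_pct[n_active == 1]),
    best_pair = max(at090_reduction_pct[n_active == 2]), .groups = "drop")
  expect_true(all(best$best_pair >= best$best_single - 1e-9))
})

test_that("design-level evaluation equals a brute-force scan", {
  cam <- tiny_campaign()
  dtab <- evaluate_designs(cam)
  expect_equal(nrow(dtab), 2 * 2 * 70)
  des <- enumerate_lead_designs()
  set.seed(3)
  for (i in sample(nrow(des), 8)) {
    cfgs <- design_configurations(des$electrodes[[i]])
    for (s in unique(cam$records$subject)) {
      rs <- cam$records[cam$records$subject == s & cam$records$vein == "LA" &
                          cam$records$config %in% cfgs, ]
      got <- dtab[dtab$subject == s & dtab$vein == "LA" &
                    dtab$design == des$design[i], ]
      expect_equal(got$at090_reduction_pct, max(rs$at090_reduction_pct))
    }
  }
})

test_that("unreached active tissue is reported as an error", {
  box <- make_box_mesh(c(6, 2, 2), edge = 2)
  # cut the bar in half with inactive elements
  cent <- quadlead:::element_centroids(box)
  scar <- cent[, 1] > 2 & cent[, 1] < 4
  fld <- build_velocity_field(box, conduction_parameters(k_xf = 1),
                              scar_mask = scar)
  src <- which(rowSums(abs(box$nodes)) < 1e-9)
  map <- solve_eikonal(box, fld, src)
  expect_error(compute_tat(map, box), class = "quadlead_unreached_error")
  expect_error(compute_at090(map, box), class = "quadlead_unreached_error")
})
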