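test_that("all five vein tracks are constructible with constant rotation", {
  m <- coarse_hf_mesh()
  u <- coarse_hf_uvc()
  va <- vein_angles()
  expect_identical(names(va), c("IN", "IL", "LA", "AL", "AN"))
  expect_equal(unname(va), c(150, 120, 90, 60, 30))  # AHA 4/5, 5, 5/6, 6, 6/1
  for (v in vein_names()) {
    ln <- locate_vein_line(m, u, v)
    expect_gte(max(ln$arc_mm), 52.5)
    expect_equal(ln$zuvc[1], 0.8, tolerance = 1e-6)
    phl <- atan2(ln$y - u$centre[2], ln$x - u$centre[1]) * 180 / pi
    expect_lt(max(abs(phl - va[[v]])), 5)
    # vertices lie on the epicardial surface triangles
    owner_lv <- m$region[m$boundary$owner] == "LV_WALL"
    tris <- m$boundary$tris[m$boundary$label == "EPI" & owner_lv, , drop = FALSE]
    d <- quadlead:::surface_distance_cpp(cbind(ln$x, ln$y, ln$z), m$nodes,
                                         tris - 1L)
    expect_lt(max(d), 1e-6)
  }
  expect_error(locate_vein_line(m, u, "XX"), class = "quadlead_argument_error")
})

test_that("electrodes are spaced 7.5 mm over 52.5 mm, basal first", {
  m <- coarse_hf_mesh()
  u <- coarse_hf_uvc()
  ln <- locate_vein_line(m, u, "LA")
  lead <- place_electrodes(m, ln)
  el <- lead$electrodes
  expect_identical(el$label, letters[1:8])
  expect_equal(diff(range(el$arc_target_mm)), 52.5)
  expect_equal(unique(diff(el$arc_target_mm)), 7.5)
  # electrode "a" is the most basal of the eight
  expect_equal(which.max(u$z[el$node]), 1L)
  expect_equal(u$z[el$node[1]], 0.8, tolerance = 0.06)
  # snapped arc positions within the local mesh edge length of the targets
  expect_lt(max(abs(el$arc_mm - el$arc_target_mm)), 9)
  # insufficient arc length is a geometry error
  short <- ln[ln$arc_mm <= 40, ]
  class(short) <- class(ln); attr(short, "vein") <- "LA"
  expect_error(place_electrodes(m, short), class = "quadlead_geometry_error")
})

test_that("distinct veins never share electrodes", {
  s <- coarse_subjects()[[1]]
  nodes <- lapply(s$leads, function(l) l$electrodes$node)
  for (i in 1:(length(nodes) - 1)) {
    for (j in (i + 1):length(nodes)) {
      expect_length(intersect(nodes[[i]], nodes[[j]]), 0)
    }
  }
})

test_that("RV electrode sites satisfy their anatomical constraints", {
  m <- coarse_hf_mesh()
  u <- coarse_hf_uvc()
  apex <- place_rv_electrode(m, u, "APEX")
  rv_endo <- quadlead:::nodes_on_label(m, "RV_ENDO")
  expect_true(apex %in% rv_endo)
  expect_lt(u$z[apex], 0.1)
  sept <- place_rv_electrode(m, u, "SEPTAL_MID")
  expect_true(sept %in% rv_endo)
  expect_gte(u$z[sept], 0.4)
  expect_lte(u$z[sept], 0.6)
  expect_error(place_rv_electrode(m, u, "ELSEWHERE"))
  # both sites must be usable as eikonal sources on active tissue
  fld <- build_velocity_field(m, conduction_parameters())
  expect_s3_class(solve_eikonal(m, fld, apex), "activation_map")
  expect_s3_class(solve_eikonal(m, fld, sept), "activation_map")
})

test_that("configuration enumeration yields the 36 stimulus sets", {
  s <- coarse_subjects()[[1]]
  cfg <- enumerate_configurations(s$leads[["LA"]], s$rv_apex)
  expect_equal(nrow(cfg), choose(8, 1) + choose(8, 2))
  expect_identical(cfg$config, sort(cfg$config))       # lexicographic
  expect_true(all(cfg$rv_node == s$rv_apex))           # RV always included
  expect_identical(config_name(c("d", "a")), "ad")     # sorted naming
  # brute force: all subsets of size 1..2 of the 8 labels
  brute <- sort(c(letters[1:8],
                  apply(utils::combn(letters[1:8], 2), 2, paste, collapse = "")))
  expect_identical(cfg$config, brute)
})

test_that("design enumeration yields 70 distinct designs with 10 configs each", {
  des <- enumerate_lead_designs()
  expect_equal(nrow(des), 70)
  expect_false(anyDuplicated(des$design) > 0)
  expect_identical(des$design, sort(des$design))
  expect_setequal(design_configurations(c("a", "c", "d", "h")),
                  c("a", "c", "d", "h", "ac", "ad", "ah", "cd", "ch", "dh"))
  # coverage counts: each singleton in choose(7,3)=35 designs, each pair in
  # choose(6,2)=15 (brute force over the full design list)
  cover_count <- function(cfg) {
    sum(vapply(des$electrodes, function(d)
      all(strsplit(cfg, "")[[1]] %in% d), TRUE))
  }
  expect_true(all(vapply(letters[1:8], cover_count, 0) == 35))
  pairs <- apply(utils::combn(letters[1:8], 2), 2, paste, collapse = "")
  expect_true(all(vapply(pairs, cover_count, 0) == 15))
})

test_that("full-campaign bookkeeping multiplies out to 15400", {
  expect_equal(count_design_evaluations(70, 5, 44), 15400)
})

test_that("lead construction is invariant under mesh node reordering", {
  m <- coarse_hf_mesh()
  u <- coarse_hf_uvc()
  lead <- place_electrodes(m, locate_vein_line(m, u, "AL"))
  set.seed(7)
  perm <- sample(nrow(m$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m2 <- m
  m2$nodes <- m$nodes[perm, ]
  m2$tets <- matrix(inv[m$tets], ncol = 4)
  m2$boundary$tris <- matrix(inv[m$boundary$tris], ncol = 3)
  u2 <- u
  for (f in c("z", "rho", "phi", "nu", "rho_lv", "rho_rv")) u2[[f]] <- u[[f]][perm]
  u2$apex_nodes <- inv[u$apex_nodes]; u2$base_nodes <- inv[u$base_nodes]
  lead2 <- place_electrodes(m2, locate_vein_line(m2, u2, "AL"))
  expect_equal(m2$nodes[lead2$electrodes$node, ],
               m$nodes[lead$electrodes$node, ], tolerance = 1e-12)
})
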