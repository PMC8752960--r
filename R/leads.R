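# Virtual quadripolar lead placement: idealized epicardial vein tracks on
# the LV free wall anchored to AHA rotational sectors, 8 electrode
# positions per track, the RV electrode, and the enumeration of pacing
# configurations and 4-electrode lead designs.

#' The five idealized vein tracks
#'
#' Vein rotational angles are anchored to the basal AHA segments: `IN` at
#' the border of segments 4/5, `IL` at the centre of 5, `LA` at the border
#' 5/6, `AL` at the centre of 6 and `AN` at the border 6/1. Border angles
#' are the mean of the adjacent segment-centre angles.
#'
#' @return Named numeric vector of rotational angles (degrees, in the
#'   package phi convention: anterior = 0, increasing towards lateral).
#' @export
vein_angles <- function() {
  ctr <- aha_basal_angles
  c(IN = mean(c(ctr[["4"]], ctr[["5"]])),
    IL = ctr[["5"]],
    LA = mean(c(ctr[["5"]], ctr[["6"]])),
    AL = ctr[["6"]],
    AN = mean(c(ctr[["6"]], ctr[["1"]])))
}

#' Names of the five vein tracks, basal AHA order
#' @return Character vector `c("IN","IL","LA","AL","AN")`.
#' @export
vein_names <- function() names(vein_angles())

#' Trace an epicardial vein polyline
#'
#' Intersects the LV epicardial surface with the meridian half-plane at the
#' vein's rotational angle and returns the resulting polyline from the
#' basal starting height down towards the apex. Every vertex lies on an
#' epicardial boundary triangle and has (by construction) the vein's exact
#' rotational coordinate.
#'
#' @param mesh A `ventricular_mesh`.
#' @param coords Matching [compute_uvc()] coordinates.
#' @param vein One of `"IN"`, `"IL"`, `"LA"`, `"AL"`, `"AN"`.
#' @param basal_z Apicobasal coordinate of the basal end of the track.
#' @param min_length Minimal required arc length, mm; shorter tracks raise a
#'   geometry error.
#' @return A tibble (class `vein_polyline`) with columns `x`, `y`, `z`
#'   (mm), `zuvc` (apicobasal coordinate) and `arc_mm` measured from the
#'   basal end.
#' @export
locate_vein_line <- function(mesh, coords, vein, basal_z = 0.8,
                             min_length = 52.5) {
  stopifnot(inherits(mesh, "ventricular_mesh"),
            inherits(coords, "ventricular_coordinates"))
  va <- vein_angles()
  if (!vein %in% names(va)) {
    abort(sprintf("unknown vein '%s' (expected one of %s)", vein,
                  paste(names(va), collapse = ", ")),
          class = "quadlead_argument_error")
  }
  phi_v <- (va[[vein]] * pi / 180 + coords$anterior_angle)
  ctr <- coords$centre
  u <- c(cos(phi_v), sin(phi_v))
  nrm <- c(-sin(phi_v), cos(phi_v))
  owner_lv <- mesh$region[mesh$boundary$owner] == "LV_WALL"
  tris <- mesh$boundary$tris[mesh$boundary$label == "EPI" & owner_lv, , drop = FALSE]
  nd <- mesh$nodes
  s <- nrm[1] * (nd[, 1] - ctr[1]) + nrm[2] * (nd[, 2] - ctr[2])
  r <- u[1] * (nd[, 1] - ctr[1]) + u[2] * (nd[, 2] - ctr[2])
  # unique edges of the epicardial triangles
  ed <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(1, 3)])
  lo <- pmin(ed[, 1], ed[, 2]); hi <- pmax(ed[, 1], ed[, 2])
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  eps <- 1e-7 * max(abs(nd))
  cross <- (s[lo] * s[hi] < 0) & abs(s[lo]) > eps & abs(s[hi]) > eps &
    (r[lo] > 0 | r[hi] > 0)
  # the plane may pass exactly through a node column; keep those nodes too
  # (but not the near-axis apex nodes, whose rotation is undefined)
  epi_nodes <- sort(unique(as.vector(tris)))
  on_plane <- epi_nodes[abs(s[epi_nodes]) <= eps & r[epi_nodes] > 1]
  lo <- lo[cross]; hi <- hi[cross]
  if (!length(lo) && !length(on_plane)) {
    abort("vein plane does not intersect the epicardium", class = "quadlead_geometry_error")
  }
  tt <- s[lo] / (s[lo] - s[hi])
  pts <- rbind(nd[lo, , drop = FALSE] +
                 tt * (nd[hi, , drop = FALSE] - nd[lo, , drop = FALSE]),
               nd[on_plane, , drop = FALSE])
  zu <- c(coords$z[lo] + tt * (coords$z[hi] - coords$z[lo]), coords$z[on_plane])
  on_half <- (u[1] * (pts[, 1] - ctr[1]) + u[2] * (pts[, 2] - ctr[2])) > 0
  pts <- pts[on_half, , drop = FALSE]; zu <- zu[on_half]
  o <- order(pts[, 3], decreasing = TRUE)   # base (high z) to apex (low z)
  pts <- pts[o, , drop = FALSE]; zu <- zu[o]
  # drop coincident points (crossings that hit a shared mesh node)
  if (nrow(pts) > 1) {
    seg0 <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
    keep_pt <- c(TRUE, seg0 > 1e-9)
    pts <- pts[keep_pt, , drop = FALSE]; zu <- zu[keep_pt]
  }
  # trim to start exactly at the requested apicobasal height
  below <- which(zu <= basal_z)
  if (!length(below) || below[1] == 1L) {
    start_pt <- pts[1, ]; start_zu <- zu[1]
    idx <- seq_along(zu)
  } else {
    i <- below[1]
    w <- (basal_z - zu[i - 1]) / (zu[i] - zu[i - 1])
    start_pt <- pts[i - 1, ] + w * (pts[i, ] - pts[i - 1, ])
    start_zu <- basal_z
    idx <- i:length(zu)
  }
  P <- rbind(start_pt, pts[idx, , drop = FALSE])
  Z <- c(start_zu, zu[idx])
  seg <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  if (max(arc) < min_length) {
    abort(sprintf("vein track %s is %.1f mm long, shorter than the required %.1f mm",
                  vein, max(arc), min_length),
          class = "quadlead_geometry_error")
  }
  out <- tibble(x = P[, 1], y = P[, 2], z = P[, 3], zuvc = Z, arc_mm = arc)
  class(out) <- c("vein_polyline", class(out))
  attr(out, "vein") <- vein
  attr(out, "phi_deg") <- va[[vein]]
  out
}

#' Place electrodes along a vein polyline
#'
#' Electrode `k` sits at arc distance `(k-1) * spacing` from the basal end
#' of the track and is snapped to the nearest epicardial mesh node. Labels
#' run `a` (most basal) to `h` (most apical).
#'
#' @param mesh A `ventricular_mesh`.
#' @param line A [locate_vein_line()] polyline.
#' @param n Number of electrodes.
#' @param spacing Inter-electrode arc spacing, mm.
#' @return A `crt_lead`: list with the vein name and an `electrodes` tibble
#'   (label, node, designed arc position `arc_target_mm`, snapped arc
#'   position `arc_mm`, coordinates).
#' @export
place_electrodes <- function(mesh, line, n = 8, spacing = 7.5) {
  stopifnot(inherits(line, "vein_polyline"))
  span <- (n - 1) * spacing
  if (max(line$arc_mm) < span) {
    abort(sprintf("vein track arc (%.1f mm) shorter than the electrode span (%.1f mm)",
                  max(line$arc_mm), span),
          class = "quadlead_geometry_error")
  }
  targets <- (seq_len(n) - 1) * spacing
  px <- stats::approx(line$arc_mm, line$x, xout = targets)$y
  py <- stats::approx(line$arc_mm, line$y, xout = targets)$y
  pz <- stats::approx(line$arc_mm, line$z, xout = targets)$y
  owner_lv <- mesh$region[mesh$boundary$owner] == "LV_WALL"
  epi_nodes <- sort(unique(as.vector(
    mesh$boundary$tris[mesh$boundary$label == "EPI" & owner_lv, , drop = FALSE])))
  nd <- mesh$nodes[epi_nodes, , drop = FALSE]
  nodes <- integer(n); arc_snap <- numeric(n)
  for (k in seq_len(n)) {
    d2 <- (nd[, 1] - px[k])^2 + (nd[, 2] - py[k])^2 + (nd[, 3] - pz[k])^2
    nodes[k] <- epi_nodes[which.min(d2)]   # ties: lowest node index
    pv <- mesh$nodes[nodes[k], ]
    dv <- (line$x - pv[1])^2 + (line$y - pv[2])^2 + (line$z - pv[3])^2
    arc_snap[k] <- line$arc_mm[which.min(dv)]
  }
  electrodes <- tibble(
    label = letters[seq_len(n)],
    node = nodes,
    arc_target_mm = targets,
    arc_mm = arc_snap,
    x = mesh$nodes[nodes, 1], y = mesh$nodes[nodes, 2], z = mesh$nodes[nodes, 3])
  structure(list(vein = attr(line, "vein"), electrodes = electrodes, line = line),
            class = "crt_lead")
}

#' @export
print.crt_lead <- function(x, ...) {
  cat(sprintf("<crt_lead> vein %s, %d electrodes over %.1f mm\n",
              x$vein, nrow(x$electrodes), diff(range(x$electrodes$arc_target_mm))))
  invisible(x)
}

#' Place the RV pacing electrode
#'
#' `APEX` returns the RV endocardial node with the smallest apicobasal
#' coordinate (RV apical pacing, the baseline that stands in for left
#' bundle branch block activation); `SEPTAL_MID` the septal RV endocardial
#' node closest to mid apicobasal height.
#'
#' @param mesh A `ventricular_mesh`.
#' @param coords Matching [compute_uvc()] coordinates.
#' @param site `"APEX"` or `"SEPTAL_MID"`.
#' @return A node index.
#' @export
place_rv_electrode <- function(mesh, coords, site = c("APEX", "SEPTAL_MID")) {
  site <- match.arg(site)
  rv_endo_all <- nodes_on_label(mesh, "RV_ENDO")
  if (!length(rv_endo_all)) abort("mesh has no RV endocardium", class = "quadlead_label_error")
  if (site == "APEX") {
    return(rv_endo_all[which.min(coords$z[rv_endo_all])])
  }
  septal <- nodes_on_label(mesh, "RV_ENDO", "LV_WALL")
  if (!length(septal)) septal <- rv_endo_all
  # septum is centred opposite the anterior-lateral free wall
  phi_sept <- -pi / 2
  dphi <- abs(((coords$phi[septal] - phi_sept + pi) %% (2 * pi)) - pi)
  in_sector <- dphi <= pi / 4
  if (any(in_sector)) septal <- septal[in_sector]
  dz <- abs(coords$z[septal] - 0.5)
  dphi <- dphi[if (any(in_sector)) in_sector else TRUE]
  septal[order(dz, dphi)][1]
}

config_name <- function(letters_vec) paste(sort(letters_vec), collapse = "")

#' Enumerate pacing configurations of a lead
#'
#' All single-electrode and electrode-pair stimulus sets of the 8 lead
#' positions: `choose(8,1) + choose(8,2) = 36` unique configurations, each
#' stimulated simultaneously with the RV electrode. Names are sorted letter
#' strings (the pair {d, a} is `"ad"`), listed in lexicographic order.
#'
#' @param lead A [place_electrodes()] lead.
#' @param rv_node RV electrode node index.
#' @return Tibble with columns `config`, `n_active`, `lv_nodes`
#'   (list-column), `rv_node`.
#' @export
enumerate_configurations <- function(lead, rv_node) {
  stopifnot(inherits(lead, "crt_lead"))
  el <- lead$electrodes
  singles <- lapply(el$label, identity)
  pairs <- combn(el$label, 2, simplify = FALSE)
  sets <- c(singles, pairs)
  nm <- vapply(sets, config_name, "")
  o <- order(nm)
  sets <- sets[o]; nm <- nm[o]
  tibble(
    config = nm,
    n_active = lengths(sets),
    lv_nodes = lapply(sets, function(s) el$node[match(s, el$label)]),
    rv_node = rv_node)
}

#' Enumerate quadripolar lead designs
#'
#' All 4-electrode subsets of the 8 candidate positions: `choose(8,4) = 70`
#' designs in lexicographic order. Each design admits
#' `choose(4,1) + choose(4,2) = 10` of the 36 pacing configurations.
#'
#' @return Tibble with columns `design` (sorted letter string) and
#'   `electrodes` (list-column of 4 letters).
#' @export
enumerate_lead_designs <- function() {
  sets <- combn(letters[1:8], 4, simplify = FALSE)
  nm <- vapply(sets, config_name, "")
  o <- order(nm)
  tibble(design = nm[o], electrodes = sets[o])
}

#' Admissible configurations of a design
#'
#' @param design_letters Character vector of 4 electrode letters.
#' @return Character vector of the 10 admissible configuration names.
#' @export
design_configurations <- function(design_letters) {
  stopifnot(length(design_letters) == 4)
  c(sort(design_letters),
    sort(vapply(combn(design_letters, 2, simplify = FALSE), config_name, "")))
}

# design -> configuration lookup (700 rows)
config_design_map <- function() {
  designs <- enumerate_lead_designs()
  tibble(design = rep(designs$design, each = 10L),
         config = unlist(lapply(designs$electrodes, design_configurations)))
}

#' Bookkeeping: design evaluations in a full campaign
#'
#' @param n_designs Number of lead designs (70).
#' @param n_veins Number of vein locations (5).
#' @param n_subjects Number of subjects across the cohorts.
#' @return `n_designs * n_veins * n_subjects`.
#' @export
count_design_evaluations <- function(n_designs = 70, n_veins = 5, n_subjects = 44) {
  n_designs * n_veins * n_subjects
}
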