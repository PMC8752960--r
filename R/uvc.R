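# Universal-ventricular-coordinate style fields on a biventricular mesh:
# apicobasal and transmural Laplace solves with linear tetrahedral finite
# elements, a rotational angle about the LV long axis, and the 17-segment
# AHA map derived from them.

# per-element P1 basis gradients and centroids
tet_basis <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  d1 <- nodes[tets[, 2], , drop = FALSE] - p1
  d2 <- nodes[tets[, 3], , drop = FALSE] - p1
  d3 <- nodes[tets[, 4], , drop = FALSE] - p1
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c23 <- cr(d2, d3); c31 <- cr(d3, d1); c12 <- cr(d1, d2)
  det <- rowSums(d1 * c23)
  g2 <- c23 / det; g3 <- c31 / det; g4 <- c12 / det
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), volume = det / 6)
}

element_centroids <- function(mesh, elements = NULL) {
  tets <- if (is.null(elements)) mesh$tets else mesh$tets[elements, , drop = FALSE]
  (mesh$nodes[tets[, 1], , drop = FALSE] + mesh$nodes[tets[, 2], , drop = FALSE] +
     mesh$nodes[tets[, 3], , drop = FALSE] + mesh$nodes[tets[, 4], , drop = FALSE]) / 4
}

# gradient of a nodal field on each listed element
element_gradient <- function(mesh, u, elements = NULL) {
  tets <- if (is.null(elements)) mesh$tets else mesh$tets[elements, , drop = FALSE]
  tb <- tet_basis(mesh$nodes, tets)
  gx <- tb$g[[1]] * u[tets[, 1]] + tb$g[[2]] * u[tets[, 2]] +
    tb$g[[3]] * u[tets[, 3]] + tb$g[[4]] * u[tets[, 4]]
  gx
}

# Laplace solve with Dirichlet data; returns NA outside the element subset
laplace_field <- function(mesh, dirichlet_nodes, dirichlet_values,
                          elements = NULL) {
  tets <- if (is.null(elements)) mesh$tets else mesh$tets[elements, , drop = FALSE]
  n <- nrow(mesh$nodes)
  tb <- tet_basis(mesh$nodes, tets)
  ii <- jj <- xx <- vector("list", 16L)
  idx <- 1L
  for (a in 1:4) {
    for (b in 1:4) {
      ii[[idx]] <- tets[, a]
      jj[[idx]] <- tets[, b]
      xx[[idx]] <- tb$volume * rowSums(tb$g[[a]] * tb$g[[b]])
      idx <- idx + 1L
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  used <- sort(unique(as.vector(tets)))
  dir_keep <- dirichlet_nodes %in% used
  dn <- dirichlet_nodes[dir_keep]; dv <- dirichlet_values[dir_keep]
  if (anyDuplicated(dn)) {
    first <- !duplicated(dn)
    dn <- dn[first]; dv <- dv[first]
  }
  free <- setdiff(used, dn)
  u <- rep(NA_real_, n)
  u[dn] <- dv
  if (length(free)) {
    Kff <- K[free, free, drop = FALSE]
    rhs <- -K[free, dn, drop = FALSE] %*% dv
    sol <- Matrix::solve(Kff, rhs)
    u[free] <- as.numeric(sol)
  }
  u
}

# interior faces shared by an LV element and an RV element
region_interface_faces <- function(mesh) {
  tets <- mesh$tets
  n_nodes <- nrow(mesh$nodes)
  f <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
             tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  owner <- rep.int(seq_len(nrow(tets)), 4L)
  a <- pmin(f[, 1], f[, 2], f[, 3])
  cmax <- pmax(f[, 1], f[, 2], f[, 3])
  b <- f[, 1] + f[, 2] + f[, 3] - a - cmax
  np <- as.numeric(n_nodes) + 1
  key <- (a * np + b) * np + cmax
  o <- order(key)
  ks <- key[o]
  same_next <- c(ks[-length(ks)] == ks[-1], FALSE)
  i1 <- o[which(same_next)]
  i2 <- o[which(same_next) + 1L]
  mixed <- mesh$region[owner[i1]] != mesh$region[owner[i2]]
  cbind(a, b, cmax)[i1[mixed], , drop = FALSE]
}

# geodesic (unit-speed eikonal) distance from a node set, mm
unit_speed_distance <- function(mesh, from_nodes) {
  m <- nrow(mesh$tets)
  V <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = m), nrow = m)
  eikonal_solve_cpp(mesh$nodes, mesh$tets - 1L, V, rep(TRUE, m),
                    as.integer(from_nodes) - 1L,
                    rep(0, length(from_nodes)), 1e-9)
}

nodes_on_label <- function(mesh, labels, owner_region = NULL) {
  sel <- mesh$boundary$label %in% labels
  if (!is.null(owner_region)) {
    sel <- sel & mesh$region[mesh$boundary$owner] %in% owner_region
  }
  sort(unique(as.vector(mesh$boundary$tris[sel, , drop = FALSE])))
}

#' Compute universal-ventricular-coordinate style fields
#'
#' Apicobasal coordinate `z` solves a Laplace problem with `z = 1` on the
#' basal plane and `z = 0` at the apex node(s); the transmural coordinate
#' `rho` solves Laplace problems per ventricle with 0 on the endocardium and
#' 1 on the epicardium (for the LV, the septal surface facing the RV cavity
#' counts as its outer shell); `phi` is the rotational angle about the LV
#' long axis, 0 on the anterior free wall and increasing towards the lateral
#' wall; `nu` labels each node LV or RV (LV wins on shared nodes). All
#' Laplace solves use linear tetrahedral finite elements and a direct sparse
#' factorization.
#'
#' @param mesh A `ventricular_mesh` with labelled boundary surfaces.
#' @param anterior_angle Rotational origin: the raw `atan2(y, x)` angle (rad)
#'   of the anterior LV free wall in the mesh frame. 0 for meshes from
#'   [generate_biventricular_mesh()].
#' @param apex_ball Horizontal capture radius of the apex node set, as a
#'   fraction of the bounding-box diagonal; the set spans the transmural
#'   apex column above the lowest node.
#' @return An object of class `ventricular_coordinates` with per-node fields
#'   `z`, `rho`, `phi` (radians in (-pi, pi]), `nu` (`"LV"`/`"RV"`), and the
#'   per-ventricle transmural solutions `rho_lv`, `rho_rv`.
#' @export
compute_uvc <- function(mesh, anterior_angle = 0, apex_ball = 0.02) {
  stopifnot(inherits(mesh, "ventricular_mesh"))
  labs <- unique(mesh$boundary$label)
  need <- c("LV_ENDO", "RV_ENDO", "EPI", "BASE")
  if (!all(need %in% labs)) {
    abort(sprintf("missing surface label(s): %s",
                  paste(setdiff(need, labs), collapse = ", ")),
          class = "quadlead_label_error")
  }
  n <- nrow(mesh$nodes)
  base_nodes <- nodes_on_label(mesh, "BASE")
  bbox <- apply(mesh$nodes, 2, range)
  diag_len <- sqrt(sum((bbox[2, ] - bbox[1, ])^2))
  lowest <- which.min(mesh$nodes[, 3])
  # apex set = the transmural apex column: nodes on the long axis through
  # the lowest point, from the epicardial to the endocardial apex
  h_dist <- sqrt((mesh$nodes[, 1] - mesh$nodes[lowest, 1])^2 +
                   (mesh$nodes[, 2] - mesh$nodes[lowest, 2])^2)
  z_extent <- diff(range(mesh$nodes[, 3]))
  apex_nodes <- which(h_dist <= apex_ball * diag_len &
                        mesh$nodes[, 3] <= mesh$nodes[lowest, 3] + 0.12 * z_extent)

  # apicobasal coordinate from normalized geodesic distance fields: a raw
  # harmonic interpolant between a near-point apex and the broad basal plane
  # collapses almost all variation into the apical neighbourhood, whereas
  # the normalized distance ratio tracks the apicobasal arc fraction that
  # the AHA bands, the FEC extent and electrode placement assume.
  d_apex <- unit_speed_distance(mesh, apex_nodes)
  d_base <- unit_speed_distance(mesh, base_nodes)
  z <- d_apex / (d_apex + d_base)
  z <- pmin(1, pmax(0, z))

  lv_el <- which(mesh$region == "LV_WALL")
  rv_el <- which(mesh$region == "RV_WALL")
  lv_nodes <- sort(unique(as.vector(mesh$tets[lv_el, ])))
  endo_lv <- nodes_on_label(mesh, "LV_ENDO")
  outer_lv <- intersect(nodes_on_label(mesh, c("EPI", "RV_ENDO"), "LV_WALL"), lv_nodes)
  rho_lv <- laplace_field(mesh,
                          c(endo_lv, setdiff(outer_lv, endo_lv)),
                          c(rep(0, length(endo_lv)),
                            rep(1, length(setdiff(outer_lv, endo_lv)))),
                          elements = lv_el)
  # the LV-RV interface is the inner shell of the attached RV wall
  iface <- unique(as.vector(region_interface_faces(mesh)))
  endo_rv <- union(nodes_on_label(mesh, "RV_ENDO", "RV_WALL"), iface)
  outer_rv <- setdiff(nodes_on_label(mesh, "EPI", "RV_WALL"), endo_rv)
  rho_rv <- laplace_field(mesh,
                          c(endo_rv, outer_rv),
                          c(rep(0, length(endo_rv)), rep(1, length(outer_rv))),
                          elements = rv_el)
  rho_lv <- pmin(1, pmax(0, rho_lv))
  rho_rv <- pmin(1, pmax(0, rho_rv))

  nu <- rep("RV", n)
  nu[lv_nodes] <- "LV"
  rho <- ifelse(nu == "LV" & !is.na(rho_lv), rho_lv, rho_rv)

  ctr <- colMeans(mesh$nodes[endo_lv, , drop = FALSE])
  phi <- atan2(mesh$nodes[, 2] - ctr[2], mesh$nodes[, 1] - ctr[1]) - anterior_angle
  phi <- ((phi + pi) %% (2 * pi)) - pi
  phi[phi <= -pi] <- pi

  structure(list(z = z, rho = rho, phi = phi, nu = nu,
                 rho_lv = rho_lv, rho_rv = rho_rv,
                 apex_nodes = apex_nodes, base_nodes = base_nodes,
                 centre = ctr, anterior_angle = anterior_angle),
            class = "ventricular_coordinates")
}

#' @export
print.ventricular_coordinates <- function(x, ...) {
  cat("<ventricular_coordinates>\n")
  cat(sprintf("  %d nodes (%d LV / %d RV); z in [%.3f, %.3f]\n",
              length(x$z), sum(x$nu == "LV"), sum(x$nu == "RV"),
              min(x$z), max(x$z)))
  invisible(x)
}

# rotational centre angles (degrees) of the six basal AHA segments in the
# package convention: anterior = 0, increasing towards the lateral wall
aha_basal_angles <- c(`1` = 0, `6` = 60, `5` = 120, `4` = 180, `3` = 240, `2` = 300)

seg_from_phi6 <- function(phi_deg, segs) {
  idx <- floor(((phi_deg + 30) %% 360) / 60) + 1L
  segs[idx]
}

#' Map LV nodes to the 17-segment AHA model
#'
#' Segments are assigned from the apicobasal coordinate band and rotational
#' sector: the apical cap (17) for `z` up to the cap threshold, then 4
#' apical, 6 mid-cavity and 6 basal segments. The bands are conventions
#' (config-exposed), defaulting to 0.15 / 0.45 / 0.72.
#'
#' @param coords A [compute_uvc()] result.
#' @param bands Numeric vector `c(apex_cap, apical, mid)` of upper `z`
#'   bounds for the apex cap, apical and mid bands.
#' @return Integer vector of segments 1..17 per node (`NA` for RV nodes),
#'   class `aha17_map`.
#' @export
map_aha17 <- function(coords, bands = c(0.15, 0.45, 0.72)) {
  stopifnot(inherits(coords, "ventricular_coordinates"))
  stopifnot(length(bands) == 3, all(diff(bands) > 0), bands[1] > 0, bands[3] < 1)
  n <- length(coords$z)
  seg <- rep(NA_integer_, n)
  lv <- coords$nu == "LV"
  phi_deg <- coords$phi * 180 / pi
  z <- coords$z
  cap <- lv & z <= bands[1]
  api <- lv & z > bands[1] & z <= bands[2]
  mid <- lv & z > bands[2] & z <= bands[3]
  bas <- lv & z > bands[3]
  seg[cap] <- 17L
  idx4 <- floor(((phi_deg + 45) %% 360) / 90) + 1L
  seg[api] <- c(13L, 16L, 15L, 14L)[idx4[api]]
  seg[mid] <- seg_from_phi6(phi_deg[mid], c(7L, 12L, 11L, 10L, 9L, 8L))
  seg[bas] <- seg_from_phi6(phi_deg[bas], c(1L, 6L, 5L, 4L, 3L, 2L))
  structure(seg, class = "aha17_map", bands = bands)
}

#' LV wall thickness per element
#'
#' For each LV element, thickness is the length of the transmural path
#' through the element centroid, measured as the exact distance from the
#' centroid to the endocardial surface plus its distance to the outer
#' (epicardial or septal) surface. On a uniform shell this equals the wall
#' thickness exactly; it is insensitive to the basal tilt of harmonic
#' transmural gradients. RV elements get `NA`.
#'
#' Thickness is element-wise (not nodal) because the thin-wall scar rule
#' blocks conduction per element.
#'
#' @param mesh A `ventricular_mesh`.
#' @param coords Matching [compute_uvc()] result.
#' @return Numeric vector, mm, one entry per element (`NA` on the RV).
#' @export
compute_wall_thickness <- function(mesh, coords) {
  stopifnot(inherits(mesh, "ventricular_mesh"),
            inherits(coords, "ventricular_coordinates"))
  lv_el <- which(mesh$region == "LV_WALL")
  grad <- element_gradient(mesh, coords$rho_lv, elements = lv_el)
  gn <- sqrt(rowSums(grad^2))
  if (any(gn < 1e-12)) {
    abort(sprintf("degenerate transmural gradient on element(s): %s",
                  paste(head(lv_el[gn < 1e-12], 5), collapse = ", ")),
          class = "quadlead_numerical_error")
  }
  cent <- element_centroids(mesh, lv_el)
  owner_lv <- mesh$region[mesh$boundary$owner] == "LV_WALL"
  inner <- mesh$boundary$tris[mesh$boundary$label == "LV_ENDO", , drop = FALSE]
  outer <- rbind(
    mesh$boundary$tris[mesh$boundary$label %in% c("EPI", "RV_ENDO") & owner_lv, ,
                       drop = FALSE],
    region_interface_faces(mesh))   # LV outer shell under the RV attachment
  th <- surface_distance_cpp(cent, mesh$nodes, inner - 1L) +
    surface_distance_cpp(cent, mesh$nodes, outer - 1L)
  out <- rep(NA_real_, nrow(mesh$tets))
  out[lv_el] <- th
  out
}
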