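#' Shape parameters for an idealized biventricular anatomy
#'
#' Bundles the morphological parameters of the synthetic biventricular
#' geometry: a truncated prolate-ellipsoid LV shell fused with a thinner
#' crescent-shaped RV shell that wraps around part of the LV epicardium.
#' All lengths are in millimetres.
#'
#' @param lv_long_axis LV endocardial long (apex-to-base) semi-axis, mm.
#' @param lv_endo_radius LV endocardial short semi-axis (cavity radius), mm.
#' @param lv_wall_thickness LV wall thickness, mm; must be smaller than
#'   `lv_endo_radius`.
#' @param rv_wall_thickness RV free-wall thickness, mm.
#' @param rv_lateral_extent Maximal outward extent of the RV cavity from the
#'   LV epicardium, mm. Controls RV cavity size.
#' @param base_truncation_fraction Fraction of the full apex-to-base height
#'   kept below the flat basal truncation plane, in (0, 1).
#' @param target_edge_length Requested mesh edge length, mm. Controls mesh
#'   resolution; the wall is always at least two elements thick.
#'
#' @return An object of class `shape_parameters`.
#' @seealso [hf_shape_defaults()], [rr_shape_defaults()],
#'   [generate_biventricular_mesh()]
#' @export
shape_parameters <- function(lv_long_axis = 61.4,
                             lv_endo_radius = 27.9,
                             lv_wall_thickness = 8,
                             rv_wall_thickness = 4,
                             rv_lateral_extent = 18,
                             base_truncation_fraction = 0.8,
                             target_edge_length = 6) {
  p <- list(
    lv_long_axis = lv_long_axis,
    lv_endo_radius = lv_endo_radius,
    lv_wall_thickness = lv_wall_thickness,
    rv_wall_thickness = rv_wall_thickness,
    rv_lateral_extent = rv_lateral_extent,
    base_truncation_fraction = base_truncation_fraction,
    target_edge_length = target_edge_length
  )
  lengths <- p[c("lv_long_axis", "lv_endo_radius", "lv_wall_thickness",
                 "rv_wall_thickness", "rv_lateral_extent",
                 "target_edge_length")]
  if (!all(vapply(lengths, function(x) is.numeric(x) && length(x) == 1 && x > 0, TRUE))) {
    abort("all shape lengths must be single positive numbers", class = "quadlead_argument_error")
  }
  if (p$lv_wall_thickness >= p$lv_endo_radius) {
    abort("infeasible geometry: lv_wall_thickness must be smaller than lv_endo_radius",
          class = "quadlead_geometry_error")
  }
  if (!(p$base_truncation_fraction > 0 && p$base_truncation_fraction < 1)) {
    abort("base_truncation_fraction must lie strictly in (0, 1)",
          class = "quadlead_argument_error")
  }
  structure(p, class = "shape_parameters")
}

#' Default shape parameters for the two synthetic cohorts
#'
#' `hf_shape_defaults()` emulates dilated, thinner-walled failing hearts
#' (mean LV cavity volume about 180 mL, 8 mm wall); `rr_shape_defaults()`
#' emulates smaller reverse-remodelled hearts (about 120 mL, 10 mm wall).
#' These are configurable generator defaults with plausible magnitudes, not
#' claims about any measured population.
#'
#' @param target_edge_length Mesh edge length, mm.
#' @return A `shape_parameters` object.
#' @export
hf_shape_defaults <- function(target_edge_length = 6) {
  shape_parameters(lv_long_axis = 61.4, lv_endo_radius = 27.9,
                   lv_wall_thickness = 8, rv_wall_thickness = 4,
                   rv_lateral_extent = 18,
                   target_edge_length = target_edge_length)
}

#' @rdname hf_shape_defaults
#' @export
rr_shape_defaults <- function(target_edge_length = 6) {
  shape_parameters(lv_long_axis = 53.7, lv_endo_radius = 24.4,
                   lv_wall_thickness = 10, rv_wall_thickness = 4.5,
                   rv_lateral_extent = 16,
                   target_edge_length = target_edge_length)
}

# ---- low-level mesh helpers -------------------------------------------------

tet_signed_volume <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  cc <- nodes[tets[, 4], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
     a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
     a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# boundary triangles (faces belonging to exactly one tet) and owning elements
boundary_faces <- function(tets, n_nodes) {
  m <- nrow(tets)
  f <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
             tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  owner <- rep.int(seq_len(m), 4L)
  a <- pmin(f[, 1], f[, 2], f[, 3])
  cmax <- pmax(f[, 1], f[, 2], f[, 3])
  b <- f[, 1] + f[, 2] + f[, 3] - a - cmax
  np <- as.numeric(n_nodes) + 1
  if (np^3 > 2^52) abort("mesh too large for exact face hashing")
  key <- (a * np + b) * np + cmax
  o <- order(key)
  ks <- key[o]
  dup_prev <- c(FALSE, ks[-1] == ks[-length(ks)])
  dup_next <- c(dup_prev[-1], FALSE)
  idx <- o[!(dup_prev | dup_next)]
  list(tris = cbind(a, b, cmax)[idx, , drop = FALSE], owner = owner[idx])
}

# split a set of prisms into 3 tets each with conforming quad diagonals.
# B, Tt: n x 3 node-id matrices; column i of Tt lies above column i of B.
# Each vertical quad is split along the diagonal through its smaller
# bottom id, which depends only on the shared face, so adjacent prisms agree.
prism_tets <- function(B, Tt) {
  n <- nrow(B)
  i_min <- ifelse(B[, 1] <= B[, 2] & B[, 1] <= B[, 3], 1L,
                  ifelse(B[, 2] <= B[, 3], 2L, 3L))
  i_max <- ifelse(B[, 1] >= B[, 2] & B[, 1] >= B[, 3], 1L,
                  ifelse(B[, 2] >= B[, 3], 2L, 3L))
  i_mid <- 6L - i_min - i_max
  rows <- seq_len(n)
  b1 <- B[cbind(rows, i_min)]; b2 <- B[cbind(rows, i_mid)]; b3 <- B[cbind(rows, i_max)]
  t1 <- Tt[cbind(rows, i_min)]; t2 <- Tt[cbind(rows, i_mid)]; t3 <- Tt[cbind(rows, i_max)]
  rbind(cbind(b1, b2, b3, t3),
        cbind(b1, b2, t3, t2),
        cbind(b1, t1, t2, t3))
}

orient_tets <- function(nodes, tets) {
  sv <- tet_signed_volume(nodes, tets)
  neg <- sv < 0
  if (any(neg)) {
    tmp <- tets[neg, 3]
    tets[neg, 3] <- tets[neg, 4]
    tets[neg, 4] <- tmp
  }
  tets
}

new_ventricular_mesh <- function(nodes, tets, fibre, region, boundary, build = NULL) {
  vol <- tet_signed_volume(nodes, tets)
  structure(
    list(nodes = nodes, tets = tets, fibre = fibre, region = region,
         volume = vol, boundary = boundary, build = build),
    class = "ventricular_mesh")
}

#' @export
print.ventricular_mesh <- function(x, ...) {
  cat("<ventricular_mesh>\n")
  cat(sprintf("  nodes: %d, tets: %d (LV %d / RV %d)\n",
              nrow(x$nodes), nrow(x$tets),
              sum(x$region == "LV_WALL"), sum(x$region == "RV_WALL")))
  cat(sprintf("  myocardial volume: %.1f mL\n", sum(x$volume) / 1000))
  cat(sprintf("  boundary: %s\n",
              paste(sprintf("%s=%d", names(table(x$boundary$label)),
                            table(x$boundary$label)), collapse = ", ")))
  invisible(x)
}

#' Validate a ventricular mesh
#'
#' Checks the structural invariants: positive element volumes, unit fibre
#' vectors, boundary labels forming a partition, and a single connected
#' component.
#'
#' @param mesh A `ventricular_mesh`.
#' @return `mesh`, invisibly; aborts with an informative error otherwise.
#' @export
validate_ventricular_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "ventricular_mesh"))
  if (any(mesh$volume <= 0)) {
    abort(sprintf("%d tetrahedra have non-positive volume", sum(mesh$volume <= 0)))
  }
  fn <- sqrt(rowSums(mesh$fibre^2))
  if (any(abs(fn - 1) > 1e-9)) abort("element fibres must be unit vectors")
  if (!all(mesh$region %in% c("LV_WALL", "RV_WALL"))) abort("unknown element region label")
  bf <- boundary_faces(mesh$tets, nrow(mesh$nodes))
  if (nrow(bf$tris) != nrow(mesh$boundary$tris)) {
    abort("stored boundary does not match mesh topology")
  }
  if (!all(mesh$boundary$label %in% c("LV_ENDO", "RV_ENDO", "EPI", "BASE"))) {
    abort("unknown surface label")
  }
  g <- igraph::graph_from_edgelist(
    rbind(mesh$tets[, c(1, 2)], mesh$tets[, c(1, 3)], mesh$tets[, c(1, 4)]),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$nodes) - igraph::vcount(g)))
  if (igraph::count_components(g) != 1L) abort("mesh is not a single connected component")
  invisible(mesh)
}

smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# ---- generator --------------------------------------------------------------

#' Generate an idealized biventricular tetrahedral mesh
#'
#' Builds a truncated prolate-ellipsoid LV shell fused with a thinner
#' crescent RV shell. The RV free wall is offset outward from the LV
#' epicardium over a circumferential sector centred on the septum and is
#' welded back onto the epicardium at the sector edges and towards the apex,
#' so the mesh is a single face-connected component. The basal truncation
#' plane is flat. Element fibres follow a linear transmural helix-angle rule
#' evaluated on the construction coordinates (see
#' [assign_rule_based_fibres()] for the general, coordinate-based rule).
#'
#' In the frame of the generated mesh the long axis is z (apex down), the
#' anterior LV free wall faces +x and the septum is centred on -y, so the
#' rotational coordinate `atan2(y, x)` is 0 on the anterior wall and
#' increases towards the lateral wall.
#'
#' @param params A [shape_parameters()] object.
#' @param seed Integer recorded in the mesh provenance. Generation is fully
#'   deterministic given `params`; the seed tags cohort draws.
#' @param alpha_endo,alpha_epi Endocardial and epicardial fibre helix angles,
#'   degrees.
#' @return A `ventricular_mesh` with nodes (mm), 1-based tetrahedra, unit
#'   element fibres, element regions (`LV_WALL`/`RV_WALL`), element volumes
#'   (mm^3) and labelled boundary triangles
#'   (`LV_ENDO`/`RV_ENDO`/`EPI`/`BASE`).
#' @export
generate_biventricular_mesh <- function(params = hf_shape_defaults(), seed = 0L,
                                        alpha_endo = 60, alpha_epi = -60) {
  stopifnot(inherits(params, "shape_parameters"))
  p <- params
  h <- p$target_edge_length
  c_en <- p$lv_long_axis; a_en <- p$lv_endo_radius; tw <- p$lv_wall_thickness
  z_base <- c_en * (2 * p$base_truncation_fraction - 1)
  n_w <- max(2L, as.integer(round(tw / h)))

  # ring/column counts from the endocardial meridian arc and mid-wall girth
  th_max_en <- acos(max(-1, min(1, -z_base / c_en)))
  th <- seq(0, th_max_en, length.out = 257L)
  darc <- sqrt((a_en * cos(th))^2 + (c_en * sin(th))^2)
  arc <- sum((darc[-1] + darc[-length(th)]) / 2) * diff(th[1:2])
  n_u <- max(8L, as.integer(round(arc / h)))
  n_v <- max(16L, as.integer(round(2 * pi * (a_en + tw / 2) / h)))
  if (n_w < 2L) abort("wall must be at least two elements thick", class = "quadlead_geometry_error")

  n_s <- 1L + n_u * n_v                       # surface nodes per layer
  sid <- function(j, k) 1L + (j - 1L) * n_v + (k %% n_v) + 1L  # j >= 1, k 0-based

  # one shared surface triangulation, reused for every extrusion
  k0 <- 0:(n_v - 1L)
  fan <- cbind(1L, sid(1L, k0), sid(1L, k0 + 1L))
  tri <- fan
  if (n_u > 1L) {
    jj <- rep(1:(n_u - 1L), each = n_v)
    kk <- rep(k0, n_u - 1L)
    A <- sid(jj, kk); B <- sid(jj, kk + 1L)
    Cc <- sid(jj + 1L, kk); D <- sid(jj + 1L, kk + 1L)
    tri <- rbind(tri, cbind(A, Cc, D), cbind(A, D, B))
  }
  node_j <- integer(n_s); node_k <- rep(NA_integer_, n_s)
  node_j[1L] <- 0L
  node_j[-1L] <- rep(1:n_u, each = n_v)
  node_k[-1L] <- rep(k0, n_u)

  # layered LV nodes: layer w in 0..n_w, id = w * n_s + surface id
  w_frac <- (0:n_w) / n_w
  a_w <- a_en + w_frac * tw
  c_w <- c_en + w_frac * tw
  phi_k <- 2 * pi * k0 / n_v
  lv_nodes <- matrix(0, nrow = (n_w + 1L) * n_s, ncol = 3L)
  for (wi in seq_along(w_frac)) {
    th_max <- acos(max(-1, min(1, -z_base / c_w[wi])))
    th_j <- th_max * (1:n_u) / n_u
    sin_t <- sin(th_j); cos_t <- cos(th_j)
    xs <- a_w[wi] * outer(sin_t, cos(phi_k))
    ys <- a_w[wi] * outer(sin_t, sin(phi_k))
    zs <- matrix(-c_w[wi] * cos_t, n_u, n_v)
    zs[n_u, ] <- z_base   # exact flat base
    off <- (wi - 1L) * n_s
    lv_nodes[off + 1L, ] <- c(0, 0, -c_w[wi])
    lv_nodes[off + 1L + seq_len(n_u * n_v), ] <-
      cbind(as.vector(t(xs)), as.vector(t(ys)), as.vector(t(zs)))
  }

  lv_tets <- NULL
  for (w in 0:(n_w - 1L)) {
    bot <- tri + w * n_s
    lv_tets <- rbind(lv_tets, prism_tets(bot, bot + n_s))
  }
  n_lv_tets <- nrow(lv_tets)

  # ---- RV crescent ----
  sector <- c(195, 345) * pi / 180            # septum centred on -y
  ks <- k0[phi_k >= sector[1] & phi_k <= sector[2]]
  n_k <- length(ks)
  if (n_k < 5L) abort("mesh too coarse for the RV sector; reduce target_edge_length",
                      class = "quadlead_geometry_error")
  j0 <- max(1L, as.integer(round(0.08 * n_u)))
  if (j0 + 3L >= n_u) abort("mesh too coarse apicobasally for the RV; reduce target_edge_length",
                            class = "quadlead_geometry_error")
  n_wr <- max(1L, as.integer(round(p$rv_wall_thickness / h)))
  jr <- j0:n_u
  n_jr <- length(jr)

  pos <- 0:(n_k - 1L)
  sphi <- sinpi(pmin(1, pmax(0, (pos - 1) / (n_k - 3))))
  r0 <- j0 + 1L
  r1 <- min(n_u - 1L, r0 + max(2L, as.integer(round(0.35 * (n_u - j0)))))
  sz <- smoothstep((jr - r0) / (r1 - r0))
  g <- p$rv_lateral_extent * outer(sz, sphi)   # n_jr x n_k
  g[g < 1e-9] <- 0

  # epi-layer geometry at the RV grid points
  a_ep <- a_w[n_w + 1L]; c_ep <- c_w[n_w + 1L]
  th_max_ep <- acos(max(-1, min(1, -z_base / c_ep)))
  th_r <- th_max_ep * jr / n_u
  px <- a_ep * outer(sin(th_r), cos(phi_k[ks + 1L]))
  py <- a_ep * outer(sin(th_r), sin(phi_k[ks + 1L]))
  pz <- matrix(-c_ep * cos(th_r), n_jr, n_k)
  pz[n_jr, ] <- z_base
  nx <- px / a_ep^2; ny <- py / a_ep^2; nz <- pz / c_ep^2
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  nx <- nx / nn; ny <- ny / nn; nz <- nz / nn

  epi_id <- matrix(n_w * n_s + sid(rep(jr, n_k), rep(ks, each = n_jr)),
                   n_jr, n_k)

  rid <- array(NA_integer_, dim = c(n_jr, n_k, n_wr + 1L))
  next_id <- nrow(lv_nodes)
  rv_xyz <- list(); rv_rho <- list()
  t_rv <- p$rv_wall_thickness
  for (m in 0:n_wr) {
    lift <- g + (m / n_wr) * t_rv
    weld <- (m == 0L) & (g == 0)
    new <- !weld
    ids <- matrix(NA_integer_, n_jr, n_k)
    ids[weld] <- epi_id[weld]
    n_new <- sum(new)
    if (n_new > 0L) {
      ids[new] <- next_id + seq_len(n_new)
      next_id <- next_id + n_new
      X <- px + nx * lift; Y <- py + ny * lift; Z <- pz + nz * lift
      Z[n_jr, ] <- z_base                      # keep the base flat
      rv_xyz[[length(rv_xyz) + 1L]] <- cbind(X[new], Y[new], Z[new])
      rv_rho[[length(rv_rho) + 1L]] <- rep(m / n_wr, n_new)
    }
    rid[, , m + 1L] <- ids
  }
  nodes <- rbind(lv_nodes, do.call(rbind, rv_xyz))

  # RV prisms over the surface triangles fully inside the sector grid
  jv <- matrix(node_j[tri], ncol = 3L)
  kv <- matrix(node_k[tri], ncol = 3L)
  in_grid <- matrix(jv >= j0 & !is.na(kv) & (kv %in% ks), ncol = 3L)
  rv_tri <- tri[rowSums(in_grid) == 3L, , drop = FALSE]
  jvr <- matrix(node_j[rv_tri], ncol = 3L) - j0 + 1L
  pvr <- matrix(match(node_k[rv_tri], ks), ncol = 3L)
  rv_tets <- NULL
  for (m in 0:(n_wr - 1L)) {
    bot <- cbind(rid[cbind(jvr[, 1], pvr[, 1], m + 1L)],
                 rid[cbind(jvr[, 2], pvr[, 2], m + 1L)],
                 rid[cbind(jvr[, 3], pvr[, 3], m + 1L)])
    top <- cbind(rid[cbind(jvr[, 1], pvr[, 1], m + 2L)],
                 rid[cbind(jvr[, 2], pvr[, 2], m + 2L)],
                 rid[cbind(jvr[, 3], pvr[, 3], m + 2L)])
    rv_tets <- rbind(rv_tets, prism_tets(bot, top))
  }

  tets <- orient_tets(nodes, rbind(lv_tets, rv_tets))
  region <- rep(c("LV_WALL", "RV_WALL"), c(n_lv_tets, nrow(rv_tets)))

  # ---- node attributes for boundary classification and fibres ----
  n_nodes <- nrow(nodes)
  is_layer0 <- seq_len(n_nodes) <= n_s
  is_epi_layer <- seq_len(n_nodes) > n_w * n_s & seq_len(n_nodes) <= (n_w + 1L) * n_s
  node_g <- rep(NA_real_, n_nodes)
  node_g[epi_id] <- g
  is_rv_inner <- rep(FALSE, n_nodes)
  inner_ids <- rid[, , 1L][g > 0]
  is_rv_inner[inner_ids] <- TRUE
  node_rho_lv <- rep(NA_real_, n_nodes)
  node_rho_lv[seq_len((n_w + 1L) * n_s)] <- rep(w_frac, each = n_s)
  node_rho_rv <- rep(NA_real_, n_nodes)
  for (m in 0:n_wr) node_rho_rv[rid[, , m + 1L]] <- m / n_wr

  bf <- boundary_faces(tets, n_nodes)
  zb_tol <- 1e-8 * max(1, abs(z_base))
  on_base <- abs(nodes[, 3] - z_base) < zb_tol
  cav_strict <- is_rv_inner | (is_epi_layer & !is.na(node_g) & node_g > 0)
  cav_ok <- cav_strict | (is_epi_layer & !is.na(node_g) & node_g == 0)
  f1 <- bf$tris[, 1]; f2 <- bf$tris[, 2]; f3 <- bf$tris[, 3]
  lab <- rep("EPI", nrow(bf$tris))
  rvendo <- cav_ok[f1] & cav_ok[f2] & cav_ok[f3] &
    (cav_strict[f1] | cav_strict[f2] | cav_strict[f3])
  lab[rvendo] <- "RV_ENDO"
  lab[is_layer0[f1] & is_layer0[f2] & is_layer0[f3]] <- "LV_ENDO"
  lab[on_base[f1] & on_base[f2] & on_base[f3]] <- "BASE"
  boundary <- list(tris = bf$tris, owner = bf$owner, label = lab)

  # ---- construction-rule fibres ----
  cent <-(nodes[tets[, 1], ] + nodes[tets[, 2], ] +
             nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  rho_mat <- matrix(node_rho_lv[tets], ncol = 4L)
  rho_rv_mat <- matrix(node_rho_rv[tets], ncol = 4L)
  rv_rows <- region == "RV_WALL"
  rho_mat[rv_rows, ] <- rho_rv_mat[rv_rows, ]
  rho_e <- rowMeans(rho_mat)
  a_mid <- a_en + tw / 2; c_mid <- c_en + tw / 2
  fibre <- helix_fibres(cent, rho_e, a_mid, c_mid, alpha_endo, alpha_epi)

  build <- list(params = p, seed = as.integer(seed),
                n_u = n_u, n_v = n_v, n_w = n_w, n_s = n_s, n_wr = n_wr,
                z_base = z_base, sector = sector, j0 = j0,
                node_rho_lv = node_rho_lv, node_rho_rv = node_rho_rv,
                node_g = node_g,
                alpha_endo = alpha_endo, alpha_epi = alpha_epi)
  new_ventricular_mesh(nodes, tets, fibre, region, boundary, build)
}

# helix-angle fibre rule evaluated on an ellipsoidal reference frame:
# transmural direction = outward ellipsoid normal at the element centroid,
# helix angle linear in the transmural coordinate.
helix_fibres <- function(cent, rho_e, a_mid, c_mid, alpha_endo, alpha_epi) {
  mx <- cent[, 1] / a_mid^2; my <- cent[, 2] / a_mid^2; mz <- cent[, 3] / c_mid^2
  mn <- sqrt(mx^2 + my^2 + mz^2)
  mx <- mx / mn; my <- my / mn; mz <- mz / mn
  # apicobasal direction: +z projected off the transmural direction
  lx <- -mz * mx; ly <- -mz * my; lz <- 1 - mz * mz
  ln <- sqrt(lx^2 + ly^2 + lz^2)
  deg <- ln < 1e-8
  if (any(deg)) { lx[deg] <- 1; ly[deg] <- 0; lz[deg] <- 0; ln[deg] <- 1 }
  lx <- lx / ln; ly <- ly / ln; lz <- lz / ln
  # circumferential = l x m (counter-clockwise seen from the base)
  cx <- ly * mz - lz * my
  cy <- lz * mx - lx * mz
  cz <- lx * my - ly * mx
  al <- (alpha_endo + (alpha_epi - alpha_endo) * rho_e) * pi / 180
  f <- cbind(cos(al) * cx + sin(al) * lx,
             cos(al) * cy + sin(al) * ly,
             cos(al) * cz + sin(al) * lz)
  f / sqrt(rowSums(f^2))
}

#' Uniformly scale a mesh about its centroid
#'
#' Node coordinates are scaled by `factor` about the mean node position;
#' element volumes scale by `factor^3`; fibres and all labels are unchanged.
#'
#' @param mesh A `ventricular_mesh`.
#' @param factor Positive scale factor (0.75 shrinks to 42.2% of the
#'   original volume; 1 is the identity).
#' @return The scaled `ventricular_mesh`.
#' @export
scale_mesh <- function(mesh, factor) {
  stopifnot(inherits(mesh, "ventricular_mesh"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    abort("scale factor must be a single positive number", class = "quadlead_argument_error")
  }
  ctr <- colMeans(mesh$nodes)
  mesh$nodes <- sweep(sweep(mesh$nodes, 2, ctr) * factor, 2, ctr, `+`)
  mesh$volume <- tet_signed_volume(mesh$nodes, mesh$tets)
  if (!is.null(mesh$build)) mesh$build$scaled_by <- (mesh$build$scaled_by %||% 1) * factor
  mesh
}

#' Specification of a synthetic virtual cohort
#'
#' @param n_subjects Number of subjects to draw (>= 1).
#' @param cohort_type `"HF"` (dilated, thin-walled) or `"RR"`
#'   (reverse-remodelled, smaller).
#' @param shape_mean Mean [shape_parameters()]; defaults to
#'   [hf_shape_defaults()] or [rr_shape_defaults()] by `cohort_type`.
#' @param shape_cv Coefficient of variation applied to the length
#'   parameters; either a single number or a named vector over the length
#'   fields.
#' @param random_seed Integer seed; cohort generation is a deterministic
#'   function of the specification.
#' @return An object of class `cohort_specification`.
#' @export
cohort_specification <- function(n_subjects, cohort_type = c("HF", "RR"),
                                 shape_mean = NULL, shape_cv = 0.1,
                                 random_seed = 1L) {
  cohort_type <- match.arg(cohort_type)
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 1) {
    abort("n_subjects must be a positive integer", class = "quadlead_argument_error")
  }
  if (any(shape_cv < 0)) abort("shape_cv must be non-negative", class = "quadlead_argument_error")
  if (is.null(shape_mean)) {
    shape_mean <- if (cohort_type == "HF") hf_shape_defaults() else rr_shape_defaults()
  }
  structure(list(n_subjects = as.integer(n_subjects), cohort_type = cohort_type,
                 shape_mean = shape_mean, shape_cv = shape_cv,
                 random_seed = as.integer(random_seed)),
            class = "cohort_specification")
}

with_preserved_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Draw a synthetic virtual cohort of biventricular meshes
#'
#' Each subject's shape parameters are drawn independently around the cohort
#' means with the requested coefficient of variation (normal draws truncated
#' at 2.5 standard deviations); per-subject seeds are derived
#' deterministically from the specification seed, so identical
#' specifications yield identical cohorts.
#'
#' @param spec A [cohort_specification()].
#' @return A list of `ventricular_mesh` objects of length `n_subjects`, with
#'   a `manifest` attribute (tibble of subject ids, seeds and shape draws).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_specification"))
  mean_p <- spec$shape_mean
  fields <- c("lv_long_axis", "lv_endo_radius", "lv_wall_thickness",
              "rv_wall_thickness", "rv_lateral_extent")
  cv <- spec$shape_cv
  if (length(cv) == 1L) cv <- setNames(rep(cv, length(fields)), fields)
  meshes <- vector("list", spec$n_subjects)
  rows <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    sub_seed <- (spec$random_seed * 1009L + i) %% 2147483647L
    draw <- with_preserved_seed(sub_seed, {
      z <- pmin(2.5, pmax(-2.5, stats::rnorm(length(fields))))
      vals <- vapply(seq_along(fields), function(k) {
        mean_p[[fields[k]]] * (1 + (cv[[fields[k]]] %||% 0) * z[k])
      }, numeric(1))
      setNames(vals, fields)
    })
    # keep the draw geometrically feasible
    draw["lv_wall_thickness"] <- min(draw["lv_wall_thickness"],
                                     0.6 * draw["lv_endo_radius"])
    params <- shape_parameters(
      lv_long_axis = draw[["lv_long_axis"]],
      lv_endo_radius = draw[["lv_endo_radius"]],
      lv_wall_thickness = draw[["lv_wall_thickness"]],
      rv_wall_thickness = draw[["rv_wall_thickness"]],
      rv_lateral_extent = draw[["rv_lateral_extent"]],
      base_truncation_fraction = mean_p$base_truncation_fraction,
      target_edge_length = mean_p$target_edge_length)
    meshes[[i]] <- generate_biventricular_mesh(params, seed = sub_seed)
    rows[[i]] <- tibble(
      id = sprintf("%s%02d", spec$cohort_type, i),
      cohort = spec$cohort_type, seed = sub_seed,
      !!!as.list(draw))
  }
  names(meshes) <- sprintf("%s%02d", spec$cohort_type, seq_len(spec$n_subjects))
  attr(meshes, "manifest") <- bind_rows(rows)
  attr(meshes, "spec") <- spec
  meshes
}

#' LV cavity volume of a mesh
#'
#' Volume enclosed by the LV endocardial surface and its flat basal cap,
#' computed with the divergence theorem over the labelled boundary
#' triangles.
#'
#' @param mesh A `ventricular_mesh`.
#' @return Cavity volume in mm^3.
#' @export
lv_cavity_volume <- function(mesh) {
  closed_surface_volume(mesh, "LV_ENDO")
}

# volume enclosed by the given endocardial label plus its flat basal cap.
# Boundary triangles are stored with sorted node ids, so orientation is
# recovered from the owning tet: the outward-from-tet normal of an
# endocardial face points into the cavity.
closed_surface_volume <- function(mesh, label) {
  sel <- mesh$boundary$label == label
  tris <- mesh$boundary$tris[sel, , drop = FALSE]
  if (nrow(tris) == 0) abort(sprintf("no boundary triangles labelled %s", label))
  tris <- orient_boundary_tris(mesh, tris, mesh$boundary$owner[sel])
  nd <- mesh$nodes
  p1 <- nd[tris[, 1], , drop = FALSE]
  p2 <- nd[tris[, 2], , drop = FALSE]
  p3 <- nd[tris[, 3], , drop = FALSE]
  # oriented so normals point out of the wall, i.e. INTO the cavity
  flux_v <- sum(p1[, 1] * (p2[, 2] * p3[, 3] - p3[, 2] * p2[, 3]) -
                  p2[, 1] * (p1[, 2] * p3[, 3] - p3[, 2] * p1[, 3]) +
                  p3[, 1] * (p1[, 2] * p2[, 3] - p2[, 2] * p1[, 3])) / 6
  e1 <- p2 - p1; e2 <- p3 - p1
  flux_z <- sum(e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  zb <- max(nd[unique(as.vector(tris)), 3])
  # cavity-outward orientation is the flip of into-cavity; cap area from the
  # closed-surface zero-flux identity for the constant field e_z
  a_cap <- flux_z
  -flux_v + zb * a_cap / 3
}

# reorder triangle nodes so (p2-p1) x (p3-p1) points away from the owner tet
orient_boundary_tris <- function(mesh, tris, owner) {
  nd <- mesh$nodes
  tet <- mesh$tets[owner, , drop = FALSE]
  # the tet vertex opposite the face
  opp <- integer(nrow(tris))
  for (k in 1:4) {
    cand <- tet[, k]
    is_opp <- cand != tris[, 1] & cand != tris[, 2] & cand != tris[, 3]
    opp[is_opp] <- cand[is_opp]
  }
  p1 <- nd[tris[, 1], , drop = FALSE]
  e1 <- nd[tris[, 2], , drop = FALSE] - p1
  e2 <- nd[tris[, 3], , drop = FALSE] - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  inward <- rowSums(nrm * (nd[opp, , drop = FALSE] - p1)) > 0
  if (any(inward)) {
    tmp <- tris[inward, 2]
    tris[inward, 2] <- tris[inward, 3]
    tris[inward, 3] <- tmp
  }
  tris
}

#' Structured tetrahedral box mesh
#'
#' A rectangular box split into conforming tetrahedra, used for solver
#' verification against closed-form travel times. The fibre direction is
#' constant and user-chosen; all boundary triangles are labelled `EPI`.
#'
#' @param lengths Box edge lengths `c(lx, ly, lz)` in mm.
#' @param edge Target element edge length, mm.
#' @param fibre Constant unit fibre direction.
#' @return A `ventricular_mesh`.
#' @export
make_box_mesh <- function(lengths = c(10, 10, 10), edge = 1,
                          fibre = c(1, 0, 0)) {
  nx <- max(1L, as.integer(round(lengths[1] / edge)))
  ny <- max(1L, as.integer(round(lengths[2] / edge)))
  nz <- max(1L, as.integer(round(lengths[3] / edge)))
  xs <- seq(0, lengths[1], length.out = nx + 1L)
  ys <- seq(0, lengths[2], length.out = ny + 1L)
  zs <- seq(0, lengths[3], length.out = nz + 1L)
  nid <- function(i, j) i + (nx + 1L) * (j - 1L)       # 2D grid id, 1-based
  n2d <- (nx + 1L) * (ny + 1L)
  ii <- rep(1:nx, ny); jj <- rep(1:ny, each = nx)
  A <- nid(ii, jj); B <- nid(ii + 1L, jj); Cc <- nid(ii, jj + 1L); D <- nid(ii + 1L, jj + 1L)
  tri <- rbind(cbind(A, B, D), cbind(A, D, Cc))
  nodes <- cbind(rep(rep(xs, ny + 1L), nz + 1L),
                 rep(rep(ys, each = nx + 1L), nz + 1L),
                 rep(zs, each = n2d))
  tets <- NULL
  for (w in 0:(nz - 1L)) {
    bot <- tri + w * n2d
    tets <- rbind(tets, prism_tets(bot, bot + n2d))
  }
  tets <- orient_tets(nodes, tets)
  fib <- matrix(rep(fibre / sqrt(sum(fibre^2)), each = nrow(tets)), ncol = 3L)
  bf <- boundary_faces(tets, nrow(nodes))
  boundary <- list(tris = bf$tris, owner = bf$owner,
                   label = rep("EPI", nrow(bf$tris)))
  new_ventricular_mesh(nodes, tets, fib, rep("LV_WALL", nrow(tets)), boundary)
}
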