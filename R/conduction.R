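# Conduction model: per-element squared-velocity tensors for anisotropic
# myocardium, an isotropic fast endocardial conduction (FEC) layer standing
# in for the Purkinje system, and thickness-based scar blocking.

#' Conduction parameters
#'
#' Velocities are in mm/ms (numerically equal to m/s).
#'
#' @param cv_fibre Conduction velocity along the fibre direction, mm/ms.
#' @param k_xf Cross-fibre anisotropy ratio: sheet/normal velocity is
#'   `k_xf * cv_fibre`. In (0, 1].
#' @param k_fec FEC multiplier: the endocardial layer conducts isotropically
#'   at `k_fec * cv_fibre`. >= 1.
#' @param fec_extent Apicobasal fraction of the endocardium covered by the
#'   FEC layer (0.33 covers the bottom third), in `[0, 1]`.
#' @param scar_threshold LV wall-thickness threshold (mm) below which
#'   elements are treated as non-conducting scar, or `NULL` for no scar.
#' @return An object of class `conduction_parameters`.
#' @export
conduction_parameters <- function(cv_fibre = 0.5, k_xf = 0.6, k_fec = 5,
                                  fec_extent = 0.33, scar_threshold = NULL) {
  if (!is.numeric(cv_fibre) || cv_fibre <= 0) {
    abort("cv_fibre must be positive", class = "quadlead_argument_error")
  }
  if (!is.numeric(k_xf) || k_xf <= 0 || k_xf > 1) {
    abort("k_xf must lie in (0, 1]", class = "quadlead_argument_error")
  }
  if (!is.numeric(k_fec) || k_fec < 1) {
    abort("k_fec must be >= 1", class = "quadlead_argument_error")
  }
  if (!is.numeric(fec_extent) || fec_extent < 0 || fec_extent > 1) {
    abort("fec_extent must lie in [0, 1]", class = "quadlead_argument_error")
  }
  if (!is.null(scar_threshold) && (!is.numeric(scar_threshold) || scar_threshold < 0)) {
    abort("scar_threshold must be non-negative or NULL", class = "quadlead_argument_error")
  }
  structure(list(cv_fibre = cv_fibre, k_xf = k_xf, k_fec = k_fec,
                 fec_extent = fec_extent, scar_threshold = scar_threshold),
            class = "conduction_parameters")
}

#' @export
print.conduction_parameters <- function(x, ...) {
  cat(sprintf("<conduction_parameters> cv_fibre=%.3g mm/ms, k_xf=%.3g, k_fec=%.3g, fec_extent=%.3g, scar_threshold=%s\n",
              x$cv_fibre, x$k_xf, x$k_fec, x$fec_extent,
              if (is.null(x$scar_threshold)) "none" else format(x$scar_threshold)))
  invisible(x)
}

#' Mark the fast endocardial conduction layer
#'
#' The FEC layer is one element thick: exactly the elements with at least
#' one boundary face on an endocardial surface whose mean apicobasal
#' coordinate lies within the requested extent measured from the apex.
#'
#' @param mesh A `ventricular_mesh`.
#' @param coords Matching [compute_uvc()] coordinates.
#' @param fec_extent Apicobasal fraction in `[0, 1]`; 0 marks nothing, 1 the
#'   whole endocardium.
#' @param surfaces Endocardial labels considered; both ventricles by
#'   default.
#' @return Logical vector, one entry per element.
#' @export
mark_fec_layer <- function(mesh, coords, fec_extent = 0.33,
                           surfaces = c("LV_ENDO", "RV_ENDO")) {
  stopifnot(inherits(mesh, "ventricular_mesh"),
            inherits(coords, "ventricular_coordinates"))
  if (!is.numeric(fec_extent) || length(fec_extent) != 1 ||
      fec_extent < 0 || fec_extent > 1) {
    abort("fec_extent must lie in [0, 1]", class = "quadlead_argument_error")
  }
  m <- nrow(mesh$tets)
  endo_adj <- rep(FALSE, m)
  endo_adj[mesh$boundary$owner[mesh$boundary$label %in% surfaces]] <- TRUE
  mean_z <- rowMeans(matrix(coords$z[mesh$tets], ncol = 4L))
  endo_adj & mean_z <= fec_extent
}

#' Mark thickness-based scar
#'
#' A first-order scar surrogate: LV elements whose wall thickness falls
#' below the threshold are treated as non-conducting. RV elements are never
#' marked.
#'
#' @param thickness Per-element wall thickness from
#'   [compute_wall_thickness()] (`NA` on the RV).
#' @param threshold Thickness threshold, mm (>= 0). `Inf` marks every LV
#'   element.
#' @return Logical vector, one entry per element.
#' @export
mark_scar <- function(thickness, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0) {
    abort("scar threshold must be a non-negative number", class = "quadlead_argument_error")
  }
  !is.na(thickness) & thickness < threshold
}

#' Build the per-element squared-velocity tensor field
#'
#' Plain myocardium gets the transversely isotropic tensor
#' `V = cv_fibre^2 f f' + (k_xf cv_fibre)^2 (I - f f')`; FEC elements are
#' isotropic at `k_fec * cv_fibre` (the fast layer overrides anisotropy);
#' scar elements are inactive and never traversed. An element that is both
#' thin-walled and endocardial counts as scar: scar is the stronger
#' pathological statement.
#'
#' @param mesh A `ventricular_mesh` with unit element fibres.
#' @param params [conduction_parameters()].
#' @param fec_mask,scar_mask Optional logical per-element masks from
#'   [mark_fec_layer()] and [mark_scar()]; `NULL` means none.
#' @return An object of class `velocity_field`: per-element 3x3 tensors
#'   (row-major, (mm/ms)^2) and an `active` flag.
#' @export
build_velocity_field <- function(mesh, params = conduction_parameters(),
                                 fec_mask = NULL, scar_mask = NULL) {
  stopifnot(inherits(mesh, "ventricular_mesh"),
            inherits(params, "conduction_parameters"))
  m <- nrow(mesh$tets)
  if (is.null(fec_mask)) fec_mask <- rep(FALSE, m)
  if (is.null(scar_mask)) scar_mask <- rep(FALSE, m)
  stopifnot(length(fec_mask) == m, length(scar_mask) == m)
  f <- mesh$fibre
  fn <- sqrt(rowSums(f^2))
  if (any(abs(fn - 1) > 1e-6)) {
    abort("element fibres must be unit vectors", class = "quadlead_validation_error")
  }
  v_f2 <- params$cv_fibre^2
  v_x2 <- (params$k_xf * params$cv_fibre)^2
  d <- v_f2 - v_x2
  V <- cbind(v_x2 + d * f[, 1] * f[, 1], d * f[, 1] * f[, 2], d * f[, 1] * f[, 3],
             d * f[, 2] * f[, 1], v_x2 + d * f[, 2] * f[, 2], d * f[, 2] * f[, 3],
             d * f[, 3] * f[, 1], d * f[, 3] * f[, 2], v_x2 + d * f[, 3] * f[, 3])
  fec <- fec_mask & !scar_mask
  if (any(fec)) {
    v_e2 <- (params$k_fec * params$cv_fibre)^2
    V[fec, ] <- matrix(rep(c(v_e2, 0, 0, 0, v_e2, 0, 0, 0, v_e2),
                           each = sum(fec)), nrow = sum(fec))
  }
  structure(list(V = V, active = !scar_mask, params = params,
                 fec = fec, scar = scar_mask),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d elements (%d FEC, %d scar/inactive)\n",
              nrow(x$V), sum(x$fec), sum(!x$active)))
  invisible(x)
}
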