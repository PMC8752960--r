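# Coordinate-based rule-based fibres: a simplified one-rotation helix rule.
# The transmural direction is the gradient of the transmural Laplace
# coordinate, the fibre lies in the local wall-tangent plane, and its helix
# angle rotates linearly from alpha_endo on the endocardium to alpha_epi on
# the epicardium.

#' Assign rule-based fibres from ventricular coordinates
#'
#' Replaces the element fibre field: each element gets the unit vector in
#' its wall-tangent plane whose helix angle (measured from the local
#' circumferential direction towards the apicobasal direction) varies
#' linearly in the transmural coordinate from `alpha_endo` to `alpha_epi`.
#' By construction the fibre is orthogonal to the local transmural
#' gradient.
#'
#' @param mesh A `ventricular_mesh`.
#' @param coords Matching [compute_uvc()] coordinates.
#' @param alpha_endo,alpha_epi Helix angles on the endo- and epicardium,
#'   degrees (defaults +60 / -60).
#' @return The mesh with its `fibre` field replaced.
#' @export
assign_rule_based_fibres <- function(mesh, coords, alpha_endo = 60,
                                     alpha_epi = -60) {
  stopifnot(inherits(mesh, "ventricular_mesh"),
            inherits(coords, "ventricular_coordinates"))
  m <- nrow(mesh$tets)
  rho_node <- ifelse(!is.na(coords$rho_lv), coords$rho_lv, coords$rho_rv)
  lv_rows <- mesh$region == "LV_WALL"
  grad_rho <- matrix(NA_real_, m, 3)
  grad_rho[lv_rows, ] <- element_gradient(mesh, coords$rho_lv,
                                          elements = which(lv_rows))
  if (any(!lv_rows)) {
    grad_rho[!lv_rows, ] <- element_gradient(mesh, coords$rho_rv,
                                             elements = which(!lv_rows))
  }
  gn <- sqrt(rowSums(grad_rho^2))
  bad <- which(!is.finite(gn) | gn < 1e-10)
  if (length(bad)) {
    abort(sprintf("degenerate transmural gradient on element(s): %s%s",
                  paste(head(bad, 5), collapse = ", "),
                  if (length(bad) > 5) ", ..." else ""),
          class = "quadlead_numerical_error")
  }
  mh <- grad_rho / gn
  gz <- element_gradient(mesh, coords$z)
  lv <- gz - rowSums(gz * mh) * mh
  ln <- sqrt(rowSums(lv^2))
  weak <- ln < 1e-8
  if (any(weak)) {
    # fall back to the global long axis projected into the tangent plane
    zax <- cbind(0, 0, 1)[rep(1, sum(weak)), , drop = FALSE]
    lv[weak, ] <- zax - rowSums(zax * mh[weak, , drop = FALSE]) * mh[weak, , drop = FALSE]
    ln[weak] <- sqrt(rowSums(lv[weak, , drop = FALSE]^2))
    still <- weak
    still[weak] <- ln[weak] < 1e-8
    if (any(still)) { lv[still, ] <- c(1, 0, 0); ln[still] <- 1 }
  }
  lh <- lv / ln
  ch <- cbind(lh[, 2] * mh[, 3] - lh[, 3] * mh[, 2],
              lh[, 3] * mh[, 1] - lh[, 1] * mh[, 3],
              lh[, 1] * mh[, 2] - lh[, 2] * mh[, 1])
  rho_e <- rowMeans(matrix(rho_node[mesh$tets], ncol = 4L))
  al <- (alpha_endo + (alpha_epi - alpha_endo) * rho_e) * pi / 180
  f <- cos(al) * ch + sin(al) * lh
  mesh$fibre <- f / sqrt(rowSums(f^2))
  if (!is.null(mesh$build)) {
    mesh$build$alpha_endo <- alpha_endo
    mesh$build$alpha_epi <- alpha_epi
  }
  mesh
}

#' Helix angle of the current fibre field
#'
#' Diagnostic: the signed angle (degrees) between each element fibre and
#' the local circumferential direction, positive towards the base.
#'
#' @inheritParams assign_rule_based_fibres
#' @return Numeric vector of helix angles per element, degrees.
#' @export
fibre_helix_angles <- function(mesh, coords) {
  m <- nrow(mesh$tets)
  lv_rows <- mesh$region == "LV_WALL"
  grad_rho <- matrix(NA_real_, m, 3)
  grad_rho[lv_rows, ] <- element_gradient(mesh, coords$rho_lv,
                                          elements = which(lv_rows))
  if (any(!lv_rows)) {
    grad_rho[!lv_rows, ] <- element_gradient(mesh, coords$rho_rv,
                                             elements = which(!lv_rows))
  }
  mh <- grad_rho / sqrt(rowSums(grad_rho^2))
  gz <- element_gradient(mesh, coords$z)
  lv <- gz - rowSums(gz * mh) * mh
  lh <- lv / sqrt(rowSums(lv^2))
  ch <- cbind(lh[, 2] * mh[, 3] - lh[, 3] * mh[, 2],
              lh[, 3] * mh[, 1] - lh[, 1] * mh[, 3],
              lh[, 1] * mh[, 2] - lh[, 2] * mh[, 1])
  atan2(rowSums(mesh$fibre * lh), rowSums(mesh$fibre * ch)) * 180 / pi
}

#' Multipoint-pacing gain ratio
#'
#' The factor by which optimal two-electrode pacing multiplies the AT090
#' reduction of conventional single-electrode pacing. Callable either on
#' two summary means or on a campaign (mean over subjects of the best
#' two-electrode reduction at the best vein, against the mean
#' single-electrode reduction).
#'
#' @param two_electrode_reduction_pct Mean AT090 reduction (%) of optimal
#'   two-electrode pacing, or a `crt_campaign`.
#' @param single_electrode_reduction_pct Mean AT090 reduction (%) of
#'   single-electrode pacing (ignored when a campaign is given).
#' @param cohort Cohort filter when a campaign is given.
#' @return The ratio (dimensionless).
#' @export
mpp_gain_ratio <- function(two_electrode_reduction_pct,
                           single_electrode_reduction_pct = NULL,
                           cohort = NULL) {
  if (inherits(two_electrode_reduction_pct, "crt_campaign")) {
    campaign <- two_electrode_reduction_pct
    rec <- campaign$records
    if (!is.null(cohort)) rec <- rec[rec$cohort %in% cohort, ]
    subjects <- unique(rec$subject)
    best2 <- vapply(subjects, function(s) {
      bv <- patient_optimal(campaign, s)$vein
      rs <- rec[rec$subject == s & rec$vein == bv & rec$n_active == 2, ]
      max(rs$at090_reduction_pct)
    }, 0)
    single <- rec$at090_reduction_pct[rec$n_active == 1]
    return(mean(best2) / mean(single))
  }
  if (single_electrode_reduction_pct <= 0) {
    abort("single-electrode reduction must be positive", class = "quadlead_argument_error")
  }
  two_electrode_reduction_pct / single_electrode_reduction_pct
}
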