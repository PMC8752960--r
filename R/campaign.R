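# Synchrony metrics (TAT, AT090), RV-pacing baselines, and the full
# subjects x veins x configurations simulation campaign assembling the
# response matrix.

element_activation_times <- function(map, mesh) {
  rowMeans(matrix(unclass(map)[mesh$tets], ncol = 4L))
}

check_reached <- function(map, mesh, active) {
  act_nodes <- unique(as.vector(mesh$tets[active, , drop = FALSE]))
  bad <- act_nodes[!is.finite(unclass(map)[act_nodes])]
  if (length(bad)) {
    abort(sprintf("activation did not reach %d active-tissue node(s): %s%s",
                  length(bad), paste(head(bad, 10), collapse = ", "),
                  if (length(bad) > 10) ", ..." else ""),
          class = "quadlead_unreached_error")
  }
}

#' Total activation time
#'
#' Maximum activation time over the nodes of active (non-scar) myocardium;
#' the simulated surrogate for QRS duration.
#'
#' @param map An `activation_map`.
#' @param mesh The mesh it was computed on.
#' @return TAT in ms.
#' @export
compute_tat <- function(map, mesh) {
  active <- attr(map, "active") %||% rep(TRUE, nrow(mesh$tets))
  check_reached(map, mesh, active)
  act_nodes <- unique(as.vector(mesh$tets[active, , drop = FALSE]))
  max(unclass(map)[act_nodes])
}

# volume-weighted activation quantile over element times
at090_from_elements <- function(times, volumes, fraction = 0.9) {
  stopifnot(length(times) == length(volumes), all(volumes > 0))
  o <- order(times)
  cum <- cumsum(volumes[o])
  times[o][which(cum >= fraction * sum(volumes))[1]]
}

#' Time to activate 90% of the myocardial volume
#'
#' The smallest time `t` such that the summed volume of active elements
#' with element activation time `<= t` reaches 90% of the total active
#' myocardial volume. Element activation time is the mean of its four node
#' times (the unbiased volume-CDF estimate; see the methods vignette).
#'
#' @inheritParams compute_tat
#' @param fraction Activated volume fraction (0.9).
#' @return AT090 in ms.
#' @export
compute_at090 <- function(map, mesh, fraction = 0.9) {
  active <- attr(map, "active") %||% rep(TRUE, nrow(mesh$tets))
  check_reached(map, mesh, active)
  et <- element_activation_times(map, mesh)
  at090_from_elements(et[active], mesh$volume[active], fraction)
}

synchrony_metrics <- function(map, mesh) {
  tibble(tat_ms = compute_tat(map, mesh), at090_ms = compute_at090(map, mesh))
}

#' Reduction of paced metrics against the RV-pacing baseline
#'
#' Positive reductions mean improvement; worsening keeps its negative sign.
#' Percent reductions are `100 * (baseline - paced) / baseline`.
#'
#' @param baseline,paced One-row tibbles with `tat_ms` and `at090_ms`.
#' @return The `paced` row extended with `tat_reduction_ms`,
#'   `tat_reduction_pct`, `at090_reduction_ms`, `at090_reduction_pct`.
#' @export
compute_reduction <- function(baseline, paced) {
  if (baseline$tat_ms <= 0 || baseline$at090_ms <= 0) {
    abort("baseline activation times must be positive", class = "quadlead_argument_error")
  }
  mutate(paced,
         tat_reduction_ms = baseline$tat_ms - tat_ms,
         tat_reduction_pct = 100 * (baseline$tat_ms - tat_ms) / baseline$tat_ms,
         at090_reduction_ms = baseline$at090_ms - at090_ms,
         at090_reduction_pct = 100 * (baseline$at090_ms - at090_ms) / baseline$at090_ms)
}

#' Run the RV-pacing baseline simulation
#'
#' Pacing from the RV electrode alone approximates left-bundle-branch-block
#' activation and serves as the reference for every paced configuration.
#'
#' @param mesh A `ventricular_mesh`.
#' @param field A [build_velocity_field()] result.
#' @param rv_node RV electrode node.
#' @return List with the `activation_map` and a one-row `metrics` tibble.
#' @export
run_baseline <- function(mesh, field, rv_node) {
  map <- solve_eikonal(mesh, field, rv_node)
  list(map = map, metrics = synchrony_metrics(map, mesh))
}

#' Prepare a subject for the pacing campaign
#'
#' Computes coordinates, the AHA map, wall thickness, the five vein leads
#' and the RV electrode sites for one anatomy.
#'
#' @param mesh A `ventricular_mesh`.
#' @param id Subject identifier.
#' @param cohort Cohort label (`"HF"`/`"RR"`).
#' @param veins Vein tracks to prepare.
#' @param n_electrodes,spacing Lead geometry (8 electrodes, 7.5 mm).
#' @param basal_z Apicobasal coordinate of the most basal electrode.
#' @return A `crt_subject` list.
#' @export
prepare_subject <- function(mesh, id, cohort = "HF", veins = vein_names(),
                            n_electrodes = 8, spacing = 7.5, basal_z = 0.8) {
  coords <- compute_uvc(mesh)
  aha <- map_aha17(coords)
  thickness <- compute_wall_thickness(mesh, coords)
  leads <- lapply(veins, function(v) {
    line <- locate_vein_line(mesh, coords, v, basal_z = basal_z,
                             min_length = (n_electrodes - 1) * spacing)
    place_electrodes(mesh, line, n = n_electrodes, spacing = spacing)
  })
  names(leads) <- veins
  structure(list(id = id, cohort = cohort, mesh = mesh, coords = coords,
                 aha = aha, thickness = thickness, leads = leads,
                 rv_apex = place_rv_electrode(mesh, coords, "APEX"),
                 rv_septal = place_rv_electrode(mesh, coords, "SEPTAL_MID")),
            class = "crt_subject")
}

#' @export
print.crt_subject <- function(x, ...) {
  cat(sprintf("<crt_subject> %s (%s): %d tets, veins %s\n", x$id, x$cohort,
              nrow(x$mesh$tets), paste(names(x$leads), collapse = ",")))
  invisible(x)
}

subject_field <- function(subject, params) {
  fec <- mark_fec_layer(subject$mesh, subject$coords, params$fec_extent)
  scar <- if (is.null(params$scar_threshold)) NULL else
    mark_scar(subject$thickness, params$scar_threshold)
  build_velocity_field(subject$mesh, params, fec, scar)
}

#' Run the pacing campaign over a cohort
#'
#' For every subject, solves the RV-only baseline and then every requested
#' pacing configuration in every requested vein (each configuration fires
#' its LV electrode(s) simultaneously with the RV electrode at onset 0),
#' scoring TAT and AT090 and their reductions against the subject's
#' baseline. The result is the tidy response matrix that feeds design
#' optimization, clustering and statistics. Deterministic given its inputs.
#'
#' @param subjects List of [prepare_subject()] objects.
#' @param params [conduction_parameters()] used for every subject.
#' @param veins Vein tracks to pace.
#' @param rv_site `"APEX"` (default) or `"SEPTAL_MID"`.
#' @param configurations Configuration names to run (default: all 36).
#' @return A `crt_campaign`: list with `records` (one row per subject x
#'   vein x configuration), `baselines` (one row per subject) and `meta`.
#' @export
run_campaign <- function(subjects, params = conduction_parameters(),
                         veins = vein_names(), rv_site = "APEX",
                         configurations = NULL) {
  stopifnot(all(vapply(subjects, inherits, TRUE, "crt_subject")))
  rec <- list(); bas <- list()
  n_solves <- 0L
  for (s in subjects) {
    if (!all(veins %in% names(s$leads))) {
      abort(sprintf("subject %s is missing lead(s): %s", s$id,
                    paste(setdiff(veins, names(s$leads)), collapse = ", ")))
    }
    field <- subject_field(s, params)
    rv_node <- if (rv_site == "APEX") s$rv_apex else s$rv_septal
    # one single-source solve per distinct electrode node; every pacing
    # configuration is then the exact pointwise minimum of its fronts
    cache <- new.env(parent = emptyenv())
    check_sources_active(s$mesh, field, tibble(node = rv_node, onset = 0))
    t_rv <- cached_single_solve(s$mesh, field, rv_node, cache)
    base_map <- structure(t_rv, class = "activation_map",
                          sources = tibble(node = rv_node, onset = 0),
                          active = field$active)
    base <- list(map = base_map, metrics = synchrony_metrics(base_map, s$mesh))
    bas[[length(bas) + 1L]] <- mutate(base$metrics, cohort = s$cohort,
                                      subject = s$id, .before = 1)
    for (v in veins) {
      cfgs <- enumerate_configurations(s$leads[[v]], rv_node)
      if (!is.null(configurations)) cfgs <- cfgs[cfgs$config %in% configurations, ]
      el_nodes <- unique(unlist(cfgs$lv_nodes))
      check_sources_active(s$mesh, field, tibble(node = el_nodes, onset = 0))
      for (i in seq_len(nrow(cfgs))) {
        fronts <- lapply(cfgs$lv_nodes[[i]], function(nd)
          cached_single_solve(s$mesh, field, nd, cache))
        t_cfg <- do.call(pmin, c(list(t_rv), fronts))
        map <- structure(t_cfg, class = "activation_map",
                         sources = tibble(node = c(cfgs$lv_nodes[[i]], rv_node),
                                          onset = 0),
                         active = field$active)
        met <- compute_reduction(base$metrics, synchrony_metrics(map, s$mesh))
        rec[[length(rec) + 1L]] <- mutate(met, cohort = s$cohort, subject = s$id,
                                          vein = v, config = cfgs$config[i],
                                          n_active = cfgs$n_active[i], .before = 1)
      }
    }
    n_solves <- n_solves + length(ls(cache))
  }
  structure(list(records = bind_rows(rec), baselines = bind_rows(bas),
                 meta = list(params = params, veins = veins, rv_site = rv_site,
                             n_solves = n_solves,
                             n_subjects = length(subjects),
                             params_hash = rlang::hash(list(params, veins, rv_site,
                                                            configurations)))),
            class = "crt_campaign")
}

#' @export
print.crt_campaign <- function(x, ...) {
  cat(sprintf("<crt_campaign> %d subjects, %d records (%d solves), rv %s\n",
              x$meta$n_subjects, nrow(x$records), x$meta$n_solves, x$meta$rv_site))
  invisible(x)
}

#' @export
glance.crt_campaign <- function(x, ...) {
  tibble(n_subjects = x$meta$n_subjects,
         n_records = nrow(x$records),
         n_veins = length(x$meta$veins),
         mean_baseline_tat_ms = mean(x$baselines$tat_ms),
         mean_at090_reduction_pct = mean(x$records$at090_reduction_pct),
         mean_tat_reduction_pct = mean(x$records$tat_reduction_pct))
}

#' Design-level response table
#'
#' Evaluates each 4-electrode lead design by table lookup over its 10
#' admissible configurations: the design-level response of a subject in a
#' vein is the best AT090 reduction among the configurations the design
#' can deliver. Identical to simulating each design separately, at a
#' fraction of the cost.
#'
#' @param campaign A [run_campaign()] result.
#' @return Tibble with one row per subject x vein x design: the best
#'   configuration and its reductions.
#' @export
evaluate_designs <- function(campaign) {
  stopifnot(inherits(campaign, "crt_campaign"))
  map <- config_design_map()
  campaign$records |>
    dplyr::inner_join(map, by = "config", relationship = "many-to-many") |>
    group_by(cohort, subject, vein, design) |>
    arrange(desc(at090_reduction_pct), config, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(cohort, subject, vein, design, best_config = config,
           at090_reduction_ms, at090_reduction_pct,
           tat_reduction_ms, tat_reduction_pct)
}
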