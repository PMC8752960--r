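# One-at-a-time sensitivity campaign: each scenario perturbs exactly one
# model ingredient away from the literature baseline and repeats the full
# campaign and design optimization.

#' The one-at-a-time sensitivity grid
#'
#' Eleven scenarios, each differing from the baseline in exactly one
#' ingredient: FEC extent 0.70 and 1.00 (whole endocardium); fibre velocity
#' 0.07 and 0.8 mm/ms; cross-fibre ratio 0.29 and 1; FEC multiplier 7 and
#' 10; RV pacing moved to the septal mid-wall; and thickness-based scar at
#' 5 mm and 6 mm.
#'
#' @return Tibble with columns `scenario`, `parameter`, `value`.
#' @export
oat_scenarios <- function() {
  tibble(
    parameter = c("fec_extent", "fec_extent", "cv_fibre", "cv_fibre",
                  "k_xf", "k_xf", "k_fec", "k_fec",
                  "rv_site", "scar_threshold", "scar_threshold"),
    value = c(0.70, 1.00, 0.07, 0.8, 0.29, 1, 7, 10, NA, 5, 6)) |>
    mutate(scenario = ifelse(parameter == "rv_site", "rv_site_SEPTAL_MID",
                             paste0(parameter, "_", value)),
           .before = 1)
}

# apply a one-parameter override; errors if it would not be one-at-a-time
scenario_settings <- function(base_params, parameter, value,
                              base_rv_site = "APEX") {
  fields <- c("cv_fibre", "k_xf", "k_fec", "fec_extent", "scar_threshold")
  if (parameter == "rv_site") {
    if (base_rv_site == "SEPTAL_MID") {
      abort("scenario does not differ from the baseline RV site",
            class = "quadlead_config_error")
    }
    return(list(params = base_params, rv_site = "SEPTAL_MID"))
  }
  if (!parameter %in% fields) {
    abort(sprintf("unknown sensitivity parameter '%s'", parameter),
          class = "quadlead_config_error")
  }
  current <- base_params[[parameter]]
  if (!is.null(current) && !is.na(value) && isTRUE(all.equal(current, value))) {
    abort(sprintf("scenario value for %s equals the baseline: not one-at-a-time",
                  parameter),
          class = "quadlead_config_error")
  }
  p <- unclass(base_params)
  p[[parameter]] <- value
  list(params = do.call(conduction_parameters, p), rv_site = base_rv_site)
}

#' Run the one-at-a-time sensitivity campaign
#'
#' Repeats the pacing campaign and the cohort-level design optimization for
#' each scenario, keeping every other ingredient at baseline. The baseline
#' campaign itself is included as scenario `"baseline"`.
#'
#' @param subjects List of [prepare_subject()] objects.
#' @param base_params Baseline [conduction_parameters()].
#' @param scenarios Scenario grid, by default [oat_scenarios()].
#' @param veins Vein tracks to pace.
#' @param keep_campaigns Keep the per-scenario campaign objects (memory
#'   permitting).
#' @return A `crt_sensitivity` object with a `summary` tibble (scenario,
#'   parameter, value, mean reductions, primary design) and optionally the
#'   campaigns.
#' @export
run_oat_sensitivity <- function(subjects, base_params = conduction_parameters(),
                                scenarios = oat_scenarios(),
                                veins = vein_names(),
                                keep_campaigns = FALSE) {
  run_one <- function(scenario, params, rv_site) {
    cam <- run_campaign(subjects, params, veins = veins, rv_site = rv_site)
    sel <- cohort_optimal(cam)
    list(campaign = cam,
         row = tibble(scenario = scenario,
                      mean_baseline_tat_ms = mean(cam$baselines$tat_ms),
                      mean_at090_reduction_pct = mean(cam$records$at090_reduction_pct),
                      mean_tat_reduction_pct = mean(cam$records$tat_reduction_pct),
                      primary_design = sel$primary_design,
                      n_chosen_designs = length(sel$chosen_designs)))
  }
  base <- run_one("baseline", base_params, "APEX")
  rows <- list(mutate(base$row, parameter = "none", value = NA_real_, .after = 1))
  campaigns <- list(baseline = if (keep_campaigns) base$campaign)
  for (i in seq_len(nrow(scenarios))) {
    st <- scenario_settings(base_params, scenarios$parameter[i], scenarios$value[i])
    res <- run_one(scenarios$scenario[i], st$params, st$rv_site)
    rows[[length(rows) + 1L]] <- mutate(res$row, parameter = scenarios$parameter[i],
                                        value = scenarios$value[i], .after = 1)
    if (keep_campaigns) campaigns[[scenarios$scenario[i]]] <- res$campaign
  }
  structure(list(summary = bind_rows(rows),
                 campaigns = if (keep_campaigns) campaigns,
                 base_params = base_params, veins = veins),
            class = "crt_sensitivity")
}

#' @export
print.crt_sensitivity <- function(x, ...) {
  cat(sprintf("<crt_sensitivity> %d scenario(s) + baseline over veins %s\n",
              nrow(x$summary) - 1L, paste(x$veins, collapse = ",")))
  invisible(x)
}

#' @export
tidy.crt_sensitivity <- function(x, ...) x$summary
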