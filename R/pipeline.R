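# End-to-end orchestration: configuration, validation, cohort generation,
# campaign, optimization, statistics, optional sensitivity, and artifact
# output with provenance.

#' Build a run configuration
#'
#' All arguments have defaults describing a small but complete virtual
#' trial. The configuration round-trips through YAML/JSON
#' ([read_run_config()]) and its hash is recorded in every output manifest.
#'
#' @param hf_subjects,rr_subjects Cohort sizes.
#' @param target_edge_length Mesh resolution, mm.
#' @param shape_cv Morphological coefficient of variation.
#' @param veins Vein tracks to pace.
#' @param n_electrodes,spacing,basal_z Lead geometry.
#' @param conduction Named list of [conduction_parameters()] arguments.
#' @param rv_site Baseline RV pacing site.
#' @param seed Global seed.
#' @param sensitivity `FALSE`, `TRUE` (full grid) or a character vector of
#'   [oat_scenarios()] names.
#' @param clustering Named list: `vein`, `k`.
#' @param output_dir Directory for artifacts, or `NULL` to skip writing.
#' @param write_meshes Also write per-subject VTU meshes with coordinates
#'   and baseline activation.
#' @return A `run_configuration` list.
#' @export
pipeline_config <- function(hf_subjects = 2, rr_subjects = 2,
                            target_edge_length = 8, shape_cv = 0.1,
                            veins = vein_names(),
                            n_electrodes = 8, spacing = 7.5, basal_z = 0.8,
                            conduction = list(), rv_site = "APEX",
                            seed = 1L, sensitivity = FALSE,
                            clustering = list(vein = "LA", k = 4),
                            output_dir = NULL, write_meshes = FALSE) {
  cfg <- list(hf_subjects = hf_subjects, rr_subjects = rr_subjects,
              target_edge_length = target_edge_length, shape_cv = shape_cv,
              veins = veins, n_electrodes = n_electrodes, spacing = spacing,
              basal_z = basal_z, conduction = conduction, rv_site = rv_site,
              seed = as.integer(seed), sensitivity = sensitivity,
              clustering = clustering, output_dir = output_dir,
              write_meshes = write_meshes)
  class(cfg) <- "run_configuration"
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Fails before any computation, naming the offending key.
#'
#' @param config A `run_configuration` or plain named list.
#' @return The validated `run_configuration`.
#' @export
validate_run_config <- function(config) {
  cfg <- unclass(config)
  bad_vein <- setdiff(cfg$veins, vein_names())
  if (length(bad_vein)) {
    abort(sprintf("config key `veins`: unknown vein name(s) %s",
                  paste(sprintf('"%s"', bad_vein), collapse = ", ")),
          class = "quadlead_config_error")
  }
  if (!is.numeric(cfg$hf_subjects) || !is.numeric(cfg$rr_subjects) ||
      cfg$hf_subjects < 0 || cfg$rr_subjects < 0 ||
      cfg$hf_subjects + cfg$rr_subjects < 1) {
    abort("config keys `hf_subjects`/`rr_subjects`: need at least one subject",
          class = "quadlead_config_error")
  }
  if (!cfg$rv_site %in% c("APEX", "SEPTAL_MID")) {
    abort("config key `rv_site`: must be APEX or SEPTAL_MID",
          class = "quadlead_config_error")
  }
  if (!is.null(cfg$clustering$vein) && !cfg$clustering$vein %in% cfg$veins) {
    abort("config key `clustering$vein`: not among the campaign veins",
          class = "quadlead_config_error")
  }
  if (is.character(cfg$sensitivity)) {
    bad <- setdiff(cfg$sensitivity, oat_scenarios()$scenario)
    if (length(bad)) {
      abort(sprintf("config key `sensitivity`: unknown scenario(s) %s",
                    paste(bad, collapse = ", ")),
            class = "quadlead_config_error")
    }
  }
  do.call(conduction_parameters, cfg$conduction)  # validates conduction keys
  structure(cfg, class = "run_configuration")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A validated `run_configuration`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- pipeline_config()
  keep <- intersect(names(raw), names(unclass(defaults)))
  unknown <- setdiff(names(raw), names(unclass(defaults)))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "quadlead_config_error")
  }
  cfg <- utils::modifyList(unclass(defaults), raw[keep])
  # a custom vein list with the default clustering block: follow the veins
  if (!"clustering" %in% names(raw) &&
      !is.null(cfg$clustering$vein) && !cfg$clustering$vein %in% cfg$veins) {
    cfg$clustering$vein <- cfg$veins[1]
  }
  validate_run_config(structure(cfg, class = "run_configuration"))
}

#' Run the full virtual-trial pipeline
#'
#' Generates the synthetic HF and RR cohorts, prepares coordinates and
#' leads, runs the pacing campaign, selects patient- and cohort-based
#' optimal designs, applies each cohort's primary design to the other
#' cohort, runs the statistics block, clusters responses, and (optionally)
#' the one-at-a-time sensitivity grid. Every artifact carries the
#' configuration hash and seed; rerunning an identical configuration
#' reproduces the outputs.
#'
#' @param config A [pipeline_config()] result (or validated list).
#' @return A `crt_trial` object with the campaign, selections, statistics,
#'   clustering, sensitivity summary, manifest, and paths of any files
#'   written.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- validate_run_config(config)
  cfg_hash <- rlang::hash(unclass(cfg))
  params <- do.call(conduction_parameters, cfg$conduction)

  cohorts <- list()
  if (cfg$hf_subjects > 0) {
    cohorts$HF <- sample_cohort(cohort_specification(
      cfg$hf_subjects, "HF",
      shape_mean = hf_shape_defaults(cfg$target_edge_length),
      shape_cv = cfg$shape_cv, random_seed = cfg$seed))
  }
  if (cfg$rr_subjects > 0) {
    cohorts$RR <- sample_cohort(cohort_specification(
      cfg$rr_subjects, "RR",
      shape_mean = rr_shape_defaults(cfg$target_edge_length),
      shape_cv = cfg$shape_cv, random_seed = cfg$seed + 1L))
  }
  subjects <- list()
  for (ct in names(cohorts)) {
    for (id in names(cohorts[[ct]])) {
      subjects[[id]] <- prepare_subject(cohorts[[ct]][[id]], id, ct,
                                        veins = cfg$veins,
                                        n_electrodes = cfg$n_electrodes,
                                        spacing = cfg$spacing,
                                        basal_z = cfg$basal_z)
    }
  }

  campaign <- run_campaign(subjects, params, veins = cfg$veins,
                           rv_site = cfg$rv_site)

  present <- unique(campaign$records$cohort)
  selections <- lapply(present, function(ct) cohort_optimal(campaign, ct))
  names(selections) <- present
  if (length(present) > 1) selections[["RR+HF"]] <- cohort_optimal(campaign)

  cross_eval <- list()
  if (all(c("HF", "RR") %in% present)) {
    cross_eval$rr_design_in_hf <-
      cross_cohort_evaluate(campaign, selections$RR$primary_design, "HF")
    cross_eval$hf_design_in_rr <-
      cross_cohort_evaluate(campaign, selections$HF$primary_design, "RR")
  }

  stats_block <- trial_statistics(campaign, selections, cross_eval)

  clustering <- NULL
  if (!is.null(cfg$clustering$vein) &&
      length(unique(campaign$records$subject)) >= 2) {
    clustering <- hac_cluster(campaign, "subjects", vein = cfg$clustering$vein,
                              k = cfg$clustering$k %||% 4)
  }

  sens <- NULL
  if (!isFALSE(cfg$sensitivity)) {
    scen <- oat_scenarios()
    if (is.character(cfg$sensitivity)) {
      scen <- scen[scen$scenario %in% cfg$sensitivity, ]
    }
    sens <- run_oat_sensitivity(subjects, params, scenarios = scen,
                                veins = cfg$veins)
  }

  manifest <- list(config_hash = cfg_hash, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("quadlead")),
                   n_subjects = length(subjects),
                   n_records = nrow(campaign$records),
                   n_solves = campaign$meta$n_solves,
                   veins = cfg$veins,
                   design_evaluations = count_design_evaluations(
                     70, length(cfg$veins), length(subjects)))

  trial <- structure(
    list(config = cfg, campaign = campaign, selections = selections,
         cross_eval = cross_eval, statistics = stats_block,
         clustering = clustering, sensitivity = sens,
         subjects = subjects, cohorts = cohorts, manifest = manifest,
         paths = NULL),
    class = "crt_trial")

  if (!is.null(cfg$output_dir)) trial$paths <- write_trial(trial, cfg$output_dir)
  trial
}

# the statistics block of a trial: effect sizes always accompany p-values
trial_statistics <- function(campaign, selections, cross_eval) {
  out <- list()
  for (ct in unique(campaign$records$cohort)) {
    vals <- campaign$records$at090_reduction_pct[campaign$records$cohort == ct]
    out[[paste0("reduction_gt0_", ct)]] <-
      tryCatch(wilcoxon_signed_rank(vals), error = function(e) NULL)
  }
  if (all(c("HF", "RR") %in% campaign$records$cohort)) {
    hf <- campaign$records$at090_reduction_pct[campaign$records$cohort == "HF"]
    rr <- campaign$records$at090_reduction_pct[campaign$records$cohort == "RR"]
    out$hf_vs_rr <- mann_whitney(hf, rr)
  }
  for (nm in names(cross_eval)) {
    ct <- unique(cross_eval[[nm]]$cohort)
    pers <- selections[[ct]]$per_subject_best$at090_reduction_pct
    out[[paste0("personalised_vs_", nm)]] <-
      mann_whitney(pers, cross_eval[[nm]]$at090_reduction_pct)
  }
  ps <- vapply(out, function(t) if (is.null(t)) NA_real_ else t$p_value, 0)
  keep <- !is.na(ps)
  adj <- bonferroni(ps[keep])
  list(tests = out[keep],
       table = bind_rows(lapply(out[keep], tidy), .id = "comparison") |>
         mutate(p_adjusted = adj, significant = adj < 0.01))
}

#' @export
print.crt_trial <- function(x, ...) {
  cat(sprintf("<crt_trial> %d subjects, %d records; primary designs: %s\n",
              x$manifest$n_subjects, x$manifest$n_records,
              paste(sprintf("%s=%s", names(x$selections),
                            vapply(x$selections, function(s) s$primary_design, "")),
                    collapse = ", ")))
  invisible(x)
}

#' @export
glance.crt_trial <- function(x, ...) {
  g <- glance(x$campaign)
  mutate(g, config_hash = x$manifest$config_hash, seed = x$manifest$seed)
}

# write the artifact set; returns the named file paths
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list()
  stamp <- function(df) mutate(df, config_hash = trial$manifest$config_hash)
  p$records <- file.path(dir, "response_records.csv")
  utils::write.csv(stamp(trial$campaign$records), p$records, row.names = FALSE)
  p$baselines <- file.path(dir, "baselines.csv")
  utils::write.csv(stamp(trial$campaign$baselines), p$baselines, row.names = FALSE)
  p$designs <- file.path(dir, "design_responses.csv")
  utils::write.csv(stamp(evaluate_designs(trial$campaign)), p$designs, row.names = FALSE)
  p$selections <- file.path(dir, "selections.json")
  jsonlite::write_json(
    lapply(trial$selections, function(s) list(
      cohort = s$cohort, primary_design = s$primary_design,
      chosen_designs = s$chosen_designs,
      coverage = s$coverage[s$chosen_designs])),
    p$selections, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  p$statistics <- file.path(dir, "statistics.json")
  jsonlite::write_json(trial$statistics$table, p$statistics,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(trial$sensitivity)) {
    p$sensitivity <- file.path(dir, "sensitivity.csv")
    utils::write.csv(stamp(trial$sensitivity$summary), p$sensitivity,
                     row.names = FALSE)
  }
  p$manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(trial$manifest, p$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (isTRUE(trial$config$write_meshes)) {
    for (id in names(trial$subjects)) {
      s <- trial$subjects[[id]]
      p[[paste0("mesh_", id)]] <- file.path(dir, paste0(id, ".vtu"))
      write_vtu(s$mesh, p[[paste0("mesh_", id)]],
                point_data = list(z = s$coords$z, rho = s$coords$rho,
                                  phi = s$coords$phi,
                                  segment = ifelse(is.na(s$aha), 0, s$aha)),
                cell_data = list(thickness_mm = s$thickness))
    }
  }
  p
}
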