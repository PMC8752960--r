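# Shared fixtures, memoized per test run. Meshes are coarse (9-10 mm
# edges) so the whole suite stays fast; resolution-sensitive checks build
# their own finer meshes locally.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

coarse_hf_mesh <- function() fixture("hf_mesh", function() {
  generate_biventricular_mesh(hf_shape_defaults(target_edge_length = 9), seed = 11)
})

coarse_hf_uvc <- function() fixture("hf_uvc", function() compute_uvc(coarse_hf_mesh()))

coarse_subjects <- function() fixture("subjects", function() {
  hf <- generate_biventricular_mesh(hf_shape_defaults(9), seed = 11)
  rr <- generate_biventricular_mesh(rr_shape_defaults(9), seed = 12)
  list(prepare_subject(hf, "HF01", "HF"), prepare_subject(rr, "RR01", "RR"))
})

tiny_campaign <- function() fixture("campaign", function() {
  run_campaign(coarse_subjects(), veins = c("LA", "AN"))
})

# a borderline-walled heart for scar scenarios (wall 6.4 mm: a 6 mm
# threshold marks a patchy thin minority, a 5 mm threshold marks nothing,
# and the free wall stays conductive enough to pace)
thin_wall_subject <- function() fixture("thin_subject", function() {
  p <- shape_parameters(lv_long_axis = 61.4, lv_endo_radius = 27.9,
                        lv_wall_thickness = 6.4, rv_wall_thickness = 4,
                        rv_lateral_extent = 18, target_edge_length = 9)
  prepare_subject(generate_biventricular_mesh(p, seed = 21), "TH01", "HF")
})

# wrap hand-made records into a minimal campaign object for the
# optimization layer (which reads only $records)
fake_campaign <- function(records) {
  structure(list(records = records,
                 baselines = NULL,
                 meta = list(n_subjects = length(unique(records$subject)),
                             n_solves = 0L, veins = unique(records$vein),
                             rv_site = "APEX")),
            class = "crt_campaign")
}

# full response grid for synthetic optimization scenarios: every subject x
# vein x configuration, with chosen configurations boosted per subject
synthetic_records <- function(best_configs, base = 5, boost = 10, veins = "LA") {
  cfgs <- c(letters[1:8],
            apply(utils::combn(letters[1:8], 2), 2, paste, collapse = ""))
  rows <- list()
  for (s in names(best_configs)) {
    for (v in veins) {
      red <- base + 0.01 * seq_along(cfgs)          # distinct, low
      red[match(best_configs[[s]], cfgs)] <- boost  # subject's optima
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cohort = "HF", subject = s, vein = v, config = cfgs,
        n_active = nchar(cfgs),
        tat_ms = 100, at090_ms = 90,
        tat_reduction_ms = 0, tat_reduction_pct = 0,
        at090_reduction_ms = red, at090_reduction_pct = red)
    }
  }
  dplyr::bind_rows(rows)
}
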