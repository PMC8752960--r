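# Optimal lead design selection: per-patient argmax, cohort-level exact
# minimal set cover over the 70 quadripolar designs, hierarchical
# clustering of the response matrix, and cross-cohort design evaluation.

vein_order <- function() vein_names()

#' Patient-based optimal configuration
#'
#' The (vein, configuration) pair maximizing the AT090 percent reduction
#' for one subject. Ties break to the lexicographically smallest
#' configuration name, then the anatomical vein order IN, IL, LA, AL, AN.
#'
#' @param campaign A [run_campaign()] result.
#' @param subject Subject id.
#' @param scope `"best_vein"` (argmax over veins and configurations) or
#'   `"per_vein"` (one argmax per vein).
#' @return One-row (or one-row-per-vein) tibble with the winning vein,
#'   configuration and reductions.
#' @export
patient_optimal <- function(campaign, subject, scope = c("best_vein", "per_vein")) {
  scope <- match.arg(scope)
  stopifnot(inherits(campaign, "crt_campaign"))
  rec <- campaign$records[campaign$records$subject == subject, ]
  if (nrow(rec) == 0) {
    abort(sprintf("no campaign records for subject %s", subject),
          class = "quadlead_argument_error")
  }
  rec <- rec |>
    mutate(vein = factor(vein, levels = vein_order())) |>
    arrange(desc(at090_reduction_pct), config, vein)
  out <- if (scope == "best_vein") {
    rec[1, ]
  } else {
    rec |> group_by(vein) |> slice(1) |> ungroup()
  }
  out |>
    mutate(vein = as.character(vein)) |>
    select(cohort, subject, vein, config, at090_reduction_ms, at090_reduction_pct)
}

# designs (rows of enumerate_lead_designs()) covering each configuration set
designs_covering <- function(config_sets) {
  designs <- enumerate_lead_designs()
  lapply(config_sets, function(cfgs) {
    keep <- vapply(designs$electrodes, function(d) {
      any(vapply(cfgs, function(cf) all(strsplit(cf, "")[[1]] %in% d), TRUE))
    }, TRUE)
    designs$design[keep]
  })
}

# exact minimal set cover by incremental exhaustive search over cover sizes
exact_min_cover <- function(cover_sets, universe, max_size = 8L) {
  candidates <- sort(unique(unlist(cover_sets)))
  covered_by <- lapply(candidates, function(d) {
    universe[vapply(seq_along(universe), function(i) d %in% cover_sets[[i]], TRUE)]
  })
  names(covered_by) <- candidates
  for (k in seq_len(min(max_size, length(candidates)))) {
    combos <- combn(candidates, k, simplify = FALSE)
    for (cc in combos) {
      if (setequal(unique(unlist(covered_by[cc])), universe)) return(cc)
    }
  }
  abort("no design cover found within the size limit")
}

# greedy cover used as a cross-check only
greedy_cover <- function(cover_sets, universe) {
  chosen <- character(0)
  left <- universe
  candidates <- sort(unique(unlist(cover_sets)))
  while (length(left)) {
    gain <- vapply(candidates, function(d) {
      sum(vapply(seq_along(universe), function(i)
        universe[i] %in% left && d %in% cover_sets[[i]], TRUE))
    }, 0)
    best <- candidates[which.max(gain)]
    chosen <- c(chosen, best)
    left <- left[!vapply(match(left, universe), function(i) best %in% cover_sets[[i]], TRUE)]
  }
  chosen
}

#' Cohort-based optimal lead design selection
#'
#' Collects each subject's optimal configuration (at its best vein), then
#' chooses the minimum number of 4-electrode lead designs such that every
#' subject's optimal configuration is deliverable by some chosen design
#' (exact minimal set cover, found by exhaustive search over cover sizes 1,
#' 2, 3, ... across the 70 designs). The primary design is the single
#' design whose admissible configurations are optimal for the most
#' subjects, ties broken by lexicographic name.
#'
#' @param campaign A [run_campaign()] result.
#' @param cohort Cohort label(s) to include (`NULL` = all subjects).
#' @param epsilon Optimality tolerance in percent-reduction points:
#'   configurations within `epsilon` of a subject's maximum all count as
#'   optimal for that subject (default 0 = exact argmax).
#' @return A `crt_selection` object.
#' @export
cohort_optimal <- function(campaign, cohort = NULL, epsilon = 0) {
  stopifnot(inherits(campaign, "crt_campaign"))
  rec <- campaign$records
  if (!is.null(cohort)) rec <- rec[rec$cohort %in% cohort, ]
  if (nrow(rec) == 0) abort("empty cohort", class = "quadlead_argument_error")
  subjects <- sort(unique(rec$subject))
  best_rows <- bind_rows(lapply(subjects, function(s) patient_optimal(campaign, s)))
  best_rows <- best_rows[best_rows$subject %in% subjects, ]
  # per-subject optimal configuration set (within epsilon, at any vein)
  opt_sets <- lapply(subjects, function(s) {
    rs <- rec[rec$subject == s, ]
    sort(unique(rs$config[rs$at090_reduction_pct >= max(rs$at090_reduction_pct) - epsilon]))
  })
  cover_sets <- designs_covering(opt_sets)
  chosen <- exact_min_cover(cover_sets, subjects)
  designs <- enumerate_lead_designs()
  coverage <- lapply(seq_len(nrow(designs)), function(i) {
    subjects[vapply(seq_along(subjects), function(j)
      designs$design[i] %in% cover_sets[[j]], TRUE)]
  })
  names(coverage) <- designs$design
  n_cov <- lengths(coverage)
  primary <- names(coverage)[order(-n_cov, names(coverage))][1]
  structure(list(per_subject_best = best_rows,
                 optimal_config_sets = setNames(opt_sets, subjects),
                 chosen_designs = chosen,
                 primary_design = primary,
                 coverage = coverage,
                 cohort = cohort %||% "all", epsilon = epsilon),
            class = "crt_selection")
}

#' @export
print.crt_selection <- function(x, ...) {
  cat(sprintf("<crt_selection> cohort %s: primary design \"%s\", minimal cover {%s} (%d design(s))\n",
              paste(x$cohort, collapse = "+"), x$primary_design,
              paste(x$chosen_designs, collapse = ", "), length(x$chosen_designs)))
  invisible(x)
}

#' @describeIn cohort_optimal Tidy per-design coverage of a selection.
#' @param x A `crt_selection`.
#' @param ... Unused.
#' @export
tidy.crt_selection <- function(x, ...) {
  tibble(design = names(x$coverage),
         n_covered = lengths(x$coverage),
         chosen = names(x$coverage) %in% x$chosen_designs,
         primary = names(x$coverage) == x$primary_design) |>
    arrange(desc(n_covered), design)
}

#' @describeIn cohort_optimal One-row summary of a selection.
#' @export
glance.crt_selection <- function(x, ...) {
  tibble(cohort = paste(x$cohort, collapse = "+"),
         n_subjects = nrow(x$per_subject_best),
         n_chosen_designs = length(x$chosen_designs),
         primary_design = x$primary_design,
         primary_coverage = length(x$coverage[[x$primary_design]]),
         epsilon = x$epsilon)
}

#' Hierarchical clustering of the response matrix
#'
#' Agglomerative clustering with Euclidean distances and the Ward
#' criterion in its distance-input ("Ward2", Murtagh-Legendre) form, of
#' either the subjects (rows = subjects, features = configurations) or the
#' configurations, using the AT090 percent reductions of one vein.
#'
#' @param campaign A [run_campaign()] result.
#' @param axis Cluster `"subjects"` or `"configurations"`.
#' @param vein Vein whose response sub-matrix is clustered.
#' @param k Number of clusters for the reported labels.
#' @return A `crt_hac` object: the merge tree, per-item labels at `k`, and
#'   the underlying `hclust` fit.
#' @export
hac_cluster <- function(campaign, axis = c("subjects", "configurations"),
                        vein = "LA", k = 4) {
  axis <- match.arg(axis)
  stopifnot(inherits(campaign, "crt_campaign"))
  rec <- campaign$records[campaign$records$vein == vein, ]
  if (nrow(rec) == 0) abort(sprintf("no records for vein %s", vein))
  wide <- rec |>
    select(subject, config, at090_reduction_pct) |>
    tidyr::pivot_wider(names_from = config, values_from = at090_reduction_pct) |>
    arrange(subject)
  X <- as.matrix(wide[, -1])
  rownames(X) <- wide$subject
  if (axis == "configurations") X <- t(X)
  if (nrow(X) < 2) abort("need at least two items to cluster",
                         class = "quadlead_argument_error")
  hc <- hclust(dist(X), method = "ward.D2")
  k <- min(k, nrow(X))
  merge_tree <- tibble(step = seq_len(nrow(hc$merge)),
                       i = hc$merge[, 1], j = hc$merge[, 2],
                       height = hc$height,
                       size = vapply(seq_len(nrow(hc$merge)), function(s) {
                         length(unlist(cut_members(hc$merge, s)))
                       }, 0L))
  structure(list(merge_tree = merge_tree,
                 labels_at_k = cutree(hc, k = k),
                 k = k, axis = axis, vein = vein, hclust = hc,
                 items = rownames(X)),
            class = "crt_hac")
}

# members (negative singleton indices resolved) of the cluster formed at step s
cut_members <- function(merge, s) {
  lapply(merge[s, ], function(ix) {
    if (ix < 0) -ix else unlist(cut_members(merge, ix))
  })
}

#' @export
print.crt_hac <- function(x, ...) {
  cat(sprintf("<crt_hac> %d %s clustered on vein %s; %d clusters at k=%d\n",
              length(x$items), x$axis, x$vein,
              length(unique(x$labels_at_k)), x$k))
  invisible(x)
}

#' @describeIn hac_cluster Tidy merge tree of a clustering.
#' @param x A `crt_hac`.
#' @param ... Unused.
#' @export
tidy.crt_hac <- function(x, ...) x$merge_tree

#' @describeIn hac_cluster One-row clustering summary.
#' @export
glance.crt_hac <- function(x, ...) {
  tibble(axis = x$axis, vein = x$vein, n_items = length(x$items), k = x$k,
         max_height = max(x$merge_tree$height),
         heights_nondecreasing = !is.unsorted(x$merge_tree$height))
}

#' Evaluate one lead design across a cohort
#'
#' For each subject, the best AT090 percent reduction achievable with the
#' design's 10 admissible configurations at the subject's best vein — the
#' distribution compared against personalised optima when judging how much
#' a single population-level design gives up.
#'
#' @param campaign A [run_campaign()] result.
#' @param design Design name (4 sorted letters) or character vector of 4
#'   electrode letters.
#' @param cohort Cohort label(s) (`NULL` = all).
#' @return Tibble with one row per subject: the vein, delivered
#'   configuration and reduction.
#' @export
cross_cohort_evaluate <- function(campaign, design, cohort = NULL) {
  stopifnot(inherits(campaign, "crt_campaign"))
  if (length(design) == 1) design <- strsplit(design, "")[[1]]
  if (length(design) != 4 || !all(design %in% letters[1:8]) ||
      anyDuplicated(design)) {
    abort("design must be 4 distinct electrode letters a..h",
          class = "quadlead_argument_error")
  }
  cfgs <- design_configurations(sort(design))
  rec <- campaign$records
  if (!is.null(cohort)) rec <- rec[rec$cohort %in% cohort, ]
  if (nrow(rec) == 0) abort("empty cohort", class = "quadlead_argument_error")
  subjects <- sort(unique(rec$subject))
  bind_rows(lapply(subjects, function(s) {
    bv <- patient_optimal(campaign, s)$vein
    rs <- rec[rec$subject == s & rec$vein == bv & rec$config %in% cfgs, ]
    rs |>
      arrange(desc(at090_reduction_pct), config) |>
      slice(1) |>
      select(cohort, subject, vein, config, at090_reduction_ms, at090_reduction_pct)
  }))
}
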