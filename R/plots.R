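# ggplot2 views of the result types.

#' @importFrom ggplot2 ggplot aes geom_density geom_col geom_segment
#'   geom_text geom_step geom_vline labs theme_minimal coord_flip
NULL

#' Density of AT090 reductions by cohort
#'
#' Kernel density of the per-record percent reductions, the campaign-level
#' picture of how much LV pacing helps in each cohort.
#'
#' @param object A `crt_campaign`.
#' @param metric Column of the record table to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crt_campaign <- function(object, metric = "at090_reduction_pct", ...) {
  ggplot(object$records, aes(x = .data[[metric]], colour = cohort, fill = cohort)) +
    geom_density(alpha = 0.25) +
    labs(x = metric, y = "density",
         title = "Pacing response distribution") +
    theme_minimal()
}

#' Coverage of the best-covering lead designs
#'
#' @param object A `crt_selection`.
#' @param top Number of designs shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crt_selection <- function(object, top = 15, ...) {
  df <- tidy(object) |> head(top)
  df$design <- factor(df$design, levels = rev(df$design))
  ggplot(df, aes(x = design, y = n_covered, fill = chosen)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "subjects whose optimal configuration is covered",
         title = sprintf("Design coverage (primary: %s)", object$primary_design)) +
    theme_minimal()
}

#' Dendrogram of a response-matrix clustering
#'
#' @param object A `crt_hac`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crt_hac <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$order)
  leaf_x <- numeric(n)
  leaf_x[hc$order] <- seq_len(n)
  cl_x <- numeric(nrow(hc$merge)); cl_h <- hc$height
  xpos <- function(ix) if (ix < 0) leaf_x[-ix] else cl_x[ix]
  hgt <- function(ix) if (ix < 0) 0 else cl_h[ix]
  segs <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    x1 <- xpos(hc$merge[s, 1]); x2 <- xpos(hc$merge[s, 2])
    h1 <- hgt(hc$merge[s, 1]); h2 <- hgt(hc$merge[s, 2])
    cl_x[s] <- (x1 + x2) / 2
    segs[[s]] <- tibble(x = c(x1, x2, x1), xend = c(x1, x2, x2),
                        y = c(h1, h2, cl_h[s]), yend = c(cl_h[s], cl_h[s], cl_h[s]))
  }
  labs_df <- tibble(x = leaf_x, label = object$items)
  ggplot() +
    geom_segment(data = bind_rows(segs),
                 aes(x = x, xend = xend, y = y, yend = yend)) +
    geom_text(data = labs_df, aes(x = x, y = 0, label = label),
              angle = 90, hjust = 1.1, size = 3) +
    labs(x = NULL, y = "merge height (Ward2)",
         title = sprintf("HAC of %s, vein %s", object$axis, object$vein)) +
    theme_minimal()
}

#' Activated-volume curve of an activation map
#'
#' Volume-weighted cumulative activation with the AT090 and TAT marks;
#' falls back to the node-time ECDF when no mesh is supplied.
#'
#' @param object An `activation_map`.
#' @param mesh The mesh the map was solved on (optional but recommended).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.activation_map <- function(object, mesh = NULL, ...) {
  if (is.null(mesh)) {
    t_ms <- sort(as.numeric(object)[is.finite(object)])
    df <- tibble(t_ms = t_ms, frac = seq_along(t_ms) / length(t_ms))
    return(ggplot(df, aes(t_ms, frac)) + geom_step() +
             labs(x = "activation time (ms)", y = "fraction of nodes") +
             theme_minimal())
  }
  active <- attr(object, "active") %||% rep(TRUE, nrow(mesh$tets))
  et <- element_activation_times(object, mesh)[active]
  vol <- mesh$volume[active]
  o <- order(et)
  df <- tibble(t_ms = et[o], frac = cumsum(vol[o]) / sum(vol))
  at090 <- compute_at090(object, mesh)
  tat <- compute_tat(object, mesh)
  ggplot(df, aes(t_ms, frac)) +
    geom_step() +
    geom_vline(xintercept = at090, linetype = 2) +
    geom_vline(xintercept = tat, linetype = 3) +
    labs(x = "activation time (ms)", y = "activated volume fraction",
         subtitle = sprintf("AT090 = %.1f ms (dashed), TAT = %.1f ms (dotted)",
                            at090, tat)) +
    theme_minimal()
}
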