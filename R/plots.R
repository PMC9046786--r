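#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   facet_wrap labs theme_minimal scale_colour_manual
#' @export
ggplot2::autoplot

#' Plot small-world curves over the sparsity grid
#'
#' One panel per metric with the small-world reference level (1) marked on
#' the normalized indices.
#'
#' @param object a [small_world_curve()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot sw_curve
autoplot.sw_curve <- function(object, ...) {
  long <- pivot_longer(as_tibble(object),
                       c("cp", "lp", "eglob", "eloc", "gamma", "lambda", "sigma"),
                       names_to = "metric", values_to = "value")
  ref <- tibble(metric = c("gamma", "lambda", "sigma"), value = 1)
  ggplot(long, aes(x = .data$sparsity, y = .data$value)) +
    geom_hline(data = ref, aes(yintercept = .data$value), linetype = 2,
               colour = "grey50") +
    geom_line() +
    geom_point(size = 0.8) +
    facet_wrap(~ .data$metric, scales = "free_y") +
    labs(x = "sparsity threshold", y = NULL) +
    theme_minimal()
}

#' Plot nodal metric curves
#'
#' @param object a [nodal_metric_curves()] result.
#' @param nodes optional subset of node labels to display.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot nodal_curve
autoplot.nodal_curve <- function(object, nodes = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(nodes)) df <- filter(df, .data$node %in% nodes)
  ggplot(df, aes(x = .data$sparsity, y = .data$value,
                 group = .data$node, colour = .data$node)) +
    geom_line(alpha = 0.7) +
    facet_wrap(~ .data$metric, scales = "free_y") +
    labs(x = "sparsity threshold", y = NULL) +
    theme_minimal()
}

#' Plot LOOCV predictions in feature space
#'
#' Scatter of the first two features with truth as colour and misclassified
#' subjects highlighted.
#'
#' @param object an [loocv_svm()] report.
#' @param features the feature table the classifier was fitted on.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot svm_loocv
autoplot.svm_loocv <- function(object, features, ...) {
  f <- as_tibble(features)
  xy <- object$features[1:min(2, length(object$features))]
  df <- bind_cols(f[xy], object$folds)
  if (length(xy) == 1) df$.y <- 0 else names(df)[2] <- ".y"
  names(df)[1] <- ".x"
  ggplot(df, aes(x = .data$.x, y = .data$.y, colour = .data$truth,
                 shape = .data$correct)) +
    geom_point(size = 2) +
    labs(x = xy[1], y = if (length(xy) > 1) xy[2] else NULL,
         shape = "correct") +
    theme_minimal()
}
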