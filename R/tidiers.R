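#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @method tidy melnet_stat
#' @rdname melnet_tidiers
#' @param x a fitted melnet object.
#' @param ... unused.
#' @name melnet_tidiers
#' @title Broom-style tidiers for melnet results
#' @description One-row-per-term (`tidy`) and one-row-per-fit (`glance`)
#'   summaries of group tests and classifier reports.
tidy.melnet_stat <- function(x, ...) {
  tibble(term = x$term, stat_name = x$stat_name, statistic = x$statistic,
         df1 = x$df1, df2 = x$df2, p_raw = x$p_raw, p_perm = x$p_perm)
}

#' @export
#' @method glance melnet_stat
#' @rdname melnet_tidiers
glance.melnet_stat <- function(x, ...) {
  tibble(method = x$method, n = x$n, n_perm = x$n_perm,
         covariates = paste(x$covariates, collapse = "+"))
}

#' @export
#' @method tidy svm_loocv
#' @rdname melnet_tidiers
tidy.svm_loocv <- function(x, ...) x$folds

#' @export
#' @method glance svm_loocv
#' @rdname melnet_tidiers
glance.svm_loocv <- function(x, ...) {
  tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, tp = x$tp, fp = x$fp, tn = x$tn,
         fn = x$fn, n = x$n, kernel = x$kernel, cost = x$cost,
         gamma = x$gamma, positive = x$positive)
}
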