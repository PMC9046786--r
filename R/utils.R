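#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_wider pivot_longer
#' @importFrom purrr map map_dbl map2 imap list_rbind
NULL

# relative tolerance used when comparing sums of inverse-weight path lengths
.melnet_path_tol <- 1e-10

#' Derive a reproducible child seed from a master seed
#'
#' Deterministically spawns per-stage / per-subject / per-threshold seeds from
#' a single master seed so that pipeline stages never share RNG streams.
#' The result always lies in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... further integer indices (stage number, subject index, ...).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, 1, 3)
derive_seed <- function(master, ...) {
  idx <- c(...)
  stopifnot(length(master) == 1, is.finite(master))
  x <- as.double(master) %% 2147483647
  for (i in seq_along(idx)) {
    x <- (x * 48271 + as.double(idx[i]) * 2654435761 + i * 97) %% 2147483647
  }
  as.integer(x %% 2147483645 + 1)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)),
          class = "melnet_parameter_error")
  }
  invisible(x)
}

param_error <- function(msg) abort(msg, class = "melnet_parameter_error")
format_error <- function(msg) abort(msg, class = "melnet_format_error")
lookup_error <- function(msg) abort(msg, class = "melnet_lookup_error")
validation_error <- function(msg) abort(msg, class = "melnet_validation_error")
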