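#' Model parameters for the active/inactive wave system
#'
#' Bundles the wave speed `c` and the inactive-production rate `r` of the
#' normalized reaction-diffusion system
#' \deqn{A_t = A_{xx} + A - A(A+I), \qquad I_t = A(A+I) + rA.}
#' In the comoving variable \eqn{z = x - ct} a traveling wave solves the
#' first-order system
#' \deqn{a' = b, \quad b' = a(a+i) - a - cb, \quad i' = -\tfrac{1}{c} a(a+i+r).}
#'
#' @param c Wave speed, must be a single finite value > 0.
#' @param r Rate at which active particles produce inactive ones, >= 0.
#'
#' @return An object of class `model_params`: a list with elements `c` and `r`.
#' @examples
#' p <- model_params(c = 2, r = 0)
#' critical_density(p$c)
#' @export
model_params <- function(c = 2, r = 0) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c),
            is.numeric(r), length(r) == 1L, is.finite(r))
  if (c <= 0) stop("wave speed `c` must be positive", call. = FALSE)
  if (r < 0) stop("production rate `r` must be non-negative", call. = FALSE)
  structure(list(c = as.numeric(c), r = as.numeric(r)), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params>  c = %g, r = %g  (i_c = %g)\n",
              x$c, x$r, critical_density(x$c)))
  invisible(x)
}

as_model_params <- function(params) {
  if (inherits(params, "model_params")) return(params)
  if (is.list(params) && all(c("c", "r") %in% names(params)))
    return(model_params(params$c, params$r))
  stop("`params` must be created by model_params()", call. = FALSE)
}

check_state <- function(s) {
  if (!is.numeric(s) || length(s) != 3L || !all(is.finite(s)))
    stop("phase state must be a finite numeric triple (a, b, i)", call. = FALSE)
  unname(as.numeric(s))
}
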