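#' Periportal-to-pericentral feature gradient
#'
#' A gradient specification maps a path-length coordinate `d` (distance from
#' the lobule's periportal entrance, in sinusoid-segment grid spaces) to a
#' feature value such as an event probability or a threshold. Three shapes
#' are supported:
#'
#' * `"constant"`: the value `v_pp` everywhere (requires `v_pp == v_cv`);
#' * `"linear"`: `v_pp + (v_cv - v_pp) * d / d_max`;
#' * `"reverse_sigmoid"`: `v_cv + (v_pp - v_cv) / (1 + exp(steepness * (d - inflection)))`,
#'   i.e. a logistic transition from `v_pp` near the entrance to `v_cv` near
#'   the central vein, with its inflection at `inflection` grid spaces.
#'
#' @param shape One of `"constant"`, `"linear"`, `"reverse_sigmoid"`.
#' @param v_pp Value at the periportal entrance (`d = 0`).
#' @param v_cv Value at the central vein end (`d = d_max`).
#' @param inflection Inflection point in grid spaces (reverse sigmoid only).
#' @param steepness Transition steepness per grid space (reverse sigmoid only).
#' @return An object of class `gradient_spec`.
#' @examples
#' g <- gradient_spec("linear", v_pp = 0.35, v_cv = 0.95)
#' gradient_value(g, d = 25, d_max = 50)
#' @export
gradient_spec <- function(shape = c("constant", "linear", "reverse_sigmoid"),
                          v_pp, v_cv = v_pp, inflection = NULL,
                          steepness = NULL) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(v_pp), length(v_pp) == 1L,
            is.numeric(v_cv), length(v_cv) == 1L)
  if (shape == "constant" && !isTRUE(all.equal(v_pp, v_cv))) {
    stop("a constant gradient requires v_pp == v_cv", call. = FALSE)
  }
  if (shape == "reverse_sigmoid") {
    if (is.null(inflection) || is.null(steepness)) {
      stop("reverse_sigmoid requires `inflection` and `steepness`",
           call. = FALSE)
    }
    stopifnot(steepness >= 0)
  }
  structure(
    list(shape = shape, v_pp = v_pp, v_cv = v_cv,
         inflection = inflection, steepness = steepness),
    class = "gradient_spec"
  )
}

#' @export
print.gradient_spec <- function(x, ...) {
  cat(sprintf("<gradient_spec> %s: v_pp = %g, v_cv = %g", x$shape,
              x$v_pp, x$v_cv))
  if (x$shape == "reverse_sigmoid") {
    cat(sprintf(", inflection = %g, steepness = %g", x$inflection,
                x$steepness))
  }
  cat("\n")
  invisible(x)
}

#' Evaluate a gradient at one or more lobular positions
#'
#' @param spec A [gradient_spec()].
#' @param d Numeric vector of path-length coordinates in grid spaces,
#'   each in `[0, d_max]`.
#' @param d_max Total mean periportal-to-central-vein path length.
#' @return Numeric vector of gradient values, guaranteed to lie within
#'   `[min(v_pp, v_cv), max(v_pp, v_cv)]`.
#' @export
gradient_value <- function(spec, d, d_max) {
  stopifnot(inherits(spec, "gradient_spec"), is.numeric(d),
            is.numeric(d_max), d_max > 0)
  if (any(d < 0 | d > d_max)) {
    stop("position(s) outside [0, d_max]", call. = FALSE)
  }
  v <- switch(spec$shape,
    constant = rep(spec$v_pp, length(d)),
    linear = spec$v_pp + (spec$v_cv - spec$v_pp) * d / d_max,
    reverse_sigmoid = spec$v_cv + (spec$v_pp - spec$v_cv) /
      (1 + exp(spec$steepness * (d - spec$inflection)))
  )
  pmin(pmax(v, min(spec$v_pp, spec$v_cv)), max(spec$v_pp, spec$v_cv))
}

#' Calibrate a gradient so its population mean hits a target
#'
#' Solves, by monotone root finding over a single free parameter, for the
#' gradient whose mean value over a population of hepatocyte positions
#' equals `target_mean`. This is how the zonated mechanism presets are made
#' comparable at the whole-lobule level to their location-independent
#' counterparts: e.g. the zonated glutathione depletion threshold is
#' calibrated so its census-wide mean equals the constant threshold 3.5, and
#' the reverse-sigmoid mitochondrial-damage mitigation probability is
#' calibrated to a census-wide mean of 0.67.
#'
#' @param spec A [gradient_spec()] providing the fixed parameters.
#' @param population Numeric vector of path-length coordinates (`dPP` values)
#'   of the hepatocyte population, in grid spaces.
#' @param target_mean The required population mean.
#' @param free_parameter `"v_cv"` (any shape except constant) or
#'   `"steepness"` (reverse sigmoid only).
#' @param d_max Total mean path length used to scale the gradient.
#' @param tol Absolute tolerance on the achieved mean (default `1e-6`).
#' @return A calibrated `gradient_spec`.
#' @export
calibrate_gradient_mean <- function(spec, population, target_mean,
                                    free_parameter = c("v_cv", "steepness"),
                                    d_max, tol = 1e-6) {
  free_parameter <- match.arg(free_parameter)
  stopifnot(length(population) > 0, is.finite(target_mean))
  if (spec$shape == "constant") {
    # only the constant value itself can move
    return(gradient_spec("constant", v_pp = target_mean, v_cv = target_mean))
  }
  pop_mean <- function(s) mean(gradient_value(s, population, d_max))
  with_par <- function(value) {
    s <- spec
    s[[free_parameter]] <- value
    s
  }
  bounds <- if (free_parameter == "steepness") c(1e-9, 1e3) else c(-1e4, 1e4)
  if (free_parameter == "steepness" && spec$shape != "reverse_sigmoid") {
    stop("steepness is only free for reverse_sigmoid gradients",
         call. = FALSE)
  }
  f <- function(value) pop_mean(with_par(value)) - target_mean
  f_lo <- f(bounds[1]); f_hi <- f(bounds[2])
  if (sign(f_lo) == sign(f_hi)) {
    stop(sprintf(
      "target mean %g unreachable; achievable range is [%g, %g]",
      target_mean,
      min(f_lo, f_hi) + target_mean, max(f_lo, f_hi) + target_mean),
      call. = FALSE)
  }
  root <- stats::uniroot(f, interval = bounds, tol = 1e-12)$root
  out <- with_par(root)
  achieved <- pop_mean(out)
  if (abs(achieved - target_mean) > tol) {
    stop(sprintf("calibration did not converge: mean %g vs target %g",
                 achieved, target_mean), call. = FALSE)
  }
  out
}
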