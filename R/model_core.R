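# Trimodal quasi-probability-density model of the HU distribution:
# sum of two skewed and one standard (alpha = 0) Gaussian component.

# Complementary error function via the normal CDF: erfc(z) = 2*Phi(-z*sqrt(2)).
erfc <- function(z) 2 * stats::pnorm(z * sqrt(2), lower.tail = FALSE)

#' Parameters of one tissue component
#'
#' Bundles the four parameters of a single (possibly skewed) Gaussian
#' component of the trimodal HU model. `N` is the component's total count
#' (the area under its density curve, in voxel-count units): the erfc-form
#' density integrates exactly to `N` for every skewness. The field keeps the
#' conventional name "amplitude", but the semantics are area; the peak
#' height is a derived quantity (`N / (sigma * sqrt(2*pi))` when
#' `alpha = 0`).
#'
#' @param N amplitude (total count carried by the component), `>= 0`.
#' @param mu location in HU, within `[-200, 200]`.
#' @param sigma width in HU, within `[0.1, 200]`.
#' @param alpha skewness (dimensionless), within `[-20, 20]`. Positive
#'   `alpha` skews mass toward *lower* HU: the model multiplies the Gaussian
#'   by `erfc(alpha * (x - mu) / (sigma * sqrt(2)))`, which is the mirror of
#'   the textbook skew-normal convention `2*phi*Phi(lambda*z)` (it equals it
#'   with `lambda = -alpha`).
#' @return an object of class `component_params`.
#' @export
#' @examples
#' component_params(N = 1000, mu = 55, sigma = 13, alpha = 1.8)
component_params <- function(N, mu, sigma, alpha = 0) {
  stopifnot(length(N) == 1, length(mu) == 1, length(sigma) == 1,
            length(alpha) == 1)
  if (!is.finite(N) || N < 0)
    stop("invalid parameter: N must be finite and >= 0", call. = FALSE)
  if (!is.finite(sigma) || sigma < PARAM_BOUNDS$sigma[1] ||
      sigma > PARAM_BOUNDS$sigma[2])
    stop("invalid parameter: sigma must be in [",
         PARAM_BOUNDS$sigma[1], ", ", PARAM_BOUNDS$sigma[2], "] HU",
         call. = FALSE)
  if (!is.finite(mu) || mu < -200 || mu > 200)
    stop("invalid parameter: mu must be in [-200, 200] HU", call. = FALSE)
  if (!is.finite(alpha) || abs(alpha) > PARAM_BOUNDS$alpha[2])
    stop("invalid parameter: |alpha| must be <= ", PARAM_BOUNDS$alpha[2],
         call. = FALSE)
  structure(list(N = as.numeric(N), mu = as.numeric(mu),
                 sigma = as.numeric(sigma), alpha = as.numeric(alpha)),
            class = "component_params")
}

#' @export
print.component_params <- function(x, ...) {
  cat(sprintf("component: N = %.6g, mu = %.4g HU, sigma = %.4g HU, alpha = %.4g\n",
              x$N, x$mu, x$sigma, x$alpha))
  invisible(x)
}

#' The 11-parameter trimodal model
#'
#' Combines fat, connective and muscle [component_params] into the full
#' trimodal model. The connective component is structurally a standard
#' Gaussian: its skewness is fixed at exactly zero and is never a free
#' parameter, so the model has 3*4 - 1 = 11 free parameters. Component
#' locations must be ordered `fat$mu < connective$mu < muscle$mu`
#' (identifiability: each component tracks one tissue's HU domain).
#'
#' @param fat,connective,muscle [component_params] for each tissue.
#' @return an object of class `trimodal_params`.
#' @export
#' @examples
#' trimodal_params(
#'   fat        = component_params(5e5, -80, 22, -1.2),
#'   connective = component_params(1.5e5, 5, 30, 0),
#'   muscle     = component_params(1e6, 55, 13, 1.8)
#' )
trimodal_params <- function(fat, connective, muscle) {
  for (p in list(fat, connective, muscle))
    if (!inherits(p, "component_params"))
      stop("fat, connective and muscle must be component_params objects",
           call. = FALSE)
  if (connective$alpha != 0)
    stop("connective skewness must be exactly 0 (structural constraint)",
         call. = FALSE)
  if (!(fat$mu < connective$mu && connective$mu < muscle$mu))
    stop("component locations must satisfy fat$mu < connective$mu < muscle$mu",
         call. = FALSE)
  structure(list(fat = fat, connective = connective, muscle = muscle),
            class = "trimodal_params")
}

#' @export
print.trimodal_params <- function(x, ...) {
  cat("trimodal model parameters (11 free):\n")
  for (tissue in TISSUES) {
    cat(sprintf("  %-11s", tissue))
    print(x[[tissue]])
  }
  invisible(x)
}

#' @export
coef.trimodal_params <- function(object, ...) {
  unlist(lapply(TISSUES, function(t) {
    p <- object[[t]]
    stats::setNames(c(p$N, p$mu, p$sigma, p$alpha),
                    paste(t, c("N", "mu", "sigma", "alpha"), sep = "_"))
  }))
}

#' Skewed-Gaussian component density
#'
#' Evaluates one component's quasi-density at HU values `x`:
#' `N/(sigma*sqrt(2*pi)) * exp(-(x-mu)^2/(2*sigma^2)) *
#'  erfc(alpha*(x-mu)/(sigma*sqrt(2)))`.
#' The curve integrates to `N` for every `alpha` (because
#' `erfc(alpha*z/sqrt(2)) = 2*Phi(-alpha*z)` and the skew-normal density
#' `2*phi(z)*Phi(-alpha*z)` integrates to one).
#'
#' @param x HU value(s); vectorized.
#' @param p a [component_params] object.
#' @return non-negative density value(s) in counts per HU, same length as `x`.
#' @export
#' @examples
#' component_density(0, component_params(1, 0, 1, 0))  # 1/sqrt(2*pi)
component_density <- function(x, p) {
  if (!inherits(p, "component_params"))
    p <- do.call(component_params, as.list(p))
  z <- (x - p$mu) / p$sigma
  p$N / (p$sigma * sqrt(2 * pi)) * exp(-z^2 / 2) * erfc(p$alpha * z / sqrt(2))
}

#' Trimodal quasi-density
#'
#' Sum of the three component densities at HU value(s) `x`.
#'
#' @param x HU value(s); vectorized.
#' @param tp a [trimodal_params] object.
#' @return non-negative density value(s) in counts per HU.
#' @export
trimodal_density <- function(x, tp) {
  stopifnot(inherits(tp, "trimodal_params"))
  component_density(x, tp$fat) + component_density(x, tp$connective) +
    component_density(x, tp$muscle)
}

#' Model counts at histogram bin centers
#'
#' Evaluates the trimodal density at each bin center. The density values
#' are compared to bin counts directly during fitting (no bin-width
#' factor), so a fitted `N` carries an implicit `1/binwidth` scale: a
#' component holding `n` voxels of a 3.125-HU-wide histogram fits
#' `N = n * 3.125`.
#'
#' @param tp a [trimodal_params] object.
#' @param bin_centers ascending HU bin centers.
#' @return numeric vector of model counts, one per bin center.
#' @export
predicted_counts <- function(tp, bin_centers) {
  if (length(bin_centers) == 0)
    stop("bin_centers must be nonempty", call. = FALSE)
  if (is.unsorted(bin_centers, strictly = TRUE))
    stop("bin_centers must be strictly ascending", call. = FALSE)
  trimodal_density(bin_centers, tp)
}

#' Total count carried by a component
#'
#' Numerical quadrature of [component_density] over
#' `[mu - 40*sigma, mu + 40*sigma]`. Analytically equals `N` for every
#' skewness; exposed so the area semantics of `N` can be checked and so
#' per-tissue voxel totals can be read off fitted parameters.
#'
#' @param p a [component_params] object.
#' @return the component area (equals `p$N` up to quadrature error).
#' @export
component_area <- function(p) {
  if (!inherits(p, "component_params"))
    p <- do.call(component_params, as.list(p))
  if (p$N == 0) return(0)
  stats::integrate(function(x) component_density(x, p),
                   lower = p$mu - 40 * p$sigma, upper = p$mu + 40 * p$sigma,
                   rel.tol = 1e-10, abs.tol = 0)$value
}

#' Read trimodal parameters from a JSON file
#'
#' Expects the layout
#' `{"fat": {"N":..,"mu":..,"sigma":..,"alpha":..}, "connective": {...},
#'   "muscle": {...}}`. Files where `connective$alpha != 0` are rejected.
#'
#' @param path JSON file path.
#' @return a [trimodal_params] object.
#' @export
read_trimodal_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(TISSUES, names(obj))
  if (length(missing))
    stop("parameter file lacks components: ", paste(missing, collapse = ", "),
         call. = FALSE)
  comp <- function(t) {
    f <- obj[[t]]
    component_params(N = f$N, mu = f$mu, sigma = f$sigma,
                     alpha = if (is.null(f$alpha)) 0 else f$alpha)
  }
  trimodal_params(fat = comp("fat"), connective = comp("connective"),
                  muscle = comp("muscle"))
}

#' Write trimodal parameters to a JSON file
#'
#' @param tp a [trimodal_params] object.
#' @param path output JSON file path.
#' @return `path`, invisibly.
#' @export
write_trimodal_json <- function(tp, path) {
  stopifnot(inherits(tp, "trimodal_params"))
  obj <- lapply(tp[TISSUES], function(p) p[c("N", "mu", "sigma", "alpha")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
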