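# Synthetic data: voxel populations drawn from known trimodal parameters
# and concentric 2D phantoms with a fat/muscle interface, so every module
# is testable with known ground truth.

#' Sample voxel HU values from a trimodal model
#'
#' Each draw selects a component with probability `N_i / sum(N)`, then
#' samples that component's skew-normal. The model's erfc convention
#' (positive alpha skews mass toward lower HU) corresponds to the
#' standard skew-normal with shape parameter `-alpha`; sampling uses the
#' exact two-Gaussian (delta-parameterization) construction, with no
#' rejection loop.
#'
#' @param tp a [trimodal_params] object with `sum(N) > 0`.
#' @param n number of voxels to draw, `>= 1`.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return numeric vector of `n` HU values (unbounded; values outside
#'   `[-200, 200]` can occur in the tails and are handled downstream by
#'   [build_histogram]).
#' @export
sample_trimodal <- function(tp, n, seed = 1L) {
  stopifnot(inherits(tp, "trimodal_params"), n >= 1)
  weights <- vapply(tp[TISSUES], function(p) p$N, numeric(1))
  if (sum(weights) == 0)
    stop("all component amplitudes are zero; nothing to sample",
         call. = FALSE)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  comp <- sample.int(3L, n, replace = TRUE, prob = weights / sum(weights))
  out <- numeric(n)
  for (i in 1:3) {
    sel <- comp == i
    m <- sum(sel)
    if (m == 0) next
    p <- tp[[TISSUES[i]]]
    lambda <- -p$alpha                       # standard skew-normal shape
    delta <- lambda / sqrt(1 + lambda^2)
    z0 <- abs(stats::rnorm(m))
    z1 <- stats::rnorm(m)
    out[sel] <- p$mu + p$sigma * (delta * z0 + sqrt(1 - delta^2) * z1)
  }
  out
}

#' Healthy-like demonstration parameters
#'
#' A documented trimodal parameter set for demos and validation runs. The
#' muscle peak sits at 55 HU, matching the reference healthy-subject
#' distribution; the fat peak at -80 HU and every other value are fixture
#' choices representing a plausible healthy adult leg: a dominant,
#' moderately narrow muscle peak skewed toward lower HU, a blunter fat
#' peak skewed toward higher HU, and a low, broad, symmetric connective
#' band between them. Amplitudes are in count x bin-width units for a
#' volume of roughly half a million voxels.
#'
#' @return a [trimodal_params] object.
#' @export
default_healthy_params <- function() {
  trimodal_params(
    fat        = component_params(N = 5e5,   mu = -80, sigma = 22, alpha = -1.2),
    connective = component_params(N = 1.5e5, mu = 5,   sigma = 30, alpha = 0),
    muscle     = component_params(N = 1e6,   mu = 55,  sigma = 13, alpha = 1.8)
  )
}

#' Specification of a concentric 2D CT phantom
#'
#' A muscle disk of radius `r_core` inside a fat ring of outer radius
#' `r_outer`, centered in a `size` x `size` image, on background. Across
#' the fat/muscle interface, tissue mean HU blends linearly over a band
#' of total width `blend_width` pixels (the partial-volume analogue);
#' independent Gaussian noise of `noise_sd` HU is added to every
#' in-phantom pixel.
#'
#' @param size image side length in pixels.
#' @param r_core muscle-core radius (pixels).
#' @param r_outer fat-ring outer radius (pixels), `> r_core`.
#' @param fat_hu,muscle_hu tissue mean HU values.
#' @param blend_width interface blend width in pixels, `>= 0`.
#' @param noise_sd Gaussian HU noise standard deviation, `>= 0`.
#' @param seed integer seed; fixed seed gives a bit-identical phantom.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 64L, r_core = 18, r_outer = 28,
                         fat_hu = -80, muscle_hu = 55,
                         blend_width = 2, noise_sd = 5, seed = 1L) {
  if (r_core <= 0 || r_outer <= r_core)
    stop("radii must satisfy 0 < r_core < r_outer", call. = FALSE)
  if (2 * r_outer > size)
    stop("fat ring (diameter ", 2 * r_outer, ") exceeds image size ", size,
         call. = FALSE)
  if (blend_width < 0 || noise_sd < 0)
    stop("blend_width and noise_sd must be >= 0", call. = FALSE)
  structure(list(size = as.integer(size), r_core = r_core, r_outer = r_outer,
                 fat_hu = fat_hu, muscle_hu = muscle_hu,
                 blend_width = blend_width, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a 2D CT-like phantom with ground truth
#'
#' @param spec a [phantom_spec].
#' @return list with `hu` (numeric matrix; background pixels at
#'   -1000 HU), `labels` (ground-truth geometry labels, ignoring
#'   blending: `muscle` inside `r_core`, `fat` in the ring, otherwise
#'   `background`), `mask` (logical in-phantom matrix) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  ctr <- (n + 1) / 2
  dist <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`))
  labels <- array("background", dim = c(n, n))
  labels[dist <= spec$r_outer] <- "fat"
  labels[dist <= spec$r_core] <- "muscle"
  mask <- labels != "background"

  # linear blend across the fat/muscle interface over total width
  # blend_width, centered on the core boundary
  if (spec$blend_width > 0) {
    frac <- pmin(pmax((dist - spec$r_core) / spec$blend_width + 0.5, 0), 1)
  } else {
    frac <- (dist > spec$r_core) + 0  # keep matrix shape
  }
  hu <- spec$muscle_hu + frac * (spec$fat_hu - spec$muscle_hu)
  hu[!mask] <- -1000

  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(spec$seed)
    hu[mask] <- hu[mask] + stats::rnorm(sum(mask), 0, spec$noise_sd)
  }
  list(hu = hu, labels = labels, mask = mask, spec = spec)
}
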