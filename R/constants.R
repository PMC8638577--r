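#' Physical constants for muscle architecture calculations
#'
#' Bundles the constants used throughout the package: muscle tissue density,
#' maximal isometric muscle stress, and gravitational acceleration. The
#' defaults are the values conventionally used for vertebrate skeletal
#' muscle (density 1,060 kg/m^3; stress 300,000 N/m^2) and standard gravity.
#'
#' Scaling exponents fitted on log10 data are invariant to the choice of
#' \code{stress} (it shifts intercepts only); the density enters PCSA
#' multiplicatively and likewise leaves slopes untouched.
#'
#' @param density Muscle tissue density in kg/m^3. Must be > 0.
#' @param stress Maximal isometric muscle stress in N/m^2. Must be > 0.
#' @param g Gravitational acceleration in m/s^2. Must be > 0.
#' @return An object of class \code{"limb_constants"}: a named list with
#'   elements \code{density}, \code{stress}, \code{g}.
#' @examples
#' limb_constants()
#' limb_constants(stress = 2e5)
#' @export
limb_constants <- function(density = 1060, stress = 3e5, g = 9.81) {
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) || density <= 0)
    stop("'density' must be a single positive number (kg/m^3)")
  if (!is.numeric(stress) || length(stress) != 1L || !is.finite(stress) || stress <= 0)
    stop("'stress' must be a single positive number (N/m^2)")
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0)
    stop("'g' must be a single positive number (m/s^2)")
  structure(list(density = density, stress = stress, g = g),
            class = "limb_constants")
}

#' @export
print.limb_constants <- function(x, ...) {
  cat("Muscle constants:\n")
  cat(sprintf("  density: %g kg/m^3\n", x$density))
  cat(sprintf("  stress:  %g N/m^2\n", x$stress))
  cat(sprintf("  g:       %g m/s^2\n", x$g))
  invisible(x)
}
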