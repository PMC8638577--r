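#' Physiological cross-sectional area (PCSA)
#'
#' Computes PCSA from muscle belly mass, pennation angle and fascicle
#' length:
#' \deqn{PCSA = m \cos(\alpha) / (\rho \ell)}
#' with mass \eqn{m} in kg, pennation \eqn{\alpha} in degrees, fascicle
#' length \eqn{\ell} in m and tissue density \eqn{\rho} in kg/m^3. PCSA
#' approximates the summed cross-sectional area of all fascicles acting in
#' parallel, and multiplied by the maximal isometric stress gives an
#' estimate of the muscle's maximal isometric force.
#'
#' @param mass Muscle belly mass in kg (vectorized). Must be >= 0.
#' @param pennation Pennation angle in degrees, in [0, 90).
#' @param fascicle_length Fascicle length in m. Must be > 0.
#' @param density Muscle tissue density in kg/m^3 (default 1060).
#' @param muscle Optional muscle names used in error messages.
#' @return PCSA in m^2, same length as the inputs.
#' @examples
#' pcsa(0.053, 0, 0.05)            # 1e-3 m^2
#' pcsa(0.053, 60, 0.05)           # half of the unpennated value
#' @seealso [fmax_star()], [char_fascicle_length()]
#' @export
pcsa <- function(mass, pennation, fascicle_length, density = 1060,
                 muscle = NULL) {
  n <- max(length(mass), length(pennation), length(fascicle_length))
  mass <- rep_len(mass, n)
  pennation <- rep_len(pennation, n)
  fascicle_length <- rep_len(fascicle_length, n)
  lab <- function(i) {
    if (!is.null(muscle)) sprintf(" (muscle '%s')", rep_len(muscle, n)[i]) else
      sprintf(" (record %d)", i)
  }
  if (any(bad <- !is.finite(mass) | mass < 0))
    stop("muscle mass must be finite and >= 0", lab(which(bad)[1L]))
  if (any(bad <- !is.finite(pennation) | pennation < 0 | pennation >= 90))
    stop("pennation angle must lie in [0, 90) degrees", lab(which(bad)[1L]))
  if (any(bad <- !is.finite(fascicle_length) | fascicle_length <= 0))
    stop("fascicle length must be finite and > 0", lab(which(bad)[1L]))
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("'density' must be a single positive number")
  mass * cos(pennation * pi / 180) / (density * fascicle_length)
}

#' Size-normalized maximal isometric strength
#'
#' Converts a PCSA (or any summary of PCSAs) into maximal isometric force
#' expressed in multiples of body weight:
#' \deqn{F^*_{max} = PCSA \cdot \sigma / (m_{body} \cdot g)}
#' The result is dimensionless ("body weights"). Changing \code{stress}
#' rescales all values by the same factor and therefore cannot change a
#' fitted log-log scaling exponent.
#'
#' @param pcsa PCSA in m^2 (vectorized). Must be >= 0.
#' @param body_mass Body mass in kg. Must be > 0.
#' @param stress Maximal isometric muscle stress in N/m^2 (default 3e5).
#' @param g Gravitational acceleration in m/s^2 (default 9.81).
#' @return Strength in body weights.
#' @examples
#' fmax_star(1e-3, 10)   # ~3.058 BW
#' @export
fmax_star <- function(pcsa, body_mass, stress = 3e5, g = 9.81) {
  if (any(!is.finite(pcsa) | pcsa < 0)) stop("'pcsa' must be finite and >= 0")
  if (any(!is.finite(body_mass) | body_mass <= 0))
    stop("'body_mass' must be finite and > 0")
  pcsa * stress / (body_mass * g)
}

#' Characteristic fascicle length of a set of muscles
#'
#' The characteristic fascicle length L* replaces the musculature of a limb
#' (or limb compartment) with a single equivalent muscle:
#' \deqn{L^* = \Sigma m / (\rho \cdot \Sigma PCSA)}
#' which is the mass- and pennation-weighted harmonic mean of the
#' individual fascicle lengths. For a single muscle it reduces to
#' \eqn{\ell / \cos(\alpha)}; pennation can only increase L* relative to
#' the plain harmonic mean of fascicle lengths.
#'
#' @param mass Muscle belly masses in kg.
#' @param pennation Pennation angles in degrees.
#' @param fascicle_length Fascicle lengths in m.
#' @param density Muscle tissue density in kg/m^3.
#' @return L* in m (a single number).
#' @examples
#' char_fascicle_length(0.1, 0, 0.04)    # 0.04
#' char_fascicle_length(0.1, 60, 0.04)   # 0.08
#' @export
char_fascicle_length <- function(mass, pennation, fascicle_length,
                                 density = 1060) {
  if (length(mass) == 0L) stop("at least one muscle record is required")
  a <- pcsa(mass, pennation, fascicle_length, density)
  sum(mass) / (density * sum(a))
}

#' Isometric (geometric-similarity) expectation for a scaling exponent
#'
#' Returns the log-log slope expected under geometric similarity for each
#' anatomical comparison: total muscle mass vs body mass scales as mass^1;
#' body-weight-normalized strength (mean, median or total F*max) as
#' mass^(-1/3) (the PCSA exponent 2/3 minus 1); characteristic fascicle
#' length as mass^(1/3); and total PCSA vs total muscle mass as mass^(2/3).
#'
#' @param comparison One of \code{"mass_v_body"}, \code{"fmax_mean"},
#'   \code{"fmax_median"}, \code{"fmax_total"}, \code{"Lstar"},
#'   \code{"pcsa_v_mass"}.
#' @return The expected slope (a single number).
#' @examples
#' isometric_slope("mass_v_body")  # 1
#' isometric_slope("pcsa_v_mass")  # 2/3
#' @export
isometric_slope <- function(comparison) {
  comparison <- match.arg(comparison, names(.comparison_registry))
  .comparison_registry[[comparison]]$iso
}

# Registry of the six anatomical comparisons: isometric expectation plus the
# aggregate columns used as predictor (x) and response (y), both on the
# linear scale (log10 taken at fit time).
.comparison_registry <- list(
  mass_v_body = list(iso = 1,      x = "body_mass",    y = "sum_mass"),
  fmax_mean   = list(iso = -1 / 3, x = "body_mass",    y = "fmax_mean"),
  fmax_median = list(iso = -1 / 3, x = "body_mass",    y = "fmax_median"),
  fmax_total  = list(iso = -1 / 3, x = "body_mass",    y = "fmax_total"),
  Lstar       = list(iso = 1 / 3,  x = "body_mass",    y = "L_star"),
  pcsa_v_mass = list(iso = 2 / 3,  x = "sum_mass",     y = "sum_pcsa")
)

#' The six anatomical comparisons
#'
#' @return Character vector of comparison identifiers understood by
#'   [isometric_slope()], [aggregate_limbs()] output columns and
#'   [run_limb_analysis()].
#' @export
limb_comparisons <- function() names(.comparison_registry)

.validate_muscle_df <- function(data) {
  required <- c("species", "group", "limb", "compartment", "muscle",
                "mass", "fascicle_length", "pennation", "is_cfl",
                "body_mass")
  missing <- setdiff(required, names(data))
  if (length(missing))
    stop("muscle table is missing required columns: ",
         paste(missing, collapse = ", "))
  if (!all(data$limb %in% c("fore", "hind")))
    stop("'limb' must be 'fore' or 'hind'")
  mo <- .is_mass_only(data)
  if (!all(data$compartment[!mo] %in% c("proximal", "distal")))
    stop("'compartment' must be 'proximal' or 'distal' for architecture records")
  if (any(!is.finite(data$body_mass) | data$body_mass <= 0))
    stop("'body_mass' must be finite and > 0 on every row")
  bm <- tapply(data$body_mass, data$species, function(v) length(unique(v)))
  if (any(bm > 1L))
    stop("inconsistent body_mass within species: ",
         paste(names(bm)[bm > 1L], collapse = ", "))
  if (any(!is.finite(data$mass) | data$mass < 0))
    stop("'mass' must be finite and >= 0 on every row")
  if (any(!mo & (!is.finite(data$pennation) | data$pennation < 0 |
                   data$pennation >= 90)))
    stop("'pennation' must lie in [0, 90) degrees for architecture records")
  if (any(!mo & (!is.finite(data$fascicle_length) | data$fascicle_length <= 0)))
    stop("'fascicle_length' must be > 0 for architecture records")
  invisible(data)
}

# Mass-only records carry mass but no architecture (NA fascicle length).
.is_mass_only <- function(data) {
  !is.finite(data$fascicle_length) | !is.finite(data$pennation)
}

#' Read a per-muscle architecture table from CSV
#'
#' Reads and validates the package's CSV dialect: one row per measured
#' muscle with columns \code{species, group, limb, compartment, muscle,
#' mass, fascicle_length, pennation, is_cfl, body_mass}. \code{body_mass}
#' is repeated on every row of a species and must be consistent. Rows with
#' missing \code{fascicle_length}/\code{pennation} are treated as mass-only
#' records: they contribute to total muscle mass but not to PCSA-derived
#' metrics.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param mass_unit Unit of the \code{mass} and \code{body_mass} columns:
#'   \code{"kg"} (default) or \code{"g"}; converted to kg on read.
#' @param length_unit Unit of \code{fascicle_length}: \code{"m"} (default),
#'   \code{"cm"} or \code{"mm"}; converted to m on read.
#' @return A validated data.frame in kg/m units.
#' @seealso [aggregate_limbs()], [write_muscle_table()]
#' @export
read_muscle_table <- function(path, mass_unit = c("kg", "g"),
                              length_unit = c("m", "cm", "mm")) {
  mass_unit <- match.arg(mass_unit)
  length_unit <- match.arg(length_unit)
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  mf <- c(kg = 1, g = 1e-3)[[mass_unit]]
  lf <- c(m = 1, cm = 1e-2, mm = 1e-3)[[length_unit]]
  data$mass <- data$mass * mf
  data$body_mass <- data$body_mass * mf
  data$fascicle_length <- data$fascicle_length * lf
  data$is_cfl <- as.logical(data$is_cfl)
  .validate_muscle_df(data)
}

#' Write a per-muscle architecture table to CSV
#'
#' @param data A muscle table data.frame (kg/m units).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_muscle_table <- function(data, path) {
  .validate_muscle_df(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate per-muscle records into whole-limb (or compartment) metrics
#'
#' For every species x limb in a muscle table, computes the aggregate
#' quantities used by the anatomical comparisons: total muscle mass, total,
#' mean and median PCSA, the corresponding body-weight-normalized strengths
#' (F*max), the characteristic fascicle length L*, and the number of
#' muscles used. The summation scope is the whole limb or only its proximal
#' or distal compartment, and the caudofemoralis longus (CFL) can be
#' excluded, mirroring the re-run variants of the analysis.
#'
#' Species contributing only muscle mass (no architecture) appear with
#' \code{sum_mass} populated and all PCSA-derived columns \code{NA}.
#'
#' @param data A muscle table (see [read_muscle_table()]).
#' @param scope \code{"whole"}, \code{"proximal"} or \code{"distal"}.
#' @param exclude_cfl If \code{TRUE}, drop records flagged \code{is_cfl}.
#' @param constants A [limb_constants()] object.
#' @return A data.frame with one row per species x limb: columns
#'   \code{species, group, limb, body_mass, n_muscles, sum_mass, sum_pcsa,
#'   mean_pcsa, median_pcsa, fmax_mean, fmax_median, fmax_total, L_star,
#'   mass_only}.
#' @examples
#' d <- isometric_fixture(8, seed = 1)
#' agg <- aggregate_limbs(d$muscles)
#' head(agg)
#' @export
aggregate_limbs <- function(data, scope = c("whole", "proximal", "distal"),
                            exclude_cfl = FALSE,
                            constants = limb_constants()) {
  scope <- match.arg(scope)
  .validate_muscle_df(data)
  if (exclude_cfl) data <- data[!data$is_cfl, , drop = FALSE]
  if (scope != "whole") {
    keep <- data$compartment == scope | .is_mass_only(data)
    data <- data[keep, , drop = FALSE]
  }
  key <- interaction(data$species, data$limb, drop = TRUE)
  rows <- lapply(split(data, key), function(d) {
    mo <- .is_mass_only(d)
    arch <- d[!mo, , drop = FALSE]
    out <- data.frame(species = d$species[1L], group = d$group[1L],
                      limb = d$limb[1L], body_mass = d$body_mass[1L],
                      n_muscles = nrow(arch), sum_mass = sum(d$mass),
                      sum_pcsa = NA_real_, mean_pcsa = NA_real_,
                      median_pcsa = NA_real_, fmax_mean = NA_real_,
                      fmax_median = NA_real_, fmax_total = NA_real_,
                      L_star = NA_real_, mass_only = nrow(arch) == 0L,
                      stringsAsFactors = FALSE)
    if (nrow(arch)) {
      a <- pcsa(arch$mass, arch$pennation, arch$fascicle_length,
                constants$density, muscle = arch$muscle)
      out$sum_pcsa <- sum(a)
      out$mean_pcsa <- mean(a)
      out$median_pcsa <- stats::median(a)  # even counts: midpoint of central pair
      out$fmax_mean <- fmax_star(out$mean_pcsa, out$body_mass,
                                 constants$stress, constants$g)
      out$fmax_median <- fmax_star(out$median_pcsa, out$body_mass,
                                   constants$stress, constants$g)
      out$fmax_total <- fmax_star(out$sum_pcsa, out$body_mass,
                                  constants$stress, constants$g)
      out$L_star <- sum(arch$mass) / (constants$density * out$sum_pcsa)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$limb, out$species), , drop = FALSE]
}

#' Extract the log10 predictor/response pair for a comparison
#'
#' Pulls the x and y variables of one anatomical comparison from an
#' aggregate table (see [aggregate_limbs()]) and log10-transforms them.
#' Mass-only species are retained for the total-mass comparison and dropped
#' (with a message) for PCSA-derived comparisons.
#'
#' @param agg An aggregate table from [aggregate_limbs()].
#' @param comparison A comparison id (see [limb_comparisons()]).
#' @param quiet Suppress the notice about skipped mass-only species.
#' @return A data.frame with columns \code{species, group, x, y} where x, y
#'   are on the log10 scale.
#' @export
comparison_xy <- function(agg, comparison, quiet = FALSE) {
  comparison <- match.arg(comparison, names(.comparison_registry))
  spec <- .comparison_registry[[comparison]]
  d <- agg
  if (comparison != "mass_v_body") {
    drop <- d$mass_only
    if (any(drop) && !quiet)
      message("skipping mass-only species for '", comparison, "': ",
              paste(d$species[drop], collapse = ", "))
    d <- d[!drop, , drop = FALSE]
  }
  x <- d[[spec$x]]
  y <- d[[spec$y]]
  if (any(!is.finite(x) | x <= 0 | !is.finite(y) | y <= 0))
    stop("non-positive values cannot be log10-transformed for comparison '",
         comparison, "'")
  data.frame(species = d$species, group = d$group,
             x = log10(x), y = log10(y), stringsAsFactors = FALSE)
}
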