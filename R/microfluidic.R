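#' Laminar co-flow mixer geometry
#'
#' Geometry and flow settings of a cross-shaped microfluidic chip in which
#' a central protein stream is flanked by two buffer streams and mixing
#' proceeds by transverse diffusion. Defaults describe a 100 x 100 um
#' channel of 87 mm length at a total flow of 14 ul/min with equal inlet
#' flows, and infinite-dilution diffusion coefficients for the aqueous
#' metal cations Mn2+, Fe3+, Cu2+ and Zn2+.
#'
#' @param channel_width,channel_depth channel cross-section, um.
#' @param channel_length channel length, mm.
#' @param total_flow_rate total volumetric flow, ul/min.
#' @param inlet_flow_fractions three nonnegative fractions summing to 1.
#' @param diffusion_coefficients named vector, m^2/s.
#' @export
mixing_geometry <- function(channel_width = 100, channel_depth = 100,
                            channel_length = 87, total_flow_rate = 14,
                            inlet_flow_fractions = rep(1 / 3, 3),
                            diffusion_coefficients = c(Mn = 6.88e-10,
                                                       Fe = 6.05e-10,
                                                       Cu = 7.33e-10,
                                                       Zn = 7.15e-10)) {
  stopifnot(channel_width > 0, channel_depth > 0, channel_length > 0,
            total_flow_rate > 0, length(inlet_flow_fractions) == 3L,
            all(inlet_flow_fractions >= 0))
  if (abs(sum(inlet_flow_fractions) - 1) > 1e-12)
    stop("inlet_flow_fractions must sum to 1")
  structure(list(channel_width = channel_width,
                 channel_depth = channel_depth,
                 channel_length = channel_length,
                 total_flow_rate = total_flow_rate,
                 inlet_flow_fractions = inlet_flow_fractions,
                 diffusion_coefficients = diffusion_coefficients),
            class = "mixing_geometry")
}

#' Characteristic diffusion time (Fick's law)
#'
#' \eqn{t_D = y^2 / (2D)}: the time for a species with diffusion
#' coefficient D to traverse the half-width y of the channel.
#'
#' @param D diffusion coefficient, m^2/s; must be positive.
#' @param half_width half channel width, m (50 um = 5e-5 m by default).
#' @return time in seconds.
#' @export
diffusion_time <- function(D, half_width = 5e-5) {
  if (any(D <= 0)) stop("domain error: D must be positive")
  if (any(half_width < 0)) stop("domain error: half_width must be >= 0")
  half_width^2 / (2 * D)
}

#' Mean axial flow velocity of the channel
#'
#' v = Q / A with Q the total flow rate and A the channel cross-section.
#'
#' @param geom a \code{\link{mixing_geometry}}.
#' @return velocity in mm/s.
#' @export
mean_velocity <- function(geom) {
  q_m3s <- geom$total_flow_rate * 1e-9 / 60          # ul/min -> m^3/s
  area_m2 <- geom$channel_width * geom$channel_depth * 1e-12
  (q_m3s / area_m2) * 1e3                             # m/s -> mm/s
}

#' Map an axial channel position to a post-mixing time
#'
#' Plug-flow conversion t = x / v at the mean velocity v = Q/A.
#'
#' @param x axial distance along the channel, mm; within
#'   [0, channel_length].
#' @param geom a \code{\link{mixing_geometry}}.
#' @return time in seconds, with the velocity (mm/s) as attribute
#'   \code{velocity}.
#' @export
position_to_time <- function(x, geom = mixing_geometry()) {
  if (any(x < 0 | x > geom$channel_length))
    stop("domain error: x outside [0, channel_length]")
  v <- mean_velocity(geom)
  structure(x / v, velocity = v)
}

#' Steady-state dilution plateau from the inlet mass balance
#'
#' Once transverse diffusion has homogenized the channel, the protein
#' concentration — and hence the normalized forward intensity
#' I(0)/I(0)_0 — settles at the protein inlet's share of the total flow.
#'
#' @param geom a \code{\link{mixing_geometry}}.
#' @param protein_inlet inlet index 1..3 (2 = central stream, the default).
#' @return the normalized steady-state concentration.
#' @export
dilution_plateau <- function(geom = mixing_geometry(), protein_inlet = 2L) {
  stopifnot(protein_inlet %in% 1:3)
  geom$inlet_flow_fractions[protein_inlet]
}

#' Mixing report
#'
#' Diffusion times per species, the mean velocity, the dilution plateau and
#' the time corresponding to each requested measurement position.
#'
#' @param geom a \code{\link{mixing_geometry}}.
#' @param positions measurement positions along the channel, mm.
#' @return list with \code{diffusion_times} (data.frame), \code{velocity}
#'   (mm/s), \code{plateau}, and \code{time_grid} (data.frame).
#' @export
mixing_report <- function(geom = mixing_geometry(), positions = NULL) {
  y <- geom$channel_width / 2 * 1e-6
  td <- diffusion_time(geom$diffusion_coefficients, y)
  v <- mean_velocity(geom)
  out <- list(
    diffusion_times = data.frame(species = names(td),
                                 D_m2s = unname(geom$diffusion_coefficients),
                                 t_d_s = unname(td),
                                 axial_mm = unname(td) * v),
    velocity = v,
    plateau = dilution_plateau(geom))
  if (!is.null(positions))
    out$time_grid <- data.frame(position_mm = positions,
                                time_s = as.numeric(position_to_time(positions, geom)))
  out
}
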