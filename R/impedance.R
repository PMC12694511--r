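#' Dipole pair geometry
#'
#' Geometry of the transmit/receive dipole pair. The default separation of
#' 0.35 m matches the antenna spacing of the sensing setup the package
#' emulates.
#'
#' @param l Dipole length in m.
#' @param r Dipole separation in m (default 0.35).
#' @return An object of class `respiq_geometry`.
#' @export
dipole_geometry <- function(l = 0.05, r = 0.35) {
  if (!(l > 0 && r > 0)) abort("dipole length and separation must be > 0")
  if (l >= r) abort("dipole length must be smaller than the separation (0 < l < r)")
  structure(list(l = l, r = r), class = "respiq_geometry")
}

#' Effective propagation-medium model
#'
#' Lumped dielectric model of the thoracic coupling path. Air entering the
#' lungs lowers the effective permittivity linearly:
#' `eps(t) = eps_baseline - eps_per_litre * V(t)` with `V(t)` the inhaled air
#' volume above end-expiration. `eps_baseline` is an effective coupling
#' parameter of the antenna/thorax system, not a tissue permittivity. Defaults
#' give a relative |Z12| modulation of about 2 % per 0.5 L at 433 MHz.
#'
#' @param eps_baseline Effective permittivity at end-expiration, F/m.
#' @param eps_per_litre Permittivity decrease per litre of inhaled air, F/m/L.
#' @param mu Magnetic permeability, H/m (default vacuum).
#' @param R0 Free-space wave resistance, Ohm (default 376.73).
#' @return An object of class `respiq_medium`.
#' @export
medium_model <- function(eps_baseline = 1.2 * 8.8541878128e-12,
                         eps_per_litre = 5.3e-12,
                         mu = 1.25663706212e-6,
                         R0 = 376.73) {
  if (eps_baseline <= 0) abort("eps_baseline must be > 0")
  if (eps_per_litre < 0) abort("eps_per_litre must be >= 0")
  structure(list(eps_baseline = eps_baseline, eps_per_litre = eps_per_litre,
                 mu = mu, R0 = R0), class = "respiq_medium")
}

#' Carrier configuration
#'
#' @param frequency Carrier frequency in Hz (default 433 MHz, the ISM band the
#'   sensor operates in).
#' @return An object of class `respiq_carrier` with derived angular frequency
#'   `omega` (rad/s) and wavelength `lambda` (m).
#' @export
carrier_config <- function(frequency = 433e6) {
  if (frequency <= 0) abort("carrier frequency must be > 0")
  structure(list(frequency = frequency,
                 omega = 2 * pi * frequency,
                 lambda = 299792458 / frequency),
            class = "respiq_carrier")
}

#' Mutual impedance of two small coupled dipoles
#'
#' Evaluates the small-dipole mutual-impedance model
#' \deqn{Z_{12} = \frac{l^2}{4\pi r^2}\left(\frac{1}{j\omega\epsilon r} + R_0
#'   + j\omega\mu r\right) e^{-j 2\pi r/\lambda},}
#' whose bracket is an equivalent circuit of a capacitive, resistive and
#' inductive component. The capacitive term is inversely proportional to the
#' permittivity of the medium, which is how lung air volume modulates the
#' coupling between the antennas.
#'
#' @param geom A [dipole_geometry()].
#' @param medium A [medium_model()].
#' @param carrier A [carrier_config()].
#' @param eps Permittivity value(s) in F/m at which to evaluate; defaults to
#'   `medium$eps_baseline`. Vectorised.
#' @return Complex impedance(s) in Ohm.
#' @export
#' @examples
#' mutual_impedance(dipole_geometry(0.05, 0.35), medium_model(), carrier_config())
mutual_impedance <- function(geom, medium, carrier, eps = medium$eps_baseline) {
  stopifnot(inherits(geom, "respiq_geometry"), inherits(medium, "respiq_medium"),
            inherits(carrier, "respiq_carrier"))
  if (geom$r == 0) abort("dipole separation r must be non-zero")
  if (any(eps <= 0)) abort("permittivity eps must be > 0")
  w <- carrier$omega
  r <- geom$r
  bracket <- 1 / (1i * w * eps * r) + medium$R0 + 1i * w * medium$mu * r
  (geom$l^2 / (4 * pi * r^2)) * bracket * exp(-1i * 2 * pi * r / carrier$lambda)
}

#' Theoretical timing floor of the sensor grid
#'
#' One sample interval of the sensor acquisition grid, in milliseconds: the
#' resolution floor any event-timing comparison against the sensor inherits
#' (about 30 ms at the 33 Hz acquisition rate).
#'
#' @param sensor_rate_hz Sensor sampling rate in Hz (default 33).
#' @return Timing floor in ms.
#' @export
#' @examples
#' sensor_timing_floor_ms() # 1000 / 33
sensor_timing_floor_ms <- function(sensor_rate_hz = 33) {
  if (sensor_rate_hz <= 0) abort("sensor rate must be > 0")
  1000 / sensor_rate_hz
}
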