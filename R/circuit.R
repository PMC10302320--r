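#' Electrode geometry for the stratum-corneum capacitance model
#'
#' Describes the cylindrical-capacitor approximation of the skin-electrode
#' interface of a metal handle electrode: the stratum corneum (SC), the
#' outermost skin layer of the palm, acts as the dielectric between the hand
#' and the electrode barrel.
#'
#' @param l_elec Effective electrode length in metres (device manual value
#'   0.045 m).
#' @param d_elec Electrode radius in metres (device manual value 0.011 m).
#' @param d_sc Stratum corneum thickness in metres; physiological range on the
#'   palm is roughly 10 um to 800 um.
#' @param eps_r Relative permittivity of the SC (dimensionless, >= 1);
#'   reported range 1e3 to 1e5 depending on skin humidity.
#' @param eps_0 Vacuum permittivity in F/m (fixed physical constant).
#'
#' @return An object of class `electrode_geometry` (a named list).
#' @seealso [stratum_corneum_capacitance()]
#' @export
electrode_geometry <- function(l_elec = 0.045, d_elec = 0.011,
                               d_sc = 200e-6, eps_r = 1e4,
                               eps_0 = 8.8541878128e-12) {
  vals <- c(l_elec = l_elec, d_elec = d_elec, d_sc = d_sc,
            eps_r = eps_r, eps_0 = eps_0)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("electrode geometry parameters must be finite and strictly positive",
         call. = FALSE)
  if (d_sc >= d_elec)
    stop("stratum corneum thickness must be smaller than the electrode radius",
         call. = FALSE)
  if (eps_r < 1)
    stop("relative permittivity must be >= 1", call. = FALSE)
  structure(list(l_elec = l_elec, d_elec = d_elec, d_sc = d_sc,
                 eps_r = eps_r, eps_0 = eps_0),
            class = "electrode_geometry")
}

#' Equivalent circuit parameters of the measurement chain
#'
#' Lumped parameters of the measurement front end: the skin-electrode
#' interface of each hand (parallel `R_sc`/`C_sc`), the series coupling
#' capacitance `C_cpl` at the amplifier input, and the amplifier input
#' resistance `R_in`. `C_cpl` and `R_in` form a first-order high-pass filter
#' whose cutoff governs how strongly beat morphology is distorted.
#'
#' @param R_sc Stratum corneum resistance in Ohm (default 1 MOhm).
#' @param C_sc Stratum corneum capacitance in F (default 10 uF).
#' @param C_cpl Coupling capacitance in F.
#' @param R_in Amplifier input resistance in Ohm (default 50 GOhm).
#'
#' @return An object of class `circuit_params`.
#' @seealso [highpass_cutoff()], [transfer_function()], [simulate_measurement()]
#' @export
circuit_params <- function(R_sc = 1e6, C_sc = 10e-6, C_cpl = 0.3e-12,
                           R_in = 50e9) {
  vals <- c(R_sc = R_sc, C_sc = C_sc, C_cpl = C_cpl, R_in = R_in)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("circuit parameters must be finite and strictly positive",
         call. = FALSE)
  structure(as.list(vals), class = "circuit_params")
}

#' Stratum corneum capacitance from the cylindrical-capacitor model
#'
#' Approximates the capacitance of the stratum corneum under a cylindrical
#' metal handle electrode as a coaxial capacitor with the SC as dielectric:
#' \deqn{C_{sc} = \frac{2\pi \epsilon_0 \epsilon_r l_{elec}}
#'                     {\ln((d_{elec} + d_{sc}) / d_{elec})}.}
#' The capacitance is linear in `eps_r` and `l_elec` and strictly decreasing
#' in `d_sc`.
#'
#' @param geom An [electrode_geometry()] object.
#' @return Capacitance in farad (scalar).
#' @examples
#' stratum_corneum_capacitance(electrode_geometry(d_sc = 800e-6, eps_r = 1e3))
#' @export
stratum_corneum_capacitance <- function(geom) {
  stopifnot(inherits(geom, "electrode_geometry"))
  2 * pi * geom$eps_0 * geom$eps_r * geom$l_elec /
    log((geom$d_elec + geom$d_sc) / geom$d_elec)
}

#' First-order high-pass cutoff of the coupling stage
#'
#' The series coupling capacitance and the amplifier input resistance form a
#' passive first-order high-pass with cutoff \eqn{f_c = 1/(2\pi R_{in} C_{cpl})}.
#'
#' @param params A [circuit_params()] object.
#' @return Cutoff frequency in Hz.
#' @examples
#' highpass_cutoff(circuit_params(C_cpl = 0.3e-12)) # ~10.6 Hz at 50 GOhm
#' @export
highpass_cutoff <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  1 / (2 * pi * params$R_in * params$C_cpl)
}

#' Complex transfer function of the measurement chain
#'
#' Solves the voltage divider of the equivalent circuit: two identical
#' skin-electrode interfaces (one per hand, each a parallel `R_sc`/`C_sc`)
#' in series with the coupling capacitor, measured across the amplifier
#' input resistance:
#' \deqn{H(j\omega) = \frac{Z_{in}}{Z_{in} + 2 Z_{skin} + Z_{cpl}}}
#' with \eqn{Z_{skin} = R_{sc} / (1 + j\omega R_{sc} C_{sc})},
#' \eqn{Z_{cpl} = 1/(j\omega C_{cpl})} and \eqn{Z_{in} = R_{in}}.
#' At DC the series capacitor blocks the signal (gain 0, handled
#' analytically); well above the cutoff the gain approaches 1 whenever the
#' skin impedance is small against `R_in`.
#'
#' @param params A [circuit_params()] object.
#' @param freqs Vector of frequencies in Hz (>= 0).
#' @return Complex gain, one value per frequency.
#' @export
transfer_function <- function(params, freqs) {
  stopifnot(inherits(params, "circuit_params"))
  if (any(!is.finite(freqs)) || any(freqs < 0))
    stop("frequencies must be finite and non-negative", call. = FALSE)
  w <- 2 * pi * freqs
  h <- complex(length.out = length(freqs), real = 0, imaginary = 0)
  pos <- w > 0
  if (any(pos)) {
    jw <- 1i * w[pos]
    z_skin <- params$R_sc / (1 + jw * params$R_sc * params$C_sc)
    z_cpl <- 1 / (jw * params$C_cpl)
    h[pos] <- params$R_in / (params$R_in + 2 * z_skin + z_cpl)
  }
  h
}

#' Simulate the distorted measurement of a clean ECG
#'
#' Passes a clean ECG through the equivalent circuit of the hand-held device,
#' discretised with the bilinear transform at the signal's sampling rate. The
#' dominant effect is the first-order high-pass formed by `C_cpl` and `R_in`;
#' the skin interface adds a (usually negligible) series impedance. The
#' filter removes DC and, for small coupling capacitances, reshapes P/S/T
#' morphology (the T wave acquires a negative lobe).
#'
#' @param samples Clean ECG samples in mV (`U_ecg`).
#' @param fs Sampling rate in Hz.
#' @param params A [circuit_params()] object.
#' @return An object of class `simulated_measurement`: a list with
#'   `input_signal`, `output_signal` (`U_meas`, same length), `fs` and
#'   `cutoff_hz`.
#' @export
simulate_measurement <- function(samples, fs, params) {
  stopifnot(inherits(params, "circuit_params"))
  if (length(samples) == 0L) stop("empty signal", call. = FALSE)
  if (!all(is.finite(samples))) stop("signal must be finite", call. = FALSE)
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)

  # Bilinear transform of H(s) = Rin / (Rin + 2*Zskin(s) + 1/(s*Ccpl)).
  # Multiplying through by s*Ccpl*(1 + s*Rsc*Csc) gives a quadratic rational
  # transfer function in s; map s -> (2*fs)*(1 - z^-1)/(1 + z^-1).
  Rin <- params$R_in; Rsc <- params$R_sc
  Csc <- params$C_sc; Ccpl <- params$C_cpl
  # numerator:   Rin*Ccpl * s * (1 + Rsc*Csc*s)
  # denominator: (Rin + 2*Rsc)*Ccpl*s + (Rin*Ccpl*Rsc*Csc)*s^2*0 ... expand:
  #   (Rin + 2*Zskin + 1/(s*Ccpl)) * s*Ccpl*(1+s*Rsc*Csc)
  # = Rin*Ccpl*s*(1+s*Rsc*Csc) + 2*Rsc*Ccpl*s + (1+s*Rsc*Csc)
  num_s <- c(Rin * Ccpl * Rsc * Csc, Rin * Ccpl, 0)        # s^2, s^1, s^0
  den_s <- c(Rin * Ccpl * Rsc * Csc,
             Rin * Ccpl + 2 * Rsc * Ccpl + Rsc * Csc, 1)
  ba <- bilinear_sos(num_s, den_s, fs)
  out <- as.numeric(signal::filter(signal::Arma(b = ba$b, a = ba$a), samples))
  structure(list(input_signal = samples, output_signal = out, fs = fs,
                 cutoff_hz = highpass_cutoff(params)),
            class = "simulated_measurement")
}

# Bilinear transform of a second-order analog rational function.
# num_s, den_s: coefficients (s^2, s^1, s^0). Returns digital b, a.
bilinear_sos <- function(num_s, den_s, fs) {
  K <- 2 * fs
  # substitute s = K (1 - z)/(1 + z) with z = z^-1; multiply by (1+z)^2
  poly_map <- function(cf) {
    # cf = c(a2, a1, a0) for a2 s^2 + a1 s + a0
    c(cf[1] * K^2 + cf[2] * K + cf[3],        # z^0
      -2 * cf[1] * K^2 + 2 * cf[3],           # z^-1
      cf[1] * K^2 - cf[2] * K + cf[3])        # z^-2
  }
  b <- poly_map(num_s)
  a <- poly_map(den_s)
  list(b = b / a[1], a = a / a[1])
}

#' Mean-cycle morphology over a grid of coupling capacitances
#'
#' Repeats the measurement-chain simulation for each coupling capacitance in
#' `c_cpl_grid`, detects R peaks on the distorted output, and averages beat
#' morphology on a fixed heart-cycle-percentage grid. Reproduces the family
#' of increasingly distorted mean cycles seen as the high-pass cutoff rises.
#'
#' @param samples Clean ECG samples (mV).
#' @param fs Sampling rate in Hz.
#' @param c_cpl_grid Vector of coupling capacitances in F.
#' @param params Base [circuit_params()]; `C_cpl` is overridden per grid point.
#' @param n_points Cycle grid length (default 200).
#' @return A list with one element per grid value: either a list
#'   (`c_cpl`, `cutoff_hz`, `cycle`, `n_beats`) or, if peak detection fails
#'   for that entry, a list with `failed = TRUE` (the sweep continues).
#' @export
morphology_sweep <- function(samples, fs, c_cpl_grid,
                             params = circuit_params(), n_points = 200) {
  if (length(c_cpl_grid) == 0L) stop("empty C_cpl grid", call. = FALSE)
  lapply(c_cpl_grid, function(cc) {
    p <- circuit_params(R_sc = params$R_sc, C_sc = params$C_sc,
                        C_cpl = cc, R_in = params$R_in)
    sim <- simulate_measurement(samples, fs, p)
    res <- tryCatch({
      peaks <- detect_r_peaks(sim$output_signal, fs)
      beats <- segment_beats(sim$output_signal, peaks$indices)
      morph <- average_morphology(beats, n_points = n_points)
      list(c_cpl = cc, cutoff_hz = highpass_cutoff(p),
           cycle = morph$cycle, n_beats = morph$n_beats, failed = FALSE)
    }, error = function(e) {
      list(c_cpl = cc, cutoff_hz = highpass_cutoff(p),
           failed = TRUE, reason = conditionMessage(e))
    })
    res
  })
}
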