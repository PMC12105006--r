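# PAMPA blood-brain-barrier assay calculations: percent transmittance from
# plate absorbances, effective permeability Pe, and CNS classification by
# calibration against reference drugs with literature permeabilities.

#' PAMPA plate geometry
#'
#' Defaults are the standard 96-well layout: 0.2 cm^3 donor and receptor
#' volumes, 0.2642 cm^2 membrane area, 3 h (10,800 s) incubation.
#'
#' @param v_donor donor volume, cm^3.
#' @param v_receptor receptor volume, cm^3.
#' @param area membrane area, cm^2.
#' @param time incubation time, seconds.
#' @return object of class `pampa_geometry`.
#' @export
pampa_geometry <- function(v_donor = 0.2, v_receptor = 0.2, area = 0.2642,
                           time = 10800) {
  vals <- c(v_donor = v_donor, v_receptor = v_receptor, area = area,
            time = time)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry parameters must be strictly positive")
  }
  structure(as.list(vals), class = "pampa_geometry")
}

#' @export
print.pampa_geometry <- function(x, ...) {
  cat(sprintf("PAMPA geometry: Vd = %g cm^3, Vr = %g cm^3, area = %g cm^2, t = %g s\n",
              x$v_donor, x$v_receptor, x$area, x$time))
  invisible(x)
}

#' Percent transmittance
#'
#' `%T = 100 * (Vr * Ar) / (Vd * Ad)`: the fraction of compound (by
#' absorbance x volume) found in the acceptor compartment after incubation,
#' relative to the donor loading before incubation.
#'
#' @param a_donor_pre donor absorbance before incubation (must be > 0).
#' @param a_receptor_post acceptor absorbance after incubation.
#' @param geom a [pampa_geometry()].
#' @return percent transmittance (vectorized).
#' @export
transmittance <- function(a_donor_pre, a_receptor_post,
                          geom = pampa_geometry()) {
  stopifnot(inherits(geom, "pampa_geometry"))
  if (any(a_receptor_post < 0)) stop("absorbances must be non-negative")
  if (any(a_donor_pre <= 0)) {
    stop("donor pre-incubation absorbance must be strictly positive")
  }
  100 * (geom$v_receptor * a_receptor_post) / (geom$v_donor * a_donor_pre)
}

#' Effective permeability Pe from percent transmittance
#'
#' The default form is the standard two-compartment solution
#' `Pe = [Vd*Vr / ((Vd+Vr)*area*time)] * (-ln(1 - f/f_eq))` with transferred
#' fraction `f = %T/100` and equilibrium fraction `f_eq = Vr/(Vd+Vr)`,
#' reported in 1e-6 cm/s. A compound at or beyond the equilibrium fraction
#' is a saturation error (no finite permeability explains it).
#'
#' `formula = "printed"` evaluates an alternative closed form
#' `[Vd*Vr/((Vd-Vr)*area*time)] * [100*Vd / (100*Vd - %T*(Vd-Vr))]` whose
#' `(Vd - Vr)` denominators vanish for equal-volume plates; it is provided
#' for audit only and is rejected with a diagnostic when `Vd == Vr`.
#'
#' @param percent_t percent transmittance (vectorized).
#' @param geom a [pampa_geometry()].
#' @param formula `"standard"` (default) or `"printed"`.
#' @return permeability in 1e-6 cm/s.
#' @export
pampa_permeability <- function(percent_t, geom = pampa_geometry(),
                               formula = c("standard", "printed")) {
  stopifnot(inherits(geom, "pampa_geometry"))
  formula <- match.arg(formula)
  if (any(percent_t < 0)) stop("'percent_t' must be non-negative")
  vd <- geom$v_donor
  vr <- geom$v_receptor
  if (formula == "printed") {
    if (abs(vd - vr) < 1e-12) {
      stop("the 'printed' Pe expression has (Vd - Vr) in a denominator and is undefined for equal donor/receptor volumes; use formula = \"standard\"")
    }
    pe <- vd * vr / ((vd - vr) * geom$area * geom$time) *
      (100 * vd) / (100 * vd - percent_t * (vd - vr))
    return(pe * 1e6)
  }
  f <- percent_t / 100
  f_eq <- vr / (vd + vr)
  if (any(f >= f_eq)) {
    stop(sprintf("saturation: transferred fraction %.4g reaches the equilibrium fraction %.4g; compound is effectively equilibrated",
                 max(f), f_eq))
  }
  pe <- vd * vr / ((vd + vr) * geom$area * geom$time) * (-log(1 - f / f_eq))
  pe * 1e6
}

#' Analyze a PAMPA plate table
#'
#' Averages replicate/wavelength transmittance per compound (with the
#' per-compound standard deviation) and computes Pe.
#'
#' @param plate data.frame with columns `compound`, `a_donor_pre`,
#'   `a_receptor_post` and optionally `replicate`, `wavelength`.
#' @param geom a [pampa_geometry()].
#' @return data.frame per compound: `percent_t`, `percent_t_sd`, `pe`
#'   (1e-6 cm/s), `n_wells`.
#' @export
pampa_analyze <- function(plate, geom = pampa_geometry()) {
  needed <- c("compound", "a_donor_pre", "a_receptor_post")
  if (!is.data.frame(plate) || !all(needed %in% names(plate))) {
    stop("'plate' must contain columns ", paste(needed, collapse = ", "))
  }
  tt <- transmittance(plate$a_donor_pre, plate$a_receptor_post, geom)
  agg <- stats::aggregate(tt, by = list(compound = plate$compound),
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(compound = agg$compound,
                    percent_t = agg$x[, "mean"],
                    percent_t_sd = agg$x[, "sd"],
                    n_wells = as.integer(agg$x[, "n"]))
  out$pe <- pampa_permeability(out$percent_t, geom)
  out
}

#' Calibrate Pe thresholds against reference drugs and classify
#'
#' Least-squares fit of experimental Pe on literature Pe over the reference
#' drugs; the bibliographic class bounds (4 and 2, in 1e-6 cm/s) are mapped
#' through the fit to the experimental scale (`t_hi`, `t_lo`). Compounds
#' above `t_hi` are CNS+ (passive BBB permeation expected), below `t_lo`
#' CNS-, and between them CNS+/-.
#'
#' @param experimental experimental Pe of the reference drugs (1e-6 cm/s).
#' @param literature literature Pe of the same drugs (1e-6 cm/s).
#' @param hi,lo bibliographic class bounds (defaults 4 and 2).
#' @return object of class `cns_calibration` with `slope`, `intercept`,
#'   `t_hi`, `t_lo` and the underlying `lm` fit.
#' @export
cns_calibration <- function(experimental, literature, hi = 4, lo = 2) {
  if (length(experimental) != length(literature)) {
    stop("'experimental' and 'literature' must have the same length")
  }
  if (length(experimental) < 3L) {
    stop("at least 3 reference drugs are required for calibration")
  }
  if (stats::var(literature) == 0) {
    stop("literature permeabilities are degenerate (zero spread)")
  }
  fit <- stats::lm(experimental ~ literature)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0) {
    stop(sprintf("calibration slope %.4g is not positive; assay run is invalid",
                 slope))
  }
  structure(list(slope = slope, intercept = intercept,
                 t_hi = slope * hi + intercept,
                 t_lo = slope * lo + intercept,
                 fit = fit, n = length(experimental)),
            class = "cns_calibration")
}

#' @export
print.cns_calibration <- function(x, ...) {
  cat(sprintf("CNS calibration over %d reference drugs: experimental = %.4g * literature + %.4g\n",
              x$n, x$slope, x$intercept))
  cat(sprintf("  thresholds (experimental scale): CNS+ above %.4g, CNS- below %.4g\n",
              x$t_hi, x$t_lo))
  invisible(x)
}

#' Classify compounds by calibrated permeability
#'
#' @param calibration a [cns_calibration()].
#' @param pe experimental Pe value(s), 1e-6 cm/s.
#' @return factor with levels `CNS+`, `CNS+/-`, `CNS-`.
#' @export
classify_cns <- function(calibration, pe) {
  stopifnot(inherits(calibration, "cns_calibration"))
  cls <- ifelse(pe > calibration$t_hi, "CNS+",
                ifelse(pe < calibration$t_lo, "CNS-", "CNS+/-"))
  factor(cls, levels = c("CNS+", "CNS+/-", "CNS-"))
}

#' Read a PAMPA plate CSV
#'
#' @param path CSV with columns `compound`, `replicate`, `wavelength`,
#'   `a_donor_pre`, `a_receptor_post` (replicate/wavelength optional).
#' @return data.frame.
#' @export
read_pampa_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("compound", "a_donor_pre", "a_receptor_post")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("plate CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}
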