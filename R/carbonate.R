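#' Carbonate-system parameters
#'
#' Bundles the apparent equilibrium constants used by the dosing model for a
#' bicarbonate-buffered freshwater medium (BG-11-like) bubbled with a
#' CO2-containing gas phase.
#'
#' Defaults correspond to 30 degrees C and practical salinity 1.5: the CO2
#' solubility is evaluated from the Weiss (1974) formula via [kh_weiss()]
#' (0.029640 mol L-1 atm-1, i.e. the value usually quoted as 0.02964), and the
#' apparent dissociation exponents are the empirically titrated pKa1 = 6.35
#' (CO2/HCO3-) and pKa2 = 10.15 (HCO3-/CO3 2-). `pkw` is the water ion-product
#' exponent at 30 degrees C, needed only for the closed-system titration charge
#' balance and the optional full-charge-balance pH solver.
#'
#' @param kh CO2 solubility (Henry constant), mol L-1 atm-1.
#' @param pka1 First apparent dissociation exponent (CO2/HCO3-).
#' @param pka2 Second apparent dissociation exponent (HCO3-/CO3 2-).
#' @param temperature Temperature in K.
#' @param salinity Practical salinity.
#' @param pkw Water self-ionization exponent (-log10 Kw).
#' @return An object of class `carbonate_params`.
#' @examples
#' p <- carbonate_params()
#' p$kh
#' @export
carbonate_params <- function(kh = kh_weiss(303.15, 1.5),
                             pka1 = 6.35, pka2 = 10.15,
                             temperature = 303.15, salinity = 1.5,
                             pkw = 13.83) {
  stopifnot(is.numeric(kh), length(kh) == 1L, is.finite(kh))
  if (kh <= 0) stop("kh must be > 0")
  if (!(pka2 > pka1)) stop("pka2 must exceed pka1")
  if (temperature <= 0) stop("temperature must be > 0 (K)")
  structure(list(kh = kh, pka1 = pka1, pka2 = pka2,
                 temperature = temperature, salinity = salinity, pkw = pkw),
            class = "carbonate_params")
}

#' CO2 solubility from the Weiss (1974) formula
#'
#' Volumetric solubility K0 in mol L-1 atm-1 as a function of temperature and
#' salinity, using the published fit coefficients for the mol/(l * atm) form.
#'
#' @param temperature Temperature in K. Values outside 271-313 K trigger a
#'   warning (the fit range), but the value is still computed.
#' @param salinity Practical salinity (0 for fresh water).
#' @return Solubility in mol L-1 atm-1.
#' @examples
#' kh_weiss(303.15, 1.5)   # ~0.02964, the constant used for BG-11 at 30 C
#' kh_weiss(298.15, 0)     # ~0.034, fresh water at 25 C
#' @export
kh_weiss <- function(temperature, salinity = 0) {
  stopifnot(is.numeric(temperature), is.numeric(salinity))
  if (any(temperature <= 271 | temperature >= 313))
    warning("temperature outside the 271-313 K fit range of the Weiss formula")
  tk <- temperature / 100
  lnk0 <- -58.0931 + 90.5069 / tk + 22.2940 * log(tk) +
    salinity * (0.027766 - 0.025888 * tk + 0.0050578 * tk^2)
  exp(lnk0)
}

#' Carbonate speciation at fixed pH and CO2 partial pressure
#'
#' Computes the dissolved inorganic carbon species of a medium equilibrated
#' with a gas phase at partial pressure `pco2` while the pH is held at `ph`:
#' `[CO2] = kh * pco2`, `[HCO3-] = [CO2] * 10^(ph - pka1)`,
#' `[CO3 2-] = [HCO3-] * 10^(ph - pka2)`. Carbonate alkalinity is
#' `CA = [HCO3-] + 2 [CO3 2-]` and total inorganic carbon
#' `TIC = [CO2] + [HCO3-] + [CO3 2-]`.
#'
#' @param pco2 CO2 partial pressure in atm (>= 0); vectorized.
#' @param ph pH; recycled against `pco2`.
#' @param params A [carbonate_params()] object.
#' @return A data.frame with columns `pco2`, `ph`, `co2`, `hco3`, `co3`, `ca`,
#'   `tic`, all concentrations in mM.
#' @examples
#' speciate_at_ph(0.30, 7.5)   # the 30% CO2 medium: CA ~126.2 mM
#' @export
speciate_at_ph <- function(pco2, ph, params = carbonate_params()) {
  stopifnot(is.numeric(pco2), is.numeric(ph))
  if (any(pco2 < 0)) stop("pco2 must be non-negative")
  if (any(ph <= 0 | ph >= 14)) stop("ph must lie in (0, 14)")
  n <- max(length(pco2), length(ph))
  pco2 <- rep_len(pco2, n); ph <- rep_len(ph, n)
  co2 <- params$kh * pco2 * 1000                 # mM
  hco3 <- co2 * 10^(ph - params$pka1)
  co3 <- hco3 * 10^(ph - params$pka2)
  data.frame(pco2 = pco2, ph = ph, co2 = co2, hco3 = hco3, co3 = co3,
             ca = hco3 + 2 * co3, tic = co2 + hco3 + co3)
}

#' NaHCO3 dose required to reach a target pH under CO2 bubbling
#'
#' The dose equals the carbonate alkalinity predicted at the target pH and CO2
#' partial pressure, since sodium bicarbonate supplies one mole of alkalinity
#' per mole added.
#'
#' @inheritParams speciate_at_ph
#' @param target_ph Target pH at gas-liquid equilibrium.
#' @return Dose in mM (vectorized over `pco2`).
#' @examples
#' nahco3_dose(0.30, 7.5)   # ~126.2 mM for 30% CO2
#' @export
nahco3_dose <- function(pco2, target_ph = 7.5, params = carbonate_params()) {
  speciate_at_ph(pco2, target_ph, params)$ca
}

#' Total sodium concentration of the dosed medium
#'
#' @param dose NaHCO3 dose in mM.
#' @param baseline_na Sodium contributed by the base medium and buffer
#'   adjustment, mM. The default 32.0 mM reproduces the reported totals for a
#'   BG-11 + 20 mM HEPES medium adjusted to pH 7.5 with NaOH.
#' @return Total Na+ in mM, rounded to 1 decimal.
#' @export
total_sodium <- function(dose, baseline_na = 32.0) {
  stopifnot(all(dose >= 0), all(baseline_na >= 0))
  round(dose + baseline_na, 1)
}

#' Equilibrium pH of a dosed medium under CO2 bubbling
#'
#' Inverts the dosing model: finds the pH at which the predicted carbonate
#' alkalinity equals the supplied alkalinity `ca` (the NaHCO3 dose). With
#' `water = TRUE` the full charge balance `ca + [H+] = [OH-] + CA(ph)` is
#' solved instead, which matters only at very low alkalinity (for `ca = 0` it
#' yields the pH of a pure CO2 solution, ~4.2 at 30% CO2).
#'
#' @param ca Carbonate alkalinity supplied (NaHCO3 dose), mM.
#' @param pco2 CO2 partial pressure, atm (> 0).
#' @param params A [carbonate_params()] object.
#' @param water Include water self-ionization in the balance (default FALSE,
#'   the exact inverse of [nahco3_dose()]).
#' @param tol Absolute tolerance on the alkalinity residual, mM.
#' @return pH.
#' @examples
#' equilibrium_ph(nahco3_dose(0.30, 7.5), 0.30)  # 7.5
#' @export
equilibrium_ph <- function(ca, pco2, params = carbonate_params(),
                           water = FALSE, tol = 1e-9) {
  stopifnot(length(ca) == 1L, length(pco2) == 1L)
  if (ca < 0) stop("ca must be non-negative")
  if (pco2 <= 0) stop("pco2 must be positive")
  f <- function(ph) {
    sp <- speciate_at_ph(pco2, ph, params)
    res <- ca - sp$ca
    if (water) res <- res + 1000 * (10^(-ph) - 10^(ph - params$pkw))
    res
  }
  lo <- 2; hi <- 12
  if (sign(f(lo)) == sign(f(hi)))
    stop("no sign change on pH in [2, 12]; alkalinity outside model range")
  ph <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  if (abs(f(ph)) > tol)
    stop("pH solver did not reach the requested alkalinity residual")
  ph
}

# Ionization fractions of the diprotic carbonate system at a given pH.
carbonate_alphas <- function(ph, params) {
  h <- 10^(-ph)
  ka1 <- 10^(-params$pka1); ka2 <- 10^(-params$pka2)
  denom <- h^2 + h * ka1 + ka1 * ka2
  list(a0 = h^2 / denom, a1 = h * ka1 / denom, a2 = ka1 * ka2 / denom)
}

# Closed-system pH of c0 mM total carbonate titrated with `acid` mmol HCl per
# litre of initial solution, including dilution by the acid volume.
titration_ph_single <- function(acid, c0, na0, acid_conc, params) {
  dil <- 1 / (1 + acid / (1000 * acid_conc))  # volume factor
  na <- na0 * dil; cl <- acid * dil; tic <- c0 * dil
  f <- function(ph) {
    al <- carbonate_alphas(ph, params)
    oh <- 1000 * 10^(ph - params$pkw)  # mM
    h <- 1000 * 10^(-ph)               # mM
    na + h - cl - oh - tic * (al$a1 + 2 * al$a2)
  }
  if (sign(f(0)) == sign(f(14)))
    stop(sprintf("titration charge balance has no root at acid = %g mmol/L", acid))
  stats::uniroot(f, c(0, 14), tol = 1e-12)$root
}

#' Simulate a closed-system acid titration of sodium carbonate
#'
#' Models the titration used to determine the apparent pKa values: `c0` mM
#' Na2CO3 titrated with HCl of concentration `acid_conc`, assuming total
#' inorganic carbon is conserved (no CO2 degassing during a rapid titration)
#' and accounting for dilution by the added acid volume. The pH at each acid
#' amount solves the charge balance
#' `Na+ + H+ = Cl- + OH- + [HCO3-] + 2 [CO3 2-]`.
#'
#' @param c0 Initial total carbonate, mM.
#' @param acid_conc Acid concentration, M.
#' @param acid_grid Non-negative increasing amounts of acid added, mmol per
#'   litre of initial solution.
#' @param params A [carbonate_params()] object.
#' @param na0 Initial sodium, mM; defaults to `2 * c0` (from Na2CO3).
#' @return An object of class `titration_curve`: list with `acid_added`, `ph`,
#'   `c0`, `acid_conc`.
#' @examples
#' tc <- simulate_titration(20, 1.0, seq(0, 55, by = 1))
#' plot(tc$acid_added, tc$ph, type = "l")
#' @export
simulate_titration <- function(c0, acid_conc, acid_grid,
                               params = carbonate_params(), na0 = 2 * c0) {
  stopifnot(c0 > 0, acid_conc > 0)
  if (any(acid_grid < 0) || is.unsorted(acid_grid))
    stop("acid_grid must be non-negative and increasing")
  ph <- vapply(acid_grid, titration_ph_single, numeric(1),
               c0 = c0, na0 = na0, acid_conc = acid_conc, params = params)
  structure(list(acid_added = acid_grid, ph = ph, c0 = c0,
                 acid_conc = acid_conc, na0 = na0),
            class = "titration_curve")
}

#' Fit apparent pKa values to a titration curve
#'
#' Least-squares fit of the closed-system titration model's two dissociation
#' exponents to an observed pH-versus-acid curve, as used to calibrate the
#' speciation model empirically. The fit minimizes the sum of squared pH
#' residuals over the full curve.
#'
#' @param curve A `titration_curve` (observed pH may have noise).
#' @param params Parameters supplying `pkw`; `pka1`/`pka2` entries are ignored
#'   (they are the fit targets).
#' @param start Starting values `c(pka1, pka2)`.
#' @return List with `pka1`, `pka2`, `residual_sd` and the `optim` fit object.
#' @export
fit_pka <- function(curve, params = carbonate_params(), start = c(6, 10)) {
  stopifnot(inherits(curve, "titration_curve"))
  if (max(curve$acid_added) < 2 * curve$c0 * 0.999)
    stop("titration curve must span both equivalence points (acid >= 2 * c0)")
  model_ph <- function(pka) {
    p <- params; p$pka1 <- pka[1]; p$pka2 <- pka[2]
    vapply(curve$acid_added, titration_ph_single, numeric(1),
           c0 = curve$c0, na0 = curve$na0, acid_conc = curve$acid_conc,
           params = p)
  }
  obj <- function(pka) {
    if (pka[1] >= pka[2]) return(1e6)
    sum((model_ph(pka) - curve$ph)^2)
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  n <- length(curve$ph)
  list(pka1 = fit$par[1], pka2 = fit$par[2],
       residual_sd = sqrt(fit$value / max(1, n - 2)), fit = fit)
}

#' Predicted-chemistry report for a set of CO2 gas fractions
#'
#' One row per gas-phase CO2 fraction: the NaHCO3 dose needed to hold the
#' target pH, the predicted species concentrations, carbonate alkalinity,
#' total inorganic carbon, and the resulting total sodium. Values are
#' unrounded; the conventional report rounding is 3 decimals for species and
#' 3 significant digits for the dose.
#'
#' @param co2_fractions Gas-phase CO2 fractions in \[0, 1\] (= pCO2 in atm at
#'   1 atm total pressure).
#' @param target_ph Target equilibrium pH.
#' @param params A [carbonate_params()] object.
#' @param baseline_na Baseline medium sodium, mM (see [total_sodium()]).
#' @return data.frame with columns `co2_pct`, `nahco3_mM`, `co2_mM`,
#'   `hco3_mM`, `co3_mM`, `ca_mM`, `tic_mM`, `na_total_mM`.
#' @examples
#' run_carbonate_report(c(0.0004, 0.04, 0.15, 0.30))
#' @export
run_carbonate_report <- function(co2_fractions, target_ph = 7.5,
                                 params = carbonate_params(),
                                 baseline_na = 32.0) {
  stopifnot(all(co2_fractions >= 0), all(co2_fractions <= 1))
  if (length(co2_fractions) == 0L) {
    return(data.frame(co2_pct = numeric(0), nahco3_mM = numeric(0),
                      co2_mM = numeric(0), hco3_mM = numeric(0),
                      co3_mM = numeric(0), ca_mM = numeric(0),
                      tic_mM = numeric(0), na_total_mM = numeric(0)))
  }
  sp <- speciate_at_ph(co2_fractions, target_ph, params)
  data.frame(co2_pct = 100 * co2_fractions,
             nahco3_mM = sp$ca,
             co2_mM = sp$co2, hco3_mM = sp$hco3, co3_mM = sp$co3,
             ca_mM = sp$ca, tic_mM = sp$tic,
             na_total_mM = total_sodium(sp$ca, baseline_na))
}
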