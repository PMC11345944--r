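#' Published population PK parameter set
#'
#' Typical values, covariate exponents, between-subject variabilities and
#' residual-error magnitudes of the final two-compartment population model
#' for a 100 mg oral dose, per formulation. Disposition (CL/F 75.23 L/h,
#' V1/F 86.69 L, Q/F 41.43 L/h, V2/F 31.38 L, all per 70 kg) is shared;
#' absorption (`tlag`, `ka`) differs between the immediate-release tablet
#' and the hard capsule.
#'
#' @param formulation `"capsule"` or `"tablet"`
#' @return a [pop_pk_params()] object
#' @export
default_poppk <- function(formulation = c("capsule", "tablet")) {
  formulation <- match.arg(formulation)
  abs_par <- switch(formulation,
    tablet = list(tlag = 0.157, ka = 5.08, bsv_tlag = 77.86, bsv_ka = 107.0),
    capsule = list(tlag = 0.36, ka = 4.88, bsv_tlag = 28.88, bsv_ka = 117.34))
  pop_pk_params(
    tlag = abs_par$tlag, ka = abs_par$ka,
    CL = 75.23, V1 = 86.69, Q = 41.43, V2 = 31.38,
    bsv = c(tlag = abs_par$bsv_tlag, ka = abs_par$bsv_ka,
            CL = 37.61, V1 = 40.69, Q = 0, V2 = 25.75),
    beta_CL = 1.21, beta_V1 = 0.73,
    # the additive residual SD of 0.70 is on the bioanalytical ng/mL
    # (= ug/L) scale of the plasma assay; expressed here in mg/L
    sigma_add = 0.70e-3, sigma_prop = 0.12,
    formulation = formulation)
}

#' Clinical blood-sampling schedule
#'
#' @return sampling times in hours after dosing
#' @export
clinical_times <- function() c(0.5, 1, 1.5, 2, 3, 4, 6, 12, 16, 24)

#' Gastric-motility group prevalences
#'
#' Population fractions of the six motility patterns (sprint, tight,
#' average, gentle stomach, and the two late-emptying lazy patterns).
#'
#' @return named fraction vector summing to 1
#' @export
group_prevalences <- function() {
  c(g1 = 0.27, g2 = 0.22, g3 = 0.18, g4 = 0.13, g5 = 0.13, g6 = 0.07)
}

# In vitro housekeeper-wave (GET) times by group, minutes.
group_get_min <- c(15, 30, 30, 30, 60, 90)

#' Default in vitro dissolution scenario for a motility group
#'
#' Encodes the six apparatus programs: GET at 15/30/30/30/60/90 min for
#' Groups 1-6; two 300 mbar phase-II stress waves at 10 and 13 min for
#' Group 2; a single 200 mbar wave at 5 min for Group 3; no pre-GET stress
#' otherwise. The flow program starts at 50 mL/min, ramps linearly down to
#' 8 mL/min at 14 min, and includes the 110 mL/min x 18 s refill pulse of
#' the gastric-emptying sequence.
#'
#' @param group group id, 1-6
#' @return a [dissolution_scenario()]
#' @export
default_scenario <- function(group) {
  stopifnot(group %in% 1:6)
  get_min <- group_get_min[group]
  stresses <- switch(as.character(group),
    `2` = data.frame(time_min = c(10, 13), mbar = c(300, 300),
                     kind = "phaseII"),
    `3` = data.frame(time_min = 5, mbar = 200, kind = "phaseII"),
    data.frame(time_min = numeric(0), mbar = numeric(0),
               kind = character(0)))
  dissolution_scenario(group = group, get_min = get_min, stresses = stresses)
}

#' Default capsule release/dissolution parameter sets per group (synthetic)
#'
#' The apparatus study fits one Weibull or double-Weibull release model per
#' motility group; the fitted coefficients themselves are not published, so
#' these shipped defaults are synthetic stand-ins chosen once to reproduce
#' the qualitative behaviour reported for each program: spontaneous
#' disintegration from about 10 min; complete stress-triggered release in
#' Group 2; partial stress-initiated release with a slow second phase in
#' Group 3 (double Weibull); very slow spontaneous release in Group 4;
#' complete spontaneous release before the late GET in Groups 5/6. The
#' dissolution coefficient is the published capsule value z = 1.08 mL/mg/h
#' with solubility 27 mg/mL and a 100 mg dose.
#'
#' @param group group id 1-6, or `"tablet"` for the immediate-release
#'   tablet (disintegration within about a minute)
#' @return a [release_params()] object
#' @export
default_release_params <- function(group) {
  if (identical(group, "tablet"))
    return(release_params(kind = "weibull", tlag = 0, tau = 1, b = 1,
                          z = 1.08, cs = 27, x0 = 100))
  stopifnot(group %in% 1:6)
  args <- switch(as.character(group),
    `1` = list(kind = "weibull", tlag = 10, tau = 30, b = 1.2),
    `2` = list(kind = "weibull", tlag = 10, tau = 1, b = 2),
    `3` = list(kind = "double_weibull", tlag = 5, tau = 8, b = 1.3,
               tau2 = 150, b2 = 1.5, w = 0.5),
    `4` = list(kind = "weibull", tlag = 10, tau = 80, b = 1.3),
    `5` = list(kind = "weibull", tlag = 10, tau = 10, b = 1.5),
    `6` = list(kind = "weibull", tlag = 10, tau = 10, b = 1.5))
  do.call(release_params, c(args, list(z = 1.08, cs = 27, x0 = 100)))
}

# Cubic coefficients (a0 + a1 t + a2 t^2 + a3 t^3, t in h, volume in mL)
# describing small-intestinal segment fluid volumes after ingestion of
# 240 mL water, anchored to fasted-state MRI observations (baseline ~45 mL
# total, transient rise after the drink, re-equilibration by ~1-2 h).
# Synthetic stand-ins; replaceable through the GI config.
default_vol_poly <- function() {
  rbind(
    duodenum     = c(6, 46.0952, -61.1429, 19.0476),
    prox_jejunum = c(15, 75.2381, -100.857, 31.619),
    dist_jejunum = c(12, 46.0952, -61.1429, 19.0476),
    prox_ileum   = c(8, 23.0476, -30.5714, 9.52381),
    dist_ileum   = c(5, 17.2857, -22.9286, 7.14286))
}

#' Default gastrointestinal configuration
#'
#' Physiological constants of the six-compartment absorption-transit model:
#' stomach plus duodenum, proximal/distal jejunum and proximal/distal ileum.
#' Fluid ingested with the dose is 240 mL of water; the basal gastric volume
#' is 35 mL. Continuous gastric emptying is first order in `kge` (1-14 1/h)
#' until the housekeeper wave at `get_h`, after which emptying accelerates
#' to `kge_post` = 100 1/h. Transit between small-intestinal segments uses
#' four fixed constants of 1.4 1/h (about 3.5 h mean small-intestinal
#' residence across five segments) plus a colon-exit constant of 1.4 1/h
#' with no colonic absorption. Absorption of dissolved drug in each
#' small-intestinal segment is first order with rate `2 Peff / R`, with
#' effective permeability `peff` = 1.5e-4 cm/s and effective radius
#' `radius_cm` chosen so that this permeability reproduces the mean tablet
#' Tmax of 0.5 h at the average gastric-emptying constant of 8.5 1/h (see
#' [calibrate_peff()]).
#'
#' @param kge continuous gastric-emptying rate constant (1/h)
#' @param get_h housekeeper-wave (complete gastric emptying) time (h)
#' @param peff effective permeability (cm/s)
#' @param radius_cm effective absorptive radius (cm)
#' @return an object of class `gi_config`
#' @export
default_gi_config <- function(kge = 8.5, get_h = 0.5,
                              peff = 1.5e-4, radius_cm = 0.163) {
  gi_config(kge = kge, get_h = get_h, kge_post = 100,
            kt = rep(1.4, 4), k_colon = 1.4,
            radius_cm = radius_cm, peff = peff,
            water_ml = 240, v_basal_ml = 35,
            vol_poly = default_vol_poly(), vol_poly_tmax = 2,
            vol_floor_ml = 1)
}

#' Construct a gastrointestinal configuration
#'
#' @param kge continuous gastric-emptying rate constant (1/h); physiological
#'   range 1-14
#' @param get_h housekeeper-wave time (h), > 0
#' @param kge_post gastric-emptying constant after the housekeeper wave (1/h)
#' @param kt vector of four inter-segment small-intestinal transit
#'   constants (1/h)
#' @param k_colon distal-ileum-to-colon exit constant (1/h)
#' @param radius_cm effective absorptive radius (cm)
#' @param peff effective permeability (cm/s)
#' @param water_ml co-ingested water volume (mL)
#' @param v_basal_ml basal (residual) gastric fluid volume (mL)
#' @param vol_poly 5 x 4 matrix of cubic coefficients (rows: duodenum,
#'   proximal jejunum, distal jejunum, proximal ileum, distal ileum) giving
#'   segment fluid volume (mL) as a function of time (h)
#' @param vol_poly_tmax time (h) beyond which the polynomials are held at
#'   their end value (no extrapolation outside the fitted range)
#' @param vol_floor_ml positive floor on segment volumes (mL)
#' @return an object of class `gi_config`
#' @export
gi_config <- function(kge, get_h, kge_post = 100, kt = rep(1.4, 4),
                      k_colon = 1.4, radius_cm = 0.163, peff = 1.5e-4,
                      water_ml = 240, v_basal_ml = 35,
                      vol_poly = default_vol_poly(), vol_poly_tmax = 2,
                      vol_floor_ml = 1) {
  if (kge <= 0 || kge_post <= 0 || any(kt <= 0) || k_colon <= 0)
    stop("all rate constants must be positive")
  if (get_h <= 0) stop("GET must be positive")
  if (length(kt) != 4L) stop("kt must have four inter-segment constants")
  vol_poly <- as.matrix(vol_poly)
  if (nrow(vol_poly) != 5L || ncol(vol_poly) != 4L)
    stop("vol_poly must be a 5 x 4 coefficient matrix")
  structure(list(kge = kge, get_h = get_h, kge_post = kge_post, kt = kt,
                 k_colon = k_colon, radius_cm = radius_cm, peff = peff,
                 water_ml = water_ml, v_basal_ml = v_basal_ml,
                 vol_poly = vol_poly, vol_poly_tmax = vol_poly_tmax,
                 vol_floor_ml = vol_floor_ml),
            class = "gi_config")
}

#' @export
print.gi_config <- function(x, ...) {
  cat("GI configuration: kge ", x$kge, " 1/h (", x$kge_post,
      " after GET at ", x$get_h, " h), Peff ", x$peff,
      " cm/s, radius ", x$radius_cm, " cm\n", sep = "")
  invisible(x)
}

#' Motility-group scenario for in vivo simulation
#'
#' In vivo counterpart of the six dissolution programs. GET times follow the
#' apparatus programs converted to hours (0.25/0.5/0.5/0.5/1.0/1.5 h for
#' Groups 1-6). In the final simulation rules, Groups 5 and 6 borrow the
#' Group 3 release parameters (early gentle phase-II stresses opening the
#' capsule despite the late housekeeper wave), and the gastric-emptying
#' constant is fixed at 3 1/h for Group 2 and 2 1/h for Groups 5 and 6,
#' otherwise drawn uniformly from 3-14 1/h.
#'
#' @param group group id, 1-6
#' @param final if `TRUE` (default) apply the final simulation rules;
#'   otherwise each group uses its own release parameters and the uniform
#'   3-14 1/h emptying rule
#' @return an object of class `motility_scenario` with fields `group`,
#'   `get_h`, `release_group`, `kge_rule`
#' @export
motility_scenario <- function(group, final = TRUE) {
  stopifnot(group %in% 1:6)
  get_h <- c(0.25, 0.5, 0.5, 0.5, 1.0, 1.5)[group]
  release_group <- if (final && group %in% c(5, 6)) 3L else as.integer(group)
  kge_rule <-
    if (final && group == 2) list(type = "fixed", value = 3)
    else if (final && group %in% c(5, 6)) list(type = "fixed", value = 2)
    else list(type = "uniform", min = 3, max = 14)
  structure(list(group = as.integer(group), get_h = get_h,
                 release_group = release_group, kge_rule = kge_rule),
            class = "motility_scenario")
}

#' Final simulation scenario set for all six groups
#'
#' @param final apply the final simulation rules (see [motility_scenario()])
#' @return list of six [motility_scenario()] objects
#' @export
motility_scenarios <- function(final = TRUE) {
  lapply(1:6, motility_scenario, final = final)
}
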