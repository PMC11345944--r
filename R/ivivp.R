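#' Gastric fluid volume over time
#'
#' `V_g(t) = V_basal + water * exp(-kge * t)` before the housekeeper wave;
#' the basal volume afterwards. Models first-order emptying of the 240 mL
#' of water co-ingested with the dose.
#'
#' @param t time (h), vectorised
#' @param cfg a [gi_config()]
#' @param kge gastric-emptying constant (1/h); defaults to `cfg$kge`
#' @param get_h housekeeper-wave time (h); defaults to `cfg$get_h`
#' @return gastric fluid volume (mL)
#' @export
gastric_volume <- function(t, cfg, kge = cfg$kge, get_h = cfg$get_h) {
  stopifnot(inherits(cfg, "gi_config"))
  ifelse(t < get_h,
         cfg$v_basal_ml + cfg$water_ml * exp(-kge * t),
         cfg$v_basal_ml)
}

#' Small-intestinal segment fluid volume
#'
#' Evaluates the configured cubic polynomial for the segment at `t`
#' (held at its end value beyond `vol_poly_tmax`, i.e. the fitted range is
#' not extrapolated), multiplies the duodenal volume by `exp(eta_abs)`
#' (the absorption-variability mapping), and floors the result at
#' `vol_floor_ml`.
#'
#' @param t time (h), vectorised
#' @param segment segment index 1-5 (duodenum .. distal ileum) or row name
#' @param cfg a [gi_config()]
#' @param eta_abs log-scale absorption-variability deviate applied to the
#'   duodenal volume only
#' @return fluid volume (mL)
#' @export
intestinal_volume <- function(t, segment, cfg, eta_abs = 0) {
  stopifnot(inherits(cfg, "gi_config"))
  if (is.character(segment)) segment <- match(segment, rownames(cfg$vol_poly))
  if (is.na(segment) || !segment %in% 1:5)
    stop("segment must identify one of the five small-intestinal segments")
  co <- cfg$vol_poly[segment, ]
  tc <- pmin(t, cfg$vol_poly_tmax)
  v <- co[1] + co[2] * tc + co[3] * tc^2 + co[4] * tc^3
  if (segment == 1L) v <- v * exp(eta_abs)
  pmax(v, cfg$vol_floor_ml)
}

# State layout of the absorption-transit system (amounts in mg):
# 1 E     encapsulated solid (stomach)
# 2 St    free solid, stomach          3 Dt  dissolved, stomach
# 4:8     free solid, SI segments 1-5  9:13  dissolved, SI segments 1-5
# 14 Ac   central compartment          15 Ap peripheral compartment
# 16 El   eliminated (cumulative)
# 17 CS   solid lost to colon          18 CD  dissolved lost to colon
gi_state_names <- c("E", "St", "Dt", paste0("S", 1:5), paste0("D", 1:5),
                    "Ac", "Ap", "El", "ColS", "ColD")

#' Simulate one subject through the absorption-transit model
#'
#' Integrates the six-compartment gastrointestinal system coupled to the
#' two-compartment disposition model. Capsule release (Weibull, gastric
#' lumen only) produces free solid; solid dissolves by the modified
#' Noyes-Whitney rate in the local, time-varying fluid volume; free solid
#' and dissolved drug empty from the stomach at the continuous first-order
#' rate `kge` while the intact capsule is retained; at the housekeeper wave
#' (`get_h`) remaining encapsulated drug becomes free solid and the
#' emptying constant switches to `cfg$kge_post` (100 1/h); transit through
#' the small-intestinal segments uses the four fixed constants plus a colon
#' exit; dissolved drug in each small-intestinal segment is absorbed with
#' first-order constant `2 Peff / R` into the central compartment. No
#' precipitation and no colonic absorption are modelled.
#'
#' @param ind an [individual_pk_params()] supplying CL, V1, Q, V2 (its
#'   `ka`/`tlag` are not used: absorption is mechanistic)
#' @param release a [release_params()]; minute-scale parameters are
#'   converted to hours internally
#' @param cfg a [gi_config()]
#' @param times output times (h)
#' @param scenario optional [motility_scenario()] overriding `get_h`
#' @param kge gastric-emptying constant (1/h); defaults to `cfg$kge`
#' @param eta_abs log-scale deviate applied to the duodenal fluid volume
#' @param dose dose (mg)
#' @param rtol,atol integrator tolerances
#' @param keep_states attach the full amounts trajectory as attribute
#'   `"states"`
#' @return a [plasma_profile()] (`C = A_c / V_1`)
#' @export
simulate_subject <- function(ind, release, cfg, times,
                             scenario = NULL, kge = NULL, eta_abs = 0,
                             dose = 100, rtol = 1e-8, atol = 1e-8,
                             keep_states = FALSE) {
  stopifnot(inherits(ind, "individual_pk_params"),
            inherits(release, "release_params"),
            inherits(cfg, "gi_config"))
  if (dose < 0) stop("dose must be >= 0")
  get_h <- if (!is.null(scenario)) scenario$get_h else cfg$get_h
  if (is.null(kge)) kge <- cfg$kge

  # release parameters on the hour scale
  rel_h <- release
  rel_h$tlag <- release$tlag / 60
  rel_h$tau <- release$tau / 60
  if (!is.null(release$tau2)) rel_h$tau2 <- release$tau2 / 60
  rel_h$x0 <- dose

  th <- ind$theta
  k10 <- th[["CL"]] / th[["V1"]]
  k12 <- th[["Q"]] / th[["V1"]]
  k21 <- th[["Q"]] / th[["V2"]]
  k_abs <- 2 * cfg$peff * 3600 / cfg$radius_cm  # cm/s -> 1/h
  kt <- cfg$kt
  k_colon <- cfg$k_colon
  z <- release$z
  cs <- release$cs
  x0_cbrt <- dose^(1 / 3)
  vp <- cfg$vol_poly
  vp[1, ] <- vp[1, ] * exp(eta_abs)
  tmax_poly <- cfg$vol_poly_tmax
  v_floor <- cfg$vol_floor_ml
  v_basal <- cfg$v_basal_ml
  water <- cfg$water_ml

  # parameter vector for the compiled RHS (see src/models.c, gi_derivs)
  gi_parms <- function(post) {
    c(if (post) cfg$kge_post else kge,   # kge_eff
      as.numeric(!post),                 # release_on
      dose, z, cs, x0_cbrt, k_abs,
      kt, k_colon, k10, k12, k21,
      v_basal, water, kge, tmax_poly, v_floor,
      as.vector(t(vp)),
      pack_release(rel_h))
  }

  t_end <- max(times)
  y <- stats::setNames(numeric(18), gi_state_names)
  y["E"] <- dose
  out_t <- numeric(0)
  out_y <- NULL
  phases <- if (t_end > get_h) {
    list(c(0, get_h, FALSE), c(get_h, t_end, TRUE))
  } else list(c(0, t_end, FALSE))
  for (ph in phases) {
    t0 <- ph[1]; t1 <- ph[2]; post <- as.logical(ph[3])
    tt <- sort(unique(c(t0, times[times > t0 & times <= t1], t1)))
    if (length(tt) < 2L) tt <- c(t0, t1)
    if (dose > 0) {
      # cap the step before the housekeeper wave so the solver cannot step
      # over a narrow Weibull release pulse
      hmax_pre <- max(min(0.02, rel_h$tau / 4,
                          if (is.null(rel_h$tau2)) Inf else rel_h$tau2 / 4),
                      1e-3)
      sol <- deSolve::lsoda(y, tt, func = "gi_derivs", dllname = "gastroPK",
                            initfunc = "gi_initpar", parms = gi_parms(post),
                            rtol = rtol, atol = atol, maxsteps = 50000,
                            hmax = if (post) NULL else hmax_pre)
      if (nrow(sol) < length(tt))
        stop("integration did not reach the end of the phase")
    } else {
      sol <- cbind(tt, matrix(0, length(tt), 18))
    }
    keep <- sol[, 1] %in% times & sol[, 1] > t0
    if (t0 == 0 && 0 %in% times) keep[1] <- TRUE
    out_t <- c(out_t, sol[keep, 1])
    out_y <- rbind(out_y, sol[keep, -1, drop = FALSE])
    y <- sol[nrow(sol), -1]
    if (!post && t1 == get_h && t_end > get_h) {
      # housekeeper wave: remaining capsule contents become free solid
      y["St"] <- y["St"] + y["E"]
      y["E"] <- 0
    }
  }
  if (length(out_t) != length(times))
    stop("integrator did not reach all requested output times")
  colnames(out_y) <- gi_state_names
  if (dose > 0) {
    total <- rowSums(out_y)
    if (any(abs(total - dose) > 1e-6 * dose))
      stop("mass-balance drift exceeds 1e-6 of the dose")
  }
  conc <- pmax(out_y[, "Ac"] / th[["V1"]], 0)
  prof <- plasma_profile(out_t, conc, dose = dose, formulation = "simulated",
                         grid = if (length(times) > 50) "dense" else "clinical")
  if (keep_states) attr(prof, "states") <- cbind(time = out_t, out_y)
  prof
}

#' Calibrate effective permeability against a target tablet Tmax
#'
#' Scalar root-find on `Peff` such that the dense-grid Tmax of a typical
#' 70 kg subject given the immediate-release tablet equals `target_tmax`
#' (within 0.02 h) at the supplied gastric-emptying constant.
#'
#' @param cfg a [gi_config()]
#' @param target_tmax target time of maximum concentration (h)
#' @param kge gastric-emptying constant used during calibration (1/h)
#' @param release tablet release parameters (immediate by default)
#' @param interval log10 search interval for Peff (cm/s)
#' @param dt dense-grid resolution (h)
#' @return calibrated Peff (cm/s)
#' @export
calibrate_peff <- function(cfg, target_tmax = 0.5, kge = 8.5,
                           release = default_release_params("tablet"),
                           interval = c(-6, -2), dt = 0.005) {
  stopifnot(inherits(cfg, "gi_config"))
  typ <- covariate_scale(default_poppk("tablet"), 70)
  grid <- seq(0, max(4 * target_tmax, 1.5), by = dt)
  tmax_at <- function(log10_peff) {
    cfg2 <- cfg
    cfg2$peff <- 10^log10_peff
    prof <- simulate_subject(typ, release, cfg2, grid, kge = kge,
                             rtol = 1e-8, atol = 1e-8)
    nca(prof)$tmax
  }
  f <- function(lp) tmax_at(lp) - target_tmax
  flo <- f(interval[1]); fhi <- f(interval[2])
  # Tmax decreases with permeability: the low end must be late, the high
  # end early, otherwise the target is unreachable
  if (flo < 0 || fhi > 0)
    stop("target Tmax is not bracketed by the permeability interval")
  root <- stats::uniroot(f, interval, tol = 1e-4)
  peff <- 10^root$root
  if (abs(tmax_at(root$root) - target_tmax) > 0.02)
    stop("calibration did not reach the target Tmax within 0.02 h")
  peff
}

#' Sensitivity of simulated profiles to the gastric-emptying constant
#'
#' Simulates a common set of virtual subjects under each scenario and each
#' gastric-emptying constant on the grid, and summarises the plasma
#' profiles as mean and SD per time point.
#'
#' @param scenarios list of [motility_scenario()] objects
#' @param kge_grid gastric-emptying constants (1/h), each within 1-14
#' @param n_subjects number of virtual subjects (shared across cells)
#' @param seed integer seed for the subject draw
#' @param pop a [pop_pk_params()] (capsule by default)
#' @param cfg a [gi_config()]
#' @param release_sets list mapping group id to [release_params()]
#' @param times output times (h)
#' @return data.frame with columns `group, kge, time_h, mean, sd`
#' @export
kge_sensitivity <- function(scenarios, kge_grid, n_subjects = 12,
                            seed = NULL, pop = default_poppk("capsule"),
                            cfg = default_gi_config(),
                            release_sets = lapply(1:6, default_release_params),
                            times = seq(0, 6, by = 0.1)) {
  if (any(kge_grid < 1 | kge_grid > 14))
    stop("kge grid must lie within the physiological 1-14 1/h range")
  inds <- sample_individuals(pop, n_subjects, seed = seed)
  out <- list()
  for (sc in scenarios) {
    rel <- release_sets[[sc$release_group]]
    for (kge in kge_grid) {
      profs <- vapply(inds, function(ind)
        simulate_subject(ind, rel, cfg, times, scenario = sc, kge = kge,
                         eta_abs = ind$eta[["ka"]])$conc,
        numeric(length(times)))
      out[[length(out) + 1L]] <- data.frame(
        group = sc$group, kge = kge, time_h = times,
        mean = rowMeans(profs),
        sd = apply(profs, 1, stats::sd))
    }
  }
  do.call(rbind, out)
}

#' Count concentration peaks in a plasma profile
#'
#' Counts strict local maxima whose topographic prominence exceeds a
#' fraction of Cmax; a late housekeeper wave combined with slow continuous
#' emptying produces the double-peak phenomenon.
#'
#' @param profile a [plasma_profile()] on a dense grid
#' @param prominence_frac minimum prominence as a fraction of Cmax
#' @return integer count of local maxima (0 for a flat profile)
#' @export
detect_double_peak <- function(profile, prominence_frac = 0.05) {
  stopifnot(inherits(profile, "plasma_profile"))
  cc <- profile$conc
  cmax <- max(cc)
  if (cmax <= 0) return(0L)
  # collapse plateaus so strict comparisons see one value per run
  r <- rle(cc)
  v <- r$values
  n <- length(v)
  if (n < 3L) {
    return(if (n == 1L) 0L else as.integer(which.max(v) != n && which.max(v) != 1))
  }
  peaks <- which(v[-c(1, n)] > v[-c(n - 1, n)] & v[-c(1, n)] > v[-(1:2)]) + 1L
  # a profile rising to a single crest counts through the boundary check
  if (!length(peaks) && which.max(v) %in% 2:(n - 1)) peaks <- which.max(v)
  count <- 0L
  for (i in peaks) {
    h <- v[i]
    left <- v[seq_len(i - 1)]
    right <- v[seq(i + 1, n)]
    higher_l <- which(left > h)
    higher_r <- which(right > h)
    base_l <- min(left[seq(if (length(higher_l)) max(higher_l) else 1,
                           i - 1)])
    base_r <- min(right[seq_len(if (length(higher_r)) min(higher_r)
                                else length(right))])
    prom <- h - max(base_l, base_r)
    if (prom >= prominence_frac * cmax) count <- count + 1L
  }
  count
}
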