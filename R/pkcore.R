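#' Population pharmacokinetic parameter set
#'
#' Container for the typical values, covariate exponents, between-subject
#' variabilities (BSV) and residual-error terms of a two-compartment oral
#' disposition model with lag time and first-order absorption. All apparent
#' parameters (CL/F, V1/F, Q/F, V2/F) are scaled to a 70 kg reference body
#' weight; BSV is expressed as a percent coefficient of variation on the
#' log-normal scale.
#'
#' @param tlag lag time before absorption starts (h)
#' @param ka first-order absorption rate constant (1/h)
#' @param CL apparent clearance CL/F (L/h per 70 kg)
#' @param V1 apparent central volume V1/F (L per 70 kg)
#' @param Q apparent intercompartmental clearance Q/F (L/h per 70 kg)
#' @param V2 apparent peripheral volume V2/F (L)
#' @param bsv named numeric vector of BSV (% CV) for any of
#'   `tlag, ka, CL, V1, Q, V2`; omitted names default to 0
#' @param beta_CL,beta_V1 allometric exponents on body weight (centred at
#'   70 kg) for CL/F and V1/F
#' @param sigma_add additive residual error SD (mg/L)
#' @param sigma_prop proportional residual error SD (fraction)
#' @param eta_cor optional 6x6 correlation matrix for the log-scale random
#'   effects, ordered as `tlag, ka, CL, V1, Q, V2`; identity when `NULL`
#' @param formulation label carried through to simulated profiles
#'
#' @return an object of class `pop_pk_params`
#' @seealso [default_poppk()] for the published parameter set
#' @export
pop_pk_params <- function(tlag, ka, CL, V1, Q, V2,
                          bsv = numeric(0),
                          beta_CL = 0, beta_V1 = 0,
                          sigma_add = 0, sigma_prop = 0,
                          eta_cor = NULL,
                          formulation = "capsule") {
  theta <- c(tlag = tlag, ka = ka, CL = CL, V1 = V1, Q = Q, V2 = V2)
  if (any(!is.finite(theta)) || any(theta[-1] <= 0) || theta[["tlag"]] < 0)
    stop("all typical values must be positive (tlag may be zero)")
  full_bsv <- c(tlag = 0, ka = 0, CL = 0, V1 = 0, Q = 0, V2 = 0)
  if (length(bsv)) {
    if (is.null(names(bsv)) || !all(names(bsv) %in% names(full_bsv)))
      stop("bsv must be named with a subset of: ",
           paste(names(full_bsv), collapse = ", "))
    if (any(bsv < 0)) stop("BSV must be >= 0")
    full_bsv[names(bsv)] <- bsv
  }
  if (sigma_add < 0 || sigma_prop < 0) stop("residual error SDs must be >= 0")
  if (!is.null(eta_cor)) {
    eta_cor <- as.matrix(eta_cor)
    if (!isTRUE(all.equal(eta_cor, t(eta_cor))) ||
        !isTRUE(all.equal(unname(diag(eta_cor)), rep(1, 6))) ||
        min(eigen(eta_cor, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("eta_cor must be a symmetric PSD correlation matrix with unit diagonal")
  }
  structure(
    list(theta = theta, bsv = full_bsv,
         beta = c(CL = beta_CL, V1 = beta_V1),
         sigma_add = sigma_add, sigma_prop = sigma_prop,
         eta_cor = eta_cor, formulation = formulation),
    class = "pop_pk_params")
}

#' @export
print.pop_pk_params <- function(x, ...) {
  cat("Population PK parameters (", x$formulation, ")\n", sep = "")
  tab <- data.frame(typical = x$theta, `BSV %` = x$bsv, check.names = FALSE)
  print(round(tab, 4))
  cat("beta (weight/70): CL ", x$beta[["CL"]], ", V1 ", x$beta[["V1"]], "\n",
      "residual error: additive ", x$sigma_add, " mg/L, proportional ",
      x$sigma_prop, "\n", sep = "")
  invisible(x)
}

pk_par_names <- c("tlag", "ka", "CL", "V1", "Q", "V2")

#' Individual pharmacokinetic parameter realisation
#'
#' @param subject subject identifier
#' @param weight body weight (kg)
#' @param tlag,ka,CL,V1,Q,V2 realised individual parameters (same units as
#'   [pop_pk_params()])
#' @param eta named log-scale random-effect vector (may be zero)
#' @return an object of class `individual_pk_params`
#' @export
individual_pk_params <- function(subject = 1L, weight = 70,
                                 tlag, ka, CL, V1, Q, V2,
                                 eta = stats::setNames(numeric(6), pk_par_names)) {
  if (weight <= 0) stop("weight must be positive")
  th <- c(tlag = tlag, ka = ka, CL = CL, V1 = V1, Q = Q, V2 = V2)
  if (any(th[-1] <= 0) || th[["tlag"]] < 0)
    stop("rates and volumes must be positive (tlag may be zero)")
  structure(list(subject = subject, weight = weight, theta = th, eta = eta),
            class = "individual_pk_params")
}

#' @export
print.individual_pk_params <- function(x, ...) {
  cat("Individual PK parameters, subject ", x$subject,
      " (", x$weight, " kg)\n", sep = "")
  print(round(x$theta, 4))
  invisible(x)
}

#' Apply covariate scaling and random effects to typical values
#'
#' Computes the individual parameter vector
#' `theta_i = theta * exp(eta) * (weight/70)^beta`, where the allometric
#' exponent `beta` is nonzero only for CL/F and V1/F.
#'
#' @param pop a [pop_pk_params()] object
#' @param weight body weight in kg (must be > 0)
#' @param eta log-scale random-effect vector, length 6 (ordered
#'   `tlag, ka, CL, V1, Q, V2`) or named; defaults to all-zero
#' @param subject subject identifier to attach
#' @return an [individual_pk_params()] object
#' @export
covariate_scale <- function(pop, weight, eta = numeric(6), subject = 1L) {
  stopifnot(inherits(pop, "pop_pk_params"))
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0)
    stop("weight must be a positive scalar")
  if (is.null(names(eta))) {
    stopifnot(length(eta) == 6L)
    names(eta) <- pk_par_names
  }
  eta_full <- stats::setNames(numeric(6), pk_par_names)
  eta_full[names(eta)] <- eta
  wt_scale <- stats::setNames(rep(1, 6), pk_par_names)
  wt_scale["CL"] <- (weight / 70)^pop$beta[["CL"]]
  wt_scale["V1"] <- (weight / 70)^pop$beta[["V1"]]
  th <- pop$theta * exp(eta_full) * wt_scale
  individual_pk_params(subject = subject, weight = weight,
                       tlag = th[["tlag"]], ka = th[["ka"]], CL = th[["CL"]],
                       V1 = th[["V1"]], Q = th[["Q"]], V2 = th[["V2"]],
                       eta = eta_full)
}

bsv_to_omega2 <- function(bsv_pct) log(1 + (bsv_pct / 100)^2)

#' Sample virtual individuals from the population model
#'
#' Random effects are drawn from a multivariate normal on the log scale with
#' variances `log(1 + (BSV/100)^2)` and the configured eta correlation
#' (identity by default). Body weight is either fixed at 70 kg or drawn
#' log-normally with median 70 kg and a 15% CV.
#'
#' @param pop a [pop_pk_params()] object
#' @param n number of subjects (>= 1)
#' @param seed optional integer seed for reproducibility
#' @param weight_source `"fixed"` (all 70 kg) or `"lognormal"`
#' @return a list of [individual_pk_params()] objects
#' @export
sample_individuals <- function(pop, n, seed = NULL,
                               weight_source = c("fixed", "lognormal")) {
  stopifnot(inherits(pop, "pop_pk_params"), n >= 1)
  weight_source <- match.arg(weight_source)
  if (!is.null(seed)) set.seed(seed)
  omega <- sqrt(bsv_to_omega2(pop$bsv))
  cor_mat <- if (is.null(pop$eta_cor)) diag(6) else pop$eta_cor
  Sigma <- diag(omega) %*% cor_mat %*% diag(omega)
  eta <- MASS::mvrnorm(n, mu = numeric(6), Sigma = Sigma, tol = 1e-6)
  if (n == 1L) eta <- matrix(eta, nrow = 1)
  colnames(eta) <- pk_par_names
  weights <- switch(weight_source,
    fixed = rep(70, n),
    lognormal = 70 * exp(stats::rnorm(n, 0, sqrt(log(1 + 0.15^2)))))
  lapply(seq_len(n), function(i)
    covariate_scale(pop, weights[i], eta[i, ], subject = i))
}

#' Plasma concentration-time profile
#'
#' @param times sampling times (h), strictly increasing
#' @param conc concentrations (mg/L), finite and >= 0 (residual error may
#'   later push values to the zero floor)
#' @param dose administered dose (mg)
#' @param formulation formulation label
#' @param grid `"dense"` or `"clinical"`
#' @return an object of class `plasma_profile`
#' @export
plasma_profile <- function(times, conc, dose = 100,
                           formulation = "capsule",
                           grid = c("clinical", "dense")) {
  grid <- match.arg(grid)
  if (length(times) != length(conc)) stop("times and conc lengths differ")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(!is.finite(conc))) stop("concentrations must be finite")
  structure(list(times = as.numeric(times), conc = as.numeric(conc),
                 dose = dose, formulation = formulation, grid = grid),
            class = "plasma_profile")
}

#' @export
print.plasma_profile <- function(x, ...) {
  cat("Plasma profile (", x$formulation, ", ", x$dose, " mg, ", x$grid,
      " grid): ", length(x$times), " points, Cmax ",
      signif(max(x$conc), 4), " mg/L\n", sep = "")
  invisible(x)
}

# Integrate the 4-state oral two-compartment system (compiled RHS).
two_cpt_solve <- function(theta, dose, tau, rtol, atol) {
  parms <- c(theta[["ka"]], theta[["CL"]] / theta[["V1"]],
             theta[["Q"]] / theta[["V1"]], theta[["Q"]] / theta[["V2"]])
  deSolve::lsoda(y = c(dose, 0, 0, 0), times = tau,
                 func = "twocpt_derivs", dllname = "gastroPK",
                 initfunc = "twocpt_initpar", parms = parms,
                 rtol = rtol, atol = atol)
}

#' Simulate a plasma profile from individual parameters
#'
#' Solves the two-compartment oral-absorption system
#' \deqn{dA_a/dt = -k_a A_a,\quad
#'       dA_c/dt = k_a A_a - (CL/V_1 + Q/V_1) A_c + (Q/V_2) A_p,\quad
#'       dA_p/dt = (Q/V_1) A_c - (Q/V_2) A_p}
#' with absorption starting at `tlag` (the integration restarts at the lag
#' time so the event is resolved exactly) and reports `C = A_c/V_1`.
#'
#' @param ind an [individual_pk_params()] object
#' @param dose dose (mg), >= 0
#' @param times output times (h), sorted
#' @param grid grid tag recorded on the result
#' @param keep_states if `TRUE`, attach the amounts matrix (`Aa, Ac, Ap,
#'   eliminated`) as attribute `"states"` for mass-balance diagnostics
#' @param rtol,atol integrator tolerances
#' @return a [plasma_profile()]
#' @export
simulate_plasma <- function(ind, dose, times, grid = "clinical",
                            keep_states = FALSE, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(ind, "individual_pk_params"))
  if (dose < 0) stop("dose must be >= 0")
  if (is.unsorted(times)) stop("times must be sorted")
  p <- ind$theta
  conc <- numeric(length(times))
  states <- matrix(0, nrow = length(times), ncol = 4,
                   dimnames = list(NULL, c("Aa", "Ac", "Ap", "eliminated")))
  states[, "Aa"] <- ifelse(times < p[["tlag"]], dose, 0)
  post <- times > p[["tlag"]]
  if (dose > 0 && any(post)) {
    tau <- c(0, times[post] - p[["tlag"]])
    sol <- two_cpt_solve(p, dose, tau, rtol, atol)
    sol <- sol[-1, , drop = FALSE]
    conc[post] <- sol[, 3] / p[["V1"]]
    states[post, ] <- sol[, 2:5]
    states[times == p[["tlag"]], "Aa"] <- dose
  } else if (dose > 0) {
    states[times == p[["tlag"]], "Aa"] <- dose
  }
  out <- plasma_profile(times, pmax(conc, 0), dose = dose,
                        formulation = "simulated",
                        grid = match.arg(grid, c("clinical", "dense")))
  if (keep_states) attr(out, "states") <- states
  out
}

#' Add combined additive + proportional residual error
#'
#' Observations are generated as `y = f (1 + eps_prop) + eps_add` with
#' independent zero-mean normal errors, then floored at zero.
#'
#' @param profile a [plasma_profile()]
#' @param pop a [pop_pk_params()] supplying `sigma_add` (mg/L) and
#'   `sigma_prop` (fraction)
#' @param seed optional integer seed
#' @return a [plasma_profile()] with perturbed concentrations
#' @export
add_residual_error <- function(profile, pop, seed = NULL) {
  stopifnot(inherits(profile, "plasma_profile"), inherits(pop, "pop_pk_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(profile$conc)
  y <- profile$conc * (1 + stats::rnorm(n, 0, pop$sigma_prop)) +
    stats::rnorm(n, 0, pop$sigma_add)
  profile$conc <- pmax(y, 0)
  profile
}

#' Noncompartmental analysis of a plasma profile
#'
#' Computes `Cmax` and `Tmax` from the grid maximum (earliest time on ties),
#' `AUC_last` by the linear trapezoidal rule, and the concentration at 0.5 h
#' by exact lookup or linear interpolation.
#'
#' @param profile a [plasma_profile()] with at least two points
#' @return a list of class `nca_result` with elements `cmax`, `tmax`,
#'   `auc_last`, `c_05` (NA when 0.5 h precedes the first sample)
#' @export
nca <- function(profile) {
  stopifnot(inherits(profile, "plasma_profile"))
  tt <- profile$times; cc <- profile$conc
  if (length(tt) < 2L) stop("profile must have at least two time points")
  imax <- which.max(cc)  # which.max returns the first maximum: earliest tie
  auc <- sum(diff(tt) * (head_(cc) + tail_(cc)) / 2)
  c05 <- if (0.5 < tt[1]) NA_real_ else stats::approx(tt, cc, xout = 0.5)$y
  structure(list(cmax = cc[imax], tmax = tt[imax], auc_last = auc, c_05 = c05),
            class = "nca_result")
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1]

#' @export
print.nca_result <- function(x, ...) {
  cat("NCA: Cmax ", signif(x$cmax, 4), " mg/L at Tmax ", x$tmax,
      " h; AUC_last ", signif(x$auc_last, 5), " mg*h/L; C(0.5 h) ",
      signif(x$c_05, 4), " mg/L\n", sep = "")
  invisible(x)
}

#' Two-stage individual fit of the two-compartment oral model
#'
#' Fits `tlag, ka, CL, V1, Q, V2` to one subject's observed concentrations by
#' weighted least squares with `1/Ypred^2` weights (Levenberg-Marquardt).
#' When a reference tablet fit is supplied, the disposition parameters
#' (CL, V1, Q, V2) are constrained to within 20% of the reference values,
#' reflecting formulation-independent disposition. The lag time is
#' initialised at the midpoint of `(t_first - 0.5 h, t_first)`, where
#' `t_first` is the first observed time, and three jittered starts guard
#' against local minima in `tlag`.
#'
#' @param observed a [plasma_profile()] with at least 6 points
#' @param init an [individual_pk_params()] giving starting values
#' @param tablet_ref optional [individual_pk_params()] whose disposition
#'   parameters anchor the +/-20% bounds
#' @param n_starts number of jittered starts (first start is unjittered)
#' @param seed optional seed controlling the jitter
#' @return an [individual_pk_params()] with a `fit` element: list with
#'   `converged`, `ssr`, `info`, `message`. Non-convergence and degenerate
#'   inputs are flagged, never raised.
#' @export
fit_individual <- function(observed, init, tablet_ref = NULL,
                           n_starts = 3L, seed = NULL) {
  stopifnot(inherits(observed, "plasma_profile"),
            inherits(init, "individual_pk_params"))
  if (length(observed$times) < 6L)
    stop("at least 6 observed points are required")
  if (!is.null(seed)) set.seed(seed)
  yobs <- observed$conc
  flagged <- function(msg) {
    out <- init
    out$fit <- list(converged = FALSE, ssr = NA_real_, info = NA_integer_,
                    message = msg)
    out
  }
  if (max(yobs) <= 0) return(flagged("all observations are zero"))

  t_first <- observed$times[1]
  tlag0 <- max(mean(c(t_first - 0.5, t_first)), 0)
  theta0 <- init$theta
  theta0["tlag"] <- tlag0

  lower <- c(tlag = 0, ka = 0.05, CL = theta0[["CL"]] / 50,
             V1 = theta0[["V1"]] / 50, Q = theta0[["Q"]] / 50,
             V2 = theta0[["V2"]] / 50)
  upper <- c(tlag = t_first, ka = 60, CL = theta0[["CL"]] * 50,
             V1 = theta0[["V1"]] * 50, Q = theta0[["Q"]] * 50,
             V2 = theta0[["V2"]] * 50)
  if (!is.null(tablet_ref)) {
    for (nm in c("CL", "V1", "Q", "V2")) {
      lower[nm] <- 0.8 * tablet_ref$theta[[nm]]
      upper[nm] <- 1.2 * tablet_ref$theta[[nm]]
      theta0[nm] <- min(max(theta0[[nm]], lower[[nm]]), upper[[nm]])
    }
  }
  # floor on Ypred in the 1/Ypred^2 weights: without it, points predicted
  # near zero (late terminal samples) would dominate the objective through
  # their additive assay noise
  eps <- max(1e-3, 5e-3 * max(yobs))
  resid_fun <- function(par) {
    th <- stats::setNames(pmin(pmax(par, lower), upper), pk_par_names)
    ind <- init
    ind$theta <- th
    pred <- simulate_plasma(ind, observed$dose, observed$times,
                            rtol = 1e-8, atol = 1e-10)$conc
    (yobs - pred) / pmax(pred, eps)
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- theta0
    if (s > 1L) {
      start[-1] <- start[-1] * exp(stats::rnorm(5, 0, 0.15))
      start["tlag"] <- stats::runif(1, max(t_first - 0.5, 0), t_first)
    }
    start <- pmin(pmax(start, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || (is.finite(ssr) && ssr < best$ssr))
      best <- list(par = fit$par, ssr = ssr, info = fit$info,
                   message = fit$message)
  }
  if (is.null(best)) return(flagged("all optimisation starts failed"))

  th <- stats::setNames(pmin(pmax(best$par, lower), upper), pk_par_names)
  out <- individual_pk_params(subject = init$subject, weight = init$weight,
                              tlag = th[["tlag"]], ka = th[["ka"]],
                              CL = th[["CL"]], V1 = th[["V1"]],
                              Q = th[["Q"]], V2 = th[["V2"]],
                              eta = init$eta)
  out$fit <- list(converged = best$info %in% 1:3 && is.finite(best$ssr),
                  ssr = best$ssr, info = best$info, message = best$message)
  out
}
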