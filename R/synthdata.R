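#' Specification of a synthetic crossover trial
#'
#' Defaults emulate the study conditions: 118 subjects, 100 mg dose given
#' as an immediate-release tablet (2 x 50 mg) and a capsule (1 x 100 mg),
#' clinical blood sampling at 0.5, 1, 1.5, 2, 3, 4, 6, 12, 16 and 24 h,
#' group prevalences 27/22/18/13/13/7%, log-normal between-subject
#' variability and combined residual error.
#'
#' @param n number of subjects
#' @param times sampling schedule (h)
#' @param dose dose (mg)
#' @param prevalences motility-group prevalence vector (sums to 1)
#' @param noise add residual error to the simulated observations?
#' @param weight_source `"fixed"` (70 kg) or `"lognormal"`
#' @param seed integer seed
#' @return object of class `virtual_trial_spec`
#' @export
virtual_trial_spec <- function(n = 118, times = clinical_times(), dose = 100,
                               prevalences = group_prevalences(),
                               noise = TRUE,
                               weight_source = "fixed", seed = 1L) {
  if (abs(sum(prevalences) - 1) > 1e-6) stop("prevalences must sum to 1")
  structure(list(n = n, times = times, dose = dose,
                 prevalences = prevalences, noise = noise,
                 weight_source = weight_source, seed = seed),
            class = "virtual_trial_spec")
}

#' Generate a synthetic crossover trial with known motility ground truth
#'
#' Per subject: disposition random effects are drawn from the capsule
#' population model, the motility group comes from the prevalence-weighted
#' allocation, and the gastric-emptying constant follows the group rule.
#' The tablet profile is simulated through the absorption-transit model
#' with immediate release; the capsule profile uses the group scenario and
#' its release parameters. Residual error is then added (when `noise` is
#' on) and the ground truth is returned alongside the observations.
#'
#' @param spec a [virtual_trial_spec()]
#' @param pop capsule [pop_pk_params()]
#' @param cfg a [gi_config()]
#' @param scenarios list of six [motility_scenario()] objects
#' @param release_sets list mapping group id to [release_params()]
#' @return list with `pk` (long data.frame `subject, time_h, conc_mg_L,
#'   formulation, dose_mg`), `truth` (per-subject group, kge, weight and
#'   realised parameters) and `profiles` (named list of noiseless capsule
#'   [plasma_profile()]s)
#' @export
generate_virtual_trial <- function(spec = virtual_trial_spec(),
                                   pop = default_poppk("capsule"),
                                   cfg = default_gi_config(),
                                   scenarios = motility_scenarios(),
                                   release_sets = lapply(1:6, default_release_params)) {
  stopifnot(inherits(spec, "virtual_trial_spec"))
  set.seed(spec$seed)
  inds <- sample_individuals(pop, spec$n, weight_source = spec$weight_source)
  alloc <- allocate_population(spec$n, spec$prevalences)
  kge <- assign_kge(alloc$labels)
  tablet_rel <- default_release_params("tablet")
  pk_rows <- vector("list", 2L * spec$n)
  truth_rows <- vector("list", spec$n)
  capsule_profiles <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    ind <- inds[[i]]
    sc <- scenarios[[alloc$labels[i]]]
    rel <- release_sets[[sc$release_group]]
    tab <- simulate_subject(ind, tablet_rel, cfg, spec$times,
                            kge = kge[i], eta_abs = ind$eta[["ka"]],
                            dose = spec$dose)
    cap <- simulate_subject(ind, rel, cfg, spec$times, scenario = sc,
                            kge = kge[i], eta_abs = ind$eta[["ka"]],
                            dose = spec$dose)
    capsule_profiles[[i]] <- cap
    if (spec$noise) {
      tab <- add_residual_error(tab, pop)
      cap <- add_residual_error(cap, pop)
    }
    pk_rows[[2 * i - 1]] <- data.frame(
      subject = i, time_h = spec$times, conc_mg_L = tab$conc,
      formulation = "tablet", dose_mg = spec$dose)
    pk_rows[[2 * i]] <- data.frame(
      subject = i, time_h = spec$times, conc_mg_L = cap$conc,
      formulation = "capsule", dose_mg = spec$dose)
    truth_rows[[i]] <- data.frame(
      subject = i, group = alloc$labels[i], kge = kge[i],
      weight = ind$weight, CL = ind$theta[["CL"]], V1 = ind$theta[["V1"]],
      Q = ind$theta[["Q"]], V2 = ind$theta[["V2"]],
      eta_abs = ind$eta[["ka"]])
  }
  names(capsule_profiles) <- as.character(seq_len(spec$n))
  list(pk = do.call(rbind, pk_rows), truth = do.call(rbind, truth_rows),
       profiles = capsule_profiles)
}

#' Generate noisy in vitro dissolution fixtures with known parameters
#'
#' Simulates each scenario with its true release parameters, then adds
#' additive Gaussian noise (in percent of dose) to every replicate and
#' clips to the physical 0-100% range. Dissolution tests are performed in
#' triplicate by default.
#'
#' @param scenarios list of [dissolution_scenario()] objects
#' @param params_list list of [release_params()] matching `scenarios`
#' @param noise_sd noise SD in percent of dose (>= 0)
#' @param replicates replicates per scenario
#' @param seed integer seed
#' @return data.frame `group, time_min, replicate, dissolved_pct`
#' @export
generate_invitro_fixtures <- function(scenarios = lapply(1:6, default_scenario),
                                      params_list = lapply(1:6, default_release_params),
                                      noise_sd = 2, replicates = 3,
                                      seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  out <- list()
  for (k in seq_along(scenarios)) {
    prof <- simulate_invitro(scenarios[[k]], params_list[[k]])
    for (r in seq_len(replicates)) {
      pct <- prof$dissolved_pct + stats::rnorm(length(prof$times), 0, noise_sd)
      out[[length(out) + 1L]] <- data.frame(
        group = scenarios[[k]]$group, time_min = prof$times,
        replicate = r, dissolved_pct = pmin(pmax(pct, 0), 100))
    }
  }
  do.call(rbind, out)
}

#' Write the default configuration files
#'
#' Emits the population-parameter file (both formulations), the six in
#' vitro scenario files, the release-parameter files, the final in vivo
#' scenario rules and the default GI configuration as YAML into `out_dir`.
#' Regenerating into the same directory reproduces identical files.
#'
#' @param out_dir writable output directory (created if missing)
#' @return invisibly, the paths written
#' @export
make_default_configs <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  wy <- function(x, fname) {
    path <- file.path(out_dir, fname)
    yaml::write_yaml(x, path, precision = 12)
    paths <<- c(paths, path)
  }
  pop_list <- function(pop) list(
    tlag = unname(pop$theta[["tlag"]]), ka = unname(pop$theta[["ka"]]),
    CL = unname(pop$theta[["CL"]]), V1 = unname(pop$theta[["V1"]]),
    Q = unname(pop$theta[["Q"]]), V2 = unname(pop$theta[["V2"]]),
    bsv = as.list(pop$bsv), beta_CL = unname(pop$beta[["CL"]]),
    beta_V1 = unname(pop$beta[["V1"]]), sigma_add = pop$sigma_add,
    sigma_prop = pop$sigma_prop, formulation = pop$formulation)
  wy(list(tablet = pop_list(default_poppk("tablet")),
          capsule = pop_list(default_poppk("capsule"))), "poppk.yaml")

  for (g in 1:6) {
    sc <- default_scenario(g)
    wy(list(group = g, get_min = sc$get_min,
            stresses = if (nrow(sc$stresses))
              lapply(seq_len(nrow(sc$stresses)), function(i)
                list(time_min = sc$stresses$time_min[i],
                     mbar = sc$stresses$mbar[i],
                     kind = sc$stresses$kind[i]))
            else list(),
            v_stress = sc$v_stress, v_res = sc$v_res,
            dt_sample = sc$dt_sample),
       sprintf("scenario_group%d.yaml", g))
    p <- default_release_params(g)
    wy(list(group = g, kind = p$kind, tlag = p$tlag, tau = p$tau, b = p$b,
            tau2 = p$tau2, b2 = p$b2, w = p$w, z = p$z, cs = p$cs,
            x0 = p$x0),
       sprintf("release_group%d.yaml", g))
  }

  cfg <- default_gi_config()
  wy(list(kge = cfg$kge, get_h = cfg$get_h, kge_post = cfg$kge_post,
          kt = cfg$kt, k_colon = cfg$k_colon, radius_cm = cfg$radius_cm,
          peff = cfg$peff, water_ml = cfg$water_ml,
          v_basal_ml = cfg$v_basal_ml,
          vol_poly = lapply(seq_len(nrow(cfg$vol_poly)), function(i)
            list(segment = rownames(cfg$vol_poly)[i],
                 coef = as.numeric(cfg$vol_poly[i, ]))),
          vol_poly_tmax = cfg$vol_poly_tmax,
          vol_floor_ml = cfg$vol_floor_ml), "gi_default.yaml")

  final <- lapply(motility_scenarios(), function(sc)
    list(group = sc$group, get_h = sc$get_h,
         release_group = sc$release_group, kge_rule = sc$kge_rule))
  wy(list(scenarios = final,
          prevalences = as.list(group_prevalences())),
     "final_scenarios.yaml")
  invisible(paths)
}
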