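#' Read a long-format plasma-concentration CSV
#'
#' Expected columns: `subject, time_h, conc_mg_L, formulation, dose_mg`
#' (header mandatory; empty cells become `NA`).
#'
#' @param path CSV file path
#' @return data.frame with those columns
#' @export
read_plasma_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "time_h", "conc_mg_L", "formulation", "dose_mg")
  if (!all(need %in% names(df)))
    stop("plasma CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write a long-format plasma-concentration CSV
#'
#' @param df data.frame with columns `subject, time_h, conc_mg_L,
#'   formulation, dose_mg`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_plasma_csv <- function(df, path) {
  need <- c("subject", "time_h", "conc_mg_L", "formulation", "dose_mg")
  if (!all(need %in% names(df)))
    stop("plasma table must have columns: ", paste(need, collapse = ", "))
  utils::write.csv(df[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a long plasma table into per-subject profiles
#'
#' @param df long plasma table (see [read_plasma_csv()])
#' @param formulation keep only this formulation (default: all rows)
#' @return named list of [plasma_profile()] objects, one per subject
#' @export
plasma_profiles_from_table <- function(df, formulation = NULL) {
  if (!is.null(formulation)) df <- df[df$formulation == formulation, ]
  split_df <- split(df, df$subject)
  lapply(split_df, function(d) {
    d <- d[order(d$time_h), ]
    plasma_profile(d$time_h, d$conc_mg_L, dose = d$dose_mg[1],
                   formulation = as.character(d$formulation[1]))
  })
}

#' Read a dissolution CSV (`time_min, replicate, dissolved_pct`)
#'
#' @param path CSV file path
#' @return data.frame
#' @export
read_dissolution_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "replicate", "dissolved_pct")
  if (!all(need %in% names(df)))
    stop("dissolution CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write a dissolution CSV
#'
#' @param df data.frame with columns `time_min, replicate, dissolved_pct`
#'   (extra columns such as `group` are kept)
#' @param path output path
#' @return invisibly, `path`
#' @export
write_dissolution_csv <- function(df, path) {
  need <- c("time_min", "replicate", "dissolved_pct")
  if (!all(need %in% names(df)))
    stop("dissolution table must have columns: ", paste(need, collapse = ", "))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average dissolution replicates into a mean profile
#'
#' @param df dissolution table (`time_min, replicate, dissolved_pct`),
#'   optionally filtered to one `group`
#' @param x0 dose (mg) used to convert percent back to amount
#' @param group optional group filter (uses column `group` when present)
#' @return an [invitro_profile()] of the replicate mean
#' @export
mean_invitro_profile <- function(df, x0 = 100, group = NULL) {
  if (!is.null(group) && "group" %in% names(df)) df <- df[df$group == group, ]
  agg <- stats::aggregate(dissolved_pct ~ time_min, data = df, FUN = mean)
  agg <- agg[order(agg$time_min), ]
  invitro_profile(agg$time_min, agg$dissolved_pct / 100 * x0, x0 = x0,
                  replicate = 0L,
                  group = if (is.null(group)) NA_integer_ else group)
}

#' Read population PK parameters from a YAML config
#'
#' @param path YAML file written by [make_default_configs()] (keys mirror
#'   [pop_pk_params()] fields, one block per formulation)
#' @param formulation `"capsule"` or `"tablet"`
#' @return a [pop_pk_params()]
#' @export
read_poppk_config <- function(path, formulation = c("capsule", "tablet")) {
  formulation <- match.arg(formulation)
  y <- yaml::read_yaml(path)[[formulation]]
  if (is.null(y)) stop("no '", formulation, "' block in ", path)
  pop_pk_params(tlag = y$tlag, ka = y$ka, CL = y$CL, V1 = y$V1, Q = y$Q,
                V2 = y$V2, bsv = unlist(y$bsv), beta_CL = y$beta_CL,
                beta_V1 = y$beta_V1, sigma_add = y$sigma_add,
                sigma_prop = y$sigma_prop, formulation = y$formulation)
}

#' Read a GI configuration from a YAML config
#'
#' @param path YAML file written by [make_default_configs()]
#' @return a [gi_config()]
#' @export
read_gi_config <- function(path) {
  y <- yaml::read_yaml(path)
  vp <- do.call(rbind, lapply(y$vol_poly, function(s) s$coef))
  rownames(vp) <- vapply(y$vol_poly, function(s) s$segment, character(1))
  gi_config(kge = y$kge, get_h = y$get_h, kge_post = y$kge_post,
            kt = unlist(y$kt), k_colon = y$k_colon,
            radius_cm = y$radius_cm, peff = y$peff, water_ml = y$water_ml,
            v_basal_ml = y$v_basal_ml, vol_poly = vp,
            vol_poly_tmax = y$vol_poly_tmax, vol_floor_ml = y$vol_floor_ml)
}

#' Read an in vitro scenario from a YAML config
#'
#' @param path YAML file written by [make_default_configs()]
#' @return a [dissolution_scenario()]
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  stresses <- if (length(y$stresses))
    do.call(rbind, lapply(y$stresses, function(s)
      data.frame(time_min = s$time_min, mbar = s$mbar, kind = s$kind)))
  else data.frame(time_min = numeric(0), mbar = numeric(0),
                  kind = character(0))
  dissolution_scenario(group = y$group, get_min = y$get_min,
                       stresses = stresses, v_stress = y$v_stress,
                       v_res = y$v_res, dt_sample = y$dt_sample)
}

#' Read release/dissolution parameters from a YAML config
#'
#' @param path YAML file written by [make_default_configs()]
#' @return a [release_params()]
#' @export
read_release_config <- function(path) {
  y <- yaml::read_yaml(path)
  release_params(kind = y$kind, tlag = y$tlag, tau = y$tau, b = y$b,
                 tau2 = y$tau2, b2 = y$b2,
                 w = if (is.null(y$w)) 1 else y$w,
                 z = y$z, cs = y$cs, x0 = y$x0)
}
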