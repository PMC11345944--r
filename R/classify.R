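#' Classify a PK profile into a gastric-motility group
#'
#' Rule-based assignment from the time of maximum concentration and the
#' early-exposure ratio `C(0.5 h)/Cmax`:
#' group 1 when `Tmax <= 0.5` h (sprint stomach); for `0.5 < Tmax <= 1` h
#' the ratio splits groups 2/3/4 at `[0.6, 0.95]`, `[0.3, 0.6)` and
#' `[0, 0.3)`; group 5 when `1 < Tmax <= 1.5` h and group 6 when
#' `Tmax > 1.5` h (lazy stomach). A ratio above 0.95 with `Tmax` in
#' `(0.5, 1]` is not covered by the group definitions and is flagged
#' unclassifiable (`NA` group).
#'
#' @param tmax time of maximum concentration (h)
#' @param c_05 concentration at 0.5 h (mg/L); only used for `Tmax` in
#'   `(0.5, 1]`
#' @param cmax maximum concentration (mg/L), > 0
#' @return list with `group` (integer or `NA`), `ratio`, and `flag`
#'   (`NA_character_` or a reason)
#' @export
classify_profile <- function(tmax, c_05, cmax) {
  if (!is.finite(cmax) || cmax <= 0) stop("cmax must be positive")
  if (!is.finite(tmax) || tmax <= 0) stop("tmax must be positive")
  ratio <- NA_real_
  if (tmax <= 0.5) return(list(group = 1L, ratio = ratio, flag = NA_character_))
  if (tmax <= 1.0) {
    if (!is.finite(c_05))
      return(list(group = NA_integer_, ratio = NA_real_,
                  flag = "missing 0.5 h concentration"))
    ratio <- c_05 / cmax
    group <- if (ratio >= 0.6 && ratio <= 0.95) 2L
             else if (ratio >= 0.3) 3L
             else if (ratio >= 0) 4L
             else NA_integer_
    if (ratio > 0.95)
      return(list(group = NA_integer_, ratio = ratio,
                  flag = "ratio above 0.95 with Tmax in (0.5, 1]"))
    return(list(group = group, ratio = ratio, flag = NA_character_))
  }
  if (tmax <= 1.5) return(list(group = 5L, ratio = ratio, flag = NA_character_))
  list(group = 6L, ratio = ratio, flag = NA_character_)
}

#' Classify every profile of a trial and tabulate group prevalences
#'
#' Runs [nca()] on each profile (observed-grid Tmax, matching how clinical
#' profiles are read), applies [classify_profile()], and estimates group
#' prevalences as counts over classified subjects.
#'
#' @param profiles list of [plasma_profile()] objects; names are used as
#'   subject ids when present
#' @return list with `assignments` (data.frame `subject, group, tmax_h,
#'   ratio, flag`) and `prevalence` (fractions over groups 1-6, summing to
#'   1 over classified subjects)
#' @export
classify_trial <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ids <- if (!is.null(names(profiles))) names(profiles)
         else as.character(seq_along(profiles))
  rows <- lapply(seq_along(profiles), function(i) {
    res <- nca(profiles[[i]])
    cl <- classify_profile(res$tmax, res$c_05, res$cmax)
    data.frame(subject = ids[i], group = cl$group, tmax_h = res$tmax,
               ratio = cl$ratio, flag = cl$flag, stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  counts <- tabulate(assignments$group, nbins = 6)
  n_classified <- sum(counts)
  prevalence <- if (n_classified > 0) counts / n_classified else rep(NA_real_, 6)
  names(prevalence) <- paste0("g", 1:6)
  list(assignments = assignments, prevalence = prevalence)
}
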