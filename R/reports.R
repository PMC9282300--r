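# Report drivers behind the command-line interface (inst/cli/elderfit).
# Each run_* function is a pure function of its configuration and input
# files: reruns produce byte-identical outputs.

resolve_profiles <- function(profiles) {
  if (is.character(profiles)) read_profiles(profiles) else profiles
}

resolve_social <- function(config, omega) {
  relatedness_profile(shape = config$relatedness_shape %||% "constant",
                      level = config$relatedness %||% 0.2,
                      omega = omega,
                      k = config$cooperation %||% 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the calibration step and write a summary
#'
#' @param profiles a profiles CSV path or a list with \code{lh} and \code{sub}.
#' @param gamma curvature parameter.
#' @param r_target baseline growth rate (default 0.01).
#' @param r_max,rescale_fertility see \code{\link{calibrate_profiles}}.
#' @param out_dir output directory (created if missing); when NULL nothing is
#'   written.
#' @return The \code{\link{calibrate_profiles}} result, invisibly when writing.
#' @export
run_calibrate <- function(profiles, gamma, r_target = 0.01, r_max = NULL,
                          rescale_fertility = FALSE, out_dir = NULL) {
  p <- resolve_profiles(profiles)
  cal <- calibrate_profiles(p$lh, p$sub, gamma = gamma, r_target = r_target,
                            r_max = r_max, rescale_fertility = rescale_fertility)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    con <- file(file.path(out_dir, "calibration.txt"), "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("gamma %.10g", cal$gamma),
      sprintf("replete_scale %.10g", cal$replete_scale),
      sprintf("rho %.10g", cal$rho),
      sprintf("E0 %.10g", cal$E0),
      sprintf("Emin %.10g", cal$Emin),
      sprintf("r_max %.10g", cal$r_max),
      sprintf("r_baseline %.10g", cal$summary$r),
      sprintf("lambda_baseline %.10g", cal$summary$lambda)
    ), con)
    return(invisible(cal))
  }
  cal
}

#' Run the full metrics pipeline and write the per-age table and summary
#'
#' Writes \code{metrics.csv} (columns \code{age,px,mx,Px,Dx,lx,s_mx,s_px,
#' e_mx,e_px_scaled,dlambda_Px,m_star,RV,PV}) and \code{summary.txt} with the
#' headline quantities (growth, food ratios, mean ages, elasticity totals,
#' share profiles after ages 30/40/50, TFR_50).
#'
#' @param profiles a profiles CSV path or a list with \code{lh} and \code{sub}.
#' @param gamma curvature parameter.
#' @param config named list of options: \code{relatedness} (level, default
#'   0.2), \code{relatedness_shape} ("constant"), \code{cooperation}
#'   (k, default 0.5), \code{r_target} (0.01), \code{cut_ages} (30,40,50).
#' @param out_dir output directory; when NULL nothing is written.
#' @return The \code{\link{selection_report}}, invisibly when writing.
#' @export
run_metrics <- function(profiles, gamma, config = list(), out_dir = NULL) {
  p <- resolve_profiles(profiles)
  cal <- calibrate_profiles(p$lh, p$sub, gamma = gamma,
                            r_target = config$r_target %||% 0.01)
  social <- resolve_social(config, omega_of(p$lh))
  rep <- selection_report(cal, social,
                          cut_ages = config$cut_ages %||% c(30, 40, 50))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(format(rep$table, digits = 10, trim = TRUE),
                     file.path(out_dir, "metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    s <- rep$summary
    kv <- c(lambda = s$lambda, r = s$r, E0 = s$E0, Emin = s$Emin,
            gamma = s$gamma, R0 = s$R0, e0 = s$e0, TFR = s$TFR,
            x_M = s$x_M, x_P = s$x_P, x_D = s$x_D,
            fertility_elasticity_total = s$fertility_elasticity_total,
            stats::setNames(s$production_share,
                            paste0("production_share_", names(s$production_share))),
            stats::setNames(s$indirect_share,
                            paste0("indirect_share_", names(s$indirect_share))),
            stats::setNames(s$fertility_share,
                            paste0("fertility_share_", names(s$fertility_share))),
            TFR_50 = s$TFR_50,
            stable_share_over50 = s$stable_share_over50)
    writeLines(sprintf("%s %.10g", names(kv), kv),
               file.path(out_dir, "summary.txt"))
    return(invisible(rep))
  }
  rep
}

#' Run the four-way life-history by subsistence counterfactual
#'
#' Permutes two profile sources into all 2x2 combinations of life history and
#' subsistence, runs the metrics pipeline on each, and (optionally) writes one
#' subdirectory per cell plus a comparison table.
#'
#' @param profiles_a,profiles_b the two profile sources (paths or lists).
#' @param gamma curvature parameter.
#' @param config as in \code{\link{run_metrics}}.
#' @param out_dir output directory; when NULL nothing is written.
#' @param labels length-2 character labels for the sources.
#' @return A list of four \code{\link{selection_report}}s named
#'   \code{<lh>_lh.<sub>_sub}, plus \code{comparison}, a data frame of
#'   headline metrics per cell.
#' @export
run_counterfactual <- function(profiles_a, profiles_b, gamma, config = list(),
                               out_dir = NULL, labels = c("a", "b")) {
  pa <- resolve_profiles(profiles_a)
  pb <- resolve_profiles(profiles_b)
  sources <- stats::setNames(list(pa, pb), labels)
  cells <- list()
  rows <- list()
  for (lh_nm in labels) for (sub_nm in labels) {
    comp <- permute_counterfactual(sources[[lh_nm]]$lh, sources[[sub_nm]]$sub)
    cell <- paste0(lh_nm, "_lh.", sub_nm, "_sub")
    rep <- run_metrics(comp, gamma, config,
                       out_dir = if (is.null(out_dir)) NULL
                                 else file.path(out_dir, cell))
    cells[[cell]] <- rep
    s <- rep$summary
    rows[[cell]] <- data.frame(
      cell = cell, lambda = s$lambda, E0 = s$E0,
      x_P_minus_x_D = s$x_P - s$x_D,
      indirect_share_after40 = unname(s$indirect_share["after40"]),
      fertility_elasticity_total = s$fertility_elasticity_total,
      TFR_50 = s$TFR_50)
  }
  comparison <- do.call(rbind, rows)
  rownames(comparison) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(format(comparison, digits = 10, trim = TRUE),
                     file.path(out_dir, "comparison.csv"),
                     row.names = FALSE, quote = FALSE)
  c(cells, list(comparison = comparison))
}

#' Run a pedagogy teacher-age sweep and write the gain curve
#'
#' @param preset \code{"high-skill"} or \code{"low-skill"}.
#' @param gamma curvature parameter.
#' @param phi,theta,a,t regime parameters (see \code{\link{pedagogy_regime}}).
#' @param config as in \code{\link{run_metrics}}; also \code{omega} (default 90)
#'   and \code{seed} (default 1) for the human-like life-history backdrop.
#' @param out_dir output directory; when NULL nothing is written.
#' @return The \code{\link{optimize_teacher_age}} result.
#' @export
run_pedagogy <- function(preset = "high-skill", gamma = 0.3, phi = 0.05,
                         theta = 1, a = 10, t = 10, config = list(),
                         out_dir = NULL) {
  omega <- config$omega %||% 90L
  base <- synth_profiles("human-like", omega = omega, seed = config$seed %||% 1L)
  model <- skill_production_model(preset, omega = omega)
  cal <- calibrate_profiles(base$lh, subsistence(Px = model$Px, Dx = base$sub$Dx),
                            gamma = gamma, r_target = config$r_target %||% 0.01)
  social <- resolve_social(config, omega)
  sweep <- optimize_teacher_age(cal, model, social, phi = phi, theta = theta,
                                a = a, t = t)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(format(sweep$curve, digits = 10, trim = TRUE),
                     file.path(out_dir, "pedagogy_gain.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  sweep
}

#' Generate and write a synthetic profile fixture
#'
#' @param kind,omega,seed see \code{\link{synth_profiles}}.
#' @param out_path CSV destination.
#' @return The profiles, invisibly.
#' @export
run_synth <- function(kind, omega = NULL, seed = 1L, out_path) {
  p <- synth_profiles(kind, omega = omega, seed = seed)
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  write_profiles(p$lh, p$sub, out_path)
  invisible(p)
}
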