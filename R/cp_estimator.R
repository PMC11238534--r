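#' Fit the temperature derivative of the mean energy
#'
#' Ordinary least-squares regression of per-temperature mean potential
#' energies on temperature. The slope estimates \eqn{\partial U/\partial T}
#' (a heat capacity, kcal/mol/K); its uncertainty is the asymptotic OLS
#' standard error. Points are unweighted: with well-converged simulations the
#' scatter about the line, not the per-point SEM, carries the information.
#'
#' @param scan A `temperature_scan` from [aggregate_scan()], with at least 3
#'   distinct temperatures.
#' @return A `linear_fit`: list with `slope`, `intercept`, `slope_se`,
#'   `r_squared`, `n_points`.
#' @export
fit_dudt <- function(scan) {
  stopifnot(inherits(scan, "temperature_scan"))
  pts <- scan$points
  if (nrow(pts) < 3 || length(unique(pts$temperature)) < 3)
    stop("insufficient data: need >= 3 distinct temperatures", call. = FALSE)
  fit <- stats::lm(mean_energy ~ temperature, data = pts)
  # summary.lm warns on numerically exact lines; that case is legitimate
  # here (noise-free synthetic scans) and handled below
  sm <- suppressWarnings(summary(fit))
  slope_se <- sm$coefficients["temperature", "Std. Error"]
  # exact-line data: lm reports NaN se when residual variance underflows
  if (!is.finite(slope_se)) slope_se <- 0
  r2 <- sm$r.squared
  structure(
    list(slope = unname(stats::coef(fit)["temperature"]),
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         slope_se = slope_se,
         r_squared = if (is.finite(r2)) r2 else 1,
         n_points = nrow(pts)),
    class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_fit> dU/dT = %.4f +/- %.4f kcal/mol/K  (R^2 = %.6f, n = %d)\n",
    x$slope, x$slope_se, x$r_squared, x$n_points))
  invisible(x)
}

#' Binding heat capacity from the four-system thermodynamic cycle
#'
#' Combines the energy-temperature derivatives of holoprotein, apoprotein,
#' ligand-in-water and pure-water systems into the binding heat capacity
#' change:
#' \deqn{\Delta C_p = (d_{holo} - d_{apo}) - (d_{lig} - d_{wat}) + c_w}
#' where \eqn{c_w = -n_{imb} \cdot C_p^{water}} corrects for any imbalance in
#' water count between the holo and apo systems (ideally the systems are
#' built with matched water counts and \eqn{n_{imb} = 0}). Kinetic-energy
#' contributions cancel in the cycle because the compared systems have equal
#' numbers of degrees of freedom. The uncertainty is the quadrature sum of
#' the four asymptotic slope standard errors.
#'
#' @param holo,apo,lig,wat `linear_fit` objects from [fit_dudt()], or bare
#'   numeric slopes (then slope SEs are taken as 0).
#' @param n_water_imbalance Waters in the holo system minus waters in the apo
#'   system (default 0).
#' @param per_water_cp Heat capacity per water molecule, kcal/mol/K (default
#'   0.018, the experimental bulk value).
#' @return A `cp_binding_result`: list with the four derivatives `d_holo`,
#'   `d_apo`, `d_lig`, `d_wat`, the `water_imbalance_correction`, `delta_cp`
#'   and `delta_cp_se` (all kcal/mol/K).
#' @export
binding_heat_capacity <- function(holo, apo, lig, wat,
                                  n_water_imbalance = 0L,
                                  per_water_cp = 0.018) {
  as_fit <- function(x) {
    if (inherits(x, "linear_fit")) x
    else list(slope = as.numeric(x), slope_se = 0)
  }
  fits <- lapply(list(holo, apo, lig, wat), as_fit)
  sl <- vapply(fits, `[[`, numeric(1), "slope")
  se <- vapply(fits, `[[`, numeric(1), "slope_se")
  corr <- -n_water_imbalance * per_water_cp
  structure(
    list(d_holo = sl[1], d_apo = sl[2], d_lig = sl[3], d_wat = sl[4],
         water_imbalance_correction = corr,
         delta_cp = (sl[1] - sl[2]) - (sl[3] - sl[4]) + corr,
         delta_cp_se = sqrt(sum(se^2))),
    class = "cp_binding_result")
}

#' @export
print.cp_binding_result <- function(x, ...) {
  cat(sprintf("<cp_binding_result> delta_Cp = %.3f +/- %.3f kcal/mol/K\n",
              x$delta_cp, x$delta_cp_se))
  cat(sprintf("  dU/dT: holo %.3f  apo %.3f  lig %.3f  wat %.3f\n",
              x$d_holo, x$d_apo, x$d_lig, x$d_wat))
  if (x$water_imbalance_correction != 0)
    cat(sprintf("  water imbalance correction: %.4f\n",
                x$water_imbalance_correction))
  invisible(x)
}

#' Heat capacity per molecule of a bulk system
#'
#' Divides a fitted potential-energy temperature derivative by the number of
#' molecules and adds the 3R equipartition kinetic-energy term, converting a
#' potential-only derivative into a per-molecule total heat capacity. For
#' bulk water this recovers approximately 0.018 kcal/mol/K.
#'
#' @param wat A `linear_fit` for the bulk system (or a bare numeric slope).
#' @param n_molecules Number of molecules in the system (> 0).
#' @return Per-molecule heat capacity, kcal/mol/K.
#' @export
per_molecule_cp <- function(wat, n_molecules) {
  if (n_molecules <= 0) stop("n_molecules must be > 0", call. = FALSE)
  slope <- if (inherits(wat, "linear_fit")) wat$slope else as.numeric(wat)
  slope / n_molecules + 3 * .RGAS
}

#' Constant-heat-capacity van't Hoff parameters
#'
#' @param dh0 Binding enthalpy at the reference temperature, kcal/mol.
#' @param ds0 Binding entropy at the reference temperature, kcal/mol/K.
#' @param dcp Constant heat capacity change, kcal/mol/K.
#' @param t0 Reference temperature in kelvin (default 298.15).
#' @return A `vant_hoff_params` object.
#' @export
vant_hoff_params <- function(dh0, ds0, dcp, t0 = 298.15) {
  if (t0 <= 0) stop("t0 must be positive", call. = FALSE)
  structure(list(dh0 = dh0, ds0 = ds0, dcp = dcp, t0 = t0),
            class = "vant_hoff_params")
}

#' Binding free energy under a constant heat capacity change
#'
#' Gibbs-Helmholtz integration with constant \eqn{\Delta C_p}:
#' \deqn{\Delta G(T) = \Delta H_0 - T \Delta S_0 +
#'   \Delta C_p [(T - T_0) - T \ln(T/T_0)]}
#' Its curvature satisfies
#' \eqn{\Delta C_p = -T \, \partial^2 \Delta G / \partial T^2}.
#'
#' @param params A [vant_hoff_params()] object.
#' @param t Temperature(s) in kelvin (> 0); vectorised.
#' @return \eqn{\Delta G(T)} in kcal/mol.
#' @export
vant_hoff_dg <- function(params, t) {
  stopifnot(inherits(params, "vant_hoff_params"))
  if (any(t <= 0)) stop("temperature must be positive", call. = FALSE)
  with(params, dh0 - t * ds0 + dcp * ((t - t0) - t * log(t / t0)))
}

#' Fit the constant-heat-capacity van't Hoff model to free energies
#'
#' Least-squares fit of [vant_hoff_dg()] to (temperature, free energy)
#' points. The model is linear in its three parameters, so the fit is an
#' exact linear least-squares solve; noise-free model data is recovered to
#' machine precision. With narrow temperature ranges the curvature parameter
#' `dcp` is ill-determined — its standard error is typically large relative
#' to plausible values — which is the quantitative reason free-energy
#' van't Hoff analysis is a poor route to binding heat capacities.
#'
#' @param points A data.frame (or 2-column matrix) with columns temperature
#'   (kelvin) and dg (kcal/mol); at least 4 distinct temperatures (3 when
#'   `fix_dcp` is given).
#' @param t0 Reference temperature in kelvin (default 298.15).
#' @param fix_dcp Optional: hold `dcp` fixed at this value (e.g. 0 for the
#'   classic linear van't Hoff fit) and estimate only `dh0`, `ds0`.
#' @return A list with `params` ([vant_hoff_params()]), `se` (named vector of
#'   asymptotic standard errors for the free parameters) and `residual_sd`.
#' @export
fit_vant_hoff <- function(points, t0 = 298.15, fix_dcp = NULL) {
  points <- as.data.frame(points)
  names(points)[1:2] <- c("temperature", "dg")
  n_par <- if (is.null(fix_dcp)) 3L else 2L
  n_min <- n_par + 1L
  if (nrow(points) < n_min || length(unique(points$temperature)) < n_min)
    stop("insufficient data: need >= ", n_min, " distinct temperatures",
         call. = FALSE)
  tt <- points$temperature
  curv <- (tt - t0) - tt * log(tt / t0)
  y <- points$dg
  if (is.null(fix_dcp)) {
    X <- cbind(dh0 = 1, ds0 = -tt, dcp = curv)
  } else {
    X <- cbind(dh0 = 1, ds0 = -tt)
    y <- y - fix_dcp * curv
  }
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  dof <- nrow(points) - n_par
  s2 <- sum(fit$residuals^2) / dof
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * diag(XtXinv))
  names(se) <- colnames(X)
  dcp_hat <- if (is.null(fix_dcp)) unname(cf["dcp"]) else fix_dcp
  list(params = vant_hoff_params(unname(cf["dh0"]), unname(cf["ds0"]),
                                 dcp_hat, t0),
       se = se,
       residual_sd = sqrt(s2))
}

#' Write a binding heat capacity report
#'
#' Emits a tab-delimited table (one row per result) and, alongside it, a
#' human-readable structured-text summary. Units are embedded in the column
#' names.
#'
#' @param results Named list of `cp_binding_result` objects (names identify
#'   ligands/systems).
#' @param path Output path for the delimited table; the text summary goes to
#'   `paste0(path, ".txt")`.
#' @param expt Optional named numeric vector of experimental reference
#'   \eqn{\Delta C_p} values (kcal/mol/K), matched by name.
#' @return `path`, invisibly.
#' @export
write_cp_report <- function(results, path, expt = NULL) {
  if (inherits(results, "cp_binding_result")) results <- list(result = results)
  rows <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(system = nm,
               dUdT_holo_kcal_mol_K = r$d_holo,
               dUdT_apo_kcal_mol_K = r$d_apo,
               dUdT_lig_kcal_mol_K = r$d_lig,
               dUdT_wat_kcal_mol_K = r$d_wat,
               water_corr_kcal_mol_K = r$water_imbalance_correction,
               delta_cp_kcal_mol_K = r$delta_cp,
               delta_cp_se_kcal_mol_K = r$delta_cp_se,
               delta_cp_expt_kcal_mol_K =
                 if (!is.null(expt) && nm %in% names(expt)) expt[[nm]]
                 else NA_real_)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  txt <- c("Binding heat capacity report", "")
  for (i in seq_len(nrow(rows))) {
    txt <- c(txt, sprintf("%s: delta_Cp = %.3f +/- %.3f kcal/mol/K%s",
                          rows$system[i], rows$delta_cp_kcal_mol_K[i],
                          rows$delta_cp_se_kcal_mol_K[i],
                          if (is.na(rows$delta_cp_expt_kcal_mol_K[i])) ""
                          else sprintf("  (expt %.3f)",
                                       rows$delta_cp_expt_kcal_mol_K[i])))
  }
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
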