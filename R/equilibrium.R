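#' Mandatory-coupling equilibrium parameters
#'
#' Parameters of the two-state scheme \eqn{(E+L)' \rightleftharpoons E+L
#' \rightarrow EL}: only the binding-competent state \eqn{E+L} can form the
#' complex, while \eqn{(E+L)'} is inactive (a different conformation of the
#' enzyme or the ligand). `dh_eq`/`ds_eq` describe the active-to-inactive
#' equilibrium, `dh_b`/`ds_b` the true (intrinsic) binding step of the
#' active state.
#'
#' @param dh_eq Equilibrium enthalpy, active -> inactive, kcal/mol.
#' @param ds_eq Equilibrium entropy, kcal/mol/K.
#' @param dh_b True binding enthalpy, kcal/mol.
#' @param ds_b True binding entropy, kcal/mol/K (`NA` if not determined; it
#'   does not enter the apparent enthalpy or heat capacity).
#' @return An `equilibrium_params` object.
#' @export
equilibrium_params <- function(dh_eq, ds_eq, dh_b, ds_b = NA_real_) {
  vals <- c(dh_eq, ds_eq, dh_b)
  if (!all(is.finite(vals)))
    stop("dh_eq, ds_eq, dh_b must be finite", call. = FALSE)
  structure(list(dh_eq = dh_eq, ds_eq = ds_eq, dh_b = dh_b, ds_b = ds_b),
            class = "equilibrium_params")
}

#' @export
print.equilibrium_params <- function(x, ...) {
  cat(sprintf(
    "<equilibrium_params> dH_eq %.3f  dS_eq %.5f  dH_b %.3f  dS_b %s\n",
    x$dh_eq, x$ds_eq, x$dh_b,
    if (is.na(x$ds_b)) "NA" else sprintf("%.5f", x$ds_b)))
  invisible(x)
}

.check_temp <- function(t) {
  if (any(t <= 0)) stop("temperature must be positive", call. = FALSE)
}

#' Conformational equilibrium constant
#'
#' \eqn{K_{eq}(T) = \exp[-(\Delta H_{eq} - T\Delta S_{eq})/(RT)]}, the ratio
#' of inactive to active populations of the free species.
#'
#' @param params An [equilibrium_params()] object.
#' @param t Temperature(s) in kelvin (> 0); vectorised.
#' @return Dimensionless equilibrium constant(s).
#' @export
keq <- function(params, t) {
  .check_temp(t)
  exp(-(params$dh_eq - t * params$ds_eq) / (.RGAS * t))
}

#' Apparent binding enthalpy of the mandatory-coupling model
#'
#' The calorimetrically observed enthalpy is the true binding enthalpy of
#' the active state minus the equilibrium enthalpy weighted by the inactive
#' population:
#' \deqn{\Delta H_{app}(T) = \Delta H_b -
#'   \Delta H_{eq} \frac{K_{eq}}{1 + K_{eq}}}
#' With \eqn{\Delta H_{eq} > 0} it decreases monotonically with temperature
#' between the limits \eqn{\Delta H_b} (low T, all-active) and
#' \eqn{\Delta H_b - \Delta H_{eq}} (high T, all-inactive).
#'
#' @inheritParams keq
#' @return \eqn{\Delta H_{app}(T)} in kcal/mol.
#' @export
apparent_enthalpy <- function(params, t) {
  k <- keq(params, t)
  params$dh_b - params$dh_eq * k / (1 + k)
}

#' Apparent binding heat capacity of the mandatory-coupling model
#'
#' The analytic temperature derivative of [apparent_enthalpy()]:
#' \deqn{\Delta C_p^{app}(T) = -\frac{\Delta H_{eq}^2}{R T^2}
#'   \cdot \frac{1}{1+K_{eq}} \cdot \frac{K_{eq}}{1+K_{eq}}}
#' the two rightmost factors being the active and inactive populations. It
#' is always negative (for \eqn{\Delta H_{eq} \neq 0}), with its strongest
#' dip \eqn{-\Delta H_{eq}^2/(4RT^2)} at the transition temperature where
#' the two states are equally populated.
#'
#' @inheritParams keq
#' @return \eqn{\Delta C_p^{app}(T)} in kcal/mol/K.
#' @export
apparent_cp <- function(params, t) {
  k <- keq(params, t)
  -(params$dh_eq^2 / (.RGAS * t^2)) * (1 / (1 + k)) * (k / (1 + k))
}

#' Apparent binding free energy of the mandatory-coupling model
#'
#' \deqn{\Delta G_{app}(T) = \Delta G_b + RT\ln(1 + K_{eq})}
#' with \eqn{\Delta G_b = \Delta H_b - T\Delta S_b}. The logarithmic term is
#' the free-energy cost of depleting the inactive state, equivalent to the
#' apparent binding constant \eqn{K_{app} = K_b/(1 + K_{eq})}.
#'
#' @inheritParams keq
#' @return \eqn{\Delta G_{app}(T)} in kcal/mol. Requires `ds_b` to be set.
#' @export
apparent_free_energy <- function(params, t) {
  if (is.na(params$ds_b))
    stop("ds_b is undefined; supply it or fit with a reference dG_app",
         call. = FALSE)
  k <- keq(params, t)
  (params$dh_b - t * params$ds_b) + .RGAS * t * log(1 + k)
}

#' The mirror solution of the equilibrium model
#'
#' The apparent-enthalpy expression always admits two parameter solutions
#' that are observationally indistinguishable: negating
#' \eqn{\Delta H_{eq}, \Delta S_{eq}} (swapping which conformer is called
#' active) while shifting the binding terms,
#' \eqn{\Delta H_b' = \Delta H_b - \Delta H_{eq}},
#' \eqn{\Delta S_b' = \Delta S_b - \Delta S_{eq}}. Applying the transform
#' twice returns the original parameters; every apparent (observable)
#' quantity is identical between the two solutions at all temperatures.
#'
#' @param params An [equilibrium_params()] object.
#' @return The transformed `equilibrium_params`.
#' @export
alternate_solution <- function(params) {
  equilibrium_params(dh_eq = -params$dh_eq,
                     ds_eq = -params$ds_eq,
                     dh_b = params$dh_b - params$dh_eq,
                     ds_b = params$ds_b - params$ds_eq)
}

#' Construct an ITC-style enthalpy series
#'
#' @param temperature Temperatures in kelvin (distinct).
#' @param dh_app Apparent binding enthalpies, kcal/mol.
#' @param sd Optional per-point standard deviations, kcal/mol.
#' @return An `itc_series`: data.frame with columns `temperature`, `dh_app`
#'   and optionally `sd`.
#' @export
itc_series <- function(temperature, dh_app, sd = NULL) {
  if (length(temperature) != length(dh_app))
    stop("temperature and dh_app must have equal length", call. = FALSE)
  if (anyDuplicated(temperature))
    stop("temperatures must be distinct", call. = FALSE)
  df <- data.frame(temperature = temperature, dh_app = dh_app)
  if (!is.null(sd)) df$sd <- sd
  class(df) <- c("itc_series", "data.frame")
  df
}

#' Read / write ITC enthalpy tables
#'
#' Delimited text with header columns `temperature_K`,
#' `dH_app_kcal_per_mol` and optionally `sd_kcal_per_mol`.
#'
#' @param x An [itc_series()].
#' @param path File path.
#' @return `read_itc_table()` returns an `itc_series`; `write_itc_table()`
#'   returns `path` invisibly.
#' @export
read_itc_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  itc_series(tab$temperature_K, tab$dH_app_kcal_per_mol,
             sd = tab$sd_kcal_per_mol)
}

#' @rdname read_itc_table
#' @export
write_itc_table <- function(x, path) {
  out <- data.frame(temperature_K = x$temperature,
                    dH_app_kcal_per_mol = x$dh_app)
  if (!is.null(x$sd)) out$sd_kcal_per_mol <- x$sd
  utils::write.table(format(out, digits = 17), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit the mandatory-coupling model to apparent binding enthalpies
#'
#' Nonlinear least squares (Levenberg-Marquardt) of [apparent_enthalpy()]
#' to an ITC-style (temperature, enthalpy) series, estimating `dh_eq`,
#' `ds_eq` and `dh_b`. The objective has two mirror minima (see
#' [alternate_solution()]) and can be flat when the conformational
#' transition lies outside the data range, so the optimiser is run from a
#' small multistart grid and the best optimum is kept; the returned solution
#' is normalised to the `dh_eq > 0` branch. Points are weighted by
#' \eqn{1/sd^2} when the series carries standard deviations.
#'
#' `ds_b` is not identifiable from enthalpies alone; when a reference
#' apparent binding free energy is supplied it is solved from
#' \eqn{\Delta G_{app} = \Delta H_b - T\Delta S_b + RT\ln(1+K_{eq})},
#' otherwise it is left `NA`.
#'
#' @param data An [itc_series()] (or data.frame with columns `temperature`,
#'   `dh_app`, optional `sd`) with at least 3 distinct temperatures.
#' @param dg_app_ref Optional length-2 numeric `c(temperature_K, dg_app)`
#'   fixing the apparent binding free energy at one temperature.
#' @param branch `"positive"` (default) or `"negative"`: sign of `dh_eq` of
#'   the reported solution.
#' @return A list with `params` ([equilibrium_params()]), `se` (asymptotic
#'   standard errors for dh_eq, ds_eq, dh_b), `rss`, `residual_sd`,
#'   `converged`, and `ds_b_source` (`"reference"` or `"undefined"`).
#' @export
fit_equilibrium <- function(data, dg_app_ref = NULL, branch = "positive") {
  data <- as.data.frame(data)
  if (!all(c("temperature", "dh_app") %in% names(data)))
    stop("data needs columns temperature and dh_app", call. = FALSE)
  if (nrow(data) < 3 || length(unique(data$temperature)) < 3)
    stop("insufficient data: need >= 3 distinct temperatures", call. = FALSE)
  branch <- match.arg(branch, c("positive", "negative"))
  tt <- data$temperature
  y <- data$dh_app
  w <- if (!is.null(data$sd)) 1 / data$sd^2 else rep(1, length(y))
  sw <- sqrt(w)

  resid_fn <- function(p) {
    pars <- equilibrium_params(p[1], p[2], p[3])
    sw * (apparent_enthalpy(pars, tt) - y)
  }
  starts <- lapply(c(5, 10, 20, 40), function(h)
    c(dh_eq = h, ds_eq = h / 300, dh_b = mean(y)))
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("fit failure: no start converged", call. = FALSE)
  p <- best$par
  pars <- equilibrium_params(p[["dh_eq"]], p[["ds_eq"]], p[["dh_b"]])
  if ((branch == "positive" && pars$dh_eq < 0) ||
      (branch == "negative" && pars$dh_eq > 0))
    pars <- alternate_solution(pars)

  # asymptotic SEs from the Jacobian at the optimum (of the reported branch)
  eps <- 1e-6
  p0 <- c(pars$dh_eq, pars$ds_eq, pars$dh_b)
  base <- resid_fn(p0)
  J <- vapply(seq_along(p0), function(j) {
    ph <- p0; ph[j] <- ph[j] + eps * max(1, abs(ph[j]))
    (resid_fn(ph) - base) / (ph[j] - p0[j])
  }, numeric(length(y)))
  dof <- length(y) - 3L
  s2 <- if (dof > 0) sum(base^2) / dof else NA_real_
  se <- tryCatch(sqrt(s2 * diag(chol2inv(chol(crossprod(J))))),
                 error = function(e) rep(NA_real_, 3))
  names(se) <- c("dh_eq", "ds_eq", "dh_b")

  ds_b_source <- "undefined"
  if (!is.null(dg_app_ref)) {
    tref <- dg_app_ref[[1]]
    dgref <- dg_app_ref[[2]]
    k <- keq(pars, tref)
    pars$ds_b <- (pars$dh_b + .RGAS * tref * log(1 + k) - dgref) / tref
    ds_b_source <- "reference"
  }
  list(params = pars, se = se,
       rss = best$deviance,
       residual_sd = if (dof > 0) sqrt(s2) else NA_real_,
       converged = best$info %in% 1:4,
       ds_b_source = ds_b_source)
}

#' Summarise a set of equilibrium-model fits
#'
#' Builds a per-ligand parameter table (with derived 298.15 K quantities
#' \eqn{\Delta H_{app}}, \eqn{\Delta G_{eq}}, \eqn{\Delta G_b},
#' \eqn{\Delta G_{app}}) and the across-ligand mean and standard error of
#' the mean of `dh_eq` and `ds_eq`.
#'
#' @param fits Named list of [equilibrium_params()] objects.
#' @param t_ref Reference temperature in kelvin (default 298.15).
#' @return A list with `table` (data.frame, one row per ligand) and
#'   `dh_eq_mean`, `dh_eq_sem`, `ds_eq_mean`, `ds_eq_sem`.
#' @export
summarize_equilibrium <- function(fits, t_ref = 298.15) {
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    p <- fits[[nm]]
    data.frame(
      ligand = nm,
      dH_eq = p$dh_eq, dS_eq = p$ds_eq, dH_b = p$dh_b, dS_b = p$ds_b,
      dH_app_298 = apparent_enthalpy(p, t_ref),
      dG_eq_298 = p$dh_eq - t_ref * p$ds_eq,
      dG_b_298 = if (is.na(p$ds_b)) NA_real_ else p$dh_b - t_ref * p$ds_b,
      dG_app_298 = if (is.na(p$ds_b)) NA_real_
                   else apparent_free_energy(p, t_ref))
  }))
  dh <- tab$dH_eq
  ds <- tab$dS_eq
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  list(table = tab,
       dh_eq_mean = mean(dh), dh_eq_sem = sem(dh),
       ds_eq_mean = mean(ds), ds_eq_sem = sem(ds))
}
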