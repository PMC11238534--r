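#' Specification for a synthetic four-system energy scan
#'
#' Defines the generating process for synthetic molecular-dynamics energy
#' series of the four systems entering the binding heat-capacity cycle. Per
#' system and temperature the series is
#' \eqn{U_t = u_0 + (\partial U/\partial T)\,T + \epsilon_t}, with
#' \eqn{\epsilon_t} a stationary AR(1) process of marginal standard
#' deviation `noise_sd`: mean energies are linear in temperature (the
#' behaviour of converged simulations), while frames are serially
#' correlated so block averaging is non-trivial.
#'
#' @param slopes Named numeric vector `c(holo=, apo=, lig=, wat=)` of true
#'   \eqn{\partial U/\partial T} values, kcal/mol/K.
#' @param intercepts Named numeric vector of intercepts \eqn{u_0}, kcal/mol
#'   (default 0 for all four).
#' @param temperatures Distinct temperatures in kelvin; default
#'   `c(283, 288, 293, 298, 303)`.
#' @param n_frames Frames per trace (default 1000).
#' @param n_replicas Replicas per (system, temperature) (default 1).
#' @param noise_sd Marginal standard deviation of the AR(1) noise, kcal/mol
#'   (default 1).
#' @param ar1 AR(1) coefficient in \[0, 1) (default 0.9).
#' @return A `scan_spec` object. Its `true_delta_cp` element is the implied
#'   binding heat capacity `(holo - apo) - (lig - wat)`.
#' @export
scan_spec <- function(slopes = c(holo = 66.962, apo = 67.307,
                                 lig = 23.083, wat = 22.871),
                      intercepts = c(holo = 0, apo = 0, lig = 0, wat = 0),
                      temperatures = c(283, 288, 293, 298, 303),
                      n_frames = 1000L, n_replicas = 1L,
                      noise_sd = 1, ar1 = 0.9) {
  req <- c("holo", "apo", "lig", "wat")
  stopifnot(all(req %in% names(slopes)), all(req %in% names(intercepts)))
  if (anyDuplicated(temperatures))
    stop("temperatures must be distinct", call. = FALSE)
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must be in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(slopes = slopes[req], intercepts = intercepts[req],
         temperatures = sort(temperatures), n_frames = as.integer(n_frames),
         n_replicas = as.integer(n_replicas), noise_sd = noise_sd, ar1 = ar1,
         true_delta_cp = unname((slopes["holo"] - slopes["apo"]) -
                                (slopes["lig"] - slopes["wat"]))),
    class = "scan_spec")
}

# stationary AR(1) noise with marginal sd `sd`
.ar1_noise <- function(n, sd, phi) {
  if (sd == 0) return(rep(0, n))
  if (phi == 0) return(stats::rnorm(n, sd = sd))
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::arima.sim(model = list(ar = phi), n = n,
                              sd = innov_sd))
}

#' Generate a synthetic four-system energy scan
#'
#' Draws the energy traces defined by a [scan_spec()] and returns both the
#' raw traces and their per-system temperature scans. Deterministic for a
#' fixed seed.
#'
#' @param spec A [scan_spec()].
#' @param seed Integer seed.
#' @return A list with `traces` (named list of [energy_trace()] lists per
#'   system), `scans` (named list of `temperature_scan`s), and
#'   `true_delta_cp`.
#' @export
gen_energy_scan <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scan_spec"))
  set.seed(seed)
  traces <- list()
  for (sys in names(spec$slopes)) {
    tr <- list()
    for (temp in spec$temperatures) {
      for (rep_id in seq_len(spec$n_replicas)) {
        u <- spec$intercepts[[sys]] + spec$slopes[[sys]] * temp +
          .ar1_noise(spec$n_frames, spec$noise_sd, spec$ar1)
        tr[[length(tr) + 1L]] <- energy_trace(sys, temp, rep_id, u)
      }
    }
    traces[[sys]] <- tr
  }
  list(traces = traces,
       scans = lapply(traces, aggregate_scan),
       true_delta_cp = spec$true_delta_cp)
}

#' Generate a synthetic ITC enthalpy series
#'
#' Apparent binding enthalpies from the mandatory-coupling model
#' ([apparent_enthalpy()]) with additive Gaussian noise, emulating a
#' temperature series of calorimetric measurements.
#'
#' @param params An [equilibrium_params()] object (the generating truth).
#' @param temperatures Temperatures in kelvin; default 283-313 K in 5 K
#'   steps.
#' @param noise_sd Gaussian noise standard deviation, kcal/mol (default
#'   0.1).
#' @param seed Integer seed.
#' @return An [itc_series()] with `sd` set to `noise_sd` when it is > 0.
#' @export
gen_itc_series <- function(params, temperatures = seq(283, 313, by = 5),
                           noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(params, "equilibrium_params"))
  set.seed(seed)
  mu <- apparent_enthalpy(params, temperatures)
  y <- mu + stats::rnorm(length(mu), sd = noise_sd)
  itc_series(temperatures, y,
             sd = if (noise_sd > 0) rep(noise_sd, length(mu)) else NULL)
}

#' Specification for a synthetic two-state conformational trajectory
#'
#' Models a ligand that exchanges between a compact (binding-competent)
#' conformer and an extended (inactive) one. Each frame's state is drawn
#' with inactive probability \eqn{K_{eq}/(1+K_{eq})} at the requested
#' temperature (or a directly supplied fraction); the end-to-end distance
#' is Gaussian within each state; intramolecular and ligand-solvent
#' interaction energies follow opposing linear trends in distance, the
#' physical picture being that separating two charged groups relieves their
#' mutual repulsion while weakening their hydration.
#'
#' @param equilibrium An [equilibrium_params()] giving the compact/extended
#'   equilibrium, or `NULL` if `inactive_fraction` is supplied.
#' @param inactive_fraction Optional fixed extended-state probability in
#'   \[0, 1\], overriding `equilibrium`.
#' @param compact_mean,compact_sd Compact-state distance, angstroms
#'   (defaults 5.5, 0.7).
#' @param extended_mean,extended_sd Extended-state distance, angstroms
#'   (defaults 12.5, 1.8).
#' @param intra_slope Intramolecular energy slope vs distance, kcal/mol/A
#'   (default -2: more favourable when extended).
#' @param solvent_slope Ligand-solvent energy slope vs distance, kcal/mol/A
#'   (default +3: less favourable when extended).
#' @param energy_noise_sd Gaussian noise on each energy, kcal/mol
#'   (default 1).
#' @param n_frames Frames (default 10000).
#' @return A `two_state_spec` object.
#' @export
two_state_spec <- function(equilibrium = NULL, inactive_fraction = NULL,
                           compact_mean = 5.5, compact_sd = 0.7,
                           extended_mean = 12.5, extended_sd = 1.8,
                           intra_slope = -2, solvent_slope = 3,
                           energy_noise_sd = 1, n_frames = 10000L) {
  if (is.null(equilibrium) && is.null(inactive_fraction))
    stop("supply equilibrium params or a direct inactive_fraction",
         call. = FALSE)
  if (compact_mean >= extended_mean)
    stop("compact_mean must be < extended_mean", call. = FALSE)
  if (compact_sd <= 0 || extended_sd <= 0)
    stop("state sds must be > 0", call. = FALSE)
  structure(
    list(equilibrium = equilibrium, inactive_fraction = inactive_fraction,
         compact_mean = compact_mean, compact_sd = compact_sd,
         extended_mean = extended_mean, extended_sd = extended_sd,
         intra_slope = intra_slope, solvent_slope = solvent_slope,
         energy_noise_sd = energy_noise_sd, n_frames = as.integer(n_frames)),
    class = "two_state_spec")
}

#' Generate a synthetic two-state conformational trajectory
#'
#' @param spec A [two_state_spec()].
#' @param temperature Temperature in kelvin at which state populations are
#'   evaluated (ignored when the spec fixes `inactive_fraction`).
#' @param seed Integer seed.
#' @param ensemble If `TRUE`, also return a minimal two-atom
#'   [coordinate_ensemble()] realising the distances along the x axis.
#' @return A list with `distances` (angstroms), `states` (`"compact"` /
#'   `"extended"` per frame), `intra_energy`, `solvent_energy` (kcal/mol),
#'   `p_extended` (the generating probability), and optionally `ensemble`.
#' @export
gen_two_state_trajectory <- function(spec, temperature = 298.15, seed = 1L,
                                     ensemble = FALSE) {
  stopifnot(inherits(spec, "two_state_spec"))
  set.seed(seed)
  p_ext <- if (!is.null(spec$inactive_fraction)) spec$inactive_fraction
           else {
             k <- keq(spec$equilibrium, temperature)
             k / (1 + k)
           }
  n <- spec$n_frames
  extended <- stats::runif(n) < p_ext
  d <- ifelse(extended,
              stats::rnorm(n, spec$extended_mean, spec$extended_sd),
              stats::rnorm(n, spec$compact_mean, spec$compact_sd))
  d <- pmax(d, 0.1)  # distances are physical
  out <- list(
    distances = d,
    states = ifelse(extended, "extended", "compact"),
    intra_energy = spec$intra_slope * d +
      stats::rnorm(n, sd = spec$energy_noise_sd),
    solvent_energy = spec$solvent_slope * d +
      stats::rnorm(n, sd = spec$energy_noise_sd),
    p_extended = p_ext)
  if (ensemble) {
    coords <- array(0, dim = c(n, 2, 3))
    coords[, 2, 1] <- d
    atoms <- data.frame(name = c("A1", "A2"), resno = c(1L, 1L),
                        resid = c("LIG", "LIG"), chain = c("A", "A"))
    out$ensemble <- coordinate_ensemble(coords, atoms)
  }
  out
}

#' Generate a synthetic coordinate ensemble around a base structure
#'
#' Frames are the base structure plus independent isotropic Gaussian
#' displacements per atom, scaled by that atom's residue-level standard
#' deviation; optionally each frame additionally receives a random
#' rigid-body rotation and translation, so that superposition is exercised
#' before fluctuation analysis.
#'
#' @param base Atoms x 3 coordinate matrix (angstroms).
#' @param atoms Atom metadata data.frame (see [coordinate_ensemble()]); its
#'   `resno` column maps atoms to `res_sd`.
#' @param res_sd Named (by residue number) or positionally matched numeric
#'   vector of per-residue displacement standard deviations, angstroms
#'   (> 0).
#' @param n_frames Number of frames (default 200).
#' @param seed Integer seed.
#' @param rigid_motion If `TRUE` (default), apply a random rotation (up to
#'   ~0.3 rad) and translation (sd 2 A) per frame.
#' @return A [coordinate_ensemble()].
#' @export
gen_ensemble <- function(base, atoms, res_sd, n_frames = 200L, seed = 1L,
                         rigid_motion = TRUE) {
  base <- as.matrix(base)
  stopifnot(ncol(base) == 3, nrow(base) == nrow(atoms))
  if (any(res_sd <= 0)) stop("res_sd values must be > 0", call. = FALSE)
  resno <- atoms$resno
  res_levels <- sort(unique(resno))
  sd_by_res <- if (!is.null(names(res_sd))) res_sd[as.character(res_levels)]
               else rep_len(res_sd, length(res_levels))
  atom_sd <- sd_by_res[match(resno, res_levels)]
  set.seed(seed)
  na <- nrow(base)
  # all displacements drawn first so the field is identical with and
  # without rigid motion under the same seed
  disp <- array(stats::rnorm(n_frames * na * 3), dim = c(n_frames, na, 3))
  coords <- array(NA_real_, dim = c(n_frames, na, 3))
  for (f in seq_len(n_frames)) {
    fr <- base + disp[f, , ] * atom_sd
    if (rigid_motion) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      th <- stats::runif(1, -0.3, 0.3)
      K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
                  3, 3)
      rot <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
      fr <- sweep(fr %*% rot, 2, stats::rnorm(3, sd = 2), "+")
    }
    coords[f, , ] <- fr
  }
  coordinate_ensemble(coords, atoms)
}
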