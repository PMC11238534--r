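#' Construct a coordinate ensemble
#'
#' A `coordinate_ensemble` stores a stack of conformations (frames) of the
#' same molecule: a numeric array `frames x atoms x 3` of coordinates in
#' angstroms plus per-atom metadata.
#'
#' @param coords Numeric array of dimension (frames, atoms, 3), finite.
#' @param atoms data.frame with one row per atom: columns `name` (atom
#'   name), `resno` (residue number), `resid` (residue name), `chain`.
#' @param bfactor Optional per-atom crystallographic B-factors (angstrom^2).
#' @return A `coordinate_ensemble` object.
#' @export
coordinate_ensemble <- function(coords, atoms, bfactor = NULL) {
  coords <- as.array(coords)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be a frames x atoms x 3 array", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  atoms <- as.data.frame(atoms)
  if (nrow(atoms) != dim(coords)[2])
    stop("atoms table must have one row per atom", call. = FALSE)
  structure(list(coords = coords, atoms = atoms, bfactor = bfactor),
            class = "coordinate_ensemble")
}

#' @export
print.coordinate_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<coordinate_ensemble> %d frames x %d atoms (%d residues)\n",
              d[1], d[2], length(unique(x$atoms$resno))))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble A [coordinate_ensemble()].
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

# Resolve an atom selector to atom indices.
# A selector is either an integer index vector or a named list of
# atom-table filters, e.g. list(name = "CA", resno = 10).
.select_atoms <- function(ensemble, selector) {
  if (is.numeric(selector)) return(as.integer(selector))
  keep <- rep(TRUE, nrow(ensemble$atoms))
  for (field in names(selector))
    keep <- keep & ensemble$atoms[[field]] %in% selector[[field]]
  which(keep)
}

#' Per-frame distance between two atoms
#'
#' Euclidean distance between two selected atoms in every frame, in frame
#' order. Each selector (an atom index, or a named list of atom-table
#' filters such as `list(name = "N1")`) must match exactly one atom.
#'
#' @param ensemble A [coordinate_ensemble()].
#' @param atom_a,atom_b Atom selectors.
#' @return Numeric vector of distances in angstroms, one per frame.
#' @export
end_to_end_series <- function(ensemble, atom_a, atom_b) {
  ia <- .select_atoms(ensemble, atom_a)
  ib <- .select_atoms(ensemble, atom_b)
  for (sel in list(a = ia, b = ib))
    if (length(sel) != 1L)
      stop("selection error: selector matches ", length(sel),
           " atoms (need exactly 1)", call. = FALSE)
  d <- ensemble$coords[, ia, , drop = FALSE] -
       ensemble$coords[, ib, , drop = FALSE]
  sqrt(rowSums(matrix(d, nrow = dim(ensemble$coords)[1], ncol = 3)^2))
}

#' Normalised distance distribution
#'
#' Histogram of distances on a fixed grid, normalised to unit probability
#' over the in-range values. Values outside the range are not silently
#' dropped: they are counted in an overflow tally.
#'
#' @param distances Numeric vector of distances, angstroms (non-empty).
#' @param bin_width Bin width in angstroms (> 0, default 0.5).
#' @param range Length-2 numeric `(min, max)` of the histogram support,
#'   default `c(3, 20)`.
#' @return A `distance_distribution`: list with `bin_edges`,
#'   `probabilities` (summing to 1), `counts`, and `n_overflow`.
#' @export
distance_distribution <- function(distances, bin_width = 0.5,
                                  range = c(3, 20)) {
  if (length(distances) == 0)
    stop("insufficient data: empty distance series", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  edges <- seq(range[1], range[2] + bin_width * 0.5, by = bin_width)
  inside <- distances >= range[1] & distances <= edges[length(edges)]
  n_over <- sum(!inside)
  if (!any(inside))
    stop("insufficient data: no distances inside range", call. = FALSE)
  counts <- graphics::hist(distances[inside], breaks = edges,
                           plot = FALSE)$counts
  structure(list(bin_edges = edges,
                 probabilities = counts / sum(counts),
                 counts = counts,
                 n_overflow = n_over),
            class = "distance_distribution")
}

#' Local maxima of a distance distribution
#'
#' Finds bins whose probability exceeds both neighbours, then greedily
#' keeps maxima in decreasing order of probability, discarding any closer
#' than `min_separation` to one already kept. The separation filter
#' suppresses the spurious shoulder maxima that finite sampling puts on a
#' broad peak, so a bimodal trajectory reports exactly its two
#' conformational modes.
#'
#' @param dist A [distance_distribution()].
#' @param min_separation Minimum distance between reported modes,
#'   angstroms (default 2).
#' @return Numeric vector of bin-centre positions of the modes, in
#'   decreasing order of probability.
#' @export
distribution_modes <- function(dist, min_separation = 2) {
  p <- dist$probabilities
  centers <- dist$bin_edges[-length(dist$bin_edges)] + diff(dist$bin_edges) / 2
  n <- length(p)
  left <- c(-Inf, p[-n])
  right <- c(p[-1], -Inf)
  cand <- which(p > 0 & p > left & p >= right)
  cand <- cand[order(p[cand], decreasing = TRUE)]
  kept <- numeric(0)
  for (i in cand)
    if (!length(kept) || all(abs(centers[i] - kept) >= min_separation))
      kept <- c(kept, centers[i])
  kept
}

#' Conformational state fractions from a distance series
#'
#' Classifies frames as compact (d <= `compact_cut`), intermediate, or
#' extended (d > `extended_cut`) and returns the three fractions (summing
#' to 1). The defaults separate a compact mode near 5.5 angstroms from
#' extended conformers beyond 11 angstroms.
#'
#' @param distances Numeric distance series, angstroms.
#' @param compact_cut Upper bound of the compact state (default 8).
#' @param extended_cut Lower bound of the extended state (default 11); must
#'   exceed `compact_cut`.
#' @return Named numeric vector `c(f_compact, f_intermediate, f_extended)`.
#' @export
state_fractions <- function(distances, compact_cut = 8, extended_cut = 11) {
  if (compact_cut >= extended_cut)
    stop("compact_cut must be < extended_cut", call. = FALSE)
  n <- length(distances)
  c(f_compact = sum(distances <= compact_cut) / n,
    f_intermediate = sum(distances > compact_cut &
                         distances <= extended_cut) / n,
    f_extended = sum(distances > extended_cut) / n)
}

#' Distance-binned mean energy profile
#'
#' Mean of a per-frame energy within distance bins. Empty bins are reported
#' as `NA`, never as zero energy.
#'
#' @param distances Per-frame distances, angstroms.
#' @param energies Per-frame energies, kcal/mol; same length as `distances`.
#' @param bin_width Bin width in angstroms (default 0.5).
#' @param range Histogram support (default `c(3, 20)`).
#' @return An `energy_profile`: data.frame with `bin_center`, `mean_energy`
#'   (`NA` where `count` is 0) and `count`.
#' @export
binned_energy_profile <- function(distances, energies, bin_width = 0.5,
                                  range = c(3, 20)) {
  if (length(distances) != length(energies))
    stop("alignment error: distances and energies differ in length",
         call. = FALSE)
  edges <- seq(range[1], range[2] + bin_width * 0.5, by = bin_width)
  idx <- findInterval(distances, edges, rightmost.closed = TRUE)
  ok <- idx >= 1 & idx <= length(edges) - 1
  nbin <- length(edges) - 1
  counts <- tabulate(idx[ok], nbins = nbin)
  sums <- rep(0, nbin)
  agg <- tapply(energies[ok], idx[ok], sum)
  sums[as.integer(names(agg))] <- agg
  prof <- data.frame(
    bin_center = edges[-length(edges)] + bin_width / 2,
    mean_energy = ifelse(counts > 0, sums / pmax(counts, 1), NA_real_),
    count = counts)
  class(prof) <- c("energy_profile", "data.frame")
  prof
}

# Kabsch optimal rotation of mobile (n x 3) onto fixed (n x 3), both
# already centred at the origin. Returns the 3x3 matrix Q minimising
# ||mobile %*% Q - fixed|| over proper rotations (row-vector convention).
.kabsch_rotation <- function(mobile, fixed) {
  s <- svd(crossprod(mobile, fixed))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Rigid-body superpose one frame (m x 3 over all atoms) onto reference
# coordinates of the selection (k x 3); transform applied to all atoms.
.superpose_frame <- function(frame, ref_sel, sel) {
  mob <- frame[sel, , drop = FALSE]
  cm <- colMeans(mob)
  cr <- colMeans(ref_sel)
  rot <- .kabsch_rotation(sweep(mob, 2, cm), sweep(ref_sel, 2, cr))
  sweep(sweep(frame, 2, cm) %*% rot, 2, cr, "+")
}

#' Iteratively superpose an ensemble onto its mean structure
#'
#' Aligns every frame to the running mean structure by least-squares
#' rigid-body (Kabsch) superposition over the selected atoms, recomputes
#' the mean, and repeats until the mean moves less than `tol` (RMSD over
#' the selection). The first frame seeds the reference. Each sweep cannot
#' increase the total squared deviation of the selection from the running
#' mean, so the procedure converges.
#'
#' @param ensemble A [coordinate_ensemble()].
#' @param selection Atom selector (see [end_to_end_series()]) with at least
#'   3 atoms; default `list(name = "CA")`.
#' @param tol Convergence tolerance on the mean shift, angstroms
#'   (default 1e-6).
#' @param max_iter Maximum sweeps (default 100).
#' @return A list with `ensemble` (aligned copy), `average` (atoms x 3 mean
#'   coordinates), `iterations`, and `converged`.
#' @export
superpose_ensemble <- function(ensemble, selection = list(name = "CA"),
                               tol = 1e-6, max_iter = 100L) {
  sel <- .select_atoms(ensemble, selection)
  if (length(sel) < 3L)
    stop("degenerate superposition: need >= 3 selected atoms", call. = FALSE)
  co <- ensemble$coords
  nf <- dim(co)[1]
  ref <- co[1, sel, ]
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (f in seq_len(nf))
      co[f, , ] <- .superpose_frame(co[f, , ], ref, sel)
    new_ref <- apply(co[, sel, , drop = FALSE], c(2, 3), mean)
    shift <- sqrt(mean(rowSums((new_ref - ref)^2)))
    ref <- new_ref
    if (shift < tol) { converged <- TRUE; break }
  }
  avg <- apply(co, c(2, 3), mean)
  out <- ensemble
  out$coords <- co
  list(ensemble = out, average = avg, iterations = iter,
       converged = converged)
}

#' RMSD between two structures after optimal superposition
#'
#' Least-squares rigid-body superposition (Kabsch) of the selected atoms of
#' `structure_b` onto those of `structure_a`, then the root-mean-square
#' deviation over the selection.
#'
#' @param structure_a,structure_b Atoms x 3 coordinate matrices (e.g. the
#'   `average` of [superpose_ensemble()]), or single-frame
#'   [coordinate_ensemble()] objects.
#' @param selection Optional row indices of the atoms to compare (applied
#'   to both); default all rows.
#' @return RMSD in angstroms.
#' @export
ca_rmsd <- function(structure_a, structure_b, selection = NULL) {
  as_mat <- function(x) {
    if (inherits(x, "coordinate_ensemble")) {
      if (n_frames(x) != 1L)
        stop("expected a single-frame structure", call. = FALSE)
      matrix(x$coords[1, , ], ncol = 3)
    } else matrix(as.numeric(x), ncol = 3)
  }
  a <- as_mat(structure_a)
  b <- as_mat(structure_b)
  if (!is.null(selection)) {
    a <- a[selection, , drop = FALSE]
    b <- b[selection, , drop = FALSE]
  }
  if (nrow(a) != nrow(b))
    stop("alignment error: selections differ in atom count", call. = FALSE)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  rot <- .kabsch_rotation(bc, ac)
  sqrt(mean(rowSums((bc %*% rot - ac)^2)))
}

#' Per-residue RMSF of a superposed ensemble
#'
#' Root-mean-square fluctuation of each selected atom about its
#' ensemble-average position, averaged within residues. The ensemble is
#' expected to be superposed already ([superpose_ensemble()]); if the
#' centroid of the selection drifts more than 1 angstrom across frames a
#' warning is issued (fluctuations would then mix rigid-body motion).
#'
#' @param ensemble A superposed [coordinate_ensemble()].
#' @param selection Atom selector; default `list(name = "CA")`. Use e.g.
#'   `list(name = c("N", "CA", "C", "O"))` for backbone RMSF.
#' @return data.frame with `resno` and `rmsf` (angstroms), one row per
#'   residue present in the selection.
#' @export
rmsf_per_residue <- function(ensemble, selection = list(name = "CA")) {
  sel <- .select_atoms(ensemble, selection)
  if (length(sel) == 0) stop("empty selection", call. = FALSE)
  co <- ensemble$coords[, sel, , drop = FALSE]
  cent <- apply(co, c(1, 3), mean)
  drift <- max(sqrt(rowSums(sweep(cent, 2, colMeans(cent))^2)))
  if (drift > 1)
    warning("selection centroid drifts ", round(drift, 2),
            " A across frames; superpose the ensemble first")
  avg <- apply(co, c(2, 3), mean)
  dev2 <- sweep(co, c(2, 3), avg)^2
  atom_rmsf <- sqrt(vapply(seq_along(sel), function(j)
    mean(rowSums(matrix(dev2[, j, ], ncol = 3))), numeric(1)))
  resno <- ensemble$atoms$resno[sel]
  agg <- tapply(atom_rmsf, resno, mean)
  out <- data.frame(resno = as.integer(names(agg)), rmsf = as.numeric(agg))
  out[order(out$resno), , drop = FALSE]
}

#' Convert crystallographic B-factors to RMSF
#'
#' Isotropic harmonic relation \eqn{B = (8\pi^2/3)\,\mathrm{RMSF}^2}, i.e.
#' \eqn{\mathrm{RMSF} = \sqrt{3B/(8\pi^2)}}.
#'
#' @param b Numeric vector of B-factors, angstrom^2 (>= 0).
#' @return RMSF values in angstroms.
#' @export
rmsf_from_bfactors <- function(b) {
  if (any(b < 0)) stop("B-factors must be non-negative", call. = FALSE)
  sqrt(3 * b / (8 * pi^2))
}
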