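#' Read a multi-model PDB file into a coordinate ensemble
#'
#' MODEL/ENDMDL records delimit frames. Atom names, residue numbers (kept
#' 1-based as in the input, no renumbering), residue names, chains and the
#' B-factor column are carried into the ensemble. Parsing is delegated to
#' \pkg{bio3d}.
#'
#' @param path Path to a PDB file (single- or multi-model).
#' @return A [coordinate_ensemble()].
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  coords <- array(NA_real_, dim = c(nf, na, 3))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, by = 3, length.out = na),
                                      drop = FALSE]
  atoms <- data.frame(name = pdb$atom$elety,
                      resno = pdb$atom$resno,
                      resid = pdb$atom$resid,
                      chain = pdb$atom$chain)
  coordinate_ensemble(coords, atoms, bfactor = pdb$atom$b)
}

#' Write a coordinate ensemble as a multi-model PDB file
#'
#' @param ensemble A [coordinate_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  co <- ensemble$coords
  nf <- dim(co)[1]
  na <- dim(co)[2]
  xyz <- matrix(NA_real_, nf, na * 3L)
  for (k in 1:3) xyz[, seq(k, by = 3, length.out = na)] <- co[, , k]
  b <- if (is.null(ensemble$bfactor)) rep(0, na) else ensemble$bfactor
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", na),
                   resno = ensemble$atoms$resno,
                   resid = ensemble$atoms$resid,
                   eleno = seq_len(na),
                   elety = ensemble$atoms$name,
                   chain = ensemble$atoms$chain,
                   b = b)
  invisible(path)
}
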