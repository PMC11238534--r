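# Shared fixtures built in code.

# A compact globular fake structure: na atoms labelled CA, one per residue.
make_ca_structure <- function(na = 30, seed = 101, sd = 8) {
  set.seed(seed)
  list(base = matrix(rnorm(na * 3, sd = sd), na, 3),
       atoms = data.frame(name = "CA", resno = seq_len(na),
                          resid = "ALA", chain = "A"))
}

# Table of fitted equilibrium-model parameters for the six thrombin
# ligands (kcal/mol and kcal/mol/K).
ligand_params <- function() {
  list(
    l0 = equilibrium_params(17.89, 0.0590, 0.07, 0.0422),
    l1 = equilibrium_params(17.49, 0.0579, 1.86, 0.0467),
    l2 = equilibrium_params(17.63, 0.0583, 2.21, 0.0486),
    l3 = equilibrium_params(17.86, 0.0601, 3.69, 0.0559),
    l4 = equilibrium_params(17.02, 0.0565, 1.70, 0.0491),
    l5 = equilibrium_params(17.50, 0.0575, 1.50, 0.0477))
}

# dU/dT derivative quadruples (holo, apo, lig, wat) and the published
# binding delta-Cp for the six simulated systems.
derivative_rows <- function() {
  data.frame(
    row = c("2-hir", "2+hir", "3-hir", "3+hir", "4-hir", "4+hir"),
    holo = c(66.962, 66.699, 67.191, 66.649, 67.310, 66.829),
    apo  = c(67.307, 66.857, 67.307, 66.857, 67.307, 66.857),
    lig  = c(23.083, 23.083, 23.072, 23.072, 23.063, 23.063),
    wat  = c(22.871, 22.871, 22.871, 22.871, 22.871, 22.871),
    dcp  = c(-0.56, -0.37, -0.32, -0.41, -0.19, -0.22))
}

rotate_translate <- function(mat, angle = 0.7, shift = c(5, -3, 2)) {
  rot <- matrix(c(cos(angle), sin(angle), 0,
                  -sin(angle), cos(angle), 0,
                  0, 0, 1), 3, 3)
  sweep(mat %*% rot, 2, shift, "+")
}
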