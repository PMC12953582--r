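# Fixtures built in code, and independent oracles used across the suite.

# minimal trajectory with a flat 4-phosphate bilayer plus arbitrary extra
# atoms; extra = data.frame(atom_name, residue_name, residue_number,
# chain_id) and coords = list of n_extra x 3 matrices (one per frame)
make_toy_traj <- function(extra = NULL, extra_coords = NULL, n_frames = 1,
                          leaflet_z = 20) {
  p_atoms <- data.frame(atom_name = rep("P", 4),
                        residue_name = rep("DSPC", 4),
                        residue_number = 1:4,
                        chain_id = rep("M", 4),
                        stringsAsFactors = FALSE)
  p_xyz <- rbind(c(-10, -10, leaflet_z), c(10, 10, leaflet_z),
                 c(-10, 10, -leaflet_z), c(10, -10, -leaflet_z))
  atoms <- p_atoms
  if (!is.null(extra)) atoms <- rbind(p_atoms, extra)
  atoms <- cbind(atom_id = seq_len(nrow(atoms)), atoms)
  xyz <- array(NA_real_, dim = c(nrow(atoms), 3, n_frames))
  for (k in seq_len(n_frames)) {
    xyz[1:4, , k] <- p_xyz
    if (!is.null(extra))
      xyz[4 + seq_len(nrow(extra)), , k] <-
        if (is.list(extra_coords)) extra_coords[[k]] else extra_coords
  }
  trajectory(atoms, xyz)
}

phosphate_sel <- function() selection("phosphates", atom_name = "P")

# deterministic synthetic AlphaFold-style single-model PDB: one CA atom per
# residue, pLDDT in the B-factor column
write_synthetic_af_pdb <- function(path, plddt, chain = "A") {
  n <- length(plddt)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(n), chain, seq_len(n), seq_len(n) * 1.5, 0, 0, 1, plddt)
  writeLines(c(lines, "END"), path)
  path
}

# two-chain backbone structure: n_res residues x N/CA/C/O
make_backbone_traj <- function(n_res, resnum_offset = 0, jitter_seed = NULL) {
  names4 <- c("N", "CA", "C", "O")
  atoms <- data.frame(
    atom_name = rep(names4, n_res),
    residue_name = rep("ALA", 4 * n_res),
    residue_number = rep(seq_len(n_res) + resnum_offset, each = 4),
    chain_id = rep("A", 4 * n_res),
    stringsAsFactors = FALSE)
  atoms <- cbind(atom_id = seq_len(nrow(atoms)), atoms)
  base <- cbind(rep(seq_len(n_res), each = 4) * 3.8,
                rep(c(0, 0.5, 1.0, 1.8), n_res),
                rep(c(0, 1.2, 0.3, -0.4), n_res))
  if (!is.null(jitter_seed)) {
    set.seed(jitter_seed)
    base <- base + matrix(rnorm(length(base), 0, 0.3), nrow(base))
  }
  trajectory(atoms, array(base, dim = c(nrow(base), 3, 1)))
}

rot_about <- function(axis, deg) {
  th <- deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, byrow = TRUE),
         y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, byrow = TRUE),
         z = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, byrow = TRUE))
}

# independent brute-force superposition oracle: coarse Euler-angle grid
# followed by Nelder-Mead polish; never touches the SVD route
oracle_min_rmsd <- function(X, Y, grid_step = 30) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  rmsd_of <- function(ang) {
    R <- rot_about("z", ang[3]) %*% rot_about("y", ang[2]) %*%
      rot_about("x", ang[1])
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  }
  grid <- seq(0, 360 - grid_step, by = grid_step)
  best <- NULL; best_v <- Inf
  for (a in grid) for (b in seq(0, 180, by = grid_step)) for (c in grid) {
    v <- rmsd_of(c(a, b, c))
    if (v < best_v) { best_v <- v; best <- c(a, b, c) }
  }
  polish <- optim(best, rmsd_of, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-14))
  polish <- optim(polish$par, rmsd_of, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-14))
  polish$value
}

# fine-histogram mode oracle for KDE checks
oracle_hist_mode <- function(x, bin = 0.1) {
  br <- seq(floor(min(x)) - bin, ceiling(max(x)) + bin, by = bin)
  h <- hist(x, breaks = br, plot = FALSE)
  h$mids[which.max(h$counts)]
}
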