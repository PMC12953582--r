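# Synthetic trajectory and titration generators with known ground truth.
# The generators emulate the simulated study systems reduced to what the
# metrics actually consume: phosphate marker atoms on two jittered leaflet
# planes, a glycolipid headgroup axis precessing about a prescribed tilt
# mode, an Ig-domain C-alpha cloud following an orientation schedule, a
# four-atom salt-bridge geometry realising scheduled pair distances, and a
# sidechain set following an insertion-depth schedule.

rotation_between <- function(a, b) {
  # proper rotation mapping unit vector a onto unit vector b (Rodrigues)
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {
    # opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * tcrossprod(v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Recipe for a synthetic membrane trajectory
#'
#' Defaults emulate the study conditions of the simulated systems: a
#' phosphatidylcholine/cholesterol bilayer reduced to phosphate markers at
#' +/- 19 Angstrom with 0.5 Angstrom z-jitter, a ganglioside headgroup whose
#' tilt precesses about the measured GM1 mode (31.32 degrees), and a
#' salt-bridge on/off schedule formed for 68.5% of frames at 4 / 8 Angstrom
#' pair distances. The seed is mandatory: no generated fixture is silently
#' nondeterministic.
#'
#' @param n_frames number of frames (>= 1).
#' @param seed integer RNG seed (mandatory).
#' @param bilayer list: `n_per_leaflet` (default 64), `leaflet_z` (Angstrom,
#'   default 19), `z_jitter` (sd, default 0.5).
#' @param glycolipid `NULL` to omit, or list: `tilt_mode` (degrees, default
#'   31.32), `tilt_spread` (angular sd, degrees, default 7),
#'   `headgroup_length` (Angstrom, default 10).
#' @param domain `NULL` (default) to omit, or list: `n_ca` (default 60),
#'   `cloud_sd` (3 sd's of the C-alpha cloud, default `c(3, 2, 8)`),
#'   `tilt_schedule` (per-frame degrees; recycled if length 1, default 30).
#' @param saltbridge `NULL` to omit, or list: `schedule` (per-frame logical,
#'   formed/broken; default: formed for the first 68.5% of frames),
#'   `formed_distance` (default 4), `broken_distance` (default 8).
#' @param insertion `NULL` (default) to omit, or list: `depth_schedule`
#'   (per-frame sidechain COM depth below the upper surface, Angstrom,
#'   positive = inserted), `residue_name` (default `"TRP"`), `residue_number`
#'   (default 127).
#' @return object of class `"membrane_recipe"`.
#' @export
membrane_recipe <- function(n_frames, seed, bilayer = list(),
                            glycolipid = list(), domain = NULL,
                            saltbridge = list(), insertion = NULL) {
  if (missing(seed)) stop("membrane_recipe: seed is mandatory")
  if (n_frames < 1) stop("n_frames must be >= 1")
  bl <- utils::modifyList(list(n_per_leaflet = 64, leaflet_z = 19,
                               z_jitter = 0.5), bilayer)
  gl <- if (is.null(glycolipid)) NULL else
    utils::modifyList(list(tilt_mode = 31.32, tilt_spread = 7,
                           headgroup_length = 10), glycolipid)
  dm <- if (is.null(domain)) NULL else
    utils::modifyList(list(n_ca = 60, cloud_sd = c(3, 2, 8),
                           tilt_schedule = 30), domain)
  sb <- if (is.null(saltbridge)) NULL else
    utils::modifyList(list(schedule = NULL, formed_distance = 4,
                           broken_distance = 8), saltbridge)
  if (!is.null(sb) && is.null(sb$schedule))
    sb$schedule <- seq_len(n_frames) <= round(0.685 * n_frames)
  ins <- if (is.null(insertion)) NULL else
    utils::modifyList(list(depth_schedule = 1, residue_name = "TRP",
                           residue_number = 127), insertion)
  check_len <- function(v, what) {
    if (length(v) == 1) v <- rep(v, n_frames)
    if (length(v) != n_frames)
      stop(what, " schedule length ", length(v), " != n_frames ", n_frames)
    v
  }
  if (!is.null(dm)) dm$tilt_schedule <- check_len(dm$tilt_schedule,
                                                  "domain tilt")
  if (!is.null(sb)) sb$schedule <- check_len(as.logical(sb$schedule),
                                             "salt-bridge")
  if (!is.null(ins)) ins$depth_schedule <- check_len(ins$depth_schedule,
                                                     "insertion depth")
  structure(list(n_frames = as.integer(n_frames), seed = as.integer(seed),
                 bilayer = bl, glycolipid = gl, domain = dm,
                 saltbridge = sb, insertion = ins),
            class = "membrane_recipe")
}

#' Generate a synthetic membrane trajectory
#'
#' Deterministic given the recipe seed. Schedule-driven quantities
#' (salt-bridge occupancy, insertion percentage, domain orientation) are
#' realised exactly; distribution-driven ones (headgroup tilt) are drawn
#' from a wrapped-normal polar angle with uniform azimuth about the
#' prescribed mode. Sidechain insertion depths are placed relative to the
#' realised (jittered) per-frame upper-leaflet surface so the schedule holds
#' exactly under [fit_bilayer_surface()].
#'
#' @param recipe a [membrane_recipe()].
#' @return a [trajectory()].
#' @export
generate_membrane_trajectory <- function(recipe) {
  stopifnot(inherits(recipe, "membrane_recipe"))
  set.seed(recipe$seed)
  nf <- recipe$n_frames
  bl <- recipe$bilayer

  atoms <- list()
  add_atoms <- function(name, resname, resnum, chain) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      atom_name = name, residue_name = resname, residue_number = resnum,
      chain_id = chain, stringsAsFactors = FALSE)
  }

  npl <- bl$n_per_leaflet
  side <- ceiling(sqrt(npl))
  gx <- (seq_len(side) - (side + 1) / 2) * 60 / side
  grid <- as.matrix(expand.grid(x = gx, y = gx))[seq_len(npl), , drop = FALSE]
  add_atoms(rep("P", npl), rep("DSPC", npl), seq_len(npl), rep("M", npl))
  add_atoms(rep("P", npl), rep("DSPC", npl), npl + seq_len(npl), rep("M", npl))

  has_gl <- !is.null(recipe$glycolipid)
  if (has_gl) {
    add_atoms("C1", "GAL", 1001L, "L")
    add_atoms(c("C2", "C3"), "SIA", 1002L, "L")
  }
  has_sb <- !is.null(recipe$saltbridge)
  if (has_sb) {
    add_atoms(c("NH1", "NH2"), "ARG", 122L, "P")
    add_atoms(c("O11", "O12"), "SIA", 1002L, "L")
  }
  has_dm <- !is.null(recipe$domain)
  if (has_dm)
    add_atoms(rep("CA", recipe$domain$n_ca), rep("ALA", recipe$domain$n_ca),
              200L + seq_len(recipe$domain$n_ca), rep("P", recipe$domain$n_ca))
  has_ins <- !is.null(recipe$insertion)
  if (has_ins) {
    ins <- recipe$insertion
    nm <- sidechain_atom_names(ins$residue_name)[1:4]
    add_atoms(nm, rep(ins$residue_name, 4), rep(ins$residue_number, 4),
              rep("P", 4))
  }
  atoms <- do.call(rbind, atoms)
  atoms <- cbind(atom_id = seq_len(nrow(atoms)), atoms)
  na <- nrow(atoms)
  xyz <- array(0, dim = c(na, 3, nf))

  # pre-draw everything in a fixed order so the stream is reproducible
  jit_up <- matrix(stats::rnorm(npl * nf, 0, bl$z_jitter), npl, nf)
  jit_lo <- matrix(stats::rnorm(npl * nf, 0, bl$z_jitter), npl, nf)
  if (has_gl) {
    gl <- recipe$glycolipid
    theta <- recipe$glycolipid$tilt_mode +
      stats::rnorm(nf, 0, gl$tilt_spread)
    theta <- abs(theta)                      # reflect at 0
    theta <- ifelse(theta > 180, 360 - theta, theta)
    phi <- stats::runif(nf, 0, 2 * pi)
  }
  if (has_dm) {
    dm <- recipe$domain
    base_cloud <- cbind(stats::rnorm(dm$n_ca, 0, dm$cloud_sd[1]),
                        stats::rnorm(dm$n_ca, 0, dm$cloud_sd[2]),
                        stats::rnorm(dm$n_ca, 0, dm$cloud_sd[3]))
    base_cloud <- sweep(base_cloud, 2, colMeans(base_cloud))
    ev <- eigen(stats::cov(base_cloud), symmetric = TRUE)
    pc1_base <- ev$vectors[, 1]
    if (pc1_base[3] < 0) pc1_base <- -pc1_base
  }

  row0 <- 0L
  p_up <- row0 + seq_len(npl); row0 <- row0 + npl
  p_lo <- row0 + seq_len(npl); row0 <- row0 + npl
  if (has_gl) { i_base <- row0 + 1L; i_tip <- row0 + 2:3; row0 <- row0 + 3L }
  if (has_sb) { i_cat <- row0 + 1:2; i_ani <- row0 + 3:4; row0 <- row0 + 4L }
  if (has_dm) { i_ca <- row0 + seq_len(recipe$domain$n_ca)
                row0 <- row0 + recipe$domain$n_ca }
  if (has_ins) { i_sc <- row0 + 1:4; row0 <- row0 + 4L }

  sc_offsets <- rbind(c(0.8, 0, 0), c(-0.8, 0, 0), c(0, 0.8, 0), c(0, -0.8, 0))

  for (k in seq_len(nf)) {
    xyz[p_up, 1:2, k] <- grid
    xyz[p_up, 3, k] <- bl$leaflet_z + jit_up[, k]
    xyz[p_lo, 1:2, k] <- grid
    xyz[p_lo, 3, k] <- -bl$leaflet_z + jit_lo[, k]

    if (has_gl) {
      gl <- recipe$glycolipid
      th <- theta[k] * pi / 180
      u <- c(sin(th) * cos(phi[k]), sin(th) * sin(phi[k]), cos(th))
      base <- c(0, 0, bl$leaflet_z)
      centroid <- base + gl$headgroup_length * u
      # perpendicular offset splitting the two tip atoms symmetrically
      w <- c(-sin(phi[k]), cos(phi[k]), 0)
      xyz[i_base, , k] <- base
      xyz[i_tip[1], , k] <- centroid + 0.7 * w
      xyz[i_tip[2], , k] <- centroid - 0.7 * w
    }
    if (has_sb) {
      sb <- recipe$saltbridge
      d <- if (sb$schedule[k]) sb$formed_distance else sb$broken_distance
      a <- 0.6
      if (d^2 <= 2 * a^2) stop("scheduled distance too small for geometry")
      zd <- sqrt(d^2 - 2 * a^2)
      ctr <- c(12, 0, bl$leaflet_z + 6)
      xyz[i_cat[1], , k] <- ctr + c(a, 0, 0)
      xyz[i_cat[2], , k] <- ctr + c(-a, 0, 0)
      xyz[i_ani[1], , k] <- ctr + c(0, a, zd)
      xyz[i_ani[2], , k] <- ctr + c(0, -a, zd)
    }
    if (has_dm) {
      dm <- recipe$domain
      th <- dm$tilt_schedule[k] * pi / 180
      target <- c(sin(th), 0, cos(th))
      R <- rotation_between(pc1_base, target)
      com <- c(-15, 0, bl$leaflet_z + 20)
      xyz[i_ca, , k] <- sweep(base_cloud %*% t(R), 2, com, "+")
    }
    if (has_ins) {
      ins <- recipe$insertion
      surf_z <- mean(xyz[p_up, 3, k])   # realised upper surface this frame
      com <- c(8, -8, surf_z - ins$depth_schedule[k])
      xyz[i_sc, , k] <- sweep(sc_offsets, 2, com, "+")
    }
  }
  trajectory(atoms, xyz, time_ns = (seq_len(nf) - 1L) * 1.0,
             metadata = list(generator = "generate_membrane_trajectory",
                             seed = recipe$seed))
}

#' Recipe for a synthetic COIN titration series
#'
#' @param kd,de,cl true binding parameters: dissociation constant
#'   (micromolar), detection efficiency, ligand flux rate (micromolar/min).
#' @param p0 protein concentration, micromolar.
#' @param times time points, minutes.
#' @param noise_sigma Gaussian noise sd on the fraction bound (>= 0).
#' @param abundance_scale protein ion abundance used to map fractions to
#'   abundances.
#' @param seed integer RNG seed (mandatory).
#' @return object of class `"coin_recipe"`.
#' @export
coin_recipe <- function(kd, de, cl, p0, times = seq_len(60),
                        noise_sigma = 0, abundance_scale = 1000, seed) {
  if (missing(seed)) stop("coin_recipe: seed is mandatory")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (any(c(kd, de, cl, p0) <= 0)) stop("kd, de, cl, p0 must be positive")
  structure(list(kd = kd, de = de, cl = cl, p0 = p0,
                 times = as.numeric(times), noise_sigma = noise_sigma,
                 abundance_scale = abundance_scale, seed = as.integer(seed)),
            class = "coin_recipe")
}

#' Generate a synthetic COIN titration dataset
#'
#' Fractions bound follow [occupancy_model()] plus Gaussian noise truncated
#' at zero; the protein abundance channel is constant at `abundance_scale`
#' and the ligand channel is `F_t * abundance_scale`, so
#' [fraction_bound()] inverts the construction exactly at zero noise.
#'
#' @param recipe a [coin_recipe()].
#' @return a [coin_dataset()].
#' @export
generate_coin_series <- function(recipe) {
  stopifnot(inherits(recipe, "coin_recipe"))
  set.seed(recipe$seed)
  F_true <- occupancy_model(recipe$times, recipe$kd, recipe$de, recipe$cl,
                            recipe$p0)
  F_obs <- pmax(F_true + stats::rnorm(length(F_true), 0,
                                      recipe$noise_sigma), 0)
  coin_dataset(recipe$times,
               ab_ligand = F_obs * recipe$abundance_scale,
               ab_protein = rep(recipe$abundance_scale,
                                length(recipe$times)),
               p0 = recipe$p0)
}

#' Write the reference fixture suite
#'
#' Emits a versioned set of small plain-text fixtures (multi-model PDB,
#' frame tables, COIN CSVs) together with `manifest.json` recording the
#' ground-truth value and comparison tolerance for each. All seeds are fixed
#' inside, so regenerating into the same directory is byte-identical.
#'
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
reference_fixture_suite <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(version = 1, fixtures = list())
  note <- function(file, metric, value, tolerance, comment = NULL) {
    manifest$fixtures[[length(manifest$fixtures) + 1]] <<- list(
      file = file, metric = metric, value = value, tolerance = tolerance,
      comment = comment)
  }

  # salt-bridge schedule: 137 of 200 frames formed -> occupancy 0.685
  r1 <- membrane_recipe(n_frames = 200, seed = 101,
                        bilayer = list(n_per_leaflet = 8),
                        glycolipid = NULL,
                        saltbridge = list(schedule =
                          seq_len(200) <= 137))
  write_multimodel_pdb(generate_membrane_trajectory(r1),
                       file.path(dir, "traj_saltbridge.pdb"))
  note("traj_saltbridge.pdb", "saltbridge_occupancy", 0.685, 0,
       "schedule-driven, exact")

  # insertion schedule: 6 of 20 frames below the surface -> 30%
  r2 <- membrane_recipe(n_frames = 20, seed = 102,
                        bilayer = list(n_per_leaflet = 8),
                        glycolipid = NULL, saltbridge = NULL,
                        insertion = list(depth_schedule =
                          ifelse(seq_len(20) <= 6, 1.5, -1.5)))
  write_frame_table(generate_membrane_trajectory(r2),
                    file.path(dir, "traj_insertion.csv"))
  note("traj_insertion.csv", "insertion_percent", 30, 0,
       "schedule-driven, exact")

  # glycan tilt about the GM1 mode; KDE mode is statistical
  r3 <- membrane_recipe(n_frames = 2000, seed = 103,
                        bilayer = list(n_per_leaflet = 8),
                        glycolipid = list(tilt_mode = 31.32,
                                          tilt_spread = 7),
                        saltbridge = NULL)
  write_frame_table(generate_membrane_trajectory(r3),
                    file.path(dir, "traj_tilt.csv"))
  note("traj_tilt.csv", "tilt_kde_mode", 31.32, 1.5,
       "distribution-driven, statistical")

  # COIN titrations, Kd 500 uM (0.5 mM)
  c1 <- coin_recipe(kd = 500, de = 0.8, cl = 1, p0 = 0.8,
                    times = seq_len(60), noise_sigma = 0, seed = 104)
  write_coin_csv(generate_coin_series(c1), file.path(dir, "coin_noiseless.csv"))
  note("coin_noiseless.csv", "kd_uM", 500, 1e-3, "noiseless, exact recovery")

  # noisy series in the protein-depletion regime (kd ~ p0), where kd is
  # identified; even there kd recovery is long-tailed at this noise level,
  # hence the broad statistical band
  c2 <- coin_recipe(kd = 0.5, de = 0.8, cl = 0.05, p0 = 0.8,
                    times = seq(0.5, 30, length.out = 60),
                    noise_sigma = 0.01, seed = 105)
  write_coin_csv(generate_coin_series(c2), file.path(dir, "coin_noisy.csv"))
  note("coin_noisy.csv", "kd_uM", 0.5, 4,
       "sigma 0.01, statistical (99% sampling band)")

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
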