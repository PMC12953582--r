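# Bilayer surface model, tilt angles, salt bridge, insertion, KDE mode.

test_that("bilayer surface: means, leaflet assignment, degenerate leaflet", {
  tr <- make_toy_traj()
  surf <- fit_bilayer_surface(tr, phosphate_sel())
  expect_equal(surf$frames$midplane_z, 0)
  expect_equal(surf$frames$upper_surface_z, 20)
  expect_equal(surf$frames$lower_surface_z, -20)
  expect_equal(surf$normal, c(0, 0, 1))

  # all phosphates at one z: a leaflet is empty
  flat <- tr
  flat$xyz[1:4, 3, 1] <- 15
  expect_error(fit_bilayer_surface(flat, phosphate_sel()), "leaflet")
})

test_that("bilayer surface equals the direct mean of jittered marker z", {
  set.seed(21)
  n_side <- 16; nf <- 5
  jit_up <- matrix(rnorm(n_side * nf, 0, 0.5), n_side, nf)
  jit_lo <- matrix(rnorm(n_side * nf, 0, 0.5), n_side, nf)
  atoms <- data.frame(atom_id = 1:(2 * n_side), atom_name = "P",
                      residue_name = "DSPC",
                      residue_number = 1:(2 * n_side), chain_id = "M")
  xyz <- array(0, dim = c(2 * n_side, 3, nf))
  for (k in 1:nf) {
    xyz[1:n_side, 1, k] <- seq_len(n_side)
    xyz[1:n_side, 3, k] <- 19 + jit_up[, k]
    xyz[n_side + 1:n_side, 1, k] <- seq_len(n_side)
    xyz[n_side + 1:n_side, 3, k] <- -19 + jit_lo[, k]
  }
  surf <- fit_bilayer_surface(trajectory(atoms, xyz), phosphate_sel())
  # oracle: direct mean of the very z draws that built each frame
  expect_equal(surf$frames$upper_surface_z, 19 + colMeans(jit_up))
  expect_equal(surf$frames$lower_surface_z, -19 + colMeans(jit_lo))
  expect_lt(max(abs(surf$frames$upper_surface_z - 19)),
            3 * 0.5 / sqrt(n_side))
})

glycan_fixture <- function(v, base = c(0, 0, 25)) {
  extra <- data.frame(atom_name = c("C1", "C2", "C3"),
                      residue_name = c("GAL", "SIA", "SIA"),
                      residue_number = c(1, 2, 2), chain_id = "L")
  tipc <- base + v
  coords <- rbind(base, tipc + c(0.5, 0, 0) * 0, tipc)  # two tips, centroid v
  coords[2, ] <- tipc + c(0, 0.3, 0)
  coords[3, ] <- tipc - c(0, 0.3, 0)
  make_toy_traj(extra, coords)
}

tilt_of <- function(v) {
  tr <- glycan_fixture(v)
  surf <- fit_bilayer_surface(tr, phosphate_sel())
  sp <- tilt_spec(selection("base", atom_name = "C1"),
                  selection("tip", atom_name = c("C2", "C3")))
  glycan_tilt_series(tr, sp, surf)$values
}

test_that("glycan tilt: closed-form angles against the leaflet normal", {
  expect_equal(tilt_of(c(0, 0, 5)), 0)
  expect_equal(tilt_of(c(1, 0, 0)), 90)
  expect_equal(tilt_of(c(0, 3, 4)), acos(4 / 5) * 180 / pi)  # 36.87
  # lower-leaflet glycolipid: outward normal flips, angles mirror
  tr <- glycan_fixture(c(0, 0, -5), base = c(0, 0, -25))
  surf <- fit_bilayer_surface(tr, phosphate_sel())
  sp <- tilt_spec(selection("base", atom_name = "C1"),
                  selection("tip", atom_name = c("C2", "C3")))
  expect_equal(glycan_tilt_series(tr, sp, surf)$values, 0)
})

test_that("glycan tilt: rigid-motion invariance and in-plane rotation law", {
  set.seed(5)
  for (rep in 1:5) {
    v <- rnorm(3); v <- 5 * v / sqrt(sum(v^2))
    t0 <- tilt_of(v)
    # rotation about the normal leaves the tilt unchanged
    expect_equal(tilt_of(as.numeric(rot_about("z", runif(1, 0, 360)) %*% v)),
                 t0, tolerance = 1e-10)
    # translation of the whole frame leaves it unchanged (base shifts)
    tr <- glycan_fixture(v, base = c(13, -7, 25))
    surf <- fit_bilayer_surface(tr, phosphate_sel())
    sp <- tilt_spec(selection("base", atom_name = "C1"),
                    selection("tip", atom_name = c("C2", "C3")))
    expect_equal(glycan_tilt_series(tr, sp, surf)$values, t0,
                 tolerance = 1e-10)
  }
  # rotating v about an in-plane axis changes the tilt by exactly that angle
  expect_equal(tilt_of(as.numeric(rot_about("y", 25) %*% c(0, 0, 5))), 25)
  # degenerate axis vector is masked with a warning
  expect_warning(ts <- {
    tr <- glycan_fixture(c(0, 0, 1e-8))
    surf <- fit_bilayer_surface(tr, phosphate_sel())
    glycan_tilt_series(tr, tilt_spec(selection("b", atom_name = "C1"),
                                     selection("t", atom_name = c("C2", "C3"))),
                       surf)
  }, "masked")
  expect_false(ts$mask[1])
})

# symmetric C-alpha cloud whose empirical principal axis is exactly +z
sym_cloud <- function() {
  rbind(c(1, 0, 4), c(-1, 0, 4), c(0, 1, 4), c(0, -1, 4),
        c(1, 0, -4), c(-1, 0, -4), c(0, 1, -4), c(0, -1, -4))
}

domain_fixture <- function(cloud_frames) {
  n <- nrow(cloud_frames[[1]])
  extra <- data.frame(atom_name = rep("CA", n), residue_name = "ALA",
                      residue_number = 200 + seq_len(n), chain_id = "P")
  make_toy_traj(extra, cloud_frames, n_frames = length(cloud_frames))
}

test_that("domain tilt: static and rigidly rotated clouds", {
  cl <- sym_cloud()
  tr <- domain_fixture(list(cl, cl))
  surf <- fit_bilayer_surface(tr, phosphate_sel())
  sp <- domain_axis_spec(selection("ca", atom_name = "CA"))
  expect_equal(domain_tilt_series(tr, sp, surf)$values, c(0, 0))

  cl30 <- cl %*% t(rot_about("y", 30))
  tr30 <- domain_fixture(list(cl30, cl30))
  expect_equal(domain_tilt_series(tr30, sp,
                                  fit_bilayer_surface(tr30, phosphate_sel()))$values,
               c(30, 30), tolerance = 1e-10)
  # per-frame mode tracks a changing orientation
  tr_mix <- domain_fixture(list(cl, cl30))
  sp_pf <- domain_axis_spec(selection("ca", atom_name = "CA"),
                            mode = "per_frame")
  expect_equal(domain_tilt_series(tr_mix, sp_pf,
                                  fit_bilayer_surface(tr_mix, phosphate_sel()))$values,
               c(0, 30), tolerance = 1e-10)
})

test_that("domain tilt PC1 matches an independent SVD oracle; errors", {
  set.seed(31)
  nf <- 50; nca <- 12
  clouds <- lapply(1:nf, function(k)
    cbind(rnorm(nca, 0, 2), rnorm(nca, 0, 1), rnorm(nca, 0, 6)) +
      matrix(rnorm(3, 0, 5), nca, 3, byrow = TRUE))
  tr <- domain_fixture(clouds)
  surf <- fit_bilayer_surface(tr, phosphate_sel())
  ts <- domain_tilt_series(tr, domain_axis_spec(selection("ca", atom_name = "CA")),
                           surf)
  pc1 <- attr(ts, "pc1")
  # oracle: right singular vector of the pooled per-frame-centred matrix
  pooled <- do.call(rbind, lapply(clouds, function(cl)
    sweep(cl, 2, colMeans(cl))))
  v1 <- svd(pooled)$v[, 1]
  expect_lt(abs(abs(sum(pc1 * v1)) - 1), 1e-8)
  expect_true(all(ts$values >= 0 & ts$values <= 180))

  # isotropic cloud: ambiguous principal axis
  iso <- rbind(c(4, 0, 0), c(-4, 0, 0), c(0, 4, 0), c(0, -4, 0),
               c(0, 0, 4), c(0, 0, -4))
  tri <- domain_fixture(list(iso, iso))
  expect_error(domain_tilt_series(tri,
                                  domain_axis_spec(selection("ca", atom_name = "CA")),
                                  fit_bilayer_surface(tri, phosphate_sel())),
               "ambiguous|degenerate")
  # too few atoms / frames
  small <- domain_fixture(list(sym_cloud()[1:3, ], sym_cloud()[1:3, ]))
  expect_error(domain_tilt_series(small,
                                  domain_axis_spec(selection("ca", atom_name = "CA")),
                                  fit_bilayer_surface(small, phosphate_sel())),
               ">= 4")
})

saltbridge_fixture <- function(dists_per_frame) {
  # one cation, four anions: pair distances are set directly per frame
  extra <- data.frame(atom_name = c("NH1", "O11", "O12", "O13", "O14"),
                      residue_name = c("ARG", rep("SIA", 4)),
                      residue_number = c(122, rep(1002, 4)), chain_id = "X")
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 1) / sqrt(3))
  coords <- lapply(dists_per_frame, function(d)
    rbind(c(0, 0, 0), dirs * d))
  make_toy_traj(extra, coords, n_frames = length(dists_per_frame))
}

test_that("salt bridge: aggregate distance, inclusive threshold, formed flag", {
  tr <- saltbridge_fixture(list(c(3, 4, 4.5, 4.9), c(3, 4, 4.5, 5.1)))
  spec <- salt_bridge_spec(selection("cat", atom_name = "NH1"),
                           selection("ani", atom_name = c("O11", "O12",
                                                          "O13", "O14")))
  sb <- salt_bridge_series(tr, spec)
  expect_equal(sb$distance$values, c(4.9, 5.1))
  expect_equal(sb$formed$values, c(1, 0))

  # exact boundary: 3-4-5 triangle, threshold inclusive
  tr5 <- make_toy_traj(
    data.frame(atom_name = c("NH1", "O11"), residue_name = c("ARG", "SIA"),
               residue_number = c(122, 1002), chain_id = "X"),
    rbind(c(0, 0, 0), c(3, 4, 0)))
  sb5 <- salt_bridge_series(tr5,
                            salt_bridge_spec(selection("c", atom_name = "NH1"),
                                             selection("a", atom_name = "O11")))
  expect_equal(sb5$distance$values, 5)
  expect_equal(sb5$formed$values, 1)

  # max aggregate dominates min; max-formed implies min-formed
  spec_min <- salt_bridge_spec(selection("cat", atom_name = "NH1"),
                               selection("ani", atom_name = c("O11", "O12",
                                                              "O13", "O14")),
                               aggregator = "min")
  sb_min <- salt_bridge_series(tr, spec_min)
  expect_true(all(sb$distance$values >= sb_min$distance$values))
  expect_true(all(sb$formed$values <= sb_min$formed$values))
})

test_that("occupancy: arithmetic, ranges, complement identity, guards", {
  all1 <- metric_series("f", "fraction", rep(1, 10))
  expect_equal(as.numeric(occupancy(all1)), 1)

  sched <- metric_series("f", "fraction",
                         as.numeric(seq_len(200) <= 137))
  occ <- occupancy(sched)
  expect_equal(as.numeric(occ), 0.685)
  expect_equal(attr(occ, "percent"), 68.5)

  comp <- metric_series("f", "fraction", 1 - sched$values)
  expect_equal(as.numeric(occupancy(sched)) + as.numeric(occupancy(comp)), 1)

  # 0-based inclusive frame range
  expect_equal(as.numeric(occupancy(sched, frame_range = c(0, 136))), 1)
  expect_equal(as.numeric(occupancy(sched, frame_range = c(137, 199))), 0)
  expect_error(occupancy(sched, frame_range = c(300, 400)), "no unmasked")
  expect_error(occupancy(metric_series("f", "fraction", c(0, 0.5, 1))),
               "binary")
})

test_that("insertion: depth sign, percentages, residue guard", {
  mk <- function(com_zs) {
    extra <- data.frame(atom_name = c("CB", "CG", "CD", "CE", "NZ"),
                        residue_name = "LYS", residue_number = 126,
                        chain_id = "P")
    coords <- lapply(com_zs, function(z)
      cbind(1:5, 0, z + c(-0.2, -0.1, 0, 0.1, 0.2)))
    make_toy_traj(extra, coords, n_frames = length(com_zs))
  }
  # COM 2 A above the upper surface (z = 22 vs surface 20): never inserted
  tr <- mk(rep(22, 5))
  surf <- fit_bilayer_surface(tr, phosphate_sel())
  sel <- sidechain_selection("LYS", 126)
  ins <- insertion_series(tr, sel, surf, "upper")
  expect_equal(as.numeric(occupancy(ins$inserted)), 0)
  expect_equal(ins$depth$values, rep(-2, 5))

  # below the surface in 3 of 10 frames
  tr3 <- mk(c(rep(19, 3), rep(21, 7)))
  ins3 <- insertion_series(tr3, sel, fit_bilayer_surface(tr3, phosphate_sel()),
                           "upper")
  expect_equal(100 * as.numeric(occupancy(ins3$inserted)), 30)

  # sinusoidal COM crossing the surface: analytic fraction of samples below
  n <- 40
  zs <- 20 + 3 * sin(2 * pi * (seq_len(n) - 0.5) / n)
  trs <- mk(zs)
  inss <- insertion_series(trs, sel, fit_bilayer_surface(trs, phosphate_sel()),
                           "upper")
  expect_equal(as.numeric(occupancy(inss$inserted)), mean(zs < 20))
  expect_equal(as.numeric(occupancy(inss$inserted)), 0.5)

  # selection crossing residues is rejected
  bad <- make_toy_traj(
    data.frame(atom_name = c("CB", "CB"), residue_name = c("LYS", "TRP"),
               residue_number = c(126, 127), chain_id = "P"),
    rbind(c(0, 0, 10), c(1, 1, 10)))
  expect_error(insertion_series(bad, selection("two", atom_name = "CB"),
                                fit_bilayer_surface(bad, phosphate_sel()),
                                "upper"),
               "crosses residues")
  # lower leaflet mirrors the sign convention: inserted means above the
  # lower phosphate plane, towards the midplane
  trl <- mk(rep(-19, 4))
  insl <- insertion_series(trl, sel, fit_bilayer_surface(trl, phosphate_sel()),
                           "lower")
  expect_equal(insl$depth$values, rep(1, 4))
})

test_that("kde_mode: degenerate, guards, tie-break and grid layout", {
  k <- kde_mode(rep(30, 1000))
  expect_true(k$degenerate)
  expect_equal(k$mode, 30)
  expect_error(kde_mode(1:9), ">= 10")

  set.seed(77)
  x <- rnorm(500, 30, 5)
  k2 <- kde_mode(x)
  expect_equal(k2$bandwidth, sd(x) * 500^(-1 / 5))   # Scott's rule
  expect_equal(diff(k2$grid)[1], 0.01, tolerance = 1e-9)
  expect_equal(k2$mode, k2$grid[which.max(k2$density)])
  # density integrates to ~1 on the 3-bandwidth-padded grid
  tr_int <- sum(diff(k2$grid) *
                  (head(k2$density, -1) + tail(k2$density, -1)) / 2)
  expect_equal(tr_int, 1, tolerance = 1e-3)
})

test_that("kde_mode recovers a unimodal generating mode; converges in n", {
  set.seed(11)
  x_big <- rnorm(1e5, 30, 5)
  k_big <- kde_mode(x_big)
  expect_lt(abs(k_big$mode - 30), 0.3)
  # oracle: fine-histogram argmax on the same sample
  expect_lt(abs(k_big$mode - oracle_hist_mode(x_big)), 0.5)
  # error shrinks with sample size (averaged over replicates so the
  # comparison reflects the rates, not one lucky draw)
  err <- function(n, seed) {
    set.seed(seed)
    abs(kde_mode(rnorm(n, 30, 5))$mode - 30)
  }
  e_small <- mean(vapply(1:5, function(s) err(1e3, s), 1))
  e_big <- mean(vapply(1:5, function(s) err(2e4, s), 1))
  expect_lt(e_big, e_small)
})
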