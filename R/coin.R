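# COIN-CaR-nMS binding model: fraction bound from ion abundances, the
# time-dependent occupancy model, Kd fitting, and nanodisc stoichiometry.
#
# In a concentration-independent catch-and-release native MS experiment, slow
# in-emitter mixing makes the free-ligand exposure grow (approximately
# linearly) with time, L(t) = C_L * t. For a 1:1 equilibrium with protein at
# initial concentration P0, the fraction of protein sites occupied at
# exposure L is the root of the binding quadratic, scaled by the detection
# efficiency DE of the released-ligand ion relative to the protein ion:
#
#   F(t) = DE * (P0 + C_L t + Kd - sqrt((Kd - C_L t + P0)^2 + 4 Kd C_L t))
#              / (2 P0)
#
# F(0) = 0 and F -> DE as t -> Inf. Kd is fitted (with DE and C_L) by least
# squares against F_t = Ab_t(ligand) / Ab_t(protein).

#' Construct a COIN titration dataset
#'
#' @param times strictly increasing time points, minutes.
#' @param ab_ligand released-ligand ion abundance per time (arbitrary
#'   units >= 0).
#' @param ab_protein free-protein ion abundance per time (> 0).
#' @param p0 initial protein concentration, micromolar.
#' @return object of class `"coin_dataset"`.
#' @export
coin_dataset <- function(times, ab_ligand, ab_protein, p0) {
  times <- as.numeric(times)
  if (length(times) < 1 || any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (length(ab_ligand) != length(times) ||
      length(ab_protein) != length(times))
    stop("abundance vectors must match the number of time points")
  if (any(ab_ligand < 0)) stop("ab_ligand must be non-negative")
  if (length(p0) != 1 || p0 <= 0) stop("p0 must be a single positive value")
  structure(list(times = times, ab_ligand = as.numeric(ab_ligand),
                 ab_protein = as.numeric(ab_protein), p0 = p0),
            class = "coin_dataset")
}

#' Read a COIN dataset from CSV (+ JSON sidecar)
#'
#' CSV columns `time_min,ab_ligand,ab_protein`; the protein concentration is
#' taken from `p0_uM` in a JSON sidecar (`<path>.json` by default) or passed
#' directly.
#'
#' @param path CSV path.
#' @param p0 protein concentration in micromolar; if `NULL`, read from the
#'   sidecar.
#' @return a [coin_dataset()].
#' @export
read_coin_csv <- function(path, p0 = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_min", "ab_ligand", "ab_protein")
  if (!all(need %in% names(df)))
    stop("COIN CSV needs columns ", paste(need, collapse = ","))
  if (is.null(p0)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("p0 not given and sidecar ", sidecar, " not found")
    p0 <- jsonlite::fromJSON(sidecar)$p0_uM
  }
  coin_dataset(df$time_min, df$ab_ligand, df$ab_protein, p0)
}

#' Write a COIN dataset to CSV with its JSON sidecar
#'
#' @param ds a [coin_dataset()].
#' @param path CSV path; `<path>.json` receives `{"p0_uM": ...}`.
#' @return `path`, invisibly.
#' @export
write_coin_csv <- function(ds, path) {
  stopifnot(inherits(ds, "coin_dataset"))
  con <- file(path, open = "wt")
  writeLines("time_min,ab_ligand,ab_protein", con)
  writeLines(sprintf("%.15g,%.15g,%.15g", ds$times, ds$ab_ligand,
                     ds$ab_protein), con)
  close(con)
  writeLines(jsonlite::toJSON(list(p0_uM = ds$p0), auto_unbox = TRUE,
                              digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Fraction bound from ion abundances
#'
#' The time-dependent fractional occupancy is the ratio of released-ligand to
#' free-protein ion abundance. No clipping is applied: values may exceed 1
#' when the detection efficiency is above unity.
#'
#' @param ds a [coin_dataset()].
#' @return numeric vector of per-time fractions.
#' @export
fraction_bound <- function(ds) {
  stopifnot(inherits(ds, "coin_dataset"))
  bad <- which(ds$ab_protein <= 0)
  if (length(bad) > 0)
    stop("non-positive protein abundance at time index ", bad[1])
  ds$ab_ligand / ds$ab_protein
}

#' Time-dependent occupancy model
#'
#' Evaluates the catch-and-release occupancy curve (see the package
#' vignette): a 1:1 binding quadratic under a linearly growing ligand
#' exposure `L(t) = cl * t`, scaled by the detection efficiency. A
#' caller-supplied exposure table can replace the linear ramp for non-linear
#' flux.
#'
#' @param t time, minutes (vectorised).
#' @param kd dissociation constant, micromolar.
#' @param de detection efficiency, dimensionless.
#' @param cl ligand concentration flux rate, micromolar per minute.
#' @param p0 initial protein concentration, micromolar.
#' @param exposure optional function `L(t)` returning the cumulative ligand
#'   exposure in micromolar; defaults to the linear ramp `cl * t`.
#' @return fraction bound at each `t`.
#' @export
occupancy_model <- function(t, kd, de, cl, p0, exposure = NULL) {
  if (any(t < 0)) stop("t must be non-negative")
  if (kd <= 0 || de <= 0 || cl <= 0 || p0 <= 0)
    stop("kd, de, cl and p0 must all be positive")
  L <- if (is.null(exposure)) cl * t else exposure(t)
  de * (p0 + L + kd - sqrt((kd - L + p0)^2 + 4 * kd * L)) / (2 * p0)
}

# standard errors from the local quadratic approximation at the optimum:
# sigma^2 (J' W J)^-1 with a central-difference Jacobian
coin_fit_stderr <- function(t, est, p0, F_obs, fv, w) {
  J <- matrix(NA_real_, length(t), 3)
  for (j in 1:3) {
    h <- max(abs(est[j]), 1e-8) * 1e-6
    up <- dn <- est
    up[j] <- est[j] + h
    dn[j] <- max(est[j] - h, 1e-12)
    J[, j] <- (occupancy_model(t, up["kd"], up["de"], up["cl"], p0 = p0) -
               occupancy_model(t, dn["kd"], dn["de"], dn["cl"], p0 = p0)) /
      (up[j] - dn[j])
  }
  sse <- sum(w * (F_obs - fv)^2)
  sigma2 <- sse / max(length(t) - 3, 1)
  vc <- tryCatch(sigma2 * solve(crossprod(J * sqrt(w))),
                 error = function(e) NULL)
  if (is.null(vc)) return(stats::setNames(rep(NA_real_, 3),
                                          c("kd", "de", "cl")))
  stats::setNames(sqrt(pmax(diag(vc), 0)), c("kd", "de", "cl"))
}

#' Fit the COIN-CaR-nMS occupancy model
#'
#' Least-squares fit of the occupancy curve to observed fractions bound
#' ([fraction_bound()]) over `(kd, de, cl)` with positivity bounds
#' (`de <= 5`). The objective has a nearly flat ridge when `kd >> p0` (to
#' first order only `de` and `kd / cl` are identified; `kd` itself is pinned
#' by an O(p0 / kd) correction), so the fit proceeds in two deterministic
#' stages: a bounded Levenberg-Marquardt pass over all three parameters
#' (with five log-spaced `kd` restarts if it fails), then profile
#' refinement - Brent minimisation of the profile sum of squares over
#' `log10(kd)`, refitting the well-conditioned `(de, cl)` subproblem at each
#' candidate `kd`.
#'
#' Default start: `de` from the plateau (max observed fraction, clipped to
#' (0, 2]), `cl` from the initial slope, `kd = p0`.
#'
#' @param data a [coin_dataset()] with >= 5 time points.
#' @param start optional named list/vector with `kd`, `de`, `cl` overriding
#'   the default start.
#' @param lower,upper optional named bounds for `kd`, `de`, `cl`.
#' @param weights optional per-point weights for weighted least squares.
#' @return object of class `"coin_fit"` with methods `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @export
coin_fit <- function(data, start = NULL, lower = NULL, upper = NULL,
                     weights = NULL) {
  stopifnot(inherits(data, "coin_dataset"))
  if (length(data$times) < 5)
    stop("coin_fit needs >= 5 time points, got ", length(data$times))
  t <- data$times
  F_obs <- fraction_bound(data)
  p0 <- data$p0

  lo <- c(kd = 1e-9, de = 1e-9, cl = 1e-9)
  hi <- c(kd = Inf, de = 5, cl = Inf)
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)

  de0 <- max(F_obs)
  de0 <- if (de0 <= 0) 0.5 else min(de0, 2)
  n_slope <- min(5L, length(t))
  sl <- as.numeric(stats::coef(stats::lm(F_obs[1:n_slope] ~ t[1:n_slope]))[2])
  # noise can make the local slope non-positive; fall back to the global rise
  if (!is.finite(sl) || sl <= 0)
    sl <- max((max(F_obs) - F_obs[1]) / diff(range(t)), 1e-6)
  cl0 <- max(sl * p0 / de0, 1e-6)
  default_start <- c(kd = p0, de = de0, cl = cl0)
  if (!is.null(start)) default_start[names(start)] <- unlist(start)
  default_start <- pmin(pmax(default_start, lo), pmin(hi, 1e12))

  w <- if (is.null(weights)) rep(1, length(t)) else weights
  df_fit <- data.frame(t = t, F = F_obs, w = w)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1024, ftol = 1e-15,
                                     ptol = 1e-15, maxfev = 100000)

  try_fit <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(F ~ occupancy_model(t, kd, de, cl, p0 = p0),
                        data = df_fit, start = as.list(st),
                        lower = lo[c("kd", "de", "cl")],
                        upper = hi[c("kd", "de", "cl")],
                        weights = w, control = ctrl),
      error = function(e) NULL)
  }

  fit <- try_fit(default_start)
  converged <- !is.null(fit) && fit$convInfo$isConv
  if (!converged) {
    kd_grid <- p0 * 10^seq(-2, 2, length.out = 5)
    for (kd0 in kd_grid) {
      st <- default_start
      st["kd"] <- kd0
      cand <- try_fit(st)
      if (!is.null(cand) &&
          (is.null(fit) || stats::deviance(cand) < stats::deviance(fit))) {
        fit <- cand
        converged <- cand$convInfo$isConv
        if (converged) break
      }
    }
  }
  if (!is.null(fit)) {
    est <- stats::coef(fit)
    sse0 <- stats::deviance(fit)
  } else {
    # derivative-free fallback on the log scale; never errors
    obj <- function(lp) {
      p <- exp(lp)
      if (p[2] > hi["de"]) return(1e300)
      sum(w * (F_obs - occupancy_model(t, p[1], p[2], p[3], p0 = p0))^2)
    }
    om <- stats::optim(log(default_start), obj, method = "Nelder-Mead",
                       control = list(maxit = 10000, reltol = 1e-14))
    est <- stats::setNames(exp(om$par), c("kd", "de", "cl"))
    sse0 <- om$value
    converged <- FALSE
  }

  # profile refinement over log10(kd): the (de, cl) subproblem is
  # well-conditioned, so Brent on the profile SSE resolves kd along the
  # flat ridge far beyond what the full 3-parameter pass can
  warm <- est[c("de", "cl")]
  inner <- function(kd_fix, return_fit = FALSE) {
    f2 <- tryCatch(
      minpack.lm::nlsLM(F ~ occupancy_model(t, kd_fix, de, cl, p0 = p0),
                        data = df_fit, start = as.list(warm),
                        lower = lo[c("de", "cl")],
                        upper = hi[c("de", "cl")],
                        weights = w, control = ctrl),
      error = function(e) NULL)
    if (is.null(f2)) return(if (return_fit) NULL else 1e300)
    warm <<- stats::coef(f2)
    if (return_fit) f2 else stats::deviance(f2)
  }
  lk0 <- log10(est[["kd"]])
  opt <- stats::optimize(function(lk) inner(10^lk),
                         interval = c(lk0 - 3, lk0 + 3), tol = 1e-9)
  if (opt$objective <= sse0) {
    kd_hat <- 10^opt$minimum
    inner_fit <- inner(kd_hat, return_fit = TRUE)
    if (!is.null(inner_fit)) {
      est <- c(kd = kd_hat, stats::coef(inner_fit)[c("de", "cl")])
      names(est) <- c("kd", "de", "cl")
      converged <- converged || inner_fit$convInfo$isConv
    }
  }

  fv <- occupancy_model(t, est[["kd"]], est[["de"]], est[["cl"]], p0 = p0)
  se <- coin_fit_stderr(t, est, p0, F_obs, fv, w)
  structure(list(coefficients = est,
                 stderr = stats::setNames(as.numeric(se), names(est)),
                 p0 = p0,
                 data = data,
                 observed = F_obs,
                 fitted.values = fv,
                 residuals = F_obs - fv,
                 sse = sum(w * (F_obs - fv)^2),
                 n = length(t),
                 converged = converged,
                 weights = w,
                 call = match.call()),
            class = "coin_fit")
}

#' @export
coef.coin_fit <- function(object, ...) object$coefficients

#' @export
fitted.coin_fit <- function(object, ...) object$fitted.values

#' @export
residuals.coin_fit <- function(object, ...) object$residuals

#' @export
print.coin_fit <- function(x, ...) {
  cat("COIN-CaR-nMS occupancy fit\n")
  cat(sprintf("  Kd = %.4g uM (%.4g mM)   DE = %.4g   C_L = %.4g uM/min\n",
              x$coefficients["kd"], x$coefficients["kd"] / 1000,
              x$coefficients["de"], x$coefficients["cl"]))
  cat(sprintf("  [P]0 = %.4g uM, %d points, SSE = %.4g, converged: %s\n",
              x$p0, x$n, x$sse, x$converged))
  invisible(x)
}

#' @export
summary.coin_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$stderr)
  rownames(tab) <- c("kd (uM)", "de", "cl (uM/min)")
  out <- list(coefficients = tab,
              kd_mM = object$coefficients[["kd"]] / 1000,
              sse = object$sse,
              sigma = sqrt(object$sse / max(object$n - 3, 1)),
              n = object$n, p0 = object$p0, converged = object$converged)
  class(out) <- "summary.coin_fit"
  out
}

#' @export
print.summary.coin_fit <- function(x, ...) {
  cat("COIN-CaR-nMS occupancy fit\n\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nKd = %.4g mM; residual SE = %.4g on %d points; [P]0 = %.4g uM\n",
              x$kd_mM, x$sigma, x$n, x$p0))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' Predict fractions bound from a fitted COIN model
#'
#' @param object a [coin_fit()].
#' @param newdata optional data.frame with a `t` column (minutes), or a
#'   numeric time vector; defaults to the fitted times.
#' @param ... unused.
#' @return predicted fractions bound.
#' @export
predict.coin_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$times
       else if (is.data.frame(newdata)) newdata$t
       else as.numeric(newdata)
  est <- object$coefficients
  occupancy_model(t, est[["kd"]], est[["de"]], est[["cl"]], p0 = object$p0)
}

#' Plot a fitted COIN occupancy curve
#'
#' Observed fractions bound with the fitted curve overlaid (base graphics).
#'
#' @param x a [coin_fit()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.coin_fit <- function(x, ...) {
  t <- x$data$times
  graphics::plot(t, x$observed, xlab = "time (min)",
                 ylab = "fraction bound", pch = 16, ...)
  tt <- seq(min(t), max(t), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = 2, lwd = 2)
  invisible(x)
}

#' Simulate datasets from a fitted COIN model
#'
#' Draws Gaussian noise (sd = residual standard error) around the fitted
#' curve at the observed times, producing new [coin_dataset()]s.
#'
#' @param object a [coin_fit()].
#' @param nsim number of datasets.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param ... unused.
#' @return list of [coin_dataset()] objects.
#' @export
simulate.coin_fit <- function(object, nsim = 1, seed, ...) {
  if (missing(seed)) stop("simulate.coin_fit requires an explicit seed")
  set.seed(seed)
  sigma <- sqrt(object$sse / max(object$n - 3, 1))
  scale <- mean(object$data$ab_protein)
  lapply(seq_len(nsim), function(i) {
    F_sim <- pmax(object$fitted.values + stats::rnorm(object$n, 0, sigma), 0)
    coin_dataset(object$data$times, F_sim * scale,
                 rep(scale, object$n), object$p0)
  })
}

#' Nanodisc ganglioside/phospholipid stoichiometry
#'
#' A nanodisc holds `lipids_per_nd` lipids; the ganglioside mole fraction
#' fixes the per-disc ganglioside count (rounded to the nearest integer) and
#' the phospholipid complement. Totals scale linearly with the nanodisc
#' concentration.
#'
#' @param ganglioside_mol_fraction mole fraction of ganglioside in \[0, 1\].
#' @param nd_concentration nanodisc concentration, micromolar.
#' @param lipids_per_nd lipids per nanodisc (default 200).
#' @return list: `gangliosides_per_nd`, `phospholipids_per_nd`,
#'   `total_ganglioside_uM`, `total_phospholipid_uM`.
#' @export
nd_stoichiometry <- function(ganglioside_mol_fraction, nd_concentration,
                             lipids_per_nd = 200) {
  if (ganglioside_mol_fraction < 0 || ganglioside_mol_fraction > 1)
    stop("ganglioside_mol_fraction must lie in [0, 1]")
  if (nd_concentration < 0) stop("nd_concentration must be non-negative")
  g <- round(ganglioside_mol_fraction * lipids_per_nd)
  p <- lipids_per_nd - g
  list(gangliosides_per_nd = g,
       phospholipids_per_nd = p,
       total_ganglioside_uM = g * nd_concentration,
       total_phospholipid_uM = p * nd_concentration)
}

#' Nanodisc concentration from scaffold-protein absorbance
#'
#' Beer-Lambert on the membrane scaffold protein MSP1E1
#' (`epsilon_280 = 32430 /M/cm`), with two scaffold copies per disc so
#' `[ND] = [MSP1E1] / msp_per_nd`.
#'
#' @param a280 absorbance at 280 nm.
#' @param path_cm optical path length, cm.
#' @param epsilon_280 molar extinction coefficient, per M per cm.
#' @param msp_per_nd scaffold proteins per nanodisc (default 2).
#' @return nanodisc concentration, micromolar.
#' @export
nd_concentration_from_a280 <- function(a280, path_cm = 1,
                                       epsilon_280 = 32430, msp_per_nd = 2) {
  if (a280 < 0) stop("a280 must be non-negative")
  if (path_cm <= 0) stop("path_cm must be positive")
  msp_M <- a280 / (epsilon_280 * path_cm)
  1e6 * msp_M / msp_per_nd
}
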