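# Mean squared displacement and self-diffusion (Einstein relation).

#' Centre-of-mass positions of every molecule of a species
#'
#' @param traj an unwrapped `Trajectory`.
#' @param topo a `Topology`.
#' @param species species name.
#' @return array `n_molecules x 3 x n_frames`, pm.
#' @keywords internal
com_positions <- function(traj, topo, species) {
  mols <- topo$molecules[topo$molecules$species == species, ]
  if (nrow(mols) == 0) stop(sprintf("no molecules of species %s", species))
  idx <- unlist(mapply(seq, mols$first, mols$last, SIMPLIFY = FALSE))
  grp <- rep(seq_len(nrow(mols)), mols$last - mols$first + 1)
  w <- topo$atoms$mass[idx]
  wsum <- rowsum(w, grp)
  nf <- n_frames(traj)
  out <- array(0, c(nrow(mols), 3, nf))
  for (f in seq_len(nf)) {
    fr <- traj$coords[idx, , f, drop = FALSE]
    dim(fr) <- dim(fr)[1:2]
    out[, , f] <- rowsum(fr * w, grp) / matrix(wsum, nrow(mols), 3)
  }
  out
}

#' Mean squared displacement of molecular centres of mass
#'
#' Averages over every molecule of the species and every sliding time
#' origin (spacing one frame). Requires an unwrapped trajectory: wrapped
#' coordinates fold the displacement back into the box and destroy the
#' Einstein-regime slope.
#'
#' @param traj an unwrapped `Trajectory`.
#' @param topo a `Topology`.
#' @param species species to analyse.
#' @param max_lag maximum lag, ps; must be below the trajectory length.
#' @return an `MSDCurve`: `lag` (ps), `msd` (pm^2), `n_samples` per lag,
#'   `timestep`.
#' @export
compute_msd <- function(traj, topo, species, max_lag = NULL) {
  if (traj$wrapped)
    stop("trajectory is wrapped: call unwrap_trajectory() before computing MSD")
  nf <- n_frames(traj)
  dt <- traj$timestep
  if (is.null(max_lag)) max_lag <- (nf - 1) * dt / 2
  lag_f <- floor(max_lag / dt)
  if (lag_f >= nf)
    stop("max_lag must be shorter than the trajectory")
  pos <- com_positions(traj, topo, species)
  res <- msd_kernel(as.numeric(pos), dim(pos), as.integer(lag_f))
  structure(list(lag = (0:lag_f) * dt, msd = res$ssd / res$n,
                 n_samples = res$n, timestep = dt),
            class = "MSDCurve")
}

#' @export
print.MSDCurve <- function(x, ...) {
  cat(sprintf("MSD: %d lags to %g ps; MSD(max) = %.4g pm^2\n",
              length(x$lag), max(x$lag), x$msd[length(x$msd)]))
  invisible(x)
}

#' Self-diffusion coefficient from the MSD slope
#'
#' Unweighted least squares of `MSD(tau)` on a lag window (default
#' 10-50% of the maximum lag, skipping the early ballistic/cage regime
#' and the noisy tail); `D = slope / 6`, reported in m^2/s
#' (1 pm^2/ps = 1e-12 m^2/s). A window fit with `R^2 < 0.98` flags a
#' non-diffusive regime but still returns the estimate.
#'
#' @param msd an `MSDCurve`.
#' @param window fractions (lo, hi) of the maximum lag to fit.
#' @return a `DiffusionEstimate`: `D` (m^2/s), `D_1e12` (units of
#'   1e-12 m^2/s, the usual reporting scale), `slope` and `intercept`
#'   (pm^2/ps, pm^2), `window` (ps), `r_squared`, `warning` flag.
#' @export
fit_diffusion <- function(msd, window = c(0.1, 0.5)) {
  lmax <- max(msd$lag)
  sel <- which(msd$lag >= window[1] * lmax & msd$lag <= window[2] * lmax)
  if (length(sel) < 10)
    stop("fit window contains fewer than 10 lag points")
  fit <- lm(msd$msd[sel] ~ msd$lag[sel])
  slope <- coef(fit)[[2]]
  r2 <- if (sd(msd$msd[sel]) == 0 && slope == 0) 1 else
    suppressWarnings(summary(fit)$r.squared)   # exact lines trip summary.lm
  D <- max(slope, 0) / 6            # pm^2/ps
  warn <- is.na(r2) || r2 < 0.98
  if (warn)
    warning("non-diffusive regime: MSD window fit has R^2 < 0.98")
  structure(list(D = D * 1e-12, D_1e12 = D, slope = slope,
                 intercept = coef(fit)[[1]],
                 window = range(msd$lag[sel]), r_squared = r2,
                 warning = warn),
            class = "DiffusionEstimate")
}

#' @export
print.DiffusionEstimate <- function(x, ...) {
  cat(sprintf("D = %.4g x 10^-12 m^2/s (window %g-%g ps, R^2 = %.4f)%s\n",
              x$D_1e12, x$window[1], x$window[2], x$r_squared,
              if (x$warning) " [non-diffusive]" else ""))
  invisible(x)
}

#' Export an MSD curve and diffusion summary
#' @param msd an `MSDCurve`.
#' @param est a `DiffusionEstimate` (optional, for the JSON summary).
#' @param csv_path CSV output (lag_ps, msd_pm2, n_samples).
#' @param json_path JSON summary output.
#' @export
write_msd <- function(msd, csv_path, est = NULL, json_path = NULL) {
  write.csv(data.frame(lag_ps = msd$lag, msd_pm2 = msd$msd,
                       n_samples = msd$n_samples),
            csv_path, row.names = FALSE)
  if (!is.null(json_path) && !is.null(est))
    jsonlite::write_json(list(D_m2_per_s = est$D, D_1e12 = est$D_1e12,
                              window_ps = est$window,
                              r_squared = est$r_squared,
                              non_diffusive_warning = est$warning),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
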