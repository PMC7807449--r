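# Lateral lipid diffusion from restarted MSD curves and Arrhenius
# activation energies.

R_KCAL <- 1.9872e-3 # gas constant, kcal/(mol K)

# unwrapped per-lipid xy centre-of-mass track: n_lipids x n_frames matrices
lipid_com_tracks <- function(traj, species = NULL) {
  keep <- !is.na(traj$particles$lipid_id)
  if (!is.null(species)) keep <- keep & traj$particles$species %in% species
  if (!any(keep)) stop("species absent from trajectory", call. = FALSE)
  idx <- which(keep)
  lids <- traj$particles$lipid_id[idx]
  ulid <- sort(unique(lids))
  li <- match(lids, ulid)
  nf <- n_frames(traj)
  np <- length(idx)
  # unwrap each particle from frame-to-frame minimum-image displacements
  cx <- matrix(0, np, nf)
  cy <- matrix(0, np, nf)
  prev <- traj$xyz[[1]][idx, 1:2, drop = FALSE]
  cx[, 1] <- prev[, 1]
  cy[, 1] <- prev[, 2]
  for (f in seq_len(nf)[-1]) {
    cur <- traj$xyz[[f]][idx, 1:2, drop = FALSE]
    dx <- min_image(cur[, 1] - prev[, 1], traj$box[f, 1])
    dy <- min_image(cur[, 2] - prev[, 2], traj$box[f, 2])
    cx[, f] <- cx[, f - 1] + dx
    cy[, f] <- cy[, f - 1] + dy
    prev <- cur
  }
  # per-lipid COM (equal-weight particles)
  nl <- length(ulid)
  agg <- function(m) {
    out <- matrix(0, nl, nf)
    cnt <- tabulate(li, nl)
    for (f in seq_len(nf)) out[, f] <- tapply(m[, f], li, mean)
    out
  }
  leaflet <- traj$particles$leaflet[idx][match(ulid, lids)]
  list(x = agg(cx), y = agg(cy), lipid_id = ulid, leaflet = leaflet)
}

#' Restarted lateral mean squared displacement
#'
#' Per-lipid xy centre-of-mass displacements, unwrapped across periodic
#' boundaries, with the per-leaflet centre-of-mass motion removed, averaged
#' over lipids and over time origins placed every `restart_interval`.
#'
#' @param traj A [ple_trajectory()].
#' @param species Optional species code(s) to restrict to.
#' @param restart_interval Spacing of time origins (ns; default 1).
#' @param max_lag Largest lag to evaluate (ns; default half the trajectory).
#' @return A tibble (class `msd_curve`) with columns `lag` (ns), `msd`
#'   (nm^2) and `n_origins`.
#' @export
msd_lateral <- function(traj, species = NULL, restart_interval = 1,
                        max_lag = NULL) {
  if (n_frames(traj) < 2) stop("need at least 2 frames", call. = FALSE)
  trk <- lipid_com_tracks(traj, species)
  nf <- n_frames(traj)
  dt <- traj$times[2] - traj$times[1]
  # remove leaflet COM drift
  for (lf in unique(trk$leaflet)) {
    rows <- trk$leaflet == lf
    trk$x[rows, ] <- sweep(trk$x[rows, , drop = FALSE], 2, colMeans(trk$x[rows, , drop = FALSE]))
    trk$y[rows, ] <- sweep(trk$y[rows, , drop = FALSE], 2, colMeans(trk$y[rows, , drop = FALSE]))
  }
  max_lag <- max_lag %||% (traj$times[nf] - traj$times[1]) / 2
  lags <- seq_len(max(1, min(nf - 1, floor(max_lag / dt))))
  origin_step <- max(1L, round(restart_interval / dt))
  msd <- numeric(length(lags))
  n_orig <- integer(length(lags))
  for (k in seq_along(lags)) {
    L <- lags[k]
    origins <- seq(1L, nf - L, by = origin_step)
    dx <- trk$x[, origins + L, drop = FALSE] - trk$x[, origins, drop = FALSE]
    dy <- trk$y[, origins + L, drop = FALSE] - trk$y[, origins, drop = FALSE]
    msd[k] <- mean(dx^2 + dy^2)
    n_orig[k] <- length(origins)
  }
  out <- tibble::tibble(
    lag = c(0, lags * dt), msd = c(0, msd), n_origins = c(nf, n_orig)
  )
  class(out) <- c("msd_curve", class(out))
  out
}

#' Lateral diffusion coefficient from an MSD curve
#'
#' Least-squares slope of the MSD over the fit window, divided by 4 (the
#' two-dimensional Einstein relation) and converted to cm^2/s.
#'
#' @param msd An [msd_lateral()] result.
#' @param fit_window Lag window (ns) for the linear fit; the atomistic
#'   convention is 10-30 ns (coarse-grained analyses use 100-300 ns).
#' @return Diffusion coefficient (cm^2/s).
#' @export
diffusion_coefficient <- function(msd, fit_window = c(10, 30)) {
  if (fit_window[2] <= fit_window[1]) stop("non-positive lag span", call. = FALSE)
  sel <- msd$lag >= fit_window[1] & msd$lag <= fit_window[2]
  if (sum(sel) < 2) stop("fit window outside available lags", call. = FALSE)
  slope <- unname(stats::coef(stats::lm(msd ~ lag, data = msd[sel, ]))[2])
  slope / 4 * 1e-5 # nm^2/ns -> cm^2/s
}

#' Per-species diffusion coefficients of a trajectory
#'
#' @param traj A [ple_trajectory()].
#' @param restart_interval,fit_window Passed to [msd_lateral()] and
#'   [diffusion_coefficient()].
#' @return A tibble with columns `species`, `D` (cm^2/s), `n_lipids`.
#' @export
diffusion_by_species <- function(traj, restart_interval = 1,
                                 fit_window = c(10, 30)) {
  sp <- traj$particles |>
    dplyr::filter(!is.na(.data$lipid_id)) |>
    dplyr::distinct(.data$lipid_id, .data$species)
  sp |>
    dplyr::count(.data$species, name = "n_lipids") |>
    dplyr::rowwise() |>
    dplyr::mutate(D = diffusion_coefficient(
      msd_lateral(traj, species = .data$species, restart_interval = restart_interval),
      fit_window
    )) |>
    dplyr::ungroup() |>
    dplyr::select("species", "D", "n_lipids")
}

#' Arrhenius fit of rates against temperature
#'
#' Unweighted least squares of `ln(k)` on `1/T` following
#' `ln(k) = ln(A) - (E_a/R) (1/T)`; the activation energy is minus the
#' slope times the gas constant, reported in kcal/mol.
#'
#' @param rates A tibble with columns `temperature` (K) and `value`
#'   (positive rates, any consistent unit), e.g. from
#'   [temperature_series()].
#' @return An object of class `arrhenius_fit` with elements `Ea`
#'   (kcal/mol), `se_Ea`, `lnA`, `se_lnA`, `r_squared`, `fit`, `data`.
#' @export
arrhenius <- function(rates) {
  stopifnot(all(c("temperature", "value") %in% names(rates)))
  if (nrow(rates) < 2) stop("need at least 2 temperatures", call. = FALSE)
  if (any(rates$value <= 0)) stop("rates must be positive", call. = FALSE)
  d <- tibble::tibble(inv_T = 1 / rates$temperature, ln_k = log(rates$value))
  fit <- stats::lm(ln_k ~ inv_T, data = d)
  cf <- suppressWarnings(summary(fit))$coefficients
  slope_se <- if (nrow(rates) > 2) cf[2, 2] else NA_real_
  structure(
    list(
      Ea = -unname(stats::coef(fit)[2]) * R_KCAL,
      se_Ea = slope_se * R_KCAL,
      lnA = unname(stats::coef(fit)[1]),
      se_lnA = if (nrow(rates) > 2) cf[1, 2] else NA_real_,
      r_squared = suppressWarnings(summary(fit))$r.squared,
      fit = fit,
      data = rates
    ),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "<arrhenius_fit> E_a = %.3f kcal/mol (s.e. %.3f), ln A = %.3f, n = %d\n",
    x$Ea, x$se_Ea, x$lnA, nrow(x$data)
  ))
  if (!is.null(x$excluded) && nrow(x$excluded) > 0) {
    cat(sprintf(
      "  %d point(s) excluded below the rate threshold\n", nrow(x$excluded)
    ))
  }
  invisible(x)
}
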