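# Transmembrane water permeation: event counting with a three-state
# hysteresis machine and Arrhenius temperature fits.

#' Count full transmembrane water crossings
#'
#' Each role-tagged water is tracked on its unwrapped z coordinate through
#' three states: above the upper boundary plane, inside the slab, below the
#' lower plane. An event is recorded only when a water moves from fully
#' above to fully below (or the reverse) having passed through the inside
#' state; excursions that return to the starting side count nothing.
#' Boundary planes default to the mean phosphate planes of the first
#' analysed frame, which prevents plane breathing from creating phantom
#' crossings; `per_frame_planes = TRUE` re-evaluates them each frame.
#'
#' @param traj A [ple_trajectory()] with `role == "water"` particles.
#' @param boundaries Optional length-2 numeric `c(lower, upper)` z planes
#'   (nm, in box coordinates).
#' @param buffer Hysteresis margin (nm) shrinking the inside state
#'   (default 0).
#' @param per_frame_planes Recompute the phosphate planes each frame.
#' @return A tibble of events: `water_id`, `direction` (`"+z"` or
#'   `"-z"`), `entry_time`, `exit_time` (ns), `entry_frame`, `exit_frame`.
#' @export
count_permeations <- function(traj, boundaries = NULL, buffer = 0,
                              per_frame_planes = FALSE) {
  widx <- which(traj$particles$role == "water")
  if (length(widx) == 0) stop("no role-tagged waters", call. = FALSE)
  nf <- n_frames(traj)
  box_z <- traj$box[1, 3]
  # re-centre the bilayer at box_z/2 so a membrane wrapped across the
  # periodic boundary is made whole before the state machine runs. The
  # midplane estimate is the circular mean of all lipid particle z of
  # frame 1: the tails fill the slab interior, which makes the estimate
  # well defined even when the membrane straddles the boundary.
  offset <- 0
  if (is.null(boundaries)) {
    lidx <- !is.na(traj$particles$lipid_id)
    th <- traj$xyz[[1]][lidx, 3] / box_z * 2 * pi
    mid <- (atan2(mean(sin(th)), mean(cos(th))) / (2 * pi) * box_z) %% box_z
    offset <- box_z / 2 - mid
  }
  recenter <- function(v, bz) (v + offset) %% bz
  planes_at <- function(f) {
    fr <- traj$xyz[[f]]
    hu <- traj$particles$role == "headgroup_ref" & traj$particles$leaflet == "upper"
    hl <- traj$particles$role == "headgroup_ref" & traj$particles$leaflet == "lower"
    bz <- traj$box[f, 3]
    c(mean(recenter(fr[hl, 3], bz)), mean(recenter(fr[hu, 3], bz)))
  }
  if (is.null(boundaries)) boundaries <- planes_at(1)
  boundaries <- sort(as.numeric(boundaries))
  if (boundaries[1] >= boundaries[2]) stop("boundaries inverted", call. = FALSE)

  # unwrap z per water (in the re-centred coordinates)
  z <- matrix(0, length(widx), nf)
  prev <- recenter(traj$xyz[[1]][widx, 3], box_z)
  z[, 1] <- prev
  if (nf > 1) {
    for (f in 2:nf) {
      cur <- recenter(traj$xyz[[f]][widx, 3], traj$box[f, 3])
      z[, f] <- z[, f - 1] + min_image(cur - prev, traj$box[f, 3])
      prev <- cur
    }
  }
  # re-reference unwrapped tracks so frame-1 positions are in-box
  events <- list()
  for (w in seq_along(widx)) {
    zl <- boundaries[1]
    zu <- boundaries[2]
    state <- integer(nf) # 1 above, -1 below, 0 inside
    for (f in seq_len(nf)) {
      if (per_frame_planes) {
        pl <- planes_at(f)
        zl <- pl[1]
        zu <- pl[2]
      }
      state[f] <- if (z[w, f] > zu + buffer) 1L else if (z[w, f] < zl - buffer) -1L else 0L
    }
    side <- state[state != 0]
    side_f <- which(state != 0)
    if (length(side) < 2) next
    flips <- which(side[-1] != side[-length(side)])
    for (k in flips) {
      f_entry <- side_f[k] # last frame on the old side
      f_exit <- side_f[k + 1] # first frame on the new side
      events[[length(events) + 1]] <- tibble::tibble(
        water_id = traj$particles$id[widx[w]],
        direction = if (side[k + 1] < side[k]) "-z" else "+z",
        entry_time = traj$times[f_entry],
        exit_time = traj$times[f_exit],
        entry_frame = f_entry,
        exit_frame = f_exit
      )
    }
  }
  if (length(events) == 0) {
    return(tibble::tibble(
      water_id = integer(0), direction = character(0),
      entry_time = numeric(0), exit_time = numeric(0),
      entry_frame = integer(0), exit_frame = integer(0)
    ))
  }
  dplyr::bind_rows(events)
}

#' Permeation rates from an event table
#'
#' @param events Event tibble from [count_permeations()] (or any data
#'   frame with one row per event).
#' @param total_time Analysed time (ns).
#' @param area Projected membrane area (nm^2).
#' @return A one-row tibble: `n_events`, `total_time`, `area`,
#'   `rate` (events/ns) and `rate_per_area` (events/ns/nm^2).
#' @export
permeation_rate <- function(events, total_time, area) {
  if (total_time <= 0) stop("total_time must be positive", call. = FALSE)
  n <- if (is.data.frame(events)) nrow(events) else as.integer(events)
  tibble::tibble(
    n_events = n, total_time = total_time, area = area,
    rate = n / total_time,
    rate_per_area = n / total_time / area
  )
}

#' Arrhenius fit of permeation rates with a low-statistics exclusion
#'
#' Temperatures whose rate falls below the exclusion threshold (default 1
#' event per 100 ns, i.e. 0.01 events/ns) are dropped before the fit, the
#' convention for discarding statistically unreliable low-temperature
#' points; the excluded rows are carried in the result.
#'
#' @param rates Tibble with columns `temperature` (K) and `value`
#'   (events/ns).
#' @param exclusion_threshold Minimum rate retained (events/ns).
#' @return An `arrhenius_fit` (see [arrhenius()]) with an extra element
#'   `excluded`.
#' @export
permeation_arrhenius <- function(rates, exclusion_threshold = 0.01) {
  keep <- rates$value >= exclusion_threshold
  if (sum(keep) < 2) {
    stop("fewer than 2 temperatures retained after exclusion", call. = FALSE)
  }
  fit <- arrhenius(rates[keep, ])
  fit$excluded <- rates[!keep, ]
  fit
}
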