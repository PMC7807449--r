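#' Bilayer trajectory container
#'
#' Bundles per-particle metadata (constant across frames) with per-frame
#' coordinates, times and box vectors. Coordinates are stored wrapped into
#' `[0, box)`; analyses that need unwrapped motion (MSD, permeation) unwrap
#' internally from frame-to-frame minimum-image displacements.
#'
#' @param particles Tibble with one row per particle: columns `id`,
#'   `lipid_id`, `species`, `headgroup`, `leaflet` (`"upper"`, `"lower"` or
#'   `"none"`), `role` (one of `headgroup_ref`, `glycerol_ref`, `carbonyl`,
#'   `first_methylene`, `tail_carbon`, `terminal_methyl`, `water`, `ion`,
#'   `protein_atom`), `tail` (tail number within the lipid), `carbon`
#'   (carbon index along the tail), `residue`, `chain`.
#' @param xyz List of `n x 3` coordinate matrices (nm), one per frame.
#' @param times Numeric vector of frame times (ns), strictly increasing.
#' @param box Numeric matrix `n_frames x 3` of orthorhombic box lengths (nm).
#' @param resolution `"AA"` or `"CG"`.
#' @param temperature Simulation temperature (K).
#' @return An object of class `ple_trajectory`.
#' @export
ple_trajectory <- function(particles, xyz, times, box,
                           resolution = "AA", temperature = NA_real_) {
  particles <- tibble::as_tibble(particles)
  needed <- c(
    "id", "lipid_id", "species", "headgroup", "leaflet", "role",
    "tail", "carbon", "residue", "chain"
  )
  miss <- setdiff(needed, names(particles))
  for (m in miss) {
    particles[[m]] <- if (m %in% c("lipid_id", "tail", "carbon", "residue")) {
      NA_integer_
    } else {
      NA_character_
    }
  }
  stopifnot(is.list(xyz), length(xyz) == length(times))
  if (is.null(dim(box))) box <- matrix(box, nrow = length(times), ncol = 3, byrow = TRUE)
  stopifnot(nrow(box) == length(times), ncol(box) == 3)
  if (any(box <= 0)) stop("box lengths must be positive", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  n <- nrow(particles)
  xyz <- lapply(seq_along(xyz), function(f) {
    m <- xyz[[f]]
    stopifnot(nrow(m) == n, ncol(m) == 3)
    dimnames(m) <- NULL
    wrap_coords(m, box[f, ])
  })
  structure(
    list(
      particles = particles, xyz = xyz, times = as.numeric(times),
      box = box, resolution = resolution, temperature = temperature
    ),
    class = "ple_trajectory"
  )
}

wrap_coords <- function(m, box) {
  sweep(m, 2, box, function(x, l) x - floor(x / l) * l)
}

#' @export
print.ple_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ple_trajectory> %d frames x %d particles, %s resolution, T = %s K\n",
    n_frames(x), nrow(x$particles), x$resolution, format(x$temperature)
  ))
  cat(sprintf(
    "  time %g..%g ns, box %s nm\n",
    x$times[1], x$times[n_frames(x)],
    paste(signif(x$box[1, ], 4), collapse = " x ")
  ))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [ple_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract one frame as a tidy particle table
#'
#' @param traj A [ple_trajectory()].
#' @param i Frame index (1-based).
#' @return A tibble of particle records with coordinate columns `x`, `y`,
#'   `z` (class `bilayer_frame`); the box lengths and time are attached as
#'   attributes `box` and `time`.
#' @export
traj_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  fr <- traj$particles
  fr$x <- traj$xyz[[i]][, 1]
  fr$y <- traj$xyz[[i]][, 2]
  fr$z <- traj$xyz[[i]][, 3]
  attr(fr, "box") <- traj$box[i, ]
  attr(fr, "time") <- traj$times[i]
  attr(fr, "resolution") <- traj$resolution
  class(fr) <- c("bilayer_frame", class(fr))
  fr
}

#' Build a single-frame object from a particle table
#'
#' @param particles Tibble with particle metadata plus `x`, `y`, `z` (nm).
#' @param box Orthorhombic box lengths, length-3 numeric (nm).
#' @param time Frame time (ns).
#' @param resolution `"AA"` or `"CG"`.
#' @return A `bilayer_frame` tibble.
#' @export
bilayer_frame <- function(particles, box, time = 0, resolution = "AA") {
  stopifnot(all(c("x", "y", "z") %in% names(particles)), length(box) == 3)
  if (any(box <= 0)) stop("box lengths must be positive", call. = FALSE)
  fr <- tibble::as_tibble(particles)
  for (m in c("lipid_id", "tail", "carbon", "residue")) {
    if (is.null(fr[[m]])) fr[[m]] <- NA_integer_
  }
  for (m in c("id", "species", "headgroup", "leaflet", "role", "chain")) {
    if (is.null(fr[[m]])) fr[[m]] <- NA
  }
  xyz <- wrap_coords(as.matrix(fr[, c("x", "y", "z")]), box)
  fr$x <- xyz[, 1]
  fr$y <- xyz[, 2]
  fr$z <- xyz[, 3]
  attr(fr, "box") <- as.numeric(box)
  attr(fr, "time") <- time
  attr(fr, "resolution") <- resolution
  class(fr) <- c("bilayer_frame", class(fr))
  fr
}

frame_box <- function(frame) attr(frame, "box")

#' Coordinates of a frame or trajectory subset as a matrix
#' @noRd
frame_xyz <- function(frame) as.matrix(frame[, c("x", "y", "z")])
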