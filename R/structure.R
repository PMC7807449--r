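# Structural metrics: areas, volumes, thicknesses, interdigitation,
# compressibility, and temperature-trend fits.

#' Box-derived area per lipid
#'
#' The projected membrane area divided by the number of lipids in one
#' leaflet: `box_x * box_y / n_per_leaflet`.
#'
#' @param frame A [bilayer_frame()].
#' @param n_per_leaflet Number of lipids per leaflet; inferred from the
#'   frame's upper leaflet when `NULL`.
#' @return Area per lipid (nm^2).
#' @export
apl_box <- function(frame, n_per_leaflet = NULL) {
  box <- frame_box(frame)
  if (is.null(n_per_leaflet)) {
    n_per_leaflet <- dplyr::n_distinct(frame$lipid_id[frame$leaflet == "upper" &
      !is.na(frame$lipid_id)])
  }
  if (!is.numeric(n_per_leaflet) || n_per_leaflet <= 0) {
    stop("n_per_leaflet must be positive", call. = FALSE)
  }
  box[1] * box[2] / n_per_leaflet
}

#' Per-frame area-per-lipid series of a trajectory
#'
#' @param traj A [ple_trajectory()].
#' @param n_per_leaflet Lipids per leaflet; inferred when `NULL`.
#' @return A tibble with columns `frame`, `time`, `apl` (nm^2).
#' @export
apl_series <- function(traj, n_per_leaflet = NULL) {
  if (is.null(n_per_leaflet)) {
    n_per_leaflet <- dplyr::n_distinct(
      traj$particles$lipid_id[traj$particles$leaflet == "upper" &
        !is.na(traj$particles$lipid_id)]
    )
  }
  tibble::tibble(
    frame = seq_len(n_frames(traj)),
    time = traj$times,
    apl = traj$box[, 1] * traj$box[, 2] / n_per_leaflet
  )
}

#' Area per lipid by periodic Voronoi tessellation
#'
#' Tessellates each leaflet with a periodic 2-D Voronoi diagram over the
#' headgroup reference particles (the phosphate of PE/PG lipids; both
#' phosphates of a cardiolipin, whose two cell areas are summed so the CL
#' counts as one lipid). Within a leaflet the cell areas sum exactly to the
#' box area.
#'
#' @param frame A [bilayer_frame()].
#' @return A tibble with one row per lipid: `lipid_id`, `species`,
#'   `headgroup`, `leaflet`, `area` (nm^2). The box area is attached as
#'   attribute `box_area`.
#' @export
apl_voronoi <- function(frame) {
  box <- frame_box(frame)
  refs <- dplyr::filter(
    frame, .data$role == "headgroup_ref", .data$leaflet %in% c("upper", "lower")
  )
  if (nrow(refs) == 0) stop("no headgroup reference particles", call. = FALSE)
  out <- refs |>
    dplyr::group_by(.data$leaflet) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) stop("each leaflet needs >= 3 generator points", call. = FALSE)
      d$cell_area <- voronoi_areas_periodic(cbind(d$x, d$y), box[1:2])
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$lipid_id, .data$species, .data$headgroup, .data$leaflet) |>
    dplyr::summarise(area = sum(.data$cell_area), .groups = "drop")
  attr(out, "box_area") <- box[1] * box[2]
  out
}

#' Ratio of curved to projected area per lipid
#'
#' Interpolates the phosphate surface of each leaflet onto a regular grid
#' (nearest-reference z under periodic xy distance), triangulates every
#' grid cell into two triangles, and divides the summed triangle area by
#' the projected box area. A perfectly flat leaflet gives 1; corrugation
#' can only increase the ratio.
#'
#' @param frame A [bilayer_frame()].
#' @param grid Length-2 integer, grid resolution (nx, ny); at least 2 x 2.
#' @return Dimensionless ratio (mean of the two leaflets), `>= 1` up to
#'   interpolation error.
#' @export
curved_apl_ratio <- function(frame, grid = c(15, 15)) {
  if (length(grid) == 1) grid <- c(grid, grid)
  if (any(grid < 2)) stop("grid must be at least 2 x 2", call. = FALSE)
  box <- frame_box(frame)
  refs <- dplyr::filter(frame, .data$role == "headgroup_ref")
  if (nrow(refs) == 0) stop("no headgroup reference particles", call. = FALSE)
  nx <- grid[1]
  ny <- grid[2]
  gx <- (seq_len(nx) - 0.5) * box[1] / nx
  gy <- (seq_len(ny) - 0.5) * box[2] / ny
  gpts <- as.matrix(expand.grid(x = gx, y = gy))
  leaf_ratio <- function(d) {
    dm <- pdist_min_image(gpts, cbind(d$x, d$y), box[1:2])
    zg <- matrix(d$z[apply(dm, 1, which.min)], nx, ny)
    # triangulated surface area over one periodic tile
    dx <- box[1] / nx
    dy <- box[2] / ny
    ip <- c(2:nx, 1)
    jp <- c(2:ny, 1)
    z00 <- zg
    z10 <- zg[ip, , drop = FALSE]
    z01 <- zg[, jp, drop = FALSE]
    z11 <- zg[ip, jp, drop = FALSE]
    tri_area <- function(za, zb, zc, ea, eb) {
      # vertices (0,0,za), ea=(dx,0,zb-za) style edge vectors
      u <- cbind(ea[1], ea[2], zb - za)
      v <- cbind(eb[1], eb[2], zc - za)
      0.5 * sqrt((u[, 2] * v[, 3] - u[, 3] * v[, 2])^2 +
        (u[, 3] * v[, 1] - u[, 1] * v[, 3])^2 +
        (u[, 1] * v[, 2] - u[, 2] * v[, 1])^2)
    }
    a1 <- tri_area(as.vector(z00), as.vector(z10), as.vector(z01), c(dx, 0), c(0, dy))
    a2 <- tri_area(as.vector(z11), as.vector(z01), as.vector(z10), c(-dx, 0), c(0, -dy))
    sum(a1 + a2) / (box[1] * box[2])
  }
  ratios <- refs |>
    dplyr::filter(.data$leaflet %in% c("upper", "lower")) |>
    dplyr::group_by(.data$leaflet) |>
    dplyr::group_map(~ leaf_ratio(.x))
  mean(unlist(ratios))
}

#' Volume per lipid
#'
#' Subtracts the water and ion volumes from the box volume and divides by
#' the lipid count: `(V_box - N_water v_water - sum_i N_ion_i v_ion_i) /
#' N_lipids`.
#'
#' @param frame A [bilayer_frame()].
#' @param v_water Molecular volume of one water (nm^3).
#' @param v_ion_map Named numeric of per-ion-species volumes (nm^3);
#'   matched against the `species` of `role == "ion"` particles.
#' @return Volume per lipid (nm^3).
#' @export
volume_per_lipid <- function(frame, v_water, v_ion_map = NULL) {
  box <- frame_box(frame)
  v_box <- prod(box)
  n_water <- sum(frame$role == "water", na.rm = TRUE)
  n_lip <- dplyr::n_distinct(frame$lipid_id[!is.na(frame$lipid_id)])
  if (n_lip == 0) stop("frame contains no lipids", call. = FALSE)
  v_ions <- 0
  ions <- frame[frame$role %in% "ion", ]
  if (nrow(ions) > 0) {
    if (is.null(v_ion_map)) stop("ion volumes required", call. = FALSE)
    cnt <- table(ions$species)
    miss <- setdiff(names(cnt), names(v_ion_map))
    if (length(miss)) stop("missing ion volume for: ", paste(miss, collapse = ", "), call. = FALSE)
    v_ions <- sum(cnt * v_ion_map[names(cnt)])
  }
  rem <- v_box - n_water * v_water - v_ions
  if (rem < 0) stop("negative lipid volume: inconsistent inputs", call. = FALSE)
  rem / n_lip
}

#' Gridded bilayer thickness map
#'
#' Local thickness on an `nx x ny` grid: per cell, the z of the nearest
#' upper-leaflet reference minus the z of the nearest lower-leaflet
#' reference (periodic xy distance, nearest-reference assignment in the
#' GridMAT style). The `"phosphate"` boundary uses headgroup reference
#' particles; the `"hydrophobic"` boundary uses, per tail, the midpoint of
#' the carbonyl and the first methylene (atomistic) or of the glycerol
#' reference and the first tail bead (coarse-grained).
#'
#' @param frame A [bilayer_frame()].
#' @param nx,ny Grid resolution (default 15 x 15).
#' @param boundary `"phosphate"` or `"hydrophobic"`.
#' @return A tibble (class `thickness_map`) with columns `ix`, `iy`, `x`,
#'   `y`, `thickness` (nm); `mean(x$thickness)` is the map mean.
#' @export
thickness_grid <- function(frame, nx = 15, ny = 15,
                           boundary = c("phosphate", "hydrophobic")) {
  boundary <- match.arg(boundary)
  box <- frame_box(frame)
  if (boundary == "phosphate") {
    refs <- dplyr::filter(frame, .data$role == "headgroup_ref")
  } else {
    cg <- identical(attr(frame, "resolution"), "CG")
    a <- dplyr::filter(frame, .data$role == if (cg) "glycerol_ref" else "carbonyl")
    b <- if (cg) {
      dplyr::filter(frame, .data$role == "tail_carbon", .data$carbon == 1)
    } else {
      dplyr::filter(frame, .data$role == "first_methylene")
    }
    if (cg) {
      # one glycerol per lipid, pair with each tail's first bead
      a <- dplyr::select(a, "lipid_id", "leaflet", gx = "x", gy = "y", gz = "z")
      refs <- b |>
        dplyr::inner_join(a, by = c("lipid_id", "leaflet")) |>
        dplyr::mutate(
          x = (.data$x + .data$gx) / 2, y = (.data$y + .data$gy) / 2,
          z = (.data$z + .data$gz) / 2
        )
    } else {
      a <- dplyr::select(a, "lipid_id", "tail", "leaflet", cx = "x", cy = "y", cz = "z")
      refs <- b |>
        dplyr::inner_join(a, by = c("lipid_id", "tail", "leaflet")) |>
        dplyr::mutate(
          x = (.data$x + .data$cx) / 2, y = (.data$y + .data$cy) / 2,
          z = (.data$z + .data$cz) / 2
        )
    }
  }
  up <- refs[refs$leaflet == "upper", ]
  lo <- refs[refs$leaflet == "lower", ]
  if (nrow(up) == 0 || nrow(lo) == 0) stop("empty leaflet", call. = FALSE)
  gx <- (seq_len(nx) - 0.5) * box[1] / nx
  gy <- (seq_len(ny) - 0.5) * box[2] / ny
  gpts <- as.matrix(expand.grid(x = gx, y = gy))
  zu <- up$z[apply(pdist_min_image(gpts, cbind(up$x, up$y), box[1:2]), 1, which.min)]
  zl <- lo$z[apply(pdist_min_image(gpts, cbind(lo$x, lo$y), box[1:2]), 1, which.min)]
  out <- tibble::tibble(
    ix = rep(seq_len(nx), times = ny),
    iy = rep(seq_len(ny), each = nx),
    x = gpts[, 1], y = gpts[, 2],
    thickness = zu - zl
  )
  attr(out, "boundary") <- boundary
  attr(out, "grid") <- c(nx, ny)
  class(out) <- c("thickness_map", class(out))
  out
}

#' Interleaflet tail interdigitation
#'
#' Counts cross-leaflet pairs of lipid tail carbons (terminal methyls
#' excluded) within a minimum-image cutoff and normalises by the total
#' number of tails of the frame.
#'
#' @param frame A [bilayer_frame()].
#' @param cutoff Contact cutoff (nm); the packaged defaults mirror the
#'   cluster cutoffs: 0.35 nm atomistic, 0.65 nm coarse-grained.
#' @return Contacts per tail (dimensionless).
#' @export
interdigitation <- function(frame, cutoff = if (identical(attr(frame, "resolution"), "CG")) 0.65 else 0.35) {
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  box <- frame_box(frame)
  tailat <- dplyr::filter(
    frame,
    .data$role %in% c("carbonyl", "first_methylene", "tail_carbon"),
    .data$leaflet %in% c("upper", "lower")
  )
  if (nrow(tailat) == 0) stop("no tail particles", call. = FALSE)
  up <- tailat[tailat$leaflet == "upper", ]
  lo <- tailat[tailat$leaflet == "lower", ]
  n_tails <- frame |>
    dplyr::filter(!is.na(.data$tail)) |>
    dplyr::distinct(.data$lipid_id, .data$tail) |>
    nrow()
  if (nrow(up) == 0 || nrow(lo) == 0) {
    return(0)
  }
  d <- pdist_min_image(
    cbind(up$x, up$y, up$z), cbind(lo$x, lo$y, lo$z), box
  )
  sum(d <= cutoff) / n_tails
}

#' Area compressibility from a closed-form fluctuation expression
#'
#' Literal evaluation of `kappa_T = n_L * sA_L^2 / (2 k_B T <A_L>)` with
#' the area quantities in nm^2, converted to m/N.
#'
#' @param mean_apl Mean area per lipid (nm^2).
#' @param se_apl Standard error of the (block-averaged) area per lipid
#'   (nm^2).
#' @param n_lipids Number of lipids per leaflet.
#' @param temperature Temperature (K).
#' @return Isothermal area compressibility (m/N).
#' @export
compressibility_from_stats <- function(mean_apl, se_apl, n_lipids, temperature) {
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  kB <- 1.380649e-23 # J/K
  n_lipids * se_apl^2 * 1e-18 / (2 * kB * temperature * mean_apl)
}

#' Fluctuation-based membrane area compressibility
#'
#' Computes `kappa_T = n_L (sA_L)^2 / (2 k_B T <A_L>)` from a per-frame
#' area-per-lipid series, with `sA_L` the standard error of the
#' block-averaged series.
#'
#' @param apl Numeric per-frame area-per-lipid series (nm^2), or the
#'   tibble from [apl_series()].
#' @param temperature Temperature (K).
#' @param n_lipids Lipids per leaflet (the per-leaflet convention, since
#'   the area per lipid is a per-leaflet quantity).
#' @param block_frames Block length in frames for the block averages;
#'   `NULL` treats each frame as its own block.
#' @return Isothermal area compressibility (m/N).
#' @export
area_compressibility <- function(apl, temperature, n_lipids, block_frames = NULL) {
  if (is.data.frame(apl)) apl <- apl$apl
  if (length(apl) < 2) stop("need at least 2 area values", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  blocks <- if (is.null(block_frames)) {
    apl
  } else {
    grp <- (seq_along(apl) - 1) %/% block_frames
    as.numeric(tapply(apl, grp, mean))
  }
  if (length(blocks) < 2) stop("need at least 2 blocks", call. = FALSE)
  se <- stats::sd(blocks) / sqrt(length(blocks))
  compressibility_from_stats(mean(apl), se, n_lipids, temperature)
}

#' Linear fit of a metric against temperature
#'
#' Ordinary least squares of value on temperature, e.g. for area
#' expansivity (nm^2/K) or thickness contractility (nm/K). Points can be
#' excluded, as is customary when low-temperature points depart from the
#' linear regime.
#'
#' @param series A tibble with columns `temperature` (K) and `value`
#'   (metric units), e.g. built with [temperature_series()].
#' @param exclude Optional numeric vector of temperatures to drop before
#'   fitting.
#' @return An object of class `temperature_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `fit` (the `lm`), `data`, `excluded`.
#' @export
fit_vs_temperature <- function(series, exclude = NULL) {
  stopifnot(all(c("temperature", "value") %in% names(series)))
  kept <- series[!series$temperature %in% exclude, ]
  if (nrow(kept) < 2) stop("fewer than 2 retained points", call. = FALSE)
  fit <- stats::lm(value ~ temperature, data = kept)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = suppressWarnings(summary(fit))$r.squared,
      fit = fit,
      data = kept,
      excluded = series[series$temperature %in% exclude, ]
    ),
    class = "temperature_fit"
  )
}

#' Assemble a temperature series
#'
#' @param temperatures Strictly increasing temperatures (K).
#' @param values Metric values at those temperatures.
#' @param uncertainties Optional standard errors.
#' @param label,units Description of the metric.
#' @return A tibble with columns `temperature`, `value`, `uncertainty`.
#' @export
temperature_series <- function(temperatures, values, uncertainties = NA_real_,
                               label = "", units = "") {
  stopifnot(length(temperatures) == length(values))
  if (length(temperatures) > 1 && any(diff(temperatures) <= 0)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(
    temperature = temperatures, value = values, uncertainty = uncertainties
  )
  attr(out, "label") <- label
  attr(out, "units") <- units
  out
}

#' @export
print.temperature_fit <- function(x, ...) {
  cat(sprintf(
    "<temperature_fit> slope = %.4g per K, intercept = %.4g, R^2 = %.4f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, nrow(x$data)
  ))
  invisible(x)
}
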