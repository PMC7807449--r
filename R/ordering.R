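# Tail ordering: atomistic trans-dihedral statistics and bond P2 order
# parameters.

# vectorised dihedrals for arbitrary index quadruples into a coordinate
# matrix; bond vectors are taken minimum-image so tails broken across the
# periodic boundary stay intact
dihedral_quads <- function(xyz, i1, i2, i3, i4, box = NULL) {
  b1 <- xyz[i2, , drop = FALSE] - xyz[i1, , drop = FALSE]
  b2 <- xyz[i3, , drop = FALSE] - xyz[i2, , drop = FALSE]
  b3 <- xyz[i4, , drop = FALSE] - xyz[i3, , drop = FALSE]
  if (!is.null(box)) {
    for (k in 1:3) {
      b1[, k] <- min_image(b1[, k], box[k])
      b2[, k] <- min_image(b2[, k], box[k])
      b3[, k] <- min_image(b3[, k], box[k])
    }
  }
  cr <- function(u, v) {
    cbind(
      u[, 2] * v[, 3] - u[, 3] * v[, 2],
      u[, 3] * v[, 1] - u[, 1] * v[, 3],
      u[, 1] * v[, 2] - u[, 2] * v[, 1]
    )
  }
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  b2u <- b2 / sqrt(rowSums(b2^2))
  m1 <- cr(n1, b2u)
  atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
}

# index table of tail dihedral quadruples with all four carbons inside
# carbon_range; one row per (lipid, tail, start carbon)
tail_dihedral_index <- function(particles, carbon_range) {
  tails <- particles |>
    dplyr::filter(!is.na(.data$tail), !is.na(.data$carbon)) |>
    dplyr::select("id", "lipid_id", "species", "tail", "carbon") |>
    dplyr::arrange(.data$lipid_id, .data$tail, .data$carbon)
  if (nrow(tails) == 0) {
    return(NULL)
  }
  lo <- carbon_range[1]
  hi <- carbon_range[2]
  quads <- tails |>
    dplyr::group_by(.data$lipid_id, .data$tail, .data$species) |>
    dplyr::reframe({
      d <- dplyr::pick("id", "carbon")
      keep <- d$carbon >= lo & d$carbon <= hi
      ids <- d$id[keep]
      if (length(ids) < 4) {
        tibble::tibble(
          i1 = integer(0), i2 = integer(0), i3 = integer(0), i4 = integer(0)
        )
      } else {
        k <- seq_len(length(ids) - 3)
        tibble::tibble(i1 = ids[k], i2 = ids[k + 1], i3 = ids[k + 2], i4 = ids[k + 3])
      }
    })
  if (nrow(quads) == 0) NULL else quads
}

#' Fraction of trans tail dihedrals
#'
#' Over all tails, frames and dihedral angles formed by tail carbons inside
#' `carbon_range`, the fraction of angles falling in the trans window
#' (default `[130, 230]` degrees, endpoints included; angles are reduced to
#' `[0, 360)`). This global ordering statistic is independent of lipid tilt
#' and of tail chemistry, which makes it comparable across mixtures.
#'
#' @param traj A [ple_trajectory()] at atomistic resolution.
#' @param carbon_range Inclusive carbon position range along each tail
#'   (default positions 2 to 16).
#' @param window Trans window in degrees.
#' @param frames Optional frame indices to analyse (default all).
#' @param by Optional grouping: `"species"` returns a per-species tibble.
#' @return The overall trans fraction (scalar), or a tibble with columns
#'   `species`, `trans_fraction`, `n_dihedrals` when `by = "species"`.
#' @export
trans_fraction <- function(traj, carbon_range = c(2, 16), window = c(130, 230),
                           frames = NULL, by = NULL) {
  if (identical(traj$resolution, "CG")) {
    stop("trans_fraction requires atomistic (AA) input", call. = FALSE)
  }
  quads <- tail_dihedral_index(traj$particles, carbon_range)
  if (is.null(quads)) stop("no eligible dihedrals", call. = FALSE)
  frames <- frames %||% seq_len(n_frames(traj))
  idx <- match(c(quads$i1, quads$i2, quads$i3, quads$i4), traj$particles$id)
  nq <- nrow(quads)
  i1 <- idx[seq_len(nq)]
  i2 <- idx[nq + seq_len(nq)]
  i3 <- idx[2 * nq + seq_len(nq)]
  i4 <- idx[3 * nq + seq_len(nq)]
  tally <- numeric(nq)
  for (f in frames) {
    ang <- dihedral_quads(traj$xyz[[f]], i1, i2, i3, i4, traj$box[f, ]) %% 360
    tally <- tally + (ang >= window[1] & ang <= window[2])
  }
  if (is.null(by)) {
    return(sum(tally) / (nq * length(frames)))
  }
  stopifnot(identical(by, "species"))
  tibble::tibble(species = quads$species, hits = tally) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      trans_fraction = sum(.data$hits) / (dplyr::n() * length(frames)),
      n_dihedrals = dplyr::n() * length(frames),
      .groups = "drop"
    )
}

#' Consecutive tail-carbon bonds of a trajectory
#'
#' Builds the bond selection connecting successive tail carbons of every
#' lipid, labelled by carbon pair (e.g. `"C1-C2"`), for use with
#' [p2_bond_order()].
#'
#' @param traj A [ple_trajectory()].
#' @return A tibble with columns `i`, `j` (particle ids) and `bond`.
#' @export
tail_bonds <- function(traj) {
  tails <- traj$particles |>
    dplyr::filter(!is.na(.data$tail), !is.na(.data$carbon)) |>
    dplyr::arrange(.data$lipid_id, .data$tail, .data$carbon)
  tails |>
    dplyr::group_by(.data$lipid_id, .data$tail) |>
    dplyr::reframe({
      d <- dplyr::pick("id", "carbon")
      k <- seq_len(max(0, nrow(d) - 1))
      tibble::tibble(
        i = d$id[k], j = d$id[k + 1],
        bond = sprintf("C%d-C%d", d$carbon[k], d$carbon[k + 1])
      )
    }) |>
    dplyr::select("i", "j", "bond")
}

#' P2 bond order parameter against the membrane normal
#'
#' `P2 = 0.5 * <3 cos^2(theta) - 1>` per bond label, with `theta` the angle
#' between the (minimum-image) bond vector and the membrane normal,
#' averaged over lipids and frames. Values lie in `[-0.5, 1]`: 1 for
#' perfect alignment with the normal, 0 for random orientation, -0.5 for
#' bonds lying in the membrane plane.
#'
#' @param traj A [ple_trajectory()].
#' @param bonds Bond selection tibble with columns `i`, `j`, `bond`
#'   (particle ids and a grouping label); defaults to [tail_bonds()].
#' @param normal Membrane normal vector (default z axis).
#' @param frames Optional frame indices (default all).
#' @return A tibble (class `order_result`) with columns `bond`, `p2`, `sd`
#'   (s.d. over individual bond instances and frames) and `n`.
#' @export
p2_bond_order <- function(traj, bonds = NULL, normal = c(0, 0, 1), frames = NULL) {
  bonds <- bonds %||% tail_bonds(traj)
  if (nrow(bonds) == 0) stop("empty bond selection", call. = FALSE)
  frames <- frames %||% seq_len(n_frames(traj))
  nrm <- unit3(normal)
  ii <- match(bonds$i, traj$particles$id)
  jj <- match(bonds$j, traj$particles$id)
  acc <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    v <- traj$xyz[[f]][jj, , drop = FALSE] - traj$xyz[[f]][ii, , drop = FALSE]
    v <- sweep(v, 2, traj$box[f, ], function(d, l) d - l * round(d / l))
    cth <- (v %*% nrm) / sqrt(rowSums(v^2))
    acc[[k]] <- 0.5 * (3 * cth^2 - 1)
  }
  p2_all <- do.call(cbind, acc)
  out <- tibble::tibble(bond = bonds$bond, p2i = rowMeans(p2_all)) |>
    dplyr::mutate(allv = split(p2_all, seq_len(nrow(p2_all)))) |>
    dplyr::group_by(.data$bond) |>
    dplyr::summarise(
      p2 = mean(.data$p2i),
      sd = stats::sd(unlist(.data$allv)),
      n = dplyr::n() * length(frames),
      .groups = "drop"
    )
  class(out) <- c("order_result", class(out))
  out
}

#' Difference in ordering between two systems
#'
#' Elementwise difference of per-bond P2 values (first minus second), with
#' standard deviations propagated in quadrature. Scalars (e.g. two trans
#' fractions) are subtracted directly.
#'
#' @param a,b Two [p2_bond_order()] results with matching bond labels, or
#'   two numeric scalars.
#' @return A tibble with `bond`, `delta_p2`, `sd`, or a scalar difference.
#' @export
ordering_difference <- function(a, b) {
  if (is.numeric(a) && is.numeric(b)) {
    return(a - b)
  }
  stopifnot(is.data.frame(a), is.data.frame(b))
  if (!setequal(a$bond, b$bond) || nrow(a) == 0) {
    stop("bond selections do not match", call. = FALSE)
  }
  dplyr::inner_join(a, b, by = "bond", suffix = c("_a", "_b")) |>
    dplyr::transmute(
      bond = .data$bond,
      delta_p2 = .data$p2_a - .data$p2_b,
      sd = sqrt(.data$sd_a^2 + .data$sd_b^2)
    )
}
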