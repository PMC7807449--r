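# Lateral organisation: headgroup neighbour enrichment, single-linkage
# cluster-size distributions, and 2-D density maps.

# one reference particle per lipid: PE/PG phosphate, CL central glycerol
lipid_reference_particles <- function(frame) {
  refs <- dplyr::filter(
    frame,
    (.data$headgroup %in% c("PE", "PG") & .data$role == "headgroup_ref") |
      (.data$headgroup == "CL" & .data$role == "glycerol_ref")
  )
  dplyr::distinct(refs, .data$lipid_id, .keep_all = TRUE)
}

enrichment_one_frame <- function(frame, cutoff) {
  box <- frame_box(frame)
  refs <- lipid_reference_particles(frame)
  cls <- refs$headgroup
  d <- pdist_min_image(frame_xyz(refs), frame_xyz(refs), box)
  diag(d) <- Inf
  contact <- d <= cutoff
  classes <- sort(unique(cls))
  # mean number of class-Y neighbours of any lipid (the normaliser)
  grid <- expand.grid(center = classes, neighbor = classes, stringsAsFactors = FALSE)
  grid$enrichment <- mapply(function(X, Y) {
    nX <- cls == X
    nY <- cls == Y
    per_X <- mean(rowSums(contact[nX, nY, drop = FALSE]))
    per_any <- mean(rowSums(contact[, nY, drop = FALSE]))
    if (per_any == 0) NA_real_ else per_X / per_any
  }, grid$center, grid$neighbor)
  tibble::as_tibble(grid)
}

#' Headgroup neighbour enrichment matrix
#'
#' For each pair of headgroup classes X (center) and Y (neighbour), the
#' mean number of class-Y reference particles within the cutoff of a
#' class-X lipid, normalised by the mean number of class-Y contacts of a
#' lipid of any class. The ratio is formed per frame and then averaged
#' over frames. Reference particles are the PE/PG phosphates and the CL
#' central glycerol carbon; self-contacts are excluded and distances are
#' minimum-image. An ideally mixed membrane gives 1 for every entry.
#'
#' @param traj A [ple_trajectory()] (or a single [bilayer_frame()]).
#' @param cutoff Contact cutoff (nm); 0.9 nm is the first-solvation-shell
#'   convention for the CL glycerol bead.
#' @param frames Optional frame indices (default all).
#' @return A tibble (class `enrichment_matrix`) with columns `center`,
#'   `neighbor`, `enrichment` (frame mean) and `sd` (s.d. over frames).
#' @export
neighbor_enrichment <- function(traj, cutoff = 0.9, frames = NULL) {
  if (inherits(traj, "bilayer_frame")) {
    per <- list(enrichment_one_frame(traj, cutoff))
  } else {
    frames <- frames %||% seq_len(n_frames(traj))
    per <- lapply(frames, function(f) enrichment_one_frame(traj_frame(traj, f), cutoff))
  }
  out <- dplyr::bind_rows(per, .id = "frame") |>
    dplyr::group_by(.data$center, .data$neighbor) |>
    dplyr::summarise(
      sd = stats::sd(.data$enrichment),
      enrichment = mean(.data$enrichment),
      .groups = "drop"
    ) |>
    dplyr::select("center", "neighbor", "enrichment", "sd")
  class(out) <- c("enrichment_matrix", class(out))
  out
}

# union-find over molecule contacts
union_find_clusters <- function(contact) {
  n <- nrow(contact)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- which(contact & upper.tri(contact), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    a <- find(idx[k, 1])
    b <- find(idx[k, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Single-linkage cluster-size distribution of a lipid species class
#'
#' Two molecules belong to the same cluster when any particle of one lies
#' within the cutoff of any particle of the other (minimum-image distance,
#' single linkage, both leaflets pooled so intra- and interleaflet
#' clusters are included). The printed conventions are 0.35 nm with all
#' atoms at atomistic resolution and 0.65 nm with all beads at
#' coarse-grained resolution.
#'
#' @param frame A [bilayer_frame()].
#' @param species_class A headgroup class (`"CL"`, `"PG"`, `"PE"`) or a
#'   species code.
#' @param cutoff Linkage cutoff (nm).
#' @return A tibble (class `cluster_distribution`) with columns `size` and
#'   `n_clusters`; attribute `fractions` holds the molecule fractions in
#'   monomers, dimers, trimers and higher oligomers, and `membership` the
#'   per-molecule cluster ids.
#' @export
cluster_size_distribution <- function(frame, species_class, cutoff = 0.35) {
  sel <- frame$headgroup %in% species_class | frame$species %in% species_class
  sel <- sel & !is.na(frame$lipid_id)
  if (!any(sel)) stop("species class absent from frame", call. = FALSE)
  atoms <- frame[sel, ]
  box <- frame_box(frame)
  mols <- sort(unique(atoms$lipid_id))
  mi <- match(atoms$lipid_id, mols)
  d <- pdist_min_image(frame_xyz(atoms), frame_xyz(atoms), box)
  close_at <- d <= cutoff
  nm <- length(mols)
  contact <- matrix(FALSE, nm, nm)
  hit <- which(close_at, arr.ind = TRUE)
  contact[cbind(mi[hit[, 1]], mi[hit[, 2]])] <- TRUE
  diag(contact) <- FALSE
  comp <- union_find_clusters(contact)
  sizes <- as.integer(table(comp))
  dist <- tibble::tibble(size = sort(unique(sizes))) |>
    dplyr::mutate(n_clusters = vapply(
      .data$size, function(s) sum(sizes == s), integer(1)
    ))
  # molecule-weighted fractions by the size of the molecule's own cluster
  size_of_mol <- as.integer(table(comp))[match(comp, sort(unique(comp)))]
  fr <- c(
    monomer = sum(size_of_mol == 1) / nm,
    dimer = sum(size_of_mol == 2) / nm,
    trimer = sum(size_of_mol == 3) / nm,
    higher = sum(size_of_mol > 3) / nm
  )
  attr(dist, "fractions") <- fr
  attr(dist, "membership") <- tibble::tibble(lipid_id = mols, cluster = comp)
  class(dist) <- c("cluster_distribution", class(dist))
  dist
}

#' Time-averaged 2-D number density map
#'
#' Per-leaflet xy histogram of lipid reference particles, normalised by
#' bin area and frame count.
#'
#' @param traj A [ple_trajectory()].
#' @param species_class Headgroup class or species code to map.
#' @param bins Length-2 integer (nx, ny), at least 2 per axis.
#' @param frames Optional frame indices.
#' @return A tibble with columns `leaflet`, `ix`, `iy`, `x`, `y`,
#'   `density` (counts/nm^2).
#' @export
density_map_2d <- function(traj, species_class, bins = c(15, 15), frames = NULL) {
  if (length(bins) == 1) bins <- c(bins, bins)
  if (any(bins < 2)) stop("need at least 2 bins per axis", call. = FALSE)
  frames <- frames %||% seq_len(n_frames(traj))
  box <- traj$box[frames[1], ]
  counts <- list(
    upper = matrix(0, bins[1], bins[2]),
    lower = matrix(0, bins[1], bins[2])
  )
  found <- FALSE
  for (f in frames) {
    fr <- traj_frame(traj, f)
    refs <- lipid_reference_particles(fr)
    refs <- refs[refs$headgroup %in% species_class | refs$species %in% species_class, ]
    if (nrow(refs) == 0) next
    found <- TRUE
    for (lf in c("upper", "lower")) {
      d <- refs[refs$leaflet == lf, ]
      if (nrow(d) == 0) next
      ix <- pmin(bins[1], 1 + floor(d$x / box[1] * bins[1]))
      iy <- pmin(bins[2], 1 + floor(d$y / box[2] * bins[2]))
      for (k in seq_len(nrow(d))) {
        counts[[lf]][ix[k], iy[k]] <- counts[[lf]][ix[k], iy[k]] + 1
      }
    }
  }
  if (!found) stop("species class absent from trajectory", call. = FALSE)
  bin_area <- (box[1] / bins[1]) * (box[2] / bins[2])
  purrr::map_dfr(c("upper", "lower"), function(lf) {
    tibble::tibble(
      leaflet = lf,
      ix = rep(seq_len(bins[1]), times = bins[2]),
      iy = rep(seq_len(bins[2]), each = bins[1]),
      x = (rep(seq_len(bins[1]), times = bins[2]) - 0.5) * box[1] / bins[1],
      y = (rep(seq_len(bins[2]), each = bins[1]) - 0.5) * box[2] / bins[2],
      density = as.vector(counts[[lf]]) / bin_area / length(frames)
    )
  })
}
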