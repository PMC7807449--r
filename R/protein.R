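# Lipid-protein context: annular shell enrichment, per-residue binding
# probability, binding durations, and local membrane thinning.

protein_atoms <- function(frame) {
  p <- dplyr::filter(frame, .data$role == "protein_atom")
  if (nrow(p) == 0) stop("protein absent from frame", call. = FALSE)
  p
}

# minimum distance of each lipid to any protein atom. "reference" uses the
# lateral (xy) distance of the lipid's reference particle, the annular-shell
# convention for a membrane-spanning inclusion; "any_particle" the 3-D
# minimum over all particles of the lipid.
lipid_protein_mindist <- function(frame, method = c("reference", "any_particle")) {
  method <- match.arg(method)
  prot <- protein_atoms(frame)
  box <- frame_box(frame)
  if (method == "reference") {
    lip <- lipid_reference_particles(frame)
    d <- pdist_min_image(cbind(lip$x, lip$y), cbind(prot$x, prot$y), box[1:2])
  } else {
    lip <- dplyr::filter(frame, !is.na(.data$lipid_id))
    d <- pdist_min_image(frame_xyz(lip), frame_xyz(prot), box)
  }
  tibble::tibble(lipid_id = lip$lipid_id, mind = row_mins(d)) |>
    dplyr::group_by(.data$lipid_id) |>
    dplyr::summarise(mind = min(.data$mind), .groups = "drop")
}

#' Lipid class enrichment in the protein's first solvation shell
#'
#' Fraction of shell lipids of each headgroup class divided by that class's
#' bulk fraction (lipids outside the shell), optionally resolved per
#' leaflet; the uncertainty is the standard deviation over time windows.
#' A lipid is in the shell when any of its particles lies within `shell`
#' of any protein atom.
#'
#' @param traj A [ple_trajectory()] containing `protein_atom` particles.
#' @param shell First-shell cutoff (nm, default 0.65).
#' @param per_leaflet Report cytoplasmic/extracellular leaflets separately
#'   (the upper leaflet is taken as cytoplasmic unless relabelled).
#' @param frames Optional frame indices.
#' @param n_windows Number of time windows for the uncertainty (default 3).
#' @param method Shell membership: `"reference"` (default) takes the
#'   lateral distance of the lipid's reference particle to the nearest
#'   protein atom, the annular-shell convention for a membrane-spanning
#'   inclusion; `"any_particle"` uses the 3-D minimum over all particles.
#' @return A tibble with columns `leaflet` (or `"both"`), `headgroup`,
#'   `enrichment`, `sd`, `n_shell`.
#' @export
shell_enrichment <- function(traj, shell = 0.65, per_leaflet = FALSE,
                             frames = NULL, n_windows = 3,
                             method = c("reference", "any_particle")) {
  method <- match.arg(method)
  frames <- frames %||% seq_len(n_frames(traj))
  lip_meta <- traj$particles |>
    dplyr::filter(!is.na(.data$lipid_id)) |>
    dplyr::distinct(.data$lipid_id, .data$headgroup, .data$leaflet)
  one_frame <- function(f) {
    fr <- traj_frame(traj, f)
    md <- lipid_protein_mindist(fr, method)
    md$in_shell <- md$mind <= shell
    dplyr::left_join(md, lip_meta, by = "lipid_id")
  }
  per <- lapply(frames, one_frame)
  enr_of <- function(d) {
    if (!any(d$in_shell)) stop("empty protein shell", call. = FALSE)
    shell_frac <- prop.table(table(factor(d$headgroup[d$in_shell],
      levels = sort(unique(d$headgroup))
    )))
    bulk_frac <- prop.table(table(factor(d$headgroup[!d$in_shell],
      levels = sort(unique(d$headgroup))
    )))
    tibble::tibble(
      headgroup = names(shell_frac),
      enrichment = as.numeric(shell_frac) / as.numeric(bulk_frac),
      n_shell = sum(d$in_shell)
    )
  }
  win <- cut(seq_along(per), breaks = max(1, min(n_windows, length(per))), labels = FALSE)
  groupings <- if (per_leaflet) c("upper", "lower") else "both"
  purrr::map_dfr(groupings, function(lf) {
    per_lf <- lapply(per, function(d) {
      if (lf == "both") d else d[d$leaflet == lf, ]
    })
    overall <- enr_of(dplyr::bind_rows(per_lf))
    by_win <- purrr::map_dfr(unique(win), function(w) {
      enr_of(dplyr::bind_rows(per_lf[win == w]))
    })
    sds <- by_win |>
      dplyr::group_by(.data$headgroup) |>
      dplyr::summarise(sd = stats::sd(.data$enrichment), .groups = "drop")
    overall |>
      dplyr::left_join(sds, by = "headgroup") |>
      dplyr::mutate(leaflet = if (lf == "both") {
        "both"
      } else if (lf == "upper") "CP" else "EC", .before = 1)
  })
}

# frame x residue x class contact computation shared by the two binding
# analyses; returns per-frame contact information
residue_contacts_frame <- function(fr, species_class, cutoff) {
  prot <- protein_atoms(fr)
  box <- frame_box(fr)
  lip <- dplyr::filter(
    fr, !is.na(.data$lipid_id),
    .data$headgroup %in% species_class | .data$species %in% species_class
  )
  if (nrow(lip) == 0) {
    return(NULL)
  }
  d <- pdist_min_image(frame_xyz(lip), frame_xyz(prot), box)
  hits <- which(d <= cutoff, arr.ind = TRUE)
  tibble::tibble(
    lipid_id = lip$lipid_id[hits[, 1]],
    residue = prot$residue[hits[, 2]],
    chain = prot$chain[hits[, 2]]
  )
}

#' Per-residue lipid binding probability
#'
#' For each protein residue, the fraction of frames in which any particle
#' of any lipid of the class lies within the cutoff of any atom of that
#' residue.
#'
#' @param traj A [ple_trajectory()] with protein atoms carrying residue
#'   indices.
#' @param species_class Headgroup class or species code.
#' @param cutoff Contact cutoff (nm, default 0.65).
#' @param frames Optional frame indices.
#' @return A tibble with columns `residue`, `chain`, `probability`.
#' @export
residue_binding_probability <- function(traj, species_class, cutoff = 0.65,
                                        frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  res_tbl <- traj$particles |>
    dplyr::filter(.data$role == "protein_atom") |>
    dplyr::distinct(.data$residue, .data$chain)
  hit_count <- stats::setNames(numeric(nrow(res_tbl)), res_tbl$residue)
  for (f in frames) {
    con <- residue_contacts_frame(traj_frame(traj, f), species_class, cutoff)
    if (is.null(con)) next
    touched <- unique(con$residue)
    hit_count[as.character(touched)] <- hit_count[as.character(touched)] + 1
  }
  res_tbl |>
    dplyr::mutate(probability = unname(hit_count) / length(frames)) |>
    dplyr::arrange(.data$residue)
}

#' Lipid-protein binding events and durations
#'
#' Per lipid of the class, contiguous intervals of contact with the whole
#' protein (any lipid particle within the cutoff of any protein atom),
#' merging interruptions of at most `gap_tolerance` frames. Durations are
#' the time spanned from the first to the last contact frame of the event.
#'
#' @param traj A [ple_trajectory()] with protein atoms.
#' @param species_class Headgroup class or species code.
#' @param cutoff Contact cutoff (nm, default 0.65).
#' @param gap_tolerance Longest interruption (frames) merged into one
#'   event (default 1).
#' @param frames Optional frame indices.
#' @return A tibble of events: `lipid_id`, `species`, `start_frame`,
#'   `end_frame`, `start_time`, `end_time`, `duration` (ns),
#'   `n_contact_frames`.
#' @export
binding_durations <- function(traj, species_class, cutoff = 0.65,
                              gap_tolerance = 1, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  masks <- list()
  for (k in seq_along(frames)) {
    con <- residue_contacts_frame(traj_frame(traj, frames[k]), species_class, cutoff)
    if (!is.null(con) && nrow(con) > 0) {
      masks[[length(masks) + 1]] <- tibble::tibble(
        lipid_id = unique(con$lipid_id), step = k
      )
    }
  }
  if (length(masks) == 0) {
    return(tibble::tibble(
      lipid_id = integer(0), species = character(0),
      start_frame = integer(0), end_frame = integer(0),
      start_time = numeric(0), end_time = numeric(0),
      duration = numeric(0), n_contact_frames = integer(0)
    ))
  }
  sp_of <- traj$particles |>
    dplyr::filter(!is.na(.data$lipid_id)) |>
    dplyr::distinct(.data$lipid_id, .data$species)
  dplyr::bind_rows(masks) |>
    dplyr::group_by(.data$lipid_id) |>
    dplyr::reframe({
      st <- sort(.data$step)
      brk <- c(0, which(diff(st) > gap_tolerance + 1), length(st))
      purrr::map_dfr(seq_len(length(brk) - 1), function(e) {
        seg <- st[(brk[e] + 1):brk[e + 1]]
        tibble::tibble(
          start_frame = frames[seg[1]],
          end_frame = frames[seg[length(seg)]],
          n_contact_frames = length(seg)
        )
      })
    }) |>
    dplyr::mutate(
      start_time = traj$times[.data$start_frame],
      end_time = traj$times[.data$end_frame],
      duration = .data$end_time - .data$start_time
    ) |>
    dplyr::left_join(sp_of, by = "lipid_id") |>
    dplyr::select(
      "lipid_id", "species", "start_frame", "end_frame",
      "start_time", "end_time", "duration", "n_contact_frames"
    )
}

#' Local membrane thinning around a protein inclusion
#'
#' Phosphate-to-phosphate thickness evaluated on a grid restricted to
#' positions within each shell distance of the protein surface, minus a
#' bulk reference thickness; positive values mean thinning. The reference
#' is either supplied (a number, or a protein-free trajectory) or taken
#' from the far field of the same frames.
#'
#' @param traj A [ple_trajectory()] with protein atoms.
#' @param shells Shell distances from the protein surface (nm; default
#'   0.5 and 1.0).
#' @param grid Grid spacing (nm, default 1).
#' @param reference Bulk thickness (nm), a protein-free
#'   [ple_trajectory()], or `NULL` to use grid cells farther than
#'   `max(shells) + 1` nm from the protein.
#' @param frames Optional frame indices.
#' @return A tibble with columns `shell`, `thinning` (nm), `local`,
#'   `bulk`, `n_cells`.
#' @export
local_thinning <- function(traj, shells = c(0.5, 1.0), grid = 1,
                           reference = NULL, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  box <- traj$box[frames[1], ]
  if (any(shells >= min(box[1:2]) / 2)) {
    stop("shell larger than half the box", call. = FALSE)
  }
  nx <- max(2L, round(box[1] / grid))
  ny <- max(2L, round(box[2] / grid))
  gx <- (seq_len(nx) - 0.5) * box[1] / nx
  gy <- (seq_len(ny) - 0.5) * box[2] / ny
  gpts <- as.matrix(expand.grid(x = gx, y = gy))

  shell_thickness <- function(fr, s) {
    prot <- protein_atoms(fr)
    heads <- dplyr::filter(fr, .data$role == "headgroup_ref")
    # restrict to phosphates found within the shell of the protein
    # (lateral distance, the annular convention for a spanning inclusion)
    d <- pdist_min_image(
      cbind(heads$x, heads$y), cbind(prot$x, prot$y), frame_box(fr)[1:2]
    )
    heads <- heads[row_mins(d) <= s, ]
    up <- heads[heads$leaflet == "upper", ]
    lo <- heads[heads$leaflet == "lower", ]
    if (nrow(up) == 0 || nrow(lo) == 0) {
      stop("empty shell at ", s, " nm", call. = FALSE)
    }
    # grid cells covering the selected references
    du <- pdist_min_image(gpts, cbind(up$x, up$y), box[1:2])
    dl <- pdist_min_image(gpts, cbind(lo$x, lo$y), box[1:2])
    covered <- row_mins(du) <= grid | row_mins(dl) <= grid
    zu <- up$z[apply(du, 1, which.min)]
    zl <- lo$z[apply(dl, 1, which.min)]
    c(mean((zu - zl)[covered]), sum(covered))
  }

  bulk <- if (is.numeric(reference) && length(reference) == 1) {
    reference
  } else {
    src <- if (inherits(reference, "ple_trajectory")) reference else traj
    src_frames <- frames[frames <= n_frames(src)]
    vals <- vapply(src_frames, function(f) {
      fr <- traj_frame(src, f)
      heads <- dplyr::filter(fr, .data$role == "headgroup_ref")
      if (!inherits(reference, "ple_trajectory")) {
        # far field of the same frame
        prot <- protein_atoms(fr)
        d <- pdist_min_image(
          cbind(heads$x, heads$y), cbind(prot$x, prot$y), box[1:2]
        )
        heads <- heads[row_mins(d) > max(shells) + 1, ]
        if (nrow(heads) == 0) stop("no far-field references for the bulk", call. = FALSE)
      }
      mean(heads$z[heads$leaflet == "upper"]) - mean(heads$z[heads$leaflet == "lower"])
    }, numeric(1))
    mean(vals)
  }

  purrr::map_dfr(shells, function(s) {
    per <- vapply(frames, function(f) shell_thickness(traj_frame(traj, f), s),
      numeric(2)
    )
    tibble::tibble(
      shell = s,
      local = mean(per[1, ]),
      bulk = bulk,
      thinning = bulk - mean(per[1, ]),
      n_cells = mean(per[2, ])
    )
  })
}
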