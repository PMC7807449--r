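#' Parameters for the synthetic bilayer generator
#'
#' Collects every knob of the seeded trajectory generator together with its
#' default study conditions: a SimplePOM-like leaflet of 128 lipids at an
#' area per lipid of 0.62 nm^2, a phosphate-phosphate thickness of 3.9 nm,
#' a trans-dihedral probability of 0.58, lateral diffusion of
#' 0.6e-7 cm^2/s for every species, and Poisson water crossings at
#' 0.05 events/ns.
#'
#' @param composition A composition from [load_composition()] or a preset
#'   name.
#' @param n_per_leaflet Lipids per leaflet (both leaflets are identical).
#' @param target_apl Area per lipid (nm^2); the box area is exactly
#'   `n_per_leaflet * target_apl`.
#' @param pp_thickness Phosphate-plane separation (nm).
#' @param hydrophobic_offset Distance from the headgroup reference to the
#'   hydrophobic boundary (midpoint of carbonyl and first methylene), nm.
#' @param p_trans Probability that a tail dihedral is drawn trans.
#' @param dihedral_jitter Gaussian s.d. (degrees) around 180 / +-60.
#' @param z_jitter Gaussian s.d. (nm) of the headgroup plane roughness.
#' @param D_map Named numeric, species -> lateral diffusion coefficient in
#'   cm^2/s; a single unnamed value applies to all species.
#' @param n_frames,dt Number of frames and time step (ns).
#' @param water_count Number of role-tagged waters.
#' @param permeation_rate Poisson rate of scripted full crossings
#'   (events/ns).
#' @param demixing_strength 0..1; 0 = ideal mixing, larger values place a
#'   growing fraction of each species in contiguous like-species clusters.
#' @param protein Optional list `list(radius =, thinning_depth =,
#'   thinning_range =, shell_enrichment =)` describing a rigid cylindrical
#'   inclusion; `thinning_depth` is the total bilayer thinning at the
#'   protein wall (nm, each leaflet contributes half),
#'   `shell_enrichment` a named vector of headgroup-class enrichment
#'   factors for first-shell occupancy.
#' @param seed Integer RNG seed; identical parameters and seed give a
#'   bitwise-identical trajectory.
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(composition = "SimplePOM",
                             n_per_leaflet = 128,
                             target_apl = 0.62,
                             pp_thickness = 3.9,
                             hydrophobic_offset = 0.45,
                             p_trans = 0.58,
                             dihedral_jitter = 15,
                             z_jitter = 0.05,
                             D_map = 0.6e-7,
                             n_frames = 200,
                             dt = 1,
                             water_count = 200,
                             permeation_rate = 0.05,
                             demixing_strength = 0,
                             protein = NULL,
                             seed = 1) {
  if (is.character(composition)) composition <- load_composition(composition)
  stopifnot(inherits(composition, "ple_composition"))
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
  stopifnot(
    num_ok(n_per_leaflet), num_ok(target_apl), num_ok(pp_thickness),
    num_ok(hydrophobic_offset), num_ok(dihedral_jitter), num_ok(z_jitter),
    num_ok(n_frames), num_ok(dt), num_ok(water_count), num_ok(permeation_rate)
  )
  if (p_trans < 0 || p_trans > 1) stop("p_trans must be in [0, 1]", call. = FALSE)
  if (demixing_strength < 0 || demixing_strength > 1) {
    stop("demixing_strength must be in [0, 1]", call. = FALSE)
  }
  if (any(D_map < 0)) stop("diffusion coefficients must be >= 0", call. = FALSE)
  if (is.null(names(D_map))) {
    stopifnot(length(D_map) == 1L)
    D_map <- stats::setNames(rep(D_map, nrow(composition)), composition$species)
  }
  miss <- setdiff(composition$species, names(D_map))
  if (length(miss)) stop("D_map misses species: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!is.null(protein)) {
    stopifnot(is.list(protein), num_ok(protein$radius))
    protein$thinning_depth <- protein$thinning_depth %||% 0
    protein$thinning_range <- protein$thinning_range %||% 1
    protein$shell_enrichment <- protein$shell_enrichment %||% c(PE = 1, PG = 1, CL = 1)
    protein$shell <- protein$shell %||% 0.65
  }
  structure(
    list(
      composition = composition, n_per_leaflet = as.integer(n_per_leaflet),
      target_apl = target_apl, pp_thickness = pp_thickness,
      hydrophobic_offset = hydrophobic_offset, p_trans = p_trans,
      dihedral_jitter = dihedral_jitter, z_jitter = z_jitter, D_map = D_map,
      n_frames = as.integer(n_frames), dt = dt,
      water_count = as.integer(water_count), permeation_rate = permeation_rate,
      demixing_strength = demixing_strength, protein = protein,
      seed = as.integer(seed)
    ),
    class = "synthetic_params"
  )
}

# species assignment over lattice sites; d > 0 grows contiguous
# like-species clusters by nearest-site preferential attachment
assign_species_sites <- function(sites, counts, box, d) {
  n <- nrow(sites)
  pool <- rep(counts$species, counts$count)
  stopifnot(length(pool) == n)
  if (d <= 0) {
    return(sample(pool))
  }
  assign <- rep(NA_character_, n)
  unass <- seq_len(n)
  for (sp in sample(unique(counts$species))) {
    k <- sum(pool == sp)
    k_cl <- round(d * k)
    if (k_cl < 2 || length(unass) == 0) next
    seed_site <- sample(unass, 1)
    members <- seed_site
    assign[seed_site] <- sp
    unass <- setdiff(unass, seed_site)
    while (length(members) < k_cl && length(unass) > 0) {
      dmat <- pdist_min_image(
        sites[unass, , drop = FALSE], sites[members, , drop = FALSE], box
      )
      nearest <- unass[which.min(apply(dmat, 1, min))]
      assign[nearest] <- sp
      members <- c(members, nearest)
      unass <- setdiff(unass, nearest)
    }
    pool <- pool[-which(pool == sp)[seq_along(members)]]
  }
  # remaining species randomly on leftover sites
  left <- pool
  if (length(unass)) assign[unass] <- sample(left)[seq_along(unass)]
  assign
}

build_lipid_particles <- function(lipid_id, species_row, site, sgn, params) {
  sp <- species_row
  pp2 <- params$pp_thickness / 2
  prot <- params$protein
  # local thinning of the headgroup plane near the protein wall
  thin <- 0
  if (!is.null(prot) && prot$thinning_depth > 0) {
    r <- sqrt(sum((site - attr(params, "center"))^2))
    if (r >= prot$radius) {
      thin <- (prot$thinning_depth / 2) * exp(-(r - prot$radius) / prot$thinning_range)
    } else {
      thin <- prot$thinning_depth / 2
    }
  }
  head_z <- sgn * (pp2 - thin) + stats::rnorm(1, 0, params$z_jitter)
  rows <- list()
  tails <- sp$tails[[1]]
  is_cl <- sp$headgroup == "CL"
  if (is_cl) {
    phi <- stats::runif(1, 0, 2 * pi)
    off <- 0.25 * c(cos(phi), sin(phi))
    p1 <- c(site + off, head_z)
    p2 <- c(site - off, head_z + stats::rnorm(1, 0, params$z_jitter / 2))
    rows[[length(rows) + 1]] <- data.frame(
      role = c("headgroup_ref", "headgroup_ref", "glycerol_ref"),
      tail = NA_integer_, carbon = NA_integer_,
      x = c(p1[1], p2[1], site[1]), y = c(p1[2], p2[2], site[2]),
      z = c(p1[3], p2[3], head_z)
    )
    anchors <- rbind(
      site + off + c(0.08, 0), site + off - c(0.08, 0),
      site - off + c(0.08, 0), site - off - c(0.08, 0)
    )
  } else {
    rows[[length(rows) + 1]] <- data.frame(
      role = "headgroup_ref", tail = NA_integer_, carbon = NA_integer_,
      x = site[1], y = site[2], z = head_z
    )
    anchors <- rbind(site + c(0.08, 0), site - c(0.08, 0))
  }
  reg <- tail_registry()
  tors_all <- list()
  for (t in seq_along(tails)) {
    nc <- reg$carbons[match(tails[t], reg$code)]
    n_tors <- nc - 3
    is_trans <- stats::runif(n_tors) < params$p_trans
    tors <- ifelse(
      is_trans,
      180 + stats::rnorm(n_tors, 0, params$dihedral_jitter),
      sample(c(-60, 60), n_tors, replace = TRUE) +
        stats::rnorm(n_tors, 0, params$dihedral_jitter)
    )
    tors_all[[t]] <- is_trans
    z1 <- head_z - sgn * (params$hydrophobic_offset - 0.153 / 2)
    chain <- build_chain(
      nc, tors,
      origin = c(anchors[t, ], z1),
      direction = c(0, 0, -sgn)
    )
    # random azimuthal rotation of the chain about its anchor
    phi <- stats::runif(1, 0, 2 * pi)
    rel <- sweep(chain[, 1:2, drop = FALSE], 2, anchors[t, ])
    chain[, 1] <- anchors[t, 1] + cos(phi) * rel[, 1] - sin(phi) * rel[, 2]
    chain[, 2] <- anchors[t, 2] + sin(phi) * rel[, 1] + cos(phi) * rel[, 2]
    role <- c(
      "carbonyl", "first_methylene",
      rep("tail_carbon", nc - 3), "terminal_methyl"
    )
    rows[[length(rows) + 1]] <- data.frame(
      role = role, tail = t, carbon = seq_len(nc),
      x = chain[, 1], y = chain[, 2], z = chain[, 3]
    )
  }
  out <- do.call(rbind, rows)
  out$lipid_id <- lipid_id
  out$species <- sp$species
  out$headgroup <- sp$headgroup
  out$leaflet <- if (sgn > 0) "upper" else "lower"
  list(particles = out, trans = unlist(tors_all))
}

#' Generate a seeded synthetic bilayer trajectory with ground truth
#'
#' Builds two mirror-symmetric leaflets on a jittered square lattice whose
#' box area realises `target_apl` exactly, grows each acyl tail by torsion
#' placement (bond 0.153 nm, angle 111 deg) with torsions drawn trans
#' (180 deg +- jitter) with probability `p_trans` and gauche (+-60 deg)
#' otherwise, evolves lipid lateral positions as per-species Brownian
#' motion, scripts Poisson-timed transmembrane water crossings, and
#' optionally embeds a rigid cylindrical protein with local thinning and
#' first-shell species enrichment. All randomness is governed by
#' `params$seed`; the returned ground truth records every recoverable
#' quantity.
#'
#' @param params A [synthetic_params()] object.
#' @return A list with elements `trajectory` (a [ple_trajectory()]) and
#'   `ground_truth` (class `ple_ground_truth`).
#' @examples
#' sim <- generate_bilayer(synthetic_params(
#'   n_per_leaflet = 16, n_frames = 5,
#'   water_count = 10, permeation_rate = 0.01, seed = 42
#' ))
#' sim$trajectory
#' @export
generate_bilayer <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  withr::with_seed(params$seed, generate_bilayer_impl(params))
}

generate_bilayer_impl <- function(params) {
  comp <- params$composition
  n <- params$n_per_leaflet
  if (n < 4) stop("n_per_leaflet must be >= 4", call. = FALSE)
  prot <- params$protein
  area <- n * params$target_apl +
    if (!is.null(prot)) pi * (prot$radius + 0.3)^2 else 0
  L <- sqrt(area)
  box_z <- params$pp_thickness + 3
  if (!is.null(prot) && prot$radius >= L / 2) {
    stop("protein radius must be smaller than half the box", call. = FALSE)
  }

  # jittered square lattice of lipid sites
  m <- ceiling(sqrt(n + if (!is.null(prot)) ceiling(pi * (prot$radius + 0.4)^2 / params$target_apl) else 0))
  s <- L / m
  if (0.6 * s < 0.4) {
    stop("target_apl x n_per_leaflet too small to place lipids without overlap",
      call. = FALSE
    )
  }
  grid <- expand.grid(i = seq_len(m) - 0.5, j = seq_len(m) - 0.5)
  sites <- cbind(grid$i * s, grid$j * s)
  sites <- sites + matrix(stats::runif(2 * nrow(sites), -0.2 * s, 0.2 * s), ncol = 2)
  sites[, 1] <- sites[, 1] %% L
  sites[, 2] <- sites[, 2] %% L
  center <- c(L / 2, L / 2)
  attr(params, "center") <- center
  if (!is.null(prot)) {
    keep <- sqrt((sites[, 1] - center[1])^2 + (sites[, 2] - center[2])^2) >
      prot$radius + 0.25
    sites <- sites[keep, , drop = FALSE]
  }
  if (nrow(sites) < n) {
    stop("not enough lattice sites to place all lipids", call. = FALSE)
  }
  if (nrow(sites) > n) {
    # drop surplus sites from the bulk only, so an annular first shell
    # around the inclusion is always populated
    if (!is.null(prot)) {
      rc <- sqrt((sites[, 1] - center[1])^2 + (sites[, 2] - center[2])^2)
      protected <- which(rc <= prot$radius + 1)
    } else {
      protected <- integer(0)
    }
    droppable <- setdiff(seq_len(nrow(sites)), protected)
    drop <- sample(droppable, nrow(sites) - n)
    sites <- sites[-drop, , drop = FALSE]
  }

  # species assignment (identical in both leaflets)
  counts <- realize_counts(comp, n)
  if (is.null(prot) || all(prot$shell_enrichment == 1)) {
    species_at <- assign_species_sites(sites, counts, c(L, L), params$demixing_strength)
  } else {
    hg_frac <- headgroup_fractions(comp)
    f <- stats::setNames(hg_frac$percent / 100, hg_frac$headgroup)
    e <- prot$shell_enrichment
    e <- stats::setNames(
      ifelse(names(f) %in% names(e), e[names(f)], 1), names(f)
    )
    p_shell <- f * e
    boosted <- e > 1
    spare <- 1 - sum(p_shell[boosted])
    p_shell[!boosted] <- f[!boosted] * spare / sum(f[!boosted])
    rxy <- sqrt((sites[, 1] - center[1])^2 + (sites[, 2] - center[2])^2)
    in_shell <- rxy <= prot$radius + prot$shell
    species_at <- rep(NA_character_, n)
    draw_species <- function(k, class_probs) {
      cls <- sample(names(class_probs), k, replace = TRUE, prob = class_probs)
      vapply(cls, function(cl) {
        sub <- comp[comp$headgroup == cl, ]
        sample(sub$species, 1, prob = sub$fraction)
      }, character(1))
    }
    species_at[in_shell] <- draw_species(sum(in_shell), p_shell)
    species_at[!in_shell] <- draw_species(sum(!in_shell), f)
  }

  # build base particle table (midplane z frame), both leaflets mirrored
  sp_rows <- split(comp, seq_len(nrow(comp)))
  names(sp_rows) <- comp$species
  parts <- vector("list", 2 * n)
  trans_drawn <- logical(0)
  lid <- 0L
  for (leaf in c(1, -1)) {
    for (i in seq_len(n)) {
      lid <- lid + 1L
      built <- build_lipid_particles(
        lid, sp_rows[[species_at[i]]], sites[i, ], leaf, params
      )
      parts[[lid]] <- built$particles
      trans_drawn <- c(trans_drawn, built$trans)
    }
  }
  lipid_tbl <- do.call(rbind, parts)

  # waters and scripted permeation events
  total_time <- (params$n_frames - 1) * params$dt
  margin <- 4 * params$dt
  n_events <- if (params$permeation_rate > 0 && total_time > 0) {
    stats::rpois(1, params$permeation_rate * total_time)
  } else {
    0L
  }
  if (n_events > 0 && total_time <= 2 * margin) {
    stop("trajectory too short for scripted permeation events", call. = FALSE)
  }
  if (n_events > params$water_count) {
    stop("water_count too small for the drawn number of permeation events",
      call. = FALSE
    )
  }
  events <- tibble::tibble(
    water = seq_len(n_events),
    time = sort(stats::runif(n_events, margin, total_time - margin)),
    direction = sample(c("-z", "+z"), n_events, replace = TRUE)
  )
  nw <- params$water_count
  water_tbl <- NULL
  if (nw > 0) {
    side <- rep(c(1, -1), length.out = nw)
    if (n_events > 0) {
      side[events$water] <- ifelse(events$direction == "-z", 1, -1)
    }
    wz <- side * stats::runif(nw, params$pp_thickness / 2 + 0.4, params$pp_thickness / 2 + 1.2)
    wz[seq_len(n_events)] <- side[seq_len(n_events)] * (params$pp_thickness / 2 + 0.8)
    water_tbl <- data.frame(
      role = "water", tail = NA_integer_, carbon = NA_integer_,
      x = stats::runif(nw, 0, L), y = stats::runif(nw, 0, L), z = wz,
      lipid_id = NA_integer_, species = "SOL", headgroup = NA_character_,
      leaflet = "none"
    )
  }

  # protein cylinder
  prot_tbl <- NULL
  if (!is.null(prot)) {
    zlev <- seq(-params$pp_thickness / 2, params$pp_thickness / 2, by = 0.4)
    nphi <- max(8L, round(2 * pi * prot$radius / 0.4))
    phis <- seq(0, 2 * pi, length.out = nphi + 1)[-(nphi + 1)]
    pg <- expand.grid(z = zlev, phi = phis)
    prot_tbl <- data.frame(
      role = "protein_atom", tail = NA_integer_, carbon = NA_integer_,
      x = center[1] + prot$radius * cos(pg$phi),
      y = center[2] + prot$radius * sin(pg$phi),
      z = pg$z,
      lipid_id = NA_integer_, species = "PROT", headgroup = NA_character_,
      leaflet = "none"
    )
  }

  base <- rbind(lipid_tbl, water_tbl, prot_tbl)
  base$id <- seq_len(nrow(base))
  if (nrow(events) > 0) {
    events$water_id <- base$id[base$role == "water"][events$water]
  } else {
    events$water_id <- integer(0)
  }
  base$residue <- NA_integer_
  base$chain <- NA_character_
  if (!is.null(prot_tbl)) {
    pidx <- base$role == "protein_atom"
    base$residue[pidx] <- seq_len(sum(pidx))
    base$chain[pidx] <- "A"
  }
  particles <- tibble::as_tibble(base[, c(
    "id", "lipid_id", "species", "headgroup", "leaflet", "role",
    "tail", "carbon", "residue", "chain"
  )])

  # per-lipid Brownian lateral displacements
  nf <- params$n_frames
  lip_ids <- seq_len(2L * n)
  lip_species <- rep(species_at, 2)
  D_nm <- params$D_map[lip_species] * 1e5 # cm^2/s -> nm^2/ns
  sd_step <- sqrt(2 * D_nm * params$dt)
  disp_x <- matrix(0, 2 * n, nf)
  disp_y <- matrix(0, 2 * n, nf)
  if (nf > 1) {
    disp_x[, -1] <- t(apply(
      matrix(stats::rnorm((nf - 1) * 2 * n, 0, sd_step), nrow = 2 * n), 1, cumsum
    ))
    disp_y[, -1] <- t(apply(
      matrix(stats::rnorm((nf - 1) * 2 * n, 0, sd_step), nrow = 2 * n), 1, cumsum
    ))
  }

  # scripted water z paths
  times <- (seq_len(nf) - 1) * params$dt
  water_z <- NULL
  if (nw > 0) {
    w0 <- water_tbl$z
    water_z <- matrix(rep(w0, nf), nrow = nw)
    if (nf > 1) {
      jit <- matrix(stats::rnorm(nw * nf, 0, 0.05), nrow = nw)
      water_z <- water_z + jit
      # keep non-permeators strictly outside the slab
      lim <- params$pp_thickness / 2 + 0.15
      water_z[] <- ifelse(abs(water_z) < lim, sign(water_z) * lim, water_z)
    }
    if (n_events > 0) {
      half_cross <- 3 * params$dt
      for (k in seq_len(n_events)) {
        wid <- events$water[k]
        z0 <- w0[wid]
        frac <- (times - (events$time[k] - half_cross)) / (2 * half_cross)
        frac <- pmin(pmax(frac, 0), 1)
        water_z[wid, ] <- z0 * (1 - 2 * frac)
      }
    }
  }

  # assemble frames
  base_xyz <- as.matrix(base[, c("x", "y", "z")])
  base_xyz[, 3] <- base_xyz[, 3] + box_z / 2
  lip_row_idx <- which(!is.na(base$lipid_id))
  lip_of_row <- base$lipid_id[lip_row_idx]
  wat_row_idx <- which(base$role == "water")
  xyz <- vector("list", nf)
  for (f in seq_len(nf)) {
    mf <- base_xyz
    mf[lip_row_idx, 1] <- mf[lip_row_idx, 1] + disp_x[lip_of_row, f]
    mf[lip_row_idx, 2] <- mf[lip_row_idx, 2] + disp_y[lip_of_row, f]
    if (nw > 0) mf[wat_row_idx, 3] <- water_z[, f] + box_z / 2
    xyz[[f]] <- mf
  }

  traj <- ple_trajectory(
    particles, xyz, times,
    box = matrix(rep(c(L, L, box_z), each = nf), nrow = nf),
    resolution = "AA", temperature = NA_real_
  )

  gt <- structure(
    list(
      params = params,
      box = c(L, L, box_z),
      counts = counts,
      species_by_lipid = tibble::tibble(
        lipid_id = lip_ids, species = lip_species,
        leaflet = rep(c("upper", "lower"), each = n)
      ),
      permeation_events = events,
      n_dihedrals = length(trans_drawn),
      n_trans_drawn = sum(trans_drawn),
      site_xy = sites,
      center = center
    ),
    class = "ple_ground_truth"
  )
  list(trajectory = traj, ground_truth = gt)
}

#' Summarise the recoverable ground truth of a synthetic trajectory
#'
#' @param gt The `ground_truth` element returned by [generate_bilayer()].
#' @return A JSON-serialisable list of the generator inputs and realised
#'   quantities, with units stated in the names.
#' @export
ground_truth_report <- function(gt) {
  stopifnot(inherits(gt, "ple_ground_truth"))
  p <- gt$params
  list(
    composition = attr(p$composition, "composition_name"),
    n_per_leaflet = p$n_per_leaflet,
    target_apl_nm2 = p$target_apl,
    pp_thickness_nm = p$pp_thickness,
    hydrophobic_offset_nm = p$hydrophobic_offset,
    p_trans = p$p_trans,
    D_map_cm2_s = as.list(p$D_map),
    n_frames = p$n_frames,
    dt_ns = p$dt,
    box_nm = gt$box,
    counts_per_leaflet = stats::setNames(
      as.list(gt$counts$count), gt$counts$species
    ),
    n_permeation_events = nrow(gt$permeation_events),
    permeation_event_times_ns = gt$permeation_events$time,
    permeation_event_directions = gt$permeation_events$direction,
    n_dihedrals = gt$n_dihedrals,
    n_trans_drawn = gt$n_trans_drawn,
    seed = p$seed
  )
}
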