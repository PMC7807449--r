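# GRO / PDB coordinate I/O. Role tags survive round trips through a
# documented atom-naming convention, so no force-field atom names are
# needed:
#   headgroup_ref   "PO4" (PE/PG) or "PO41"/"PO42" (CL)
#   glycerol_ref    "GL0"
#   tail atoms      "C<carbon><tail letter>", tails lettered A-D; carbon 1
#                   is the carbonyl, carbon 2 the first methylene, the
#                   last carbon the terminal methyl
#   water           atom "W", residue "SOL"
#   ion             atom/residue "ION"
#   protein         atom "BB", residue "PROT", residue number = residue id
# Cardiolipin residue names are shortened to 5 characters by replacing
# "-CL" with "X" (e.g. MPPO-CL -> MPPOX).

res_name_of <- function(species, role) {
  out <- species
  out[grepl("-CL$", out)] <- sub("-CL$", "X", out[grepl("-CL$", out)])
  out[role == "water"] <- "SOL"
  out[role == "ion"] <- "ION"
  out[role == "protein_atom"] <- "PROT"
  out
}

atom_name_of <- function(particles) {
  role <- particles$role
  nm <- character(nrow(particles))
  tl <- c("A", "B", "C", "D")
  is_tail <- !is.na(particles$carbon)
  nm[is_tail] <- sprintf("C%d%s", particles$carbon[is_tail], tl[particles$tail[is_tail]])
  hg <- role == "headgroup_ref"
  cl_hg <- hg & particles$headgroup %in% "CL"
  nm[hg & !cl_hg] <- "PO4"
  if (any(cl_hg)) {
    # number the two CL phosphates per lipid in order of appearance
    ord <- stats::ave(seq_len(nrow(particles))[cl_hg],
      particles$lipid_id[cl_hg],
      FUN = seq_along
    )
    nm[cl_hg] <- sprintf("PO4%d", ord)
  }
  nm[role == "glycerol_ref"] <- "GL0"
  nm[role == "water"] <- "W"
  nm[role == "ion"] <- "ION"
  nm[role == "protein_atom"] <- "BB"
  nm
}

#' Write a trajectory or frame as (multi-frame) GRO
#'
#' @param x A [ple_trajectory()] or [bilayer_frame()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(x, path) {
  if (inherits(x, "bilayer_frame")) {
    frames <- list(x)
    boxes <- list(frame_box(x))
    times <- attr(x, "time") %||% 0
  } else {
    frames <- lapply(seq_len(n_frames(x)), function(f) traj_frame(x, f))
    boxes <- lapply(seq_len(n_frames(x)), function(f) x$box[f, ])
    times <- x$times
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    resid <- dplyr::coalesce(fr$lipid_id, fr$residue, fr$id)
    lines <- sprintf(
      "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
      resid %% 100000L,
      substr(res_name_of(fr$species, fr$role), 1, 5),
      substr(atom_name_of(fr), 1, 5),
      fr$id %% 100000L,
      fr$x, fr$y, fr$z
    )
    writeLines(c(
      sprintf("synthetic PLE bilayer t= %.4f", times[f]),
      sprintf("%5d", nrow(fr)),
      lines,
      sprintf("%10.5f%10.5f%10.5f", boxes[[f]][1], boxes[[f]][2], boxes[[f]][3])
    ), con)
  }
  invisible(path)
}

decode_particles <- function(resid, resname, atom, id) {
  n <- length(resid)
  role <- rep(NA_character_, n)
  tail <- rep(NA_integer_, n)
  carbon <- rep(NA_integer_, n)
  species <- rep(NA_character_, n)
  headgroup <- rep(NA_character_, n)
  lipid_id <- rep(NA_integer_, n)
  residue <- rep(NA_integer_, n)
  chain <- rep(NA_character_, n)

  is_w <- resname == "SOL" | atom == "W"
  is_ion <- resname == "ION"
  is_prot <- resname == "PROT"
  role[is_w] <- "water"
  species[is_w] <- "SOL"
  role[is_ion] <- "ion"
  species[is_ion] <- "ION"
  role[is_prot] <- "protein_atom"
  species[is_prot] <- "PROT"
  residue[is_prot] <- resid[is_prot]
  chain[is_prot] <- "A"

  is_lip <- !(is_w | is_ion | is_prot)
  lipid_id[is_lip] <- resid[is_lip]
  sp <- resname[is_lip]
  sp <- ifelse(grepl("X$", sp) & nchar(sp) == 5, paste0(substr(sp, 1, 4), "-CL"), sp)
  species[is_lip] <- sp
  headgroup[is_lip] <- ifelse(
    grepl("-CL$", sp), "CL", substr(sp, nchar(sp) - 1, nchar(sp))
  )
  a <- atom
  hg <- is_lip & grepl("^PO4", a)
  role[hg] <- "headgroup_ref"
  role[is_lip & a == "GL0"] <- "glycerol_ref"
  tail_at <- is_lip & grepl("^C[0-9]+[A-D]$", a)
  tail[tail_at] <- match(sub("^C[0-9]+", "", a[tail_at]), c("A", "B", "C", "D"))
  carbon[tail_at] <- as.integer(sub("^C([0-9]+)[A-D]$", "\\1", a[tail_at]))
  # roles along the tail; terminal methyl = largest carbon of its tail
  role[tail_at & carbon == 1] <- "carbonyl"
  role[tail_at & carbon == 2] <- "first_methylene"
  role[tail_at & carbon > 2] <- "tail_carbon"
  if (any(tail_at)) {
    key <- paste(lipid_id, tail, sep = "/")
    mx <- tapply(carbon[tail_at], key[tail_at], max)
    is_term <- tail_at & carbon > 2 & carbon == mx[key]
    role[is_term] <- "terminal_methyl"
  }
  tibble::tibble(
    id = id, lipid_id = lipid_id, species = species, headgroup = headgroup,
    leaflet = NA_character_, role = role, tail = tail, carbon = carbon,
    residue = residue, chain = chain
  )
}

# leaflet from the lipid's first headgroup/glycerol reference z relative
# to the box midplane
infer_leaflet <- function(particles, z, box_z) {
  ref <- particles$role %in% c("headgroup_ref", "glycerol_ref")
  ref_z <- tapply(z[ref], particles$lipid_id[ref], function(v) v[1])
  up <- names(ref_z)[ref_z > box_z / 2]
  out <- rep(NA_character_, nrow(particles))
  lip <- !is.na(particles$lipid_id)
  out[lip] <- ifelse(particles$lipid_id[lip] %in% as.integer(up), "upper", "lower")
  out[!lip] <- "none"
  out
}

#' Read a (multi-frame) GRO file
#'
#' Positions are wrapped into the box on read; role tags are recovered
#' from the packaged atom-naming convention and leaflets are inferred from
#' the headgroup positions relative to the box midplane.
#'
#' @param path GRO file path.
#' @param resolution `"AA"` or `"CG"`.
#' @param temperature Trajectory temperature (K), if known.
#' @return A [ple_trajectory()].
#' @export
read_gro <- function(path, resolution = "AA", temperature = NA_real_) {
  lines <- readLines(path)
  pos <- 1L
  xyz <- list()
  boxes <- list()
  times <- numeric(0)
  particles <- NULL
  while (pos <= length(lines)) {
    title <- lines[pos]
    natoms <- as.integer(trimws(lines[pos + 1L]))
    at <- lines[pos + 1L + seq_len(natoms)]
    boxline <- scan(text = lines[pos + 2L + natoms], quiet = TRUE)
    t <- if (grepl("t=", title)) {
      as.numeric(sub(".*t=\\s*([-0-9.eE+]+).*", "\\1", title))
    } else {
      length(times)
    }
    resid <- as.integer(substr(at, 1, 5))
    resname <- trimws(substr(at, 6, 10))
    atname <- trimws(substr(at, 11, 15))
    atid <- as.integer(substr(at, 16, 20))
    m <- cbind(
      as.numeric(substr(at, 21, 28)),
      as.numeric(substr(at, 29, 36)),
      as.numeric(substr(at, 37, 44))
    )
    if (is.null(particles)) {
      particles <- decode_particles(resid, resname, atname, atid)
      particles$leaflet <- infer_leaflet(particles, m[, 3], boxline[3])
    }
    xyz[[length(xyz) + 1L]] <- m
    boxes[[length(boxes) + 1L]] <- boxline[1:3]
    times <- c(times, t)
    pos <- pos + 3L + natoms
  }
  ple_trajectory(
    particles, xyz, times, do.call(rbind, boxes),
    resolution = resolution, temperature = temperature
  )
}

#' Read a PDB coordinate file
#'
#' Minimal PDB reader for ATOM/HETATM records with a CRYST1 box;
#' coordinates are converted from Angstrom to nm and particles decoded
#' with the same naming convention as [read_gro()]. Multiple MODEL blocks
#' become trajectory frames.
#'
#' @inheritParams read_gro
#' @return A [ple_trajectory()].
#' @export
read_pdb <- function(path, resolution = "AA", temperature = NA_real_) {
  lines <- readLines(path)
  cry <- lines[grepl("^CRYST1", lines)]
  if (length(cry) == 0) stop("PDB lacks a CRYST1 box record", call. = FALSE)
  box <- as.numeric(c(
    substr(cry[1], 7, 15), substr(cry[1], 16, 24), substr(cry[1], 25, 33)
  )) / 10
  at_lines <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- which(grepl("^MODEL", lines))
  frame_of <- if (length(model_starts) == 0) {
    rep(1L, sum(at_lines))
  } else {
    findInterval(which(at_lines), model_starts)
  }
  at <- lines[at_lines]
  atname <- trimws(substr(at, 13, 16))
  resname <- trimws(substr(at, 18, 21))
  chain <- trimws(substr(at, 22, 22))
  resid <- as.integer(substr(at, 23, 26))
  m <- cbind(
    as.numeric(substr(at, 31, 38)),
    as.numeric(substr(at, 39, 46)),
    as.numeric(substr(at, 47, 54))
  ) / 10
  first <- frame_of == frame_of[1]
  particles <- decode_particles(
    resid[first], resname[first], atname[first],
    seq_len(sum(first))
  )
  pc <- chain[first]
  particles$chain[particles$role == "protein_atom"] <-
    pc[particles$role == "protein_atom"]
  particles$leaflet <- infer_leaflet(particles, m[first, 3], box[3])
  nfr <- length(unique(frame_of))
  xyz <- lapply(sort(unique(frame_of)), function(f) m[frame_of == f, , drop = FALSE])
  ple_trajectory(
    particles, xyz, seq_len(nfr) - 1,
    matrix(rep(box, each = nfr), nrow = nfr),
    resolution = resolution, temperature = temperature
  )
}
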