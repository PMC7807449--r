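# Builders for small hand-made frames used across the tests.

# a frame of bare headgroup reference particles on given xy/z positions
make_head_frame <- function(x, y, z, leaflet, box,
                            species = "POPE", headgroup = "PE") {
  n <- length(x)
  bilayer_frame(
    tibble::tibble(
      id = seq_len(n), lipid_id = seq_len(n),
      species = rep_len(species, n), headgroup = rep_len(headgroup, n),
      leaflet = rep_len(leaflet, n), role = "headgroup_ref",
      x = x, y = y, z = z
    ),
    box = box
  )
}

# a frame holding arbitrary particles given as a tibble
make_frame <- function(particles, box) bilayer_frame(particles, box = box)

# brute-force O(N^2) minimum-image pair distance
brute_dist <- function(a, b, box) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- a[i, ] - b[j, ]
      d <- d - box * round(d / box)
      out[i, j] <- sqrt(sum(d^2))
    }
  }
  out
}

# quick single-lipid trajectory wrapper around coordinates over frames
make_traj <- function(particles, xyz_list, times, box, resolution = "AA") {
  ple_trajectory(particles, xyz_list, times, box, resolution = resolution)
}

default_sim <- function(...) {
  args <- list(...)
  # waterless test systems script no crossings unless a rate is requested
  if (is.null(args$permeation_rate) &&
    (!is.null(args$water_count) && args$water_count == 0)) {
    args$permeation_rate <- 0
  }
  generate_bilayer(do.call(synthetic_params, args))
}
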