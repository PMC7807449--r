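test_that("a single-species membrane has enrichment exactly 1", {
  set.seed(12)
  fr <- make_head_frame(
    x = runif(40, 0, 6), y = runif(40, 0, 6), z = 5,
    leaflet = "upper", box = c(6, 6, 8)
  )
  e <- neighbor_enrichment(fr, cutoff = 1.2)
  expect_equal(e$enrichment, 1)
})

test_that("a hand-placed toy layout matches the brute-force definition", {
  pts <- rbind(
    c(1.0, 1.0), c(1.6, 1.0), c(3.0, 3.0),
    c(3.6, 3.0), c(1.0, 3.2), c(3.2, 1.2)
  )
  hg <- c("PE", "PE", "PE", "PG", "PG", "CL")
  parts <- tibble::tibble(
    id = 1:6, lipid_id = 1:6,
    species = c("POPE", "POPE", "POPE", "MMPG", "MMPG", "MPPO-CL"),
    headgroup = hg, leaflet = "upper",
    role = ifelse(hg == "CL", "glycerol_ref", "headgroup_ref"),
    x = pts[, 1], y = pts[, 2], z = 3
  )
  box <- c(4.5, 4.5, 6)
  fr <- make_frame(parts, box)
  cutoff <- 1.5
  # brute force straight from the definition
  d <- brute_dist(cbind(pts, 3), cbind(pts, 3), box)
  diag(d) <- Inf
  contact <- d <= cutoff
  classes <- c("CL", "PE", "PG")
  expected <- expand.grid(
    center = classes, neighbor = classes,
    stringsAsFactors = FALSE
  )
  expected$enrichment <- mapply(function(X, Y) {
    per_X <- mean(rowSums(contact[hg == X, hg == Y, drop = FALSE]))
    per_any <- mean(rowSums(contact[, hg == Y, drop = FALSE]))
    per_X / per_any
  }, expected$center, expected$neighbor)
  got <- neighbor_enrichment(fr, cutoff = cutoff)
  merged <- dplyr::inner_join(got, expected,
    by = c("center", "neighbor"), suffix = c("", "_bf")
  )
  expect_equal(merged$enrichment, merged$enrichment_bf)
})

test_that("an ideally mixed membrane has enrichment 1 within sampling error", {
  per_seed <- lapply(1:12, function(s) {
    sim <- default_sim(
      n_per_leaflet = 128, n_frames = 4, water_count = 0,
      demixing_strength = 0, seed = 300 + s
    )
    neighbor_enrichment(sim$trajectory, cutoff = 0.9)
  })
  pooled <- dplyr::bind_rows(per_seed) |>
    dplyr::group_by(center, neighbor) |>
    dplyr::summarise(enrichment = mean(enrichment), .groups = "drop")
  # tolerance follows the pair-count statistics of each entry: PE pairs are
  # abundant (~150 per frame), PG pairs ~20, CL pairs a handful, so the
  # 12-seed means carry ~0.01 / 0.04 / 0.1 standard errors respectively
  tol_of <- function(center, neighbor) {
    if (center == "CL" || neighbor == "CL") 0.35
    else if (center == "PG" || neighbor == "PG") 0.12
    else 0.05
  }
  for (k in seq_len(nrow(pooled))) {
    expect_lt(
      abs(pooled$enrichment[k] - 1),
      tol_of(pooled$center[k], pooled$neighbor[k])
    )
  }
})

test_that("like-neighbor enrichment grows with demixing strength", {
  self_enr <- function(d, s) {
    sim <- default_sim(
      n_per_leaflet = 128, n_frames = 2, water_count = 0,
      demixing_strength = d, seed = s
    )
    e <- neighbor_enrichment(sim$trajectory, cutoff = 0.9)
    e[e$center == e$neighbor, c("center", "enrichment")]
  }
  e0 <- dplyr::bind_rows(lapply(1:3, function(s) self_enr(0, 400 + s)))
  e5 <- dplyr::bind_rows(lapply(1:3, function(s) self_enr(0.5, 410 + s)))
  e1 <- dplyr::bind_rows(lapply(1:3, function(s) self_enr(1, 420 + s)))
  m <- function(e) mean(e$enrichment)
  expect_lt(m(e0), m(e5))
  expect_lt(m(e5), m(e1))
  # fully demixed: every class is self-enriched
  by_class <- e1 |>
    dplyr::group_by(center) |>
    dplyr::summarise(enrichment = mean(enrichment))
  expect_true(all(by_class$enrichment > 1))
})

test_that("single-linkage clustering obeys transitivity and isolation", {
  mk <- function(pts) {
    tibble::tibble(
      id = seq_len(nrow(pts)), lipid_id = seq_len(nrow(pts)),
      species = "MPPO-CL", headgroup = "CL", leaflet = "upper",
      role = "glycerol_ref", x = pts[, 1], y = pts[, 2], z = 3
    )
  }
  # all far apart: all monomers
  far <- make_frame(mk(rbind(c(1, 1), c(4, 1), c(1, 4), c(4, 4))), c(8, 8, 6))
  d_far <- cluster_size_distribution(far, "CL", cutoff = 0.35)
  expect_equal(d_far$size, 1L)
  expect_equal(d_far$n_clusters, 4L)
  expect_equal(attr(d_far, "fractions")[["monomer"]], 1)
  # chain a-b-c joined only through b
  chain <- make_frame(mk(rbind(c(1, 1), c(1.3, 1), c(1.6, 1))), c(8, 8, 6))
  d_chain <- cluster_size_distribution(chain, "CL", cutoff = 0.32)
  expect_equal(d_chain$size, 3L)
  expect_equal(d_chain$n_clusters, 1L)
  expect_equal(attr(d_chain, "fractions")[["trimer"]], 1)
})

test_that("clustering equals an igraph components oracle on random layouts", {
  set.seed(71)
  for (rep in 1:4) {
    n <- 50
    pts <- cbind(runif(n, 0, 7), runif(n, 0, 7))
    parts <- tibble::tibble(
      id = seq_len(n), lipid_id = seq_len(n), species = "MPPO-CL",
      headgroup = "CL", leaflet = sample(c("upper", "lower"), n, TRUE),
      role = "glycerol_ref", x = pts[, 1], y = pts[, 2],
      z = ifelse(sample(c(TRUE, FALSE), n, TRUE), 5, 3)
    )
    fr <- make_frame(parts, c(7, 7, 8))
    cutoff <- 0.9
    got <- cluster_size_distribution(fr, "CL", cutoff)
    # independent oracle: adjacency + graph components
    d <- brute_dist(
      as.matrix(parts[, c("x", "y", "z")]),
      as.matrix(parts[, c("x", "y", "z")]), c(7, 7, 8)
    )
    adj <- d <= cutoff
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    sizes <- as.integer(table(igraph::components(g)$membership))
    oracle <- sort(sizes)
    expanded <- rep(got$size, got$n_clusters)
    expect_equal(sort(expanded), oracle)
  }
})

test_that("cluster fractions sum to one over the molecules", {
  sim <- default_sim(n_per_leaflet = 64, n_frames = 1, water_count = 0, seed = 88)
  fr <- traj_frame(sim$trajectory, 1)
  dist <- cluster_size_distribution(fr, "CL", cutoff = 0.35)
  expect_equal(sum(attr(dist, "fractions")), 1)
  expect_equal(
    sum(dist$size * dist$n_clusters),
    dplyr::n_distinct(fr$lipid_id[fr$headgroup == "CL"])
  )
  expect_error(cluster_size_distribution(fr, "XX", 0.35), "absent")
})

test_that("density maps conserve counts and flatten for uniform systems", {
  sim <- default_sim(n_per_leaflet = 100, n_frames = 3, water_count = 0, seed = 93)
  dm <- density_map_2d(sim$trajectory, "PE", bins = c(8, 8))
  box <- sim$trajectory$box[1, ]
  bin_area <- box[1] * box[2] / 64
  n_pe_upper <- sim$ground_truth$species_by_lipid |>
    dplyr::filter(leaflet == "upper", grepl("PE$", species)) |>
    nrow()
  integral <- sum(dm$density[dm$leaflet == "upper"]) * bin_area
  expect_equal(integral, n_pe_upper, tolerance = 1e-9)
  expect_error(density_map_2d(sim$trajectory, "PE", bins = 1), "at least 2")
})

test_that("demixed placement shows up as density hot spots", {
  sim <- default_sim(
    n_per_leaflet = 128, n_frames = 1, water_count = 0,
    demixing_strength = 1, seed = 95
  )
  dm <- density_map_2d(sim$trajectory, "PG", bins = c(6, 6))
  up <- dm$density[dm$leaflet == "upper"]
  # clustered species concentrate: strong contrast between hot and empty bins
  expect_gt(max(up), 2 * mean(up))
  expect_true(any(up == 0))
})
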