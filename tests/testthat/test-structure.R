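test_that("box APL is area over leaflet count", {
  fr <- make_head_frame(
    x = runif(20, 0, 10), y = runif(20, 0, 10), z = 5,
    leaflet = "upper", box = c(10, 10, 8)
  )
  expect_equal(apl_box(fr, 160), 0.625)
  expect_error(apl_box(fr, 0), "positive")
})

test_that("periodic Voronoi conserves the box area to machine precision", {
  set.seed(31)
  sim <- default_sim(n_per_leaflet = 36, n_frames = 1, water_count = 0, seed = 31)
  fr <- traj_frame(sim$trajectory, 1)
  ap <- apl_voronoi(fr)
  box_area <- attr(ap, "box_area")
  for (lf in c("upper", "lower")) {
    expect_equal(sum(ap$area[ap$leaflet == lf]), box_area, tolerance = 1e-9)
  }
  expect_true(all(ap$area > 0))
})

test_that("a perfect square lattice gives equal Voronoi cells", {
  g <- expand.grid(x = (0:4 + 0.5), y = (0:4 + 0.5))
  ar <- plext:::voronoi_areas_periodic(cbind(g$x, g$y), c(5, 5))
  expect_equal(ar, rep(1, 25), tolerance = 1e-9)
})

test_that("Voronoi areas of a mixed PE/CL layout match Monte-Carlo sampling", {
  # 4 single-site PE lipids plus one CL contributing two generator sites
  pts <- rbind(
    c(1, 1), c(3.5, 1.2), c(1.2, 3.4), c(3.3, 3.3), # PE phosphates
    c(2.2, 2.4), c(2.6, 2.0) # the two CL phosphates
  )
  box <- c(4.5, 4.5)
  parts <- tibble::tibble(
    id = 1:6, lipid_id = c(1:4, 5L, 5L),
    species = c(rep("POPE", 4), "MPPO-CL", "MPPO-CL"),
    headgroup = c(rep("PE", 4), "CL", "CL"),
    leaflet = "upper", role = "headgroup_ref",
    x = pts[, 1], y = pts[, 2], z = 2
  )
  fr <- make_frame(parts, box = c(box, 6))
  ap <- apl_voronoi(fr)
  # Monte-Carlo point-sampling oracle
  set.seed(99)
  m <- 4e5
  smp <- cbind(runif(m, 0, box[1]), runif(m, 0, box[2]))
  d <- plext:::pdist_min_image(smp, pts, box)
  near <- max.col(-d)
  mc_area <- tabulate(near, 6) / m * prod(box)
  mc_per_lipid <- c(mc_area[1:4], mc_area[5] + mc_area[6])
  got <- ap$area[order(ap$lipid_id)]
  expect_equal(got, mc_per_lipid, tolerance = 0.01)
  # CL counted once, with the sum of its two cells
  expect_equal(nrow(ap), 5)
})

test_that("curved APL ratio is 1 for flat leaflets and matches the sinusoid integral", {
  g <- expand.grid(x = (seq_len(30) - 0.5) / 3, y = (seq_len(30) - 0.5) / 3)
  flat <- dplyr::bind_rows(
    make_head_frame(g$x, g$y, 6, "upper", c(10, 10, 8))[, ],
    make_head_frame(g$x, g$y, 2, "lower", c(10, 10, 8))[, ]
  )
  flat$lipid_id <- seq_len(nrow(flat))
  flat$id <- seq_len(nrow(flat))
  fr <- make_frame(flat, c(10, 10, 8))
  expect_equal(curved_apl_ratio(fr, grid = c(20, 20)), 1, tolerance = 1e-12)

  A <- 0.3
  L <- 10
  k <- 2 * pi / L
  n <- 40
  g2 <- expand.grid(x = (seq_len(n) - 0.5) * L / n, y = (seq_len(n) - 0.5) * L / n)
  wavy <- tibble::tibble(
    id = seq_len(2 * nrow(g2)), lipid_id = seq_len(2 * nrow(g2)),
    species = "POPE", headgroup = "PE",
    leaflet = rep(c("upper", "lower"), each = nrow(g2)),
    role = "headgroup_ref",
    x = rep(g2$x, 2), y = rep(g2$y, 2),
    z = rep(A * sin(k * g2$x), 2) + rep(c(6, 2), each = nrow(g2))
  )
  fr2 <- make_frame(wavy, c(L, L, 8))
  exact <- stats::integrate(
    function(x) sqrt(1 + (A * k * cos(k * x))^2), 0, L
  )$value / L
  expect_equal(curved_apl_ratio(fr2, grid = c(50, 50)), exact, tolerance = 0.01)
  expect_error(curved_apl_ratio(fr2, grid = c(1, 1)), "at least 2")
})

test_that("volume per lipid subtracts solvent volumes", {
  mk <- function(n_lip, n_wat, box) {
    parts <- dplyr::bind_rows(
      tibble::tibble(
        id = seq_len(n_lip), lipid_id = seq_len(n_lip), species = "POPE",
        headgroup = "PE", leaflet = "upper", role = "headgroup_ref",
        x = runif(n_lip, 0, box[1]), y = runif(n_lip, 0, box[2]), z = box[3] / 2
      ),
      if (n_wat > 0) {
        tibble::tibble(
          id = n_lip + seq_len(n_wat), lipid_id = NA_integer_, species = "SOL",
          headgroup = NA_character_, leaflet = "none", role = "water",
          x = runif(n_wat, 0, box[1]), y = runif(n_wat, 0, box[2]), z = 0.2
        )
      }
    )
    make_frame(parts, box)
  }
  set.seed(1)
  expect_equal(volume_per_lipid(mk(800, 0, c(10, 10, 10)), v_water = 0.03), 1.25)
  expect_equal(
    volume_per_lipid(mk(550, 10000, c(10, 10, 10)), v_water = 0.030),
    (1000 - 300) / 550
  )
  expect_error(
    volume_per_lipid(mk(5, 10000, c(2, 2, 2)), v_water = 0.03),
    "negative"
  )
})

test_that("thickness grid reads flat phosphate planes exactly", {
  set.seed(7)
  n <- 40
  up <- make_head_frame(runif(n, 0, 8), runif(n, 0, 8), 6.05, "upper", c(8, 8, 8))
  lo <- make_head_frame(runif(n, 0, 8), runif(n, 0, 8), 1.95, "lower", c(8, 8, 8))
  both <- dplyr::bind_rows(up[, ], lo[, ])
  both$id <- seq_len(nrow(both))
  both$lipid_id <- seq_len(nrow(both))
  fr <- make_frame(both, c(8, 8, 8))
  tg <- thickness_grid(fr)
  expect_equal(nrow(tg), 225)
  expect_equal(tg$thickness, rep(4.10, 225))
})

test_that("generator phosphate thickness is recovered within 0.02 nm", {
  means <- vapply(1:6, function(s) {
    sim <- default_sim(
      n_per_leaflet = 64, n_frames = 1, water_count = 0,
      pp_thickness = 3.9, z_jitter = 0.05, seed = s
    )
    mean(thickness_grid(traj_frame(sim$trajectory, 1))$thickness)
  }, numeric(1))
  expect_lt(abs(mean(means) - 3.9), 0.02)
})

test_that("hydrophobic-boundary thickness sits below the phosphate thickness", {
  sim <- default_sim(
    n_per_leaflet = 36, n_frames = 1, water_count = 0,
    pp_thickness = 3.9, hydrophobic_offset = 0.45, seed = 8
  )
  fr <- traj_frame(sim$trajectory, 1)
  hp <- mean(thickness_grid(fr, boundary = "phosphate")$thickness)
  hh <- mean(thickness_grid(fr, boundary = "hydrophobic")$thickness)
  # boundary placed hydrophobic_offset below each head
  expect_equal(hp - hh, 2 * 0.45, tolerance = 0.05)
})

test_that("thickness grid is invariant under translation by a cell pitch", {
  sim <- default_sim(n_per_leaflet = 36, n_frames = 1, water_count = 0, seed = 13)
  fr <- traj_frame(sim$trajectory, 1)
  box <- attr(fr, "box")
  tg1 <- thickness_grid(fr, 15, 15)
  shifted <- fr
  shifted$x <- (fr$x + box[1] / 15) %% box[1]
  fr2 <- make_frame(shifted, box)
  tg2 <- thickness_grid(fr2, 15, 15)
  expect_equal(sort(tg1$thickness), sort(tg2$thickness), tolerance = 1e-9)
})

test_that("interdigitation equals the brute-force pair count and excludes terminal methyls", {
  # two opposing 4-carbon tails placed so exactly 3 cross pairs are in range
  tail_z_up <- c(2.4, 2.2, 2.05, 1.9) # carbons 1..4, last is terminal methyl
  tail_z_lo <- c(1.6, 1.8, 1.95, 2.1)
  parts <- tibble::tibble(
    id = 1:8,
    lipid_id = c(rep(1L, 4), rep(2L, 4)),
    species = "POPE", headgroup = "PE",
    leaflet = rep(c("upper", "lower"), each = 4),
    role = rep(c("carbonyl", "first_methylene", "tail_carbon", "terminal_methyl"), 2),
    tail = 1L, carbon = rep(1:4, 2),
    x = 2, y = 2, z = c(tail_z_up, tail_z_lo)
  )
  fr <- make_frame(parts, c(4, 4, 4))
  cutoff <- 0.35
  # brute-force count over non-terminal carbons
  up <- parts[parts$leaflet == "upper" & parts$role != "terminal_methyl", ]
  lo <- parts[parts$leaflet == "lower" & parts$role != "terminal_methyl", ]
  bf <- sum(brute_dist(
    as.matrix(up[, c("x", "y", "z")]), as.matrix(lo[, c("x", "y", "z")]),
    c(4, 4, 4)
  ) <= cutoff)
  expect_equal(bf, 3)
  expect_equal(interdigitation(fr, cutoff), 3 / 2)

  # separated leaflets give zero
  far <- parts
  far$z <- ifelse(far$leaflet == "upper", far$z + 1, far$z - 1)
  expect_equal(interdigitation(make_frame(far, c(4, 4, 6)), cutoff), 0)

  # contacts only between terminal methyls count zero
  onlyterm <- parts
  onlyterm$z <- ifelse(onlyterm$leaflet == "upper",
    onlyterm$z + 0.5, onlyterm$z - 0.5
  )
  onlyterm$z[onlyterm$role == "terminal_methyl"] <- 2
  expect_equal(interdigitation(make_frame(onlyterm, c(4, 4, 6)), cutoff), 0)
})

test_that("interdigitation matches an O(N^2) oracle on generated frames", {
  sim <- default_sim(n_per_leaflet = 9, n_frames = 1, water_count = 0, seed = 21)
  fr <- traj_frame(sim$trajectory, 1)
  box <- attr(fr, "box")
  tails <- fr[fr$role %in% c("carbonyl", "first_methylene", "tail_carbon"), ]
  up <- tails[tails$leaflet == "upper", ]
  lo <- tails[tails$leaflet == "lower", ]
  n_tails <- nrow(dplyr::distinct(fr[!is.na(fr$tail), ], lipid_id, tail))
  for (cutoff in c(0.35, 0.8, 1.5)) {
    bf <- sum(brute_dist(
      as.matrix(up[, c("x", "y", "z")]), as.matrix(lo[, c("x", "y", "z")]), box
    ) <= cutoff) / n_tails
    expect_equal(interdigitation(fr, cutoff), bf)
  }
})

test_that("area compressibility evaluates the fluctuation formula", {
  expect_equal(compressibility_from_stats(0.62, 0.002, 288, 310), 0.217,
    tolerance = 5e-4
  )
  # quadratic dependence on the fluctuation amplitude
  expect_equal(
    compressibility_from_stats(0.62, 0.001, 288, 310) /
      compressibility_from_stats(0.62, 0.002, 288, 310),
    0.25
  )
  expect_equal(area_compressibility(rep(0.62, 50), 310, 288), 0)
  expect_error(area_compressibility(0.62, 310, 288), "at least 2")
  expect_error(area_compressibility(c(0.6, 0.62), -1, 288), "positive")
})

test_that("kappa_T from seeded Gaussian series matches the closed form within 20%", {
  n <- 400
  sigma <- 0.004
  est <- vapply(1:20, function(s) {
    withr::with_seed(s, area_compressibility(rnorm(n, 0.62, sigma), 310, 288))
  }, numeric(1))
  expected <- compressibility_from_stats(0.62, sigma / sqrt(n), 288, 310)
  expect_lt(abs(mean(est) - expected) / expected, 0.2)
})

test_that("block averaging shortens the series before the standard error", {
  withr::with_seed(5, {
    x <- rnorm(300, 0.62, 0.004)
    k_blocked <- area_compressibility(x, 310, 288, block_frames = 50)
    k_raw <- area_compressibility(x, 310, 288)
    expect_true(k_blocked > 0 && k_raw > 0)
    # 6 blocks instead of 300 samples changes the standard error estimate
    expect_false(isTRUE(all.equal(k_blocked, k_raw)))
  })
})

test_that("temperature fits recover exact linear trends", {
  s <- temperature_series(c(277, 285, 296, 310, 320), 0.001 * c(277, 285, 296, 310, 320) + 0.3)
  fit <- fit_vs_temperature(s)
  expect_equal(fit$slope, 0.001, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # two points interpolate exactly
  fit2 <- fit_vs_temperature(temperature_series(c(280, 300), c(1, 2)))
  expect_equal(fit2$slope, 0.05)
  expect_equal(fit2$r_squared, 1)
  # exclusion list drops points before fitting
  s3 <- temperature_series(c(277, 285, 296), c(10, 0.285, 0.296))
  fit3 <- fit_vs_temperature(s3, exclude = 277)
  expect_equal(nrow(fit3$data), 2)
  expect_equal(nrow(fit3$excluded), 1)
  expect_error(fit_vs_temperature(s3, exclude = c(277, 285)), "fewer than 2")
  expect_equal(glance(fit3)$n_excluded, 1)
  expect_equal(nrow(tidy(fit)), 2)
})
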