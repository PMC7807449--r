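# scripted protein-lipid fixture: one protein atom per residue at fixed
# positions, one lipid particle whose distance toggles over frames
contact_traj <- function(contact_frames, n_frames, cutoff = 0.65) {
  parts <- tibble::tibble(
    id = 1:3,
    lipid_id = c(1L, NA_integer_, NA_integer_),
    species = c("MPPO-CL", "PROT", "PROT"),
    headgroup = c("CL", NA, NA),
    leaflet = c("upper", "none", "none"),
    role = c("glycerol_ref", "protein_atom", "protein_atom"),
    residue = c(NA_integer_, 42L, 43L),
    chain = c(NA, "A", "A")
  )
  xyz <- lapply(seq_len(n_frames), function(f) {
    lip_x <- if (f %in% contact_frames) 2.5 else 4.5
    rbind(c(lip_x, 3, 3), c(3, 3, 3), c(3, 3, 4))
  })
  ple_trajectory(parts, xyz, times = seq_len(n_frames) - 1, box = c(8, 8, 8))
}

test_that("residue binding probability counts contact frames per residue", {
  tr <- contact_traj(contact_frames = 1:10, n_frames = 10)
  rb <- residue_binding_probability(tr, "CL", cutoff = 0.65)
  expect_equal(rb$probability[rb$residue == 42], 1)
  expect_equal(rb$probability[rb$residue == 43], 0)
  # scripted 50% occupancy
  tr2 <- contact_traj(contact_frames = seq(1, 20, by = 2), n_frames = 20)
  rb2 <- residue_binding_probability(tr2, "CL", cutoff = 0.65)
  expect_equal(rb2$probability[rb2$residue == 42], 0.5)
  # no contacts at all
  tr3 <- contact_traj(contact_frames = integer(0), n_frames = 5)
  expect_equal(residue_binding_probability(tr3, "CL")$probability, c(0, 0))
})

test_that("binding events merge interruptions up to the gap tolerance", {
  # contact in frames 10..20 only
  tr <- contact_traj(contact_frames = 10:20, n_frames = 30)
  ev <- binding_durations(tr, "CL", gap_tolerance = 0)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 10) # ns at dt = 1
  expect_equal(ev$n_contact_frames, 11)
  # two bursts with a 1-frame hole merge under gap_tolerance 2 but not 0
  tr2 <- contact_traj(contact_frames = c(10:14, 16:20), n_frames = 30)
  expect_equal(nrow(binding_durations(tr2, "CL", gap_tolerance = 2)), 1)
  expect_equal(nrow(binding_durations(tr2, "CL", gap_tolerance = 0)), 2)
})

test_that("binding events are disjoint and cover the merged contact mask", {
  withr::with_seed(10, {
    on <- sort(sample(1:200, 60))
    tr <- contact_traj(contact_frames = on, n_frames = 200)
    gap <- 1
    ev <- binding_durations(tr, "CL", gap_tolerance = gap)
    # disjoint and ordered
    expect_true(all(diff(ev$start_frame) > 0))
    expect_true(all(ev$end_frame[-nrow(ev)] < ev$start_frame[-1]))
    # events cover exactly the contact frames
    expect_equal(sum(ev$n_contact_frames), length(on))
    # oracle: run-length encoding of the gap-merged mask
    mask <- rep(FALSE, 200)
    mask[on] <- TRUE
    merged <- mask
    r <- rle(merged)
    holes <- which(!r$values & r$lengths <= gap)
    holes <- holes[holes > 1 & holes < length(r$values)]
    r$values[holes] <- TRUE
    expect_equal(nrow(ev), sum(rle(inverse.rle(r))$values))
  })
})

test_that("telegraph-process binding durations recover the mean on-time", {
  mean_on <- 20
  mean_off <- 30
  durations <- unlist(lapply(1:20, function(s) {
    withr::with_seed(600 + s, {
      frames <- integer(0)
      t <- 1
      repeat {
        on_len <- rgeom(1, 1 / mean_on) + 1
        off_len <- rgeom(1, 1 / mean_off) + 1
        if (t + on_len + off_len >= 400) break # drop truncated final run
        frames <- c(frames, t:(t + on_len - 1))
        t <- t + on_len + off_len
      }
      tr <- contact_traj(contact_frames = frames, n_frames = 400)
      binding_durations(tr, "CL", gap_tolerance = 0)$duration
    })
  }))
  # duration spans (end - start) estimate the on-time minus one step
  expect_lt(abs(mean(durations + 1) - mean_on) / mean_on, 0.15)
})

test_that("shell enrichment recovers the generator bias and the unbiased null", {
  prot_null <- list(radius = 1.5, thinning_depth = 0, thinning_range = 1)
  sim <- default_sim(
    composition = "SimplePOM", n_per_leaflet = 150, n_frames = 3,
    water_count = 0, permeation_rate = 0, protein = prot_null, seed = 7
  )
  se <- shell_enrichment(sim$trajectory)
  expect_setequal(se$headgroup, c("CL", "PE", "PG"))
  # unbiased shell: the abundant PE class sits near 1
  expect_lt(abs(se$enrichment[se$headgroup == "PE"] - 1), 0.25)
  # per-leaflet reporting labels CP/EC
  sel <- shell_enrichment(sim$trajectory, per_leaflet = TRUE)
  expect_setequal(unique(sel$leaflet), c("CP", "EC"))
  # protein absent -> error
  nop <- default_sim(n_per_leaflet = 16, n_frames = 1, water_count = 0, seed = 1)
  expect_error(shell_enrichment(nop$trajectory), "protein absent")
})

test_that("pooled shell composition recovers a planted CL enrichment", {
  prot <- list(
    radius = 2.0, thinning_depth = 0, thinning_range = 1,
    shell_enrichment = c(CL = 2.0)
  )
  shell_cnt <- c(CL = 0, PE = 0, PG = 0)
  bulk_cnt <- c(CL = 0, PE = 0, PG = 0)
  for (s in 1:20) {
    sim <- default_sim(
      composition = "SimplePOM", n_per_leaflet = 100, n_frames = 1,
      water_count = 0, permeation_rate = 0, protein = prot, seed = 700 + s
    )
    fr <- traj_frame(sim$trajectory, 1)
    md <- plext:::lipid_protein_mindist(fr)
    meta <- sim$ground_truth$species_by_lipid
    hg <- ifelse(grepl("-CL$", meta$species), "CL",
      substr(meta$species, nchar(meta$species) - 1, nchar(meta$species))
    )
    in_shell <- md$mind[match(meta$lipid_id, md$lipid_id)] <= 0.65
    for (cl in names(shell_cnt)) {
      shell_cnt[cl] <- shell_cnt[cl] + sum(hg == cl & in_shell)
      bulk_cnt[cl] <- bulk_cnt[cl] + sum(hg == cl & !in_shell)
    }
  }
  est <- (shell_cnt["CL"] / sum(shell_cnt)) / (bulk_cnt["CL"] / sum(bulk_cnt))
  # pooled over 20 seeds the binomial sampling error is about 0.2 (1 s.d.)
  expect_lt(abs(est - 2.0), 0.65)
})

test_that("local thinning recovers the analytic radial profile", {
  prot <- list(radius = 1.5, thinning_depth = 0.3, thinning_range = 1.0)
  devs <- vapply(1:6, function(s) {
    sim <- default_sim(
      composition = "SimplePOM", n_per_leaflet = 200, n_frames = 3,
      water_count = 0, permeation_rate = 0, protein = prot, seed = 800 + s
    )
    th <- local_thinning(sim$trajectory, reference = 3.9)
    fr <- traj_frame(sim$trajectory, 1)
    heads <- fr[fr$role == "headgroup_ref", ]
    ctr <- sim$ground_truth$center
    r <- sqrt((heads$x - ctr[1])^2 + (heads$y - ctr[2])^2)
    sel <- r - 1.5 <= 0.5
    th$thinning[th$shell == 0.5] - 0.3 * mean(exp(-pmax(0, r[sel] - 1.5) / 1.0))
  }, numeric(1))
  expect_lt(abs(mean(devs)), 0.05)
})

test_that("thinning vanishes without a planted deformation and far from the wall", {
  prot <- list(radius = 1.5, thinning_depth = 0, thinning_range = 1)
  # headgroup-plane roughness (s.d. 0.05 nm, static over frames) leaves
  # ~0.03 nm noise on a handful of shell references; average three seeds
  thn <- sapply(1:3, function(s) {
    sim <- default_sim(
      composition = "SimplePOM", n_per_leaflet = 150, n_frames = 3,
      water_count = 0, permeation_rate = 0, pp_thickness = 3.9,
      protein = prot, seed = 819 + s
    )
    local_thinning(sim$trajectory, reference = 3.9)$thinning
  })
  expect_true(all(abs(rowMeans(thn)) < 0.06))
  # a deformed membrane relaxes to bulk at large shell radius
  prot2 <- list(radius = 1.5, thinning_depth = 0.4, thinning_range = 0.6)
  sim2 <- default_sim(
    composition = "SimplePOM", n_per_leaflet = 220, n_frames = 2,
    water_count = 0, permeation_rate = 0, pp_thickness = 3.9,
    protein = prot2, seed = 821
  )
  th2 <- local_thinning(sim2$trajectory, shells = c(0.5, 4.5), reference = 3.9)
  expect_gt(th2$thinning[th2$shell == 0.5], 0.1)
  expect_lt(abs(th2$thinning[th2$shell == 4.5]), 0.06)
  expect_error(
    local_thinning(sim2$trajectory, shells = 50, reference = 3.9),
    "half the box"
  )
})
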