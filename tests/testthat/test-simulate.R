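test_that("noise-free fully labeled pore reproduces the 32-site template exactly", {
  cfg <- npc_sim_config(n_npcs = 1, p_le = 1, max_tilt_deg = 0,
                        noise = noise_model(0),
                        visits = visit_model("fixed", mean_visits = 1),
                        seed = 5)
  sim <- make_npc_ensemble(cfg)
  expect_equal(nrow(sim$sites), 32)
  expect_true(all(sim$sites$labeled))
  expect_equal(nrow(sim$localizations), 32)
  # localizations coincide with the ground-truth site positions
  ord <- match(sim$localizations$site_id, sim$sites$site_id)
  expect_equal(sim$localizations$x, sim$sites$x[ord])
  expect_equal(sim$localizations$z, sim$sites$z[ord])
  # ring structure: 16 sites per ring, separated by ring_spacing axially
  ctr <- sim$complexes[1, ]
  rel_z <- sim$sites$z - ctr$z
  expect_equal(sort(unique(round(rel_z, 9))), c(-25, 25))
  # ring radius
  r <- sqrt((sim$sites$x - ctr$x)^2 + (sim$sites$y - ctr$y)^2)
  expect_equal(r, rep(107 / 2, 32), tolerance = 1e-9)
})

test_that("p_le = 0 yields no localizations but a full unlabeled ground truth", {
  sim <- make_npc_ensemble(npc_sim_config(n_npcs = 1, p_le = 0, seed = 2))
  expect_equal(nrow(sim$sites), 32)
  expect_false(any(sim$sites$labeled))
  expect_equal(nrow(sim$localizations), 0)
})

test_that("labeled-site fraction matches p_le within binomial error", {
  cfg <- npc_sim_config(n_npcs = 500, p_le = 0.6, seed = 17)
  sim <- make_npc_ensemble(cfg)
  n_sites <- nrow(sim$sites)
  expect_equal(n_sites, 500 * 32)
  frac <- mean(sim$sites$labeled)
  se <- sqrt(0.6 * 0.4 / n_sites)
  expect_lt(abs(frac - 0.6), 3 * se)
})

test_that("generators are deterministic given the seed", {
  cfg <- npc_sim_config(n_npcs = 5, seed = 123)
  a <- make_npc_ensemble(cfg)
  b <- make_npc_ensemble(cfg)
  expect_identical(a$localizations, b$localizations)
  expect_identical(a$sites, b$sites)
  lay1 <- make_lattice_layout(5, 5, occupancy = 0.7, seed = 9)
  lay2 <- make_lattice_layout(5, 5, occupancy = 0.7, seed = 9)
  expect_identical(lay1, lay2)
  f1 <- make_tetramer_field(lay1, seed = 4)
  f2 <- make_tetramer_field(lay2, seed = 4)
  expect_identical(f1$localizations, f2$localizations)
})

test_that("every trace maps to one site and visit counts equal distinct TIDs", {
  cfg <- npc_sim_config(n_npcs = 10, seed = 31,
                        visits = visit_model(mean_visits = 1.6))
  sim <- make_npc_ensemble(cfg)
  # each TID maps to exactly one ground-truth site
  map <- unique(sim$localizations[, c("tid", "site_id")])
  expect_equal(nrow(map), length(unique(sim$localizations$tid)))
  # per-site distinct-TID count equals the recorded visit count
  per_site <- table(map$site_id)
  visit_counts <- table(sim$visits$site_id)
  expect_identical(per_site, visit_counts)
  # zero-truncation: every labeled site has at least one visit
  labeled_ids <- sim$sites$site_id[sim$sites$labeled]
  expect_setequal(unique(sim$visits$site_id), labeled_ids)
})

test_that("zero-truncated visit counts hit the requested conditional mean", {
  cfg <- npc_sim_config(n_npcs = 300, p_le = 1, seed = 77,
                        visits = visit_model(mean_visits = 1.18))
  sim <- make_npc_ensemble(cfg)
  v <- as.integer(table(sim$visits$site_id))
  expect_true(all(v >= 1))
  expect_lt(abs(mean(v) - 1.18), 3 * sd(v) / sqrt(length(v)))
})

test_that("lattice layout places and thins tetramers as configured", {
  lay <- make_lattice_layout(2, 2, pitch = 30, occupancy = 1)
  expect_equal(nrow(lay), 4)
  expect_setequal(lay$x, c(0, 30))
  expect_setequal(lay$y, c(0, 30))
  expect_error(make_lattice_layout(2, 2, pitch = 0), "pitch")
  expect_error(make_lattice_layout(0, 2), "at least one")
  # binomial thinning: mean retained count over seeds ~ n * occupancy
  counts <- vapply(1:40, function(s)
    nrow(make_lattice_layout(10, 10, occupancy = 0.5, seed = s)), integer(1))
  se <- sqrt(100 * 0.25) / sqrt(40)
  expect_lt(abs(mean(counts) - 50), 4 * se)
})

test_that("tag-square expansion has the published geometry", {
  # GFP tag square: side 16 nm, corners 16/sqrt(2) nm from the center
  g <- expand_layout_to_tag_sites(make_lattice_layout(1, 1, tag_kind = "GFP16"))
  expect_equal(nrow(g), 4)
  expect_equal(sqrt(g$x^2 + g$y^2 + g$z^2), rep(16 / sqrt(2), 4), tolerance = 1e-9)
  # RFP tag square: adjacent-corner distance = side = 20 nm
  r <- expand_layout_to_tag_sites(make_lattice_layout(1, 1, tag_kind = "RFP20"))
  d <- sort(as.numeric(dist(cbind(r$x, r$y, r$z))))
  expect_equal(d[1:4], rep(20, 4), tolerance = 1e-9)         # sides
  expect_equal(d[5:6], rep(20 * sqrt(2), 2), tolerance = 1e-9)  # diagonals
  # empty layout
  empty <- make_lattice_layout(1, 1)[0, ]
  expect_equal(nrow(expand_layout_to_tag_sites(empty)), 0)
})

test_that("tetramer field labels subunits Binomial(4, p_su)", {
  lay <- make_lattice_layout(10, 10, pitch = 100)
  # retained fraction across a large field
  sim <- make_tetramer_field(lay, p_su = 0.5, seed = 8)
  frac <- mean(sim$sites$labeled)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 400))
  # per-tetramer labeled counts vs exhaustive 2^4 enumeration at p = 0.5
  counts <- integer(5)
  for (s in 1:300) {
    f <- make_tetramer_field(make_lattice_layout(1, 1), p_su = 0.5, seed = s)
    k <- sum(f$sites$labeled)
    counts[k + 1] <- counts[k + 1] + 1
  }
  pmf <- counts / sum(counts)
  expected <- choose(4, 0:4) / 16  # 0.0625 0.25 0.375 0.25 0.0625
  expect_lt(max(abs(pmf - expected)), 0.08)
  expect_equal(expected[1], 0.0625)
  expect_equal(sum(expected[4:5]), 0.3125)
})

test_that("noise-free single-visit field reproduces labeled sites exactly", {
  lay <- make_lattice_layout(3, 3, pitch = 60)
  sim <- make_tetramer_field(lay, p_su = 1, noise = noise_model(0),
                             visits = visit_model("fixed", 1), seed = 1)
  expect_equal(nrow(sim$localizations), nrow(sim$sites))
  ord <- match(sim$localizations$site_id, sim$sites$site_id)
  expect_equal(sim$localizations$x, sim$sites$x[ord])
  expect_equal(sim$localizations$y, sim$sites$y[ord])
})

test_that("invalid configurations error", {
  expect_error(npc_sim_config(1, p_le = 1.2), "p_le")
  expect_error(npc_sim_config(1, ring_spacing = -1), "positive")
  expect_error(noise_model(-1), "sigma")
  expect_error(noise_model(2, outlier_fraction = 2), "outlier_fraction")
  expect_error(visit_model(mean_visits = 0.5), "mean_visits")
  expect_error(make_tetramer_field(make_lattice_layout(1, 1)[0, ]), "empty")
})

test_that("shipped synthetic layouts load and feed the simulation pipeline", {
  for (f in c("synthetic_lattice_layout.csv", "synthetic_irregular_layout.csv")) {
    lay <- read_cluster_layout(system.file("extdata", f, package = "minfluxr"))
    expect_s3_class(lay, "cluster_layout")
    expect_gt(nrow(lay), 10)
    sites <- expand_layout_to_tag_sites(lay)
    expect_equal(nrow(sites), 4 * nrow(lay))
    sim <- simulate_cluster_appearance(lay, p_su = 0.5, sigma = 3, seed = 1)
    expect_true(all(sim$complex_id %in% lay$tetramer_id))
  }
  # missing columns are reported
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tetramer_id,x,y", "1,0,0"), bad)
  expect_error(read_cluster_layout(bad), "angle_deg")
})
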