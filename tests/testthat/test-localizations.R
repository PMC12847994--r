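test_that("localization tables round-trip through CSV and TSV", {
  tbl <- tibble::tibble(tid = c(1, 1, 2), x = c(0.5, 1.5, 10),
                        y = c(-3, -2, 8), z = c(0.1, 0.2, 5))
  for (ext in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_localizations(tbl, path)
    back <- read_localizations(path)
    expect_equal(as.data.frame(back), as.data.frame(tbl))
    expect_equal(length(unique(back$tid)), 2)
  }
})

test_that("malformed localization files are rejected with useful messages", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("tid,x,y", path)
  expect_error(read_localizations(path), "empty")
  writeLines(c("tid,x,y", "1,0,0"), path)
  expect_error(read_localizations(path), "z")
  writeLines(c("tid,x,y,z", "1,0,0,0", "2,oops,1,1"), path)
  expect_error(read_localizations(path), "row 2")
  expect_error(read_localizations(withr::local_tempfile(fileext = ".csv")),
               "not found")
})

test_that("combine_traces averages per trace and applies the length filter", {
  tbl <- tibble::tibble(tid = c(7, 7, 9), x = c(0, 2, 5), y = c(0, 0, 5),
                        z = c(0, 0, 5))
  sites <- combine_traces(tbl)
  s7 <- sites[sites$tid == 7, ]
  expect_equal(s7$x, 1)
  expect_equal(s7$n_locs, 2L)
  expect_equal(s7$spread_x, sqrt(2))  # sd of (0, 2)
  expect_equal(s7$spread_y, 0)
  s9 <- sites[sites$tid == 9, ]
  expect_equal(s9$n_locs, 1L)
  expect_equal(s9$spread_x, 0)  # singleton: spread defined as 0
  # min_locs drops short traces
  expect_equal(nrow(combine_traces(tbl, min_locs = 2)), 1)
  expect_equal(nrow(combine_traces(tbl, min_locs = 3)), 0)
})

test_that("reduction conserves localization and site mass", {
  cfg <- npc_sim_config(n_npcs = 8, seed = 3,
                        visits = visit_model(mean_visits = 1.4, locs_per_visit = 4),
                        noise = noise_model(2), p_le = 0.7)
  sim <- make_npc_ensemble(cfg)
  sites <- combine_traces(sim$localizations)
  expect_equal(sum(sites$n_locs), nrow(sim$localizations))
  subs <- merge_subunits(sites, eps = 1)
  expect_equal(sum(subs$n_sites_merged), nrow(sites))
  expect_equal(sum(subs$n_locs_total), nrow(sim$localizations))
})

test_that("per-site spread matches the generator noise", {
  cfg <- npc_sim_config(n_npcs = 20, seed = 11, p_le = 1,
                        noise = noise_model(2),
                        visits = visit_model("fixed", 1, locs_per_visit = 10))
  sim <- make_npc_ensemble(cfg)
  sites <- combine_traces(sim$localizations)
  expect_equal(median(sites$spread_x), 2, tolerance = 0.15)
  expect_equal(median(sites$spread_z), 2, tolerance = 0.15)
})

test_that("merge_subunits joins nearby sites and leaves distant ones apart", {
  near <- tibble::tibble(site_id = 1:2, x = c(0, 0.5), y = 0, z = 0,
                         n_locs = c(3L, 1L), n_traces = 1L)
  m <- merge_subunits(near, eps = 1)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_sites_merged, 2L)
  expect_equal(m$x, (0 * 3 + 0.5 * 1) / 4)  # localization-weighted mean
  expect_equal(m$n_traces, 2L)
  far <- tibble::tibble(site_id = 1:2, x = c(0, 5), y = 0, z = 0,
                        n_locs = 1L, n_traces = 1L)
  expect_equal(nrow(merge_subunits(far, eps = 1)), 2)
})

test_that("DBSCAN at min_pts 1 equals brute-force connected components", {
  set.seed(42)
  for (case in 1:3) {
    n <- 200
    xyz <- matrix(runif(n * 3, 0, 30), ncol = 3)
    sites <- tibble::tibble(site_id = seq_len(n), x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], n_locs = 1L, n_traces = 1L)
    for (eps in c(1, 3)) {
      labels <- minfluxr:::dbscan_labels(xyz, eps = eps, min_pts = 1)
      oracle <- brute_force_components(xyz, eps)
      expect_identical(canonical_partition(labels), canonical_partition(oracle))
    }
  }
})

test_that("merge_subunits is invariant to input permutation", {
  set.seed(7)
  n <- 80
  sites <- tibble::tibble(site_id = 1:n, x = runif(n, 0, 20), y = runif(n, 0, 20),
                          z = runif(n, 0, 20), n_locs = sample(1:5, n, TRUE),
                          n_traces = 1L)
  a <- merge_subunits(sites, eps = 2)
  perm <- sample(n)
  b <- merge_subunits(sites[perm, ], eps = 2)
  key <- function(m) m[order(m$x, m$y, m$z),
                       c("x", "y", "z", "n_sites_merged", "n_locs_total")]
  expect_equal(as.data.frame(key(a)), as.data.frame(key(b)), tolerance = 1e-12)
})

test_that("subunit count equals labeled-site count for single visits", {
  cfg <- npc_sim_config(n_npcs = 10, seed = 21, p_le = 0.6,
                        visits = visit_model("fixed", 1))
  sim <- make_npc_ensemble(cfg)
  subs <- merge_subunits(combine_traces(sim$localizations), eps = 1)
  expect_equal(nrow(subs), sum(sim$sites$labeled))
})

test_that("precision summary reports per-axis medians of trace SDs", {
  one <- tibble::tibble(tid = c(1, 1), x = c(0, 2), y = 0, z = 0)
  ps <- precision_summary(one)
  expect_equal(ps$median_sd_x, sqrt(2))
  expect_equal(ps$median_sd_y, 0)
  # all-singleton tables are an error
  singles <- tibble::tibble(tid = 1:3, x = 1:3, y = 0, z = 0)
  expect_error(precision_summary(singles), "undefined")
  # synthetic data at sigma = 2 nm recovers ~2 nm per axis
  cfg <- npc_sim_config(n_npcs = 25, seed = 13, p_le = 1, noise = noise_model(2),
                        visits = visit_model("fixed", 1, locs_per_visit = 10))
  sim <- make_npc_ensemble(cfg)
  ps2 <- precision_summary(sim$localizations)
  expect_equal(ps2$median_sd_x, 2, tolerance = 0.15)
  expect_equal(ps2$median_sd_y, 2, tolerance = 0.15)
  expect_equal(ps2$median_sd_z, 2, tolerance = 0.15)
})
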