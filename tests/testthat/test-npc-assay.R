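# helpers building small, fully controlled pore point sets -------------------

noise_free_pore <- function(tilt_deg = 0, spin_deg = 0, azim_deg = 0,
                            center = c(0, 0, 0), p_keep = 1, seed = 1) {
  cfg <- npc_sim_config(n_npcs = 1, p_le = 1, max_tilt_deg = 0,
                        noise = noise_model(0), visits = visit_model("fixed", 1),
                        seed = seed)
  tmpl <- minfluxr:::npc_template_sites(cfg)
  tilt <- tilt_deg * pi / 180
  azim <- azim_deg * pi / 180
  axis <- c(sin(tilt) * cos(azim), sin(tilt) * sin(azim), cos(tilt))
  R <- minfluxr:::rotation_align_z(axis) %*%
    minfluxr:::rotation_z(spin_deg * pi / 180)
  world <- as.matrix(tmpl[, c("x", "y", "z")]) %*% t(R)
  out <- tibble::tibble(x = world[, 1] + center[1], y = world[, 2] + center[2],
                        z = world[, 3] + center[3], segment = tmpl$segment)
  if (p_keep < 1) {
    withr::with_seed(seed, out <- out[runif(nrow(out)) < p_keep, ])
  }
  out
}

test_that("template anchors have the double-ring geometry", {
  a <- npc_template_anchors(npc_template())
  expect_equal(dim(a), c(16, 3))
  expect_equal(sqrt(a[, 1]^2 + a[, 2]^2), rep(107 / 2, 16))
  expect_equal(sort(unique(a[, 3])), c(-25, 25))
  # 8-fold symmetry: rotating anchors by 45 degrees permutes them
  rot <- a %*% t(minfluxr:::rotation_z(pi / 4))
  d <- as.matrix(dist(rbind(rot, a)))[1:16, 17:32]
  expect_lt(max(apply(d, 1, min)), 1e-9)
})

test_that("candidate detection separates pores and filters small groups", {
  a <- noise_free_pore(center = c(0, 0, 0))
  b <- noise_free_pore(center = c(500, 0, 0))
  pts <- rbind(a, b)
  cand <- detect_npc_candidates(pts, group_eps = 75, min_points = 6)
  expect_equal(nrow(cand), 2)
  # a 2-point group is discarded at min_points 6
  few <- tibble::tibble(x = c(0, 1), y = 0, z = 0)
  expect_equal(nrow(detect_npc_candidates(few, group_eps = 75, min_points = 6)), 0)
})

test_that("candidate detection recovers nearly all pores in a dense field", {
  sim <- make_npc_ensemble(npc_sim_config(n_npcs = 100, p_le = 0.6, seed = 6))
  subs <- merge_subunits(combine_traces(sim$localizations))
  cand <- detect_npc_candidates(subs)
  expect_gte(nrow(cand), 95)
  expect_lte(nrow(cand), 100)
})

test_that("noise-free fit recovers pose and geometry exactly", {
  pts <- noise_free_pore(tilt_deg = 20, spin_deg = 30, azim_deg = 70,
                         center = c(5, -3, 2))
  fit <- fit_npc_template(pts, free_geometry = TRUE)
  expect_equal(fit$center, c(5, -3, 2), tolerance = 1e-3)
  true_axis <- c(sin(20 * pi / 180) * cos(70 * pi / 180),
                 sin(20 * pi / 180) * sin(70 * pi / 180), cos(20 * pi / 180))
  expect_lt(acos(abs(sum(fit$axis * true_axis))) * 180 / pi, 0.1)
  expect_equal(fit$spacing, 50, tolerance = 0.1)
  expect_equal(fit$diameter, 107, tolerance = 0.3)
  expect_error(fit_npc_template(pts[1:3, ]), "unidentifiable")
})

test_that("template fit is equivariant under rigid transforms", {
  pts <- noise_free_pore(tilt_deg = 15, spin_deg = 10, p_keep = 0.7, seed = 4)
  fit0 <- fit_npc_template(pts)
  shift <- c(120, -40, 60)
  Rz30 <- minfluxr:::rotation_z(30 * pi / 180)
  moved <- as.matrix(pts[, c("x", "y", "z")]) %*% t(Rz30)
  moved <- sweep(moved, 2, -shift)
  fit1 <- fit_npc_template(moved)
  expect_equal(fit1$center, as.numeric(Rz30 %*% fit0$center) + shift,
               tolerance = 0.05)
  expect_lt(acos(abs(sum(fit1$axis * as.numeric(Rz30 %*% fit0$axis)))) * 180 / pi,
            0.5)
})

test_that("pose recovery stays tight at sigma 2 nm and 25-degree tilt", {
  n_rep <- 100
  ok <- logical(n_rep)
  for (s in seq_len(n_rep)) {
    pts <- noise_free_pore(tilt_deg = 25, spin_deg = (s * 7) %% 45,
                           azim_deg = (s * 31) %% 360)
    withr::with_seed(1000 + s, {
      pts$x <- pts$x + rnorm(32, 0, 2)
      pts$y <- pts$y + rnorm(32, 0, 2)
      pts$z <- pts$z + rnorm(32, 0, 2)
    })
    fit <- fit_npc_template(pts)
    true_axis <- c(sin(25 * pi / 180) * cos((s * 31) %% 360 * pi / 180),
                   sin(25 * pi / 180) * sin((s * 31) %% 360 * pi / 180),
                   cos(25 * pi / 180))
    ok[s] <- acos(abs(sum(fit$axis * true_axis))) * 180 / pi < 5 &&
      sqrt(sum(fit$center^2)) < 2
  }
  expect_gte(mean(ok), 0.95)
})

test_that("segment counting is exact on clean and one-ring data", {
  pts <- noise_free_pore(tilt_deg = 10, spin_deg = 20)
  fit <- fit_npc_template(pts)
  segs <- count_labeled_segments(fit, pts)
  expect_equal(sum(segs$labeled), 16)
  expect_equal(segs$n_points, rep(2L, 16))
  # one ring only
  one_ring <- pts[pts$segment <= 8, ]
  fit1 <- fit_npc_template(one_ring)
  segs1 <- count_labeled_segments(fit1, one_ring)
  expect_lte(sum(segs1$labeled), 8)
})

test_that("per-pore segment counts match ground truth at p_le 0.6", {
  sim <- make_npc_ensemble(npc_sim_config(n_npcs = 40, p_le = 0.6, seed = 19))
  subs <- merge_subunits(combine_traces(sim$localizations))
  cand <- detect_npc_candidates(subs)
  hits <- vapply(seq_len(nrow(cand)), function(i) {
    fit <- fit_npc_template(cand$data[[i]])
    k <- sum(count_labeled_segments(fit, cand$data[[i]])$labeled)
    d <- sqrt((sim$complexes$x - fit$center[1])^2 +
                (sim$complexes$y - fit$center[2])^2 +
                (sim$complexes$z - fit$center[3])^2)
    j <- which.min(d)
    truth <- sim$sites[sim$sites$complex_id == j & sim$sites$labeled, ]
    k == length(unique(truth$segment))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("predicted segment distribution matches closed forms and Monte Carlo", {
  # point masses at the extremes
  expect_equal(predicted_segment_distribution(1)$prob,
               c(rep(0, 16), 1))
  expect_equal(predicted_segment_distribution(0, kmin = 0)$prob,
               c(1, rep(0, 16)))
  # mean at p = 0.6: q = 0.84, 16 q = 13.44
  pred <- predicted_segment_distribution(0.6)
  expect_equal(sum(pred$k * pred$prob), 16 * (1 - 0.4^2))
  expect_equal(1 - (1 - 0.6)^2, 0.84)
  # distribution sums to one across p and kmin
  for (p in c(0, 0.17, 0.5, 0.83, 1)) {
    for (kmin in c(0, 1, 5)) {
      expect_equal(sum(predicted_segment_distribution(p, kmin = kmin)$prob), 1)
    }
  }
  # site-level Monte Carlo oracle: simulate 32 labeled/unlabeled sites,
  # count segments with >= 1 labeled site
  withr::with_seed(8, {
    n_mc <- 1e5
    labels <- matrix(runif(n_mc * 32) < 0.6, ncol = 32)
    seg_any <- labels[, seq(1, 32, 2)] | labels[, seq(2, 32, 2)]
    k_mc <- rowSums(seg_any)
  })
  emp <- tabulate(k_mc + 1L, nbins = 17) / n_mc
  pred <- predicted_segment_distribution(0.6, kmin = 0)$prob
  expect_lt(sum(abs(emp - pred)) / 2, 0.01)  # total-variation distance
})

test_that("labeling-efficiency estimator is self-consistent and monotone", {
  for (p in seq(0.1, 0.9, by = 0.1)) {
    pred <- predicted_segment_distribution(p, kmin = 1)
    hist <- c(0, round(pred$prob * 1e4))
    est <- estimate_labeling_efficiency(histogram = hist, kmin = 1)
    expect_equal(est$p_le, p, tolerance = 2e-3)
  }
  # stochastically larger histograms give larger estimates
  lo <- estimate_labeling_efficiency(histogram = c(0, 10, 30, 40, 20, rep(0, 12)))
  hi <- estimate_labeling_efficiency(histogram = c(rep(0, 10), 10, 30, 40, 20, 0, 0, 0))
  expect_gt(hi$p_le, lo$p_le)
  # boundary: every pore fully labeled
  all16 <- estimate_labeling_efficiency(histogram = c(rep(0, 16), 25))
  expect_equal(all16$p_le, 1)
  expect_true(all16$boundary)
  expect_error(estimate_labeling_efficiency(histogram = rep(0, 17)), "nothing to fit")
})

test_that("geometry summary recovers and discriminates ring spacing", {
  fits50 <- lapply(1:12, function(s) {
    pts <- noise_free_pore(tilt_deg = 15, spin_deg = s * 3, azim_deg = s * 29)
    withr::with_seed(s, {
      pts$x <- pts$x + rnorm(32, 0, 2); pts$y <- pts$y + rnorm(32, 0, 2)
      pts$z <- pts$z + rnorm(32, 0, 2)
    })
    fit_npc_template(pts, free_geometry = TRUE)
  })
  geom <- estimate_npc_geometry(fits50)
  sp <- geom$estimate[geom$parameter == "ring_spacing"]
  expect_equal(sp, 50, tolerance = 0.02)  # within 1 nm
  # a 57.5 nm ensemble separates clearly from the 50 nm one
  cfg <- npc_sim_config(n_npcs = 12, ring_spacing = 57.5, p_le = 1,
                        noise = noise_model(2),
                        visits = visit_model("fixed", 1), seed = 3)
  sim <- make_npc_ensemble(cfg)
  subs <- merge_subunits(combine_traces(sim$localizations))
  cand <- detect_npc_candidates(subs)
  fits57 <- lapply(cand$data, fit_npc_template, free_geometry = TRUE)
  geom57 <- estimate_npc_geometry(fits57)
  sp57 <- geom57$estimate[geom57$parameter == "ring_spacing"]
  expect_gt(sp57 - sp, 5)
  # single fit: SE undefined
  single <- estimate_npc_geometry(fits50[1])
  expect_true(all(is.na(single$se)))
})

test_that("visit rate recovery: exact at full labeling, corrected otherwise", {
  pts <- noise_free_pore()
  fit <- fit_npc_template(pts)
  segs <- count_labeled_segments(fit, pts)
  # every segment carries its 2 single-visit sites -> 1.0 visits per site
  expect_equal(site_visit_rate(segs)$mean_visits_per_site, 1)
  # no labeled segments errors
  empty_segs <- segs
  empty_segs$labeled <- FALSE
  expect_error(site_visit_rate(empty_segs), "undefined")
})

test_that("tidy/glance/autoplot work on a labeling-efficiency estimate", {
  pred <- predicted_segment_distribution(0.55, kmin = 1)
  est <- estimate_labeling_efficiency(histogram = c(0, round(pred$prob * 500)))
  td <- tidy(est)
  expect_equal(nrow(td), 17)
  expect_equal(sum(td$prop_predicted, na.rm = TRUE), 1, tolerance = 1e-9)
  gl <- glance(est)
  expect_equal(gl$p_le, 0.55, tolerance = 0.02)
  expect_s3_class(autoplot(est), "ggplot")
})
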