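nc_meta <- list(video_id = "n1", pathology = "inflammation", truth = "non_cancer")
ca_meta <- list(video_id = "c1", pathology = "EGC_diff", truth = "cancer")

test_that("defaults encode the documented cohort and calibration constants", {
  spec <- default_cohort()
  expect_equal(sum(spec$counts), 117L)
  expect_equal(sum(spec$counts[c("EGC_poor_diff", "EGC_diff")]), 53L)
  p <- default_params()
  expect_equal(p$fps, 30)
  expect_equal(p$fp_burst_prob, 0.219)
  expect_equal(p$fn_silent_prob, 0.094)
  ov <- default_subtype_overrides()
  expect_equal(ov$atrophy_IM$fp_burst_prob, 6 / 16)
  expect_equal(ov$LGIN$fp_burst_prob, 4 / 7)
})

test_that("invalid parameters are rejected before any sampling", {
  bad <- default_emission(); bad[1, 1] <- 0.9  # row no longer sums to 1
  expect_error(sim_params(emission = bad), "sum to 1")
  expect_error(sim_params(persistence_rho = 1), "persistence")
  expect_error(sim_params(fp_burst_prob = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(subtype_overrides = list(polyp = list())), "unknown")
  expect_error(simulate_video(list(video_id = "x", pathology = "polyp",
                                   truth = "cancer"), seed = 1), "unknown")
})

test_that("simulation is deterministic and leaves the session RNG untouched", {
  p <- default_params()
  set.seed(99); before <- .Random.seed
  s1 <- simulate_video(ca_meta, p, seed = 123)
  expect_identical(.Random.seed, before)
  s2 <- simulate_video(ca_meta, p, seed = 123)
  expect_identical(s1, s2)
  expect_false(identical(s1, simulate_video(ca_meta, p, seed = 124)))
  co1 <- simulate_cohort(cohort_spec(counts = c(inflammation = 2, EGC_diff = 2)),
                         p, seed = 7)
  co2 <- simulate_cohort(cohort_spec(counts = c(inflammation = 2, EGC_diff = 2)),
                         p, seed = 7)
  expect_identical(co1, co2)
})

test_that("probability-zero cancer emission yields streams with no cancer tags", {
  p <- sim_params(fp_burst_prob = 0)
  for (seed in 1:10) {
    s <- simulate_video(nc_meta, p, seed = seed)
    expect_false(any(s$records$label == "cancer"))
    expect_equal(nrow(extract_rois(s)), 0L)
  }
})

test_that("a forced always-tagged episode reproduces its span as TTROI", {
  em <- rbind(EGC = c(1, 0, 0, 0),
              benign_lesion = c(0, 0.6, 0.3, 0.1),
              background = c(0, 0.05, 0.8, 0.15))
  p <- sim_params(emission = em, persistence_rho = 0, fn_silent_prob = 0)
  s <- simulate_video(ca_meta, p, seed = 5, duration_s = 200,
                      episodes = data.frame(start_s = 100, end_s = 130))
  sv <- summarize_video(s)
  expect_equal(sv$n_rois, 1L)
  expect_equal(sv$ttroi_s, 30, tolerance = 1 / 30 + 1e-9)
  expect_true(all(s$records$label[s$records$t >= 100 & s$records$t <= 130] ==
                    "cancer"))
})

test_that("cohort composition, frame grid and total footage match the design", {
  co <- simulate_cohort(seed = 2026)
  expect_equal(nrow(co$meta), 117L)
  expect_equal(sum(co$meta$truth == "cancer"), 53L)
  expect_equal(length(co$series), 117L)
  s <- co$series[[1]]
  expect_equal(diff(s$records$t), rep(1 / 30, nrow(s$records) - 1))
  total_h <- sum(vapply(co$series, function(x) x$duration_s, numeric(1))) / 3600
  expect_lt(abs(total_h - 10) / 10, 0.2)
  # small cohorts honour the requested counts
  tiny <- simulate_cohort(cohort_spec(counts = c(inflammation = 2)),
                          seed = 1)
  expect_equal(nrow(tiny$meta), 2L)
  expect_true(all(tiny$meta$truth == "non_cancer"))
  expect_error(simulate_cohort(cohort_spec(counts = c(inflammation = 0)),
                               seed = 1), "empty cohort")
})

test_that("with zero persistence the label stream is i.i.d. from the emission row", {
  # an all-background video sampled with rho = 0: empirical label frequencies
  # must fit the background emission row (chi-square goodness of fit)
  p <- sim_params(persistence_rho = 0, fp_burst_prob = 0)
  s <- simulate_video(nc_meta, p, seed = 77, duration_s = 400,
                      episodes = data.frame(start_s = numeric(0),
                                            end_s = numeric(0)))
  obs <- table(factor(s$records$label, frame_labels()))
  probs <- default_emission()["background", ]
  keep <- probs > 0
  gof <- suppressWarnings(chisq.test(obs[keep], p = probs[keep] / sum(probs[keep])))
  expect_gt(gof$p.value, 0.01)
  expect_equal(sum(obs[!keep]), 0)
})

test_that("persistence produces longer label runs at equal marginals", {
  run_len <- function(s) mean(rle(s$records$label)$lengths)
  p0 <- sim_params(persistence_rho = 0)
  p8 <- sim_params(persistence_rho = 0.8)
  mean0 <- mean(vapply(1:5, function(i)
    run_len(simulate_video(nc_meta, p0, seed = i)), numeric(1)))
  mean8 <- mean(vapply(1:5, function(i)
    run_len(simulate_video(nc_meta, p8, seed = i)), numeric(1)))
  expect_gt(mean8, 2 * mean0)
})

test_that("subtype overrides redirect burst probability per pathology", {
  p <- sim_params(fp_burst_prob = 0,
                  subtype_overrides = list(LGIN = list(fp_burst_prob = 1)))
  lgin <- list(video_id = "l1", pathology = "LGIN", truth = "non_cancer")
  burst_hits <- vapply(1:20, function(i)
    any(simulate_video(lgin, p, seed = i)$records$label == "cancer"),
    logical(1))
  expect_true(mean(burst_hits) > 0.9)  # burst nearly always emits some tags
  calm_hits <- vapply(1:20, function(i)
    any(simulate_video(nc_meta, p, seed = i)$records$label == "cancer"),
    logical(1))
  expect_false(any(calm_hits))
})

test_that("video-level sensitivity rises with the frame-level cancer emission", {
  # paired seeds + inverse-CDF coupling make the sweep strictly comparable
  grid <- c(0.05, 0.2, 0.4, 0.6, 0.8)
  sens <- vapply(grid, function(pc) {
    em <- default_emission()
    em["EGC", ] <- c(pc, (1 - pc) * c(1 / 3, 4 / 9, 2 / 9))
    p <- sim_params(emission = em, fn_silent_prob = 0.094)
    pred <- vapply(1:30, function(i) {
      s <- simulate_video(ca_meta, p, seed = 1000 + i)
      classify_video(summarize_video(s)$ttroi_s)
    }, character(1))
    mean(pred == "cancer")
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[length(sens)], sens[1])
})
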