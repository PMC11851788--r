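test_that("delta notation arithmetic is exact and invertible", {
  expect_equal(delta_from_ratio(0.0112372, 0.0112372), 0)
  expect_equal(delta_from_ratio(1.001 * 0.0112372, 0.0112372), 1.0)
  set.seed(42)
  r <- runif(50, 0.005, 0.05)
  expect_equal(ratio_from_delta(delta_from_ratio(r, 0.0112372), 0.0112372),
               r, tolerance = 1e-12)
  expect_error(delta_from_ratio(0.01, 0), "r_standard")
  expect_error(delta_from_ratio(0.01, -1), "r_standard")
})

test_that("lipid correction applies strictly above the C:N threshold", {
  expect_equal(lipid_correct(-18.0, 3.0), -18.0)
  expect_equal(lipid_correct(-18.0, 3.5), -18.0)  # equality untouched
  expect_equal(lipid_correct(-18.0, 4.0), -17.36)
  # the linear term vanishes exactly at C:N = 3.32/0.99
  expect_equal(lipid_correct(-18.0, 3.32 / 0.99, threshold = 3), -18.0)
  # vectorized over mixed samples
  expect_equal(lipid_correct(c(-18, -18), c(3, 4)), c(-18, -17.36))
  expect_error(lipid_correct(-18, -0.1), "c_to_n")
})

test_that("baseline correction is an exact shift with the stated algebra", {
  expect_equal(baseline_correct(12.0, 9.5, 9.5), 12.0)
  expect_equal(baseline_correct(12.0, 9.0, 9.5), 12.5)
  # equally sampled stations whose local baselines average to the mean
  # baseline leave the overall mean unchanged
  set.seed(7)
  local <- rnorm(6)
  local <- local - mean(local) + 9.2
  vals <- matrix(rnorm(60, 12), nrow = 6)
  corrected <- sweep(vals, 1, -local + 9.2, `+`)
  expect_equal(mean(corrected), mean(vals), tolerance = 1e-12)
  expect_error(baseline_correct(12, NA, 9.5, station = "S07"), "S07")
})

test_that("trophic level is linear in d15N with slope 1/3.4 and baseline 2", {
  expect_equal(trophic_level(9.12, 9.12), 2)
  d <- seq(3, 16, by = 0.5)
  tl <- trophic_level(d, 9.12)
  expect_true(all(diff(tl) > 0))
  expect_equal(diff(tl) / diff(d), rep(1 / 3.4, length(d) - 1))
  expect_error(trophic_level(10, 9, enrichment = 0), "enrichment")
})

test_that("scaled nitrogen TEF follows its linear form", {
  expect_equal(proportional_tef(0), 5.92)
  expect_equal(proportional_tef(5.92 / 0.27), 0)
  expect_equal(proportional_tef(14.74), 1.9402)
})

test_that("published group table is consistent with the TL equation", {
  tb <- beibu_groups()
  cons <- tb[tb$role == "consumer", ]
  expect_equal(nrow(cons), 13)
  base <- solve_baseline_d15n(cons$d15n_mean, cons$tl_mean)
  # the solved baseline re-predicts every published TL closely
  expect_equal(trophic_level(cons$d15n_mean, base), cons$tl_mean,
               tolerance = 0.01 / min(cons$tl_mean))
  # scaled TEF at the fish-group means: below the constant 3.4 alternative
  fish <- cons[grepl("fish", cons$group), ]
  tef <- proportional_tef(fish$d15n_mean)
  expect_true(all(tef > 1.5 & tef < 2.3))
  expect_true(all(tef < 3.4))
})

test_that("group summaries report moments, TLs and TEFs per group", {
  samples <- data.frame(
    functional_group = c("a", "a", "a", "b"),
    d13c = c(-18, -17, -19, -16),
    d15n = c(10, 11, 12, 13)
  )
  sm <- summarize_groups(samples, d15n_base = 9.0)
  expect_equal(nrow(sm), 2)
  expect_equal(sm$n, c(3, 1))
  expect_equal(sm$d13c_mean[1], -18)
  expect_equal(sm$d13c_sd[1], sd(c(-18, -17, -19)))
  expect_equal(sm$d15n_sd[2], 0)          # single member: sd 0, flagged
  expect_true(sm$single[2])
  expect_equal(sm$tl_mean[1], mean(trophic_level(c(10, 11, 12), 9)))
  expect_equal(sm$tef15n_mean[2], proportional_tef(13))
  expect_warning(
    summarize_groups(data.frame(functional_group = c("a", NA),
                                d13c = c(-18, -17), d15n = c(10, 11)), 9),
    "dropped")
})

test_that("group summaries recover simulated scenario means within 4 SE", {
  src <- toy_sources_3()
  p <- c(0.2, 0.5, 0.3)
  scn <- scenario(src, true_diet = list(cons = p), n_consumers = 400,
                  process_sd = c(0.3, 0.3), seed = 5)
  ds <- simulate_consumers(scn)
  sm <- summarize_groups(ds$samples, d15n_base = 9)
  mu <- sum(p * (src$mean_c + src$tef_mean_c))
  v <- sum(p^2 * (src$sd_c^2 + src$tef_sd_c^2)) + 0.09
  expect_lt(abs(sm$d13c_mean - mu), 4 * sqrt(v / 400))
})
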