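test_that("source generation stores specifications verbatim and validates", {
  spec <- data.frame(label = c("Phytoplankton", "POM"),
                     mean_c = c(-19.64, -20.67), sd_c = c(0.93, 2.71),
                     mean_n = c(5.62, 3.58), sd_n = c(0.57, 0.94))
  src <- generate_sources(spec)
  expect_s3_class(src, "source_summary")
  expect_equal(src$mean_c, spec$mean_c)
  expect_equal(src$sd_n, spec$sd_n)
  expect_identical(generate_sources(spec), generate_sources(spec))
  spec$sd_c[1] <- -0.1
  expect_error(generate_sources(spec), "SD")
})

test_that("degenerate mixtures collapse to the TEF-shifted source mean", {
  src <- source_summary(c("A", "B"), mean_c = c(-20, -15), sd_c = 0,
                        mean_n = c(5, 10), sd_n = 0,
                        tef_mean_c = 1, tef_sd_c = 0,
                        tef_mean_n = 3, tef_sd_n = 0)
  scn <- scenario(src, true_diet = list(g = c(1, 0)), n_consumers = 10,
                  process_sd = c(0, 0), seed = 1)
  ds <- simulate_consumers(scn)
  expect_equal(ds$samples$d13c, rep(-19, 10))
  expect_equal(ds$samples$d15n, rep(8, 10))
})

test_that("simulation is bit-reproducible and group substreams are stable", {
  src <- toy_sources_2()
  scn <- scenario(src, true_diet = list(g1 = c(0.6, 0.4)), seed = 11)
  expect_identical(simulate_consumers(scn), simulate_consumers(scn))
  # appending a group leaves the first group's draws untouched
  scn2 <- scenario(src, true_diet = list(g1 = c(0.6, 0.4),
                                         g2 = c(0.2, 0.8)), seed = 11)
  ds1 <- simulate_consumers(scn)
  ds2 <- simulate_consumers(scn2)
  expect_equal(ds2$samples[ds2$samples$functional_group == "g1",
                           c("d13c", "d15n")],
               ds1$samples[, c("d13c", "d15n")])
})

test_that("simulated moments converge to the mixture moments", {
  src <- toy_sources_3()
  p <- c(0.5, 0.3, 0.2)
  scn <- scenario(src, true_diet = list(g = p), n_consumers = 1000,
                  process_sd = c(0.4, 0.4), seed = 21)
  ds <- simulate_consumers(scn)
  mu <- c(sum(p * (src$mean_c + src$tef_mean_c)),
          sum(p * (src$mean_n + src$tef_mean_n)))
  v <- c(sum(p^2 * (src$sd_c^2 + src$tef_sd_c^2)),
         sum(p^2 * (src$sd_n^2 + src$tef_sd_n^2))) + 0.16
  n <- 1000
  expect_lt(abs(mean(ds$samples$d13c) - mu[1]), 4 * sqrt(v[1] / n))
  expect_lt(abs(mean(ds$samples$d15n) - mu[2]), 4 * sqrt(v[2] / n))
  # variance converges too (SE of a variance ~ V * sqrt(2/(n-1)))
  expect_lt(abs(var(ds$samples$d13c) - v[1]), 4 * v[1] * sqrt(2 / (n - 1)))
  expect_lt(abs(var(ds$samples$d15n) - v[2]), 4 * v[2] * sqrt(2 / (n - 1)))
})

test_that("dataset bookkeeping ties samples to stations", {
  scn <- scenario(toy_sources_2(),
                  true_diet = list(g1 = c(0.5, 0.5), g2 = c(0.2, 0.8)),
                  n_consumers = 25, n_stations = 7, seed = 2)
  ds <- simulate_consumers(scn)
  expect_true(all(ds$samples$station_id %in% ds$stations$station_id))
  expect_equal(nrow(ds$samples), 25 * 2)
  expect_equal(nrow(ds$stations), 7)
  expect_equal(ds$stations$depth, seq(10, 90, length.out = 7))
})

test_that("scenario validation enforces the simplex and design bounds", {
  src <- toy_sources_2()
  expect_error(scenario(src, true_diet = list(g = c(0.6, 0.5))), "summing")
  expect_error(scenario(src, true_diet = list(g = c(1.2, -0.2))), "non-negative")
  expect_error(scenario(src, true_diet = list(g = c(0.5, 0.5)),
                        depth_range = c(90, 10)))
  expect_error(scenario(src, true_diet = list(g = c(0.5, 0.5)),
                        process_sd = c(-1, 0)))
})

test_that("baseline gradients shift stations additively and invert exactly", {
  scn <- scenario(toy_sources_2(), true_diet = list(g = c(0.5, 0.5)),
                  n_consumers = 20, n_stations = 5, seed = 3)
  ds <- simulate_consumers(scn)
  zero <- data.frame(station_id = ds$stations$station_id,
                     offset_c = 0, offset_n = 0)
  expect_equal(simulate_baseline_gradient(ds, zero)$samples, ds$samples)

  grad <- data.frame(station_id = ds$stations$station_id,
                     offset_c = c(1, 0, 0, 0, 0), offset_n = 0)
  shifted <- simulate_baseline_gradient(ds, grad)
  s1 <- ds$samples$station_id == "S01"
  expect_equal(shifted$samples$d13c[s1], ds$samples$d13c[s1] + 1)
  expect_equal(shifted$samples$d13c[!s1], ds$samples$d13c[!s1])

  # apply then correct with the true local baselines: exact inversion
  grad2 <- data.frame(station_id = ds$stations$station_id,
                      offset_c = rnorm(5), offset_n = rnorm(5))
  sh <- simulate_baseline_gradient(ds, grad2)
  idx <- match(sh$samples$station_id, grad2$station_id)
  base_mean <- 9.0
  rec_c <- baseline_correct(sh$samples$d13c, base_mean + grad2$offset_c[idx],
                            base_mean)
  rec_n <- baseline_correct(sh$samples$d15n, base_mean + grad2$offset_n[idx],
                            base_mean)
  expect_equal(rec_c, ds$samples$d13c, tolerance = 1e-12)
  expect_equal(rec_n, ds$samples$d15n, tolerance = 1e-12)

  expect_error(simulate_baseline_gradient(ds, grad2[-1, ]), "S01")
})

test_that("station environment variables track the depth gradient", {
  st <- make_stations(24, c(10, 90), seed = 4)
  expect_true(cor(st$depth, st$bot_temp) < -0.9)
  expect_true(cor(st$depth, st$salinity) > 0.9)
  expect_true(cor(st$depth, log(st$chla)) < -0.9)
  expect_identical(make_stations(24, c(10, 90), 4), st)
})
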