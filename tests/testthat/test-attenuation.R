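test_that("spherical loss follows 20 log10 of the distance ratio", {
  expect_equal(spherical_loss(0.5), 0)
  expect_equal(spherical_loss(1), 20 * log10(2), tolerance = 1e-9)
  expect_equal(spherical_loss(1), 6.02, tolerance = 0.005)
  expect_equal(spherical_loss(8), 24.08, tolerance = 0.005)
  expect_error(spherical_loss(-1), "positive")
  expect_error(spherical_loss(0.2), "below the reference")
})

test_that("excess attenuation subtracts the spherical prediction with the right sign", {
  # a purely spherical field: 75 dB at 0.5 m is 50.92 dB at 8 m
  expect_equal(excess_attenuation(75, 75 - 20 * log10(16), 8), 0)
  expect_equal(excess_attenuation(75, 50.92, 8), 0, tolerance = 0.005)
  expect_equal(excess_attenuation(75, 45, 8), 5.92, tolerance = 0.005)
  # negative: attenuated less than spherical
  expect_equal(excess_attenuation(75, 65, 2), -2.04, tolerance = 0.005)
})

test_that("db_mean averages on the linear pressure scale", {
  expect_equal(round_half_away(db_mean(c(1.76, 0.22)), 2), 1.02)
  expect_equal(round_half_away(db_mean(c(2.17, 1.20, -0.80, 3.42)), 2),
               1.63)
  # idempotent on constants
  expect_equal(db_mean(rep(-3.7, 6)), -3.7, tolerance = 1e-12)
  expect_error(db_mean(numeric(0)), "empty")
  expect_error(db_mean(c(1, NA)), "finite")
})

test_that("db_mean dominates the arithmetic mean (Jensen) and nests", {
  set.seed(10)
  for (i in 1:25) {
    v <- rnorm(8, sd = 6)
    expect_gte(db_mean(v), mean(v) - 1e-12)
    # nesting: grand linear mean equals linear mean of equal-sized halves
    expect_equal(db_mean(v),
                 db_mean(c(db_mean(v[1:4]), db_mean(v[5:8]))),
                 tolerance = 1e-9)
  }
  v <- rep(2.5, 4)
  expect_equal(db_mean(v), mean(v))  # equality iff all equal
})

test_that("frequency binning matches the printed category ranges", {
  expect_equal(as.character(bin_frequency(500)), "F1")
  expect_equal(as.character(bin_frequency(2500)), "F4")
  expect_equal(as.character(bin_frequency(3000)), "F4")
  expect_equal(as.character(bin_frequency(c(200, 1000, 1100, 3500, 5000))),
               c("F1", "F2", "F3", "F5", "F5"))
  expect_true(is.na(bin_frequency(3200)))   # gap 3.0-3.5
  expect_true(is.na(bin_frequency(550)))    # gap 0.5-0.6
  expect_true(is.na(bin_frequency(5500)))   # above range
})

test_that("EA records pair far distances with the reference and drop invalid rows", {
  m <- data.frame(
    locality = "L", substrate = "water",
    distance = c(0.5, 1, 2, 4, 8, 0.5, 1),
    signal_id = c(rep("tone_1000", 5), "tone_9999", "tone_9999"),
    kind = "tone", frequency = c(rep(1000, 5), 9999, 9999),
    species = NA_character_,
    spl_rms = c(70, 63.98, 57.96, 51.94, 45.92, 70, 60),
    spl_peak = 99, snr = 40,
    valid = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  ea <- ea_from_measurements(m, quiet = TRUE)
  expect_equal(nrow(ea), 4)  # invalid far row dropped
  expect_equal(ea$excess_attenuation, rep(0, 4), tolerance = 0.005)
  expect_equal(as.character(ea$frequency_category), rep("F2", 4))
})

test_that("per-cell call averaging uses the linear scale and flags small cells", {
  ea <- expand.grid(call = paste0("c", 1:6), distance = c(1, 2))
  ea$signal_id <- paste0("Pp1_", ea$call)
  ea$individual <- "Pp1"
  ea$locality <- "L"; ea$substrate <- "soil"; ea$kind <- "call"
  ea$species <- "P_perezi"
  ea$excess_attenuation <- ifelse(ea$distance == 1, 4, c(2, 1, -1, 3, 2, 0))
  out <- species_call_ea(ea)
  expect_equal(nrow(out), 2)
  expect_equal(out$excess_attenuation[out$distance == 1], 4)
  expect_equal(out$excess_attenuation[out$distance == 2],
               db_mean(c(2, 1, -1, 3, 2, 0)))
  expect_false(any(out$flagged))
  out2 <- species_call_ea(ea[ea$call %in% c("c1", "c2"), ], min_calls = 4)
  expect_true(all(out2$flagged))
})

test_that("summary cells bound their linear mean by the dB extrema", {
  set.seed(3)
  ea <- expand.grid(substrate = c("water", "soil"),
                    frequency_category = c("F1", "F2"),
                    rep = 1:10)
  ea$excess_attenuation <- rnorm(nrow(ea), sd = 5)
  s <- summarize_ea(ea, c("substrate", "frequency_category"))
  expect_equal(nrow(s), 4)
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
  expect_true(all(s$n == 10))
  # group means exceed arithmetic means (linear-scale averaging)
  arith <- aggregate(excess_attenuation ~ substrate + frequency_category,
                     ea, mean)
  expect_true(all(s$mean >= arith$excess_attenuation - 1e-12))
})

test_that("recovered EA matches an imposed flat profile across distances", {
  tr <- cached("flat3", flat_transect(ea = 3, noise_spl = 10))
  got <- ea_by_distance(tr)
  expect_equal(got$excess_attenuation, 3 * log2(c(1, 2, 4, 8) / 0.5),
               tolerance = 0.5)
})
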