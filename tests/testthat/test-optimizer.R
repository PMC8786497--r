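cfg0 <- hybrid_config()

test_that("chromosome layout is 57 bits with the stated resolutions", {
  expect_identical(length(encode_transform(rigid_transform(), cfg0)), 57L)
  res <- encoding_resolution(cfg0)
  expect_equal(unname(res["translation_mm"]), 30 / 511)
  expect_equal(unname(res["rotation_deg"]), 20 / 1023)
  expect_equal(round(unname(res["translation_mm"]), 2), 0.06)
  expect_equal(round(unname(res["rotation_deg"]), 2), 0.02)
})

test_that("encoding maps range edges to all-zero / all-one chromosomes", {
  lo <- rigid_transform(t = rep(-15, 3), phi = rep(-10, 3))
  hi <- rigid_transform(t = rep(15, 3), phi = rep(10, 3))
  expect_identical(encode_transform(lo, cfg0), rep(0L, 57))
  expect_identical(encode_transform(hi, cfg0), rep(1L, 57))
  # out-of-range parameters are clamped, not errors
  far <- rigid_transform(t = rep(100, 3), phi = rep(-100, 3))
  bits <- encode_transform(far, cfg0)
  expect_identical(bits[1:27], rep(1L, 27))
  expect_identical(bits[28:57], rep(0L, 30))
})

test_that("decoding inverts encoding and quantizes the identity to half a step", {
  expect_rigid_equal(decode_chromosome(rep(0L, 57), cfg0),
                     rigid_transform(t = rep(-15, 3), phi = rep(-10, 3)))
  # single lowest-order bit in the tx field
  bits <- rep(0L, 57); bits[9] <- 1L
  tf <- decode_chromosome(bits, cfg0)
  expect_equal(tf$t[1], -15 + 30 / 511, tolerance = 1e-12)
  expect_equal(tf$t[1], -14.9413, tolerance = 1e-4)
  # zero transform decodes back within half a quantization step
  tf0 <- decode_chromosome(encode_transform(rigid_transform(), cfg0), cfg0)
  res <- encoding_resolution(cfg0)
  expect_true(all(abs(tf0$t) <= res["translation_mm"] / 2))
  expect_true(all(abs(tf0$phi) <= res["rotation_deg"] / 2))
  # encode(decode(bits)) is the identity on random chromosomes
  set.seed(41)
  for (i in 1:20) {
    b <- as.integer(runif(57) < 0.5)
    expect_identical(encode_transform(decode_chromosome(b, cfg0), cfg0), b)
  }
  expect_error(decode_chromosome(rep(0L, 56), cfg0), "57")
})

test_that("initial temperature follows the mean positive increment closed form", {
  # objective alternating 0, 1 makes every pair increment +1 or -1
  flip <- local({ k <- 0; function(tf) { k <<- k + 1; k %% 2 } })
  cfg <- hybrid_config(chi0 = exp(-1), t0_samples = 50L)
  set.seed(42)
  expect_equal(initial_temperature(flip, cfg), 1)
  # mean positive increment 0.5 at chi0 = 0.9
  half <- local({ k <- 0; function(tf) { k <<- k + 1; 0.5 * (k %% 2) } })
  cfg9 <- hybrid_config(chi0 = 0.9, t0_samples = 50L)
  set.seed(42)
  expect_equal(initial_temperature(half, cfg9), 0.5 / log(10 / 9),
               tolerance = 1e-12)
  expect_equal(0.5 / log(10 / 9), 4.746, tolerance = 1e-3)
  set.seed(42)
  expect_error(initial_temperature(function(tf) 1, cfg9), "degenerate")
})

test_that("worse moves at T0 are accepted at roughly the configured rate", {
  set.seed(43)
  mi_vals <- runif(400, 0.2, 0.8)
  obj <- local({ k <- 0; function(tf) { k <<- k + 1; mi_vals[k] } })
  cfg <- hybrid_config(chi0 = 0.9, t0_samples = 200L)
  set.seed(44)
  T0 <- initial_temperature(obj, cfg)
  # acceptance rate of typical worse moves at T0
  set.seed(45)
  dec <- replicate(20000, {
    d <- abs(diff(sample(mi_vals, 2)))
    metropolis_accept(0, d, T0)
  })
  expect_gte(mean(dec), cfg$chi0 - 0.15)
  expect_lte(mean(dec), 1)
})

test_that("fitness shift anchors the minimum at zero and preserves order", {
  expect_equal(fitness_shift(c(0.3, 0.5, 0.2)), c(0.1, 0.3, 0.0))
  expect_equal(fitness_shift(rep(0.4, 5)), rep(0, 5))
  x <- c(0.12, 0.93, 0.48, 0.2)
  expect_equal(fitness_shift(x + 7), fitness_shift(x))
  expect_identical(order(fitness_shift(x)), order(x))
})

test_that("roulette selection frequencies match fitness proportions", {
  set.seed(46)
  sel <- roulette_select(c(1, 0, 0), 100)
  expect_true(all(sel == 1L))

  set.seed(47)
  sel <- roulette_select(c(3, 1), 5e4)  # 1e5 draws
  expect_equal(mean(sel == 1L), 0.75, tolerance = 0.015)

  set.seed(48)
  sel <- roulette_select(c(0, 0, 0, 0), 5e4)
  freq <- tabulate(sel, 4) / length(sel)
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("crossover and mutation behave as configured", {
  p1 <- rep(0L, 57); p2 <- rep(1L, 57)
  # no variation: children equal parents
  cfg <- hybrid_config(p_cross = 0, p_mut = 0)
  kids <- crossover_mutate(p1, p2, cfg)
  expect_identical(kids[[1]], p1)
  expect_identical(kids[[2]], p2)
  # forced crossover swaps tails at the drawn cut point
  cfg1 <- hybrid_config(p_cross = 1, p_mut = 0)
  set.seed(49)
  found_cut9 <- FALSE
  for (i in 1:200) {
    kids <- crossover_mutate(p1, p2, cfg1)
    cut <- sum(kids[[1]] == 0L)
    expect_identical(kids[[1]], c(rep(0L, cut), rep(1L, 57 - cut)))
    expect_identical(kids[[2]], c(rep(1L, cut), rep(0L, 57 - cut)))
    if (cut == 9) found_cut9 <- TRUE
  }
  expect_true(found_cut9)
  # expected flips per child = 57 * 0.02 = 1.14
  cfgm <- hybrid_config(p_cross = 0, p_mut = 0.02)
  set.seed(50)
  flips <- replicate(5e3, {
    kids <- crossover_mutate(p1, p2, cfgm)
    c(sum(kids[[1]] != p1), sum(kids[[2]] != p2))
  })
  expect_equal(mean(flips), 1.14, tolerance = 0.05 / 1.14)
})

test_that("Metropolis acceptance is exact for improving moves and calibrated for worse ones", {
  set.seed(51)
  expect_true(metropolis_accept(0.5, 0.4, 1e-8))
  expect_true(metropolis_accept(0.4, 0.4, 1e-8))
  # acceptance frequency e^-1 at a deficit equal to T
  set.seed(52)
  acc <- replicate(1e5, metropolis_accept(0.3, 0.3 + 0.05, 0.05))
  expect_equal(mean(acc), exp(-1), tolerance = 0.01 / exp(-1))
  # greedy limit
  set.seed(53)
  expect_false(any(replicate(100, metropolis_accept(0.2, 0.4, 1e-12))))
  expect_error(metropolis_accept(1, 0, 0), "temperature")
})

test_that("hybrid runs are reproducible, elitist and absorbing without variation", {
  pp <- small_phantom(seed = 54)
  cfg <- hybrid_config(seed = 7, pop_size = 20L, max_generations = 12L,
                       stagnation_generations = 12L)
  r1 <- run_hybrid(pp$ref, pp$flt, cfg, bins = 16)
  r2 <- run_hybrid(pp$ref, pp$flt, cfg, bins = 16)
  expect_identical(r1$history, r2$history)
  expect_rigid_equal(r1$best_transform, r2$best_transform)
  # best-ever trace is non-decreasing and matches the reported maximum
  expect_true(all(diff(r1$history$best_mi) >= 0))
  expect_equal(max(r1$history$best_mi), r1$best_mi, tolerance = 1e-12)
  expect_identical(nrow(r1$history), r1$generations_run)

  # with no crossover and no mutation every slot keeps an initial genotype
  cfg0v <- hybrid_config(seed = 8, pop_size = 12L, p_cross = 0, p_mut = 0,
                         max_generations = 6L, stagnation_generations = 6L)
  set.seed(cfg0v$seed)
  obj <- mi_objective(pp$ref, pp$flt, bins = 16)
  r0 <- run_hybrid_objective(obj, cfg0v)
  set.seed(cfg0v$seed)
  invisible(initial_temperature(obj, cfg0v))
  init <- replicate(12, paste(as.integer(runif(57) < 0.5), collapse = ""))
  best_key <- paste(encode_transform(r0$best_transform, cfg0v), collapse = "")
  expect_true(best_key %in% init)
})

test_that("self-registration recovers the identity near the quantization floor", {
  # aligned multimodal pair: the optimum is the identity up to sub-voxel
  # CoG offsets between the two renderings; most seeded runs must land
  # within half a millimetre / half a degree of it
  pp <- make_phantom_pair(phantom_spec(dims = c(32, 32, 32), seed = 55))
  mask <- foreground_mask(pp$ref, 0.5)
  hits <- 0L
  for (s in 1:5) {
    r <- run_hybrid(pp$ref, pp$flt, hybrid_config(seed = s), bins = 32,
                    mask = mask)
    ok <- all(abs(r$best_transform$t) < 0.5) &&
      all(abs(r$best_transform$phi) < 0.5)
    hits <- hits + ok
  }
  expect_gte(hits, 4L)
})
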