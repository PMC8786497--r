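#' Configuration of the hybrid GA-SA optimizer
#'
#' The optimizer searches the 6 rigid parameters as binary chromosomes of
#' length 57: translations on 9 bits each over `t_range` mm and rotations
#' on 10 bits each over `phi_range` degrees, giving quantization steps of
#' about 0.06 mm/bit and 0.02 deg/bit. Each generation applies roulette
#' selection, single-point crossover and per-bit mutation; children replace
#' their parents according to a Metropolis criterion at the current
#' temperature, which then cools geometrically (`T <- alpha * T`).
#'
#' @param pop_size population size (even, `>= 4`; default 50).
#' @param p_cross single-point crossover probability (default 0.6).
#' @param p_mut per-bit mutation probability (default 0.02).
#' @param t_range translation search range in mm (default `c(-15, 15)`).
#' @param phi_range rotation search range in degrees (default `c(-10, 10)`).
#' @param chi0 target initial acceptance rate in `(0, 1)` used to derive the
#'   starting temperature (default 0.9; the closer to 1, the hotter the
#'   start).
#' @param alpha geometric cooling factor in `(0, 1)` (default 0.95).
#' @param t0_samples number of random transform pairs used to estimate the
#'   mean positive objective increment for the starting temperature
#'   (default 50).
#' @param max_generations stop after this many generations (default 200).
#' @param stagnation_generations stop when the best-ever MI has not improved
#'   for this many generations (default 60).
#' @param t_min_frac stop when the temperature drops below this fraction of
#'   the starting temperature (default 1e-5).
#' @param seed RNG seed making a run fully reproducible.
#' @return a list of class `hybrid_config`.
#' @export
hybrid_config <- function(pop_size = 50L, p_cross = 0.6, p_mut = 0.02,
                          t_range = c(-15, 15), phi_range = c(-10, 10),
                          chi0 = 0.9, alpha = 0.95, t0_samples = 50L,
                          max_generations = 200L,
                          stagnation_generations = 60L,
                          t_min_frac = 1e-5, seed = 1L) {
  pop_size <- as.integer(pop_size)
  if (is.na(pop_size) || pop_size < 4L || pop_size %% 2L != 0L)
    stop("'pop_size' must be an even integer >= 4")
  if (p_cross < 0 || p_cross > 1 || p_mut < 0 || p_mut > 1)
    stop("probabilities must lie in [0, 1]")
  if (t_range[1] >= t_range[2] || phi_range[1] >= phi_range[2])
    stop("parameter ranges must be ordered (lo < hi)")
  if (chi0 <= 0 || chi0 >= 1) stop("'chi0' must lie strictly in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie strictly in (0, 1)")
  structure(list(pop_size = pop_size, p_cross = p_cross, p_mut = p_mut,
                 t_range = as.numeric(t_range),
                 phi_range = as.numeric(phi_range),
                 chi0 = chi0, alpha = alpha,
                 t0_samples = as.integer(t0_samples),
                 max_generations = as.integer(max_generations),
                 stagnation_generations = as.integer(stagnation_generations),
                 t_min_frac = t_min_frac, seed = as.integer(seed)),
            class = "hybrid_config")
}

# bit widths per parameter in coding order (tx, ty, tz, phi_x, phi_y, phi_z)
CHROMOSOME_BITS <- c(9L, 9L, 9L, 10L, 10L, 10L)
CHROMOSOME_LENGTH <- sum(CHROMOSOME_BITS)  # 57

#' Parameter quantization resolution
#'
#' Step sizes `(hi - lo) / (2^bits - 1)` implied by the encoding: about
#' 0.06 mm/bit for translations (30 mm over 9 bits) and about 0.02 deg/bit
#' for rotations (20 degrees over 10 bits).
#'
#' @param cfg a [hybrid_config()].
#' @return named vector `c(translation_mm = , rotation_deg = )`.
#' @export
encoding_resolution <- function(cfg = hybrid_config()) {
  c(translation_mm = diff(cfg$t_range) / (2^9 - 1),
    rotation_deg = diff(cfg$phi_range) / (2^10 - 1))
}

int_to_bits <- function(i, b) {
  # big-endian plain binary
  rev(as.integer(bitwAnd(bitwShiftR(i, 0:(b - 1L)), 1L)))
}

bits_to_int <- function(bits) {
  sum(bits * 2^(rev(seq_along(bits)) - 1))
}

chromosome_fields <- function() {
  ends <- cumsum(CHROMOSOME_BITS)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(seq, starts, ends)
}

param_ranges <- function(cfg) {
  rbind(matrix(cfg$t_range, 3, 2, byrow = TRUE),
        matrix(cfg$phi_range, 3, 2, byrow = TRUE))
}

#' Encode a rigid transform as a 57-bit chromosome
#'
#' Each parameter `p` is clamped to its range, quantized to the integer
#' `round((p - lo) / (hi - lo) * (2^b - 1))` and written big-endian as
#' plain binary; fields are concatenated in the order
#' (tx, ty, tz, phi_x, phi_y, phi_z) with 9 bits per translation and 10
#' bits per rotation.
#'
#' @param tf a [rigid_transform()].
#' @param cfg a [hybrid_config()] supplying the parameter ranges.
#' @return integer vector of 57 bits (0/1).
#' @export
encode_transform <- function(tf, cfg = hybrid_config()) {
  params <- c(tf$t, tf$phi)
  rng <- param_ranges(cfg)
  fields <- chromosome_fields()
  bits <- integer(CHROMOSOME_LENGTH)
  for (k in 1:6) {
    lo <- rng[k, 1]; hi <- rng[k, 2]
    p <- min(max(params[k], lo), hi)
    i <- as.integer(round((p - lo) / (hi - lo) * (2^CHROMOSOME_BITS[k] - 1)))
    bits[fields[[k]]] <- int_to_bits(i, CHROMOSOME_BITS[k])
  }
  bits
}

#' Decode a 57-bit chromosome into a rigid transform
#'
#' Inverse of [encode_transform()]: `p = lo + i / (2^b - 1) * (hi - lo)`,
#' so both range endpoints are reachable exactly.
#'
#' @param bits integer vector of 57 bits (0/1).
#' @inheritParams encode_transform
#' @return a [rigid_transform()].
#' @export
decode_chromosome <- function(bits, cfg = hybrid_config()) {
  if (length(bits) != CHROMOSOME_LENGTH)
    stop("chromosome must have exactly ", CHROMOSOME_LENGTH, " bits")
  rng <- param_ranges(cfg)
  fields <- chromosome_fields()
  params <- vapply(1:6, function(k) {
    i <- bits_to_int(bits[fields[[k]]])
    rng[k, 1] + i / (2^CHROMOSOME_BITS[k] - 1) * (rng[k, 2] - rng[k, 1])
  }, numeric(1))
  rigid_transform(t = params[1:3], phi = params[4:6])
}

#' Starting temperature from random objective increments
#'
#' Draws `cfg$t0_samples` pairs of random transforms uniform over the
#' search ranges, takes the mean of the positive objective increments
#' between the members of each pair, and sets
#' `T0 = mean_increment / log(1 / chi0)` so that a typical worsening move
#' is initially accepted with probability about `chi0`.
#'
#' Consumes the current RNG stream.
#'
#' @param objective function `RigidTransform -> scalar` being maximized.
#' @param cfg a [hybrid_config()].
#' @return positive scalar starting temperature.
#' @export
initial_temperature <- function(objective, cfg = hybrid_config()) {
  draw <- function() {
    rigid_transform(t = stats::runif(3, cfg$t_range[1], cfg$t_range[2]),
                    phi = stats::runif(3, cfg$phi_range[1], cfg$phi_range[2]))
  }
  inc <- vapply(seq_len(cfg$t0_samples), function(i) {
    objective(draw()) - objective(draw())
  }, numeric(1))
  pos <- inc[inc > 0]
  if (length(pos) == 0L)
    stop("degenerate objective: no positive increments among random transforms")
  mean(pos) / log(1 / cfg$chi0)
}

#' Shift mutual-information values to non-negative fitness
#'
#' Fitness of each individual is its MI minus the generation's minimum MI,
#' making fitness non-negative for roulette selection while preserving the
#' ordering.
#'
#' @param mi_values numeric vector of MI values.
#' @return numeric vector with minimum 0.
#' @export
fitness_shift <- function(mi_values) {
  if (length(mi_values) == 0L) stop("empty fitness list")
  mi_values - min(mi_values)
}

#' Fitness-proportionate (roulette) selection of parent pairs
#'
#' Each parent is drawn independently with probability proportional to its
#' fitness; when all fitness values are zero the draw is uniform. Pairs may
#' repeat.
#'
#' @param fitness non-negative numeric vector.
#' @param n_pairs number of pairs to draw.
#' @return `n_pairs x 2` integer matrix of parent indices.
#' @export
roulette_select <- function(fitness, n_pairs) {
  stopifnot(n_pairs >= 1, all(fitness >= 0))
  prob <- if (sum(fitness) > 0) fitness / sum(fitness)
          else rep(1 / length(fitness), length(fitness))
  idx <- sample.int(length(fitness), 2L * n_pairs, replace = TRUE,
                    prob = prob)
  matrix(idx, ncol = 2L)
}

#' Single-point crossover and bitwise mutation
#'
#' With probability `p_cross` a cut point uniform in 1..56 swaps the tails
#' of the two parents; each bit of each child then flips independently with
#' probability `p_mut`.
#'
#' @param p1,p2 parent chromosomes (57 bits each).
#' @param cfg a [hybrid_config()].
#' @return list of two child chromosomes.
#' @export
crossover_mutate <- function(p1, p2, cfg = hybrid_config()) {
  stopifnot(length(p1) == CHROMOSOME_LENGTH,
            length(p2) == CHROMOSOME_LENGTH)
  c1 <- p1; c2 <- p2
  if (stats::runif(1) < cfg$p_cross) {
    cut <- sample.int(CHROMOSOME_LENGTH - 1L, 1L)
    tail_idx <- (cut + 1L):CHROMOSOME_LENGTH
    c1[tail_idx] <- p2[tail_idx]
    c2[tail_idx] <- p1[tail_idx]
  }
  if (cfg$p_mut > 0) {
    f1 <- stats::runif(CHROMOSOME_LENGTH) < cfg$p_mut
    f2 <- stats::runif(CHROMOSOME_LENGTH) < cfg$p_mut
    c1[f1] <- 1L - c1[f1]
    c2[f2] <- 1L - c2[f2]
  }
  list(c1, c2)
}

#' Metropolis acceptance for a maximization step
#'
#' A child at least as good as its parent is always accepted; a worse one
#' is accepted with probability `exp(-(f_parent - f_child) / T)`, letting
#' the search escape local optima while the temperature is high.
#'
#' @param f_child,f_parent objective values (being maximized).
#' @param temperature current temperature, `> 0`.
#' @return logical.
#' @export
metropolis_accept <- function(f_child, f_parent, temperature) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be positive")
  if (f_child >= f_parent) return(TRUE)
  stats::runif(1) < exp(-(f_parent - f_child) / temperature)
}

#' Register two volumes with the hybrid GA-SA optimizer
#'
#' Maximizes the partial-volume mutual information between `ref` and the
#' transformed `flt` over the 6 rigid parameters. Per generation: all
#' individuals are scored, fitness is the MI shifted by the generation
#' minimum, `pop_size / 2` parent pairs are drawn by roulette, children are
#' produced by single-point crossover and bitwise mutation, and each child
#' competes against its own parent under the Metropolis criterion on raw MI
#' at the current temperature, which afterwards cools by `alpha`. The
#' best-ever individual is archived separately (elitism) and returned. The
#' run stops at `max_generations`, on best-MI stagnation, or when the
#' temperature falls below `t_min_frac * T0`.
#'
#' A single RNG stream seeded from `cfg$seed` drives, in order: the
#' starting-temperature probe, population initialization, and then per
#' generation selection, crossover/mutation and Metropolis draws, so runs
#' are bit-reproducible.
#'
#' @param ref,flt reference and floating [volume()]s.
#' @param cfg a [hybrid_config()].
#' @param bins,mask,stride forwarded to [mi_objective()].
#' @param verbose print a per-generation line.
#' @return An object of class `registration_result` with fields
#'   `best_transform`, `best_mi`, `generations_run`, `history` (data frame
#'   with generation, temperature, best and mean MI) and `seed`.
#' @export
run_hybrid <- function(ref, flt, cfg = hybrid_config(), bins = 64L,
                       mask = NULL, stride = c(1L, 1L, 1L),
                       verbose = FALSE) {
  objective <- mi_objective(ref, flt, bins = bins, mask = mask,
                            stride = stride)
  run_hybrid_objective(objective, cfg, verbose = verbose)
}

#' Run the hybrid optimizer on an arbitrary objective
#'
#' The same search as [run_hybrid()] but over a user-supplied objective
#' function `RigidTransform -> scalar` (maximized). Useful for testing the
#' optimizer on analytic surfaces.
#'
#' @param objective function of a [rigid_transform()].
#' @inheritParams run_hybrid
#' @return a `registration_result`.
#' @export
run_hybrid_objective <- function(objective, cfg = hybrid_config(),
                                 verbose = FALSE) {
  stopifnot(inherits(cfg, "hybrid_config"))
  set.seed(cfg$seed)
  n <- cfg$pop_size

  temperature <- initial_temperature(objective, cfg)
  t_min <- cfg$t_min_frac * temperature

  pop <- lapply(seq_len(n), function(i)
    as.integer(stats::runif(CHROMOSOME_LENGTH) < 0.5))
  mi <- vapply(pop, function(b) objective(decode_chromosome(b, cfg)),
               numeric(1))

  best_i <- which.max(mi)
  best_bits <- pop[[best_i]]
  best_mi <- mi[best_i]
  stagnant <- 0L
  history <- vector("list", cfg$max_generations)
  gen <- 0L

  while (gen < cfg$max_generations &&
         stagnant < cfg$stagnation_generations &&
         temperature >= t_min) {
    gen <- gen + 1L
    pairs <- roulette_select(fitness_shift(mi), n %/% 2L)
    # children compete with their own parents in place: the population
    # persists and an individual changes only when it is selected and its
    # child passes the Metropolis test, so good genotypes ratchet upward
    # while unselected ones survive as a diversity reservoir
    for (k in seq_len(nrow(pairs))) {
      i1 <- pairs[k, 1]; i2 <- pairs[k, 2]
      kids <- crossover_mutate(pop[[i1]], pop[[i2]], cfg)
      parents_idx <- c(i1, i2)
      for (m in 1:2) {
        pi <- parents_idx[m]
        f_child <- objective(decode_chromosome(kids[[m]], cfg))
        if (metropolis_accept(f_child, mi[pi], temperature)) {
          pop[[pi]] <- kids[[m]]
          mi[pi] <- f_child
        }
      }
    }

    gen_best <- which.max(mi)
    if (mi[gen_best] > best_mi + 1e-12) {
      best_mi <- mi[gen_best]
      best_bits <- pop[[gen_best]]
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
    }
    history[[gen]] <- data.frame(generation = gen,
                                 temperature = temperature,
                                 best_mi = best_mi,
                                 mean_mi = mean(mi))
    if (verbose)
      message(sprintf("gen %3d  T=%.5g  best MI=%.5f  mean MI=%.5f",
                      gen, temperature, best_mi, mean(mi)))
    temperature <- temperature * cfg$alpha
  }

  structure(list(best_transform = decode_chromosome(best_bits, cfg),
                 best_mi = best_mi,
                 generations_run = gen,
                 history = do.call(rbind, history[seq_len(gen)]),
                 seed = cfg$seed),
            class = "registration_result")
}

#' Read an optimizer configuration from a key-value file
#'
#' Plain-text `key: value` lines naming [hybrid_config()] arguments
#' (`pop_size`, `p_cross`, `p_mut`, `t_range`, `phi_range`, `chi0`,
#' `alpha`, `t0_samples`, `max_generations`, `stagnation_generations`,
#' `t_min_frac`, `seed`); ranges take two numbers. Unknown keys are an
#' error; omitted keys keep their defaults.
#'
#' @param path config file.
#' @return a [hybrid_config()].
#' @export
read_hybrid_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- lapply(kv, function(x)
    as.numeric(strsplit(trimws(paste(x[-1], collapse = ":")), "[ ,]+")[[1]]))
  names(vals) <- keys
  allowed <- names(formals(hybrid_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(hybrid_config, vals)
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> best MI = %.5f nats after %d generations (seed %d)\n",
              x$best_mi, x$generations_run, x$seed))
  print(x$best_transform)
  invisible(x)
}
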