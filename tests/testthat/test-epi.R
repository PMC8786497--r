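test_that("detection and lesion rates reproduce the cohort percentages", {
  expect_equal(rate(157, 190), 82.6)
  expect_equal(rate(56, 190), 29.5)
  expect_equal(rate(132, 157), 84.1)
  expect_equal(rate(0, 190), 0)
  expect_error(rate(1, 0), "positive")
  expect_error(rate(-1, 10), "k")
  # complementary rates sum to 100 within rounding
  for (k in c(0, 7, 93, 157)) {
    expect_equal(rate(k, 190) + rate(190 - k, 190), 100, tolerance = 0.051)
  }
})

test_that("lesion tables carry counts verbatim with one rate row per label", {
  types <- c(plaque = 132, intimal_thickening = 64, arteriosclerosis = 38,
             stenosis = 32, occlusion = 16)
  tab <- lesion_table(types, 157)
  expect_equal(tab$percent, c(84.1, 40.8, 24.2, 20.4, 10.2))
  expect_identical(tab$count, as.integer(types))

  arteries <- c(posterior_tibial = 105, dorsal = 90, femoral = 65,
                anterior_tibial = 54, radial = 40)
  expect_equal(lesion_table(arteries, 157)$percent,
               c(66.9, 57.3, 41.4, 34.4, 25.5))

  empty <- lesion_table(c(), 157)
  expect_identical(nrow(empty), 0L)
  expect_error(lesion_table(c(a = 200), 157), "denominator")
})

test_that("summary t tests match closed forms and stats::t.test", {
  a <- group_summary(157, 66.2, 6.6)
  b <- group_summary(33, 51.8, 5.4)
  eq <- two_sample_t(a, a)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  # pooled t from the printed summaries (textbook formula)
  tt <- two_sample_t(a, b, "pooled")
  expect_equal(tt$t, 11.73, tolerance = 1e-3)
  expect_equal(tt$df, 188)
  expect_lt(tt$p, 1e-10)

  tiny <- two_sample_t(group_summary(2, 0, 1), group_summary(2, 1, 1))
  expect_equal(tiny$t, -1)
  expect_equal(tiny$df, 2)

  # welch variant agrees with stats::t.test on raw data
  set.seed(71)
  x <- rnorm(20, 1, 2); y <- rnorm(15, 0, 1)
  ours <- two_sample_t(group_summary(20, mean(x), sd(x)),
                       group_summary(15, mean(y), sd(y)), "welch")
  ref <- t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_error(two_sample_t(group_summary(3, 1, 0), group_summary(3, 1, 0)),
               "variance")
})

test_that("2x2 chi-square follows the closed form and the z-test identity", {
  flat <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(flat$chisq, 0)
  expect_equal(flat$p, 1)

  sep <- chi_square_2x2(matrix(c(20, 0, 0, 20), 2, 2))
  expect_equal(sep$chisq, 40)
  expect_identical(sep$df, 1L)

  set.seed(72)
  for (i in 1:10) {
    m <- matrix(rpois(4, 30) + 1, 2, 2)
    chi <- chi_square_2x2(m)
    # squared two-proportion z statistic (no correction)
    p1 <- m[1, 1] / sum(m[1, ]); p2 <- m[2, 1] / sum(m[2, ])
    pp <- sum(m[, 1]) / sum(m)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / sum(m[1, ]) + 1 / sum(m[2, ])))
    expect_equal(chi$chisq, z^2, tolerance = 1e-9)
  }
  expect_error(chi_square_2x2(matrix(c(5, 5, 0, 0), 2, 2)), "marginal")
})

test_that("rank-sum statistics agree with wilcox.test and conserve ranks", {
  sep <- rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$W, 6)  # minimum possible rank sum

  set.seed(73)
  x <- round(rnorm(25, 0, 2), 1)  # rounding forces ties
  y <- round(rnorm(30, 0.5, 2), 1)
  ours <- rank_sum(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  # wilcox.test reports U = W - n1 (n1 + 1) / 2
  expect_equal(ours$W - length(x) * (length(x) + 1) / 2,
               unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)

  # rank conservation
  expect_equal(ours$W + rank_sum(y, x)$W,
               (length(x) + length(y)) * (length(x) + length(y) + 1) / 2)

  idn <- rank_sum(1:20, 1:20)
  expect_gt(idn$p, 0.9)
})

test_that("IRLS logistic regression matches glm and satisfies the score equations", {
  set.seed(74)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 0.8 * x1 - 0.5 * x2))
  X <- cbind(x1, x2)
  fit <- fit_logistic(X, y)
  ref <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-6)
  # score equations at convergence
  resid <- y - fit$fitted
  expect_lt(max(abs(crossprod(cbind(1, X), resid))), 1e-6)

  # intercept-only model fits the outcome prevalence
  fit0 <- fit_logistic(matrix(nrow = n, ncol = 0), y)
  expect_equal(unique(round(fit0$fitted, 12)), round(mean(y), 12))

  # complete separation is flagged
  ys <- as.integer(x1 > 0)
  expect_error(fit_logistic(cbind(x1), ys), "converge|separation")
})

test_that("a null slope stays within 3 standard errors of zero", {
  set.seed(75)
  n <- 500
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.4)  # independent of x
  fit <- fit_logistic(cbind(x), y)
  expect_lt(abs(fit$coefficients[2] / fit$se[2]), 3)
})

test_that("IRLS matches a brute-force likelihood grid on a small example", {
  x <- c(-2, -1.5, -1, -0.5, 0.5, 1, 1.5, 2)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  fit <- fit_logistic(cbind(x), y)
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * x)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  # coarse-to-fine grid maximization of the log-likelihood (vectorized)
  grid_max <- function(b0s, b1s) {
    lls <- matrix(0, length(b0s), length(b1s))
    for (i in seq_along(x)) {
      eta <- outer(b0s, b1s * x[i], `+`)
      lls <- lls + y[i] * plogis(eta, log.p = TRUE) +
        (1 - y[i]) * plogis(-eta, log.p = TRUE)
    }
    k <- arrayInd(which.max(lls), dim(lls))
    list(b0 = b0s[k[1]], b1 = b1s[k[2]], ll = max(lls))
  }
  coarse <- grid_max(seq(-3, 3, by = 0.01), seq(-1, 3, by = 0.01))
  fine <- grid_max(seq(coarse$b0 - 0.02, coarse$b0 + 0.02, by = 1e-4),
                   seq(coarse$b1 - 0.02, coarse$b1 + 0.02, by = 1e-4))
  expect_equal(unname(fit$coefficients[1]), fine$b0, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients[2]), fine$b1, tolerance = 1e-4)
  expect_gte(fit$loglik, fine$ll - 1e-8)
})

test_that("Hosmer-Lemeshow handles flat fits and detects miscalibration", {
  set.seed(76)
  y <- rbinom(300, 1, 0.3)
  flat <- hosmer_lemeshow(rep(mean(y), 300), y)
  expect_equal(flat$H, 0, tolerance = 1e-9)

  # miscalibrated probabilities (true p vs reported p^2) are rejected often
  rej <- replicate(40, {
    p <- runif(2000, 0.1, 0.9)
    yy <- rbinom(2000, 1, p)
    hosmer_lemeshow(p^2, yy)$p < 0.05
  })
  expect_gt(mean(rej), 0.5)

  expect_error(hosmer_lemeshow(runif(10), rbinom(10, 1, 0.5), g = 10),
               "observations")
})

test_that("ROC analysis is exact on separable data and null-calibrated", {
  y <- c(rep(0, 10), rep(1, 10))
  s <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  r <- roc(s, y)
  expect_equal(r$auc, 1)
  expect_equal(r$youden$sensitivity, 1)
  expect_equal(r$youden$specificity, 1)

  set.seed(77)
  y2 <- rbinom(1000, 1, 0.5)
  r2 <- roc(runif(1000), y2)
  expect_equal(r2$auc, 0.5, tolerance = 0.1)

  expect_error(roc(runif(5), rep(1, 5)), "classes")
})

test_that("trapezoid AUC equals the tie-corrected Mann-Whitney probability", {
  set.seed(78)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    r <- roc(s, y)
    s1 <- s[y == 1]; s0 <- s[y == 0]
    u <- mean(outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(r$auc, u, tolerance = 1e-12)
    # complement symmetry
    expect_equal(roc(s, 1 - y)$auc, 1 - r$auc, tolerance = 1e-12)
  }
})

test_that("our ROC agrees with pROC on a tied example", {
  set.seed(79)
  y <- rbinom(80, 1, 0.4)
  s <- round(runif(80), 2)
  ours <- roc(s, y)
  theirs <- suppressMessages(pROC::roc(y, s, direction = "<"))
  expect_equal(ours$auc, as.numeric(pROC::auc(theirs)), tolerance = 1e-12)
})

test_that("synthetic cohorts track the target group summaries", {
  params <- cohort_params()
  tab <- simulate_cohort(seed = 80)
  expect_identical(nrow(tab), 190L)
  expect_identical(sum(tab$outcome), 157L)
  for (v in names(params$vars)) {
    for (gi in 1:2) {
      sub <- tab[[v]][tab$outcome == (gi == 1)]
      m <- params$vars[[v]]$mean[gi]; s <- params$vars[[v]]$sd[gi]
      expect_lt(abs(mean(sub) - m), 3 * s / sqrt(length(sub)) + 1e-9)
    }
  }
  expect_identical(simulate_cohort(seed = 80), tab)
  expect_error(simulate_cohort(params = within(cohort_params(), {
    vars$age$sd <- c(0, 1)
  })), "positive")
})

test_that("group differences built into the generator are recovered by the t test", {
  set.seed(83)
  seeds <- sample.int(1e6, 100)
  hits <- vapply(seeds, function(sd) {
    tab <- simulate_cohort(seed = sd)
    g1 <- tab$age[tab$outcome == 1]; g0 <- tab$age[tab$outcome == 0]
    tt <- two_sample_t(group_summary(length(g1), mean(g1), sd(g1)),
                       group_summary(length(g0), mean(g0), sd(g0)))
    tt$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cohort CSV roundtrips through read/write with validation", {
  dir <- withr::local_tempdir()
  tab <- simulate_cohort(seed = 81)
  path <- file.path(dir, "cohort.csv")
  write_cohort(tab, path)
  tab2 <- read_cohort(path)
  expect_equal(tab2$age, tab$age, tolerance = 1e-9)
  expect_identical(tab2$outcome, tab$outcome)

  bad <- tab; bad$age[1] <- NA
  write_cohort(bad, path)
  expect_error(read_cohort(path), "missing")
})

test_that("the risk model pipeline screens, fits, calibrates and discriminates", {
  tab <- simulate_cohort(seed = 82)
  rm <- risk_model(tab, g = 8L)
  expect_true(all(c("age", "sbp") %in% rm$selected))
  expect_gt(rm$roc$auc, 0.8)
  expect_true(is.finite(rm$hl$H))
  expect_identical(length(rm$fit$fitted), nrow(tab))
})
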