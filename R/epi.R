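#' Detection / lesion rate as a percentage
#'
#' @param k numerator count, `0 <= k <= n`.
#' @param n denominator count, `> 0`.
#' @return percentage rounded to one decimal.
#' @examples
#' rate(157, 190)  # 82.6
#' @export
rate <- function(k, n) {
  if (length(n) != 1L || is.na(n) || n <= 0) stop("'n' must be positive")
  if (any(k < 0) || any(k > n)) stop("'k' must lie in [0, n]")
  round(100 * k / n, 1)
}

#' Lesion-type / artery-involvement rate table
#'
#' One row per label with its count and percentage of the common
#' denominator, e.g. lesion types among detected vasculopathy cases.
#'
#' @param counts named integer vector of counts.
#' @param denominator common denominator, `> 0`.
#' @return data frame with columns `label`, `count`, `percent`.
#' @export
lesion_table <- function(counts, denominator) {
  if (length(counts) == 0L)
    return(data.frame(label = character(), count = integer(),
                      percent = numeric()))
  if (any(counts > denominator)) stop("counts cannot exceed the denominator")
  data.frame(label = names(counts),
             count = as.integer(counts),
             percent = rate(as.numeric(counts), denominator),
             row.names = NULL)
}

#' Group summary (n, mean, sd)
#'
#' Summary statistics of one variable in one group, as printed in clinical
#' baseline tables (`mean +/- sd`).
#'
#' @param n group size (`>= 2` for variance-based tests).
#' @param mean,sd sample mean and standard deviation (`sd >= 0`).
#' @return list of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  if (n < 2) stop("'n' must be >= 2")
  if (sd < 0) stop("'sd' must be >= 0")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' Two-sample t test from group summaries
#'
#' Pooled-variance (Student) or Welch t test computed directly from
#' `(n, mean, sd)` per group, with a two-sided p-value.
#'
#' @param a,b [group_summary()] objects.
#' @param variant `"pooled"` or `"welch"`.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (variant == "pooled") {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    if (sp2 <= 0) stop("zero pooled variance")
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    if (va + vb <= 0) stop("zero variance in both groups")
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  tval <- (a$mean - b$mean) / se
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Thin wrapper over [stats::chisq.test()] without continuity correction by
#' default (Yates available via `correct = TRUE`), with explicit checks on
#' the margins.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param correct apply Yates continuity correction.
#' @return list with `chisq`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L)) || any(table < 0))
    stop("'table' must be a 2x2 matrix of non-negative counts")
  if (sum(table) <= 0 || any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in the 2x2 table")
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(chisq = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Wilcoxon rank-sum test (normal approximation, tie-corrected)
#'
#' Reports the rank sum `W` of the first sample (midranks for ties) and a
#' two-sided p-value from the normal approximation with the tie-corrected
#' variance.
#'
#' @param x,y numeric samples.
#' @return list with `W` (rank sum of `x`), `z`, `p`.
#' @export
rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(list(W = W, z = 0, p = 1))  # all observations tied
  z <- (W - mu) / sqrt(v)
  list(W = W, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of `P(y = 1 | x) = plogis(b0 + x %*% b)`.
#' Newton-Raphson / IRLS iterations stop when the largest coefficient
#' change falls below `tol` or after `max_iter` iterations; a fit drifting
#' towards complete separation (fitted probabilities pinned at 0/1 with
#' unbounded coefficients) is flagged as non-converged and raises an error
#' unless `allow_nonconverged` is set.
#'
#' @param X numeric covariate matrix (subjects in rows), without an
#'   intercept column; one is added internally.
#' @param y binary 0/1 outcomes.
#' @param max_iter,tol IRLS controls.
#' @param allow_nonconverged return (with a warning) instead of erroring
#'   when the fit does not converge.
#' @return object of class `logistic_fit`: `coefficients`, `se`, `fitted`,
#'   `loglik`, `iterations`, `converged`.
#' @export
fit_logistic <- function(X, y, max_iter = 100L, tol = 1e-8,
                         allow_nonconverged = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1")
  if (nrow(X) != length(y)) stop("row count of 'X' must match length of 'y'")
  if (nrow(X) <= ncol(X) + 1L) stop("need more subjects than covariates")
  Xd <- cbind(`(Intercept)` = 1, X)
  if (qr(Xd)$rank < ncol(Xd)) stop("covariates are collinear")
  beta <- rep(0, ncol(Xd))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    w <- pmax(w, 1e-12)
    z <- eta + (y - p) / w
    fit <- stats::lm.wfit(Xd, z, w)
    delta <- fit$coefficients - beta
    beta <- fit$coefficients
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  p <- stats::plogis(drop(Xd %*% beta))
  if (!converged || max(abs(beta)) > 1e4) {
    msg <- "logistic fit did not converge (possible complete separation)"
    if (allow_nonconverged) warning(msg) else stop(msg)
    converged <- FALSE
  }
  info <- crossprod(Xd * sqrt(pmax(p * (1 - p), 1e-12)))
  se <- sqrt(diag(solve(info)))
  names(se) <- colnames(Xd)
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  structure(list(coefficients = beta, se = se, fitted = p, loglik = ll,
                 iterations = iter, converged = converged),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> log-likelihood", format(x$loglik, digits = 6),
      "after", x$iterations, "IRLS iterations\n")
  print(round(cbind(estimate = x$coefficients, se = x$se), 3))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Subjects are sorted by fitted risk and split into `g` near-equal-count
#' groups; tied fitted values are kept together in the lower group. The
#' statistic sums `(O - E)^2 / (E (1 - E / n_g))` over groups, where `O`
#' and `E` are observed and expected event counts, and is referred to a
#' chi-square distribution with `g - 2` degrees of freedom. Groups with
#' `E = 0` or `E = n_g` are merged with their neighbour (with a warning and
#' a reduced df).
#'
#' @param fitted fitted probabilities in `(0, 1)`.
#' @param y binary 0/1 outcomes.
#' @param g number of risk groups (default 10; requires `n >= 2 g`).
#' @return list with `H`, `df`, `p`, `groups` (per-group O/E table).
#' @export
hosmer_lemeshow <- function(fitted, y, g = 10L) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1")
  n <- length(fitted)
  if (n != length(y)) stop("lengths differ")
  if (n < 2L * g) stop("need at least 2 g observations")

  ord <- order(fitted)
  f <- fitted[ord]; yo <- y[ord]
  # near-equal-count boundaries, pushed past tied runs so ties stay
  # together in the lower group
  bounds <- round(n * seq_len(g - 1L) / g)
  bounds <- vapply(bounds, function(b) {
    while (b < n && f[b] == f[b + 1L]) b <- b + 1L
    b
  }, numeric(1))
  bounds <- unique(bounds[bounds < n])
  grp <- findInterval(seq_len(n), c(0, bounds) + 1L)

  O <- tapply(yo, grp, sum)
  E <- tapply(f, grp, sum)
  ng <- tapply(yo, grp, length)

  # merge degenerate groups (all or none expected) with the neighbour
  merged <- FALSE
  repeat {
    bad <- which(E <= 0 | E >= ng)
    if (length(bad) == 0L || length(O) == 1L) break
    i <- bad[1L]
    j <- if (i == 1L) 2L else i - 1L
    O[j] <- O[j] + O[i]; E[j] <- E[j] + E[i]; ng[j] <- ng[j] + ng[i]
    O <- O[-i]; E <- E[-i]; ng <- ng[-i]
    merged <- TRUE
  }
  if (merged)
    warning("degenerate risk groups merged; degrees of freedom reduced")

  H <- sum((O - E)^2 / pmax(E * (1 - E / ng), 1e-12))
  df <- length(O) - 2L
  p <- if (df >= 1L) stats::pchisq(H, df, lower.tail = FALSE) else NA_real_
  list(H = H, df = df, p = p,
       groups = data.frame(n = as.integer(ng), observed = as.numeric(O),
                           expected = as.numeric(E)))
}

#' Empirical ROC curve, AUC and Youden cutoff
#'
#' ROC over all distinct score thresholds (predict positive when
#' `score >= threshold`); AUC by the trapezoid rule, which for the full
#' threshold set equals the tie-corrected Mann-Whitney probability
#' `U / (n1 n0)`. The reported operating point maximizes Youden's
#' `J = sensitivity + specificity - 1` (ties broken towards the lowest
#' threshold).
#'
#' @param scores numeric risk scores (e.g. fitted probabilities).
#' @param y binary 0/1 outcomes, both classes present.
#' @return object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `youden` (list with `threshold`, `sensitivity`,
#'   `specificity`, `J`).
#' @export
roc <- function(scores, y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1")
  if (length(scores) != length(y)) stop("lengths differ")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & y == 0) / n0, numeric(1))

  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)

  J <- sens + spec - 1
  finite <- is.finite(thr)
  best <- which(finite)[J[finite] == max(J[finite])]
  best <- best[which.min(thr[best])]

  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc,
                 youden = list(threshold = thr[best],
                               sensitivity = sens[best],
                               specificity = spec[best],
                               J = J[best])),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f; Youden cutoff %.4g: sensitivity %.2f%%, specificity %.2f%%\n",
              x$auc, x$youden$threshold, 100 * x$youden$sensitivity,
              100 * x$youden$specificity))
  invisible(x)
}

#' Default synthetic-cohort parameters
#'
#' Two-group covariate structure of a diabetic cohort screened for
#' peripheral vascular disease: 157 subjects with sonographically detected
#' lesions versus 33 without. Age, disease duration, systolic blood
#' pressure, LDL cholesterol, triglycerides and total cholesterol differ
#' between groups; BMI, diastolic pressure, fasting glucose, HbA1c and HDL
#' cholesterol are drawn from a common (precision-weighted) distribution,
#' reproducing the typical significance pattern of such baseline tables.
#' Sex is Bernoulli with the group-specific male fractions.
#'
#' @return nested list with elements `n` (group sizes, lesion first),
#'   `male_frac`, and `vars`: per-variable `list(mean = c(lesion, control),
#'   sd = c(lesion, control))`.
#' @export
cohort_params <- function() {
  shared <- function(m1, s1, n1, m2, s2, n2) {
    # common distribution for variables that do not differ between groups
    m <- (n1 * m1 + n2 * m2) / (n1 + n2)
    s <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
    list(mean = c(m, m), sd = c(s, s))
  }
  list(
    n = c(lesion = 157L, control = 33L),
    male_frac = c(lesion = 108 / 157, control = 20 / 33),
    vars = list(
      age      = list(mean = c(66.2, 51.8), sd = c(6.6, 5.4)),
      duration = list(mean = c(9.1, 5.5),   sd = c(2.5, 1.6)),
      bmi      = shared(24.1, 2.7, 157, 23.8, 2.2, 33),
      sbp      = list(mean = c(160.4, 129.0), sd = c(16.1, 14.9)),
      dbp      = shared(78.2, 7.8, 157, 74.1, 6.2, 33),
      fbg      = shared(9.7, 2.5, 157, 9.6, 3.3, 33),
      hba1c    = shared(8.2, 0.9, 157, 8.6, 1.0, 33),
      hdl      = shared(1.3, 0.5, 157, 1.4, 0.8, 33),
      ldl      = list(mean = c(2.9, 2.1), sd = c(0.9, 1.0)),
      tg       = list(mean = c(2.6, 2.0), sd = c(1.2, 1.8)),
      tc       = list(mean = c(5.6, 4.9), sd = c(1.3, 0.7))
    )
  )
}

#' Simulate a two-group clinical cohort
#'
#' Draws per-subject covariates from group-wise normal distributions given
#' by `params` (see [cohort_params()] for the defaults) and assigns the
#' binary outcome by group membership (1 = lesion group). Deterministic
#' given `seed`.
#'
#' @param params parameter list shaped like [cohort_params()].
#' @param n optional length-2 override of the group sizes (lesion,
#'   control).
#' @param seed RNG seed.
#' @return data frame of class `cohort_table` with columns `group`, `sex`,
#'   the covariates, and `outcome`.
#' @export
simulate_cohort <- function(params = cohort_params(), n = NULL, seed = 1L) {
  if (!is.null(n)) params$n <- as.integer(n)
  if (any(params$n < 2L)) stop("group sizes must be >= 2")
  for (v in params$vars)
    if (any(v$sd <= 0)) stop("all covariate sds must be positive")
  set.seed(seed)
  groups <- c("lesion", "control")
  rows <- lapply(1:2, function(gi) {
    ng <- params$n[gi]
    covs <- lapply(params$vars, function(v)
      stats::rnorm(ng, v$mean[gi], v$sd[gi]))
    data.frame(group = groups[gi],
               sex = ifelse(stats::runif(ng) < params$male_frac[gi],
                            "male", "female"),
               covs,
               outcome = as.integer(gi == 1L))
  })
  out <- do.call(rbind, rows)
  out$age <- pmax(out$age, 18)
  out$duration <- pmax(out$duration, 0.1)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Read / write a cohort table as CSV
#'
#' Columns: `group`, `sex`, the covariates of [cohort_params()] (`age`,
#' `duration`, `bmi`, `sbp`, `dbp`, `fbg`, `hba1c`, `hdl`, `ldl`, `tg`,
#' `tc`), and binary `outcome`. Validation rejects missing values,
#' non-binary outcomes and non-positive ages.
#'
#' @param path CSV file.
#' @return `read_cohort` returns a validated `cohort_table` data frame.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "sex", names(cohort_params()$vars), "outcome")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop("cohort file lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyNA(tab[need])) stop("cohort table contains missing values")
  if (!all(tab$outcome %in% c(0, 1))) stop("'outcome' must be binary 0/1")
  if (any(tab$age <= 0)) stop("ages must be positive")
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' @rdname read_cohort
#' @param cohort a `cohort_table` data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Two-group baseline comparison table
#'
#' For each covariate, group means/sds and the two-sample t test; for sex,
#' counts and the chi-square test. The analysis pipeline behind a typical
#' clinical "Table 2".
#'
#' @param cohort a `cohort_table` (see [simulate_cohort()], [read_cohort()]).
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @return data frame with one row per variable: group summaries,
#'   statistic, p-value.
#' @export
compare_groups <- function(cohort, variant = "pooled") {
  g1 <- cohort[cohort$outcome == 1, ]
  g0 <- cohort[cohort$outcome == 0, ]
  vars <- names(cohort_params()$vars)
  vars <- intersect(vars, names(cohort))
  rows <- lapply(vars, function(v) {
    a <- group_summary(nrow(g1), mean(g1[[v]]), stats::sd(g1[[v]]))
    b <- group_summary(nrow(g0), mean(g0[[v]]), stats::sd(g0[[v]]))
    tt <- two_sample_t(a, b, variant)
    data.frame(variable = v,
               lesion = sprintf("%.1f ± %.1f", a$mean, a$sd),
               control = sprintf("%.1f ± %.1f", b$mean, b$sd),
               statistic = round(tt$t, 3), p = round(tt$p, 4))
  })
  sex_tab <- rbind(table(factor(g1$sex, c("male", "female"))),
                   table(factor(g0$sex, c("male", "female"))))
  chi <- chi_square_2x2(sex_tab)
  rbind(data.frame(variable = "sex",
                   lesion = sprintf("%d/%d", sex_tab[1, 1], sex_tab[1, 2]),
                   control = sprintf("%d/%d", sex_tab[2, 1], sex_tab[2, 2]),
                   statistic = round(chi$chisq, 3), p = round(chi$p, 4)),
        do.call(rbind, rows))
}

#' Logistic risk model with calibration and discrimination summaries
#'
#' Screens the candidate covariates by univariate logistic regression at
#' `alpha`, fits the multivariable model on those retained, and reports the
#' Hosmer-Lemeshow calibration test and the ROC/AUC with the Youden
#' operating point.
#'
#' @param cohort a `cohort_table`.
#' @param covariates candidate covariate names (default: the numeric
#'   covariates of [cohort_params()]).
#' @param alpha univariate screening level (default 0.05; set to 1 to keep
#'   all candidates).
#' @param g Hosmer-Lemeshow group count.
#' @return list with `fit` ([fit_logistic()]), `selected`, `hl`
#'   ([hosmer_lemeshow()]), `roc` ([roc()]).
#' @export
risk_model <- function(cohort, covariates = NULL, alpha = 0.05, g = 10L) {
  if (is.null(covariates))
    covariates <- intersect(names(cohort_params()$vars), names(cohort))
  y <- cohort$outcome
  selected <- covariates
  if (alpha < 1) {
    pvals <- vapply(covariates, function(v) {
      f <- fit_logistic(as.matrix(cohort[[v]]), y, allow_nonconverged = TRUE)
      2 * stats::pnorm(-abs(f$coefficients[2] / f$se[2]))
    }, numeric(1))
    selected <- covariates[pvals < alpha]
    if (length(selected) == 0L) selected <- covariates
  }
  X <- as.matrix(cohort[selected])
  # strongly separated groups can push the MLE towards the boundary; the
  # truncated fit still ranks subjects, so discrimination summaries remain
  # meaningful and the non-convergence is reported rather than fatal
  fit <- fit_logistic(X, y, allow_nonconverged = TRUE)
  list(fit = fit, selected = selected,
       hl = suppressWarnings(hosmer_lemeshow(fit$fitted, y, g = g)),
       roc = roc(fit$fitted, y))
}
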