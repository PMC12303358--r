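test_that("stratum log-likelihood matches enumeration and null symmetry", {
  # 1 hazard vs 1 control at beta = 0: log(1/2)
  expect_equal(stratum_loglik(cbind(x = c(1.3, -0.2)), c(1, 0), 0)$ll,
               log(1 / 2))
  # m = 4, k = 2 against direct enumeration over all 6 subsets
  set.seed(1)
  X <- matrix(rnorm(8), 4, 2)
  y <- c(1, 0, 1, 0)
  b <- c(0.4, -0.7)
  expect_equal(stratum_loglik(X, y, b)$ll, oracle_stratum_loglik(X, y, b),
               tolerance = 1e-12)
  # identical exposure values in every window: zero score at any beta
  Xc <- matrix(1, 5, 1)
  expect_equal(stratum_loglik(Xc, c(1, 1, 0, 0, 0), 2.3)$score, 0)
  # concordant strata are non-informative
  expect_false(stratum_loglik(X, c(1, 1, 1, 1), b)$informative)
})

test_that("score and information agree with finite differences", {
  set.seed(7)
  for (rep in 1:10) {
    m <- sample(3:7, 1)
    k <- sample(seq_len(m - 1), 1)
    X <- matrix(rnorm(2 * m), m, 2)
    y <- sample(c(rep(1, k), rep(0, m - k)))
    b <- rnorm(2, sd = 0.5)
    got <- stratum_loglik(X, y, b)
    fd <- fd_score_info(X, y, b)
    expect_equal(got$score, fd$score, tolerance = 1e-6)
    expect_equal(got$info, fd$info, tolerance = 1e-4)
  }
})

test_that("likelihood depends only on within-stratum contrasts", {
  set.seed(2)
  X <- matrix(rnorm(6), 6, 1)
  y <- c(1, 1, 0, 0, 0, 0)
  for (b in c(-1, 0.3, 2)) {
    l1 <- stratum_loglik(X, y, b)$ll
    l2 <- stratum_loglik(X + 17.5, y, b)$ll
    expect_equal(l1, l2, tolerance = 1e-9)
  }
})

test_that("matched-pairs fits recover the log(n10/n01) closed form", {
  d <- matched_pairs(20, 10)
  fit <- cclogit(case ~ x, d, strata = "stratum")
  expect_equal(unname(coef(fit)), log(20 / 10), tolerance = 1e-6)
  expect_true(fit$converged)
  # concordant pairs were dropped as non-informative
  expect_equal(fit$n_strata, 30)
  expect_equal(fit$n_dropped, 5)
})

test_that("fits agree with the survival package's exact conditional logit", {
  library(survival)
  set.seed(11)
  # multi-case strata with varying sizes
  d <- do.call(rbind, lapply(1:40, function(s) {
    m <- sample(3:6, 1)
    k <- sample(seq_len(m - 1), 1)
    data.frame(stratum = s, case = sample(c(rep(1, k), rep(0, m - k))),
               x1 = rnorm(m), x2 = rnorm(m))
  }))
  fit <- cclogit(case ~ x1 + x2, d, strata = "stratum")
  ref <- clogit(case ~ x1 + x2 + strata(stratum), d, method = "exact")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(sqrt(diag(fit$var))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  expect_equal(unname(as.numeric(logLik(fit))),
               unname(as.numeric(logLik(ref))), tolerance = 1e-6)
})

test_that("degenerate designs fail loudly instead of returning estimates", {
  d <- matched_pairs(0, 0, n_conc = 8)
  expect_error(cclogit(case ~ x, d, strata = "stratum"), "no informative")
  # complete separation: exposed window is always the case
  d2 <- matched_pairs(25, 0)
  expect_warning(fit <- cclogit(case ~ x, d2, strata = "stratum"),
                 "separation")
  expect_true(fit$separation)
})

test_that("robust and model SEs coincide for independent 1:1 strata", {
  set.seed(5)
  n <- 4000
  x <- rnorm(2 * n)
  eta <- 0.5 * x
  d <- data.frame(stratum = rep(seq_len(n), each = 2), x = x)
  # case allocation follows the conditional logit model exactly
  d$case <- 0
  for (s in seq_len(n)) {
    i <- c(2 * s - 1, 2 * s)
    p1 <- exp(eta[i[1]]) / (exp(eta[i[1]]) + exp(eta[i[2]]))
    pick <- if (runif(1) < p1) i[1] else i[2]
    d$case[pick] <- 1
  }
  fit <- cclogit(case ~ x, d, strata = "stratum")
  se_m <- sqrt(diag(vcov(fit, "model")))
  se_r <- sqrt(diag(vcov(fit, "robust")))
  expect_lt(abs(se_r / se_m - 1), 0.05)
  expect_lt(abs(unname(coef(fit)) - 0.5), 0.1)
})

test_that("model methods expose coefficients, CIs and predictions", {
  d <- matched_pairs(18, 9)
  fit <- cclogit(case ~ x, d, strata = "stratum", cluster = "stratum")
  s <- summary(fit)
  expect_equal(s$table$or, exp(unname(coef(fit))))
  ci <- confint(fit)
  expect_equal(unname(exp(ci[1, ])),
               c(s$table$ci_low, s$table$ci_high))
  expect_equal(unname(predict(fit, data.frame(x = c(0, 1)))),
               c(0, unname(coef(fit))))
  expect_output(print(s), "cluster-robust")
})
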