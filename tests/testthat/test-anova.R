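test_that("response transforms are monotone and invertible", {
  set.seed(8)
  v <- rnorm(40, sd = 6)
  for (m in c("shifted_log", "identity", "linear_log")) {
    tv <- transform_response(v, m)
    expect_equal(order(tv), order(v))              # strictly monotone
    expect_equal(inv_transform_response(tv), v, tolerance = 1e-12)
  }
  # with minimum 1 the shifted log reduces to the plain log
  w <- c(1, 2, 5, 10)
  expect_equal(as.numeric(transform_response(w, "shifted_log")), log(w))
  expect_error(transform_response(c(1, Inf)), "finite")
})

test_that("mauchly test is vacuous at 2 levels and calibrated under the null", {
  d <- null_rm_data(n_per = 10, g = 1)
  mt <- mauchly_test(d, "y", "subject", "substrate")
  expect_equal(mt$w, 1)
  expect_equal(mt$p, 1)
  expect_true(mt$trivial)

  # under compound symmetry p-values are approximately uniform
  set.seed(123)
  ps <- replicate(300, {
    dd <- expand.grid(subject = paste0("s", 1:30), distance = 1:4)
    dd$y <- rnorm(nrow(dd)) + rnorm(30)[dd$subject]
    mauchly_test(dd, "y", "subject", "distance")$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("mauchly test detects strong sphericity violations", {
  set.seed(77)
  n <- 30; k <- 6; rho <- 0.95
  S <- rho^abs(outer(1:k, 1:k, "-")) * (1:k %o% (1:k))^0.5
  L <- chol(S)
  Y <- matrix(rnorm(n * k), n) %*% L
  dd <- data.frame(subject = rep(1:n, k), level = rep(1:k, each = n),
                   y = as.vector(Y))
  mt <- mauchly_test(dd, "y", "subject", "level")
  expect_lt(mt$w, 0.5)
  expect_lt(mt$p, 0.05)
})

test_that("rm_anova agrees with the multivariate route (car) on a fixed design", {
  set.seed(42)
  n <- 12
  subj <- paste0("s", 1:n)
  d <- expand.grid(subject = subj, distance = c(1, 2, 4, 8),
                   substrate = c("water", "soil"),
                   stringsAsFactors = FALSE)
  d$between <- rep(c("A", "B"), each = 6)[match(d$subject, subj)]
  d$y <- rnorm(nrow(d)) + as.numeric(factor(d$distance)) * 0.3 +
    rnorm(n)[match(d$subject, subj)]
  fit <- rm_anova(d, "y", "subject", c("distance", "substrate"),
                  between = "between")

  d$cell <- paste0("c", as.integer(factor(d$distance)),
                   as.integer(factor(d$substrate)))
  w <- stats::reshape(d[, c("subject", "between", "cell", "y")],
                      idvar = c("subject", "between"), timevar = "cell",
                      direction = "wide")
  resp <- as.matrix(w[, -(1:2)])
  info <- sub("^y\\.c", "", colnames(resp))
  idata <- data.frame(distance = factor(substr(info, 1, 1)),
                      substrate = factor(substr(info, 2, 2)))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  mlm <- stats::lm(resp ~ between, data = w)
  av <- suppressWarnings(summary(
    car::Anova(mlm, idata = idata, idesign = ~distance * substrate,
               type = 3), multivariate = FALSE))
  ut <- av$univariate.tests
  pick <- function(eff) fit$table[fit$table$effect == eff, ]
  for (eff in c("between", "distance", "substrate", "distance:substrate")) {
    expect_equal(pick(eff)$F, ut[eff, "F value"], tolerance = 1e-8)
    expect_equal(pick(eff)$df_num, ut[eff, "num Df"])
    expect_equal(pick(eff)$df_den, ut[eff, "den Df"])
  }
  sp <- av$sphericity.tests
  expect_equal(pick("distance")$mauchly_w, sp["distance", "Test statistic"],
               tolerance = 1e-8)
  expect_equal(pick("distance")$mauchly_p, sp["distance", "p-value"],
               tolerance = 5e-3)
  pa <- av$pval.adjustments
  expect_equal(pick("distance")$epsilon_gg, pa["distance", "GG eps"],
               tolerance = 1e-8)
  expect_equal(pick("distance")$epsilon_hf,
               min(1, pa["distance", "HF eps"]), tolerance = 1e-8)
})

test_that("F statistics are invariant to a location shift of the response", {
  set.seed(5)
  d <- null_rm_data()
  f1 <- rm_anova(d, "y", "subject", c("distance", "substrate"),
                 between = "group")
  d$y <- d$y + 100
  f2 <- rm_anova(d, "y", "subject", c("distance", "substrate"),
                 between = "group")
  expect_equal(f1$table$F, f2$table$F, tolerance = 1e-9)
})

test_that("epsilon decreases along an AR(1) family and truncates at 1 under sphericity", {
  est_eps <- function(rho, seed, whiten = FALSE) {
    set.seed(seed)
    n <- 120; k <- 5
    S <- rho^abs(outer(1:k, 1:k, "-"))
    Y <- matrix(rnorm(n * k), n) %*% chol(S)
    if (whiten) {  # force the sample covariance to the exact target
      Yc <- scale(Y, scale = FALSE)
      Y <- Yc %*% solve(chol(stats::cov(Yc))) %*% chol(S)
    }
    dd <- data.frame(subject = rep(1:n, k), level = rep(1:k, each = n),
                     y = as.vector(Y))
    fit <- rm_anova(dd, "y", "subject", "level")
    fit$table[fit$table$effect == "level",
              c("epsilon_gg", "epsilon_hf")]
  }
  # exactly compound-symmetric covariance: GG = 1, HF truncates to 1
  e0 <- est_eps(0, 1, whiten = TRUE)
  expect_equal(e0$epsilon_gg, 1, tolerance = 1e-9)
  expect_equal(e0$epsilon_hf, 1)
  s0 <- est_eps(0, 1); s5 <- est_eps(0.6, 2); s9 <- est_eps(0.95, 3)
  expect_gt(s0$epsilon_gg, s5$epsilon_gg)
  expect_gt(s5$epsilon_gg, s9$epsilon_gg)
})

test_that("unbalanced or incomplete designs are rejected by name", {
  d <- null_rm_data()
  d2 <- d[-5, ]
  expect_error(rm_anova(d2, "y", "subject", c("distance", "substrate"),
                        between = "group"), "unbalanced")
  d3 <- d; d3$group[1:8] <- c("a", "b")[1 + (1:8 %% 2)]
  expect_error(rm_anova(d3, "y", "subject", c("distance", "substrate"),
                        between = "group"), "exactly one")
})

test_that("an injected distance effect is detected essentially always", {
  set.seed(31)
  hits <- replicate(60, {
    d <- null_rm_data(n_per = 5, g = 2, distance_effect = 2)
    fit <- rm_anova(d, "y", "subject", c("distance", "substrate"),
                    between = "group")
    fit$table$p_reported[fit$table$effect == "distance"] < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("bonferroni pairwise comparisons enumerate and cap correctly", {
  set.seed(9)
  d <- expand.grid(subject = paste0("s", 1:10),
                   locality = paste0("L", 1:7))
  d$y <- rnorm(nrow(d))
  out <- bonferroni_pairwise(d, "y", "subject", "locality")
  expect_equal(nrow(out), choose(7, 2))  # 21 pairs
  expect_equal(out$p_bonferroni, pmin(1, 21 * out$p_raw))
  expect_true(all(out$p_bonferroni <= 1))
  d1 <- d[d$locality == "L1", ]
  expect_error(bonferroni_pairwise(d1, "y", "subject", "locality"),
               "at least 2")
})
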