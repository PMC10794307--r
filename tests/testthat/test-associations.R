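test_that("group summaries reproduce closed-form tests", {
  # 2x2 chi-square equals N(ad-bc)^2 / row/col products (Pearson, no
  # continuity correction)
  sexes <- c(rep("female", 299), rep("male", 141),
             rep("female", 264), rep("male", 167))
  tilt <- c(rep("tilted", 440), rep("non_tilted", 431))
  co <- data.frame(sex = sexes, tilt_class = tilt)
  gs <- summarize_groups(co, "tilt_class", "sex")
  a <- 264; b <- 299; c_ <- 167; d <- 141   # non/tilted x female/male
  n <- a + b + c_ + d
  stat <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_equal(gs$table$p, stats::pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-9)

  # two identical groups: t-test p = 1
  co2 <- data.frame(g = rep(c("A", "B"), each = 5), x = rep(2.5, 10))
  expect_equal(summarize_groups(co2, "g", "x")$table$p, 1)

  # >2 groups: ANOVA omnibus + Bonferroni pairwise never below unadjusted
  set.seed(5)
  co3 <- data.frame(g = rep(c("A", "B", "C"), each = 40),
                    x = stats::rnorm(120))
  gs3 <- summarize_groups(co3, "g", "x")
  raw <- stats::pairwise.t.test(co3$x, co3$g, p.adjust.method = "none",
                                pool.sd = TRUE)$p.value
  adj <- gs3$pairwise$x
  expect_true(all(adj >= raw - 1e-12, na.rm = TRUE))
  expect_true(all(adj <= 1, na.rm = TRUE))
  expect_error(summarize_groups(co3, "missing_col", "x"), "not found")
})

test_that("ANOVA omnibus holds its nominal type-I error rate", {
  set.seed(41)
  rej <- vapply(1:400, function(i) {
    df <- data.frame(g = rep(c("A", "B", "C", "D"), each = 50),
                     x = stats::rnorm(200))
    summarize_groups(df, "g", "x")$table$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("normality check behaves as a Lilliefors test", {
  set.seed(13)
  norm_p <- normality_check(stats::rnorm(500))$p.value
  expect_gt(norm_p, 1e-4)
  expo_p <- normality_check(stats::rexp(500))$p.value
  expect_lt(expo_p, 0.01)
  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(c(1, 2)), "at least 5")
  # nominal rejection rate under the null
  rej <- vapply(1:200, function(i)
    normality_check(stats::rnorm(60))$p.value < 0.05, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.04)
})

test_that("logistic odds ratio on a collapsed 2x2 equals ad/bc", {
  df <- data.frame(
    y = c(rep("tilted", 30), rep("non_tilted", 70),
          rep("tilted", 60), rep("non_tilted", 40)),
    x = rep(c(0, 1), c(100, 100)))
  fit <- fit_tilt_logistic(df, "x", outcome = "y")
  expect_equal(fit$terms$estimate, (60 * 70) / (40 * 30), tolerance = 1e-6)
  expect_true(fit$terms$conf_low <= fit$terms$estimate &
                fit$terms$estimate <= fit$terms$conf_high)
})

test_that("univariate screening keeps p<0.10 terms and applies the collinearity rule", {
  set.seed(19)
  n <- 600
  co <- data.frame(x_strong = stats::rnorm(n), x_null = stats::rnorm(n),
                   SE = stats::rnorm(n), S_RPC = stats::rnorm(n))
  eta <- 0.8 * co$x_strong + 0.8 * co$SE
  co$tilt_class <- ifelse(stats::runif(n) < stats::plogis(eta), "tilted",
                          "non_tilted")
  scr <- univariate_screen(co, "tilt_class",
                           c("x_strong", "x_null", "SE", "S_RPC"))
  expect_true("x_strong" %in% scr$selected)
  # SE and RPC columns are screened out of the multivariate candidates
  # even when univariately significant
  expect_false(any(c("SE", "S_RPC") %in% scr$selected))
  expect_equal(nrow(scr$estimates), 4L)
  expect_true(all(c("estimate", "conf_low", "conf_high", "p") %in%
                    names(scr$estimates)))

  # continuous outcome goes through OLS
  co$rotation_deg <- 2 * co$x_strong + stats::rnorm(n)
  scr2 <- univariate_screen(co, "rotation_deg", c("x_strong", "x_null"))
  expect_identical(scr2$model, "linear")
  expect_true("x_strong" %in% scr2$selected)
})

test_that("stepwise selection recovers planted terms and rejects noise", {
  set.seed(37)
  n <- 500
  df <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n),
                   noise1 = stats::rnorm(n), noise2 = stats::rnorm(n))
  df$rotation_deg <- 1.5 * df$a - 2 * df$b + stats::rnorm(n, 0, 2)
  sw <- fit_rotation_stepwise(df, c("a", "b", "noise1", "noise2"))
  expect_setequal(intersect(sw$selected, c("a", "b")), c("a", "b"))
  expect_true(sw$adj_r2 <= sw$r2)
  expect_true(all(sw$terms$conf_low <= sw$terms$estimate &
                    sw$terms$estimate <= sw$terms$conf_high))

  # standardized beta matches B * sd(x) / sd(y)
  arow <- sw$terms[sw$terms$term == "a", ]
  expect_equal(arow$std_beta,
               arow$estimate * stats::sd(df$a) / stats::sd(df$rotation_deg),
               tolerance = 1e-9)

  # no surviving candidate: empty model, R2 = 0
  df0 <- data.frame(z = stats::rnorm(50))
  df0$rotation_deg <- stats::rnorm(50)
  sw0 <- fit_rotation_stepwise(df0, "z")
  if (!length(sw0$selected)) {
    expect_equal(sw0$r2, 0)
    expect_equal(nrow(sw0$terms), 0L)
  }
})

test_that("stepwise entry rate on pure noise is near the entry level", {
  set.seed(43)
  hits <- replicate(300, {
    df <- data.frame(x1 = stats::rnorm(80), x2 = stats::rnorm(80),
                     x3 = stats::rnorm(80))
    df$rotation_deg <- stats::rnorm(80)
    sw <- fit_rotation_stepwise(df, c("x1", "x2", "x3"))
    c("x1", "x2", "x3") %in% sw$selected
  })
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})

test_that("the full report assembles all five table analogues", {
  sim <- generate_cohort(simulation_config(n_eyes = 500, seed = 77))
  rep <- build_report(sim$cohort)
  expect_s3_class(rep$al_summary, "group_summary")
  expect_true(all(c("AL", "tilt_ratio", "N_SVD") %in%
                    rep$al_summary$table$variable))
  expect_identical(rep$tilt_summary$groups, c("non_tilted", "tilted"))
  expect_identical(sort(rep$rotation_summary$groups),
                   sort(c("non_rotation", "inferior", "superior")))
  expect_true(all(c("N_SVD", "T_SVD", "RLP") %in% rep$tilt_model$terms$term))
  expect_true(length(rep$rotation_model$selected) >= 3)
  expect_false(any(grepl("_RPC|^SE$", rep$tilt_screen$selected)))
  expect_equal(sum(rep$prevalence[c("non_rotation", "inferior",
                                    "superior")]), 1)
  expect_equal(unname(rep$prevalence["tilted"]),
               mean(sim$cohort$tilt_class == "tilted"))
})
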