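test_that("noise-free data are fit perfectly", {
  d <- data.frame(dY = 2 + 3 * rep(c(0, 1), each = 4),
                  g_level = rep(c(0, 1), each = 4),
                  task_dynamic = rep(c(0, 1), 4))
  f <- com_gravfit(d, "dY")
  expect_equal(unname(coef(f)[c("constant", "g_level", "task")]), c(2, 3, 0))
  expect_equal(f$r.squared, 1)
  expect_equal(f$sigma, 0, tolerance = 1e-9)
})

test_that("the 4-row toy drops the constant task column and matches hand OLS", {
  d <- data.frame(dY = c(0, 1, 2, 3), g_level = c(0, 0, 1, 1),
                  task_dynamic = 0L)
  f <- com_gravfit(d, "dY")
  expect_identical(f$dropped, "task")
  expect_equal(unname(coef(f)["g_level"]), 2.0)
  expect_equal(unname(coef(f)["constant"]), 0.5)
})

test_that("fit_ols matches the QR oracle on random well-conditioned designs", {
  set.seed(55)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    d <- data.frame(g_level = rbinom(n, 1, 0.5),
                    task_dynamic = rbinom(n, 1, 0.5))
    d$dY <- 1 + 2 * d$g_level - 0.5 * d$task_dynamic + rnorm(n, 0, 2)
    if (length(unique(d$g_level)) < 2 || length(unique(d$task_dynamic)) < 2) next
    f <- com_gravfit(d, "dY")
    o <- lm(dY ~ g_level + task_dynamic, data = d)  # QR decomposition path
    so <- summary(o)
    expect_equal(unname(coef(f)), unname(coef(o)), tolerance = 1e-9)
    expect_equal(unname(f$se), unname(so$coefficients[, 2]), tolerance = 1e-9)
    expect_equal(unname(f$p.value), unname(so$coefficients[, 4]), tolerance = 1e-9)
    expect_equal(f$r.squared, so$r.squared, tolerance = 1e-12)
    expect_equal(f$adj.r.squared, so$adj.r.squared, tolerance = 1e-12)
    expect_equal(f$sigma, so$sigma, tolerance = 1e-12)
    expect_equal(unname(f$fstatistic["value"]), unname(so$fstatistic[1]),
                 tolerance = 1e-9)
  }
})

test_that("degenerate designs error, small n errors", {
  d <- data.frame(dY = rnorm(10), g_level = rep(c(0, 1), 5))
  d$task_dynamic <- d$g_level  # perfectly collinear
  expect_error(com_gravfit(d, "dY"), "collinear")
  expect_error(com_gravfit(d[1:3, ], "dY"), "at least 4")
})

test_that("sex filtering and methods behave", {
  set.seed(9)
  d <- data.frame(sex = rep(c("male", "female"), each = 30),
                  g_level = rep(c(0, 1), 30),
                  task_dynamic = rep(c(0, 0, 1, 1), 15),
                  participant = rep(sprintf("p%02d", 1:10), each = 6))
  d$dY <- 1 + 5 * d$g_level + rnorm(60)
  f <- com_gravfit(d, "dY", sex = "male", robust = TRUE)
  expect_equal(f$n, 30)
  expect_length(f$se_robust, 3L)
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, data.frame(g_level = 1, task_dynamic = 0)),
               sum(coef(f)[c("constant", "g_level")]), ignore_attr = TRUE)
  expect_equal(length(residuals(f)), 30)
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(30L, 2L))
  expect_output(print(summary(f)), "residual SE")
})

test_that("null g_level p-values give nominal type-I error", {
  set.seed(4242)
  n <- 60
  d0 <- data.frame(g_level = rep(c(0, 1), n / 2),
                   task_dynamic = rep(c(0, 0, 1, 1), n / 4))
  rej <- logical(5000)
  for (r in seq_len(5000)) {
    d0$dY <- 1 + 0.5 * d0$task_dynamic + rnorm(n)
    f <- com_gravfit(d0, "dY")
    rej[r] <- f$p.value["g_level"] < 0.05
  }
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("shapiro_wilk matches the reference implementation and flags skew", {
  set.seed(42); x <- rnorm(50)
  sw <- shapiro_wilk(x)
  # frozen from an independent reference implementation (scipy.stats.shapiro)
  expect_equal(sw$W, 0.980214678491, tolerance = 1e-6)
  expect_equal(sw$p.value, 0.561053161228, tolerance = 1e-6)
  expect_true(sw$W > 0 && sw$W <= 1)
  set.seed(99); y <- rexp(200)
  expect_lt(shapiro_wilk(y)$p.value, 0.05)
  expect_error(shapiro_wilk(rep(1, 10)), "equal")
  expect_error(shapiro_wilk(1:2))
})

test_that("report rendering round-trips and stars follow the legend", {
  set.seed(12)
  d <- data.frame(g_level = rep(c(0, 1), each = 30),
                  task_dynamic = rep(c(0, 1), 30))
  d$dY <- -8 + 17 * d$g_level + 3 * d$task_dynamic + rnorm(60, 0, 4)
  d$dZ <- 6 - 1.5 * d$g_level + rnorm(60, 0, 8)
  fits <- list(M_Y = com_gravfit(d, "dY"), M_Z = com_gravfit(d, "dZ"))
  rep1 <- table3_report(fits)
  expect_equal(dim(unclass(rep1)), c(8L, 2L))
  # strongly significant g effect renders with the triple star
  expect_match(rep1["G-level", "M_Y"], "\\*\\*\\*")
  back <- parse_report(rep1)
  expect_equal(back$M_Y$g_level[["estimate"]],
               unname(coef(fits$M_Y)["g_level"]), tolerance = 0.005)
  expect_equal(back$M_Y$g_level[["se"]], unname(fits$M_Y$se["g_level"]),
               tolerance = 0.005)
  expect_equal(back$M_Z$n, 60L)
  expect_equal(back$M_Z$sigma, fits$M_Z$sigma, tolerance = 0.005)
  # empty input renders an empty grid with headers
  expect_equal(ncol(table3_report(list())), 0L)
  # conventional legend is configurable
  rep2 <- table3_report(fits, star_legend = c("***" = 0.01, "**" = 0.05))
  expect_match(rep2["G-level", "M_Y"], "\\*\\*\\*")
  expect_output(print(rep1), "G-level")
})
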