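test_that("growth rate is the log slope, exact on exponentials", {
  g <- growth_rate(c(0, 1), c(0.2, 0.4))
  expect_equal(g$mu, log(2))
  expect_equal(g$time, 0.5)
  expect_equal(growth_rate(c(0, 1, 2), c(0.3, 0.3, 0.3))$mu, c(0, 0))
  # exact on a pure exponential for an irregular grid
  tt <- c(0, 0.3, 1.1, 2.5, 4)
  expect_equal(growth_rate(tt, 0.1 * exp(0.27 * tt))$mu, rep(0.27, 4))
  expect_error(growth_rate(c(0, 1), c(0.2, 0)), "positive")
  expect_error(growth_rate(c(1, 1), c(0.2, 0.4)), "increasing")
})

test_that("productivity is the dry-weight finite difference", {
  p <- productivity(c(0, 2), c(1, 2))
  expect_equal(p$productivity, 0.5)
  expect_equal(productivity(c(0, 1, 2), c(2, 2, 2))$productivity, c(0, 0))
})

test_that("COD aggregation follows stoichiometry and the eeq convention", {
  expect_equal(cod_aggregate(c(fructose = 1))$cod, 192 / 180,
               tolerance = 1e-3)
  # 8 gCOD = 1 eeq
  expect_equal(cod_aggregate(c(acetate = 8 / cod_factor("C2H4O2")))$eeq, 1)
  expect_equal(cod_aggregate(c(fructose = 0, methanol = 0))$cod, 0)
  expect_equal(unname(cod_factor("CH4O")), 1.5, tolerance = 1e-2)
  expect_error(cod_aggregate(c(unobtainium = 1)), "unobtainium")
})

test_that("phase classification recovers generator truth labels", {
  cfg <- sim_config(seed = 31)
  for (lim in c("carbon", "nitrogen", "dual")) {
    s <- simulate_batch(cfg, lim, noise = FALSE)
    got <- classify_phase(s, lim)
    expect_gte(mean(got == s$phase), 0.9)
  }
  # degenerate bound: threshold at 100% of initial marks everything limiting
  s <- simulate_batch(cfg, "carbon", noise = FALSE)
  s2 <- s
  s2$COD <- s$COD * 0.999  # strictly below initial everywhere
  got <- classify_phase(s2, "carbon", theta = 1.001, mu_frac = NULL)
  expect_true(all(got == "limiting"))
  expect_true(all(classify_phase(s, "carbon", theta = 0) == "abundant"))
  expect_error(classify_phase(s, "helium"), "arg")
})

test_that("Spearman correlogram matches the rank-then-Pearson oracle", {
  set.seed(77)
  for (i in 1:10) {
    x <- sample(1:6, 12, replace = TRUE)  # heavy ties
    y <- sample(1:6, 12, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    cg <- correlogram(data.frame(x = x, y = y))
    expect_equal(cg$rho["x", "y"], spearman_oracle(x, y), tolerance = 1e-12)
  }
  cg <- correlogram(data.frame(a = 1:8, b = 8:1, c = (1:8)^3))
  expect_equal(cg$rho["a", "b"], -1)
  expect_equal(cg$rho["a", "c"], 1)  # invariant under monotone transform
  expect_equal(cg$rho, t(cg$rho))
  expect_true(all(diag(cg$rho) == 1))
})

test_that("correlogram handles constants, alpha and BH adjustment", {
  df <- data.frame(x = 1:10, y = rep(2, 10))
  expect_warning(cg <- correlogram(df), "constant")
  expect_true(is.na(cg$rho["x", "y"]))
  set.seed(5)
  df2 <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  raw <- correlogram(df2)
  bh <- correlogram(df2, adjust = "BH")
  up <- upper.tri(raw$p)
  expect_true(all(bh$p[up] >= raw$p[up] - 1e-15))
})

test_that("linear fits reproduce exact lines and have t-based bands", {
  x <- 1:10
  fit <- linear_fit_ci(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_lt(max(fit$band$upr - fit$band$lwr), 1e-8)
  set.seed(9)
  f2 <- linear_fit_ci(x, 2 * x + rnorm(10), newx = seq(1, 10, 0.5))
  width <- f2$band$upr - f2$band$lwr
  expect_equal(f2$band$x[which.min(width)], 5.5)  # narrowest at mean(x)
  expect_error(linear_fit_ci(rep(1, 5), rnorm(5)), "variance")
})

test_that("confidence bands achieve nominal coverage of the mean response", {
  set.seed(123)
  x <- seq(0, 1, length.out = 15)
  x0 <- 0.25
  truth <- 1 + 2 * x0
  hits <- 0L
  reps <- 1000L
  for (r in seq_len(reps)) {
    y <- 1 + 2 * x + rnorm(15, 0, 0.5)
    b <- linear_fit_ci(x, y, newx = x0)
    hits <- hits + (b$band$lwr <= truth && truth <= b$band$upr)
  }
  expect_gt(hits / reps, 0.93)
  expect_lt(hits / reps, 0.97)
})

test_that("interval estimates join composition samples by nearest time", {
  series <- data.frame(time = c(0, 1, 2), od = c(1, 2, 3))
  iv <- data.frame(time = c(0.4, 1.6), mu = c(0.5, 0.7))
  j <- join_nearest_time(series, iv, tolerance = 0.5)
  expect_equal(j$mu, c(0.5, NA, 0.7))
  j2 <- join_nearest_time(series, iv, tolerance = 2)
  expect_equal(j2$mu, c(0.5, 0.5, 0.7))
})

test_that("stratified correlograms split by phase and limitation", {
  cfg <- sim_config(seed = 41)
  s <- rbind(as.data.frame(simulate_batch(cfg, "carbon")),
             as.data.frame(simulate_batch(cfg, "nitrogen")))
  cgs <- suppressWarnings(
    correlogram_strata(s, vars = c("mu", "na_intensity", "protein")))
  expect_true(all(c("all", "abundant", "limiting", "limitation_carbon",
                    "limitation_nitrogen") %in% names(cgs)))
  expect_equal(cgs$all$stratum, "all")
})
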