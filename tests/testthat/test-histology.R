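# Histology statistics: percentages, CIs, densities, ANOVA, exponential
# trajectories, mixed-model LRTs, orientation summaries.

test_that("pooled percentages reproduce worked examples exactly", {
  expect_equal(pooled_percentage(277, 764), 36.3)
  expect_equal(pooled_percentage(31, 177), 17.5)
  expect_equal(pooled_percentage(0, 10), 0)
  expect_error(pooled_percentage(1, 0), "positive")
  expect_error(pooled_percentage(11, 10), "exceeds")
})

test_that("the t-based CI reproduces the printed Ki-67 interval from its summary statistics", {
  ci <- t_ci(85.6, 86.8, 26)
  expect_lt(abs(ci[1] - 50.56), 0.2)
  expect_lt(abs(ci[2] - 120.7), 0.2)
  s <- stack_summary(c(2, 2, 2, 2))
  expect_equal(s$sd, 0)
  expect_equal(diff(s$ci), 0)
  expect_error(stack_summary(5), "at least 2")
})

test_that("the t-CI achieves nominal coverage on resampled null data", {
  set.seed(30)
  n <- 12; mu <- 4
  cover <- vapply(1:10000, function(i) {
    v <- stats::rnorm(n, mu, 2)
    ci <- stack_summary(v)$ci
    ci[1] <= mu && mu <= ci[2]
  }, logical(1))
  expect_lt(abs(mean(cover) - 0.95), 0.01)
})

test_that("densities behave linearly and recover a planted Poisson rate", {
  expect_equal(cell_density(10, 0.1), 100)
  expect_equal(cell_density(0, 2), 0)
  expect_equal(cell_density(30, 0.5), 2 * cell_density(30, 1))
  expect_error(cell_density(3, 0), "positive")
  set.seed(31)
  lambda <- 120; area <- 0.25
  counts <- stats::rpois(400, lambda * area)
  d <- cell_density(counts, area)
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - lambda), 3 * se)
})

test_that("cluster summaries match sort-based quantile oracles and are order-stable", {
  set.seed(32)
  tab <- data.frame(age_group = rep(c("birth", "adult"), c(8, 6)),
                    cluster_count = c(rpois(8, 80), rpois(6, 9)))
  areas <- lapply(seq_len(14), function(i) stats::rlnorm(20, 8, 1))
  tab$cluster_areas <- I(areas)
  s <- cluster_summary(tab)
  birth_areas <- sort(unlist(areas[1:8]))
  # linear-interpolation quantile oracle
  qi <- function(v, p) {
    h <- (length(v) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  row <- s[s$age_group == "birth", ]
  expect_equal(row$area_median, qi(birth_areas, 0.5))
  expect_equal(row$area_q25, qi(birth_areas, 0.25))
  expect_equal(row$area_q75, qi(birth_areas, 0.75))
  shuf <- tab[sample(nrow(tab)), ]
  s2 <- cluster_summary(shuf)
  expect_equal(s[order(s$age_group), -1], s2[order(s2$age_group), -1],
               ignore_attr = TRUE)
  # single-section group: mean defined, no CI
  s3 <- cluster_summary(data.frame(age_group = "x", cluster_count = 7))
  expect_equal(s3$mean_count, 7)
  expect_true(is.na(s3$ci_lo))
})

test_that("one-way ANOVA equals t^2 for two groups and matches a textbook toy", {
  set.seed(33)
  a <- stats::rnorm(15); b <- stats::rnorm(12, 0.5)
  res <- one_way_anova(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_lt(abs(res$F - tt$statistic^2), 1e-10)
  expect_lt(abs(res$p - tt$p.value), 1e-10)
  # 3 groups of 3, hand-computed decomposition
  g <- list(c(1, 2, 3), c(2, 3, 4), c(6, 7, 8))
  means <- vapply(g, mean, numeric(1)); gm <- mean(unlist(g))
  ssb <- 3 * sum((means - gm)^2)
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  Fh <- (ssb / 2) / (ssw / 6)
  res3 <- one_way_anova(g)
  expect_lt(abs(res3$F - Fh), 1e-10)
  expect_equal(c(res3$df1, res3$df2), c(2, 6))
  expect_error(one_way_anova(list(c(1, 1), c(2, 2))), "variance")
})

test_that("a null ANOVA rejects at close to the nominal rate", {
  set.seed(34)
  rej <- vapply(1:1000, function(i) {
    g <- lapply(1:3, function(j) stats::rnorm(8))
    one_way_anova(g)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("the exponential trajectory fit is exact on noiseless data and flat data", {
  ages <- seq(0, 77, length.out = 25)
  y <- 100 * exp(-0.3 * ages) + 5
  fit <- fit_exponential_trajectory(ages, y)
  expect_lt(abs(fit$a - 100), 1e-6)
  expect_lt(abs(fit$b - 0.3), 1e-6)
  expect_lt(abs(fit$c - 5), 1e-6)
  # exactly flat data: fitted curve is flat with zero residual
  yf <- rep(10, 25)
  flat <- fit_exponential_trajectory(ages, yf)
  expect_lt(flat$rss, 1e-9)
  expect_lt(max(abs(flat$fitted_fn(ages) - 10)), 1e-4)
  expect_error(fit_exponential_trajectory(c(1, 2, 3), c(1, 2, 3)),
               ">= 4 points")
})

test_that("trajectory parameters are recovered from simulated histology tables", {
  sim <- simulate_histology_counts(histo_sim_config(seed = 2))
  agg <- stats::aggregate(cbind(marker_count, dapi_count) ~ individual + age,
                          sim$table, sum)
  fit <- fit_exponential_trajectory(agg$age,
                                    agg$marker_count / agg$dapi_count)
  expect_lt(abs(fit$a - 0.8) / 0.8, 0.1)
  expect_lt(abs(fit$b - 0.2) / 0.2, 0.1)
  expect_lt(abs(fit$c - 0.05) / 0.05, 0.1)
})

test_that("the mixed-model LRT is invariant to response rescaling and checks nesting", {
  sim <- simulate_histology_counts(histo_sim_config(
    seed = 40, n_individuals = 20, trajectory_a = 0.3, trajectory_b = 0.02,
    trajectory_c = 0, donor_logit_sd = 0.3, section_logit_sd = 0.15))
  tab <- sim$table
  r1 <- lmm_age_region_lrt(tab, effect_of_interest = "age")
  tab2 <- tab
  tab2$marker_count2 <- tab$marker_count
  y2 <- 1000 * tab$marker_count / tab$area_mm2
  r2 <- lmm_age_region_lrt(tab, response = y2, effect_of_interest = "age")
  expect_lt(abs(r1$chi2 - r2$chi2), 1e-4)
  expect_gte(r1$chi2, 0)
  expect_equal(r1$df, 1)
  tab$region <- "MPL"
  expect_error(lmm_age_region_lrt(tab, effect_of_interest = "region"),
               "single level")
  expect_error(lmm_age_region_lrt(tab[tab$individual %in%
                                        c("D1", "D2", "D3"), ],
                                  effect_of_interest = "age"),
               "4 individuals")
})

test_that("orientation summaries capture toward/away fractions and circular limits", {
  # all processes pointing exactly at the reference
  t1 <- data.frame(x = c(0, 10, 0, -5), y = c(10, 0, -10, 5),
                   process_angle = c(270, 180, 90, 315) %% 360)
  # vectors to reference (0,0): down, left, up, right-down
  t1$process_angle <- (atan2(-t1$y, -t1$x) * 180 / pi) %% 360
  s1 <- orientation_summary(t1, reference = c(0, 0))
  expect_equal(s1$frac_toward, 1)
  same <- data.frame(x = rnorm(5), y = rnorm(5), process_angle = rep(42, 5))
  expect_equal(orientation_summary(same, c(10, 10))$resultant_length, 1)
  set.seed(41)
  unif <- data.frame(x = rnorm(2000), y = rnorm(2000),
                     process_angle = stats::runif(2000, 0, 360))
  s2 <- orientation_summary(unif, c(0, 0))
  expect_lt(s2$resultant_length, 0.06)
  expect_warning(
    orientation_summary(data.frame(x = c(0, 1), y = c(0, 1),
                                   process_angle = c(10, 20)), c(0, 0)),
    "excluded")
  expect_error(
    orientation_summary(data.frame(x = 1, y = 1, process_angle = 380),
                        c(0, 0)), "angles")
})

test_that("uniform orientations pass the binomial test in most replicates", {
  set.seed(42)
  ps <- vapply(1:100, function(i) {
    t <- data.frame(x = stats::rnorm(1000, 5, 2),
                    y = stats::rnorm(1000, -3, 2),
                    process_angle = stats::runif(1000, 0, 360))
    orientation_summary(t, c(0, 0))$binom_p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})
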