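# The ANOVA/Tukey oracles below recompute the decompositions from raw sums
# of squares and the studentized range distribution, independently of the
# model-fitting route used by the package.

oracle_anova <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  gm <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

oracle_tukey_p <- function(groups, i, j) {
  k <- length(groups)
  n <- sum(lengths(groups))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  mse <- ssw / (n - k)
  se <- sqrt(mse / 2 * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
  q <- abs(mean(groups[[i]]) - mean(groups[[j]])) / se
  ptukey(q, k, n - k, lower.tail = FALSE)
}

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  set.seed(15)
  for (rep in 1:25) {
    groups <- lapply(1:3, function(i) rnorm(4 + rep %% 4, mean = i * runif(1)))
    got <- anova_one_way(groups)
    want <- oracle_anova(groups)
    expect_equal(got$f, want$f, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  g <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(anova_one_way(g)$f, 0, tolerance = 1e-12)
  expect_equal(anova_one_way(g)$p, 1, tolerance = 1e-12)
  expect_message(res <- anova_one_way(list(c(1, 1), c(1, 1))), "identical")
  expect_equal(res$p, 1)
})

test_that("Tukey HSD matches the studentized-range oracle", {
  set.seed(16)
  for (rep in 1:25) {
    groups <- list(a = rnorm(6), b = rnorm(6, 0.5), c = rnorm(5, 1))
    tk <- tukey_hsd(groups)
    expect_equal(tk$p_adj[tk$pair == "b-a"], oracle_tukey_p(groups, 2, 1),
                 tolerance = 1e-8)
    expect_equal(tk$p_adj[tk$pair == "c-b"], oracle_tukey_p(groups, 3, 2),
                 tolerance = 1e-8)
  }
})

test_that("Tukey flags a strongly shifted group and respects multiplicity", {
  set.seed(17)
  base <- rnorm(8, 0, 1)
  groups <- list(a = base, b = base + rnorm(8, 0, 1), c = base + 10)
  tk <- tukey_hsd(groups)
  expect_lt(tk$p_adj[tk$pair == "c-a"], 1e-6)
  expect_lt(tk$p_adj[tk$pair == "c-b"], 1e-6)
  # adjusted p >= the unadjusted pairwise test on the same pooled variance
  k <- length(groups)
  n <- sum(lengths(groups))
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1)) / (n - k)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    i <- pair[1]; j <- pair[2]
    se <- sqrt(mse * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
    raw <- 2 * pt(abs(mean(groups[[i]]) - mean(groups[[j]])) / se, n - k,
                  lower.tail = FALSE)
    adj <- tk$p_adj[tk$pair == paste0(names(groups)[j], "-",
                                      names(groups)[i])]
    expect_gte(adj + 1e-12, raw)
  }
})

test_that("observed-vs-predicted tests detect shifts and perfection", {
  set.seed(18)
  obs <- rnorm(20, 10)
  cp <- rbind(
    data.frame(window = "A", plant_id = 1:20, observed = obs,
               predicted = obs),
    data.frame(window = "B", plant_id = 1:20, observed = obs,
               predicted = obs + 5)
  )
  out <- observed_vs_predicted_tests(cp)
  a <- out[out$window == "A", ]
  expect_equal(a$t_p, 1)
  expect_equal(a$spearman_r, 1)
  expect_false(a$significant)
  b <- out[out$window == "B", ]
  expect_lt(b$t_p, 0.01)
  expect_true(b$significant)
  expect_error(observed_vs_predicted_tests(
    data.frame(window = "A", plant_id = 1:2, observed = 1:2,
               predicted = 1:2)), "at least 3")
})

test_that("anova/t-test agree with the reference route on random fixtures", {
  set.seed(19)
  for (rep in 1:25) {
    x <- rnorm(10); y <- x + rnorm(10, 0.2)
    cp <- data.frame(window = "W", plant_id = 1:10, observed = x,
                     predicted = y)
    got <- observed_vs_predicted_tests(cp)
    expect_equal(got$t_p, t.test(x, y, paired = TRUE)$p.value,
                 tolerance = 1e-10)
    expect_equal(got$spearman_r, cor(x, y, method = "spearman"),
                 tolerance = 1e-10)
  }
})

test_that("validation report bundles ANOVA, Tukey and per-window tests", {
  set.seed(20)
  obs <- rnorm(15, 10)
  cp <- rbind(
    data.frame(window = "T1", plant_id = 1:15, time_step = 165,
               observed = obs, predicted = obs + rnorm(15, 0, 0.1)),
    data.frame(window = "T5", plant_id = 1:15, time_step = 165,
               observed = obs, predicted = obs - 2)
  )
  rep_ <- validation_report(cp)
  expect_s3_class(rep_, "validation_report")
  expect_true(rep_$anova_p < 0.01)
  tt <- rep_$tests
  expect_false(tt$significant[tt$window == "T1"])
  expect_true(tt$significant[tt$window == "T5"])
  txt <- capture.output(print(rep_))
  expect_true(any(grepl("ANOVA", txt)))
})

test_that("protocol repeats across seeds with close correlation estimates", {
  run_once <- function(seed) {
    rec <- simulate_growth_curves(growth_sim_config(n_plants = 16,
                                                    seed = seed))
    cfg <- forecast_config(learner = "gbt", seed = seed)
    cmp <- suppressWarnings(compare_windows(rec, table1_windows()["T3"],
                                            cfg))
    out <- observed_vs_predicted_tests(
      cmp$checkpoints[cmp$checkpoints$time_step == 165, ])
    out$spearman_r
  }
  r1 <- run_once(101)
  r2 <- run_once(202)
  expect_gt(r1, 0.7)
  expect_gt(r2, 0.7)
  expect_lt(abs(r1 - r2), 0.25)
})
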