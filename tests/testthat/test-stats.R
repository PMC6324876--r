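test_that("t-tests match closed-form oracles", {
  set.seed(101)
  x <- rnorm(12, 1, 2); y <- rnorm(9, 0, 2)
  # pooled (Student) oracle
  sp2 <- ((11 * var(x) + 8 * var(y)) / 19)
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 12 + 1 / 9))
  p_oracle <- 2 * pt(-abs(t_oracle), 19)
  r <- t_test(x, y)
  expect_equal(r$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(r$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(r$degrees_of_freedom, 19)
  hw <- qt(0.975, 19) * sqrt(sp2 * (1 / 12 + 1 / 9))
  expect_equal(r$ci95, mean(x) - mean(y) + c(-hw, hw), tolerance = 1e-10)
  # Welch oracle
  se2 <- var(x) / 12 + var(y) / 9
  tw <- (mean(x) - mean(y)) / sqrt(se2)
  dfw <- se2^2 / ((var(x) / 12)^2 / 11 + (var(y) / 9)^2 / 8)
  rw <- t_test(x, y, welch = TRUE)
  expect_equal(rw$statistic, tw, tolerance = 1e-10)
  expect_equal(rw$degrees_of_freedom, dfw, tolerance = 1e-10)
  # paired oracle
  y2 <- rnorm(12, 0.5, 1)
  d <- x - y2
  tp <- mean(d) / (sd(d) / sqrt(12))
  rp <- t_test(x, y2, paired = TRUE)
  expect_equal(rp$statistic, tp, tolerance = 1e-10)
  expect_equal(rp$p_value, 2 * pt(-abs(tp), 11), tolerance = 1e-10)
})

test_that("degenerate t-test inputs raise errors, identical groups give p = 1", {
  expect_error(t_test(1:4, 1:4, paired = TRUE), "zero variance")
  expect_error(t_test(rep(1, 4), rep(1, 4)), "zero variance")
  r <- t_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("ci95_mean follows the t-interval closed form", {
  # constant data: zero-width interval
  expect_equal(ci95_mean(rep(7, 5)), c(7, 7))
  # worked example
  x <- c(0, 0, 10, 10)
  half <- qt(0.975, 3) * sd(x) / 2
  expect_equal(ci95_mean(x), 5 + c(-half, half), tolerance = 1e-12)
  expect_equal(ci95_mean(x), c(-4.18693, 14.18693), tolerance = 1e-5)
  # width shrinks as 1/sqrt(n) on replicated data (up to the t quantile)
  w1 <- diff(ci95_mean(c(0, 10)))
  w4 <- diff(ci95_mean(rep(c(0, 10), 50)))
  expect_lt(w4, w1 / 5)
  expect_error(ci95_mean(3), "at least 2")
})

test_that("repeated-measures ANOVA matches the hand-partition oracle", {
  m <- matrix(c(3, 5, 4,
                6, 8, 7,
                2, 4, 6), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("c", 1:3)))
  out <- rm_anova(m)
  # oracle: explicit partition
  grand <- mean(m)
  ss_s <- 3 * sum((rowMeans(m) - grand)^2)
  ss_c <- 3 * sum((colMeans(m) - grand)^2)
  ss_t <- sum((m - grand)^2)
  ss_r <- ss_t - ss_s - ss_c
  f <- (ss_c / 2) / (ss_r / 4)
  expect_equal(out$sum_sq[out$effect == "condition"], ss_c,
               tolerance = 1e-12)
  expect_equal(out$sum_sq[out$effect == "subject"], ss_s,
               tolerance = 1e-12)
  expect_equal(out$statistic[out$effect == "condition"], f,
               tolerance = 1e-12)
  expect_equal(out$p_value[out$effect == "condition"],
               pf(f, 2, 4, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("repeated-measures ANOVA agrees with aov error strata", {
  set.seed(111)
  n_s <- 6; n_c <- 4
  m <- matrix(rnorm(n_s * n_c), n_s, n_c) +
    outer(rnorm(n_s), rep(0, n_c), `+`) +
    outer(rep(0, n_s), c(0, 0.5, 1, 1.5), `+`)
  long <- data.frame(subject = factor(rep(1:n_s, n_c)),
                     condition = factor(rep(1:n_c, each = n_s)),
                     value = as.vector(m))
  fit <- summary(aov(value ~ condition + Error(subject), data = long))
  tab <- fit[["Error: Within"]][[1]]
  out <- rm_anova(m)
  expect_equal(out$statistic[out$effect == "condition"],
               tab["condition", "F value"], tolerance = 1e-9)
  expect_equal(out$p_value[out$effect == "condition"],
               tab["condition", "Pr(>F)"], tolerance = 1e-9)
})

test_that("two-condition RM ANOVA reproduces the paired t-test (F = t^2)", {
  set.seed(121)
  x <- rnorm(10); y <- x + rnorm(10, 0.5)
  f <- rm_anova(cbind(a = x, b = y))
  tt <- t_test(x, y, paired = TRUE)
  expect_equal(f$statistic[f$effect == "condition"], tt$statistic^2,
               tolerance = 1e-9)
  expect_equal(f$p_value[f$effect == "condition"], tt$p_value,
               tolerance = 1e-9)
})

test_that("flat tables give F = 0, p = 1; incomplete tables error", {
  m <- matrix(5, 4, 3)
  out <- rm_anova(m)
  expect_equal(out$statistic[out$effect == "condition"], 0)
  expect_equal(out$p_value[out$effect == "condition"], 1)
  long <- data.frame(subject = c("a", "a", "b"),
                     condition = c("c1", "c2", "c1"),
                     value = 1:3)
  expect_error(rm_anova(long), "one value per")
})

test_that("mixed ANOVA matches aov on a split-plot design", {
  set.seed(131)
  subj <- paste0("s", 1:8)
  region <- rep(c("striatum", "GPe"), each = 4)
  conds <- c("ca0.5", "ca2", "ca4")
  long <- expand.grid(subject = subj, condition = conds,
                      stringsAsFactors = FALSE)
  long$region <- region[match(long$subject, subj)]
  slope <- ifelse(long$region == "striatum", 2, 1)
  long$value <- slope * as.numeric(factor(long$condition)) +
    rep(rnorm(8), 3)[order(rep(1:3, each = 8))] + rnorm(24, 0, 0.5)
  out <- mixed_anova(long)

  fit <- summary(aov(value ~ region * condition + Error(subject),
                     data = transform(long,
                                      subject = factor(subject),
                                      region = factor(region),
                                      condition = factor(condition))))
  btab <- fit[["Error: subject"]][[1]]
  wtab <- fit[["Error: Within"]][[1]]
  expect_equal(out$statistic[out$effect == "region"],
               btab["region", "F value"], tolerance = 1e-9)
  expect_equal(out$statistic[out$effect == "condition"],
               wtab["condition", "F value"], tolerance = 1e-9)
  expect_equal(out$statistic[out$effect == "region:condition"],
               wtab["region:condition", "F value"], tolerance = 1e-9)
  expect_equal(out$p_value[out$effect == "region:condition"],
               wtab["region:condition", "Pr(>F)"], tolerance = 1e-9)
})

test_that("mixed ANOVA validates its design", {
  long <- data.frame(subject = rep(c("a", "b", "c"), each = 2),
                     region = rep(c("x", "x", "y"), each = 2),
                     condition = rep(c("c1", "c2"), 3),
                     value = rnorm(6))
  expect_error(mixed_anova(long), "at least 2 subjects")
  flat <- data.frame(subject = rep(c("a", "b", "c", "d"), each = 2),
                     region = rep(c("x", "y"), each = 4),
                     condition = rep(c("c1", "c2"), 4),
                     value = 3)
  out <- mixed_anova(flat)
  expect_true(all(out$statistic[!is.na(out$statistic)] == 0))
})
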