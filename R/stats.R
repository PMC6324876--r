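# Inferential layer: t-tests with CI95 conventions, one-way
# repeated-measures ANOVA and mixed (between x within) ANOVA.

#' Two-tailed t-test with 95% confidence interval
#'
#' Paired or unpaired two-sample t-test. The unpaired test uses the
#' pooled-variance (Student) form by default, with the Welch correction
#' available by flag. Degenerate zero-variance input raises an explicit
#' error rather than producing an infinite statistic.
#'
#' @param x,y Numeric samples; equal length required when `paired`.
#' @param paired Paired test on the within-subject differences?
#' @param welch Use the Welch (unequal-variance) correction? Unpaired
#'   only.
#' @return Object of class `"ffn_test_result"`: `statistic`,
#'   `degrees_of_freedom`, `p_value`, `ci95` (on the mean difference),
#'   `n` (per group), `method`.
#' @export
t_test <- function(x, y, paired = FALSE, welch = FALSE) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop_invalid("`x` and `y` must be numeric")
  }
  if (anyNA(x) || anyNA(y)) stop_invalid("missing values are not allowed")
  if (length(x) < 2L || length(y) < 2L) {
    stop_invalid("need at least 2 observations per group")
  }
  if (paired) {
    if (length(x) != length(y)) {
      stop_invalid("paired test requires equal-length samples")
    }
    if (stats::sd(x - y) == 0) {
      stop_invalid("degenerate paired differences (zero variance)")
    }
    fit <- stats::t.test(x, y, paired = TRUE, conf.level = 0.95)
  } else {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      stop_invalid("both groups have zero variance; t-test undefined")
    }
    fit <- stats::t.test(x, y, paired = FALSE, var.equal = !welch,
                         conf.level = 0.95)
  }
  structure(list(statistic = unname(fit$statistic),
                 degrees_of_freedom = unname(fit$parameter),
                 p_value = fit$p.value,
                 ci95 = as.vector(fit$conf.int),
                 n = c(length(x), length(y)),
                 method = fit$method),
            class = "ffn_test_result")
}

#' t-based 95% confidence interval of a mean
#'
#' `mean(x) +/- t_{0.975, n-1} * SEM`, the interval convention used to
#' report AUC values per condition.
#'
#' @param x Numeric sample with `n >= 2`.
#' @return Numeric length-2 `c(low, high)`.
#' @export
ci95_mean <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop_invalid("need at least 2 observations")
  }
  if (anyNA(x)) stop_invalid("missing values are not allowed")
  n <- length(x)
  half <- stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n)
  mean(x) + c(-half, half)
}

# Coerce subject x condition input (wide matrix or long data.frame with
# subject/condition/value columns) to a complete wide matrix.
as_rm_matrix <- function(table) {
  if (is.matrix(table)) {
    m <- table
  } else if (is.data.frame(table)) {
    need <- c("subject", "condition", "value")
    if (!all(need %in% names(table))) {
      stop_invalid("long input needs columns subject, condition, value")
    }
    m <- stats::xtabs(value ~ subject + condition, data = table)
    counts <- stats::xtabs(~ subject + condition, data = table)
    if (any(counts != 1)) {
      stop_invalid("input must have exactly one value per ",
                   "subject x condition cell")
    }
    m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  } else {
    stop_invalid("input must be a matrix or a long data.frame")
  }
  if (anyNA(m)) stop_invalid("missing cells in the subject x condition table")
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop_invalid("need at least 2 subjects and 2 conditions")
  }
  m
}

# Assemble an anova_table data.frame; zero-SS effects get F = 0, p = 1.
anova_row <- function(effect, ss, df, ss_err, df_err) {
  if (ss <= .Machine$double.eps * max(ss_err, 1)) {
    f <- 0; p <- 1
  } else if (ss_err <= 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ss / df) / (ss_err / df_err)
    p <- stats::pf(f, df, df_err, lower.tail = FALSE)
  }
  data.frame(effect = effect, sum_sq = ss, df = df, statistic = f,
             p_value = p, stringsAsFactors = FALSE)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA for designs where each subject (slice) is
#' measured under every condition (e.g. AUC at 0.5, 2 and 4 mM calcium).
#' The total sum of squares is partitioned into subject, condition and
#' residual (subject x condition) components; the condition effect is
#' tested against the residual. No sphericity correction is applied by
#' default; the Greenhouse-Geisser correction is available by flag.
#'
#' @param table Subject x condition numeric matrix, or a long data.frame
#'   with columns `subject`, `condition`, `value` (complete and balanced).
#' @param gg_correction Apply the Greenhouse-Geisser epsilon correction
#'   to the condition test's degrees of freedom?
#' @return Object of class `"anova_table"`: a data.frame with one row per
#'   effect (`condition`, `subject`, `residual`) and columns `effect`,
#'   `sum_sq`, `df`, `statistic`, `p_value`.
#' @export
rm_anova <- function(table, gg_correction = FALSE) {
  m <- as_rm_matrix(table)
  n_s <- nrow(m); n_c <- ncol(m)
  grand <- mean(m)
  ss_subj <- n_c * sum((rowMeans(m) - grand)^2)
  ss_cond <- n_s * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_res <- ss_tot - ss_subj - ss_cond
  df_cond <- n_c - 1
  df_res <- (n_s - 1) * (n_c - 1)

  out <- anova_row("condition", ss_cond, df_cond, ss_res, df_res)
  if (gg_correction && out$statistic > 0) {
    eps <- gg_epsilon(m)
    out$p_value <- stats::pf(out$statistic, eps * df_cond, eps * df_res,
                             lower.tail = FALSE)
  }
  out <- rbind(
    out,
    data.frame(effect = "subject", sum_sq = ss_subj, df = n_s - 1,
               statistic = NA_real_, p_value = NA_real_),
    data.frame(effect = "residual", sum_sq = ss_res, df = df_res,
               statistic = NA_real_, p_value = NA_real_))
  structure(out, class = c("anova_table", "data.frame"))
}

# Greenhouse-Geisser epsilon from the within-subject covariance matrix.
gg_epsilon <- function(m) {
  s <- stats::cov(m)
  k <- ncol(s)
  dbar <- mean(diag(s))
  sbar <- mean(s)
  num <- (k * (dbar - sbar))^2
  row_means <- rowMeans(s)
  den <- (k - 1) * (sum(s^2) - 2 * k * sum(row_means^2) + k^2 * sbar^2)
  max(min(num / den, 1), 1 / (k - 1))
}

#' Mixed (between x within) two-factor ANOVA
#'
#' Split-plot ANOVA with one between-subjects factor (e.g. region:
#' striatum vs GPe) and one within-subjects factor (e.g. calcium level or
#' stimulus frequency). The between effect is tested against
#' subjects-within-groups; the within effect and the interaction are
#' tested against the within-subject residual.
#'
#' @param table Long data.frame with columns `subject`, `region`
#'   (between), `condition` (within), `value`. Each subject belongs to
#'   one region and contributes one value per condition; every region
#'   needs at least 2 subjects.
#' @return An `"anova_table"` with rows `region`, `subjects_within`,
#'   `condition`, `region:condition`, `residual`.
#' @export
mixed_anova <- function(table) {
  need <- c("subject", "region", "condition", "value")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop_invalid("input needs columns subject, region, condition, value")
  }
  table$subject <- as.character(table$subject)
  table$region <- as.character(table$region)
  table$condition <- as.character(table$condition)
  reg_of <- tapply(table$region, table$subject,
                   function(r) length(unique(r)))
  if (any(reg_of != 1)) {
    stop_invalid("each subject must belong to exactly one region")
  }
  subj_region <- tapply(table$region, table$subject, `[`, 1)
  if (any(table(subj_region) < 2)) {
    stop_invalid("every region needs at least 2 subjects")
  }
  counts <- stats::xtabs(~ subject + condition, data = table)
  if (any(counts != 1)) {
    stop_invalid("each subject needs exactly one value per condition")
  }

  subjects <- sort(unique(table$subject))
  conditions <- sort(unique(table$condition))
  regions <- sort(unique(subj_region))
  a <- length(regions); b <- length(conditions)
  n_s <- length(subjects)
  m <- stats::xtabs(value ~ subject + condition, data = table)
  m <- matrix(as.numeric(m), n_s, b,
              dimnames = list(sort(unique(table$subject)), conditions))
  sreg <- subj_region[rownames(m)]

  grand <- mean(m)
  subj_means <- rowMeans(m)
  cond_means <- colMeans(m)
  reg_means <- tapply(subj_means, sreg, mean)
  cell_means <- matrix(0, a, b, dimnames = list(regions, conditions))
  for (g in regions) {
    cell_means[g, ] <- colMeans(m[sreg == g, , drop = FALSE])
  }
  n_per_reg <- as.vector(table(sreg)[regions])

  ss_region <- b * sum(n_per_reg * (reg_means[regions] - grand)^2)
  ss_subj_within <- b * sum((subj_means - reg_means[sreg])^2)
  ss_cond <- n_s * sum((cond_means - grand)^2)
  # interaction: sum over cells n_g (cell - reg - cond + grand)^2
  ss_inter <- 0
  for (gi in seq_len(a)) {
    for (ci in seq_len(b)) {
      ss_inter <- ss_inter + n_per_reg[gi] *
        (cell_means[gi, ci] - reg_means[regions[gi]] -
           cond_means[ci] + grand)^2
    }
  }
  ss_tot <- sum((m - grand)^2)
  ss_res <- ss_tot - ss_region - ss_subj_within - ss_cond - ss_inter

  df_sw <- n_s - a
  df_res <- df_sw * (b - 1)
  out <- rbind(
    anova_row("region", ss_region, a - 1, ss_subj_within, df_sw),
    data.frame(effect = "subjects_within", sum_sq = ss_subj_within,
               df = df_sw, statistic = NA_real_, p_value = NA_real_),
    anova_row("condition", ss_cond, b - 1, ss_res, df_res),
    anova_row("region:condition", ss_inter, (a - 1) * (b - 1),
              ss_res, df_res),
    data.frame(effect = "residual", sum_sq = ss_res, df = df_res,
               statistic = NA_real_, p_value = NA_real_))
  structure(out, class = c("anova_table", "data.frame"))
}

#' @export
print.ffn_test_result <- function(x, ...) {
  cat(sprintf("%s: t = %.4g, df = %.4g, p = %.4g, CI95 [%.4g, %.4g]\n",
              x$method, x$statistic, x$degrees_of_freedom, x$p_value,
              x$ci95[1], x$ci95[2]))
  invisible(x)
}
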