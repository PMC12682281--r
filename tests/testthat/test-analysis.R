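# Exclusions, bias statistic, group tests, evenness correlation, ridge with
# permutation inference.

make_rows <- function(participant, set, n_note, n_contour, n_nodiff = 0,
                      comprehension = 5L) {
  data.frame(
    participant_id = participant, cohort = "t", set_id = set,
    melody_length = 12L, block = 1L,
    trial = seq_len(n_note + n_contour + n_nodiff),
    choice = c(rep("note", n_note), rep("contour", n_contour),
               rep("no_difference", n_nodiff)),
    comprehension_rating = comprehension, years_training = 0,
    plays_instrument = FALSE, stringsAsFactors = FALSE
  )
}

test_that("exclusion rules apply the documented thresholds exactly", {
  tab <- rbind(
    make_rows(1, "A", 10, 10),                      # 20 usable, keep
    make_rows(2, "A", 10, 10, comprehension = 3L),  # boundary: exclude
    make_rows(3, "A", 10, 10, comprehension = 4L),  # keep
    make_rows(3, "B", 8, 6, n_nodiff = 6),          # 14 usable: drop cond
    make_rows(4, "B", 8, 7, n_nodiff = 5)           # 15 usable: keep
  )
  kept <- apply_exclusions(tab)
  excl <- attr(kept, "exclusions")
  expect_identical(excl$participants$participant_id, 2)
  expect_identical(nrow(excl$conditions), 1L)
  expect_identical(excl$conditions$n_usable, 14L)
  expect_identical(excl$conditions$participant_id, 3)
  expect_setequal(unique(paste(kept$participant_id, kept$set_id)),
                  c("1 A", "3 A", "4 B"))
  expect_error(apply_exclusions(tab[, -3]), class = "scalegeom_schema_error")
  bad <- tab
  bad$choice[1] <- "banana"
  expect_error(apply_exclusions(bad), class = "scalegeom_schema_error")
})

test_that("bias follows its definition and excludes no-difference trials", {
  tab <- make_rows(1, "A", 30, 20)
  expect_equal(compute_bias(tab)$bias, 0.2)
  expect_equal(compute_bias(make_rows(1, "A", 12, 12))$bias, 0)
  expect_equal(compute_bias(make_rows(1, "A", 17, 0))$bias, 1)

  # adding no-difference rows never changes bias
  with_nd <- rbind(make_rows(1, "A", 30, 20), make_rows(1, "A", 0, 0, 40))
  expect_equal(compute_bias(with_nd)$bias, 0.2)
  expect_identical(compute_bias(with_nd)$n_nodiff, 40L)

  # antisymmetry under relabeling note <-> contour
  flipped <- make_rows(1, "A", 20, 30)
  expect_equal(compute_bias(flipped)$bias, -0.2)

  # zero usable responses is flagged, not silently zero
  only_nd <- make_rows(1, "A", 0, 0, 20)
  b <- compute_bias(only_nd)
  expect_true(b$flagged)
  expect_true(is.na(b$bias))
})

test_that("t tests report the textbook effect sizes", {
  x <- c(0.2, 0.5, 0.1, 0.4, 0.3, 0.6)
  y <- c(0.1, 0.2, 0.0, 0.3, 0.2, 0.1)
  one <- t_one_sample(x)
  expect_equal(one$effect_size, mean(x) / sd(x))
  expect_equal(one$df, 5)
  pair <- t_paired(x, y)
  expect_equal(pair$effect_size, mean(x - y) / sd(x - y))
  ind <- t_independent(x, y, var_equal = TRUE)
  sp <- sqrt((5 * var(x) + 5 * var(y)) / 10)
  expect_equal(ind$effect_size, (mean(x) - mean(y)) / sp)
  expect_identical(ind$df, 10)
  # degenerate inputs follow the error path
  expect_error(t_one_sample(rep(0.3, 5)), "variance")
  expect_error(t_paired(x, x), "variance")
  expect_error(t_paired(x, y[-1]), "equal length")
})

test_that("the mixed ANOVA matches a hand-computed sums-of-squares oracle", {
  # 3 between groups x 2 within levels, 4 subjects per group, balanced
  set.seed(99)
  d <- expand.grid(s = 1:12, w = c("c1", "c2"), KEEP.OUT.ATTRS = FALSE)
  d$b <- rep(rep(c("g1", "g2", "g3"), each = 4), 2)
  d$y <- round(rnorm(24, mean = 1 + 0.5 * (d$w == "c2") +
                       0.3 * as.integer(factor(d$b))), 2)

  res <- mixed_anova(d, dv = "y", within = "w", between = "b", id = "s")

  # oracle: textbook decomposition for the balanced two-way mixed design
  n_s <- 12; n_w <- 2; n_b <- 3; per <- 4
  gm <- mean(d$y)
  subj_means <- tapply(d$y, d$s, mean)
  b_means <- tapply(d$y, d$b, mean)
  w_means <- tapply(d$y, d$w, mean)
  cell_means <- tapply(d$y, list(d$b, d$w), mean)
  ss_between_subj <- n_w * sum((subj_means - gm)^2)
  ss_b <- n_w * per * sum((b_means - gm)^2)
  ss_subj_within <- ss_between_subj - ss_b
  ss_w <- n_s * sum((w_means - gm)^2)
  ss_bw <- per * sum((cell_means - gm)^2) - ss_b - ss_w
  ss_total <- sum((d$y - gm)^2)
  ss_err <- ss_total - ss_between_subj - ss_w - ss_bw
  f_b <- (ss_b / (n_b - 1)) / (ss_subj_within / (n_s - n_b))
  f_w <- (ss_w / (n_w - 1)) / (ss_err / ((n_s - n_b) * (n_w - 1)))
  f_bw <- (ss_bw / ((n_b - 1) * (n_w - 1))) /
    (ss_err / ((n_s - n_b) * (n_w - 1)))

  expect_equal(res$F, c(f_b, f_w, f_bw))
  expect_equal(res$df1, c(2, 1, 2))
  expect_equal(res$df2, c(9, 9, 9))
  expect_equal(res$pes, c(ss_b / (ss_b + ss_subj_within),
                          ss_w / (ss_w + ss_err),
                          ss_bw / (ss_bw + ss_err)))
  expect_equal(res$p[1], stats::pf(f_b, 2, 9, lower.tail = FALSE))
})

test_that("mixed ANOVA drops incomplete subjects listwise with a warning", {
  d <- expand.grid(s = 1:8, w = c("c1", "c2"), KEEP.OUT.ATTRS = FALSE)
  d$b <- rep(rep(c("g1", "g2"), each = 4), 2)
  set.seed(2)
  d$y <- rnorm(16)
  d <- d[-1, ]  # subject 1 loses one within level
  expect_warning(res <- mixed_anova(d, "y", "w", "b", "s"), "incomplete")
  expect_identical(res$df2[1], 5)  # 7 subjects - 2 groups
})

test_that("group_tests assembles per-condition, paired and ANOVA reports", {
  set.seed(10)
  n <- 24
  summaries <- rbind(
    data.frame(participant_id = 1:n, set_id = "pent",
               melody_length = rep(c(8L, 12L), each = n / 2),
               bias = rnorm(n, 0.4, 0.2)),
    data.frame(participant_id = 1:n, set_id = "chrom",
               melody_length = rep(c(8L, 12L), each = n / 2),
               bias = rnorm(n, 0.1, 0.2))
  )
  out <- group_tests(summaries, between = "melody_length")
  expect_setequal(out$t_tests$test,
                  c("one_sample_t:chrom", "one_sample_t:pent",
                    "paired_t:chrom_vs_pent"))
  expect_identical(out$anova$effect, c("between", "within", "interaction"))
  # paired test agrees with a direct computation
  pt <- out$t_tests[out$t_tests$test == "paired_t:chrom_vs_pent", ]
  direct <- t_paired(summaries$bias[summaries$set_id == "chrom"],
                     summaries$bias[summaries$set_id == "pent"])
  expect_equal(pt$statistic, direct$statistic)
})

test_that("evenness correlation handles exact and degenerate cases", {
  feats <- features_66()
  sc <- feats
  sc$mean_bias <- 0.1 + 0.2 * sc$evenness  # exactly linear
  ec <- evenness_correlation(sc)
  expect_equal(ec$R, 1)
  expect_lt(ec$p, 1e-10)
  sc$mean_bias <- rep(0.3, nrow(sc))
  expect_error(evenness_correlation(sc), "variance")
  expect_error(evenness_correlation(sc[1:2, ]), "3 sets")
})

test_that("ridge at penalty ~ 0 equals the normal-equation OLS solution", {
  set.seed(42)
  n <- 40
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("ic", 1:6)))
  beta <- c(0.5, -0.3, 0.2, 0, 0.1, -0.4)
  y <- drop(2 + X %*% beta + rnorm(n, 0, 0.1))
  sc <- data.frame(X, mean_bias = y)
  fit <- ridge_interval_regression(sc, penalty = 1e-10, n_perm = 100,
                                   seed = 1)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(fit$coefficients), unname(ols[-1]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-8)
})

test_that("ridge at penalty 1.0 matches scikit-learn on a fixture", {
  skip_if_not(python_available(), "python with scikit-learn not available")
  feats <- features_66()
  sc <- feats
  sc$mean_bias <- expected_set_bias(response_model(), feats)
  fit <- ridge_interval_regression(sc, penalty = 1.0, n_perm = 100, seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(sc[, c(paste0("ic", 1:6), "mean_bias")], csv, row.names = FALSE)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from sklearn.linear_model import Ridge",
    "d = np.genfromtxt(sys.argv[1], delimiter=',', skip_header=1)",
    "m = Ridge(alpha=1.0).fit(d[:, :6], d[:, 6])",
    "print(' '.join('%.12f' % c for c in list(m.coef_) + [m.intercept_]))"
  ), script)
  out <- system2("python", c(script, csv), stdout = TRUE)
  ref <- as.numeric(strsplit(trimws(out[length(out)]), " ")[[1]])
  expect_equal(unname(fit$coefficients), ref[1:6], tolerance = 1e-8)
  expect_equal(fit$intercept, ref[7], tolerance = 1e-8)
})

test_that("permutation inference is seed-deterministic and shift-invariant", {
  feats <- features_66()
  sc <- feats
  set.seed(1)
  sc$mean_bias <- expected_set_bias(response_model(), feats) +
    rnorm(66, 0, 0.03)
  a <- ridge_interval_regression(sc, n_perm = 500, seed = 9)
  b <- ridge_interval_regression(sc, n_perm = 500, seed = 9)
  expect_identical(a$p_model, b$p_model)
  expect_identical(a$p, b$p)

  shifted <- sc
  shifted$mean_bias <- sc$mean_bias + 0.37
  s <- ridge_interval_regression(shifted, n_perm = 500, seed = 9)
  expect_equal(s$R, a$R)
  expect_identical(s$p_model, a$p_model)
  expect_identical(s$p, a$p)
  expect_equal(unname(s$coefficients), unname(a$coefficients))

  # p floor: never exactly zero; CIs contain the estimate
  expect_true(all(a$p > 0) && a$p_model > 0)
  expect_true(all(a$ci["lower", ] <= a$coefficients &
                    a$coefficients <= a$ci["upper", ]))
  expect_error(ridge_interval_regression(sc[1:5, ]), "more sets")
  expect_warning(ridge_interval_regression(sc, n_perm = 50, seed = 1),
                 "crude")
})

test_that("leave-one-out model R is computable and bounded", {
  feats <- features_66()
  sc <- feats
  set.seed(4)
  sc$mean_bias <- expected_set_bias(response_model(), feats) +
    rnorm(66, 0, 0.05)
  r_loo <- ridge_loo_r(sc)
  r_in <- ridge_interval_regression(sc, n_perm = 100, seed = 1)$R
  expect_true(abs(r_loo) <= 1)
  expect_lt(r_loo, r_in + 1e-8)  # held-out never beats in-sample here
})
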