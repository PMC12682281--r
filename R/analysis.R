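# Statistical pipeline: exclusion rules, the note/contour response-bias
# statistic, group tests, the evenness correlation, and interval-vector
# ridge regression with permutation inference.

RESPONSE_COLUMNS <- c("participant_id", "set_id", "choice",
                      "comprehension_rating")

check_schema <- function(table) {
  missing <- setdiff(RESPONSE_COLUMNS, names(table))
  if (length(missing) > 0L) {
    abort(sprintf("response table lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "scalegeom_schema_error")
  }
  bad <- setdiff(unique(table$choice), c("note", "contour", "no_difference"))
  if (length(bad) > 0L) {
    abort(sprintf("unknown choice value(s): %s", paste(bad, collapse = ", ")),
          class = "scalegeom_schema_error")
  }
  invisible(table)
}

#' Apply the study exclusion rules
#'
#' Two rules: (1) participants reporting they did not understand the task
#' (comprehension rating at or below `comprehension_cutoff` on a 5-point
#' scale) are removed entirely; (2) (participant, set) conditions with
#' fewer than `min_responses` usable responses are removed, where usable
#' means a note or contour choice ("no difference" reports do not count
#' toward the denominator because they are excluded from the analysis).
#' Every removal is recorded in the `exclusions` attribute.
#'
#' @param table a response table ([simulate_cohort()] schema).
#' @param min_responses minimum usable responses per condition (default 15).
#' @param comprehension_cutoff highest excluded rating (default 3,
#'   i.e. "three or less" is excluded).
#' @return the filtered table, with an `exclusions` attribute (a list of
#'   data.frames `participants` and `conditions`).
#' @export
apply_exclusions <- function(table, min_responses = 15L,
                             comprehension_cutoff = 3L) {
  check_schema(table)
  comp <- unique(table[, c("participant_id", "comprehension_rating")])
  bad_p <- comp$participant_id[comp$comprehension_rating <=
                                 comprehension_cutoff]
  excluded_participants <- data.frame(
    participant_id = bad_p,
    reason = rep("low_comprehension", length(bad_p))
  )
  kept <- table[!(table$participant_id %in% bad_p), , drop = FALSE]

  usable <- kept$choice != "no_difference"
  key <- interaction(kept$participant_id, kept$set_id, drop = TRUE)
  n_usable <- tapply(usable, key, sum)
  bad_k <- names(n_usable)[n_usable < min_responses]
  excluded_conditions <- do.call(rbind, lapply(bad_k, function(k) {
    rows <- which(key == k)
    data.frame(participant_id = kept$participant_id[rows[1]],
               set_id = kept$set_id[rows[1]],
               n_usable = as.integer(n_usable[[k]]),
               reason = "fewer_than_min_responses")
  })) %||% data.frame(participant_id = integer(0), set_id = character(0),
                      n_usable = integer(0), reason = character(0))
  if (length(bad_k) > 0L) kept <- kept[!(key %in% bad_k), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "exclusions") <- list(participants = excluded_participants,
                                   conditions = excluded_conditions)
  kept
}

#' Response bias toward note deviations
#'
#' Per (participant, set) condition: `bias = (n_note - n_contour) /
#' (n_note + n_contour)`. "No difference" trials are excluded from the
#' denominator. A condition with zero usable responses gets `bias = NA`
#' and `flagged = TRUE` rather than a silent zero.
#'
#' @param table a response table, normally after [apply_exclusions()].
#' @return a data.frame with one row per (participant, set): counts
#'   `n_note`, `n_contour`, `n_nodiff`, plus `bias` and `flagged`; carries
#'   over `melody_length` and `cohort` when present.
#' @export
compute_bias <- function(table) {
  check_schema(table)
  dt <- data.table::as.data.table(table)
  extra <- intersect(c("melody_length", "cohort"), names(dt))
  out <- dt[, c(list(
    n_note = sum(choice == "note"),
    n_contour = sum(choice == "contour"),
    n_nodiff = sum(choice == "no_difference")),
    lapply(.SD, data.table::first)),
    by = .(participant_id, set_id), .SDcols = extra]
  out[, `:=`(
    bias = ifelse(n_note + n_contour > 0L,
                  (n_note - n_contour) / (n_note + n_contour), NA_real_),
    flagged = n_note + n_contour == 0L
  )]
  as.data.frame(out)
}

#' Per-set mean bias joined to geometric features
#'
#' Averages the condition-level bias across participants for every set and
#' joins the set's evenness and interval-class counts.
#'
#' @param summaries output of [compute_bias()].
#' @param features a [set_class_table()].
#' @return a data.frame: `set_id`, `mean_bias`, `n_participants`,
#'   `evenness`, `sd_deviation`, `ic1`..`ic6`.
#' @export
set_scores <- function(summaries, features) {
  ok <- !is.na(summaries$bias)
  agg <- aggregate(bias ~ set_id, data = summaries[ok, ], FUN = mean)
  names(agg)[2] <- "mean_bias"
  agg$n_participants <- as.integer(
    table(summaries$set_id[ok])[agg$set_id])
  m <- match(agg$set_id, features$set_id)
  if (anyNA(m)) {
    abort(sprintf("set id(s) missing from feature table: %s",
                  paste(agg$set_id[is.na(m)], collapse = ", ")))
  }
  cbind(agg, features[m, c("evenness", "sd_deviation", paste0("ic", 1:6))],
        row.names = NULL)
}

# --- group tests -------------------------------------------------------

cohens_d_one <- function(x, mu = 0) (mean(x) - mu) / sd(x)

cohens_d_two <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

tidy_t <- function(ht, d, label) {
  data.frame(test = label, statistic = unname(ht$statistic),
             df = unname(ht$parameter), p = ht$p.value, effect_size = d,
             effect_size_type = "cohens_d")
}

#' One-sample, paired and independent t tests with Cohen's d
#'
#' Two-tailed throughout. `t_one_sample` tests a mean against zero (d =
#' mean / SD); `t_paired` tests the mean of differences (d on the
#' difference scale); `t_independent` compares two groups (classical
#' pooled-SD d; Welch correction optional via `var_equal = FALSE`).
#' A zero-variance sample is an error, not a silent Inf.
#'
#' @param x,y numeric samples.
#' @param mu null value for the one-sample test.
#' @param var_equal pass `TRUE` for the Student (pooled) test.
#' @return a one-row data.frame: `test`, `statistic`, `df`, `p`,
#'   `effect_size`, `effect_size_type`.
#' @export
t_one_sample <- function(x, mu = 0) {
  if (length(x) < 2L || sd(x) == 0) {
    abort("one-sample t test needs >= 2 observations with nonzero variance")
  }
  tidy_t(stats::t.test(x, mu = mu), cohens_d_one(x, mu), "one_sample_t")
}

#' @rdname t_one_sample
#' @export
t_paired <- function(x, y) {
  if (length(x) != length(y)) abort("paired samples must have equal length")
  d <- x - y
  if (sd(d) == 0) abort("paired differences have zero variance")
  tidy_t(stats::t.test(x, y, paired = TRUE), cohens_d_one(d, 0), "paired_t")
}

#' @rdname t_one_sample
#' @export
t_independent <- function(x, y, var_equal = FALSE) {
  tidy_t(stats::t.test(x, y, var.equal = var_equal), cohens_d_two(x, y),
         if (var_equal) "independent_t" else "welch_t")
}

#' Two-way mixed ANOVA with partial eta squared
#'
#' One within-subjects factor crossed with one between-subjects factor
#' (e.g. condition within, melody length between), computed via the
#' classical univariate sums-of-squares decomposition with subject error
#' strata. Participants missing any within-factor cell are dropped listwise
#' with a warning. Partial eta squared is SS_effect / (SS_effect +
#' SS_error-of-its-stratum).
#'
#' @param data long data.frame.
#' @param dv name of the numeric response column.
#' @param within name of the within-subjects factor column.
#' @param between name of the between-subjects factor column.
#' @param id name of the subject identifier column.
#' @return a data.frame with rows for the between effect, the within
#'   effect and their interaction: `effect`, `df1`, `df2`, `F`, `p`,
#'   `pes` (partial eta squared).
#' @export
mixed_anova <- function(data, dv, within, between, id) {
  d <- data.frame(y = data[[dv]],
                  w = factor(data[[within]]),
                  b = factor(data[[between]]),
                  s = factor(data[[id]]))
  d <- d[stats::complete.cases(d), ]
  # listwise deletion of subjects without a full set of within levels
  full <- tapply(d$w, d$s, function(w) length(unique(w)))
  keep <- names(full)[full == nlevels(d$w)]
  if (length(keep) < length(full)) {
    warning(sprintf("dropping %d subject(s) with incomplete within-factor data",
                    length(full) - length(keep)))
    d <- d[d$s %in% keep, ]
    d$s <- droplevels(d$s)
  }
  if (nlevels(d$s) < 2L) abort("need >= 2 complete subjects")
  fit <- stats::aov(y ~ b * w + Error(s / w), data = d)
  sm <- summary(fit)
  s_strat <- as.data.frame(sm[["Error: s"]][[1]])
  sw_strat <- as.data.frame(sm[["Error: s:w"]][[1]])
  row_of <- function(strat, name) {
    i <- which(trimws(rownames(strat)) == name)
    unlist(strat[i, c("Df", "Sum Sq", "F value", "Pr(>F)")])
  }
  err_s <- row_of(s_strat, "Residuals")
  err_sw <- row_of(sw_strat, "Residuals")
  eff <- rbind(
    c(row_of(s_strat, "b"), err = err_s[["Sum Sq"]], dfe = err_s[["Df"]]),
    c(row_of(sw_strat, "w"), err = err_sw[["Sum Sq"]], dfe = err_sw[["Df"]]),
    c(row_of(sw_strat, "b:w"), err = err_sw[["Sum Sq"]], dfe = err_sw[["Df"]])
  )
  data.frame(
    effect = c("between", "within", "interaction"),
    df1 = eff[, "Df"], df2 = eff[, "dfe"], F = eff[, "F value"],
    p = eff[, "Pr(>F)"],
    pes = eff[, "Sum Sq"] / (eff[, "Sum Sq"] + eff[, "err"]),
    row.names = NULL
  )
}

#' Standard group-level test report
#'
#' For condition-level bias summaries: a one-sample t against zero per
#' condition, a paired t for each pair of conditions shared within
#' participants, and (when a between-subjects factor such as melody length
#' is supplied and spans more than one level) the two-way mixed ANOVA.
#'
#' @param summaries output of [compute_bias()]; the `set_id` column is the
#'   condition label.
#' @param between optional name of a between-subjects column in
#'   `summaries` (e.g. `"melody_length"`).
#' @return a list with `t_tests` (tidy data.frame) and `anova` (or `NULL`).
#' @export
group_tests <- function(summaries, between = NULL) {
  ok <- summaries[!is.na(summaries$bias), ]
  conds <- sort(unique(ok$set_id))
  tt <- do.call(rbind, lapply(conds, function(cn) {
    res <- t_one_sample(ok$bias[ok$set_id == cn])
    res$test <- paste0("one_sample_t:", cn)
    res
  }))
  if (length(conds) > 1L) {
    for (i in seq_len(length(conds) - 1L)) {
      for (j in (i + 1L):length(conds)) {
        a <- ok[ok$set_id == conds[i], c("participant_id", "bias")]
        b <- ok[ok$set_id == conds[j], c("participant_id", "bias")]
        shared <- intersect(a$participant_id, b$participant_id)
        if (length(shared) >= 2L) {
          res <- t_paired(a$bias[match(shared, a$participant_id)],
                          b$bias[match(shared, b$participant_id)])
          res$test <- sprintf("paired_t:%s_vs_%s", conds[i], conds[j])
          tt <- rbind(tt, res)
        }
      }
    }
  }
  an <- NULL
  if (!is.null(between) && length(unique(ok[[between]])) > 1L &&
      length(conds) > 1L) {
    an <- mixed_anova(ok, dv = "bias", within = "set_id",
                      between = between, id = "participant_id")
  }
  list(t_tests = tt, anova = an)
}

#' Pearson correlation between evenness and mean bias across sets
#'
#' @param scores output of [set_scores()].
#' @return a list with `R` (Pearson correlation) and `p` (two-tailed).
#' @export
evenness_correlation <- function(scores) {
  if (nrow(scores) < 3L) abort("need at least 3 sets")
  if (sd(scores$evenness) == 0 || sd(scores$mean_bias) == 0) {
    abort("zero variance in evenness or mean bias")
  }
  ht <- stats::cor.test(scores$evenness, scores$mean_bias,
                        method = "pearson")
  list(R = unname(ht$estimate), p = ht$p.value)
}

# --- ridge regression with permutation inference -----------------------

ridge_fit <- function(X, y, penalty) {
  # unpenalized intercept via centering; predictors enter raw (unscaled)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - mean(y)
  A <- crossprod(Xc) + diag(penalty, ncol(X))
  H <- solve(A, t(Xc))        # coefficient operator: b = H %*% y
  b <- drop(H %*% yc)
  intercept <- mean(y) - sum(xbar * b)
  fitted <- intercept + drop(X %*% b)
  list(coefficients = b, intercept = intercept, fitted = fitted,
       R = if (sd(fitted) > 0) cor(fitted, y) else 0, H = H, Xc = Xc)
}

#' Ridge regression of set bias on interval-class counts, with
#' permutation inference
#'
#' Fits `mean_bias ~ ic1 + ... + ic6` by ridge regression with an
#' unpenalized intercept and raw (unstandardized) count predictors, at the
#' given penalty (default 1.0). For a fixed cardinality the six counts sum
#' to `choose(k, 2)`, so the predictors are exactly collinear; the ridge
#' penalty is what makes the fit identified — coefficients should be read
#' as regularized contrasts, not as independent slopes.
#'
#' Model performance is the Pearson correlation R between fitted and
#' observed set scores. Inference is by permutation: the response is
#' permuted across sets `n_perm` times and the model refitted. The model
#' p-value is the fraction of permuted R at or above the observed R;
#' per-coefficient two-sided p-values are tail fractions of `|B_perm| >=
#' |B_obs|`; both use the `(r + 1) / (n_perm + 1)` floor so p is never 0.
#' 95% CIs are `B_obs +/- q`, where `q` is the 97.5th percentile of
#' `|B_perm - mean(B_perm)|` (a centered-absolute-quantile construction;
#' recorded in the result metadata).
#'
#' @param scores output of [set_scores()] (needs `mean_bias`, `ic1`..`ic6`).
#' @param penalty ridge penalty (default 1.0).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutations.
#' @return an object of class `ridge_perm`: coefficients, fitted values,
#'   `R`, `p_model`, per-coefficient `p` and `ci` (2 x 6), `penalty`,
#'   `n_perm`, `ci_method`.
#' @export
ridge_interval_regression <- function(scores, penalty = 1.0,
                                      n_perm = 10000L, seed = 1L) {
  need <- c("mean_bias", paste0("ic", 1:6))
  if (!all(need %in% names(scores))) {
    abort("`scores` must contain mean_bias and ic1..ic6")
  }
  X <- as.matrix(scores[, paste0("ic", 1:6)])
  y <- scores$mean_bias
  n <- nrow(X)
  if (n <= ncol(X)) abort("need more sets than predictors")
  if (n_perm < 100L) warning("n_perm < 100: permutation inference is crude")
  fit <- ridge_fit(X, y, penalty)

  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n))
  Yp <- matrix(y[perm_idx], nrow = n)           # n x n_perm
  Ypc <- sweep(Yp, 2L, colMeans(Yp))
  Bp <- fit$H %*% Ypc                           # 6 x n_perm
  Fp <- fit$Xc %*% Bp                           # centered fitted values
  # cor(fitted, y_perm) column-wise
  Rp <- colSums(Fp * Ypc) /
    (sqrt(colSums(Fp^2)) * sqrt(colSums(Ypc^2)))
  Rp[!is.finite(Rp)] <- 0

  p_model <- (sum(Rp >= fit$R) + 1) / (n_perm + 1)
  b <- fit$coefficients
  p_coef <- (rowSums(abs(Bp) >= abs(b)) + 1) / (n_perm + 1)
  half <- apply(abs(Bp - rowMeans(Bp)), 1L, stats::quantile, probs = 0.975)
  ci <- rbind(lower = b - half, upper = b + half)
  colnames(ci) <- paste0("ic", 1:6)

  structure(
    list(coefficients = setNames(b, paste0("ic", 1:6)),
         intercept = fit$intercept, fitted = fit$fitted,
         R = fit$R, p_model = p_model,
         p = setNames(p_coef, paste0("ic", 1:6)), ci = ci,
         penalty = penalty, n_perm = as.integer(n_perm), seed = seed,
         ci_method = "centered absolute 97.5% permutation quantile"),
    class = "ridge_perm"
  )
}

#' @export
print.ridge_perm <- function(x, ...) {
  cat(sprintf("<ridge_perm> penalty %.3g, %d permutations\n", x$penalty,
              x$n_perm))
  cat(sprintf("model R = %.3f, permutation p = %.4g\n", x$R, x$p_model))
  tab <- data.frame(B = round(x$coefficients, 4),
                    ci_low = round(x$ci["lower", ], 4),
                    ci_high = round(x$ci["upper", ], 4),
                    p = signif(x$p, 3))
  print(tab)
  invisible(x)
}

#' Leave-one-out cross-validated model R (labeled extra)
#'
#' The headline model R is in-sample (correlation of fitted with observed).
#' This companion recomputes predictions with each set held out in turn and
#' correlates held-out predictions with the observed scores — a stricter,
#' clearly labeled alternative.
#'
#' @param scores output of [set_scores()].
#' @param penalty ridge penalty.
#' @return the leave-one-out Pearson R.
#' @export
ridge_loo_r <- function(scores, penalty = 1.0) {
  X <- as.matrix(scores[, paste0("ic", 1:6)])
  y <- scores$mean_bias
  preds <- vapply(seq_len(nrow(X)), function(i) {
    f <- ridge_fit(X[-i, , drop = FALSE], y[-i], penalty)
    f$intercept + sum(X[i, ] * f$coefficients)
  }, numeric(1))
  cor(preds, y)
}
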