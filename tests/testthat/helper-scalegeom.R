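# Shared fixtures, built in code. The 66-class feature table is computed
# once per test run and cached.

features_66 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- set_class_table(12L, 5L)
    cache
  }
})

pentatonic_set <- function() pc_set(c(0, 2, 4, 7, 9))
chromatic_set <- function() pc_set(0:11)

# Burnside-lemma oracle for the number of k-subsets of Z_n up to rotation:
# average over all rotations r of the number of subsets fixed by r. A
# rotation of order n/g (g = gcd(r, n)) has g orbits of size n/g; a fixed
# subset is a union of orbits.
burnside_class_count <- function(n, k) {
  fixed <- vapply(0:(n - 1), function(r) {
    g <- if (r == 0) n else {
      a <- r; b <- n
      while (b != 0) { t <- b; b <- a %% b; a <- t }
      a
    }
    orbit <- n / g
    if (k %% orbit == 0) choose(g, k / orbit) else 0
  }, numeric(1))
  sum(fixed) / n
}

# Brute-force rotation oracle: all distinct rotations re-anchored at 0.
brute_modes <- function(steps, n) {
  k <- length(steps)
  out <- unique(lapply(seq_len(k), function(i) {
    sort((steps[c(i:k, seq_len(i - 1))] - steps[i]) %% n)
  }))
  out
}

# Expected set-level bias under a response model, integrating the logistic
# over the participant random-intercept distribution (independent oracle
# for the noiseless limit of the simulator + bias pipeline).
expected_set_bias <- function(model, features, melody_length = 12L) {
  X <- as.matrix(features[, paste0("ic", 1:6)])
  eta <- model$intercept + model$beta_evenness * features$evenness +
    drop(X %*% model$beta_ic) +
    model$beta_length * (melody_length - 8)
  u <- seq(-5, 5, length.out = 401) * max(model$sigma_u, 1e-9)
  w <- stats::dnorm(u, 0, max(model$sigma_u, 1e-9))
  w <- w / sum(w)
  pbar <- vapply(eta, function(e) sum(stats::plogis(e + u) * w), numeric(1))
  lapse_usable <- model$lapse / (1 - model$nodiff_rate)
  2 * (lapse_usable * 0.5 + (1 - lapse_usable) * pbar) - 1
}

python_available <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- nzchar(Sys.which("python")) &&
        suppressWarnings(system2("python", c("-c", shQuote("import sklearn")),
                                 stdout = FALSE, stderr = FALSE)) == 0
    }
    cache
  }
})
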