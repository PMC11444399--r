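# The statistical layer: hand-computed examples, textbook brute-force
# agreement, invariants, null calibrations, and the mixed-model contract.

test_that("paired_t matches hand computation and guards degeneracy", {
  r <- paired_t(c(1, 2, 3), c(2, 3, 5))
  expect_equal(r$statistic, -4)
  expect_equal(r$df, 2)
  expect_equal(r$effect, -4 / sqrt(3))   # -2.309...; d = t / sqrt(n)
  expect_equal(r$p, 2 * pt(-4, 2))
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)),
               class = "canicoh_degenerate_input")
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)),
               class = "canicoh_degenerate_input")
  expect_error(paired_t(1:2, 2:3), class = "canicoh_degenerate_input")
  expect_error(paired_t(1:3, 1:4), class = "canicoh_invalid_input")
})

test_that("paired_t is antisymmetric and agrees with brute force", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    x <- rnorm(n); y <- rnorm(n)
    a <- paired_t(x, y); b <- paired_t(y, x)
    expect_identical(a$statistic, -b$statistic)
    # textbook formula, written out
    d <- x - y
    t_bf <- mean(d) / sqrt(sum((d - mean(d))^2) / (n - 1) / n)
    expect_equal(a$statistic, t_bf, tolerance = 1e-10)
  }
})

test_that("mann_whitney: rank example, symmetry, U1 + U2 identity, and
          exhaustive-enumeration agreement", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 9)
  expect_equal(r$df, 4)
  expect_equal(r$effect, (4.5 / sqrt(5.25)) / sqrt(6), tolerance = 1e-12)
  # symmetric interleave of equal-size samples: U1 = U2 = n^2 / 2
  ri <- mann_whitney(c(1, 4, 5, 8), c(2, 3, 6, 7))
  expect_equal(ri$extra$U1, 8)
  expect_equal(ri$extra$U2, 8)
  set.seed(32)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
    m <- mann_whitney(x, y)
    expect_equal(m$extra$U1 + m$extra$U2, length(x) * length(y))
    # brute force: count pairs (x_i > y_j) + ties/2
    u1 <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(m$extra$U1, u1, tolerance = 1e-10)
  }
  expect_error(mann_whitney(c(1, 1), c(1, 1)),
               class = "canicoh_degenerate_input")
  expect_error(mann_whitney(1, c(1, 2)), class = "canicoh_invalid_input")
})

test_that("mann_whitney and paired_t achieve nominal type-I error", {
  set.seed(33)
  p_mwu <- replicate(4000, mann_whitney(rnorm(12), rnorm(12))$p)
  expect_lt(abs(mean(p_mwu < 0.05) - 0.05), 0.01)
  p_t <- replicate(4000, paired_t(rnorm(12), rnorm(12))$p)
  expect_lt(abs(mean(p_t < 0.05) - 0.05), 0.01)
})

test_that("kruskal_dunn: hand example, identical groups, Dunn output", {
  r <- kruskal_dunn(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(nrow(r$extra$dunn), 3)
  expect_true(all(r$extra$dunn$p_adj >= 0 & r$extra$dunn$p_adj <= 1))
  same <- kruskal_dunn(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_error(kruskal_dunn(list(1:3, 4:6)),
               class = "canicoh_invalid_input")
})

test_that("kruskal H is invariant under strictly monotone transforms and
          matches the tie-corrected textbook formula", {
  set.seed(34)
  for (i in 1:10) {
    g <- lapply(1:3, function(j) sample(1:8, 4, replace = TRUE))
    h1 <- kruskal_dunn(g)$statistic
    h2 <- kruskal_dunn(lapply(g, function(v) exp(v / 2)))$statistic
    expect_equal(h1, h2, tolerance = 1e-12)
    # textbook formula with tie correction, written out
    pooled <- unlist(g)
    N <- length(pooled)
    rk <- rank(pooled)
    idx <- rep(seq_along(g), lengths(g))
    H <- 12 / (N * (N + 1)) *
      sum(tapply(rk, idx, function(v) length(v) *
                   (mean(v) - (N + 1) / 2)^2))
    ties <- table(pooled)
    H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
    expect_equal(h1, H, tolerance = 1e-10)
  }
})

test_that("fit_lmm recovers a planted slope with honest intervals", {
  covered <- vapply(1:100, function(s) {
    set.seed(s)
    nsub <- 30
    d <- expand.grid(subject = factor(seq_len(nsub)), cond = 1:9)
    d$x <- rnorm(nrow(d))
    d$y <- 0.5 * d$x + rep(rnorm(nsub, 0, 0.5), 9) + rnorm(nrow(d))
    f <- fit_lmm(d, y ~ x, ~ 1 | subject)
    ci <- nlme::intervals(f$fit, which = "fixed")$fixed
    ci["x", "lower"] <= 0.5 && ci["x", "upper"] >= 0.5
  }, TRUE)
  expect_gte(sum(covered), 90)
})

test_that("fit_lmm F test holds its size under the null", {
  p <- vapply(1:300, function(s) {
    set.seed(1000 + s)
    nsub <- 12
    d <- expand.grid(subject = factor(seq_len(nsub)), cond = 1:6)
    d$x <- rnorm(nrow(d))
    d$y <- rep(rnorm(nsub, 0, 0.7), 6) + rnorm(nrow(d))
    fit_lmm(d, y ~ x, ~ 1 | subject)$terms$x$p
  }, 0)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("fit_lmm degenerates to ordinary regression with one group and
          reports Tukey contrasts for factors", {
  set.seed(35)
  d <- data.frame(subject = factor("s1"), x = rnorm(40))
  d$y <- 0.3 * d$x + rnorm(40)
  f <- fit_lmm(d, y ~ x, ~ 1 | subject)
  expect_equal(f$df_method, "classical")
  lm_f <- anova(lm(y ~ x, d))["x", "F value"]
  expect_equal(f$terms$x$statistic, lm_f, tolerance = 1e-12)
  # factor term with Tukey post hocs
  d2 <- expand.grid(subject = factor(1:10), g = c("a", "b", "c"))
  d2$y <- ifelse(d2$g == "c", 1, 0) + rep(rnorm(10, 0, 0.3), 3) +
    rnorm(30, 0, 0.4)
  f2 <- fit_lmm(d2, y ~ g, ~ 1 | subject, tukey_term = "g")
  expect_equal(f2$df_method, "containment")
  expect_equal(nrow(f2$tukey), 3)
  # c differs from a and b; a vs b does not
  pa <- f2$tukey$p_adj[f2$tukey$group1 == "a" & f2$tukey$group2 == "b"]
  pc <- f2$tukey$p_adj[f2$tukey$group2 == "c"]
  expect_gt(pa, 0.05)
  expect_true(all(pc < 0.05))
})

test_that("paired_register_tests reproduces the generator's stated world", {
  tab <- gen_paired_speech_table(12, seed = 42)
  res <- paired_register_tests(tab)
  # positive rate slowdown, negative F0 difference (ADS < DDS)
  expect_gt(res$rate$statistic, 0)
  expect_lt(res$f0$statistic, 0)
  expect_equal(res$rate$df, 11)
  # effect sizes land near the stated d = 0.8 / -0.6 world on average
  set.seed(43)
  dbar <- rowMeans(vapply(1:40, function(s) {
    r <- paired_register_tests(gen_paired_speech_table(12, seed = s))
    c(r$rate$effect, r$f0$effect)
  }, numeric(2)))
  expect_equal(dbar[1], 0.8, tolerance = 0.2)
  expect_equal(dbar[2], -0.6, tolerance = 0.2)
})
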