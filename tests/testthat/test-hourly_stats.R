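test_that("identical hourly groups give F = 0 and an empty matrix", {
  set.seed(3)
  day <- rnorm(10, 50, 5)
  f <- folded_from_matrix(matrix(rep(day, 24), 10, 24))  # same group 24 times
  a <- hourly_anova(f)
  expect_equal(a$F, 0, tolerance = 1e-12)
  expect_equal(a$df_between, 23)
  expect_equal(a$df_within, 24 * 10 - 24)
  sig <- tukey_kramer(f)
  expect_false(any(sig$greater))
  expect_true(all(sig$p_adjusted[upper.tri(sig$p_adjusted)] > 0.999))
})

test_that("degenerate all-constant input raises rather than returning NaN", {
  f <- folded_from_matrix(matrix(50, 5, 24))
  expect_error(hourly_anova(f), "degenerate variance")
  expect_error(tukey_kramer(f), "degenerate variance")
})

test_that("pairwise_tukey agrees with TukeyHSD on toy groups", {
  # 3 groups, means 0/0/5, SD 1 -> (3,1) and (3,2) significant, (1,2) not
  set.seed(4)
  values <- c(rnorm(5, 0), rnorm(5, 0), rnorm(5, 5))
  groups <- factor(rep(c("g1", "g2", "g3"), each = 5))
  sig <- pairwise_tukey(values, groups, alpha = 0.05)
  expect_true(sig$greater["g3", "g1"])
  expect_true(sig$greater["g3", "g2"])
  expect_false(sig$greater["g1", "g2"])
  expect_false(sig$greater["g2", "g1"])

  # adjusted p equal to the independent base-R studentized-range route
  hsd <- TukeyHSD(aov(values ~ groups))$groups
  expect_equal(sig$p_adjusted["g2", "g1"], hsd["g2-g1", "p adj"],
               tolerance = 1e-8)
  expect_equal(sig$p_adjusted["g3", "g1"], hsd["g3-g1", "p adj"],
               tolerance = 1e-8)
  expect_equal(sig$p_adjusted["g3", "g2"], hsd["g3-g2", "p adj"],
               tolerance = 1e-8)

  # Tukey-Kramer unequal-n form, same oracle
  set.seed(5)
  values <- c(rnorm(4, 0), rnorm(9, 1), rnorm(6, 3))
  groups <- factor(rep(c("a", "b", "c"), times = c(4, 9, 6)))
  sig <- pairwise_tukey(values, groups)
  hsd <- TukeyHSD(aov(values ~ groups))$groups
  for (pair in rownames(hsd)) {
    ij <- strsplit(pair, "-", fixed = TRUE)[[1]]
    expect_equal(sig$p_adjusted[ij[1], ij[2]], hsd[pair, "p adj"],
                 tolerance = 1e-8)
  }
})

test_that("a large hourly offset is detected, agreeing with a permutation oracle", {
  set.seed(6)
  m <- matrix(rnorm(31 * 24, 50, 2), 31, 24)
  m[, 3] <- m[, 3] + 20   # hour 2 offset by 10 SD
  f <- folded_from_matrix(m)
  a <- hourly_anova(f)
  expect_lt(a$p, 0.001)
  p_perm <- perm_anova_p(as.vector(m), rep(1:24, each = 31), 24,
                         reps = 2000, seed = 7)
  expect_lt(p_perm, 0.05)   # oracle agrees on significance
  sig <- tukey_kramer(f)
  expect_true(all(sig$greater["2", as.character(c(0:1, 3:23))]))
})

test_that("raising one hour's values never loses 'greater' verdicts", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- matrix(rnorm(12 * 24, 50, 5), 12, 24)
    before <- tukey_kramer(folded_from_matrix(m))
    m2 <- m
    m2[, 7] <- m2[, 7] + 4
    after <- tukey_kramer(folded_from_matrix(m2))
    expect_gte(sum(after$greater["6", ]), sum(before$greater["6", ]))
  }
})

test_that("significance-matrix structural invariants hold on random inputs", {
  for (seed in 1:25) {
    set.seed(seed)
    m <- matrix(rnorm(8 * 24, 50, 5), 8, 24)
    if (seed %% 3 == 0) m[, sample(24, 4)] <- m[, sample(24, 4)] + 8
    sig <- tukey_kramer(folded_from_matrix(m))
    expect_false(any(sig$greater & t(sig$greater)))        # antisymmetry
    expect_false(any(diag(sig$greater)))
    expect_equal(unname(diag(sig$p_adjusted)), rep(1, 24))
    expect_equal(sig$p_adjusted, t(sig$p_adjusted))
    expect_true(all(sig$p_adjusted >= 0 & sig$p_adjusted <= 1))
    expect_identical(unname(sig$n_by_hour), rep(8L, 24L))
  }
})

test_that("alpha outside (0, 0.5] is rejected", {
  f <- folded_from_matrix(matrix(rnorm(48), 2, 24))
  expect_error(tukey_kramer(f, alpha = 0), "alpha")
  expect_error(tukey_kramer(f, alpha = 0.6), "alpha")
})
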