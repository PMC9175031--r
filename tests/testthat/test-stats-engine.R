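# Small balanced-within / unbalanced-between toy data with known structure.
toy_long <- function(n1 = 6, n2 = 5, k = 3, effect = 0, seed = 1,
                     within_name = "condition") {
  set.seed(seed)
  subj <- sprintf("S%02d", seq_len(n1 + n2))
  grp <- rep(c("glaucoma", "control"), c(n1, n2))
  out <- expand.grid(
    participant_id = subj, level = paste0("L", seq_len(k)),
    stringsAsFactors = FALSE
  )
  out$group <- grp[match(out$participant_id, subj)]
  base <- rnorm(n1 + n2, sd = 1.5)[match(out$participant_id, subj)]
  out$y <- base + rnorm(nrow(out)) +
    effect * (out$group == "control") * as.integer(factor(out$level))
  names(out)[names(out) == "level"] <- within_name
  out
}

test_that("mixed ANOVA F values match the projection-matrix GLM oracle", {
  for (case in list(
    list(k = 2, effect = 0, seed = 1), list(k = 3, effect = 0, seed = 2),
    list(k = 4, effect = 0.8, seed = 3), list(k = 3, effect = 0.4, seed = 4)
  )) {
    d <- toy_long(k = case$k, effect = case$effect, seed = case$seed)
    fit <- mixed_anova(d, "y", "condition", "group", "participant_id")
    oracle <- glm_anova_oracle(d, "y", "condition", "group", "participant_id")
    tab <- tidy(fit)
    for (e in oracle$effect) {
      expect_equal(
        tab$f[tab$effect == e], oracle$f[oracle$effect == e],
        tolerance = 1e-8, label = sprintf("F(%s), k=%d", e, case$k)
      )
    }
  }
})

test_that("two within-factor designs also match the GLM oracle", {
  set.seed(9)
  d <- tidyr::expand_grid(
    participant_id = sprintf("S%02d", 1:9),
    condition = c("A", "B", "C"), percept = c("grouped", "ungrouped")
  )
  d$group <- rep(c("glaucoma", "control"), c(5, 4))[match(
    d$participant_id, sprintf("S%02d", 1:9)
  )]
  d$y <- rnorm(nrow(d)) + (d$percept == "grouped") * 0.5
  fit <- mixed_anova(d, "y", c("condition", "percept"), "group", "participant_id")
  oracle <- glm_anova_oracle(d, "y", c("condition", "percept"), "group", "participant_id")
  tab <- tidy(fit)
  for (e in oracle$effect) {
    matched <- tab$f[tab$effect == e]
    if (!length(matched)) { # interaction naming order may differ
      parts <- strsplit(e, ":", fixed = TRUE)[[1]]
      hit <- vapply(tab$effect, function(x) {
        setequal(strsplit(x, ":", fixed = TRUE)[[1]], parts)
      }, logical(1))
      matched <- tab$f[hit]
    }
    expect_equal(matched, oracle$f[oracle$effect == e], tolerance = 1e-8, label = e)
  }
})

test_that("mixed ANOVA rejects degenerate or incomplete designs", {
  d <- toy_long(k = 3)
  d$y <- 1
  expect_error(
    mixed_anova(d, "y", "condition", "group", "participant_id"),
    "singular"
  )
  d2 <- toy_long(k = 3)
  d2 <- d2[!(d2$participant_id == "S03" & d2$condition == "L2"), ]
  expect_error(
    mixed_anova(d2, "y", "condition", "group", "participant_id"),
    "S03/L2"
  )
  d3 <- toy_long(k = 2)
  d3 <- rbind(d3, d3[1, ])
  expect_error(
    mixed_anova(d3, "y", "condition", "group", "participant_id"),
    "duplicated"
  )
})

test_that("the age covariate adjusts only the between-subject test", {
  d <- toy_long(k = 2, seed = 5)
  ages <- stats::setNames(round(runif(11, 45, 75)), sprintf("S%02d", 1:11))
  d$age <- ages[d$participant_id]
  plain <- tidy(mixed_anova(d, "y", "condition", "group", "participant_id"))
  adj <- tidy(mixed_anova(d, "y", "condition", "group", "participant_id", covariate = "age"))
  # one denominator df is consumed by the covariate on the between test
  expect_equal(adj$df_den[adj$effect == "group"], plain$df_den[plain$effect == "group"] - 1)
  expect_true("age" %in% adj$effect)
  # within-subject rows are reported from the unadjusted model
  expect_equal(
    adj$f[adj$effect == "condition"],
    plain$f[plain$effect == "condition"]
  )
  # group sizes 17/14 give the pooled t df of 29 and ANCOVA den df of 28
  sim <- toy_long(n1 = 17, n2 = 14, k = 2, seed = 6)
  sim$age <- round(runif(31, 45, 75))[match(sim$participant_id, unique(sim$participant_id))]
  fit <- tidy(mixed_anova(sim, "y", "condition", "group", "participant_id", covariate = "age"))
  expect_equal(fit$df_den[fit$effect == "group"], 28)
})

test_that("Greenhouse-Geisser epsilon matches the classic formula and bounds", {
  expect_equal(gg_epsilon(matrix(rnorm(20), ncol = 2)), 1)
  cs <- 0.4 * diag(4) + 0.6 # compound symmetry
  expect_equal(gg_epsilon(cs), 1)
  set.seed(33)
  for (i in 1:50) {
    k <- sample(3:6, 1)
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A) + diag(k) * 0.1
    eps <- gg_epsilon(S)
    expect_equal(eps, gg_epsilon_oracle(S), tolerance = 1e-10)
    expect_gte(eps, 1 / (k - 1) - 1e-12)
    expect_lte(eps, 1 + 1e-12)
  }
  expect_error(gg_epsilon(matrix(1, 1, 5)), "at least 2 participants")
  expect_error(gg_epsilon(matrix(0, 3, 3)), "degenerate")
})

test_that("epsilon reported by the ANOVA equals the contrast-space estimate", {
  d <- toy_long(k = 4, seed = 8)
  fit <- mixed_anova(d, "y", "condition", "group", "participant_id")
  tab <- tidy(fit)
  # pooled within-group covariance of the cell scores
  wide <- tidyr::pivot_wider(d, names_from = "condition", values_from = "y")
  Y <- as.matrix(wide[, paste0("L", 1:4)])
  grp <- wide$group
  centred <- do.call(rbind, lapply(unique(grp), function(g) {
    scale(Y[grp == g, ], scale = FALSE)
  }))
  S <- crossprod(centred) / (nrow(Y) - 2)
  eps <- gg_epsilon(S, contrasts = orthonormal_contrasts(4))
  expect_equal(tab$gg_epsilon[tab$effect == "condition"], eps, tolerance = 1e-8)
  # corrected p uses epsilon-scaled dfs
  row <- tab[tab$effect == "condition", ]
  expect_equal(
    row$p_gg,
    pf(row$f, row$gg_epsilon * row$df_num, row$gg_epsilon * row$df_den, lower.tail = FALSE)
  )
})

test_that("partial eta-squared reproduces its defining identity", {
  expect_equal(round(partial_eta_squared(232, 1.7, 48.2), 2), 0.89)
  expect_equal(round(partial_eta_squared(18.7, 1, 29), 2), 0.39)
  expect_equal(partial_eta_squared(0, 3, 10), 0)
  expect_error(partial_eta_squared(-1, 1, 10), ">= 0")
  # identity on every ANOVA row, raw and GG dfs alike
  d <- toy_long(k = 4, effect = 0.6, seed = 12)
  tab <- tidy(mixed_anova(d, "y", "condition", "group", "participant_id"))
  expect_equal(tab$pes, tab$f * tab$df_num / (tab$f * tab$df_num + tab$df_den),
    tolerance = 1e-9
  )
  within <- !is.na(tab$gg_epsilon)
  expect_equal(
    tab$pes[within],
    tab$f[within] * tab$df_num_gg[within] /
      (tab$f[within] * tab$df_num_gg[within] + tab$df_den_gg[within]),
    tolerance = 1e-9
  )
})

test_that("Cohen's d from t equals the direct pooled-SD formula", {
  expect_equal(round(cohens_d_from_t(2.55, 17, 14), 2), 0.92)
  expect_equal(cohens_d_from_t(0, 10, 12), 0)
  expect_error(cohens_d_from_t(1, 1, 5), ">= 2")
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(sample(5:20, 1), mean = runif(1, -1, 1))
    y <- rnorm(sample(5:20, 1))
    res <- independent_t(x, y)
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2))
    expect_equal(res$d, (mean(x) - mean(y)) / sp, tolerance = 1e-10)
    expect_equal(res$d, cohens_d_from_t(res$t, length(x), length(y)), tolerance = 1e-12)
  }
})

test_that("t-tests follow the classical pooled and paired forms", {
  # hand-worked 3-point toy: x = (1,2,3), y = (2,3,4)
  res <- independent_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  x <- rnorm(17)
  y <- rnorm(14)
  expect_equal(independent_t(x, y)$df, 29)
  expect_error(independent_t(rep(1, 5), rep(1, 6)), "pooled variance")

  pres <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(pres$df, 2)
  expect_equal(pres$mean_diff, 2)
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "zero variance")
  expect_error(paired_t(1:4, 1:3), "equal length")
})

test_that("Mann-Whitney U matches pair counting and exact enumeration", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$u, 0)
  # identical multisets: all rank mass symmetric, U = n^2/2
  for (n in c(2, 4, 6)) {
    x <- seq_len(n)
    expect_equal(mann_whitney_u(x, x)$u, n^2 / 2)
  }
  set.seed(14)
  for (i in 1:25) {
    n1 <- sample(3:7, 1)
    n2 <- sample(3:7, 1)
    x <- round(rnorm(n1), 2)
    y <- round(rnorm(n2, mean = runif(1, -1, 1)), 2)
    res <- mann_whitney_u(x, y)
    oracle <- mwu_oracle(x, y)
    expect_equal(res$u, oracle$u, label = sprintf("U rep %d", i))
    if (res$method == "exact") {
      expect_equal(res$p, oracle$p, tolerance = 1e-12, label = sprintf("p rep %d", i))
    }
  }
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("pairwise comparisons apply the familywise correction", {
  d <- toy_long(k = 4, effect = 1, seed = 10)
  bon <- pairwise_comparisons(d, "y", "condition", "participant_id", method = "bonferroni")
  expect_equal(nrow(bon), 6L)
  expect_equal(bon$p_adj, pmin(1, bon$p * 6))
  expect_true(all(bon$p_adj >= bon$p))
  expect_true(all(bon$p_adj <= 1))
  lsd <- pairwise_comparisons(d, "y", "condition", "participant_id", method = "lsd")
  expect_equal(lsd$p_adj, lsd$p)
})

test_that("Pearson correlation matches the direct covariance formula", {
  x <- c(1, 2, 4, 6, 9)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -2 * x + 5)$r, -1)
  set.seed(20)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(length(a)) + 0.3 * a
    r <- pearson_r(a, b)$r
    expect_equal(
      r,
      sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)),
      tolerance = 1e-12
    )
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("a null group effect rejects at the nominal rate", {
  set.seed(91)
  n_rep <- 300
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    d <- toy_long(n1 = 17, n2 = 14, k = 2, effect = 0, seed = 91000 + r)
    tab <- tidy(mixed_anova(d, "y", "condition", "group", "participant_id"))
    rej[r] <- tab$p[tab$effect == "group"] < 0.05
  }
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
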