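test_that("a perfectly separable predictor reaches AUC 1 under a weak penalty", {
  y <- rep(c(1, 0), each = 30)
  x <- cbind(matrix(y, ncol = 1), rbinom(60, 1, 0.5))
  dm <- make_dm(x, y)
  grid <- cv_tune(dm, tuning_config(mixing_grid = 0.5, n_folds = 15,
                                    n_repeats = 1,
                                    strength_grid = c(0.01, 0.001), seed = 1))
  expect_equal(grid$mean_cv_auc[grid$strength == 0.001], 1.0)
})

test_that("an outcome independent of all columns gives null AUC", {
  set.seed(101)
  n <- 2000
  x <- matrix(rbinom(n * 5, 1, 0.4), n, 5)
  y <- rbinom(n, 1, 0.5)
  dm <- make_dm(x, y)
  grid <- cv_tune(dm, tuning_config(mixing_grid = c(0.5, 1), n_folds = 15,
                                    n_repeats = 1,
                                    strength_grid = c(0.05, 0.005), seed = 2))
  expect_true(all(abs(grid$mean_cv_auc - 0.5) < 0.05))
})

test_that("an overwhelming penalty shrinks every coefficient away", {
  set.seed(7)
  y <- rbinom(100, 1, 0.5)
  x <- matrix(rbinom(300, 1, 0.5), 100, 3)
  dm <- make_dm(x, y)
  grid <- cv_tune(dm, tuning_config(mixing_grid = c(0.3, 1), n_folds = 15,
                                    n_repeats = 1,
                                    strength_grid = c(1e6, 1), seed = 3))
  expect_true(all(grid$n_nonzero_at_full_fit[grid$strength == 1e6] == 0))
  fit <- fit_final(dm, 1.0, 1e6)
  expect_equal(fit$n_nonzero, 0)
})

test_that("the elbow rule prefers the sparsest strength within one SE", {
  # flat AUC: pure sparsity preference
  flat <- data.frame(strength = c(1, 2, 4), mean_cv_auc = 0.8,
                     se_cv_auc = 0.01)
  expect_equal(select_strength(flat), 4)
  # hand-applied rule: threshold 0.80 - 0.02 admits 0.79 but not 0.70
  rows <- data.frame(strength = c(1, 2, 4),
                     mean_cv_auc = c(0.80, 0.79, 0.70),
                     se_cv_auc = c(0.02, 0.02, 0.02))
  expect_equal(select_strength(rows), 2)
  single <- data.frame(strength = 3, mean_cv_auc = 0.7, se_cv_auc = 0.01)
  expect_equal(select_strength(single), 3)
  expect_error(select_strength(rows[0, ]), "at least one")
})

test_that("a null-association design fits intercept-only", {
  set.seed(61)
  y <- rep(c(1, 1, 1, 0), 25)  # prevalence 0.75
  x <- matrix(rbinom(200, 1, 0.5), 100, 2)  # no configured association
  dm <- make_dm(x, y)
  fit <- fit_final(dm, 0.5, 0.5)
  expect_equal(fit$n_nonzero, 0)
  expect_equal(fit$intercept, qlogis(0.75), tolerance = 1e-3)
  expect_equal(fit$aic, 2 * 1 - 2 * fit$log_likelihood)
})

test_that("the penalized estimate lies between zero and the unpenalized MLE", {
  cfg <- cohort_config(
    2000,
    outcome_model = list(intercept = 0, effects = list(sdu_6m = c(yes = 1.0))),
    former_user_rate = 0, unspecified_prep_rate = 0, seed = 23
  )
  rec <- generate_cohort(cfg)
  x <- matrix(as.numeric(rec$sdu_6m == "yes"), ncol = 1)
  y <- as.numeric(rec$prep_status == "current")
  dm <- make_dm(x, y)
  mle <- unname(coef(glm(y ~ x, family = binomial))[2])
  fit <- fit_final(dm, 0.5, 0.01)
  b <- unname(fit$beta[1])
  expect_gt(b, 0.5)
  expect_lte(b, mle + 1e-8)
  expect_gte(b, 0)
})

test_that("model choice is lexicographic in sparsity then AIC then mixing", {
  fake <- function(nnz, aic, mixing) {
    structure(list(mixing = mixing, strength = 1, intercept = 0,
                   beta = numeric(0), n_nonzero = nnz,
                   log_likelihood = -aic / 2, aic = aic),
              class = "enet_fit")
  }
  a <- fake(5, 100, 0.5); b <- fake(3, 120, 0.3)
  expect_equal(choose_model(list(a, b))$n_nonzero, 3)
  c2 <- fake(3, 110, 0.2)
  expect_equal(choose_model(list(b, c2))$aic, 110)
  d <- fake(3, 110, 0.9)
  expect_equal(choose_model(list(c2, d))$mixing, 0.9)
  expect_equal(choose_model(list(a))$n_nonzero, 5)
  expect_error(choose_model(list()), "no candidate")
})

test_that("sparsity is non-increasing in strength along the full path", {
  set.seed(31)
  n <- 400
  x <- matrix(rbinom(n * 8, 1, 0.4), n, 8)
  y <- rbinom(n, 1, plogis(x[, 1] - x[, 2]))
  dm <- make_dm(x, y)
  grid <- cv_tune(dm, tuning_config(mixing_grid = c(0.2, 1), n_folds = 15,
                                    n_repeats = 1, seed = 4))
  for (m in unique(grid$mixing)) {
    rows <- grid[grid$mixing == m, ]
    rows <- rows[order(-rows$strength), ]
    expect_true(all(diff(rows$n_nonzero_at_full_fit) >= 0),
                label = sprintf("monotone support at mixing %.1f", m))
  }
})

test_that("tuning is deterministic under a fixed seed", {
  set.seed(41)
  x <- matrix(rbinom(600, 1, 0.5), 200, 3)
  y <- rbinom(200, 1, plogis(x[, 1]))
  dm <- make_dm(x, y)
  cfg <- tuning_config(mixing_grid = c(0.4, 0.8), n_folds = 15,
                       n_repeats = 2, seed = 99)
  g1 <- cv_tune(dm, cfg)
  g2 <- cv_tune(dm, cfg)
  expect_identical(g1, g2)
})

test_that("a single-class outcome is a stratification error", {
  dm <- make_dm(matrix(rbinom(40, 1, 0.5), 20, 2), rep(1, 20))
  expect_error(cv_tune(dm), "stratification")
  dm2 <- make_dm(matrix(rbinom(40, 1, 0.5), 20, 2), rep(c(0, 1), 10))
  expect_error(cv_tune(dm2, tuning_config(n_folds = 15)), "stratification")
})

test_that("the rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  scores <- rnorm(200)
  y <- rbinom(200, 1, plogis(scores))
  ours <- prepbarriers:::auc_rank(scores, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})
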