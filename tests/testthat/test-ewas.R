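# Small three-arm study used across the EWAS tests.
ewas_fixture <- function(seed = 70, n_probes = 500, n_age = 60,
                         planted_rejuvenation = 60, noise_sd = 0.03) {
  base <- methyl_sim_config(n_probes = n_probes, n_age_probes = n_age,
                            tissues = c(blood = 18), noise_sd = noise_sd,
                            seed = seed)
  simulate_treatment_study(treatment_sim_config(
    base = base, n_per_group = 6, planted_rejuvenation = planted_rejuvenation,
    seed = seed + 1))
}

test_that("empirical control probes avoid the planted age probes deterministically", {
  study <- ewas_fixture(seed = 71)
  controls <- select_control_probes(study$beta, study$annotation,
                                    n_controls = 100)
  expect_length(controls, 100)
  expect_gte(mean(!controls %in% study$truth$age_probes$probe_id), 0.95)
  # deterministic across repeated calls and sample order
  expect_identical(controls,
                   select_control_probes(study$beta, study$annotation, 100))
  # boundary: all but the single most associated probe
  all_but_one <- select_control_probes(study$beta, study$annotation,
                                       nrow(study$beta) - 1)
  expect_length(all_but_one, nrow(study$beta) - 1)
  expect_error(select_control_probes(study$beta, study$annotation,
                                     nrow(study$beta)), "below the total")
})

test_that("RUV factors are orthonormal and recover a planted batch shift", {
  study <- ewas_fixture(seed = 72)
  controls <- select_control_probes(study$beta, study$annotation, 150)
  ruv <- estimate_ruv_factors(study$beta, controls, k = 2)
  expect_equal(crossprod(unclass(ruv)), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)

  # k = 0 gives an empty factor set and an unchanged design
  ruv0 <- estimate_ruv_factors(study$beta, controls, k = 0)
  expect_equal(ncol(ruv0), 0)
  d0 <- ewas_design(study$annotation)
  d0b <- ewas_design(study$annotation, ruv = NULL)
  expect_identical(colnames(d0), colnames(d0b))

  # plant a strong batch shift on the control probes of half the samples
  m <- study$beta
  batch <- rep(c(0, 1), length.out = ncol(m))
  m[controls, batch == 1] <- clip01(m[controls, batch == 1] + 0.15)
  f1 <- estimate_ruv_factors(m, controls, k = 1)
  expect_gt(abs(cor(unclass(f1)[, 1], batch)), 0.9)
})

test_that("per-probe least squares matches hand-solved normal equations", {
  # 4-sample toy: design with intercept and one covariate
  X <- cbind(intercept = 1, x = c(0, 1, 2, 3))
  y1 <- c(0.1, 0.3, 0.5, 0.7)          # exact fit: slope 0.2
  y2 <- c(0.2, 0.1, 0.4, 0.3)
  beta <- rbind(p1 = y1, p2 = y2)
  colnames(beta) <- paste0("s", 1:4)
  fit <- fit_probe_models(beta, X)
  bhat <- solve(t(X) %*% X) %*% t(X) %*% y2
  expect_equal(unname(fit$coefficients["p2", ]), unname(drop(bhat)),
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["p1", "x"]), 0.2, tolerance = 1e-12)
  expect_equal(fit$s2[[1]], 0, tolerance = 1e-20)
  r2 <- y2 - X %*% bhat
  expect_equal(fit$s2[[2]], sum(r2^2) / 2, tolerance = 1e-12)
  expect_equal(fit$df, 2)

  # a probe identical to a design column gets coefficient 1 on it
  X2 <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  beta2 <- rbind(p1 = c(1, 1, 0, 0))
  colnames(beta2) <- paste0("s", 1:4)
  fit2 <- fit_probe_models(beta2, X2)
  expect_equal(unname(fit2$coefficients["p1", ]), c(1, 0), tolerance = 1e-12)

  # rank-deficient designs are refused with the aliased column named
  X3 <- cbind(a = c(1, 1, 1, 1), b = c(2, 2, 2, 2))
  expect_error(fit_probe_models(beta2, X3), "aliased")
})

test_that("null z-scores are calibrated", {
  set.seed(73)
  n <- 20
  X <- cbind(intercept = 1, x = rnorm(n))
  beta <- matrix(rnorm(2000 * n, 0.5, 0.05), nrow = 2000,
                 dimnames = list(sprintf("p%04d", 1:2000), paste0("s", 1:n)))
  fit <- fit_probe_models(beta, X)
  res <- apply_contrast(fit, c(x = 1), moderated = FALSE)
  # ordinary t under the null: p-values uniform
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.02)
})

test_that("empirical-Bayes moderation recovers planted hyperparameters and limits", {
  # identical residual variances: no excess dispersion, infinite prior df,
  # every probe shrunk fully to the common prior variance (the chi-square
  # log-bias correction makes the prior exp(log(d/2) - digamma(d/2)) times
  # the observed value, exactly as the moderated-t estimator defines it)
  fit <- structure(list(coefficients = matrix(0, 5, 1), s2 = rep(0.02, 5),
                        df = 10, xtx_inv = matrix(1), design = matrix(1, 11, 1),
                        probe_ids = paste0("p", 1:5)),
                   class = "ewas_fit")
  mod <- ebayes_moderate(fit)
  expect_true(is.infinite(mod$d0))
  expect_equal(mod$s2_tilde,
               rep(0.02 * exp(log(5) - digamma(5)), 5), tolerance = 1e-9)
  expect_equal(diff(range(mod$s2_tilde)), 0)

  # scaled-inverse-chi-square prior: recover (d0, s0^2) within 10%
  d0 <- 8; s0_2 <- 0.04; d <- 6
  set.seed(74)
  sigma2 <- d0 * s0_2 / rchisq(10000, df = d0)
  s2 <- sigma2 * rchisq(10000, df = d) / d
  fit2 <- structure(list(coefficients = matrix(0, 10000, 1), s2 = s2, df = d,
                         xtx_inv = matrix(1), design = matrix(1, d + 1, 1),
                         probe_ids = sprintf("p%05d", 1:10000)),
                    class = "ewas_fit")
  mod2 <- ebayes_moderate(fit2)
  expect_lt(abs(mod2$d0 - d0) / d0, 0.10)
  expect_lt(abs(mod2$s0_2 - s0_2) / s0_2, 0.10)
  expect_equal(mod2$s2_tilde, (mod2$d0 * mod2$s0_2 + d * s2) / (mod2$d0 + d),
               tolerance = 1e-12)

  # d0 -> 0: moderated t collapses to the ordinary t
  forced <- mod2
  forced$d0 <- 0
  forced$s2_tilde <- forced$s2
  set.seed(75)
  forced$coefficients <- matrix(rnorm(10000), ncol = 1,
                                dimnames = list(NULL, "x"))
  colnames(forced$design) <- "x"
  dimnames(forced$xtx_inv) <- list("x", "x")
  t_mod <- apply_contrast(forced, c(x = 1))$t
  t_ord <- apply_contrast(forced, c(x = 1), moderated = FALSE)$t
  expect_equal(t_mod, t_ord, tolerance = 1e-12)

  # d0 -> Inf: every probe shares the pooled prior variance (z-like)
  pooled <- mod2
  pooled$d0 <- Inf
  pooled$s2_tilde <- rep(pooled$s0_2, length(pooled$s2))
  pooled$coefficients <- forced$coefficients
  colnames(pooled$design) <- "x"
  dimnames(pooled$xtx_inv) <- list("x", "x")
  t_inf <- apply_contrast(pooled, c(x = 1))$t
  expect_equal(t_inf, drop(forced$coefficients) / sqrt(pooled$s0_2),
               tolerance = 1e-12)
})

test_that("moderation agrees with an independent moderated-t implementation", {
  skip_if_not_installed("limma")
  study <- ewas_fixture(seed = 76, n_probes = 300, n_age = 40)
  design <- ewas_design(study$annotation)
  fit <- ebayes_moderate(fit_probe_models(study$beta, design))
  lfit <- limma::eBayes(limma::lmFit(study$beta, design))
  expect_equal(fit$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$s0_2, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(unname(fit$s2_tilde), unname(lfit$s2.post), tolerance = 1e-8)
  cm <- limma::makeContrasts(
    contrasts = "group_old_control - group_young_control", levels = design)
  lc <- limma::eBayes(limma::contrasts.fit(limma::lmFit(study$beta, design), cm))
  mine <- apply_contrast(fit, c(group_old_control = 1, group_young_control = -1))
  expect_equal(mine$t, unname(lc$t[, 1]), tolerance = 1e-8)
  expect_equal(mine$p, unname(lc$p.value[, 1]), tolerance = 1e-8)
})

test_that("contrasts match hand computation and find planted age effects", {
  study <- ewas_fixture(seed = 77)
  res <- run_ewas(study$beta, study$annotation, k = 2, n_controls = 100)
  truth <- study$truth$age_probes$probe_id
  sens <- mean(truth %in% res$age$probe_id[res$age$significant])
  expect_gt(sens, 0.8)

  # self-contrast is identically zero
  fit <- res$fit
  zero <- apply_contrast(fit, c(group_old_control = 1, group_old_control = -1))
  expect_true(all(zero$estimate == 0))
  expect_error(apply_contrast(fit, c(nonexistent = 1)), "not in design")

  # single-probe hand oracle: c' beta_hat and its standard error
  cvec <- setNames(numeric(ncol(fit$design)), colnames(fit$design))
  cvec["group_old_control"] <- 1; cvec["group_young_control"] <- -1
  est_hand <- drop(fit$coefficients %*% cvec)
  se_hand <- sqrt(fit$s2_tilde * drop(t(cvec) %*% fit$xtx_inv %*% cvec))
  mine <- apply_contrast(fit, c(group_old_control = 1,
                                group_young_control = -1))
  expect_equal(mine$estimate, unname(est_hand), tolerance = 1e-12)
  expect_equal(mine$t, unname(est_hand / se_hand), tolerance = 1e-12)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  set.seed(78)
  p <- runif(200)^2
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  oracle <- numeric(m); oracle[o] <- pmin(q_sorted, 1)
  expect_equal(bh_adjust(p), oracle, tolerance = 1e-12)
  # order invariance
  perm <- sample(m)
  expect_equal(bh_adjust(p[perm]), oracle[perm], tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("reversal summary: mirror gives 1, noise gives ~0.5, planted rejuvenation > 0.9", {
  mk <- function(est, q) tibble::tibble(
    probe_id = sprintf("p%04d", seq_along(est)), contrast = "x",
    estimate = est, t = est, p = q, q = q, significant = q < 0.05)
  set.seed(79)
  est <- rnorm(300)
  age <- mk(est, rep(0.01, 300))
  expect_equal(reversal_summary(age, mk(-est, rep(0.5, 300)))$reversal_proportion, 1.0)
  noise <- mk(rnorm(300), rep(0.5, 300))
  expect_lt(abs(reversal_summary(age, noise)$reversal_proportion - 0.5), 0.1)
  empty <- reversal_summary(mk(est, rep(0.9, 300)), noise)
  expect_equal(empty$n_age_significant, 0L)

  study <- ewas_fixture(seed = 80, planted_rejuvenation = 50)
  res <- run_ewas(study$beta, study$annotation, k = 2, n_controls = 100)
  truth <- study$truth$age_probes$probe_id
  sig_true <- res$age$significant & res$age$probe_id %in% truth
  age_t <- res$age[sig_true, ]
  elix_t <- res$elixir[res$elixir$probe_id %in% age_t$probe_id, ]
  rev_true <- reversal_summary(
    dplyr::mutate(age_t, q = 0.01), dplyr::mutate(elix_t, q = 0.5))
  expect_gt(rev_true$reversal_proportion, 0.9)
})

test_that("the global-null EWAS controls the false discovery rate", {
  set.seed(81)
  fdps <- vapply(1:200, function(r) {
    n <- 18
    X <- cbind(g1 = rep(c(1, 0), c(9, 9)), g2 = rep(c(0, 1), c(9, 9)))
    beta <- matrix(rnorm(200 * n, 0.5, 0.04), nrow = 200,
                   dimnames = list(sprintf("p%03d", 1:200), paste0("s", 1:n)))
    fit <- ebayes_moderate(fit_probe_models(beta, X))
    res <- apply_contrast(fit, c(g1 = 1, g2 = -1))
    disc <- sum(res$significant)
    if (disc == 0) 0 else disc / disc  # all discoveries are false under the null
  }, numeric(1))
  expect_lte(mean(fdps), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("RUV factors recover power lost to a planted batch effect", {
  wins <- vapply(1:6, function(s) {
    base <- methyl_sim_config(n_probes = 300, n_age_probes = 40,
                              tissues = c(blood = 18), batch_effect_sd = 0.4,
                              n_batches = 2, seed = 90 + s)
    study <- simulate_treatment_study(treatment_sim_config(
      base = base, n_per_group = 6, planted_rejuvenation = 50, seed = 190 + s))
    truth <- study$truth$age_probes$probe_id
    # omit the plate covariate so the batch signal is unmodelled unless RUV absorbs it
    ann <- dplyr::mutate(study$annotation, batch_plate = "unknown",
                         batch_column = "unknown")
    power_k <- function(k) {
      res <- run_ewas(study$beta, ann, k = k, n_controls = 100)
      mean(truth %in% res$age$probe_id[res$age$significant])
    }
    power_k(2) - power_k(0)
  }, numeric(1))
  expect_gt(mean(wins), 0)
})
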