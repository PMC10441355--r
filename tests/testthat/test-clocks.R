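test_that("relative age uses the configured lifespan constants", {
  expect_equal(relative_age(1.9, "rat"), 0.5)
  expect_equal(relative_age(122.5, "human"), 1.0)
  expect_equal(relative_age(0, "rat"), 0.0)
  expect_warning(relative_age(4.0, "rat"), "above 1")
  expect_error(relative_age(1, "pig"), "no maximum lifespan")
  expect_error(relative_age(-1, "rat"), "non-negative")
})

test_that("a single noiseless age probe is found and predicts near-perfectly", {
  # probe 1 equals age/lifespan exactly; all others pure noise
  set.seed(40)
  n <- 60
  ages <- runif(n, 0.1, 3.4)
  m <- matrix(runif(100 * n), nrow = 100,
              dimnames = list(sprintf("cg%05d", 1:100),
                              sprintf("s%03d", 1:n)))
  m[1, ] <- ages / 3.8
  ann <- annotation_for(m, ages = ages)
  clock <- fit_clock(m, ann, age_transform("relative"), seed = 2)
  pred <- predict_age(clock, m, ann)
  expect_gt(pearson_r(pred$dnam_age, ages), 0.999)
  # single-covariate least-squares oracle on the informative probe
  oracle <- fitted(lm(ages ~ m[1, ]))
  expect_gt(pearson_r(pred$dnam_age, oracle), 0.999)
  expect_true("cg00001" %in% names(clock$weights))
})

test_that("constant training ages give a degenerate zero-weight clock", {
  m <- random_beta(10, 5)
  ann <- annotation_for(m, ages = rep(1.2, 5))
  clock <- fit_clock(m, ann, seed = 1)
  expect_length(clock$weights, 0)
  expect_equal(clock$intercept, 1.2)
  pred <- predict_age(clock, m, ann)
  expect_equal(pred$dnam_age, rep(1.2, 5))
})

test_that("most selected clock probes are planted age probes on the default panel", {
  sim <- simulate_methylomes(methyl_sim_config(seed = 1))
  clock <- fit_clock(sim$beta, sim$annotation, seed = 1)
  sel <- names(clock$weights)
  expect_gt(length(sel), 0)
  expect_gte(mean(sel %in% sim$truth$age_probes$probe_id), 0.80)
})

test_that("predict_age is the linear score, back-transformed per species", {
  # zero-weight clock: every sample gets the inverse-transformed intercept
  tr <- age_transform("relative")
  clock <- structure(list(weights = setNames(numeric(0), character(0)),
                          intercept = 0.5, transform = tr, lambda = NA_real_,
                          training_meta = list(), probe_universe = character(0)),
                     class = "clock_model")
  m <- random_beta(5, 3)
  ann <- annotation_for(m)
  pred <- predict_age(clock, m, ann)
  expect_equal(pred$dnam_age, rep(0.5 * 3.8, 3))  # rat: score 0.5 -> 1.9 y

  # explicit dot-product oracle on a held-out batch
  sim <- simulate_methylomes(small_panel_config(seed = 18))
  clock2 <- fit_clock(sim$beta, sim$annotation, seed = 3)
  held <- simulate_methylomes(small_panel_config(seed = 18), sample_seed = 77)
  pred2 <- predict_age(clock2, held$beta, held$annotation)
  oracle <- vapply(seq_len(ncol(held$beta)), function(j) {
    s <- clock2$intercept
    for (p in names(clock2$weights)) s <- s + clock2$weights[[p]] * held$beta[p, j]
    s
  }, numeric(1))
  expect_equal(pred2$dnam_age, oracle, tolerance = 1e-12)
  expect_equal(pred2$age_acceleration, pred2$dnam_age - pred2$age)

  # missing clock probes are listed
  expect_error(predict_age(clock2, held$beta[-match(names(clock2$weights)[1],
                                                    rownames(held$beta)), , drop = FALSE],
                           held$annotation),
               names(clock2$weights)[1])
})

test_that("prediction is linear on the transformed scale", {
  sim <- simulate_methylomes(small_panel_config(seed = 19, n = 20))
  clock <- fit_clock(sim$beta, sim$annotation, seed = 4)
  a <- simulate_methylomes(small_panel_config(seed = 19), sample_seed = 1)$beta[, 1:5]
  b <- simulate_methylomes(small_panel_config(seed = 19), sample_seed = 2)$beta[, 1:5]
  colnames(b) <- colnames(a)
  ann <- annotation_for(a)
  avg <- (a + b) / 2
  p_avg <- predict_age(clock, avg, ann)$dnam_age
  p_mean <- (predict_age(clock, a, ann)$dnam_age +
               predict_age(clock, b, ann)$dnam_age) / 2
  expect_equal(p_avg, p_mean, tolerance = 1e-12)
})

test_that("LOOCV bookkeeping: each sample predicted once by a model not trained on it", {
  sim <- simulate_methylomes(small_panel_config(seed = 20, n = 10,
                                                n_probes = 60,
                                                n_age_probes = 15))
  cv <- cross_validate_clock(sim$beta, sim$annotation, scheme = "loocv",
                             seed = 6)
  expect_equal(nrow(cv$predictions), 10L)
  expect_equal(sort(unique(cv$predictions$fold)), 1:10)
  expect_setequal(cv$predictions$sample_id, colnames(sim$beta))
})

test_that("LOOCV equals manually assembled hold-out fits", {
  sim <- simulate_methylomes(small_panel_config(seed = 21, n = 4,
                                                n_probes = 40,
                                                n_age_probes = 10))
  cv <- cross_validate_clock(sim$beta, sim$annotation, scheme = "loocv",
                             seed = 2)
  manual <- vapply(1:4, function(i) {
    clock_i <- fit_clock(sim$beta[, -i, drop = FALSE], sim$annotation[-i, ],
                         seed = 2 + i)
    predict_age(clock_i, sim$beta[, i, drop = FALSE],
                sim$annotation[i, ])$dnam_age
  }, numeric(1))
  expect_equal(cv$predictions$dnam_age, manual, tolerance = 1e-12)
})

test_that("k-fold folds partition the samples and reject invalid k", {
  sim <- simulate_methylomes(small_panel_config(seed = 22, n = 12,
                                                n_probes = 40,
                                                n_age_probes = 10))
  cv <- cross_validate_clock(sim$beta, sim$annotation, scheme = 4, seed = 1)
  expect_equal(sort(table(cv$predictions$fold)), sort(table(rep(1:4, 3))),
               ignore_attr = TRUE)
  expect_error(cross_validate_clock(sim$beta, sim$annotation, scheme = 13),
               "2 <= k <= n")
})

test_that("clock save/load round-trips predictions exactly", {
  sim <- simulate_methylomes(small_panel_config(seed = 23, n = 15))
  clock <- fit_clock(sim$beta, sim$annotation, age_transform("relative"),
                     seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  save_clock(clock, path)
  back <- load_clock(path)
  p1 <- predict_age(clock, sim$beta, sim$annotation)
  p2 <- predict_age(back, sim$beta, sim$annotation)
  expect_identical(p1$dnam_age, p2$dnam_age)
  expect_equal(back$transform$kind, "relative")
  expect_equal(back$transform$max_lifespan[["rat"]], 3.8)

  # corrupting the transform kind is rejected
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  meta$transform$kind <- "loglinear"
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  expect_error(load_clock(path), "unknown transform kind")
})

test_that("a hand-written coefficient file predicts by hand arithmetic", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("term,weight", "(Intercept),0.4", "cgA,2", "cgB,-1"), path)
  jsonlite::write_json(
    list(format_version = 1, transform = list(kind = "identity",
                                              max_lifespan = list(rat = 3.8)),
         lambda = 0.1, training_meta = list(alpha = 0.5)),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  clock <- load_clock(path)
  m <- matrix(c(0.25, 0.5), nrow = 2, dimnames = list(c("cgA", "cgB"), "s1"))
  ann <- annotation_for(m, ages = 1)
  # 0.4 + 2*0.25 - 1*0.5 = 0.4
  expect_equal(predict_age(clock, m, ann)$dnam_age, 0.4)
})

test_that("relative-age training handles both species where identity training skews the short-lived one", {
  cfg_rat <- methyl_sim_config(n_probes = 800, n_age_probes = 100,
                               tissues = c(blood = 60), age_range = c(0, 3.8),
                               seed = 31)
  cfg_human <- methyl_sim_config(n_probes = 800, n_age_probes = 100,
                                 tissues = c(blood = 60), species = "human",
                                 age_range = c(0, 122.5), seed = 32)
  train <- simulate_two_species(cfg_rat, cfg_human, TRUE)
  test_rat <- simulate_methylomes(cfg_rat, sample_seed = 91)
  rel_clock <- fit_clock(train$beta, train$annotation,
                         age_transform("relative"), seed = 7)
  id_clock <- fit_clock(train$beta, train$annotation,
                        age_transform("identity"), seed = 7)
  r_rel <- pearson_r(predict_age(rel_clock, test_rat$beta,
                                 test_rat$annotation)$dnam_age,
                     test_rat$annotation$age)
  mae_id <- median_abs_error(predict_age(id_clock, test_rat$beta,
                                         test_rat$annotation)$dnam_age,
                             test_rat$annotation$age)
  mae_rel <- median_abs_error(predict_age(rel_clock, test_rat$beta,
                                          test_rat$annotation)$dnam_age,
                              test_rat$annotation$age)
  expect_gt(r_rel, 0.9)
  # absolute-age training across a 3.8 vs 122.5 year span skews rat errors
  expect_lt(mae_rel, mae_id)
})
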