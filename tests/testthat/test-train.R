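test_that("random splits have 60/20/20 sizes, disjoint and exhaustive", {
  set.seed(1)
  s <- suppressWarnings(split_records(1000))
  expect_length(s$train_idx, 600)
  expect_length(s$test_idx, 200)
  expect_length(s$valid_idx, 200)
  all_idx <- c(s$train_idx, s$test_idx, s$valid_idx)
  expect_equal(sort(all_idx), 1:1000)

  set.seed(1)
  s2 <- suppressWarnings(split_records(1000))
  expect_equal(s, s2)

  set.seed(2)
  expect_warning(s10 <- split_records(10), "2,000")
  expect_length(s10$train_idx, 6)
  expect_length(s10$test_idx, 2)
  expect_length(s10$valid_idx, 2)
  expect_error(split_records(5), "at least 10")
})

test_that("model efficiency is the Nash-Sutcliffe score", {
  o <- c(1, 2, 3, 4)
  expect_equal(model_efficiency(o, o), 1)
  expect_equal(model_efficiency(o, rep(mean(o), 4)), 0)
  expect_equal(model_efficiency(c(1, 2, 3), c(1, 2, 5)), -1)
  expect_error(model_efficiency(rep(1, 5), 1:5), "zero variance")
})

test_that("training recovers a noiseless teacher network", {
  drv <- fixture_drivers()
  st <- network_structure(3, 4, 9, 12)
  set.seed(100)
  teacher <- init_network(st)
  fwd_t <- nn_forward(teacher, drv)
  drv2 <- drv
  drv2$nee_norm <- fwd_t$nee_norm
  drv2$train_mask <- drv$valid_mask
  n_avail <- sum(drv2$train_mask)

  set.seed(101)
  split <- split_records(n_avail)
  set.seed(102)
  student <- init_network(st)
  m <- train_member(student, drv2, split,
                    train_options(max_iter = 80, patience = 20))
  expect_lt(m$train_mse, 1e-4)
  expect_true(m$sign_ok)

  # zero-iteration budget returns the initial parameters with scores
  set.seed(102)
  init <- init_network(st)
  m0 <- train_member(init, drv2, split,
                     train_options(max_iter = 0, max_reinit = 0))
  expect_equal(m0$params$W1_reco, init$W1_reco)
  expect_equal(m0$n_iter, 0L)
  expect_true(is.finite(m0$valid_mse))
})

test_that("the ensemble protocol produces the documented counts and is
           deterministic under the master seed", {
  drv <- fixture_drivers()
  st34 <- list(c(3L, 4L))
  cfg <- ensemble_config(n_datasets = 2, structures = st34, n_inits = 2,
                         master_seed = 7,
                         opts = train_options(max_iter = 4))
  ens <- run_ensemble(drv, cfg)
  expect_length(ens$candidates, 2L)            # best-of-inits per split
  expect_length(ens$selected_per_dataset, 2L)
  expect_length(ens$final_members, 2L)

  ens2 <- run_ensemble(drv, cfg)
  expect_equal(vapply(ens2$final_members, `[[`, 0, "nee_model_efficiency"),
               vapply(ens$final_members, `[[`, 0, "nee_model_efficiency"))

  # reduced-config arithmetic: 5 datasets x 2 structures x 2 inits
  rc <- reduced_config()
  expect_equal(rc$n_datasets * length(rc$structures), 10)
  expect_equal(rc$n_final, 5)
})

test_that("teacher data is recovered to R2 >= 0.99 by a reduced ensemble", {
  drv <- fixture_drivers()
  st <- network_structure(3, 4, 9, 12)
  set.seed(100)
  teacher <- init_network(st)
  fwd_t <- nn_forward(teacher, drv)
  drv2 <- drv
  drv2$nee_norm <- fwd_t$nee_norm
  drv2$train_mask <- drv$valid_mask
  cfg <- ensemble_config(n_datasets = 2, structures = list(c(3, 4)),
                         n_inits = 2, master_seed = 5,
                         opts = train_options(max_iter = 60,
                                              patience = 15))
  ens <- run_ensemble(drv2, cfg)
  res <- predict_ensemble(ens, drv2)
  ok <- drv2$valid_mask
  expect_gt(cor(res$nee_pred[ok], fwd_t$nee_pred[ok])^2, 0.99)
})

test_that("ensemble prediction is the member mean and keeps constraints", {
  drv <- fixture_drivers()
  st <- network_structure(3, 4, 9, 12)
  set.seed(61)
  m1 <- list(params = init_network(st))
  m2 <- list(params = init_network(st))
  ens1 <- structure(list(final_members = list(m1)),
                    class = "flux_ensemble")
  ens2 <- structure(list(final_members = list(m1, m2)),
                    class = "flux_ensemble")
  r1 <- predict_ensemble(ens1, drv)
  f1 <- nn_forward(m1$params, drv)
  expect_equal(r1$gpp_pred, f1$gpp_pred)
  r2 <- predict_ensemble(ens2, drv)
  f2 <- nn_forward(m2$params, drv)
  expect_equal(r2$reco_pred, (f1$reco_pred + f2$reco_pred) / 2)
  expect_true(all(r2$reco_pred > 0))
  expect_true(all(r2$gpp_pred[drv$sw_in_raw == 0] == 0))
  expect_lt(max(abs(r2$nee_pred - (r2$reco_pred - r2$gpp_pred))), 1e-12)
})

test_that("early stopping never returns parameters worse than the best
           test score seen", {
  drv <- fixture_drivers()
  st <- network_structure(3, 4, 9, 12)
  n_avail <- sum(drv$train_mask)
  set.seed(71)
  split <- split_records(n_avail)
  set.seed(72)
  p <- init_network(st)
  m_short <- train_member(p, drv, split, train_options(max_iter = 5))
  set.seed(72)
  p <- init_network(st)
  m_long <- train_member(p, drv, split, train_options(max_iter = 40))
  expect_lte(m_long$test_mse, m_short$test_mse)
})
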