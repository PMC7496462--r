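#' Random 60/20/20 record split
#'
#' Randomly partitions the available records into training (60%), test
#' (20%, used only for early stopping) and validation (20%, used only for
#' member selection) sets, without replacement. Uses the current RNG state;
#' seed upstream for determinism.
#'
#' @param n_available number of records carrying all drivers and a measured
#'   NEE target.
#' @param fractions numeric triple summing to 1 (default `c(.6, .2, .2)`).
#' @return list of class `split_indices` with `train_idx`, `test_idx`,
#'   `valid_idx` (indices into the available-record set).
#' @export
split_records <- function(n_available, fractions = c(0.6, 0.2, 0.2)) {
  if (n_available < 10) stop("need at least 10 available records")
  if (n_available < 2000) {
    warning("fewer than 2,000 available records (", n_available, ")")
  }
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  perm <- sample.int(n_available)
  n_train <- round(fractions[1] * n_available)
  n_test <- round(fractions[2] * n_available)
  structure(list(
    train_idx = sort(perm[seq_len(n_train)]),
    test_idx = sort(perm[n_train + seq_len(n_test)]),
    valid_idx = sort(perm[(n_train + n_test + 1):n_available])),
    class = "split_indices")
}

#' Nash-Sutcliffe model efficiency
#'
#' `1 - sum((o - p)^2) / sum((o - mean(o))^2)`; 1 for a perfect model, 0 for
#' a model no better than the observed mean. The standard skill score for
#' flux time-series models.
#'
#' @param observed,predicted aligned numeric vectors (pairs with missing
#'   values are dropped; at least 2 finite pairs required).
#' @return scalar efficiency.
#' @export
model_efficiency <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]
  p <- predicted[ok]
  if (length(o) < 2) stop("need at least 2 finite pairs")
  denom <- sum((o - mean(o))^2)
  if (denom == 0) stop("observed series has zero variance")
  1 - sum((o - p)^2) / denom
}

#' Training options for a single member
#'
#' @param max_iter maximum accepted Levenberg-Marquardt iterations
#'   (default 200).
#' @param patience early-stopping patience: accepted iterations without
#'   test-set improvement before stopping (default 6).
#' @param lambda0 initial damping (default 1e-3); multiplied by 10 on a
#'   rejected step, divided by 10 on acceptance.
#' @param grad_tol stop when the gradient infinity-norm falls below this
#'   (default 1e-8).
#' @param max_reinit re-initializations allowed on sign-convention failure
#'   (default 5).
#' @return list of options.
#' @export
train_options <- function(max_iter = 200, patience = 6, lambda0 = 1e-3,
                          grad_tol = 1e-8, max_reinit = 5) {
  list(max_iter = max_iter, patience = patience, lambda0 = lambda0,
       grad_tol = grad_tol, max_reinit = max_reinit)
}

# One Levenberg-Marquardt fit of the normalized-NEE residuals on the
# training rows, with early stopping on the test rows. Returns the
# parameters at the test-MSE minimum.
lm_fit <- function(params, drivers, rows_train, rows_test, opts) {
  target <- drivers$nee_norm
  t_train <- target[rows_train]
  t_test <- target[rows_test]
  theta <- flatten_params(params)
  st <- params$structure
  mse <- function(th, rows, tgt) {
    f <- nn_forward(unflatten_params(th, st), drivers, rows)
    mean((f$nee_norm - tgt)^2)
  }
  fwd <- nn_forward(params, drivers, rows_train)
  r <- fwd$nee_norm - t_train
  sse <- sum(r^2)
  if (!all(is.finite(r))) stop("non-finite residuals at initialization")
  best_theta <- theta
  best_test <- mse(theta, rows_test, t_test)
  lambda <- opts$lambda0
  stall <- 0L
  n_iter <- 0L
  while (n_iter < opts$max_iter) {
    p <- unflatten_params(theta, st)
    J <- nn_jacobian(p, drivers, rows_train, fwd = fwd)
    g <- crossprod(J, r)
    if (max(abs(g)) < opts$grad_tol) break
    A <- crossprod(J)
    dA <- diag(A)
    dA[dA < 1e-12] <- 1e-12
    accepted <- FALSE
    while (!accepted && lambda < 1e10) {
      step <- tryCatch(
        solve(A + lambda * diag(dA, nrow = length(dA)), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        theta_new <- theta + drop(step)
        fwd_new <- nn_forward(unflatten_params(theta_new, st), drivers,
                              rows_train)
        r_new <- fwd_new$nee_norm - t_train
        sse_new <- sum(r_new^2)
        if (is.finite(sse_new) && sse_new < sse) {
          theta <- theta_new
          fwd <- fwd_new
          r <- r_new
          sse <- sse_new
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
        }
      }
      if (!accepted) lambda <- lambda * 10
    }
    if (!accepted) break
    n_iter <- n_iter + 1L
    test_mse <- mse(theta, rows_test, t_test)
    if (test_mse < best_test) {
      best_test <- test_mse
      best_theta <- theta
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= opts$patience) break
    }
  }
  list(params = unflatten_params(best_theta, st),
       test_mse = best_test, train_mse = sse / length(rows_train),
       n_iter = n_iter)
}

#' Train a single ensemble member
#'
#' Minimizes the mean squared error of the normalized NEE prediction on the
#' training rows by Levenberg-Marquardt (damped Gauss-Newton on the residual
#' vector with the analytic Jacobian), early-stopping on the test rows:
#' the returned parameters are those at the test-MSE minimum. The fixed
#' output weights are never updated. If the trained member fails
#' [check_sign_convention()], it is re-initialized and retrained up to
#' `opts$max_reinit` times; a member still failing is flagged.
#'
#' @param params initial [network_params][init_network].
#' @param drivers a [driver_set][build_driver_set].
#' @param split a [split_indices][split_records] over the available records.
#' @param opts a [train_options()] list.
#' @return list of class `trained_member`: `params`, `split`,
#'   `valid_mse`, `nee_model_efficiency` (on all available records),
#'   `train_mse`, `test_mse`, `n_iter`, `reinit_count`, `sign_ok`.
#' @export
train_member <- function(params, drivers, split,
                         opts = train_options()) {
  avail <- which(drivers$train_mask)
  rows_train <- avail[split$train_idx]
  rows_test <- avail[split$test_idx]
  rows_valid <- avail[split$valid_idx]
  target <- drivers$nee_norm
  reinit <- 0L
  repeat {
    if (opts$max_iter == 0) {
      fit <- list(params = params,
                  test_mse = mean((nn_forward(params, drivers,
                    rows_test)$nee_norm - target[rows_test])^2),
                  train_mse = mean((nn_forward(params, drivers,
                    rows_train)$nee_norm - target[rows_train])^2),
                  n_iter = 0L)
    } else {
      fit <- lm_fit(params, drivers, rows_train, rows_test, opts)
    }
    fwd_tr <- nn_forward(fit$params, drivers, rows_train)
    ok <- check_sign_convention(fwd_tr,
      denormalize_pm1(target[rows_train], drivers$norm_nee),
      drivers$night_flag[rows_train])
    if (ok || reinit >= opts$max_reinit) break
    reinit <- reinit + 1L
    params <- init_network(params$structure)
  }
  fwd_v <- nn_forward(fit$params, drivers, rows_valid)
  valid_mse <- mean((fwd_v$nee_norm - target[rows_valid])^2)
  fwd_all <- nn_forward(fit$params, drivers, avail)
  me <- model_efficiency(target[avail], fwd_all$nee_norm)
  structure(list(params = fit$params, split = split,
                 valid_mse = valid_mse, nee_model_efficiency = me,
                 train_mse = fit$train_mse, test_mse = fit$test_mse,
                 n_iter = fit$n_iter, reinit_count = reinit,
                 sign_ok = ok),
            class = "trained_member")
}

#' Ensemble protocol configuration
#'
#' Defaults follow the full reference protocol: 25 random splits, the five
#' hidden-layer structures, 5 random initializations each (125 candidate
#' networks), selection by validation MSE within each split and final
#' selection of the 5 members with the best NEE model efficiency.
#'
#' @param n_datasets number of random splits (default 25).
#' @param structures list of `c(n_hidden_reco, n_hidden_gpp)` pairs
#'   (default [reference_structures()]).
#' @param n_inits random initializations per split x structure (default 5).
#' @param n_final number of finally selected members (default 5).
#' @param master_seed single seed controlling all randomness (default 1).
#' @param opts a [train_options()] list.
#' @return list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_datasets = 25,
                            structures = reference_structures(),
                            n_inits = 5, n_final = 5, master_seed = 1,
                            opts = train_options()) {
  structure(list(n_datasets = n_datasets, structures = structures,
                 n_inits = n_inits, n_final = n_final,
                 master_seed = master_seed, opts = opts),
            class = "ensemble_config")
}

#' Reduced protocol for desk-scale runs
#'
#' 5 splits x 2 structures x 2 initializations with `max_iter` capped at
#' 100: the configuration used throughout the synthetic-recovery checks.
#'
#' @param master_seed seed (default 1).
#' @param ... overrides passed to [ensemble_config()].
#' @export
reduced_config <- function(master_seed = 1, ...) {
  ensemble_config(n_datasets = 5,
                  structures = reference_structures()[c(1, 3)],
                  n_inits = 2, master_seed = master_seed,
                  opts = train_options(max_iter = 100), ...)
}

#' Run the full ensemble training protocol
#'
#' For each of `n_datasets` random 60/20/20 splits and each structure,
#' trains `n_inits` members with random initial weights and keeps the one
#' with the lowest validation MSE (the candidates; 125 under the full
#' protocol). Within each split, the best candidate by validation MSE is
#' selected (25), and those are ranked by Nash-Sutcliffe model efficiency
#' of NEE over all available records; the top `n_final` (5) form the final
#' ensemble. Ties break by lower validation MSE, then lower member index.
#' Fully deterministic under `config$master_seed`.
#'
#' @param drivers a [driver_set][build_driver_set].
#' @param config an [ensemble_config()].
#' @param verbose print progress (default `FALSE`).
#' @return list of class `flux_ensemble`: `candidates`,
#'   `selected_per_dataset`, `final_members`, `config`.
#' @export
run_ensemble <- function(drivers, config = ensemble_config(),
                         verbose = FALSE) {
  n_avail <- sum(drivers$train_mask)
  set.seed(config$master_seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             config$n_datasets * (1 + length(config$structures))),
                  nrow = config$n_datasets)
  candidates <- list()
  for (ds in seq_len(config$n_datasets)) {
    set.seed(seeds[ds, 1])
    split <- split_records(n_avail)
    for (si in seq_along(config$structures)) {
      hs <- config$structures[[si]]
      st <- network_structure(hs[1], hs[2],
                              ncol(drivers$reco_matrix),
                              ncol(drivers$gpp_matrix))
      set.seed(seeds[ds, 1 + si])
      inits <- vector("list", config$n_inits)
      for (ii in seq_len(config$n_inits)) {
        m <- train_member(init_network(st), drivers, split, config$opts)
        m$dataset_id <- ds
        m$structure_id <- si
        m$init_id <- ii
        inits[[ii]] <- m
      }
      inits <- Filter(function(m) m$sign_ok, inits)
      if (!length(inits)) next
      best <- inits[[order(vapply(inits, `[[`, 0, "valid_mse"))[1]]]
      candidates[[length(candidates) + 1L]] <- best
      if (verbose) {
        message(sprintf(
          "dataset %d structure %d: valid MSE %.3g, ME %.3f (%d iters)",
          ds, si, best$valid_mse, best$nee_model_efficiency, best$n_iter))
      }
    }
  }
  if (!length(candidates)) stop("no candidate passed the sign convention")
  ds_ids <- vapply(candidates, `[[`, 0, "dataset_id")
  selected <- lapply(unique(ds_ids), function(ds) {
    grp <- candidates[ds_ids == ds]
    grp[[order(vapply(grp, `[[`, 0, "valid_mse"))[1]]]
  })
  me <- vapply(selected, `[[`, 0, "nee_model_efficiency")
  vm <- vapply(selected, `[[`, 0, "valid_mse")
  ord <- order(-me, vm, seq_along(selected))
  final <- selected[ord[seq_len(min(config$n_final, length(selected)))]]
  structure(list(candidates = candidates,
                 selected_per_dataset = selected,
                 final_members = final, config = config),
            class = "flux_ensemble")
}

#' @export
print.flux_ensemble <- function(x, ...) {
  cat(sprintf(
    "<flux_ensemble> candidates=%d selected=%d final=%d\n",
    length(x$candidates), length(x$selected_per_dataset),
    length(x$final_members)))
  me <- vapply(x$final_members, `[[`, 0, "nee_model_efficiency")
  cat(sprintf("  final NEE model efficiency: %s\n",
              paste(sprintf("%.3f", me), collapse = ", ")))
  invisible(x)
}

#' Ensemble prediction of the partitioned fluxes
#'
#' Evaluates every final member over all records and averages the physical
#' GPP and RECO predictions; the ensemble NEE is the difference of the two
#' means, so positivity, the night-zero GPP constraint and the identity
#' `nee = reco - gpp` all survive averaging. Per-member series are
#' retained.
#'
#' @param ensemble a [flux_ensemble][run_ensemble].
#' @param drivers a [driver_set][build_driver_set].
#' @return list of class `partition_result` with `timestamp`, `nee_pred`,
#'   `gpp_pred`, `reco_pred`, `lue_pred` (ensemble means) and matrices
#'   `gpp_members`, `reco_members`, `lue_members`.
#' @export
predict_ensemble <- function(ensemble, drivers) {
  members <- ensemble$final_members
  if (!length(members)) stop("ensemble has no final members")
  fwd <- lapply(members, function(m) nn_forward(m$params, drivers))
  gm <- sapply(fwd, `[[`, "gpp_pred")
  rm_ <- sapply(fwd, `[[`, "reco_pred")
  lm_ <- sapply(fwd, `[[`, "lue_pred")
  gpp <- rowMeans(gm)
  reco <- rowMeans(rm_)
  structure(list(timestamp = drivers$timestamps,
                 nee_pred = reco - gpp, gpp_pred = gpp, reco_pred = reco,
                 lue_pred = rowMeans(lm_),
                 gpp_members = gm, reco_members = rm_, lue_members = lm_),
            class = "partition_result")
}

#' Serialize an ensemble to a directory of member JSON files
#'
#' @param ensemble a [flux_ensemble][run_ensemble].
#' @param dir output directory (created if absent).
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ensemble$final_members)) {
    write_network_json(ensemble$final_members[[i]]$params,
                       file.path(dir, sprintf("member_%02d.json", i)))
  }
  manifest <- list(
    n_final = length(ensemble$final_members),
    master_seed = ensemble$config$master_seed,
    n_datasets = ensemble$config$n_datasets,
    n_inits = ensemble$config$n_inits,
    model_efficiency = vapply(ensemble$final_members, `[[`, 0,
                              "nee_model_efficiency"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
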