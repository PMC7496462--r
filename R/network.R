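#' Network structure of the two-branch partitioning network
#'
#' The partitioning network consists of two subnetworks sharing one output
#' node. The respiration branch has `n_hidden_reco` tanh neurons feeding a
#' single logistic neuron, so its output lies in (0, 1). The GPP branch has
#' `n_hidden_gpp` tanh neurons feeding a logistic neuron whose output is an
#' instantaneous light-use efficiency (LUE); a product node multiplies the
#' LUE by incoming shortwave radiation (scaled to [0, 1] by its annual
#' maximum) through a positive-linear transfer, so GPP is nonnegative and
#' exactly zero in darkness. The output node combines the branches with
#' weights fixed at +1 (respiration) and -1 (GPP) and bias fixed at 0,
#' reproducing NEE = RECO - GPP.
#'
#' The five reference structures pair 10-14 respiration neurons with 13-17
#' GPP neurons: (10,13), (11,14), (12,15), (13,16), (14,17).
#'
#' @param n_hidden_reco,n_hidden_gpp first-layer sizes of the two branches.
#' @param n_inputs_reco,n_inputs_gpp driver counts of the two branches.
#' @param lue_gain fixed gain on the product node (default 8). The logistic
#'   LUE neuron is bounded above by 1, so with shortwave scaled to [0, 1]
#'   the representable light-use efficiency would be capped at
#'   `max|NEE| / max(SW_IN)` (of order 0.04 umol CO2 per W) -- below real
#'   low-light efficiencies. The gain raises that ceiling well above any
#'   ecosystem value while preserving the LUE interpretation and the exact
#'   night-zero constraint; it is a structural constant, never trained.
#' @return list of class `network_structure`.
#' @export
network_structure <- function(n_hidden_reco, n_hidden_gpp,
                              n_inputs_reco, n_inputs_gpp, lue_gain = 8) {
  stopifnot(n_hidden_reco >= 1, n_hidden_gpp >= 1,
            n_inputs_reco >= 1, n_inputs_gpp >= 1, lue_gain > 0)
  structure(list(n_hidden_reco = as.integer(n_hidden_reco),
                 n_hidden_gpp = as.integer(n_hidden_gpp),
                 n_inputs_reco = as.integer(n_inputs_reco),
                 n_inputs_gpp = as.integer(n_inputs_gpp),
                 lue_gain = lue_gain),
            class = "network_structure")
}

#' The five reference hidden-layer pairings
#' @return list of `c(n_hidden_reco, n_hidden_gpp)` pairs.
#' @export
reference_structures <- function() {
  list(c(10L, 13L), c(11L, 14L), c(12L, 15L), c(13L, 16L), c(14L, 17L))
}

#' Number of trainable parameters of a structure
#' @param structure a [network_structure].
#' @return integer count (the fixed +/-1 output weights and 0 output bias
#'   are not trainable).
#' @export
n_params <- function(structure) {
  s <- structure
  (s$n_inputs_reco * s$n_hidden_reco + s$n_hidden_reco) +
    (s$n_hidden_reco + 1L) +
    (s$n_inputs_gpp * s$n_hidden_gpp + s$n_hidden_gpp) +
    (s$n_hidden_gpp + 1L)
}

#' Initialize network parameters
#'
#' Trainable weights and biases are drawn uniformly in +/- 0.5 (inputs are
#' pre-normalized to [-1, 1], so small symmetric initial weights keep both
#' activations in their responsive range). The output weights (+1 for
#' respiration, -1 for GPP) and output bias (0) are fixed and never updated.
#' Uses the current R RNG state; seed upstream for reproducibility.
#'
#' @param structure a [network_structure].
#' @return list of class `network_params` with matrices `W1_reco`,
#'   `b1_reco`, `w2_reco`, `b2_reco`, `W1_gpp`, `b1_gpp`, `w2_gpp`,
#'   `b2_gpp`, the fixed `w_out = c(reco = 1, gpp = -1)` and `b_out = 0`,
#'   and the `structure`.
#' @export
init_network <- function(structure) {
  s <- structure
  u <- function(n) stats::runif(n, -0.5, 0.5)
  structure(list(
    W1_reco = matrix(u(s$n_inputs_reco * s$n_hidden_reco),
                     s$n_inputs_reco, s$n_hidden_reco),
    b1_reco = u(s$n_hidden_reco),
    w2_reco = u(s$n_hidden_reco),
    b2_reco = u(1),
    W1_gpp = matrix(u(s$n_inputs_gpp * s$n_hidden_gpp),
                    s$n_inputs_gpp, s$n_hidden_gpp),
    b1_gpp = u(s$n_hidden_gpp),
    w2_gpp = u(s$n_hidden_gpp),
    b2_gpp = u(1),
    w_out = c(reco = 1, gpp = -1),
    b_out = 0,
    structure = s), class = "network_params")
}

flatten_params <- function(p) {
  c(as.numeric(p$W1_reco), p$b1_reco, p$w2_reco, p$b2_reco,
    as.numeric(p$W1_gpp), p$b1_gpp, p$w2_gpp, p$b2_gpp)
}

unflatten_params <- function(theta, structure) {
  s <- structure
  i <- 0L
  take <- function(n) {
    v <- theta[(i + 1L):(i + n)]
    i <<- i + n
    v
  }
  p <- list(
    W1_reco = matrix(take(s$n_inputs_reco * s$n_hidden_reco),
                     s$n_inputs_reco, s$n_hidden_reco),
    b1_reco = take(s$n_hidden_reco),
    w2_reco = take(s$n_hidden_reco),
    b2_reco = take(1L),
    W1_gpp = matrix(take(s$n_inputs_gpp * s$n_hidden_gpp),
                    s$n_inputs_gpp, s$n_hidden_gpp),
    b1_gpp = take(s$n_hidden_gpp),
    w2_gpp = take(s$n_hidden_gpp),
    b2_gpp = take(1L),
    w_out = c(reco = 1, gpp = -1),
    b_out = 0,
    structure = s)
  stopifnot(i == length(theta))
  class(p) <- "network_params"
  p
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Forward pass of the partitioning network
#'
#' Evaluates both branches and combines them at the fixed output node.
#' On the normalized scale, `nee_norm = s_reco - s_gpp` where
#' `s_reco = logistic(.) in (0, 1)` and `s_gpp = poslin(lue * sw_scaled)`,
#' `sw_scaled = SW_IN / max(SW_IN)`. Physical fluxes are recovered with the
#' zero-preserving linear factor of the NEE target normalization
#' (`max |NEE|`), so positivity and the night-zero constraint survive
#' denormalization and `nee_pred = reco_pred - gpp_pred` holds exactly.
#'
#' @param params a [network_params][init_network].
#' @param drivers a [driver_set][build_driver_set].
#' @param rows optional integer subset of records to evaluate.
#' @return list with normalized quantities (`s_reco`, `s_gpp`, `lue`,
#'   `nee_norm`) and physical predictions (`reco_pred`, `gpp_pred`,
#'   `nee_pred`, `lue_pred` in umol CO2 J-1-scale proxy units).
#' @export
nn_forward <- function(params, drivers, rows = NULL) {
  Xr <- drivers$reco_matrix
  Xg <- drivers$gpp_matrix
  sw <- drivers$sw_in_raw / drivers$sw_max
  if (!is.null(rows)) {
    Xr <- Xr[rows, , drop = FALSE]
    Xg <- Xg[rows, , drop = FALSE]
    sw <- sw[rows]
  }
  s <- params$structure
  if (ncol(Xr) != s$n_inputs_reco || ncol(Xg) != s$n_inputs_gpp) {
    stop("driver matrices do not match the network input dimensions")
  }
  Hr <- tanh(sweep(Xr %*% params$W1_reco, 2, params$b1_reco, "+"))
  s_reco <- logistic(drop(Hr %*% params$w2_reco) + params$b2_reco)
  Hg <- tanh(sweep(Xg %*% params$W1_gpp, 2, params$b1_gpp, "+"))
  lue <- logistic(drop(Hg %*% params$w2_gpp) + params$b2_gpp)
  gain <- s$lue_gain %||% 1
  s_gpp <- pmax(0, lue * gain * sw)
  nee_norm <- s_reco * params$w_out[["reco"]] +
    s_gpp * abs(params$w_out[["gpp"]]) * sign(params$w_out[["gpp"]]) +
    params$b_out
  scale <- drivers$norm_nee$xmax
  list(s_reco = s_reco, s_gpp = s_gpp, lue = lue, nee_norm = nee_norm,
       reco_pred = scale * s_reco, gpp_pred = scale * s_gpp,
       nee_pred = scale * s_reco - scale * s_gpp,
       lue_pred = scale * lue * gain / drivers$sw_max,
       Hr = Hr, Hg = Hg)
}

#' Analytic Jacobian of the normalized NEE prediction
#'
#' Returns the `n x p` matrix of partial derivatives of `nee_norm` with
#' respect to the flat trainable parameter vector (layout of
#' `flatten_params`): the respiration block enters with weight +1, the GPP
#' block with weight -1 times the scaled shortwave at each record. Used by
#' the Levenberg-Marquardt trainer and verified against central finite
#' differences in the test suite.
#'
#' @param params a [network_params][init_network].
#' @param drivers a [driver_set][build_driver_set].
#' @param rows optional record subset.
#' @param fwd optional precomputed [nn_forward()] output for these rows.
#' @return numeric matrix, rows = records, columns = trainable parameters.
#' @export
nn_jacobian <- function(params, drivers, rows = NULL, fwd = NULL) {
  if (is.null(fwd)) fwd <- nn_forward(params, drivers, rows)
  Xr <- drivers$reco_matrix
  Xg <- drivers$gpp_matrix
  sw <- drivers$sw_in_raw / drivers$sw_max
  if (!is.null(rows)) {
    Xr <- Xr[rows, , drop = FALSE]
    Xg <- Xg[rows, , drop = FALSE]
    sw <- sw[rows]
  }
  branch_block <- function(X, H, w2, gate) {
    # gate = d nee_norm / d z2 at each record (n-vector)
    d <- ncol(X)
    h <- ncol(H)
    A <- (1 - H^2) * outer(gate, w2)         # n x h : d nee / d z1_k
    J_W1 <- X[, rep(seq_len(d), times = h), drop = FALSE] *
      A[, rep(seq_len(h), each = d), drop = FALSE]
    cbind(J_W1, A, gate * H, gate)
  }
  gate_r <- fwd$s_reco * (1 - fwd$s_reco)
  gain <- params$structure$lue_gain %||% 1
  gate_g <- -gain * sw * fwd$lue * (1 - fwd$lue)  # poslin active (lue*sw >= 0)
  cbind(branch_block(Xr, fwd$Hr, params$w2_reco, gate_r),
        branch_block(Xg, fwd$Hg, params$w2_gpp, gate_g))
}

#' Check the flux sign convention of a trained member
#'
#' Positivity of respiration and nonnegativity of GPP hold by construction;
#' the check additionally requires the GPP predictions to be positively
#' associated with daytime carbon uptake (Pearson correlation of `gpp_pred`
#' with `-NEE` over daytime records > 0), guarding against degenerate
#' members in which the GPP branch collapses and the respiration branch
#' absorbs the diurnal cycle. Failure triggers re-initialization upstream.
#'
#' @param fwd output of [nn_forward()] on the training records.
#' @param nee_obs observed NEE on the same records.
#' @param night_flag logical nighttime flag on the same records.
#' @return `TRUE` if the convention is respected.
#' @export
check_sign_convention <- function(fwd, nee_obs, night_flag) {
  if (any(fwd$reco_pred <= 0) || any(fwd$gpp_pred < 0)) return(FALSE)
  day <- !night_flag & is.finite(nee_obs)
  if (sum(day) < 3) return(TRUE)
  g <- fwd$gpp_pred[day]
  if (stats::sd(g) == 0) return(FALSE)
  stats::cor(g, -nee_obs[day]) > 0
}

#' Serialize network parameters to JSON
#'
#' Writes layer shapes, flat weight arrays and the fixed output weights to
#' a JSON file readable by [read_network_json()].
#'
#' @param params a [network_params][init_network].
#' @param path file path.
#' @export
write_network_json <- function(params, path) {
  s <- params$structure
  obj <- list(structure = unclass(s),
              theta = flatten_params(params),
              w_out = as.list(params$w_out), b_out = params$b_out)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- do.call(network_structure, as.list(obj$structure))
  unflatten_params(as.numeric(obj$theta), st)
}
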