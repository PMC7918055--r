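# Recurrent fuzzy neural network regressor.
#
# Four layers: inputs pass straight through; a Gaussian fuzzification
# layer with one membership function per (input, rule); a rule layer
# whose firing strength is the product (fuzzy AND) of memberships and
# whose node carries an internal recurrent state; and a defuzzification
# layer taking the state-weighted average of rule weights. Structure is
# initialised by k-means clustering; all parameters (centers, widths,
# recurrent ratios, weights) are learned by per-sample gradient descent.
# Inputs and outputs are min-max normalized to [0, 1] inside the model.
# The per-sample inner loops live in src/rfnn.cpp.

#' Learning configuration for the RFNN
#'
#' @param eta_m,eta_sigma,eta_lambda,eta_w Learning rates for the
#'   Gaussian centers, widths, recurrent ratios and output weights
#'   (default 0.01 each).
#' @param epochs Training epochs (default 150).
#' @param n_rules Initial number of fuzzy rules (default 15).
#' @param sigma_min Floor on Gaussian widths in normalized units
#'   (default 1e-3).
#' @param add_threshold If the best firing strength seen for a sample
#'   falls below this, a rule is added there (default 0.1).
#' @param prune_threshold Rules whose mean firing over an epoch falls
#'   below this are removed (default 1e-4).
#' @param width_scale Multiplier on cluster standard deviations when
#'   initialising widths (default 3.5; product-AND over many inputs makes
#'   unscaled widths fire too weakly).
#' @param tol Minimum epoch-loss improvement counted as progress
#'   (default 1e-8).
#' @param patience Stop after this many consecutive epochs without
#'   progress; the best-loss parameters are kept (default 20).
#' @param seed Seed for clustering initialisation.
#' @return A list of class `rfnn_config`.
#' @export
rfnn_config <- function(eta_m = 0.01, eta_sigma = 0.01, eta_lambda = 0.01,
                        eta_w = 0.01, epochs = 150L, n_rules = 15L,
                        sigma_min = 1e-3, add_threshold = 0.1,
                        prune_threshold = 1e-4, width_scale = 3.5,
                        tol = 1e-8, patience = 20L, seed = 1L) {
  rates <- c(eta_m, eta_sigma, eta_lambda, eta_w)
  if (any(rates <= 0)) {
    stop_emg("All learning rates must be positive.", "emgdecode_config_error")
  }
  if (add_threshold <= 0 || add_threshold >= 1 ||
      prune_threshold <= 0 || prune_threshold >= 1) {
    stop_emg("Firing thresholds must lie in (0, 1).", "emgdecode_config_error")
  }
  structure(
    list(eta_m = eta_m, eta_sigma = eta_sigma, eta_lambda = eta_lambda,
         eta_w = eta_w, epochs = as.integer(epochs),
         n_rules = as.integer(n_rules), sigma_min = sigma_min,
         add_threshold = add_threshold, prune_threshold = prune_threshold,
         width_scale = width_scale, tol = tol,
         patience = as.integer(patience), seed = as.integer(seed)),
    class = "rfnn_config"
  )
}

new_rfnn <- function(m, sigma, lambda, w, norm_x, norm_y, config,
                     history = numeric()) {
  stopifnot(all(sigma > 0), all(lambda >= 0 & lambda <= 1))
  structure(
    list(m = m, sigma = sigma, lambda = lambda, w = w,
         norm_x = norm_x, norm_y = norm_y, config = config,
         n_inputs = nrow(m), n_rules = ncol(m), n_outputs = ncol(w),
         history = history),
    class = "rfnn"
  )
}

# min-max normalizers; a zero range is widened so constant dimensions
# map to 0 and denormalize back exactly.
make_normalizer <- function(X) {
  mn <- unname(apply(X, 2, min))
  mx <- unname(apply(X, 2, max))
  degenerate <- mx <= mn
  mx[degenerate] <- mn[degenerate] + 1
  list(min = mn, max = mx)
}

norm_apply <- function(X, nrm) {
  sweep(sweep(X, 2, nrm$min, `-`), 2, nrm$max - nrm$min, `/`)
}

norm_invert <- function(X, nrm) {
  sweep(sweep(X, 2, nrm$max - nrm$min, `*`), 2, nrm$min, `+`)
}

as_sequence_list <- function(X) {
  if (is.list(X) && !is.data.frame(X)) {
    lapply(X, function(x) as.matrix(x))
  } else {
    list(as.matrix(X))
  }
}

#' Gaussian fuzzification of one (normalized) input vector
#'
#' Membership of input i in rule j:
#' `exp(-(x_i - m_ij)^2 / sigma_ij^2)`, always in (0, 1].
#'
#' @param x Normalized input vector (length `n_inputs`).
#' @param model An `rfnn`.
#' @return `n_inputs` x `n_rules` membership matrix.
#' @export
fuzzify <- function(x, model) {
  if (length(x) != model$n_inputs) {
    stop_emg("Input dimension mismatch.", "emgdecode_dim_error")
  }
  exp(-((x - model$m)^2) / model$sigma^2)
}

#' Rule firing strengths (fuzzy AND)
#'
#' @param memberships Matrix from [fuzzify()].
#' @return Vector of per-rule products over inputs, each in (0, 1].
#' @export
rule_strength <- function(memberships) {
  apply(memberships, 2, prod)
}

#' Recurrent rule-state update
#'
#' `u_j(t) = lambda_j * s_j(t) + (1 - lambda_j) * u_j(t-1)`: each rule
#' blends its current firing strength with its own previous state;
#' `lambda = 1` is memoryless, `lambda = 0` frozen.
#'
#' @param s Current firing strengths.
#' @param u_prev Previous rule states (0 at sequence start).
#' @param lambda Per-rule recurrent ratios in \[0, 1\].
#' @return Updated state vector.
#' @export
recurrent_update <- function(s, u_prev, lambda) {
  if (any(lambda < 0 | lambda > 1)) {
    stop_emg("`lambda` must lie in [0, 1].", "emgdecode_lambda_error")
  }
  lambda * s + (1 - lambda) * u_prev
}

#' Defuzzification: state-weighted average of rule weights
#'
#' @param u Rule states; their sum must be positive.
#' @param w `n_rules` x `n_outputs` weight matrix.
#' @return Output vector, a convex combination of the rows of `w`.
#' @export
defuzzify <- function(u, w) {
  denom <- sum(u)
  if (denom <= 1e-12) {
    stop_emg("Zero total rule activation: defuzzification undefined.",
             "emgdecode_activation_error")
  }
  as.numeric(crossprod(u, w)) / denom
}

#' Run the network over a sequence
#'
#' Applies fuzzification, rule firing, the recurrent state update and
#' defuzzification at every time step in order, starting from zero state.
#' Inputs are normalized with the model's stored normalizers and outputs
#' denormalized back to physical units. Steps with (numerically) zero
#' total activation hold the previous output.
#'
#' @param model A fitted `rfnn`.
#' @param X T x `n_inputs` matrix (or tibble) in original input units.
#' @param denormalize Return outputs in original units (default `TRUE`).
#' @return T x `n_outputs` matrix of predictions; attributes `"held"`
#'   (logical vector of hold steps) and `"states"` (T x `n_rules` rule
#'   states).
#' @export
forward_sequence <- function(model, X, denormalize = TRUE) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_inputs) {
    stop_emg("Input dimension mismatch.", "emgdecode_dim_error")
  }
  Xn <- norm_apply(X, model$norm_x)
  res <- rfnn_forward_cpp(model$m, model$sigma, model$lambda, model$w,
                          Xn, numeric(model$n_rules))
  Y <- res$Y
  if (denormalize) Y <- norm_invert(Y, model$norm_y)
  attr(Y, "held") <- res$held
  attr(Y, "states") <- res$U
  Y
}

#' Per-sample gradients of the squared-error cost
#'
#' Gradients of `E = 1/2 * sum_o (y_o - target_o)^2` with respect to the
#' centers, widths, recurrent ratios and weights, computed by
#' backpropagation with the previous rule state treated as a constant
#' (depth-1 truncation). All quantities are in normalized units.
#'
#' @param model An `rfnn`.
#' @param x Normalized input vector.
#' @param u_prev Previous rule state.
#' @param y_target Normalized target vector.
#' @return List with `gm`, `gsig`, `glam`, `gw`, the forward values
#'   (`s`, `u`, `y`), the cost `E`, and `valid` (FALSE when total
#'   activation underflowed and the step was held).
#' @export
rfnn_gradients <- function(model, x, u_prev, y_target) {
  rfnn_grads_cpp(model$m, model$sigma, model$lambda, model$w,
                 as.numeric(x), as.numeric(u_prev), as.numeric(y_target))
}

#' One gradient-descent update
#'
#' Applies the four learning-rate updates to a model for a single
#' (input, target) pair, clipping `lambda` to \[0, 1\] and flooring the
#' widths at `sigma_min`.
#'
#' @inheritParams rfnn_gradients
#' @param cfg An [rfnn_config()].
#' @return List with the updated `model` and the new rule state `u`.
#' @export
grad_step <- function(model, x, u_prev, y_target, cfg = model$config) {
  g <- rfnn_gradients(model, x, u_prev, y_target)
  if (!all(vapply(g[c("gm", "gsig", "glam", "gw")],
                  function(z) all(is.finite(z)), logical(1)))) {
    stop_emg("Non-finite gradient encountered.", "emgdecode_gradient_error")
  }
  if (g$valid) {
    model$m <- model$m - cfg$eta_m * g$gm
    model$sigma <- pmax(model$sigma - cfg$eta_sigma * g$gsig, cfg$sigma_min)
    model$lambda <- pmin(pmax(model$lambda - cfg$eta_lambda * g$glam, 0), 1)
    model$w <- model$w - cfg$eta_w * g$gw
  }
  list(model = model, u = g$u)
}

#' Initialise the rule base by clustering
#'
#' Seeded k-means on the normalized inputs gives one rule per cluster:
#' centers at the cluster means, widths at `width_scale` times the
#' within-cluster standard deviation (floored at `sigma_min`), weights at
#' the cluster-mean normalized targets, and recurrent ratios at 0.5.
#'
#' @param X,Y Training inputs/targets (matrices or lists of per-sequence
#'   matrices, original units).
#' @param cfg An [rfnn_config()]; `cfg$n_rules` clusters are used.
#' @return An unfitted `rfnn`.
#' @export
structure_init <- function(X, Y, cfg = rfnn_config()) {
  Xall <- do.call(rbind, as_sequence_list(X))
  Yall <- do.call(rbind, as_sequence_list(Y))
  R <- cfg$n_rules
  if (R < 1L || R > nrow(Xall)) {
    stop_emg("`n_rules` must lie in [1, n training samples].",
             "emgdecode_config_error")
  }
  norm_x <- make_normalizer(Xall)
  norm_y <- make_normalizer(Yall)
  Xn <- norm_apply(Xall, norm_x)
  Yn <- norm_apply(Yall, norm_y)
  I <- ncol(Xn); O <- ncol(Yn)
  if (R == 1L) {
    cluster <- rep(1L, nrow(Xn))
    centers <- matrix(colMeans(Xn), 1L, I)
  } else {
    km <- with_seed_(cfg$seed, kmeans(Xn, centers = R, nstart = 5L,
                                      iter.max = 100L))
    cluster <- km$cluster
    centers <- km$centers
  }
  m <- t(centers)
  dimnames(m) <- NULL
  sigma <- matrix(cfg$sigma_min, I, R)
  w <- matrix(0, R, O)
  for (j in seq_len(R)) {
    rows <- which(cluster == j)
    sds <- apply(Xn[rows, , drop = FALSE], 2, sd)
    sds[!is.finite(sds)] <- 0
    sigma[, j] <- pmax(cfg$width_scale * sds, cfg$sigma_min)
    w[j, ] <- colMeans(Yn[rows, , drop = FALSE])
  }
  new_rfnn(m, sigma, pmin(pmax(rep(0.5, R), 0), 1), w,
           norm_x, norm_y, cfg)
}

#' Add or prune rules from firing-strength evidence
#'
#' If an input's best firing strength over the current rule base falls
#' below `add_threshold`, a new rule is created at that input (widths from
#' the distance to the nearest existing rule, weights from the model's
#' current prediction, recurrent ratio 0.5). Rules whose mean firing over
#' an epoch fell below `prune_threshold` are removed, but at least one
#' rule always remains.
#'
#' @param model An `rfnn`.
#' @param x Optional input vector in original units; triggers the
#'   add-rule check.
#' @param firing_mean Optional per-rule mean firing strengths over an
#'   epoch; triggers pruning.
#' @param add_threshold,prune_threshold Override the model config's
#'   thresholds.
#' @return The (possibly) modified model.
#' @export
structure_adapt <- function(model, x = NULL, firing_mean = NULL,
                            add_threshold = model$config$add_threshold,
                            prune_threshold = model$config$prune_threshold) {
  if (!is.null(firing_mean)) {
    keep <- firing_mean >= prune_threshold
    if (!any(keep)) keep[which.max(firing_mean)] <- TRUE
    if (!all(keep)) {
      model$m <- model$m[, keep, drop = FALSE]
      model$sigma <- model$sigma[, keep, drop = FALSE]
      model$lambda <- model$lambda[keep]
      model$w <- model$w[keep, , drop = FALSE]
      model$n_rules <- sum(keep)
    }
  }
  if (!is.null(x)) {
    xn <- as.numeric(norm_apply(matrix(as.numeric(x), 1L), model$norm_x))
    s <- rule_strength(fuzzify(xn, model))
    if (max(s) < add_threshold) {
      jn <- which.max(s)
      diff <- abs(xn - model$m[, jn])
      sigma_new <- pmax(diff, apply(model$sigma, 1, median),
                        model$config$sigma_min)
      w_new <- if (sum(s) > 1e-12) defuzzify(s, model$w) else colMeans(model$w)
      model$m <- cbind(model$m, xn)
      model$sigma <- cbind(model$sigma, sigma_new)
      model$lambda <- c(model$lambda, 0.5)
      model$w <- rbind(model$w, w_new)
      model$n_rules <- model$n_rules + 1L
      dimnames(model$m) <- dimnames(model$sigma) <- NULL
      dimnames(model$w) <- NULL
    }
  }
  model
}

#' Fit the recurrent fuzzy network
#'
#' Initialises the rule base by clustering, then runs sequential
#' per-sample gradient descent: each epoch visits every training sequence
#' in order, resetting the recurrent state at each sequence start, and
#' updates all four parameter groups after every sample. After each epoch
#' rules with negligible mean firing are pruned and, if some sample was
#' covered by no rule (best firing below the add threshold), one rule is
#' added there. Training stops after `cfg$epochs` epochs or when the
#' epoch loss stops improving by more than `cfg$tol`.
#'
#' @param X Inputs: a T x p matrix/tibble or a list of per-sequence
#'   matrices (original units).
#' @param Y Targets, same shape convention as `X`.
#' @param cfg An [rfnn_config()].
#' @return A fitted `rfnn`; `$history` holds the per-epoch mean loss
#'   (normalized units).
#' @export
rfnn_fit <- function(X, Y, cfg = rfnn_config()) {
  Xs <- as_sequence_list(X)
  Ys <- as_sequence_list(Y)
  model <- structure_init(Xs, Ys, cfg)
  Xn <- lapply(Xs, norm_apply, nrm = model$norm_x)
  Yn <- lapply(Ys, norm_apply, nrm = model$norm_y)
  history <- numeric(0)
  best_loss <- Inf
  best_params <- NULL
  stall <- 0L
  for (ep in seq_len(cfg$epochs)) {
    res <- rfnn_train_epoch_cpp(model$m, model$sigma, model$lambda, model$w,
                                Xn, Yn, cfg$eta_m, cfg$eta_sigma,
                                cfg$eta_lambda, cfg$eta_w, cfg$sigma_min)
    model$m <- res$m
    model$sigma <- res$sig
    model$lambda <- res$lam
    model$w <- res$w
    model$n_rules <- ncol(model$m)
    history <- c(history, res$loss)
    model <- structure_adapt(model, firing_mean = res$firing_mean)
    if (is.finite(res$worst_fire) &&
        res$worst_fire < cfg$add_threshold) {
      xraw <- norm_invert(matrix(res$worst_x, 1L), model$norm_x)
      model <- structure_adapt(model, x = as.numeric(xraw))
    }
    if (res$loss < best_loss - cfg$tol) {
      best_loss <- res$loss
      best_params <- model[c("m", "sigma", "lambda", "w", "n_rules")]
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  # keep the best-loss parameters seen (per-sample SGD can oscillate)
  if (!is.null(best_params)) model[names(best_params)] <- best_params
  model$history <- history
  model
}

#' Predict from a fitted RFNN
#'
#' @param object A fitted `rfnn`.
#' @param newdata T x `n_inputs` matrix or data frame.
#' @param ... Unused.
#' @return Tibble of predictions, one column per output.
#' @export
predict.rfnn <- function(object, newdata, ...) {
  Y <- forward_sequence(object, newdata)
  colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  tibble::as_tibble(Y)
}

#' @export
print.rfnn <- function(x, ...) {
  cat(sprintf(
    "<rfnn> %d inputs -> %d rules -> %d outputs; %d training epochs, final loss %.3g\n",
    x$n_inputs, x$n_rules, x$n_outputs, length(x$history),
    if (length(x$history)) tail(x$history, 1) else NA_real_
  ))
  invisible(x)
}

#' Tidy a fitted RFNN
#'
#' One row per fuzzy rule: the recurrent ratio, the mean center and width
#' across inputs, and the (normalized) output weights.
#'
#' @param x A fitted `rfnn`.
#' @param ... Unused.
#' @return A tibble with one row per rule.
#' @export
tidy.rfnn <- function(x, ...) {
  w <- x$w
  colnames(w) <- paste0("weight_y", seq_len(ncol(w)))
  dplyr::bind_cols(
    tibble::tibble(
      rule = seq_len(x$n_rules),
      lambda = as.numeric(x$lambda),
      center_mean = colMeans(x$m),
      width_mean = colMeans(x$sigma)
    ),
    tibble::as_tibble(w)
  )
}

#' One-row summary of a fitted RFNN
#'
#' @param x A fitted `rfnn`.
#' @param ... Unused.
#' @return A one-row tibble: rule/input/output counts, epochs run and
#'   final training loss.
#' @export
glance.rfnn <- function(x, ...) {
  tibble::tibble(
    n_inputs = x$n_inputs,
    n_rules = x$n_rules,
    n_outputs = x$n_outputs,
    epochs = length(x$history),
    final_loss = if (length(x$history)) tail(x$history, 1) else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
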