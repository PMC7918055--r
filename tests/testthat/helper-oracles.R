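# Independent scalar-loop oracles used to cross-check the vectorized and
# compiled implementations, plus small fixtures cached across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

quick_recording <- function() {
  fixture("quick_rec",
          simulate_recording(task_profile("Task_1"), "quick", seed = 101L))
}

slow_recording <- function() {
  fixture("slow_rec",
          simulate_recording(task_profile("Task_2"), "slow", seed = 202L))
}

quick_processed <- function() {
  fixture("quick_proc", preprocess_recording(quick_recording()))
}

slow_processed <- function() {
  fixture("slow_proc", preprocess_recording(slow_recording()))
}

quick_segments <- function() {
  fixture("quick_segs", segment_cycles(quick_processed()))
}

# Reduced-scale synthetic experiment (3 trials per condition) shared by
# the end-to-end acceptance checks.
reduced_experiment <- function() {
  fixture("reduced_exp", generate_experiment(
    experiment_config(trials_per_condition = 3L, seed = 11L)
  ))
}

# A small random network with identity normalizers so oracle arithmetic
# happens in the same units as the model's.
test_model <- function(seed, I = 3L, R = 4L, O = 2L, lambda = NULL) {
  set.seed(seed)
  m <- matrix(runif(I * R), I, R)
  sigma <- matrix(runif(I * R, 0.2, 0.8), I, R)
  if (is.null(lambda)) lambda <- runif(R)
  w <- matrix(runif(R * O), R, O)
  unit <- function(k) list(min = rep(0, k), max = rep(1, k))
  emgdecode:::new_rfnn(m, sigma, lambda, w, unit(I), unit(O), rfnn_config())
}

# One fully scalar network step: explicit loops over rules, inputs and
# outputs, no vectorization shared with the implementation.
oracle_step <- function(m, sigma, lambda, w, x, u_prev) {
  I <- nrow(m); R <- ncol(m); O <- ncol(w)
  s <- numeric(R)
  for (j in seq_len(R)) {
    p <- 1
    for (i in seq_len(I)) {
      p <- p * exp(-((x[i] - m[i, j])^2) / sigma[i, j]^2)
    }
    s[j] <- p
  }
  u <- numeric(R)
  for (j in seq_len(R)) u[j] <- lambda[j] * s[j] + (1 - lambda[j]) * u_prev[j]
  y <- numeric(O)
  den <- sum(u)
  for (o in seq_len(O)) {
    num <- 0
    for (j in seq_len(R)) num <- num + u[j] * w[j, o]
    y[o] <- num / den
  }
  list(s = s, u = u, y = y)
}

# Four-nested-loop forward pass over a whole sequence (time, rule, input,
# output), in normalized units.
oracle_forward <- function(model, X, u0 = rep(0, model$n_rules)) {
  Y <- matrix(0, nrow(X), model$n_outputs)
  u_prev <- u0
  for (t in seq_len(nrow(X))) {
    st <- oracle_step(model$m, model$sigma, model$lambda, model$w,
                      X[t, ], u_prev)
    Y[t, ] <- st$y
    u_prev <- st$u
  }
  Y
}

# Squared-error cost of one step with the previous state held constant.
oracle_cost <- function(m, sigma, lambda, w, x, u_prev, y_target) {
  st <- oracle_step(m, sigma, lambda, w, x, u_prev)
  0.5 * sum((st$y - y_target)^2)
}

# Central finite differences of the one-step cost for every parameter.
fd_gradients <- function(m, sigma, lambda, w, x, u_prev, y_target,
                         h = 1e-5) {
  params <- list(m = m, sigma = sigma, lambda = lambda, w = w)
  fd_block <- function(name) {
    block <- params[[name]]
    g <- block
    for (k in seq_along(block)) {
      up <- params; up[[name]][k] <- up[[name]][k] + h
      dn <- params; dn[[name]][k] <- dn[[name]][k] - h
      e_up <- oracle_cost(up$m, up$sigma, up$lambda, up$w, x, u_prev, y_target)
      e_dn <- oracle_cost(dn$m, dn$sigma, dn$lambda, dn$w, x, u_prev, y_target)
      g[k] <- (e_up - e_dn) / (2 * h)
    }
    g
  }
  list(gm = fd_block("m"), gsig = fd_block("sigma"),
       glam = fd_block("lambda"), gw = fd_block("w"))
}

# Largest elementwise discrepancy relative to the block's gradient scale.
max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-8)
}

# Causal direct-form difference-equation filter, written independently.
oracle_df_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  y <- numeric(length(x))
  for (t in seq_along(x)) {
    acc <- 0
    for (k in seq_along(b)) {
      if (t - k + 1L >= 1L) acc <- acc + b[k] * x[t - k + 1L]
    }
    if (length(a) >= 2L) {
      for (k in 2:length(a)) {
        if (t - k + 1L >= 1L) acc <- acc - a[k] * y[t - k + 1L]
      }
    }
    y[t] <- acc
  }
  y
}

# Brute-force reflected-edge running median.
oracle_despike <- function(x, kernel) {
  h <- kernel %/% 2L
  n <- length(x)
  padded <- c(x[pmin(1L + (h:1), n)], x, x[pmax(n - (1:h), 1L)])
  vapply(seq_len(n), function(i) median(padded[i:(i + 2L * h)]), numeric(1))
}

# First-order teacher system: a smoothed random input drives
# y(t) = 0.8 y(t-1) + 0.2 x(t), which the recurrent rule layer can
# represent.
teacher_sequence <- function(seed, len = 300L) {
  set.seed(seed)
  raw <- runif(len + 24L)
  x <- as.numeric(stats::filter(raw, rep(1 / 25, 25L), sides = 1L))
  x <- x[25:(len + 24L)]
  y <- numeric(len)
  prev <- 0.5
  for (t in seq_len(len)) {
    prev <- 0.8 * prev + 0.2 * x[t]
    y[t] <- prev
  }
  list(X = matrix(x, ncol = 1L), Y = matrix(y, ncol = 1L))
}
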