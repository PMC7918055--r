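test_that("fuzzification matches the Gaussian closed form", {
  model <- test_model(31)
  # at the center the membership peaks at 1
  expect_equal(unname(fuzzify(model$m[, 3], model)[, 3]),
               rep(1, model$n_inputs))
  # one width away it is exactly e^-1
  a <- fuzzify(model$m[, 2] + model$sigma[, 2], model)
  expect_equal(unname(a[, 2]), rep(exp(-1), model$n_inputs),
               tolerance = 1e-15)
  set.seed(32)
  x <- runif(model$n_inputs)
  a <- fuzzify(x, model)
  expect_true(all(a > 0 & a <= 1))
  # element-wise scalar-loop oracle
  for (i in seq_len(model$n_inputs)) {
    for (j in seq_len(model$n_rules)) {
      expect_equal(a[i, j],
                   exp(-((x[i] - model$m[i, j])^2) / model$sigma[i, j]^2),
                   tolerance = 1e-15)
    }
  }
  expect_error(fuzzify(c(1, 2), model), class = "emgdecode_dim_error")
})

test_that("rule strength is the product AND over inputs", {
  expect_equal(rule_strength(matrix(1, 4, 3)), rep(1, 3))
  expect_equal(rule_strength(matrix(0.5, 2, 1)), 0.25)
  set.seed(33)
  a <- matrix(runif(12, 0.1, 1), 3, 4)
  s <- rule_strength(a)
  a2 <- a
  a2[2, 3] <- a2[2, 3] / 2
  expect_lte(rule_strength(a2)[3], s[3])
  expect_equal(rule_strength(a2)[-3], s[-3])
})

test_that("the recurrent update blends current and past state", {
  s <- c(0.4, 0.9)
  u_prev <- c(0.8, 0.1)
  expect_equal(recurrent_update(s, u_prev, c(1, 1)), s)
  expect_equal(recurrent_update(s, u_prev, c(0, 0)), u_prev)
  expect_equal(recurrent_update(0.4, 0.8, 0.5), 0.6)
  expect_error(recurrent_update(s, u_prev, c(1.2, 0.5)),
               class = "emgdecode_lambda_error")
})

test_that("defuzzification is a convex combination of rule weights", {
  w <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2)
  expect_equal(defuzzify(rep(0.2, 3), w), c(2, 20))
  expect_equal(defuzzify(c(0, 1, 0), w), w[2, ])
  set.seed(34)
  for (i in 1:10) {
    u <- runif(3)
    y <- defuzzify(u, w)
    expect_true(all(y >= apply(w, 2, min) - 1e-12))
    expect_true(all(y <= apply(w, 2, max) + 1e-12))
  }
  expect_error(defuzzify(rep(0, 3), w),
               class = "emgdecode_activation_error")
})

test_that("forward pass matches the scalar four-nested-loop oracle", {
  for (seed in 1:3) {
    model <- test_model(seed * 10, I = 2L + seed, R = 3L + seed, O = seed)
    set.seed(seed * 10 + 1)
    X <- matrix(runif(30 * model$n_inputs), 30)
    Y <- forward_sequence(model, X, denormalize = FALSE)
    expect_lt(max(abs(Y - oracle_forward(model, X))), 1e-12)
  }
})

test_that("with lambda = 1 the network is memoryless", {
  model <- test_model(35, lambda = rep(1, 4))
  set.seed(36)
  X <- matrix(runif(20 * model$n_inputs), 20)
  perm <- sample(nrow(X))
  Y <- forward_sequence(model, X, denormalize = FALSE)
  Yp <- forward_sequence(model, X[perm, ], denormalize = FALSE)
  expect_equal(Yp[seq_len(nrow(X)), , drop = FALSE],
               Y[perm, , drop = FALSE], tolerance = 1e-14)
})

test_that("a repeated constant input converges to the memoryless output", {
  set.seed(37)
  lam <- runif(4, 0.2, 0.9)
  model <- test_model(37, lambda = lam)
  model_memoryless <- model
  model_memoryless$lambda <- rep(1, 4)
  x <- runif(model$n_inputs)
  X <- matrix(x, 400, model$n_inputs, byrow = TRUE)
  y_end <- forward_sequence(model, X, denormalize = FALSE)[400, ]
  y_star <- forward_sequence(model_memoryless, X[1, , drop = FALSE],
                             denormalize = FALSE)[1, ]
  expect_equal(y_end, y_star, tolerance = 1e-8)
})

test_that("gradients vanish at the cost minimum and descend otherwise", {
  model <- test_model(38)
  set.seed(39)
  x <- runif(model$n_inputs)
  u_prev <- runif(model$n_rules)
  # read the network's own prediction so the target sits exactly at the
  # cost minimum
  y_hat <- rfnn_gradients(model, x, u_prev,
                          rep(0, model$n_outputs))$y
  g0 <- rfnn_gradients(model, x, u_prev, y_hat)
  expect_equal(max(abs(g0$gm)), 0)
  expect_equal(max(abs(g0$gsig)), 0)
  expect_equal(max(abs(g0$glam)), 0)
  expect_equal(max(abs(g0$gw)), 0)
  stepped <- grad_step(model, x, u_prev, y_hat)
  expect_identical(stepped$model$m, model$m)
  expect_identical(stepped$model$w, model$w)
  # away from the minimum, a small step does not increase the cost
  y_target <- y_hat + 0.3
  small <- rfnn_config(eta_m = 1e-3, eta_sigma = 1e-3, eta_lambda = 1e-3,
                       eta_w = 1e-3)
  e_before <- oracle_cost(model$m, model$sigma, model$lambda, model$w,
                          x, u_prev, y_target)
  upd <- grad_step(model, x, u_prev, y_target, small)$model
  e_after <- oracle_cost(upd$m, upd$sigma, upd$lambda, upd$w,
                         x, u_prev, y_target)
  expect_lte(e_after, e_before)
})

test_that("analytic gradients match central finite differences", {
  for (case in 1:20) {
    set.seed(1000 + case)
    I <- sample(2:4, 1)
    R <- sample(2:5, 1)
    O <- sample(1:3, 1)
    m <- matrix(runif(I * R), I, R)
    sigma <- matrix(runif(I * R, 0.2, 0.8), I, R)
    lambda <- runif(R, 0.05, 0.95)
    w <- matrix(runif(R * O), R, O)
    unit <- function(k) list(min = rep(0, k), max = rep(1, k))
    model <- emgdecode:::new_rfnn(m, sigma, lambda, w, unit(I), unit(O),
                                  rfnn_config())
    x <- runif(I)
    u_prev <- runif(R, 0.05, 1)
    y_target <- runif(O)
    g <- rfnn_gradients(model, x, u_prev, y_target)
    f <- fd_gradients(m, sigma, lambda, w, x, u_prev, y_target)
    expect_lt(max_rel_err(g$gm, f$gm), 1e-5)
    expect_lt(max_rel_err(g$gsig, f$gsig), 1e-5)
    expect_lt(max_rel_err(g$glam, f$glam), 1e-5)
    expect_lt(max_rel_err(g$gw, f$gw), 1e-5)
    expect_equal(g$E, oracle_cost(m, sigma, lambda, w, x, u_prev, y_target),
                 tolerance = 1e-12)
  }
})

test_that("structure_init places rules at cluster structure", {
  set.seed(41)
  X <- rbind(matrix(rnorm(120, mean = 0, sd = 0.3), 60, 2),
             matrix(rnorm(120, mean = 5, sd = 0.3), 60, 2))
  Y <- cbind(c(rep(0, 60), rep(1, 60)))
  model <- structure_init(X, Y, rfnn_config(n_rules = 2L, seed = 7L))
  Xn <- emgdecode:::norm_apply(X, model$norm_x)
  blob_means <- rbind(colMeans(Xn[1:60, ]), colMeans(Xn[61:120, ]))
  centers <- t(model$m)
  ord <- order(centers[, 1])
  expect_lt(max(abs(centers[ord, ] - blob_means[order(blob_means[, 1]), ])),
            0.05)
  expect_true(all(model$sigma >= model$config$sigma_min))
  expect_equal(model$lambda, rep(0.5, 2))
})

test_that("structure_init with one rule uses global means", {
  set.seed(42)
  X <- matrix(runif(60), 20, 3)
  Y <- matrix(runif(40), 20, 2)
  model <- structure_init(X, Y, rfnn_config(n_rules = 1L))
  Xn <- emgdecode:::norm_apply(X, model$norm_x)
  Yn <- emgdecode:::norm_apply(Y, model$norm_y)
  expect_equal(as.numeric(model$m), colMeans(Xn))
  expect_equal(as.numeric(model$w), colMeans(Yn))
  expect_error(structure_init(X, Y, rfnn_config(n_rules = 21L)),
               class = "emgdecode_config_error")
})

test_that("structure_adapt adds uncovered rules and prunes silent ones", {
  model <- test_model(43)
  R <- model$n_rules
  # an input far from every center triggers the add branch
  grown <- structure_adapt(model, x = rep(5, model$n_inputs))
  expect_identical(grown$n_rules, R + 1L)
  expect_identical(ncol(grown$m), R + 1L)
  # an input at an existing center changes nothing
  same <- structure_adapt(model, x = model$m[, 1])
  expect_identical(same$n_rules, R)
  # a rule that never fired during an epoch is pruned
  pruned <- structure_adapt(model, firing_mean = c(0, rep(0.5, R - 1L)))
  expect_identical(pruned$n_rules, R - 1L)
  # but at least one rule always survives
  floor1 <- structure_adapt(model, firing_mean = rep(0, R))
  expect_identical(floor1$n_rules, 1L)
})

test_that("fitting a constant target converges to the constant", {
  set.seed(44)
  X <- matrix(runif(200), 100, 2)
  Y <- matrix(3.5, 100, 1)
  model <- rfnn_fit(X, Y, rfnn_config(n_rules = 4L, epochs = 20L))
  expect_lt(tail(model$history, 1), 1e-3)
  pred <- forward_sequence(model, X)
  expect_lt(max(abs(pred - 3.5)), 0.05)
})

test_that("fitting is deterministic for a fixed seed", {
  set.seed(45)
  X <- matrix(runif(300), 100, 3)
  Y <- matrix(rowSums(X) + 0.1 * runif(100), 100, 1)
  cfg <- rfnn_config(n_rules = 5L, epochs = 10L, seed = 9L)
  a <- rfnn_fit(X, Y, cfg)
  b <- rfnn_fit(X, Y, cfg)
  expect_identical(a$m, b$m)
  expect_identical(a$sigma, b$sigma)
  expect_identical(a$lambda, b$lambda)
  expect_identical(a$w, b$w)
  expect_identical(a$history, b$history)
  # constraints hold after training
  expect_true(all(a$sigma >= cfg$sigma_min))
  expect_true(all(a$lambda >= 0 & a$lambda <= 1))
})

test_that("tidy and glance summarise a fitted network", {
  set.seed(46)
  X <- matrix(runif(200), 100, 2)
  Y <- matrix(X[, 1] - X[, 2], 100, 1)
  model <- rfnn_fit(X, Y, rfnn_config(n_rules = 4L, epochs = 5L))
  td <- tidy(model)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), model$n_rules)
  expect_true(all(c("rule", "lambda", "center_mean", "width_mean",
                    "weight_y1") %in% names(td)))
  gl <- glance(model)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_rules, model$n_rules)
  pred <- predict(model, X)
  expect_s3_class(pred, "tbl_df")
  expect_identical(dim(pred), c(100L, 1L))
})

test_that("learning configuration is validated", {
  expect_error(rfnn_config(eta_m = 0), class = "emgdecode_config_error")
  expect_error(rfnn_config(add_threshold = 1.5),
               class = "emgdecode_config_error")
  expect_error(rfnn_config(prune_threshold = 0),
               class = "emgdecode_config_error")
})
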