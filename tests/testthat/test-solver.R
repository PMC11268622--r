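toy_problem <- function() {
  ## D = identity (length-1 psf), y = (1, 0) as a 1 x 2 image
  restoration_problem(matrix(c(1, 0), 1, 2), psf = make_motion_psf(1, 0))
}

test_that("one step from x0 = y matches the hand-computed closed form", {
  pr <- toy_problem()
  cfg <- solver_config(step_size = 0.5, reg_weight = 0.2, max_iters = 10)
  ## grad f(y) = y - y = 0; w = soft(y, 0.1) = (0.9, 0)
  ## x1 = w - 0.5 (grad f(w) - 0) = w - 0.5 (w - y) = (0.95, 0)
  st <- tseng_step(matrix(c(1, 0), 1, 2), pr, cfg)
  expect_equal(st$w, matrix(c(0.9, 0), 1, 2), tolerance = 1e-12)
  expect_equal(st$x_next, matrix(c(0.95, 0), 1, 2), tolerance = 1e-12)
  ## and one more hand step from x1:
  ## grad = (-0.05, 0); w = soft((0.975, 0), 0.1) = (0.875, 0)
  ## x2 = w - 0.5 ((w - y) - (x1 - y)) = w - 0.5 (w - x1) = (0.9125, 0)
  st2 <- tseng_step(st$x_next, pr, cfg)
  expect_equal(st2$w, matrix(c(0.875, 0), 1, 2), tolerance = 1e-12)
  expect_equal(st2$x_next, matrix(c(0.9125, 0), 1, 2), tolerance = 1e-12)
})

test_that("a fixed point of the iteration is preserved", {
  pr <- toy_problem()
  cfg <- solver_config(step_size = 0.5, reg_weight = 0.2, max_iters = 5000,
                       rel_tol = 1e-14)
  fit <- tseng_solve(pr, cfg)
  st <- tseng_step(fit$restored, pr, cfg)
  expect_lt(max(abs(st$x_next - fit$restored)), 1e-12)
})

test_that("a vanishing step size freezes the iterate", {
  pr <- toy_problem()
  x <- matrix(c(0.7, -0.2), 1, 2)
  st <- tseng_step(x, pr, solver_config(step_size = 1e-15, reg_weight = 0.3))
  expect_lt(max(abs(st$w - x)), 1e-12)
  expect_lt(max(abs(st$x_next - x)), 1e-12)
})

test_that("an already-optimal start returns immediately", {
  clean <- generate_phantom(phantom_spec(size = 16, kind = "chest"))
  obs <- degrade(clean, degradation_spec(psf_length = 1, psf_angle = 0,
                                         noise_family = "none"))
  fit <- tseng_solve(restoration_problem(obs),
                     solver_config(reg_weight = 0, rel_tol = 0))
  expect_identical(fit$restored, clean)
  expect_identical(fit$iterations, 1L)
  expect_true(fit$converged)
})

test_that("the solver reaches the ISTA reference objective", {
  set.seed(41)
  clean <- rand_image(8)
  p <- make_motion_psf(3, 45)
  y <- apply_blur(clean, p) + matrix(rnorm(64, 0, 0.03), 8)
  mu <- 0.05
  ref <- ista_reference(p$kernel, y, mu, iters = 5e4)
  pr <- restoration_problem(y, psf = p)
  fit <- tseng_solve(pr, solver_config(step_size = 0.9, reg_weight = mu,
                                       max_iters = 20000, rel_tol = 1e-12))
  expect_lt(abs(fit$trace$objective[fit$iterations] - ref$objective) /
            ref$objective, 1e-4)
})

test_that("converged solutions satisfy the proximal fixed-point optimality condition", {
  set.seed(42)
  clean <- rand_image(12)
  p <- make_motion_psf(4, 30)
  y <- apply_blur(clean, p) + matrix(rnorm(144, 0, 0.02), 12)
  mu <- 0.03
  pr <- restoration_problem(y, psf = p)
  cfg <- solver_config(step_size = 0.9, reg_weight = mu, max_iters = 60000,
                       rel_tol = 1e-10)
  fit <- tseng_solve(pr, cfg)
  x <- fit$restored
  resid <- x - prox_l1(x - cfg$step_size * grad_f(x, pr),
                       cfg$step_size * mu)
  expect_lt(sqrt(sum(resid^2)), 1e-6)
})

test_that("iterates approach the reference minimiser monotonically", {
  set.seed(43)
  clean <- rand_image(8)
  p <- make_motion_psf(3, 135)
  y <- apply_blur(clean, p) + matrix(rnorm(64, 0, 0.02), 8)
  mu <- 0.04
  ref <- ista_reference(p$kernel, y, mu, iters = 1e5)
  fit <- tseng_solve(restoration_problem(y, psf = p),
                     solver_config(step_size = 0.9, reg_weight = mu,
                                   max_iters = 300, rel_tol = 0,
                                   keep_iterates = TRUE))
  d <- vapply(fit$trace$iterates,
              function(xk) sqrt(sum((xk - ref$x)^2)), numeric(1))
  d <- c(sqrt(sum((y - ref$x)^2)), d)
  expect_true(all(diff(d) <= 1e-12))
})

test_that("the trace is internally consistent", {
  clean <- generate_phantom(phantom_spec(size = 16, kind = "chest"))
  obs <- degrade(clean, degradation_spec(psf_length = 4, psf_angle = 60,
                                         noise_level = 1e-4, seed = 2))
  fit <- tseng_solve(restoration_problem(obs),
                     solver_config(step_size = 0.9, reg_weight = 0.01,
                                   max_iters = 3000, rel_tol = 1e-5,
                                   trace_metrics = TRUE))
  tr <- fit$trace
  expect_length(tr$objective, tr$iterations_run)
  expect_length(tr$step_norm, tr$iterations_run)
  expect_true(all(tr$step_norm >= 0))
  expect_length(tr$ssim, tr$iterations_run)
  ## step norms fall below the relative tolerance before the iteration cap
  expect_true(fit$converged)
  expect_lt(fit$iterations, 3000)
})

test_that("the solver is deterministic", {
  clean <- generate_phantom(phantom_spec(size = 16, kind = "chest"))
  obs <- degrade(clean, degradation_spec(psf_length = 5, psf_angle = 30,
                                         seed = 8))
  pr <- restoration_problem(obs)
  cfg <- solver_config(max_iters = 40)
  f1 <- tseng_solve(pr, cfg)
  f2 <- tseng_solve(pr, cfg)
  expect_identical(f1$restored, f2$restored)
  expect_identical(f1$trace$objective, f2$trace$objective)
})

test_that("a step size violating lambda * L < 1 is rejected", {
  pr <- toy_problem()   # identity operator, L = 1
  expect_error(tseng_solve(pr, solver_config(step_size = 1.5)),
               "convergence condition")
})

test_that("solver and restoration methods expose the fit", {
  clean <- generate_phantom(phantom_spec(size = 16, kind = "chest"))
  obs <- degrade(clean, degradation_spec(psf_length = 4, psf_angle = 45,
                                         noise_level = 1e-4, seed = 4))
  fit <- tseng_restore(obs, step_size = 0.9, reg_weight = 0.01,
                       max_iters = 60)
  expect_s3_class(fit, "tseng_restoration")
  expect_identical(fitted(fit), fit$restored)
  r <- residuals(fit)
  expect_identical(dim(r), dim(clean))
  ## data-fit residual should be far smaller than the blur-induced one
  expect_lt(sqrt(sum(r^2)), sqrt(sum((obs$observed - clean)^2)))
  s <- summary(fit)
  expect_s3_class(s, "summary.tseng_restoration")
  expect_output(print(fit), "Tseng")
  expect_output(print(s), "SSIM")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
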