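# shared small fitting problem: endpoint data from the default base
# model, only alpha free, coarse inference grid for speed
make_alpha_problem <- function(n_embryos = 5, noise = "none") {
  truth <- std_base()
  data <- generate_dataset(synthetic_spec(truth, n_embryos = n_embryos,
                                          sampling = "endpoint",
                                          noise = noise, seed = 17))
  fixed <- list(beta = truth$beta, rho = truth$rho, zeta = truth$zeta,
                l = truth$l, eta = truth$eta, m = truth$m)
  list(truth = truth, data = data,
       model = base_model_simulator(fixed = fixed, dt = 1),
       priors = prior_spec(alpha = prior_uniform(0.01, 0.15)))
}

test_that("a huge epsilon accepts essentially every proposal", {
  prob <- make_alpha_problem()
  post <- abc_mcmc(prob$model, prob$data, prob$priors,
                   abc_config(epsilon = 1e12, n_iterations = 200,
                              seed = 1))
  expect_gt(post$acceptance_rate, 0.8) # only out-of-support moves fail
  expect_equal(post$n_proposed, 200)
  rej <- rejection_abc(prob$model, prob$data, prob$priors,
                       epsilon = 1e12, target_acceptances = 50, seed = 1)
  expect_equal(rej$n_proposed, 50)
})

test_that("the chain never leaves the prior support", {
  prob <- make_alpha_problem()
  priors <- prior_spec(alpha = prior_uniform(0.05, 0.07))
  post <- abc_mcmc(prob$model, prob$data, priors,
                   abc_config(epsilon = 1e12, n_iterations = 300,
                              seed = 2))
  expect_true(all(post$accepted$alpha >= 0.05 &
                    post$accepted$alpha <= 0.07))
})

test_that("ABC runs are reproducible count-for-count under a seed", {
  prob <- make_alpha_problem(noise = "multinomial")
  cfg <- abc_config(epsilon = 5000, n_iterations = 150, seed = 5)
  a <- abc_mcmc(prob$model, prob$data, prob$priors, cfg)
  b <- abc_mcmc(prob$model, prob$data, prob$priors, cfg)
  expect_identical(a$accepted, b$accepted)
  expect_identical(a$n_accepted_moves, b$n_accepted_moves)
  r1 <- rejection_abc(prob$model, prob$data, prob$priors, epsilon = 5000,
                      target_acceptances = 20, seed = 9)
  r2 <- rejection_abc(prob$model, prob$data, prob$priors, epsilon = 5000,
                      target_acceptances = 20, seed = 9)
  expect_identical(r1$accepted, r2$accepted)
  expect_identical(r1$n_proposed, r2$n_proposed)
})

test_that("acceptance rate is non-decreasing in epsilon", {
  prob <- make_alpha_problem(noise = "multinomial")
  rates <- vapply(c(2000, 10000, 1e12), function(eps)
    rejection_abc(prob$model, prob$data, prob$priors, epsilon = eps,
                  target_acceptances = 15, max_proposals = 5e4,
                  seed = 3)$acceptance_rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("an unreachable epsilon reports the minimum S seen", {
  prob <- make_alpha_problem()
  expect_error(
    abc_mcmc(prob$model, prob$data, prob$priors,
             abc_config(epsilon = 1e-8, n_iterations = 10, seed = 1,
                        init_budget = 30)),
    "minimum S")
  expect_error(
    rejection_abc(prob$model, prob$data, prob$priors, epsilon = 1e-8,
                  target_acceptances = 5, max_proposals = 30, seed = 1),
    "minimum S")
})

test_that("noise-free recovery: posterior median approaches the truth", {
  prob <- make_alpha_problem()
  cal <- calibrate_epsilon(prob$model, prob$data, prob$priors,
                           n_pilot = 150, quantile = 0.05, seed = 4)
  post <- abc_mcmc(prob$model, prob$data, prob$priors,
                   abc_config(epsilon = cal$epsilon, n_iterations = 500,
                              seed = 4))
  med <- posterior_median_params(post)
  expect_lt(abs(med[["alpha"]] - prob$truth$alpha),
            0.15 * prob$truth$alpha)
})

test_that("the better-fitting model wins the acceptance-rate contest", {
  prob <- make_alpha_problem(noise = "multinomial")
  # competitor lacking both specification feedbacks cannot populate P/E
  bad_fixed <- list(beta = 0.3, rho = 0.35, zeta = 0, l = 0L,
                    eta = 0, m = 0L)
  bad_model <- base_model_simulator(fixed = bad_fixed, dt = 1)
  cal <- calibrate_epsilon(prob$model, prob$data, prob$priors,
                           n_pilot = 100, quantile = 0.15, seed = 6)
  good <- rejection_abc(prob$model, prob$data, prob$priors,
                        epsilon = cal$epsilon, target_acceptances = 15,
                        max_proposals = 2e4, seed = 6)
  expect_gt(good$acceptance_rate, 0.01)
  # without the specification feedbacks the model cannot populate the
  # PrE/EPI compartments: at this threshold it is either never accepted
  # (budget error reporting its distance floor) or vastly out-accepted
  bad <- tryCatch(
    rejection_abc(bad_model, prob$data, prob$priors,
                  epsilon = cal$epsilon, target_acceptances = 15,
                  max_proposals = 2e4, seed = 6),
    error = function(e) e)
  if (inherits(bad, "error")) {
    expect_match(conditionMessage(bad), "minimum S")
  } else {
    bf <- bayes_factor(good, bad, "with feedback", "no feedback")
    expect_gt(bf$bayes_factor, 3)
  }
})

test_that("posterior point estimates: medians and discrete modes", {
  priors <- prior_spec(alpha = prior_uniform(0, 1), l = prior_discrete())
  mk <- function(df) structure(list(accepted = df, priors = priors,
                                    n_proposed = nrow(df),
                                    n_accepted_moves = nrow(df),
                                    acceptance_rate = 1, epsilon = 1,
                                    min_S = 0, method = "rejection_abc"),
                               class = "posterior_sample")
  one <- mk(data.frame(alpha = 0.07, l = 2, S = 0))
  expect_equal(posterior_median_params(one), c(alpha = 0.07, l = 2))
  expect_equal(posterior_median_params(
    mk(data.frame(alpha = c(0.05, 0.06, 0.07), l = c(1, 2, 2),
                  S = 0)))[["alpha"]], 0.06)
  # tie on the discrete exponent breaks toward the larger value
  expect_equal(posterior_median_params(
    mk(data.frame(alpha = 0.05, l = c(0, 0, 2, 2), S = 0)))[["l"]], 2)
  expect_error(posterior_median_params(mk(data.frame())), "empty")
})

test_that("Bayes-factor arithmetic reproduces published bookkeeping", {
  base_cmp <- bayes_factor(posterior_counts(500, 6289, 17300),
                           posterior_counts(500, 105027, 17300),
                           "PrE feedback", "no feedback")
  expect_equal(base_cmp$bayes_factor, 105027 / 6289, tolerance = 1e-12)
  expect_equal(round(base_cmp$bayes_factor), 17)
  expect_equal(base_cmp$evidence, "positive")
  chi_cmp <- bayes_factor(posterior_counts(500, 585, 117000),
                          posterior_counts(500, 26575, 117000),
                          "GFC", "FC")
  expect_equal(round(chi_cmp$bayes_factor), 45)
  expect_equal(chi_cmp$evidence, "strong")
  # identical bookkeeping: no evidence either way
  even <- bayes_factor(posterior_counts(100, 1000, 5),
                       posterior_counts(100, 1000, 5))
  expect_equal(even$bayes_factor, 1)
  expect_equal(even$evidence, "barely worth mentioning")
  expect_error(bayes_factor(posterior_counts(10, 100, 5),
                            posterior_counts(0, 100, 5)), "undefined")
  expect_error(bayes_factor(posterior_counts(10, 100, 5),
                            posterior_counts(10, 100, 6)),
               "common epsilon")
})
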