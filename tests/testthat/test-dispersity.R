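# Dispersity statistics (Ln, Lw, sigma, PDI) and Poisson fitting of label
# histograms.

test_that("dispersity summary matches hand-evaluated closed forms", {
  # monodisperse
  mono <- dispersity_summary(length_sample(rep(100, 7)))
  expect_equal(mono$Ln, 100)
  expect_equal(mono$Lw, 100)
  expect_equal(mono$sigma, 0)
  expect_equal(mono$PDI, 1)

  # hand evaluation of the four formulas on {100, 100, 200}
  s <- dispersity_summary(length_sample(c(100, 100, 200)))
  expect_equal(s$Ln, 400 / 3, tolerance = 1e-12)       # 133.33
  expect_equal(s$Lw, 150)                              # 60000 / 400
  expect_equal(s$sigma, sqrt(20000 / 9), tolerance = 1e-12)  # 47.14
  expect_equal(s$PDI, 1.125)
  expect_equal(s$N, 3)
})

test_that("multiplicities are honored (brute-force expansion oracle)", {
  withr::with_seed(5, {
    for (i in 1:25) {
      k <- sample(2:8, 1)
      vals <- stats::runif(k, 10, 400)
      mult <- sample(1:5, k, replace = TRUE)
      got <- dispersity_summary(length_sample(vals, mult))
      want <- oracle_dispersity(vals, mult)
      expect_equal(got$Ln, want$Ln)
      expect_equal(got$Lw, want$Lw)
      expect_equal(got$sigma, want$sigma)
      expect_equal(got$PDI, want$PDI)
      # Cauchy-Schwarz: Lw >= Ln, hence PDI >= 1
      expect_gte(got$PDI, 1)
    }
  })
})

test_that("length samples reject degenerate input", {
  expect_error(length_sample(numeric(0)), "empty")
  expect_error(length_sample(c(10, 0)), "> 0")
  expect_error(length_sample(c(10, -4)), "> 0")
  expect_error(dispersity_summary(length_sample(c(1, 2), c(1, -1))))
})

test_that("living PDI of detectable chains follows the truncated Poisson form", {
  # Lw/Ln over chains with >= 1 tile: (1 + mu)(1 - e^-mu)/mu. Zero
  # truncation makes the curve non-monotone below mu ~ 2 (short undetected
  # chains are censored), so strict decrease holds from ratio 2 on.
  ratios <- c(1, 2, 5, 10)
  pdis <- vapply(ratios, function(r) {
    pop <- simulate_living(r, n_initiators = 4000, seed = 100 + r)
    dispersity_summary(length_sample(pop$tiles[pop$tiles > 0]))$PDI
  }, 0)
  expect_equal(pdis, (1 + ratios) * (1 - exp(-ratios)) / ratios,
               tolerance = 0.03)
  expect_true(all(diff(pdis[-1]) < 0))
})

test_that("untruncated Poisson MLE is the weighted mean", {
  withr::with_seed(17, {
    x <- stats::rpois(10000, 2)
    fit <- fit_poisson(tabulate_labels(x, truncated = FALSE))
    expect_equal(fit$lambda_hat, mean(x))
    expect_equal(fit$lambda_hat, 2, tolerance = 0.05 / 2)
    expect_false(fit$truncated)
    expect_equal(fit$log_likelihood,
                 sum(stats::dpois(x, fit$lambda_hat, log = TRUE)))
  })
})

test_that("zero-truncated MLE solves the truncated likelihood equation", {
  withr::with_seed(23, {
    x <- rztpois(10000, 1)
    fit <- fit_poisson(tabulate_labels(x, truncated = TRUE))
    expect_true(fit$truncated)
    # self-consistency: lambda/(1 - exp(-lambda)) equals the sample mean
    expect_equal(fit$lambda_hat / (1 - exp(-fit$lambda_hat)), mean(x),
                 tolerance = 1e-7)
    expect_equal(fit$lambda_hat, 1, tolerance = 0.05)
  })
})

test_that("truncated-fit parameter recovery is unbiased across a grid", {
  withr::with_seed(29, {
    for (lambda in c(0.5, 2, 5)) {
      err <- vapply(c(200L, 20000L), function(n) {
        fit <- fit_poisson(tabulate_labels(rztpois(n, lambda),
                                           truncated = TRUE))
        abs(fit$lambda_hat - lambda) / lambda
      }, 0)
      expect_lt(err[2], 0.02)     # bias < 2% at large n
      expect_lt(err[2], err[1] + 0.02)  # error shrinking with n
    }
  })
})

test_that("Poisson-fit edge cases are reported, not silent", {
  # all mass at k = 1 under truncation: boundary, not convergence failure
  b <- fit_poisson(label_histogram(c(`1` = 1000), truncated = TRUE))
  expect_true(b$boundary)
  expect_equal(b$lambda_hat, 0)
  # all mass at zero is unidentifiable
  expect_error(fit_poisson(label_histogram(c(`0` = 50))), "k = 0")
  # truncated histograms must not contain a zero class
  expect_error(label_histogram(c(`0` = 5, `1` = 2), truncated = TRUE),
               "k = 0")
})

test_that("label counts follow Binomial(n_A, efficiency) with truncation", {
  pop <- tiny_pop(ratio = 2, n = 1000, seed = 3)
  comp <- chain_composition(pop)
  # full labeling: counts equal n_A exactly
  h <- label_counts(pop, 1, truncated = FALSE)
  expect_equal(sum(h$k * h$freq), sum(comp$n_A))
  expect_equal(sum(h$freq), 1000)
  # truncation drops the invisible zero-label chains
  ht <- label_counts(pop, 1, truncated = TRUE)
  expect_true(ht$truncated)
  expect_equal(sum(ht$freq), sum(comp$n_A > 0))
  # zero efficiency: empty truncated histogram surfaces downstream
  h0 <- label_counts(pop, 0, seed = 1, truncated = TRUE)
  expect_error(fit_poisson(h0), "no observations")
  # partial labeling preserves the Binomial mean
  hp <- label_counts(pop, 0.5, seed = 9, truncated = FALSE)
  expect_equal(sum(hp$k * hp$freq) / sum(hp$freq), 0.5 * mean(comp$n_A),
               tolerance = 0.1)
})
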