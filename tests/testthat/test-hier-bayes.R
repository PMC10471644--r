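# Small fits shared by several blocks.
tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sv <- small_survey()
      spec <- model_spec("y", "normal", categorical = "lake_type",
                         continuous = "latitude")
      resp <- generate_responses(
        sv, spec, list(mu0 = 3, tau2_0 = 0.01, sigma2_site = 0.01,
                       sigma2 = 0.02, beta_cont = c(latitude = 0)),
        seed = 2)
      dat <- ancova_data(sv, resp)
      cache <<- fit_ancova(spec, dat, n_iter = 800, n_chains = 2,
                           n_adapt = 400, burn_in = 300, thin = 2, seed = 31)
    }
    cache
  }
})

test_that("linear predictor matches an independent dot-product evaluation", {
  set.seed(14)
  sv <- small_survey()
  spec <- model_spec("y", "normal",
                     categorical = c("lake_type", "vegetation"),
                     continuous = c("latitude", "tp"))
  key <- paste(sv$lake_id, sv$site_id, sep = "::")
  lt_lv <- unique(sv$lake_type); veg_lv <- unique(sv$vegetation)
  state <- list(
    beta0_site = setNames(rnorm(nrow(sv)), key),
    beta1 = setNames(rnorm(length(lt_lv)), lt_lv),
    beta2 = setNames(rnorm(length(veg_lv)), veg_lv),
    beta_cont = list(latitude = rnorm(1), tp = rnorm(1)))
  eta <- linear_predictor(state, sv, spec)
  manual <- state$beta0_site[key] + state$beta1[sv$lake_type] +
    state$beta2[sv$vegetation] +
    state$beta_cont$latitude * log(sv$latitude) +
    state$beta_cont$tp * log(sv$tp)
  expect_equal(eta, unname(manual))

  # unknown categorical level
  sv2 <- as.data.frame(sv); sv2$lake_type[1] <- "T99"
  sv2 <- as_pufa_survey(sv2, attr(sv, "taxa"))
  expect_error(linear_predictor(state, sv2, spec), "T99")
})

test_that("log-likelihood reproduces closed forms and a density oracle", {
  one_site <- data.frame(lake_id = "L1", site_id = "s1", y = 0,
                         richness = 2)
  state <- list(beta0_site = c("L1::s1" = 0))

  spec_p <- model_spec("y", "poisson")
  expect_equal(log_likelihood(state, spec_p, one_site), -1)

  spec_b <- model_spec("y", "binomial", size = "richness")
  one_site$y <- 1
  expect_equal(log_likelihood(state, spec_b, one_site), log(0.5))

  # brute-force product-of-densities oracle on a random dataset
  set.seed(4)
  n <- 12
  dat <- data.frame(lake_id = rep(c("L1", "L2"), each = n / 2),
                    site_id = paste0("s", 1:n),
                    latitude = runif(n, 60, 66),
                    y = rpois(n, 6) + 1, richness = 20)
  key <- paste(dat$lake_id, dat$site_id, sep = "::")
  st <- list(beta0_site = setNames(rnorm(n, 2), key),
             beta_cont = list(latitude = -0.3), sigma2 = 0.5)
  spec_n <- model_spec("y", "normal", continuous = "latitude")
  eta <- st$beta0_site[key] + st$beta_cont$latitude * log(dat$latitude)
  expect_equal(log_likelihood(st, spec_n, dat),
               sum(log(dnorm(log(dat$y), unname(eta), sqrt(0.5)))))
  spec_p2 <- model_spec("y", "poisson", continuous = "latitude")
  expect_equal(log_likelihood(st, spec_p2, dat),
               sum(log(dpois(dat$y, exp(unname(eta))))))

  dat$y <- 0
  expect_error(log_likelihood(st, spec_n, dat), "strictly positive")
})

test_that("model specifications validate their terms and families", {
  expect_error(model_spec("y", "normal", categorical = "weather"),
               "unknown categorical")
  expect_error(model_spec("y", "normal", continuous = "altitude"),
               "unknown continuous")
  s <- model_spec("y", "binomial", size = "richness")
  dat <- data.frame(lake_id = c("L1", "L2"), site_id = "s1", y = c(5, 1),
                    richness = c(3, 10))
  st <- list(beta0_site = setNames(c(0, 0), paste(dat$lake_id, dat$site_id,
                                                  sep = "::")))
  expect_error(log_likelihood(st, s, dat), "<= size")
})

test_that("Gelman-Rubin statistic separates converged from divergent chains", {
  set.seed(6)
  x <- matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(gelman_rubin(list(x, x))), c(1, 1) * sqrt(1999 / 2000),
               tolerance = 1e-12)
  long <- list(matrix(rnorm(5000), ncol = 1), matrix(rnorm(5000), ncol = 1))
  expect_lt(gelman_rubin(long)[1], 1.05)
  apart <- list(matrix(rnorm(500, 0), ncol = 1),
                matrix(rnorm(500, 100), ncol = 1))
  expect_gt(gelman_rubin(apart)[1], 10)
  expect_error(gelman_rubin(list(x)), "2 chains")
})

test_that("MC-error ratio scales as 1/sqrt(n) and flags bad cases", {
  set.seed(9)
  iid <- rnorm(1e4)
  r <- mc_error_ratio(iid)
  expect_lt(abs(r - 0.01), 0.005)
  expect_false(attr(r, "flagged")[1])

  const <- rep(1, 500)
  rc <- mc_error_ratio(const)
  expect_true(is.nan(rc[1]))
  expect_true(attr(rc, "flagged")[1])

  # strong autocorrelation inflates the ratio
  ar <- as.numeric(arima.sim(list(ar = 0.9), 1e4))
  expect_gt(mc_error_ratio(ar)[1], r[1] * 2)
})

test_that("fits are bit-reproducible and satisfy the zero-sum constraint", {
  fit <- tiny_fit()
  sv <- small_survey()
  spec <- fit$spec
  resp <- generate_responses(
    sv, spec, list(mu0 = 3, tau2_0 = 0.01, sigma2_site = 0.01,
                   sigma2 = 0.02, beta_cont = c(latitude = 0)), seed = 2)
  dat <- ancova_data(sv, resp)
  fit2 <- fit_ancova(spec, dat, n_iter = 800, n_chains = 2, n_adapt = 400,
                     burn_in = 300, thin = 2, seed = 31)
  expect_identical(fit$draws, fit2$draws)

  for (ch in fit$draws) {
    eff <- ch[, grepl("^beta_lake_type", colnames(ch)), drop = FALSE]
    expect_lt(max(abs(rowSums(eff))), 1e-10)
  }
})

test_that("DIC identities hold as stored and vanish for a degenerate posterior", {
  fit <- tiny_fit()
  expect_identical(fit$dic, fit$dbar + fit$pd)
  expect_identical(fit$pd, fit$dbar - fit$d_at_mean)

  # collapse the posterior onto a single draw: pD must be exactly 0
  deg <- fit
  one <- fit$draws[[1]][1, , drop = FALSE]
  deg$draws <- list(one[rep(1, 10), ])
  deg$deviance <- list(rep(fit$deviance[[1]][1], 10))
  deg$summary$mean <- as.numeric(one)
  d <- dic(deg, deg$spec, deg$data)
  expect_equal(d$pd, 0, tolerance = 1e-8)
  expect_equal(d$dic, d$d_at_mean, tolerance = 1e-8)
})

test_that("marginal DIC integrates the intercepts out and stays parsimonious", {
  fit <- tiny_fit()
  m <- dic(fit, focus = "marginal")
  expect_equal(m$dic, m$dbar + m$pd)
  expect_equal(m$pd, m$dbar - m$d_at_mean)
  expect_identical(fit$marginal, m)
  # integrating out the intercepts leaves only the structural parameters
  # (hypermean, categorical effects, slope, variance components)
  n_struct <- sum(!grepl("^b0_", fit$summary$parameter))
  expect_gt(m$pd, 0)
  expect_lt(m$pd, n_struct + 2)
  # marginal deviance at the plug-in point (means for locations, medians
  # for variances) matches a direct per-lake multivariate-normal evaluation
  pm <- setNames(fit$summary$mean, fit$summary$parameter)
  vpar <- grepl("^s2_lake\\[|^s2_site$|^tau2_0$|^sigma2$",
                fit$summary$parameter)
  pm[vpar] <- fit$summary$median[vpar]
  dat <- fit$data
  z <- log(dat$y)
  eff <- pm[paste0("beta_lake_type[", sort(unique(dat$lake_type)), "]")]
  names(eff) <- sort(unique(dat$lake_type))
  cfix <- pm["mu0"] + unname(eff[dat$lake_type]) +
    pm["beta[latitude]"] * log(dat$latitude)
  dev <- 0
  for (l in unique(dat$lake_id)) {
    i <- dat$lake_id == l
    n <- sum(i)
    Sig <- diag(pm["sigma2"] + pm[paste0("s2_lake[", l, "]")], n) +
      matrix(pm["tau2_0"], n, n)
    r <- z[i] - cfix[i]
    dev <- dev + n * log(2 * pi) + determinant(Sig)$modulus[1] +
      sum(r * solve(Sig, r))
  }
  expect_equal(m$d_at_mean, unname(dev), tolerance = 1e-8)
  # conditional focus rejects non-normal-family marginalisation
  expect_error(dic(fit, spec = model_spec("y", "poisson"),
                   focus = "marginal"), "normal family")
})

test_that("posterior summaries track the stored draws", {
  fit <- tiny_fit()
  all <- do.call(rbind, fit$draws)
  i <- match("mu0", fit$summary$parameter)
  expect_equal(fit$summary$mean[i], mean(all[, "mu0"]))
  expect_equal(fit$summary$sd[i], sd(all[, "mu0"]))
  expect_equal(fit$summary$q2.5[i],
               unname(quantile(all[, "mu0"], 0.025)))
})

test_that("single-candidate selection returns the candidate", {
  sv <- small_survey()
  spec <- model_spec("sim_count", "poisson")
  resp <- generate_responses(sv, spec, list(mu0 = 2.5), seed = 5)
  dat <- ancova_data(sv, resp)
  rank <- select_model("sim_count", dat, family = "poisson",
                       n_iter = 400, n_adapt = 200, burn_in = 200,
                       thin = 2, seed = 3)
  expect_equal(nrow(rank), 1L)
  expect_equal(rank$terms, "(intercept)")
  expect_true(rank$within_2_of_best)
})

test_that("the selection budget produces a partial ranking with a warning", {
  sv <- small_survey()
  spec <- model_spec("y", "normal")
  resp <- generate_responses(sv, spec,
                             list(mu0 = 3, sigma2 = 0.05), seed = 6)
  dat <- ancova_data(sv, resp)
  expect_warning(
    rank <- select_model("y", dat,
                         candidate_continuous = c("latitude", "color", "ph"),
                         n_iter = 300, n_adapt = 100, burn_in = 100,
                         thin = 2, seed = 3, max_models = 3),
    "partial")
  expect_equal(nrow(rank), 3L)
})
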