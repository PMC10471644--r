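test_that("default survey respects the published envelope", {
  sv <- generate_survey(generator_config(), seed = 1)
  expect_s3_class(sv, "pufa_survey")
  expect_equal(length(unique(sv$lake_id)), 95L)
  expect_true(all(table(sv$lake_id) %in% 1:3))
  expect_true(all(sv$tp >= 2 & sv$tp <= 123))
  expect_true(all(sv$tn >= 115 & sv$tn <= 1450))
  expect_true(all(sv$color >= 3 & sv$color <= 271))
  expect_true(all(sv$ph >= 5.4 & sv$ph <= 7.8))
  expect_true(all(sv$latitude >= 60 & sv$latitude <= 66.5))
  counts <- as.matrix(as.data.frame(sv)[attr(sv, "taxa")])
  expect_true(all(rowSums(counts) >= 11 & rowSums(counts) <= 1899))
  rich <- rowSums(counts > 0)
  expect_true(all(rich >= 5 & rich <= 46))
  expect_equal(length(unique(sv$lake_type)) <= 14, TRUE)
  # generated data pass the shared validators
  expect_silent(validate_survey(sv))
})

test_that("generation is deterministic and streams are independent", {
  cfg <- generator_config(n_lakes = 15)
  expect_identical(generate_survey(cfg, seed = 4),
                   generate_survey(cfg, seed = 4))
  sv <- generate_survey(cfg, seed = 4)
  spec <- model_spec("y", "normal")
  r1 <- generate_responses(sv, spec, list(mu0 = 2, sigma2 = 0.1), seed = 1)
  r2 <- generate_responses(sv, spec, list(mu0 = 2, sigma2 = 0.1), seed = 2)
  expect_false(isTRUE(all.equal(r1$y, r2$y)))
  # a different response seed never touches the survey itself
  expect_identical(sv, generate_survey(cfg, seed = 4))
})

test_that("composition converges to the base frequencies at high concentration", {
  cfg <- generator_config(n_lakes = 334, sites_per_lake = c(3, 3),
                          concentration = 1e5)
  sv <- generate_survey(cfg, seed = 2)
  counts <- as.matrix(as.data.frame(sv)[attr(sv, "taxa")])
  props <- counts / rowSums(counts)
  tv <- 0.5 * sum(abs(colMeans(props) - cfg$base_freq))
  expect_gte(nrow(counts), 1000)
  expect_lt(tv, 0.05)
})

test_that("response generation matches the family moments", {
  cfg <- generator_config(n_lakes = 500, sites_per_lake = c(2, 2))
  sv <- generate_survey(cfg, seed = 3)
  n <- nrow(sv)

  # noise-free normal limit: response is exactly exp(mu0)
  spec_n <- model_spec("y", "normal")
  r <- generate_responses(sv, spec_n,
                          list(mu0 = log(20), tau2_0 = 0, sigma2_site = 0,
                               sigma2 = 0), seed = 1)
  expect_equal(r$y, rep(20, n))

  # Poisson mean at eta = ln 5
  spec_p <- model_spec("y", "poisson")
  r <- generate_responses(sv, spec_p, list(mu0 = log(5)), seed = 2)
  expect_lt(abs(mean(r$y) - 5), 3 * sqrt(5 / n))

  # binomial at eta = 0 halves the richness on average
  spec_b <- model_spec("y", "binomial")
  r <- generate_responses(sv, spec_b, list(mu0 = 0), seed = 3)
  expect_lt(abs(mean(r$y / r$richness) - 0.5), 0.05)
})

test_that("simulated mass fractions follow the truncated-normal moments", {
  tp <- taxon_profiles()
  fa <- generate_fa_samples(tp, tp$n_lakes, seed = 1)
  expect_equal(nrow(fa), sum(tp$n_lakes))
  expect_equal(as.vector(table(factor(fa$taxon, levels = tp$taxon))),
               tp$n_lakes)
  expect_true(all(fa$ara >= 0 & fa$epa >= 0 & fa$dha >= 0))

  # not-detected means generate exact zeros
  expect_true(all(fa$dha[fa$taxon == "Diptera/Tabanidae"] == 0))

  # Pallasidae DHA: mean 4.6, SD 3.9, truncated at zero
  big <- generate_fa_samples(tp[grepl("Pallasidae", tp$taxon), ],
                             1e4, seed = 2)
  mu <- trunc_normal_mean(4.6, 3.9)
  se <- sd(big$dha) / sqrt(1e4)
  expect_lt(abs(mean(big$dha) - mu), 3 * se)

  # missing SDs are replaced by the median CV over the table, not dropped
  many <- generate_fa_samples(tp, 200, seed = 3)
  expect_gt(sd(many$ara[many$taxon == "Nematoda"]), 0)
  # a table with no imputable CV cannot back-fill a missing SD
  expect_error(generate_fa_samples(tp[tp$taxon == "Nematoda", ], 5,
                                   seed = 3), "impute")

  # SD = 0 collapses onto the mean
  prof <- make_profiles(c(1, 2, 3, 4), sds = 0)
  fa0 <- generate_fa_samples(prof, 5, seed = 4)
  expect_equal(fa0$ara, rep(c(1, 2, 3, 4), each = 5))
})

test_that("zero-truncated normal sampler is non-negative and exact at sd 0", {
  set.seed(10)
  x <- rtrunc_normal(5000, 0.3, 1)
  expect_true(all(x >= 0))
  expect_lt(abs(mean(x) - trunc_normal_mean(0.3, 1)), 0.05)
  expect_equal(rtrunc_normal(3, 2, 0), c(2, 2, 2))
})

test_that("an infeasible richness constraint errors after bounded retries", {
  cfg <- generator_config(n_lakes = 2, richness = c(20, 46),
                          abundance = c(11, 12))
  expect_error(generate_survey(cfg, seed = 1, max_tries = 20),
               "richness constraint")
})
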