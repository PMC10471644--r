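test_that("weighted metrics match direct evaluation", {
  fa <- c(A = 1, B = 5)
  s <- c(A = 2, B = 3)
  expect_equal(abundance_fa_weighted(s, fa), 17 / 6)
  expect_equal(fa_abundance_weighted(s, fa), 17 / 5)
  expect_equal(fa_x_abundance(s, fa), 17)

  # weights cancel for a one-taxon universe
  expect_equal(abundance_fa_weighted(c(A = 10), c(A = 2)), 10)
  # a shared content value is returned whatever the abundances
  expect_equal(fa_abundance_weighted(c(A = 7, B = 1), c(A = 3, B = 3)), 3)

  # empty community
  expect_equal(abundance_fa_weighted(c(A = 0, B = 0), fa), 0)
  expect_equal(fa_x_abundance(c(A = 0, B = 0), fa), 0)
  expect_error(fa_abundance_weighted(c(A = 0, B = 0), fa), "undefined")
})

test_that("rich-taxon counts use the class > threshold rule", {
  cl <- c(A = 5, B = 4, C = 3, D = 2)
  s <- c(A = 1, B = 2, C = 3, D = 4)
  expect_equal(count_rich_taxa(s, cl, 3), 2)
  expect_equal(count_rich_taxa(s, cl, 4), 1)
  expect_equal(pct_rich_taxa(s, cl, 3), 0.5)
  expect_equal(count_rich_taxa(c(A = 0, B = 0, C = 0, D = 0), cl, 3), 0)
  expect_equal(pct_rich_taxa(c(A = 0, B = 0, C = 0, D = 0), cl, 3), 0)
  expect_error(count_rich_taxa(s, cl, 2), "3 or 4")
})

test_that("the five jointly PUFA-rich reference taxa all count as rich", {
  tp <- taxon_profiles()
  rich5 <- c("Heteroptera/Corixidae", "Oligochaeta", "Amphipoda/Pallasidae",
             "Platyhelminthes", "Odonata/Zygoptera")
  for (p in c("ara", "epa", "dha")) {
    cl <- setNames(tp[[paste0("class_", p)]], tp$taxon)
    s <- setNames(as.numeric(tp$taxon %in% rich5), tp$taxon)
    expect_equal(count_rich_taxa(s, cl, 3), 5)
  }
})

test_that("taxa absent from the profile table follow the configured policy", {
  fa <- c(A = 1, B = 5)
  s <- c(A = 2, Mystery = 3)
  expect_error(abundance_fa_weighted(s, fa), "Mystery")
  expect_warning(out <- fa_abundance_weighted(s, fa, missing_taxa = "drop"),
                 "Mystery")
  expect_equal(out, 1)  # only A remains
})

test_that("per-site response table satisfies the structural invariants", {
  sv <- small_survey()
  tp <- taxon_profiles()
  resp <- community_responses(sv, tp)
  expect_equal(nrow(resp), nrow(sv))
  for (p in c("ara", "epa", "dha")) {
    cgt3 <- resp[[paste0("count_gt3_", p)]]
    cgt4 <- resp[[paste0("count_gt4_", p)]]
    expect_true(all(cgt4 <= cgt3))
    expect_true(all(cgt3 <= resp$richness))
    expect_equal(resp[[paste0("pct_gt3_", p)]], cgt3 / resp$richness)
    expect_true(all(resp[[paste0("pct_gt4_", p)]] >= 0 &
                    resp[[paste0("pct_gt4_", p)]] <= 1))

    # exact identity between metrics (i) and (iii)
    cl <- setNames(tp[[paste0("class_", p)]], tp$taxon)
    expect_equal(resp[[paste0("fa_x_abundance_", p)]],
                 resp[[paste0("abundance_fa_weighted_", p)]] * sum(cl))

    # abundance-weighted content is bounded by the present taxa's content
    counts <- as.matrix(as.data.frame(sv)[attr(sv, "taxa")])
    for (i in seq_len(nrow(sv))) {
      present <- cl[colnames(counts)[counts[i, ] > 0]]
      w <- resp[[paste0("fa_abundance_weighted_", p)]][i]
      expect_gte(w, min(present))
      expect_lte(w, max(present))
    }
  }
})

test_that("metrics are invariant to taxon column order", {
  sv <- small_survey()
  tp <- taxon_profiles()
  resp <- community_responses(sv, tp)
  taxa <- attr(sv, "taxa")
  perm <- rev(taxa)
  sv2 <- as_pufa_survey(
    as.data.frame(sv)[c(setdiff(names(sv), taxa), perm)], perm)
  resp2 <- community_responses(sv2, tp)
  expect_equal(resp2, resp)
})

test_that("mass fractions can replace classes as the content value", {
  sv <- small_survey()
  tp <- taxon_profiles()
  resp <- community_responses(sv, tp, fa_values = "mean")
  m <- setNames(tp$mean_ara, tp$taxon)
  counts <- as.matrix(as.data.frame(sv)[attr(sv, "taxa")])
  expect_equal(resp$fa_x_abundance_ara[1],
               sum(counts[1, names(m)] * m))
})

test_that("log-log richness regression behaves at the edges and recovers", {
  # exactly collinear
  ab <- c(10, 100, 1000)
  ri <- exp(0.4 * log(ab) + 1)
  out <- loglog_richness_regression(ri, ab)
  expect_equal(out$r_squared, 1)
  expect_equal(out$slope, 0.4)

  # constant richness
  out <- loglog_richness_regression(rep(5, 10), 1:10 * 10)
  expect_equal(out$slope, 0)
  expect_equal(out$r_squared, 0)

  expect_error(loglog_richness_regression(c(0, 1, 2), c(1, 2, 3)),
               "positive")

  # recovery of a known slope within 2 standard errors
  set.seed(42)
  ab <- exp(runif(120, log(11), log(1899)))
  ri <- pmax(1, round(exp(0.3 * log(ab) + 0.5 + rnorm(120, 0, 0.15))))
  out <- loglog_richness_regression(ri, ab)
  expect_lt(abs(out$slope - 0.3), 2 * out$slope_se)
})
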