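# Builders for small in-code fixtures.

# Minimal valid profile table; class columns are derived so the
# "class 1 iff mean 0" invariant always holds.
make_profiles <- function(means_ara, means_epa = means_ara,
                          means_dha = means_ara, sds = 0.5,
                          taxa = sprintf("taxon%02d", seq_along(means_ara))) {
  n <- length(means_ara)
  df <- data.frame(taxon = taxa, n_lakes = rep(3L, n),
                   stringsAsFactors = FALSE)
  for (p in c("ara", "epa", "dha")) {
    m <- get(paste0("means_", p))
    b <- compute_boundaries(m, p)
    df[[paste0("mean_", p)]] <- m
    df[[paste0("sd_", p)]] <- rep_len(sds, n)
    df[[paste0("class_", p)]] <- assign_class(m, b)
  }
  class(df) <- c("taxon_profiles", "data.frame")
  df
}

# Small deterministic survey: `counts` is a matrix (sites x taxa) with
# dimnames; covariates are fixed mid-range values unless overridden.
make_survey <- function(counts, lake_id = NULL, site_id = NULL,
                        latitude = 63, color = 50, ph = 6.5,
                        tp = 20, tn = 500,
                        lake_type = "T01", vegetation = "emergent",
                        substrate = "hard") {
  n <- nrow(counts)
  if (is.null(lake_id)) lake_id <- sprintf("L%02d", seq_len(n))
  if (is.null(site_id)) site_id <- rep("s1", n)
  df <- data.frame(lake_id = lake_id, site_id = site_id,
                   lake_type = rep_len(lake_type, n),
                   vegetation = rep_len(vegetation, n),
                   substrate = rep_len(substrate, n),
                   latitude = rep_len(latitude, n),
                   color = rep_len(color, n), ph = rep_len(ph, n),
                   tp = rep_len(tp, n), tn = rep_len(tn, n),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(counts, check.names = FALSE))
  as_pufa_survey(df, colnames(counts))
}

# A small generated survey shared across tests (cheap, deterministic).
small_survey <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_survey(generator_config(n_lakes = 12), seed = 7)
    cache
  }
})
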