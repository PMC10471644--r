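# Synthetic lake-survey generator.
#
# Emulates the statistical structure of the 95-lake littoral monitoring
# extract that the ANCOVA consumes: per-lake water chemistry and typology,
# 1-3 kick-net sites per lake, and overdispersed (Dirichlet-multinomial)
# taxon compositions over the 24-taxon PUFA reference list. All ranges
# default to the published survey ranges; generating parameters are known,
# so fits can be checked for recovery.

#' Default per-taxon base frequencies
#'
#' Rough relative prevalences of the dominant littoral groups
#' (Ephemeroptera, Chironomidae, Asellus, Oligochaeta, Trichoptera) with the
#' remaining reference taxa sharing the residual mass.
#' @param taxa character vector of taxon labels.
#' @return named probability vector summing to 1.
#' @keywords internal
.default_base_freq <- function(taxa) {
  named <- c("Ephemeroptera" = 0.26, "Diptera/Chironomidae" = 0.15,
             "Isopoda (Asellus aquaticus)" = 0.12, "Oligochaeta" = 0.09,
             "Trichoptera" = 0.06)
  p <- setNames(rep(0, length(taxa)), taxa)
  hit <- intersect(names(named), taxa)
  p[hit] <- named[hit]
  rest <- setdiff(taxa, hit)
  p[rest] <- (1 - sum(p)) / length(rest)
  p / sum(p)
}

#' Survey generator configuration
#'
#' Bundles the generating conditions of a synthetic lake survey. Defaults
#' reproduce the published survey envelope: 95 lakes, 1--3 sites per lake,
#' 14 lake-typology groups, TP 2--123 ug/L, TN 115--1450 ug/L, color
#' 3--271 mg Pt/L, pH 5.4--7.8, latitude 60--66.5 deg N, total abundance
#' 11--1899 individuals per sampling effort and richness 5--46 taxa (capped
#' by the size of the taxon list).
#'
#' @param n_lakes number of lakes.
#' @param sites_per_lake integer range `c(min, max)` of sites per lake.
#' @param n_lake_types number of typology groups (labelled `T01`, ...).
#' @param lake_type_probs sampling weights over the typology groups; two
#'   groups are rarer by default, mirroring the under-represented
#'   calcium-rich and large humic types.
#' @param vegetation_levels,substrate_levels site-habitat codes.
#' @param tp,tn,color,ph,latitude covariate ranges (`c(min, max)`); TP, TN
#'   and color are drawn log-uniformly, pH and latitude uniformly.
#' @param abundance total-count range per site (log-uniform).
#' @param richness admissible per-site richness range (rejection-enforced).
#' @param base_freq per-taxon composition mean (defaults to
#'   [.default_base_freq()] over `taxa`).
#' @param concentration Dirichlet concentration: site compositions are
#'   `Dirichlet(concentration * base_freq)`; smaller values give stronger
#'   among-site overdispersion.
#' @param taxa taxon universe (defaults to the packaged reference taxa).
#' @param true_params generating parameters for [generate_responses()]:
#'   list with `mu0`, `tau2_0` (lake-level variance), `sigma2_site`
#'   (site-in-lake variance), `sigma2` (normal observation variance),
#'   `beta_cont` (named slopes on log covariates), and optional zero-sum
#'   `beta1`/`beta2`/`beta3` categorical effects.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_lakes = 95,
                             sites_per_lake = c(1, 3),
                             n_lake_types = 14,
                             lake_type_probs = NULL,
                             vegetation_levels = c("emergent", "submerged",
                                                   "bryophytes", "none"),
                             substrate_levels = c("hard", "soft", "mixed"),
                             tp = c(2, 123), tn = c(115, 1450),
                             color = c(3, 271), ph = c(5.4, 7.8),
                             latitude = c(60, 66.5),
                             abundance = c(11, 1899),
                             richness = c(5, 46),
                             base_freq = NULL,
                             concentration = 30,
                             taxa = NULL,
                             true_params = list()) {
  if (is.null(taxa)) taxa <- taxon_profiles()$taxon
  if (is.null(base_freq)) base_freq <- .default_base_freq(taxa)
  if (is.null(lake_type_probs)) {
    lake_type_probs <- c(rep(1, n_lake_types - 2L), 0.3, 0.6)
  }
  lake_type_probs <- lake_type_probs / sum(lake_type_probs)
  for (rng in list(sites_per_lake, tp, tn, color, ph, latitude, abundance,
                   richness)) {
    if (length(rng) != 2L || rng[1L] > rng[2L])
      stop("ranges must be ordered c(min, max)", call. = FALSE)
  }
  if (abs(sum(base_freq) - 1) > 1e-8)
    stop("base_freq must sum to 1", call. = FALSE)
  tp_default <- list(mu0 = 3, tau2_0 = 0.01, sigma2_site = 0.01,
                     sigma2 = 0.0225, beta_cont = numeric(0))
  structure(list(n_lakes = n_lakes, sites_per_lake = sites_per_lake,
                 n_lake_types = n_lake_types,
                 lake_type_probs = lake_type_probs,
                 vegetation_levels = vegetation_levels,
                 substrate_levels = substrate_levels,
                 tp = tp, tn = tn, color = color, ph = ph,
                 latitude = latitude, abundance = abundance,
                 richness = richness, base_freq = base_freq,
                 concentration = concentration, taxa = taxa,
                 true_params = modifyList(tp_default, true_params)),
            class = "generator_config")
}

.runif_log <- function(n, range) exp(runif(n, log(range[1L]), log(range[2L])))

#' Generate a synthetic lake survey
#'
#' Draws lake-level covariates (TP, TN, color log-uniform; pH and latitude
#' uniform) and typology codes, site-level habitat codes, and per-site
#' abundances: a log-uniform total allocated over taxa by a
#' Dirichlet-multinomial composition around `base_freq`. Site richness
#' outside the admissible range triggers composition redraws (bounded at
#' `max_tries`, then an error).
#'
#' Covariates and compositions use separate seed streams, so composition
#' settings do not perturb the covariate draws.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; full determinism for a fixed seed.
#' @param max_tries per-site redraw bound for the richness constraint.
#' @return a validated `pufa_survey` data frame.
#' @export
generate_survey <- function(config, seed = 1, max_tries = 200) {
  stopifnot(inherits(config, "generator_config"))
  n_taxa <- length(config$taxa)
  rich_rng <- c(max(1, config$richness[1L]),
                min(n_taxa, config$richness[2L]))

  set.seed(as.integer(seed))
  lakes <- sprintf("L%03d", seq_len(config$n_lakes))
  lake_type <- sample(sprintf("T%02d", seq_len(config$n_lake_types)),
                      config$n_lakes, replace = TRUE,
                      prob = config$lake_type_probs)
  lat <- runif(config$n_lakes, config$latitude[1L], config$latitude[2L])
  ph <- runif(config$n_lakes, config$ph[1L], config$ph[2L])
  tp <- .runif_log(config$n_lakes, config$tp)
  tn <- .runif_log(config$n_lakes, config$tn)
  color <- .runif_log(config$n_lakes, config$color)
  sites_seq <- seq(config$sites_per_lake[1L], config$sites_per_lake[2L])
  n_sites <- sites_seq[sample.int(length(sites_seq), config$n_lakes,
                                  replace = TRUE)]
  veg <- sample(config$vegetation_levels, sum(n_sites), replace = TRUE)
  sub <- sample(config$substrate_levels, sum(n_sites), replace = TRUE)

  set.seed(as.integer(seed) + 104729L)  # independent composition stream
  rows <- vector("list", sum(n_sites))
  r <- 0L
  alpha <- config$concentration * config$base_freq
  for (l in seq_len(config$n_lakes)) {
    for (s in seq_len(n_sites[l])) {
      r <- r + 1L
      total <- max(config$abundance[1L],
                   round(.runif_log(1L, config$abundance)))
      counts <- NULL
      for (try in seq_len(max_tries)) {
        w <- rgamma(n_taxa, shape = alpha)
        if (all(w == 0)) next
        cand <- as.vector(rmultinom(1L, total, w / sum(w)))
        rich <- sum(cand > 0)
        if (rich >= rich_rng[1L] && rich <= rich_rng[2L]) {
          counts <- cand
          break
        }
      }
      if (is.null(counts))
        stop("could not satisfy the richness constraint for total = ",
             total, " after ", max_tries, " tries", call. = FALSE)
      rows[[r]] <- c(list(lake_id = lakes[l],
                          site_id = sprintf("s%d", s),
                          lake_type = lake_type[l],
                          vegetation = veg[r], substrate = sub[r],
                          latitude = lat[l], color = color[l], ph = ph[l],
                          tp = tp[l], tn = tn[l]),
                     as.list(setNames(counts, config$taxa)))
    }
  }
  df <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, check.names = FALSE, stringsAsFactors = FALSE)))
  as_pufa_survey(df, config$taxa)
}

#' Forward-simulate responses from known parameters
#'
#' Draws per-site responses from the observation family at the linear
#' predictor implied by `true_params`: lake intercepts from
#' `N(mu0, tau2_0)`, site intercepts from `N(b0_lake, sigma2_site)`,
#' categorical and continuous effects as supplied.
#'
#' @param survey a `pufa_survey`.
#' @param spec an [model_spec()]; `spec$response` names the generated
#'   column. For the binomial family the size is the observed site richness.
#' @param true_params see [generator_config()].
#' @param seed integer seed (independent of the survey stream).
#' @return data frame `lake_id`, `site_id`, `richness`, `<response>`, with
#'   the generating state in `attr(x, "true_state")`.
#' @export
generate_responses <- function(survey, spec, true_params, seed = 1) {
  stopifnot(inherits(spec, "ancova_spec"))
  tp <- modifyList(list(mu0 = 0, tau2_0 = 0, sigma2_site = 0, sigma2 = 0,
                        beta_cont = numeric(0)), true_params)
  set.seed(as.integer(seed))
  lakes <- unique(survey$lake_id)
  b0_lake <- setNames(rnorm(length(lakes), tp$mu0, sqrt(tp$tau2_0)), lakes)
  key <- paste(survey$lake_id, survey$site_id, sep = "::")
  b0_site <- setNames(rnorm(nrow(survey), b0_lake[survey$lake_id],
                            sqrt(tp$sigma2_site)), key)
  state <- list(beta0_site = b0_site,
                beta1 = tp$beta1, beta2 = tp$beta2, beta3 = tp$beta3,
                beta_cont = as.list(tp$beta_cont), sigma2 = tp$sigma2)
  eta <- linear_predictor(state, survey, spec)
  counts <- as.matrix(as.data.frame(survey)[attr(survey, "taxa")])
  rich <- rowSums(counts > 0)
  y <- switch(spec$family,
    normal = exp(rnorm(length(eta), eta, sqrt(tp$sigma2))),
    poisson = rpois(length(eta), exp(eta)),
    binomial = rbinom(length(eta), rich, plogis(eta)))
  out <- data.frame(lake_id = survey$lake_id, site_id = survey$site_id,
                    richness = rich, stringsAsFactors = FALSE)
  out[[spec$response]] <- y
  attr(out, "true_state") <- state
  out
}

#' Simulate per-sample fatty-acid mass fractions
#'
#' Draws replicate mass fractions per taxon from a zero-truncated normal
#' with the reference mean and SD of each taxon and PUFA, producing the long
#' per-sample table the PERMANOVA stage consumes. Taxa with a missing SD
#' (sampled in a single lake) use the median coefficient of variation across
#' taxa for that PUFA; not-detected taxa (mean 0) yield zeros.
#'
#' @param profiles a `taxon_profiles` data frame.
#' @param replicates_per_taxon scalar or per-taxon integer vector (e.g. the
#'   recorded per-taxon lake counts).
#' @param seed integer seed.
#' @return data frame with columns `taxon`, `replicate`, `ara`, `epa`,
#'   `dha`.
#' @export
generate_fa_samples <- function(profiles, replicates_per_taxon, seed = 1) {
  validate_taxon_profiles(profiles)
  n_taxa <- nrow(profiles)
  reps <- rep_len(replicates_per_taxon, n_taxa)
  if (any(reps < 1 | reps != round(reps)))
    stop("replicates_per_taxon must be positive integers", call. = FALSE)
  set.seed(as.integer(seed))
  out <- data.frame(taxon = rep(profiles$taxon, reps),
                    replicate = unlist(lapply(reps, seq_len)),
                    stringsAsFactors = FALSE)
  for (p in PUFAS) {
    m <- profiles[[paste0("mean_", p)]]
    s <- profiles[[paste0("sd_", p)]]
    cv <- s / m
    med_cv <- median(cv[is.finite(cv) & m > 0], na.rm = TRUE)
    s[is.na(s)] <- m[is.na(s)] * med_cv
    s[m == 0] <- 0
    if (any(is.na(s)))
      stop("cannot impute a missing SD for ", toupper(p),
           ": no taxon provides a coefficient of variation", call. = FALSE)
    out[[p]] <- unlist(lapply(seq_len(n_taxa), function(i)
      rtrunc_normal(reps[i], m[i], s[i])))
  }
  out
}

#' Zero-truncated normal draws
#'
#' Inverse-CDF sampler for `N(mean, sd)` truncated to `[0, Inf)`; `sd = 0`
#' returns the mean exactly.
#'
#' @param n number of draws.
#' @param mean,sd untruncated moments.
#' @return numeric vector of non-negative draws.
#' @export
rtrunc_normal <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- pnorm(0, mean, sd)
  qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

#' Mean of the zero-truncated normal
#'
#' Closed form `mean + sd * phi(a) / (1 - Phi(a))` with
#' `a = -mean/sd`; used as the moment oracle for [rtrunc_normal()].
#'
#' @inheritParams rtrunc_normal
#' @return scalar expectation.
#' @export
trunc_normal_mean <- function(mean, sd) {
  if (sd == 0) return(mean)
  a <- -mean / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}
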