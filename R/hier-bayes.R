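# Hierarchical Bayesian ANCOVA for community PUFA responses.
#
# Linear predictor (identity link for the normal-on-log and log link for the
# Poisson family, logit link for the binomial family):
#
#   eta_ij = b0_site[i(j)] + b1[lake type] + b2[vegetation] + b3[substrate]
#            + sum_n beta_n * ln X_n,   X_n in {latitude, color, pH, TP, TN}
#
# with nested intercepts b0_site ~ N(b0_lake[j], s2_lake[j]),
# b0_lake ~ N(mu0, tau2_0), zero-sum constraints on each categorical block,
# N(0, 1e4) priors on all location effects, and Gamma(0.001, 0.001) priors
# on all precisions.
#
# Sampling: component-wise adaptive random-walk Metropolis for all location
# parameters (proposal SD scaled by 1.1 per 50-iteration batch outside the
# 20-40% acceptance window, frozen after `n_adapt` iterations); precisions
# are conjugate given the normal layers and are drawn exactly by Gibbs.
# Continuous covariates are mean-centred on the log scale inside the sampler
# for mixing; stored intercept draws are shifted back to the original scale,
# leaving the posterior unchanged.

.ancova_cat_blocks <- c("lake_type", "vegetation", "substrate")
.ancova_cont_terms <- c("latitude", "color", "ph", "tp", "tn")
.prior_sd_effect <- 100        # N(0, 10000)
.prior_gamma <- 0.001          # Gamma(shape, rate) on precisions

#' Specify a hierarchical ANCOVA model
#'
#' @param response name of the response column.
#' @param family observation family: `"normal"` models the natural log of a
#'   strictly positive response, `"poisson"` an integer count with log link,
#'   `"binomial"` an integer count out of `size` with logit link.
#' @param categorical subset of `c("lake_type", "vegetation", "substrate")`;
#'   each included block gets zero-sum fixed effects.
#' @param continuous subset of
#'   `c("latitude", "color", "ph", "tp", "tn")`; each enters as its natural
#'   log.
#' @param size name of the binomial size column (default `"richness"`).
#' @param log_latitude if `FALSE`, latitude enters untransformed.
#' @param shared_site_variance if `TRUE`, one common within-lake variance
#'   replaces the per-lake variances `s2_lake[j]` (useful when lakes have
#'   very few sites).
#' @return object of class `ancova_spec`.
#' @export
model_spec <- function(response,
                       family = c("normal", "poisson", "binomial"),
                       categorical = character(),
                       continuous = character(),
                       size = "richness",
                       log_latitude = TRUE,
                       shared_site_variance = FALSE) {
  family <- match.arg(family)
  bad <- setdiff(categorical, .ancova_cat_blocks)
  if (length(bad)) stop("unknown categorical terms: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(continuous, .ancova_cont_terms)
  if (length(bad)) stop("unknown continuous terms: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(response = response, family = family,
                 categorical = categorical, continuous = continuous,
                 size = size, log_latitude = log_latitude,
                 shared_site_variance = shared_site_variance),
            class = "ancova_spec")
}

#' Merge a survey with its per-site responses
#'
#' @param survey a `pufa_survey` data frame.
#' @param responses a `community_responses` data frame (or any data frame
#'   keyed by `lake_id`, `site_id`).
#' @return data frame with covariates and responses, one row per site.
#' @export
ancova_data <- function(survey, responses) {
  covars <- as.data.frame(survey)[.survey_id_cols]
  merge(covars, as.data.frame(responses), by = c("lake_id", "site_id"),
        sort = FALSE)
}

.cov_value <- function(data, v, spec) {
  x <- data[[v]]
  if (is.null(x)) stop("data lack covariate '", v, "'", call. = FALSE)
  if (any(x <= 0)) stop("covariate '", v, "' must be positive", call. = FALSE)
  if (v == "latitude" && !spec$log_latitude) x else log(x)
}

#' Evaluate the linear predictor
#'
#' @param state named list with (any of) `beta0_site` (named by
#'   `"lake::site"` key), `beta1`/`beta2`/`beta3` (categorical effects named
#'   by level, for lake type / vegetation / substrate), `beta_cont` (named
#'   by covariate).
#' @param data data frame of site records (see [ancova_data()]).
#' @param spec an [model_spec()] object selecting the included terms.
#' @return numeric vector `eta`, one value per row of `data`.
#' @export
linear_predictor <- function(state, data, spec) {
  key <- paste(data$lake_id, data$site_id, sep = "::")
  eta <- rep(0, nrow(data))
  if (!is.null(state$beta0_site)) {
    miss <- setdiff(key, names(state$beta0_site))
    if (length(miss)) stop("no site intercept for: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    eta <- eta + unname(state$beta0_site[key])
  }
  blocks <- c(lake_type = "beta1", vegetation = "beta2", substrate = "beta3")
  for (b in spec$categorical) {
    eff <- state[[blocks[[b]]]]
    if (is.null(eff)) next
    lv <- as.character(data[[b]])
    miss <- setdiff(lv, names(eff))
    if (length(miss)) stop("unknown ", b, " level: ",
                           paste(unique(miss), collapse = ", "),
                           call. = FALSE)
    eta <- eta + unname(eff[lv])
  }
  for (v in spec$continuous) {
    bc <- state$beta_cont[[v]]
    if (is.null(bc) || is.na(bc)) next
    eta <- eta + bc * .cov_value(data, v, spec)
  }
  eta
}

.check_response <- function(y, spec, size = NULL) {
  if (any(!is.finite(y))) stop("non-finite response", call. = FALSE)
  switch(spec$family,
    normal = if (any(y <= 0))
      stop("normal-on-log family requires strictly positive responses",
           call. = FALSE),
    poisson = if (any(y < 0) || any(y != round(y)))
      stop("poisson family requires non-negative integer responses",
           call. = FALSE),
    binomial = {
      if (any(y < 0) || any(y != round(y)))
        stop("binomial family requires non-negative integer responses",
             call. = FALSE)
      if (is.null(size) || any(size < y))
        stop("binomial family requires integer responses <= size",
             call. = FALSE)
    })
  invisible(y)
}

.family_loglik <- function(family) {
  switch(family,
    normal = function(eta, y, size, sigma2)
      dnorm(log(y), eta, sqrt(sigma2), log = TRUE),
    poisson = function(eta, y, size, sigma2)
      dpois(y, exp(pmin(eta, 700)), log = TRUE),
    binomial = function(eta, y, size, sigma2)
      dbinom(y, size, plogis(eta), log = TRUE))
}

#' Model log-likelihood
#'
#' Sum over sites of the observation-family log density at the linear
#' predictor implied by `state`. The binomial density includes the binomial
#' coefficient (constant in the parameters; shifts the absolute deviance but
#' not model comparisons).
#'
#' @inheritParams linear_predictor
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(state, spec, data) {
  y <- data[[spec$response]]
  size <- if (spec$family == "binomial") data[[spec$size]] else NULL
  .check_response(y, spec, size)
  eta <- linear_predictor(state, data, spec)
  sum(.family_loglik(spec$family)(eta, y, size, state$sigma2))
}

# ---------------------------------------------------------------------------
# sampler

.ancova_prep <- function(spec, data) {
  y <- data[[spec$response]]
  if (is.null(y)) stop("data lack response '", spec$response, "'",
                       call. = FALSE)
  size <- if (spec$family == "binomial") data[[spec$size]] else NULL
  .check_response(y, spec, size)
  key <- paste(data$lake_id, data$site_id, sep = "::")
  if (anyDuplicated(key)) stop("duplicate site records", call. = FALSE)
  lake <- factor(data$lake_id, levels = unique(data$lake_id))
  if (nlevels(lake) < 2L) stop("need at least 2 lakes", call. = FALSE)
  Z <- NULL; centers <- numeric(0)
  if (length(spec$continuous)) {
    Z <- vapply(spec$continuous, function(v) .cov_value(data, v, spec),
                numeric(nrow(data)))
    Z <- matrix(Z, nrow = nrow(data),
                dimnames = list(NULL, spec$continuous))
    centers <- colMeans(Z)
    Z <- sweep(Z, 2L, centers)
  }
  cats <- lapply(spec$categorical, function(b) {
    f <- factor(as.character(data[[b]]))
    if (nlevels(f) < 2L)
      stop("categorical term '", b, "' has fewer than 2 observed levels",
           call. = FALSE)
    list(name = b, idx = as.integer(f), levels = levels(f), L = nlevels(f))
  })
  names(cats) <- spec$categorical
  list(y = y, z = if (spec$family == "normal") log(y) else NULL,
       size = size, key = key, lake = as.integer(lake),
       lake_ids = levels(lake), n_lakes = nlevels(lake), n_sites = nrow(data),
       Z = Z, centers = centers, cats = cats)
}

.param_names <- function(spec, prep) {
  nm <- c(paste0("b0_site[", prep$key, "]"),
          paste0("b0_lake[", prep$lake_ids, "]"),
          if (spec$shared_site_variance) "s2_site" else
            paste0("s2_lake[", prep$lake_ids, "]"),
          "mu0", "tau2_0")
  for (cb in prep$cats)
    nm <- c(nm, paste0("beta_", cb$name, "[", cb$levels, "]"))
  if (length(spec$continuous))
    nm <- c(nm, paste0("beta[", spec$continuous, "]"))
  if (spec$family == "normal") nm <- c(nm, "sigma2")
  nm
}

# one MCMC chain; returns list(draws, deviance, accept)
.run_chain <- function(spec, prep, n_iter, n_adapt, burn_in, thin, seed) {
  set.seed(seed)
  I <- prep$n_sites; J <- prep$n_lakes
  y <- prep$y; z <- prep$z; size <- prep$size
  lake <- prep$lake
  n_j <- tabulate(lake, nbins = J)
  llfun <- .family_loglik(spec$family)
  P <- length(spec$continuous)
  shared <- spec$shared_site_variance

  # deterministic data-based inits, jittered per chain
  raw0 <- switch(spec$family,
                 normal = z,
                 poisson = log(y + 0.5),
                 binomial = qlogis((y + 0.5) / (size + 1)))
  b0s <- raw0 + rnorm(I, 0, 0.1)
  b0l <- as.vector(rowsum(b0s, lake) / n_j)
  mu0 <- mean(b0l)
  tau2 <- max(var(b0l), 0.01)
  s2l <- rep(max(var(b0s - b0l[lake]), 0.01), if (shared) 1L else J)
  eff <- lapply(prep$cats, function(cb) setNames(rep(0, cb$L), cb$levels))
  bc <- setNames(rep(0, P), spec$continuous)
  sigma2 <- if (spec$family == "normal")
    max(var(z - b0s), 1e-4) else NA_real_

  eta <- b0s  # effects and slopes start at zero

  # proposal SDs and acceptance bookkeeping
  sd_s <- rep(0.5, I); sd_l <- rep(0.5, J); sd_m <- 0.5
  sd_cat <- lapply(prep$cats, function(cb) rep(0.2, cb$L - 1L))
  sd_bc <- rep(0.2, P)
  acc_s <- integer(I); acc_l <- integer(J); acc_m <- 0L
  acc_cat <- lapply(prep$cats, function(cb) integer(cb$L - 1L))
  acc_bc <- integer(P)
  tot_acc <- 0; tot_prop <- 0

  # translation (likelihood-invariant) sweeps: pre-computed lake means of
  # each slope/effect direction and the within-lake deviations from them
  zbar <- if (P) rowsum(prep$Z, lake) / n_j else NULL        # J x P
  zdev <- if (P) prep$Z - zbar[lake, , drop = FALSE] else NULL
  wbar <- lapply(prep$cats, function(cb) {
    sapply(seq_len(cb$L - 1L), function(r) {
      w <- (cb$idx == r) - (cb$idx == cb$L)
      as.vector(rowsum(w, lake)) / n_j
    })
  })
  sd_lj <- rep(0.5, J); sd_gm <- 0.5
  sd_bcT <- rep(0.5, P)
  sd_catT <- lapply(prep$cats, function(cb) rep(0.5, cb$L - 1L))
  acc_lj <- integer(J); acc_gm <- 0L
  acc_bcT <- integer(P)
  acc_catT <- lapply(prep$cats, function(cb) integer(cb$L - 1L))

  n_keep <- max(0L, (n_iter - burn_in) %/% thin)
  nm <- .param_names(spec, prep)
  draws <- matrix(NA_real_, n_keep, length(nm), dimnames = list(NULL, nm))
  dev <- numeric(n_keep)
  k <- 0L
  shift_names <- c(paste0("b0_site[", prep$key, "]"),
                   paste0("b0_lake[", prep$lake_ids, "]"), "mu0")

  s2_of_site <- function() if (shared) rep(s2l, I) else s2l[lake]

  for (iter in seq_len(n_iter)) {
    ## site intercepts (vectorised component-wise Metropolis)
    prop <- b0s + sd_s * rnorm(I)
    eta_p <- eta + (prop - b0s)
    s2s <- s2_of_site()
    d <- llfun(eta_p, y, size, sigma2) - llfun(eta, y, size, sigma2) +
      (-(prop - b0l[lake])^2 + (b0s - b0l[lake])^2) / (2 * s2s)
    acc <- log(runif(I)) < d
    b0s[acc] <- prop[acc]
    eta[acc] <- eta_p[acc]
    acc_s <- acc_s + acc

    ## lake means
    prop_l <- b0l + sd_l * rnorm(J)
    s2j <- if (shared) rep(s2l, J) else s2l
    dev_sites <- as.vector(
      rowsum(-(b0s - prop_l[lake])^2 + (b0s - b0l[lake])^2, lake)) /
      (2 * s2j)
    d <- dev_sites + (-(prop_l - mu0)^2 + (b0l - mu0)^2) / (2 * tau2)
    acc <- log(runif(J)) < d
    b0l[acc] <- prop_l[acc]
    acc_l <- acc_l + acc

    ## within-lake variance(s): conjugate Gibbs
    ssr <- (b0s - b0l[lake])^2
    if (shared) {
      s2l <- 1 / rgamma(1L, .prior_gamma + I / 2,
                        rate = .prior_gamma + sum(ssr) / 2)
    } else {
      s2l <- 1 / rgamma(J, .prior_gamma + n_j / 2,
                        rate = .prior_gamma + as.vector(rowsum(ssr, lake)) / 2)
    }

    ## hypermean
    prop_m <- mu0 + sd_m * rnorm(1L)
    d <- sum(-(b0l - prop_m)^2 + (b0l - mu0)^2) / (2 * tau2) +
      dnorm(prop_m, 0, .prior_sd_effect, log = TRUE) -
      dnorm(mu0, 0, .prior_sd_effect, log = TRUE)
    if (log(runif(1L)) < d) { mu0 <- prop_m; acc_m <- acc_m + 1L }

    ## hypervariance: Gibbs
    tau2 <- 1 / rgamma(1L, .prior_gamma + J / 2,
                       rate = .prior_gamma + sum((b0l - mu0)^2) / 2)

    ## categorical zero-sum blocks: K-1 free effects, last = -sum(free)
    for (b in seq_along(prep$cats)) {
      cb <- prep$cats[[b]]
      for (r in seq_len(cb$L - 1L)) {
        delta <- sd_cat[[b]][r] * rnorm(1L)
        sel <- cb$idx == r | cb$idx == cb$L
        w <- (cb$idx[sel] == r) - (cb$idx[sel] == cb$L)
        eta_sel <- eta[sel]
        eta_sel_p <- eta_sel + delta * w
        d <- sum(llfun(eta_sel_p, y[sel], size[sel], sigma2) -
                 llfun(eta_sel, y[sel], size[sel], sigma2)) +
          dnorm(eff[[b]][r] + delta, 0, .prior_sd_effect, log = TRUE) -
          dnorm(eff[[b]][r], 0, .prior_sd_effect, log = TRUE)
        if (log(runif(1L)) < d) {
          eff[[b]][r] <- eff[[b]][r] + delta
          eff[[b]][cb$L] <- eff[[b]][cb$L] - delta
          eta[sel] <- eta_sel_p
          acc_cat[[b]][r] <- acc_cat[[b]][r] + 1L
        }
      }
    }

    ## continuous slopes
    for (p in seq_len(P)) {
      delta <- sd_bc[p] * rnorm(1L)
      eta_p <- eta + delta * prep$Z[, p]
      d <- sum(llfun(eta_p, y, size, sigma2) - llfun(eta, y, size, sigma2)) +
        dnorm(bc[p] + delta, 0, .prior_sd_effect, log = TRUE) -
        dnorm(bc[p], 0, .prior_sd_effect, log = TRUE)
      if (log(runif(1L)) < d) {
        bc[p] <- bc[p] + delta
        eta <- eta_p
        acc_bc[p] <- acc_bc[p] + 1L
      }
    }

    ## translation sweeps: joint moves that shift a higher-level parameter
    ## together with the intercept layers so the linear predictor (and
    ## hence the likelihood) is unchanged where possible. These cure the
    ## slow random-walk mixing that conditioning on the nested intercepts
    ## would otherwise cause.

    ## (a) lake blocks: shift a lake mean together with its sites
    prop_d <- sd_lj * rnorm(J)
    eta_p <- eta + prop_d[lake]
    ll_diff <- as.vector(rowsum(llfun(eta_p, y, size, sigma2) -
                                llfun(eta, y, size, sigma2), lake))
    d <- ll_diff + (-(b0l + prop_d - mu0)^2 + (b0l - mu0)^2) / (2 * tau2)
    acc <- log(runif(J)) < d
    if (any(acc)) {
      b0l[acc] <- b0l[acc] + prop_d[acc]
      adj <- ifelse(acc, prop_d, 0)
      b0s <- b0s + adj[lake]
      eta <- eta + adj[lake]
    }
    acc_lj <- acc_lj + acc

    ## (b) global level: shift mu0 with both intercept layers
    delta <- sd_gm * rnorm(1L)
    d <- sum(llfun(eta + delta, y, size, sigma2) -
             llfun(eta, y, size, sigma2)) +
      dnorm(mu0 + delta, 0, .prior_sd_effect, log = TRUE) -
      dnorm(mu0, 0, .prior_sd_effect, log = TRUE)
    if (log(runif(1L)) < d) {
      mu0 <- mu0 + delta; b0l <- b0l + delta; b0s <- b0s + delta
      eta <- eta + delta
      acc_gm <- acc_gm + 1L
    }

    ## (c) continuous slopes: beta_p += delta with compensating intercept
    ## shifts (likelihood-invariant; only the prior layers move)
    s2s <- s2_of_site()
    for (p in seq_len(P)) {
      delta <- sd_bcT[p] * rnorm(1L)
      rlake <- b0l - mu0
      d <- sum(-(rlake - delta * zbar[, p])^2 + rlake^2) / (2 * tau2) +
        dnorm(bc[p] + delta, 0, .prior_sd_effect, log = TRUE) -
        dnorm(bc[p], 0, .prior_sd_effect, log = TRUE)
      dv <- zdev[, p]
      if (any(dv != 0)) {
        rsite <- b0s - b0l[lake]
        d <- d + sum((-(rsite - delta * dv)^2 + rsite^2) / (2 * s2s))
      }
      if (log(runif(1L)) < d) {
        bc[p] <- bc[p] + delta
        b0l <- b0l - delta * zbar[, p]
        b0s <- b0s - delta * prep$Z[, p]
        acc_bcT[p] <- acc_bcT[p] + 1L
      }
    }

    ## (d) categorical effects, same construction
    for (b in seq_along(prep$cats)) {
      cb <- prep$cats[[b]]
      for (r in seq_len(cb$L - 1L)) {
        delta <- sd_catT[[b]][r] * rnorm(1L)
        w <- (cb$idx == r) - (cb$idx == cb$L)
        wb <- wbar[[b]][, r]
        rlake <- b0l - mu0
        d <- sum(-(rlake - delta * wb)^2 + rlake^2) / (2 * tau2) +
          dnorm(eff[[b]][r] + delta, 0, .prior_sd_effect, log = TRUE) -
          dnorm(eff[[b]][r], 0, .prior_sd_effect, log = TRUE)
        dv <- w - wb[lake]
        if (any(dv != 0)) {
          rsite <- b0s - b0l[lake]
          d <- d + sum((-(rsite - delta * dv)^2 + rsite^2) / (2 * s2s))
        }
        if (log(runif(1L)) < d) {
          eff[[b]][r] <- eff[[b]][r] + delta
          eff[[b]][cb$L] <- eff[[b]][cb$L] - delta
          b0l <- b0l - delta * wb
          b0s <- b0s - delta * w
          acc_catT[[b]][r] <- acc_catT[[b]][r] + 1L
        }
      }
    }

    ## observation variance: Gibbs (normal family)
    if (spec$family == "normal") {
      sigma2 <- 1 / rgamma(1L, .prior_gamma + I / 2,
                           rate = .prior_gamma + sum((z - eta)^2) / 2)
    }

    ## adaptation (frozen after n_adapt)
    if (iter %% 50L == 0L) {
      if (iter <= n_adapt) {
        tune <- function(sd, acc) {
          rate <- acc / 50
          sd * ifelse(rate > 0.4, 1.1, ifelse(rate < 0.2, 1 / 1.1, 1))
        }
        sd_s <- tune(sd_s, acc_s); sd_l <- tune(sd_l, acc_l)
        sd_m <- tune(sd_m, acc_m)
        for (b in seq_along(sd_cat)) sd_cat[[b]] <- tune(sd_cat[[b]],
                                                         acc_cat[[b]])
        sd_bc <- tune(sd_bc, acc_bc)
        sd_lj <- tune(sd_lj, acc_lj); sd_gm <- tune(sd_gm, acc_gm)
        sd_bcT <- tune(sd_bcT, acc_bcT)
        for (b in seq_along(sd_catT)) sd_catT[[b]] <- tune(sd_catT[[b]],
                                                           acc_catT[[b]])
      } else {
        tot_acc <- tot_acc + sum(acc_s) + sum(acc_l) + acc_m +
          sum(unlist(acc_cat)) + sum(acc_bc) + sum(acc_lj) + acc_gm +
          sum(acc_bcT) + sum(unlist(acc_catT))
        tot_prop <- tot_prop +
          50 * (I + 2L * J + 2L + 2L * length(unlist(acc_cat)) + 2L * P)
      }
      acc_s[] <- 0L; acc_l[] <- 0L; acc_m <- 0L
      for (b in seq_along(acc_cat)) acc_cat[[b]][] <- 0L
      acc_bc[] <- 0L
      acc_lj[] <- 0L; acc_gm <- 0L; acc_bcT[] <- 0L
      for (b in seq_along(acc_catT)) acc_catT[[b]][] <- 0L
    }

    ## storage
    if (iter > burn_in && (iter - burn_in) %% thin == 0L) {
      k <- k + 1L
      shift <- if (P) sum(bc * prep$centers) else 0
      row <- c(b0s - shift, b0l - shift, s2l, mu0 - shift, tau2,
               unlist(eff, use.names = FALSE), bc,
               if (spec$family == "normal") sigma2)
      draws[k, ] <- row
      dev[k] <- -2 * sum(llfun(eta, y, size, sigma2))
    }
  }
  list(draws = draws, deviance = dev,
       acceptance = if (tot_prop > 0) tot_acc / tot_prop else NA_real_)
}

#' Fit the hierarchical Bayesian ANCOVA
#'
#' Draws from the posterior of the nested-intercept ANCOVA by adaptive
#' random-walk Metropolis (conjugate Gibbs for the variance components),
#' with multiple chains, burn-in, thinning, Gelman-Rubin and
#' Monte-Carlo-error diagnostics, and DIC.
#'
#' @param spec an [model_spec()] object.
#' @param data per-site data frame (see [ancova_data()]).
#' @param n_iter iterations per chain (default 50000).
#' @param n_chains number of chains (default 2).
#' @param n_adapt iterations over which proposal SDs adapt (default 4000).
#' @param burn_in discarded initial iterations (default 5000).
#' @param thin keep every `thin`-th post-burn-in draw (default 10).
#' @param seed integer seed; chain `c` uses `seed + 7919 * (c - 1)`, so a
#'   fixed seed gives a bit-identical draw sequence.
#' @return Object of class `ancova_fit` with elements `draws` (list of
#'   per-chain matrices, columns named by parameter), `deviance` (per-chain
#'   vectors), `summary` (posterior mean, SD, 2.5/50/97.5 percentiles,
#'   Rhat, MC-error ratio), `acceptance_rates`, `dbar`, `d_at_mean`, `pd`,
#'   `dic`.
#' @export
fit_ancova <- function(spec, data, n_iter = 50000, n_chains = 2,
                       n_adapt = 4000, burn_in = 5000, thin = 10,
                       seed = 1) {
  stopifnot(inherits(spec, "ancova_spec"))
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter",
                              call. = FALSE)
  prep <- .ancova_prep(spec, data)
  chains <- lapply(seq_len(n_chains), function(cc)
    .run_chain(spec, prep, n_iter, n_adapt, burn_in, thin,
               seed = as.integer(seed + 7919 * (cc - 1L))))
  draws <- lapply(chains, `[[`, "draws")
  devs <- lapply(chains, `[[`, "deviance")
  acc <- vapply(chains, `[[`, numeric(1), "acceptance")
  if (any(!is.na(acc) & (acc < 0.05 | acc > 0.7)))
    warning("post-adaptation Metropolis acceptance rate far outside the ",
            "20-40% target; consider longer adaptation", call. = FALSE)
  all_draws <- do.call(rbind, draws)
  post_mean <- colMeans(all_draws)
  post_sd <- apply(all_draws, 2L, sd)
  qs <- t(apply(all_draws, 2L, quantile, probs = c(0.025, 0.5, 0.975)))
  rhat <- if (n_chains >= 2L) gelman_rubin(draws) else
    rep(NA_real_, ncol(all_draws))
  mcr <- mc_error_ratio(all_draws)
  summary <- data.frame(parameter = colnames(all_draws),
                        mean = post_mean, sd = post_sd,
                        q2.5 = qs[, 1L], median = qs[, 2L], q97.5 = qs[, 3L],
                        rhat = rhat, mc_error_ratio = mcr,
                        row.names = NULL, stringsAsFactors = FALSE)
  fit <- structure(list(spec = spec, draws = draws, deviance = devs,
                        acceptance_rates = acc, summary = summary,
                        prep = prep, data = data, n_iter = n_iter,
                        burn_in = burn_in, thin = thin, n_chains = n_chains,
                        seed = seed),
                   class = "ancova_fit")
  fit[c("dbar", "d_at_mean", "pd", "dic")] <- dic(fit, spec, data)
  if (spec$family == "normal") fit$marginal <- .marginal_dic(fit)
  fit
}

#' Rebuild a `linear_predictor()` state from a parameter vector
#'
#' @param params named numeric vector (e.g. a draw row or posterior means).
#' @param fit an `ancova_fit` object.
#' @return state list usable with [linear_predictor()] and
#'   [log_likelihood()].
#' @export
state_from_params <- function(params, fit) {
  prep <- fit$prep; spec <- fit$spec
  take <- function(prefix, keys) {
    v <- params[paste0(prefix, "[", keys, "]")]
    names(v) <- keys
    v
  }
  state <- list(beta0_site = take("b0_site", prep$key))
  blocks <- c(lake_type = "beta1", vegetation = "beta2", substrate = "beta3")
  for (b in names(prep$cats))
    state[[blocks[[b]]]] <- take(paste0("beta_", b), prep$cats[[b]]$levels)
  if (length(spec$continuous)) {
    bc <- take("beta", spec$continuous)
    state$beta_cont <- as.list(bc)
  }
  if (spec$family == "normal") state$sigma2 <- unname(params["sigma2"])
  state
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`, where `Dbar` is the
#' posterior mean deviance (deviance = -2 log-likelihood, averaged over the
#' stored draws) and `D(theta_bar)` the deviance at the posterior mean of
#' each parameter (variances averaged on the variance scale).
#'
#' Two deviance focuses are available. The `"conditional"` focus evaluates
#' the observation likelihood given the site intercepts. Because each site
#' contributes one response, the site intercepts can track the data
#' regardless of which lake-level covariates are present, so the
#' conditional deviance barely reacts to terms such as latitude or water
#' chemistry. The `"marginal"` focus (normal family only) integrates the
#' nested intercepts out analytically -- each lake contributes a
#' multivariate normal with compound-symmetric covariance
#' `(sigma2 + s2_lake) I + tau2_0 J` -- and is the appropriate focus for
#' comparing covariate structures. Its plug-in point estimate uses
#' posterior means for location parameters and posterior medians for the
#' variance components, whose heavy-tailed posteriors make means poor
#' central values.
#'
#' @param fit an `ancova_fit`.
#' @param spec,data the model specification and data used for the fit
#'   (defaulting to those stored in the fit).
#' @param focus `"conditional"` (default) or `"marginal"`.
#' @return list with `dbar`, `d_at_mean`, `pd`, `dic`.
#' @export
dic <- function(fit, spec = fit$spec, data = fit$data,
                focus = c("conditional", "marginal")) {
  focus <- match.arg(focus)
  if (focus == "marginal") {
    if (spec$family != "normal")
      stop("marginal DIC is implemented for the normal family only",
           call. = FALSE)
    return(.marginal_dic(fit))
  }
  devs <- unlist(fit$deviance)
  if (!length(devs)) stop("no stored draws", call. = FALSE)
  dbar <- mean(devs)
  post_mean <- setNames(fit$summary$mean, fit$summary$parameter)
  state <- state_from_params(post_mean, fit)
  d_at_mean <- -2 * log_likelihood(state, spec, data)
  pd <- dbar - d_at_mean
  list(dbar = dbar, d_at_mean = d_at_mean, pd = pd, dic = dbar + pd)
}

# Marginal (random-effects-integrated) deviance for the normal family.
# For lake j with n_j sites, z_j | theta ~ N(mu0 + c_j, a_j I + b J) with
# a_j = sigma2 + s2_lake[j], b = tau2_0 and c the categorical + continuous
# fixed part; log-density via the closed-form determinant and inverse of a
# compound-symmetric matrix.
.marginal_dev_rows <- function(fit, params) {
  # params: matrix (rows = draws) of the stored parameter columns
  prep <- fit$prep; spec <- fit$spec
  z <- prep$z
  I <- prep$n_sites; J <- prep$n_lakes
  lake <- prep$lake
  n_j <- tabulate(lake, nbins = J)
  ind <- matrix(0, I, J); ind[cbind(seq_len(I), lake)] <- 1

  cmat <- matrix(params[, "mu0"], nrow(params), I)
  for (b in names(prep$cats)) {
    cb <- prep$cats[[b]]
    eff <- params[, paste0("beta_", b, "[", cb$levels, "]"), drop = FALSE]
    cmat <- cmat + eff[, cb$idx, drop = FALSE]
  }
  if (length(spec$continuous)) {
    Zu <- vapply(spec$continuous, function(v)
      .cov_value(fit$data, v, spec), numeric(I))
    bc <- params[, paste0("beta[", spec$continuous, "]"), drop = FALSE]
    cmat <- cmat + bc %*% t(matrix(Zu, nrow = I))
  }
  r <- matrix(z, nrow(params), I, byrow = TRUE) - cmat
  Sr <- r %*% ind            # draws x J, per-lake residual sums
  rr <- (r * r) %*% ind
  s2l <- if (spec$shared_site_variance)
    matrix(params[, "s2_site"], nrow(params), J) else
    params[, paste0("s2_lake[", prep$lake_ids, "]"), drop = FALSE]
  a <- params[, "sigma2"] + s2l      # draws x J
  b <- params[, "tau2_0"]            # length draws, recycled by column
  anb <- a + b * matrix(n_j, nrow(params), J, byrow = TRUE)
  ld <- sweep(log(a), 2, n_j - 1, function(x, k) x * k) + log(anb)
  quad <- rr / a - b * Sr^2 / (a * anb)
  rowSums(ld + quad) + I * log(2 * pi)
}

.marginal_dic <- function(fit) {
  params <- do.call(rbind, fit$draws)
  dev <- .marginal_dev_rows(fit, params)
  dbar <- mean(dev)
  # plug-in: posterior means for location parameters, posterior medians for
  # the variance components -- their heavy-tailed posteriors (notably the
  # per-lake variances of one-site lakes) make the mean a poor central
  # value for the marginal density
  center <- colMeans(params)
  vcols <- grepl("^s2_lake\\[|^s2_site$|^tau2_0$|^sigma2$", colnames(params))
  center[vcols] <- apply(params[, vcols, drop = FALSE], 2L, median)
  d_at_mean <- as.numeric(.marginal_dev_rows(
    fit, matrix(center, 1, ncol(params),
                dimnames = list(NULL, colnames(params)))))
  pd <- dbar - d_at_mean
  list(dbar = dbar, d_at_mean = d_at_mean, pd = pd, dic = dbar + pd)
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("Hierarchical Bayesian ANCOVA: %s (%s family)\n",
              x$spec$response, x$spec$family))
  cat(sprintf("  %d sites in %d lakes; %d chain(s) x %d iterations ",
              x$prep$n_sites, x$prep$n_lakes, x$n_chains, x$n_iter))
  cat(sprintf("(burn-in %d, thin %d)\n", x$burn_in, x$thin))
  cat(sprintf("  DIC = %.2f (Dbar = %.2f, pD = %.2f)\n",
              x$dic, x$dbar, x$pd))
  show <- x$summary[!grepl("^b0_site|^s2_lake", x$summary$parameter), ]
  print(head(show, 25), digits = 3, row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# diagnostics

#' Gelman-Rubin potential scale reduction factor
#'
#' Brooks-Gelman PSRF per parameter: with `m` chains of length `n`, pooled
#' within-chain variance `W` and between-chain variance `B`, the statistic is
#' `sqrt(((n-1)/n * W + B/n) / W)`. Values near 1 indicate convergence.
#'
#' @param draws list of per-chain draw matrices (or vectors) with identical
#'   columns.
#' @return named numeric vector of PSRFs (NA for constant parameters).
#' @export
gelman_rubin <- function(draws) {
  if (!is.list(draws) || length(draws) < 2L)
    stop("need at least 2 chains", call. = FALSE)
  mats <- lapply(draws, function(d) if (is.matrix(d)) d else cbind(par = d))
  n <- nrow(mats[[1L]])
  means <- sapply(mats, colMeans)
  vars <- sapply(mats, function(m) apply(m, 2L, var))
  if (is.null(dim(means))) { means <- rbind(means); vars <- rbind(vars) }
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1L, var)
  vhat <- (n - 1) / n * W + B_over_n
  out <- sqrt(vhat / W)
  out[W == 0 & B_over_n == 0] <- 1
  out[W == 0 & B_over_n > 0] <- Inf
  setNames(out, colnames(mats[[1L]]))
}

#' Monte-Carlo error relative to the posterior SD
#'
#' Batch-means estimate of the Monte-Carlo standard error of the posterior
#' mean, divided by the posterior SD. Parameters with a ratio at or above
#' 5% are conventionally considered too noisy to summarise.
#'
#' @param draws numeric vector or matrix (columns = parameters).
#' @param batch_size batch length (default `floor(sqrt(n))`).
#' @return named numeric vector of ratios (NaN for constant parameters,
#'   which are flagged via attribute `flagged` together with ratios
#'   `>= 0.05`).
#' @export
mc_error_ratio <- function(draws, batch_size = NULL) {
  m <- if (is.matrix(draws)) draws else cbind(par = draws)
  n <- nrow(m)
  bs <- if (is.null(batch_size)) max(1L, floor(sqrt(n))) else batch_size
  nb <- n %/% bs
  if (nb < 2L) stop("too few draws for batch means", call. = FALSE)
  idx <- rep(seq_len(nb), each = bs)
  bm <- rowsum(m[seq_len(nb * bs), , drop = FALSE], idx) / bs
  mcse <- apply(bm, 2L, sd) / sqrt(nb)
  ratio <- mcse / apply(m, 2L, sd)
  attr(ratio, "flagged") <- is.nan(ratio) | ratio >= 0.05
  ratio
}

# ---------------------------------------------------------------------------
# generic adaptive Metropolis engine (used for closed-form cross-checks and
# small custom posteriors)

#' Component-wise adaptive random-walk Metropolis sampler
#'
#' Generic engine: symmetric normal proposals per component, proposal SD
#' multiplied or divided by 1.1 per 50-iteration batch while the batch
#' acceptance rate is outside 20--40%, adaptation frozen after `n_adapt`
#' iterations.
#'
#' @param log_post function taking the full parameter vector, returning the
#'   unnormalised log posterior.
#' @param init named numeric start vector.
#' @param n_iter total iterations.
#' @param n_adapt adaptation horizon (default `min(n_iter %/% 2, 4000)`).
#' @param burn_in discarded draws (default `n_adapt`).
#' @param sd0 initial proposal SD (scalar or per-component).
#' @param seed optional integer seed.
#' @return list with `draws` (matrix), `acceptance` (per component),
#'   `proposal_sd`.
#' @export
adaptive_metropolis <- function(log_post, init, n_iter,
                                n_adapt = min(n_iter %/% 2L, 4000L),
                                burn_in = n_adapt, sd0 = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(init)
  x <- init
  lp <- log_post(x)
  if (!is.finite(lp)) stop("log_post not finite at init", call. = FALSE)
  sds <- rep_len(sd0, p)
  acc_batch <- integer(p); acc_tot <- integer(p)
  keep <- n_iter - burn_in
  draws <- matrix(NA_real_, keep, p,
                  dimnames = list(NULL, names(init)))
  for (iter in seq_len(n_iter)) {
    for (j in seq_len(p)) {
      prop <- x
      prop[j] <- x[j] + sds[j] * rnorm(1L)
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) && log(runif(1L)) < lp_prop - lp) {
        x <- prop; lp <- lp_prop
        acc_batch[j] <- acc_batch[j] + 1L
        if (iter > burn_in) acc_tot[j] <- acc_tot[j] + 1L
      }
    }
    if (iter %% 50L == 0L) {
      if (iter <= n_adapt) {
        rate <- acc_batch / 50
        sds <- sds * ifelse(rate > 0.4, 1.1, ifelse(rate < 0.2, 1 / 1.1, 1))
      }
      acc_batch[] <- 0L
    }
    if (iter > burn_in) draws[iter - burn_in, ] <- x
  }
  list(draws = draws, acceptance = acc_tot / max(keep, 1L),
       proposal_sd = sds)
}

# ---------------------------------------------------------------------------
# DIC-based covariate selection

#' Rank covariate sets by DIC
#'
#' Exhaustively fits every inclusion pattern of the candidate categorical
#' and continuous terms (up to `max_models`) with a reduced sampler budget
#' and ranks the models by DIC in ascending order. Models within 2 DIC units
#' of the best are flagged as practically tied.
#'
#' @param response,family passed to [model_spec()].
#' @param data per-site data frame.
#' @param candidate_categorical,candidate_continuous term pools to search.
#' @param n_iter,n_chains,n_adapt,burn_in,thin reduced sampler settings per
#'   candidate fit.
#' @param seed integer seed; candidate `m` uses `seed + 104729 * m`.
#' @param max_models fitting budget; if the pattern count exceeds it, only
#'   the first `max_models` patterns are fitted and a warning marks the
#'   ranking as partial.
#' @param dic_focus deviance focus used for ranking (see [dic()]).
#'   `"auto"` (default) uses the marginal focus for the normal family --
#'   the conditional deviance is nearly invariant to lake-level covariates
#'   when every site carries its own intercept -- and the conditional focus
#'   otherwise.
#' @param ... further arguments to [model_spec()] (e.g. `size`,
#'   `shared_site_variance`).
#' @return Object of class `dic_ranking`: data frame with one row per
#'   fitted model (`terms`, `dbar`, `pd`, `dic`, `delta_dic`,
#'   `within_2_of_best`), best first; the winning [model_spec()] is in
#'   `attr(x, "best_spec")`.
#' @export
select_model <- function(response, data, family = "normal",
                         candidate_categorical = character(),
                         candidate_continuous = character(),
                         n_iter = 3000, n_chains = 1, n_adapt = 1000,
                         burn_in = 1000, thin = 5, seed = 1,
                         max_models = 256,
                         dic_focus = c("auto", "conditional", "marginal"),
                         ...) {
  dic_focus <- match.arg(dic_focus)
  if (dic_focus == "auto")
    dic_focus <- if (family == "normal") "marginal" else "conditional"
  if (dic_focus == "marginal" && family != "normal")
    stop("marginal DIC is implemented for the normal family only",
         call. = FALSE)
  terms <- c(candidate_categorical, candidate_continuous)
  is_cat <- c(rep(TRUE, length(candidate_categorical)),
              rep(FALSE, length(candidate_continuous)))
  n_terms <- length(terms)
  patterns <- if (n_terms) expand.grid(rep(list(c(FALSE, TRUE)), n_terms))
    else data.frame(row.names = 1L)
  n_pat <- max(nrow(patterns), 1L)
  partial <- FALSE
  if (n_pat > max_models) {
    warning("candidate set exceeds max_models; returning a partial ranking",
            call. = FALSE)
    partial <- TRUE
    n_pat <- max_models
  }
  rows <- vector("list", n_pat)
  specs <- vector("list", n_pat)
  for (m in seq_len(n_pat)) {
    inc <- if (n_terms) unlist(patterns[m, ]) else logical(0)
    spec <- model_spec(response, family,
                       categorical = terms[is_cat & inc],
                       continuous = terms[!is_cat & inc], ...)
    fit <- suppressWarnings(fit_ancova(
      spec, data, n_iter = n_iter, n_chains = n_chains,
      n_adapt = n_adapt, burn_in = burn_in, thin = thin,
      seed = as.integer((seed + 104729 * m) %% .Machine$integer.max)))
    d <- if (dic_focus == "marginal") fit$marginal else
      fit[c("dbar", "d_at_mean", "pd", "dic")]
    lbl <- paste(terms[inc], collapse = "+")
    rows[[m]] <- data.frame(terms = if (nzchar(lbl)) lbl else "(intercept)",
                            n_terms = sum(inc), dbar = d$dbar,
                            pd = d$pd, dic = d$dic,
                            stringsAsFactors = FALSE)
    specs[[m]] <- spec
  }
  out <- do.call(rbind, rows)
  ord <- order(out$dic)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$delta_dic <- out$dic - out$dic[1L]
  out$within_2_of_best <- out$delta_dic < 2
  attr(out, "best_spec") <- specs[[ord[1L]]]
  attr(out, "partial") <- partial
  attr(out, "dic_focus") <- dic_focus
  class(out) <- c("dic_ranking", "data.frame")
  out
}

#' @export
print.dic_ranking <- function(x, ...) {
  cat("DIC model ranking (", nrow(x), " candidate models",
      if (isTRUE(attr(x, "partial"))) ", PARTIAL", ")\n", sep = "")
  print.data.frame(head(as.data.frame(x), 15), digits = 4, row.names = FALSE)
  invisible(x)
}
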