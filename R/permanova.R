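# One-way permutational ANOVA (Euclidean distances) with components of
# variation.
#
# For Euclidean distances the Anderson partition
#   SS_total  = sum_{i<j} d_ij^2 / N
#   SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g
# reduces coordinate-wise to the classical sums of squares, so the
# implementation works column-wise on the data matrix; univariate inputs
# reproduce the classical one-way ANOVA F statistic exactly, and permutation
# relabelling only needs group sums.

#' log(x + 1) transform
#'
#' The variance-stabilising transform applied to mass fractions before the
#' among-taxon partition.
#'
#' @param values non-negative numeric vector.
#' @return `log(values + 1)` (natural log).
#' @export
log1_transform <- function(values) {
  if (any(!is.finite(values))) stop("non-finite input", call. = FALSE)
  if (any(values < 0)) stop("negative input", call. = FALSE)
  log1p(values)
}

.ss_partition <- function(x, g) {
  # x: numeric matrix (N x p); g: integer group index
  n_g <- tabulate(g)
  tot <- colSums(x)
  gs <- rowsum(x, g)                       # group sums per coordinate
  ss_b <- sum(gs^2 / n_g) - sum(tot^2) / nrow(x)
  ss_t <- sum(x^2) - sum(tot^2) / nrow(x)
  c(between = ss_b, within = ss_t - ss_b, total = ss_t)
}

#' One-way PERMANOVA
#'
#' Partitions squared Euclidean distances among and within groups, forms the
#' pseudo-F ratio of mean squares, and attaches a permutation p-value (from
#' `n_perm` random relabellings, observed statistic included in numerator
#' and denominator), a Monte-Carlo p-value from the classical F reference
#' distribution, and components-of-variation effect sizes
#' (see [variance_components()]).
#'
#' @param values numeric vector (univariate) or matrix (rows = samples).
#' @param groups group labels, one per sample; at least 2 groups, each
#'   non-empty, and more samples than groups.
#' @param n_perm number of random relabellings (default 9999).
#' @param seed optional integer seed for the permutation stream.
#' @return Object of class `permanova`: df, SS, MS, `pseudo_f`, `p_perm`,
#'   `p_mc`, `n0`, `var_between`, `var_within`, `effect_size`.
#' @export
one_way_permanova <- function(values, groups, n_perm = 9999, seed = NULL) {
  x <- as.matrix(values)
  storage.mode(x) <- "double"
  g <- factor(groups)
  if (nrow(x) != length(g)) stop("values and groups differ in length",
                                 call. = FALSE)
  a <- nlevels(g)
  n <- nrow(x)
  if (a < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tabulate(as.integer(g), nbins = a) == 0L))
    stop("every group needs at least one sample", call. = FALSE)
  if (n <= a) stop("need more samples than groups", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  gi <- as.integer(g)
  ss <- .ss_partition(x, gi)
  df_b <- a - 1L
  df_w <- n - a
  ms_b <- ss[["between"]] / df_b
  ms_w <- ss[["within"]] / df_w
  f_obs <- ms_b / ms_w
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    ssp <- .ss_partition(x, gi[sample.int(n)])
    f_p <- (ssp[["between"]] / df_b) / (ssp[["within"]] / df_w)
    if (f_p >= f_obs) exceed <- exceed + 1L
  }
  p_perm <- (exceed + 1L) / (n_perm + 1L)
  p_mc <- pf(f_obs, df_b, df_w, lower.tail = FALSE)
  res <- permanova_from_partition(ss[["between"]], ss[["within"]],
                                  df_b, df_w)
  res$p_perm <- p_perm
  res$p_mc <- p_mc
  res$n_perm <- n_perm
  vc <- variance_components(res, tabulate(gi))
  res[names(vc)] <- vc
  res
}

#' PERMANOVA statistics from a printed partition
#'
#' Builds the deterministic part of a [one_way_permanova()] result directly
#' from sums of squares and degrees of freedom, as published in ANOVA
#' tables. Used for worked examples when the per-sample data are not
#' available.
#'
#' @param ss_between,ss_within sums of squares.
#' @param df_between,df_within degrees of freedom.
#' @return Object of class `permanova` with MS, `pseudo_f` and the
#'   Monte-Carlo p-value filled in; permutation p and variance components
#'   are `NA` until per-sample information is supplied.
#' @export
permanova_from_partition <- function(ss_between, ss_within,
                                     df_between, df_within) {
  ms_b <- ss_between / df_between
  ms_w <- ss_within / df_within
  structure(list(
    df_between = df_between, df_within = df_within,
    df_total = df_between + df_within,
    ss_between = ss_between, ss_within = ss_within,
    ss_total = ss_between + ss_within,
    ms_between = ms_b, ms_within = ms_w,
    pseudo_f = ms_b / ms_w,
    p_perm = NA_real_,
    p_mc = pf(ms_b / ms_w, df_between, df_within, lower.tail = FALSE),
    n_perm = NA_integer_,
    n0 = NA_real_, var_between = NA_real_, var_within = NA_real_,
    effect_size = NA_real_), class = "permanova")
}

#' Components of variation and effect size
#'
#' ANOVA-type variance components for an unbalanced one-way design:
#' `n0 = (N - sum(n_g^2)/N) / (a - 1)` (the effective group size),
#' `var_within = MS_within`,
#' `var_between = max(0, (MS_between - MS_within)/n0)` (negative estimates
#' floored at zero), and the effect size
#' `var_between / (var_between + var_within)` -- the between-group share of
#' total variance.
#'
#' @param result a `permanova` object (or any list with `ms_between`,
#'   `ms_within`).
#' @param group_sizes integer vector of group sample sizes.
#' @return list with `n0`, `var_between`, `var_within`, `effect_size`.
#' @export
variance_components <- function(result, group_sizes) {
  n <- sum(group_sizes)
  a <- length(group_sizes)
  if (n <= a) stop("degenerate design: one observation per group",
                   call. = FALSE)
  n0 <- (n - sum(group_sizes^2) / n) / (a - 1)
  var_w <- result$ms_within
  var_b <- max(0, (result$ms_between - result$ms_within) / n0)
  list(n0 = n0, var_between = var_b, var_within = var_w,
       effect_size = var_b / (var_b + var_w))
}

#' @export
print.permanova <- function(x, digits = 5, ...) {
  cat("One-way PERMANOVA (Euclidean)\n")
  tab <- data.frame(
    df = c(x$df_between, x$df_within, x$df_total),
    SS = signif(c(x$ss_between, x$ss_within, x$ss_total), digits),
    MS = c(signif(c(x$ms_between, x$ms_within), digits), NA),
    row.names = c("between", "within", "total"))
  print(tab)
  cat(sprintf("pseudo-F = %s", format(signif(x$pseudo_f, digits))))
  if (!is.na(x$p_perm))
    cat(sprintf(", P(perm) = %.4g [%d permutations]", x$p_perm, x$n_perm))
  cat(sprintf(", P(MC) = %.4g\n", x$p_mc))
  if (!is.na(x$effect_size))
    cat(sprintf("effect size (components of variation) = %.3f\n",
                x$effect_size))
  invisible(x)
}

#' PERMANOVA of taxon effects on each PUFA
#'
#' Convenience wrapper running [one_way_permanova()] on log(x+1)-transformed
#' ARA, EPA and DHA mass fractions from a long per-sample table.
#'
#' @param fa_samples data frame with columns `taxon`, `ara`, `epa`, `dha`
#'   (one row per analysed sample), e.g. from [generate_fa_samples()].
#' @param n_perm,seed passed to [one_way_permanova()]; each PUFA uses an
#'   offset seed so the three tests are independent.
#' @return named list of `permanova` objects (`ara`, `epa`, `dha`).
#' @export
pufa_permanova <- function(fa_samples, n_perm = 9999, seed = NULL) {
  out <- list()
  for (i in seq_along(PUFAS)) {
    p <- PUFAS[i]
    out[[p]] <- one_way_permanova(log1_transform(fa_samples[[p]]),
                                  fa_samples$taxon, n_perm = n_perm,
                                  seed = if (is.null(seed)) NULL else
                                    seed + i - 1L)
  }
  out
}
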