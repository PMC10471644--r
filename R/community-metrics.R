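# Community-level PUFA response variables.
#
# Each metric combines per-taxon abundances S_n from one site with a
# per-taxon PUFA content value FA_n. By default FA_n is the ordinal content
# class (1-5), the only content information carried into the large survey;
# mean mass fractions can be substituted via `fa_values = "mean"`.

.fa_values_for <- function(profiles, pufa, fa_values = c("class", "mean"),
                           derived = FALSE) {
  fa_values <- match.arg(fa_values)
  col <- if (fa_values == "class") {
    if (derived) paste0("derived_class_", pufa) else paste0("class_", pufa)
  } else paste0("mean_", pufa)
  fa <- profiles[[col]]
  if (is.null(fa)) stop("profiles lack column '", col, "'", call. = FALSE)
  names(fa) <- profiles$taxon
  fa
}

.align_counts <- function(counts, fa,
                          missing_taxa = c("error", "drop")) {
  missing_taxa <- match.arg(missing_taxa)
  if (is.null(names(counts))) stop("counts must be named by taxon",
                                   call. = FALSE)
  unknown <- setdiff(names(counts)[counts > 0], names(fa))
  if (length(unknown)) {
    if (missing_taxa == "error")
      stop("taxa missing from the profile table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    warning("dropping taxa missing from the profile table: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  s <- setNames(numeric(length(fa)), names(fa))
  common <- intersect(names(counts), names(fa))
  s[common] <- counts[common]
  s
}

#' Taxon richness of one site
#'
#' @param counts named (by taxon) vector of abundances.
#' @return number of taxa with positive abundance.
#' @export
richness <- function(counts) sum(counts > 0)

#' PUFA-weighted total abundance
#'
#' Total community abundance after weighting each taxon's abundance by its
#' PUFA content: `sum(S_n * FA_n) / sum(FA_n)`, with both sums running over
#' the full taxon universe `N` of the profile table (absent taxa contribute
#' zero to the numerator only, so the denominator is a dataset constant).
#'
#' @param counts named vector of abundances `S_n`.
#' @param fa named vector of per-taxon content values `FA_n` over the full
#'   taxon universe.
#' @param missing_taxa policy for abundant taxa absent from `fa`:
#'   `"error"` (default) or `"drop"` with a warning.
#' @return non-negative scalar.
#' @export
abundance_fa_weighted <- function(counts, fa, missing_taxa = "error") {
  s <- .align_counts(counts, fa, missing_taxa)
  denom <- sum(fa)
  if (denom <= 0) stop("sum of FA_n over the taxon universe must be > 0",
                       call. = FALSE)
  sum(s * fa) / denom
}

#' Abundance-weighted mean PUFA content
#'
#' `sum(S_n * FA_n) / sum(S_n)`: the mean content value of an individual
#' drawn from the community, i.e. a community-weighted mean trait.
#'
#' @inheritParams abundance_fa_weighted
#' @return scalar between the smallest and largest `FA_n` among present taxa.
#' @export
fa_abundance_weighted <- function(counts, fa, missing_taxa = "error") {
  s <- .align_counts(counts, fa, missing_taxa)
  tot <- sum(s)
  if (tot <= 0) stop("undefined weighted mean: empty community",
                     call. = FALSE)
  sum(s * fa) / tot
}

#' Total PUFA content of the community
#'
#' `sum(S_n * FA_n)`; equals [abundance_fa_weighted()] times the constant
#' `sum(FA_n)`.
#'
#' @inheritParams abundance_fa_weighted
#' @return non-negative scalar.
#' @export
fa_x_abundance <- function(counts, fa, missing_taxa = "error") {
  s <- .align_counts(counts, fa, missing_taxa)
  sum(s * fa)
}

#' Count (and fraction) of PUFA-rich taxa present
#'
#' Counts the present taxa whose ordinal content class exceeds the threshold
#' (3: classes 4 and 5; 4: class 5 only).
#'
#' @param counts named vector of abundances.
#' @param classes named vector of ordinal classes 1--5 over the taxon
#'   universe.
#' @param threshold 3 or 4.
#' @param missing_taxa policy for abundant taxa absent from `classes`.
#' @return integer count; [pct_rich_taxa()] returns `count / richness`
#'   (a proportion in `[0, 1]`).
#' @export
count_rich_taxa <- function(counts, classes, threshold,
                            missing_taxa = "error") {
  if (!threshold %in% c(3, 4)) stop("threshold must be 3 or 4",
                                    call. = FALSE)
  s <- .align_counts(counts, classes, missing_taxa)
  sum(s > 0 & classes > threshold)
}

#' @rdname count_rich_taxa
#' @export
pct_rich_taxa <- function(counts, classes, threshold,
                          missing_taxa = "error") {
  rich <- richness(counts)
  if (rich == 0) return(0)
  count_rich_taxa(counts, classes, threshold, missing_taxa) / rich
}

#' Per-site community response variables
#'
#' Computes, for every site of a survey and every PUFA, the response
#' variables fed to the Bayesian models: richness, total abundance,
#' PUFA-weighted abundance, abundance-weighted content, content-by-abundance
#' product sum, and counts/percentages of PUFA-rich (class > 3, class > 4)
#' taxa. Per-PUFA columns are suffixed `_ara`, `_epa`, `_dha`.
#'
#' @param survey a `pufa_survey` data frame.
#' @param profiles a `taxon_profiles` data frame (optionally with derived
#'   classes from [classify_all()]).
#' @param fa_values use the ordinal `"class"` (default) or the `"mean"` mass
#'   fraction as the content value `FA_n` in the weighted metrics.
#' @param use_derived_classes use `derived_class_*` columns instead of the
#'   recorded `class_*` columns.
#' @param missing_taxa policy for survey taxa absent from the profile table.
#' @return data frame of class `community_responses`, one row per site.
#' @export
community_responses <- function(survey, profiles,
                                fa_values = c("class", "mean"),
                                use_derived_classes = FALSE,
                                missing_taxa = "error") {
  fa_values <- match.arg(fa_values)
  validate_survey(survey)
  taxa <- attr(survey, "taxa")
  counts <- as.matrix(survey[taxa])
  out <- data.frame(lake_id = survey$lake_id, site_id = survey$site_id,
                    stringsAsFactors = FALSE)
  out$richness <- apply(counts, 1L, function(x) sum(x > 0))
  out$total_abundance <- rowSums(counts)
  for (p in PUFAS) {
    fa <- .fa_values_for(profiles, p, fa_values, derived = use_derived_classes)
    cl <- .fa_values_for(profiles, p, "class", derived = use_derived_classes)
    res <- t(apply(counts, 1L, function(x) {
      s <- setNames(as.numeric(x), taxa)
      c(abundance_fa_weighted(s, fa, missing_taxa),
        fa_abundance_weighted(s, fa, missing_taxa),
        fa_x_abundance(s, fa, missing_taxa),
        count_rich_taxa(s, cl, 3, missing_taxa),
        count_rich_taxa(s, cl, 4, missing_taxa),
        pct_rich_taxa(s, cl, 3, missing_taxa),
        pct_rich_taxa(s, cl, 4, missing_taxa))
    }))
    colnames(res) <- paste0(c("abundance_fa_weighted_", "fa_abundance_weighted_",
                              "fa_x_abundance_", "count_gt3_", "count_gt4_",
                              "pct_gt3_", "pct_gt4_"), p)
    out <- cbind(out, as.data.frame(res))
  }
  class(out) <- c("community_responses", "data.frame")
  out
}

#' Log--log regression of richness on total abundance
#'
#' Ordinary least squares of `ln(richness)` on `ln(total abundance)` across
#' sites, summarising how much of the richness variability total abundance
#' explains.
#'
#' @param richness,abundance positive numeric vectors (>= 3 sites).
#' @return list with `slope`, `intercept`, `r_squared`, `slope_se`, `n`.
#' @export
loglog_richness_regression <- function(richness, abundance) {
  if (length(richness) != length(abundance) || length(richness) < 3L)
    stop("need >= 3 paired sites", call. = FALSE)
  if (any(richness <= 0) || any(abundance <= 0))
    stop("richness and abundance must be positive for log-log regression",
         call. = FALSE)
  if (var(log(richness)) == 0) {
    return(list(slope = 0, intercept = log(richness[1L]), r_squared = 0,
                slope_se = 0, n = length(richness)))
  }
  fit <- lm(log(richness) ~ log(abundance))
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = sm$r.squared,
       slope_se = unname(sm$coefficients[2L, 2L]), n = length(richness))
}
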