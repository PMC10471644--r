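# Quartile-based ordinal classification of taxon PUFA content.
#
# Class 1 marks taxa in which a fatty acid was not detected (mean mass
# fraction 0); classes 2-5 are the four quartile bins of the mass-fraction
# values, with lower-inclusive interval closure.

#' Quartile class boundaries for one PUFA
#'
#' Computes the three quartile cut points (q1, q2, q3) of a set of mass
#' fractions by linear interpolation of order statistics
#' (`stats::quantile(type = 7)`, position `p*(n-1)+1` on the sorted
#' sample). Zeros (not-detected taxa) are included in the sample.
#'
#' @param values numeric mass fractions (ug/mg DW), all `>= 0`, at least 4.
#' @param pufa label, one of `"ara"`, `"epa"`, `"dha"` (free-form labels are
#'   accepted for generic use).
#' @return An object of class `class_boundaries`: list with `pufa`, `q1`,
#'   `q2`, `q3` and the interval convention.
#' @examples
#' compute_boundaries(1:8, "ara") # q1 2.75, q2 4.5, q3 6.25
#' @export
compute_boundaries <- function(values, pufa = "pufa") {
  if (length(values) < 4L) stop("need at least 4 values", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite mass fraction", call. = FALSE)
  if (any(values < 0)) stop("negative mass fraction", call. = FALSE)
  q <- unname(quantile(values, probs = c(0.25, 0.5, 0.75), type = 7))
  structure(list(pufa = pufa, q1 = q[1], q2 = q[2], q3 = q[3],
                 convention = "lower-inclusive"),
            class = "class_boundaries")
}

#' @export
print.class_boundaries <- function(x, ...) {
  cat(sprintf("PUFA class boundaries (%s): q1 = %g, q2 = %g, q3 = %g\n",
              x$pufa, x$q1, x$q2, x$q3))
  cat("classes: 1 = not detected; 2 < q1; 3 in [q1, q2); 4 in [q2, q3);",
      "5 >= q3\n")
  invisible(x)
}

#' Assign ordinal content classes 1--5
#'
#' Class 1 is reserved for exactly zero (not detected). Positive values fall
#' into the quartile bins with lower-inclusive closure: class 2 below `q1`,
#' class 3 in `[q1, q2)`, class 4 in `[q2, q3)`, class 5 at or above `q3`.
#'
#' @param value numeric vector of mass fractions, `>= 0`.
#' @param boundaries a [compute_boundaries()] result.
#' @return integer vector of classes in 1--5.
#' @export
assign_class <- function(value, boundaries) {
  stopifnot(inherits(boundaries, "class_boundaries"))
  if (any(!is.finite(value))) stop("non-finite mass fraction", call. = FALSE)
  if (any(value < 0)) stop("negative mass fraction", call. = FALSE)
  cl <- 2L + (value >= boundaries$q1) + (value >= boundaries$q2) +
    (value >= boundaries$q3)
  cl[value == 0] <- 1L
  as.integer(cl)
}

#' Derive classes for all taxa and audit against printed classes
#'
#' Computes per-PUFA quartile boundaries over all taxon mean mass fractions
#' (zeros included), assigns derived classes, and compares them with the
#' classes recorded in the profile table. Disagreements are reported together
#' with the distance of the (1-decimal, rounded) printed mean from the
#' nearest derived boundary; a disagreement within `rounding_margin` of a
#' boundary is a rounding-induced boundary case rather than a real conflict.
#'
#' @param profiles a `taxon_profiles` data frame (at least 4 taxa).
#' @param rounding_margin half-width of the printed rounding interval
#'   (ug/mg DW); defaults to 0.05, the margin of a 1-decimal table.
#' @return An object of class `pufa_classification`: list with `profiles`
#'   (input plus `derived_class_*` columns), `boundaries` (named list of
#'   [compute_boundaries()] results), and `report` (data frame of
#'   disagreements with a `boundary_case` flag).
#' @export
classify_all <- function(profiles, rounding_margin = 0.05) {
  validate_taxon_profiles(profiles)
  if (nrow(profiles) < 4L) stop("need at least 4 profiles", call. = FALSE)
  boundaries <- list()
  report <- list()
  for (p in PUFAS) {
    m <- profiles[[paste0("mean_", p)]]
    b <- compute_boundaries(m, p)
    boundaries[[p]] <- b
    derived <- assign_class(m, b)
    profiles[[paste0("derived_class_", p)]] <- derived
    printed <- profiles[[paste0("class_", p)]]
    dis <- which(derived != printed)
    if (length(dis)) {
      cuts <- c(b$q1, b$q2, b$q3)
      dist <- vapply(m[dis], function(v) min(abs(v - cuts)), numeric(1))
      report[[p]] <- data.frame(
        taxon = profiles$taxon[dis], pufa = p, mean = m[dis],
        printed_class = printed[dis], derived_class = derived[dis],
        boundary_distance = dist,
        boundary_case = dist <= rounding_margin,
        stringsAsFactors = FALSE)
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(taxon = character(), pufa = character(), mean = numeric(),
               printed_class = integer(), derived_class = integer(),
               boundary_distance = numeric(), boundary_case = logical())
  rownames(report) <- NULL
  structure(list(profiles = profiles, boundaries = boundaries,
                 report = report),
            class = "pufa_classification")
}

#' @export
print.pufa_classification <- function(x, ...) {
  cat("PUFA classification of", nrow(x$profiles), "taxa\n")
  for (p in names(x$boundaries)) {
    b <- x$boundaries[[p]]
    cat(sprintf("  %s: q1 = %g, q2 = %g, q3 = %g\n", toupper(p),
                b$q1, b$q2, b$q3))
  }
  n <- nrow(x$report)
  if (!n) {
    cat("derived classes agree with recorded classes for every taxon\n")
  } else {
    cat(n, "derived/recorded disagreement(s),",
        sum(x$report$boundary_case), "within the rounding margin of a",
        "boundary\n")
  }
  invisible(x)
}
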