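# Domain types and delimited-text I/O shared by all pipeline stages.
#
# All tables are comma-separated UTF-8 text with a header row; lines starting
# with "#" are comments. Missing values are encoded as an empty field or an
# en/em dash (as printed in field tables for n = 1 taxa).

PUFAS <- c("ara", "epa", "dha")

#' Column order of a taxon PUFA profile table
#' @keywords internal
.profile_cols <- function() {
  c("taxon", "n_lakes",
    as.vector(t(outer(c("mean_", "sd_", "class_"), PUFAS, paste0))))
}

.survey_id_cols <- c("lake_id", "site_id", "lake_type", "vegetation",
                     "substrate", "latitude", "color", "ph", "tp", "tn")

.is_missing_token <- function(x) {
  is.na(x) | trimws(x) %in% c("", "-", "–", "—", "NA")
}

.read_lines_nocomment <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

.num_or_stop <- function(x, what, lineno) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !.is_missing_token(x)
  if (any(bad)) {
    stop(sprintf("malformed %s value '%s' at line %d", what,
                 x[bad][1], lineno[bad][1]), call. = FALSE)
  }
  out[.is_missing_token(x)] <- NA_real_
  out
}

#' Read a taxon PUFA profile table
#'
#' Reads a comma-separated table with one row per taxon giving the number of
#' lakes sampled, and mean/SD mass fractions (ug/mg dry weight) plus printed
#' ordinal content classes (1--5) for ARA, EPA and DHA. Missing standard
#' deviations (taxa sampled in a single lake) may be encoded as empty fields
#' or dashes.
#'
#' @param path path to a delimited text file.
#' @return A `data.frame` of class `taxon_profiles` with columns `taxon`,
#'   `n_lakes`, and `mean_*`, `sd_*`, `class_*` for each of `ara`, `epa`,
#'   `dha`.
#' @seealso [taxon_profiles()] for the packaged 24-taxon reference table.
#' @export
read_taxon_table <- function(path) {
  src <- .read_lines_nocomment(path)
  if (length(src$lines) < 2L) stop("no records in '", path, "'", call. = FALSE)
  df <- read.csv(text = paste(src$lines, collapse = "\n"),
                 colClasses = "character", check.names = FALSE,
                 strip.white = TRUE)
  need <- .profile_cols()
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  lineno <- src$lineno[-1L]
  out <- data.frame(taxon = df$taxon, stringsAsFactors = FALSE)
  out$n_lakes <- .num_or_stop(df$n_lakes, "n_lakes", lineno)
  for (p in PUFAS) {
    for (f in c("mean_", "sd_", "class_")) {
      col <- paste0(f, p)
      out[[col]] <- .num_or_stop(df[[col]], col, lineno)
    }
  }
  class(out) <- c("taxon_profiles", "data.frame")
  validate_taxon_profiles(out)
  out
}

#' Validate a taxon PUFA profile table
#'
#' Checks the structural invariants of a profile table: finite non-negative
#' means, non-negative SDs where present, classes in 1--5, and the
#' "class 1 if and only if mean 0" not-detected rule.
#'
#' @param profiles a `taxon_profiles` data frame.
#' @return `profiles`, invisibly.
#' @export
validate_taxon_profiles <- function(profiles) {
  if (!nrow(profiles)) stop("no records", call. = FALSE)
  if (anyDuplicated(profiles$taxon))
    stop("duplicated taxon labels", call. = FALSE)
  if (any(is.na(profiles$n_lakes)) || any(profiles$n_lakes < 1) ||
      any(profiles$n_lakes != round(profiles$n_lakes)))
    stop("n_lakes must be a positive integer", call. = FALSE)
  for (p in PUFAS) {
    m <- profiles[[paste0("mean_", p)]]
    s <- profiles[[paste0("sd_", p)]]
    cl <- profiles[[paste0("class_", p)]]
    if (any(!is.finite(m)) || any(m < 0))
      stop("mean ", toupper(p), " mass fractions must be finite and >= 0",
           call. = FALSE)
    if (any(s[!is.na(s)] < 0))
      stop("negative SD for ", toupper(p), call. = FALSE)
    if (any(!cl %in% 1:5))
      stop("classes must be integers in 1..5 (", toupper(p), ")",
           call. = FALSE)
    bad <- (cl == 1L) != (m == 0)
    if (any(bad))
      stop("class 1 must correspond exactly to not-detected (mean 0) ",
           toupper(p), " values: ",
           paste(profiles$taxon[bad], collapse = ", "), call. = FALSE)
  }
  invisible(profiles)
}

#' Packaged taxon PUFA reference table
#'
#' The 24-taxon table of littoral macroinvertebrate ARA, EPA and DHA mass
#' fractions (means and SDs over up to 25 boreal lakes, ug/mg dry weight)
#' together with the printed ordinal content classes. Per-taxon lake counts
#' sum to 238.
#'
#' @return A `taxon_profiles` data frame with 24 rows.
#' @export
taxon_profiles <- function() {
  read_taxon_table(system.file("extdata", "taxon_pufa_profiles.csv",
                               package = "benthicpufa", mustWork = TRUE))
}

#' Packaged reference ANOVA partition of the taxon PUFA data
#'
#' Degrees of freedom and sums of squares of the one-way (taxon) partition of
#' log(x+1)-transformed ARA, EPA and DHA mass fractions in the 25-lake
#' fatty-acid survey (243 samples, 24 taxon groups). The per-sample data
#' behind the partition are not deposited, so the partition itself serves as
#' the worked-example input for pseudo-F arithmetic.
#'
#' @return A data frame with columns `pufa`, `source`, `df`, `ss`.
#' @export
fa_anova_partition <- function() {
  src <- .read_lines_nocomment(system.file(
    "extdata", "fa_taxon_anova_partition.csv",
    package = "benthicpufa", mustWork = TRUE))
  read.csv(text = paste(src$lines, collapse = "\n"), strip.white = TRUE)
}

#' Read a community survey table
#'
#' Reads per-site littoral survey records: identifiers, categorical habitat
#' and lake-typology codes, continuous covariates (latitude, water color, pH,
#' total phosphorus, total nitrogen), and per-taxon abundance counts.
#'
#' @param path path to a delimited text file.
#' @param layout `"wide"` (one column per taxon) or `"long"` (columns
#'   `taxon`, `count`, one row per site-taxon).
#' @param taxa optional character vector of known taxon labels; unknown
#'   labels in the file are reported with a warning.
#' @return A `data.frame` of class `pufa_survey`; abundance columns follow
#'   the identifier/covariate columns and are recorded in
#'   `attr(x, "taxa")`.
#' @export
read_survey <- function(path, layout = c("wide", "long"), taxa = NULL) {
  layout <- match.arg(layout)
  src <- .read_lines_nocomment(path)
  if (length(src$lines) < 2L) stop("no records in '", path, "'", call. = FALSE)
  df <- read.csv(text = paste(src$lines, collapse = "\n"),
                 check.names = FALSE, strip.white = TRUE,
                 stringsAsFactors = FALSE)
  if (layout == "long") {
    need <- c(.survey_id_cols, "taxon", "count")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    wide <- reshape(df, idvar = .survey_id_cols, timevar = "taxon",
                    direction = "wide", v.names = "count")
    names(wide) <- sub("^count\\.", "", names(wide))
    wide[is.na(wide)] <- 0
    df <- wide
  }
  miss <- setdiff(.survey_id_cols, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  taxcols <- setdiff(names(df), .survey_id_cols)
  if (!length(taxcols)) stop("no abundance columns", call. = FALSE)
  if (!is.null(taxa)) {
    unknown <- setdiff(taxcols, taxa)
    if (length(unknown))
      warning("unknown taxon labels: ", paste(unknown, collapse = ", "),
              call. = FALSE)
  }
  out <- df[c(.survey_id_cols, taxcols)]
  for (col in taxcols) out[[col]] <- as.numeric(out[[col]])
  out <- as_pufa_survey(out, taxcols)
  out
}

#' Construct/validate a survey object from a data frame
#'
#' @param df data frame with the identifier/covariate columns and one
#'   abundance column per taxon.
#' @param taxa character vector naming the abundance columns.
#' @return a validated `pufa_survey` data frame.
#' @export
as_pufa_survey <- function(df, taxa = setdiff(names(df), .survey_id_cols)) {
  attr(df, "taxa") <- taxa
  class(df) <- c("pufa_survey", "data.frame")
  validate_survey(df)
  df
}

#' Validate a community survey table
#'
#' Enforces: strictly positive continuous covariates (they are
#' log-transformed downstream), pH within (0, 14], non-negative integer
#' counts with at least one positive count per site, and site ids unique
#' within a lake.
#'
#' @param survey a `pufa_survey` data frame.
#' @return `survey`, invisibly.
#' @export
validate_survey <- function(survey) {
  taxa <- attr(survey, "taxa")
  if (is.null(taxa) || !length(taxa)) stop("no taxa recorded", call. = FALSE)
  for (v in c("latitude", "color", "ph", "tp", "tn")) {
    x <- survey[[v]]
    if (any(!is.finite(x)) || any(x <= 0))
      stop("covariate '", v, "' must be strictly positive ",
           "(log-transformed downstream)", call. = FALSE)
  }
  if (any(survey$ph > 14)) stop("pH out of range", call. = FALSE)
  counts <- as.matrix(survey[taxa])
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("abundances must be non-negative integer counts", call. = FALSE)
  if (any(rowSums(counts) == 0))
    stop("every site needs at least one taxon with abundance > 0",
         call. = FALSE)
  key <- paste(survey$lake_id, survey$site_id)
  if (anyDuplicated(key))
    stop("site ids must be unique within a lake", call. = FALSE)
  invisible(survey)
}

#' Validate lake provenance records
#'
#' Optional metadata for fatty-acid survey lakes: name, surface area
#' (hectares), water color (mg Pt/L) and nutrient concentrations (ug/L).
#'
#' @param df data frame with columns `lake_id`, `name`, `area`, `color`,
#'   `tn`, `tp`.
#' @return `df` with class `lake_meta`, invisibly validated.
#' @export
as_lake_meta <- function(df) {
  need <- c("lake_id", "name", "area", "color", "tn", "tp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(!is.finite(df$area)) || any(df$area <= 0))
    stop("area must be > 0", call. = FALSE)
  class(df) <- c("lake_meta", "data.frame")
  df
}

#' Write a record table to delimited text
#'
#' Generic writer producing files that round-trip through the corresponding
#' readers. Numeric fields are written with full (15 significant digit)
#' precision so that write-then-read is the identity; missing values are
#' written as empty fields.
#'
#' @param records a `taxon_profiles`, `pufa_survey`, or plain data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) UseMethod("write_table")

.write_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      x <- format(df[[col]], digits = 15, trim = TRUE, scientific = FALSE)
      x[is.na(df[[col]])] <- ""
      df[[col]] <- x
    }
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_table
#' @export
write_table.taxon_profiles <- function(records, path) {
  .write_csv(records[.profile_cols()], path)
}

#' @rdname write_table
#' @export
write_table.pufa_survey <- function(records, path) {
  .write_csv(records[c(.survey_id_cols, attr(records, "taxa"))], path)
}

#' @rdname write_table
#' @export
write_table.data.frame <- function(records, path) {
  .write_csv(records, path)
}
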