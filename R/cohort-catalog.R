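# Cohort catalog: a machine-readable transcription of the 44-subject
# rearrangement table bundled with the package, plus the aggregate
# statistics computed from it (class counts, parental-origin tables, size
# ranges).  Sizes printed as "~x Mb" are stored with an `approximate` flag
# and excluded from min/max summaries.

CLASS_LEVELS <- c(terminal_deletion = "Terminal deletion",
                  interstitial_deletion = "Interstitial deletion",
                  ring22 = "Ring 22",
                  derivative = "Derivative chromosome")
MECH_LEVELS <- c(telomere_healing = "Telomere healing",
                 telomere_capture = "Telomere capture",
                 NHEJ = "NHEJ", FoSTeS = "FoSTeS")

#' Path to the bundled cohort catalog
#' @return Path to the installed `table1_cohort.tsv`.
#' @export
catalog_path <- function() {
  system.file("extdata", "table1_cohort.tsv", package = "junctionmech",
              mustWork = TRUE)
}

parse_size_bp <- function(x, row) {
  x <- trimws(x)
  out <- list(bp = NA_real_, approximate = FALSE)
  if (x == "" || is.na(x)) return(out)
  if (grepl("^[~≈∼]", x)) {
    out$approximate <- TRUE
    x <- sub("^[~≈∼]\\s*", "", x)
  }
  m <- regmatches(x, regexec("^([0-9.,]+)\\s*(Mb|kb|bp)$", x))[[1]]
  if (length(m) != 3L) {
    stop(sprintf("row %d: unparseable size '%s'", row, x), call. = FALSE)
  }
  val <- as.numeric(gsub(",", "", m[2]))
  mult <- c(Mb = 1e6, kb = 1e3, bp = 1)[[m[3]]]
  out$bp <- val * mult
  out
}

#' Load and validate the cohort catalog
#'
#' Reads the tab-separated catalog, normalizes units (Mb/kb to bp),
#' validates the closed vocabularies and flags approximate ("~") sizes.
#' Unparseable rows raise an error naming the row number.
#'
#' @param path Catalog TSV (defaults to the bundled table).
#' @return data.frame of class `patient_catalog`: `patient_id`, `sex`,
#'   `ascertainment`, `rearrangement_class` (one of `terminal_deletion`,
#'   `interstitial_deletion`, `ring22`, `derivative`), `del_size_bp`,
#'   `approximate`, `associated_imbalance`, `repair_mechanism` (one of
#'   `telomere_healing`, `telomere_capture`, `NHEJ`, `FoSTeS`, `unknown`),
#'   `parental_origin` (`paternal`/`maternal`/`unknown`), `mosaic_percent`.
#' @export
load_catalog <- function(path = catalog_path()) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = NULL)
  need <- c("patient_id", "sex", "ascertainment", "rearrangement",
            "del22q13_size", "repair_mechanism", "parental_origin")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("catalog missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(raw)
  cls <- names(CLASS_LEVELS)[match(trimws(raw$rearrangement), CLASS_LEVELS)]
  if (anyNA(cls)) {
    stop(sprintf("row %d: unknown rearrangement class '%s'",
                 which(is.na(cls))[1], raw$rearrangement[which(is.na(cls))[1]]),
         call. = FALSE)
  }
  if (anyDuplicated(raw$patient_id)) {
    stop("duplicate patient_id: ", raw$patient_id[duplicated(raw$patient_id)][1],
         call. = FALSE)
  }
  sizes <- lapply(seq_len(n), function(i) parse_size_bp(raw$del22q13_size[i], i))
  del_bp <- vapply(sizes, `[[`, numeric(1), "bp")
  if (any(!is.na(del_bp) & del_bp <= 0)) {
    stop("non-positive deletion size", call. = FALSE)
  }
  mech_raw <- trimws(raw$repair_mechanism)
  mech <- names(MECH_LEVELS)[match(mech_raw, MECH_LEVELS)]
  mech[mech_raw == ""] <- "unknown"
  if (anyNA(mech)) {
    stop(sprintf("row %d: unknown repair mechanism '%s'",
                 which(is.na(mech))[1], mech_raw[which(is.na(mech))[1]]),
         call. = FALSE)
  }
  ori <- c(Pat = "paternal", Mat = "maternal", U = "unknown")[
    trimws(raw$parental_origin)]
  ori[trimws(raw$parental_origin) == ""] <- "unknown"
  if (anyNA(ori)) {
    stop(sprintf("row %d: unknown parental origin '%s'",
                 which(is.na(ori))[1], raw$parental_origin[which(is.na(ori))[1]]),
         call. = FALSE)
  }
  if (!all(raw$sex %in% c("M", "F"))) {
    stop("sex must be M or F", call. = FALSE)
  }
  mosaic <- suppressWarnings(as.integer(raw$mosaic_percent %||%
                                          rep("", n)))
  out <- data.frame(
    patient_id = raw$patient_id, sex = raw$sex,
    ascertainment = raw$ascertainment,
    rearrangement_class = cls, del_size_bp = del_bp,
    approximate = vapply(sizes, `[[`, logical(1), "approximate"),
    associated_imbalance = trimws(raw$associated_imbalance %||% rep("", n)),
    repair_mechanism = mech, parental_origin = unname(ori),
    mosaic_percent = mosaic, stringsAsFactors = FALSE)
  class(out) <- c("patient_catalog", "data.frame")
  out
}

#' Rearrangement-class counts
#'
#' @param records A `patient_catalog`.
#' @return Named integer vector over the four classes; sums to
#'   `nrow(records)`.
#' @export
class_counts <- function(records) {
  lv <- names(CLASS_LEVELS)
  out <- vapply(lv, function(k) sum(records$rearrangement_class == k),
                integer(1))
  stopifnot(sum(out) == nrow(records))
  out
}

#' Parental-origin summary for a set of rearrangement classes
#'
#' Derivative (inherited) chromosomes are excluded by default: the
#' parental-origin tables describe de novo rearrangements only.
#' Percentages are rounded to integers, as conventionally printed.
#'
#' @param records A `patient_catalog`.
#' @param classes Character vector of rearrangement classes to include.
#' @param label Row label.
#' @return One-row data.frame: `group`, `n_informative`, `n_paternal`,
#'   `n_maternal`, `pct_paternal`.
#' @export
parental_origin_table <- function(records,
                                  classes = c("terminal_deletion",
                                              "interstitial_deletion"),
                                  label = paste(classes, collapse = "+")) {
  stopifnot(!"derivative" %in% classes)
  r <- records[records$rearrangement_class %in% classes, ]
  pat <- sum(r$parental_origin == "paternal")
  mat <- sum(r$parental_origin == "maternal")
  inf <- pat + mat
  data.frame(group = label, n_informative = inf, n_paternal = pat,
             n_maternal = mat,
             pct_paternal = if (inf > 0) as.integer(round(100 * pat / inf))
                            else NA_integer_)
}

#' Parental-origin table over the standard de novo groups
#'
#' Rows: simple deletions (terminal + interstitial), rings, and their
#' total, mirroring how de novo origins are conventionally tabulated.
#'
#' @param records A `patient_catalog`.
#' @return data.frame with one row per group.
#' @export
parental_origin_summary <- function(records) {
  rbind(
    parental_origin_table(records, c("terminal_deletion",
                                     "interstitial_deletion"), "del(22)"),
    parental_origin_table(records, "ring22", "ring 22"),
    parental_origin_table(records, c("terminal_deletion",
                                     "interstitial_deletion", "ring22"),
                          "total"))
}

#' Deletion-size summary for one rearrangement class
#'
#' Approximate ("~") and missing sizes are excluded.
#'
#' @param records A `patient_catalog`.
#' @param class One of the four rearrangement classes.
#' @return `list(min_bp, max_bp, n)` where `n` counts all records of the
#'   class (including those without an exact size).
#' @export
size_summary <- function(records, class) {
  if (!class %in% names(CLASS_LEVELS)) {
    stop("unknown rearrangement class: ", class, call. = FALSE)
  }
  r <- records[records$rearrangement_class == class, ]
  sz <- r$del_size_bp[!r$approximate & !is.na(r$del_size_bp)]
  list(min_bp = if (length(sz)) min(sz) else NA_real_,
       max_bp = if (length(sz)) max(sz) else NA_real_,
       n = nrow(r))
}

#' Full cohort report
#'
#' Aggregates the catalog: record count, class counts with recomputed
#' percentages (and, optionally, the as-published rounded figures for
#' side-by-side comparison), the de novo parental-origin tables, and the
#' per-class size ranges.
#'
#' @param records A `patient_catalog`.
#' @param printed_class_percent Optional named numeric vector of published
#'   class percentages to display alongside the recomputed ones (they were
#'   printed with a different rounding base; the discrepancy is surfaced,
#'   not hidden).
#' @return A list of class `cohort_report`; `format()`/`print()` give a
#'   text rendering, [jsonlite::toJSON()] a JSON one.
#' @export
cohort_report <- function(records, printed_class_percent = NULL) {
  cc <- class_counts(records)
  rep_ <- list(
    n_records = nrow(records),
    class_counts = as.list(cc),
    class_percent_recomputed = as.list(round(100 * cc / nrow(records), 1)),
    parental_origin = parental_origin_summary(records),
    origin_by_class = rbind(
      parental_origin_table(records, "terminal_deletion", "terminal"),
      parental_origin_table(records, "interstitial_deletion", "interstitial")),
    size_ranges = lapply(stats::setNames(nm = names(CLASS_LEVELS)),
                         function(k) size_summary(records, k)),
    mechanism_counts = as.list(table(records$repair_mechanism)))
  if (!is.null(printed_class_percent)) {
    rep_$class_percent_printed <- as.list(printed_class_percent)
  }
  class(rep_) <- "cohort_report"
  rep_
}

#' @export
format.cohort_report <- function(x, ...) {
  cc <- unlist(x$class_counts)
  lines <- c(
    sprintf("cohort of %d subjects", x$n_records),
    sprintf("  %-22s %2d (%s%%)", names(cc), cc,
            unlist(x$class_percent_recomputed)),
    "parental origin (de novo):",
    sprintf("  %-12s informative %2d: %2d paternal / %2d maternal (%d%%)",
            x$parental_origin$group, x$parental_origin$n_informative,
            x$parental_origin$n_paternal, x$parental_origin$n_maternal,
            x$parental_origin$pct_paternal))
  if (!is.null(x$class_percent_printed)) {
    lines <- c(lines,
               sprintf("as-published class percentages: %s",
                       paste(sprintf("%s=%s%%", names(x$class_percent_printed),
                                     unlist(x$class_percent_printed)),
                             collapse = ", ")))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
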