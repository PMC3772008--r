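#' Fit the LBB calibration line against KMnO4 standards
#'
#' The leucoberbelin-blue (LBB) assay reads oxidized Mn colorimetrically at
#' 620 nm; KMnO4 serves as the standard. This fits an ordinary least-squares
#' line of absorbance on KMnO4 concentration. A through-origin fit is
#' available since Beer-Lambert behavior implies a zero intercept.
#'
#' @param standards data.frame (or matrix) with columns `kmno4_uM` and
#'   `absorbance`; at least two distinct concentrations required.
#' @param throughOrigin constrain the intercept to zero.
#' @return a [CalibrationCurve-class].
#' @examples
#' fitCalibration(data.frame(kmno4_uM = c(0, 10, 20),
#'                           absorbance = c(0, 0.5, 1.0)))
#' @export
fitCalibration <- function(standards, throughOrigin = FALSE) {
  standards <- as.data.frame(standards)
  if (!all(c("kmno4_uM", "absorbance") %in% names(standards)))
    colnames(standards)[1:2] <- c("kmno4_uM", "absorbance")
  x <- standards$kmno4_uM
  y <- standards$absorbance
  if (length(x) < 2L)
    stop("calibration requires at least 2 standards")
  if (length(unique(x)) < 2L)
    stop("calibration requires at least 2 distinct concentrations")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(y < 0) || any(x < 0))
    stop("standards must be finite and non-negative")
  fit <- if (throughOrigin) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[if (throughOrigin) "x" else "x"])
  intercept <- if (throughOrigin) 0 else unname(stats::coef(fit)["(Intercept)"])
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ssTot
  new("CalibrationCurve", slope = slope, intercept = intercept,
      rSquared = min(max(r2, 0), 1), throughOrigin = throughOrigin)
}

#' Convert absorbance readings to KMnO4-equivalent concentrations
#'
#' Inverts the calibration line: concentration = (absorbance - intercept) /
#' slope, floored at zero.
#'
#' @param absorbance absorbance at 620 nm (vectorized).
#' @param curve a [CalibrationCurve-class].
#' @return KMnO4 concentration(s), uM.
#' @export
absorbanceToKmno4 <- function(absorbance, curve) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (any(absorbance < 0, na.rm = TRUE))
    stop("absorbance must be non-negative")
  pmax((absorbance - curve@intercept) / curve@slope, 0)
}

#' Convert between KMnO4-equivalent and MnO2-equivalent concentrations
#'
#' The LBB assay is calibrated so that 1 uM of formed MnO2 corresponds to
#' 0.4 uM KMnO4; the conversion is linear through the origin.
#'
#' @param kmno4_uM,mno2_uM concentrations in uM (vectorized).
#' @return the converted concentration(s), uM.
#' @examples
#' kmno4ToMno2(0.4)  # 1
#' mno2ToKmno4(1)    # 0.4
#' @export
kmno4ToMno2 <- function(kmno4_uM) {
  if (any(!is.finite(kmno4_uM)) || any(kmno4_uM < 0))
    stop("kmno4_uM must be finite and non-negative")
  kmno4_uM / 0.4
}

#' @rdname kmno4ToMno2
#' @export
mno2ToKmno4 <- function(mno2_uM) {
  if (any(!is.finite(mno2_uM)) || any(mno2_uM < 0))
    stop("mno2_uM must be finite and non-negative")
  mno2_uM * 0.4
}

#' Categorize Mn(II)-oxidizing activity from MnO2-equivalent concentration
#'
#' Four categories: high (>= 50 uM MnO2), medium (10-50 uM), low (1-10 uM),
#' none (< 1 uM). Interior boundaries are half-open, closed on the left
#' (`[10, 50)`, `[1, 10)`), matching the inclusive ">= 50" convention at the
#' top boundary.
#'
#' @param mno2_uM MnO2-equivalent concentration(s), uM, non-negative.
#' @return factor with levels high, medium, low, none.
#' @examples
#' categorizeActivity(c(60, 50, 25, 5, 0.5))
#' @export
categorizeActivity <- function(mno2_uM) {
  if (any(is.na(mno2_uM)) || any(!is.finite(mno2_uM)))
    stop("mno2_uM must be finite and non-missing")
  if (any(mno2_uM < 0))
    stop("mno2_uM must be non-negative")
  cat <- ifelse(mno2_uM >= 50, "high",
         ifelse(mno2_uM >= 10, "medium",
         ifelse(mno2_uM >= 1, "low", "none")))
  factor(cat, levels = ACTIVITY_CATEGORIES)
}

#' Build the horizon-by-category activity contingency table
#'
#' Cross-tabulates isolate activity categories across soil horizons,
#' mirroring the compiled presentation used for stratified-soil isolate
#' surveys: per-horizon rows, a compiled row, category percentages of the
#' grand total, and each horizon's share within a category.
#'
#' @param records data.frame with columns `isolate_id`, `horizon` (A/B/C)
#'   and either `category` or `mno2_uM` (categorized via
#'   [categorizeActivity()] when `category` is absent).
#' @return an [ActivityTable-class].
#' @examples
#' rec <- data.frame(isolate_id = paste0("i", 1:4),
#'                   horizon = c("A", "A", "B", "C"),
#'                   mno2_uM = c(60, 12, 3, 0.2))
#' tabulateActivity(rec)
#' @export
tabulateActivity <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no activity records supplied")
  if (!"horizon" %in% names(records)) stop("records need a 'horizon' column")
  if (!"category" %in% names(records)) {
    if (!"mno2_uM" %in% names(records))
      stop("records need a 'category' or 'mno2_uM' column")
    records$category <- categorizeActivity(records$mno2_uM)
  }
  hz <- as.character(records$horizon)
  if (!all(hz %in% HORIZONS))
    stop("horizon must be one of A, B, C")
  cat <- factor(as.character(records$category), levels = ACTIVITY_CATEGORIES)
  if (any(is.na(cat))) stop("unknown activity category in records")
  cts <- unclass(table(factor(hz, levels = HORIZONS), cat))
  cts <- cts[HORIZONS %in% hz, , drop = FALSE]
  storage.mode(cts) <- "integer"
  names(dimnames(cts)) <- NULL
  new("ActivityTable", counts = cts)
}

#' Percentage summaries of an ActivityTable
#'
#' `columnPercentages()` gives each category's share of the grand total;
#' `withinCategoryPercentages()` gives each horizon's share within each
#' category ("no band" categories with zero total give NA). Both are
#' reported rounded to one decimal by default, matching how such tables are
#' usually printed; pass `digits = NA` for raw ratios.
#'
#' @param object an [ActivityTable-class].
#' @param digits decimals to round to, or NA for unrounded.
#' @return named numeric vector (`columnPercentages`) or matrix
#'   (`withinCategoryPercentages`).
#' @export
columnPercentages <- function(object, digits = 1) {
  stopifnot(is(object, "ActivityTable"))
  p <- 100 * colSums(object@counts) / sum(object@counts)
  if (!is.na(digits)) p <- round(p, digits)
  p
}

#' @rdname columnPercentages
#' @export
withinCategoryPercentages <- function(object, digits = 1) {
  stopifnot(is(object, "ActivityTable"))
  cts <- object@counts
  p <- sweep(cts, 2, colSums(cts), "/") * 100
  if (!is.na(digits)) p <- round(p, digits)
  p
}

#' Read activity records / write an activity table as CSV
#'
#' `readActivityCSV` reads per-isolate records (`isolate_id,horizon,mno2_uM`
#' or `...,absorbance`, converted through a calibration curve and the
#' KMnO4-to-MnO2 ratio when `curve` is given). `writeActivityTable` writes
#' the contingency table with its compiled row and totals.
#'
#' @param path CSV file path.
#' @param curve optional [CalibrationCurve-class] used to convert an
#'   `absorbance` column.
#' @param object an [ActivityTable-class].
#' @return `readActivityCSV`: data.frame of records with `mno2_uM` and
#'   `category`; `writeActivityTable`: the path, invisibly.
#' @export
readActivityCSV <- function(path, curve = NULL) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"mno2_uM" %in% names(rec)) {
    if (is.null(curve) || !"absorbance" %in% names(rec))
      stop("CSV needs an 'mno2_uM' column, or an 'absorbance' column plus a calibration curve")
    rec$mno2_uM <- kmno4ToMno2(absorbanceToKmno4(rec$absorbance, curve))
  }
  rec$category <- categorizeActivity(rec$mno2_uM)
  rec
}

#' @rdname readActivityCSV
#' @export
writeActivityTable <- function(object, path) {
  stopifnot(is(object, "ActivityTable"))
  cts <- object@counts
  out <- rbind(cts, Compiled = colSums(cts))
  out <- cbind(out, Total = rowSums(out))
  utils::write.csv(data.frame(horizon = rownames(out), out,
                              check.names = FALSE, row.names = NULL),
                   path, row.names = FALSE)
  invisible(path)
}
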