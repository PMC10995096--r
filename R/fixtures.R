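#' Packaged study tables
#'
#' The package ships the four printed tables of the Fucheng District
#' 2015-2022 study as plain CSV fixtures: the 29-indicator weighting system
#' ("table2"), the 17-column yearly model inputs ("table3"), the green/water
#' landscape index series ("table5"), and the true LQCI series with the
#' reference BP / GA-BP predictions and quality levels ("table6").
#'
#' @param table one of "table2", "table3", "table5", "table6".
#' @return "table2" returns an [IndicatorSystem-class]; the others return a
#'   data.frame with one row per record as printed.
#' @examples
#' loadFixture("table6")
#' @export
loadFixture <- function(table = c("table2", "table3", "table5", "table6")) {
  table <- match.arg(table)
  file <- switch(table,
    table2 = "table2_indicator_system.csv",
    table3 = "table3_model_inputs.csv",
    table5 = "table5_gwli.csv",
    table6 = "table6_lqci_truth.csv")
  path <- system.file("extdata", file, package = "lqci")
  if (!nzchar(path) || !file.exists(path))
    stop("fixture '", table, "' is missing from the installed package")
  df <- read.csv(path, stringsAsFactors = FALSE)
  ok <- switch(table,
    table2 = nrow(df) == 29 && all(c("abbrev", "weight_percent") %in% names(df)),
    table3 = nrow(df) == 8 && ncol(df) == 18,
    table5 = nrow(df) == 16 && all(df$class %in% c("green", "water")),
    table6 = nrow(df) == 8 && all(df$level %in% c("I", "II", "III", "IV")))
  if (!isTRUE(ok)) stop("fixture '", table, "' is corrupt")
  if (table == "table2") indicatorSystem(df) else df
}

#' The 8 yearly training samples of the study
#'
#' Convenience assembly of the model inputs: the 17 yearly indicator
#' columns as a matrix `x` (8 years x 17 indicators) and the true LQCI
#' series as `y`, both in raw (unnormalized) units.
#'
#' @return list with `years`, `x` (matrix), `y` (numeric).
#' @export
fixtureSamples <- function() {
  t3 <- loadFixture("table3")
  t6 <- loadFixture("table6")
  stopifnot(identical(t3$year, t6$year))
  x <- as.matrix(t3[, setdiff(names(t3), "year")])
  rownames(x) <- t3$year
  list(years = t3$year, x = x, y = t6$truth_lqci)
}
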