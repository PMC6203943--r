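#' Taylor power-law dispersion diagnostic for positive CPUE
#'
#' Groups positive CPUE into covariate cells (year by area by default),
#' computes each cell's mean and variance, and regresses log variance on
#' log mean by least squares. A slope near 2 indicates variance
#' proportional to the square of the mean, the mean-variance scaling of a
#' constant-shape gamma distribution, and is the diagnostic that
#' justifies modelling positive catches with a gamma error.
#'
#' @param records logbook data.frame.
#' @param species shark species label.
#' @param cells character vector of grouping columns (default
#'   `c("year", "area")`; the columns must exist in `records`).
#' @param min_per_cell minimum positive observations per cell for the
#'   cell to enter the regression.
#' @param min_cells minimum number of qualifying cells.
#' @return list with `status` (`"ok"` or `"insufficient_cells"`); when
#'   `"ok"`, also `slope` (the Taylor exponent), `intercept` and
#'   `n_cells`. The slope is never fabricated when the diagnostic is
#'   unavailable.
#' @export
dispersion_diagnostic <- function(records, species = "blue",
                                  cells = c("year", "area"),
                                  min_per_cell = 5, min_cells = 3) {
  missing_cols <- setdiff(cells, names(records))
  if (length(missing_cols)) {
    stop_config("grouping column(s) not in records: %s",
                paste(missing_cols, collapse = ", "))
  }
  cpue <- compute_cpue(records, species)
  pos <- cpue > 0 & !is.na(cpue)
  if (!any(pos)) {
    return(list(status = "insufficient_cells", n_cells = 0L))
  }
  key <- interaction(records[pos, cells, drop = FALSE], drop = TRUE)
  n_per <- tabulate(key)
  keep_cells <- which(n_per >= min_per_cell)
  if (length(keep_cells) < min_cells) {
    return(list(status = "insufficient_cells", n_cells = length(keep_cells)))
  }
  x <- cpue[pos]
  means <- tapply(x, key, mean)[keep_cells]
  vars <- tapply(x, key, stats::var)[keep_cells]
  usable <- is.finite(log(vars)) & is.finite(log(means))
  if (sum(usable) < min_cells) {
    return(list(status = "insufficient_cells", n_cells = sum(usable)))
  }
  fit <- stats::lm(log(vars[usable]) ~ log(means[usable]))
  list(status = "ok",
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_cells = sum(usable))
}
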