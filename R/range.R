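#' Threshold maximizing sensitivity plus specificity (MaxSSS)
#'
#' Scans the union of observed presence and background suitability scores
#' as candidate thresholds and returns the one maximizing
#' sensitivity(t) + specificity(t), where a cell with score >= t is
#' classified suitable (boundary cells suitable; set `inclusive = FALSE`
#' for a strict `>` rule). Ties break to the lowest threshold.
#'
#' @param presence_scores suitability scores at presence points, in \[0, 1\].
#' @param background_scores suitability scores at background points.
#' @param inclusive treat cells exactly at the threshold as suitable.
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
max_sss_threshold <- function(presence_scores, background_scores,
                              inclusive = TRUE) {
  if (!length(presence_scores) || !length(background_scores)) {
    stop("both score vectors must be non-empty")
  }
  sc <- c(presence_scores, background_scores)
  if (any(sc < 0 | sc > 1)) stop("scores must lie in [0, 1]")
  cand <- sort(unique(sc))
  if (length(cand) == 1L) stop("degenerate scores: all values identical")
  cmp <- if (inclusive) `>=` else `>`
  sens <- vapply(cand, function(t) mean(cmp(presence_scores, t)), 0)
  spec <- vapply(cand, function(t) mean(!cmp(background_scores, t)), 0)
  best <- which.max(sens + spec)  # which.max takes the first (lowest) tie
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best])
}

#' Binarize a suitability raster at a threshold
#' @param grid continuous suitability [raster_grid()].
#' @param threshold cut-off; cells `>= threshold` become 1 (see
#'   [max_sss_threshold()]).
#' @param inclusive boundary handling as in [max_sss_threshold()].
#' @return binary [raster_grid()] (0/1, nodata preserved).
#' @export
binarize_suitability <- function(grid, threshold, inclusive = TRUE) {
  cmp <- if (inclusive) `>=` else `>`
  v <- ifelse(cmp(grid$values, threshold), 1, 0)
  raster_grid(v, grid$cellsize, grid$xllcorner, grid$yllcorner, grid$nodata)
}

#' Ensemble several binary suitability maps by cell-wise majority
#' @param maps list of congruent binary [raster_grid()]s.
#' @return binary [raster_grid()] (ties count as suitable).
#' @export
ensemble_majority <- function(maps) {
  stopifnot(length(maps) >= 1)
  acc <- Reduce(`+`, lapply(maps, function(m) m$values))
  v <- ifelse(acc >= length(maps) / 2, 1, 0)
  m1 <- maps[[1]]
  raster_grid(v, m1$cellsize, m1$xllcorner, m1$yllcorner, m1$nodata)
}

#' Range-change accounting across time slices
#'
#' Counts suitable cells per binary map within the study mask and reports,
#' per time slice: the suitable-cell count, the percentage of the study
#' area suitable, and the percentage range change relative to the present
#' slice, `100 * (cells_t - cells_present)/cells_present`. Percentages are
#' rounded to one decimal in the `reported_*` columns; cross-slice ratios
#' (`ratio_vs_present`) are derived from the reported change percentages
#' so the table is internally consistent at its printed precision.
#'
#' @param maps named list of binary [raster_grid()]s (or plain 0/1
#'   matrices), one per time slice.
#' @param present name of the present-day slice.
#' @param mask optional logical matrix restricting the study area
#'   (default: all non-`NA` cells of each map).
#' @return `range_report` data frame with columns `slice`, `suitable_cells`,
#'   `pct_area`, `pct_change`, `reported_pct_area`, `reported_pct_change`,
#'   `ratio_vs_present`.
#' @export
range_report <- function(maps, present = "present", mask = NULL) {
  if (is.null(names(maps)) || !present %in% names(maps)) {
    stop("maps must be named and include the present slice '", present, "'")
  }
  getv <- function(m) if (inherits(m, "raster_grid")) m$values else as.matrix(m)
  dims <- unique(lapply(maps, function(m) dim(getv(m))))
  if (length(dims) != 1L) stop("maps are not congruent")
  if (!is.null(mask) && !all(dim(mask) == dims[[1]])) {
    stop("mask not congruent with maps")
  }
  counts <- vapply(maps, function(m) {
    v <- getv(m)
    sel <- if (is.null(mask)) !is.na(v) else mask & !is.na(v)
    sum(v[sel] == 1)
  }, 0)
  area <- if (is.null(mask)) {
    max(vapply(maps, function(m) sum(!is.na(getv(m))), 0))
  } else sum(mask)
  cp <- counts[[present]]
  if (cp == 0) stop("zero suitable cells in the present slice; change undefined")
  pct_area <- 100 * counts / area
  pct_change <- 100 * (counts - cp) / cp
  rep_area <- round(pct_area, 1)
  rep_change <- round(pct_change, 1)
  # ratio of each slice's range to the present range, consistent with the
  # reported change column: (100 + change)/100
  ratio <- (100 + rep_change) / 100
  out <- data.frame(slice = names(maps), suitable_cells = unname(counts),
                    pct_area = unname(pct_area),
                    pct_change = unname(pct_change),
                    reported_pct_area = unname(rep_area),
                    reported_pct_change = unname(rep_change),
                    ratio_vs_present = unname(ratio),
                    stringsAsFactors = FALSE)
  out$pct_change[out$slice == present] <- NA
  out$reported_pct_change[out$slice == present] <- NA
  class(out) <- c("range_report", "data.frame")
  out
}

#' Ratio between two slices of a range report at reported precision
#'
#' Expressed as a percentage of the denominator slice's range, computed
#' from the `ratio_vs_present` column (i.e. from the one-decimal change
#' percentages), then rounded to one decimal.
#'
#' @param report a [range_report()].
#' @param numerator,denominator slice names.
#' @return percentage (numeric scalar).
#' @export
range_ratio_pct <- function(report, numerator, denominator) {
  rn <- report$ratio_vs_present[report$slice == numerator]
  rd <- report$ratio_vs_present[report$slice == denominator]
  if (!length(rn) || !length(rd)) stop("unknown slice name")
  round(100 * rn / rd, 1)
}

#' Write a range report as CSV
#' @param report a [range_report()].
#' @param path output path.
#' @export
write_range_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
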