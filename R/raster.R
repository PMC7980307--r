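#' Single-band georeferenced raster grid
#'
#' Row-major storage with row 1 the northernmost row, matching the ESRI
#' ASCII grid layout used for all landscape inputs and outputs.
#'
#' @param values numeric matrix (`nrows x ncols`), `NA` for nodata.
#' @param cellsize positive cell size in map units.
#' @param xllcorner,yllcorner coordinates of the lower-left corner.
#' @param nodata value used to encode `NA` on disk (default -9999).
#' @return `raster_grid` object.
#' @export
raster_grid <- function(values, cellsize = 1, xllcorner = 0, yllcorner = 0,
                        nodata = -9999) {
  values <- as.matrix(values)
  if (cellsize <= 0) stop("cellsize must be positive")
  structure(list(values = values, nrows = nrow(values), ncols = ncol(values),
                 cellsize = cellsize, xllcorner = xllcorner,
                 yllcorner = yllcorner, nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d, cellsize %g, origin (%g, %g), %d nodata cells\n",
              x$nrows, x$ncols, x$cellsize, x$xllcorner, x$yllcorner,
              sum(is.na(x$values))))
  invisible(x)
}

#' Map-unit coordinates of a cell centre
#'
#' Cells are indexed `(row, col)` with row 1 the northernmost row.
#' @param grid a [raster_grid()].
#' @param row,col cell indices (1-based).
#' @return cbind(x, y) of cell-centre coordinates.
#' @export
cell_xy <- function(grid, row, col) {
  x <- grid$xllcorner + (col - 0.5) * grid$cellsize
  y <- grid$yllcorner + (grid$nrows - row + 0.5) * grid$cellsize
  cbind(x = x, y = y)
}

#' Read an ESRI ASCII grid (.asc)
#' @param path file path.
#' @return a [raster_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr))) {
    stop("malformed ASCII grid header at line ", i, " of ", path)
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[seq.int(i, length(lines))], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols) {
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$nrows * hdr$ncols)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  raster_grid(m, cellsize = hdr$cellsize, xllcorner = hdr$xllcorner,
              yllcorner = hdr$yllcorner, nodata = nodata)
}

#' Write an ESRI ASCII grid (.asc)
#' @param grid a [raster_grid()].
#' @param path output path.
#' @export
write_ascii_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$ncols),
               sprintf("nrows %d", grid$nrows),
               sprintf("xllcorner %.10g", grid$xllcorner),
               sprintf("yllcorner %.10g", grid$yllcorner),
               sprintf("cellsize %.10g", grid$cellsize),
               sprintf("NODATA_value %.10g", grid$nodata)), con)
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  utils::write.table(format(v, trim = TRUE, digits = 10, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Resistance cost scheme
#'
#' Maps categories (or value ranges) of a landscape variable to movement
#' resistance costs in `[1, 100]` (1 = no resistance, 100 = strong barrier).
#'
#' @param variable name of the landscape variable.
#' @param label scheme label used for reporting and tie-breaking.
#' @param categories data frame with columns `from`, `to` (closed-lower,
#'   open-upper value ranges; use equal values for exact categories) and
#'   `cost`.
#' @return `cost_scheme` object.
#' @export
cost_scheme <- function(variable, label, categories) {
  stopifnot(all(c("from", "to", "cost") %in% names(categories)))
  if (any(categories$cost < 1 | categories$cost > 100)) {
    stop("costs must lie in [1, 100]")
  }
  structure(list(variable = variable, label = label,
                 categories = categories), class = "cost_scheme")
}

#' Reclassify a raster to a resistance surface
#'
#' Each non-nodata cell value is looked up in the scheme's category table:
#' a row matches if `from <= value <= to`. Nodata propagates. Unmapped
#' values raise an error naming the offending value.
#'
#' @param raster a [raster_grid()].
#' @param scheme a [cost_scheme()].
#' @return a [raster_grid()] of resistance costs.
#' @export
reclassify <- function(raster, scheme) {
  v <- raster$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  cat_tab <- scheme$categories
  idx <- which(!is.na(v))
  vals <- v[idx]
  assigned <- rep(NA_real_, length(vals))
  for (k in seq_len(nrow(cat_tab))) {
    hit <- vals >= cat_tab$from[k] & vals <= cat_tab$to[k] & is.na(assigned)
    assigned[hit] <- cat_tab$cost[k]
  }
  if (anyNA(assigned)) {
    stop("unmapped raster value(s) in scheme '", scheme$label, "': ",
         paste(utils::head(unique(vals[is.na(assigned)]), 5), collapse = ", "))
  }
  out[idx] <- assigned
  raster_grid(out, raster$cellsize, raster$xllcorner, raster$yllcorner,
              raster$nodata)
}

#' Node set: population sites anchored to raster cells
#'
#' @param labels population labels.
#' @param rows,cols 1-based cell indices (row 1 = north).
#' @return `node_set` data frame.
#' @export
node_set <- function(labels, rows, cols) {
  df <- data.frame(label = as.character(labels), row = as.integer(rows),
                   col = as.integer(cols), stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("row", "col")])) stop("nodes must be on distinct cells")
  structure(df, class = c("node_set", "data.frame"))
}

#' Read site coordinates CSV and anchor them to a grid
#'
#' The CSV has columns `label,x,y` in projected map units (metres).
#' @param path CSV path.
#' @param grid a [raster_grid()] used to convert coordinates to cells.
#' @return a [node_set()] (with `x`, `y` kept as extra columns).
#' @export
read_sites_csv <- function(path, grid = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "x", "y") %in% names(df))) {
    stop("sites CSV must have columns label,x,y")
  }
  if (is.null(grid)) return(df)
  col <- floor((df$x - grid$xllcorner) / grid$cellsize) + 1L
  row <- grid$nrows - floor((df$y - grid$yllcorner) / grid$cellsize)
  ns <- node_set(df$label, row, col)
  ns$x <- df$x; ns$y <- df$y
  ns
}

#' Euclidean distances between sites
#' @param sites data frame with `label`, `x`, `y` in projected metres.
#' @return a [pairwise_matrix()] of Euclidean distances.
#' @export
euclidean_distances <- function(sites) {
  d <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  dimnames(d) <- list(sites$label, sites$label)
  pairwise_matrix(d, "Euclidean")
}
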