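#' @import methods
#' @importFrom stats cor median quantile rnorm runif sd var setNames
#'   binomial coef glm glm.fit p.adjust pnorm predict plogis qlogis rbinom
#'   chisq.test as.formula
#' @importFrom utils head read.csv write.csv
NULL

#' Single-band geographic raster
#'
#' A minimal raster lattice on geographic (WGS-84 degree) coordinates with
#' square cells. Row 1 is the northernmost row; cells are addressed by
#' `(row, col)`. Missing cells are stored as `NA` internally and serialized
#' as the `nodata` sentinel in ESRI ASCII files.
#'
#' @slot values numeric matrix (rows x cols), `NA` for NODATA.
#' @slot xll,yll longitude/latitude of the lower-left corner (degrees).
#' @slot cellSize cell edge length in degrees (square cells).
#' @slot nodata sentinel value used on disk.
#' @slot name short layer label, e.g. `"ELE"` or `"Bio11"`.
#'
#' @export
setClass("Grid",
  representation(
    values = "matrix",
    xll = "numeric",
    yll = "numeric",
    cellSize = "numeric",
    nodata = "numeric",
    name = "character"
  ),
  prototype(nodata = -9999, name = "layer")
)

setValidity("Grid", function(object) {
  msgs <- character()
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  v <- object@values
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (any(is.infinite(v)))
    msgs <- c(msgs, "non-NODATA values must be finite")
  if (nrow(v) < 1 || ncol(v) < 1) msgs <- c(msgs, "grid must have cells")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Grid
#'
#' @param values numeric matrix, row 1 = north; `NA` marks NODATA.
#' @param xll,yll lower-left corner coordinates in degrees.
#' @param cellSize cell size in degrees.
#' @param nodata NODATA sentinel used when writing to disk.
#' @param name layer label.
#' @return A [Grid-class] object.
#' @examples
#' g <- grid(matrix(1:4, 2, 2), xll = 0, yll = 0, cellSize = 0.5)
#' nRows(g)
#' @export
grid <- function(values, xll = 0, yll = 0, cellSize = 1,
                 nodata = -9999, name = "layer") {
  new("Grid", values = values, xll = xll, yll = yll,
      cellSize = cellSize, nodata = nodata, name = name)
}

#' @describeIn grid number of rows
#' @param x a `Grid`
#' @export
nRows <- function(x) nrow(x@values)

#' @describeIn grid number of columns
#' @export
nCols <- function(x) ncol(x@values)

#' @describeIn grid raster values as a matrix (`NA` = NODATA)
#' @export
gridValues <- function(x) x@values

#' @describeIn grid cell size in degrees
#' @export
cellSize <- function(x) x@cellSize

setMethod("show", "Grid", function(object) {
  v <- object@values
  cat(sprintf("Grid '%s': %d x %d cells, %.6g deg, ll = (%.6g, %.6g)\n",
              object@name, nrow(v), ncol(v), object@cellSize,
              object@xll, object@yll))
  cat(sprintf("  valid cells: %d / %d; range: [%s, %s]\n",
              sum(!is.na(v)), length(v),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE)))))
})

## two grids share a geometry (tolerant float comparison)
sameGeometry <- function(a, b, tol = 1e-9) {
  nrow(a@values) == nrow(b@values) && ncol(a@values) == ncol(b@values) &&
    abs(a@xll - b@xll) < tol && abs(a@yll - b@yll) < tol &&
    abs(a@cellSize - b@cellSize) < tol
}

#' Latitude of the centre of a grid row
#'
#' Row 1 is the northernmost row.
#' @param grid a [Grid-class]
#' @param row row index (1-based from the top)
#' @return latitude in degrees
#' @export
rowLatitude <- function(grid, row) {
  nr <- nRows(grid)
  if (any(row < 1 | row > nr)) stop("row index out of range [1, ", nr, "]")
  grid@yll + (nr - row + 0.5) * grid@cellSize
}

## longitude of column centres
colLongitude <- function(grid, col) {
  grid@xll + (col - 0.5) * grid@cellSize
}

#' Area of one cell in a given row, in square kilometres
#'
#' Spherical cosine-latitude approximation with 1 degree ~ 111.195 km:
#' `area = (cellSize * 111.195)^2 * cos(latitude of row centre)`. Adequate
#' for relative area accounting; documented as approximate.
#'
#' @inheritParams rowLatitude
#' @return area per cell in km^2 (vectorized over `row`)
#' @examples
#' g <- grid(matrix(0, 3, 3), yll = -1.5, cellSize = 1)
#' cellAreaKm2(g, 2)  # equatorial row: ~12364.3 km^2
#' @export
cellAreaKm2 <- function(grid, row) {
  lat <- rowLatitude(grid, row)
  (grid@cellSize * 111.195)^2 * cos(lat * pi / 180)
}

## per-cell area matrix (rows x cols), NA where grid is NODATA
cellAreaMatrix <- function(grid) {
  a <- cellAreaKm2(grid, seq_len(nRows(grid)))
  m <- matrix(a, nRows(grid), nCols(grid))
  m[is.na(grid@values)] <- NA
  m
}

#' Total area of a binary habitat map, in km^2
#'
#' Sums [cellAreaKm2()] over cells equal to 1 (NODATA excluded).
#' @param binaryMap a [Grid-class] with values in \{0, 1, NA\}
#' @return total habitat area (km^2)
#' @export
habitatAreaKm2 <- function(binaryMap) {
  a <- cellAreaMatrix(binaryMap)
  sum(a[which(binaryMap@values == 1)], na.rm = TRUE)
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid I/O

#' Read an ESRI ASCII grid (.asc)
#'
#' Parses the six-key header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by row-major cell values (row 1 =
#' north). Cells equal to the NODATA sentinel become `NA`.
#'
#' @param path path to the `.asc` file
#' @param name layer label for the returned grid (defaults to the file stem)
#' @return a [Grid-class]
#' @export
readAsciiGrid <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", trimws(lines[i]))) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop("malformed header line: '", lines[i], "'")
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) stop("non-numeric header value for key '", parts[1], "'")
    hdr[[tolower(parts[1])]] <- val
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(need, names(hdr))
  if (length(missing))
    stop("malformed ASCII grid header: missing key(s) ",
         paste(missing, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  body <- lines[seq(i, length.out = length(lines) - i + 1)]
  toks <- unlist(strsplit(trimws(body), "\\s+"), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop("non-numeric cell value '", toks[bad], "' at body position ", bad,
         " (approx. row ", ceiling(bad / nc), ")")
  }
  if (length(vals) != nr * nc)
    stop("body has ", length(vals), " values; header declares ",
         nr, " x ", nc, " = ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellSize = hdr$cellsize, nodata = nodata, name = name)
}

#' Write a Grid as an ESRI ASCII file
#'
#' The written file round-trips through [readAsciiGrid()] losslessly at the
#' printed precision (15 significant digits).
#'
#' @param grid a [Grid-class]
#' @param path output path
#' @param digits significant digits for cell values
#' @return invisibly, `path`
#' @export
writeAsciiGrid <- function(grid, path, digits = 15) {
  stopifnot(is(grid, "Grid"))
  v <- grid@values
  v[is.na(v)] <- grid@nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid@xll),
    sprintf("yllcorner %.10g", grid@yll),
    sprintf("cellsize %.10g", grid@cellSize),
    sprintf("NODATA_value %.10g", grid@nodata)
  )
  rows <- apply(v, 1, function(r)
    paste(trimws(formatC(r, digits = digits, format = "g")), collapse = " "))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Environmental stack

#' Stack of co-registered environmental layers
#'
#' An ordered collection of [Grid-class] layers sharing one geometry, each
#' tagged with a role from the four variable families used in the workflow
#' (`bioclimatic`, `soil`, `terrain`, `land_cover`). NODATA masks are
#' unioned for analysis: a cell missing in any layer is excluded everywhere.
#'
#' @slot layers named list of `Grid`
#' @slot roles character vector, one role per layer
#' @export
setClass("EnvStack",
  representation(layers = "list", roles = "character"))

setValidity("EnvStack", function(object) {
  ls <- object@layers
  if (!length(ls)) return("stack must contain at least one layer")
  if (!all(vapply(ls, is, TRUE, "Grid"))) return("all layers must be Grid")
  if (is.null(names(ls)) || any(!nzchar(names(ls))))
    return("layers must be named")
  ok <- vapply(ls, sameGeometry, TRUE, b = ls[[1]])
  if (!all(ok)) return("all layers must share one geometry")
  valid_roles <- c("bioclimatic", "soil", "terrain", "land_cover")
  if (length(object@roles) != length(ls))
    return("one role per layer required")
  if (!all(object@roles %in% valid_roles))
    return(paste("roles must be among:", paste(valid_roles, collapse = ", ")))
  TRUE
})

#' Construct an EnvStack
#' @param layers named list of [Grid-class] sharing a geometry
#' @param roles one role per layer: `bioclimatic`, `soil`, `terrain`
#'   or `land_cover`
#' @return an [EnvStack-class]
#' @export
envStack <- function(layers, roles) {
  new("EnvStack", layers = layers, roles = setNames(roles, names(layers)))
}

#' @describeIn envStack layer names
#' @param x an `EnvStack`
#' @export
layerNames <- function(x) names(x@layers)

#' @describeIn envStack extract one layer as a `Grid`
#' @param name layer name
#' @export
getLayer <- function(x, name) {
  if (!name %in% names(x@layers))
    stop("no layer '", name, "' in stack (have: ",
         paste(names(x@layers), collapse = ", "), ")")
  x@layers[[name]]
}

#' @describeIn envStack replace or add a layer (geometry checked)
#' @param value a `Grid`
#' @param role role tag for a new layer
#' @export
setLayer <- function(x, name, value, role = "bioclimatic") {
  stopifnot(is(value, "Grid"), sameGeometry(value, x@layers[[1]]))
  if (name %in% names(x@layers)) role <- x@roles[[name]]
  x@layers[[name]] <- value
  x@roles[name] <- role
  validObject(x)
  x
}

setMethod("show", "EnvStack", function(object) {
  cat(sprintf("EnvStack: %d layers, %d x %d cells\n",
              length(object@layers),
              nRows(object@layers[[1]]), nCols(object@layers[[1]])))
  for (nm in names(object@layers))
    cat(sprintf("  %-10s [%s]\n", nm, object@roles[[nm]]))
})

#' Unioned validity mask of a stack
#'
#' @param stack an [EnvStack-class]
#' @return logical matrix, `TRUE` where every layer has data
#' @export
validMask <- function(stack) {
  m <- !is.na(stack@layers[[1]]@values)
  for (g in stack@layers[-1]) m <- m & !is.na(g@values)
  m
}

# ---------------------------------------------------------------------------
# Point extraction

## map lon/lat to (row, col); cells are half-open [edge, edge + cellSize)
pointToCell <- function(grid, lon, lat) {
  nr <- nRows(grid); nc <- nCols(grid); cs <- grid@cellSize
  col <- floor((lon - grid@xll) / cs) + 1L
  rowFromBottom <- floor((lat - grid@yll) / cs)
  row <- nr - rowFromBottom
  inb <- col >= 1L & col <= nc & row >= 1L & row <= nr
  data.frame(row = ifelse(inb, row, NA_integer_),
             col = ifelse(inb, col, NA_integer_),
             inBounds = inb)
}

#' Extract layer values at points
#'
#' Each point maps to the cell containing it (half-open cell intervals,
#' row 1 = north). Points outside the grid, or falling on a cell that is
#' NODATA in any layer, are flagged invalid rather than raising an error.
#'
#' @param stack an [EnvStack-class]
#' @param points data frame with columns `lon`, `lat`
#' @return list with `features` (points x layers numeric matrix, `NA` rows
#'   for invalid points) and `valid` (logical vector)
#' @export
extractAtPoints <- function(stack, points) {
  nms <- layerNames(stack)
  if (nrow(points) == 0) {
    return(list(features = matrix(numeric(0), 0, length(nms),
                                  dimnames = list(NULL, nms)),
                valid = logical(0)))
  }
  g1 <- stack@layers[[1]]
  cells <- pointToCell(g1, points$lon, points$lat)
  feats <- matrix(NA_real_, nrow(points), length(nms),
                  dimnames = list(NULL, nms))
  inb <- which(cells$inBounds)
  idx <- cbind(cells$row[inb], cells$col[inb])
  for (j in seq_along(nms))
    feats[inb, j] <- stack@layers[[j]]@values[idx]
  valid <- cells$inBounds & !apply(is.na(feats), 1, any)
  list(features = feats, valid = valid)
}
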