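#' Create a region of interest (ROI)
#'
#' ROIs mark areas of the camera field of view selected for patterned
#' illumination. Three shapes are supported, mirroring manual pattern
#' drawing tools: axis-aligned rectangles, axis-aligned ellipses, and
#' arbitrary (possibly self-intersecting) polygons. Coordinates are camera
#' pixels, origin top-left.
#'
#' @param kind one of `"rectangle"`, `"ellipse"`, `"polygon"`.
#' @param params shape parameters: rectangle `c(x0, y0, x1, y1)` with
#'   `x1 > x0`, `y1 > y0`; ellipse `c(cx, cy, rx, ry)` with positive radii;
#'   polygon an n x 2 matrix (or data frame) of vertices, n >= 3, with
#'   nonzero enclosed area.
#' @param label free-text label.
#' @param id optional id; a fresh unique id is generated when `NULL`.
#' @return an object of class `"roi"`.
#' @export
#' @examples
#' make_roi("rectangle", c(0, 0, 10, 10))
#' make_roi("ellipse", c(50, 50, 10, 10))
#' make_roi("polygon", cbind(c(0, 10, 5), c(0, 0, 8)))
make_roi <- function(kind = c("rectangle", "ellipse", "polygon"), params,
                     label = "", id = NULL) {
  kind <- match.arg(kind)
  if (kind == "rectangle") {
    params <- as.numeric(params)
    if (length(params) != 4L) stopf("rectangle params must be (x0, y0, x1, y1)")
    if (params[3] <= params[1]) stopf("invalid rectangle: x1 (%g) must exceed x0 (%g)", params[3], params[1])
    if (params[4] <= params[2]) stopf("invalid rectangle: y1 (%g) must exceed y0 (%g)", params[4], params[2])
  } else if (kind == "ellipse") {
    params <- as.numeric(params)
    if (length(params) != 4L) stopf("ellipse params must be (cx, cy, rx, ry)")
    if (params[3] <= 0) stopf("invalid ellipse: rx (%g) must be > 0", params[3])
    if (params[4] <= 0) stopf("invalid ellipse: ry (%g) must be > 0", params[4])
  } else {
    params <- as.matrix(params)
    storage.mode(params) <- "double"
    if (ncol(params) != 2L) stopf("polygon params must be an n x 2 vertex matrix")
    if (nrow(params) < 3L) stopf("invalid polygon: needs >= 3 vertices, got %d", nrow(params))
    if (abs(polygon_area(params[, 1], params[, 2])) < 1e-12)
      stopf("invalid polygon: zero enclosed area")
    colnames(params) <- c("x", "y")
  }
  structure(list(id = id %||% next_id("roi"), kind = kind, params = params,
                 label = label),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi %s> %s%s\n", x$id, x$kind,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else ""))
  invisible(x)
}

# signed shoelace area
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Camera-to-DMD calibration transform
#'
#' Affine map from camera pixel coordinates to DMD (micromirror) pixel
#' coordinates, plus the physical scale of a camera pixel. The default is
#' the identity (camera and DMD share a pixel grid).
#'
#' @param matrix 2 x 3 affine matrix `[A | b]` mapping camera `(x, y)` to
#'   DMD `(x, y)` as `A %*% c(x, y) + b`; the 2 x 2 linear part must be
#'   invertible.
#' @param um_per_camera_px physical size of one camera pixel, micrometres.
#' @return object of class `"calibration_transform"`.
#' @export
calibration_transform <- function(matrix = NULL, um_per_camera_px = 1) {
  m <- matrix %||% cbind(diag(2), c(0, 0))
  m <- base::matrix(as.numeric(m), nrow = 2L)
  if (!identical(dim(m), c(2L, 3L))) stopf("transform matrix must be 2 x 3")
  if (abs(det(m[, 1:2])) < 1e-12) stopf("transform is not invertible (zero determinant)")
  if (!is.numeric(um_per_camera_px) || um_per_camera_px <= 0)
    stopf("um_per_camera_px must be > 0")
  structure(list(matrix = m, um_per_camera_px = um_per_camera_px),
            class = "calibration_transform")
}

#' Fit a transform mapping camera bounds onto the full DMD
#'
#' Convenience constructor: per-axis scale and shift taking the half-open
#' camera rectangle `bounds = c(x0, y0, x1, y1)` onto `[0, dmd_cols) x
#' [0, dmd_rows)`.
#'
#' @param bounds camera-pixel rectangle `c(x0, y0, x1, y1)`.
#' @param dmd_shape `c(rows, cols)` of the DMD.
#' @param um_per_camera_px physical camera pixel size, micrometres.
#' @return a [calibration_transform()].
#' @export
fit_camera_to_dmd <- function(bounds, dmd_shape, um_per_camera_px = 1) {
  sx <- dmd_shape[2] / (bounds[3] - bounds[1])
  sy <- dmd_shape[1] / (bounds[4] - bounds[2])
  m <- rbind(c(sx, 0, -sx * bounds[1]),
             c(0, sy, -sy * bounds[2]))
  calibration_transform(m, um_per_camera_px)
}

# map DMD-space points (2 x n matrix, rows x;y) back to camera space
dmd_to_camera <- function(transform, pts) {
  A <- transform$matrix[, 1:2]
  b <- transform$matrix[, 3]
  solve(A, pts - b)
}

# --- point membership ---------------------------------------------------

rect_contains <- function(x, y, p, closed = TRUE) {
  if (closed) x >= p[1] & x <= p[3] & y >= p[2] & y <= p[4]
  else        x >= p[1] & x <  p[3] & y >= p[2] & y <  p[4]
}

ellipse_contains <- function(x, y, p) {
  ((x - p[1]) / p[3])^2 + ((y - p[2]) / p[4])^2 <= 1
}

# even-odd (crossing-number) point-in-polygon test, vectorized over points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    dy <- vy[j] - vy[i]
    if (dy != 0) {
      crosses <- ((vy[i] > py) != (vy[j] > py)) &
        (px < (vx[j] - vx[i]) * (py - vy[i]) / dy + vx[i])
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

roi_contains <- function(roi, x, y, closed_rect = TRUE) {
  switch(roi$kind,
    rectangle = rect_contains(x, y, roi$params, closed = closed_rect),
    ellipse   = ellipse_contains(x, y, roi$params),
    polygon   = point_in_polygon(x, y, roi$params[, 1], roi$params[, 2]))
}

# --- pattern masks ------------------------------------------------------

#' Construct a pattern mask
#'
#' A pattern mask names which DMD micromirrors are switched ON for one
#' stimulus: a logical matrix in DMD pixel space plus the ids of the
#' ROIs/grid cells it was built from.
#'
#' @param id mask id.
#' @param grid logical matrix `(dmd_rows, dmd_cols)`.
#' @param member_roi_ids character vector of contributing ROI/cell ids.
#' @return object of class `"pattern_mask"`.
#' @export
pattern_mask <- function(id, grid, member_roi_ids = character()) {
  if (!is.matrix(grid)) stopf("mask grid must be a matrix")
  grid <- grid & TRUE  # coerce to logical, keep dims
  structure(list(id = id, grid = grid, member_roi_ids = member_roi_ids),
            class = "pattern_mask")
}

#' @export
print.pattern_mask <- function(x, ...) {
  cat(sprintf("<pattern_mask %s> %d x %d, %d ON px (members: %s)\n",
              x$id, nrow(x$grid), ncol(x$grid), sum(x$grid),
              paste(x$member_roi_ids, collapse = ", ")))
  invisible(x)
}

#' Rasterize an ROI to a DMD pattern mask
#'
#' A DMD pixel `(r, c)` is ON iff its center `(c + 0.5, r + 0.5)`, mapped
#' back to camera coordinates through the inverse calibration transform,
#' lies inside the ROI. Boundary rule: inside-or-on for rectangles and
#' ellipses (`(dx/rx)^2 + (dy/ry)^2 <= 1`), even-odd crossing test for
#' polygons. An ROI that covers no DMD pixel yields an empty mask with a
#' warning, not an error.
#'
#' @param roi an [make_roi()] object.
#' @param transform a [calibration_transform()].
#' @param dmd_shape integer `c(rows, cols)` of the DMD; must be positive.
#' @param half_open use half-open `[x0, x1)` membership for rectangles
#'   (grid-cell rasterization, keeps adjacent cells disjoint).
#' @return a [pattern_mask()].
#' @export
#' @examples
#' m <- rasterize(make_roi("ellipse", c(50, 50, 10, 10)),
#'                calibration_transform(), dmd_shape = c(100, 100))
#' sum(m$grid)
rasterize <- function(roi, transform = calibration_transform(),
                      dmd_shape = c(684, 608), half_open = FALSE) {
  dmd_shape <- as.integer(dmd_shape)
  if (length(dmd_shape) != 2L || any(dmd_shape < 1L))
    stopf("dmd_shape must be positive (rows, cols)")
  if (!inherits(transform, "calibration_transform"))
    stopf("transform must be a calibration_transform")
  nr <- dmd_shape[1]; nc <- dmd_shape[2]
  # pixel centers, column-major to match matrix layout
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  cam <- dmd_to_camera(transform, rbind(cx, cy))
  on <- roi_contains(roi, cam[1, ], cam[2, ], closed_rect = !half_open)
  grid <- matrix(on, nrow = nr, ncol = nc)
  if (!any(grid))
    warnf("ROI '%s' maps to no DMD pixels (outside the DMD extent)", roi$id)
  pattern_mask(roi$id, grid, member_roi_ids = roi$id)
}

#' Combine pattern masks by pixelwise OR
#'
#' @param masks list of [pattern_mask()] objects with identical shape.
#' @param id id for the combined mask; defaults to the member ids joined
#'   with `"+"`.
#' @return a [pattern_mask()] whose grid is the union of the inputs.
#' @export
combine_masks <- function(masks, id = NULL) {
  if (length(masks) == 0L) stopf("no masks to combine")
  g <- masks[[1]]$grid
  for (m in masks[-1]) {
    if (!identical(dim(m$grid), dim(g))) stopf("mask shapes differ")
    g <- g | m$grid
  }
  members <- unlist(lapply(masks, function(m) m$member_roi_ids))
  pattern_mask(id %||% paste(vapply(masks, `[[`, "", "id"), collapse = "+"),
               g, members)
}

#' Write / read a pattern mask stack
#'
#' Masks are persisted as a multi-page 8-bit TIFF (one page per pattern,
#' OFF = 0, ON = 255) plus a JSON sidecar holding ids, member provenance,
#' the calibration transform and the physical pixel size.
#'
#' @param masks list of [pattern_mask()] objects.
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @param transform optional [calibration_transform()] recorded in the sidecar.
#' @return `write_masks`: invisibly, the sidecar path. `read_masks`: the
#'   list of masks, with the sidecar contents in attribute `"sidecar"`.
#' @export
write_masks <- function(masks, path, transform = NULL) {
  pages <- lapply(masks, function(m) {
    g <- matrix(as.numeric(m$grid), nrow = nrow(m$grid))
    g  # writeTIFF expects [0,1]; ON = 1 -> 255 at 8 bit
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  sidecar <- list(
    ids = vapply(masks, `[[`, "", "id"),
    member_roi_ids = lapply(masks, `[[`, "member_roi_ids"),
    dmd_shape = dim(masks[[1]]$grid),
    transform = if (!is.null(transform)) list(
      matrix = transform$matrix, um_per_camera_px = transform$um_per_camera_px)
  )
  sidecar_path <- paste0(path, ".json")
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(sidecar_path)
}

#' @rdname write_masks
#' @param path path to the TIFF stack written by `write_masks`.
#' @export
read_masks <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) stopf("missing mask sidecar '%s'", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  masks <- vector("list", length(pages))
  for (i in seq_along(pages)) {
    members <- if (is.list(sc$member_roi_ids)) unlist(sc$member_roi_ids[[i]])
               else sc$member_roi_ids[i]
    masks[[i]] <- pattern_mask(sc$ids[i], pages[[i]] > 0.5, members)
  }
  names(masks) <- sc$ids
  attr(masks, "sidecar") <- sc
  masks
}

#' Read a background field-of-view image
#'
#' Accepts 8/16-bit grayscale (or RGB, averaged to gray) TIFF and PNG.
#'
#' @param path image path, extension `.tif`, `.tiff` or `.png`.
#' @return numeric matrix in `[0, 1]`, rows = image rows.
#' @export
read_background <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stopf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}
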