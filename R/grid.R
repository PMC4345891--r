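#' Hierarchical rectangular grid of stimulation cells
#'
#' `grid_create` tiles a camera-pixel rectangle into `rows x cols` leaf
#' cells. Cells can then be subdivided ([grid_subdivide()]), merged back
#' ([grid_merge()]), selected ([grid_select()]) and exported to DMD masks
#' ([grid_export()]). Bounds are half-open `[x0, x1) x [y0, y1)`; when the
#' bounds are whole pixels the split uses an integer partition in which
#' column/row sizes differ by at most one pixel, remainder pixels going to
#' the lowest-index columns/rows (left-to-right, top-to-bottom).
#'
#' @param bounds `c(x0, y0, x1, y1)` camera px, `x1 > x0`, `y1 > y0`.
#' @param rows,cols number of rows/columns, each >= 1.
#' @return object of class `"smart_grid"`.
#' @export
#' @examples
#' g <- grid_create(c(0, 0, 2172, 1653), 3, 3)
#' grid_leaves(g)
grid_create <- function(bounds, rows, cols) {
  bounds <- as.numeric(bounds)
  if (length(bounds) != 4L || bounds[3] <= bounds[1] || bounds[4] <= bounds[2])
    stopf("degenerate bounds")
  if (rows < 1L || cols < 1L) stopf("rows and cols must be >= 1")
  root <- subdivide_cell(new_cell("root", bounds), rows, cols)
  structure(list(bounds = bounds, root = root), class = "smart_grid")
}

new_cell <- function(id, bounds) {
  list(id = id, bounds = as.numeric(bounds), children = NULL, selected = FALSE)
}

cell_is_leaf <- function(cell) is.null(cell$children)

# split [a, b) into n spans; integer partition with remainder to the
# lowest-index spans when the endpoints are whole pixels
split_points <- function(a, b, n) {
  if (is_whole(c(a, b))) {
    w <- round(b) - round(a)
    base <- w %/% n
    if (base < 1L) stopf("cannot split %d px into %d cells: below the pixel limit", w, n)
    rem <- w %% n
    widths <- rep(base, n) + c(rep(1L, rem), rep(0L, n - rem))
    round(a) + cumsum(c(0L, widths))
  } else {
    if ((b - a) / n < 1) stopf("cannot split %g px into %d cells: below the pixel limit", b - a, n)
    seq(a, b, length.out = n + 1L)
  }
}

subdivide_cell <- function(cell, rows, cols) {
  xs <- split_points(cell$bounds[1], cell$bounds[3], cols)
  ys <- split_points(cell$bounds[2], cell$bounds[4], rows)
  prefix <- if (cell$id == "root") "" else paste0(cell$id, ":")
  children <- vector("list", rows * cols)
  k <- 0L
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    k <- k + 1L
    children[[k]] <- new_cell(sprintf("%sr%dc%d", prefix, r, c),
                              c(xs[c], ys[r], xs[c + 1L], ys[r + 1L]))
  }
  cell$children <- children
  cell$selected <- FALSE
  cell
}

find_cell <- function(cell, id) {
  if (cell$id == id) return(cell)
  for (ch in cell$children) {
    hit <- find_cell(ch, id)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

# apply f to the cell with the given id, rebuilding the tree
map_cell <- function(cell, id, f) {
  if (cell$id == id) return(f(cell))
  if (!is.null(cell$children)) {
    cell$children <- lapply(cell$children, map_cell, id = id, f = f)
  }
  cell
}

collect_leaves <- function(cell, acc = list()) {
  if (cell_is_leaf(cell)) return(c(acc, list(cell)))
  for (ch in cell$children) acc <- collect_leaves(ch, acc)
  acc
}

#' Leaf cells of a grid
#'
#' @param grid a [grid_create()] object.
#' @return data frame with one row per leaf: id, bounds, width/height (px),
#'   selection flag.
#' @export
grid_leaves <- function(grid) {
  ls <- collect_leaves(grid$root)
  data.frame(
    id = vapply(ls, `[[`, "", "id"),
    x0 = vapply(ls, function(l) l$bounds[1], 0),
    y0 = vapply(ls, function(l) l$bounds[2], 0),
    x1 = vapply(ls, function(l) l$bounds[3], 0),
    y1 = vapply(ls, function(l) l$bounds[4], 0),
    width = vapply(ls, function(l) l$bounds[3] - l$bounds[1], 0),
    height = vapply(ls, function(l) l$bounds[4] - l$bounds[2], 0),
    selected = vapply(ls, `[[`, TRUE, "selected"),
    stringsAsFactors = FALSE)
}

#' Subdivide one leaf cell into a sub-grid
#'
#' @inheritParams grid_leaves
#' @param cell_id id of a leaf cell.
#' @param rows,cols sub-grid dimensions; subdivision below one pixel per
#'   cell is refused (the micromirror pixel is the resolution limit).
#' @return the updated grid.
#' @export
grid_subdivide <- function(grid, cell_id, rows, cols) {
  cell <- find_cell(grid$root, cell_id)
  if (is.null(cell)) stopf("unknown cell '%s'", cell_id)
  if (!cell_is_leaf(cell)) stopf("cell '%s' is not a leaf", cell_id)
  if (rows < 1L || cols < 1L) stopf("rows and cols must be >= 1")
  grid$root <- map_cell(grid$root, cell_id, function(c) subdivide_cell(c, rows, cols))
  grid
}

#' Merge sibling leaf cells into one
#'
#' The named cells must be leaves sharing the same parent, and their bounds
#' must tile a rectangle exactly (an L-shaped or gapped union is refused).
#' Merging all children of a parent turns the parent back into a leaf.
#'
#' @inheritParams grid_subdivide
#' @param cell_ids ids of the sibling leaves to merge (>= 2).
#' @return the updated grid.
#' @export
grid_merge <- function(grid, cell_ids) {
  if (length(cell_ids) < 2L) stopf("need at least two cells to merge")
  parent <- find_parent(grid$root, cell_ids[1])
  if (is.null(parent)) stopf("unknown cell '%s'", cell_ids[1])
  child_ids <- vapply(parent$children, `[[`, "", "id")
  if (!all(cell_ids %in% child_ids))
    stopf("cells to merge are not siblings of one parent")
  sel <- parent$children[match(cell_ids, child_ids)]
  if (!all(vapply(sel, cell_is_leaf, TRUE)))
    stopf("can only merge leaf cells")
  bb <- c(min(vapply(sel, function(c) c$bounds[1], 0)),
          min(vapply(sel, function(c) c$bounds[2], 0)),
          max(vapply(sel, function(c) c$bounds[3], 0)),
          max(vapply(sel, function(c) c$bounds[4], 0)))
  areas <- vapply(sel, function(c)
    (c$bounds[3] - c$bounds[1]) * (c$bounds[4] - c$bounds[2]), 0)
  if (abs(sum(areas) - (bb[3] - bb[1]) * (bb[4] - bb[2])) > 1e-9)
    stopf("cells do not tile a rectangle; cannot merge")
  merged <- new_cell(paste(sort(cell_ids), collapse = "+"), bb)
  grid$root <- map_cell(grid$root, parent$id, function(p) {
    keep <- p$children[!child_ids %in% cell_ids]
    if (length(keep) == 0L && all(abs(bb - p$bounds) < 1e-9)) {
      p$children <- NULL  # parent becomes a leaf again
    } else {
      p$children <- c(keep, list(merged))
    }
    p
  })
  grid
}

find_parent <- function(cell, child_id) {
  for (ch in cell$children) {
    if (ch$id == child_id) return(cell)
    hit <- find_parent(ch, child_id)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Select or deselect leaf cells
#'
#' Only leaf cells carry a selection flag; selecting an internal cell is an
#' error.
#'
#' @inheritParams grid_subdivide
#' @param cell_ids leaf ids to (de)select.
#' @param selected logical.
#' @return the updated grid.
#' @export
grid_select <- function(grid, cell_ids, selected = TRUE) {
  for (id in cell_ids) {
    cell <- find_cell(grid$root, id)
    if (is.null(cell)) stopf("unknown cell '%s'", id)
    if (!cell_is_leaf(cell)) stopf("cell '%s' is not a leaf; only leaves can be selected", id)
    grid$root <- map_cell(grid$root, id, function(c) { c$selected <- selected; c })
  }
  grid
}

#' Export grid cells as DMD pattern masks
#'
#' Each cell rasterizes as a half-open rectangle (adjacent cells never share
#' a DMD pixel). With `grouped = TRUE` a single mask equal to the pixelwise
#' OR of the per-cell masks is returned, enabling simultaneous stimulation
#' of non-adjacent areas; provenance is kept in `member_roi_ids`.
#'
#' @inheritParams grid_subdivide
#' @param selected_ids leaf ids to export; default: all cells flagged
#'   selected. Empty selection is an error.
#' @param grouped return one combined mask instead of one mask per cell.
#' @param transform a [calibration_transform()].
#' @param dmd_shape `c(rows, cols)` of the DMD.
#' @return list of [pattern_mask()] (length 1 when `grouped`).
#' @export
grid_export <- function(grid, selected_ids = NULL, grouped = FALSE,
                        transform = calibration_transform(),
                        dmd_shape = c(684, 608)) {
  if (is.null(selected_ids)) {
    lv <- grid_leaves(grid)
    selected_ids <- lv$id[lv$selected]
  }
  if (length(selected_ids) == 0L) stopf("empty selection: nothing to export")
  masks <- lapply(selected_ids, function(id) {
    cell <- find_cell(grid$root, id)
    if (is.null(cell)) stopf("unknown cell '%s'", id)
    if (!cell_is_leaf(cell)) stopf("cell '%s' is not a leaf", id)
    roi <- make_roi("rectangle", cell$bounds, id = id)
    rasterize(roi, transform, dmd_shape, half_open = TRUE)
  })
  names(masks) <- selected_ids
  if (grouped) {
    m <- combine_masks(masks)
    masks <- stats::setNames(list(m), m$id)
  }
  masks
}

#' Physical dimensions of one grid cell
#'
#' Pixel span times the physical pixel size, reported to the nearest
#' micrometre (ties round half away from zero) — the convention used when
#' printing grid cell sizes on figures.
#'
#' @inheritParams grid_subdivide
#' @param cell_id cell id (leaf or internal).
#' @param um_per_camera_px physical camera pixel size, micrometres.
#' @return `c(width_um, height_um)`, integer-valued.
#' @export
#' @examples
#' g <- grid_create(c(0, 0, 724, 551), 3, 3)
#' cell_dimensions_um(g, "r2c2", 1)
cell_dimensions_um <- function(grid, cell_id, um_per_camera_px = 1) {
  cell <- find_cell(grid$root, cell_id)
  if (is.null(cell)) stopf("unknown cell '%s'", cell_id)
  w <- (cell$bounds[3] - cell$bounds[1]) * um_per_camera_px
  h <- (cell$bounds[4] - cell$bounds[2]) * um_per_camera_px
  c(width_um = round_half_away(w), height_um = round_half_away(h))
}

#' Representative (modal) leaf-cell size of a grid
#'
#' Integer pixel partitioning makes sibling cells differ by up to one pixel;
#' figure captions quote a single size per grid. This returns the most
#' common leaf width and height, in micrometres (nearest-μm rounding).
#'
#' @inheritParams cell_dimensions_um
#' @return `c(width_um, height_um)` of the modal leaf cell.
#' @export
grid_cell_size_um <- function(grid, um_per_camera_px = 1) {
  lv <- grid_leaves(grid)
  modal <- function(x) as.numeric(names(sort(table(x), decreasing = TRUE))[1])
  c(width_um = round_half_away(modal(lv$width) * um_per_camera_px),
    height_um = round_half_away(modal(lv$height) * um_per_camera_px))
}

# --- serialization ------------------------------------------------------

cell_to_list <- function(cell) {
  out <- list(id = cell$id, bounds = cell$bounds, selected = cell$selected)
  if (!cell_is_leaf(cell)) out$children <- lapply(cell$children, cell_to_list)
  out
}

cell_from_list <- function(x) {
  cell <- new_cell(x$id, unlist(x$bounds))
  cell$selected <- isTRUE(x$selected)
  if (!is.null(x$children)) cell$children <- lapply(x$children, cell_from_list)
  cell
}

#' Serialize a grid to / from JSON
#'
#' @inheritParams grid_subdivide
#' @param path file path.
#' @return `grid_to_json` invisibly returns `path`; `grid_from_json`
#'   returns the reconstructed grid.
#' @export
grid_to_json <- function(grid, path) {
  jsonlite::write_json(list(bounds = grid$bounds,
                            root = cell_to_list(grid$root)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname grid_to_json
#' @export
grid_from_json <- function(path) {
  x <- jsonlite::read_json(path)
  structure(list(bounds = unlist(x$bounds), root = cell_from_list(x$root)),
            class = "smart_grid")
}

#' @export
print.smart_grid <- function(x, ...) {
  lv <- grid_leaves(x)
  cat(sprintf("<smart_grid> bounds [%g, %g) x [%g, %g), %d leaves (%d selected)\n",
              x$bounds[1], x$bounds[3], x$bounds[2], x$bounds[4],
              nrow(lv), sum(lv$selected)))
  invisible(x)
}
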