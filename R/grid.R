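#' Build an empty forest grid
#'
#' The simulation domain is discretized into 1 x 1 x 1 m voxels. Each ground
#' voxel (1 m2 of ground) can hold at most one living tree, so the number of
#' ground voxels is also the maximum number of trees. Spatial queries use
#' either toroidal wraparound (the default, which avoids edge artifacts on
#' small domains) or hard edges.
#'
#' @param width,length Horizontal domain extent in metres (positive integers).
#' @param height Domain height in metres (positive integer); must accommodate
#'   the tallest trees.
#' @param boundary `"torus"` (default) or `"hard"`.
#' @return An object of class `forest_grid`.
#' @examples
#' g <- forest_grid(50, 40, 50)
#' n_ground_voxels(g) # 2000
#' @export
forest_grid <- function(width, length, height = 50,
                        boundary = c("torus", "hard")) {
  boundary <- match.arg(boundary)
  for (v in list(width = width, length = length, height = height)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 ||
        v != round(v)) {
      stop("grid dimensions must be positive integers", call. = FALSE)
    }
  }
  structure(list(
    width = as.integer(width), length = as.integer(length),
    height = as.integer(height), boundary = boundary,
    trees = empty_tree_table(), next_id = 1L
  ), class = "forest_grid")
}

empty_tree_table <- function() {
  data.frame(
    tree_id = integer(), species_id = character(),
    x = integer(), y = integer(),
    dbh = numeric(), height = numeric(),
    crown_radius = numeric(), crown_depth = numeric(),
    leaf_area = numeric(), npp_negative_months = integer(),
    alive = logical(), stringsAsFactors = FALSE
  )
}

#' Number of ground-level voxels in a grid
#'
#' Equals `width * length`; also the maximum number of simultaneously living
#' trees.
#' @param grid A `forest_grid`.
#' @export
n_ground_voxels <- function(grid) {
  stopifnot(inherits(grid, "forest_grid"))
  as.integer(grid$width) * as.integer(grid$length)
}

#' @export
print.forest_grid <- function(x, ...) {
  cat(sprintf("<forest_grid> %d x %d x %d m (%s boundary), %d living trees\n",
              x$width, x$length, x$height, x$boundary,
              sum(x$trees$alive)))
  invisible(x)
}

#' Center-to-center distance between two ground voxels
#'
#' Euclidean distance between voxel centers, with wraparound when the grid
#' boundary is toroidal.
#' @param grid A `forest_grid`.
#' @param from,to Length-2 integer vectors `c(x, y)` (0-based indices).
#' @export
voxel_distance <- function(grid, from, to) {
  dx <- abs(from[[1]] - to[[1]])
  dy <- abs(from[[2]] - to[[2]])
  if (grid$boundary == "torus") {
    dx <- pmin(dx, grid$width - dx)
    dy <- pmin(dy, grid$length - dy)
  }
  sqrt(dx^2 + dy^2)
}

#' Ground voxels within a radius of a center voxel
#'
#' Returns all ground voxels whose center lies within Euclidean distance
#' `radius` of the center voxel, under the grid's boundary rule. Radius 0
#' returns only the center itself.
#'
#' @param grid A `forest_grid`.
#' @param center Length-2 integer vector `c(x, y)`, 0-based.
#' @param radius Nonnegative search radius in metres.
#' @return A data frame with columns `x`, `y`, `dist`, ordered by `(x, y)`.
#' @export
voxels_within <- function(grid, center, radius) {
  stopifnot(inherits(grid, "forest_grid"))
  if (!is.numeric(radius) || length(radius) != 1 || is.na(radius) ||
      radius < 0) {
    stop("radius must be a nonnegative number", call. = FALSE)
  }
  cx <- as.integer(center[[1]]); cy <- as.integer(center[[2]])
  if (cx < 0 || cx >= grid$width || cy < 0 || cy >= grid$length) {
    stop("center voxel outside the grid", call. = FALSE)
  }
  r <- floor(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, , drop = FALSE]
  x <- cx + off$dx
  y <- cy + off$dy
  d <- sqrt(off$dx^2 + off$dy^2)
  if (grid$boundary == "torus") {
    x <- ((x %% grid$width) + grid$width) %% grid$width
    y <- ((y %% grid$length) + grid$length) %% grid$length
  } else {
    keep <- x >= 0 & x < grid$width & y >= 0 & y < grid$length
    x <- x[keep]; y <- y[keep]; d <- d[keep]
  }
  out <- data.frame(x = x, y = y, dist = d)
  out <- out[!duplicated(out[c("x", "y")]), , drop = FALSE]
  out <- out[order(out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Place a tree on the grid
#'
#' Test and setup helper: adds one living tree of a given species at a voxel,
#' deriving height, crown geometry, and leaf area from the species allometry.
#' Fails if the voxel is already occupied by a living tree.
#'
#' @param grid A `forest_grid`.
#' @param traits One row of a species-trait table (see [species_traits()]).
#' @param x,y Voxel indices, 0-based.
#' @param dbh Diameter at breast height, cm (>= 1).
#' @param phys Physiology parameters, see [physiology_params()].
#' @param leaf_area Optional leaf area (m2); defaults to crown area times an
#'   LAI of 2.
#' @return The updated grid.
#' @export
place_tree <- function(grid, traits, x, y, dbh,
                       phys = physiology_params(), leaf_area = NULL) {
  stopifnot(inherits(grid, "forest_grid"))
  if (dbh < 1) stop("trees have dbh >= 1 cm", call. = FALSE)
  occ <- grid$trees$alive & grid$trees$x == x & grid$trees$y == y
  if (any(occ)) stop("voxel already occupied by a living tree", call. = FALSE)
  h <- min(allometric_height(dbh, traits), grid$height)
  cr <- phys$cr_a * dbh^phys$cr_b
  cd <- max(1, round(phys$cd_frac * h))
  ncol_crown <- max(1L, nrow(voxels_within(grid, c(x, y), floor(cr))))
  if (is.null(leaf_area)) leaf_area <- 2 * ncol_crown
  tree <- data.frame(
    tree_id = grid$next_id, species_id = as.character(traits$species_id),
    x = as.integer(x), y = as.integer(y), dbh = dbh, height = h,
    crown_radius = cr, crown_depth = cd, leaf_area = leaf_area,
    npp_negative_months = 0L, alive = TRUE, stringsAsFactors = FALSE
  )
  grid$trees <- rbind(grid$trees, tree)
  grid$next_id <- grid$next_id + 1L
  grid
}
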