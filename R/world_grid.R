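# Bounded 2-D resource grid with regeneration timers, 8-direction facing
# geometry and the 45-degree view cone.
#
# The world is an environment (reference semantics) holding a 0/1 resource
# matrix and an integer regeneration-timer matrix. Coordinates are 0-based
# (x, y) with the origin at the top-left; x grows rightward, y downward.

# facing 1..8 = N, NE, E, SE, S, SW, W, NW
FACING_DX <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
FACING_DY <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)

#' Create a bounded grid world
#'
#' Every cell starts with one unit of resource; a consumed cell replenishes
#' `regen_delay` updates after consumption. The grid is bounded (no
#' wrap-around): movement off an edge is refused.
#'
#' @param width,height Grid dimensions in cells.
#' @param regen_delay Updates until a consumed cell replenishes (default 100).
#' @return An environment with matrices `resource` and `timer` plus the
#'   dimensions, of class `grid_world`.
#' @export
new_world <- function(width, height, regen_delay = 100L) {
  stopifnot(width >= 1, height >= 1, regen_delay >= 1)
  w <- new.env(parent = emptyenv())
  w$width <- as.integer(width)
  w$height <- as.integer(height)
  w$regen_delay <- as.integer(regen_delay)
  w$resource <- matrix(1L, nrow = height, ncol = width)
  w$timer <- matrix(0L, nrow = height, ncol = width)
  class(w) <- "grid_world"
  w
}

in_bounds <- function(world, x, y) {
  x >= 0L & x < world$width & y >= 0L & y < world$height
}

#' Consume the resource in a cell
#'
#' A full cell yields its single unit, empties, and starts its regeneration
#' timer; an empty cell yields nothing and its timer is untouched.
#'
#' @param world A [new_world()] grid.
#' @param x,y 0-based cell coordinate.
#' @return Units consumed (0 or 1).
#' @export
consume <- function(world, x, y) {
  if (!in_bounds(world, x, y)) stop("cell (", x, ",", y, ") out of bounds")
  i <- y + 1L; j <- x + 1L
  if (world$resource[i, j] == 1L) {
    world$resource[i, j] <- 0L
    world$timer[i, j] <- world$regen_delay
    1L
  } else 0L
}

#' Advance regeneration timers by one update
#'
#' Decrements every running timer; cells whose timer reaches zero are
#' replenished to one unit.
#'
#' @param world A [new_world()] grid (modified in place).
#' @return The world, invisibly.
#' @export
tick_regeneration <- function(world) {
  running <- world$timer > 0L
  if (any(running)) {
    world$timer[running] <- world$timer[running] - 1L
    refill <- running & world$timer == 0L
    world$resource[refill] <- 1L
  }
  invisible(world)
}

#' Cells inside the 45-degree view sector
#'
#' The sector comprises cells whose bearing from the looker lies within
#' +/- 22.5 degrees of the facing direction and whose Chebyshev distance is
#' at most `max_range`, truncated at the grid boundary. The looker's own
#' cell is excluded. Lattice bearings never fall exactly on the 22.5-degree
#' boundary, so membership is unambiguous.
#'
#' @param world A [new_world()] grid.
#' @param x,y Looker's cell.
#' @param facing Facing 1..8 (N, NE, E, SE, S, SW, W, NW).
#' @param max_range Maximum Chebyshev distance (default 20).
#' @return A data.frame with columns `x`, `y`, `dist`, sorted by distance
#'   then y then x.
#' @export
sector_cells <- function(world, x, y, facing, max_range = 20L) {
  stopifnot(max_range >= 1, facing %in% 1:8)
  dx <- FACING_DX[facing]; dy <- FACING_DY[facing]
  face_ang <- atan2(-dy, dx)          # y axis points down
  xs <- max(0L, x - max_range):min(world$width - 1L, x + max_range)
  ys <- max(0L, y - max_range):min(world$height - 1L, y + max_range)
  g <- expand.grid(cx = xs, cy = ys)
  rx <- g$cx - x; ry <- g$cy - y
  keep <- !(rx == 0L & ry == 0L)
  g <- g[keep, , drop = FALSE]; rx <- rx[keep]; ry <- ry[keep]
  ang <- atan2(-ry, rx)
  diff <- abs(((ang - face_ang + pi) %% (2 * pi)) - pi)
  dist <- pmax(abs(rx), abs(ry))
  inside <- diff <= (pi / 8) & dist <= max_range
  out <- data.frame(x = g$cx[inside], y = g$cy[inside], dist = dist[inside])
  out <- out[order(out$dist, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sightings in the view cone
#'
#' Returns, nearest first, the resources and organisms visible in the
#' 45-degree sector in front of a looker. Organisms are reported as `prey`
#' or `predator` (a realized predator or an injected predator counts as
#' `predator`).
#'
#' @inheritParams sector_cells
#' @param org_x,org_y Integer vectors of organism positions to scan.
#' @param org_is_pred Logical vector parallel to `org_x`.
#' @param self Optional index into the organism vectors to exclude (the
#'   looker itself).
#' @return A data.frame with columns `type` (`resource`/`prey`/`predator`),
#'   `x`, `y`, `dist`, sorted by distance (ties: resource, prey, predator,
#'   then y, x).
#' @export
view_cone <- function(world, x, y, facing, max_range = 20L,
                      org_x = integer(), org_y = integer(),
                      org_is_pred = logical(), self = NULL) {
  cells <- sector_cells(world, x, y, facing, max_range)
  if (nrow(cells) == 0L)
    return(data.frame(type = character(), x = integer(), y = integer(),
                      dist = integer(), stringsAsFactors = FALSE))
  res_idx <- world$resource[cbind(cells$y + 1L, cells$x + 1L)] == 1L
  out <- data.frame(type = rep("resource", sum(res_idx)),
                    x = cells$x[res_idx], y = cells$y[res_idx],
                    dist = cells$dist[res_idx], stringsAsFactors = FALSE)
  if (length(org_x) > 0L) {
    take <- rep(TRUE, length(org_x))
    if (!is.null(self)) take[self] <- FALSE
    key <- paste(org_x, org_y)
    cellkey <- paste(cells$x, cells$y)
    hit <- take & (key %in% cellkey)
    if (any(hit)) {
      d <- cells$dist[match(key[hit], cellkey)]
      out <- rbind(out, data.frame(
        type = ifelse(org_is_pred[hit], "predator", "prey"),
        x = org_x[hit], y = org_y[hit], dist = d,
        stringsAsFactors = FALSE))
    }
  }
  tord <- match(out$type, c("resource", "prey", "predator"))
  out <- out[order(out$dist, tord, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rotate a facing by one 45-degree step
#'
#' @param facing Facing 1..8.
#' @param dir `-1` for left (counter-clockwise), `+1` for right.
#' @return The new facing.
#' @export
turn <- function(facing, dir) {
  ((facing - 1L + as.integer(dir)) %% 8L) + 1L
}
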