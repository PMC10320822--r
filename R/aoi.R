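#' Area-of-interest layout for a matrix completion display
#'
#' A layout describes ten axis-aligned rectangles on the screen: the nine
#' matrix cells, numbered 1--9 in row-major order (1--3 across the top row,
#' 1/4/7 down the left column), and the entire solution array as AOI 10.
#' Coordinates use the usual screen convention: origin at the top-left,
#' x rightward, y downward, pixel units. Rectangles are half-open,
#' \code{[x0, x1) x [y0, y1)}, so shared edges cannot produce ties.
#'
#' @param rects data frame with columns \code{aoi} (integers 1--10),
#'   \code{x0}, \code{y0}, \code{x1}, \code{y1} (pixels).
#' @param margin non-negative tolerance in pixels: a point within
#'   \code{margin} of a rectangle (but inside none) is still assigned to it.
#'   If several rectangles qualify through the margin, the one whose centre
#'   is nearest wins.
#' @return An object of class \code{aoi_layout}.
#' @seealso [default_aoi_layout()], [read_aoi_layout()], [assign_aoi()]
#' @export
aoi_layout <- function(rects, margin = 0) {
  rects <- as.data.frame(rects)
  need <- c("aoi", "x0", "y0", "x1", "y1")
  if (!all(need %in% names(rects)))
    stop("layout needs columns: ", paste(need, collapse = ", "))
  rects <- rects[order(rects$aoi), need]
  if (!identical(as.integer(rects$aoi), 1:10))
    stop("layout must contain AOIs 1..10 exactly once each")
  if (any(rects$x1 <= rects$x0) || any(rects$y1 <= rects$y0))
    stop("degenerate rectangle: require x1 > x0 and y1 > y0")
  m <- rects[rects$aoi <= 9, ]
  for (i in 1:8) for (j in (i + 1):9) {
    if (m$x0[i] < m$x1[j] && m$x0[j] < m$x1[i] &&
        m$y0[i] < m$y1[j] && m$y0[j] < m$y1[i])
      stop("matrix cell rectangles ", i, " and ", j, " overlap")
  }
  if (margin < 0) stop("margin must be >= 0")
  structure(list(rects = rects, margin = margin), class = "aoi_layout")
}

#' Default layout: 3x3 matrix above a full-width solution array
#'
#' Cells are 180 px squares on a 20 px grid pitch starting at (200, 80) on a
#' nominal 1280 x 1024 display; the solution array spans the lower screen.
#' The geometry is arbitrary but fixed; analyses depend only on AOI labels.
#'
#' @inheritParams aoi_layout
#' @return An \code{aoi_layout}.
#' @export
default_aoi_layout <- function(margin = 0) {
  cell <- 180; pitch <- 200; ox <- 200; oy <- 80
  row <- (0:8) %/% 3; col <- (0:8) %% 3
  rects <- data.frame(
    aoi = 1:10,
    x0 = c(ox + col * pitch, 140),
    y0 = c(oy + row * pitch, 760),
    x1 = c(ox + col * pitch + cell, 1140),
    y1 = c(oy + row * pitch + cell, 980)
  )
  aoi_layout(rects, margin = margin)
}

#' Read an AOI layout from a YAML or JSON file
#'
#' The file holds a list of ten named rectangles, e.g.
#' \preformatted{
#' margin: 0
#' aois:
#'   - {aoi: 1, x0: 200, y0: 80, x1: 380, y1: 260}
#'   ...
#' }
#'
#' @param path file path; format chosen by extension (\code{.yaml}/\code{.yml}
#'   parsed as YAML, anything else as JSON, which YAML subsumes).
#' @return An \code{aoi_layout}.
#' @export
read_aoi_layout <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$aois)) stop("layout file must have an 'aois' entry")
  rects <- do.call(rbind, lapply(obj$aois, as.data.frame))
  aoi_layout(rects, margin = if (is.null(obj$margin)) 0 else obj$margin)
}

#' @exportS3Method base::print
print.aoi_layout <- function(x, ...) {
  cat("AOI layout: 9 matrix cells + solution array (AOI 10), margin",
      x$margin, "px\n")
  print(x$rects, row.names = FALSE)
  invisible(x)
}

#' Assign points to AOIs
#'
#' Labels each (x, y) point with the AOI rectangle containing it, or
#' \code{NA} if it lies outside all rectangles (and outside the margin).
#'
#' @param x,y numeric vectors of screen coordinates (px).
#' @param layout an [aoi_layout()].
#' @return Integer vector of AOI labels 1--10, \code{NA} for off-AOI points.
#' @export
assign_aoi <- function(x, y, layout = default_aoi_layout()) {
  stopifnot(inherits(layout, "aoi_layout"), length(x) == length(y))
  r <- layout$rects
  out <- rep(NA_integer_, length(x))
  for (k in 1:10) {
    hit <- x >= r$x0[k] & x < r$x1[k] & y >= r$y0[k] & y < r$y1[k]
    out[is.na(out) & hit] <- k
  }
  mg <- layout$margin
  if (mg > 0 && anyNA(out)) {
    idx <- which(is.na(out) & !is.na(x) & !is.na(y))
    if (length(idx)) {
      # distance from point to each inflated rectangle; nearest centre breaks ties
      best <- rep(NA_integer_, length(idx))
      bestd <- rep(Inf, length(idx))
      cx <- (r$x0 + r$x1) / 2; cy <- (r$y0 + r$y1) / 2
      for (k in 1:10) {
        inm <- x[idx] >= r$x0[k] - mg & x[idx] < r$x1[k] + mg &
               y[idx] >= r$y0[k] - mg & y[idx] < r$y1[k] + mg
        d <- (x[idx] - cx[k])^2 + (y[idx] - cy[k])^2
        take <- inm & d < bestd
        best[take] <- k
        bestd[take] <- d[take]
      }
      out[idx] <- best
    }
  }
  out
}
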