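# viz: Lambert equal-area projections of tilt/heading trajectories,
# RGB overlay of group histograms, pluggable 2-D embedding hook.

#' Lambert azimuthal equal-area projection of unit vectors
#'
#' Projects unit 3-vectors to the plane about the chosen pole:
#' `rho = 2 sin(theta/2)` with `theta` the angle from the pole, so the pole
#' maps to the origin, the equator to radius `sqrt(2)` and the antipode to
#' the boundary circle of radius 2 (antipodal points are flagged).  Equal
#' areas on the sphere map to equal areas in the plane.
#'
#' @param unit_vectors k x 3 matrix (renormalized; vectors further than
#'   1e-3 from unit norm are an error).
#' @param pole `"north"` (0,0,1) or `"south"` (0,0,-1).
#' @return object of class `projection2d`: list with `points` (k x 2),
#'   `pole`, and `antipodal` (logical flags).
#' @export
lambert_project <- function(unit_vectors, pole = c("north", "south")) {
  pole <- match.arg(pole)
  v <- rbind(unit_vectors)
  nrm <- sqrt(rowSums(v^2))
  if (any(abs(nrm - 1) > 1e-3))
    stop_value("inputs must be unit vectors (max norm deviation %.3g)",
               max(abs(nrm - 1)))
  v <- v / nrm
  z <- if (pole == "north") v[, 3] else -v[, 3]
  rho <- sqrt(pmax(0, 2 * (1 - z)))
  phi <- atan2(v[, 2], v[, 1])
  anti <- z < -1 + 1e-12
  phi[anti & v[, 1] == 0 & v[, 2] == 0] <- 0
  structure(list(points = cbind(x = rho * cos(phi), y = rho * sin(phi)),
                 pole = pole, antipodal = anti),
            class = "projection2d")
}

#' @export
print.projection2d <- function(x, ...) {
  cat(sprintf("<projection2d> %d points about the %s pole (max radius %.3f)\n",
              nrow(x$points), x$pole, max(sqrt(rowSums(x$points^2)))))
  invisible(x)
}

# rotate 3-vectors about the Earth vertical by angle (deg)
rotate_about_z <- function(v, angle_deg) {
  a <- angle_deg * pi / 180
  cbind(cos(a) * v[, 1] - sin(a) * v[, 2],
        sin(a) * v[, 1] + cos(a) * v[, 2], v[, 3])
}

#' Paired tilt and heading trajectories of selected segments
#'
#' For each segment, returns the Lambert-projected trajectory of the
#' gravitational acceleration in the head frame (tilt, about the head
#' vertical) and of the heading vector in the Earth frame, the latter
#' rotated about the Earth vertical so that the segment's first sample has
#' azimuth 0 (making segments comparable); azimuth-zeroing leaves the tilt
#' trajectory untouched.
#'
#' @param kin a [estimate_attitude()] result.
#' @param segments list of 0-based `c(start, end)` pairs, or a
#'   [segmentation()] plus `ids`.
#' @param ids segment ids when `segments` is a segmentation.
#' @param pole projection pole (default `"north"`).
#' @return list (one element per segment) of lists with `tilt` and
#'   `heading` ([lambert_project()] results).
#' @export
trajectory_overlay <- function(kin, segments, ids = NULL, pole = "north") {
  if (inherits(segments, "segmentation")) {
    b <- segment_bounds(segments)
    if (is.null(ids)) ids <- seq_len(nrow(b))
    segments <- lapply(ids, function(i) c(b$start[i], b$end[i]))
  }
  lapply(segments, function(se) {
    rows <- (se[1] + 1L):se[2]
    aG <- kin$aG[rows, , drop = FALSE]
    h <- kin$heading[rows, , drop = FALSE]
    az0 <- atan2(h[1, 2], h[1, 1]) * 180 / pi
    list(tilt = lambert_project(aG / sqrt(rowSums(aG^2)), pole),
         heading = lambert_project(rotate_about_z(h, -az0), pole))
  })
}

#' RGB overlay of up to three groups of 2-D points
#'
#' Each group's points are binned on a shared `grid` x `grid` histogram;
#' each histogram is normalized by its `clip_pct` percentile (values above
#' 1 clipped) and written into one color channel (group 1 = red,
#' 2 = green, 3 = blue).
#'
#' @param embeddings list of up to 3 matrices (k x 2); empty matrices give
#'   a black channel.
#' @param grid histogram resolution per axis (default 500).
#' @param clip_pct normalization percentile (default 99.8).
#' @return `grid` x `grid` x 3 array in \[0, 1\], with attributes `xlim`
#'   and `ylim` (shared axis limits).
#' @export
rgb_overlay <- function(embeddings, grid = 500L, clip_pct = 99.8) {
  if (length(embeddings) > 3L) stop_config("at most 3 groups (one per channel)")
  pts <- do.call(rbind, Filter(function(m) nrow(m) > 0, lapply(embeddings, rbind)))
  if (is.null(pts) || nrow(pts) == 0) stop_value("no points to overlay")
  xlim <- range(pts[, 1]); ylim <- range(pts[, 2])
  xbr <- seq(xlim[1], xlim[2], length.out = grid + 1L)
  ybr <- seq(ylim[1], ylim[2], length.out = grid + 1L)
  img <- array(0, dim = c(grid, grid, 3))
  for (g in seq_along(embeddings)) {
    m <- rbind(embeddings[[g]])
    if (nrow(m) == 0) next
    ix <- pmin(grid, pmax(1L, findInterval(m[, 1], xbr, rightmost.closed = TRUE)))
    iy <- pmin(grid, pmax(1L, findInterval(m[, 2], ybr, rightmost.closed = TRUE)))
    h <- matrix(0, grid, grid)
    tab <- table(ix, iy)
    h[cbind(as.integer(rownames(tab))[row(tab)],
            as.integer(colnames(tab))[col(tab)])] <- as.numeric(tab)
    qn <- quantile(h, clip_pct / 100, names = FALSE)
    if (qn <= 0) qn <- max(h)
    img[, , g] <- pmin(1, h / qn)
  }
  attr(img, "xlim") <- xlim; attr(img, "ylim") <- ylim
  img
}

.embed_backends <- new.env(parent = emptyenv())

#' Pluggable 2-D embedding hook
#'
#' The pipeline treats 2-D embedding as visualization only and delegates it
#' to a registered backend.  The built-in `"pca"` backend projects on the
#' first two principal components; external backends (e.g. a UMAP
#' implementation, for which the reference parameters are `n_neighbors = 8`,
#' `target_weight = 1e-9`, `min_dist = 1e-3`) can be registered with
#' [register_embed_backend()].  The result records the backend, parameters
#' and seed used.
#'
#' @param X feature or PC matrix (rows = observations).
#' @param labels optional per-row labels, passed to supervised backends.
#' @param backend backend name (default `"pca"`).
#' @param seed RNG seed forwarded to the backend.
#' @param ... backend parameters.
#' @return k x 2 coordinate matrix with attribute `embed_info`.
#' @export
embed_hook <- function(X, labels = NULL, backend = "pca", seed = 1L, ...) {
  fn <- .embed_backends[[backend]]
  if (is.null(fn))
    stop_config("embedding backend '%s' is not registered (available: %s)",
                backend, paste(ls(.embed_backends), collapse = ", "))
  set.seed(seed)
  out <- fn(as.matrix(X), labels, ...)
  stopifnot(ncol(out) == 2L)
  attr(out, "embed_info") <- list(backend = backend, seed = seed,
                                  params = list(...))
  out
}

#' @rdname embed_hook
#' @param name backend name.
#' @param fn function `(X, labels, ...) -> k x 2 matrix`.
#' @export
register_embed_backend <- function(name, fn) {
  stopifnot(is.function(fn))
  assign(name, fn, envir = .embed_backends)
  invisible(name)
}

# built-in backends registered at load time
.register_default_backends <- function() {
  register_embed_backend("pca", function(X, labels, ...) {
    if (ncol(X) < 2L) return(cbind(X[, 1], 0))
    p <- prcomp(X, rank. = 2L)
    unname(p$x[, 1:2])
  })
  register_embed_backend("passthrough", function(X, labels, ...) {
    if (ncol(X) != 2L) stop_value("passthrough backend needs 2-D input")
    unname(as.matrix(X))
  })
}

.onLoad <- function(libname, pkgname) {
  .register_default_backends()
}
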