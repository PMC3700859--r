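#' Per-population haplogroup frequencies
#'
#' Counts carriers of a haplogroup among classified samples, per population
#' and pooled over the whole area. Pooling uses pooled counts
#' (\eqn{\sum count / \sum n}), never the mean of per-population ratios —
#' the two differ whenever sample sizes differ.
#'
#' @param classifications data frame with columns `haplotype_id`,
#'   `best_node` and `population` (a [classify_panel()] result merged with
#'   sample metadata).
#' @param populations data frame `population_id`, `latitude`, `longitude`
#'   and optionally `n` (survey size; defaults to the number of classified
#'   samples per population).
#' @param haplogroup target haplogroup; carriers are samples classified to
#'   it or to any nested subclade (prefix match on the name).
#' @param total add a pooled `"total"` row (no coordinates).
#' @return Data frame `population_id`, `latitude`, `longitude`, `n`,
#'   `count`, `frequency`.
#' @export
tabulate_frequencies <- function(classifications, populations, haplogroup,
                                 total = TRUE) {
  need <- c("haplotype_id", "best_node", "population")
  stopifnot(all(need %in% names(classifications)))
  unknown <- setdiff(classifications$population, populations$population_id)
  if (length(unknown)) {
    stop("sample(s) from population(s) without metadata: ",
         paste(unknown, collapse = ", "))
  }
  carrier <- startsWith(classifications$best_node, haplogroup)
  out <- populations[, c("population_id", "latitude", "longitude")]
  n_class <- vapply(out$population_id, function(p) {
    sum(classifications$population == p)
  }, 0L)
  out$n <- if ("n" %in% names(populations)) populations$n else n_class
  out$count <- vapply(out$population_id, function(p) {
    sum(carrier & classifications$population == p)
  }, 0L)
  if (any(out$count > out$n)) stop("carrier count exceeds population n")
  out$frequency <- ifelse(out$n > 0, out$count / out$n, 0)
  if (total) {
    out <- rbind(out, data.frame(population_id = "total", latitude = NA,
                                 longitude = NA, n = sum(out$n),
                                 count = sum(out$count),
                                 frequency = sum(out$count) / sum(out$n)))
  }
  rownames(out) <- NULL
  out
}

#' Interpolate a haplogroup frequency surface
#'
#' Ordinary kriging (default) with a linear variogram \eqn{\gamma(h) = h}
#' and zero nugget — an exact interpolator whose predictions are
#' scale-invariant in the variogram slope — or inverse-distance weighting.
#' Coordinates are treated as planar degrees, adequate over a region a few
#' degrees across. Interpolated values are clipped to \[0, 1\].
#'
#' @param freqs data frame with `longitude`, `latitude`, `frequency`
#'   (a [tabulate_frequencies()] result; rows without coordinates, such as
#'   the pooled total, are dropped).
#' @param grid_spec list with `nx`, `ny` and optionally `bbox`
#'   (`c(lon_min, lon_max, lat_min, lat_max)`; defaults to the data extent).
#' @param method `"kriging"` or `"idw"`.
#' @param idw_power inverse-distance power for `"idw"`.
#' @return A `frequency_surface`: `lon`, `lat` grid vectors, `values`
#'   matrix (rows = lon, cols = lat), `method`, `bbox`.
#' @export
interpolate_surface <- function(freqs, grid_spec = list(nx = 60, ny = 60),
                                method = c("kriging", "idw"),
                                idw_power = 2) {
  method <- match.arg(method)
  freqs <- freqs[!is.na(freqs$latitude) & !is.na(freqs$longitude), ]
  xy <- cbind(freqs$longitude, freqs$latitude)
  z <- freqs$frequency
  dup <- duplicated(xy)
  if (any(dup)) {
    for (k in which(dup)) {
      same <- which(xy[, 1] == xy[k, 1] & xy[, 2] == xy[k, 2])
      if (length(unique(z[same])) > 1L) {
        stop("duplicate coordinates with conflicting frequencies")
      }
    }
    xy <- xy[!dup, , drop = FALSE]; z <- z[!dup]
  }
  if (method == "kriging" && nrow(xy) >= 3L) {
    spread <- svd(scale(xy, scale = FALSE))$d
    if (spread[2] < 1e-9) stop("degenerate geometry: points are collinear")
  }
  if (method == "kriging" && nrow(xy) < 3L) {
    stop("kriging needs at least 3 non-collinear points; use method = \"idw\"")
  }
  bbox <- grid_spec$bbox %||% c(range(xy[, 1]), range(xy[, 2]))
  lon <- seq(bbox[1], bbox[2], length.out = grid_spec$nx)
  lat <- seq(bbox[3], bbox[4], length.out = grid_spec$ny)
  g <- as.matrix(expand.grid(lon = lon, lat = lat))
  pred <- interpolate_points(xy, z, g, method, idw_power)
  values <- matrix(pmin(1, pmax(0, pred)), nrow = length(lon))
  structure(list(lon = lon, lat = lat, values = values, method = method,
                 bbox = bbox, data = data.frame(longitude = xy[, 1],
                                                latitude = xy[, 2],
                                                frequency = z)),
            class = "frequency_surface")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict the interpolated frequency at arbitrary points
#'
#' @param xy data coordinate matrix (lon, lat) or a `frequency_surface`.
#' @param z data values (omit when `xy` is a surface).
#' @param at two-column matrix of prediction points.
#' @param method,idw_power as in [interpolate_surface()].
#' @return Numeric vector of predictions (unclipped).
#' @export
interpolate_points <- function(xy, z = NULL, at, method = "kriging",
                               idw_power = 2) {
  if (inherits(xy, "frequency_surface")) {
    s <- xy
    return(interpolate_points(as.matrix(s$data[, c("longitude", "latitude")]),
                              s$data$frequency, at, s$method, idw_power))
  }
  at <- matrix(at, ncol = 2L)
  n <- nrow(xy)
  D <- as.matrix(stats::dist(xy))
  d0 <- outer(seq_len(n), seq_len(nrow(at)), function(i, j) {
    sqrt((xy[i, 1] - at[j, 1])^2 + (xy[i, 2] - at[j, 2])^2)
  })
  if (method == "kriging") {
    # ordinary kriging system with linear variogram gamma(h) = h
    A <- rbind(cbind(D, 1), c(rep(1, n), 0))
    B <- rbind(d0, 1)
    W <- solve(A, B)
    as.vector(crossprod(W[seq_len(n), , drop = FALSE], z))
  } else {
    apply(d0, 2L, function(d) {
      hit <- d < 1e-12
      if (any(hit)) return(z[which(hit)[1]])
      w <- 1 / d^idw_power
      sum(w * z) / sum(w)
    })
  }
}

#' @export
print.frequency_surface <- function(x, ...) {
  cat("<frequency_surface> ", length(x$lon), " x ", length(x$lat),
      " grid (", x$method, "), value range ",
      sprintf("%.3f-%.3f", min(x$values), max(x$values)), "\n", sep = "")
  invisible(x)
}

#' Plot a frequency surface as a grayscale map
#'
#' Dark = high frequency; sampled populations overplotted as circles.
#'
#' @param x a `frequency_surface`.
#' @param ... passed to [graphics::image()].
#' @export
plot.frequency_surface <- function(x, ...) {
  graphics::image(x$lon, x$lat, x$values, col = gray(seq(1, 0, length.out = 64)),
                  xlab = "longitude", ylab = "latitude", useRaster = TRUE, ...)
  graphics::points(x$data$longitude, x$data$latitude, pch = 21,
                   bg = "white")
  invisible(x)
}

#' Grid cell of the surface maximum
#'
#' @param surface a `frequency_surface`.
#' @return Named vector `c(longitude, latitude)` of the argmax cell centre.
#' @export
surface_peak <- function(surface) {
  ij <- arrayInd(which.max(surface$values), dim(surface$values))
  c(longitude = surface$lon[ij[1]], latitude = surface$lat[ij[2]])
}

#' Write a surface as an ESRI ASCII grid
#'
#' @param surface a `frequency_surface`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(surface, path) {
  nx <- length(surface$lon); ny <- length(surface$lat)
  cell <- if (nx > 1) diff(surface$lon[1:2]) else 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", nx), paste("nrows", ny),
               paste("xllcorner", surface$lon[1] - cell / 2),
               paste("yllcorner", surface$lat[1] - cell / 2),
               paste("cellsize", cell), "NODATA_value -9999"), con)
  for (j in rev(seq_len(ny))) {     # top row first
    writeLines(paste(signif(surface$values[, j], 6), collapse = " "), con)
  }
  invisible(path)
}
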