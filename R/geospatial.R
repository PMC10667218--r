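#' Surface grid container
#'
#' A regular lon/lat raster of interpolated values: a numeric matrix with
#' row 1 at the northern edge, cell-center coordinates, and metadata
#' naming the variable, season and source (observed values or a model's
#' predictions). `nodata` cells hold `NA` in memory and the nodata marker
#' (-9999) on export.
#'
#' @param values Numeric matrix (rows = latitudes, north first).
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#' @param cell Cell size in degrees.
#' @param variable,season,source Metadata labels.
#' @return An object of class `surface_grid`.
#' @export
surface_grid <- function(values, bbox, cell, variable = "value",
                         season = NA_character_, source = "observed") {
  nx <- ncol(values); ny <- nrow(values)
  if (abs(bbox[1] + nx * cell - bbox[2]) > cell * 1e-6 + 1e-12 ||
      abs(bbox[3] + ny * cell - bbox[4]) > cell * 1e-6 + 1e-12) {
    abort("value array dimensions do not match the bounding box and cell size.")
  }
  structure(
    list(values = values,
         lon = bbox[1] + (seq_len(nx) - 0.5) * cell,
         lat = bbox[4] - (seq_len(ny) - 0.5) * cell,
         bbox = bbox, cell = cell, nodata = -9999,
         variable = variable, season = season, source = source),
    class = "surface_grid"
  )
}

#' @export
print.surface_grid <- function(x, ...) {
  cat("<surface_grid>", x$variable,
      if (!is.na(x$season)) paste0("(", x$season, ")"), "from", x$source,
      ":", nrow(x$values), "x", ncol(x$values), "cells of", x$cell, "deg\n")
  invisible(x)
}

# planar local projection (equirectangular): adequate over a
# sub-degree coastal study extent
project_local <- function(lon, lat, lat0) {
  k <- pi / 180 * 6371
  list(x = k * lon * cos(lat0 * pi / 180), y = k * lat)
}

#' Inverse-distance-weighted interpolation of station values
#'
#' Builds a continuous surface over a regular grid: each cell value is
#' the distance-weighted mean of station values, `sum(w_i v_i) /
#' sum(w_i)` with `w_i = d_i^-power`. Distances are computed after an
#' equirectangular local projection (planar geometry is adequate over a
#' small study extent). A cell closer than 1e-9 degrees to a station
#' takes that station's value exactly; the surface is therefore exact at
#' stations and bounded by the station value range for any positive
#' power.
#'
#' @param stations Data frame with `lon`, `lat` and the value column.
#' @param value Name of the value column (default `"value"`).
#' @param bbox Grid bounding box; defaults to the station extent padded
#'   by 5 cells.
#' @param cell Cell size in degrees.
#' @param power IDW power (> 0), default 2.
#' @param max_neighbors Use only the nearest `max_neighbors` stations per
#'   cell (default all).
#' @param variable,season,source Metadata labels for the result.
#' @return A [surface_grid()].
#' @export
idw_interpolate <- function(stations, value = "value", bbox = NULL,
                            cell = 0.01, power = 2, max_neighbors = Inf,
                            variable = value, season = NA_character_,
                            source = "observed") {
  if (!nrow(stations)) abort("at least one station is required.")
  if (power <= 0) abort("`power` must be > 0.")
  v <- stations[[value]]
  key <- paste(stations$lon, stations$lat)
  if (anyDuplicated(key)) {
    agg <- tapply(v, key, function(z) diff(range(z)))
    if (any(agg > 0)) {
      abort("duplicate station coordinates with conflicting values.")
    }
    keep <- !duplicated(key)
    stations <- stations[keep, , drop = FALSE]
    v <- v[keep]
  }
  if (is.null(bbox)) {
    pad <- 5 * cell
    bbox <- c(min(stations$lon) - pad, max(stations$lon) + pad,
              min(stations$lat) - pad, max(stations$lat) + pad)
  }
  nx <- max(1L, ceiling((bbox[2] - bbox[1]) / cell - 1e-9))
  ny <- max(1L, ceiling((bbox[4] - bbox[3]) / cell - 1e-9))
  bbox[2] <- bbox[1] + nx * cell
  bbox[4] <- bbox[3] + ny * cell
  lon_c <- bbox[1] + (seq_len(nx) - 0.5) * cell
  lat_c <- bbox[4] - (seq_len(ny) - 0.5) * cell
  lat0 <- mean(bbox[3:4])
  st <- project_local(stations$lon, stations$lat, lat0)
  gx <- project_local(rep(lon_c, each = ny), rep(lat_c, times = nx), lat0)
  # n_cells x n_stations squared distance matrix (small grids only)
  d2 <- outer(gx$x, st$x, "-")^2 + outer(gx$y, st$y, "-")^2
  eps_deg <- 1e-9
  eps2 <- (pi / 180 * 6371 * eps_deg)^2
  vals <- apply(d2, 1, function(d) {
    hit <- d <= eps2
    if (any(hit)) return(v[which(hit)[1]])
    if (is.finite(max_neighbors) && max_neighbors < length(d)) {
      use <- order(d)[seq_len(max_neighbors)]
      d <- d[use]
      vv <- v[use]
    } else {
      vv <- v
    }
    w <- d^(-power / 2)
    sum(w * vv) / sum(w)
  })
  surface_grid(matrix(vals, nrow = ny, ncol = nx), bbox, cell,
               variable = variable, season = season, source = source)
}

#' Cellwise difference of two surfaces
#'
#' `predicted - observed` on identical grids, for observed-versus-model
#' comparison maps. The mean absolute cell difference is attached as
#' attribute `mean_abs_diff`.
#'
#' @param observed,predicted Two [surface_grid()]s on the same grid.
#' @return A `surface_grid` of differences.
#' @export
surface_difference <- function(observed, predicted) {
  same <- isTRUE(all.equal(observed$bbox, predicted$bbox)) &&
    isTRUE(all.equal(observed$cell, predicted$cell)) &&
    all(dim(observed$values) == dim(predicted$values))
  if (!same) abort("surfaces are on different grids.")
  out <- surface_grid(predicted$values - observed$values, observed$bbox,
                      observed$cell,
                      variable = paste0(observed$variable, "_difference"),
                      season = observed$season,
                      source = paste(predicted$source, "-", observed$source))
  attr(out, "mean_abs_diff") <- mean(abs(out$values), na.rm = TRUE)
  out
}

#' Classify a surface into ordered bands
#'
#' Maps each cell to the band containing it. Bands must be ordered,
#' non-overlapping and exhaustive over the surface's value range; a cell
#' value sitting exactly on an edge goes to the lower band, matching
#' [classify_hpi()]. Cell counts per band are attached as attribute
#' `band_counts`.
#'
#' @param surface A [surface_grid()].
#' @param bands Tibble with `lower`, `upper`, `label` (default
#'   [hpi_bands()]).
#' @return A `surface_grid` whose values are an integer band index with a
#'   `band_labels` element.
#' @export
band_surface <- function(surface, bands = hpi_bands()) {
  if (any(diff(bands$lower) <= 0)) abort("bands must be ordered.")
  if (any(bands$upper[-nrow(bands)] > bands$lower[-1] + 1e-12)) {
    abort("bands overlap.")
  }
  if (any(bands$upper[-nrow(bands)] < bands$lower[-1] - 1e-12)) {
    abort("bands leave gaps.")
  }
  v <- surface$values
  lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
  if (lo < bands$lower[1] || (is.finite(bands$upper[nrow(bands)]) &&
                              hi > bands$upper[nrow(bands)])) {
    abort("bands do not cover the surface's value range.")
  }
  # same edge convention as classify_hpi: an edge value falls in the
  # lower band (0 itself belongs to the first band)
  idx <- matrix(pmax(findInterval(v, bands$lower, left.open = TRUE), 1L),
                nrow(v), ncol(v))
  out <- surface_grid(idx, surface$bbox, surface$cell,
                      variable = paste0(surface$variable, "_band"),
                      season = surface$season, source = surface$source)
  out$band_labels <- bands$label
  counts <- tabulate(idx, nbins = nrow(bands))
  attr(out, "band_counts") <- setNames(counts, bands$label)
  out
}

#' Surface grid as a tidy tibble
#'
#' @param x A [surface_grid()].
#' @param ... Unused.
#' @return Tibble with `lon`, `lat`, `value` (and `band` for banded
#'   surfaces).
#' @export
tidy.surface_grid <- function(x, ...) {
  out <- tibble(
    lon = rep(x$lon, each = nrow(x$values)),
    lat = rep(x$lat, times = ncol(x$values)),
    value = as.numeric(x$values)
  )
  if (!is.null(x$band_labels)) {
    out$band <- factor(x$band_labels[out$value], levels = x$band_labels)
  }
  out
}

#' @export
autoplot.surface_grid <- function(object, ...) {
  d <- tidy(object)
  fill <- if (!is.null(object$band_labels)) "band" else "value"
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       fill = .data[[fill]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(object$variable,
                                if (!is.na(object$season)) object$season,
                                "-", object$source),
                  x = "longitude", y = "latitude")
  if (fill == "value") p <- p + ggplot2::scale_fill_viridis_c()
  p
}

#' Export a surface as an ESRI ASCII grid
#'
#' Plain-text raster interchange format readable by standard GIS tools;
#' `NA` cells are written as the nodata marker.
#'
#' @param surface A [surface_grid()].
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(surface, path) {
  v <- surface$values
  v[is.na(v)] <- surface$nodata
  hdr <- c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", surface$bbox[1]), paste("yllcorner", surface$bbox[3]),
    paste("cellsize", surface$cell), paste("NODATA_value", surface$nodata)
  )
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#' @param path `.asc` path.
#' @param variable,season,source Metadata labels.
#' @return A [surface_grid()].
#' @export
read_ascii_grid <- function(path, variable = "value",
                            season = NA_character_, source = "observed") {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], " +")
  val <- setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                  tolower(vapply(hdr, `[`, "", 1)))
  v <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), " +")[[1]])
  }))
  v[v == val[["nodata_value"]]] <- NA
  bbox <- c(val[["xllcorner"]],
            val[["xllcorner"]] + val[["ncols"]] * val[["cellsize"]],
            val[["yllcorner"]],
            val[["yllcorner"]] + val[["nrows"]] * val[["cellsize"]])
  surface_grid(v, bbox, val[["cellsize"]], variable = variable,
               season = season, source = source)
}

#' Export a banded surface as GeoJSON
#'
#' Writes one square Polygon feature per cell, carrying the band label,
#' as a WGS84 GeoJSON FeatureCollection.
#'
#' @param banded A banded [surface_grid()] from [band_surface()].
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_surface_geojson <- function(banded, path) {
  if (is.null(banded$band_labels)) abort("`banded` must come from band_surface().")
  d <- tidy(banded)
  half <- banded$cell / 2
  features <- purrr::pmap(d, function(lon, lat, value, band) {
    ring <- list(c(lon - half, lat - half), c(lon + half, lat - half),
                 c(lon + half, lat + half), c(lon - half, lat + half),
                 c(lon - half, lat - half))
    list(type = "Feature",
         properties = list(band = as.character(band),
                           band_index = value),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' PNG quick-look of a surface
#' @param surface A [surface_grid()].
#' @param path Output `.png` path.
#' @param width,height Inches.
#' @return `path`, invisibly.
#' @export
write_surface_png <- function(surface, path, width = 6, height = 5) {
  ggplot2::ggsave(path, autoplot(surface), width = width, height = height,
                  dpi = 120)
  invisible(path)
}
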