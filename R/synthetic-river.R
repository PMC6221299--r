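#' Configuration for the synthetic river model
#'
#' A sinuous north--south river characterized the way the roosting analysis
#' needs it: centerline stations every ~30 m carrying a smoothly varying
#' active-channel width, per-period 30 m rasters of the water / sandbar /
#' vegetation mixture inside the channel, a 10 m bank-vegetation-height
#' raster restricted to within 50 m of the channel, and bridge crossings at
#' regular intervals.
#'
#' @param station_spacing_m centerline station spacing (m)
#' @param width_range_m min and max active-channel width (m); widths vary
#'   smoothly within this range (the study river spans roughly 40--220 m)
#' @param n_periods number of bi-monthly composites (3 covers Oct--Nov,
#'   Dec--Jan, Feb--Mar)
#' @param bridge_spacing_m distance between bridges along the river (m)
#' @param bank_cellsize_m bank-vegetation-height grid resolution (m)
#' @param sinuosity_amp_m,sinuosity_wavelength_m amplitude and wavelength of
#'   the centerline meander (m)
#' @param seed integer seed
#' @return a `river_config` list
#' @export
river_config <- function(station_spacing_m = 30,
                         width_range_m = c(40, 220),
                         n_periods = 3L,
                         bridge_spacing_m = 6000,
                         bank_cellsize_m = 10,
                         sinuosity_amp_m = 700,
                         sinuosity_wavelength_m = 9000,
                         seed = 1L) {
  if (any(width_range_m <= 0) || diff(width_range_m) < 0) {
    stop("`width_range_m` must be positive and non-decreasing")
  }
  if (n_periods < 1L) stop("`n_periods` must be at least 1")
  structure(
    list(
      station_spacing_m = station_spacing_m, width_range_m = width_range_m,
      n_periods = as.integer(n_periods), bridge_spacing_m = bridge_spacing_m,
      bank_cellsize_m = bank_cellsize_m, sinuosity_amp_m = sinuosity_amp_m,
      sinuosity_wavelength_m = sinuosity_wavelength_m, seed = as.integer(seed)
    ),
    class = "river_config"
  )
}

## smooth AR(1)-filtered noise, sd ~ `sd`
smooth_noise <- function(n, sd, rho = 0.995) {
  as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - rho^2)),
                           rho, method = "recursive"))
}

period_names <- function(n) {
  if (n == 3L) c("oct_nov", "dec_jan", "feb_mar") else paste0("period_", seq_len(n))
}

#' Generate a synthetic river model
#'
#' @param config a [river_config()]
#' @param extent_m landscape extent the river flows through (south to north)
#' @param cellsize 30 m grid the proportion rasters live on (shared with the
#'   landscape grid)
#' @return a `crane_river` with elements `stations` (data.frame x, y, arc,
#'   width), `channel` (logical `grid_raster`), `proportions` (per period, a
#'   list of water/sandbar/vegetation `grid_raster`s), `bank` (data.frame of
#'   10 m bank cells: x, y, height, arc), `bridges` (matrix x, y), `polygon`
#'   (closed bank outline), `periods`, `config`
#' @export
generate_river <- function(config = river_config(),
                           extent_m = c(12000, 16000), cellsize = 30) {
  stopifnot(inherits(config, "river_config"))
  with_seed(config$seed + 101L, {
    sp <- config$station_spacing_m
    ys <- seq(sp / 2, extent_m[2] - sp / 2, by = sp)
    n <- length(ys)
    cx <- extent_m[1] / 2 +
      config$sinuosity_amp_m * sin(2 * pi * ys / config$sinuosity_wavelength_m) +
      0.35 * config$sinuosity_amp_m *
        sin(2 * pi * ys / (config$sinuosity_wavelength_m / 2.7) + 1.3) +
      smooth_noise(n, 120)
    arc <- c(0, cumsum(sqrt(diff(cx)^2 + diff(ys)^2)))

    wr <- config$width_range_m
    mid <- mean(wr); amp <- diff(wr) / 2
    width <- mid + 0.75 * amp * sin(2 * pi * arc / 7000 + 0.4) +
      smooth_noise(n, 0.35 * amp)
    width <- pmin(pmax(width, wr[1]), wr[2])

    stations <- data.frame(x = cx, y = ys, arc = arc, width = width)

    ## channel raster: cell centers within half the width of the station row
    nc <- as.integer(ceiling(extent_m[1] / cellsize))
    nr <- as.integer(ceiling(extent_m[2] / cellsize))
    ccy <- (seq_len(nr) - 0.5) * cellsize
    ccx <- (seq_len(nc) - 0.5) * cellsize
    sidx_row <- pmin(pmax(round((ccy - ys[1]) / sp) + 1L, 1L), n)
    chan <- abs(outer(cx[sidx_row], ccx, function(a, b) b - a)) <=
      width[sidx_row] / 2
    channel <- grid_raster(chan, 0, 0, cellsize)

    ## per-period mixture fields on channel cells: water in the thalweg,
    ## sandbars at mid-lateral position, vegetation toward the banks
    idx <- which(chan, arr.ind = TRUE)
    px <- ccx[idx[, 2L]]; py <- ccy[idx[, 1L]]
    si <- sidx_row[idx[, 1L]]
    t_lat <- pmin(abs(px - cx[si]) / (width[si] / 2), 1)
    base_water <- 1.4 - 1.5 * t_lat + 0.25 * sin(arc[si] / 1400)
    base_sand <- 0.35 + 1.3 * t_lat * (1 - t_lat) + 0.15 * sin(arc[si] / 900 + 2)
    base_veg <- 0.08 + 0.9 * t_lat^3
    periods <- period_names(config$n_periods)
    proportions <- vector("list", config$n_periods)
    names(proportions) <- periods
    for (p in seq_len(config$n_periods)) {
      pw <- pmax(base_water + smooth_noise(n, 0.25)[si], 0.02)
      ps <- pmax(base_sand + smooth_noise(n, 0.20)[si], 0.02)
      pv <- pmax(base_veg + smooth_noise(n, 0.12)[si], 0.02)
      tot <- pw + ps + pv
      mk <- function(vals) {
        m <- matrix(NA_real_, nr, nc)
        m[idx] <- vals
        grid_raster(m, 0, 0, cellsize)
      }
      proportions[[p]] <- list(
        water = mk(pw / tot), sandbar = mk(ps / tot), vegetation = mk(pv / tot)
      )
    }

    ## 10 m bank cells within 50 m laterally of the channel edge; height
    ## decreases with channel width (incised narrow reaches carry tall
    ## woody vegetation)
    bs <- config$bank_cellsize_m
    corridor <- c(max(0, min(cx - width / 2) - 60),
                  min(extent_m[1], max(cx + width / 2) + 60))
    bx <- seq(corridor[1] + bs / 2, corridor[2], by = bs)
    by <- seq(bs / 2, extent_m[2], by = bs)
    bsi <- pmin(pmax(round((by - ys[1]) / sp) + 1L, 1L), n)
    lat <- abs(outer(by, bx, function(yy, xx) xx)[, , drop = FALSE] -
                 matrix(cx[bsi], length(by), length(bx))) -
      matrix(width[bsi] / 2, length(by), length(bx))
    keep <- which(lat > 0 & lat <= 50, arr.ind = TRUE)
    ksi <- bsi[keep[, 1L]]
    h_base <- pmax(0, 7.5 - 0.03 * width[ksi] + smooth_noise(n, 1.1)[ksi] +
                     stats::rnorm(nrow(keep), 0, 0.3))
    bank <- data.frame(
      x = bx[keep[, 2L]], y = by[keep[, 1L]],
      height = h_base, arc = arc[ksi]
    )

    nb <- max(1L, floor(max(arc) / config$bridge_spacing_m))
    barc <- config$bridge_spacing_m * (seq_len(nb) - 0.5)
    bi <- vapply(barc, function(a) which.min(abs(arc - a)), 1L)
    bridges <- cbind(x = cx[bi], y = ys[bi])

    polygon <- rbind(
      cbind(x = cx - width / 2, y = ys),
      cbind(x = rev(cx + width / 2), y = rev(ys)),
      cbind(x = cx[1] - width[1] / 2, y = ys[1])
    )

    structure(
      list(
        stations = stations, channel = channel, proportions = proportions,
        bank = bank, bridges = bridges, polygon = polygon,
        periods = periods, config = config
      ),
      class = "crane_river"
    )
  })
}

#' @export
print.crane_river <- function(x, ...) {
  cat(sprintf(
    "<crane_river> %d stations, width %.0f-%.0f m, %d periods, %d bridges, %d bank cells\n",
    nrow(x$stations), min(x$stations$width), max(x$stations$width),
    length(x$periods), nrow(x$bridges), nrow(x$bank)
  ))
  invisible(x)
}

#' Nearest centerline station index for points
#' @param river a `crane_river`
#' @param x,y point coordinates (m)
#' @return integer station indices
#' @export
nearest_station <- function(river, x, y) {
  st <- river$stations
  sp <- river$config$station_spacing_m
  i0 <- pmin(pmax(round((y - st$y[1]) / sp) + 1L, 1L), nrow(st))
  ## refine over a small neighborhood: the centerline is monotone in y, so
  ## the 2D-nearest station is within a few rows of the y-nearest one
  vapply(seq_along(x), function(k) {
    win <- max(1L, i0[k] - 5L):min(nrow(st), i0[k] + 5L)
    win[which.min((st$x[win] - x[k])^2 + (st$y[win] - y[k])^2)]
  }, 1L)
}

#' Test whether points lie inside the active channel
#' @param river a `crane_river`
#' @param x,y point coordinates (m)
#' @return logical vector
#' @export
in_channel <- function(river, x, y) {
  st <- river$stations
  i <- nearest_station(river, x, y)
  ok <- abs(x - st$x[i]) <= st$width[i] / 2 &
    y >= st$y[1] - river$config$station_spacing_m / 2 &
    y <= st$y[nrow(st)] + river$config$station_spacing_m / 2
  ok & is.finite(x) & is.finite(y)
}
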