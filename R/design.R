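#' Sample available (control) locations around a used location
#'
#' Draws points uniformly on the intersection of the availability disc with a
#' mask raster, by rejection from the uniform law on the disc. This is the
#' control-sampling step of the matched 1:50 used--available design: for the
#' diurnal period the mask is the eligible (field / pasture / wetland) layer,
#' for the roosting period the active river channel.
#'
#' @param center length-2 numeric, the used location (x, y) in meters
#' @param radius availability radius (m)
#' @param mask logical `grid_raster`; `TRUE` cells are available
#' @param n number of points
#' @return data.frame of `n` points (x, y), all inside the disc and mask
#' @export
sample_available <- function(center, radius, mask, n) {
  stopifnot(length(center) == 2L, radius > 0, n >= 1L)
  got_x <- numeric(0); got_y <- numeric(0)
  tries <- 0L
  while (length(got_x) < n) {
    m <- max(2L * (n - length(got_x)), 64L)
    u <- stats::runif(m); a <- stats::runif(m, 0, 2 * pi)
    d <- radius * sqrt(u)
    x <- center[1] + d * cos(a); y <- center[2] + d * sin(a)
    ok <- raster_value(mask, x, y)
    ok <- !is.na(ok) & ok
    got_x <- c(got_x, x[ok]); got_y <- c(got_y, y[ok])
    tries <- tries + 1L
    if (tries >= 60L && length(got_x) == 0L) {
      ## confirm emptiness before giving up: scan cells in the disc
      if (!disc_has_mask(center, radius, mask)) {
        stop(sprintf(
          "no available cells within %.0f m of used location (%.0f, %.0f)",
          radius, center[1], center[2]
        ))
      }
    }
    if (tries > 20000L) {
      stop("available-location sampling did not terminate")
    }
  }
  data.frame(x = got_x[seq_len(n)], y = got_y[seq_len(n)])
}

disc_has_mask <- function(center, radius, mask) {
  cs <- mask$cellsize
  xs <- seq(center[1] - radius, center[1] + radius, by = cs)
  ys <- seq(center[2] - radius, center[2] + radius, by = cs)
  g <- expand.grid(x = xs, y = ys)
  g <- g[(g$x - center[1])^2 + (g$y - center[2])^2 <= radius^2, ]
  v <- raster_value(mask, g$x, g$y)
  any(!is.na(v) & v)
}

## distance to nearest point set and counts within radii, chunked so the
## pairwise matrix never gets large
point_set_stats <- function(px, py, qx, qy, radii) {
  n <- length(px)
  dist <- rep(Inf, n)
  counts <- matrix(0L, n, length(radii))
  if (length(qx) > 0L) {
    chunk <- max(1L, floor(2e6 / max(length(qx), 1L)))
    for (s in seq(1L, n, by = chunk)) {
      i <- s:min(n, s + chunk - 1L)
      d2 <- outer(px[i], qx, "-")^2 + outer(py[i], qy, "-")^2
      dist[i] <- sqrt(apply(d2, 1L, min))
      for (k in seq_along(radii)) {
        counts[i, k] <- rowSums(d2 <= radii[k]^2)   # boundary-inclusive
      }
    }
  }
  list(dist = dist, counts = counts)
}

#' Annotate points with diurnal-period covariates
#'
#' Attaches land-use class (reference level alfalfa/hay), ownership
#' (reference private), distance to the nearest human structure (km), and
#' structure counts within 100, 500 and 1000 m (boundary-inclusive). With no
#' structures on the map, counts are 0 and the distance falls back to the
#' landscape diagonal as a finite sentinel (recorded in the result's
#' attributes).
#'
#' @param points data.frame with columns x, y (m), inside the landscape
#' @param landscape a `crane_landscape`
#' @return data.frame of covariates, one row per point
#' @export
annotate_diurnal <- function(points, landscape) {
  lu <- raster_value(landscape$landuse, points$x, points$y)
  if (anyNA(lu)) stop("point outside landscape extent cannot be annotated")
  own <- raster_value(landscape$ownership, points$x, points$y)
  st <- landscape$structures
  radii <- study_constants()$density_radii_m
  ps <- point_set_stats(points$x, points$y, st[, "x"], st[, "y"], radii)
  sentinel <- !is.finite(ps$dist)
  if (any(sentinel)) {
    diag_m <- sqrt(sum(landscape$config$extent_m^2))
    ps$dist[sentinel] <- diag_m
  }
  out <- data.frame(
    landuse = factor(landscape$classes[lu], levels = landscape$classes),
    ownership = factor(ifelse(own == 1L, "public", "private"),
                       levels = c("private", "public")),
    dist_structure_km = ps$dist / 1000,
    dens100 = ps$counts[, 1L],
    dens500 = ps$counts[, 2L],
    dens1000 = ps$counts[, 3L]
  )
  attr(out, "distance_sentinel_used") <- any(sentinel)
  out
}

#' Annotate points with roosting-period covariates
#'
#' Attaches the active-channel width at the nearest centerline station (no
#' interpolation; expressed in units of 100 m so coefficients are
#' commensurate with the proportion covariates), the period-matched water /
#' sandbar / vegetation proportions of the 30 m pixel, mean bank-vegetation
#' height (m) over 10 m bank cells within along-channel stretches of 100,
#' 500 and 1000 m centered at the point's centerline projection, distance to
#' the nearest bridge (km), and -- when structures are supplied -- distance
#' to the nearest structure (km) and the structure count within 1000 m.
#'
#' @param points data.frame with columns x, y (m), inside the active channel
#' @param river a `crane_river`
#' @param period period name (e.g. `"dec_jan"`) or index
#' @param structures optional matrix of structure points (x, y)
#' @return data.frame of covariates, one row per point
#' @export
annotate_roost <- function(points, river, period, structures = NULL) {
  if (is.numeric(period)) period <- river$periods[period]
  if (!period %in% river$periods) {
    stop(sprintf("period '%s' does not match the river's raster sets (%s)",
                 period, paste(river$periods, collapse = ", ")))
  }
  st <- river$stations
  i <- nearest_station(river, points$x, points$y)
  pr <- river$proportions[[period]]
  water <- raster_value(pr$water, points$x, points$y)
  sandbar <- raster_value(pr$sandbar, points$x, points$y)
  vegetation <- raster_value(pr$vegetation, points$x, points$y)
  ## points that fall in a non-channel corner of an edge pixel borrow the
  ## nearest station's mid-channel pixel
  miss <- which(is.na(water))
  if (length(miss)) {
    water[miss] <- raster_value(pr$water, st$x[i[miss]], st$y[i[miss]])
    sandbar[miss] <- raster_value(pr$sandbar, st$x[i[miss]], st$y[i[miss]])
    vegetation[miss] <- raster_value(pr$vegetation, st$x[i[miss]], st$y[i[miss]])
  }
  if (anyNA(water)) stop("point could not be matched to a channel pixel")

  stretch <- study_constants()$stretch_radii_m
  arc0 <- st$arc[i]
  bank_arc <- river$bank$arc
  bank_h <- river$bank$height
  ord <- order(bank_arc)
  ba <- bank_arc[ord]; bh <- bank_h[ord]
  csum <- c(0, cumsum(bh))
  bank_mean <- function(half) {
    lo <- findInterval(arc0 - half, ba) + 1L
    hi <- findInterval(arc0 + half, ba)
    m <- rep(NA_real_, length(arc0))
    ok <- hi >= lo
    m[ok] <- (csum[hi[ok] + 1L] - csum[lo[ok]]) / (hi[ok] - lo[ok] + 1L)
    m[!ok] <- 0     # no bank cells in the window
    m
  }

  br <- river$bridges
  dbridge <- sqrt(
    apply(outer(points$x, br[, "x"], "-")^2 +
            outer(points$y, br[, "y"], "-")^2, 1L, min)
  )

  out <- data.frame(
    width = st$width[i] / 100,
    water = water, sandbar = sandbar, vegetation = vegetation,
    bank_veg_100 = bank_mean(stretch[1] / 2),
    bank_veg_500 = bank_mean(stretch[2] / 2),
    bank_veg_1000 = bank_mean(stretch[3] / 2),
    dist_bridge_km = dbridge / 1000
  )
  if (!is.null(structures) && nrow(structures) > 0L) {
    ps <- point_set_stats(points$x, points$y,
                          structures[, "x"], structures[, "y"], 1000)
    out$dist_structure_km <- ps$dist / 1000
    out$dens1000 <- ps$counts[, 1L]
  }
  out
}

## bi-monthly period from a timestamp: Oct-Nov / Dec-Jan / Feb-Mar
bimonthly_period <- function(timestamp) {
  m <- as.integer(format(timestamp, "%m"))
  p <- rep(NA_character_, length(m))
  p[m %in% c(10L, 11L)] <- "oct_nov"
  p[m %in% c(12L, 1L)] <- "dec_jan"
  p[m %in% c(2L, 3L)] <- "feb_mar"
  p
}

#' Build the matched used--available strata for one period
#'
#' For every used fix, samples `n_available` control locations uniformly on
#' the availability disc intersected with the period mask, annotates used and
#' available rows with the period covariates, and labels rows by stratum and
#' by individual (the GEE cluster). Deterministic under `seed`.
#'
#' @param used data.frame of used fixes with columns `individual_id`, `x`,
#'   `y` and (for the roosting period) `timestamp` to resolve the bi-monthly
#'   raster set; a `period` column or the `period` argument may override
#' @param period `"diurnal"` or `"roost"`
#' @param landscape a `crane_landscape` (mask + diurnal covariates;
#'   structures also feed roost annotation)
#' @param river a `crane_river`, required for the roosting period
#' @param constants a [study_constants()] list
#' @param seed integer seed for control sampling
#' @param standardize if `TRUE`, z-score the continuous covariates over all
#'   rows and store the transform in `attr(, "standardization")` (applied
#'   again at prediction time); default `FALSE` -- covariates are already on
#'   commensurate units
#' @return a `strata_set`: data.frame with `stratum_id`, `cluster_id`,
#'   `is_used`, `period`, `x`, `y` and covariate columns; attributes
#'   `covariates`, `M`, `radius_m`, `seed`, `standardization`
#' @export
build_strata <- function(used, period = c("diurnal", "roost"),
                         landscape, river = NULL,
                         constants = study_constants(), seed = 1L,
                         standardize = FALSE) {
  period <- match.arg(period)
  if (period == "roost" && is.null(river)) stop("roost strata require `river`")
  M <- constants$n_available
  radius <- constants$radius_m
  mask <- if (period == "diurnal") landscape$eligible else river$channel
  n_used <- nrow(used)
  if (n_used == 0L) stop("no used fixes supplied")

  with_seed(seed, {
    avail <- vector("list", n_used)
    for (s in seq_len(n_used)) {
      avail[[s]] <- sample_available(c(used$x[s], used$y[s]), radius, mask, M)
    }
    pts <- data.frame(
      stratum_id = c(seq_len(n_used), rep(seq_len(n_used), each = M)),
      cluster_id = c(used$individual_id,
                     rep(used$individual_id, each = M)),
      is_used = c(rep(1L, n_used), rep(0L, n_used * M)),
      x = c(used$x, unlist(lapply(avail, `[[`, "x"))),
      y = c(used$y, unlist(lapply(avail, `[[`, "y")))
    )
    pts <- pts[order(pts$stratum_id, -pts$is_used), ]
    rownames(pts) <- NULL

    cov <- if (period == "diurnal") {
      annotate_diurnal(pts[c("x", "y")], landscape)
    } else {
      per <- if (!is.null(used$period)) {
        used$period
      } else if (!is.null(used$timestamp)) {
        bimonthly_period(used$timestamp)
      } else {
        rep(river$periods[1], n_used)
      }
      if (anyNA(per)) stop("could not resolve a bi-monthly period for every used fix")
      per_row <- per[pts$stratum_id]
      parts <- lapply(split(seq_len(nrow(pts)), per_row), function(ii) {
        cbind(row = ii,
              annotate_roost(pts[ii, c("x", "y")], river, per_row[ii[1]],
                             structures = landscape$structures))
      })
      all <- do.call(rbind, parts)
      all <- all[order(all$row), ]
      all$row <- NULL
      rownames(all) <- NULL
      all
    }
    out <- cbind(pts[c("stratum_id", "cluster_id", "is_used")],
                 period = period, pts[c("x", "y")], cov)

    std <- NULL
    if (standardize) {
      cont <- names(cov)[vapply(cov, is.numeric, TRUE)]
      std <- lapply(out[cont], function(v) c(mean = mean(v), sd = stats::sd(v)))
      for (nm in cont) {
        if (std[[nm]]["sd"] > 0) {
          out[[nm]] <- (out[[nm]] - std[[nm]]["mean"]) / std[[nm]]["sd"]
        }
      }
    }

    structure(
      out,
      covariates = names(cov), M = M, radius_m = radius, seed = seed,
      standardization = std,
      class = c("strata_set", "data.frame")
    )
  })
}

#' @export
print.strata_set <- function(x, ...) {
  cat(sprintf(
    "<strata_set> %d strata (1 used + %d available), %d clusters, period %s\n  covariates: %s\n",
    length(unique(x$stratum_id)), attr(x, "M"),
    length(unique(x$cluster_id)), x$period[1],
    paste(attr(x, "covariates"), collapse = ", ")
  ))
  invisible(x)
}

#' Design matrix for a model formula on a strata set
#'
#' One-hot encodes factors against their reference level (alfalfa/hay for
#' land use, private for ownership) and expands `:` / `*` interaction terms.
#' The intercept is dropped: it is not identified by the conditional
#' likelihood.
#'
#' @param strata a `strata_set` (or any data.frame of covariates)
#' @param formula RHS-only model formula, e.g. `~ landuse + ownership + dens500`
#' @return numeric matrix with one row per design row
#' @export
build_model_matrix <- function(strata, formula) {
  vars <- all.vars(formula)
  missing <- setdiff(vars, names(strata))
  if (length(missing)) {
    stop("unknown covariate(s) in model formula: ", paste(missing, collapse = ", "))
  }
  mm <- stats::model.matrix(formula, data = strata)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}
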