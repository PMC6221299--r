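#' True selection model for the synthetic data-generating process
#'
#' Holds the diurnal and roosting selection coefficient vectors, named after
#' the design-matrix columns of their model formulas. Used locations are
#' drawn with probability proportional to `exp(x' beta)` over the available
#' cells, so these coefficients are the estimand of the downstream
#' conditional logistic fit. Reference categories (alfalfa/hay land use,
#' private ownership) carry an implicit zero.
#'
#' The defaults are the fitted winter habitat-selection coefficients for the
#' study population: strong selection for public land and corn, avoidance of
#' wetlands/other cover and of structure-dense areas by day; selection of
#' wide, water- and sandbar-rich channel reaches away from bridges with low
#' bank vegetation at night.
#'
#' @param diurnal named coefficients for the diurnal formula columns
#' @param roost named coefficients for the roost formula columns
#' @param diurnal_formula,roost_formula RHS model formulas
#' @return a `true_model` list
#' @export
true_model <- function(
    diurnal = c(
      landusecorn = 0.773, landusefallow = -0.240, landusesmall_grain = -0.478,
      landusewetland = -2.230, landuseother = -2.342,
      ownershippublic = 3.373, dens500 = -0.377
    ),
    roost = c(
      width = 0.060, sandbar = 0.207, water = 1.404,
      bank_veg_500 = -0.314, dist_bridge_km = 0.454,
      `width:sandbar` = 0.016, `width:water` = 0.248,
      `sandbar:water` = 0.114, `width:bank_veg_500` = -0.117,
      `width:sandbar:water` = 0.133
    ),
    diurnal_formula = ~ landuse + ownership + dens500,
    roost_formula = ~ width * sandbar * water + bank_veg_500 +
      width:bank_veg_500 + dist_bridge_km) {
  stopifnot(all(is.finite(diurnal)), all(is.finite(roost)))
  structure(
    list(
      diurnal = diurnal, roost = roost,
      diurnal_formula = diurnal_formula, roost_formula = roost_formula
    ),
    class = "true_model"
  )
}

## linear predictor of a truth vector on an annotated covariate table;
## beta names must be a subset of the design-matrix columns
truth_lp <- function(beta, formula, data) {
  X <- build_model_matrix(data, formula)
  miss <- setdiff(names(beta), colnames(X))
  if (length(miss)) {
    stop("truth coefficients not in design matrix: ", paste(miss, collapse = ", "))
  }
  drop(X[, names(beta), drop = FALSE] %*% beta)
}

## per-cell diurnal selection weights over the eligible landscape
diurnal_cell_weights <- function(landscape, truth) {
  elig <- which(as.vector(landscape$eligible$values))
  cc <- cell_centers(landscape$eligible)
  pts <- cc[elig, ]
  cov <- annotate_diurnal(pts, landscape)
  lp <- truth_lp(truth$diurnal, truth$diurnal_formula, cov)
  w <- exp(lp - max(lp))
  list(x = pts$x, y = pts$y, w = w, cumw = cumsum(w))
}

## per-cell roost weights inside the channel, one set per period
roost_cell_weights <- function(landscape, river, truth) {
  chan <- which(as.vector(river$channel$values))
  cc <- cell_centers(river$channel)
  pts <- cc[chan, ]
  lapply(river$periods, function(p) {
    cov <- annotate_roost(pts, river, p, structures = landscape$structures)
    lp <- truth_lp(truth$roost, truth$roost_formula, cov)
    list(x = pts$x, y = pts$y, w = exp(lp - max(lp)))
  }) |> stats::setNames(river$periods)
}

## one categorical draw proportional to w restricted to a disc, by rejection
## from the global cumulative weight; falls back to direct restriction
sample_cell_in_disc <- function(cw, cx, cy, radius) {
  tot <- cw$cumw[length(cw$cumw)]
  r2 <- radius^2
  for (k in seq_len(2000L)) {
    i <- findInterval(stats::runif(1) * tot, cw$cumw) + 1L
    if ((cw$x[i] - cx)^2 + (cw$y[i] - cy)^2 <= r2) return(i)
  }
  ok <- which((cw$x - cx)^2 + (cw$y - cy)^2 <= r2)
  if (!length(ok)) return(NA_integer_)
  ok[sample.int(length(ok), 1L, prob = cw$w[ok])]
}

#' Simulate telemetry tracks from the true selection model
#'
#' Each bird records seven GPS fixes daily at 07:00, 08:00, 10:00, 14:00,
#' 16:00, 18:00 and 24:00 (canonicalized to 00:00 of the next day). Diurnal
#' fixes are drawn from eligible cells within the availability radius of the
#' previous location with probability proportional to
#' `exp(x' beta_diurnal)`; evening and midnight fixes (and a share of 07:00
#' fixes representing birds still on the roost) are drawn from channel
#' pixels proportional to `exp(x' beta_roost)`. Occasional flying fixes are
#' injected with altitudes above the flight-filter threshold and a hidden
#' truth flag. Altitude above ground otherwise carries GPS-grade jitter.
#'
#' @param landscape a `crane_landscape`
#' @param river a `crane_river`
#' @param truth a [true_model()]
#' @param n_individuals number of tracked birds
#' @param n_days tracking days per bird; 58 days yields ~406 fixes per bird
#' @param seed integer seed
#' @param radius_m availability radius constraining successive fixes (m)
#' @param p_fly probability a fix is taken while flying
#' @param p_roost_at_7 probability the 07:00 fix is still on the roost
#' @param start_date first tracking day (winter; determines the bi-monthly
#'   raster period of each roost fix)
#' @return data.frame of fixes: `individual_id`, `timestamp` (POSIXct, UTC),
#'   `x`, `y`, `altitude` (m above ground), plus generator truth columns
#'   `truth_flying` and `truth_period`
#' @export
simulate_tracks <- function(landscape, river, truth = true_model(),
                            n_individuals = 38L, n_days = 58L, seed = 1L,
                            radius_m = study_constants()$radius_m,
                            p_fly = 0.02, p_roost_at_7 = 0.5,
                            start_date = "2014-12-01") {
  stopifnot(inherits(truth, "true_model"))
  with_seed(seed, {
    dcw <- diurnal_cell_weights(landscape, truth)
    rcw_all <- roost_cell_weights(landscape, river, truth)
    cs <- landscape$landuse$cellsize
    t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
    hours <- study_constants()$fix_hours
    warned <- FALSE

    rows <- vector("list", n_individuals)
    for (b in seq_len(n_individuals)) {
      id <- sprintf("crane%02d", b)
      i0 <- findInterval(stats::runif(1) * dcw$cumw[length(dcw$cumw)], dcw$cumw) + 1L
      cur <- c(dcw$x[i0], dcw$y[i0])
      n_fix <- n_days * length(hours)
      fx <- numeric(n_fix); fy <- numeric(n_fix); alt <- numeric(n_fix)
      flying <- logical(n_fix); per <- character(n_fix)
      ts <- rep(t0, n_fix)
      k <- 0L
      for (d in seq_len(n_days)) {
        day_date <- t0 + (d - 1) * 86400
        period <- bimonthly_period(day_date)
        if (is.na(period)) period <- river$periods[1]
        rcw <- rcw_all[[period]]
        for (h in hours) {
          k <- k + 1L
          ts[k] <- if (h == 24) day_date + 86400 else day_date + h * 3600
          is_roost <- h >= 18 || (h == 7 && stats::runif(1) < p_roost_at_7)
          if (stats::runif(1) < p_fly) {
            a <- stats::runif(1, 0, 2 * pi)
            dd <- radius_m / 2 * sqrt(stats::runif(1))
            fx[k] <- min(max(cur[1] + dd * cos(a), 1), landscape$config$extent_m[1] - 1)
            fy[k] <- min(max(cur[2] + dd * sin(a), 1), landscape$config$extent_m[2] - 1)
            alt[k] <- stats::runif(1, 60, 300)
            flying[k] <- TRUE
            per[k] <- NA_character_
            next
          }
          if (is_roost) {
            d2 <- (rcw$x - cur[1])^2 + (rcw$y - cur[2])^2
            ok <- which(d2 <= radius_m^2)
            if (!length(ok)) {
              if (!warned) {
                warning("no channel pixel within the availability radius; ",
                        "resampling from the full channel")
                warned <- TRUE
              }
              ok <- seq_along(rcw$x)
            }
            i <- ok[sample.int(length(ok), 1L, prob = rcw$w[ok])]
            px <- rcw$x[i] + stats::runif(1, -cs / 3, cs / 3)
            py <- rcw$y[i] + stats::runif(1, -cs / 3, cs / 3)
            if (!in_channel(river, px, py)) { px <- rcw$x[i]; py <- rcw$y[i] }
            per[k] <- "roost"
          } else {
            i <- sample_cell_in_disc(dcw, cur[1], cur[2], radius_m)
            if (is.na(i)) {
              if (!warned) {
                warning("no eligible cell within the availability radius; ",
                        "resampling from the full mask")
                warned <- TRUE
              }
              i <- findInterval(stats::runif(1) * dcw$cumw[length(dcw$cumw)],
                                dcw$cumw) + 1L
            }
            px <- dcw$x[i] + stats::runif(1, -cs / 2 + 0.1, cs / 2 - 0.1)
            py <- dcw$y[i] + stats::runif(1, -cs / 2 + 0.1, cs / 2 - 0.1)
            per[k] <- "diurnal"
          }
          fx[k] <- px; fy[k] <- py
          alt[k] <- stats::rnorm(1, 0, 8)
          cur <- c(px, py)
        }
      }
      rows[[b]] <- data.frame(
        individual_id = id, timestamp = ts, x = fx, y = fy, altitude = alt,
        truth_flying = flying, truth_period = per
      )
    }
    do.call(rbind, rows)
  })
}

#' Per-cell simulation cache for replicated strata generation
#'
#' Precomputes, once per (landscape, river, truth, period), the covariate
#' table of every grid cell and the true linear predictor on it, so that
#' replicated calls to [simulate_strata()] only sample cells and refit.
#'
#' @param landscape a `crane_landscape`
#' @param river a `crane_river` (roost period)
#' @param truth a [true_model()]
#' @param period `"diurnal"` or `"roost"`
#' @param roost_period bi-monthly raster set for roost annotation
#' @return a `sim_cache` list
#' @export
make_sim_cache <- function(landscape, river = NULL, truth = true_model(),
                           period = c("diurnal", "roost"),
                           roost_period = "dec_jan") {
  period <- match.arg(period)
  mask <- if (period == "diurnal") landscape$eligible else river$channel
  mask_vec <- as.vector(mask$values)
  mask_vec[is.na(mask_vec)] <- FALSE
  cc <- cell_centers(mask)
  inside <- which(mask_vec)
  cov_in <- if (period == "diurnal") {
    annotate_diurnal(cc[inside, ], landscape)
  } else {
    annotate_roost(cc[inside, ], river, roost_period,
                   structures = landscape$structures)
  }
  beta <- if (period == "diurnal") truth$diurnal else truth$roost
  form <- if (period == "diurnal") truth$diurnal_formula else truth$roost_formula
  lp <- rep(NA_real_, length(mask_vec))
  lp[inside] <- truth_lp(beta, form, cov_in)
  ## expand to one row per cell (NA rows off-mask), preserving factor levels
  cov <- cov_in[match(seq_along(mask_vec), inside), , drop = FALSE]
  rownames(cov) <- NULL
  structure(
    list(period = period, mask = mask, mask_vec = mask_vec, cc = cc,
         cov = cov, lp = lp, covariate_names = names(cov_in)),
    class = "sim_cache"
  )
}

## vectorized uniform sampling on disc(center_i) ∩ mask, one point per slot
sample_disc_cells <- function(cache, cx, cy, radius) {
  n <- length(cx)
  px <- py <- rep(NA_real_, n)
  cell <- rep(NA_integer_, n)
  todo <- seq_len(n)
  rounds <- 0L
  while (length(todo)) {
    rounds <- rounds + 1L
    if (rounds > 5000L) stop("disc sampling did not terminate: empty mask within radius?")
    m <- length(todo)
    d <- radius * sqrt(stats::runif(m))
    a <- stats::runif(m, 0, 2 * pi)
    x <- cx[todo] + d * cos(a)
    y <- cy[todo] + d * sin(a)
    ci <- raster_cell_index(cache$mask, x, y)
    ok <- !is.na(ci) & cache$mask_vec[pmax(ci, 1L)]
    ok[is.na(ok)] <- FALSE
    px[todo[ok]] <- x[ok]
    py[todo[ok]] <- y[ok]
    cell[todo[ok]] <- ci[ok]
    todo <- todo[!ok]
  }
  list(x = px, y = py, cell = cell)
}

#' Simulate matched strata directly from the selection model
#'
#' The fast generator for replicated estimator studies: for each stratum, a
#' center is placed near its cluster's home range, `M + 1` candidate
#' locations are drawn uniformly on the availability disc intersected with
#' the period mask, and the used location is selected among the candidates
#' with probability proportional to `exp(x' beta)` -- exactly the conditional
#' logistic data-generating process, so parameter recovery is a direct test
#' of the estimator. Covariates are taken at the 30 m cell of each sampled
#' point (the resolution they are defined on).
#'
#' @param landscape a `crane_landscape`
#' @param river a `crane_river` (roost period only)
#' @param truth a [true_model()]
#' @param period `"diurnal"` or `"roost"`
#' @param n_clusters number of individuals (clusters)
#' @param strata_per_cluster matched sets per individual
#' @param M available locations per used location
#' @param radius_m availability radius (m)
#' @param roost_period bi-monthly raster set for roost annotation
#' @param seed integer seed
#' @param cache optional [make_sim_cache()] result (built on the fly if
#'   absent); pass it when simulating repeatedly
#' @param home_range if `TRUE` (default), a cluster's stratum centers
#'   concentrate within half an availability radius of a cluster home,
#'   mimicking winter home ranges; if `FALSE`, centers are uniform over the
#'   mask and clusters are labels only -- the homogeneous design used for
#'   estimator calibration studies
#' @return a `strata_set` (see [build_strata()])
#' @export
simulate_strata <- function(landscape, river = NULL, truth = true_model(),
                            period = c("diurnal", "roost"),
                            n_clusters = 38L, strata_per_cluster = 10L,
                            M = 50L, radius_m = study_constants()$radius_m,
                            roost_period = "dec_jan", seed = 1L,
                            cache = NULL, home_range = TRUE) {
  period <- match.arg(period)
  if (period == "roost" && is.null(river)) stop("roost strata require `river`")
  if (is.null(cache)) {
    cache <- make_sim_cache(landscape, river, truth, period, roost_period)
  }
  with_seed(seed, {
    n_strata <- n_clusters * strata_per_cluster
    S <- M + 1L

    mask_cells <- which(cache$mask_vec)
    if (home_range) {
      ## cluster home cells, then stratum centers within half a radius
      home_i <- mask_cells[sample.int(length(mask_cells), n_clusters,
                                      replace = TRUE)]
      hx <- cache$cc$x[home_i]
      hy <- cache$cc$y[home_i]
      ctr <- sample_disc_cells(
        cache,
        rep(hx, each = strata_per_cluster),
        rep(hy, each = strata_per_cluster),
        radius_m / 2
      )
    } else {
      ctr_i <- mask_cells[sample.int(length(mask_cells), n_strata,
                                     replace = TRUE)]
      ctr <- list(x = cache$cc$x[ctr_i], y = cache$cc$y[ctr_i])
    }
    slots <- sample_disc_cells(
      cache,
      rep(ctr$x, each = S),
      rep(ctr$y, each = S),
      radius_m
    )

    stratum <- rep(seq_len(n_strata), each = S)
    lp <- cache$lp[slots$cell]
    used_row <- vapply(seq_len(n_strata), function(i) {
      ii <- ((i - 1L) * S + 1L):(i * S)
      w <- exp(lp[ii] - max(lp[ii]))
      ii[sample.int(S, 1L, prob = w)]
    }, 1L)

    ## put the used row first in its stratum block (candidates are
    ## exchangeable, so swapping preserves the law)
    perm <- seq_len(n_strata * S)
    first <- (seq_len(n_strata) - 1L) * S + 1L
    perm[first] <- used_row
    perm[used_row] <- first
    cell <- slots$cell[perm]
    is_used <- integer(n_strata * S)
    is_used[first] <- 1L

    cluster <- rep(seq_len(n_clusters), each = strata_per_cluster)
    out <- data.frame(
      stratum_id = stratum,
      cluster_id = sprintf("crane%02d", cluster[stratum]),
      is_used = is_used,
      period = period,
      x = slots$x[perm], y = slots$y[perm]
    )
    out <- cbind(out, data.frame(lapply(cache$cov, `[`, cell)))
    structure(
      out,
      covariates = cache$covariate_names, M = M, radius_m = radius_m,
      seed = seed, standardization = NULL,
      class = c("strata_set", "data.frame")
    )
  })
}
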