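#' Configuration for the synthetic winter landscape
#'
#' Describes an agricultural floodplain valley: a grid of rectangular crop
#' fields dominated by perennial alfalfa/hay with smaller corn, fallow,
#' small-grain, wetland and "other" patches, a public-ownership block (on
#' which wetland impoundments preferentially sit), and clustered human
#' structures from a Thomas (Poisson cluster) point process.
#'
#' @param extent_m landscape width and height (m). The default is an
#'   elongated 12 x 16 km valley flanking the north--south river, so every
#'   field lies within commuting reach of the roosting channel
#' @param cellsize land-use grid cell size (m); 30 m matches the satellite
#'   resolution the covariates are defined on
#' @param proportions named fractions of field area per land-use class, in
#'   the order alfalfa_hay, corn, fallow, small_grain, wetland, other; must
#'   lie in \[0, 1\] and sum to 1. Defaults put 88% of the area in
#'   alfalfa/hay, the composition observed on the wintering grounds.
#' @param public_fraction fraction of the landscape under public ownership
#' @param field_size_m mean field edge length (m); also acts as the spatial
#'   autocorrelation scale of the land-use mosaic
#' @param structure_clusters number of structure cluster centers (settlements)
#' @param structure_mean_per_cluster mean structures per cluster (Poisson)
#' @param structure_dispersion_m Gaussian scatter of structures about their
#'   cluster center (m)
#' @param seed integer seed; the generator is a pure function of the config
#' @return a `landscape_config` list
#' @export
landscape_config <- function(extent_m = c(12000, 16000),
                             cellsize = 30,
                             proportions = c(
                               alfalfa_hay = 0.88, corn = 0.04, fallow = 0.03,
                               small_grain = 0.02, wetland = 0.02, other = 0.01
                             ),
                             public_fraction = 0.2,
                             field_size_m = 400,
                             structure_clusters = 20L,
                             structure_mean_per_cluster = 8,
                             structure_dispersion_m = 150,
                             seed = 1L) {
  classes <- c("alfalfa_hay", "corn", "fallow", "small_grain", "wetland", "other")
  if (!all(classes %in% names(proportions))) {
    stop("`proportions` must be named with all of: ", paste(classes, collapse = ", "))
  }
  proportions <- proportions[classes]
  if (any(proportions < 0) || any(proportions > 1) ||
      abs(sum(proportions) - 1) > 1e-9) {
    stop("land-use proportions must lie in [0, 1] and sum to 1")
  }
  if (cellsize <= 0) stop("`cellsize` must be positive")
  structure(
    list(
      extent_m = extent_m, cellsize = cellsize, proportions = proportions,
      classes = classes, public_fraction = public_fraction,
      field_size_m = field_size_m,
      structure_clusters = as.integer(structure_clusters),
      structure_mean_per_cluster = structure_mean_per_cluster,
      structure_dispersion_m = structure_dispersion_m, seed = as.integer(seed)
    ),
    class = "landscape_config"
  )
}

## random partition of `total` cells into field blocks of ~`mean_cells` cells
field_breaks <- function(total, mean_cells) {
  sizes <- integer(0)
  left <- total
  while (left > 0) {
    s <- max(1L, round(stats::runif(1, 0.5, 1.5) * mean_cells))
    s <- min(s, left)
    sizes <- c(sizes, s)
    left <- left - s
  }
  cumsum(sizes)
}

#' Generate a synthetic winter landscape
#'
#' Builds the land-use raster (axis-aligned rectangular fields), the
#' public/private ownership raster, the clustered structure points, and the
#' eligible-diurnal mask (every agricultural, pasture or wetland cell;
#' structure-footprint cells are excluded as developed). Deterministic under
#' the config seed.
#'
#' @param config a [landscape_config()]
#' @return a `crane_landscape` with elements `landuse` (integer codes into
#'   `classes`), `ownership` (1 public / 0 private), `structures` (matrix of
#'   x, y), `eligible` (logical `grid_raster`), `classes`, `config`
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(config$seed, {
    cs <- config$cellsize
    nc <- as.integer(ceiling(config$extent_m[1] / cs))
    nr <- as.integer(ceiling(config$extent_m[2] / cs))
    mean_cells <- max(1, config$field_size_m / cs)

    xb <- field_breaks(nc, mean_cells)
    yb <- field_breaks(nr, mean_cells)
    fld_col <- findInterval(seq_len(nc) - 0.5, c(0, xb), rightmost.closed = TRUE)
    fld_row <- findInterval(seq_len(nr) - 0.5, c(0, yb), rightmost.closed = TRUE)
    nfx <- length(xb); nfy <- length(yb)

    ## field table: id, cell counts, whether its center is on public land
    fw <- diff(c(0L, xb)); fh <- diff(c(0L, yb))
    field_area <- outer(fh, fw)                 # nfy x nfx, cells per field
    ## public block: west band of the valley
    public_cols <- seq_len(max(1L, round(nc * config$public_fraction)))
    field_cx <- (c(0L, xb)[-(nfx + 1L)] + xb) / 2
    field_public <- matrix(rep(field_cx <= max(public_cols), each = nfy), nfy, nfx)

    ## greedy quota assignment of classes to fields; wetland first on public
    n_fields <- nfy * nfx
    areas <- as.vector(field_area)
    publics <- as.vector(field_public)
    total <- sum(areas)
    quota <- config$proportions * total
    cls <- integer(n_fields)

    wet_i <- which(config$classes == "wetland")
    ord <- sample.int(n_fields)
    pub_ord <- ord[publics[ord]]
    for (f in pub_ord) {
      if (quota[wet_i] < areas[f] * 0.5) break
      cls[f] <- wet_i
      quota[wet_i] <- quota[wet_i] - areas[f]
    }
    pos <- which(config$proportions > 0)        # classes absent stay absent
    for (f in ord) {
      if (cls[f] != 0L) next
      rel <- quota[pos] / config$proportions[pos]
      k <- if (all(quota[pos] <= 0)) pos[which.max(quota[pos])]
           else pos[which.max(rel)]
      cls[f] <- k
      quota[k] <- quota[k] - areas[f]
    }
    cls_m <- matrix(cls, nfy, nfx)

    landuse_vals <- cls_m[fld_row, fld_col, drop = FALSE]

    ownership_vals <- matrix(0L, nr, nc)
    ownership_vals[, public_cols] <- 1L

    ## Thomas process for human structures, clamped to the extent
    px <- stats::runif(config$structure_clusters, 0, config$extent_m[1])
    py <- stats::runif(config$structure_clusters, 0, config$extent_m[2])
    counts <- stats::rpois(config$structure_clusters,
                           config$structure_mean_per_cluster)
    sx <- rep(px, counts) + stats::rnorm(sum(counts), 0, config$structure_dispersion_m)
    sy <- rep(py, counts) + stats::rnorm(sum(counts), 0, config$structure_dispersion_m)
    sx <- pmin(pmax(sx, 0.5), config$extent_m[1] - 0.5)
    sy <- pmin(pmax(sy, 0.5), config$extent_m[2] - 0.5)
    structures <- cbind(x = sx, y = sy)

    landuse <- grid_raster(landuse_vals, 0, 0, cs)
    eligible_vals <- matrix(TRUE, nr, nc)
    rc <- raster_rowcol(landuse, sx, sy)
    eligible_vals[rc[!is.na(rc[, 1L]), , drop = FALSE]] <- FALSE

    structure(
      list(
        landuse = landuse,
        ownership = grid_raster(ownership_vals, 0, 0, cs),
        structures = structures,
        eligible = grid_raster(eligible_vals, 0, 0, cs),
        classes = config$classes,
        config = config
      ),
      class = "crane_landscape"
    )
  })
}

#' @export
print.crane_landscape <- function(x, ...) {
  fr <- landuse_fractions(x)
  cat(sprintf(
    "<crane_landscape> %g x %g km, %d structures\n  land use: %s\n",
    x$config$extent_m[1] / 1000, x$config$extent_m[2] / 1000,
    nrow(x$structures),
    paste(sprintf("%s %.1f%%", names(fr), 100 * fr), collapse = ", ")
  ))
  invisible(x)
}

#' Empirical land-use class fractions of a landscape
#' @param landscape a `crane_landscape`
#' @return named fractions over all cells
#' @export
landuse_fractions <- function(landscape) {
  tab <- tabulate(landscape$landuse$values, nbins = length(landscape$classes))
  stats::setNames(tab / sum(tab), landscape$classes)
}
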