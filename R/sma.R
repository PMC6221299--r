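#' Normalized difference water index
#'
#' `(green - nir) / (green + nir)` per pixel; high over open water. Pixels
#' where the denominator is zero are undefined and returned as `NA`.
#'
#' @param green,nir matrices (or `grid_raster`s) of the green and
#'   near-infrared bands, same shape
#' @return matrix (or `grid_raster`, matching the input) of index values
#' @export
ndwi <- function(green, nir) {
  as_ras <- inherits(green, "grid_raster")
  g <- if (as_ras) green$values else green
  n <- if (inherits(nir, "grid_raster")) nir$values else nir
  if (!identical(dim(g), dim(n))) stop("band shapes differ")
  denom <- g + n
  out <- (g - n) / denom
  out[denom == 0] <- NA_real_
  if (as_ras) grid_raster(out, green$xmin, green$ymin, green$cellsize) else out
}

#' Upper-percentile NDWI water mask
#'
#' Flags the pixels at or above the given percentile of the valid index
#' values (linear-interpolation quantile); at the default 98th percentile
#' about 2% of valid pixels are flagged, isolating the deep-water pixels
#' used to extract the water endmember.
#'
#' @param index NDWI matrix or `grid_raster`
#' @param percentile percentile threshold in (0, 100)
#' @return logical matrix; `NA` index pixels are `FALSE`
#' @export
ndwi_mask <- function(index, percentile = 98) {
  v <- if (inherits(index, "grid_raster")) index$values else index
  valid <- is.finite(v)
  if (sum(valid) < 50L) stop("need at least 50 valid pixels for the NDWI mask")
  vals <- v[valid]
  if (diff(range(vals)) == 0) {
    warning("constant NDWI raster: the percentile is degenerate, all valid pixels flagged")
    return(valid)
  }
  q <- stats::quantile(vals, percentile / 100, type = 7, names = FALSE)
  m <- valid & v >= q
  m
}

#' Extract endmember spectra from class regions
#'
#' Per-class mean spectrum over the region's pixels. Water is typically
#' supplied as an NDWI mask, sandbar and vegetation as static polygons of
#' known monotypic cover rasterized to pixel masks.
#'
#' @param image numeric array `H x W x B` (or a `pixels x B` matrix with
#'   regions as index vectors)
#' @param regions named list (`water`, `sandbar`, `vegetation`) of logical
#'   masks (`H x W`) or pixel index vectors
#' @return an `endmember_set`: 3 x B matrix of class spectra with a
#'   `provenance` attribute
#' @export
extract_endmembers <- function(image, regions) {
  need <- c("water", "sandbar", "vegetation")
  if (!all(need %in% names(regions))) {
    stop("regions must be named: ", paste(need, collapse = ", "))
  }
  pix <- if (length(dim(image)) == 3L) {
    matrix(image, prod(dim(image)[1:2]), dim(image)[3])
  } else {
    as.matrix(image)
  }
  E <- t(vapply(need, function(nm) {
    idx <- regions[[nm]]
    if (is.logical(idx)) idx <- which(idx)
    if (length(idx) == 0L) stop("empty region for class: ", nm)
    colMeans(pix[idx, , drop = FALSE])
  }, numeric(ncol(pix))))
  structure(E, class = c("endmember_set", "matrix"),
            provenance = "region means")
}

## equality-constrained least squares on a support set, via KKT system
ecls_simplex <- function(M, s, support) {
  k <- length(support)
  Ms <- M[, support, drop = FALSE]
  KKT <- rbind(cbind(2 * crossprod(Ms), rep(1, k)), c(rep(1, k), 0))
  rhs <- c(2 * crossprod(Ms, s), 1)
  sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  sol[seq_len(k)]
}

#' Fully constrained linear spectral unmixing
#'
#' Solves `min || E' p - s ||^2` subject to `p >= 0` and `sum(p) = 1` -- the
#' proportions of water, sandbar and vegetation mixed inside one pixel. The
#' optimum is found exactly by support enumeration: the sum-to-one
#' equality-constrained least-squares solution is computed on every
#' non-empty endmember subset and the feasible solution with the smallest
#' residual is returned. Deterministic; a noiseless mixture is recovered
#' with zero residual.
#'
#' @param spectrum numeric vector of B band values
#' @param endmembers an `endmember_set` (3 x B matrix, rows = classes)
#' @return an `unmix_result`: `proportions` (named, on the simplex) and
#'   `residual` (Euclidean norm)
#' @export
unmix <- function(spectrum, endmembers) {
  if (!all(is.finite(spectrum))) stop("non-finite pixel spectrum")
  E <- unclass(endmembers)
  M <- t(E)                       # B x classes
  p_full <- nrow(E)
  best <- NULL
  best_res <- Inf
  for (bits in seq_len(2^p_full - 1L)) {
    support <- which(bitwAnd(bits, 2^(seq_len(p_full) - 1L)) > 0L)
    ps <- ecls_simplex(M, spectrum, support)
    if (is.null(ps) || any(ps < -1e-10)) next
    p <- numeric(p_full)
    p[support] <- pmax(ps, 0)
    p <- p / sum(p)
    res <- sqrt(sum((M %*% p - spectrum)^2))
    if (res < best_res - 1e-15) {
      best <- p
      best_res <- res
    }
  }
  names(best) <- rownames(E)
  structure(list(proportions = best, residual = best_res),
            class = "unmix_result")
}

#' Unmix many pixels
#'
#' @param spectra `n x B` matrix of pixel spectra
#' @param endmembers an `endmember_set`
#' @return list with `proportions` (`n x 3`) and `residual` (length n)
#' @export
unmix_pixels <- function(spectra, endmembers) {
  spectra <- as.matrix(spectra)
  res <- apply(spectra, 1L, unmix, endmembers = endmembers)
  list(
    proportions = t(vapply(res, `[[`, numeric(nrow(endmembers)), "proportions")),
    residual = vapply(res, `[[`, 1, "residual")
  )
}

#' Per-period composite of an image stack
#'
#' Per-pixel mean over the valid observations of all images falling in a
#' bi-monthly period; validity masks remove cloud / cloud-shadow / snow
#' pixels. Pixels with no valid observation are returned as `NA`.
#'
#' @param stack `H x W x T` array (or list of matrices) of co-registered
#'   images
#' @param valid `H x W x T` logical array (or list of matrices); `TRUE`
#'   marks usable pixels. Default: everything finite is valid.
#' @return `H x W` matrix
#' @export
composite_period <- function(stack, valid = NULL) {
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1L))
  if (dim(stack)[3] == 0L) stop("empty image stack")
  if (is.null(valid)) valid <- is.finite(stack)
  if (is.list(valid)) valid <- simplify2array(valid)
  if (!identical(dim(valid), dim(stack))) stop("validity mask shape differs from stack")
  s <- stack
  s[!valid] <- 0
  num <- rowSums(s, dims = 2L)
  den <- rowSums(valid, dims = 2L)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
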