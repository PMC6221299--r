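#' Configuration for synthetic multispectral pixels
#'
#' Defines the three river land-cover endmembers (water, sandbar, riparian
#' vegetation) over a Landsat-8-like set of reflective bands, the Dirichlet
#' law of the true sub-pixel proportions, and additive Gaussian sensor noise.
#'
#' @param n_bands number of spectral bands (default 6, the reflective bands)
#' @param endmembers 3 x n_bands matrix of endmember reflectances with rows
#'   named water, sandbar, vegetation; must have full row rank
#' @param noise_sd standard deviation of the additive per-band noise; >= 0
#' @param dirichlet_alpha length-3 Dirichlet concentration of the true
#'   proportions
#' @param seed integer seed
#' @return a `spectra_config` list
#' @export
spectra_config <- function(n_bands = 6L,
                           endmembers = NULL,
                           noise_sd = 0.01,
                           dirichlet_alpha = c(1, 1, 1),
                           seed = 1L) {
  if (is.null(endmembers)) {
    if (n_bands != 6L) stop("provide `endmembers` explicitly when n_bands != 6")
    endmembers <- rbind(
      water      = c(0.064, 0.078, 0.096, 0.060, 0.028, 0.018),
      sandbar    = c(0.120, 0.165, 0.205, 0.262, 0.305, 0.282),
      vegetation = c(0.038, 0.068, 0.046, 0.452, 0.226, 0.104)
    )
  }
  endmembers <- as.matrix(endmembers)
  if (nrow(endmembers) != 3L || ncol(endmembers) < 3L) {
    stop("`endmembers` must be a 3 x B matrix with B >= 3")
  }
  if (qr(endmembers)$rank < 3L) stop("`endmembers` must have full row rank")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(
    list(
      n_bands = ncol(endmembers), endmembers = endmembers,
      noise_sd = noise_sd, dirichlet_alpha = dirichlet_alpha,
      seed = as.integer(seed)
    ),
    class = "spectra_config"
  )
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Simulate mixed pixels from known endmember proportions
#'
#' Each pixel spectrum is the convex combination of the endmember spectra
#' under its true proportions plus Gaussian noise; the true proportions are
#' returned alongside for unmixing validation.
#'
#' @param config a [spectra_config()]
#' @param n_pixels number of pixels to simulate
#' @param proportions optional n_pixels x 3 matrix of proportions to use
#'   instead of Dirichlet draws (rows must sum to 1)
#' @return list with `spectra` (n_pixels x B) and `proportions` (n_pixels x 3,
#'   columns water/sandbar/vegetation)
#' @export
simulate_spectra <- function(config = spectra_config(), n_pixels = 100L,
                             proportions = NULL) {
  stopifnot(inherits(config, "spectra_config"))
  with_seed(config$seed + 202L, {
    p <- if (is.null(proportions)) {
      rdirichlet(n_pixels, config$dirichlet_alpha)
    } else {
      pm <- as.matrix(proportions)
      if (any(abs(rowSums(pm) - 1) > 1e-9)) stop("proportion rows must sum to 1")
      pm
    }
    colnames(p) <- rownames(config$endmembers)
    s <- p %*% config$endmembers +
      matrix(stats::rnorm(nrow(p) * config$n_bands, 0, config$noise_sd),
             nrow(p), config$n_bands)
    list(spectra = s, proportions = p)
  })
}
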