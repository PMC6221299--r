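#' Per-cell covariate tables for prediction
#'
#' Build the covariate data underlying a prediction surface: one row per
#' grid cell of the template raster, in the template's cell order
#' (column-major, matching [cell_centers()]), with the domain mask marking
#' the cells the model applies to (the eligible-diurnal layer, or the
#' active channel for a given bi-monthly period).
#'
#' @param landscape a `crane_landscape`
#' @return list with `data` (covariate data.frame over all cells),
#'   `template` (`grid_raster` defining the grid), `mask` (logical vector in
#'   cell order)
#' @export
diurnal_covariate_table <- function(landscape) {
  cc <- cell_centers(landscape$eligible)
  list(
    data = annotate_diurnal(cc, landscape),
    template = landscape$eligible,
    mask = as.vector(landscape$eligible$values)
  )
}

#' @rdname diurnal_covariate_table
#' @param river a `crane_river`
#' @param period bi-monthly period name or index
#' @export
roost_covariate_table <- function(landscape, river, period) {
  mask <- as.vector(river$channel$values)
  cc <- cell_centers(river$channel)
  inside <- cc[mask, , drop = FALSE]
  cov_in <- annotate_roost(inside, river, period,
                           structures = landscape$structures)
  data <- cov_in[match(seq_along(mask), which(mask)), , drop = FALSE]
  rownames(data) <- NULL
  list(data = data, template = river$channel, mask = mask)
}

#' Relative-probability-of-use prediction surface
#'
#' Evaluates `w(cell) = exp(x(cell)' beta)` over the masked domain of a
#' covariate table and min--max rescales it to \[0, 1\] for display (the
#' relative probability of use in a used--available design is defined only
#' up to a positive factor, so the raw exp-scores are returned alongside).
#' A constant surface rescales to 0 by convention. Cells outside the domain
#' are `NA`. If the fit was trained on z-scored covariates, the stored
#' transform is applied before evaluation.
#'
#' @param fit a `crane_clogit`
#' @param covariates a covariate table from [diurnal_covariate_table()] or
#'   [roost_covariate_table()]
#' @return list with `surface` (rescaled `grid_raster`), `raw`
#'   (`grid_raster` of exp-scores)
#' @export
predict_surface <- function(fit, covariates) {
  data <- covariates$data
  mask <- covariates$mask
  form <- fit$formula
  if (is.null(form)) stop("fit carries no formula; cannot build cell covariates")
  vars <- all.vars(form)
  missing_layers <- setdiff(vars, names(data))
  if (length(missing_layers)) {
    stop("missing covariate layer(s): ", paste(missing_layers, collapse = ", "))
  }
  d <- data[mask, vars, drop = FALSE]
  if (!is.null(fit$standardization)) {
    for (nm in intersect(names(fit$standardization), names(d))) {
      st <- fit$standardization[[nm]]
      if (st["sd"] > 0) d[[nm]] <- (d[[nm]] - st["mean"]) / st["sd"]
    }
  }
  X <- build_model_matrix(d, form)
  keep <- intersect(colnames(X), names(fit$coefficients))
  if (length(keep) != length(fit$coefficients)) {
    stop("cell covariates do not span the fitted coefficients")
  }
  lp <- drop(X[, names(fit$coefficients), drop = FALSE] %*% fit$coefficients)
  w <- exp(lp)
  ## rescaling is invariant to the positive factor, so stabilize it
  ws <- exp(lp - max(lp))
  rng <- range(ws)
  scaled <- if (rng[2] > rng[1]) (ws - rng[1]) / (rng[2] - rng[1]) else rep(0, length(ws))

  tmpl <- covariates$template
  mk <- function(vals) {
    v <- rep(NA_real_, length(mask))
    v[mask] <- vals
    grid_raster(matrix(v, nrow(tmpl$values), ncol(tmpl$values)),
                tmpl$xmin, tmpl$ymin, tmpl$cellsize)
  }
  list(surface = mk(scaled), raw = mk(w))
}
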