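#' Built-in candidate model sets
#'
#' Returns the default candidate models for a period as named model
#' specifications. The diurnal set nests land use, land ownership and the
#' structure-density radius variants (100 / 500 / 1000 m) plus a
#' distance-to-structure alternative; the top diurnal structure is land use
#' + ownership + structure density within 500 m. The roosting set nests the
#' channel-geometry terms up to the full structure: the three-way channel
#' width x sandbar x water interaction, bank vegetation height within the
#' 500 m stretch and its interaction with width, and distance to bridge.
#' Users extend the set by concatenating their own specs.
#'
#' @param period `"diurnal"` or `"roost"`
#' @param catalog optional character vector of covariates present in the
#'   strata; when given, every term is checked against it
#' @return named list of `model_spec` objects (`name`, `period`, `formula`)
#' @export
candidate_models <- function(period = c("diurnal", "roost"), catalog = NULL) {
  period <- match.arg(period)
  specs <- if (period == "diurnal") {
    list(
      landuse = ~ landuse,
      landuse_ownership = ~ landuse + ownership,
      landuse_ownership_dens100 = ~ landuse + ownership + dens100,
      landuse_ownership_dens500 = ~ landuse + ownership + dens500,
      landuse_ownership_dens1000 = ~ landuse + ownership + dens1000,
      landuse_ownership_dist = ~ landuse + ownership + dist_structure_km
    )
  } else {
    list(
      geometry = ~ width + sandbar + water,
      geometry_interactions = ~ width * sandbar * water,
      geometry_bank = ~ width * sandbar * water + bank_veg_500 +
        width:bank_veg_500,
      geometry_bank_bridge = ~ width * sandbar * water + bank_veg_500 +
        width:bank_veg_500 + dist_bridge_km
    )
  }
  if (!is.null(catalog)) {
    if (length(catalog) == 0L) stop("empty covariate catalog")
    for (nm in names(specs)) {
      bad <- setdiff(all.vars(specs[[nm]]), catalog)
      if (length(bad)) {
        stop(sprintf("model '%s' references unknown covariate(s): %s",
                     nm, paste(bad, collapse = ", ")))
      }
    }
  }
  lapply(stats::setNames(names(specs), names(specs)), function(nm) {
    structure(list(name = nm, period = period, formula = specs[[nm]]),
              class = "model_spec")
  })
}

#' Fit a set of candidate models with per-model VIF screening
#'
#' Each candidate's main-effect columns are screened with [vif_screen()]
#' (threshold from the constants); flagged columns are dropped from that
#' model before fitting. Models whose fit fails are reported and omitted.
#'
#' @param strata a `strata_set`
#' @param specs named list of `model_spec`s (see [candidate_models()])
#' @param vif_threshold VIF exclusion threshold
#' @return named list of `crane_clogit` fits
#' @export
fit_candidates <- function(strata, specs,
                           vif_threshold = study_constants()$vif_threshold) {
  fits <- list()
  for (nm in names(specs)) {
    form <- specs[[nm]]$formula
    X <- build_model_matrix(strata, form)
    if (ncol(X) >= 2L) {
      scr <- vif_screen(strata, form, threshold = vif_threshold)
      if (length(scr$flagged)) {
        drop_main <- intersect(scr$flagged, colnames(X))
        keepcols <- setdiff(colnames(X), drop_main)
        ## rebuild a pruned formula from surviving columns is fragile for
        ## factors; instead fit on the pruned matrix directly
        fit <- tryCatch(
          fit_clogit_xy(X[, keepcols, drop = FALSE], strata$stratum_id,
                        strata$is_used, strata$cluster_id, formula = form),
          error = function(e) e
        )
        if (!inherits(fit, "error")) fit$vif_dropped <- drop_main
        fits[[nm]] <- fit
        next
      }
    }
    fits[[nm]] <- tryCatch(fit_clogit(strata, form), error = function(e) e)
  }
  failed <- vapply(fits, inherits, TRUE, what = "error")
  if (any(failed)) {
    warning("candidate model(s) failed to fit and were omitted: ",
            paste(names(fits)[failed], collapse = ", "))
  }
  fits[!failed]
}

#' Rank fitted models by QIC
#'
#' @param fits named list of converged `crane_clogit` fits on the same
#'   strata (same design rows; enforced)
#' @return data.frame sorted by QIC with `model`, `qic`, `delta_qic`,
#'   `weight` (QIC weights, summing to 1)
#' @export
rank_models <- function(fits) {
  if (!length(fits)) stop("no fits to rank")
  ns <- vapply(fits, function(f) f$n_strata, 1)
  nr <- vapply(fits, function(f) nrow(f$X), 1)
  if (length(unique(ns)) != 1L || length(unique(nr)) != 1L) {
    stop("fits were computed on differing row sets and are not comparable")
  }
  if (!all(vapply(fits, function(f) f$converged, TRUE))) {
    stop("all fits must have converged")
  }
  q <- vapply(fits, function(f) f$qic, 1)
  d <- q - min(q)
  w <- exp(-d / 2)
  w <- w / sum(w)
  out <- data.frame(
    model = names(fits), qic = q, delta_qic = d, weight = w,
    row.names = NULL
  )
  out[order(out$qic), ]
}
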