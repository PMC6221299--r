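#' Study design constants
#'
#' Central list of the design constants the analysis pipeline uses: the diel
#' windows that split fixes into diurnal and roosting periods, the
#' migration-movement cap and elapsed-time rule entering the availability
#' radius, the matched-design ratio, the covariate radii, and the
#' cross-validation and collinearity settings. All distances are meters,
#' times are hours of the local clock day.
#'
#' @param radius_m availability radius around each used location (m). The
#'   default 6700 m is the mean maximum movement distance between successive
#'   fixes at most 3 h apart after discarding migratory movements; the
#'   alternative computed from steps more than 3 h apart is 5800 m.
#' @param n_available available (control) locations matched to each used
#'   location
#' @return named list of constants
#' @export
study_constants <- function(radius_m = 6700, n_available = 50L) {
  list(
    diel_start = 7,              # diurnal window [07:00, 18:00)
    diel_end = 18,
    migration_cap_m = 10000,     # steps at least this long are migratory
    step_elapsed_max_hr = 3,     # keep steps with elapsed <= 3 h
    radius_m = radius_m,
    n_available = as.integer(n_available),
    density_radii_m = c(100, 500, 1000),
    stretch_radii_m = c(100, 500, 1000),
    flight_alt_m = 50,           # altitude above ground declaring "flying"
    cv_train_frac = 0.8,
    cv_reps = 1000L,
    vif_threshold = 5,
    fix_hours = c(7, 8, 10, 14, 16, 18, 24)
  )
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

## planar Euclidean distance
euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)
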