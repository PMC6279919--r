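#' Lomb-Scargle periodogram test at a fixed period
#'
#' Computes the variance-normalised Lomb-Scargle power at the target period
#' (with the standard phase offset tau that makes the fit equivalent to
#' least-squares sinusoid regression) and converts it to the exceedance
#' probability under the single-frequency exponential null,
#' `p = exp(-power)`. Only one period is tested so no multi-frequency
#' correction is applied. A zero-variance profile has power 0 and p = 1.
#'
#' @param y Numeric expression profile (at least 4 points).
#' @param grid Sampling hours, same length as `y`.
#' @param period Test period in hours.
#' @return A one-row tibble with `ls_power` and `ls_p`.
#' @examples
#' grid <- seq(2, 24, by = 2)
#' lomb_scargle(sin(2 * pi * grid / 24), grid)
#' @export
lomb_scargle <- function(y, grid, period = 24) {
  if (length(y) != length(grid)) {
    rlang::abort("`y` and `grid` must have the same length.")
  }
  if (length(y) < 4L) {
    rlang::abort("Lomb-Scargle requires at least 4 time points.")
  }
  v <- stats::var(y)
  if (v == 0 || is.na(v)) {
    return(tibble::tibble(ls_power = 0, ls_p = 1))
  }
  w <- 2 * pi / period
  tau <- atan2(sum(sin(2 * w * grid)), sum(cos(2 * w * grid))) / (2 * w)
  yc <- y - mean(y)
  ct <- cos(w * (grid - tau))
  st <- sin(w * (grid - tau))
  power <- (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2)) / (2 * v)
  tibble::tibble(ls_power = power, ls_p = exp(-power))
}

# Squared Fourier amplitude of the centred profile at the period.
fourier_power <- function(y, grid, period) {
  w <- 2 * pi / period
  yc <- y - mean(y)
  Mod(sum(yc * exp(-1i * w * grid)))^2
}

#' Empirical periodicity-times-regulation rhythmicity score
#'
#' A two-component empirical score in [0, 1], lower meaning more rhythmic.
#' The periodicity component is the fraction of `n_perm` random time-order
#' permutations of the profile whose Fourier power at the target period is
#' at least the observed power; the regulation component is the fraction of
#' background genes whose absolute amplitude (max - min) is at least the
#' profile's. The score is their product. Permuting a constant profile
#' never changes its power, so constant genes score 1 (least rhythmic).
#'
#' @param y Numeric expression profile.
#' @param grid Sampling hours, same length as `y`.
#' @param background A diel expression tibble of at least 50 genes whose
#'   amplitudes calibrate the regulation component.
#' @param period Test period in hours.
#' @param n_perm Number of time-order permutations (at least 100).
#' @param seed Optional integer seed making the permutations reproducible.
#' @return A one-row tibble with `dl_p_periodicity`, `dl_p_regulation`, and
#'   `dl_score`.
#' @export
de_lichtenberg <- function(y, grid, background, period = 24, n_perm = 1000,
                           seed = NULL) {
  if (length(y) != length(grid)) {
    rlang::abort("`y` and `grid` must have the same length.")
  }
  if (n_perm < 100L) {
    rlang::abort("`n_perm` must be at least 100.")
  }
  check_expr(background, "background")
  if (nrow(background) < 50L) {
    rlang::abort("`background` must contain at least 50 genes.")
  }
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) sample.int(length(y)),
             integer(length(y))))
  })
  obs <- fourier_power(y, grid, period)
  perm_pow <- apply(perms, 1L, function(ix) fourier_power(y[ix], grid, period))
  p_per <- mean(perm_pow >= obs - 1e-12)
  amps <- apply(expr_values(background), 1L, function(v) max(v) - min(v))
  p_reg <- mean(amps >= (max(y) - min(y)) - 1e-12)
  tibble::tibble(
    dl_p_periodicity = p_per, dl_p_regulation = p_reg,
    dl_score = p_per * p_reg
  )
}

#' Phase call of a profile
#'
#' The phase call is the sampling hour at which transcript abundance is
#' maximal; ties are broken by the earliest hour.
#'
#' @param y Numeric expression profile.
#' @param grid Sampling hours, same length as `y`.
#' @return The phase call in hours.
#' @examples
#' phase_call(c(0, 1, 3, 1), c(2, 4, 6, 8))
#' @export
phase_call <- function(y, grid) {
  if (length(y) != length(grid)) {
    rlang::abort("`y` and `grid` must have the same length.")
  }
  grid[which.max(y)]
}

#' Circadian parameters of a profile
#'
#' Summarises a profile by its mean FPKM, absolute amplitude (max - min),
#' fold-change (max / min, reported missing when the minimum is 0), and
#' phase call.
#'
#' @inheritParams phase_call
#' @return A one-row tibble with `mean_fpkm`, `amplitude`, `fold_change`,
#'   and `phase_call_h`.
#' @examples
#' circadian_params(c(1, 3), c(4, 8))
#' @export
circadian_params <- function(y, grid) {
  mx <- max(y)
  mn <- min(y)
  tibble::tibble(
    mean_fpkm = mean(y),
    amplitude = mx - mn,
    fold_change = if (mn == 0) NA_real_ else mx / mn,
    phase_call_h = phase_call(y, grid)
  )
}

#' Score every gene with the three rhythmicity algorithms
#'
#' Applies the JTK-CYCLE test, the fixed-period Lomb-Scargle test, and the
#' empirical periodicity-times-regulation score to each gene, with the
#' matrix itself as the regulation background, and appends the circadian
#' parameters. One permutation set is drawn and shared across genes for the
#' permutation component, which keeps whole-matrix scoring tractable; the
#' per-profile [de_lichtenberg()] draws its own.
#'
#' @param expr A diel expression tibble.
#' @param period Test period in hours.
#' @param n_perm Permutations for the periodicity component.
#' @param seed Optional integer seed for the permutation component.
#' @return A tibble with one row per gene: `gene_id`, `jtk_p`, `jtk_lag_h`,
#'   `jtk_tau`, `ls_power`, `ls_p`, `dl_score`, `mean_fpkm`, `amplitude`,
#'   `fold_change`, `phase_call_h`.
#' @export
rhythm_scores <- function(expr, period = 24, n_perm = 1000, seed = NULL) {
  check_expr(expr)
  grid <- diel_grid(expr)
  m <- expr_values(expr)
  jtk <- jtk_cycle_matrix(m, grid, period)

  ls <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    lomb_scargle(m[i, ], grid, period)
  })

  n <- length(grid)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  })
  e <- exp(-1i * 2 * pi * grid / period)
  obs_pow <- vapply(seq_len(nrow(m)), function(i) fourier_power(m[i, ], grid, period),
                    numeric(1))
  p_per <- vapply(seq_len(nrow(m)), function(i) {
    yc <- m[i, ] - mean(m[i, ])
    yp <- matrix(yc[perms], nrow = n_perm)
    pow <- Mod(yp %*% e)^2
    mean(pow >= obs_pow[i] - 1e-12)
  }, numeric(1))
  amps <- apply(m, 1L, function(v) max(v) - min(v))
  p_reg <- vapply(amps, function(a) mean(amps >= a - 1e-12), numeric(1))

  params <- purrr::map_dfr(seq_len(nrow(m)), function(i) circadian_params(m[i, ], grid))

  dplyr::bind_cols(
    jtk,
    ls,
    tibble::tibble(dl_score = p_per * p_reg),
    params
  )
}

# Run code under a temporary RNG state when a seed is given.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
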