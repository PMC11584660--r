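#' Generate a synthetic adult life table (Gompertz-Makeham)
#'
#' Deterministic single-year life table from the Gompertz-Makeham hazard
#' \eqn{\mu(x) = c + a e^{bx}}, converted to annual death probabilities
#' \eqn{q_x = 1 - e^{-\mu(x)}}. Two interpretable knobs — a flat
#' age-independent component and an exponentially rising senescent component
#' — give monotone adult mortality with easy closed-form checks. The
#' defaults are calibrated so that remaining life expectancy at age 59 under
#' the diabetes mortality uplift (1.9) is about 12.6 years, the realistic
#' magnitude for a late-middle-aged Indian cohort with diabetes; a real
#' national abridged table can be dropped in through [read_life_table()]
#' instead.
#'
#' @param makeham age-independent baseline hazard (per year).
#' @param gompertz_a level of the senescent hazard at age 0.
#' @param gompertz_b exponential slope of the senescent hazard (per year of
#'   age).
#' @param ages integer vector of ages to cover; the last age becomes the
#'   terminal age with `qx = 1`.
#' @return A [life_table].
#' @examples
#' lt <- synth_life_table()
#' implied_le(lt, age = 59, relative_risk = 1.9)  # ~ 12.6 years
#' @export
synth_life_table <- function(makeham = 0.003,
                             gompertz_a = 4.97e-05,
                             gompertz_b = 0.095,
                             ages = 18:105) {
  stopifnot(is.numeric(makeham), makeham >= 0,
            is.numeric(gompertz_a), gompertz_a >= 0,
            is.numeric(gompertz_b), gompertz_b >= 0,
            length(ages) >= 2L)
  ages <- as.integer(ages)
  body_ages <- ages[-length(ages)]
  qx <- 1 - exp(-(makeham + gompertz_a * exp(gompertz_b * body_ages)))
  early <- body_ages < 60L & qx >= 1
  if (any(early)) {
    stop(sprintf("hazard parameters give qx = 1 already at age %d; implausible adult table",
                 body_ages[which(early)[1L]]), call. = FALSE)
  }
  life_table(ages, c(qx, 1))
}

#' Remaining life expectancy implied by a life table
#'
#' Calibration helper: survival-only life expectancy at a given age, with an
#' optional mortality relative-risk uplift, counted (like the Markov model)
#' as the sum of end-of-year survival probabilities.
#'
#' @param lt a [life_table].
#' @param age starting age.
#' @param relative_risk mortality uplift applied to `qx` (default 1, none).
#' @return Remaining life expectancy in years.
#' @export
implied_le <- function(lt, age, relative_risk = 1) {
  stopifnot(inherits(lt, "life_table"))
  if (!age %in% lt$age) stop("`age` outside life-table range", call. = FALSE)
  idx <- which(lt$age >= age)
  q <- pmin(relative_risk * lt$qx[idx], 1)
  sum(cumprod(1 - q))
}

#' Simulate a screening-cascade realisation
#'
#' Stochastic stand-in for a pilot programme's patient flow: sequential
#' binomial draws down the cascade. Referral, examination attendance, STDR
#' diagnosis and treatment uptake thin the flow in order; ungradable images
#' arise among those referred, and a fraction of those receive cataract
#' surgery. Reproducible given the seed; expected counts equal the screened
#' population times cumulative branch-probability products.
#'
#' @param n_screened patients screened.
#' @param p_referral probability a screened patient is referred.
#' @param p_attendance probability a referred patient attends examination.
#' @param p_stdr probability an examined patient is diagnosed with STDR.
#' @param p_treat_stdr probability a diagnosed patient receives laser.
#' @param p_ungradable probability a referred patient had ungradable images.
#' @param p_cataract probability an ungradable-image patient receives
#'   cataract surgery.
#' @param bilateral_fraction passed to [cascade_counts()].
#' @param seed integer seed.
#' @return A [cascade_counts] with attributes `n_stdr_diagnosed` and
#'   `n_ungradable` (the intermediate draws).
#' @export
synth_cascade <- function(n_screened = 5307,
                          p_referral = 0.313,
                          p_attendance = 0.5,
                          p_stdr = 0.594,
                          p_treat_stdr = 0.7,
                          p_ungradable = 0.481,
                          p_cataract = 0.2,
                          bilateral_fraction = 0,
                          seed = 1L) {
  probs <- c(p_referral = p_referral, p_attendance = p_attendance,
             p_stdr = p_stdr, p_treat_stdr = p_treat_stdr,
             p_ungradable = p_ungradable, p_cataract = p_cataract)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop(sprintf("branch probability `%s` = %g outside [0, 1]",
                 names(probs)[bad][1L], probs[bad][1L]), call. = FALSE)
  }
  set.seed(seed)
  n_referred <- stats::rbinom(1L, n_screened, p_referral)
  n_examined <- stats::rbinom(1L, n_referred, p_attendance)
  n_stdr_diag <- stats::rbinom(1L, n_examined, p_stdr)
  n_stdr_treated <- stats::rbinom(1L, n_stdr_diag, p_treat_stdr)
  n_ungradable <- stats::rbinom(1L, n_referred, p_ungradable)
  n_cataract <- stats::rbinom(1L, n_ungradable, p_cataract)
  cc <- cascade_counts(n_screened = n_screened, n_referred = n_referred,
                       n_examined = n_examined, n_stdr_treated = n_stdr_treated,
                       n_cataract_treated = n_cataract,
                       bilateral_fraction = bilateral_fraction)
  attr(cc, "n_stdr_diagnosed") <- n_stdr_diag
  attr(cc, "n_ungradable") <- n_ungradable
  cc
}

#' The pinned Kerala 2019 replication scenario
#'
#' Every parameter of the 2019 Kerala pilot analysis pinned at its central
#' value: Markov model parameters, unit costs, the explicit cascade counts
#' (which take precedence over the printed branch rates, whose rounding is
#' not exactly self-consistent), willingness-to-pay thresholds, and the
#' deterministic/probabilistic sensitivity-analysis settings. The life table
#' defaults to the calibrated synthetic Gompertz-Makeham table; supply a
#' real table for replication against national mortality data.
#'
#' @param life_table a [life_table]; default [synth_life_table()].
#' @param bilateral_fraction proportion of laser patients treated in both
#'   eyes (0 in the base case; 0.20 in the bilateral scenario).
#' @return An object of class `cea_scenario`: list with elements `name`,
#'   `params`, `unit_costs`, `counts`, `thresholds`, `life_table`, `dsa`
#'   (a [dsa_spec]) and `psa` (a [psa_spec]).
#' @examples
#' sc <- kerala_2019_scenario()
#' sc$params$p_blind_untreated  # 0.09
#' sc$counts$n_screened         # 5307
#' @export
kerala_2019_scenario <- function(life_table = synth_life_table(),
                                 bilateral_fraction = 0) {
  structure(list(
    name = "kerala_2019",
    params = model_params(),
    unit_costs = unit_costs(),
    counts = cascade_counts(bilateral_fraction = bilateral_fraction),
    thresholds = thresholds(),
    life_table = life_table,
    dsa = dsa_spec(),
    psa = psa_spec()
  ), class = "cea_scenario")
}

#' @export
print.cea_scenario <- function(x, ...) {
  cat(sprintf("CEA scenario \"%s\"\n", x$name))
  cat(sprintf("  cascade: %d screened -> %d referred -> %d examined -> %d laser + %d cataract\n",
              x$counts$n_screened, x$counts$n_referred, x$counts$n_examined,
              x$counts$n_stdr_treated, x$counts$n_cataract_treated))
  cat(sprintf("  model: entry age %d, transition %.0f%%/%.0f%% (untreated/treated), discount %.0f%%\n",
              x$params$start_age, 100 * x$params$p_blind_untreated,
              100 * x$params$p_blind_treated, 100 * x$params$discount_rate))
  cat(sprintf("  life table: ages %d-%d\n", x$life_table$age[1L],
              attr(x$life_table, "max_age")))
  invisible(x)
}
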