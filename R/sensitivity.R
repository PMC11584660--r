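# Registry of the parameters varied in sensitivity analyses. `kind` decides
# the PSA distribution family: beta for quantities bounded in [0, 1]
# (utilities, transition probabilities, the HRQoL decline rate), gamma for
# quantities with a zero lower bound but no upper bound (unit costs, the
# blindness mortality relative risk). `where` says how the central value is
# read from / written into a scenario.
sa_registry <- function() {
  data.frame(
    name = c("u_stdr", "u_blind", "u_gain_cataract", "hrqol_decline",
             "p_blind_untreated", "p_blind_treated", "rr_blind",
             "screening_cost_per_person", "laser_package", "cataract_surgery"),
    kind = c("beta", "beta", "beta", "beta", "beta", "beta", "gamma",
             "gamma", "gamma", "gamma"),
    where = c(rep("params", 7L), "derived", "unit_costs", "unit_costs"),
    stringsAsFactors = FALSE
  )
}

#' Central values of the sensitivity-analysis parameters
#'
#' @param scenario a `cea_scenario`.
#' @return Named numeric vector of central values for every parameter in the
#'   sensitivity registry (utilities, transition probabilities, HRQoL
#'   decline, blindness mortality relative risk, screening cost per person,
#'   laser and cataract unit costs).
#' @export
central_values <- function(scenario) {
  reg <- sa_registry()
  vapply(seq_len(nrow(reg)), function(i) {
    nm <- reg$name[i]
    switch(reg$where[i],
           params = scenario$params[[nm]],
           unit_costs = scenario$unit_costs[[nm]],
           derived = screening_cost_per_patient(scenario$unit_costs,
                                                scenario$counts$n_screened))
  }, numeric(1L), USE.NAMES = FALSE) |> stats::setNames(reg$name)
}

# scenario with parameter overrides applied; `screening_cost_per_person`
# replaces the itemised screening stage with a flat per-person cost
apply_overrides <- function(scenario, overrides) {
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (nm == "screening_cost_per_person") {
      scenario$screening_cost_override <- v
    } else if (nm %in% names(scenario$params)) {
      scenario$params[[nm]] <- v
    } else if (nm %in% names(scenario$unit_costs)) {
      scenario$unit_costs[[nm]] <- v
    } else {
      stop(sprintf("unknown sensitivity parameter `%s`", nm), call. = FALSE)
    }
  }
  scenario
}

#' Evaluate a scenario end to end
#'
#' The deterministic pipeline behind the sensitivity analyses: Markov model
#' in both arms for the per-person QALY gains, cost ledger for the
#' programme total, then total cost, total QALYs and the ICER. Optional
#' overrides perturb individual parameters (see [central_values()] for the
#' recognised names).
#'
#' @param scenario a `cea_scenario`.
#' @param overrides named list of parameter values to override.
#' @return List with `total_cost`, `total_qalys`, `icer`, `gain_stdr`,
#'   `gain_cataract` and the `cost_ledger`.
#' @export
evaluate_scenario <- function(scenario, overrides = list()) {
  sc <- apply_overrides(scenario, overrides)
  fit <- stdr_markov(sc$params, sc$life_table)
  ledger <- build_cost_ledger(sc$unit_costs, sc$counts)
  tot <- cost_totals(ledger)
  total_cost <- tot$programme_total
  if (!is.null(sc$screening_cost_override)) {
    total_cost <- total_cost - tot$screening_total +
      sc$screening_cost_override * sc$counts$n_screened
  }
  qalys <- sc$counts$n_stdr_treated * fit$qaly_gain_stdr +
    sc$counts$n_cataract_treated * fit$qaly_gain_cataract
  list(total_cost = total_cost,
       total_qalys = qalys,
       icer = as.numeric(icer(total_cost, qalys)),
       gain_stdr = fit$qaly_gain_stdr,
       gain_cataract = fit$qaly_gain_cataract,
       ledger = ledger)
}

#' One-way deterministic sensitivity-analysis specification
#'
#' @param rel_range half-width of the excursion relative to the central
#'   value; the default varies each parameter from 10\% below to 10\% above.
#' @param parameters character vector of parameter names (default: the full
#'   sensitivity registry).
#' @return A list of class `dsa_spec`.
#' @export
dsa_spec <- function(rel_range = 0.10, parameters = sa_registry()$name) {
  stopifnot(rel_range >= 0, all(parameters %in% sa_registry()$name))
  structure(list(rel_range = rel_range, parameters = parameters),
            class = "dsa_spec")
}

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' Varies each parameter in turn to `(1 - rel_range)` and `(1 + rel_range)`
#' times its central value, holding everything else central, and records
#' the ICER at each leg. Excursions that would push a probability or
#' utility outside \[0, 1\] are clipped to the boundary with a warning. A
#' failed evaluation flags that parameter with `NA` and the run continues.
#'
#' @param scenario a `cea_scenario`.
#' @param spec a [dsa_spec]; defaults to the scenario's.
#' @return An object of class `tornado`: data frame `parameter, central,
#'   low_value, high_value, low_icer, high_icer, span`, sorted by
#'   descending span, with attribute `central_icer`.
#' @export
one_way_dsa <- function(scenario, spec = scenario$dsa) {
  stopifnot(inherits(spec, "dsa_spec"))
  reg <- sa_registry()
  centrals <- central_values(scenario)
  central_icer <- evaluate_scenario(scenario)$icer
  rows <- lapply(spec$parameters, function(nm) {
    kind <- reg$kind[reg$name == nm]
    cv <- centrals[[nm]]
    legs <- cv * c(1 - spec$rel_range, 1 + spec$rel_range)
    if (kind == "beta" && (legs[1L] < 0 || legs[2L] > 1)) {
      warning(sprintf("excursion of `%s` clipped to [0, 1]", nm), call. = FALSE)
      legs <- pmin(pmax(legs, 0), 1)
    }
    ics <- vapply(legs, function(v) {
      tryCatch(evaluate_scenario(scenario, stats::setNames(list(v), nm))$icer,
               error = function(e) {
                 warning(sprintf("evaluation failed for `%s` = %g: %s",
                                 nm, v, conditionMessage(e)), call. = FALSE)
                 NA_real_
               })
    }, numeric(1L))
    data.frame(parameter = nm, central = cv,
               low_value = legs[1L], high_value = legs[2L],
               low_icer = ics[1L], high_icer = ics[2L],
               span = abs(ics[2L] - ics[1L]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, central_icer = central_icer,
            class = c("tornado", "data.frame"))
}

#' Plot a tornado diagram
#'
#' @param x a `tornado` from [one_way_dsa()].
#' @param ... unused.
#' @export
plot.tornado <- function(x, ...) {
  d <- x[nrow(x):1L, ]
  ctr <- attr(x, "central_icer")
  old <- graphics::par(mar = c(4, 11, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(NA, xlim = range(c(d$low_icer, d$high_icer, ctr), na.rm = TRUE),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "ICER (INR per QALY)", ylab = "",
                 main = "One-way sensitivity analysis")
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1, cex.axis = 0.8)
  graphics::segments(d$low_icer, seq_len(nrow(d)), d$high_icer, seq_len(nrow(d)),
                     lwd = 8, col = "steelblue")
  graphics::abline(v = ctr, lty = 2)
  invisible(x)
}

#' Fit a gamma distribution by moment matching
#'
#' Shape \eqn{(\mu/\sigma)^2} and scale \eqn{\sigma^2/\mu} reproduce the
#' requested mean and standard deviation exactly. Under the SD = 25\%-of-mean
#' rule the shape is always 16, whatever the mean.
#'
#' @param mean target mean (> 0).
#' @param sd target standard deviation (> 0).
#' @return List with `shape` and `scale`.
#' @examples
#' fit_gamma_moments(12000, 3000)  # shape 16, scale 750
#' @export
fit_gamma_moments <- function(mean, sd) {
  if (!is.numeric(mean) || mean <= 0) stop("`mean` must be positive", call. = FALSE)
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be positive", call. = FALSE)
  list(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Fit a beta distribution by moment matching
#'
#' \eqn{\nu = \mu(1-\mu)/\sigma^2 - 1}, \eqn{\alpha = \mu\nu},
#' \eqn{\beta = (1-\mu)\nu}. Requires \eqn{\sigma^2 < \mu(1-\mu)}; a
#' violation is rejected naming the parameter so over-dispersed inputs are
#' caught before sampling.
#'
#' @param mean target mean in (0, 1).
#' @param sd target standard deviation (> 0).
#' @param name parameter name used in error messages.
#' @return List with `alpha` and `beta`.
#' @examples
#' fit_beta_moments(0.70, 0.175)  # alpha ~ 4.10, beta ~ 1.76
#' @export
fit_beta_moments <- function(mean, sd, name = "parameter") {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1) {
    stop(sprintf("`%s`: mean must lie strictly in (0, 1)", name), call. = FALSE)
  }
  if (!is.numeric(sd) || sd <= 0) {
    stop(sprintf("`%s`: sd must be positive", name), call. = FALSE)
  }
  if (sd^2 >= mean * (1 - mean)) {
    stop(sprintf("`%s`: sd^2 = %g violates the beta variance bound mean(1-mean) = %g",
                 name, sd^2, mean * (1 - mean)), call. = FALSE)
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Probabilistic sensitivity-analysis specification
#'
#' @param n_iterations number of Monte Carlo iterations.
#' @param sd_frac standard deviation of each sampled parameter as a fraction
#'   of its central value (the SD = 25\% rule by default).
#' @param wtp_grid willingness-to-pay grid (INR per QALY) for the CEAC; must
#'   include the headline threshold of 144,000.
#' @param seed root seed; each parameter draws from its own child stream so
#'   adding a parameter does not perturb the others' draws.
#' @param enforce_ordering if `TRUE`, iterations where the drawn treated
#'   transition probability exceeds the drawn untreated one are resampled
#'   (the count is recorded on the result). Off by default: the
#'   distributions are independent and no ordering is imposed.
#' @return A list of class `psa_spec`.
#' @export
psa_spec <- function(n_iterations = 10000,
                     sd_frac = 0.25,
                     wtp_grid = sort(unique(c(seq(0, 500000, by = 20000), 144000))),
                     seed = 1L,
                     enforce_ordering = FALSE) {
  stopifnot(n_iterations >= 1, sd_frac >= 0, all(wtp_grid >= 0))
  structure(list(n_iterations = as.integer(n_iterations), sd_frac = sd_frac,
                 wtp_grid = wtp_grid, seed = as.integer(seed),
                 enforce_ordering = isTRUE(enforce_ordering)),
            class = "psa_spec")
}

# n draws of one parameter from its child stream; degenerate sd -> constant
sample_parameter <- function(central, kind, sd_frac, n, seed, name) {
  set.seed(seed)
  sd <- sd_frac * central
  if (sd == 0) return(rep(central, n))
  x <- if (kind == "gamma") {
    g <- fit_gamma_moments(central, sd)
    stats::rgamma(n, shape = g$shape, scale = g$scale)
  } else {
    b <- fit_beta_moments(central, sd, name)
    stats::rbeta(n, b$alpha, b$beta)
  }
  # resample the (theoretically impossible) invalid draws rather than crash
  lo <- 0; hi <- if (kind == "beta") 1 else Inf
  bad <- which(!is.finite(x) | x < lo | x > hi)
  tries <- 0L
  while (length(bad) && tries < 100L) {
    x[bad] <- if (kind == "gamma") {
      g <- fit_gamma_moments(central, sd)
      stats::rgamma(length(bad), shape = g$shape, scale = g$scale)
    } else {
      b <- fit_beta_moments(central, sd, name)
      stats::rbeta(length(bad), b$alpha, b$beta)
    }
    bad <- which(!is.finite(x) | x < lo | x > hi)
    tries <- tries + 1L
  }
  x
}

# vectorised pipeline evaluation across iterations: cohort propagation with
# per-iteration parameter vectors, then costs and the ICER. Must agree with
# evaluate_scenario() at the central values (enforced by tests).
psa_evaluate <- function(samples, scenario) {
  p <- scenario$params
  lt <- scenario$life_table
  counts <- scenario$counts
  uc <- scenario$unit_costs
  n <- nrow(samples)
  max_age <- attr(lt, "max_age")
  H <- if (is.null(p$horizon)) max_age - p$start_age else as.integer(p$horizon)
  ages <- p$start_age + seq_len(H) - 1L
  qx <- lt$qx[match(ages, lt$age)]
  disc <- (1 + p$discount_rate)^(-seq_len(H))

  rr_b <- if (p$blind_uplift_combined) p$rr_diabetes * samples$rr_blind
          else samples$rr_blind
  os_u <- rep(1, n); ob_u <- numeric(n); q_u <- numeric(n)
  os_t <- rep(1, n); ob_t <- numeric(n); q_t <- numeric(n)
  for (t in seq_len(H)) {
    pd_s <- uplift_q(qx[t], p$rr_diabetes, p$uplift_scale)
    pd_b <- uplift_q(qx[t], rr_b, p$uplift_scale)
    pb_u <- samples$p_blind_untreated * (1 - pd_s)
    pb_t <- samples$p_blind_treated * (1 - pd_s)
    new_os_u <- os_u * (1 - pd_s - pb_u)
    ob_u <- os_u * pb_u + ob_u * (1 - pd_b)
    os_u <- new_os_u
    new_os_t <- os_t * (1 - pd_s - pb_t)
    ob_t <- os_t * pb_t + ob_t * (1 - pd_b)
    os_t <- new_os_t
    q_u <- q_u + (os_u * samples$u_stdr + ob_u * samples$u_blind) * disc[t]
    q_t <- q_t + (os_t * samples$u_stdr + ob_t * samples$u_blind) * disc[t]
  }
  gain_stdr <- q_t - q_u

  S <- cumprod(1 - uplift_q(qx, p$rr_diabetes, p$uplift_scale))
  w <- S * disc
  damp <- exp(outer(seq_len(H), log1p(-samples$hrqol_decline)))  # H x n
  gain_cat <- samples$u_gain_cataract * as.numeric(crossprod(damp, w))

  exam_total <- examination_cost_per_patient(uc) * counts$n_examined
  laser_total <- counts$n_stdr_treated *
    (samples$laser_package * (1 + counts$bilateral_fraction) +
       3 * uc$attendance_societal)
  cataract_total <- counts$n_cataract_treated *
    (samples$cataract_surgery + uc$attendance_societal)
  total_cost <- samples$screening_cost_per_person * counts$n_screened +
    exam_total + laser_total + cataract_total
  total_qalys <- counts$n_stdr_treated * gain_stdr +
    counts$n_cataract_treated * gain_cat
  list(total_cost = total_cost, total_qalys = total_qalys,
       icer = ifelse(total_qalys == 0, NA_real_, total_cost / total_qalys))
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws every sensitivity parameter independently from its moment-matched
#' distribution (gamma for unit costs and the blindness mortality relative
#' risk, beta for utilities and transition probabilities, SD equal to
#' `sd_frac` of the central value), re-evaluates the whole model and cost
#' ledger per iteration, and records the resulting (cost, QALY, ICER)
#' triples. Cascade counts stay fixed. One root seed spawns per-parameter
#' child streams, so results are reproducible and adding a parameter does
#' not perturb existing draws.
#'
#' @param scenario a `cea_scenario`.
#' @param spec a [psa_spec]; defaults to the scenario's.
#' @return An object of class `psa_draws`: data frame with one row per
#'   iteration (sampled parameters plus `total_cost`, `total_qalys`,
#'   `icer`), with attributes `spec` and `central` (the deterministic
#'   central-value evaluation).
#' @export
run_psa <- function(scenario, spec = scenario$psa) {
  stopifnot(inherits(spec, "psa_spec"))
  reg <- sa_registry()
  centrals <- central_values(scenario)
  samples <- as.data.frame(lapply(seq_len(nrow(reg)), function(k) {
    sample_parameter(centrals[[reg$name[k]]], reg$kind[k], spec$sd_frac,
                     spec$n_iterations, seed = spec$seed + k, name = reg$name[k])
  }))
  names(samples) <- reg$name
  n_resampled <- 0L
  if (spec$enforce_ordering) {
    set.seed(spec$seed + nrow(reg) + 1L)
    bad <- which(samples$p_blind_treated > samples$p_blind_untreated)
    n_resampled <- length(bad)
    bu <- fit_beta_moments(centrals[["p_blind_untreated"]],
                           spec$sd_frac * centrals[["p_blind_untreated"]],
                           "p_blind_untreated")
    bt <- fit_beta_moments(centrals[["p_blind_treated"]],
                           spec$sd_frac * centrals[["p_blind_treated"]],
                           "p_blind_treated")
    tries <- 0L
    while (length(bad) && tries < 1000L) {
      samples$p_blind_untreated[bad] <- stats::rbeta(length(bad), bu$alpha, bu$beta)
      samples$p_blind_treated[bad] <- stats::rbeta(length(bad), bt$alpha, bt$beta)
      bad <- which(samples$p_blind_treated > samples$p_blind_untreated)
      tries <- tries + 1L
    }
  }
  res <- psa_evaluate(samples, scenario)
  out <- cbind(samples,
               total_cost = res$total_cost,
               total_qalys = res$total_qalys,
               icer = res$icer)
  structure(out, spec = spec, central = evaluate_scenario(scenario),
            n_resampled = n_resampled,
            class = c("psa_draws", "data.frame"))
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA iterations with
#' positive net monetary benefit (\eqn{wtp \times QALYs - cost > 0}). The
#' curve is monotone non-decreasing in wtp and bounded in \[0, 1\].
#'
#' @param draws a `psa_draws` from [run_psa()].
#' @param wtp_grid willingness-to-pay grid; defaults to the one in the
#'   draws' PSA specification.
#' @return An object of class `ceac`: data frame `wtp, probability`.
#' @export
ceac <- function(draws, wtp_grid = attr(draws, "spec")$wtp_grid) {
  stopifnot(inherits(draws, "psa_draws"), nrow(draws) > 0)
  prob <- vapply(wtp_grid, function(w) {
    mean(net_monetary_benefit(w, draws$total_cost, draws$total_qalys) > 0)
  }, numeric(1L))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            n_iterations = nrow(draws),
            class = c("ceac", "data.frame"))
}

#' Probability cost-effective at one threshold, with Monte-Carlo SE
#'
#' @param draws a `psa_draws`.
#' @param wtp willingness to pay per QALY (default the headline 144,000).
#' @return Named list `probability`, `se` (binomial standard error), `n`.
#' @export
prob_cost_effective <- function(draws, wtp = 144000) {
  stopifnot(inherits(draws, "psa_draws"))
  p <- mean(net_monetary_benefit(wtp, draws$total_cost, draws$total_qalys) > 0)
  n <- nrow(draws)
  list(probability = p, se = sqrt(p * (1 - p) / n), n = n)
}

#' @export
plot.ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$probability, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "willingness to pay (INR per QALY)",
                 ylab = "probability cost-effective",
                 main = "Cost-effectiveness acceptability curve", ...)
  graphics::abline(v = 144000, lty = 2, col = "grey50")
  invisible(x)
}

#' Plot the PSA cost-QALY scatter
#'
#' @param x a `psa_draws`.
#' @param wtp willingness-to-pay line to overlay, INR per QALY.
#' @param ... passed to `plot`.
#' @export
plot.psa_draws <- function(x, wtp = 144000, ...) {
  graphics::plot(x$total_qalys, x$total_cost / 1e6, pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("steelblue", 0.4),
                 xlab = "total QALYs gained", ylab = "total cost (INR million)",
                 main = "PSA cost-effectiveness plane", ...)
  graphics::abline(0, wtp / 1e6, lty = 2)
  invisible(x)
}
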