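#' Fit the STDR progression model on a life table
#'
#' The central model object of the package. Runs the three-state Markov
#' cohort model in both arms (with and without laser photocoagulation),
#' computes remaining life expectancy and discounted lifetime QALYs in each
#' arm, the per-person QALY gain from treatment, and the per-person QALY
#' gain from cataract surgery under the same mortality assumptions.
#'
#' @param params a [model_params]; defaults to the central estimates.
#' @param lt a [life_table] with general-population mortality covering
#'   `params$start_age` up to the model horizon.
#' @return An object of class `stdr_markov` with components
#'   \describe{
#'     \item{params}{the model parameters}
#'     \item{trace_treated, trace_untreated}{`cohort_trace` matrices}
#'     \item{le_treated, le_untreated}{remaining life expectancy (years)}
#'     \item{qalys_treated, qalys_untreated}{discounted lifetime QALYs}
#'     \item{qaly_gain_stdr}{per-person gain from laser treatment}
#'     \item{qaly_gain_cataract}{per-person gain from cataract surgery}
#'   }
#' @examples
#' lt <- synth_life_table()
#' fit <- stdr_markov(model_params(), lt)
#' fit
#' summary(fit)
#' @export
stdr_markov <- function(params = model_params(), lt) {
  stopifnot(inherits(params, "model_params"), inherits(lt, "life_table"))
  tr_t <- run_cohort(params, lt, treated = TRUE)
  tr_u <- run_cohort(params, lt, treated = FALSE)
  q_t <- discounted_qalys(tr_t, params)
  q_u <- discounted_qalys(tr_u, params)
  structure(list(
    params = params,
    life_table = lt,
    trace_treated = tr_t,
    trace_untreated = tr_u,
    le_treated = life_expectancy(tr_t),
    le_untreated = life_expectancy(tr_u),
    qalys_treated = q_t,
    qalys_untreated = q_u,
    qaly_gain_stdr = q_t - q_u,
    qaly_gain_cataract = cataract_qaly_gain(params, lt)
  ), class = "stdr_markov")
}

#' @export
print.stdr_markov <- function(x, digits = 4, ...) {
  cat("Three-state STDR progression model (STDR / blind / dead)\n")
  cat(sprintf("  cohort entry age %d, %d annual cycles, discount rate %.1f%%\n",
              x$params$start_age, nrow(x$trace_treated) - 1L,
              100 * x$params$discount_rate))
  cat(sprintf("  life expectancy: %.*f yr untreated, %.*f yr treated\n",
              digits, x$le_untreated, digits, x$le_treated))
  cat(sprintf("  QALY gain per person: %.*f (laser), %.*f (cataract surgery)\n",
              digits, x$qaly_gain_stdr, digits, x$qaly_gain_cataract))
  invisible(x)
}

#' @export
summary.stdr_markov <- function(object, ...) {
  s <- data.frame(
    arm = c("untreated", "treated"),
    life_expectancy = c(object$le_untreated, object$le_treated),
    discounted_qalys = c(object$qalys_untreated, object$qalys_treated),
    final_blind = c(object$trace_untreated[nrow(object$trace_untreated), "occ_blind"],
                    object$trace_treated[nrow(object$trace_treated), "occ_blind"]),
    years_blind = c(sum(object$trace_untreated[-1L, "occ_blind"]),
                    sum(object$trace_treated[-1L, "occ_blind"]))
  )
  structure(list(arms = s,
                 qaly_gain_stdr = object$qaly_gain_stdr,
                 qaly_gain_cataract = object$qaly_gain_cataract,
                 params = object$params),
            class = "summary.stdr_markov")
}

#' @export
print.summary.stdr_markov <- function(x, digits = 4, ...) {
  cat("STDR Markov cohort model summary\n\nPer-arm results:\n")
  print(format(x$arms, digits = digits), row.names = FALSE)
  cat(sprintf("\nQALY gain per person treated: laser %.*f, cataract %.*f\n",
              digits, x$qaly_gain_stdr, digits, x$qaly_gain_cataract))
  invisible(x)
}

#' @export
coef.stdr_markov <- function(object, ...) {
  p <- object$params
  c(p_blind_untreated = p$p_blind_untreated, p_blind_treated = p$p_blind_treated,
    rr_diabetes = p$rr_diabetes, rr_blind = p$rr_blind,
    u_stdr = p$u_stdr, u_blind = p$u_blind,
    u_gain_cataract = p$u_gain_cataract, hrqol_decline = p$hrqol_decline,
    discount_rate = p$discount_rate, start_age = p$start_age)
}

#' Plot state occupancy over time for both treatment arms
#'
#' @param x a fitted [stdr_markov] object.
#' @param ... passed to `matplot`.
#' @export
plot.stdr_markov <- function(x, ...) {
  ages <- attr(x$trace_untreated, "age")
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (arm in c("untreated", "treated")) {
    tr <- if (arm == "treated") x$trace_treated else x$trace_untreated
    graphics::matplot(ages, tr, type = "l", lty = 1, lwd = 2,
                      col = c("darkorange", "firebrick", "grey40"),
                      xlab = "age (years)", ylab = "occupancy", main = arm, ...)
    graphics::legend("right", legend = c("STDR", "blind", "dead"), lwd = 2,
                     col = c("darkorange", "firebrick", "grey40"), bty = "n")
  }
  invisible(x)
}

#' Microsimulate individual patient trajectories from the fitted model
#'
#' Draws `nsim` seeded individual-level trajectories through the same
#' transition probabilities as the cohort trace. The empirical state
#' distribution converges on the cohort trace as `nsim` grows; useful for
#' visualising Monte-Carlo noise and for validation.
#'
#' @param object a fitted [stdr_markov].
#' @param nsim number of simulated individuals.
#' @param seed integer seed.
#' @param treated which arm to simulate.
#' @param ... unused.
#' @return Integer matrix `nsim x (horizon+1)` of state codes
#'   (1 = STDR, 2 = blind, 3 = dead), one row per individual.
#' @export
simulate.stdr_markov <- function(object, nsim = 1000, seed = 1L,
                                 treated = FALSE, ...) {
  set.seed(seed)
  params <- object$params
  lt <- object$life_table
  H <- nrow(object$trace_untreated) - 1L
  states <- matrix(1L, nrow = nsim, ncol = H + 1L)
  for (t in seq_len(H)) {
    age <- params$start_age + t - 1L
    rs <- transition_row(params, lt, age, "stdr", treated)
    rb <- transition_row(params, lt, age, "blind", treated)
    cur <- states[, t]
    u <- stats::runif(nsim)
    nxt <- cur
    is_s <- cur == 1L
    nxt[is_s & u < rs[["dead"]]] <- 3L
    nxt[is_s & u >= rs[["dead"]] & u < rs[["dead"]] + rs[["blind"]]] <- 2L
    is_b <- cur == 2L
    nxt[is_b & u < rb[["dead"]]] <- 3L
    nxt[cur == 3L] <- 3L
    states[, t + 1L] <- nxt
  }
  states
}
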