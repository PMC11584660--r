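#' Markov model parameters for STDR progression
#'
#' Bundles every parameter of the three-state (STDR, blind, dead)
#' annual-cycle cohort model and of the lifetime QALY computations. Defaults
#' are the central estimates used throughout the package: an annual
#' STDR-to-blindness transition probability of 9\% untreated and 2\% under
#' laser photocoagulation, mortality relative risks of 1.9 (diabetes) and
#' 2.34 (blindness) applied to the general-population annual death
#' probability, health-state utilities of 0.70 (STDR) and 0.55 (blind), an
#' annual HRQoL gain of 0.20 from cataract surgery declining by 0.07\% per
#' year of age, a 3\% annual discount rate and cohort entry at age 59.
#'
#' @param p_blind_untreated annual STDR to blindness transition probability
#'   without treatment.
#' @param p_blind_treated the same probability under laser treatment.
#' @param rr_diabetes mortality relative risk in the STDR state versus the
#'   general population.
#' @param rr_blind mortality relative risk in the blind state versus the
#'   general population. By default this replaces (not multiplies) the
#'   diabetes uplift; see `blind_uplift_combined`.
#' @param blind_uplift_combined if `TRUE`, the blind-state mortality uplift
#'   is `rr_diabetes * rr_blind` rather than `rr_blind` alone.
#' @param u_stdr,u_blind health-state utilities (EuroQoL scale, 1 = full
#'   health, 0 = death).
#' @param u_gain_cataract annual utility gain from cataract surgery.
#' @param hrqol_decline annual proportional decline of HRQoL with age
#'   (0.0007 = 0.07\% per year), applied to the cataract gain.
#' @param discount_rate annual discount rate for future benefits.
#' @param start_age cohort entry age in years.
#' @param horizon number of annual cycles; `NULL` (default) runs to the
#'   life-table terminal age, i.e. lifetime.
#' @param half_cycle if `TRUE`, life expectancy and QALYs use the half-cycle
#'   correction (average of start- and end-of-cycle occupancy); the default
#'   counts occupancy at end of cycle.
#' @param uplift_scale `"probability"` or `"hazard"`; see [apply_uplift()].
#' @param stdr_utility_decline if `TRUE`, the `hrqol_decline` factor is also
#'   applied to the STDR/blind utilities in [discounted_qalys()]; by default
#'   the decline applies only to the cataract gain.
#' @return A list of class `model_params`.
#' @export
model_params <- function(p_blind_untreated = 0.09,
                         p_blind_treated = 0.02,
                         rr_diabetes = 1.9,
                         rr_blind = 2.34,
                         blind_uplift_combined = FALSE,
                         u_stdr = 0.70,
                         u_blind = 0.55,
                         u_gain_cataract = 0.20,
                         hrqol_decline = 0.0007,
                         discount_rate = 0.03,
                         start_age = 59L,
                         horizon = NULL,
                         half_cycle = FALSE,
                         uplift_scale = c("probability", "hazard"),
                         stdr_utility_decline = FALSE) {
  p <- list(p_blind_untreated = p_blind_untreated,
            p_blind_treated = p_blind_treated,
            rr_diabetes = rr_diabetes, rr_blind = rr_blind,
            blind_uplift_combined = isTRUE(blind_uplift_combined),
            u_stdr = u_stdr, u_blind = u_blind,
            u_gain_cataract = u_gain_cataract,
            hrqol_decline = hrqol_decline,
            discount_rate = discount_rate,
            start_age = as.integer(start_age), horizon = horizon,
            half_cycle = isTRUE(half_cycle),
            uplift_scale = match.arg(uplift_scale),
            stdr_utility_decline = isTRUE(stdr_utility_decline))
  for (nm in c("p_blind_untreated", "p_blind_treated", "u_stdr", "u_blind",
               "u_gain_cataract", "hrqol_decline")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a probability/utility in [0, 1]", nm), call. = FALSE)
    }
  }
  for (nm in c("rr_diabetes", "rr_blind", "discount_rate")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) || p[[nm]] < 0) {
      stop(sprintf("`%s` must be a single non-negative number", nm), call. = FALSE)
    }
  }
  if (!is.null(horizon) && (!is.numeric(horizon) || horizon < 1)) {
    stop("`horizon` must be NULL or >= 1", call. = FALSE)
  }
  class(p) <- "model_params"
  p
}

# uplifted annual death probability on the chosen scale, capped at 1
uplift_q <- function(q, rr, scale) {
  if (scale == "hazard") 1 - (1 - q)^rr else pmin(rr * q, 1)
}

# mortality relative risk applying in each living state
state_rr <- function(params, state) {
  if (state == "blind") {
    if (params$blind_uplift_combined) params$rr_diabetes * params$rr_blind
    else params$rr_blind
  } else {
    params$rr_diabetes
  }
}

#' One-cycle transition probabilities from a living state
#'
#' Within a cycle, death acts first: the state's uplifted death probability
#' is taken off the top, and progression from STDR to blindness applies to
#' the survivors. This ordering keeps every row summing to exactly 1 without
#' renormalisation. The blind state only stays or dies.
#'
#' @param params a [model_params].
#' @param lt a [life_table] (general-population, un-uplifted).
#' @param age current age in years; must be within the table.
#' @param state `"stdr"` or `"blind"`.
#' @param treated logical; use the treated transition probability?
#' @return Named numeric vector `c(stdr, blind, dead)` summing to 1.
#' @examples
#' lt <- life_table(55:70, c(rep(0.02, 15), 1))
#' transition_row(model_params(), lt, age = 59, state = "stdr", treated = FALSE)
#' @export
transition_row <- function(params, lt, age, state = c("stdr", "blind"),
                           treated = FALSE) {
  state <- match.arg(state)
  q <- qx_at(lt, age)
  p_dead <- uplift_q(q, state_rr(params, state), params$uplift_scale)
  if (state == "blind") {
    out <- c(stdr = 0, blind = 1 - p_dead, dead = p_dead)
  } else {
    p_prog <- if (isTRUE(treated)) params$p_blind_treated else params$p_blind_untreated
    p_blind <- p_prog * (1 - p_dead)
    out <- c(stdr = 1 - p_dead - p_blind, blind = p_blind, dead = p_dead)
  }
  out
}

#' Run the cohort model forward
#'
#' Deterministic propagation of state occupancy, one annual cycle at a time,
#' with ages advancing alongside cycles. Cycle `t` carries the cohort from
#' age `start_age + t - 1` to `start_age + t`. The whole cohort starts in
#' the STDR state; death is absorbing.
#'
#' @inheritParams transition_row
#' @return A `cohort_trace`: a numeric matrix with one row per cycle (0 to
#'   horizon) and columns `occ_stdr`, `occ_blind`, `occ_dead`, with
#'   attributes `cycle`, `age` and `params`.
#' @export
run_cohort <- function(params, lt, treated = FALSE) {
  stopifnot(inherits(params, "model_params"), inherits(lt, "life_table"))
  max_age <- attr(lt, "max_age")
  if (!params$start_age %in% lt$age) {
    stop(sprintf("start_age %d outside life-table range", params$start_age),
         call. = FALSE)
  }
  H <- if (is.null(params$horizon)) max_age - params$start_age
       else as.integer(params$horizon)
  if (params$start_age + H > max_age) {
    stop(sprintf("horizon %d exceeds life table: needs ages up to %d, table ends at %d",
                 H, params$start_age + H, max_age), call. = FALSE)
  }
  trace <- matrix(0, nrow = H + 1L, ncol = 3L,
                  dimnames = list(NULL, c("occ_stdr", "occ_blind", "occ_dead")))
  trace[1L, ] <- c(1, 0, 0)
  for (t in seq_len(H)) {
    age <- params$start_age + t - 1L
    rs <- transition_row(params, lt, age, "stdr", treated)
    rb <- transition_row(params, lt, age, "blind", treated)
    occ <- trace[t, ]
    nxt <- c(
      occ[1L] * rs[["stdr"]],
      occ[1L] * rs[["blind"]] + occ[2L] * rb[["blind"]],
      occ[1L] * rs[["dead"]] + occ[2L] * rb[["dead"]] + occ[3L]
    )
    # guard against accumulation roundoff nudging occupancies past [0, 1]
    trace[t + 1L, ] <- pmin(pmax(nxt, 0), 1)
  }
  structure(trace,
            cycle = 0:H,
            age = params$start_age + 0:H,
            params = params,
            treated = isTRUE(treated),
            class = c("cohort_trace", "matrix", "array"))
}

#' Export a cohort trace as a data frame
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @return Data frame with columns `cycle`, `age`, `occ_stdr`, `occ_blind`,
#'   `occ_dead`, suitable for `write.csv`.
#' @export
trace_as_df <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  data.frame(cycle = attr(trace, "cycle"), age = attr(trace, "age"),
             occ_stdr = trace[, "occ_stdr"], occ_blind = trace[, "occ_blind"],
             occ_dead = trace[, "occ_dead"])
}

# proportion alive per cycle, with optional half-cycle averaging; drops cycle 0
alive_weights <- function(trace, half_cycle) {
  alive <- trace[, "occ_stdr"] + trace[, "occ_blind"]
  n <- length(alive)
  if (half_cycle) (alive[-n] + alive[-1L]) / 2 else alive[-1L]
}

#' Remaining life expectancy from a cohort trace
#'
#' Sums the proportion alive at the end of each cycle (or the half-cycle
#' average when the trace was run with `half_cycle = TRUE`).
#'
#' @param trace a `cohort_trace`.
#' @return Life expectancy in years.
#' @export
life_expectancy <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  sum(alive_weights(trace, attr(trace, "params")$half_cycle))
}

#' Discounted QALYs from a cohort trace
#'
#' \deqn{QALY = \sum_{t=1}^{H} [occ_{STDR}(t) u_{STDR} + occ_{blind}(t)
#'   u_{blind}] (1+r)^{-t}}
#' Discounting starts at cycle 1, so the first year's benefit is discounted
#' once. If the parameters enable `stdr_utility_decline`, both utilities are
#' additionally damped by \eqn{(1 - \delta)^t}.
#'
#' @param trace a `cohort_trace`.
#' @param params a [model_params]; defaults to the parameters the trace was
#'   run with.
#' @return Discounted QALYs.
#' @export
discounted_qalys <- function(trace, params = attr(trace, "params")) {
  stopifnot(inherits(trace, "cohort_trace"))
  n <- nrow(trace)
  t <- seq_len(n - 1L)
  disc <- (1 + params$discount_rate)^(-t)
  if (params$stdr_utility_decline) disc <- disc * (1 - params$hrqol_decline)^t
  occ_s <- trace[, "occ_stdr"]
  occ_b <- trace[, "occ_blind"]
  if (params$half_cycle) {
    occ_s <- (occ_s[-n] + occ_s[-1L]) / 2
    occ_b <- (occ_b[-n] + occ_b[-1L]) / 2
  } else {
    occ_s <- occ_s[-1L]
    occ_b <- occ_b[-1L]
  }
  sum((occ_s * params$u_stdr + occ_b * params$u_blind) * disc)
}

#' Per-person discounted lifetime QALY gain from laser treatment of STDR
#'
#' Runs the cohort model with and without treatment and differences the
#' discounted QALYs. The gain is strictly positive whenever treatment lowers
#' the blindness transition probability and sight carries more utility than
#' blindness.
#'
#' @inheritParams run_cohort
#' @return QALYs gained per person treated.
#' @export
stdr_qaly_gain <- function(params, lt) {
  discounted_qalys(run_cohort(params, lt, treated = TRUE)) -
    discounted_qalys(run_cohort(params, lt, treated = FALSE))
}

# survival curve S(t), t = 1..H, under the diabetes-uplifted table (no
# blindness state): cycle t uses the death probability at age start_age+t-1
survival_uplifted <- function(params, lt) {
  max_age <- attr(lt, "max_age")
  H <- if (is.null(params$horizon)) max_age - params$start_age
       else as.integer(params$horizon)
  ages <- params$start_age + seq_len(H) - 1L
  q <- uplift_q(lt$qx[match(ages, lt$age)], params$rr_diabetes, params$uplift_scale)
  cumprod(1 - q)
}

#' Per-person discounted lifetime QALY gain from cataract surgery
#'
#' Cataract surgery is assumed not to change life expectancy; the benefit is
#' an annual utility gain enjoyed for the rest of life, declining slightly
#' with age:
#' \deqn{gain = \sum_{t=1}^{H} u_{gain} (1-\delta)^t S(t) (1+r)^{-t}}
#' where \eqn{S(t)} is survival under the diabetes-uplifted life table and
#' \eqn{\delta} is the annual HRQoL decline.
#'
#' @inheritParams run_cohort
#' @return QALYs gained per person treated.
#' @export
cataract_qaly_gain <- function(params, lt) {
  stopifnot(inherits(params, "model_params"), inherits(lt, "life_table"))
  S <- survival_uplifted(params, lt)
  t <- seq_along(S)
  if (params$half_cycle) S <- (c(1, S[-length(S)]) + S) / 2
  sum(params$u_gain_cataract * (1 - params$hrqol_decline)^t * S *
        (1 + params$discount_rate)^(-t))
}

#' @export
print.cohort_trace <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Cohort trace: %d cycles from age %d (%s arm)\n",
              nrow(x) - 1L, p$start_age,
              if (attr(x, "treated")) "treated" else "untreated"))
  cat(sprintf("  final occupancy: STDR %.4f, blind %.4f, dead %.4f\n",
              x[nrow(x), 1L], x[nrow(x), 2L], x[nrow(x), 3L]))
  invisible(x)
}
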