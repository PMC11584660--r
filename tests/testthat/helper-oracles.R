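# Independent oracles used to cross-check the cohort model. Deliberately
# written from the model description itself (not via the package's
# transition_row / run_cohort), so they share no code with the path they
# validate.

# life table with one constant annual death probability at every age
constant_life_table <- function(q, start_age = 59, horizon = 45) {
  ages <- start_age:(start_age + horizon)
  life_table(ages, c(rep(q, horizon), 1))
}

# individual-level microsimulation of the three-state model: per cycle each
# alive individual first faces the state's uplifted death probability, then
# survivors in the STDR state progress to blindness with the transition
# probability. Returns per-cycle state proportions (cycle 0..H) as a matrix
# with columns stdr, blind, dead.
oracle_microsim <- function(params, lt, n, seed, treated = FALSE) {
  set.seed(seed)
  H <- attr(lt, "max_age") - params$start_age
  ages <- params$start_age + seq_len(H) - 1L
  qx <- lt$qx[match(ages, lt$age)]
  pp <- if (treated) params$p_blind_treated else params$p_blind_untreated
  rr_b <- if (params$blind_uplift_combined) params$rr_diabetes * params$rr_blind
          else params$rr_blind
  state <- rep(1L, n)  # 1 = STDR, 2 = blind, 3 = dead
  prop <- matrix(0, nrow = H + 1L, ncol = 3L,
                 dimnames = list(NULL, c("stdr", "blind", "dead")))
  prop[1L, ] <- c(1, 0, 0)
  for (t in seq_len(H)) {
    pd_s <- min(params$rr_diabetes * qx[t], 1)
    pd_b <- min(rr_b * qx[t], 1)
    u_death <- stats::runif(n)
    u_prog <- stats::runif(n)
    died <- (state == 1L & u_death < pd_s) | (state == 2L & u_death < pd_b)
    progressed <- state == 1L & !died & u_prog < pp
    state[progressed] <- 2L
    state[died] <- 3L
    prop[t + 1L, ] <- tabulate(state, nbins = 3L) / n
  }
  prop
}

# discounted QALYs over H cycles by direct matrix algebra on the transient
# 2x2 transition matrix Q (states STDR, blind), for an age-constant death
# probability: sum_{t=1..H} delta^t x0' Q^t u
#   = x0' [ deltaQ (I - deltaQ)^{-1} (I - (deltaQ)^H) ] u
oracle_fundamental_qalys <- function(q, params, H) {
  pd_s <- min(params$rr_diabetes * q, 1)
  pd_b <- min(params$rr_blind * q, 1)
  pp <- params$p_blind_untreated
  Q <- matrix(c((1 - pd_s) * (1 - pp), pp * (1 - pd_s),
                0, 1 - pd_b), nrow = 2L, byrow = TRUE)
  dQ <- Q / (1 + params$discount_rate)
  dQ_H <- diag(2L)
  for (i in seq_len(H)) dQ_H <- dQ_H %*% dQ
  S <- dQ %*% solve(diag(2L) - dQ) %*% (diag(2L) - dQ_H)
  u <- c(params$u_stdr, params$u_blind)
  as.numeric(c(1, 0) %*% S %*% u)
}
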