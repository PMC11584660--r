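#' Unit costs of the screening programme
#'
#' Itemised unit costs, in Indian rupees (INR), for every stage of the
#' screening cascade: camera capital and training at the screening sites,
#' per-screen staff/administration/community-health-worker costs, eye
#' examination staff and societal costs (travel and opportunity cost of the
#' patient's and an attendant's time), and treatment packages. Defaults are
#' the 2019 Kerala pilot central estimates. Staff salary inputs are
#' collapsed into the per-screen (INR 70) and per-exam (INR 205) staff
#' costs; the minute inputs are retained so scenarios with user-supplied
#' wage rates can rebuild them.
#'
#' @param camera_price INR per retinal camera.
#' @param camera_life camera lifetime in years (annuitization horizon).
#' @param n_cameras number of cameras purchased.
#' @param training_total total staff-training cost, INR.
#' @param nurse_minutes_screen,doctor_minutes_screen,grader_minutes staff
#'   minutes per patient screened (informational; see Details).
#' @param oncost_rate employer oncost uplift on salaries (proportion).
#' @param staff_cost_per_screen combined staff cost per patient screened, INR.
#' @param admin_per_screen administration cost per patient screened, INR.
#' @param asha_per_screen community health worker (ASHA) support per patient
#'   screened, INR.
#' @param exam_staff_admin staff plus administration cost per eye
#'   examination, INR.
#' @param travel_patient,travel_attendant travel cost per examination, INR.
#' @param opp_cost_patient,opp_cost_attendant opportunity cost of time per
#'   examination, INR.
#' @param laser_package laser photocoagulation package per eye treated
#'   (three attendances), INR.
#' @param attendance_societal societal cost (travel plus opportunity cost)
#'   per secondary-care attendance, INR.
#' @param cataract_surgery cataract surgery cost per patient, INR.
#' @param annuity_rate annual discount rate used to annuitize capital.
#' @return A list of class `unit_costs`.
#' @export
unit_costs <- function(camera_price = 300000,
                       camera_life = 5,
                       n_cameras = 16,
                       training_total = 560000,
                       nurse_minutes_screen = 12,
                       doctor_minutes_screen = 1,
                       grader_minutes = 5,
                       oncost_rate = 0.10,
                       staff_cost_per_screen = 70,
                       admin_per_screen = 15,
                       asha_per_screen = 15,
                       exam_staff_admin = 205,
                       travel_patient = 350,
                       travel_attendant = 350,
                       opp_cost_patient = 100,
                       opp_cost_attendant = 150,
                       laser_package = 12000,
                       attendance_societal = 950,
                       cataract_surgery = 18000,
                       annuity_rate = 0.03) {
  uc <- as.list(environment())
  for (nm in names(uc)) {
    if (!is.numeric(uc[[nm]]) || length(uc[[nm]]) != 1L || is.na(uc[[nm]]) ||
        uc[[nm]] < 0) {
      stop(sprintf("`%s` must be a single non-negative number", nm), call. = FALSE)
    }
  }
  class(uc) <- "unit_costs"
  uc
}

#' Screening-cascade counts
#'
#' Patient counts at each stage of the cascade: screened at primary care,
#' referred to secondary care, attending an eye examination, treated with
#' laser for STDR, and receiving cataract surgery. Defaults are the 2019
#' Kerala pilot counts. `bilateral_fraction` is the proportion of laser
#' patients treated in both eyes (adds one extra laser package each).
#'
#' @param n_screened,n_referred,n_examined,n_stdr_treated,n_cataract_treated
#'   non-negative integers respecting `n_screened >= n_referred >=
#'   n_examined`.
#' @param bilateral_fraction proportion in \[0, 1\].
#' @return A list of class `cascade_counts`.
#' @export
cascade_counts <- function(n_screened = 5307,
                           n_referred = 1662,
                           n_examined = 830,
                           n_stdr_treated = 345,
                           n_cataract_treated = 160,
                           bilateral_fraction = 0) {
  cc <- as.list(environment())
  for (nm in setdiff(names(cc), "bilateral_fraction")) {
    if (!is.numeric(cc[[nm]]) || length(cc[[nm]]) != 1L || is.na(cc[[nm]]) ||
        cc[[nm]] < 0) {
      stop(sprintf("`%s` must be a single non-negative count", nm), call. = FALSE)
    }
  }
  if (bilateral_fraction < 0 || bilateral_fraction > 1) {
    stop("`bilateral_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (n_screened < n_referred || n_referred < n_examined) {
    stop("cascade ordering violated: need n_screened >= n_referred >= n_examined",
         call. = FALSE)
  }
  class(cc) <- "cascade_counts"
  cc
}

#' Annuitize a capital outlay
#'
#' Converts a capital cost into the equivalent constant annual cost over the
#' asset lifetime using the annuity-immediate factor
#' \eqn{capital \times r / (1 - (1+r)^{-L})}. At `rate = 0` this degenerates
#' to straight-line `capital / lifetime`.
#'
#' @param capital capital cost, INR (>= 0).
#' @param lifetime asset lifetime in years (>= 1).
#' @param rate annual discount rate.
#' @return Annual cost, INR per year.
#' @examples
#' annuitize(16 * 300000, 5, 0.03)  # ~ 1.05 million per year
#' @export
annuitize <- function(capital, lifetime, rate = 0.03) {
  if (!is.numeric(capital) || capital < 0) stop("`capital` must be >= 0", call. = FALSE)
  if (!is.numeric(lifetime) || lifetime < 1) stop("`lifetime` must be >= 1", call. = FALSE)
  if (rate == 0) return(capital / lifetime)
  capital * rate / (1 - (1 + rate)^(-lifetime))
}

#' Screening cost per patient
#'
#' Annuitized camera and training costs spread over the screened population,
#' plus per-screen staff, administration and ASHA support. The ledger keeps
#' full precision; rounding to a reporting granularity is a presentation
#' step (see [round_inr()]).
#'
#' @param uc a [unit_costs].
#' @param n_screened number of patients screened (> 0).
#' @return Cost per patient screened, INR, at full precision.
#' @export
screening_cost_per_patient <- function(uc, n_screened) {
  stopifnot(inherits(uc, "unit_costs"))
  if (n_screened <= 0) stop("`n_screened` must be positive", call. = FALSE)
  cameras <- annuitize(uc$camera_price * uc$n_cameras, uc$camera_life, uc$annuity_rate)
  cameras / n_screened + uc$training_total / n_screened +
    uc$staff_cost_per_screen + uc$admin_per_screen + uc$asha_per_screen
}

#' Eye-examination cost per patient
#'
#' Staff and administration plus the societal components: travel for the
#' patient and an attendant, and the opportunity cost of both persons' time.
#'
#' @param uc a [unit_costs].
#' @return Cost per patient examined, INR.
#' @export
examination_cost_per_patient <- function(uc) {
  stopifnot(inherits(uc, "unit_costs"))
  uc$exam_staff_admin + uc$travel_patient + uc$travel_attendant +
    uc$opp_cost_patient + uc$opp_cost_attendant
}

#' Treatment costs for the screened cohort
#'
#' Laser treatment costs the package price plus three secondary-care
#' attendances per patient; a `bilateral_fraction` of laser patients incurs
#' one extra package (health-care cost only, no extra attendances).
#' Cataract surgery costs the surgery price plus one attendance.
#'
#' @param uc a [unit_costs].
#' @param counts a [cascade_counts].
#' @return Named list with `laser_total` and `cataract_total`, INR.
#' @export
treatment_costs <- function(uc, counts) {
  stopifnot(inherits(uc, "unit_costs"), inherits(counts, "cascade_counts"))
  laser <- counts$n_stdr_treated * (uc$laser_package + 3 * uc$attendance_societal) +
    counts$bilateral_fraction * counts$n_stdr_treated * uc$laser_package
  cataract <- counts$n_cataract_treated * (uc$cataract_surgery + uc$attendance_societal)
  list(laser_total = laser, cataract_total = cataract)
}

#' Build the itemised programme cost ledger
#'
#' Assembles every cost line of the programme — screening, eye examinations,
#' laser treatment, cataract surgery — tagged by stage and payer
#' (health-system vs societal), with stage totals and the programme total.
#' Totals are exact sums of the lines; all arithmetic is at full precision.
#'
#' @param uc a [unit_costs].
#' @param counts a [cascade_counts].
#' @return An object of class `cost_ledger`: a data frame of lines
#'   (`stage`, `payer`, `item`, `amount_inr`) with attribute `totals`, a
#'   named list: `screening_total`, `examination_total`, `pathway_total`,
#'   `laser_total`, `cataract_total`, `programme_total`, `societal_total`,
#'   `health_system_total`, and `cost_per_person_treated`.
#' @examples
#' led <- build_cost_ledger(unit_costs(), cascade_counts())
#' cost_totals(led)$programme_total  # ~ 11.3 million INR
#' @export
build_cost_ledger <- function(uc, counts) {
  stopifnot(inherits(uc, "unit_costs"), inherits(counts, "cascade_counts"))
  n_s <- counts$n_screened
  n_e <- counts$n_examined
  tc <- treatment_costs(uc, counts)
  lines <- rbind(
    data.frame(stage = "screening", payer = "health-system",
               item = c("cameras (annuitized)", "staff training",
                        "screening staff", "administration", "ASHA support"),
               amount_inr = c(
                 annuitize(uc$camera_price * uc$n_cameras, uc$camera_life,
                           uc$annuity_rate),
                 uc$training_total,
                 uc$staff_cost_per_screen * n_s,
                 uc$admin_per_screen * n_s,
                 uc$asha_per_screen * n_s)),
    data.frame(stage = "examination",
               payer = c("health-system", rep("societal", 4L)),
               item = c("exam staff and administration", "patient travel",
                        "attendant travel", "patient opportunity cost",
                        "attendant opportunity cost"),
               amount_inr = c(uc$exam_staff_admin, uc$travel_patient,
                              uc$travel_attendant, uc$opp_cost_patient,
                              uc$opp_cost_attendant) * n_e),
    data.frame(stage = "laser", payer = c("health-system", "societal"),
               item = c("laser packages", "secondary-care attendances"),
               amount_inr = c(
                 counts$n_stdr_treated * uc$laser_package *
                   (1 + counts$bilateral_fraction),
                 counts$n_stdr_treated * 3 * uc$attendance_societal)),
    data.frame(stage = "cataract", payer = c("health-system", "societal"),
               item = c("cataract surgery", "secondary-care attendances"),
               amount_inr = c(counts$n_cataract_treated * uc$cataract_surgery,
                              counts$n_cataract_treated * uc$attendance_societal))
  )
  stage_sum <- function(s) sum(lines$amount_inr[lines$stage == s])
  totals <- list(
    screening_total = stage_sum("screening"),
    examination_total = stage_sum("examination"),
    laser_total = stage_sum("laser"),
    cataract_total = stage_sum("cataract")
  )
  totals$pathway_total <- totals$screening_total + totals$examination_total
  totals$programme_total <- totals$pathway_total + totals$laser_total +
    totals$cataract_total
  totals$societal_total <- sum(lines$amount_inr[lines$payer == "societal"])
  totals$health_system_total <- sum(lines$amount_inr[lines$payer == "health-system"])
  n_treated <- counts$n_stdr_treated + counts$n_cataract_treated
  totals$cost_per_person_treated <-
    if (n_treated > 0) totals$programme_total / n_treated else NA_real_
  structure(lines, totals = totals, counts = counts,
            class = c("cost_ledger", "data.frame"))
}

#' Extract ledger totals
#'
#' @param ledger a `cost_ledger` from [build_cost_ledger()].
#' @return The named list of stage and programme totals.
#' @export
cost_totals <- function(ledger) {
  stopifnot(inherits(ledger, "cost_ledger"))
  attr(ledger, "totals")
}

#' @export
print.cost_ledger <- function(x, ...) {
  tot <- attr(x, "totals")
  cat("Programme cost ledger (INR)\n")
  print.data.frame(transform(as.data.frame(x),
                             amount_inr = round(amount_inr)),
                   row.names = FALSE)
  cat(sprintf("\n  pathway (screening + examination): %s\n",
              format(round(tot$pathway_total), big.mark = ",")))
  cat(sprintf("  programme total: %s  (health-system %s, societal %s)\n",
              format(round(tot$programme_total), big.mark = ","),
              format(round(tot$health_system_total), big.mark = ","),
              format(round(tot$societal_total), big.mark = ",")))
  invisible(x)
}

#' Write ledger lines to CSV
#'
#' @param ledger a `cost_ledger`.
#' @param path output path; columns `stage,payer,item,amount_inr`.
#' @return `path`, invisibly.
#' @export
write_cost_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "cost_ledger"))
  utils::write.csv(as.data.frame(ledger), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive cascade counts from branch rates
#'
#' Computes each stage count as the rounded (half-to-even) product of its
#' parent count and the branch rate. Explicit counts supplied through
#' `override` take precedence over the computed values — programme reports
#' often print counts whose ratios do not reproduce them exactly — and each
#' overridden discrepancy is reported via `message()`.
#'
#' @param n_screened patients screened.
#' @param referral_rate proportion of screened referred to secondary care.
#' @param attendance_rate proportion of referred attending an examination.
#' @param stdr_diagnosed count diagnosed with STDR at examination.
#' @param treat_rate_stdr proportion of diagnosed treated with laser.
#' @param ungradable count with ungradable images.
#' @param cataract_rate proportion of ungradable receiving cataract surgery.
#' @param bilateral_fraction passed through to [cascade_counts()].
#' @param override named list of explicit counts (e.g.
#'   `list(n_referred = 1662)`) taking precedence over computed values.
#' @return A [cascade_counts].
#' @export
cascade_from_rates <- function(n_screened, referral_rate, attendance_rate,
                               stdr_diagnosed, treat_rate_stdr,
                               ungradable, cataract_rate,
                               bilateral_fraction = 0, override = list()) {
  rates <- c(referral_rate = referral_rate, attendance_rate = attendance_rate,
             treat_rate_stdr = treat_rate_stdr, cataract_rate = cataract_rate)
  bad <- rates < 0 | rates > 1
  if (any(bad)) {
    stop(sprintf("rate `%s` = %g outside [0, 1]",
                 names(rates)[bad][1L], rates[bad][1L]), call. = FALSE)
  }
  computed <- list(n_screened = n_screened)
  computed$n_referred <- round(n_screened * referral_rate)
  computed$n_examined <- round(computed$n_referred * attendance_rate)
  computed$n_stdr_treated <- round(stdr_diagnosed * treat_rate_stdr)
  computed$n_cataract_treated <- round(ungradable * cataract_rate)
  for (nm in names(override)) {
    if (!nm %in% names(computed)) next
    if (override[[nm]] != computed[[nm]]) {
      message(sprintf("cascade count `%s`: computed %d overridden to %d",
                      nm, as.integer(computed[[nm]]),
                      as.integer(override[[nm]])))
    }
    computed[[nm]] <- override[[nm]]
  }
  cascade_counts(n_screened = computed$n_screened,
                 n_referred = computed$n_referred,
                 n_examined = computed$n_examined,
                 n_stdr_treated = computed$n_stdr_treated,
                 n_cataract_treated = computed$n_cataract_treated,
                 bilateral_fraction = bilateral_fraction)
}

#' Round an amount to a reporting granularity
#'
#' Presentation-only helper: ledger arithmetic stays at full precision and
#' rounding happens when figures are reported (per-patient costs to the
#' nearest INR 5, stage totals to the nearest 0.1 million, and so on).
#'
#' @param x amount in INR.
#' @param nearest granularity, e.g. `5` or `1e5`.
#' @return `x` rounded to the nearest multiple of `nearest`.
#' @export
round_inr <- function(x, nearest = 5) round(x / nearest) * nearest
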