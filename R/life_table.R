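#' Construct a single-year life table
#'
#' A life table holds age-specific annual probabilities of death \eqn{q_x}
#' for the general population; it is the mortality basis of all survival and
#' Markov computations in the package. Ages must be contiguous single years
#' and the terminal age must carry \eqn{q_x = 1} so every cohort eventually
#' dies. If the supplied table ends below age 110 without a closing
#' \eqn{q_x = 1}, a terminal age is appended one year after the last age and
#' a warning is issued.
#'
#' @param age integer vector of exact ages in years, strictly increasing and
#'   contiguous (step 1).
#' @param qx numeric vector of annual death probabilities, same length as
#'   `age`, each in \[0, 1\].
#' @return An object of class `life_table`: a data frame with columns `age`
#'   and `qx` and attribute `max_age` (the terminal age, where `qx == 1`).
#' @examples
#' lt <- life_table(age = 40:90, qx = c(seq(0.005, 0.25, length.out = 50), 1))
#' lt <- life_table(age = 40:41, qx = c(0.005, 0.006))  # terminal age appended
#' @export
life_table <- function(age, qx) {
  if (length(age) != length(qx)) {
    stop("`age` and `qx` must have the same length", call. = FALSE)
  }
  if (length(age) < 1L) stop("life table must have at least one row", call. = FALSE)
  if (anyNA(age) || anyNA(qx)) stop("life table contains missing values", call. = FALSE)
  age <- as.integer(age)
  d <- diff(age)
  if (any(d <= 0L)) {
    bad <- which(d <= 0L)[1L] + 1L
    stop(sprintf("ages must be strictly increasing; violation at row %d (age %d)",
                 bad, age[bad]), call. = FALSE)
  }
  if (any(d != 1L)) {
    bad <- which(d != 1L)[1L] + 1L
    stop(sprintf("ages must be contiguous (step 1); gap before row %d (age %d)",
                 bad, age[bad]), call. = FALSE)
  }
  bad_q <- which(qx < 0 | qx > 1)
  if (length(bad_q)) {
    stop(sprintf("qx must lie in [0, 1]; row %d (age %d) has qx = %g",
                 bad_q[1L], age[bad_q[1L]], qx[bad_q[1L]]), call. = FALSE)
  }
  n <- length(age)
  if (qx[n] < 1) {
    if (age[n] < 110L) {
      warning(sprintf(
        "table ends at age %d without qx = 1; appending terminal age %d with qx = 1",
        age[n], age[n] + 1L), call. = FALSE)
      age <- c(age, age[n] + 1L)
      qx <- c(qx, 1)
      n <- n + 1L
    } else {
      stop(sprintf("terminal age %d must have qx = 1 (found %g)", age[n], qx[n]),
           call. = FALSE)
    }
  }
  out <- data.frame(age = age, qx = as.numeric(qx))
  attr(out, "max_age") <- age[n]
  class(out) <- c("life_table", "data.frame")
  out
}

#' Read a life table from CSV
#'
#' Two dialects are accepted. Single-year: header `age,qx`, one row per exact
#' age. Abridged: header `age_start,age_end,qx`, one row per age band; bands
#' are expanded to single years by repeating the band's `qx` at every age in
#' the band (the band value is preserved, no interpolation). The dialect is
#' detected from the header unless given explicitly.
#'
#' @param path path to a UTF-8 CSV file.
#' @param dialect `"auto"` (default, detect from header), `"single-year"` or
#'   `"abridged"`.
#' @return A validated [life_table].
#' @seealso [write_life_table()]
#' @export
read_life_table <- function(path, dialect = c("auto", "single-year", "abridged")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  has_band <- all(c("age_start", "age_end", "qx") %in% names(df))
  has_single <- all(c("age", "qx") %in% names(df))
  if (dialect == "auto") {
    dialect <- if (has_band) "abridged" else if (has_single) "single-year" else
      stop("unrecognised life-table header: need `age,qx` or `age_start,age_end,qx`",
           call. = FALSE)
  }
  if (dialect == "single-year") {
    if (!has_single) stop("single-year dialect requires columns `age` and `qx`", call. = FALSE)
    return(life_table(df$age, df$qx))
  }
  if (!has_band) stop("abridged dialect requires columns `age_start`, `age_end`, `qx`",
                      call. = FALSE)
  if (any(df$age_end < df$age_start)) {
    bad <- which(df$age_end < df$age_start)[1L]
    stop(sprintf("row %d: age_end (%d) below age_start (%d)",
                 bad, df$age_end[bad], df$age_start[bad]), call. = FALSE)
  }
  age <- unlist(mapply(seq, df$age_start, df$age_end, SIMPLIFY = FALSE))
  qx <- rep(df$qx, times = df$age_end - df$age_start + 1L)
  life_table(age, qx)
}

#' Write a life table to CSV
#'
#' Writes the single-year `age,qx` dialect; [read_life_table()] round-trips
#' it exactly.
#'
#' @param lt a [life_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(lt[, c("age", "qx")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply a relative-risk mortality uplift to a life table
#'
#' Models excess mortality in a subpopulation (e.g. people with diabetes, or
#' blind people with diabetes) as a multiplier on the general-population
#' annual death probability: \eqn{q'_x = \min(rr \times q_x, 1)}. The
#' probability scale is the default reading of a "mortality rate uplift"; an
#' alternative hazard-scale uplift \eqn{q'_x = 1 - (1 - q_x)^{rr}} is
#' available, which never needs capping.
#'
#' @param lt a [life_table].
#' @param relative_risk non-negative multiplier.
#' @param scale `"probability"` (default; multiply \eqn{q_x}, cap at 1) or
#'   `"hazard"` (multiply \eqn{-\log(1-q_x)}).
#' @return A [life_table] with uplifted `qx`; the terminal age keeps `qx = 1`.
#' @examples
#' lt <- life_table(55:70, c(rep(0.01, 15), 1))
#' apply_uplift(lt, 1.9)$qx[1]  # 0.019
#' @export
apply_uplift <- function(lt, relative_risk, scale = c("probability", "hazard")) {
  stopifnot(inherits(lt, "life_table"))
  scale <- match.arg(scale)
  if (!is.numeric(relative_risk) || length(relative_risk) != 1L ||
      is.na(relative_risk) || relative_risk < 0) {
    stop("`relative_risk` must be a single non-negative number", call. = FALSE)
  }
  qx <- if (scale == "probability") {
    pmin(relative_risk * lt$qx, 1)
  } else {
    1 - (1 - lt$qx)^relative_risk
  }
  qx[length(qx)] <- 1  # terminal age is absorbing regardless of uplift
  out <- data.frame(age = lt$age, qx = qx)
  attr(out, "max_age") <- attr(lt, "max_age")
  class(out) <- c("life_table", "data.frame")
  out
}

# qx at a single age; errors if the age is outside the table
qx_at <- function(lt, age) {
  i <- match(age, lt$age)
  if (is.na(i)) {
    stop(sprintf("age %s outside life-table range [%d, %d]",
                 format(age), lt$age[1L], attr(lt, "max_age")), call. = FALSE)
  }
  lt$qx[i]
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Single-year life table: ages %d-%d (terminal qx = 1 at %d)\n",
              x$age[1L], attr(x, "max_age"), attr(x, "max_age")))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
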