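# Incremental cost-effectiveness computation and dominance classification.

#' Incremental cost-effectiveness of a comparator versus a reference
#'
#' Deltas are computed comparator minus reference. The cost-effectiveness
#' plane quadrant follows the signs of (delta QALY, delta cost): `SE`
#' (more effective, cheaper — the comparator dominates), `NE` (more
#' effective, costlier — trade-off), `SW` (less effective, cheaper —
#' trade-off), `NW` (less effective, costlier — the reference dominates).
#' The quadrant boundary `delta_cost <= 0, delta_qaly > 0` is classified SE.
#' The ICER `delta_cost / delta_qaly` is reported as a signed number even
#' when dominance makes the ratio's sign ambiguous on its own; the dominance
#' label is always attached. A zero QALY delta flags the ICER undefined
#' (`icer_flag = "undefined_with_sign"`), and two identical arms flag
#' `"equivalent"`.
#'
#' @param reference `arm_outcomes` of the incumbent strategy.
#' @param comparator `arm_outcomes` of the candidate strategy.
#' @return A `ce_result` tibble (one row): `delta_cost`, `delta_ly`,
#'   `delta_qaly`, `icer`, `icer_flag`, `quadrant`, `dominance`.
#' @examples
#' ps <- baseline_parameters()
#' icer(run_strategy(build_current_strategy(), ps),
#'      run_strategy(build_tailored_strategy(), ps))
#' @export
icer <- function(reference, comparator) {
  dc <- comparator$cost - reference$cost
  dly <- comparator$life_years - reference$life_years
  dq <- comparator$qalys - reference$qalys
  if (dq == 0 && dc == 0) {
    flag <- "equivalent"; ratio <- NA_real_
  } else if (dq == 0) {
    flag <- "undefined_with_sign"; ratio <- sign(dc) * Inf
  } else {
    flag <- "ok"; ratio <- dc / dq
  }
  quadrant <- if (dq > 0 && dc <= 0) "SE"
  else if (dq >= 0 && dc > 0) "NE"
  else if (dq < 0 && dc <= 0) "SW"
  else "NW"
  dominance <- switch(quadrant,
    SE = "comparator_dominates",
    NW = "reference_dominates",
    "trade_off")
  if (flag == "equivalent") dominance <- "equivalent"
  out <- tibble::tibble(
    delta_cost = dc, delta_ly = dly, delta_qaly = dq,
    icer = ratio, icer_flag = flag,
    quadrant = quadrant, dominance = dominance
  )
  class(out) <- c("ce_result", class(out))
  out
}

#' Net monetary benefit
#'
#' `wtp * qalys - cost` at a willingness-to-pay threshold. The sign of the
#' incremental NMB at a given threshold is the cost-effectiveness decision
#' underlying the acceptability curve.
#'
#' @param outcomes An `arm_outcomes` row (or anything with `qalys`, `cost`).
#' @param wtp Willingness to pay (SGD per QALY), non-negative; vectorised.
#' @return Net monetary benefit in SGD.
#' @export
nmb <- function(outcomes, wtp) {
  if (any(wtp < 0))
    rlang::abort("willingness-to-pay must be non-negative",
                 class = "screencea_validation_error")
  wtp * outcomes$qalys - outcomes$cost
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ce_result <- function(x, ...) {
  tibble::tibble(
    term = c("delta_cost", "delta_ly", "delta_qaly", "icer"),
    estimate = c(x$delta_cost, x$delta_ly, x$delta_qaly, x$icer)
  )
}

#' @export
glance.ce_result <- function(x, ...) {
  tibble::tibble(icer = x$icer, quadrant = x$quadrant,
                 dominance = x$dominance, icer_flag = x$icer_flag)
}
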