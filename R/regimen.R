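# Dosing regimens: ordered oral dose events with QD/BID builders.

#' Construct a dosing regimen
#'
#' A regimen is an ordered set of oral depot dose events. Times are clock
#' hours since the first dose of the regimen; amounts are mg.
#'
#' @param time numeric vector of dose times (h), non-negative, strictly
#'   increasing
#' @param amount dose amounts (mg), strictly positive; recycled if length 1
#' @return data.frame of class `pk_regimen` with columns `time`, `amount`
#' @export
regimen <- function(time, amount) {
  if (length(amount) == 1) amount <- rep(amount, length(time))
  if (length(time) == 0) stop("a regimen needs at least one dose event")
  if (length(time) != length(amount)) stop("time and amount lengths differ")
  if (any(!is.finite(time)) || any(time < 0)) stop("dose times must be >= 0")
  if (any(diff(time) <= 0)) stop("dose times must be strictly increasing")
  if (any(!is.finite(amount)) || any(amount <= 0)) stop("dose amounts must be > 0")
  structure(data.frame(time = as.numeric(time), amount = as.numeric(amount)),
            class = c("pk_regimen", "data.frame"))
}

#' @rdname regimen
#' @param dose single dose amount (mg)
#' @export
regimen_single <- function(dose) regimen(0, dose)

#' @rdname regimen
#' @param days number of dosing days
#' @export
regimen_qd <- function(dose, days = 28) regimen(24 * (seq_len(days) - 1), dose)

#' @rdname regimen
#' @export
regimen_bid <- function(dose, days = 28) regimen(12 * (seq_len(2 * days) - 1), dose)
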