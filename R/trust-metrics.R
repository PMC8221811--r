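## Investor-trustee exchange strategy metrics.
##
## Each round t >= 2 yields a vector of fractional changes: the investor's
## change as a fraction of the endowment, and the trustee's change in the
## fraction of the returnable pot (3 x investment) actually returned. The
## angle of this vector classifies the move; summing the vectors over rounds
## characterizes the exchange as a whole.

#' Construct a validated investor-trustee exchange
#'
#' @param investor per-round investor contributions.
#' @param trustee per-round trustee returns.
#' @param endowment per-round investor endowment (scalar, units of play money).
#' @param multiplier factor applied to the investment before the trustee
#'   chooses a return (default 3; the trustee may return 0..multiplier*I).
#' @return Object of class `trust_exchange`.
#' @export
trust_exchange <- function(investor, trustee, endowment = 20, multiplier = 3) {
  n <- length(investor)
  if (n < 2L) stop_config("an exchange needs at least 2 rounds")
  if (length(trustee) != n) stop_config("investor/trustee length mismatch")
  if (any(investor < 0) || any(investor > endowment + 1e-9))
    stop_config("contributions must lie in [0, endowment]")
  if (any(trustee < 0) || any(trustee > multiplier * investor + 1e-9))
    stop_config("returns must lie in [0, %s * investment]", multiplier)
  structure(list(investor = as.numeric(investor),
                 trustee = as.numeric(trustee),
                 endowment = endowment, multiplier = multiplier,
                 n_rounds = n),
            class = "trust_exchange")
}

## fraction of the returnable pot actually returned; 0 when nothing invested
.trustee_fraction <- function(ex) {
  pot <- ex$multiplier * ex$investor
  bad <- ex$investor == 0 & ex$trustee > 0
  if (any(bad)) stop_config("invalid exchange: return without investment in round %d",
                            which(bad)[1])
  ifelse(pot > 0, ex$trustee / pot, 0)
}

#' Per-round fractional-change vectors and move classes
#'
#' For rounds t >= 2, computes dI = (I_t - I_{t-1}) / endowment and
#' dT = T_t - T_{t-1} where T is the fraction of the returnable pot given
#' back. The move class follows the angle of (dI, dT) as it increases from
#' -180 to 180 degrees: retaliating (-180, -90], repairing (-90, 0],
#' honoring (0, 90], disrupting (90, 180]. Exact zero vectors are
#' unclassified.
#'
#' @param exchange a [trust_exchange()].
#' @return data.frame with columns `round`, `dI`, `dT`, `angle_deg`, `class`.
#' @export
round_vectors <- function(exchange) {
  stopifnot(inherits(exchange, "trust_exchange"))
  tf <- .trustee_fraction(exchange)
  dI <- diff(exchange$investor) / exchange$endowment
  dT <- diff(tf)
  ang <- atan2(dT, dI) * 180 / pi
  cls <- classify_angle(ang)
  cls[dI == 0 & dT == 0] <- NA_character_
  ang[dI == 0 & dT == 0] <- NA_real_
  data.frame(round = 2:exchange$n_rounds, dI = dI, dT = dT,
             angle_deg = ang, class = cls, stringsAsFactors = FALSE)
}

## quadrant labels in listed order as the angle increases from -180 to 180;
## boundaries closed on the upper edge (atan2 yields angles in (-180, 180])
classify_angle <- function(angle_deg) {
  lab <- c("retaliating", "repairing", "honoring", "disrupting")
  a <- ifelse(angle_deg <= -180, 180, angle_deg)  # -180 is equivalent to 180
  lab[findInterval(a, c(-180, -90, 0, 90), left.open = TRUE)]
}

#' Whole-exchange strategy scores
#'
#' Sums the nonzero round vectors into a resultant whose orientation
#' characterizes the exchange. Scores: `initial_trust` = first contribution
#' as a fraction of the endowment; `orientation_deg` = resultant angle;
#' `responsiveness` = resultant length / (n_rounds - 1); `cooperativeness` =
#' position in [0, 1] of the unit vector at the orientation projected onto
#' the chord from the unit vector at -135 degrees (mutual-reduction pole,
#' value 0) to the unit vector at 0 degrees (coaxing pole, value 1), clipped.
#'
#' @param exchange a [trust_exchange()].
#' @return Named list with the four scores.
#' @export
exchange_scores <- function(exchange) {
  rv <- round_vectors(exchange)
  keep <- !(rv$dI == 0 & rv$dT == 0)
  if (!any(keep))
    stop_config("all round vectors are zero: orientation undefined")
  res <- c(sum(rv$dI[keep]), sum(rv$dT[keep]))
  if (all(res == 0))
    stop_config("resultant vector is zero: orientation undefined")
  ori <- atan2(res[2], res[1]) * 180 / pi
  u <- c(cos(ori * pi / 180), sin(ori * pi / 180))
  a <- c(cos(-3 * pi / 4), sin(-3 * pi / 4))   # -135 deg pole -> 0
  b <- c(1, 0)                                 # 0 deg pole -> 1
  coop <- sum((u - a) * (b - a)) / sum((b - a)^2)
  list(initial_trust = exchange$investor[1] / exchange$endowment,
       orientation_deg = ori,
       responsiveness = sqrt(sum(res^2)) / (exchange$n_rounds - 1L),
       cooperativeness = min(max(coop, 0), 1))
}

#' Trust scores for a set of exchanges
#'
#' @param exchanges list of [trust_exchange()] objects.
#' @return data.frame, one row per exchange, with the four strategy scores.
#' @export
trust_score_table <- function(exchanges) {
  rows <- lapply(exchanges, function(ex) as.data.frame(exchange_scores(ex)))
  out <- do.call(rbind, rows)
  out$exchange <- seq_along(exchanges)
  out[, c("exchange", "initial_trust", "orientation_deg",
          "responsiveness", "cooperativeness")]
}

#' Read exchange records from a TSV file
#'
#' Expects columns `round`, `investor`, `trustee`, `endowment` and optionally
#' `exchange` (grouping) and `multiplier`.
#' @param path TSV path.
#' @return List of `trust_exchange` objects.
#' @export
read_trust_exchanges <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  grp <- d$exchange %||% rep(1L, nrow(d))
  lapply(split(d, grp), function(g) {
    g <- g[order(g$round), ]
    trust_exchange(g$investor, g$trustee, endowment = g$endowment[1],
                   multiplier = (g$multiplier %||% 3)[1])
  })
}
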