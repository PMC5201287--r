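## Nested-logit care-seeking.
##
## The decision is two-level: an upper nest choosing between "no care" (a
## singleton nest) and "seek care", and a lower softmax over the reachable
## care alternatives.  Published Ugandan coefficients are not reproduced;
## the defaults are order-of-magnitude plausible and fully configurable --
## the functional form and interface are the contract.

#' Construct a care-seeking choice model
#'
#' @param beta_cost marginal utility of out-of-pocket money (1/money; < 0)
#' @param beta_distance marginal utility of distance (1/km; < 0)
#' @param beta_quality marginal utility of provider quality (dimensionless)
#' @param beta_wealth_cost_interaction coefficient on (cost/income): makes a
#'   given price weigh more heavily on poorer agents (< 0)
#' @param asc_no_care alternative-specific constant of the no-care option
#' @param nest_dissimilarity lambda in (0, 1]; 1 collapses the nested logit
#'   to a plain multinomial logit
#' @param radius_km choice-set radius: facilities further away are excluded
#' @return an object of class `choice_model`
#' @export
choice_model <- function(beta_cost = -0.004,
                         beta_distance = -0.015,
                         beta_quality = 3,
                         beta_wealth_cost_interaction = -0.5,
                         asc_no_care = 0,
                         nest_dissimilarity = 0.7,
                         radius_km = 300) {
  if (nest_dissimilarity <= 0 || nest_dissimilarity > 1)
    stop("nest_dissimilarity must lie in (0, 1]")
  co <- c(beta_cost, beta_distance, beta_quality,
          beta_wealth_cost_interaction, asc_no_care)
  if (any(!is.finite(co))) stop("coefficients must be finite")
  structure(list(
    beta_cost = beta_cost, beta_distance = beta_distance,
    beta_quality = beta_quality,
    beta_wealth_cost_interaction = beta_wealth_cost_interaction,
    asc_no_care = asc_no_care, nest_dissimilarity = nest_dissimilarity,
    radius_km = radius_km
  ), class = "choice_model")
}

#' Systematic utility of one alternative
#'
#' For a care alternative:
#' V = beta_cost * (price + transport) + beta_distance * distance +
#'     beta_quality * quality +
#'     beta_wealth_cost_interaction * (price + transport) / income.
#' For the no-care alternative, V = asc_no_care.
#'
#' @param agent list/row with `income`
#' @param alternative list/row with `price`, `transport`, `distance`,
#'   `quality`, or `no_care = TRUE`
#' @param model a `choice_model`
#' @return numeric utility
#' @export
utility <- function(agent, alternative, model) {
  if (isTRUE(alternative$no_care)) return(model$asc_no_care)
  oop <- alternative$price + alternative$transport
  model$beta_cost * oop +
    model$beta_distance * alternative$distance +
    model$beta_quality * alternative$quality +
    model$beta_wealth_cost_interaction * oop / agent$income
}

#' Nested-logit choice probabilities
#'
#' Within the care nest, probabilities are softmax(V / lambda); the care
#' nest's inclusive value is I = lambda * log(sum(exp(V / lambda))); the
#' upper level is a binary logit between I and the no-care utility.
#' Overflow is guarded by max-subtraction.  An empty care nest yields
#' probability 1 on no-care.
#'
#' @param situation list with `agent` and `alternatives` (a data.frame with
#'   columns `price`, `transport`, `distance`, `quality`; zero rows allowed)
#' @param model a `choice_model`
#' @return named numeric vector: `no_care` first, then one entry per care
#'   alternative, summing to 1
#' @export
choice_probabilities <- function(situation, model) {
  alts <- situation$alternatives
  v0 <- model$asc_no_care
  if (is.null(alts) || nrow(alts) == 0L) {
    return(c(no_care = 1))
  }
  lam <- model$nest_dissimilarity
  oop <- alts$price + alts$transport
  v <- model$beta_cost * oop +
    model$beta_distance * alts$distance +
    model$beta_quality * alts$quality +
    model$beta_wealth_cost_interaction * oop / situation$agent$income
  vs <- v / lam
  m <- max(vs)
  within <- exp(vs - m)
  within <- within / sum(within)
  inclusive <- lam * (m + log(sum(exp(vs - m))))
  top <- c(v0, inclusive)
  tm <- max(top)
  pn <- exp(top - tm)
  pn <- pn / sum(pn)
  p <- c(no_care = pn[1], pn[2] * within)
  if (!is.null(rownames(alts))) names(p)[-1] <- rownames(alts)
  if (!is.null(alts$alt_id)) names(p)[-1] <- alts$alt_id
  p
}

#' Sample one alternative from a choice-probability vector
#'
#' @param probabilities named numeric vector summing to 1 (+/- 1e-9)
#' @return the chosen alternative's name (or index if unnamed)
#' @export
select_provider <- function(probabilities) {
  if (any(!is.finite(probabilities)) || any(probabilities < -1e-12) ||
      abs(sum(probabilities) - 1) > 1e-9)
    stop("malformed probability vector")
  p <- pmax(probabilities, 0)
  i <- sample.int(length(p), 1L, prob = p)
  if (!is.null(names(p))) names(p)[i] else i
}
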