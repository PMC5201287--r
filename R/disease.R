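## Cancer natural history.
##
## Onset is a per-cancer daily Bernoulli at rate/100,000/365 per eligible
## agent (at most one active episode per agent).  Untreated disease carries
## an exponential survival hazard parameterized by its median; treated
## disease resolves through a perioperative-mortality draw, then cure vs
## residual disease (residual reverts to the untreated hazard), with an
## independent complication flag.

EPISODE_OUTCOMES <- c("ongoing", "cured", "died_of_cancer", "died_perioperative")

#' New cancer onsets for one day
#'
#' @param cohort a `cohort`
#' @param disease_table data.frame from [generate_disease_table()] (only the
#'   district rows are consulted for incidence, which is level-free)
#' @param day calendar day of onset
#' @param active_episode logical vector (or agent-id set) marking agents who
#'   already have an active episode and are therefore ineligible
#' @return data.frame of new episodes (agent_id, cancer, onset_day)
#' @export
incident_cases <- function(cohort, disease_table, day, active_episode = integer(0)) {
  ag <- cohort$agents
  eligible <- which(ag$alive & !(ag$id %in% active_episode))
  if (!length(eligible)) {
    return(data.frame(agent_id = integer(0), cancer = character(0),
                      onset_day = integer(0), stringsAsFactors = FALSE))
  }
  rates <- unique(disease_table[, c("cancer", "incidence_rate")])
  out_agent <- integer(0); out_cancer <- character(0)
  for (k in seq_len(nrow(rates))) {
    p <- rates$incidence_rate[k] / 1e5 / 365
    if (p <= 0) next
    hit <- eligible[stats::runif(length(eligible)) < p]
    if (length(hit)) {
      out_agent <- c(out_agent, ag$id[hit])
      out_cancer <- c(out_cancer, rep(rates$cancer[k], length(hit)))
      eligible <- setdiff(eligible, hit)  # one active episode per agent
    }
  }
  data.frame(agent_id = out_agent, cancer = out_cancer,
             onset_day = rep(as.integer(day), length(out_agent)),
             stringsAsFactors = FALSE)
}

#' Daily death probability for untreated disease
#'
#' Exponential survival with the stated median: hazard
#' lambda = ln(2) / median, applied as `1 - exp(-lambda)` per day.
#'
#' @param median_survival_days untreated median survival, days (> 0)
#' @return daily death probability
#' @export
untreated_daily_death_prob <- function(median_survival_days) {
  if (any(median_survival_days <= 0)) stop("median survival must be > 0")
  1 - exp(-log(2) / median_survival_days)
}

#' One day of untreated progression for one episode
#'
#' @param episode list/row with at least `outcome`
#' @param median_survival_days untreated median survival in days
#' @return updated episode (outcome flips to "died_of_cancer" on a death
#'   draw); died_* states are absorbing
#' @export
untreated_progression <- function(episode, median_survival_days) {
  if (episode$outcome != "ongoing") return(episode)
  if (stats::runif(1) < untreated_daily_death_prob(median_survival_days))
    episode$outcome <- "died_of_cancer"
  episode
}

#' Resolve a treated episode against provider quality
#'
#' Sequential draws: perioperative death; otherwise cure vs residual
#' disease (residual keeps the episode "ongoing" and reverts to the
#' untreated hazard); an independent complication flag is set either way.
#'
#' @param episode list/row with `outcome`
#' @param quality list with `periop_mortality`, `cure_probability`,
#'   `complication_rate`, all in [0, 1]
#' @return episode with updated `outcome`, `cured` and `complication`
#' @export
treated_outcome <- function(episode, quality) {
  stopifnot(quality$periop_mortality >= 0, quality$periop_mortality <= 1,
            quality$cure_probability >= 0, quality$cure_probability <= 1,
            quality$complication_rate >= 0, quality$complication_rate <= 1)
  episode$complication <- stats::runif(1) < quality$complication_rate
  if (stats::runif(1) < quality$periop_mortality) {
    episode$outcome <- "died_perioperative"
    return(episode)
  }
  if (stats::runif(1) < quality$cure_probability) {
    episode$outcome <- "cured"
  }  # else residual disease: stays "ongoing" under the untreated hazard
  episode
}
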