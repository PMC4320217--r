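# Chain entry / exit probability models.  Chain size X_i is the number of
# ants in the connected chain i spanning (part of) a ditch.

#' Saturating chain-entry model
#'
#' Parameters of the entry probability
#' `P_e(X) = Ce0 + Ce1 * X / (Ce2 + X)`: `Ce0` is the spontaneous hanging
#' probability at `X = 0` and the curve saturates at the plateau
#' `Ce0 + Ce1`.
#'
#' @param Ce0,Ce1,Ce2 Non-negative parameters; `Ce0 + Ce1 <= 1` so the
#'   plateau is a probability; `Ce2 > 0`.
#' @return An object of class `"chain_entry_model"`.
#' @export
chain_entry_model <- function(Ce0 = 0.1, Ce1 = 0.6, Ce2 = 4.0) {
  if (Ce0 < 0 || Ce1 < 0) stop("Ce0 and Ce1 must be non-negative")
  if (Ce0 + Ce1 > 1) stop("Ce0 + Ce1 must not exceed 1 (probability plateau)")
  if (Ce2 <= 0) stop("Ce2 must be positive")
  structure(list(Ce0 = Ce0, Ce1 = Ce1, Ce2 = Ce2), class = "chain_entry_model")
}

#' Chain-exit model with size-dependent decline
#'
#' Parameters of the exit probability
#' `P_l(X) = Cs0 + Cs1 / (Cs2 + X^nu)`, non-increasing in chain size for
#' positive `Cs1` and `nu`; `nu` tunes how fast growing chains retain their
#' members.
#'
#' @param Cs0,Cs1,Cs2 Non-negative parameters, `Cs2 > 0`.
#' @param nu Growth-rate exponent (> 0).
#' @return An object of class `"chain_exit_model"`.
#' @export
chain_exit_model <- function(Cs0 = 0.05, Cs1 = 0.9, Cs2 = 1.0, nu = 2.0) {
  if (Cs0 < 0 || Cs1 < 0) stop("Cs0 and Cs1 must be non-negative")
  if (Cs2 <= 0) stop("Cs2 must be positive")
  if (nu <= 0) stop("nu must be positive")
  if (Cs0 + Cs1 / Cs2 > 1)
    stop("P_l(0) = Cs0 + Cs1/Cs2 exceeds 1; probabilities must lie in [0, 1]")
  structure(list(Cs0 = Cs0, Cs1 = Cs1, Cs2 = Cs2, nu = nu), class = "chain_exit_model")
}

#' Pheromone-coupled leave model
#'
#' Parameters of the leaving probability
#' `P(X) = a / (1 + b X^2)` with
#' `b = min(eta * log(space + 1) + eps, 1)`: `a` is the probability of
#' leaving regardless of nest mates, and `b` couples chain stability to the
#' local space-pheromone concentration, so chains on strong trails persist.
#'
#' @param a Spontaneous leave probability in \[0, 1\].
#' @param eta,eps Non-negative coupling parameters of `b`.
#' @return An object of class `"leave_model"`.
#' @export
leave_model <- function(a = 0.4, eta = 0.1, eps = 0.1) {
  if (a < 0 || a > 1) stop("a must lie in [0, 1]")
  if (eta < 0 || eps < 0) stop("eta and eps must be non-negative")
  structure(list(a = a, eta = eta, eps = eps), class = "leave_model")
}

#' Probability of entering a chain of size Xi
#'
#' @param model A [chain_entry_model()].
#' @param Xi Chain size(s), non-negative.
#' @return Probability vector.
#' @examples
#' prob_enter_chain(chain_entry_model(0.1, 0.6, 4), 4)  # 0.4
#' @export
prob_enter_chain <- function(model, Xi) {
  stopifnot(inherits(model, "chain_entry_model"), all(Xi >= 0))
  p <- model$Ce0 + model$Ce1 * Xi / (model$Ce2 + Xi)
  if (any(p < 0 | p > 1)) stop("entry probability outside [0, 1]; check parameters")
  p
}

#' Probability of leaving a chain of size Xi (size-only model)
#'
#' @param model A [chain_exit_model()].
#' @param Xi Chain size(s), non-negative.
#' @return Probability vector.
#' @examples
#' prob_leave_chain_lioni(chain_exit_model(0.05, 0.9, 1, 2), 3)  # 0.14
#' @export
prob_leave_chain_lioni <- function(model, Xi) {
  stopifnot(inherits(model, "chain_exit_model"), all(Xi >= 0))
  p <- model$Cs0 + model$Cs1 / (model$Cs2 + Xi^model$nu)
  if (any(p < 0 | p > 1)) stop("exit probability outside [0, 1]; check parameters")
  p
}

#' Probability of leaving a chain, pheromone-coupled
#'
#' `P = a / (1 + b Xi^2)` with `b = min(eta log(space_level + 1) + eps, 1)`.
#' This is the leave rule used by the default simulation.
#'
#' @param model A [leave_model()].
#' @param Xi Chain size(s), non-negative.
#' @param space_level Space-layer pheromone at the ant's cell (>= 0).
#' @return Probability vector.
#' @examples
#' prob_leave_chain_pheromone(leave_model(a = 0.4), Xi = 0, space_level = 0)  # 0.4
#' @export
prob_leave_chain_pheromone <- function(model, Xi, space_level) {
  stopifnot(inherits(model, "leave_model"), all(Xi >= 0), all(space_level >= 0))
  b <- pmin(model$eta * log(space_level + 1) + model$eps, 1)
  model$a / (1 + b * Xi^2)
}

#' Behaviour parameters
#'
#' Perception radii are the model's fixed constants (food and ditch within
#' 1 Distance; pheromone and other agents within 2 Distances).  `n` is the
#' neighbour threshold for staying in a chain; `alpha` the acceptance
#' probability for a non-straight candidate direction in the random walk.
#'
#' @param n Minimum number of other agents within `agent_radius` for a chain
#'   member to stay put (default 2).
#' @param alpha Probability of accepting a randomly selected non-straight
#'   direction (0, 1].
#' @param entry_mode `"model1"` (neighbour condition; default) or
#'   `"model2"` (pheromone threshold).
#' @param model2_threshold Space-pheromone level triggering entry under
#'   `"model2"`.
#' @param leave_rule `"pheromone"` (default; [prob_leave_chain_pheromone()])
#'   or `"lioni"` ([prob_leave_chain_lioni()]).
#' @param leave A [leave_model()].
#' @param enter A [chain_entry_model()] (reference model, not used by the
#'   default entry rule).
#' @param exit A [chain_exit_model()] (used when `leave_rule = "lioni"`).
#' @param minor_deposit_in_search Do Minor ants deposit while searching?
#' @param majors_join_chains May Major ants enter the Altruism state?
#' @param food_radius,pheromone_radius,agent_radius,ditch_radius Perception
#'   radii in Distances.
#' @return An object of class `"behavior_params"`.
#' @export
behavior_params <- function(n = 2L, alpha = 0.5,
                            entry_mode = c("model1", "model2"),
                            model2_threshold = 1.0,
                            leave_rule = c("pheromone", "lioni"),
                            leave = leave_model(),
                            enter = chain_entry_model(),
                            exit = chain_exit_model(),
                            minor_deposit_in_search = FALSE,
                            majors_join_chains = FALSE,
                            food_radius = 1L, pheromone_radius = 2L,
                            agent_radius = 2L, ditch_radius = 1L) {
  entry_mode <- match.arg(entry_mode)
  leave_rule <- match.arg(leave_rule)
  if (n < 1L) stop("n must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  structure(list(n = as.integer(n), alpha = alpha, entry_mode = entry_mode,
                 model2_threshold = model2_threshold, leave_rule = leave_rule,
                 leave = leave, enter = enter, exit = exit,
                 minor_deposit_in_search = isTRUE(minor_deposit_in_search),
                 majors_join_chains = isTRUE(majors_join_chains),
                 food_radius = as.integer(food_radius),
                 pheromone_radius = as.integer(pheromone_radius),
                 agent_radius = as.integer(agent_radius),
                 ditch_radius = as.integer(ditch_radius)),
            class = "behavior_params")
}
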