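# Agent state machine: Search / Return / Altruism.
#
# All three step functions mutate the sim_state in place (one action per
# ant per tick) and return it invisibly.  Valid transitions are
# SEARCH->RETURN (food taken), RETURN->SEARCH (delivered),
# SEARCH->ALTRUISM (joined a chain) and ALTRUISM->SEARCH (left a chain).

# RNG primitives shared (draw-for-draw) with the compiled engine, so that
# both engines consume the same uniform stream and produce identical
# trajectories under a common seed.
.pick_uniform <- function(k) {
  if (k == 1L) return(1L)
  j <- as.integer(floor(stats::runif(1) * k)) + 1L
  if (j > k) k else j
}

.pick_weighted <- function(w) {
  k <- length(w)
  if (k == 1L) return(1L)
  tot <- 0
  for (i in seq_len(k)) tot <- tot + w[i]
  u <- stats::runif(1) * tot
  cs <- 0
  for (i in seq_len(k)) {
    cs <- cs + w[i]
    if (u <= cs) return(i)
  }
  k
}

.shuffle <- function(n) {
  ord <- seq_len(n)
  if (n > 1L) for (i in n:2L) {
    j <- as.integer(floor(stats::runif(1) * i)) + 1L
    if (j > i) j <- i
    tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
  }
  ord
}

.event <- function(state, ant, from, to) {
  state$ev[[length(state$ev) + 1L]] <-
    c(state$tick, ant, from, to, state$ant_x[ant], state$ant_y[ant])
  invisible(NULL)
}

# Walker traversability over candidate padded linear indices: free
# OPEN/NEST cells, or ditch cells currently bridged by a chain member.
.free <- function(state, tl) {
  cl <- state$cls[tl]
  (state$occ[tl] == 0L) &
    ((cl == .CLS_OPEN) | (cl == .CLS_NEST) |
       ((cl == .CLS_DITCH) & (state$mem[tl] > 0L)))
}

.move_walker <- function(state, ant, from_li, to_li, dx, dy) {
  state$occ[from_li] <- 0L
  state$occ[to_li] <- ant
  state$ant_x[ant] <- state$ant_x[ant] + dx
  state$ant_y[ant] <- state$ant_y[ant] + dy
  state$ant_hx[ant] <- dx
  state$ant_hy[ant] <- dy
  invisible(NULL)
}

# Deposit after the ant's action at its (possibly new) position.  Majors
# scatter every tick; Minors only while carrying food home (optionally also
# while searching).
.maybe_deposit <- function(state, ant, li, moved_diag) {
  dep <- if (state$ant_caste[ant] == .MAJOR) TRUE
  else if (state$ant_carrying[ant]) TRUE
  else state$behavior$minor_deposit_in_search && state$ant_state[ant] == .SEARCH
  if (dep) {
    pp <- state$pheromone
    amt <- pp$deposit_ground * if (moved_diag) pp$diagonal_deposit_factor else 1
    state$ground[li] <- state$ground[li] + amt
  }
  invisible(NULL)
}

# alpha-weighted random direction: straight-ahead candidate keeps weight 1,
# any other free direction weight alpha.  Returns the chosen index into
# `idx` (positions in OFF1), or 0L if idx is empty.
.random_dir <- function(state, ant, idx) {
  if (!length(idx)) return(0L)
  if (length(idx) == 1L) return(idx)
  wgt <- ifelse(OFF1[idx, 1L] == state$ant_hx[ant] & OFF1[idx, 2L] == state$ant_hy[ant],
                1, state$behavior$alpha)
  idx[.pick_weighted(wgt)]
}

#' Pheromone-guided candidate choice
#'
#' Chooses one candidate with probability proportional to its space-layer
#' pheromone level; if every level is zero the choice is uniform.
#'
#' @param candidates Candidate cells (vector, or matrix with one row per
#'   candidate).
#' @param levels Non-negative space-pheromone level per candidate.
#' @return The chosen candidate (element or matrix row).
#' @export
pheromone_guided_move <- function(candidates, levels) {
  k <- if (is.matrix(candidates)) nrow(candidates) else length(candidates)
  stopifnot(k >= 1L, length(levels) == k, all(levels >= 0))
  pick <- if (k == 1L) 1L
  else if (all(levels == 0)) .pick_uniform(k)
  else .pick_weighted(levels)
  if (is.matrix(candidates)) candidates[pick, ] else candidates[pick]
}

#' One Search-state action
#'
#' In order: take a food unit if one lies within 1 Distance (transition to
#' Return); if the entry condition holds (Model 1: another walking agent
#' within 2 Distances -- chain members do not count, so bridges form under
#' traffic congestion instead of absorbing every passer-by; Model 2: space
#' pheromone above a threshold) and an
#' unbridged ditch cell lies within 1 Distance, step onto it and transition
#' to Altruism (cells adjacent to an existing chain are preferred, so
#' chains grow contiguously); otherwise move -- a Minor perceiving any
#' space pheromone within 2 Distances moves proportionally to candidate
#' levels, else the alpha-weighted random direction rule applies.  A fully
#' surrounded ant waits.
#'
#' @param state A `"sim_state"`.
#' @param ant Ant id.
#' @return The state, invisibly.
#' @export
search_step <- function(state, ant) {
  W <- state$W; bp <- state$behavior
  x <- state$ant_x[ant]; y <- state$ant_y[ant]
  li <- .li(x, y, W)
  caste <- state$ant_caste[ant]

  if (caste == .MINOR) {
    nb <- c(li, li + state$d1)
    sp <- state$spot[nb]
    sp <- sp[sp > 0L]
    sp <- sp[state$remaining[sp] > 0L]
    if (length(sp)) {
      s <- sp[1L]
      state$remaining[s] <- state$remaining[s] - 1L
      state$ant_carrying[ant] <- TRUE
      state$ant_cargo[ant] <- s
      state$ant_state[ant] <- .RETURN
      .event(state, ant, .SEARCH, .RETURN)
      .maybe_deposit(state, ant, li, FALSE)
      return(invisible(state))
    }
  }

  if (caste == .MINOR || bp$majors_join_chains) {
    trigger <- if (bp$entry_mode == "model1")
      any(state$occ[li + state$d2] > 0L)
    else
      max(state$space[c(li, li + state$d2)]) >= bp$model2_threshold
    if (trigger) {
      t1 <- li + state$d1
      dit <- which(state$cls[t1] == .CLS_DITCH & state$mem[t1] == 0L)
      if (length(dit)) {
        adj <- vapply(t1[dit], function(t) any(state$mem[t + state$d1] > 0L), logical(1))
        pool <- if (any(adj)) dit[adj] else dit
        k <- pool[.pick_uniform(length(pool))]
        state$occ[li] <- 0L
        state$mem[t1[k]] <- ant
        state$ant_x[ant] <- x + OFF1[k, 1L]
        state$ant_y[ant] <- y + OFF1[k, 2L]
        state$ant_hx[ant] <- 0L; state$ant_hy[ant] <- 0L
        state$ant_state[ant] <- .ALTRUISM
        .event(state, ant, .SEARCH, .ALTRUISM)
        return(invisible(state))
      }
    }
  }

  t1 <- li + state$d1
  idx <- which(.free(state, t1))
  moved_diag <- FALSE
  new_li <- li
  if (length(idx)) {
    guided <- caste == .MINOR && max(state$space[c(li, li + state$d2)]) > 0
    k <- if (guided)
      idx[pheromone_guided_move(seq_along(idx), state$space[t1[idx]])]
    else
      .random_dir(state, ant, idx)
    .move_walker(state, ant, li, t1[k], OFF1[k, 1L], OFF1[k, 2L])
    new_li <- t1[k]
    moved_diag <- OFF1[k, 1L] != 0L && OFF1[k, 2L] != 0L
  }
  .maybe_deposit(state, ant, new_li, moved_diag)
  invisible(state)
}

#' One Return-state action
#'
#' A carrier standing on a nest cell delivers its unit and transitions back
#' to Search.  Otherwise, with a ditch within 1 Distance (or under its
#' feet, on a bridge) it takes an alpha-weighted random step so it can find
#' and cross a living bridge; on open ground it takes the free neighbour
#' cell that strictly reduces the Chebyshev distance to the nest, ties
#' broken uniformly.  Blocked carriers wait.  Minors deposit ground
#' pheromone every step while carrying.
#'
#' @inheritParams search_step
#' @return The state, invisibly.
#' @export
return_step <- function(state, ant) {
  W <- state$W
  x <- state$ant_x[ant]; y <- state$ant_y[ant]
  li <- .li(x, y, W)

  if (state$cls[li] == .CLS_NEST) {
    s <- state$ant_cargo[ant]
    state$delivered[s] <- state$delivered[s] + 1L
    state$ant_carrying[ant] <- FALSE
    state$ant_cargo[ant] <- NA_integer_
    state$ant_state[ant] <- .SEARCH
    .event(state, ant, .RETURN, .SEARCH)
    .maybe_deposit(state, ant, li, FALSE)
    return(invisible(state))
  }

  t1 <- li + state$d1
  idx <- which(.free(state, t1))
  moved_diag <- FALSE
  new_li <- li
  if (length(idx)) {
    ditch_near <- state$cls[li] == .CLS_DITCH || any(state$cls[t1] == .CLS_DITCH)
    k <- 0L
    if (ditch_near || is.null(state$nest_rect)) {
      k <- .random_dir(state, ant, idx)
    } else {
      cx <- x + OFF1[idx, 1L]; cy <- y + OFF1[idx, 2L]
      d <- dist_to_rect(cx, cy, state$nest_rect)
      cur <- dist_to_rect(x, y, state$nest_rect)
      closer <- which(d < cur)
      if (length(closer)) {
        best <- closer[d[closer] == min(d[closer])]
        k <- idx[best[.pick_uniform(length(best))]]
      }
    }
    if (k > 0L) {
      .move_walker(state, ant, li, t1[k], OFF1[k, 1L], OFF1[k, 2L])
      new_li <- t1[k]
      moved_diag <- OFF1[k, 1L] != 0L && OFF1[k, 2L] != 0L
    }
  }
  .maybe_deposit(state, ant, new_li, moved_diag)
  invisible(state)
}

#' One Altruism-state action
#'
#' A chain member leaves when fewer than `n` other agents remain within
#' 2 Distances, or with the leaving probability of the configured rule
#' (default: the pheromone-coupled `a / (1 + b Xi^2)` evaluated at the
#' member's own cell).  A member with a walker standing on its back never
#' leaves (so crossing ants are never stranded on an unbridged ditch
#' cell).  A leaver steps to a free non-ditch cell within 1 Distance and
#' transitions to Search; if every such cell is taken the ant stays
#' embedded in the chain.
#'
#' @inheritParams search_step
#' @return The state, invisibly.
#' @export
altruism_step <- function(state, ant) {
  W <- state$W; bp <- state$behavior
  li <- .li(state$ant_x[ant], state$ant_y[ant], W)
  others <- sum(state$occ[li + state$d2] > 0L) + sum(state$mem[li + state$d2] > 0L)
  ci <- state$ant_chain[ant]
  Xi <- if (is.na(ci)) 1L else state$chain_sizes[ci]
  P1 <- if (bp$leave_rule == "pheromone")
    prob_leave_chain_pheromone(bp$leave, Xi, state$space[li])
  else
    prob_leave_chain_lioni(bp$exit, Xi)
  if (state$occ[li] == 0L && (others < bp$n || stats::runif(1) < P1)) {
    t1 <- li + state$d1
    cl <- state$cls[t1]
    idx <- which((cl == .CLS_OPEN | cl == .CLS_NEST) & state$occ[t1] == 0L)
    if (length(idx)) {
      k <- idx[.pick_uniform(length(idx))]
      state$mem[li] <- 0L
      state$occ[t1[k]] <- ant
      state$ant_x[ant] <- state$ant_x[ant] + OFF1[k, 1L]
      state$ant_y[ant] <- state$ant_y[ant] + OFF1[k, 2L]
      state$ant_hx[ant] <- OFF1[k, 1L]; state$ant_hy[ant] <- OFF1[k, 2L]
      state$ant_state[ant] <- .SEARCH
      state$ant_chain[ant] <- NA_integer_
      .event(state, ant, .ALTRUISM, .SEARCH)
      .maybe_deposit(state, ant, t1[k], OFF1[k, 1L] != 0L && OFF1[k, 2L] != 0L)
    }
  }
  invisible(state)
}

.rebuild_chains_internal <- function(state) {
  idx <- which(state$ant_state == .ALTRUISM)
  k <- length(idx)
  state$ant_chain <- rep(NA_integer_, state$n_ants)
  if (k == 0L) {
    state$chain_sizes <- integer(0)
    state$chain_ids <- integer(0)
    return(invisible(NULL))
  }
  xs <- state$ant_x[idx]; ys <- state$ant_y[idx]
  adj <- pmax(abs(outer(xs, xs, "-")), abs(outer(ys, ys, "-"))) <= 1L
  comp <- integer(k); nc <- 0L
  for (a in seq_len(k)) if (comp[a] == 0L) {
    nc <- nc + 1L
    stack <- a
    comp[a] <- nc
    while (length(stack)) {
      b <- stack[1L]; stack <- stack[-1L]
      nb <- which(adj[b, ] & comp == 0L)
      if (length(nb)) {
        comp[nb] <- nc
        stack <- c(stack, nb)
      }
    }
  }
  state$chain_sizes <- tabulate(comp, nc)
  state$chain_ids <- vapply(seq_len(nc), function(cc) min(idx[comp == cc]), integer(1))
  state$ant_chain[idx] <- comp
  invisible(NULL)
}

#' Rebuild chains from agent positions
#'
#' Chains are the connected components (1-Distance adjacency) of
#' Altruism-state agents; the chain size `Xi` of each component drives the
#' entry/leave probabilities.  Each chain's stable id is its smallest
#' member id.
#'
#' @param state A `"sim_state"`.
#' @return A list of chains, each `list(id, members, size)`.
#' @export
rebuild_chains <- function(state) {
  .rebuild_chains_internal(state)
  lapply(seq_along(state$chain_sizes), function(cc) {
    list(id = state$chain_ids[cc],
         members = which(!is.na(state$ant_chain) & state$ant_chain == cc),
         size = state$chain_sizes[cc])
  })
}

#' Is a cell traversable by a walking ant?
#'
#' OPEN/NEST/FOOD cells are traversable when no walker occupies them; a
#' DITCH cell is traversable only while a chain member bridges it (a single
#' walker may stand on top of a chain member).
#'
#' @param state A `"sim_state"`.
#' @param pos Cell `c(x, y)`, 0-based.
#' @return Logical flag.
#' @export
is_traversable <- function(state, pos) {
  x <- as.integer(pos[1L]); y <- as.integer(pos[2L])
  if (x < 0L || x >= state$w || y < 0L || y >= state$h) return(FALSE)
  li <- .li(x, y, state$W)
  unname(.free(state, li))
}
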