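#' Markov state space of the tetrameric gating model
#'
#' Enumerates the nine states of the integrated ladder model: the number of
#' activated common subunits (0..3) crossed with the state of the distinct
#' subunit (resting `C*` or activated `A*`), plus one open state reachable
#' only from the fully activated (3, `A*`) corner via the concerted step.
#' State ordering is deterministic: activated-common count ascending, `C*`
#' before `A*`, open last.
#'
#' Each undirected edge is stored once, in its activating (forward)
#' direction, with the signed charge it displaces: a common activation step
#' carries the full per-subunit charge of the common subunit, the distinct
#' step that of the distinct subunit, and the opening step zero charge.
#' Forward/backward statistical multiplicities (3 - n and n + 1 for the
#' common steps) are attached to the edges.
#'
#' @param asm A [channel_assembly()].
#' @return An object of class `state_space` with fields `states` (data frame
#'   with `label`, `n_common_active`, `distinct_active`, `open`),
#'   `transitions` (data frame with `from`, `to`, `type`, `mult_fwd`,
#'   `mult_rev`, `charge`), and `state_charge` (cumulative charge of each
#'   state relative to the fully resting state, e0 units).
#' @export
build_state_space <- function(asm) {
  stopifnot(inherits(asm, "channel_assembly"))
  zc <- subunit_charge(asm$common)
  zd <- subunit_charge(asm$distinct)

  grid <- expand.grid(distinct_active = c(FALSE, TRUE),
                      n_common_active = 0:3,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$n_common_active, grid$distinct_active), ]
  states <- data.frame(
    label = c(sprintf("%dA.%s", grid$n_common_active,
                      ifelse(grid$distinct_active, "A*", "C*")), "O"),
    n_common_active = c(grid$n_common_active, 3L),
    distinct_active = c(grid$distinct_active, TRUE),
    open = c(rep(FALSE, 8L), TRUE),
    stringsAsFactors = FALSE
  )
  idx <- function(n, d) 2L * n + as.integer(d) + 1L  # open state is 9

  tr <- list()
  for (d in c(FALSE, TRUE)) {
    for (n in 0:2) {
      tr[[length(tr) + 1L]] <- data.frame(
        from = idx(n, d), to = idx(n + 1L, d), type = "common",
        mult_fwd = 3L - n, mult_rev = n + 1L, charge = zc)
    }
  }
  for (n in 0:3) {
    tr[[length(tr) + 1L]] <- data.frame(
      from = idx(n, FALSE), to = idx(n, TRUE), type = "distinct",
      mult_fwd = 1L, mult_rev = 1L, charge = zd)
  }
  tr[[length(tr) + 1L]] <- data.frame(
    from = idx(3L, TRUE), to = 9L, type = "open",
    mult_fwd = 1L, mult_rev = 1L, charge = 0)
  transitions <- do.call(rbind, tr)

  state_charge <- states$n_common_active * zc +
    as.numeric(states$distinct_active) * zd

  structure(list(states = states, transitions = transitions,
                 state_charge = state_charge),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> %d states (%s), %d edges\n",
              nrow(x$states), paste(x$states$label, collapse = " "),
              nrow(x$transitions)))
  invisible(x)
}

# per-edge forward/backward rates at voltage V (vectors over edges)
.edge_rates <- function(asm, space, V, pc) {
  tr <- space$transitions
  ac <- rate_alpha(asm$common, V, pc)
  bc <- rate_beta(asm$common, V, pc)
  ad <- rate_alpha(asm$distinct, V, pc)
  bd <- rate_beta(asm$distinct, V, pc)
  base_f <- c(common = ac, distinct = ad, open = asm$opening_rate)
  base_r <- c(common = bc, distinct = bd, open = asm$closing_rate)
  list(fwd = tr$mult_fwd * base_f[tr$type],
       rev = tr$mult_rev * base_r[tr$type])
}

#' Generator (Q) matrix of the gating model at a fixed voltage
#'
#' Off-diagonal entry (i, j) is the transition rate from state i to state j
#' at voltage `V`; diagonals are minus the row sums, so every row sums to
#' zero.
#'
#' @param asm A [channel_assembly()].
#' @param V Membrane voltage, mV (scalar).
#' @param pc A [physical_constants()] object.
#' @param space Optional precomputed [build_state_space()] result.
#' @return A 9 x 9 numeric matrix (ms^-1) with state labels as dimnames and
#'   attributes `voltage` and `space`.
#' @export
generator_at_voltage <- function(asm, V, pc = physical_constants(),
                                 space = build_state_space(asm)) {
  stopifnot(length(V) == 1L)
  .check_voltage(V)
  n <- nrow(space$states)
  Q <- matrix(0, n, n, dimnames = list(space$states$label,
                                       space$states$label))
  r <- .edge_rates(asm, space, V, pc)
  tr <- space$transitions
  Q[cbind(tr$from, tr$to)] <- r$fwd
  Q[cbind(tr$to, tr$from)] <- r$rev
  diag(Q) <- -rowSums(Q)
  attr(Q, "voltage") <- V
  attr(Q, "space") <- space
  Q
}

#' Stationary distribution of the gating model at a fixed voltage
#'
#' The transition graph is a tree, so the stationary distribution satisfies
#' detailed balance and has a closed product form: the weight of a state
#' with n activated common subunits is binomial(3, n) times the n-th power
#' of the common alpha/beta ratio, times the distinct ratio if the distinct
#' subunit is activated, and the open state carries the additional
#' opening/closing equilibrium factor. Weights are accumulated in log space
#' so extreme voltages (rate ratios of 1e50 and beyond) do not overflow.
#'
#' @inheritParams generator_at_voltage
#' @return Named probability vector over the 9 states (sums to 1).
#' @export
equilibrium_distribution <- function(asm, V, pc = physical_constants(),
                                     space = build_state_space(asm)) {
  stopifnot(length(V) == 1L)
  .check_voltage(V)
  vt <- pc$thermal_voltage
  # log(alpha/beta) evaluated directly to avoid overflow of either rate
  lrc <- log(asm$common$alpha0 / asm$common$beta0) +
    subunit_charge(asm$common) * V / vt
  lrd <- log(asm$distinct$alpha0 / asm$distinct$beta0) +
    subunit_charge(asm$distinct) * V / vt
  st <- space$states
  lw <- lchoose(3, st$n_common_active) + st$n_common_active * lrc +
    as.numeric(st$distinct_active) * lrd
  lw[st$open] <- lw[st$open] + log(asm$opening_rate / asm$closing_rate)
  w <- exp(lw - max(lw))
  p <- w / sum(w)
  names(p) <- st$label
  p
}
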