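# Independent oracles used across the suite. These deliberately do not
# share code with the package's primary propagation/equilibrium paths.

# --- explicit-subunit chain: 2^3 common combinations x distinct x open ----
# 17 states: (a1, a2, a3, d) closed/open flag; open reachable only from
# (1,1,1,1). No aggregation, no multiplicity bookkeeping.
explicit_chain <- function(asm, V, pc) {
  ac <- rate_alpha(asm$common, V, pc)
  bc <- rate_beta(asm$common, V, pc)
  ad <- rate_alpha(asm$distinct, V, pc)
  bd <- rate_beta(asm$distinct, V, pc)
  conf <- expand.grid(a1 = 0:1, a2 = 0:1, a3 = 0:1, d = 0:1)
  n <- nrow(conf) + 1L  # + open
  Q <- matrix(0, n, n)
  idx <- function(a1, a2, a3, d) {
    which(conf$a1 == a1 & conf$a2 == a2 & conf$a3 == a3 & conf$d == d)
  }
  for (i in seq_len(nrow(conf))) {
    st <- conf[i, ]
    for (s in 1:3) {
      a <- unlist(st[1:3])
      if (a[s] == 0) {
        a2v <- a; a2v[s] <- 1
        Q[i, idx(a2v[1], a2v[2], a2v[3], st$d)] <- ac
      } else {
        a2v <- a; a2v[s] <- 0
        Q[i, idx(a2v[1], a2v[2], a2v[3], st$d)] <- bc
      }
    }
    Q[i, idx(st$a1, st$a2, st$a3, 1 - st$d)] <- if (st$d == 0) ad else bd
  }
  full <- idx(1, 1, 1, 1)
  Q[full, n] <- asm$opening_rate
  Q[n, full] <- asm$closing_rate
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  # map each explicit state to the aggregated (n_active, d, open) class
  class_of <- c(
    2L * (conf$a1 + conf$a2 + conf$a3) + conf$d + 1L, 9L)
  list(Q = Q, class_of = class_of, conf = conf)
}

# equilibrium of an arbitrary generator from its null space (SVD), an
# algebra-only alternative to the package's product-form solution
nullspace_equilibrium <- function(Q) {
  sv <- svd(t(Q))
  v <- sv$v[, ncol(sv$v)]
  v <- v / sum(v)
  if (any(v < -1e-12)) v <- -v
  v / sum(v)
}

# classical RK4 with fixed substeps on a constant generator
rk4_propagate <- function(Q, p0, t_end, n_sub) {
  h <- t_end / n_sub
  p <- p0
  f <- function(p) as.numeric(p %*% Q)
  for (i in seq_len(n_sub)) {
    k1 <- f(p)
    k2 <- f(p + h / 2 * k1)
    k3 <- f(p + h / 2 * k2)
    k4 <- f(p + h * k3)
    p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  p
}

# matrix-exponential occupancy at arbitrary times for a constant generator
expm_at <- function(Q, p0, t) {
  as.numeric(p0 %*% as.matrix(Matrix::expm(Q * t)))
}

# expected charge (e0 per channel) of an occupancy vector
expected_charge <- function(space, p) sum(space$state_charge * p)

# build a current_trace from raw vectors (for fitter unit tests)
make_trace <- function(time, current, step_voltage = 0, kind = "gating",
                       units = "pA", segments = NULL) {
  structure(list(time = time, current = current,
                 step_voltage = step_voltage, kind = kind, units = units,
                 segments = segments, metadata = list()),
            class = "current_trace")
}
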