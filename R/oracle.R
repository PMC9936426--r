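# Independent steady-state oracle.
#
# The ODE fixed point satisfies x_n = S(omega_n(x)) / gamma_n. A damped
# fixed-point iteration solves this directly, without any time stepping, so
# it serves as an independent cross-check of the Runge-Kutta integrator in
# the test-suite. Switch rules are re-resolved against every candidate
# state, exactly as the integrator does per step.

#' Damped fixed-point steady-state oracle
#'
#' Iterates `x <- (1 - damping) x + damping S(omega(x)) / gamma` (with
#' clamped nodes pinned) until the fixed-point residual
#' `max |x - S(omega(x)) / gamma|` falls below `tol`. Intended for small
#' networks; non-convergence (multistability on a cycle, oscillations) is
#' reported, not raised. When `initial` is `NULL` the iteration starts from
#' the all-zero state and the all-half / all-one states are additionally
#' probed and reported as `alternatives` when they reach distinct fixed
#' points.
#'
#' @param net an [interactome()].
#' @param clamps named numeric vector of clamped nodes.
#' @param initial optional named starting state; suppresses the extra
#'   starts.
#' @param damping damping factor in (0, 1].
#' @param tol fixed-point residual tolerance.
#' @param max_iter iteration cap.
#' @return list with `state` (named vector), `converged`, `residual`,
#'   `iterations`, and (for the default starts) `alternatives`.
#' @export
fixed_point_oracle <- function(net, clamps = NULL, initial = NULL,
                               damping = 0.3, tol = 1e-9, max_iter = 50000) {
  ids <- net$nodes$id
  N <- length(ids)
  h <- net$nodes$h; E <- exp(0.5 * h); gamma <- net$nodes$gamma
  clamp_idx <- integer(0); clamp_vals <- numeric(0)
  if (!is.null(clamps) && length(clamps) > 0) {
    cl <- resolve_nodes(net, names(clamps))
    clamp_idx <- match(cl, ids)
    clamp_vals <- unname(clamps)
  }
  rules <- net$switch_rules
  watch_idx <- vapply(rules, function(r) match(r$watch, ids), integer(1))
  thresholds <- vapply(rules, function(r) r$threshold, numeric(1))
  cache <- new.env(parent = emptyenv())
  topo_for <- function(x) {
    flags <- if (length(rules)) unname(x[watch_idx] > thresholds) else logical(0)
    key <- if (length(flags)) paste(as.integer(flags), collapse = "") else "0"
    topo <- cache[[key]]
    if (is.null(topo)) {
      topo <- build_topology_matrices(net, flags)
      cache[[key]] <- topo
    }
    topo
  }
  solve_from <- function(x0) {
    x <- x0
    if (length(clamp_idx)) x[clamp_idx] <- clamp_vals
    for (it in seq_len(max_iter)) {
      target <- sigmoid_core(omega_all(x, topo_for(x)), h, E) / gamma
      target[target > 1] <- 1
      if (length(clamp_idx)) target[clamp_idx] <- clamp_vals
      res <- max(abs(x - target))
      if (res < tol)
        return(list(state = stats::setNames(x, ids), converged = TRUE,
                    residual = res, iterations = it))
      x <- (1 - damping) * x + damping * target
    }
    list(state = stats::setNames(x, ids), converged = FALSE,
         residual = res, iterations = max_iter)
  }

  if (!is.null(initial)) {
    x0 <- numeric(N)
    hit <- resolve_nodes(net, names(initial))
    x0[match(hit, ids)] <- unname(initial)
    return(solve_from(x0))
  }
  primary <- solve_from(numeric(N))
  alts <- list()
  for (start in list(rep(0.5, N), rep(1, N))) {
    cand <- solve_from(start)
    if (cand$converged &&
        (!primary$converged ||
         max(abs(cand$state - primary$state)) > 1e-6)) {
      alts[[length(alts) + 1L]] <- cand
    }
  }
  primary$alternatives <- alts
  primary
}
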