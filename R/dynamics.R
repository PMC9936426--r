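# Continuous dynamics over a signed interactome.
#
# Each node n carries a normalized activation x_n in [0, 1]. Its incoming
# activating (weights alpha) and inhibiting (weights beta) edges are folded
# into one normalized input omega_n in [0, 1]; the node then relaxes towards
# a sigmoidal response S(omega_n) with gain h and decays at rate gamma:
#
#   dx_n/dt = S(omega_n) - gamma_n * x_n
#
# Stimuli are modelled by clamping nodes at a fixed value for the whole
# integration. Switch rules rewrite the effective topology whenever their
# watch node exceeds its threshold (re-evaluated once per step, reversibly).

#' Integration settings
#'
#' @param dt fixed Runge-Kutta step size (time units).
#' @param t_max integration horizon.
#' @param convergence_tol steady state is declared when the largest
#'   per-node |dx/dt| among unclamped nodes stays below this value for one
#'   full time unit.
#' @param clamp named numeric vector of nodes held fixed (values in [0, 1])
#'   for the entire integration.
#' @param method `"rk4"` (default) or `"euler"` (first order; used as an
#'   independent consistency check in the test-suite).
#' @param record_stride store every `record_stride`-th step in trajectories.
#' @param oscillation_tol trailing-window amplitude above which a
#'   non-converged run is flagged as oscillating (its reported state is then
#'   the time-average over the last 10 percent of the horizon).
#' @return a list of class `"cnet_config"`.
#' @export
integration_config <- function(dt = 0.01, t_max = 50, convergence_tol = 1e-6,
                               clamp = NULL, method = c("rk4", "euler"),
                               record_stride = 1L, oscillation_tol = 1e-3) {
  method <- match.arg(method)
  stopifnot(dt > 0, t_max >= dt, convergence_tol > 0, record_stride >= 1)
  if (!is.null(clamp)) {
    if (is.null(names(clamp)) || any(!nzchar(names(clamp))))
      stop_cnet("clamp must be a named numeric vector",
                class = "cnet_validation_error")
    if (any(clamp < 0 | clamp > 1))
      stop_cnet("clamp values must lie in [0, 1]",
                class = "cnet_validation_error")
  }
  structure(list(dt = dt, t_max = t_max, convergence_tol = convergence_tol,
                 clamp = clamp, method = method,
                 record_stride = as.integer(record_stride),
                 oscillation_tol = oscillation_tol,
                 switch_threshold_policy = "strictly_above"),
            class = "cnet_config")
}

#' Sigmoidal response function
#'
#' Normalized sigmoid mapping the total regulatory input omega onto a
#' production rate, anchored so that S(0) = 0, S(0.5) = 0.5 and S(1) = 1
#' for every gain h > 0:
#' `S(w) = (e^{-h(w - 1/2)} - e^{h/2}) / ((1 - e^{h/2}) (1 + e^{-h(w - 1/2)}))`.
#' Larger h gives a steeper, more switch-like response; the packaged
#' networks use h = 10.
#'
#' @param omega regulatory input in [0, 1] (vectorized).
#' @param h sigmoid gain, h > 0 (scalar or vector).
#' @return S(omega), in [0, 1].
#' @export
sigmoid_response <- function(omega, h = 10) {
  if (any(!is.finite(omega)) || any(omega < 0 | omega > 1))
    stop_cnet("omega must lie in [0, 1]", class = "cnet_domain_error")
  if (any(h <= 0))
    stop_cnet("h must be > 0", class = "cnet_domain_error")
  sigmoid_core(omega, h, exp(0.5 * h))
}

# unchecked vectorized core; E = exp(0.5 * h) precomputed
sigmoid_core <- function(omega, h, E) {
  tt <- exp(-h * (omega - 0.5))
  out <- (tt - E) / ((1 - E) * (1 + tt))
  bad <- !is.finite(tt)
  if (any(bad)) out[bad] <- 1 / (1 - E[bad])  # tt -> Inf limit
  out
}

#' Total normalized regulatory input of one node
#'
#' Folds a node's activator set (weights alpha, values `x^a`) and inhibitor
#' set (weights beta, values `x^i`) into a single input omega in [0, 1].
#' With `A = sum(alpha * x^a)` and `B = sum(beta * x^i)`:
#' activators only: `omega = (1 + sum(alpha))/sum(alpha) * A/(1 + A)`;
#' inhibitors only: `omega = 1 - (1 + sum(beta))/sum(beta) * B/(1 + B)`;
#' both: the product of the two terms; no inputs at all: `omega = 0`
#' (pure decay -- an unclamped source node relaxes to zero).
#'
#' @param net an [interactome()].
#' @param node node name (synonyms accepted).
#' @param state named numeric vector of activations covering the input nodes.
#' @param effective if `TRUE` (default) the switch rules are resolved
#'   against `state` before reading the node's inputs.
#' @return list with `omega` and `case` (one of `"mixed"`,
#'   `"activators_only"`, `"inhibitors_only"`, `"no_inputs"`).
#' @export
compute_omega <- function(net, node, state, effective = TRUE) {
  id <- resolve_nodes(net, node)
  edges <- if (effective) effective_topology(net, state)$edges else net$edges
  incoming <- edges[edges$target == id, , drop = FALSE]
  if (any(incoming$weight <= 0))
    stop_cnet("negative or zero edge weight on inputs of ", id,
              class = "cnet_validation_error")
  acts <- incoming[incoming$sign == "activates", , drop = FALSE]
  inhs <- incoming[incoming$sign == "inhibits", , drop = FALSE]
  need <- unique(incoming$source)
  if (!all(need %in% names(state)))
    stop_cnet("state does not cover input node(s): ",
              paste(setdiff(need, names(state)), collapse = ", "),
              class = "cnet_lookup_error")
  act_term <- 1
  if (nrow(acts) > 0) {
    sa <- sum(acts$weight); A <- sum(acts$weight * state[acts$source])
    act_term <- (1 + sa) / sa * A / (1 + A)
  }
  inh_term <- 1
  if (nrow(inhs) > 0) {
    sb <- sum(inhs$weight); B <- sum(inhs$weight * state[inhs$source])
    inh_term <- 1 - (1 + sb) / sb * B / (1 + B)
  }
  cs <- if (nrow(acts) > 0 && nrow(inhs) > 0) "mixed"
        else if (nrow(acts) > 0) "activators_only"
        else if (nrow(inhs) > 0) "inhibitors_only"
        else "no_inputs"
  omega <- if (cs == "no_inputs") 0 else act_term * inh_term
  list(omega = min(1, max(0, omega)), case = cs)
}

#' Resolve the effective topology under the switch rules
#'
#' For each switch rule whose watch node is strictly above its threshold in
#' `state`, the rule's modifications are applied to the base edge set; at or
#' below the threshold the base topology is restored exactly (the switch is
#' reversible and memoryless). For the packaged chondrocyte networks this
#' implements the RGD-driven integrin conformational change: above
#' RGD = 0.5 the integrin-to-actin edges flip from activating to inhibiting,
#' the fibronectin inputs are removed, and RGD drives the integrins, which
#' then feed the catabolic NF-kB axis.
#'
#' @param net an [interactome()].
#' @param state named numeric activation vector (must cover watch nodes).
#' @return list with `edges` (effective edge data.frame) and `switched`
#'   (logical per rule).
#' @export
effective_topology <- function(net, state) {
  flags <- vapply(net$switch_rules, function(r)
    isTRUE(unname(state[r$watch]) > r$threshold), logical(1))
  list(edges = effective_edges(net, flags), switched = flags)
}

# apply the modifications of the flagged rules to the base edge set
effective_edges <- function(net, flags) {
  edges <- net$edges
  if (length(flags) == 0 || !any(flags)) return(edges)
  for (rule in net$switch_rules[flags]) {
    for (mod in rule$when_above) {
      hit <- edges$source == mod$source & edges$target == mod$target
      if (mod$op == "flip_sign") {
        edges$sign[hit] <- ifelse(edges$sign[hit] == "activates",
                                  "inhibits", "activates")
      } else if (mod$op == "remove_edge") {
        edges <- edges[!hit, , drop = FALSE]
      } else {
        edges <- rbind(edges, data.frame(source = mod$source,
                                         target = mod$target, sign = mod$sign,
                                         weight = mod$weight %||% 1,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  rownames(edges) <- NULL
  edges
}

# ---- vectorized engine ---------------------------------------------------

# adjacency matrices and constants for one effective topology
build_topology_matrices <- function(net, flags) {
  ids <- net$nodes$id
  N <- length(ids)
  edges <- effective_edges(net, flags)
  Wa <- matrix(0, N, N, dimnames = NULL)
  Wi <- matrix(0, N, N, dimnames = NULL)
  if (nrow(edges) > 0) {
    si <- match(edges$source, ids); ti <- match(edges$target, ids)
    act <- edges$sign == "activates"
    Wa[cbind(ti[act], si[act])] <- edges$weight[act]
    Wi[cbind(ti[!act], si[!act])] <- edges$weight[!act]
  }
  sum_a <- rowSums(Wa); sum_i <- rowSums(Wi)
  ia <- which(sum_a > 0); ii <- which(sum_i > 0)
  list(Wa = Wa, Wi = Wi, ia = ia, ii = ii,
       caf = (1 + sum_a[ia]) / sum_a[ia],
       cif = (1 + sum_i[ii]) / sum_i[ii],
       none = which(sum_a == 0 & sum_i == 0))
}

# omega for all nodes at once (unchecked, clipped into [0, 1])
omega_all <- function(x, topo) {
  N <- length(x)
  act <- rep.int(1, N); inh <- rep.int(1, N)
  if (length(topo$ia) > 0) {
    sax <- (topo$Wa %*% x)[topo$ia]
    act[topo$ia] <- topo$caf * sax / (1 + sax)
  }
  if (length(topo$ii) > 0) {
    six <- (topo$Wi %*% x)[topo$ii]
    inh[topo$ii] <- 1 - topo$cif * six / (1 + six)
  }
  om <- act * inh
  if (length(topo$none) > 0) om[topo$none] <- 0
  om[om < 0] <- 0
  om[om > 1] <- 1
  om
}

#' Time derivative of the system state
#'
#' `dx_n/dt = S(omega_n) - gamma_n x_n` for unclamped nodes and 0 for
#' clamped ones. The effective topology is resolved from `state`.
#'
#' @param state named numeric activation vector over all nodes.
#' @param net an [interactome()].
#' @param config an [integration_config()] (supplies the clamp set).
#' @return named numeric vector of derivatives.
#' @export
time_derivative <- function(state, net, config = integration_config()) {
  ids <- net$nodes$id
  x <- unname(state[ids])
  flags <- vapply(net$switch_rules, function(r)
    isTRUE(unname(state[r$watch]) > r$threshold), logical(1))
  topo <- build_topology_matrices(net, flags)
  h <- net$nodes$h
  dx <- sigmoid_core(omega_all(x, topo), h, exp(0.5 * h)) - net$nodes$gamma * x
  if (!is.null(config$clamp)) {
    cl <- resolve_nodes(net, names(config$clamp))
    dx[match(cl, ids)] <- 0
  }
  stats::setNames(dx, ids)
}

# sparse edge-list topology for one switch-flag combination (0-based
# indices, as consumed by the compiled core)
sparse_topology <- function(net, flags, ids) {
  N <- length(ids)
  edges <- effective_edges(net, flags)
  suma <- numeric(N); sumi <- numeric(N)
  if (nrow(edges) > 0) {
    si <- match(edges$source, ids) - 1L
    ti <- match(edges$target, ids) - 1L
    act <- edges$sign == "activates"
    if (any(act)) {
      s <- rowsum(edges$weight[act], ti[act])
      suma[as.integer(rownames(s)) + 1L] <- s[, 1]
    }
    if (any(!act)) {
      s <- rowsum(edges$weight[!act], ti[!act])
      sumi[as.integer(rownames(s)) + 1L] <- s[, 1]
    }
    list(a_src = si[act], a_tgt = ti[act], a_w = edges$weight[act],
         i_src = si[!act], i_tgt = ti[!act], i_w = edges$weight[!act],
         suma = suma, sumi = sumi)
  } else {
    list(a_src = integer(0), a_tgt = integer(0), a_w = numeric(0),
         i_src = integer(0), i_tgt = integer(0), i_w = numeric(0),
         suma = suma, sumi = sumi)
  }
}

# shared fixed-step integrator around the compiled core.
# record: "all" or "none".
run_engine <- function(net, config, initial = NULL, record = "all",
                       .dt_override = NULL) {
  ids <- net$nodes$id
  N <- length(ids)
  h <- net$nodes$h
  gamma <- net$nodes$gamma
  dt <- .dt_override %||% config$dt
  n_steps <- ceiling(config$t_max / dt)
  sustain_needed <- max(1L, as.integer(round(1 / dt)))

  clamp_idx <- integer(0); clamp_vals <- numeric(0)
  if (!is.null(config$clamp) && length(config$clamp) > 0) {
    cl_ids <- resolve_nodes(net, names(config$clamp))
    if (anyDuplicated(cl_ids))
      stop_cnet("conflicting clamps for node(s): ",
                paste(unique(cl_ids[duplicated(cl_ids)]), collapse = ", "),
                class = "cnet_validation_error")
    clamp_idx <- match(cl_ids, ids)
    clamp_vals <- unname(config$clamp)
  }
  nclamp <- length(clamp_idx)

  x <- numeric(N)
  if (!is.null(initial)) {
    if (is.null(names(initial)) && length(initial) == N) {
      x <- as.numeric(initial)
    } else {
      hit <- resolve_nodes(net, names(initial))
      x[match(hit, ids)] <- unname(initial)
    }
  }
  if (any(x < 0 | x > 1))
    stop_cnet("initial state must lie in [0, 1]",
              class = "cnet_validation_error")
  if (nclamp) x[clamp_idx] <- clamp_vals

  rules <- net$switch_rules
  n_rules <- length(rules)
  if (n_rules > 12)
    stop_cnet("more than 12 switch rules are not supported",
              class = "cnet_validation_error")
  watch_idx <- vapply(rules, function(r) match(r$watch, ids), integer(1))
  thresholds <- vapply(rules, function(r) r$threshold, numeric(1))

  # one sparse topology per switch-flag bitmask
  masks <- seq_len(2^n_rules) - 1L
  topos <- lapply(masks, function(m) {
    flags <- as.logical(bitwAnd(m, bitwShiftL(1L, seq_len(n_rules) - 1L)))
    sparse_topology(net, flags, ids)
  })

  do_record <- identical(record, "all")
  res <- .rk4_core(
    topos, h, gamma, clamp_idx - 1L, clamp_vals, watch_idx - 1L, thresholds,
    x, dt, as.integer(n_steps), sustain_needed, config$convergence_tol,
    identical(config$method, "euler"), do_record,
    as.integer(config$record_stride), 0.9 * config$t_max,
    config$oscillation_tol)

  if (isTRUE(res$violation)) {
    if (is.null(.dt_override)) {
      # one retry at half the step, then give up
      return(run_engine(net, config, initial, record, .dt_override = dt / 2))
    }
    stop_cnet("state left [0, 1] by more than 1e-12 (network ", net$name,
              ")", class = "cnet_numerical_error")
  }

  final_flags <- if (n_rules) as.logical(
    bitwAnd(res$mask, bitwShiftL(1L, seq_len(n_rules) - 1L)) > 0) else logical(0)

  out <- list(
    steady_state = stats::setNames(res$x, ids),
    converged = res$converged, oscillating = res$oscillating,
    switched = final_flags, t_end = res$t_end, dt_used = dt, config = config)
  if (do_record) {
    keep <- seq_len(res$rec)
    states <- res$states[keep, , drop = FALSE]
    colnames(states) <- ids
    out$times <- res$times[keep]
    out$states <- states
  }
  out
}

#' Integrate the network dynamics
#'
#' Fixed-step classic Runge-Kutta (order 4) integration from an initial
#' state (all-zero by default), with clamped nodes held bit-identically at
#' their clamp value at every step. Switch rules are re-evaluated once per
#' step from the step-start state and held fixed across the four
#' sub-stages. Integration stops early once the largest per-node |dx/dt|
#' stays below `convergence_tol` for one full time unit.
#'
#' @param net an [interactome()].
#' @param config an [integration_config()].
#' @param initial named numeric vector of initial activations (missing
#'   nodes start at 0), or `NULL` for the all-zero state.
#' @return an object of class `"cnet_trajectory"`: `times`, `states`
#'   (matrix, one column per node), `converged`, `oscillating`,
#'   `steady_state` (named vector).
#' @export
simulate_network <- function(net, config = integration_config(),
                             initial = NULL) {
  res <- run_engine(net, config, initial, record = "all")
  structure(res, class = "cnet_trajectory")
}

#' @export
print.cnet_trajectory <- function(x, ...) {
  cat("<cnet_trajectory> ", length(x$times), " recorded states, t_end = ",
      x$t_end, ", converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Steady state under a set of clamps
#'
#' Runs the dynamics to convergence and returns the terminal state. If the
#' horizon is reached without convergence and the trailing 10 percent of
#' the run shows an amplitude above `oscillation_tol`, the state is flagged
#' as oscillating and reported as the time-average over that window.
#'
#' @param net an [interactome()].
#' @param clamps named numeric vector of clamped nodes (merged over
#'   `config$clamp`; these win on conflict).
#' @param config an [integration_config()].
#' @param initial optional named initial state (default all-zero).
#' @return an object of class `"cnet_state"`: `values` (named vector),
#'   `converged`, `oscillating`, `switched`, `clamps`.
#' @export
find_steady_state <- function(net, clamps = NULL,
                              config = integration_config(),
                              initial = NULL) {
  merged <- merge_clamps(net, config$clamp, clamps)
  config$clamp <- merged
  res <- run_engine(net, config, initial, record = "none")
  structure(list(values = res$steady_state, converged = res$converged,
                 oscillating = res$oscillating, switched = res$switched,
                 clamps = merged, dt_used = res$dt_used,
                 config_hash = config_hash(list(config, merged))),
            class = "cnet_state")
}

merge_clamps <- function(net, base, override) {
  if (is.null(base)) base <- numeric(0)
  if (is.null(override)) override <- numeric(0)
  if (length(base)) names(base) <- resolve_nodes(net, names(base))
  if (length(override)) names(override) <- resolve_nodes(net, names(override))
  clash <- intersect(names(base), names(override))
  if (length(clash) > 0)
    message("clamp override for: ", paste(clash, collapse = ", "))
  out <- c(override, base[setdiff(names(base), names(override))])
  if (length(out) == 0) NULL else out
}

#' @export
print.cnet_state <- function(x, ...) {
  cat("<cnet_state> ", length(x$values), " nodes, converged = ", x$converged,
      if (x$oscillating) " (oscillating, window-averaged)" else "",
      "\n", sep = "")
  top <- sort(x$values, decreasing = TRUE)
  show <- utils::head(top[top > 0.01], 10)
  if (length(show) > 0) {
    cat("  most active:", paste(sprintf("%s=%.3f", names(show), show),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract activation values from states or vectors
#' @param x a `cnet_state`, `cnet_trajectory`, or named numeric vector.
#' @return named numeric vector of activations.
#' @export
state_values <- function(x) {
  if (inherits(x, "cnet_state")) return(x$values)
  if (inherits(x, "cnet_trajectory")) return(x$steady_state)
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop_cnet("cannot interpret object as a system state",
            class = "cnet_validation_error")
}

#' Write a trajectory as TSV
#' @param traj a `cnet_trajectory`.
#' @param path output file.
#' @param full_precision write full float precision instead of 6
#'   significant digits.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, full_precision = FALSE) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  write_tsv_with_meta(df, path, meta = c(
    paste0("config_hash: ", config_hash(traj$config)),
    paste0("converged: ", traj$converged)),
    full_precision = full_precision)
}

#' Write a steady state as two-column TSV
#' @param state a `cnet_state`.
#' @param path output file.
#' @param full_precision write full float precision.
#' @return `path`, invisibly.
#' @export
write_steady_state <- function(state, path, full_precision = FALSE) {
  df <- data.frame(node = names(state$values),
                   activation = unname(state$values))
  write_tsv_with_meta(df, path, meta = c(
    paste0("config_hash: ", state$config_hash),
    paste0("converged: ", state$converged),
    paste0("oscillating: ", state$oscillating)),
    full_precision = full_precision)
}
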