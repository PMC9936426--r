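# Analytic motif networks and randomized signed networks.
#
# Every other module is testable against these without the packaged
# assets. Each motif's steady state under its documented clamps has a
# closed form through the fixed point x* = S(omega(x*)).

#' Construct a named analytic motif network
#'
#' Available motifs and their documented analytic steady states (h = 10,
#' gamma = 1, weights 1 throughout):
#'
#' * `single_chain`: `SRC -> SNK`. With SRC clamped at c, the sink settles
#'   at `S(2c / (1 + c))`; c = 1 gives exactly 1, c = 0.5 gives
#'   S(2/3) (about 0.8458).
#' * `double_activator`: `A -> T`, `B -> T`. With A = 1, B = 0 the target
#'   input is omega = (3/2)(1/2) = 0.75.
#' * `inhibitor_only`: `I -| T`. With I clamped at 0, omega = 1 and T
#'   settles at exactly 1; with I = 1, omega = 0 and T at 0.
#' * `toggle`: mutual inhibition `A -| B`, `B -| A`. With A clamped at 1,
#'   B settles at 0 (and vice versa).
#' * `rgd_switch_motif`: `FN -> {integrinA, integrinB} -> actin` with two
#'   switch rules watching RGD at threshold 0.5 (above: the integrin-actin
#'   edges flip to inhibiting, the FN inputs are removed and RGD drives the
#'   integrins). With FN clamped at 1: actin is 1 for RGD clamped at 0 and
#'   0 for RGD clamped at 1.
#' * `validation_demo`: two sensors with guaranteed directional responses
#'   for the validation harness: `S_UP -> T_UP` (up) and `S_DOWN -| T_DOWN`
#'   where T_DOWN, having only inhibitors, is constitutively ON at baseline
#'   (omega = 1) and is shut off when S_DOWN is clamped high. Its bundled
#'   expectation table ([demo_expected_responses()]) holds by construction.
#'
#' @param name motif name.
#' @return an [interactome()].
#' @export
make_motif <- function(name = c("single_chain", "double_activator",
                                "inhibitor_only", "toggle",
                                "rgd_switch_motif", "validation_demo")) {
  if (is.character(name) && length(name) == 1 &&
      !name %in% eval(formals(make_motif)$name))
    stop_cnet("unknown motif '", name, "'; available: ",
              paste(eval(formals(make_motif)$name), collapse = ", "),
              class = "cnet_lookup_error")
  name <- match.arg(name)
  ed <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(source = m[, 1], target = m[, 2], sign = m[, 3],
               weight = 1, stringsAsFactors = FALSE)
  }
  switch(name,
    single_chain = interactome(
      edges = ed("SRC", "SNK", "activates"), name = name),
    double_activator = interactome(
      edges = ed("A", "T", "activates", "B", "T", "activates"), name = name),
    inhibitor_only = interactome(
      edges = ed("I", "T", "inhibits"), name = name),
    toggle = interactome(
      edges = ed("A", "B", "inhibits", "B", "A", "inhibits"), name = name),
    rgd_switch_motif = interactome(
      nodes = c("FN", "RGD", "integrinA", "integrinB", "actin"),
      edges = ed("FN", "integrinA", "activates",
                 "FN", "integrinB", "activates",
                 "integrinA", "actin", "activates",
                 "integrinB", "actin", "activates"),
      switch_rules = list(
        switch_rule("RGD", 0.5, list(
          flip_sign("integrinA", "actin"),
          remove_edge("FN", "integrinA"),
          add_edge("RGD", "integrinA", "activates"))),
        switch_rule("RGD", 0.5, list(
          flip_sign("integrinB", "actin"),
          remove_edge("FN", "integrinB"),
          add_edge("RGD", "integrinB", "activates")))),
      name = name),
    validation_demo = interactome(
      edges = ed("S_UP", "T_UP", "activates",
                 "S_DOWN", "T_DOWN", "inhibits"),
      name = name)
  )
}

#' Expectation table bundled with the validation_demo motif
#'
#' Directions guaranteed by construction (see [make_motif()]), giving the
#' validation harness a 100 percent accuracy ground truth that is
#' independent of any packaged network asset.
#'
#' @return data.frame with columns `mechanosensor`, `target`, `direction`,
#'   `citation`.
#' @export
demo_expected_responses <- function() {
  data.frame(
    mechanosensor = c("S_UP", "S_DOWN"),
    target = c("T_UP", "T_DOWN"),
    direction = c("up", "down"),
    citation = "validation_demo construction",
    stringsAsFactors = FALSE)
}

#' Generate a random signed directed network
#'
#' Simple digraph (no self-loops, no parallel edges) with edges sampled
#' uniformly without replacement; `round(inhibitor_fraction * n_edges)`
#' edges are inhibiting. Generation is a pure function of the arguments:
#' the same seed always yields the same network, and the caller's RNG state
#' is left untouched.
#'
#' @param n_nodes number of nodes (>= 2); ids `n01`, `n02`, ...
#' @param n_edges number of edges (<= n_nodes * (n_nodes - 1)).
#' @param inhibitor_fraction fraction of inhibiting edges in [0, 1].
#' @param seed integer seed.
#' @return an [interactome()].
#' @export
make_random_network <- function(n_nodes, n_edges, inhibitor_fraction = 0.3,
                                seed = 1) {
  stopifnot(n_nodes >= 2, n_edges >= 0,
            inhibitor_fraction >= 0, inhibitor_fraction <= 1)
  if (n_edges > n_nodes * (n_nodes - 1))
    stop_cnet("n_edges exceeds the number of ordered node pairs",
              class = "cnet_validation_error")
  ids <- sprintf("n%02d", seq_len(n_nodes))
  with_private_seed(seed, {
    # ordered pairs, self-loops excluded
    pair_idx <- sample.int(n_nodes * (n_nodes - 1), n_edges)
    src <- (pair_idx - 1) %/% (n_nodes - 1) + 1
    off <- (pair_idx - 1) %% (n_nodes - 1) + 1
    tgt <- ifelse(off >= src, off + 1L, off)
    n_inh <- round(inhibitor_fraction * n_edges)
    sign <- rep("activates", n_edges)
    if (n_inh > 0) sign[sample.int(n_edges, n_inh)] <- "inhibits"
    edges <- data.frame(source = ids[src], target = ids[tgt], sign = sign,
                        weight = 1, stringsAsFactors = FALSE)
    interactome(nodes = ids, edges = edges,
                name = sprintf("random_n%d_e%d_s%d", n_nodes, n_edges, seed))
  })
}
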