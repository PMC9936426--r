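# Built-in mechano-inflammatory stimulation scenarios and reporting.

#' Create a stimulation scenario
#'
#' A scenario is a named set of clamped nodes: each clamp is held at its
#' value for the entire integration, modelling a sustained external
#' stimulus (a mechanical load regime encoded by its mechanoreceptor, or a
#' biochemical micro-environment encoded by its cytokines).
#'
#' @param name scenario label.
#' @param clamps named numeric vector, values in [0, 1].
#' @return an object of class `"cnet_scenario"`.
#' @export
scenario <- function(name, clamps) {
  if (length(clamps) > 0 && (is.null(names(clamps)) ||
                             any(clamps < 0 | clamps > 1)))
    stop_cnet("scenario clamps must be a named vector with values in [0, 1]",
              class = "cnet_validation_error")
  structure(list(name = name, clamps = clamps), class = "cnet_scenario")
}

#' The six built-in micro-environment scenarios
#'
#' Each scenario clamps its stimulus nodes at 1 for the whole simulation:
#'
#' * `PO` (physio-osmotic, healthy): TRPV4 and integrin alpha5beta1 --
#'   cyclic dynamic compression plus physiological osmotic pressure.
#' * `INF` (inflammation / synovitis): IL-1b, TNF-a, IL-6, IL-8, IL-17,
#'   IL-18.
#' * `antiINF` (hemoderivative anti-inflammatory treatment): TGF-b, IGF1,
#'   IL-4, IL-13, IL-1Ra.
#' * `HSC` (hydrostatic static compression): PTCH.
#' * `HC` (high / injurious compression): PIEZO.
#' * `TS` (excessive cyclic tensile strain): integrin aVb5.
#'
#' With `variants = TRUE` two documented alternatives are appended:
#' `antiINF_prose` (IL-10 in place of IL-13, matching the treatment
#' composition described in prose) and `TS_aVb3` (tensile strain remapped
#' to integrin aVb3, an internal inconsistency of the source literature --
#' both are provided, neither endorsed).
#'
#' @param variants include the two alternative scenario encodings.
#' @return named list of [scenario()] objects.
#' @export
builtin_scenarios <- function(variants = FALSE) {
  cl <- function(nodes) stats::setNames(rep(1, length(nodes)), nodes)
  out <- list(
    PO = scenario("PO", cl(c("TRPV4", "a5b1"))),
    INF = scenario("INF", cl(c("IL1b", "TNFa", "IL6", "IL8", "IL17", "IL18"))),
    antiINF = scenario("antiINF", cl(c("TGFb", "IGF1", "IL4", "IL13", "IL1Ra"))),
    HSC = scenario("HSC", cl("PTCH")),
    HC = scenario("HC", cl("PIEZO")),
    TS = scenario("TS", cl("aVb5")))
  if (variants) {
    out$antiINF_prose <- scenario("antiINF_prose",
                                  cl(c("TGFb", "IGF1", "IL4", "IL10", "IL1Ra")))
    out$TS_aVb3 <- scenario("TS_aVb3", cl("aVb3"))
  }
  out
}

#' Run a scenario to steady state
#'
#' Scenario clamps are merged over any clamps already present in `config`
#' (the scenario wins on conflict, with a message).
#'
#' @param net an [interactome()].
#' @param scn a [scenario()] object or a built-in scenario name.
#' @param config an [integration_config()].
#' @param initial optional initial state (default all-zero).
#' @return a `cnet_state` (see [find_steady_state()]).
#' @export
run_scenario <- function(net, scn, config = integration_config(),
                         initial = NULL) {
  if (is.character(scn)) {
    all <- builtin_scenarios(variants = TRUE)
    if (!scn %in% names(all))
      stop_cnet("unknown scenario '", scn, "'; built-ins: ",
                paste(names(all), collapse = ", "),
                class = "cnet_lookup_error")
    scn <- all[[scn]]
  }
  find_steady_state(net, clamps = scn$clamps, config = config,
                    initial = initial)
}

#' Directional comparison of two steady states
#'
#' Calls a node `up` when `stimulated - baseline > epsilon`, `down` when
#' `baseline - stimulated > epsilon`, and `unchanged` otherwise. Both
#' states must cover the same node set; node order in the result is the
#' sorted node set.
#'
#' @param baseline,stimulated `cnet_state` objects or named vectors.
#' @param epsilon change-call threshold (default 0.05).
#' @return data.frame with columns `node`, `baseline`, `stimulated`,
#'   `direction`.
#' @export
compare_states <- function(baseline, stimulated, epsilon = 0.05) {
  b <- state_values(baseline); s <- state_values(stimulated)
  if (!setequal(names(b), names(s))) {
    diffs <- c(setdiff(names(b), names(s)), setdiff(names(s), names(b)))
    stop_cnet("state node sets differ: ", paste(diffs, collapse = ", "),
              class = "cnet_contract_error")
  }
  ids <- sort(names(b))
  d <- s[ids] - b[ids]
  direction <- ifelse(d > epsilon, "up", ifelse(d < -epsilon, "down",
                                                "unchanged"))
  data.frame(node = ids, baseline = unname(b[ids]),
             stimulated = unname(s[ids]), direction = unname(direction),
             stringsAsFactors = FALSE)
}

#' Default reporting panels
#'
#' Groups a network's nodes into the six standard reporting panels by node
#' category: pro-inflammatory mediators, anti-inflammatory cytokines,
#' transcription factors, degrading enzymes, structural proteins and growth
#' factors.
#'
#' @param net an [interactome()].
#' @return named list of node-id vectors.
#' @export
default_panels <- function(net) {
  cats <- c(pro_inflammatory = "pro_inflammatory",
            anti_inflammatory = "anti_inflammatory",
            transcription_factors = "transcription_factor",
            degrading_enzymes = "degrading_enzyme",
            structural_proteins = "structural_protein",
            growth_factors = "growth_factor")
  out <- lapply(cats, function(cc) net$nodes$id[net$nodes$category == cc])
  out[lengths(out) > 0]
}

#' Long-format panel report of scenario steady states
#'
#' One row per (panel, node, scenario), suitable for grouped bar plotting
#' of node activation levels across micro-environments.
#'
#' @param states named list of `cnet_state` objects (or named vectors), one
#'   per scenario.
#' @param grouping named list mapping panel names to node vectors; each
#'   node must exist in every state.
#' @return data.frame with columns `panel`, `node`, `scenario`,
#'   `activation`.
#' @export
panel_report <- function(states, grouping) {
  stopifnot(is.list(states), length(states) > 0, !is.null(names(states)))
  vals <- lapply(states, state_values)
  rows <- list()
  for (panel in names(grouping)) {
    for (node in grouping[[panel]]) {
      for (scn in names(vals)) {
        v <- vals[[scn]]
        if (!node %in% names(v))
          stop_cnet("panel '", panel, "' references unknown node: ", node,
                    class = "cnet_lookup_error")
        rows[[length(rows) + 1L]] <- data.frame(
          panel = panel, node = node, scenario = scn,
          activation = unname(v[node]), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
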