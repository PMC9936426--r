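# Qualitative validation against literature-expected mechanosensor
# responses.
#
# The harness clamps one mechanosensor at a time at full activation,
# simulates to steady state, and compares the direction of change of each
# annotated target node against its literature expectation (up / down),
# using the same epsilon threshold as the scenario comparisons. Accuracy is
# the fraction of well-replicated responses.

#' The packaged expected-response table
#'
#' Seventeen directional checks across seven mechanosensors (connexin
#' hemichannels, TRPV4, integrins alpha5beta1 and alphaVbeta3, PIEZO,
#' PTCH and PTHrP), transcribed from published 3D-culture chondrocyte
#' mechanobiology experiments.
#'
#' @return data.frame with columns `mechanosensor`, `target`, `direction`
#'   (`"up"`/`"down"`), `citation`.
#' @export
expected_responses <- function() {
  df <- utils::read.delim(cnet_extdata("expected_responses.tsv"),
                          stringsAsFactors = FALSE)
  df$mechanosensor <- canonical_node_id(df$mechanosensor)
  df$target <- canonical_node_id(df$target)
  df
}

#' Evaluate expected responses on a network
#'
#' The baseline is the unclamped steady state (from `initial`, all-zero by
#' default); for each distinct mechanosensor one additional steady state is
#' computed with that sensor clamped at 1 (each sensor is simulated once
#' and cached, so accuracy does not depend on check order). A check passes
#' when the observed direction under [compare_states()] with threshold
#' `epsilon` matches the expectation. Checks whose nodes do not resolve in
#' the network are marked unevaluable and excluded from the total with a
#' warning -- never silently passed.
#'
#' @param net an [interactome()].
#' @param responses expectation table (default [expected_responses()]).
#' @param config an [integration_config()].
#' @param epsilon direction-call threshold (default 0.05; recorded in the
#'   report).
#' @param initial optional baseline initial state.
#' @return an object of class `"cnet_validation"`: `checks` (data.frame
#'   with observed values, observed direction and pass flag), `n_pass`,
#'   `n_total`, `accuracy_percent`, `epsilon`.
#' @export
evaluate_expected_responses <- function(net, responses = expected_responses(),
                                        config = integration_config(),
                                        epsilon = 0.05, initial = NULL) {
  stopifnot(inherits(net, "interactome"))
  resolv <- function(ids) vapply(ids, function(x) {
    tryCatch(resolve_nodes(net, x), error = function(e) NA_character_)
  }, character(1))
  sens <- resolv(responses$mechanosensor)
  targ <- resolv(responses$target)
  evaluable <- !is.na(sens) & !is.na(targ)
  if (any(!evaluable))
    warning("unevaluable check(s) dropped (node not in network): ",
            paste(sprintf("%s->%s", responses$mechanosensor[!evaluable],
                          responses$target[!evaluable]), collapse = ", "))

  baseline <- find_steady_state(net, config = config, initial = initial)
  cache <- new.env(parent = emptyenv())
  sensor_state <- function(s) {
    st <- cache[[s]]
    if (is.null(st)) {
      st <- find_steady_state(net, clamps = stats::setNames(1, s),
                              config = config, initial = initial)
      cache[[s]] <- st
    }
    st
  }

  n <- nrow(responses)
  observed_dir <- rep(NA_character_, n)
  base_val <- stim_val <- rep(NA_real_, n)
  for (i in which(evaluable)) {
    st <- sensor_state(sens[i])
    cmp <- compare_states(baseline, st, epsilon)
    row <- cmp[cmp$node == targ[i], ]
    observed_dir[i] <- row$direction
    base_val[i] <- row$baseline
    stim_val[i] <- row$stimulated
  }
  passed <- evaluable & observed_dir == responses$direction
  checks <- data.frame(
    mechanosensor = responses$mechanosensor, target = responses$target,
    expected = responses$direction, baseline = base_val,
    stimulated = stim_val, observed = observed_dir,
    status = ifelse(!evaluable, "unevaluable",
                    ifelse(passed, "pass", "fail")),
    stringsAsFactors = FALSE)
  n_total <- sum(evaluable)
  n_pass <- sum(passed)
  structure(list(checks = checks, n_pass = n_pass, n_total = n_total,
                 accuracy_percent = if (n_total > 0) 100 * n_pass / n_total
                                    else NA_real_,
                 epsilon = epsilon, network = net$name),
            class = "cnet_validation")
}

#' @export
print.cnet_validation <- function(x, ...) {
  cat("<cnet_validation> network ", x$network, ": ", x$n_pass, "/", x$n_total,
      " replicated (", sprintf("%.2f", x$accuracy_percent),
      "%), epsilon = ", x$epsilon, "\n", sep = "")
  fails <- x$checks[x$checks$status != "pass", , drop = FALSE]
  if (nrow(fails) > 0) {
    cat("  not replicated:\n")
    for (i in seq_len(nrow(fails)))
      cat(sprintf("   %s -> %s: expected %s, observed %s (%s)\n",
                  fails$mechanosensor[i], fails$target[i], fails$expected[i],
                  fails$observed[i] %||% "NA", fails$status[i]))
  }
  invisible(x)
}

#' Write / read a validation report as TSV
#' @param report a `cnet_validation` object.
#' @param path file path.
#' @return `path` (write) or a data.frame of checks plus attributes (read).
#' @export
write_validation_report <- function(report, path) {
  write_tsv_with_meta(report$checks, path, meta = c(
    paste0("network: ", report$network),
    paste0("epsilon: ", report$epsilon),
    paste0("n_pass: ", report$n_pass),
    paste0("n_total: ", report$n_total),
    paste0("accuracy_percent: ",
           format(report$accuracy_percent, digits = 15))),
    full_precision = TRUE)
}

#' @rdname write_validation_report
#' @export
read_validation_report <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- lines[startsWith(lines, "# ")]
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(hit) == 0) NA else sub(paste0("^# ", key, ": "), "", hit[1])
  }
  checks <- read_tsv_skip_meta(path)
  structure(list(checks = checks,
                 n_pass = as.integer(get_meta("n_pass")),
                 n_total = as.integer(get_meta("n_total")),
                 accuracy_percent = as.numeric(get_meta("accuracy_percent")),
                 epsilon = as.numeric(get_meta("epsilon")),
                 network = get_meta("network")),
            class = "cnet_validation")
}
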