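# Full-factorial perturbation designs and balanced ANOVA decomposition.
#
# The six perturbation categories of the built-in design are the scenario
# node sets (INF, antiINF, PO, HSC, HC, TS); each category takes one of L
# clamp levels (0, 0.5, 1 by default) and all L^c combinations are
# simulated from a common baseline. Per node, the steady-state variance
# across runs is decomposed into main effects and two-way interactions; the
# share of each effect, I = PSS / TSS * 100, ranks its influence.

#' Build a full-factorial design
#'
#' Enumerates all `L^c` level combinations exactly once, in odometer order
#' with the last category varying fastest.
#'
#' @param categories named list mapping category names to disjoint node-id
#'   vectors.
#' @param levels numeric clamp levels (>= 2 of them), each in [0, 1].
#' @return an object of class `"cnet_design"` with elements `categories`,
#'   `levels` and `runs` (data.frame of `L^c` rows, one column per
#'   category).
#' @export
build_design <- function(categories, levels = c(0, 0.5, 1)) {
  stopifnot(is.list(categories), length(categories) >= 1,
            !is.null(names(categories)), length(levels) >= 2,
            all(levels >= 0 & levels <= 1))
  all_nodes <- unlist(categories, use.names = FALSE)
  if (anyDuplicated(all_nodes))
    stop_cnet("category node sets overlap: ",
              paste(unique(all_nodes[duplicated(all_nodes)]), collapse = ", "),
              "; a node cannot take two clamp values",
              class = "cnet_design_error")
  # odometer order, last category fastest
  grid <- expand.grid(rev(lapply(categories, function(...) levels)),
                      KEEP.OUT.ATTRS = FALSE)
  runs <- grid[, rev(seq_along(categories)), drop = FALSE]
  names(runs) <- names(categories)
  rownames(runs) <- NULL
  structure(list(categories = categories, levels = levels, runs = runs),
            class = "cnet_design")
}

#' Default six-category design of the chondrocyte analysis
#'
#' INF, antiINF, PO, HSC, HC and TS (the scenario node sets) at clamp
#' levels 0, 0.5 and 1: `3^6 = 729` runs.
#'
#' @param levels clamp levels (default `c(0, 0.5, 1)`).
#' @return a `cnet_design`.
#' @export
default_design <- function(levels = c(0, 0.5, 1)) {
  scns <- builtin_scenarios()
  cats <- lapply(scns[c("INF", "antiINF", "PO", "HSC", "HC", "TS")],
                 function(s) names(s$clamps))
  build_design(cats, levels)
}

#' @export
print.cnet_design <- function(x, ...) {
  cat("<cnet_design> ", length(x$categories), " categories x ",
      length(x$levels), " levels = ", nrow(x$runs), " runs\n", sep = "")
  invisible(x)
}

#' Execute every run of a factorial design
#'
#' For each run, every node of every category is clamped at that category's
#' level for the entire integration (`level_mode = "clamp"`, the default;
#' `"initial"` instead uses the level only as the initial value, leaving
#' the node free). Unclamped nodes start from `baseline`. Non-convergent
#' runs are recorded with their flag, never fatal.
#'
#' @param net an [interactome()].
#' @param design a [build_design()] object.
#' @param baseline named activation vector used as the initial state; the
#'   built-in analysis uses the catabolic (INF scenario) steady state, i.e.
#'   an osteoarthritic chondrocyte.
#' @param config an [integration_config()].
#' @param level_mode `"clamp"` or `"initial"`.
#' @param journal optional path of a progress/resume TSV; completed runs
#'   found there are not recomputed.
#' @return an object of class `"cnet_design_runs"`: `design`, `ss` (matrix,
#'   runs x nodes), `converged` (logical per run), `level_mode`.
#' @export
run_design <- function(net, design, baseline = NULL,
                       config = integration_config(),
                       level_mode = c("clamp", "initial"), journal = NULL) {
  level_mode <- match.arg(level_mode)
  ids <- net$nodes$id
  for (cat_nodes in design$categories) resolve_nodes(net, cat_nodes)
  base_vec <- stats::setNames(numeric(length(ids)), ids)
  if (!is.null(baseline)) {
    bv <- state_values(baseline)
    base_vec[resolve_nodes(net, names(bv))] <- unname(bv)
  }
  ns_total <- nrow(design$runs)
  ss <- matrix(NA_real_, ns_total, length(ids), dimnames = list(NULL, ids))
  converged <- rep(NA, ns_total)

  done <- integer(0)
  if (!is.null(journal) && file.exists(journal)) {
    prev <- utils::read.delim(journal, stringsAsFactors = FALSE,
                              check.names = FALSE)
    keep <- prev$run[prev$run <= ns_total]
    if (length(keep) > 0) {
      done <- keep
      ss[keep, ] <- as.matrix(prev[prev$run %in% keep, ids, drop = FALSE])
      converged[keep] <- prev$converged[prev$run %in% keep]
    }
  }
  jcon <- NULL
  if (!is.null(journal)) {
    new_file <- !file.exists(journal)
    jcon <- file(journal, open = "at")
    on.exit(close(jcon))
    if (new_file)
      writeLines(paste(c("run", "converged", ids), collapse = "\t"), jcon)
  }

  for (ns in setdiff(seq_len(ns_total), done)) {
    lv <- design$runs[ns, , drop = FALSE]
    clamp_nodes <- character(0); clamp_vals <- numeric(0)
    init <- base_vec
    for (ci in seq_along(design$categories)) {
      nodes_c <- design$categories[[ci]]
      val <- as.numeric(lv[[ci]])
      if (level_mode == "clamp") {
        clamp_nodes <- c(clamp_nodes, nodes_c)
        clamp_vals <- c(clamp_vals, rep(val, length(nodes_c)))
      } else {
        init[resolve_nodes(net, nodes_c)] <- val
      }
    }
    clamps <- if (length(clamp_nodes))
      stats::setNames(clamp_vals, clamp_nodes) else NULL
    st <- find_steady_state(net, clamps = clamps, config = config,
                            initial = init)
    ss[ns, ] <- st$values[ids]
    converged[ns] <- st$converged
    if (!is.null(jcon))
      writeLines(paste(c(ns, converged[ns],
                         format(ss[ns, ], digits = 17, trim = TRUE)),
                       collapse = "\t"), jcon)
  }
  structure(list(design = design, ss = ss, converged = converged,
                 level_mode = level_mode),
            class = "cnet_design_runs")
}

#' @export
print.cnet_design_runs <- function(x, ...) {
  cat("<cnet_design_runs> ", nrow(x$ss), " runs x ", ncol(x$ss), " nodes (",
      sum(x$converged), " converged)\n", sep = "")
  invisible(x)
}

# physiologically excluded two-way interactions of the built-in analysis
default_excluded_pairs <- function() {
  list(c("HSC", "TS"), c("HC", "HSC"), c("TS", "HC"))
}

#' Balanced factorial ANOVA for one node
#'
#' Fixed-effects decomposition of the node's steady-state variance across
#' the design: main effects for every category and two-way interactions for
#' every category pair except the excluded ones; excluded pairs and all
#' higher-order interactions are pooled into the error term, so the partial
#' sums of squares and the error always add up to the total sum of squares
#' exactly. On a balanced design the effects are orthogonal, so the
#' cell-mean computation is order-free. Each effect gets an F test against
#' the pooled error and an importance score `I = PSS / TSS * 100`.
#'
#' @param runs a [run_design()] result.
#' @param node node id to analyse.
#' @param excluded_pairs list of category-name pairs whose interaction is
#'   pooled into error (default: the three physiologically irrelevant
#'   mechanical pairs HSC:TS, HC:HSC, TS:HC when present in the design).
#' @param alpha significance level for the F tests.
#' @return an object of class `"cnet_anova"`: `node`, `tss`, `effects`
#'   (data.frame: effect, type, pss, df, F, p, significant, importance,
#'   sign), `error` (pss, df), `degenerate`.
#' @export
anova_decompose <- function(runs, node, excluded_pairs = NULL, alpha = 0.05) {
  stopifnot(inherits(runs, "cnet_design_runs"))
  design <- runs$design
  cats <- names(design$categories)
  if (is.null(excluded_pairs))
    excluded_pairs <- Filter(function(p) all(p %in% cats),
                             default_excluded_pairs())
  for (p in excluded_pairs)
    if (!all(p %in% cats))
      stop_cnet("excluded pair references unknown category: ",
                paste(p, collapse = ":"), class = "cnet_design_error")
  node <- intersect(colnames(runs$ss), canonical_node_id(node))
  if (length(node) != 1)
    stop_cnet("node not found in design runs", class = "cnet_lookup_error")
  y <- runs$ss[, node]
  if (anyNA(y))
    stop_cnet("design runs incomplete (NA steady states)",
              class = "cnet_contract_error")
  L <- length(design$levels)
  NS <- nrow(design$runs)
  if (NS != L ^ length(cats))
    stop_cnet("unbalanced design: ", NS, " runs != ", L, "^", length(cats),
              class = "cnet_contract_error")

  m <- mean(y)
  tss <- sum((y - m)^2)
  degenerate <- tss < 1e-24

  excl_key <- vapply(excluded_pairs,
                     function(p) paste(sort(p), collapse = ":"), character(1))
  lv_chr <- lapply(cats, function(cc) as.character(design$runs[[cc]]))
  names(lv_chr) <- cats
  lev_all <- as.character(design$levels)
  lo <- as.character(min(design$levels)); hi <- as.character(max(design$levels))

  eff <- list()
  # main effects
  main_means <- list()
  for (cc in cats) {
    mm <- vapply(lev_all, function(l) mean(y[lv_chr[[cc]] == l]), numeric(1))
    main_means[[cc]] <- mm
    pss <- NS / L * sum((mm - m)^2)
    sgn_val <- mm[[hi]] - mm[[lo]]
    eff[[cc]] <- data.frame(
      effect = cc, type = "main", pss = pss, df = L - 1,
      sign = if (abs(sgn_val) < 1e-12) "n/a" else if (sgn_val > 0) "+" else "-",
      stringsAsFactors = FALSE)
  }
  # two-way interactions
  if (length(cats) >= 2) {
    pairs <- utils::combn(cats, 2, simplify = FALSE)
    for (p in pairs) {
      key <- paste(sort(p), collapse = ":")
      if (key %in% excl_key) next
      cm <- matrix(NA_real_, L, L, dimnames = list(lev_all, lev_all))
      for (l1 in lev_all) for (l2 in lev_all)
        cm[l1, l2] <- mean(y[lv_chr[[p[1]]] == l1 & lv_chr[[p[2]]] == l2])
      inter <- sweep(sweep(cm, 1, main_means[[p[1]]]), 2, main_means[[p[2]]]) + m
      pss <- NS / L^2 * sum(inter^2)
      contrast <- (cm[lo, lo] + cm[hi, hi]) / 2 - (cm[lo, hi] + cm[hi, lo]) / 2
      eff[[paste(p, collapse = ":")]] <- data.frame(
        effect = paste(p, collapse = ":"), type = "interaction",
        pss = pss, df = (L - 1)^2,
        sign = if (abs(contrast) < 1e-12) "n/a"
               else if (contrast > 0) "+" else "-",
        stringsAsFactors = FALSE)
    }
  }
  effects <- do.call(rbind, eff)
  rownames(effects) <- NULL
  err_pss <- max(0, tss - sum(effects$pss))
  err_df <- NS - 1 - sum(effects$df)
  if (degenerate) {
    effects$F <- NA_real_; effects$p <- NA_real_
    effects$significant <- FALSE
    effects$importance <- 0
  } else {
    if (err_df > 0) {
      mse <- err_pss / err_df
      effects$F <- (effects$pss / effects$df) / mse
      effects$p <- stats::pf(effects$F, effects$df, err_df,
                             lower.tail = FALSE)
    } else {
      # saturated model (e.g. two categories, full second-order): the
      # decomposition and importances are exact but no F test is possible
      effects$F <- NA_real_; effects$p <- NA_real_
    }
    effects$significant <- !is.na(effects$p) & effects$p < alpha
    effects$importance <- effects$pss / tss * 100
  }
  structure(list(node = node, tss = tss, effects = effects,
                 error = list(pss = err_pss, df = err_df),
                 excluded_pairs = excluded_pairs, alpha = alpha,
                 degenerate = degenerate),
            class = "cnet_anova")
}

#' @export
print.cnet_anova <- function(x, ...) {
  cat("<cnet_anova> node ", x$node, ", TSS = ", signif(x$tss, 6),
      if (x$degenerate) " (degenerate: constant response)", "\n", sep = "")
  print(importance_ranking(x))
  invisible(x)
}

#' Pareto ranking of ANOVA effects
#'
#' Effects ordered by decreasing importance, each carrying its
#' significance flag and influence sign (main effects: sign of the
#' top-level mean minus the bottom-level mean; interactions: sign of the
#' concordant-extreme minus discordant-extreme cell-mean contrast). Plot
#' importance on a logarithmic axis for the conventional Pareto chart.
#'
#' @param x a [anova_decompose()] result.
#' @return data.frame: `effect`, `type`, `importance`, `F`, `p`,
#'   `significant`, `sign`, sorted by importance.
#' @export
importance_ranking <- function(x) {
  stopifnot(inherits(x, "cnet_anova"))
  df <- x$effects[order(-x$effects$importance, x$effects$effect),
                  c("effect", "type", "importance", "F", "p", "significant",
                    "sign")]
  rownames(df) <- NULL
  df
}

#' Marginal means of a node across a design
#'
#' Average steady state over all runs sharing each level of `by`
#' (optionally further split by the levels of a second category). On a
#' balanced design each cell averages `NS / L` (or `NS / L^2`) runs.
#'
#' @param runs a [run_design()] result.
#' @param node node id.
#' @param by category whose levels index the means.
#' @param split_by optional second category.
#' @return data.frame with columns `by` level, optional `split_by` level,
#'   and `mean`.
#' @export
marginal_means <- function(runs, node, by, split_by = NULL) {
  stopifnot(inherits(runs, "cnet_design_runs"))
  cats <- names(runs$design$categories)
  if (!by %in% cats)
    stop_cnet("unknown category: ", by, class = "cnet_lookup_error")
  if (!is.null(split_by) && !split_by %in% cats)
    stop_cnet("unknown category: ", split_by, class = "cnet_lookup_error")
  node <- intersect(colnames(runs$ss), canonical_node_id(node))
  if (length(node) != 1)
    stop_cnet("node not found in design runs", class = "cnet_lookup_error")
  y <- runs$ss[, node]
  if (is.null(split_by)) {
    agg <- stats::aggregate(y, list(level = runs$design$runs[[by]]), mean)
    names(agg) <- c(by, "mean")
  } else {
    agg <- stats::aggregate(
      y, list(runs$design$runs[[by]], runs$design$runs[[split_by]]), mean)
    names(agg) <- c(by, split_by, "mean")
  }
  agg
}

#' Write design runs as TSV (design matrix + steady states)
#' @param runs a [run_design()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design_runs <- function(runs, path) {
  df <- data.frame(run = seq_len(nrow(runs$ss)), runs$design$runs,
                   converged = runs$converged, runs$ss, check.names = FALSE)
  write_tsv_with_meta(df, path, meta = c(
    paste0("levels: ", paste(runs$design$levels, collapse = ",")),
    paste0("categories: ", paste(names(runs$design$categories),
                                 collapse = ","))),
    full_precision = TRUE)
}

#' Run ANOVA for a set of nodes and collect a long table
#' @param runs a [run_design()] result.
#' @param nodes node ids (default: all).
#' @param excluded_pairs,alpha passed to [anova_decompose()].
#' @return data.frame: node, effect, type, pss, df, F, p, significant,
#'   importance, sign.
#' @export
anova_table <- function(runs, nodes = NULL, excluded_pairs = NULL,
                        alpha = 0.05) {
  nodes <- nodes %||% colnames(runs$ss)
  out <- lapply(nodes, function(nd) {
    a <- anova_decompose(runs, nd, excluded_pairs, alpha)
    cbind(node = nd, a$effects)
  })
  do.call(rbind, out)
}
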