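# shared builders and independent oracles for the test-suite

# closed-form sigmoid, written independently of the package implementation
oracle_sigmoid <- function(w, h = 10) {
  E <- exp(0.5 * h)
  tt <- exp(-h * (w - 0.5))
  (tt - E) / ((1 - E) * (1 + tt))
}

# normalized input of a single activator / inhibitor with weight 1
oracle_omega_act <- function(x) 2 * x / (1 + x)

toy_chain <- function() make_motif("single_chain")

toy_edges <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(source = m[, 1], target = m[, 2], sign = m[, 3], weight = 1,
             stringsAsFactors = FALSE)
}

# fast integration settings for small fixtures
fast_config <- function(...) integration_config(t_max = 30, ...)

# balanced-ANOVA oracle via stats::aov (only used to cross-check
# anova_decompose on small designs)
aov_pss <- function(y, runs_df, formula) {
  df <- data.frame(y = y, lapply(runs_df, factor))
  fit <- stats::aov(formula, data = df)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  stats::setNames(ss, trimws(rownames(summary(fit)[[1]])))
}

# build a cnet_design_runs object from an explicit response function,
# bypassing the simulator (for ANOVA identity tests)
synthetic_runs <- function(design, f) {
  y <- apply(design$runs, 1, f)
  ss <- matrix(y, ncol = 1, dimnames = list(NULL, "Y"))
  structure(list(design = design, ss = ss,
                 converged = rep(TRUE, nrow(design$runs)),
                 level_mode = "clamp"),
            class = "cnet_design_runs")
}
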