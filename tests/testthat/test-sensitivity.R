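# factorial designs and balanced ANOVA decomposition

test_that("build_design enumerates L^c runs exactly once, odometer order", {
  d6 <- default_design()
  expect_equal(nrow(d6$runs), 729)
  expect_named(d6$categories, c("INF", "antiINF", "PO", "HSC", "HC", "TS"))

  d1 <- build_design(list(A = "a"), levels = c(0, 0.5, 1))
  expect_equal(nrow(d1$runs), 3)
  expect_equal(d1$runs$A, c(0, 0.5, 1))

  d2 <- build_design(list(A = "a", B = "b"), levels = c(0, 1))
  expect_equal(nrow(d2$runs), 4)
  expect_equal(anyDuplicated(d2$runs), 0)
  # last category varies fastest
  expect_equal(d2$runs$B, c(0, 1, 0, 1))
  expect_equal(d2$runs$A, c(0, 0, 1, 1))

  expect_error(build_design(list(A = "x", B = "x")),
               class = "cnet_design_error")
})

test_that("run_design clamps category nodes at their level", {
  chain <- toy_chain()
  d <- build_design(list(SRC = "SRC"), levels = c(0, 1))
  runs <- run_design(chain, d, config = fast_config())
  expect_equal(unname(runs$ss[, "SNK"]), c(0, 1), tolerance = 1e-6)
  expect_true(all(runs$converged))
  # all-zero run silences the source-driven part of the network
  expect_equal(unname(runs$ss[1, ]), c(0, 0), tolerance = 1e-9)

  # 'initial' level mode leaves the node free to decay
  runs2 <- run_design(chain, d, config = fast_config(),
                      level_mode = "initial")
  expect_equal(unname(runs2$ss[2, "SRC"]), 0, tolerance = 1e-6)
})

test_that("run_design journal supports resume without recomputation", {
  chain <- toy_chain()
  d <- build_design(list(SRC = "SRC"), levels = c(0, 0.5, 1))
  journal <- withr::local_tempfile(fileext = ".tsv")
  r1 <- run_design(chain, d, config = fast_config(), journal = journal)
  expect_true(file.exists(journal))
  # resumed run reads all three rows back and reproduces the result
  r2 <- run_design(chain, d, config = fast_config(), journal = journal)
  expect_equal(r1$ss, r2$ss)
})

test_that("importance recovers exact synthetic variance decompositions", {
  d <- build_design(list(A = "a", B = "b", C = "c"), levels = c(0, 0.5, 1))
  # response equal to one factor: all importance on that main effect
  runs <- synthetic_runs(d, function(r) r[["A"]])
  a <- anova_decompose(runs, "Y", excluded_pairs = list())
  imp <- stats::setNames(a$effects$importance, a$effects$effect)
  expect_equal(unname(imp["A"]), 100, tolerance = 1e-10)
  expect_true(all(imp[setdiff(names(imp), "A")] < 1e-10))

  # additive response: 50/50 split, no interaction
  runs2 <- synthetic_runs(d, function(r) (r[["A"]] + r[["B"]]) / 2)
  a2 <- anova_decompose(runs2, "Y", excluded_pairs = list())
  imp2 <- stats::setNames(a2$effects$importance, a2$effects$effect)
  expect_equal(unname(imp2["A"]), 50, tolerance = 1e-10)
  expect_equal(unname(imp2["B"]), 50, tolerance = 1e-10)
  expect_lt(imp2["A:B"], 1e-10)

  # constant response: degenerate, no division error
  runs3 <- synthetic_runs(d, function(r) 0.3)
  a3 <- anova_decompose(runs3, "Y")
  expect_true(a3$degenerate)
  expect_true(all(a3$effects$importance == 0))
})

test_that("partial sums of squares match the stats::aov oracle", {
  d <- build_design(list(A = "a", B = "b", C = "c"), levels = c(0, 0.5, 1))
  set.seed(42)
  y <- stats::runif(nrow(d$runs))
  runs <- synthetic_runs(d, function(r) 0)
  runs$ss[, 1] <- y
  a <- anova_decompose(runs, "Y", excluded_pairs = list())
  ss_oracle <- aov_pss(y, d$runs, y ~ (A + B + C)^2)
  for (i in seq_len(nrow(a$effects))) {
    eff <- a$effects$effect[i]
    expect_equal(a$effects$pss[i], unname(ss_oracle[eff]), tolerance = 1e-8,
                 label = paste("PSS", eff))
  }
  expect_equal(a$error$pss, unname(ss_oracle["Residuals"]), tolerance = 1e-8)
  # decomposition identity
  expect_equal(sum(a$effects$pss) + a$error$pss, a$tss, tolerance = 1e-10)
})

test_that("excluded pairs are pooled into error, keeping the identity", {
  d <- build_design(list(A = "a", B = "b", C = "c"), levels = c(0, 0.5, 1))
  set.seed(7)
  runs <- synthetic_runs(d, function(r) 0)
  runs$ss[, 1] <- stats::runif(nrow(d$runs))
  full <- anova_decompose(runs, "Y", excluded_pairs = list())
  excl <- anova_decompose(runs, "Y", excluded_pairs = list(c("A", "B")))
  expect_false("A:B" %in% excl$effects$effect)
  ab <- full$effects$pss[full$effects$effect == "A:B"]
  expect_equal(excl$error$pss, full$error$pss + ab, tolerance = 1e-10)
  expect_equal(excl$error$df, full$error$df + 4)
  expect_equal(sum(excl$effects$pss) + excl$error$pss, excl$tss,
               tolerance = 1e-10)
  expect_error(anova_decompose(runs, "Y", excluded_pairs = list(c("A", "Z"))),
               class = "cnet_design_error")
})

test_that("ANOVA results are invariant to run order", {
  d <- build_design(list(A = "a", B = "b"), levels = c(0, 0.5, 1))
  set.seed(5)
  runs <- synthetic_runs(d, function(r) 0)
  runs$ss[, 1] <- stats::runif(9)
  a1 <- anova_decompose(runs, "Y")
  perm <- sample(9)
  runs2 <- runs
  runs2$ss <- runs$ss[perm, , drop = FALSE]
  runs2$design$runs <- runs$design$runs[perm, , drop = FALSE]
  a2 <- anova_decompose(runs2, "Y")
  expect_equal(a1$effects[order(a1$effects$effect), ],
               a2$effects[order(a2$effects$effect), ],
               ignore_attr = TRUE)
})

test_that("importance_ranking orders effects and assigns influence signs", {
  d <- build_design(list(A = "a", B = "b"), levels = c(0, 0.5, 1))
  r_up <- synthetic_runs(d, function(r) r[["A"]])
  rank_up <- importance_ranking(anova_decompose(r_up, "Y"))
  expect_equal(rank_up$effect[1], "A")
  expect_equal(rank_up$sign[1], "+")

  r_dn <- synthetic_runs(d, function(r) 1 - r[["A"]])
  rank_dn <- importance_ranking(anova_decompose(r_dn, "Y"))
  expect_equal(rank_dn$effect[1], "A")
  expect_equal(rank_dn$sign[1], "-")

  r_int <- synthetic_runs(d, function(r) r[["A"]] * r[["B"]])
  rank_int <- importance_ranking(anova_decompose(r_int, "Y"))
  expect_equal(rank_int$effect[rank_int$type == "interaction"][1], "A:B")
  expect_equal(rank_int$sign[rank_int$effect == "A:B"], "+")
})

test_that("marginal means average the correct run subsets", {
  d <- build_design(list(A = "a", B = "b"), levels = c(0, 0.5, 1))
  runs <- synthetic_runs(d, function(r) r[["A"]])
  mm <- marginal_means(runs, "Y", by = "A")
  expect_equal(mm$mean, c(0, 0.5, 1))

  runs_c <- synthetic_runs(d, function(r) 0.3)
  mm_c <- marginal_means(runs_c, "Y", by = "B")
  expect_true(all(mm_c$mean == 0.3))

  # additive response: split lines are parallel
  runs_add <- synthetic_runs(d, function(r) (r[["A"]] + r[["B"]]) / 2)
  mm_s <- marginal_means(runs_add, "Y", by = "A", split_by = "B")
  wide <- matrix(mm_s$mean[order(mm_s$B, mm_s$A)], nrow = 3)
  gaps <- apply(wide, 2, diff)
  expect_equal(gaps[, 1], gaps[, 2], tolerance = 1e-12)
  expect_error(marginal_means(runs, "Y", by = "Z"),
               class = "cnet_lookup_error")
})
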