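test_that("confusion metrics reproduce hand-computed rates and CIs", {
  m <- confusion_metrics(confusion_table(tp = 96, fp = 31, fn = 4, tn = 73))
  est <- setNames(round(100 * m$estimate, 1), m$metric)
  expect_equal(unname(est), c(96.0, 70.2, 75.6, 94.8))
  # Wald CI for 96/100, hand-computed: 0.96 -/+ 1.96*sqrt(0.96*0.04/100)
  sens <- m[m$metric == "sensitivity", ]
  expect_equal(round(100 * c(sens$lower, sens$upper), 1), c(92.2, 99.8))

  perfect <- confusion_metrics(confusion_table(10, 0, 0, 12))
  expect_true(all(perfect$estimate == 1))
  expect_true(all(perfect$upper == 1))

  expect_warning(
    und <- confusion_metrics(confusion_table(tp = 0, fp = 0, fn = 5, tn = 5)),
    "ppv undefined")
  expect_true(is.na(und$estimate[und$metric == "ppv"]))
})

test_that("Wilson and Clopper-Pearson variants stay inside [0,1] and bracket p", {
  for (method in c("wilson", "clopper-pearson")) {
    m <- confusion_metrics(confusion_table(29, 1, 1, 29), ci_method = method)
    expect_true(all(m$lower >= 0 & m$upper <= 1))
    expect_true(all(m$lower <= m$estimate & m$estimate <= m$upper))
  }
})

test_that("exact McNemar matches closed-form binomial tails", {
  expect_equal(mcnemar_exact(4, 4), 1)
  expect_equal(mcnemar_exact(0, 0), 1)
  expect_equal(mcnemar_exact(5, 0), 0.0625)   # 2 * (1/2)^5
  # symmetry and range over a grid of discordant pairs
  for (b in 0:6) for (cc in 0:6) {
    p <- mcnemar_exact(b, cc)
    expect_equal(p, mcnemar_exact(cc, b))
    expect_true(p > 0 && p <= 1)
  }
})

test_that("Fisher R x 2 enumeration equals closed forms and stats::fisher.test", {
  # two 2x2 tables with enumerable closed-form answers
  expect_equal(fisher_exact_rxc(rbind(c(1, 0), c(0, 1))), 1)
  expect_equal(fisher_exact_rxc(rbind(c(2, 2), c(2, 2))), 1)
  # textbook 2x2 check against the hypergeometric closed form
  tab <- rbind(c(8, 2), c(1, 5))
  expect_equal(fisher_exact_rxc(tab), fisher.test(tab)$p.value,
               tolerance = 1e-9)
  # independent oracle on random R x 2 tables
  set.seed(11)
  for (rep in 1:8) {
    R <- sample(2:4, 1)
    tab <- matrix(rpois(2 * R, 4), nrow = R)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(fisher_exact_rxc(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
  expect_error(fisher_exact_rxc(matrix(0, 2, 2)), "all-zero")
})

test_that("ROC sweep covers the unit square and matches pROC", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  roc <- roc_curve(scores, labels)
  expect_equal(roc$auc, 1)
  expect_equal(roc$points$fpr[1L], 0)
  expect_equal(roc$points$tpr[nrow(roc$points)], 1)

  set.seed(5)
  s <- round(runif(80), 2)                  # ties on purpose
  l <- runif(80) < plogis(6 * (s - 0.5))
  if (!any(l)) l[1] <- TRUE
  if (all(l)) l[1] <- FALSE
  mine <- roc_curve(s, l)
  ref <- pROC::roc(response = l, predictor = s, quiet = TRUE,
                   direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
  # reversing score sign mirrors the AUC
  expect_equal(roc_curve(-s, l)$auc, 1 - mine$auc, tolerance = 1e-9)
  expect_error(roc_curve(s, rep(TRUE, 80)), "both classes")
})

test_that("net benefit follows the decision-analytic formula", {
  perfect <- confusion_table(tp = 30, fp = 0, fn = 0, tn = 70)
  dc <- decision_curve(list(perfect = perfect))
  nb <- dc$net_benefit[dc$model == "perfect"]
  expect_equal(nb, rep(0.30, length(nb)))
  expect_true(all(dc$net_benefit[dc$model == "treat_none"] == 0))

  model <- confusion_table(tp = 25, fp = 10, fn = 5, tn = 60)
  dc2 <- decision_curve(list(m = model), pt_grid = c(0.001, 0.1, 0.5))
  expect_equal(dc2$net_benefit[dc2$model == "m"][1L], 25 / 100,
               tolerance = 1e-2)
  expect_equal(dc2$net_benefit[dc2$model == "m"][3L],
               25 / 100 - 10 / 100 * 1)
  # model and treat-all curves cross at pt = fn / (fn + tn)
  pt_star <- model$fn / (model$fn + model$tn)
  dc3 <- decision_curve(list(m = model),
                        pt_grid = c(pt_star - 0.02, pt_star + 0.02))
  gap <- with(dc3, net_benefit[model == "m"] - net_benefit[model == "treat_all"])
  expect_lt(gap[1L], 0)
  expect_gt(gap[2L], 0)

  expect_error(decision_curve(list(m = model), pt_grid = c(0, 0.5)),
               "inside \\(0, 1\\)")
  other_cohort <- confusion_table(tp = 5, fp = 5, fn = 5, tn = 5)
  expect_error(decision_curve(list(a = model, b = other_cohort)),
               "same cohort")
})

test_that("stratified comparison delegates to Fisher with Bonferroni alpha", {
  strata <- list(
    uncinate = confusion_table(tp = 5, fp = 0, fn = 1, tn = 0),
    head = confusion_table(tp = 35, fp = 0, fn = 8, tn = 0),
    body = confusion_table(tp = 26, fp = 0, fn = 7, tn = 0),
    tail = confusion_table(tp = 11, fp = 0, fn = 7, tn = 0))
  out <- stratified_compare(strata, "sensitivity", bonferroni_k = 1L)
  expect_equal(out$p_value,
               fisher_exact_rxc(rbind(c(5, 1), c(35, 8), c(26, 7), c(11, 7))))
  expect_equal(out$alpha, 0.05)

  same <- list(a = confusion_table(10, 0, 5, 0), b = confusion_table(10, 0, 5, 0))
  expect_equal(stratified_compare(same, "sensitivity")$p_value, 1)

  out4 <- stratified_compare(same, "sensitivity", bonferroni_k = 4L)
  expect_equal(out4$alpha, 0.0125)

  with_empty <- c(same, list(z = confusion_table(0, 3, 0, 7)))
  expect_warning(res <- stratified_compare(with_empty, "sensitivity"),
                 "dropped")
  expect_equal(res$dropped, "z")
})
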