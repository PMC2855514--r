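mk_learning_ph <- function(n_lethal, n_indolent) {
  phenotype_table(data.frame(
    sample_id = sprintf("s%03d", seq_len(n_lethal + n_indolent)),
    outcome = rep(c("lethal", "indolent"), c(n_lethal, n_indolent)),
    death_from_cancer = rep(c(TRUE, FALSE), c(n_lethal, n_indolent)),
    followup_years = rep(c(4, 14), c(n_lethal, n_indolent))))
}

test_that("the learning/validation split is stratified within one sample", {
  ph <- mk_learning_ph(10, 10)
  sp <- split_learning_validation(ph, 0.5, seed = 1)
  out <- setNames(as.character(ph$outcome), ph$sample_id)
  expect_equal(sum(out[sp$learning_ids] == "lethal"), 5L)
  expect_equal(sum(out[sp$learning_ids] == "indolent"), 5L)
  expect_length(intersect(sp$learning_ids, sp$validation_ids), 0L)

  ph2 <- mk_learning_ph(165, 116)
  sp2 <- split_learning_validation(ph2, 0.5, seed = 2)
  out2 <- setNames(as.character(ph2$outcome), ph2$sample_id)
  expect_true(sum(out2[sp2$learning_ids] == "lethal") %in% c(82L, 83L))
  expect_equal(sum(out2[sp2$learning_ids] == "indolent"), 58L)
})

test_that("splits and fold plans are deterministic in the seed", {
  ph <- mk_learning_ph(20, 15)
  expect_identical(split_learning_validation(ph, 0.5, seed = 7),
                   split_learning_validation(ph, 0.5, seed = 7))
  expect_false(identical(split_learning_validation(ph, 0.5, seed = 7),
                         split_learning_validation(ph, 0.5, seed = 8)))
  p1 <- make_fold_plans(ph, k = 5, repetitions = 2, seed = 7)
  p2 <- make_fold_plans(ph, k = 5, repetitions = 2, seed = 7)
  expect_identical(p1, p2)
})

test_that("fold plans partition each repetition with stratified counts", {
  ph <- mk_learning_ph(23, 17)
  plans <- make_fold_plans(ph, k = 10, repetitions = 5, seed = 3)
  expect_equal(nrow(plans), 50L)
  out <- setNames(as.character(ph$outcome), ph$sample_id)
  for (r in unique(plans$repetition)) {
    rep_plans <- plans[plans$repetition == r, ]
    test_ids <- unlist(rep_plans$test_ids)
    expect_equal(sort(test_ids), sort(ph$sample_id))  # disjoint union
    for (i in seq_len(nrow(rep_plans))) {
      te <- rep_plans$test_ids[[i]]
      expect_true(sum(out[te] == "lethal") %in% 2:3)
      expect_true(sum(out[te] == "indolent") %in% 1:2)
      expect_length(intersect(te, rep_plans$train_ids[[i]]), 0L)
    }
  }
  # 10 folds x 100 repetitions = 1000 plans
  expect_equal(nrow(make_fold_plans(mk_learning_ph(83, 58), 10, 100, 1)), 1000L)
})

test_that("AUC matches exhaustive pair counting, exactly", {
  expect_equal(auc(c(0.9, 0.4, 0.8, 0.3),
                   c("lethal", "lethal", "indolent", "indolent")), 0.75)
  expect_equal(auc(c(5, 6, 1, 2), rep(c("lethal", "indolent"), each = 2)), 1)
  expect_equal(auc(rep(2, 6), rep(c("lethal", "indolent"), 3)), 0.5)
  expect_error(auc(1:3, rep("lethal", 3)), "one class is absent")
  set.seed(21)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    labels <- sample(rep(c("lethal", "indolent"), each = 2))
    labels <- c(labels, sample(c("lethal", "indolent"), n - 4, TRUE))
    scores <- sample(seq_len(6), n, replace = TRUE)  # forces ties
    expect_identical(auc(scores, labels), auc_pairs_oracle(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(22)
  scores <- rnorm(30)
  labels <- sample(c("lethal", "indolent"), 30, TRUE)
  a <- auc(scores, labels)
  expect_equal(auc(exp(scores), labels), a)
  expect_equal(auc(scores * 3 - 10, labels), a)
})

test_that("threshold selection returns p < cut-off, capped and ordered", {
  gen <- generate_cohort(tiny_sim_config(seed = 12L))
  expr <- gen$cohort$expression
  y <- as.character(gen$cohort$phenotype$outcome)
  sel <- select_features_in_fold(expr, y, selection_config(0.01))
  tests <- gene_tests(expr, y)
  expect_setequal(sel, tests$gene_id[tests$p < 0.01])
  planted <- unlist(gen$truth$signal_gene_ids)
  # planted delta/sd = 2 signal: selection enriched >= 10-fold over the 1%
  # background rate
  expect_gte(mean(planted %in% sel), 0.1)
  sel5 <- select_features_in_fold(expr, y, selection_config(0.01, max_genes = 5))
  expect_length(sel5, 5L)
  expect_equal(sel5, tests$gene_id[order(tests$p)][1:5])
})

test_that("null-data threshold selection admits about alpha * m genes", {
  counts <- vapply(1:5, function(s) {
    gen <- generate_cohort(tiny_sim_config(
      seed = 20L + s, n_genes = 1000L, n_signal_genes = 0L,
      n_erg_signature_genes = 0L, n_stroma_genes = 0L))
    y <- as.character(gen$cohort$phenotype$outcome)
    length(select_features_in_fold(gen$cohort$expression, y,
                                   selection_config(0.01)))
  }, numeric(1))
  expect_equal(mean(counts), 10, tolerance = 0.8)  # m * alpha = 1000 * 0.01
})

test_that("stepwise selection keeps the smallest set at the maximal inner AUC", {
  # gene A separates perfectly; B is pure noise: adding B cannot raise the
  # inner AUC, so the stepwise rule must return {A} alone
  set.seed(30)
  n <- 40
  y <- rep(c("lethal", "indolent"), each = n / 2)
  expr <- rbind(
    geneA = ifelse(y == "lethal", 5, 0) + rnorm(n, 0, 0.1),
    geneB = rnorm(n),
    geneC = rnorm(n))
  colnames(expr) <- sprintf("s%02d", seq_len(n))
  sel <- select_features_in_fold(expr, y,
                                 selection_config(mode = "stepwise"), seed = 1)
  expect_equal(sel, "geneA")
})

test_that("run_cv aggregates per-fold AUCs and select_best_model breaks ties", {
  gen <- generate_cohort(tiny_sim_config(seed = 14L))
  ph <- gen$cohort$phenotype
  plans <- make_fold_plans(ph, k = 4, repetitions = 2, seed = 14)
  specs <- list(model_spec("dlda"), model_spec("knn", list(k = 3L)))
  rep_ <- run_cv(gen$cohort, specs, plans, selection_config(0.01), seed = 14)
  expect_equal(nrow(rep_$per_fold), 16L)
  expect_true(all(rep_$per_fold$auc >= 0 & rep_$per_fold$auc <= 1, na.rm = TRUE))
  expect_equal(nrow(rep_$per_repetition), 4L)
  expect_equal(nrow(rep_$summary), 2L)
  agg <- tapply(rep_$per_fold$auc, rep_$per_fold$model, mean)
  for (m in names(agg)) {
    expect_equal(rep_$summary$grand_mean_auc[rep_$summary$model == m],
                 unname(agg[[m]]), tolerance = 1e-12)
  }
  best <- select_best_model(rep_)
  expect_equal(best$label,
               rep_$summary$model[which.max(rep_$summary$grand_mean_auc)])

  # tie-breaking: equal grand means, fewer genes wins
  fake <- rep_
  fake$summary <- tibble::tibble(
    model = c("a", "b"), family = c("knn", "dlda"),
    grand_mean_auc = c(0.8, 0.8), sd_auc = 0, mean_n_genes = c(18, 12),
    n_repetitions = 2L)
  fake$specs <- list(model_spec("knn", list(k = 3L), label = "a"),
                     model_spec("dlda", label = "b"))
  expect_equal(select_best_model(fake)$label, "b")
})

test_that("in-fold selection provably reads only the training slice", {
  gen <- generate_cohort(tiny_sim_config(
    seed = 31L, n_genes = 400L, n_signal_genes = 0L,
    n_erg_signature_genes = 0L, n_stroma_genes = 0L))
  co <- gen$cohort
  y <- setNames(as.character(co$phenotype$outcome), co$phenotype$sample_id)
  plans <- make_fold_plans(co$phenotype, k = 4, repetitions = 1, seed = 31)
  # overwriting every value outside the training slice with an
  # outcome-revealing constant must leave the fold's selection unchanged
  for (i in seq_len(nrow(plans))) {
    tr <- plans$train_ids[[i]]
    te <- plans$test_ids[[i]]
    poisoned <- co$expression
    poisoned[, te] <- matrix(ifelse(y[te] == "lethal", 50, -50),
                             nrow(poisoned), length(te), byrow = TRUE)
    sel_clean <- select_features_in_fold(co$expression[, tr], y[tr],
                                         selection_config(0.05))
    sel_poisoned <- select_features_in_fold(poisoned[, tr], y[tr],
                                            selection_config(0.05))
    expect_identical(sel_poisoned, sel_clean)
  }
})

test_that("leaky whole-set selection inflates the null cross-validated AUC", {
  gen <- generate_cohort(tiny_sim_config(
    seed = 32L, n_lethal = 40L, n_indolent = 30L, n_genes = 800L,
    n_signal_genes = 0L, n_erg_signature_genes = 0L, n_stroma_genes = 0L))
  plans <- make_fold_plans(gen$cohort$phenotype, k = 5, repetitions = 4,
                           seed = 32)
  honest <- suppressWarnings(run_cv(gen$cohort, model_spec("dlda"), plans,
                                    selection_config(0.01), seed = 32))
  leaky <- suppressWarnings(run_cv(gen$cohort, model_spec("dlda"), plans,
                                   selection_config(0.01), leaky = TRUE,
                                   seed = 32))
  expect_lt(abs(honest$summary$grand_mean_auc - 0.5), 0.12)
  expect_gt(leaky$summary$grand_mean_auc - honest$summary$grand_mean_auc, 0.1)
})

test_that("validate_final reports a reproducible bootstrap CI that covers", {
  gen <- generate_cohort(tiny_sim_config(seed = 16L, effect_size_delta = 8))
  ph <- gen$cohort$phenotype
  sp <- split_learning_validation(ph, 0.5, seed = 16)
  val <- validate_final(gen$cohort, sp$learning_ids, sp$validation_ids,
                        model_spec("dlda"), selection_config(0.001),
                        bootstrap_reps = 300, seed = 16)
  expect_equal(val$auc, 1)  # separable validation set
  expect_equal(val$ci_bootstrap$hi, 1)
  val2 <- validate_final(gen$cohort, sp$learning_ids, sp$validation_ids,
                         model_spec("dlda"), selection_config(0.001),
                         bootstrap_reps = 300, seed = 16)
  expect_identical(val$ci_bootstrap, val2$ci_bootstrap)
  expect_true(val$ci_bootstrap$lo <= val$auc && val$auc <= val$ci_bootstrap$hi)
})
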