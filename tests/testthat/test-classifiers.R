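# small genes x samples training set with named dims
mk_train <- function(values, genes, samples) {
  matrix(values, length(genes), length(samples),
         dimnames = list(genes, samples))
}

test_that("DLDA score matches the hand-evaluated discriminant", {
  # one gene, class means 0 (indolent) and 2 (lethal), pooled variance 1
  r <- sqrt(0.5)
  expr <- mk_train(c(-r, r, 2 - r, 2 + r), "g1", paste0("s", 1:4))
  y <- c("indolent", "indolent", "lethal", "lethal")
  fit <- train_model(model_spec("dlda"), expr, y)
  sc <- score_samples(fit, mk_train(c(1.5, 1, 0, 2), "g1", paste0("t", 1:4)))
  expect_equal(unname(sc[1]), 2.25 - 0.25)  # x = 1.5 -> 2.0, lethal side
  expect_equal(unname(sc[2]), 0)            # midpoint -> exactly 0
  expect_equal(unname(sc[3]), -unname(sc[4]))  # symmetry about the midpoint
  # x at the lethal mean: score = sum of (mu diff)^2 / s^2 >= 0
  expect_equal(unname(sc[4]), 4)
})

test_that("DLDA drops zero-variance genes and errors without classes", {
  expr <- mk_train(c(1, 1, 5, 1, 1, 6, 1, 1, 7, 1, 1, 8), paste0("g", 1:3),
                   paste0("s", 1:4))
  y <- c("indolent", "indolent", "lethal", "lethal")
  expect_warning(fit <- train_model(model_spec("dlda"), expr, y),
                 "zero-variance")
  expect_equal(fit$fit$genes, "g3")
  expect_error(train_model(model_spec("dlda"), expr, rep("lethal", 4)),
               "class is absent")
})

test_that("kNN scores are neighbour fractions with the documented tie rule", {
  expr <- mk_train(c(0, 1, 10), "g1", c("a", "b", "c"))
  y <- c("lethal", "lethal", "indolent")
  fit1 <- train_model(model_spec("knn", list(k = 1L)), expr, y)
  expect_equal(unname(score_samples(fit1, mk_train(0, "g1", "t"))), 1)
  fit3 <- train_model(model_spec("knn", list(k = 3L)), expr, y)
  expect_equal(unname(score_samples(fit3, mk_train(0.4, "g1", "t"))), 2 / 3)
  # all exemplars equidistant: the k lowest-index samples win
  expr_eq <- mk_train(c(1, 1, 1, 1), "g1", paste0("s", 1:4))
  y_eq <- c("lethal", "indolent", "indolent", "lethal")
  fit_eq <- train_model(model_spec("knn", list(k = 3L)), expr_eq, y_eq)
  expect_equal(unname(score_samples(fit_eq, mk_train(1, "g1", "t"))), 1 / 3)
  expect_error(model_spec("knn", list(k = 4L)), "odd")
  # with k = n_train every test sample scores the lethal prevalence
  fitn <- train_model(model_spec("knn", list(k = 3L)), expr, y)
  sc <- score_samples(fitn, mk_train(c(-50, 3, 99), "g1", paste0("t", 1:3)))
  expect_true(all(sc == 2 / 3))
})

test_that("NTP cosine arithmetic matches the hand example", {
  v <- c(1, -1, 1); tmpl <- c(1, 1, -1)
  cos_sim <- sum(v * tmpl) / (sqrt(sum(v^2)) * sqrt(sum(tmpl^2)))
  expect_equal(cos_sim, -1 / 3)
  expect_equal(1 - cos_sim, 4 / 3)  # cosine distance to the template
  # model-based check: a sample proportional to the lethal template gets the
  # maximal score 2, an anti-proportional one the minimal -2
  set.seed(2)
  expr <- mk_train(rnorm(40), paste0("g", 1:4), paste0("s", 1:10))
  y <- rep(c("lethal", "indolent"), 5)
  expr[, y == "lethal"] <- expr[, y == "lethal"] + c(2, 2, -2, 2)
  fit <- train_model(model_spec("ntp"), expr, y)
  expect_equal(unname(fit$fit$template_lethal), c(1, 1, -1, 1))
  z_up <- fit$fit$center + fit$fit$scale * fit$fit$template_lethal
  sc <- score_samples(fit, mk_train(c(z_up, fit$fit$center), paste0("g", 1:4),
                                    c("up", "mid")))
  expect_equal(unname(sc["up"]), 2)   # colinear with the lethal template
  expect_equal(unname(sc["mid"]), 0)  # zero vector after standardisation
  expect_error(train_model(model_spec("ntp"), expr * 0 + 1, y), "NTP|template")
})

test_that("unpenalised logistic regression recovers the closed 2x2 solution", {
  # x=1: 20 lethal / 10 indolent; x=0: 10 lethal / 20 indolent
  x <- mk_train(rep(c(1, 0), c(30, 30)), "g1", paste0("s", 1:60))
  y <- c(rep("lethal", 20), rep("indolent", 10),
         rep("lethal", 10), rep("indolent", 20))
  fit <- train_model(model_spec("logistic", list(ridge_penalty = 0)), x, y)
  expect_true(fit$fit$converged)
  expect_equal(unname(fit$fit$coefficients["(intercept)"]), log(1 / 2),
               tolerance = 1e-6)
  expect_equal(unname(fit$fit$coefficients["g1"]), log(4), tolerance = 1e-6)
  # independent cross-check against stats::glm
  ref <- glm(I(y == "lethal") ~ t(x), family = binomial)
  expect_equal(unname(fit$fit$coefficients), unname(coef(ref)),
               tolerance = 1e-5)
})

test_that("constant features get slope 0 and the prevalence intercept", {
  x <- mk_train(rep(1, 10), "g1", paste0("s", 1:10))
  y <- rep(c("lethal", "indolent"), c(4, 6))
  # a constant column is collinear with the intercept: penalty 0 cannot
  # converge, so the fit falls back to the flagged default-ridge refit where
  # the penalised slope goes to ~0 and the intercept carries the prevalence
  expect_warning(
    fit <- train_model(model_spec("logistic", list(ridge_penalty = 0)), x, y),
    "converge|separation")
  co <- fit$fit$coefficients
  expect_lt(abs(unname(co["g1"])), 1e-2)
  expect_equal(unname(co[1] + co[2]), log(0.4 / 0.6), tolerance = 1e-3)
})

test_that("separation at penalty 0 is flagged and refit with the default ridge", {
  x <- mk_train(c(1:5, 11:15), "g1", paste0("s", 1:10))
  y <- rep(c("indolent", "lethal"), each = 5)
  expect_warning(
    fit0 <- train_model(model_spec("logistic", list(ridge_penalty = 0)), x, y),
    "separation|converge")
  expect_true(fit0$fit$refit_penalty)
  expect_true(all(is.finite(fit0$fit$coefficients)))
  fit <- train_model(model_spec("logistic"), x, y)  # default penalty 1e-4
  expect_false(fit$fit$refit_penalty)
  expect_true(all(is.finite(fit$fit$coefficients)))
})

test_that("scores are equivariant to sample order and name missing features", {
  set.seed(5)
  expr <- mk_train(rnorm(30), paste0("g", 1:3), paste0("s", 1:10))
  y <- rep(c("lethal", "indolent"), 5)
  test <- mk_train(rnorm(12), paste0("g", 1:3), paste0("t", 1:4))
  for (spec in list(model_spec("dlda"), model_spec("knn", list(k = 3L)),
                    model_spec("ntp"), model_spec("logistic"))) {
    fit <- train_model(spec, expr, y)
    sc <- score_samples(fit, test)
    expect_equal(score_samples(fit, test[, 4:1]), sc[4:1])
    expect_error(score_samples(fit, test[1:2, ]), "missing selected feature")
  }
})

test_that("scores ignore genes the model did not select", {
  set.seed(6)
  expr <- mk_train(rnorm(40), paste0("g", 1:4), paste0("s", 1:10))
  y <- rep(c("lethal", "indolent"), 5)
  test <- mk_train(rnorm(16), paste0("g", 1:4), paste0("t", 1:4))
  shifted <- test
  shifted["g4", ] <- shifted["g4", ] + 100  # non-selected gene
  for (spec in list(model_spec("dlda"), model_spec("knn", list(k = 3L)),
                    model_spec("ntp"), model_spec("logistic"))) {
    fit <- train_model(spec, expr[1:3, ], y)
    expect_equal(score_samples(fit, shifted), score_samples(fit, test))
  }
})

test_that("clinical encodings are reference-coded with G4_6 and negative", {
  ph <- phenotype_table(data.frame(
    sample_id = c("a", "b", "c"), outcome = "indolent",
    death_from_cancer = FALSE, followup_years = 12,
    age_at_diagnosis = c(60, 70, 80),
    gleason_category = c("G4_6", "G7", "G8_10"),
    erg_status = c("negative", "rearranged", "negative")))
  x <- encode_clinical(ph, c("age", "gleason_category", "erg_status"))
  expect_equal(colnames(x), c("age", "gleason_G7", "gleason_G8_10",
                              "erg_rearranged"))
  expect_equal(unname(x[, "gleason_G7"]), c(0, 1, 0))
  expect_equal(unname(x[, "erg_rearranged"]), c(0, 1, 0))
})

test_that("plugin learners run through the same train/score contract", {
  set.seed(8)
  expr <- mk_train(rnorm(40), paste0("g", 1:4), paste0("s", 1:10))
  y <- rep(c("lethal", "indolent"), 5)
  spec <- model_spec("plugin", list(
    train = function(x, y) list(w = colMeans(x[y == "lethal", , drop = FALSE]) -
                                  colMeans(x[y == "indolent", , drop = FALSE])),
    score = function(fit, x) drop(x %*% fit$w)))
  fit <- train_model(spec, expr, y)
  sc <- score_samples(fit, expr)
  expect_length(sc, 10L)
  expect_true(all(is.finite(sc)))
  expect_error(model_spec("plugin"), "train")
})

test_that("models serialise to text and score identically after reload", {
  set.seed(9)
  expr <- mk_train(rnorm(60), paste0("g", 1:6), paste0("s", 1:10))
  y <- rep(c("lethal", "indolent"), 5)
  test <- mk_train(rnorm(24), paste0("g", 1:6), paste0("t", 1:4))
  for (spec in list(model_spec("dlda"), model_spec("knn", list(k = 3L)),
                    model_spec("ntp"), model_spec("logistic"))) {
    fit <- train_model(spec, expr, y)
    f <- withr::local_tempfile(fileext = ".json")
    write_model(fit, f)
    fit2 <- read_model(f)
    expect_equal(score_samples(fit2, test), score_samples(fit, test),
                 tolerance = 1e-12)
  }
  expect_error(write_model(train_model(model_spec("plugin", list(
    train = function(x, y) NULL, score = function(f, x) rep(0, nrow(x)))),
    expr, y), tempfile()), "cannot be serialised")
})

test_that("tidy and glance summarise trained models", {
  set.seed(10)
  expr <- mk_train(rnorm(40), paste0("g", 1:4), paste0("s", 1:10))
  y <- rep(c("lethal", "indolent"), 5)
  fit <- train_model(model_spec("dlda"), expr, y)
  td <- tidy(fit)
  expect_equal(td$gene_id, paste0("g", 1:4))
  expect_true(all(c("mean_indolent", "mean_lethal", "pooled_sd") %in% names(td)))
  gl <- glance(train_model(model_spec("logistic"), expr, y))
  expect_equal(gl$family, "logistic")
  expect_true(gl$converged)
})
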