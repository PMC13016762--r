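mk_fit <- function(lnL, k, n) {
  structure(list(loglik = lnL, k = k, n_tips = n,
                 AIC = -2 * lnL + 2 * k,
                 AICc = if (n - k - 1 > 0) -2 * lnL + 2 * k +
                   2 * k * (k + 1) / (n - k - 1) else NA_real_),
            class = "fit_result")
}

toy_marginals <- function(pr, ntip = NULL) {
  m <- data.frame(node = seq_len(nrow(pr)) + 100, parent = NA, age = NA)
  m <- cbind(m, as.data.frame(pr))
  class(m) <- c("marginal_table", "data.frame")
  attr(m, "ntip") <- ntip
  m
}

test_that("AICc correction and overparameterized exclusion follow the formula", {
  f1 <- mk_fit(-47, 3, 10)   # AIC = 100
  expect_equal(f1$AIC, 100)
  expect_equal(f1$AICc, 104)
  ## k = n: correction undefined, model excluded from AICc ranking
  f2 <- mk_fit(-10, 10, 10)
  expect_true(is.na(f2$AICc))
  sc <- aic_scores(list(a = f1, b = mk_fit(-18, 1, 10), c = f2))
  expect_equal(sc$dAIC[sc$model == "b"], 0)
  expect_equal(min(sc$dAICc, na.rm = TRUE), 0)
  expect_true(is.na(sc$AICc[sc$model == "c"]))
})

test_that("Akaike weights reproduce hand-computed values and invariances", {
  expect_equal(akaike_weights(0), 1)
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  expect_equal(akaike_weights(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(sum(akaike_weights(c(3, 7, 1, 0.2))), 1)
  ## invariant to adding a constant to every AIC
  expect_equal(akaike_weights(c(5, 7) + 100), akaike_weights(c(5, 7)))
  expect_error(akaike_weights(numeric(0)), "empty")
})

test_that("raw uncertainty and its proportion of maximum match hand values", {
  m <- toy_marginals(rbind(c(1, 0), c(0.5, 0.5)))
  expect_equal(raw_uncertainty(m), 25)
  certain <- toy_marginals(rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(raw_uncertainty(certain), 0)
  unif <- toy_marginals(matrix(1 / 6, 4, 6))
  expect_equal(proportion_of_max(raw_uncertainty(unif), 6), 1)
  expect_equal(proportion_of_max(25, 2), 0.5)
  ## only internal nodes counted when the table carries tip rows
  tr <- toy_tree()
  tpl <- mk_template(2, "ER")
  tm <- encode_tips(c(A = "0", B = "0", C = "1", D = "1"), tpl, tr)
  full <- marginal_ancestral(tr, build_Q(tpl, 0.1), tm, include_tips = TRUE)
  internal <- marginal_ancestral(tr, build_Q(tpl, 0.1), tm)
  expect_equal(raw_uncertainty(full), raw_uncertainty(internal))
})

test_that("mutual information is log2(k) minus marginal entropy, bounded", {
  m <- toy_marginals(rbind(rep(1 / 6, 6), c(1, 0, 0, 0, 0, 0),
                           c(0.5, 0.5, 0, 0, 0, 0)))
  mi <- mutual_information(m, 6)
  expect_equal(unname(mi$per_node[1]), 0)
  expect_equal(unname(mi$per_node[2]), log2(6))
  expect_equal(unname(mi$per_node[3]), log2(6) - 1)
  expect_equal(mi$total, sum(mi$per_node))
  expect_true(all(mi$per_node >= 0 & mi$per_node <= log2(6)))
  expect_true(mi$total <= nrow(m) * log2(6))
})

test_that("LOOCV scores the error of predicted tip states", {
  dat <- fixture_dataset()
  codes1 <- recode(dat$codes, 1)
  tpl <- mk_template(2, "ER", states = attr(codes1, "states"))
  tm <- encode_tips(codes1, tpl, dat$tree)
  cv <- loocv(dat$tree, tpl, tm, n_starts = 2, seed = 1)
  expect_true(all(cv$per_tip$ok))
  expect_true(all(cv$per_tip$error >= 0 & cv$per_tip$error <= 1))
  expect_equal(cv$mean_error, mean(cv$per_tip$error))
  expect_equal(cv$n_folds, 12)
  expect_true(all(cv$per_tip$pred_loglik <= 0))
})

test_that("a saturated-rate model predicts uniformly, with error 1 - 1/k", {
  ## forcing the rate to the saturation plateau makes the predictive
  ## marginal the uniform stationary distribution of the ER model
  tr <- ape::read.tree(text = "((A:10,B:10):10,(C:10,D:10):10);")
  tpl <- mk_template(4, "ER")
  tm <- encode_tips(c(A = "0", B = "1", C = "2", D = "3"), tpl, tr)
  Q <- build_Q(tpl, 50)
  unk <- tm; unk["A", ] <- 1
  m <- marginal_ancestral(tr, Q, unk, include_tips = TRUE, template = tpl)
  pred <- marginal_probs(m)[m$node == 1, ]
  expect_equal(unname(pred), rep(0.25, 4), tolerance = 1e-6)
  ## error of a uniform prediction
  expect_equal(1 - sum(pred[1]), 0.75, tolerance = 1e-6)
})

test_that("ingroup LOOCV restricts folds to the ingroup", {
  dat <- fixture_dataset()
  codes1 <- recode(dat$codes, 1)
  tpl <- mk_template(2, "ER", states = attr(codes1, "states"))
  tm <- encode_tips(codes1, tpl, dat$tree)
  ingroup <- setdiff(dat$tree$tip.label, dat$outgroup)
  full <- fit_model(dat$tree, tpl, tm, n_starts = 2, seed = 1)
  cvi <- loocv_ingroup(dat$tree, tpl, tm, ingroup, full_fit = full)
  expect_setequal(cvi$per_tip$taxon, ingroup)
  ## all-tips ingroup equals plain LOOCV
  cv_all <- loocv(dat$tree, tpl, tm, full_fit = full)
  cvi_all <- loocv_ingroup(dat$tree, tpl, tm, dat$tree$tip.label,
                           full_fit = full)
  expect_equal(cvi_all$mean_error, cv_all$mean_error)
  ## single-tip ingroup mean equals that tip's error
  one <- loocv_ingroup(dat$tree, tpl, tm, ingroup[1], full_fit = full)
  expect_equal(one$mean_error, one$per_tip$error[1])
  expect_error(loocv_ingroup(dat$tree, tpl, tm, character(0)), "empty")
})

test_that("error weights follow the 1 - e normalization", {
  expect_equal(error_weights(c(0.25, 0.75)), c(0.75, 0.25))
  expect_equal(error_weights(c(0.4, 0.4, 0.4)), rep(1 / 3, 3))
  expect_equal(sum(error_weights(c(0.1, 0.5, 0.9))), 1)
  expect_warning(w <- error_weights(c(1, 1)), "uniform")
  expect_equal(w, c(0.5, 0.5))
  expect_error(error_weights(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("model averaging is convex and order-invariant", {
  pr1 <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  pr2 <- rbind(c(0.4, 0.6), c(0.5, 0.5))
  m1 <- toy_marginals(pr1); m2 <- toy_marginals(pr2)
  avg <- model_average(list(m1, m2), c(0.25, 0.75))
  expect_equal(marginal_probs(avg), 0.25 * pr1 + 0.75 * pr2,
               ignore_attr = TRUE)
  expect_rows_sum_to_one(avg)
  ## identical tables, any weights
  expect_equal(marginal_probs(model_average(list(m1, m1), c(0.9, 0.1))),
               pr1, ignore_attr = TRUE)
  ## degenerate weights pick one table
  expect_equal(marginal_probs(model_average(list(m1, m2), c(1, 0))),
               pr1, ignore_attr = TRUE)
  ## order invariance
  rev_avg <- model_average(list(m2, m1), c(0.75, 0.25))
  expect_equal(marginal_probs(avg), marginal_probs(rev_avg))
  bad <- toy_marginals(pr1); bad$node <- bad$node + 1
  expect_error(model_average(list(m1, bad), c(0.5, 0.5)), "node sets")
})

test_that("the generalizability threshold keeps models within 10% of the best", {
  e <- c(a = 0.33, b = 0.36, c = 0.40)
  sel <- select_generalizable(e, 0.10)
  expect_equal(unname(sel), c(TRUE, TRUE, FALSE))  # cutoff 0.363
  expect_equal(select_generalizable(c(x = 0.5)), c(x = TRUE))
  ## zero threshold keeps the argmin only
  expect_equal(unname(select_generalizable(e, 0)), c(TRUE, FALSE, FALSE))
  df <- data.frame(model = names(e), mean_error = unname(e))
  expect_equal(select_generalizable(df)$model, c("a", "b"))
})
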