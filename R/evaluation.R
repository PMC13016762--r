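## Model-evaluation layer: information criteria, uncertainty and information
## metrics on marginal ancestral estimates, leave-one-out cross-validation,
## and model averaging.

#' AIC / AICc / delta-AIC scores for a set of fits
#'
#' `AICc = AIC + 2k(k+1)/(n-k-1)`; AICc is reported as `NA` (and excluded
#' from AICc ranking) when `n - k - 1 <= 0`, the overparameterized case in
#' which the small-sample correction is undefined.
#'
#' @param fits List of `fit_result` objects (or a single one).
#' @return Data frame with `model`, `lnL`, `k`, `n`, `AIC`, `AICc`,
#'   `dAIC`, `dAICc`.
#' @export
aic_scores <- function(fits) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  if (!length(fits)) stop("need at least one fit")
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  d <- data.frame(
    model = nm,
    lnL = vapply(fits, function(f) f$loglik, 0),
    k   = vapply(fits, function(f) f$k, 0),
    n   = vapply(fits, function(f) f$n_tips, 0),
    AIC = vapply(fits, function(f) f$AIC, 0),
    AICc = vapply(fits, function(f) f$AICc, 0),
    stringsAsFactors = FALSE)
  d$dAIC <- d$AIC - min(d$AIC)
  d$dAICc <- d$AICc - min(d$AICc, na.rm = TRUE)
  d
}

#' Akaike weights from delta-AIC values
#'
#' `w_i = exp(-0.5 d_i) / sum_j exp(-0.5 d_j)`.
#'
#' @param deltas Numeric vector of AIC differences from the best model.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(deltas) {
  if (!length(deltas)) stop("empty delta list")
  if (any(!is.finite(deltas))) stop("deltas must be finite")
  w <- exp(-0.5 * (deltas - min(deltas)))
  w / sum(w)
}

#' Raw uncertainty of marginal ancestral estimates
#'
#' One minus the mean (over internal nodes) of the highest per-node marginal
#' probability, expressed as a percentage. Absolute certainty gives 0;
#' uniform marginals over k states give `100 * (1 - 1/k)`.
#'
#' @param m A `marginal_table` (internal nodes; tip rows, identified by
#'   `node <=` number of tips when `parent` rows are present, are ignored if
#'   flagged via `internal_only`).
#' @param internal_only Drop rows whose node id is a tip (no children in the
#'   table). Default `TRUE`.
#' @return Percent uncertainty in `[0, 100)`.
#' @export
raw_uncertainty <- function(m, internal_only = TRUE) {
  pr <- marginal_probs(m)
  ntip <- attr(m, "ntip")
  if (internal_only && !is.null(ntip) && "node" %in% colnames(m)) {
    keep <- m$node > ntip
    if (any(keep)) pr <- pr[keep, , drop = FALSE]
  }
  if (!nrow(pr)) stop("empty marginal table")
  100 * (1 - mean(apply(pr, 1L, max)))
}

#' Proportion of the maximal theoretical uncertainty
#'
#' @param uncertainty_percent Raw uncertainty (percent).
#' @param k Number of states.
#' @return Fraction in `[0, 1]` of the maximum `100 * (1 - 1/k)`.
#' @export
proportion_of_max <- function(uncertainty_percent, k) {
  if (k < 2) stop("k must be >= 2")
  uncertainty_percent / (100 * (1 - 1 / k))
}

#' Mutual information between tip data and node states
#'
#' Per node: `MI = log2(k) - H(marginal)` in bits, where `log2(k)` is the
#' unconditional node-state entropy (set by the state count, identical for
#' every node) and `H` the entropy of the data-conditioned marginal.
#' `0 * log2(0)` is taken as 0.
#'
#' @param m A `marginal_table` collapsed to observed states.
#' @param k_observed Number of observed states (default: number of
#'   probability columns).
#' @return List with `per_node` (named by node id) and `total` (bits).
#' @export
mutual_information <- function(m, k_observed = NULL) {
  pr <- marginal_probs(m)
  if (is.null(k_observed)) k_observed <- ncol(pr)
  H <- apply(pr, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  mi <- log2(k_observed) - H
  names(mi) <- m$node
  list(per_node = mi, total = sum(mi))
}

#' Leave-one-out cross-validation of a model on a tree
#'
#' For each scored tip: (1) drop the tip from the tree; (2) refit the model
#' rates; (3) restore the tip with its state set to unknown; (4) estimate
#' the tip's marginal state under the saved rates; (5) score the error as
#' 1 minus the predicted probability mass on the true state(s) (equivalently
#' the summed probability of all incorrect states). The predictive
#' log-likelihood `log p(true)` per tip is recorded as well.
#'
#' Fold refits start from the full-data MLE (plus random restarts). A fold
#' whose refit fails is flagged and excluded from the means with a warning.
#'
#' @inheritParams fit_model
#' @param taxa Taxa to drop and score (default all tips).
#' @param n_starts Optimizer starts per fold (the first is the full-data
#'   MLE warm start).
#' @param full_fit Optional precomputed full-data `fit_result` to warm-start
#'   folds from.
#' @return A `loocv_result`: list with `per_tip` data frame (`taxon`,
#'   `error`, `pred_loglik`, `ok`), `mean_error`, `mean_loglik`.
#' @export
loocv <- function(tree, template, tipmat, root_prior = "flat",
                  taxa = NULL, n_starts = 2, seed = 1, maxit = 500,
                  full_fit = NULL) {
  if (length(tree$tip.label) < 3) stop("LOOCV needs at least 3 tips")
  if (is.null(taxa)) taxa <- tree$tip.label
  if (!length(taxa) || !all(taxa %in% tree$tip.label)) {
    stop("taxa to score must be tips of the tree")
  }
  if (is.null(full_fit)) {
    full_fit <- fit_model(tree, template, tipmat, root_prior,
                          n_starts = max(n_starts, 2), seed = seed,
                          maxit = maxit)
  }
  S <- length(template$states)
  res <- data.frame(taxon = taxa, error = NA_real_, pred_loglik = NA_real_,
                    ok = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(taxa)) {
    tip <- taxa[i]
    fold <- tryCatch({
      sub <- ape::drop.tip(tree, tip)
      submat <- tipmat[sub$tip.label, , drop = FALSE]
      fit <- fit_model(sub, template, submat, root_prior,
                       n_starts = n_starts, seed = seed + i,
                       init = full_fit$rates, maxit = maxit)
      ## restore the tip as unknown and predict its state
      unk <- tipmat
      unk[tip, ] <- 1
      marg <- marginal_ancestral(tree, build_Q(template, fit$rates), unk,
                                 root_prior, template = template,
                                 include_tips = TRUE, clamp_tips = TRUE)
      pred <- marginal_probs(marg)[match(match(tip, tree$tip.label), marg$node), ]
      ## true observed-state mass of the original coding
      truth <- observed_truth(tipmat[tip, ], template)
      p_true <- sum(pred[truth > 0])
      list(error = 1 - p_true, pred_loglik = log(max(p_true, .Machine$double.xmin)))
    }, error = function(e) NULL)
    if (!is.null(fold)) {
      res$error[i] <- fold$error
      res$pred_loglik[i] <- fold$pred_loglik
      res$ok[i] <- TRUE
    }
  }
  if (any(!res$ok)) {
    warning(sum(!res$ok), " LOOCV fold(s) failed and were excluded")
  }
  ok <- res$ok
  structure(list(per_tip = res,
                 mean_error = mean(res$error[ok]),
                 mean_loglik = mean(res$pred_loglik[ok]),
                 n_folds = sum(ok)),
            class = "loocv_result")
}

## collapse a model-state tip vector back to the observed-state truth set
observed_truth <- function(tipvec, template) {
  k <- length(template$observed)
  truth <- numeric(k)
  for (s in seq_along(tipvec)) {
    if (tipvec[s] > 0) truth[template$obs_map[s]] <- 1
  }
  truth
}

#' Ingroup-restricted LOOCV mean error
#'
#' Same fold procedure as [loocv()], but only ingroup taxa are dropped and
#' scored; the mean error is taken over ingroup tips. This makes trees that
#' differ only in outgroup composition comparable.
#'
#' @inheritParams loocv
#' @param ingroup Character vector of ingroup taxa (non-empty subset of the
#'   tips).
#' @return A `loocv_result` over the ingroup taxa.
#' @export
loocv_ingroup <- function(tree, template, tipmat, ingroup,
                          root_prior = "flat", n_starts = 2, seed = 1,
                          maxit = 500, full_fit = NULL) {
  if (!length(ingroup)) stop("empty ingroup")
  if (!all(ingroup %in% tree$tip.label)) stop("ingroup taxa missing from tree")
  loocv(tree, template, tipmat, root_prior, taxa = ingroup,
        n_starts = n_starts, seed = seed, maxit = maxit, full_fit = full_fit)
}

#' Error-based model weights
#'
#' `w_i = (1 - e_i) / sum_j (1 - e_j)` for mean LOOCV errors `e_i`.
#' If every error equals 1 the weights degenerate; a uniform fallback is
#' returned with a warning.
#'
#' @param mean_errors Numeric vector of mean errors in `[0, 1]`.
#' @return Weights summing to 1.
#' @export
error_weights <- function(mean_errors) {
  if (!length(mean_errors)) stop("empty error list")
  if (any(mean_errors < 0 | mean_errors > 1)) stop("errors must be in [0, 1]")
  s <- sum(1 - mean_errors)
  if (s <= 0) {
    warning("all errors equal 1; falling back to uniform weights")
    return(rep(1 / length(mean_errors), length(mean_errors)))
  }
  (1 - mean_errors) / s
}

#' Weighted average of marginal tables over a common topology
#'
#' Per node, the weighted sum of the marginal vectors across model/tree
#' combinations; rows remain probability vectors.
#'
#' @param tables List of `marginal_table`s with identical node sets and
#'   state columns.
#' @param weights Numeric weights summing to 1 (within tolerance).
#' @return A `marginal_table`.
#' @export
model_average <- function(tables, weights) {
  if (!length(tables)) stop("no tables to average")
  if (length(weights) != length(tables)) stop("one weight per table required")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  ref <- tables[[1L]]
  refp <- marginal_probs(ref)
  acc <- matrix(0, nrow(refp), ncol(refp), dimnames = dimnames(refp))
  for (i in seq_along(tables)) {
    t_i <- tables[[i]]
    if (!identical(t_i$node, ref$node)) stop("node sets differ between tables")
    p <- marginal_probs(t_i)
    if (!identical(colnames(p), colnames(refp))) {
      stop("state columns differ between tables")
    }
    acc <- acc + weights[i] * p
  }
  out <- cbind(ref[, c("node", "parent", "age")], as.data.frame(acc))
  class(out) <- c("marginal_table", "data.frame")
  attr(out, "ntip") <- attr(ref, "ntip")
  out
}

#' Select combinations of comparable generalizability
#'
#' Returns all entries whose mean LOOCV error lies within `threshold`
#' (default 10%) of the lowest mean error, i.e.
#' `error <= (1 + threshold) * min(error)`.
#'
#' @param mean_errors Named numeric vector (or data frame with columns
#'   `model` and `mean_error`).
#' @param threshold Relative slack above the minimum (fraction, default 0.10).
#' @return Logical vector (or subset of the data frame) marking selected
#'   combinations.
#' @export
select_generalizable <- function(mean_errors, threshold = 0.10) {
  if (is.data.frame(mean_errors)) {
    sel <- select_generalizable(stats::setNames(mean_errors$mean_error,
                                                mean_errors$model), threshold)
    return(mean_errors[sel, , drop = FALSE])
  }
  e <- mean_errors[is.finite(mean_errors)]
  if (!length(e)) stop("no finite mean errors")
  cutoff <- (1 + threshold) * min(e)
  is.finite(mean_errors) & mean_errors <= cutoff
}
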