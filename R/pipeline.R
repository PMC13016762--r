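## Orchestration: run grids of tree x model ASE analyses, collect per-cell
## evaluation records, model-average, and lay results out as report tables.

#' Build an experiment configuration
#'
#' A named list of analysis cases crossed with a model set. Each case pairs
#' a time-scaled tree with a character coding; cases stand for whatever the
#' experiment varies (outgroup sets, time-scaling methods, coding
#' strategies, or just one dataset crossed with a model grid).
#'
#' @param cases Named list; each element a list with `tree` (a `phylo` /
#'   `timetree`), `codes` (named character vector of state codes), and
#'   optionally `models` (named list of `rate_template`s overriding the
#'   shared set) and `ingroup` (taxa for ingroup LOOCV).
#' @param models Named list of `rate_template`s shared by cases that do not
#'   carry their own.
#' @param root_prior Root prior for all fits (default `"flat"`).
#' @param n_starts,seed,maxit Optimizer settings passed to [fit_model()].
#' @param loocv `"none"` (default), `"all"`, or a character vector of model
#'   names to cross-validate. The full folds-times-cells grid is the
#'   study-scale setting and is expensive; restrict the scope for
#'   interactive work.
#' @param loocv_ingroup_only When `TRUE`, LOOCV drops/scores only the
#'   case's `ingroup` taxa.
#' @param focal_clade Optional character vector of >= 2 tip labels; the
#'   mutual information at their MRCA is recorded per cell.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cases, models = NULL, root_prior = "flat",
                              n_starts = 3, seed = 1, maxit = 500,
                              loocv = "none", loocv_ingroup_only = FALSE,
                              focal_clade = NULL) {
  if (!length(cases) || is.null(names(cases))) stop("cases must be a named list")
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    if (is.null(cs$tree) || is.null(cs$codes)) {
      stop("case ", nm, " needs `tree` and `codes`")
    }
    mods <- if (!is.null(cs$models)) cs$models else models
    if (is.null(mods) || !length(mods)) stop("case ", nm, " has no models")
    if (!is.null(cs$ingroup) && !all(cs$ingroup %in% cs$tree$tip.label)) {
      stop("case ", nm, ": ingroup taxa missing from tree")
    }
  }
  structure(list(cases = cases, models = models, root_prior = root_prior,
                 n_starts = n_starts, seed = as.integer(seed), maxit = maxit,
                 loocv = loocv, loocv_ingroup_only = loocv_ingroup_only,
                 focal_clade = focal_clade),
            class = "experiment_config")
}

#' Run an experiment grid
#'
#' For every case x model cell: encode tips, fit by maximum likelihood,
#' reconstruct marginal ancestral states (hidden states collapsed), and
#' record the evaluation metrics (AIC, AICc, raw uncertainty, proportion of
#' maximal uncertainty, total mutual information, optionally focal-node
#' information and LOOCV errors). Cell failures are recorded and surfaced,
#' not silently dropped; partial bundles are explicit.
#'
#' @param config An [experiment_config()].
#' @return An `ase_bundle`: list with `cells` (one data-frame row per cell),
#'   `fits`, `marginals` (named `case|model` lists), `loocv` (per-cell
#'   `loocv_result`s when requested), `failures` (named character vector of
#'   error messages), and `meta` (seed, settings).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list(); fits <- list(); marginals <- list(); cv <- list()
  failures <- character(0)
  for (case_name in names(config$cases)) {
    cs <- config$cases[[case_name]]
    mods <- if (!is.null(cs$models)) cs$models else config$models
    for (model_name in names(mods)) {
      tpl <- mods[[model_name]]
      cell <- paste(case_name, model_name, sep = "|")
      out <- tryCatch(
        run_cell(cs, tpl, config, cell, model_name),
        error = function(e) e)
      if (inherits(out, "error")) {
        failures[cell] <- conditionMessage(out)
        next
      }
      rows[[cell]] <- out$row
      fits[[cell]] <- out$fit
      marginals[[cell]] <- out$marg
      if (!is.null(out$cv)) cv[[cell]] <- out$cv
    }
  }
  cells <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(cells)) rownames(cells) <- NULL
  structure(list(cells = cells, fits = fits, marginals = marginals,
                 loocv = cv, failures = failures,
                 meta = list(seed = config$seed,
                             root_prior = config$root_prior,
                             n_starts = config$n_starts,
                             loocv = config$loocv)),
            class = "ase_bundle")
}

run_cell <- function(cs, tpl, config, cell, model_name) {
  tipmat <- encode_tips(cs$codes, tpl, tree = cs$tree)
  fit <- fit_model(cs$tree, tpl, tipmat, config$root_prior,
                   n_starts = config$n_starts, seed = config$seed,
                   maxit = config$maxit)
  Q <- build_Q(tpl, fit$rates)
  marg <- marginal_ancestral(cs$tree, Q, tipmat, config$root_prior,
                             template = tpl)
  k_obs <- length(tpl$observed)
  unc <- raw_uncertainty(marg)
  mi <- mutual_information(marg, k_obs)
  mi_focal <- NA_real_
  if (!is.null(config$focal_clade)) {
    present <- intersect(config$focal_clade, cs$tree$tip.label)
    if (length(present) >= 2) {
      node <- ape::getMRCA(cs$tree, present)
      if (!is.null(node)) mi_focal <- mi$per_node[as.character(node)]
    }
  }
  want_cv <- identical(config$loocv, "all") ||
    (is.character(config$loocv) && model_name %in% config$loocv)
  cvres <- NULL
  if (want_cv) {
    taxa <- if (config$loocv_ingroup_only && !is.null(cs$ingroup)) {
      cs$ingroup
    } else cs$tree$tip.label
    cvres <- loocv(cs$tree, tpl, tipmat, config$root_prior, taxa = taxa,
                   n_starts = min(config$n_starts, 2), seed = config$seed,
                   maxit = config$maxit, full_fit = fit)
  }
  strsplit1 <- strsplit(cell, "|", fixed = TRUE)[[1]]
  row <- data.frame(
    case = strsplit1[1], model = model_name,
    architecture = tpl$architecture, scheme = tpl$scheme,
    lnL = fit$loglik, k = fit$k, n = fit$n_tips,
    AIC = fit$AIC, AICc = fit$AICc,
    uncertainty = unc,
    prop_max_uncertainty = proportion_of_max(unc, k_obs),
    mi_total = mi$total, mi_focal = unname(mi_focal),
    loocv_mean_error = if (is.null(cvres)) NA_real_ else cvres$mean_error,
    loocv_mean_loglik = if (is.null(cvres)) NA_real_ else cvres$mean_loglik,
    stringsAsFactors = FALSE)
  list(row = row, fit = fit, marg = marg, cv = cvres)
}

#' Model-average the marginal tables of a bundle
#'
#' Weights each cell's marginal table by Akaike weights (from AIC) or by
#' LOOCV error weights and sums. Only cells sharing the reference node set
#' (same tree topology) can be averaged; pass `cases` to restrict.
#'
#' @param bundle An `ase_bundle`.
#' @param weighting `"aic"` or `"error"`.
#' @param cases Optional case names to include (default all).
#' @return List with `table` (the averaged `marginal_table`) and `weights`
#'   (named per cell).
#' @export
average_bundle <- function(bundle, weighting = c("aic", "error"),
                           cases = NULL) {
  weighting <- match.arg(weighting)
  cells <- bundle$cells
  if (is.null(cells)) stop("empty bundle")
  keep <- if (is.null(cases)) rep(TRUE, nrow(cells)) else cells$case %in% cases
  ids <- paste(cells$case, cells$model, sep = "|")[keep]
  if (!length(ids)) stop("no cells selected")
  w <- if (weighting == "aic") {
    akaike_weights(cells$AIC[keep] - min(cells$AIC[keep]))
  } else {
    e <- cells$loocv_mean_error[keep]
    if (anyNA(e)) stop("error weighting needs LOOCV on every selected cell")
    error_weights(e)
  }
  names(w) <- ids
  tabs <- bundle$marginals[ids]
  list(table = model_average(tabs, w), weights = w)
}

#' Lay a bundle out as one of the report tables
#'
#' Pivots the per-cell metric records into the layouts of the study's
#' comparison tables: rows are the analysis cases (outgroup set, tree, or
#' coding strategy), columns are the rate schemes.
#'
#' @param bundle An `ase_bundle`.
#' @param layout `"table3"` (uncertainty, SYM/ARD), `"table4"` (ingroup
#'   LOOCV mean error, ER/SYM/ARD), `"table5"` (focal-node mutual
#'   information, ER/SYM/ARD), `"table6"` (uncertainty and AICc, SYM/ARD),
#'   `"table7"` (uncertainty, ER/SYM/ARD).
#' @return A data frame, one row per case.
#' @export
tabulate_bundle <- function(bundle,
                            layout = c("table3", "table4", "table5",
                                       "table6", "table7")) {
  layout <- match.arg(layout)
  cells <- bundle$cells
  if (is.null(cells) || !nrow(cells)) stop("empty bundle")
  spec <- switch(layout,
    table3 = list(metrics = "uncertainty", schemes = c("SYM", "ARD")),
    table4 = list(metrics = "loocv_mean_error", schemes = c("ER", "SYM", "ARD")),
    table5 = list(metrics = "mi_focal", schemes = c("ER", "SYM", "ARD")),
    table6 = list(metrics = c("uncertainty", "AICc"), schemes = c("SYM", "ARD")),
    table7 = list(metrics = "uncertainty", schemes = c("ER", "SYM", "ARD")))
  out <- data.frame(case = unique(cells$case), stringsAsFactors = FALSE)
  for (scheme in spec$schemes) for (metric in spec$metrics) {
    col <- if (length(spec$metrics) > 1) paste(scheme, metric, sep = "_") else scheme
    vals <- vapply(out$case, function(cn) {
      hit <- cells$case == cn & cells$scheme == scheme
      if (!any(hit)) stop("missing ", scheme, " cell for case ", cn)
      if (sum(hit) > 1) {
        stop("layout ", layout, " needs one ", scheme, " cell per case; ",
             "restrict the model set")
      }
      v <- cells[[metric]][hit]
      if (is.na(v)) stop("metric ", metric, " missing for case ", cn)
      v
    }, 0)
    out[[col]] <- vals
  }
  out
}

#' Write a marginal table (or any data frame) as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
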