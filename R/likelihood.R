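## Felsenstein pruning likelihoods, ML rate fitting, and marginal ancestral
## state reconstruction, with hidden states collapsed for reporting.

#' Encode a raw character matrix as tip likelihood vectors
#'
#' Turns taxon state codes into per-tip likelihood vectors over the model
#' state space of a template. An ambiguity set `"a&b"` places 1 at both
#' states, `"?"` (or `NA`) gives an all-ones vector, and hidden-state models
#' copy each observed value onto all its hidden preimages.
#'
#' @param codes Named character vector (taxon -> state code). Codes refer to
#'   observed state labels or 0-based observed state indices; members of an
#'   ambiguity set are separated by `&`.
#' @param template A `rate_template` defining observed states and the
#'   observation map.
#' @param tree Optional tree; if given, taxa are checked against and ordered
#'   by `tree$tip.label`.
#' @return Numeric matrix `taxa x model states` of 0/1 likelihoods.
#' @export
encode_tips <- function(codes, template, tree = NULL) {
  if (is.null(names(codes)) || anyNA(names(codes))) stop("codes must be named by taxon")
  obs <- template$observed
  k <- length(obs)
  resolve <- function(code) {
    v <- numeric(k)
    if (is.na(code) || code == "?") return(v + 1)
    for (part in strsplit(code, "&", fixed = TRUE)[[1]]) {
      part <- trimws(part)
      i <- match(part, obs)
      if (is.na(i) && grepl("^[0-9]+$", part)) {
        j <- as.integer(part) + 1L
        if (j >= 1L && j <= k) i <- j
      }
      if (is.na(i)) stop("unknown state code: ", code)
      v[i] <- 1
    }
    if (!any(v > 0)) stop("state code resolves to no state: ", code)
    v
  }
  obs_mat <- t(vapply(codes, resolve, numeric(k)))
  if (!is.null(tree)) {
    missing <- setdiff(tree$tip.label, rownames(obs_mat))
    if (length(missing)) stop("no codes for tip(s): ", paste(missing, collapse = ", "))
    extra <- setdiff(rownames(obs_mat), tree$tip.label)
    if (length(extra)) stop("taxa absent from tree: ", paste(extra, collapse = ", "))
    obs_mat <- obs_mat[tree$tip.label, , drop = FALSE]
  }
  ## copy observed values to all hidden preimages
  out <- obs_mat[, template$obs_map, drop = FALSE]
  colnames(out) <- template$states
  out
}

## ---- transition probabilities --------------------------------------------

## Build a function t -> P(t) = expm(Q t). Eigendecomposition fast path with
## a dense scaling-and-squaring fallback when Q is nearly defective.
make_Pfun <- function(Q) {
  n <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      fnorm <- function(m) sqrt(sum(Mod(m)^2))
      kappa <- fnorm(eg$vectors) * fnorm(Vi)
      use_eigen <- is.finite(kappa) && kappa < 1e8
    }
  }
  if (use_eigen) {
    V <- eg$vectors; lam <- eg$values
    function(t) {
      P <- Re(V %*% (exp(lam * t) * Vi))
      P[P < 0] <- 0
      P
    }
  } else {
    function(t) {
      P <- as.matrix(Matrix::expm(Q * t))
      P[P < 0] <- 0
      P
    }
  }
}

root_prior_vec <- function(root_prior, Q, partial = NULL) {
  n <- nrow(Q)
  if (is.numeric(root_prior)) {
    if (length(root_prior) != n) stop("root prior length mismatch")
    return(root_prior / sum(root_prior))
  }
  switch(root_prior,
    flat = rep(1 / n, n),
    stationary = stationary_dist(Q),
    fitzjohn = {
      if (is.null(partial)) stop("fitzjohn prior needs root partials")
      if (sum(partial) <= 0) rep(1 / n, n) else partial / sum(partial)
    },
    stop("unknown root prior: ", root_prior)
  )
}

## stationary distribution of a generator: left null vector of Q
stationary_dist <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- tryCatch(as.vector(qr.solve(A, b)), error = function(e) rep(1 / n, n))
  pi[pi < 0] <- 0
  if (sum(pi) <= 0) pi <- rep(1, n)
  pi / sum(pi)
}

## Core pruning pass. Returns per-node scaled partial likelihoods, log scale
## factors, and the edge transition matrices (children indexed by edge row).
prune_pass <- function(tree, Q, tipmat) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  S <- nrow(Q)
  if (ncol(tipmat) != S) stop("tip matrix does not match Q dimension")
  if (!identical(rownames(tipmat), tree$tip.label)) {
    tipmat <- tipmat[tree$tip.label, , drop = FALSE]
  }
  po <- ape::reorder.phylo(tree, "postorder")
  Pfun <- make_Pfun(Q)
  L <- matrix(1, ntip + nnode, S)
  L[seq_len(ntip), ] <- tipmat
  logscale <- numeric(ntip + nnode)
  Pmats <- vector("list", nrow(po$edge))
  ## children contribute multiplicatively; process edges postorder
  done <- logical(ntip + nnode)
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    t_br <- po$edge.length[i]
    if (is.null(t_br) || is.na(t_br) || t_br < 0) stop("invalid branch length")
    P <- Pfun(t_br)
    Pmats[[i]] <- P
    contrib <- as.vector(P %*% L[ch, ])
    if (!done[p]) { L[p, ] <- contrib; done[p] <- TRUE } else {
      L[p, ] <- L[p, ] * contrib
    }
    logscale[p] <- logscale[p] + logscale[ch]
    m <- max(L[p, ])
    if (!is.finite(m) || m <= 0) return(NULL)  # signals -Inf likelihood
    L[p, ] <- L[p, ] / m
    logscale[p] <- logscale[p] + log(m)
  }
  list(po = po, L = L, logscale = logscale, Pmats = Pmats, Pfun = Pfun)
}

#' Pruning log-likelihood of a Markov model on a time tree
#'
#' Exact Felsenstein pruning with per-branch transition matrices
#' `expm(Q * t)`, with per-node rescaling to remain stable for large state
#' spaces and branch lengths spanning orders of magnitude.
#'
#' @param tree A rooted `phylo`/`timetree` with branch lengths (myr).
#' @param Q Generator matrix (from [build_Q()]).
#' @param tipmat Tip likelihood matrix from [encode_tips()].
#' @param root_prior `"flat"` (default), `"stationary"`, `"fitzjohn"`, or a
#'   numeric prior over model states.
#' @return Log-likelihood in nats.
#' @export
prune_loglik <- function(tree, Q, tipmat, root_prior = "flat") {
  pass <- prune_pass(tree, Q, tipmat)
  if (is.null(pass)) return(-Inf)
  root <- root_node(tree)
  pi <- root_prior_vec(root_prior, Q, partial = pass$L[root, ] *
                         exp(pass$logscale[root] - pass$logscale[root]))
  lik <- sum(pi * pass$L[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pass$logscale[root]
}

#' Marginal ancestral state estimates
#'
#' Two-pass (pruning + root-to-tip) marginal reconstruction: the marginal of
#' a node is proportional to the product of the partial likelihoods flowing
#' from every direction of the tree, weighted by the root prior. Hidden
#' states are collapsed onto observed states by summation for reporting.
#'
#' @inheritParams prune_loglik
#' @param template Optional `rate_template`; when given, hidden states are
#'   collapsed through its observation map and columns are labelled.
#' @param include_tips Also return marginals for tips.
#' @param clamp_tips When `TRUE` (default) tips with observed data keep
#'   their observed vector (renormalized by the upward flow); when `FALSE`
#'   tip states are re-estimated from the rest of the tree as if unknown.
#' @return A `marginal_table`: data frame with `node`, `parent`, `age` (if
#'   available) and one probability column per (observed) state; rows sum
#'   to 1.
#' @export
marginal_ancestral <- function(tree, Q, tipmat, root_prior = "flat",
                               template = NULL, include_tips = FALSE,
                               clamp_tips = TRUE) {
  pass <- prune_pass(tree, Q, tipmat)
  if (is.null(pass)) stop("likelihood underflow: non-finite likelihood")
  po <- pass$po
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  S <- nrow(Q)
  root <- root_node(tree)
  pi <- root_prior_vec(root_prior, Q, partial = pass$L[root, ])

  ## upward ("above") partials, preorder. U[v] is the likelihood flow into v
  ## from the rest of the tree (prior included); unnormalized, rescaled.
  U <- matrix(0, ntip + nnode, S)
  U[root, ] <- pi
  edges <- po$edge
  ## children of each parent (edge row indices), for sibling products
  kids <- split(seq_len(nrow(edges)), edges[, 1L])
  for (i in rev(seq_len(nrow(edges)))) {  # reverse postorder = preorder
    p <- edges[i, 1L]; ch <- edges[i, 2L]
    P <- pass$Pmats[[i]]
    sib <- setdiff(kids[[as.character(p)]], i)
    flow <- U[p, ]
    for (j in sib) {
      contrib <- as.vector(pass$Pmats[[j]] %*% pass$L[edges[j, 2L], ])
      flow <- flow * contrib
    }
    u <- as.vector(crossprod(P, flow))   # t(P) %*% flow
    m <- max(u)
    U[ch, ] <- if (m > 0) u / m else u
  }

  ## marginals
  nodes <- if (include_tips) seq_len(ntip + nnode) else (ntip + 1L):(ntip + nnode)
  marg <- matrix(NA_real_, length(nodes), S)
  for (r in seq_along(nodes)) {
    v <- nodes[r]
    down <- if (v <= ntip && !clamp_tips) rep(1, S) else pass$L[v, ]
    w <- down * U[v, ]
    tot <- sum(w)
    if (tot <= 0) stop("zero marginal at node ", v)
    marg[r, ] <- w / tot
  }

  ## collapse hidden states for reporting
  if (!is.null(template)) {
    k <- length(template$observed)
    cmat <- matrix(0, S, k)
    cmat[cbind(seq_len(S), template$obs_map)] <- 1
    marg <- marg %*% cmat
    colnames(marg) <- template$observed
  } else {
    colnames(marg) <- colnames(Q)
  }
  parent <- parent_vec(tree)
  age <- attr(tree, "ages")
  out <- data.frame(node = nodes, parent = parent[nodes],
                    age = if (!is.null(age)) age[nodes] else NA_real_)
  out <- cbind(out, as.data.frame(marg))
  class(out) <- c("marginal_table", "data.frame")
  attr(out, "ntip") <- ntip
  out
}

#' Probability columns of a marginal table
#' @param m A `marginal_table`.
#' @return Numeric matrix of per-node state probabilities.
#' @export
marginal_probs <- function(m) {
  as.matrix(m[, setdiff(colnames(m), c("node", "parent", "age")), drop = FALSE])
}

#' Aggregate marginal probabilities into state groups
#'
#' Sums member-state probabilities into groups (e.g. reducing a six-state
#' feather coding to absence/presence for cross-coding comparison).
#'
#' @param m A `marginal_table`.
#' @param grouping Named character vector mapping every state column of `m`
#'   to a group label.
#' @return A `marginal_table` with one probability column per group.
#' @export
aggregate_states <- function(m, grouping) {
  pr <- marginal_probs(m)
  states <- colnames(pr)
  if (!all(states %in% names(grouping))) {
    stop("grouping must cover every state: missing ",
         paste(setdiff(states, names(grouping)), collapse = ", "))
  }
  groups <- unique(unname(grouping[states]))
  agg <- sapply(groups, function(g) {
    rowSums(pr[, states[grouping[states] == g], drop = FALSE])
  })
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = 1, dimnames = list(NULL, groups))
  out <- cbind(m[, c("node", "parent", "age")], as.data.frame(agg))
  class(out) <- c("marginal_table", "data.frame")
  attr(out, "ntip") <- attr(m, "ntip")
  out
}

## ---- maximum-likelihood fitting ------------------------------------------

#' Fit a Markov model to tip data by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over log-rates with bounded
#' multi-start local optimization (`stats::optim`, L-BFGS-B). Deterministic
#' given `seed`.
#'
#' @inheritParams prune_loglik
#' @param template A `rate_template`.
#' @param n_starts Number of optimizer starts: the first from `init` (or a
#'   heuristic), the rest from log-uniform draws over the rate bounds.
#' @param seed Integer seed controlling the random restarts.
#' @param init Optional numeric vector of starting rates.
#' @param bounds Rate bounds (events/myr), default `c(1e-9, 100)`.
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @param factr L-BFGS-B convergence tolerance factor (see [stats::optim()]);
#'   larger values stop earlier.
#' @return A `fit_result`: list with `rates`, `loglik`, `k`, `n_tips`,
#'   `AIC`, `AICc` (NA when undefined), `template`, `convergence`, `starts`,
#'   `seed`.
#' @export
fit_model <- function(tree, template, tipmat, root_prior = "flat",
                      n_starts = 10, seed = 1, init = NULL,
                      bounds = c(1e-9, 100), maxit = 500, factr = 1e7) {
  k <- template$n_par
  lb <- log(bounds[1]); ub <- log(bounds[2])
  negll <- function(logr) {
    ll <- prune_loglik(tree, build_Q(template, exp(logr)), tipmat, root_prior)
    if (!is.finite(ll)) 1e10 else -ll
  }
  ## heuristic default start: about one expected event per tree depth
  depth <- max(ape::node.depth.edgelength(tree))
  start0 <- if (!is.null(init)) log(pmin(pmax(init, bounds[1]), bounds[2])) else
    rep(log(max(1 / max(depth, 1e-6), bounds[1])), k)
  starts <- list(start0)
  if (n_starts > 1) {
    rs <- withr_seed(seed, {
      lapply(seq_len(n_starts - 1L), function(i) stats::runif(k, lb, ub))
    })
    starts <- c(starts, rs)
  }
  best <- NULL
  conv <- integer(0)
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = maxit, factr = factr)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- c(conv, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimizer failed to converge on all starts")
  n <- length(tree$tip.label)
  ll <- -best$value
  aic <- -2 * ll + 2 * k
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  structure(list(rates = exp(best$par), loglik = ll, k = k, n_tips = n,
                 AIC = aic, AICc = aicc, template = template,
                 convergence = conv, starts = length(starts), seed = seed,
                 root_prior = root_prior),
            class = "fit_result")
}

#' @exportS3Method base::print
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %s %s | lnL = %.4f, k = %d, AIC = %.2f, AICc = %s\n",
              x$template$architecture, x$template$scheme, x$loglik, x$k,
              x$AIC, ifelse(is.na(x$AICc), "undef", sprintf("%.2f", x$AICc))))
  invisible(x)
}

## run code under a temporary RNG state (never touches the caller's stream)
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
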