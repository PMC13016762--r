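## Independent oracles used across the suite.

## Brute-force likelihood and marginals by full enumeration of state
## assignments to every node (tips included, weighted by their tip vectors).
## Transition matrices come from Matrix::expm directly, independent of the
## package's eigendecomposition fast path.
enum_oracle <- function(tree, Q, tipmat, prior = NULL) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  S <- nrow(Q)
  n_all <- ntip + nnode
  root <- ntip + 1L
  if (is.null(prior)) prior <- rep(1 / S, S)
  tipmat <- tipmat[tree$tip.label, , drop = FALSE]
  P <- lapply(seq_len(nrow(tree$edge)), function(i) {
    as.matrix(Matrix::expm(Q * tree$edge.length[i]))
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), n_all)))
  w <- prior[grid[, root]]
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    w <- w * P[[i]][cbind(grid[, p], grid[, ch])]
  }
  for (tip in seq_len(ntip)) {
    w <- w * tipmat[tip, grid[, tip]]
  }
  tot <- sum(w)
  marg <- matrix(NA_real_, n_all, S)
  for (v in seq_len(n_all)) {
    for (s in seq_len(S)) marg[v, s] <- sum(w[grid[, v] == s])
    marg[v, ] <- marg[v, ] / tot
  }
  list(loglik = log(tot), marginals = marg)
}

## Step-by-step oracle for equal time-scaling (legacy/even-spacing dialect):
## scans root-to-tip paths for maximal runs of zero-length branches and
## spaces each run plus its donor branch evenly, repeating until clean.
equal_oracle_ages <- function(tree, tip_age, root_length) {
  ntip <- length(tree$tip.label)
  age <- rep(NA_real_, ntip + tree$Nnode)
  age[seq_len(ntip)] <- tip_age
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]
    age[p] <- max(age[p], age[po$edge[i, 2L]], na.rm = TRUE)
  }
  root <- ntip + 1L
  age[root] <- age[root] + root_length
  parent <- rep(NA_integer_, length(age))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  repeat {
    len <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
    zi <- which(len <= 1e-10)
    if (!length(zi)) break
    ch <- tree$edge[zi[1L], 2L]
    ## climb to the top of the zero run, then to the donor
    run <- ch
    u <- parent[ch]
    while (!is.na(parent[u]) && age[parent[u]] - age[u] <= 1e-10) {
      run <- c(u, run)
      u <- parent[u]
    }
    top <- parent[u]
    span <- age[top] - age[run[length(run)]]
    path <- c(u, run)
    m <- length(path)
    for (j in seq_len(m - 1L)) {
      age[path[j]] <- age[path[m]] + span * (m - j) / m
    }
  }
  age
}

## deterministic small non-ultrametric test tree with branch lengths
toy_tree <- function(newick = "((A:1,B:1.5):0.7,(C:0.4,D:2):1.1);") {
  ape::read.tree(text = newick)
}

expect_rows_sum_to_one <- function(m, tol = 1e-9) {
  pr <- marginal_probs(m)
  expect_true(all(abs(rowSums(pr) - 1) < tol))
}
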