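#' Read a rooted tree from Newick or NEXUS
#'
#' Thin wrapper around [ape::read.tree()] / [ape::read.nexus()] that enforces
#' the preconditions the time-scaling functions rely on: the tree must be
#' rooted and tip labels must be unique. Polytomies and any branch lengths
#' present in the file are preserved.
#'
#' @param path Path to the tree file.
#' @param format `"newick"` or `"nexus"`.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- switch(format,
    newick = ape::read.tree(path),
    nexus  = ape::read.nexus(path)
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("could not parse a tree from ", path)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (!ape::is.rooted(tree)) stop("tree is not rooted")
  tree
}

#' Read a taxon age table
#'
#' Reads a CSV/TSV file with columns `taxon`, `FAD`, `LAD` (first and last
#' appearance datum, in Ma before present). Separator is sniffed from the
#' header line.
#'
#' @param path Path to the table.
#' @return A `data.frame` with columns `taxon`, `FAD`, `LAD`.
#' @export
read_taxon_ages <- function(path) {
  if (!file.exists(path)) stop("age table not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  taxon_ages(d$taxon, d$FAD, d$LAD)
}

#' Construct and validate a taxon age table
#'
#' @param taxon Character vector of taxon identifiers (unique).
#' @param FAD First appearance datum, Ma (oldest occurrence).
#' @param LAD Last appearance datum, Ma. Defaults to `FAD` (point occurrences).
#' @return A validated `data.frame` with class `taxon_ages`.
#' @export
taxon_ages <- function(taxon, FAD, LAD = FAD) {
  if (is.null(taxon) || is.null(FAD)) stop("age table needs `taxon` and `FAD`")
  taxon <- as.character(taxon)
  FAD <- as.numeric(FAD); LAD <- as.numeric(LAD)
  if (anyDuplicated(taxon)) stop("duplicate taxa in age table")
  if (anyNA(FAD) || anyNA(LAD)) stop("missing ages in age table")
  if (any(LAD < 0)) stop("negative LAD")
  if (any(FAD < LAD)) stop("FAD must be >= LAD for every taxon")
  structure(data.frame(taxon = taxon, FAD = FAD, LAD = LAD,
                       stringsAsFactors = FALSE),
            class = c("taxon_ages", "data.frame"))
}

## ---- internal age bookkeeping -------------------------------------------

## tip calibration ages: tips are dated at FAD (the oldest plausible age)
tip_calibration <- function(tree, ages) {
  idx <- match(tree$tip.label, ages$taxon)
  if (anyNA(idx)) {
    stop("no age entry for tip(s): ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  ages$FAD[idx]
}

## initial node ages: each internal node as old as its oldest descendant tip
initial_node_ages <- function(tree, tip_age) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  age <- c(tip_age, rep(-Inf, nnode))
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    age[p] <- max(age[p], age[ch])
  }
  age
}

root_node <- function(tree) length(tree$tip.label) + 1L

## depth (edge count from root) of every node
node_depths <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  depth <- rep(NA_integer_, n)
  depth[root_node(tree)] <- 0L
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pre$edge))) {
    depth[pre$edge[i, 2L]] <- depth[pre$edge[i, 1L]] + 1L
  }
  depth
}

## build a timetree object from a phylo + node ages
as_timetree <- function(tree, age, root_edge = NULL) {
  tree$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  if (!is.null(root_edge)) tree$root.edge <- root_edge
  attr(tree, "ages") <- age
  class(tree) <- c("timetree", "phylo")
  tree
}

#' Node ages of a time-scaled tree
#'
#' @param tree A `timetree` (from [timescale_equal()] or [timescale_mbl()]).
#' @return Numeric vector of ages (Ma) indexed like the `phylo` node numbers
#'   (tips first, then internal nodes).
#' @export
node_ages <- function(tree) {
  a <- attr(tree, "ages")
  if (is.null(a)) stop("not a time-scaled tree (no ages attribute)")
  a
}

ZERO_TOL <- 1e-10

## parent lookup: parent[child] = parent node (NA for root)
parent_vec <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  p <- rep(NA_integer_, n)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

#' Time-scale a tree by the equal method
#'
#' Dates tips at their FAD, places each internal node at the age of its
#' oldest descendant tip, extends the root age by `root_length`, and then
#' removes zero-length branches by letting them take an equal share of the
#' first preceding (rootward) branch of positive length. Two ordering
#' dialects are provided; both produce strictly positive branch lengths on
#' the same topology but may differ in the resulting node ages.
#'
#' @param tree Rooted `phylo`.
#' @param ages A `taxon_ages` table covering every tip.
#' @param root_length Extra time (myr) added above the root before
#'   redistribution; default 1.
#' @param ordering `"basal_first"` resolves zero-length branches one at a
#'   time from the root toward the tips, each taking half of the preceding
#'   positive branch. `"legacy"` spaces each maximal run of zero-length
#'   branches evenly over the span of the run plus its donor branch, visiting
#'   runs in cladewise (input) order.
#' @return A `timetree`: a `phylo` with positive branch lengths and an
#'   `ages` attribute (Ma).
#' @export
timescale_equal <- function(tree, ages, root_length = 1,
                            ordering = c("basal_first", "legacy")) {
  ordering <- match.arg(ordering)
  if (!is.numeric(root_length) || root_length <= 0) {
    stop("root_length must be positive")
  }
  tip_age <- tip_calibration(tree, ages)
  age <- initial_node_ages(tree, tip_age)
  root <- root_node(tree)
  age[root] <- age[root] + root_length

  parent <- parent_vec(tree)
  edge <- tree$edge

  elen <- function() age[edge[, 1L]] - age[edge[, 2L]]

  pick_zero <- function(lens) {
    z <- which(lens <= ZERO_TOL)
    if (!length(z)) return(NA_integer_)
    if (ordering == "basal_first") {
      depth <- node_depths(tree)
      z[order(depth[edge[z, 2L]], z)][1L]
    } else {
      z[1L]  # cladewise input order
    }
  }

  guard <- 0L
  repeat {
    lens <- elen()
    i <- pick_zero(lens)
    if (is.na(i)) break
    guard <- guard + 1L
    if (guard > 10L * nrow(edge)) stop("equal redistribution failed to converge")
    child <- edge[i, 2L]
    ## walk rootward collecting the consecutive zero-length chain
    chain_nodes <- child        # nodes whose ages move (child last, fixed)
    u <- edge[i, 1L]
    while (u != root && (age[parent[u]] - age[u]) <= ZERO_TOL) {
      chain_nodes <- c(u, chain_nodes)
      u <- parent[u]
    }
    ## donor branch: parent[u] -> u, positive by construction
    if (u == root) stop("zero-length branch chain reached the root")  # cannot happen
    top <- parent[u]
    donor_len <- age[top] - age[u]
    if (donor_len <= ZERO_TOL) stop("internal error: non-positive donor")
    if (ordering == "basal_first") {
      ## single zero edge takes half the donor: move its parent up
      ## (chain is this edge only: its parent's incoming branch is positive)
      age[u] <- age[chain_nodes[length(chain_nodes)]] + donor_len / 2
    } else {
      ## evenly space donor + whole zero run
      path <- c(u, chain_nodes)            # u, ..., child ; child age fixed
      m <- length(path)                     # number of edges sharing donor_len
      bottom <- age[path[m]]
      for (j in seq_len(m - 1L)) {
        age[path[j]] <- bottom + donor_len * (m - j) / m
      }
    }
  }
  as_timetree(tree, age)
}

#' Time-scale a tree by the minimum branch length (mbl) method
#'
#' Dates tips at their FAD and pushes internal nodes back in time, bottom-up,
#' until every branch is at least `min_length` myr long. The root is given a
#' root edge of `root_length` myr.
#'
#' @inheritParams timescale_equal
#' @param min_length Minimum branch duration (myr); default 1.
#' @param root_length Length (myr) of the root edge recorded on the output.
#' @return A `timetree`.
#' @export
timescale_mbl <- function(tree, ages, min_length = 1, root_length = 1) {
  if (!is.numeric(min_length) || min_length <= 0) stop("min_length must be positive")
  if (!is.numeric(root_length) || root_length <= 0) stop("root_length must be positive")
  tip_age <- tip_calibration(tree, ages)
  age <- initial_node_ages(tree, tip_age)
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    age[p] <- max(age[p], age[ch] + min_length)
  }
  as_timetree(tree, age, root_edge = root_length)
}
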