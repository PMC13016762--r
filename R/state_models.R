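## Rate-matrix templates for Markov models of discrete character evolution.
##
## A template is an integer matrix over the model state space: entry 0 marks a
## forbidden transition, equal positive integers mark transitions sharing a
## rate parameter. Hidden-state architectures (SMM, HRM) carry a many-to-one
## observation map from model states onto observed states.

#' Construct a rate template object
#'
#' Low-level constructor; most users should call [mk_template()],
#' [amalgamate_ED()], [amalgamate_SMM()] or [expand_HRM()].
#'
#' @param index Square integer matrix of parameter indices (0 = forbidden;
#'   diagonal ignored). Indices must form the contiguous set `1..max`.
#' @param states Model state labels.
#' @param observed Observed state labels.
#' @param obs_map Integer vector mapping each model state to an observed
#'   state (index into `observed`).
#' @param scheme `"ER"`, `"SYM"` or `"ARD"`.
#' @param architecture Free-text architecture label (e.g. `"unordered"`).
#' @return A `rate_template` object.
#' @export
rate_template <- function(index, states, observed = states,
                          obs_map = seq_along(states),
                          scheme, architecture) {
  index <- as.matrix(index)
  storage.mode(index) <- "integer"
  n <- nrow(index)
  if (ncol(index) != n) stop("index matrix must be square")
  if (length(states) != n) stop("state labels do not match matrix dimension")
  diag(index) <- 0L
  used <- sort(unique(index[index > 0L]))
  if (length(used) && !identical(used, seq_len(max(used)))) {
    stop("parameter indices must be contiguous 1..k")
  }
  if (anyNA(obs_map) || any(obs_map < 1L) || any(obs_map > length(observed))) {
    stop("invalid observation map")
  }
  if (!all(seq_along(observed) %in% obs_map)) {
    stop("observation map must be surjective onto observed states")
  }
  dimnames(index) <- list(states, states)
  structure(list(index = index, states = states, observed = observed,
                 obs_map = as.integer(obs_map),
                 n_par = length(used),
                 scheme = scheme, architecture = architecture),
            class = "rate_template")
}

#' @exportS3Method base::print
print.rate_template <- function(x, ...) {
  cat(sprintf("rate_template: %s %s | %d model states, %d observed, %d parameters\n",
              x$architecture, x$scheme, length(x$states), length(x$observed),
              x$n_par))
  invisible(x)
}

#' Number of free rate parameters of a template
#' @param template A `rate_template`.
#' @export
n_parameters <- function(template) template$n_par

## assign contiguous parameter indices to an allowed-transition pattern.
## allowed: logical matrix. scheme ER: one shared index; SYM: one index per
## unordered pair (requires symmetric support); ARD: one per directed entry.
## Indices are assigned row-major over allowed entries (upper triangle first
## for SYM pairs), so templates serialize reproducibly.
index_from_allowed <- function(allowed, scheme) {
  n <- nrow(allowed)
  diag(allowed) <- FALSE
  idx <- matrix(0L, n, n)
  if (scheme == "ER") {
    idx[allowed] <- 1L
  } else if (scheme == "SYM") {
    k <- 0L
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i || !(allowed[i, j] || allowed[j, i])) next
      k <- k + 1L
      if (allowed[i, j]) idx[i, j] <- k
      if (allowed[j, i]) idx[j, i] <- k
    }
  } else if (scheme == "ARD") {
    k <- 0L
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && allowed[i, j]) { k <- k + 1L; idx[i, j] <- k }
    }
  } else stop("unknown scheme: ", scheme)
  idx
}

#' Standard Mk rate template
#'
#' Builds the template of a k-state Mk model under the equal-rates (ER),
#' symmetric (SYM) or all-rates-different (ARD) scheme. With `ordered = TRUE`
#' only transitions between adjacent states in the given order are allowed
#' (a linear chain, no state skipping).
#'
#' @param n_states Number of observed states (>= 2).
#' @param scheme `"ER"`, `"SYM"` or `"ARD"`.
#' @param ordered Restrict transitions to the chain of adjacent states.
#' @param states Optional state labels (default `"0".."k-1"`).
#' @return A `rate_template`.
#' @export
mk_template <- function(n_states, scheme = c("ER", "SYM", "ARD"),
                        ordered = FALSE, states = NULL) {
  scheme <- match.arg(scheme)
  if (n_states < 2) stop("n_states must be >= 2")
  if (is.null(states)) states <- as.character(seq_len(n_states) - 1L)
  allowed <- matrix(TRUE, n_states, n_states)
  if (ordered) {
    allowed[] <- FALSE
    for (i in seq_len(n_states - 1L)) {
      allowed[i, i + 1L] <- TRUE
      allowed[i + 1L, i] <- TRUE
    }
  }
  rate_template(index_from_allowed(allowed, scheme), states,
                scheme = scheme,
                architecture = if (ordered) "ordered" else "unordered")
}

#' Nested dependency hierarchy of binary characters
#'
#' Describes a chain of binary characters in which character `i + 1` is
#' applicable only when character `i` is present (state 1). The deepest
#' present character determines the observed state, giving `m + 1`
#' observable states for `m` characters. This is the structure of a
#' controlling trait (e.g. feather presence) with increasingly complex
#' dependent elaborations.
#'
#' @param m Number of binary characters (>= 1).
#' @param labels Optional labels for the `m + 1` observable states,
#'   simplest first.
#' @return A `dependency_hierarchy` object.
#' @export
nested_hierarchy <- function(m, labels = NULL) {
  if (m < 1) stop("need at least one binary character")
  if (is.null(labels)) labels <- as.character(0:m)
  if (length(labels) != m + 1L) stop("need m + 1 observable state labels")
  structure(list(m = as.integer(m), labels = labels),
            class = "dependency_hierarchy")
}

#' Embedded-dependency (ED) amalgamation
#'
#' Amalgamates a nested hierarchy of binary characters into a single
#' character over the observable state combinations only (no hidden states).
#' Under the qualitative variant (`"QL"`) the gain of a controlling
#' character can land directly in any dependent configuration, so every
#' transition between observable states is allowed. Under the birth-death
#' variant (`"BD"`) any transition requiring two or more simultaneous trait
#' births is forbidden: gains proceed one step at a time, while a single
#' death can cascade (losing a controlling character removes everything
#' that depended on it).
#'
#' @param hierarchy A [nested_hierarchy()].
#' @param scheme `"ER"`, `"SYM"` or `"ARD"`.
#' @param variant `"QL"` or `"BD"`.
#' @return A `rate_template` over the `m + 1` observable states.
#' @export
amalgamate_ED <- function(hierarchy, scheme = c("ER", "SYM", "ARD"),
                          variant = c("QL", "BD")) {
  scheme <- match.arg(scheme); variant <- match.arg(variant)
  if (!inherits(hierarchy, "dependency_hierarchy")) stop("invalid hierarchy")
  k <- hierarchy$m + 1L
  allowed <- matrix(TRUE, k, k)
  if (variant == "BD") {
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (j > i + 1L) allowed[i, j] <- FALSE  # >= 2 births in one step
    }
  }
  rate_template(index_from_allowed(allowed, scheme), hierarchy$labels,
                scheme = scheme,
                architecture = paste0("ED-", variant))
}

## model states of the SMM amalgamation: all 2^m binary combinations,
## encoded as strings "b1b2...bm". Observed state = deepest prefix of 1s.
smm_state_space <- function(m) {
  combos <- as.matrix(expand.grid(rep(list(0:1), m))[, m:1, drop = FALSE])
  # expand.grid varies the first factor fastest; reversed so that the first
  # character is the slowest-varying digit and states sort as 00,01,10,11
  combos <- combos[order(apply(combos, 1L, paste, collapse = "")), , drop = FALSE]
  labels <- apply(combos, 1L, paste, collapse = "")
  depth <- apply(combos, 1L, function(b) {
    d <- 0L
    for (x in b) { if (x == 1L) d <- d + 1L else break }
    d
  })
  list(combos = combos, labels = labels, obs = depth + 1L)
}

#' Structured Markov model (SMM) amalgamation with hidden states
#'
#' Amalgamates a nested hierarchy of `m` binary characters over the full
#' Cartesian product of their states (`2^m` model states), retaining the
#' unobserved combinations as hidden states (e.g. absence of the
#' controlling trait with a liability toward one of the dependent states).
#' Only one character may change at a time. Under `"ind"` each character
#' evolves with rates independent of the others' states; under `"switch"`
#' a dependent character's rates take distinct parameters depending on the
#' state of its controlling character.
#'
#' Schemes act on each binary sub-character: ER and SYM share a single rate
#' per character (per context under `"switch"`); ARD gives gain and loss
#' separate parameters.
#'
#' @inheritParams amalgamate_ED
#' @param variant `"ind"` or `"switch"`.
#' @return A `rate_template` with `2^m` model states and `m + 1` observed
#'   states.
#' @export
amalgamate_SMM <- function(hierarchy, scheme = c("ER", "SYM", "ARD"),
                           variant = c("ind", "switch")) {
  scheme <- match.arg(scheme); variant <- match.arg(variant)
  if (!inherits(hierarchy, "dependency_hierarchy")) stop("invalid hierarchy")
  m <- hierarchy$m
  sp <- smm_state_space(m)
  S <- nrow(sp$combos)
  idx <- matrix(0L, S, S)
  ## parameter key per (character, direction, context); contexts matter only
  ## under "switch" (state of the controlling character, char 1 has none)
  keys <- character(0)
  key_id <- function(key) {
    pos <- match(key, keys)
    if (is.na(pos)) { keys[[length(keys) + 1L]] <<- key; pos <- length(keys) }
    pos
  }
  for (a in seq_len(S)) for (b in seq_len(S)) {
    if (a == b) next
    dif <- which(sp$combos[a, ] != sp$combos[b, ])
    if (length(dif) != 1L) next              # single-character changes only
    ch <- dif
    dir <- if (sp$combos[b, ch] == 1L) "gain" else "loss"
    ctx <- if (variant == "switch" && ch > 1L) sp$combos[a, ch - 1L] else 0L
    key <- if (scheme == "ARD") {
      paste(ch, dir, ctx, sep = "|")
    } else {
      paste(ch, ctx, sep = "|")               # gain and loss share
    }
    idx[a, b] <- key_id(key)
  }
  ## renumber row-major for reproducible serialization
  idx <- renumber_row_major(idx)
  rate_template(idx, sp$labels,
                observed = hierarchy$labels,
                obs_map = sp$obs,
                scheme = scheme,
                architecture = paste0("SMM-", variant))
}

renumber_row_major <- function(idx) {
  old <- unique(as.vector(t(idx))[as.vector(t(idx)) > 0L])
  map <- integer(max(c(0L, old)))
  map[old] <- seq_along(old)
  out <- idx
  out[idx > 0L] <- map[idx[idx > 0L]]
  out
}

#' Hidden-rates-model (HRM) expansion
#'
#' Duplicates the observed state space of a base template across 2 or 3
#' latent rate categories ("slow"/"fast"(/"intermediate")). Within each
#' category the base transition pattern applies with category-specific
#' parameters; between categories a state may switch rate category without
#' changing its observed state. Category-switch rates share one parameter
#' per unordered category pair under ER/SYM and one per ordered pair under
#' ARD.
#'
#' @param base A `rate_template` over observed states (no hidden states).
#' @param n_categories 2 or 3.
#' @param scheme `"ER"`, `"SYM"` or `"ARD"`; applied to the within-category
#'   copies of the base pattern.
#' @return A `rate_template` with `k * n_categories` model states collapsing
#'   onto the base observed states.
#' @export
expand_HRM <- function(base, n_categories = 2,
                       scheme = c("ER", "SYM", "ARD")) {
  scheme <- match.arg(scheme)
  if (!n_categories %in% c(2L, 3L)) stop("n_categories must be 2 or 3")
  n_categories <- as.integer(n_categories)
  if (length(base$states) != length(base$observed)) {
    stop("base template must be over observed states only")
  }
  k <- length(base$states)
  allowed_base <- base$index > 0L
  S <- k * n_categories
  idx <- matrix(0L, S, S)
  pos <- function(state, cat) (cat - 1L) * k + state
  offset <- 0L
  ## within-category blocks: fresh parameter set per category
  for (cat in seq_len(n_categories)) {
    blk <- index_from_allowed(allowed_base, scheme)
    npar <- max(c(0L, blk))
    blk[blk > 0L] <- blk[blk > 0L] + offset
    offset <- offset + npar
    rng <- pos(seq_len(k), cat)
    idx[rng, rng] <- blk
  }
  ## category switches: same observed state only; one parameter per
  ## unordered category pair (ER/SYM) or per ordered pair (ARD)
  for (c1 in seq_len(n_categories)) for (c2 in seq_len(n_categories)) {
    if (c1 == c2) next
    p <- if (scheme == "ARD") {
      offset + ordered_pair_rank(c1, c2, n_categories)
    } else {
      offset + unordered_pair_rank(c1, c2, n_categories)
    }
    for (s in seq_len(k)) idx[pos(s, c1), pos(s, c2)] <- p
  }
  idx <- renumber_contiguous(idx)
  labels <- as.vector(outer(base$states, paste0("R", seq_len(n_categories)),
                            paste, sep = "."))
  rate_template(idx, labels,
                observed = base$observed,
                obs_map = rep(seq_len(k), n_categories),
                scheme = scheme,
                architecture = sprintf("HRM-%dcat(%s)", n_categories,
                                       base$architecture))
}

## helpers for expand_HRM switch-parameter bookkeeping ----------------------

unordered_pair_rank <- function(c1, c2, ncat) {
  a <- min(c1, c2); b <- max(c1, c2)
  as.integer((a - 1L) * ncat - a * (a - 1L) / 2 + (b - a))
}
ordered_pair_rank <- function(c1, c2, ncat) {
  # rank of (c1, c2), c1 != c2, in row-major order over off-diagonal pairs
  r <- (c1 - 1L) * (ncat - 1L) + c2 - (c2 > c1)
  as.integer(r)
}

renumber_contiguous <- function(idx) {
  old <- sort(unique(idx[idx > 0L]))
  map <- integer(max(c(0L, old)))
  map[old] <- seq_along(old)
  out <- idx
  out[idx > 0L] <- map[idx[idx > 0L]]
  out
}

#' Instantiate a rate matrix (Markov generator) from a template
#'
#' @param template A `rate_template`.
#' @param rates Positive rate values (events/myr), one per parameter.
#' @return Square numeric generator matrix Q with rows summing to zero.
#' @export
build_Q <- function(template, rates) {
  if (length(rates) != template$n_par) {
    stop(sprintf("expected %d rates, got %d", template$n_par, length(rates)))
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) stop("rates must be positive")
  idx <- template$index
  Q <- matrix(0, nrow(idx), ncol(idx), dimnames = dimnames(idx))
  pos <- which(idx > 0L)
  Q[pos] <- rates[idx[pos]]
  diag(Q) <- -rowSums(Q)
  Q
}

## ---- model grid -----------------------------------------------------------

#' The 21-model grid for the 6-state coding
#'
#' Enumerates the seven Markov architectures (unordered, ordered, ED,
#' SMM-ind, SMM-switch, HRM 2-category, HRM 3-category) crossed with the
#' three rate schemes (ER, SYM, ARD) on the six-state feather coding.
#'
#' @param states Observed state labels, simplest first (default the
#'   six-state feather morphotype coding).
#' @param ed_variant ED variant used in the grid (default `"QL"`).
#' @return Named list of 21 `rate_template` objects, names
#'   `"<architecture>_<scheme>"`.
#' @export
model_grid <- function(states = feather_states(), ed_variant = "QL") {
  k <- length(states)
  hier <- nested_hierarchy(k - 1L, labels = states)
  schemes <- c("ER", "SYM", "ARD")
  grid <- list()
  for (scheme in schemes) {
    grid[[paste0("UNORD_", scheme)]] <-
      mk_template(k, scheme, ordered = FALSE, states = states)
    grid[[paste0("ORD_", scheme)]] <-
      mk_template(k, scheme, ordered = TRUE, states = states)
    grid[[paste0("ED_", scheme)]] <-
      amalgamate_ED(hier, scheme, variant = ed_variant)
    grid[[paste0("SMMind_", scheme)]] <-
      amalgamate_SMM(hier, scheme, variant = "ind")
    grid[[paste0("SMMsw_", scheme)]] <-
      amalgamate_SMM(hier, scheme, variant = "switch")
    grid[[paste0("HRM2_", scheme)]] <-
      expand_HRM(mk_template(k, scheme, states = states), 2L, scheme)
    grid[[paste0("HRM3_", scheme)]] <-
      expand_HRM(mk_template(k, scheme, states = states), 3L, scheme)
  }
  grid
}

#' Six-state feather morphotype labels
#'
#' Ordered by developmental complexity: scales, monofilament, basally
#' joined filaments, central filament, pennaceous, asymmetrical pennaceous.
#' @return Character vector of length 6.
#' @export
feather_states <- function() {
  c("scales", "monofilament", "basally_joined", "central_filament",
    "pennaceous", "asymmetrical")
}

#' Serialize a template to JSON-ready structure
#'
#' @param template A `rate_template`.
#' @return A plain list (labels, index matrix, observation map, scheme,
#'   architecture) suitable for `jsonlite::toJSON()`.
#' @export
template_to_list <- function(template) {
  list(states = template$states,
       observed = template$observed,
       obs_map = template$obs_map,
       index = unname(template$index),
       n_par = template$n_par,
       scheme = template$scheme,
       architecture = template$architecture)
}
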