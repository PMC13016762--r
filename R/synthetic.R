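## Synthetic data: birth-death fossil trees with FAD/LAD tables, forward
## simulation of discrete characters, feather-like hierarchical datasets and
## the nested recoding strategies.

#' Simulation configuration
#'
#' @param n_tips Target number of tips (>= 3).
#' @param birth,death Birth-death rates per lineage per myr.
#' @param age_span Simulated clade duration (myr / Ma depth of the root).
#' @param fad_width Maximum half-width (myr) of the uniform FAD/LAD range
#'   drawn around true tip ages; widths of 0 to `fad_width` exercise the
#'   zero-length-branch handling of the time-scaling methods.
#' @param ambiguity_fraction Fraction of tips receiving ambiguity codes.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tips = 94, birth = 0.06, death = 0.03,
                       age_span = 150, fad_width = 5,
                       ambiguity_fraction = 0.1, seed = 1) {
  if (n_tips < 3) stop("n_tips must be >= 3")
  if (birth < 0 || death < 0) stop("rates must be >= 0")
  if (ambiguity_fraction < 0 || ambiguity_fraction >= 1) {
    stop("ambiguity_fraction must be in [0, 1)")
  }
  structure(list(n_tips = as.integer(n_tips), birth = birth, death = death,
                 age_span = age_span, fad_width = fad_width,
                 ambiguity_fraction = ambiguity_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a birth-death time tree with fossil tips and an age table
#'
#' Simulates a birth-death tree over `age_span` myr (via [ape::rlineage()]),
#' keeping extinct lineages as fossil tips, subsamples to `n_tips` tips, and
#' draws FAD/LAD ranges around the true tip ages. Degenerate runs (too few
#' surviving lineages) are retried up to a bounded count.
#'
#' @param config A [sim_config()].
#' @param max_tries Bound on retries for degenerate parameter draws.
#' @return List with `tree` (a `timetree` with true node ages), `ages`
#'   (a `taxon_ages` table), and `config`.
#' @export
simulate_time_tree <- function(config, max_tries = 100) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, {
    tree <- NULL
    for (try in seq_len(max_tries)) {
      cand <- tryCatch(ape::rlineage(config$birth, config$death,
                                     Tmax = config$age_span),
                       error = function(e) NULL)
      if (!is.null(cand) && length(cand$tip.label) >= config$n_tips) {
        tree <- cand
        break
      }
    }
    if (is.null(tree)) {
      stop("could not simulate a tree with >= ", config$n_tips,
           " tips in ", max_tries, " tries")
    }
    if (length(tree$tip.label) > config$n_tips) {
      drop <- sample(tree$tip.label,
                     length(tree$tip.label) - config$n_tips)
      tree <- ape::drop.tip(tree, drop)
    }
    tree$tip.label <- sprintf("t%02d", seq_along(tree$tip.label))
    ## true ages: root at age_span... after drop.tip the root may have moved;
    ## measure depths from the (possibly new) root and anchor the deepest
    ## lineage end at its original time.
    depth <- ape::node.depth.edgelength(tree)
    root_age <- max(depth + 0)           # relative scale
    age <- root_age - depth
    ntip <- length(tree$tip.label)
    tip_age <- age[seq_len(ntip)]
    ## extant tips sit at age ~0 (numerical fuzz from rlineage clipped)
    tip_age[tip_age < 1e-8] <- 0
    up <- stats::runif(ntip, 0, config$fad_width)
    dn <- stats::runif(ntip, 0, config$fad_width)
    FAD <- tip_age + up
    LAD <- pmax(0, tip_age - dn)
    ## extant tips have a modern LAD and FAD at their true (0) age
    FAD[tip_age == 0] <- 0
    LAD[tip_age == 0] <- 0
    ages <- taxon_ages(tree$tip.label, FAD, LAD)
    tt <- as_timetree(tree, age)
    list(tree = tt, ages = ages, true_tip_ages = tip_age, config = config)
  })
}

#' Forward-simulate a discrete character along a time tree
#'
#' Continuous-time Markov simulation with exponential waiting times under a
#' generator `Q`, returning both the tip observations and the latent node
#' states for recovery scoring.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param Q Generator matrix (rows sum to 0).
#' @param root_state Integer state index at the root (1-based) or state
#'   label.
#' @param seed Integer seed.
#' @return List with `tip_states`, `node_states` (integer indices, named by
#'   labels where available), and `n_changes` (total changes simulated).
#' @export
simulate_history <- function(tree, Q, root_state = 1L, seed = 1) {
  S <- nrow(Q)
  if (is.character(root_state)) root_state <- match(root_state, rownames(Q))
  if (is.na(root_state) || root_state < 1 || root_state > S) {
    stop("invalid root state")
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  withr_seed(seed, {
    state <- integer(ntip + nnode)
    state[root_node(tree)] <- as.integer(root_state)
    pre <- ape::reorder.phylo(tree, "cladewise")
    changes <- 0L
    for (i in seq_len(nrow(pre$edge))) {
      s <- state[pre$edge[i, 1L]]
      t_left <- pre$edge.length[i]
      repeat {
        exit <- -Q[s, s]
        if (exit <= 0) break
        wait <- stats::rexp(1L, exit)
        if (wait >= t_left) break
        t_left <- t_left - wait
        probs <- Q[s, ]; probs[s] <- 0
        s <- sample.int(S, 1L, prob = probs)
        changes <- changes + 1L
      }
      state[pre$edge[i, 2L]] <- s
    }
    tips <- state[seq_len(ntip)]
    names(tips) <- tree$tip.label
    list(tip_states = tips,
         node_states = state[(ntip + 1L):(ntip + nnode)],
         n_changes = changes)
  })
}

#' Generate a feather-like hierarchical character dataset
#'
#' Simulates a six-state hierarchical character on a birth-death fossil
#' tree under a low-rate ordered chain model, so that developmentally
#' complex states are phylogenetically clustered near derived clades (the
#' statistical structure of feather morphotype data). A configurable set of
#' early-diverging tips is marked as outgroup and ambiguity codes are
#' injected at the configured fraction.
#'
#' @param config A [sim_config()].
#' @param rate Chain transition rate (events/myr) of the generating ordered
#'   ER model; default 0.02.
#' @param n_outgroup Number of earliest-diverging tips marked as outgroup.
#' @return List with `tree` (`timetree`, true ages), `ages`, `codes` (named
#'   character vector of state codes, with `&`/`?` ambiguity), `truth`
#'   (latent node states), `tip_truth`, `outgroup`, `states`, `template`,
#'   `rate`, `config`.
#' @export
make_feather_like_dataset <- function(config = sim_config(), rate = 0.02,
                                      n_outgroup = 3) {
  sim <- simulate_time_tree(config)
  states <- feather_states()
  template <- mk_template(6, "ER", ordered = TRUE, states = states)
  Q <- build_Q(template, rate)
  hist <- simulate_history(sim$tree, Q, root_state = 1L,
                           seed = config$seed + 1L)
  codes <- states[hist$tip_states]
  names(codes) <- names(hist$tip_states)
  ## ambiguity injection: half "?" (unknown), half a two-state set with an
  ## adjacent morphotype
  if (config$ambiguity_fraction > 0) {
    codes <- withr_seed(config$seed + 2L, {
      ntip <- length(codes)
      n_amb <- floor(config$ambiguity_fraction * ntip)
      if (n_amb > 0) {
        pick <- sample(ntip, n_amb)
        for (j in seq_along(pick)) {
          i <- pick[j]
          if (j %% 2L == 0L) {
            codes[i] <- "?"
          } else {
            s <- match(codes[i], states)
            nb <- if (s == length(states)) s - 1L else s + 1L
            codes[i] <- paste(states[sort(c(s, nb))], collapse = "&")
          }
        }
      }
      codes
    })
  }
  depth <- node_depths(sim$tree)
  outgroup <- sim$tree$tip.label[
    order(depth[seq_along(sim$tree$tip.label)])][seq_len(n_outgroup)]
  list(tree = sim$tree, ages = sim$ages, codes = codes,
       truth = hist$node_states, tip_truth = hist$tip_states,
       outgroup = outgroup, states = states, template = template,
       rate = rate, config = config)
}

#' Recode a six-state feather matrix into a coarser coding strategy
#'
#' Strategy 3 is the identity (six states); strategy 2 collapses the three
#' filamentous morphotypes into `"filamentous"` and both pennaceous
#' morphotypes into `"pennaceous"`; strategy 1 collapses all feather states
#' into `"feathers"`. Ambiguity sets are recoded memberwise and duplicate
#' members collapse; `"?"` is preserved.
#'
#' @param codes Named character vector of six-state codes.
#' @param strategy 1, 2 or 3.
#' @return Named character vector of recoded states, with attribute
#'   `"states"` giving the coding's state labels.
#' @export
recode <- function(codes, strategy) {
  if (!strategy %in% 1:3) stop("strategy must be 1, 2 or 3")
  s6 <- feather_states()
  map <- switch(as.character(strategy),
    "3" = stats::setNames(s6, s6),
    "2" = c(scales = "scales", monofilament = "filamentous",
            basally_joined = "filamentous", central_filament = "filamentous",
            pennaceous = "pennaceous", asymmetrical = "pennaceous"),
    "1" = c(scales = "scales", monofilament = "feathers",
            basally_joined = "feathers", central_filament = "feathers",
            pennaceous = "feathers", asymmetrical = "feathers"))
  levels <- switch(as.character(strategy),
    "3" = s6,
    "2" = c("scales", "filamentous", "pennaceous"),
    "1" = c("scales", "feathers"))
  out <- vapply(codes, function(code) {
    if (is.na(code) || code == "?") return("?")
    parts <- trimws(strsplit(code, "&", fixed = TRUE)[[1]])
    if (!all(parts %in% names(map))) stop("unknown state: ", code)
    mapped <- unique(unname(map[parts]))
    mapped <- mapped[order(match(mapped, levels))]
    paste(mapped, collapse = "&")
  }, character(1))
  names(out) <- names(codes)
  attr(out, "states") <- levels
  out
}

#' Canned 12-tip fixture dataset
#'
#' Small deterministic feather-like dataset used by the test suite and the
#' worked examples: 12 tips, moderate extinction, 1 ambiguous tip.
#'
#' @param seed Seed (default 42).
#' @return As [make_feather_like_dataset()].
#' @export
fixture_dataset <- function(seed = 42) {
  make_feather_like_dataset(
    sim_config(n_tips = 12, birth = 0.08, death = 0.03, age_span = 120,
               ambiguity_fraction = 0.1, seed = seed),
    rate = 0.02, n_outgroup = 2)
}
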