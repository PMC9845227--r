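#' Specification for the synthetic archosaur-like data generator
#'
#' Collects the generative parameters for the forward model the inference
#' pipeline assumes: a birth-death tree, a 3-state Mk character, and a
#' probabilistic observation layer in which uncinate scars are detected
#' only on some preserved ribs. Defaults emulate the shape of a Mesozoic
#' archosaur dataset: ~40 species, crown depth around 230 Myr (birth 0.01
#' per lineage-Myr, pure birth), about one expected character change per
#' root-to-tip path (q = 0.005 events/Myr), a handful of examinable ribs
#' per fossil taxon (Poisson mean 4), and imperfect per-rib scar detection.
#'
#' @param n_tips number of extant lineages at which the simulation stops.
#' @param birth,death per-lineage rates per Myr.
#' @param q Mk (ER) rate, events/Myr.
#' @param root_state state at the root (0, 1 or 2).
#' @param rib_mean Poisson mean of examinable ribs per taxon.
#' @param scar_detect_p per-rib probability that a taxon truly bearing
#'   processes (state 1 or 2) shows a detectable scar.
#' @param ossified_detect_p probability that a state-2 taxon preserves an
#'   ossified process directly.
#' @param false_positive_p per-rib probability of a spurious scar on a
#'   state-0 taxon (default 0).
#' @param seed mandatory integer seed.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_tips = 40L, birth = 0.01, death = 0, q = 0.005,
                     root_state = 1L, rib_mean = 4, scar_detect_p = 0.5,
                     ossified_detect_p = 0.9, false_positive_p = 0,
                     seed) {
  if (missing(seed) || is.null(seed)) stop("an integer 'seed' is mandatory")
  if (n_tips < 2L) stop("'n_tips' must be >= 2")
  if (birth < 0 || death < 0 || q < 0) stop("rates must be >= 0")
  p <- c(scar_detect_p, ossified_detect_p, false_positive_p)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (!root_state %in% STATES) stop("'root_state' must be one of 0, 1, 2")
  structure(list(n_tips = as.integer(n_tips), birth = birth, death = death,
                 q = q, root_state = as.integer(root_state),
                 rib_mean = rib_mean, scar_detect_p = scar_detect_p,
                 ossified_detect_p = ossified_detect_p,
                 false_positive_p = false_positive_p,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a birth-death tree conditioned on the number of extant tips
#'
#' Forward simulation from two crown lineages; events occur at rate
#' `(birth + death) * n_extant`. The simulation stops the first time the
#' extant lineage count reaches `n_tips`, plus one final exponential
#' waiting time (so that for a pure-birth process the expected crown age
#' is `sum(1 / (birth * i))` for `i` in `2..n_tips`). Extinct lineages are
#' retained as fossil tips, so with `death > 0` the returned tree can have
#' more than `n_tips` leaves; `n_tips` counts the extant ones. Total
#' extinction triggers an internal resample, with a bounded retry budget.
#'
#' Node ages (Ma before the stop time) and branch lengths are set; tips
#' are labeled `t1, t2, ...` in order of creation.
#'
#' @param spec a `sim_spec` (only `n_tips`, `birth`, `death`, `seed` used).
#' @param max_retries resamples allowed after total extinction.
#' @return a `phylo` with `edge.length`, `node.ages` and
#'   `bl_mode = "timescaled"`.
#' @export
simulate_tree <- function(spec, max_retries = 100L) {
  stopifnot(inherits(spec, "sim_spec"))
  .with_seed(spec$seed, {
    for (try in seq_len(max_retries)) {
      res <- .sim_bd_once(spec$n_tips, spec$birth, spec$death)
      if (!is.null(res)) return(res)
    }
    stop("all lineages went extinct in every one of ", max_retries,
         " attempts; lower 'death' or raise 'birth'")
  })
}

# one forward pass; NULL on total extinction before reaching n extant
.sim_bd_once <- function(n, birth, death) {
  # lineage bookkeeping: my-id, parent-id, start time; closed lineages get
  # an end time and a type (tip or internal)
  id_parent <- c(0L, 1L, 1L)      # id 1 = root node, ids 2,3 its children
  start <- c(0, 0, 0)
  end <- c(0, NA, NA)             # root closes at time 0
  is_tip <- c(FALSE, NA, NA)
  active <- c(2L, 3L)
  t <- 0
  total_rate <- birth + death
  if (total_rate <= 0) stop("birth + death must be > 0")
  repeat {
    m <- length(active)
    if (m == 0L) return(NULL)
    dt <- rexp(1L, total_rate * m)
    if (m == n) {                  # reached target: stop inside this wait
      t <- t + dt
      break
    }
    t <- t + dt
    j <- active[sample.int(m, 1L)]
    if (runif(1L) < birth / total_rate) {
      k1 <- length(id_parent) + 1L
      id_parent <- c(id_parent, j, j)
      start <- c(start, t, t)
      end <- c(end, NA, NA)
      is_tip <- c(is_tip, NA, NA)
      end[j] <- t; is_tip[j] <- FALSE
      active <- c(setdiff(active, j), k1, k1 + 1L)
    } else {
      end[j] <- t; is_tip[j] <- TRUE
      active <- setdiff(active, j)
    }
  }
  end[active] <- t
  is_tip[active] <- TRUE
  .lineages_to_phylo(id_parent, start, end, is_tip, t)
}

# convert the event log to an ape phylo with ages in Ma before stop time
.lineages_to_phylo <- function(id_parent, start, end, is_tip, t_stop) {
  # drop internal "nodes" that never split (shouldn't occur) and collapse
  # is unnecessary: every non-tip id has exactly 2 children by build
  ids <- seq_along(id_parent)
  tips <- ids[is_tip]
  internals <- ids[!is_tip]
  ntip <- length(tips)
  node_of <- integer(length(ids))
  node_of[tips] <- seq_len(ntip)
  node_of[internals] <- ntip + seq_along(internals)  # root (id 1) first
  E <- cbind(node_of[id_parent[-1L]], node_of[-1L])
  lens <- (end - start)[-1L]
  phy <- list(edge = E, edge.length = lens,
              tip.label = paste0("t", seq_len(ntip)),
              Nnode = length(internals))
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  ages <- numeric(ntip + length(internals))
  ages[node_of] <- t_stop - end
  phy$node.ages <- ages
  phy$bl_mode <- "timescaled"
  phy
}

#' Evolve the 3-state character along a tree under the ER Mk process
#'
#' The root state is fixed and each branch applies the closed-form ER
#' transition kernel `P(same) = 1/3 + 2/3 exp(-3 q t)`.
#'
#' @param tree `phylo` with branch lengths.
#' @param q ER rate (events/Myr); `q = 0` freezes the character.
#' @param root_state state at the root.
#' @param seed integer seed.
#' @return named integer vector of tip states; the full node-state vector
#'   is attached as attribute `"node_states"`.
#' @export
simulate_mk_character <- function(tree, q, root_state = 1L, seed) {
  validate_tree(tree)
  if (missing(seed) || is.null(seed)) stop("an integer 'seed' is mandatory")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  if (!root_state %in% STATES) stop("'root_state' must be one of 0, 1, 2")
  k <- length(STATES)
  .with_seed(seed, {
    po <- ape::reorder.phylo(tree, "postorder")
    E <- po$edge
    lens <- po$edge.length
    ntip <- length(tree$tip.label)
    nn <- ntip + tree$Nnode
    state <- integer(nn)
    root <- E[nrow(E), 1L]
    state[root] <- root_state
    for (i in rev(seq_len(nrow(E)))) {
      p <- E[i, 1L]; ch <- E[i, 2L]
      tp <- er_transition(q, lens[i], k)
      probs <- rep(tp$diff, k)
      probs[state[p] + 1L] <- tp$same
      state[ch] <- sample(STATES, 1L, prob = probs)
    }
    tips <- setNames(state[seq_len(ntip)], tree$tip.label)
    attr(tips, "node_states") <- state
    tips
  })
}

#' Simulate a specimen-evidence table from true tip states
#'
#' The observation layer: each taxon yields a Poisson number of examinable
#' ribs; on a taxon truly bearing uncinate processes (state 1 or 2) each
#' rib independently shows a detectable scar with probability
#' `scar_detect_p`; state-2 taxa additionally preserve an ossified process
#' with probability `ossified_detect_p`; state-0 taxa yield scars only at
#' the false-positive rate (0 by default).
#'
#' @param states named integer vector of true tip states.
#' @param spec a `sim_spec` (observation parameters and seed used).
#' @return a specimen-evidence `data.frame` (see [read_evidence()]).
#' @export
simulate_evidence <- function(states, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  .with_seed(spec$seed + 1L, {
    n <- length(states)
    ribs <- rpois(n, spec$rib_mean)
    p_scar <- ifelse(states %in% c(1L, 2L), spec$scar_detect_p,
                     spec$false_positive_p)
    scars <- rbinom(n, ribs, p_scar)
    process <- ifelse(states == 2L & runif(n) < spec$ossified_detect_p,
                      "ossified", "none")
    data.frame(taxon = names(states), n_ribs_examined = ribs,
               n_ribs_with_scar = scars, preserved_process = process,
               override_state = "", stringsAsFactors = FALSE)
  })
}

#' One full synthetic dataset: tree, true states, evidence, ranges
#'
#' Convenience wrapper chaining [simulate_tree()],
#' [simulate_mk_character()] and [simulate_evidence()], plus stratigraphic
#' ranges derived from the true tip ages: `FAD = age + U(0, fad_offset)`,
#' `LAD = max(age - U(0, fad_offset), 0)`, so FAD >= LAD always holds and
#' the true ages lie inside the ranges.
#'
#' @param spec a `sim_spec`.
#' @param fad_offset upper bound (Myr) of the uniform range offsets.
#' @return list with `tree`, `states`, `evidence`, `ranges`.
#' @export
simulate_dataset <- function(spec, fad_offset = 5) {
  tree <- simulate_tree(spec)
  states <- simulate_mk_character(tree, spec$q, spec$root_state,
                                  seed = spec$seed + 2L)
  evidence <- simulate_evidence(states, spec)
  ranges <- .with_seed(spec$seed + 3L, {
    ntip <- length(tree$tip.label)
    age <- tree$node.ages[seq_len(ntip)]
    fad <- age + runif(ntip, 0, fad_offset)
    lad <- pmax(age - runif(ntip, 0, fad_offset), 0)
    data.frame(taxon = tree$tip.label, fad_ma = fad, lad_ma = lad,
               stringsAsFactors = FALSE)
  })
  list(tree = tree, states = states, evidence = evidence, ranges = ranges)
}
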