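# effective sample size from the autocorrelation of a scalar chain
# (initial positive sequence truncation)
.ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::var(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

# longest root-to-tip path length
.tree_depth <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  lens <- po$edge.length
  depth <- numeric(length(tree$tip.label) + tree$Nnode)
  for (i in rev(seq_len(nrow(E))))       # reverse postorder = preorder
    depth[E[i, 2L]] <- depth[E[i, 1L]] + lens[i]
  max(depth)
}

#' Bayesian ancestral states by Metropolis-Hastings over the Mk rate
#'
#' Samples the posterior of the single ER rate `q` by random-walk
#' Metropolis-Hastings on `log q`, with an exponential prior on `q` whose
#' mean scales with tree depth (a rate of one expected change per 100 Myr
#' of root-to-tip depth; override with `prior_mean`). Node posteriors are
#' Rao-Blackwellized: for every retained sample the exact marginal
#' conditional reconstruction at the sampled rate is computed and the
#' posteriors are the average of those conditionals, which converges much
#' faster than counting sampled node states.
#'
#' The proposal standard deviation adapts during burn-in towards a 20-40%
#' acceptance rate and is frozen afterwards, so the retained chain is a
#' valid MH sample. Identical seeds give bit-identical output.
#'
#' @param tree `phylo` with positive branch lengths.
#' @param coding a `character_coding`.
#' @param seed integer RNG seed (mandatory; the run is deterministic).
#' @param iterations total MH iterations (>= 1000).
#' @param burn_in_fraction fraction of iterations discarded (default 0.2).
#' @param thin keep every `thin`-th post-burn-in sample (default 50).
#' @param prior_mean mean of the exponential prior on `q` (events/Myr);
#'   default `100 / tree depth`.
#' @param root_prior as in [mk_model()].
#' @return an `asr_result` with `method = "MB"`, `prob` (averaged node
#'   posteriors), `rate_samples`, and `diagnostics` (ESS of `log q`,
#'   post-burn-in acceptance rate, `low_ess_flag`, seed, prior mean,
#'   proposal sd).
#' @export
bayes_asr <- function(tree, coding, seed, iterations = 100000L,
                      burn_in_fraction = 0.2, thin = 50L,
                      prior_mean = NULL, root_prior = "flat") {
  validate_tree(tree)
  if (missing(seed) || is.null(seed)) stop("an integer 'seed' is mandatory")
  if (iterations < 1000L) stop("'iterations' must be at least 1000")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("'burn_in_fraction' must be in [0, 1)")
  tipM <- coding_matrix(coding, tree)
  k <- length(STATES)
  if (is.null(prior_mean)) prior_mean <- 100 / .tree_depth(tree)
  if (prior_mean <= 0) stop("'prior_mean' must be > 0")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))

  model_at <- function(q) mk_model(q, "ER", k = k, root_prior = root_prior)
  log_post <- function(lq) {
    q <- exp(lq)
    pr <- .prune(tree, tipM, model_at(q))
    # Jacobian log q for the log-scale walk
    pr$loglik + dexp(q, rate = 1 / prior_mean, log = TRUE) + lq
  }

  burn <- floor(iterations * burn_in_fraction)
  lq <- log(prior_mean)
  lp <- log_post(lq)
  step <- 1
  acc_win <- 0L; win <- 0L
  acc_post <- 0L; n_post <- 0L
  keep_at <- seq(burn + thin, iterations, by = thin)
  n_keep <- length(keep_at)
  if (n_keep < 2L) stop("too few retained samples; lower 'thin' or burn-in")
  samples <- numeric(n_keep)
  prob_sum <- matrix(0, nrow(tipM) + tree$Nnode, k)
  ki <- 1L

  for (it in seq_len(iterations)) {
    prop <- lq + rnorm(1L, 0, step)
    lpp <- log_post(prop)
    if (log(runif(1L)) < lpp - lp) {
      lq <- prop; lp <- lpp
      if (it <= burn) acc_win <- acc_win + 1L else acc_post <- acc_post + 1L
    }
    if (it <= burn) {
      win <- win + 1L
      if (win == 50L) {  # adapt towards the 20-40% acceptance band
        rate <- acc_win / win
        if (rate < 0.2) step <- step / 1.3
        if (rate > 0.4) step <- step * 1.3
        acc_win <- 0L; win <- 0L
      }
    } else {
      n_post <- n_post + 1L
    }
    if (ki <= n_keep && it == keep_at[ki]) {
      samples[ki] <- lq
      pr <- .prune(tree, tipM, model_at(exp(lq)))
      prob_sum <- prob_sum + .marginal_at(pr, model_at(exp(lq)))
      ki <- ki + 1L
    }
  }

  prob <- prob_sum / n_keep
  colnames(prob) <- paste0("state", STATES)
  ess <- .ess(samples)
  diag <- list(ess = ess, acceptance = acc_post / n_post,
               n_retained = n_keep, low_ess_flag = ess < 100,
               seed = as.integer(seed), prior_mean = prior_mean,
               proposal_sd = step, iterations = iterations,
               burn_in = burn, thin = thin)
  if (diag$low_ess_flag)
    warning("effective sample size for the rate is below 100 (",
            round(ess, 1), "); consider more iterations")
  new_asr_result(method = "MB", tree = tree, prob = prob,
                 rate_samples = exp(samples), diagnostics = diag,
                 prior_mean = prior_mean)
}
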