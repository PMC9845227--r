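#' Specify an Mk model for a k-state unordered character
#'
#' Continuous-time Markov model with generator `Q`; `ER` has a single
#' exchange rate, `SYM` one rate per unordered state pair, `ARD` one per
#' ordered pair. Rates are in expected events per Myr (per unit branch
#' length in unit-length mode).
#'
#' @param rates positive rate(s): length 1 (ER), `k(k-1)/2` (SYM) or
#'   `k(k-1)` (ARD, row-wise off-diagonal order).
#' @param parameterization `"ER"`, `"SYM"` or `"ARD"`.
#' @param k number of states (3 for the uncinate character).
#' @param root_prior `"flat"`, `"stationary"`, or a probability vector of
#'   length `k`.
#' @return an object of class `mk_model`.
#' @export
mk_model <- function(rates = 0.01, parameterization = c("ER", "SYM", "ARD"),
                     k = 3L, root_prior = "flat") {
  parameterization <- match.arg(parameterization)
  n_free <- switch(parameterization, ER = 1L, SYM = k * (k - 1L) / 2L,
                   ARD = k * (k - 1L))
  if (length(rates) != n_free)
    stop(parameterization, " with k=", k, " needs ", n_free, " rate(s)")
  if (any(rates <= 0)) stop("all rates must be > 0")
  if (is.numeric(root_prior)) {
    if (length(root_prior) != k || any(root_prior < 0) ||
        abs(sum(root_prior) - 1) > 1e-9)
      stop("numeric root prior must be a length-", k, " probability vector")
  } else if (!root_prior %in% c("flat", "stationary")) {
    stop("root_prior must be 'flat', 'stationary' or a probability vector")
  }
  structure(list(k = k, parameterization = parameterization, rates = rates,
                 root_prior = root_prior),
            class = "mk_model")
}

#' Generator matrix of an Mk model
#'
#' @param model an `mk_model`.
#' @return the `k x k` rate matrix Q (rows sum to zero).
#' @export
mk_Q <- function(model) {
  k <- model$k
  Q <- matrix(0, k, k)
  if (model$parameterization == "ER") {
    Q[] <- model$rates[1L]
  } else if (model$parameterization == "SYM") {
    Q[upper.tri(Q)] <- model$rates
    Q <- Q + t(Q)
  } else {
    r <- 0L                                   # row-wise off-diagonal order
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
      r <- r + 1L
      Q[i, j] <- model$rates[r]
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

root_prior_vector <- function(model) {
  k <- model$k
  if (is.numeric(model$root_prior)) return(model$root_prior)
  if (model$root_prior == "flat") return(rep(1 / k, k))
  # stationary distribution: left null vector of Q
  Q <- mk_Q(model)
  e <- eigen(t(Q))
  v <- Re(e$vectors[, which.min(abs(Re(e$values)))])
  v / sum(v)
}

#' Equal-rates transition probabilities in closed form
#'
#' For the ER model with `k` states and rate `q`,
#' `P(same) = 1/k + (k-1)/k * exp(-k q t)` and
#' `P(different) = 1/k - 1/k * exp(-k q t)`.
#'
#' @param q rate (> 0 allowed to be 0 here; used by simulators).
#' @param t branch length(s).
#' @param k number of states.
#' @return list with vectors `same` and `diff` (recycled over `t`).
#' @export
er_transition <- function(q, t, k = 3L) {
  e <- exp(-k * q * t)
  list(same = 1 / k + (k - 1) / k * e, diff = 1 / k - 1 / k * e)
}

# transition matrices per edge for a general Q; list of k x k matrices
.edge_P <- function(Q, lens) {
  lapply(lens, function(t) ape::matexpo(Q * t))
}

# Felsenstein pruning engine with per-node log-scaling.
# Returns: loglik; D (nn x k, each finished row scaled to max 1); logsc
# (per-node accumulated log scale of the subtree); lmsg (per-edge log
# message vector, scale included); postorder edge matrix + lengths.
.prune <- function(tree, tipM, model) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; timescale it or use unit lengths")
  if (any(tree$edge.length <= 0))
    stop("all branch lengths must be > 0 for likelihood methods")
  k <- model$k
  ntip <- nrow(tipM)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  lens <- po$edge.length
  er <- model$parameterization == "ER"
  if (er) {
    tp <- er_transition(model$rates[1L], lens, k)
    if (any(tp$diff <= 0))
      stop("degenerate transition probabilities (rate or length ~ 0)")
  } else {
    Plist <- .edge_P(mk_Q(model), lens)
  }

  D <- matrix(0, nn, k)
  D[seq_len(ntip), ] <- tipM
  logsc <- numeric(nn)
  logM <- matrix(0, nn, k)   # running sum of child log-messages
  lmsg <- matrix(0, nrow(E), k)
  done <- c(rep(TRUE, ntip), rep(FALSE, nn - ntip))

  for (i in seq_len(nrow(E))) {
    p <- E[i, 1L]; ch <- E[i, 2L]
    if (!done[ch]) {       # finalize an internal child from its messages
      mx <- max(logM[ch, ])
      D[ch, ] <- exp(logM[ch, ] - mx)
      logsc[ch] <- mx
      done[ch] <- TRUE
    }
    d <- D[ch, ]
    if (er) {
      m <- tp$diff[i] * sum(d) + (tp$same[i] - tp$diff[i]) * d
    } else {
      m <- as.vector(Plist[[i]] %*% d)
    }
    lm <- log(m) + logsc[ch]
    lmsg[i, ] <- lm
    logM[p, ] <- logM[p, ] + lm
  }
  root <- E[nrow(E), 1L]
  mx <- max(logM[root, ])
  D[root, ] <- exp(logM[root, ] - mx)
  logsc[root] <- mx
  prior <- root_prior_vector(model)
  loglik <- log(sum(prior * D[root, ])) + logsc[root]
  list(loglik = loglik, D = D, logsc = logsc, lmsg = lmsg, logM = logM,
       E = E, lens = lens, root = root, prior = prior,
       er = er, tp = if (er) tp else NULL,
       Plist = if (!er) Plist else NULL)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' Exact log-likelihood of a (possibly ambiguous) tip coding under the Mk
#' model, integrating over all ancestral states. Ambiguous tips enter as
#' indicator vectors over their allowed states. Partial likelihoods are
#' log-scaled per node, so deep trees and small rates do not underflow.
#'
#' @param tree `phylo` with strictly positive branch lengths.
#' @param coding a `character_coding` covering every tip.
#' @param model an `mk_model`.
#' @return the log-likelihood (a single number).
#' @export
mk_loglik <- function(tree, coding, model) {
  validate_tree(tree)
  tipM <- coding_matrix(coding, tree)
  .prune(tree, tipM, model)$loglik
}

#' Maximum-likelihood fit of the Mk rate(s)
#'
#' For the ER model the single rate is optimized on the log scale with a
#' bracketed one-dimensional search; SYM/ARD rates use box-constrained
#' quasi-Newton on log rates. An estimate at (or within tolerance of) the
#' search bounds is flagged, as is optimizer non-convergence.
#'
#' @param tree `phylo` with positive branch lengths.
#' @param coding a `character_coding`.
#' @param parameterization `"ER"` (default), `"SYM"` or `"ARD"`.
#' @param root_prior as in [mk_model()].
#' @param bounds rate search interval (events/Myr).
#' @return list with the fitted `model`, `loglik`, `convergence` (logical)
#'   and `at_bound` (logical).
#' @export
fit_mk <- function(tree, coding, parameterization = "ER",
                   root_prior = "flat", bounds = c(1e-8, 1e3)) {
  validate_tree(tree)
  tipM <- coding_matrix(coding, tree)
  k <- length(STATES)
  nfree <- switch(parameterization, ER = 1L, SYM = 3L, ARD = 6L,
                  stop("unknown parameterization"))
  nll <- function(lrates) {
    m <- mk_model(exp(lrates), parameterization, k = k,
                  root_prior = root_prior)
    -.prune(tree, tipM, m)$loglik
  }
  lb <- log(bounds[1L]); ub <- log(bounds[2L])
  if (nfree == 1L) {
    opt <- optimize(nll, interval = c(lb, ub), tol = 1e-8)
    lr <- opt$minimum
    ll <- -opt$objective
    conv <- TRUE
  } else {
    opt <- optim(rep(log(0.01), nfree), nll, method = "L-BFGS-B",
                 lower = lb, upper = ub)
    lr <- opt$par
    ll <- -opt$value
    conv <- opt$convergence == 0L
  }
  at_bound <- any(lr < lb + 1e-4) || any(lr > ub - 1e-4)
  if (!conv) warning("Mk rate optimization did not converge")
  list(model = mk_model(exp(lr), parameterization, k = k,
                        root_prior = root_prior),
       loglik = ll, convergence = conv, at_bound = at_bound)
}

# exact per-node marginals at fixed model, via down (D) + up (A) messages;
# returns nn x k matrix of probabilities (rows sum to 1)
.marginal_at <- function(pr, model) {
  k <- model$k
  nn <- nrow(pr$D)
  E <- pr$E
  A <- matrix(0, nn, k)
  A[pr$root, ] <- pr$prior
  logA <- matrix(0, nn, k)  # log-scale companion of A
  logA[pr$root, ] <- log(pr$prior)
  for (i in rev(seq_len(nrow(E)))) {
    p <- E[i, 1L]; ch <- E[i, 2L]
    # everything except the subtree of ch, as seen from the parent state:
    # log A(parent) + sum of sibling messages = logA + logM - own message
    lb <- logA[p, ] + pr$logM[p, ] - pr$lmsg[i, ]
    mx <- max(lb[is.finite(lb)])
    b <- exp(lb - mx)
    b[!is.finite(lb)] <- 0
    if (pr$er) {
      tp <- pr$tp
      a <- tp$diff[i] * sum(b) + (tp$same[i] - tp$diff[i]) * b
    } else {
      a <- as.vector(t(pr$Plist[[i]]) %*% b)
    }
    a[a < 0] <- 0
    logA[ch, ] <- log(a) + mx
  }
  marg <- matrix(0, nn, k)
  for (n in seq_len(nn)) {
    lw <- logA[n, ] + log(pr$D[n, ])
    fin <- is.finite(lw)
    w <- numeric(k)
    w[fin] <- exp(lw[fin] - max(lw[fin]))
    marg[n, ] <- w / sum(w)
  }
  marg
}

#' Exact marginal ancestral states under a fitted Mk model
#'
#' For every node (tips included), the probability of each state given all
#' tip data and the model, computed by one down-pass and one up-pass of
#' messages (equivalent to re-rooting at every node, but in linear time).
#' Tips with singleton codings get probability 1 on their observed state;
#' ambiguous tips get their conditional distribution.
#'
#' @inheritParams mk_loglik
#' @return an `asr_result` with `method = "ML"`, `prob` (`(Ntip+Nnode) x 3`
#'   matrix), the `model` and `loglik`.
#' @export
marginal_asr_ml <- function(tree, coding, model) {
  validate_tree(tree)
  tipM <- coding_matrix(coding, tree)
  pr <- .prune(tree, tipM, model)
  marg <- .marginal_at(pr, model)
  colnames(marg) <- paste0("state", STATES)
  new_asr_result(method = "ML", tree = tree, prob = marg, model = model,
                 loglik = pr$loglik)
}
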