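test_that("pruning likelihood matches exhaustive enumeration", {
  set.seed(55)
  for (i in 1:30) {
    n <- sample(3:6, 1L)
    tr <- rand_tree(n, star = i %% 7 == 0)
    cod <- rand_state_sets(n)
    q <- runif(1, 0.02, 1.5)
    expect_equal(mk_loglik(tr, cod, mk_model(q)),
                 enum_loglik(tr, cod, q), tolerance = 1e-12)
  }
})

test_that("analytic limits of the ER likelihood", {
  tr <- rand_tree(6)
  const <- make_coding(setNames(rep(list(1L), 6), tr$tip.label))
  # frozen character: only the root draw matters
  expect_equal(mk_loglik(tr, const, mk_model(1e-9)), log(1 / 3),
               tolerance = 1e-6)
  # saturated cherry: all states independent uniform
  cherry <- read_newick(text = "(A:4000,B:4000);")
  cod <- make_coding(list(A = 1L, B = 0L))
  expect_equal(mk_loglik(cherry, cod, mk_model(1)), log(1 / 9),
               tolerance = 1e-9)
  nolen <- read_newick(text = "(A,(B,C));")
  expect_error(mk_loglik(nolen, make_coding(list(A = 1L, B = 0L, C = 1L)),
                         mk_model(1)), "branch lengths")
  bad <- tr; bad$edge.length[1] <- 0
  expect_error(mk_loglik(bad, const, mk_model(0.1)), "> 0")
  expect_error(mk_model(0), "> 0")
})

test_that("ER results are invariant to state relabeling and qt rescaling", {
  set.seed(66)
  tr <- rand_tree(8)
  cod <- rand_state_sets(8)
  q <- 0.4
  perm <- c(2L, 0L, 1L)  # state s -> perm[s+1]
  cod_p <- make_coding(lapply(cod, function(v) sort(perm[v + 1L])))
  expect_equal(mk_loglik(tr, cod, mk_model(q)),
               mk_loglik(tr, cod_p, mk_model(q)), tolerance = 1e-12)
  m <- marginal_asr_ml(tr, cod, mk_model(q))$prob
  mp <- marginal_asr_ml(tr, cod_p, mk_model(q))$prob
  expect_equal(m, mp[, perm + 1L], ignore_attr = TRUE, tolerance = 1e-12)

  tr_c <- tr; tr_c$edge.length <- tr$edge.length * 7
  expect_equal(mk_loglik(tr, cod, mk_model(q)),
               mk_loglik(tr_c, cod, mk_model(q / 7)), tolerance = 1e-12)
})

test_that("rate fitting: boundary, grid-search oracle, cross-check", {
  tr <- rand_tree(8)
  const <- make_coding(setNames(rep(list(1L), 8), tr$tip.label))
  fit0 <- fit_mk(tr, const)
  expect_true(fit0$at_bound)                       # MLE at q -> 0
  expect_equal(fit0$loglik, log(1 / 3), tolerance = 1e-4)

  # interior MLE: two concordant cherries in different states
  quart <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  cod <- make_coding(list(A = 1L, B = 1L, C = 0L, D = 0L))
  fit <- fit_mk(quart, cod)
  grid <- exp(seq(log(1e-6), log(100), length.out = 20000))
  ll <- vapply(grid, function(q) mk_loglik(quart, cod, mk_model(q)),
               numeric(1))
  expect_false(fit$at_bound)
  expect_equal(fit$model$rates, grid[which.max(ll)], tolerance = 2e-3)
  expect_gte(fit$loglik, max(ll) - 1e-8)

  # discordant cherry: the profile flattens at saturation, and the fitted
  # likelihood sits on that plateau
  cherry <- read_newick(text = "(A:1,B:1);")
  cfit <- fit_mk(cherry, make_coding(list(A = 1L, B = 0L)))
  expect_equal(cfit$loglik, log(1 / 9), tolerance = 1e-6)

  # independent implementation agrees on informative data
  set.seed(77)
  spec <- sim_spec(n_tips = 60, birth = 0.1, q = 0.15, seed = 9)
  big <- simulate_tree(spec)
  st <- simulate_mk_character(big, 0.15, 1L, seed = 10)
  codb <- make_coding(as.list(st))
  mine <- fit_mk(big, codb)
  ph <- phytools::fitMk(big, setNames(as.character(st), names(st)),
                        model = "ER", pi = "equal")
  expect_equal(mine$loglik, as.numeric(stats::logLik(ph)), tolerance = 1e-4)
  expect_equal(mine$model$rates, ph$rates, tolerance = 0.01)
})

test_that("marginal reconstruction matches the exhaustive posterior", {
  set.seed(88)
  for (i in 1:15) {
    n <- sample(3:5, 1L)
    tr <- rand_tree(n)
    cod <- rand_state_sets(n)
    q <- runif(1, 0.05, 1)
    res <- marginal_asr_ml(tr, cod, mk_model(q))
    expect_equal(unname(res$prob), unname(enum_marginals(tr, cod, q)),
                 tolerance = 1e-12)
    expect_equal(rowSums(res$prob), rep(1, nrow(res$prob)),
                 tolerance = 1e-9)
  }
})

test_that("marginal limits: uninformative data and frozen character", {
  star <- rand_tree(6, star = TRUE)
  blank <- make_coding(setNames(rep(list(0:2), 6), star$tip.label))
  res <- marginal_asr_ml(star, blank, mk_model(0.3))
  expect_equal(unname(res$prob), matrix(1 / 3, nrow(res$prob), 3),
               tolerance = 1e-9)

  tr <- rand_tree(6)
  const <- make_coding(setNames(rep(list(1L), 6), tr$tip.label))
  root <- 7L
  p_small <- marginal_asr_ml(tr, const, mk_model(1e-4))$prob[root, 2L]
  p_tiny <- marginal_asr_ml(tr, const, mk_model(1e-6))$prob[root, 2L]
  expect_gt(p_tiny, p_small - 1e-12)
  expect_gt(p_tiny, 1 - 1e-3)
  # singleton tips keep probability 1 on their state
  mixed <- marginal_asr_ml(tr, const, mk_model(0.2))
  expect_equal(mixed$prob[1L, ], c(state0 = 0, state1 = 1, state2 = 0))
})

test_that("marginals agree with the re-rooting implementation", {
  set.seed(99)
  tr <- rand_tree(10)
  st <- sample(0:2, 10, replace = TRUE)
  cod <- make_coding(setNames(as.list(st), tr$tip.label))
  ph <- phytools::fitMk(tr, setNames(as.character(st), tr$tip.label),
                        model = "ER", pi = "equal")
  rr <- phytools::rerootingMethod(tr, setNames(as.character(st),
                                               tr$tip.label), model = "ER")
  mine <- marginal_asr_ml(tr, cod, mk_model(ph$rates))
  internal <- 11:(10 + tr$Nnode)
  expect_equal(unname(mine$prob[internal, ]),
               unname(rr$marginal.anc[as.character(internal), ]),
               tolerance = 1e-4)
})

test_that("saturation drives every node marginal to 1/3", {
  tr <- rand_tree(6)
  tr$edge.length <- tr$edge.length * 1e4
  cod <- make_coding(setNames(as.list(c(0L, 1L, 2L, 0L, 1L, 2L)),
                              tr$tip.label))
  res <- marginal_asr_ml(tr, cod, mk_model(1))
  internal <- 7:(6 + tr$Nnode)
  expect_equal(unname(res$prob[internal, ]),
               matrix(1 / 3, length(internal), 3), tolerance = 1e-6)
})

test_that("SYM and ARD generators are built correctly", {
  Q <- mk_Q(mk_model(c(1, 2, 3), "SYM"))
  expect_equal(Q[1, 2], 1); expect_equal(Q[2, 1], 1)
  expect_equal(Q[1, 3], 2); expect_equal(Q[2, 3], 3)
  expect_equal(rowSums(Q), rep(0, 3))
  Qa <- mk_Q(mk_model(1:6, "ARD"))
  expect_equal(Qa[1, 2], 1); expect_equal(Qa[1, 3], 2)
  expect_equal(Qa[2, 1], 3); expect_equal(Qa[3, 2], 6)
  expect_equal(rowSums(Qa), rep(0, 3))
  # general-Q pruning agrees with the ER closed form when rates are equal
  tr <- rand_tree(5)
  cod <- rand_state_sets(5)
  expect_equal(mk_loglik(tr, cod, mk_model(rep(0.3, 3), "SYM")),
               mk_loglik(tr, cod, mk_model(0.3, "ER")), tolerance = 1e-10)
})
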