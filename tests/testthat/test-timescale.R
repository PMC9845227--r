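rng <- function(taxa, fad, lad = pmax(fad - 5, 0))
  data.frame(taxon = taxa, fad_ma = fad, lad_ma = lad,
             stringsAsFactors = FALSE)

test_that("internal node ages equal the oldest descendant FAD", {
  tr <- read_newick(text = "(A,B);")
  ages <- assign_node_ages(tr, rng(c("A", "B"), c(150, 140)))
  expect_equal(ages, c(150, 140, 150))

  tr2 <- read_newick(text = "((A,B),C);")
  ages2 <- assign_node_ages(tr2, rng(c("A", "B", "C"), c(150, 140, 160)))
  root <- mrca_node(tr2, c("A", "C"))
  inner <- mrca_node(tr2, c("A", "B"))
  expect_equal(ages2[root], 160)
  expect_equal(ages2[inner], 150)

  expect_error(assign_node_ages(tr2, rng(c("A", "B"), c(1, 2))),
               "no stratigraphic range.*C")
  expect_error(validate_strat_ranges(rng("A", 100, 120)), "FAD < LAD")
})

test_that("tip age policies select FAD, LAD or the midpoint", {
  tr <- read_newick(text = "(A,B);")
  r <- rng(c("A", "B"), c(150, 140), c(130, 120))
  expect_equal(assign_node_ages(tr, r, "FAD")[1:2], c(150, 140))
  expect_equal(assign_node_ages(tr, r, "LAD")[1:2], c(130, 120))
  expect_equal(assign_node_ages(tr, r, "midpoint")[1:2], c(140, 130))
  # internal ages use FAD regardless of tip policy
  expect_equal(assign_node_ages(tr, r, "LAD")[3], 150)
})

test_that("minimum-branch-length correction shifts ancestors minimally", {
  tr <- read_newick(text = "(A,B);")
  ages <- c(150, 140, 150)            # zero-length branch to A
  ts <- apply_branch_lengths(tr, ages, mbl = 1)
  expect_equal(ts$node.ages[3], 151)
  expect_setequal(ts$edge.length, c(1, 11))

  # already satisfied -> untouched
  ts2 <- apply_branch_lengths(tr, c(150, 140, 155), mbl = 1)
  expect_equal(ts2$node.ages, c(150, 140, 155))

  expect_error(apply_branch_lengths(tr, ages, mbl = 0), "positive")
  expect_error(apply_branch_lengths(tr, c(150, 140, 100), mbl = 1),
               "inconsistent")
})

test_that("the total mbl shift is minimal (brute-force perturbation)", {
  tr <- read_newick(text = "((A,B),(C,D));")
  ranges <- rng(c("A", "B", "C", "D"), c(150, 150, 149, 120))
  ages <- assign_node_ages(tr, ranges)
  ts <- apply_branch_lengths(tr, ages, mbl = 2)
  expect_true(all(ts$edge.length >= 2 - 1e-12))
  ntip <- 4L
  shifted <- which(ts$node.ages != c(ages[1:ntip], ages[-(1:ntip)]) &
                     seq_along(ts$node.ages) > ntip)
  # lowering any shifted internal node by epsilon must break a floor
  for (n in shifted) {
    pert <- ts$node.ages
    pert[n] <- pert[n] - 1e-6
    E <- tr$edge
    lens <- pert[E[, 1L]] - pert[E[, 2L]]
    expect_true(any(lens < 2), info = paste("node", n, "could be lowered"))
  }
})

test_that("age recovery is exact under perfect sampling of node ages", {
  # ranges whose FADs equal the true lineage start times reproduce the
  # true node ages up to the simulated offset (here zero)
  spec <- sim_spec(n_tips = 12, birth = 0.05, seed = 11)
  tr <- simulate_tree(spec)
  ntip <- length(tr$tip.label)
  E <- tr$edge
  start_age <- tr$node.ages[E[, 1L]]       # child lineage starts at parent
  fad <- start_age[match(seq_len(ntip), E[, 2L])]
  ages <- assign_node_ages(tr, rng(tr$tip.label, fad, lad = rep(0, ntip)))
  # max-FAD dating never overshoots the true age, and is exact for every
  # internal node that directly subtends a tip (its tip child's FAD is the
  # node's own age)
  internal <- (ntip + 1L):(ntip + tr$Nnode)
  expect_true(all(ages[internal] <= tr$node.ages[internal] + 1e-9))
  with_tip_child <- unique(E[E[, 2L] <= ntip, 1L])
  expect_equal(ages[with_tip_child], tr$node.ages[with_tip_child],
               tolerance = 1e-9)
  expect_true(all(ages[E[, 1L]] >= ages[E[, 2L]]))
})

test_that("unit mode sets every branch to one and is idempotent", {
  tr <- rand_tree(5)
  u <- unit_branch_lengths(tr)
  expect_true(all(u$edge.length == 1))
  expect_equal(u$bl_mode, "unit")
  expect_equal(unit_branch_lengths(u)$edge.length, u$edge.length)
  star <- unit_branch_lengths(rand_tree(4, star = TRUE))
  expect_equal(star$Nnode, 1L)
  expect_true(all(star$edge.length == 1))
})

test_that("range tables round-trip through TSV and CSV", {
  df <- rng(c("A", "B"), c(150.5, 140), c(130, 0))
  tsv <- tempfile(fileext = ".tsv")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_strat_ranges(tsv), df)
  csv <- tempfile(fileext = ".csv")
  write.csv(df, csv, row.names = FALSE, quote = FALSE)
  expect_equal(read_strat_ranges(csv), df)
})
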