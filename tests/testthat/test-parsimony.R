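test_that("Fitch steps match the classic four-tip cases", {
  tr <- tree4()
  expect_equal(fitch_optimise(tr, list(0L, 0L, 1L, 1L), 2)$steps, 1)
  # frozen from brute force over all 2^3 internal assignments
  expect_equal(fitch_optimise(tr, list(0L, 1L, 0L, 1L), 2)$steps, 2)
  rc <- fitch_optimise(tr, list(1L, 1L, 1L, 1L), 2)
  expect_equal(rc$steps, 0)
  expect_true(all(vapply(rc$node_mpr, identical, logical(1), 1L)))
})

test_that("Sankoff handles ordered costs and reduces to Fitch at unit cost", {
  ch <- ape::read.tree(text = "(A:1,B:1);")
  r <- sankoff_optimise(ch, list(0L, 2L), 3,
                        morphoscaffold:::ordered_cost(3))
  expect_equal(r$steps, 2)
  expect_identical(r$node_mpr[[3]], 0:2)  # any root state 0..2 is optimal

  # frozen from exhaustive enumeration of internal states 0..2
  tr <- tree4()
  expect_equal(sankoff_optimise(tr, list(0L, 0L, 2L, 2L), 3,
                                morphoscaffold:::ordered_cost(3))$steps, 2)

  set.seed(41)
  for (i in 1:20) {
    tr <- random_tree(sample(4:6, 1))
    k <- sample(2:4, 1)
    col <- random_column(ape::Ntip(tr), k)
    expect_equal(sankoff_optimise(tr, col, k)$steps,
                 fitch_optimise(tr, col, k)$steps)
  }
})

test_that("cost matrix validation catches bad inputs", {
  ch <- ape::read.tree(text = "(A:1,B:1);")
  bad <- matrix(c(0, -1, -1, 0), 2)
  expect_error(sankoff_optimise(ch, list(0L, 1L), 2, bad), "negative")
  nonmetric <- matrix(c(0, 5, 1, 5, 0, 1, 1, 1, 0), 3)
  expect_warning(sankoff_optimise(ch, list(0L, 2L), 3, nonmetric),
                 "non-metric")
  expect_error(sankoff_optimise(ch, list(), 2), "empty|length")
})

test_that("all-missing and empty columns behave as specified", {
  tr <- tree4()
  r <- fitch_optimise(tr, list(NULL, NULL, NULL, NULL), 3)
  expect_equal(r$steps, 0)
  expect_true(all(vapply(r$node_mpr, identical, logical(1), 0:2)))
})

test_that("steps and MPR sets match brute force on random cases", {
  set.seed(101)
  for (i in 1:40) {
    tr <- random_tree(sample(4:6, 1))
    k <- sample(2:4, 1)
    col <- random_column(ape::Ntip(tr), k)
    ordered <- k >= 3 && runif(1) < 0.4
    cost <- if (ordered) morphoscaffold:::ordered_cost(k) else NULL
    got <- sankoff_optimise(tr, col, k,
                            if (is.null(cost)) morphoscaffold:::unit_cost(k)
                            else cost)
    sets <- morphoscaffold:::as_state_sets(col, k)
    exp <- brute_force_parsimony(tr, sets, k, cost)
    expect_equal(got$steps, exp$steps, info = paste("case", i))
    expect_identical(lapply(got$node_mpr, as.integer), exp$node_mpr,
                     info = paste("case", i))
  }
})

test_that("ordered steps dominate unordered, equal for binary data", {
  set.seed(7)
  for (i in 1:15) {
    tr <- random_tree(sample(4:6, 1))
    k <- sample(3:4, 1)
    col <- random_column(ape::Ntip(tr), k)
    so <- sankoff_optimise(tr, col, k, morphoscaffold:::ordered_cost(k))$steps
    sf <- fitch_optimise(tr, col, k)$steps
    expect_gte(so, sf)
    bin <- random_column(ape::Ntip(tr), 2, poly_prob = 0)
    expect_equal(
      sankoff_optimise(tr, bin, 3, morphoscaffold:::ordered_cost(3))$steps,
      fitch_optimise(tr, bin, 2)$steps)
  }
})

test_that("adding a tip never decreases parsimony steps", {
  set.seed(13)
  for (i in 1:10) {
    tr <- random_tree(6, polytomy_prob = 0)
    k <- 3
    col <- random_column(6, k, missing_prob = 0)
    s0 <- fitch_optimise(tr, col, k)$steps
    w <- sample(6, 1)
    tr2 <- ape::bind.tree(tr, ape::read.tree(text = "(X:1);"), where = w,
                          position = tr$edge.length[tr$edge[, 2] == w] / 2)
    col2 <- c(col, list(sample(0:(k - 1), 1)))
    names(col2) <- NULL
    ordering <- match(tr2$tip.label, c(tr$tip.label, "X"))
    expect_gte(fitch_optimise(tr2, col2[ordering], k)$steps, s0)
  }
})

test_that("a single deterministic resolution realises exactly `steps` changes", {
  set.seed(23)
  for (i in 1:10) {
    tr <- random_tree(6)
    col <- random_column(ape::Ntip(tr), 2)
    r <- fitch_optimise(tr, col, 2)
    expect_equal(nrow(r$changes), r$steps)
  }
})

test_that("linear parsimony matches its examples and the grid oracle", {
  ch <- ape::read.tree(text = "(A:1,B:1);")
  r <- linear_parsimony_continuous(ch, c(1.0, 3.0))
  expect_equal(r$steps, 2.0)
  expect_equal(r$node_mpr[[3]], c(1.0, 3.0))
  expect_equal(linear_parsimony_continuous(ch, c(2, 2))$steps, 0)

  tr <- tree4()
  expect_equal(linear_parsimony_continuous(tr, c(0, 0, 4, 4))$steps, 4.0)

  expect_error(linear_parsimony_continuous(ch, c(1, Inf)), "non-finite")

  set.seed(31)
  for (i in 1:12) {
    tr <- random_tree(sample(4:5, 1))
    vals <- round(stats::runif(ape::Ntip(tr), 0, 3), 1)
    vals[stats::runif(length(vals)) < 0.2] <- NA
    expect_equal(linear_parsimony_continuous(tr, vals)$steps,
                 brute_force_linear(tr, vals))
  }
})

test_that("linear parsimony on contiguous integers equals ordered Sankoff", {
  set.seed(37)
  for (i in 1:10) {
    tr <- random_tree(sample(4:6, 1))
    k <- sample(3:4, 1)
    states <- sample(0:(k - 1), ape::Ntip(tr), replace = TRUE)
    so <- sankoff_optimise(tr, as.list(states), k,
                           morphoscaffold:::ordered_cost(k))$steps
    expect_equal(linear_parsimony_continuous(tr, as.numeric(states))$steps, so)
  }
})

test_that("origin counts match examples and exhaustive enumeration", {
  tr <- tree4()
  r <- fitch_optimise(tr, list(0L, 1L, 0L, 1L), 2)
  expect_equal(unname(count_state_origins(r, 1L)), c(1L, 2L))
  r2 <- fitch_optimise(tr, list(0L, 0L, 0L, 0L), 2)
  expect_equal(unname(count_state_origins(r2, 1L)), c(0L, 0L))
  expect_error(count_state_origins(r, 5L), "out of range")

  # planted single origin, no reversal
  sc <- mini_scaffold()
  col <- as.list(as.integer(sc$tree$tip.label %in% c("A", "B")))
  rp <- fitch_optimise(sc$tree, col, 2)
  expect_equal(unname(count_state_origins(rp, 1L)), c(1L, 1L))

  set.seed(43)
  for (i in 1:15) {
    tr <- random_tree(sample(4:5, 1))
    k <- sample(2:3, 1)
    col <- random_column(ape::Ntip(tr), k, missing_prob = 0.1, poly_prob = 0)
    r <- fitch_optimise(tr, col, k)
    st <- sample(0:(k - 1), 1)
    sets <- morphoscaffold:::as_state_sets(col, k)
    expect_equal(count_state_origins(r, st),
                 brute_force_origins(tr, sets, k, st), info = paste("case", i))
  }
})

test_that("homoplasy indices follow their definitions and agree with phangorn", {
  tr <- tree4()
  r <- fitch_optimise(tr, list(0L, 1L, 0L, 1L), 2)
  h <- homoplasy_indices(r)
  expect_equal(h[c("m", "s", "g")], list(m = 1L, s = 2, g = 2))
  expect_equal(h$ci, 0.5)
  expect_equal(h$ri, 0)

  rc <- fitch_optimise(tr, list(1L, 1L, 1L, 1L), 2)
  hc <- homoplasy_indices(rc)
  expect_equal(hc$ci, 1)
  expect_true(is.na(hc$ri))

  r1 <- fitch_optimise(tr, list(0L, 0L, 1L, 1L), 2)
  expect_equal(homoplasy_indices(r1)$ci, 1)

  skip_if_not_installed("phangorn")
  set.seed(47)
  for (i in 1:8) {
    tr <- random_tree(6, polytomy_prob = 0)
    states <- sample(0:1, 6, replace = TRUE)
    if (length(unique(states)) < 2) next
    r <- fitch_optimise(tr, as.list(states), 2)
    h <- homoplasy_indices(r)
    dat <- phangorn::phyDat(matrix(as.character(states), ncol = 1,
                                   dimnames = list(tr$tip.label, NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(h$ci, unname(phangorn::CI(tr, dat)))
    if (!is.na(h$ri)) expect_equal(h$ri, unname(phangorn::RI(tr, dat)))
  }
})
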