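placement_fixture <- function(n_discrete = 40, missing_fraction = 0.5,
                              sim_seed = 7, fossil_seed = 3,
                              target = "furnariida", pos = 0.5) {
  sc <- small_synth_scaffold()
  cfg <- simulation_config(sc, n_discrete = n_discrete, n_continuous = 0,
                           missing_fraction = 0.02, seed = sim_seed)
  sim <- simulate_matrix(cfg)
  target_branch <- which(sc$tree$edge[, 2] ==
                           mrca_node(sc$tree, get_clade(sc, target)$tips))
  set.seed(fossil_seed)
  fos <- make_fossil(sim, branch = target_branch, pos = pos, pendant = 0.02,
                     missing_fraction = missing_fraction, name = "fx")
  m <- add_fossil_rows(sim$matrix, list(fos))
  sc2 <- scaffold_tree(sc$tree, constrained = "stem_fossil",
                       floating = "fx")
  for (nm in names(sc$clades))
    sc2 <- register_clade(sc2, nm, sc$clades[[nm]]$tips)
  list(sc = sc2, m = m, target_branch = target_branch, sim = sim)
}

test_that("the parsimony scan puts a tip-identical fossil on that tip's branch", {
  sc <- mini_scaffold()
  taxa <- c("A", "B", "C", "D", "E", "F", "O1", "O2")
  rows <- setNames(lapply(taxa, function(t)
    list(as.integer(t %in% c("A", "B")), as.integer(t %in% c("A")),
         as.integer(t %in% c("E", "F")))), taxa)
  m <- tiny_matrix(rows)
  m_f <- add_fossil_rows(m, list(list(row = list(1L, 1L, 0L), name = "fx")))
  scan <- attach_parsimony_scan("fx", sc, m_f)
  expect_equal(scan$child[1], "A")
  expect_equal(scan$added_steps[1], 0)
  expect_false(attr(scan, "uninformative"))
})

test_that("an all-missing fossil adds no steps anywhere and is flagged", {
  sc <- mini_scaffold()
  taxa <- c("A", "B", "C", "D", "E", "F", "O1", "O2")
  rows <- setNames(lapply(taxa, function(t)
    list(as.integer(t %in% c("A", "B")))), taxa)
  m <- tiny_matrix(rows)
  m_f <- add_fossil_rows(m, list(list(row = list("?"), name = "fx")))
  scan <- attach_parsimony_scan("fx", sc, m_f)
  expect_true(all(scan$added_steps == 0))
  expect_true(attr(scan, "uninformative"))
})

test_that("scan ranking equals brute-force re-optimisation on a 5-tip case", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,((C:1,D:1):1,E:1):1);")
  sc <- scaffold_tree(tr)
  set.seed(61)
  taxa <- tr$tip.label
  rows <- setNames(lapply(taxa, function(t)
    lapply(1:4, function(j) sample(0:1, 1))), taxa)
  m <- tiny_matrix(rows)
  frow <- lapply(1:4, function(j) sample(0:1, 1))
  m_f <- add_fossil_rows(m, list(list(row = frow, name = "fx")))
  scan <- attach_parsimony_scan("fx", sc, m_f)
  ctx <- morphoscaffold:::graft_ctx(tr, 1L)
  oracle <- vapply(seq_len(nrow(tr$edge)), function(e) {
    g <- morphoscaffold:::graft_phylo(ctx, rep(1, nrow(tr$edge)),
                                      morphoscaffold:::new_attachment(0L, e,
                                                                      0.5, 1),
                                      "fx")
    sum(vapply(1:4, function(j) {
      sets <- morphoscaffold::matrix_column(m_f, j, g$tip.label)
      brute_force_parsimony(g, sets, 2)$steps
    }, numeric(1)))
  }, numeric(1))
  base <- min(oracle)
  expect_equal(scan$added_steps[order(scan$branch)],
               oracle - sum(vapply(1:4, function(j)
                 brute_force_parsimony(tr, morphoscaffold::matrix_column(
                   m, j, tr$tip.label), 2)$steps, numeric(1))))
})

test_that("the sampler is reproducible and validates its inputs", {
  fx <- placement_fixture(n_discrete = 8)
  cfg <- mk_model_config(generations = 200, sample_every = 10, runs = 1,
                         chains_per_run = 2, seed = 99)
  ps1 <- run_mcmc(fx$m, fx$sc, cfg)
  ps2 <- run_mcmc(fx$m, fx$sc, cfg)
  expect_identical(lapply(ps1$samples, `[[`, "att"),
                   lapply(ps2$samples, `[[`, "att"))
  expect_identical(vapply(ps1$samples, `[[`, numeric(1), "lnL"),
                   vapply(ps2$samples, `[[`, numeric(1), "lnL"))

  sc_nofloat <- scaffold_tree(fx$sc$tree, constrained = "stem_fossil")
  expect_error(run_mcmc(fx$m, sc_nofloat, cfg), "no floating fossils")
  expect_error(mk_model_config(generations = 0), "generations")
  expect_error(mk_model_config(burnin_fraction = 1), "burnin")
})

test_that("summaries compute BPPs, consensus supports, and respect nesting", {
  fx <- placement_fixture()
  cfg <- mk_model_config(generations = 2500, sample_every = 10, runs = 2,
                         chains_per_run = 2, seed = 17)
  ps <- run_mcmc(fx$m, fx$sc, cfg)
  summ <- summarise_placement(ps, groups = list(g1 = "fx"))

  bp <- summ$branch_posterior$fx
  expect_equal(sum(bp$freq), 1, tolerance = 1e-9)

  # nesting monotonicity of clade BPPs, crown and total
  bpp <- summ$clade_bpp
  get <- function(cl, what) bpp[bpp$clade == cl, what]
  for (what in c("crown_bpp", "total_bpp")) {
    expect_lte(get("furnariida", what), get("tyrannides", what))
    expect_lte(get("tyrannides", what), get("tyranni", what))
    expect_lte(get("tyranni", what), get("eupasseres", what))
    expect_lte(get("eupasseres", what), get("passeriformes", what))
  }
  # total-clade membership always dominates crown membership
  expect_true(all(bpp$total_bpp >= bpp$crown_bpp - 1e-12))
  # a single-fossil group reproduces the per-fossil BPPs
  expect_equal(summ$group_bpp$crown_bpp, bpp$crown_bpp)

  # every consensus split has support > 0.5; the backbone splits are fixed,
  # so any split not involving the fossil must have support 1
  supports <- suppressWarnings(as.numeric(summ$consensus$node.label))
  expect_true(all(is.na(supports) | supports > 0.5 - 1e-9))

  expect_error(summarise_placement(structure(list(samples = list()),
                                             class = "placement_samples")),
               "no post-burn-in samples")
})

test_that("hand-built samples give exact membership fractions", {
  fx <- placement_fixture(n_discrete = 4)
  sc <- fx$sc
  E <- nrow(sc$tree$edge)
  target_branch <- fx$target_branch           # stem of furnariida
  inside_tip <- match(get_clade(sc, "furnariida")$tips[1], sc$tree$tip.label)
  inside_branch <- which(sc$tree$edge[, 2] == inside_tip)
  out_tip <- match("out1", sc$tree$tip.label)
  out_branch <- which(sc$tree$edge[, 2] == out_tip)
  mk_sample <- function(branch) list(
    run = 1L, gen = 1L, alpha = 1, lnL = 0, lnP = 0,
    att = morphoscaffold:::new_attachment(0L, branch, 0.5, 0.1))
  ps <- structure(list(
    samples = list(mk_sample(inside_branch), mk_sample(inside_branch),
                   mk_sample(out_branch)),
    config = mk_model_config(generations = 10, sample_every = 10, seed = 1),
    fossils = "fx", backbone = sc$tree, scaffold = sc,
    ctx = morphoscaffold:::graft_ctx(sc$tree, 1L),
    attach_freq_by_run = list(), attach_freq_sd = NA_real_),
    class = "placement_samples")
  summ <- summarise_placement(ps, clades = c("furnariida", "tyranni"))
  bpp <- summ$clade_bpp
  expect_equal(bpp$crown_bpp[bpp$clade == "furnariida"], 2 / 3,
               tolerance = 1e-9)

  # a stem attachment counts for the total clade only
  ps$samples <- list(mk_sample(target_branch))
  summ2 <- summarise_placement(ps, clades = c("furnariida", "tyranni"))
  b2 <- summ2$clade_bpp
  expect_equal(b2$crown_bpp[b2$clade == "furnariida"], 0)
  expect_equal(b2$total_bpp[b2$clade == "furnariida"], 1)
  expect_equal(b2$crown_bpp[b2$clade == "tyranni"], 1)
})

test_that("a fossil simulated inside a clade is recovered there with high BPP", {
  fx <- placement_fixture(n_discrete = 50, missing_fraction = 0.5,
                          sim_seed = 7, fossil_seed = 3)
  cfg <- mk_model_config(generations = 6000, sample_every = 20, runs = 1,
                         chains_per_run = 2, seed = 11)
  ps <- run_mcmc(fx$m, fx$sc, cfg)
  summ <- summarise_placement(ps, clades = "tyranni")
  expect_gte(summ$clade_bpp$crown_bpp[1], 0.9)
})
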