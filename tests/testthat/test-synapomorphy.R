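# The mini scaffold is ((O1,O2),(((A,B),(C,D)),(E,F))) with registered
# clades AB, CD, ABCD, EF, ingroup. Characters below are built to reproduce
# each reasoning pattern the classifier must express.

synapo_fixture <- function(rows, ...) {
  sc <- mini_scaffold()
  taxa <- c("A", "B", "C", "D", "E", "F", "O1", "O2")
  m <- tiny_matrix(setNames(lapply(taxa, function(t) rows[[t]]), taxa), ...)
  list(sc = sc, m = m, recons = optimise_matrix(m, sc))
}

row1 <- function(map, nch = 1L) {
  out <- rep(list(0L), nch)
  out
}

test_that("a planted single-origin state is an unreversed synapomorphy", {
  fx <- synapo_fixture(list(A = list(1L), B = list(1L), C = list(0L),
                            D = list(0L), E = list(0L), F = list(0L),
                            O1 = list(0L), O2 = list(0L)))
  rec <- classify_clade_state(fx$sc, "AB", 1L, 1L, fx$recons$char1, fx$m)
  expect_equal(rec$classification, "unreversed_synapomorphy")
  expect_length(rec$exceptions, 0)
  expect_equal(c(rec$min_origins, rec$max_origins), c(1L, 1L))
  expect_true(all(unlist(rec$criteria)))
})

test_that("a state reconstructable at the sister node is only ambiguous", {
  # derived state ubiquitous in AB but also present in C: the sister (CD)
  # ancestral node has an ambiguous {0,1} MPR, blocking criterion (iii)
  fx <- synapo_fixture(list(A = list(1L), B = list(1L), C = list(1L),
                            D = list(0L), E = list(0L), F = list(0L),
                            O1 = list(0L), O2 = list(0L)))
  rec <- classify_clade_state(fx$sc, "AB", 1L, 1L, fx$recons$char1, fx$m)
  expect_equal(rec$classification, "ambiguous_not_synapomorphy")
  expect_false(rec$criteria[["sister_absent"]])
  expect_match(rec$notes, "sister")
})

test_that("states inherited from rootward nodes are retained plesiomorphies", {
  fx <- synapo_fixture(list(A = list(1L), B = list(1L), C = list(1L),
                            D = list(1L), E = list(0L), F = list(0L),
                            O1 = list(0L), O2 = list(0L)))
  # ABCD carries the synapomorphy; AB merely retains it
  rec_abcd <- classify_clade_state(fx$sc, "ABCD", 1L, 1L, fx$recons$char1,
                                   fx$m)
  expect_equal(rec_abcd$classification, "unreversed_synapomorphy")
  rec_ab <- classify_clade_state(fx$sc, "AB", 1L, 1L, fx$recons$char1, fx$m)
  expect_equal(rec_ab$classification, "retained_plesiomorphy")
})

test_that("near-ubiquitous states list every exception", {
  fx <- synapo_fixture(list(A = list(1L), B = list(1L), C = list(1L),
                            D = list(1L), E = list(1L), F = list(0L),
                            O1 = list(0L), O2 = list(0L)))
  rec <- classify_clade_state(fx$sc, "ingroup", 1L, 1L, fx$recons$char1, fx$m)
  expect_equal(rec$classification, "near_ubiquitous_diagnostic")
  expect_identical(rec$exceptions, "F")
})

test_that("missing cells cannot break ubiquity but can create MPR ambiguity", {
  # B unscored: ubiquity holds on the scored member A, but the clade's
  # ancestral state becomes genuinely ambiguous (the classic missing-data
  # ambiguity pattern for fragmentary taxa)
  fx <- synapo_fixture(list(A = list(1L), B = list("?"), C = list(0L),
                            D = list(0L), E = list(0L), F = list(0L),
                            O1 = list(0L), O2 = list(0L)))
  rec <- classify_clade_state(fx$sc, "AB", 1L, 1L, fx$recons$char1, fx$m)
  expect_true(rec$criteria[["ubiquity"]])
  expect_false(rec$criteria[["mrca_unambiguous"]])
  expect_equal(rec$classification, "ambiguous_not_synapomorphy")
  expect_identical(rec$missing_taxa, "B")
  expect_match(rec$notes, "unscored: B")

  # ubiquity continues to hold with more scored members elsewhere
  sc3 <- mini_scaffold()
  m3 <- tiny_matrix(list(A = list(1L), B = list("?"), C = list(1L),
                         D = list(0L), E = list(0L), F = list(0L),
                         O1 = list(0L), O2 = list(0L)))
  sc3 <- register_clade(sc3, "ABC_plus", c("A", "B", "C", "D"))
  rec3 <- classify_clade_state(sc3, "AB", 1L, 1L,
                               optimise_matrix(m3, sc3)$char1, m3)
  expect_true(rec3$criteria[["ubiquity"]])
})

test_that("polymorphic presence is honoured and switchable", {
  fx <- synapo_fixture(list(A = list(1L), B = list(0:1), C = list(0L),
                            D = list(0L), E = list(0L), F = list(0L),
                            O1 = list(0L), O2 = list(0L)))
  rec <- classify_clade_state(fx$sc, "AB", 1L, 1L, fx$recons$char1, fx$m)
  expect_length(rec$exceptions, 0)
  rec_strict <- classify_clade_state(fx$sc, "AB", 1L, 1L, fx$recons$char1,
                                     fx$m, polymorphic_presence = FALSE)
  expect_identical(rec_strict$exceptions, "B")
})

test_that("a clade whose MRCA is the root skips the sister criterion", {
  sc <- mini_scaffold()
  sc <- register_clade(sc, "all",
                       c("A", "B", "C", "D", "E", "F", "O1", "O2"))
  taxa <- c("A", "B", "C", "D", "E", "F", "O1", "O2")
  m <- tiny_matrix(setNames(c(rep(list(list(1L)), 6), list(list(0L)),
                              list(list(0L))), taxa))
  recons <- optimise_matrix(m, sc)
  rec <- classify_clade_state(sc, "all", 1L, 1L, recons$char1, m)
  expect_match(rec$notes, "root")
  expect_true(is.na(rec$criteria[["sister_absent"]]))
})

test_that("diagnose_clade drops invariant characters and sorts by character", {
  sc <- mini_scaffold()
  taxa <- c("A", "B", "C", "D", "E", "F", "O1", "O2")
  rows <- setNames(lapply(taxa, function(t)
    list(0L, as.integer(t %in% c("A", "B")), as.integer(t %in% c("A", "B", "C", "D")))),
    taxa)
  m <- tiny_matrix(rows)
  recons <- optimise_matrix(m, sc)
  recs <- diagnose_clade(sc, "AB", recons, m)
  expect_gt(length(recs), 0)
  ids <- vapply(recs, `[[`, integer(1), "char_id")
  expect_false(1L %in% ids)         # constant character contributes nothing
  expect_identical(ids, sort(ids))

  m_const <- tiny_matrix(setNames(rep(list(list(0L, 0L)), 8), taxa))
  expect_length(diagnose_clade(sc, "AB", optimise_matrix(m_const, sc),
                               m_const), 0)
})

test_that("classification is invariant to taxon order and state relabelling", {
  taxa <- c("A", "B", "C", "D", "E", "F", "O1", "O2")
  vals <- c(A = 1L, B = 1L, C = 1L, D = 0L, E = 0L, F = 0L, O1 = 0L, O2 = 0L)
  sc <- mini_scaffold()
  class_of <- function(v, state) {
    m <- tiny_matrix(setNames(lapply(taxa, function(t) list(v[[t]])), taxa))
    classify_clade_state(sc, "AB", 1L, state,
                         optimise_matrix(m, sc)$char1, m)$classification
  }
  base <- class_of(vals, 1L)
  # permuted taxon storage order
  perm <- rev(taxa)
  m2 <- tiny_matrix(setNames(lapply(perm, function(t) list(vals[[t]])), perm))
  rec2 <- classify_clade_state(sc, "AB", 1L, 1L,
                               optimise_matrix(m2, sc)$char1, m2)
  expect_equal(rec2$classification, base)
  # relabelled states (0 <-> 1)
  expect_equal(class_of(1L - vals, 0L), base)
})

test_that("the unique-synapomorphy scan separates single and repeated origins", {
  # char 1: unique origin on AB's stem; char 2: same clade state but with a
  # second independent origin in E
  sc <- mini_scaffold()
  taxa <- c("A", "B", "C", "D", "E", "F", "O1", "O2")
  rows <- setNames(lapply(taxa, function(t)
    list(as.integer(t %in% c("A", "B")),
         as.integer(t %in% c("A", "B", "E")))), taxa)
  m <- tiny_matrix(rows)
  recons <- optimise_matrix(m, sc)
  scan <- unique_synapomorphy_scan(sc, recons, m)
  expect_equal(nrow(scan), 1L)
  expect_equal(scan$char_id, 1L)
  expect_equal(scan$clade, "AB")
  # char 2 is still an unreversed synapomorphy of AB, but not unique
  rec <- classify_clade_state(sc, "AB", 2L, 1L, recons$char2, m)
  expect_equal(rec$classification, "unreversed_synapomorphy")
  expect_equal(rec$min_origins, 2L)
})

test_that("planted markers are recovered perfectly on a clean simulation", {
  sc <- small_synth_scaffold()
  planted <- list(list(clade = "tyranni", char = 6, state = 1),
                  list(clade = "passeri", char = 7, state = 1),
                  list(clade = "furnariida", char = 8, state = 1))
  cfg <- simulation_config(sc, n_discrete = 12, n_continuous = 2,
                           planted = planted, seed = 21)
  sim <- simulate_matrix(cfg)
  recons <- optimise_matrix(sim$matrix, sc)
  detected <- list()
  for (cl in names(sc$clades)) for (rec in
    diagnose_clade(sc, cl, recons, sim$matrix)) {
    if (rec$classification == "unreversed_synapomorphy" &&
        rec$char_id %in% 6:8)
      detected[[length(detected) + 1L]] <- c(rec$clade, rec$char_id)
  }
  expect_setequal(vapply(detected, paste, character(1), collapse = ":"),
                  vapply(planted, function(p) paste(p$clade, p$char,
                                                    collapse = ":",
                                                    sep = ":"), character(1)))
})

test_that("every record's criteria log explains its classification", {
  sc <- small_synth_scaffold()
  cfg <- simulation_config(sc, n_discrete = 15, n_continuous = 0,
                           homoplasy_boost = 2, seed = 33)
  sim <- simulate_matrix(cfg)
  recons <- optimise_matrix(sim$matrix, sc)
  for (cl in c("tyranni", "passeri", "furnariida", "eupasseres")) {
    for (rec in diagnose_clade(sc, cl, recons, sim$matrix)) {
      crit <- rec$criteria
      if (rec$classification == "unreversed_synapomorphy") {
        expect_true(crit[["ubiquity"]] && crit[["mrca_unambiguous"]] &&
                      !isFALSE(crit[["sister_absent"]]))
        expect_length(rec$exceptions, 0)
      }
      if (rec$classification == "ambiguous_not_synapomorphy")
        expect_true(!crit[["mrca_unambiguous"]] ||
                      isFALSE(crit[["sister_absent"]]))
      if (rec$classification == "near_ubiquitous_diagnostic")
        expect_gt(length(rec$exceptions), 0)
    }
  }
})
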