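# Seeded simulation of character matrices and fossil rows with the
# statistical structure the analysis assumes: Mk-evolved discrete characters
# (ordered ones as nearest-neighbour stepping chains) with heterogeneous
# per-character rates, planted single-origin clade markers, Brownian-motion
# continuous ratios, sprinkled missing/inapplicable/polymorphic cells, and
# fragmentary fossils attached at known branches.

#' A synthetic passerine-like scaffold
#'
#' Builds a reproducible rooted scaffold emulating the structure of a
#' passerine phylogenomic backbone: a paraphyletic outgroup series, an
#' optional stem fossil constrained as sister to the crown, and a crown
#' splitting into a species-poor deep branch ("acanthisitti-like") plus two
#' large radiations ("tyranni-like" with eurylaimides/furnariida/tyrannida
#' subclades and "passeri-like" with corvides/passerides etc.). All named
#' clades are registered. Default sizes give 142 backbone tips.
#'
#' @param sizes Named integer vector of subclade sizes (see default).
#' @param seed Integer seed; the topology and branch lengths are a pure
#'   function of it.
#' @param total_length Sum of branch lengths, in expected changes per
#'   character at rate 1.
#' @param stem_fossil Include a constrained stem fossil tip sister to the
#'   crown.
#' @return A [scaffold_tree()] with registered clades.
#' @export
example_scaffold <- function(sizes = NULL, seed = 1L, total_length = 8,
                             stem_fossil = TRUE) {
  if (is.null(sizes))
    sizes <- c(outgroup = 10, acanthisitti = 2, eurylaimides = 12,
               furnariida = 14, tyrannida = 16, menurides = 4,
               climacterides = 6, meliphagides = 12, corvides = 30,
               passerides = 36)
  need <- c("outgroup", "acanthisitti", "eurylaimides", "furnariida",
            "tyrannida", "menurides", "climacterides", "meliphagides",
            "corvides", "passerides")
  stopifnot(all(need %in% names(sizes)), all(sizes[need] >= 1))
  set.seed(seed)
  subnwk <- function(n, prefix) {
    if (n == 1L) return(sprintf("%s1:0.1", prefix))
    tr <- ape::rcoal(n, tip.label = sprintf("%s%d", prefix, seq_len(n)))
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    gsub(";$", "", ape::write.tree(tr))
  }
  tyr <- sprintf("(%s:0.2,(%s:0.15,%s:0.15):0.1)",
                 subnwk(sizes[["eurylaimides"]], "eury"),
                 subnwk(sizes[["furnariida"]], "furn"),
                 subnwk(sizes[["tyrannida"]], "tyda"))
  pas <- sprintf("(%s:0.2,(%s:0.18,(%s:0.15,(%s:0.12,%s:0.12):0.06):0.06):0.06)",
                 subnwk(sizes[["menurides"]], "menu"),
                 subnwk(sizes[["climacterides"]], "clim"),
                 subnwk(sizes[["meliphagides"]], "meli"),
                 subnwk(sizes[["corvides"]], "corv"),
                 subnwk(sizes[["passerides"]], "pass"))
  crown <- sprintf("(%s:0.25,(%s:0.15,%s:0.15):0.1)",
                   subnwk(sizes[["acanthisitti"]], "acan"), tyr, pas)
  nwk <- if (stem_fossil)
    sprintf("(%s:0.3,(stem_fossil:0.25,%s:0.1):0.15);",
            subnwk(sizes[["outgroup"]], "out"), crown)
  else
    sprintf("(%s:0.3,%s:0.2);", subnwk(sizes[["outgroup"]], "out"), crown)
  tree <- read_newick_text(nwk)
  tree$edge.length <- tree$edge.length * total_length /
    sum(tree$edge.length)
  sc <- scaffold_tree(tree,
                      constrained = if (stem_fossil) "stem_fossil"
                                    else character(0))
  tips_of <- function(prefixes) {
    tl <- backbone_tips(sc)
    tl[grepl(paste0("^(", paste(prefixes, collapse = "|"), ")"), tl)]
  }
  reg <- list(
    passeriformes = c("acan", "eury", "furn", "tyda", "menu", "clim",
                      "meli", "corv", "pass"),
    eupasseres = c("eury", "furn", "tyda", "menu", "clim", "meli", "corv",
                   "pass"),
    acanthisitti = "acan",
    tyranni = c("eury", "furn", "tyda"),
    tyrannides = c("furn", "tyda"),
    tyrannida = "tyda",
    furnariida = "furn",
    eurylaimides = "eury",
    passeri = c("menu", "clim", "meli", "corv", "pass"),
    corvides = "corv",
    passerides = "pass",
    meliphagides = "meli",
    climacterides = "clim")
  for (nm in names(reg))
    sc <- register_clade(sc, nm, tips_of(reg[[nm]]), concept = "crown")
  sc
}

#' Simulation configuration
#'
#' The default configuration mirrors the regime of a broad morphological
#' study of a hyper-diverse clade: 5 continuous ratio characters followed by
#' 49 discrete characters with 2-4 states, about 20% of multistate
#' characters ordered, lognormal rate heterogeneity strong enough to make
#' homoplasy common, and sparse missing / inapplicable / polymorphic cells.
#'
#' @param scaffold A [scaffold_tree()]; characters evolve over its full tree
#'   (backbone plus constrained tips).
#' @param n_discrete,n_continuous Character counts.
#' @param state_counts Integer vector (recycled) of discrete state counts.
#' @param ordered_fraction Fraction of multistate characters flagged ordered.
#' @param rate_meanlog,rate_sdlog Lognormal per-character rate distribution
#'   (relative to branch lengths in expected changes at rate 1).
#' @param planted List of `list(clade =, char =, state =)` single-origin
#'   events: the character is held constant at 0 except for one transition
#'   to `state` on the clade's stem branch (its background rate is 0).
#' @param homoplasy_boost Rate multiplier applied to `boost_chars`.
#' @param boost_chars Indices of discrete characters receiving the boost
#'   (default: all non-planted).
#' @param missing_fraction,inapplicable_fraction,polymorphic_fraction
#'   Per-cell corruption probabilities for non-planted characters.
#' @param constrained_missing Extra missingness for constrained fossil tips
#'   (fragmentary stem taxa).
#' @param bm_sigma Brownian-motion standard deviation per unit branch length
#'   for continuous characters.
#' @param seed Integer seed: fixed seed implies byte-identical output.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(scaffold, n_discrete = 49L, n_continuous = 5L,
                              state_counts = c(2L, 2L, 3L, 2L, 4L),
                              ordered_fraction = 0.2,
                              rate_meanlog = log(0.3), rate_sdlog = 0.7,
                              planted = list(), homoplasy_boost = 1,
                              boost_chars = NULL,
                              missing_fraction = 0.05,
                              inapplicable_fraction = 0.01,
                              polymorphic_fraction = 0.02,
                              constrained_missing = 0.7,
                              bm_sigma = 0.05, seed = 1L) {
  stopifnot(inherits(scaffold, "scaffold"))
  fr <- c(ordered_fraction, missing_fraction, inapplicable_fraction,
          polymorphic_fraction, constrained_missing)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  for (p in planted) {
    if (is.null(scaffold$clades[[p$clade]]))
      stop("planted event on unregistered clade '", p$clade, "'")
    if (p$char <= n_continuous || p$char > n_continuous + n_discrete)
      stop("planted char ", p$char, " is not a discrete character")
  }
  structure(list(scaffold = scaffold, n_discrete = as.integer(n_discrete),
                 n_continuous = as.integer(n_continuous),
                 state_counts = as.integer(state_counts),
                 ordered_fraction = ordered_fraction,
                 rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
                 planted = planted, homoplasy_boost = homoplasy_boost,
                 boost_chars = boost_chars,
                 missing_fraction = missing_fraction,
                 inapplicable_fraction = inapplicable_fraction,
                 polymorphic_fraction = polymorphic_fraction,
                 constrained_missing = constrained_missing,
                 bm_sigma = bm_sigma, seed = as.integer(seed)),
            class = "sim_config")
}

# nearest-neighbour stepping-stone rate matrix, uniform stationary
# distribution, scaled to one expected change per unit branch length
ordered_chain_Q <- function(k) {
  Q <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    Q[i, i + 1L] <- 1; Q[i + 1L, i] <- 1
  }
  diag(Q) <- -rowSums(Q)
  Q / mean(-diag(Q))
}

transition_matrix <- function(k, t, ordered) {
  if (t <= 0) return(diag(k))
  if (!ordered) {
    e <- exp(-k * t / (k - 1))
    ps <- 1 / k + (k - 1) / k * e
    pd <- (1 - ps) / (k - 1)
    m <- matrix(pd, k, k); diag(m) <- ps
    m
  } else {
    ape::matexpo(ordered_chain_Q(k) * t)
  }
}

#' Simulate a character matrix on the scaffold
#'
#' Evolves every character along the scaffold tree (backbone plus
#' constrained tips) under its model: symmetric Mk for unordered discrete
#' characters, a nearest-neighbour stepping chain for ordered ones, Brownian
#' motion for continuous ratios, and deterministic single-origin planting for
#' `planted` markers. Missing/inapplicable/polymorphic corruption is applied
#' to non-planted characters only, so planted markers stay clean benchmarks.
#'
#' @param config A [simulation_config()].
#' @return List with `matrix` (a [char_matrix()]), and `truth`: realised
#'   node states per discrete character, continuous node values, the full
#'   change list, per-character rates and ordered flags, and the planted
#'   events.
#' @export
simulate_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sc <- config$scaffold
  tree <- sc$tree
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  elen <- po$edge.length[rev(seq_len(nrow(po$edge)))]

  nC <- config$n_continuous
  nD <- config$n_discrete
  nchar_tot <- nC + nD
  kvec <- rep_len(config$state_counts, nD)
  multistate <- which(kvec >= 3L)
  ordered <- rep(FALSE, nD)
  if (length(multistate))
    ordered[sample(multistate,
                   round(config$ordered_fraction * length(multistate)))] <- TRUE
  rates <- stats::rlnorm(nD, config$rate_meanlog, config$rate_sdlog)
  boost <- config$boost_chars
  planted_chars <- vapply(config$planted,
                          function(p) as.integer(p$char) - nC, integer(1))
  if (is.null(boost)) boost <- setdiff(seq_len(nD), planted_chars)
  rates[boost] <- rates[boost] * config$homoplasy_boost
  rates[planted_chars] <- 0

  node_states <- matrix(0L, ntot, nD)
  changes <- list()
  for (cc in seq_len(nD)) {
    k <- kvec[cc]
    pi_ <- planted_chars == cc
    if (any(pi_)) {
      ev <- config$planted[[which(pi_)[1L]]]
      cl <- get_clade(sc, ev$clade)
      mrca <- mrca_node(tree, cl$tips)
      node_states[, cc] <- 0L
      node_states[which_descendants(tree, mrca), cc] <- as.integer(ev$state)
      stem_par <- node_parent(tree, mrca)
      changes[[length(changes) + 1L]] <-
        data.frame(char = cc + nC, parent_node = stem_par, child_node = mrca,
                   from = 0L, to = as.integer(ev$state))
      next
    }
    # event-based (exact) simulation so the truth record lists every change,
    # including multiple hits on one branch
    Q <- if (ordered[cc]) ordered_chain_Q(k) else {
      q <- matrix(1 / (k - 1), k, k); diag(q) <- -1; q
    }
    st <- integer(ntot)
    st[root] <- sample.int(k, 1L) - 1L
    for (e in seq_len(nrow(pre))) {
      par <- pre[e, 1]; chd <- pre[e, 2]
      s <- st[par]
      remaining <- elen[e] * rates[cc]
      if (remaining > 0) repeat {
        exit <- -Q[s + 1L, s + 1L]
        wait <- rexp(1, exit)
        if (wait >= remaining) break
        remaining <- remaining - wait
        nxt <- sample.int(k, 1L, prob = pmax(Q[s + 1L, ], 0)) - 1L
        changes[[length(changes) + 1L]] <-
          data.frame(char = cc + nC, parent_node = par, child_node = chd,
                     from = s, to = nxt)
        s <- nxt
      }
      st[chd] <- s
    }
    node_states[, cc] <- st
  }
  changes <- if (length(changes)) do.call(rbind, changes) else
    data.frame(char = integer(0), parent_node = integer(0),
               child_node = integer(0), from = integer(0), to = integer(0))

  cont_values <- matrix(0, ntot, nC)
  for (cc in seq_len(nC)) {
    v <- numeric(ntot)
    v[root] <- 1
    for (e in seq_len(nrow(pre)))
      v[pre[e, 2]] <- v[pre[e, 1]] +
        rnorm(1, 0, config$bm_sigma * sqrt(elen[e]))
    cont_values[, cc] <- v
  }

  defs <- c(lapply(seq_len(nC), function(j)
    character_definition(j, kind = "continuous")),
    lapply(seq_len(nD), function(j)
      character_definition(nC + j, kind = "discrete", n_states = kvec[j],
                           ordered = ordered[j])))
  cells <- matrix(vector("list", ntip * nchar_tot), nrow = ntip)
  constrained <- names(sc$tip_status)[sc$tip_status == "constrained_sister"]
  for (i in seq_len(ntip)) {
    extra_miss <- if (tree$tip.label[i] %in% constrained)
      config$constrained_missing else 0
    for (j in seq_len(nchar_tot)) {
      if (j <= nC) cells[[i, j]] <- cont_values[i, j]
      else cells[[i, j]] <- node_states[i, j - nC]
      cc <- j - nC
      if (j > nC && (cc %in% planted_chars)) next
      u <- runif(1)
      if (u < config$missing_fraction + extra_miss) {
        cells[[i, j]] <- MISSING_TOKEN
      } else if (u < config$missing_fraction + extra_miss +
                 config$inapplicable_fraction) {
        cells[[i, j]] <- INAPP_TOKEN
      } else if (j > nC &&
                 u < config$missing_fraction + extra_miss +
                 config$inapplicable_fraction +
                 config$polymorphic_fraction) {
        k <- kvec[cc]
        other <- setdiff(0:(k - 1L), cells[[i, j]])
        cells[[i, j]] <- sort(c(cells[[i, j]],
                                other[sample.int(length(other), 1L)]))
      }
    }
  }
  mat <- char_matrix(tree$tip.label, defs, cells)
  list(matrix = mat,
       truth = list(node_states = node_states, cont_values = cont_values,
                    changes = changes, rates = rates, ordered = ordered,
                    kvec = kvec, planted = config$planted,
                    config = config))
}

which_descendants <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  inside <- rep(FALSE, ntip + tree$Nnode)
  inside[node] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in rev(seq_len(nrow(po))))
    if (inside[po[e, 1]]) inside[po[e, 2]] <- TRUE
  which(inside)
}

#' Simulate a fossil row from a known attachment point
#'
#' Draws the state at a point along a backbone branch from the Markov bridge
#' between the realised endpoint states (Brownian bridge for continuous
#' characters), evolves it down a pendant branch of the given length, and
#' masks a uniformly random fraction of cells as missing. With `pos = 1` and
#' `pendant = 0` the row equals the child node's realised states exactly.
#'
#' @param sim Output of [simulate_matrix()].
#' @param branch Backbone edge index (row of `scaffold$tree$edge`).
#' @param pos Attachment position along the branch, fraction from the parent
#'   end.
#' @param pendant Pendant branch length.
#' @param missing_fraction Fraction of cells masked as missing in `[0, 1]`;
#'   `1` is allowed (an entirely uninformative fossil) and flagged.
#' @param name Fossil taxon name.
#' @return List with `row` (cell list matching the matrix characters),
#'   `name`, `attachment` (branch/pos/pendant) and flag `uninformative`.
#' @export
make_fossil <- function(sim, branch, pos = 0.5, pendant = 0.05,
                        missing_fraction = 0.6, name = "fossil1") {
  stopifnot(missing_fraction >= 0, missing_fraction <= 1)
  cfg <- sim$truth$config
  tree <- cfg$scaffold$tree
  if (branch < 1 || branch > nrow(tree$edge)) stop("no branch ", branch)
  par <- tree$edge[branch, 1]; chd <- tree$edge[branch, 2]
  len <- tree$edge.length[branch]
  nC <- cfg$n_continuous; nD <- cfg$n_discrete
  row <- vector("list", nC + nD)
  for (j in seq_len(nC)) {
    a <- sim$truth$cont_values[par, j]; b <- sim$truth$cont_values[chd, j]
    mu <- a + pos * (b - a)
    v <- pos * (1 - pos) * len * cfg$bm_sigma^2
    x <- rnorm(1, mu, sqrt(v))
    row[[j]] <- x + rnorm(1, 0, cfg$bm_sigma * sqrt(pendant))
  }
  for (cc in seq_len(nD)) {
    k <- sim$truth$kvec[cc]
    rate <- sim$truth$rates[cc]
    ordd <- sim$truth$ordered[cc]
    a <- sim$truth$node_states[par, cc]; b <- sim$truth$node_states[chd, cc]
    P1 <- transition_matrix(k, pos * len * rate, ordd)
    P2 <- transition_matrix(k, (1 - pos) * len * rate, ordd)
    w <- P1[a + 1L, ] * P2[, b + 1L]
    sx <- sample.int(k, 1L, prob = w) - 1L
    Pp <- transition_matrix(k, pendant * rate, ordd)
    row[[nC + cc]] <- sample.int(k, 1L, prob = Pp[sx + 1L, ]) - 1L
  }
  mask <- runif(nC + nD) < missing_fraction
  row[mask] <- list(MISSING_TOKEN)
  list(row = row, name = name,
       attachment = list(branch = branch, pos = pos, pendant = pendant),
       uninformative = missing_fraction >= 1)
}

#' Append fossil rows to a character matrix
#'
#' @param m A [char_matrix()].
#' @param fossils List of [make_fossil()] results.
#' @return A `char_matrix` with the fossil rows appended.
#' @export
add_fossil_rows <- function(m, fossils) {
  if (inherits(fossils, "list") && !is.null(fossils$row))
    fossils <- list(fossils)
  new_cells <- do.call(rbind, lapply(fossils, function(f) {
    stopifnot(length(f$row) == n_char(m))
    matrix(f$row, nrow = 1)
  }))
  nms <- vapply(fossils, `[[`, character(1), "name")
  char_matrix(c(m$taxa, nms), m$definitions, rbind(m$cells, new_cells))
}
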