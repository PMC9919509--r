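# Independent brute-force oracles. These enumerate complete state
# assignments and use ape::matexpo for transition probabilities, sharing no
# code path with the package's dynamic programmes.

# exhaustive parsimony: minimum total cost over all internal-node labelings,
# with tips free to take any state in their allowed set
brute_force_parsimony <- function(tree, sets, k, cost = NULL) {
  if (is.null(cost)) { cost <- matrix(1, k, k); diag(cost) <- 0 }
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  internal <- ntip + seq_len(nnode)
  edges <- tree$edge
  tip_edges <- which(edges[, 2] <= ntip)
  int_edges <- which(edges[, 2] > ntip)

  grid <- as.matrix(expand.grid(rep(list(0:(k - 1L)), nnode)))
  totals <- apply(grid, 1, function(assign) {
    st <- function(v) assign[v - ntip]
    tot <- 0
    for (e in int_edges)
      tot <- tot + cost[st(edges[e, 1]) + 1L, st(edges[e, 2]) + 1L]
    for (e in tip_edges) {
      tip <- edges[e, 2]
      tot <- tot + min(cost[st(edges[e, 1]) + 1L, sets[[tip]] + 1L])
    }
    tot
  })
  steps <- min(totals)

  # MPR set of an internal node: states it takes in at least one optimum
  mpr_internal <- lapply(seq_len(nnode), function(i)
    sort(unique(grid[totals <= steps + 1e-9, i])))
  # MPR set of a tip: allowed states achieving the optimum when pinned
  mpr_tips <- lapply(seq_len(ntip), function(tip) {
    par_e <- which(edges[, 2] == tip)
    ok <- vapply(sets[[tip]], function(s) {
      tot_pinned <- apply(grid, 1, function(assign) {
        st <- function(v) assign[v - ntip]
        tot <- cost[st(edges[par_e, 1]) + 1L, s + 1L]
        for (e in int_edges)
          tot <- tot + cost[st(edges[e, 1]) + 1L, st(edges[e, 2]) + 1L]
        for (e in tip_edges) {
          if (edges[e, 2] == tip) next
          tot <- tot + min(cost[st(edges[e, 1]) + 1L,
                                sets[[edges[e, 2]]] + 1L])
        }
        tot
      })
      min(tot_pinned) <= steps + 1e-9
    }, logical(1))
    sort(sets[[tip]][ok])
  })
  list(steps = steps, node_mpr = c(mpr_tips, mpr_internal))
}

# exhaustive linear parsimony over the grid of observed tip values
brute_force_linear <- function(tree, values) {
  grid <- sort(unique(values[!is.na(values)]))
  if (!length(grid)) return(0)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  edges <- tree$edge
  combos <- as.matrix(expand.grid(rep(list(grid), nnode)))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    val <- function(v) if (v <= ntip) values[v] else combos[r, v - ntip]
    tot <- 0
    for (e in seq_len(nrow(edges))) {
      a <- val(edges[e, 1]); b <- val(edges[e, 2])
      if (!is.na(b)) tot <- tot + abs(a - b)
    }
    best <- min(best, tot)
  }
  best
}

# exhaustive min/max origin counting over all optimal reconstructions
# (origin = branch transition into `state`, plus root origination)
brute_force_origins <- function(tree, sets, k, state, cost = NULL) {
  if (is.null(cost)) { cost <- matrix(1, k, k); diag(cost) <- 0 }
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  edges <- tree$edge
  # enumerate internal AND tip assignments (tips within allowed sets)
  tip_grids <- lapply(seq_len(ntip), function(i) sets[[i]])
  all_grids <- c(tip_grids, rep(list(0:(k - 1L)), nnode))
  grid <- as.matrix(expand.grid(all_grids))
  tot <- apply(grid, 1, function(a) {
    s <- 0
    for (e in seq_len(nrow(edges)))
      s <- s + cost[a[edges[e, 1]] + 1L, a[edges[e, 2]] + 1L]
    s
  })
  steps <- min(tot)
  opt <- grid[tot <= steps + 1e-9, , drop = FALSE]
  orig <- apply(opt, 1, function(a) {
    n <- as.integer(a[ntip + 1L] == state)  # root origination
    for (e in seq_len(nrow(edges)))
      if (a[edges[e, 2]] == state && a[edges[e, 1]] != state) n <- n + 1L
    n
  })
  c(min_origins = min(orig), max_origins = max(orig))
}

# exact Mk transition matrix via matrix exponential (independent of the
# package's closed form)
oracle_pmat <- function(k, t) {
  Q <- matrix(1 / (k - 1), k, k)
  diag(Q) <- -1
  ape::matexpo(Q * t)
}

# likelihood of one character by summation over all internal-node states
brute_force_mk_char <- function(tree, tip_partial, k, rates) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  edges <- tree$edge
  mean(vapply(rates, function(r) {
    P <- lapply(seq_len(nrow(edges)), function(e)
      oracle_pmat(k, tree$edge.length[e] * r))
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      st <- function(v) grid[g, v - ntip]
      p <- 1 / k
      for (e in seq_len(nrow(edges))) {
        a <- st(edges[e, 1]); b <- edges[e, 2]
        if (b <= ntip) p <- p * sum(P[[e]][a, ] * tip_partial[, b])
        else p <- p * P[[e]][a, st(b)]
      }
      tot <- tot + p
    }
    tot
  }, numeric(1)))
}

# full-matrix Mk(v) log likelihood by enumeration
brute_force_mk_loglik <- function(tree, m, alpha, coding = "variable",
                                  ncat = 4L) {
  rates <- morphoscaffold::discrete_gamma_rates(alpha, ncat)
  taxa <- tree$tip.label
  total <- 0
  for (j in seq_len(morphoscaffold::n_char(m))) {
    def <- m$definitions[[j]]
    k <- def$n_states
    tp <- matrix(0, k, length(taxa))
    col <- morphoscaffold::matrix_column(m, j, taxa)
    for (i in seq_along(taxa)) tp[col[[i]] + 1L, i] <- 1
    L <- brute_force_mk_char(tree, tp, k, rates)
    if (coding == "variable") {
      pinv <- sum(vapply(0:(k - 1L), function(s) {
        e_s <- matrix(0, k, length(taxa)); e_s[s + 1L, ] <- 1
        brute_force_mk_char(tree, e_s, k, rates)
      }, numeric(1)))
      L <- L / (1 - pinv)
    }
    total <- total + log(L)
  }
  total
}

# random test-case generators ------------------------------------------------

random_tree <- function(n, polytomy_prob = 0.3) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1.5)
  if (stats::runif(1) < polytomy_prob && n >= 4) {
    tr <- ape::di2multi(tr, tol = stats::quantile(tr$edge.length, 0.25))
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1.5)
  }
  tr
}

random_column <- function(ntip, k, missing_prob = 0.15, poly_prob = 0.1) {
  lapply(seq_len(ntip), function(i) {
    u <- stats::runif(1)
    if (u < missing_prob) return(NULL)
    if (u < missing_prob + poly_prob && k > 1)
      return(sort(sample(0:(k - 1L), 2L)))
    sample(0:(k - 1L), 1L)
  })
}
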