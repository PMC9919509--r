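# Exact parsimony optimisation on a rooted scaffold.
#
# Everything is built on the Sankoff dynamic programme, which is exact under
# arbitrary symmetric step costs and handles hard polytomies without the
# union/intersection special-casing of textbook Fitch. Most-parsimonious
# reconstruction (MPR) state sets come from a down-pass/up-pass pair: a state
# belongs to a node's MPR set iff fixing the node to that state still admits
# a globally minimal reconstruction.

INF <- 1e18

unit_cost <- function(k) {
  m <- matrix(1, k, k); diag(m) <- 0; m
}

ordered_cost <- function(k) abs(outer(0:(k - 1L), 0:(k - 1L), "-"))

check_cost <- function(cost, k) {
  if (!is.matrix(cost) || nrow(cost) != k || ncol(cost) != k)
    stop("cost must be a ", k, " x ", k, " matrix")
  if (any(cost < 0)) stop("negative step cost")
  if (any(diag(cost) != 0)) stop("cost diagonal must be zero")
  if (any(abs(cost - t(cost)) > 1e-12)) stop("cost must be symmetric")
  # triangle inequality: violation is legal but suspicious
  for (i in seq_len(k)) for (j in seq_len(k)) {
    via <- min(cost[i, ] + cost[, j])
    if (cost[i, j] > via + 1e-9) {
      warning("step-cost matrix is non-metric (cost[", i - 1L, ",", j - 1L,
              "] exceeds an indirect path)")
      return(invisible(cost))
    }
  }
  invisible(cost)
}

# A column is a list (one entry per tip, in tree$tip.label order) of 0-based
# integer state sets; a full set means missing/inapplicable.
as_state_sets <- function(column, n_states) {
  lapply(column, function(cell) {
    if (is.null(cell) || (length(cell) == 1L && is.na(cell)))
      return(0:(n_states - 1L))
    cell <- as.integer(cell)
    if (!length(cell)) stop("empty state set in character column")
    if (any(cell < 0L | cell >= n_states)) stop("state code out of range")
    sort(unique(cell))
  })
}

#' Sankoff parsimony optimisation of one discrete character
#'
#' Computes the minimum total step cost of a character on a rooted tree
#' (polytomies allowed) under an arbitrary symmetric step-cost matrix, the
#' full MPR state set at every node, and one deterministic change list.
#' Missing and inapplicable cells enter as the full state set (zero cost to
#' every state) and can never create steps.
#'
#' @param tree Rooted `phylo` tree.
#' @param column List of 0-based integer state sets, one per tip in
#'   `tree$tip.label` order; `NULL`/`NA` entries mean missing.
#' @param n_states Number of states `k`; codes are `0..k-1`.
#' @param cost `k` x `k` symmetric zero-diagonal step-cost matrix; defaults
#'   to unit costs (unordered / Fitch).
#' @param char_id Optional 1-based character number carried into the result.
#' @return An object of class `parsimony_recon` with elements `steps`,
#'   `node_mpr` (list over all nodes, 0-based state codes),
#'   `ambiguous_nodes`, `changes` (a data frame describing one minimal
#'   resolution: parent/child node, from/to state), and the inputs.
#' @export
sankoff_optimise <- function(tree, column, n_states, cost = unit_cost(n_states),
                             char_id = NA_integer_) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  if (length(column) != ntip)
    stop("column length ", length(column), " != ", ntip, " tips")
  if (!length(column)) stop("empty character column")
  k <- as.integer(n_states)
  check_cost(cost, k)
  sets <- as_state_sets(column, k)
  scored <- !vapply(sets, function(s) length(s) == k, logical(1))

  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  n_edge <- nrow(edges)
  ntot <- ntip + tree$Nnode
  root <- ntip + 1L

  S <- matrix(0, ntot, k)
  for (i in seq_len(ntip)) {
    S[i, ] <- INF
    S[i, sets[[i]] + 1L] <- 0
  }
  D <- matrix(0, n_edge, k)  # per-edge child contribution, by parent state
  for (e in seq_len(n_edge)) {
    child <- edges[e, 2]
    for (s in seq_len(k))
      D[e, s] <- min(cost[s, ] + S[child, ])
    S[edges[e, 1], ] <- S[edges[e, 1], ] + D[e, ]
  }
  steps <- min(S[root, ])

  # up-pass: U[v, s] = minimal cost of the rest of the tree when v is fixed
  U <- matrix(0, ntot, k)
  for (e in rev(seq_len(n_edge))) {      # reverse postorder = preorder
    par <- edges[e, 1]; child <- edges[e, 2]
    rest <- U[par, ] + S[par, ] - D[e, ] # parent minus this child's branch
    for (t in seq_len(k))
      U[child, t] <- min(rest + cost[, t])
  }
  total <- S + U
  node_mpr <- lapply(seq_len(ntot), function(v)
    which(total[v, ] <= steps + 1e-9) - 1L)
  ambiguous <- which(lengths(node_mpr) > 1L)

  # one deterministic minimal resolution, preferring no-change transitions
  assign <- integer(ntot)
  assign[root] <- node_mpr[[root]][1L]
  changes <- list()
  for (e in rev(seq_len(n_edge))) {
    par <- edges[e, 1]; child <- edges[e, 2]
    sp <- assign[par] + 1L
    opts <- cost[sp, ] + S[child, ]
    best <- which(opts <= min(opts) + 1e-9)
    pick <- if ((sp) %in% best) sp else best[1L]
    assign[child] <- pick - 1L
    if (assign[child] != assign[par])
      changes[[length(changes) + 1L]] <-
        data.frame(parent_node = par, child_node = child,
                   from = assign[par], to = assign[child])
  }
  changes <- if (length(changes)) do.call(rbind, changes) else
    data.frame(parent_node = integer(0), child_node = integer(0),
               from = integer(0), to = integer(0))

  structure(list(char_id = char_id, steps = steps, node_mpr = node_mpr,
                 ambiguous_nodes = ambiguous, changes = changes,
                 resolution = assign, tree = tree, column = sets,
                 scored = scored, n_states = k, cost = cost,
                 kind = "discrete", origins_cache = new.env(parent = emptyenv())),
            class = "parsimony_recon")
}

#' Fitch (unordered) parsimony optimisation
#'
#' Generalised Fitch optimisation of an unordered discrete character,
#' implemented exactly via [sankoff_optimise()] with unit costs, which is
#' correct on polytomies.
#'
#' @inheritParams sankoff_optimise
#' @return A `parsimony_recon`; see [sankoff_optimise()].
#' @export
fitch_optimise <- function(tree, column, n_states, char_id = NA_integer_) {
  sankoff_optimise(tree, column, n_states, unit_cost(n_states), char_id)
}

#' @export
print.parsimony_recon <- function(x, ...) {
  cat(sprintf("parsimony_recon (char %s, %s): steps = %s, %d ambiguous node(s)\n",
              ifelse(is.na(x$char_id), "?", x$char_id), x$kind,
              format(x$steps), length(x$ambiguous_nodes)))
  invisible(x)
}

#' Linear parsimony for a continuous character
#'
#' Minimum total absolute change of a real-valued character on a rooted tree
#' (Manhattan / linear parsimony), with the optimal value interval at every
#' node. Exact: optima of the piecewise-linear objective are attained on the
#' grid of observed tip values, over which the dynamic programme runs.
#'
#' @param tree Rooted `phylo` tree.
#' @param values Numeric vector, one value per tip in `tree$tip.label` order;
#'   `NA` = missing. Non-finite non-`NA` values are an error.
#' @return A `parsimony_recon` with real `steps` and `node_mpr` holding
#'   `c(lower, upper)` optimal intervals per node.
#' @export
linear_parsimony_continuous <- function(tree, values, char_id = NA_integer_) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  if (length(values) != ntip) stop("values length != number of tips")
  if (any(!is.na(values) & !is.finite(values)))
    stop("non-finite value in continuous character")
  grid <- sort(unique(values[!is.na(values)]))
  ntot <- ntip + tree$Nnode
  root <- ntip + 1L
  if (!length(grid)) {
    iv <- lapply(seq_len(ntot), function(v) c(-Inf, Inf))
    return(structure(list(char_id = char_id, steps = 0, node_mpr = iv,
                          ambiguous_nodes = seq_len(ntot),
                          changes = NULL, tree = tree, values = values,
                          kind = "continuous"),
                     class = "parsimony_recon"))
  }
  G <- length(grid)
  dist <- abs(outer(grid, grid, "-"))
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  f <- matrix(0, ntot, G)
  for (i in seq_len(ntip)) {
    if (is.na(values[i])) next
    f[i, ] <- INF
    f[i, match(values[i], grid)] <- 0
  }
  D <- matrix(0, nrow(edges), G)
  for (e in seq_len(nrow(edges))) {
    child <- edges[e, 2]
    for (x in seq_len(G)) D[e, x] <- min(dist[x, ] + f[child, ])
    f[edges[e, 1], ] <- f[edges[e, 1], ] + D[e, ]
  }
  steps <- min(f[root, ])
  U <- matrix(0, ntot, G)
  for (e in rev(seq_len(nrow(edges)))) {
    par <- edges[e, 1]; child <- edges[e, 2]
    rest <- U[par, ] + f[par, ] - D[e, ]
    for (y in seq_len(G)) U[child, y] <- min(rest + dist[, y])
  }
  total <- f + U
  node_mpr <- lapply(seq_len(ntot), function(v) {
    opt <- grid[total[v, ] <= steps + 1e-9]
    c(min(opt), max(opt))
  })
  ambiguous <- which(vapply(node_mpr, function(iv) iv[2] > iv[1], logical(1)))
  structure(list(char_id = char_id, steps = steps, node_mpr = node_mpr,
                 ambiguous_nodes = ambiguous, changes = NULL, tree = tree,
                 values = values, kind = "continuous"),
            class = "parsimony_recon")
}

# min-plus / max-plus convolution of cost-indexed vectors (index 1 = cost 0)
conv_cost <- function(a, b, cap, op) {
  out <- rep(if (identical(op, max)) -INF else INF, cap + 1L)
  for (c1 in seq_along(a)) {
    if (abs(a[c1]) >= INF) next
    lim <- cap + 2L - c1
    if (lim < 1L) break
    bb <- b[seq_len(min(length(b), lim))]
    idx <- c1 + seq_along(bb) - 1L
    cand <- a[c1] + bb
    out[idx] <- if (identical(op, max)) pmax(out[idx], cand) else
      pmin(out[idx], cand)
  }
  out
}

#' Count independent origins of a state over all MPRs
#'
#' Counts, across every most-parsimonious reconstruction, the number of
#' origins of `state`: branches on which a transition into `state` occurs,
#' plus one if the state is reconstructed at the root (ancestral
#' origination). Returns the minimum and maximum over all MPRs, computed
#' exactly by a cost-and-origin dynamic programme restricted to globally
#' minimal reconstructions.
#'
#' @param recon A discrete `parsimony_recon` from [sankoff_optimise()] or
#'   [fitch_optimise()].
#' @param state 0-based state code.
#' @return `c(min_origins = , max_origins = )`.
#' @export
count_state_origins <- function(recon, state) {
  stopifnot(inherits(recon, "parsimony_recon"), recon$kind == "discrete")
  k <- recon$n_states
  state <- as.integer(state)
  if (state < 0L || state >= k) stop("state ", state, " out of range 0..", k - 1L)
  key <- as.character(state)
  if (!is.null(recon$origins_cache) &&
      !is.null(cached <- recon$origins_cache[[key]])) return(cached)
  tree <- recon$tree
  cost <- recon$cost
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  root <- ntip + 1L
  steps <- as.integer(round(recon$steps))
  if (any(abs(cost - round(cost)) > 1e-9))
    stop("origin counting requires integer step costs")
  cost <- round(cost)
  cap <- steps

  blank_min <- matrix(INF, k, cap + 1L)
  blank_max <- matrix(-INF, k, cap + 1L)
  Tmin <- rep(list(blank_min), ntot)
  Tmax <- rep(list(blank_max), ntot)
  for (i in seq_len(ntip)) {
    for (s in recon$column[[i]]) {
      Tmin[[i]][s + 1L, 1L] <- 0
      Tmax[[i]][s + 1L, 1L] <- 0
    }
  }
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  seen <- rep(FALSE, ntot)
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; child <- edges[e, 2]
    emin <- blank_min; emax <- blank_max
    for (s in seq_len(k)) {
      for (t in seq_len(k)) {
        ec <- cost[s, t]
        if (ec > cap) next
        o <- as.numeric(t == state + 1L && s != state + 1L)
        n_avail <- cap + 1L - ec
        idx <- seq_len(n_avail)
        cand_min <- Tmin[[child]][t, idx] + o
        cand_max <- Tmax[[child]][t, idx] + o
        tgt <- idx + ec
        emin[s, tgt] <- pmin(emin[s, tgt], cand_min)
        emax[s, tgt] <- pmax(emax[s, tgt], cand_max)
      }
    }
    if (!seen[par]) {
      Tmin[[par]] <- emin; Tmax[[par]] <- emax; seen[par] <- TRUE
    } else {
      for (s in seq_len(k)) {
        Tmin[[par]][s, ] <- conv_cost(Tmin[[par]][s, ], emin[s, ], cap, min)
        Tmax[[par]][s, ] <- conv_cost(Tmax[[par]][s, ], emax[s, ], cap, max)
      }
    }
  }
  root_origin <- as.numeric(seq_len(k) == state + 1L)
  feas_min <- Tmin[[root]][, cap + 1L] + root_origin
  feas_max <- Tmax[[root]][, cap + 1L] + root_origin
  feas <- Tmin[[root]][, cap + 1L] < INF / 2
  if (!any(feas)) stop("internal error: no feasible optimal reconstruction")
  out <- c(min_origins = as.integer(min(feas_min[feas])),
           max_origins = as.integer(max(feas_max[feas])))
  if (!is.null(recon$origins_cache)) recon$origins_cache[[key]] <- out
  out
}

#' Consistency and retention indices of a character
#'
#' `ci = m/s` and `ri = (g - s)/(g - m)` where `m` is the minimum conceivable
#' number of steps (observed states minus one for unordered characters;
#' observed range for ordered), `s` the optimised steps, and `g` the steps on
#' a star phylogeny. `ci = 1` iff the character shows no homoplasy; `ri` is
#' `NA` when `g = m` (no room for homoplasy).
#'
#' @param recon A discrete `parsimony_recon`.
#' @return List with `char_id`, `m`, `s`, `g`, `ci`, `ri`.
#' @export
homoplasy_indices <- function(recon) {
  stopifnot(inherits(recon, "parsimony_recon"), recon$kind == "discrete")
  k <- recon$n_states
  sets <- recon$column[recon$scored]
  s <- recon$steps
  if (!length(sets)) {
    return(list(char_id = recon$char_id, m = 0L, s = s, ci = 1, g = 0L,
                ri = NA_real_))
  }
  ordered <- !all(recon$cost[recon$cost > 0] == 1)
  # minimum conceivable steps on any tree; polymorphic cells may be satisfied
  # by any of their states, so m is the smallest hitting set (unordered) or
  # hitting range (ordered) over the scored cells, minus one
  m <- if (ordered) {
    obs <- sort(unique(unlist(sets)))
    best <- max(obs) - min(obs)
    for (a in obs) for (b in obs[obs >= a]) {
      if (all(vapply(sets, function(st) any(st >= a & st <= b), logical(1))))
        best <- min(best, b - a)
    }
    best
  } else {
    obs <- sort(unique(unlist(sets)))
    best <- length(obs) - 1L
    for (size in seq_len(length(obs))) {
      hit <- utils::combn(obs, size, function(ss)
        all(vapply(sets, function(st) any(st %in% ss), logical(1))),
        simplify = TRUE)
      if (any(hit)) { best <- size - 1L; break }
    }
    best
  }
  per_center <- vapply(0:(k - 1L), function(cen) {
    sum(vapply(sets, function(st) min(recon$cost[cen + 1L, st + 1L]),
               numeric(1)))
  }, numeric(1))
  g <- min(per_center)
  ci <- if (s > 0) m / s else 1
  ri <- if (g > m) (g - s) / (g - m) else NA_real_
  list(char_id = recon$char_id, m = m, s = s, g = g, ci = ci, ri = ri)
}

#' Optimise every character of a matrix on the scaffold
#'
#' Runs [fitch_optimise()] / [sankoff_optimise()] (ordered characters use
#' `|i - j|` costs) for each discrete character, and
#' [linear_parsimony_continuous()] for each continuous character, on the
#' diagnosis tree: the scaffold backbone plus any constrained fossil tips;
#' floating fossils are excluded (they are placed, not optimised over).
#'
#' @param m A [char_matrix()].
#' @param scaffold A [scaffold_tree()] (or bare `phylo`).
#' @return Named list of `parsimony_recon`, one per character
#'   (`"char<N>"`).
#' @export
optimise_matrix <- function(m, scaffold) {
  tree <- if (inherits(scaffold, "scaffold")) scaffold$tree else scaffold
  out <- vector("list", n_char(m))
  for (j in seq_len(n_char(m))) {
    def <- m$definitions[[j]]
    if (def$kind == "discrete") {
      col <- matrix_column(m, j, tree$tip.label)
      cost <- if (def$ordered) ordered_cost(def$n_states) else
        unit_cost(def$n_states)
      out[[j]] <- sankoff_optimise(tree, col, def$n_states, cost, def$char_id)
    } else {
      vals <- matrix_column(m, j, tree$tip.label)
      out[[j]] <- linear_parsimony_continuous(tree, vals, def$char_id)
    }
  }
  names(out) <- sprintf("char%d", seq_len(n_char(m)))
  out
}
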