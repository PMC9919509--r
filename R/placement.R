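# Fossil placement on the fixed scaffold.
#
# Two complementary routes: an exhaustive parsimony attachment scan (every
# backbone branch, ranked by added steps), and a backbone-constrained
# Bayesian sampler under Mkv + discrete-gamma in which the only topological
# moves re-attach floating fossils; extant relationships never change.

# ---- grafting machinery ----------------------------------------------------
#
# Attachment state for F floating fossils: parallel vectors
#   host_type: 0 = backbone edge, 1 = another fossil's pendant branch
#   host_id:   backbone edge index, or fossil index
#   pos:       attachment point as a fraction (0,1) along the host branch,
#              measured from its parent end
#   pendant:   pendant branch length (> 0)
#
# Grafted node numbering is deterministic: backbone tips keep their indices,
# fossil f becomes tip nb + f, backbone internal node v becomes v + F, and
# the attachment node of fossil f is nb + F + nbnode + f.

new_attachment <- function(host_type, host_id, pos, pendant) {
  list(host_type = as.integer(host_type), host_id = as.integer(host_id),
       pos = as.numeric(pos), pendant = as.numeric(pendant))
}

graft_ctx <- function(backbone, F_) {
  nb <- ape::Ntip(backbone)
  nbnode <- backbone$Nnode
  medge <- backbone$edge
  medge[medge > nb] <- medge[medge > nb] + F_
  list(backbone = backbone, E = nrow(backbone$edge), nb = nb,
       nbnode = nbnode, F_ = as.integer(F_), medge = medge,
       attach_node = nb + F_ + nbnode + seq_len(F_),
       ntip = nb + F_, nnode = nbnode + F_)
}

fossil_dependency_order <- function(att, F_) {
  done <- att$host_type == 0L
  ord <- integer(0)
  repeat {
    ready <- setdiff(which(done), ord)
    if (!length(ready)) break
    ord <- c(ord, ready)
    done[att$host_type == 1L & att$host_id %in% ready] <- TRUE
  }
  if (length(ord) != F_) stop("cyclic fossil attachment")
  ord
}

graft_edges <- function(ctx, bl, att) {
  E <- ctx$E; F_ <- ctx$F_
  M <- E + 2L * F_
  edge <- matrix(0L, M, 2)
  edge[seq_len(E), ] <- ctx$medge
  elen <- numeric(M)
  elen[seq_len(E)] <- bl
  nxt <- E
  an <- ctx$attach_node
  # fossils hosted on backbone edges: subdivide those rows
  ef <- which(att$host_type == 0L)
  for (h in unique(att$host_id[ef])) {
    fs <- ef[att$host_id[ef] == h]
    if (length(fs) > 1L) fs <- fs[order(att$pos[fs])]
    L <- bl[h]
    prev <- ctx$medge[h, 1]; pp <- 0
    for (f in fs) {
      nxt <- nxt + 1L
      edge[nxt, 1] <- prev; edge[nxt, 2] <- an[f]
      elen[nxt] <- (att$pos[f] - pp) * L
      prev <- an[f]; pp <- att$pos[f]
    }
    edge[h, 1] <- prev
    elen[h] <- (1 - pp) * L
  }
  # pendants (possibly subdivided by guest fossils), in dependency order
  ord <- if (any(att$host_type == 1L)) fossil_dependency_order(att, F_)
         else seq_len(F_)
  for (f in ord) {
    guests <- which(att$host_type == 1L & att$host_id == f)
    if (length(guests) > 1L) guests <- guests[order(att$pos[guests])]
    L <- att$pendant[f]
    prev <- an[f]; pp <- 0
    for (g in guests) {
      nxt <- nxt + 1L
      edge[nxt, 1] <- prev; edge[nxt, 2] <- an[g]
      elen[nxt] <- (att$pos[g] - pp) * L
      prev <- an[g]; pp <- att$pos[g]
    }
    nxt <- nxt + 1L
    edge[nxt, 1] <- prev; edge[nxt, 2] <- ctx$nb + f
    elen[nxt] <- (1 - pp) * L
  }
  list(edge = edge, elen = elen, ntip = ctx$ntip, nnode = ctx$nnode)
}

graft_phylo <- function(ctx, bl, att, fossil_names) {
  g <- graft_edges(ctx, bl, att)
  tr <- list(edge = g$edge, edge.length = g$elen, Nnode = g$nnode,
             tip.label = c(ctx$backbone$tip.label, fossil_names))
  class(tr) <- "phylo"
  tr
}

# backbone edge index reached by following a fossil's host chain
base_edge <- function(att, f) {
  while (att$host_type[f] == 1L) f <- att$host_id[f]
  att$host_id[f]
}

# per-clade edge classification on the backbone: edges inside the crown
# subtree, and the stem edge
clade_edge_sets <- function(backbone, tips) {
  crown <- mrca_node(backbone, tips)
  inside <- rep(FALSE, ape::Ntip(backbone) + backbone$Nnode)
  inside[crown] <- TRUE
  po <- ape::reorder.phylo(backbone, "postorder")$edge
  for (e in rev(seq_len(nrow(po))))
    if (inside[po[e, 1]]) inside[po[e, 2]] <- TRUE
  within <- which(inside[backbone$edge[, 1]])
  stem <- which(backbone$edge[, 2] == crown)
  list(within = within, stem = if (length(stem)) stem else NA_integer_)
}

# ---- parsimony attachment scan ---------------------------------------------

#' Exhaustive parsimony attachment scan for one fossil
#'
#' Attaches the fossil to every backbone branch in turn, re-optimises every
#' discrete character, and reports the parsimony steps added relative to the
#' backbone alone, ranked ascending (ties broken by the branch's postorder
#' index, so the ranking is deterministic). A fast diagnostic complement to
#' the Bayesian placement.
#'
#' @param fossil Fossil taxon name; its row is taken from `m` (taxa absent
#'   from the matrix are all-missing).
#' @param scaffold A [scaffold_tree()].
#' @param m A [char_matrix()].
#' @return Data frame with `branch` (backbone edge index), `child` (label of
#'   the node below the branch), `added_steps`, sorted best first; attribute
#'   `uninformative` is `TRUE` when the fossil row is all-missing.
#' @export
attach_parsimony_scan <- function(fossil, scaffold, m) {
  backbone <- scaffold$tree
  E <- nrow(backbone$edge)
  chars <- discrete_char_ids(m)
  cost_of <- function(def) if (def$ordered) ordered_cost(def$n_states) else
    unit_cost(def$n_states)
  base <- sum(vapply(chars, function(j) {
    def <- m$definitions[[j]]
    sankoff_optimise(backbone, matrix_column(m, j, backbone$tip.label),
                     def$n_states, cost_of(def))$steps
  }, numeric(1)))
  fi <- match(fossil, m$taxa)
  uninformative <- is.na(fi) || all(vapply(chars, function(j)
    is_blank_cell(m$cells[[fi, j]]), logical(1)))
  ctx <- graft_ctx(backbone, 1L)
  bl <- rep(1, E)
  added <- vapply(seq_len(E), function(e) {
    att <- new_attachment(0L, e, 0.5, 1)
    tr <- graft_phylo(ctx, bl, att, fossil)
    tot <- sum(vapply(chars, function(j) {
      def <- m$definitions[[j]]
      sankoff_optimise(tr, matrix_column(m, j, tr$tip.label),
                       def$n_states, cost_of(def))$steps
    }, numeric(1)))
    tot - base
  }, numeric(1))
  post_children <- ape::reorder.phylo(backbone, "postorder")$edge[, 2]
  post_idx <- match(backbone$edge[, 2], post_children)
  child_lab <- ifelse(backbone$edge[, 2] <= ape::Ntip(backbone),
                      backbone$tip.label[backbone$edge[, 2]],
                      sprintf("node%d", backbone$edge[, 2]))
  out <- data.frame(branch = seq_len(E), child = child_lab,
                    added_steps = added)
  out <- out[order(out$added_steps, post_idx), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "uninformative") <- uninformative
  out
}

# ---- MCMC ------------------------------------------------------------------

log_prior <- function(bl, pend, alpha, cfg) {
  sum(dexp(bl, cfg$branch_length_prior_rate, log = TRUE)) +
    sum(dexp(pend, cfg$branch_length_prior_rate, log = TRUE)) +
    dexp(alpha, cfg$shape_prior_rate, log = TRUE)
}

state_loglik <- function(ctx, bl, att, parts, kvec, rates, variable) {
  g <- graft_edges(ctx, bl, att)
  mk_loglik_cpp(g$edge, g$elen, g$ntip, g$nnode, parts, kvec, rates,
                variable)$total
}

# would attaching fossil f to fossil `host`'s pendant create a cycle?
creates_cycle <- function(att, f, host) {
  g <- host
  repeat {
    if (g == f) return(TRUE)
    if (att$host_type[g] != 1L) return(FALSE)
    g <- att$host_id[g]
  }
}

#' Backbone-constrained Bayesian fossil placement
#'
#' Metropolis-coupled MCMC under the Mkv + discrete-gamma model in which
#' extant relationships are hard-constrained to the scaffold: moves
#' re-attach one floating fossil to a uniformly chosen backbone branch or
#' other fossil's pendant branch, slide an attachment point, rescale a branch
#' length, or rescale the gamma shape. Chain `j` of each run is heated with
#' power `1/(1 + T (j - 1))`; adjacent chains propose swaps each generation
#' and only the cold chain is sampled. Post-burn-in samples of all runs are
#' pooled. Fully reproducible from `config$seed`.
#'
#' @param m A [char_matrix()]; continuous characters are excluded from the
#'   likelihood automatically.
#' @param scaffold A [scaffold_tree()] with at least one floating fossil; all
#'   floating fossils are placed jointly.
#' @param config An [mk_model_config()].
#' @return An object of class `placement_samples`: post-burn-in samples
#'   (attachments, alpha, log likelihood), per-run diagnostics including the
#'   between-run average deviation of attachment frequencies, and the inputs
#'   needed by [summarise_placement()].
#' @export
run_mcmc <- function(m, scaffold, config = mk_model_config()) {
  stopifnot(inherits(scaffold, "scaffold"), inherits(config, "mk_config"))
  fossils <- names(scaffold$tip_status)[scaffold$tip_status == "floating"]
  if (!length(fossils)) stop("no floating fossils to place")
  backbone <- scaffold$tree
  md <- matrix_discrete(m)
  all_tips <- c(backbone$tip.label, fossils)
  parts <- discrete_partials(md, all_tips)
  kvec <- vapply(md$definitions, `[[`, integer(1), "n_states")
  E <- nrow(backbone$edge)
  F_ <- length(fossils)
  ctx <- graft_ctx(backbone, F_)
  n_hosts <- E + F_ - 1L  # eligible hosts for any one fossil
  betas <- 1 / (1 + config$heat_temperature *
                  (seq_len(config$chains_per_run) - 1L))
  variable <- config$coding == "variable"
  ncat <- config$n_rate_categories

  set.seed(config$seed)
  samples <- list()
  run_attach_freq <- list()
  for (run in seq_len(config$runs)) {
    chains <- lapply(seq_len(config$chains_per_run), function(ch) {
      bl <- if (!is.null(backbone$edge.length) &&
                all(backbone$edge.length > 0)) backbone$edge.length
            else rexp(E, config$branch_length_prior_rate)
      att <- new_attachment(rep(0L, F_), sample.int(E, F_, replace = TRUE),
                            runif(F_),
                            rexp(F_, config$branch_length_prior_rate))
      alpha <- 1
      rates <- discrete_gamma_rates(alpha, ncat)
      lnL <- state_loglik(ctx, bl, att, parts, kvec, rates, variable)
      list(bl = bl, att = att, alpha = alpha, rates = rates, lnL = lnL,
           lnP = lnL + log_prior(bl, att$pendant, alpha, config))
    })
    run_samples <- list()
    for (gen in seq_len(config$generations)) {
      for (ci in seq_along(chains)) {
        st <- chains[[ci]]
        u_move <- runif(1)
        new <- st
        logH <- 0
        ok <- TRUE
        if (u_move < 0.45) {                      # re-attach a fossil
          f <- if (F_ > 1L) sample.int(F_, 1L) else 1L
          host <- sample.int(n_hosts, 1L)
          if (host <= E) {
            new$att$host_type[f] <- 0L; new$att$host_id[f] <- host
          } else {
            tgt <- setdiff(seq_len(F_), f)[host - E]
            if (creates_cycle(st$att, f, tgt)) ok <- FALSE
            new$att$host_type[f] <- 1L; new$att$host_id[f] <- tgt
          }
          new$att$pos[f] <- runif(1)
        } else if (u_move < 0.75) {               # branch-length multiplier
          i <- sample.int(E + F_, 1L)
          mult <- exp(1.4 * (runif(1) - 0.5))
          if (i <= E) new$bl[i] <- st$bl[i] * mult
          else new$att$pendant[i - E] <- st$att$pendant[i - E] * mult
          logH <- log(mult)
        } else if (u_move < 0.9) {                # alpha multiplier
          mult <- exp(1.4 * (runif(1) - 0.5))
          new$alpha <- st$alpha * mult
          new$rates <- discrete_gamma_rates(new$alpha, ncat)
          logH <- log(mult)
        } else {                                  # slide attachment point
          f <- if (F_ > 1L) sample.int(F_, 1L) else 1L
          new$att$pos[f] <- runif(1)
        }
        if (ok) {
          new$lnL <- state_loglik(ctx, new$bl, new$att, parts, kvec,
                                  new$rates, variable)
          new$lnP <- new$lnL + log_prior(new$bl, new$att$pendant, new$alpha,
                                         config)
          if (log(runif(1)) < betas[ci] * (new$lnP - st$lnP) + logH)
            chains[[ci]] <- new
        }
      }
      if (length(chains) > 1L) {
        i <- sample.int(length(chains) - 1L, 1L)
        dj <- (betas[i] - betas[i + 1L]) *
          (chains[[i + 1L]]$lnP - chains[[i]]$lnP)
        if (log(runif(1)) < dj) {
          tmp <- chains[[i]]; chains[[i]] <- chains[[i + 1L]]
          chains[[i + 1L]] <- tmp
        }
      }
      if (gen %% config$sample_every == 0L) {
        cold <- chains[[1L]]
        run_samples[[length(run_samples) + 1L]] <-
          list(run = run, gen = gen, alpha = cold$alpha, lnL = cold$lnL,
               lnP = cold$lnP, att = cold$att)
      }
    }
    nb_ <- floor(config$burnin_fraction * length(run_samples))
    kept <- run_samples[seq_along(run_samples) > nb_]
    samples <- c(samples, kept)
    freq <- matrix(0, F_, E)
    for (s in kept) for (f in seq_len(F_))
      freq[f, base_edge(s$att, f)] <- freq[f, base_edge(s$att, f)] + 1
    run_attach_freq[[run]] <- freq / max(1, length(kept))
  }
  # ASDSF-style diagnostic: average between-run SD of attachment
  # frequencies, over (fossil, branch) cells supported in at least one run
  asd <- if (config$runs > 1L) {
    devs <- numeric(0)
    for (f in seq_len(F_)) {
      fr <- sapply(run_attach_freq, function(x) x[f, ])
      keep <- apply(fr, 1, max) > 0.1
      if (any(keep)) devs <- c(devs, apply(fr[keep, , drop = FALSE], 1,
                                           stats::sd))
    }
    if (length(devs)) mean(devs) else 0
  } else NA_real_
  structure(list(samples = samples, config = config, fossils = fossils,
                 backbone = backbone, scaffold = scaffold, ctx = ctx,
                 attach_freq_by_run = run_attach_freq,
                 attach_freq_sd = asd),
            class = "placement_samples")
}

#' @export
print.placement_samples <- function(x, ...) {
  cat(sprintf("placement_samples: %d pooled samples, %d fossil(s), %d run(s)\n",
              length(x$samples), length(x$fossils), x$config$runs))
  if (!is.na(x$attach_freq_sd))
    cat(sprintf("  mean between-run attachment-frequency SD: %.4f\n",
                x$attach_freq_sd))
  invisible(x)
}

# ---- summaries -------------------------------------------------------------

#' Summarise fossil placement samples
#'
#' Computes, per fossil, the posterior frequency of each backbone attachment
#' branch and the crown and total-clade membership posterior probability
#' (BPP) for every registered clade, plus the 50% majority-rule consensus of
#' the sampled trees (exactly the splits with frequency above one half, with
#' supports annotated). Optional fossil `groups` yield joint membership
#' probabilities (every fossil of the group inside the clade in the same
#' sample).
#'
#' @param ps A `placement_samples` object from [run_mcmc()].
#' @param clades Clade names to evaluate (default: all registered).
#' @param groups Optional named list of fossil-name vectors.
#' @return An object of class `placement_summary` with elements
#'   `branch_posterior`, `clade_bpp`, `group_bpp` and `consensus`.
#' @export
summarise_placement <- function(ps, clades = names(ps$scaffold$clades),
                                groups = NULL) {
  stopifnot(inherits(ps, "placement_samples"))
  if (!length(ps$samples)) stop("no post-burn-in samples to summarise")
  backbone <- ps$backbone
  F_ <- length(ps$fossils)
  nS <- length(ps$samples)
  E <- nrow(backbone$edge)

  base_edges <- matrix(0L, nS, F_)
  for (s in seq_len(nS)) for (f in seq_len(F_))
    base_edges[s, f] <- base_edge(ps$samples[[s]]$att, f)

  child_lab <- ifelse(backbone$edge[, 2] <= ape::Ntip(backbone),
                      backbone$tip.label[backbone$edge[, 2]],
                      sprintf("node%d", backbone$edge[, 2]))
  branch_posterior <- lapply(seq_len(F_), function(f) {
    tab <- tabulate(base_edges[, f], nbins = E) / nS
    data.frame(branch = seq_len(E), child = child_lab, freq = tab)
  })
  names(branch_posterior) <- ps$fossils

  sets <- lapply(clades, function(cl)
    clade_edge_sets(backbone, get_clade(ps$scaffold, cl)$tips))
  names(sets) <- clades
  crown_mem <- function(f, cl) base_edges[, f] %in% sets[[cl]]$within
  total_mem <- function(f, cl) crown_mem(f, cl) |
    (!is.na(sets[[cl]]$stem) & base_edges[, f] == sets[[cl]]$stem)

  rows <- list()
  for (f in seq_len(F_)) for (cl in clades)
    rows[[length(rows) + 1L]] <- data.frame(
      fossil = ps$fossils[f], clade = cl,
      crown_bpp = mean(crown_mem(f, cl)),
      total_bpp = mean(total_mem(f, cl)), stringsAsFactors = FALSE)
  clade_bpp <- do.call(rbind, rows)

  group_bpp <- NULL
  if (!is.null(groups)) {
    grows <- list()
    for (g in names(groups)) {
      fi <- match(groups[[g]], ps$fossils)
      if (anyNA(fi)) stop("unknown fossil in group '", g, "'")
      for (cl in clades) {
        cm <- Reduce(`&`, lapply(fi, crown_mem, cl = cl))
        tm <- Reduce(`&`, lapply(fi, total_mem, cl = cl))
        grows[[length(grows) + 1L]] <- data.frame(
          group = g, clade = cl, crown_bpp = mean(cm), total_bpp = mean(tm),
          stringsAsFactors = FALSE)
      }
    }
    group_bpp <- do.call(rbind, grows)
  }

  trees <- lapply(ps$samples, function(s)
    graft_phylo(ps$ctx, rep(1, E), s$att, ps$fossils))
  class(trees) <- "multiPhylo"
  consensus <- ape::consensus(trees, p = 0.5)
  pp <- ape::prop.clades(consensus, trees, rooted = TRUE)
  consensus$node.label <- format(round(pp / nS, 3))

  structure(list(branch_posterior = branch_posterior, clade_bpp = clade_bpp,
                 group_bpp = group_bpp, consensus = consensus,
                 n_samples = nS, fossils = ps$fossils),
            class = "placement_summary")
}

#' @export
print.placement_summary <- function(x, ...) {
  cat(sprintf("placement_summary over %d samples\n", x$n_samples))
  print(x$clade_bpp)
  invisible(x)
}

#' @export
as.data.frame.placement_summary <- function(x, ...) x$clade_bpp
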