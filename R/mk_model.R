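# R-side interface to the Mkv likelihood and the analysis configuration.

#' Discrete-gamma rate categories (category means)
#'
#' Equal-probability discretisation of a Gamma(shape = alpha, rate = alpha)
#' distribution (mean 1) into `ncat` categories, each represented by its
#' conditional mean.
#'
#' @param alpha Gamma shape (> 0).
#' @param ncat Number of categories (default 4).
#' @return Numeric vector of `ncat` relative rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, ncat = 4L) {
  if (alpha <= 0) stop("alpha must be > 0")
  q <- qgamma(seq(0, 1, length.out = ncat + 1L), shape = alpha, rate = alpha)
  p <- pgamma(q, shape = alpha + 1, rate = alpha)
  ncat * diff(p)
}

# per-character tip partial matrices (k x ntaxa): ones at observed states,
# all ones for missing/inapplicable, ones at each observed state when
# polymorphic
discrete_partials <- function(m, taxa, char_ids = discrete_char_ids(m)) {
  lapply(char_ids, function(j) {
    def <- m$definitions[[j]]
    k <- def$n_states
    out <- matrix(0, k, length(taxa))
    idx <- match(taxa, m$taxa)
    for (i in seq_along(taxa)) {
      if (is.na(idx[i])) { out[, i] <- 1; next }
      cell <- m$cells[[idx[i], j]]
      if (is_blank_cell(cell)) out[, i] <- 1
      else out[cell + 1L, i] <- 1
    }
    out
  })
}

#' Mk(v) log likelihood of a discrete character matrix on a tree
#'
#' Felsenstein-pruning log likelihood under the k-state symmetric Mk model
#' with four-category (by default) discrete-gamma rate variation, each
#' character using its own state count, branch lengths in expected changes
#' per character. Under `coding = "variable"` (the Mkv model) each
#' character's likelihood is conditioned on the character being variable,
#' correcting for the ascertainment bias of morphological matrices that
#' exclude constant characters. Continuous characters must be excluded by the
#' caller ([matrix_discrete()] helps).
#'
#' @param tree Rooted `phylo` with strictly positive branch lengths.
#' @param m A [char_matrix()] containing only discrete characters.
#' @param alpha Gamma shape for among-character rate variation (> 0).
#' @param coding `"variable"` (Mkv) or `"all"` (no correction).
#' @param ncat Number of gamma categories.
#' @return Log likelihood (numeric scalar) with attribute `per_char`.
#' @export
mk_log_likelihood <- function(tree, m, alpha, coding = c("variable", "all"),
                              ncat = 4L) {
  coding <- match.arg(coding)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length <= 0)) stop("zero or negative branch length")
  if (alpha <= 0) stop("alpha must be > 0")
  if (length(continuous_char_ids(m)))
    stop("matrix contains continuous characters; use matrix_discrete() first")
  taxa <- tree$tip.label
  parts <- discrete_partials(m, taxa)
  kvec <- vapply(m$definitions, `[[`, integer(1), "n_states")
  rates <- discrete_gamma_rates(alpha, ncat)
  res <- mk_loglik_cpp(tree$edge, tree$edge.length, ape::Ntip(tree),
                       tree$Nnode, parts, kvec, rates,
                       coding == "variable")
  structure(res$total, per_char = res$per_char, log_pinv = res$log_pinv)
}

#' Restrict a matrix to its discrete characters
#'
#' Drops continuous characters (e.g. ratio characters 1-5 of a mixed matrix)
#' and renumbers the remainder contiguously, keeping the original numbers as
#' labels.
#'
#' @param m A [char_matrix()].
#' @return A `char_matrix` of the discrete characters only.
#' @export
matrix_discrete <- function(m) {
  keep <- discrete_char_ids(m)
  defs <- lapply(seq_along(keep), function(i) {
    d <- m$definitions[[keep[i]]]
    character_definition(i, label = d$label, kind = "discrete",
                         n_states = d$n_states, ordered = d$ordered,
                         state_labels = d$state_labels)
  })
  char_matrix(m$taxa, defs, m$cells[, keep, drop = FALSE])
}

#' Configuration for backbone-constrained Bayesian placement
#'
#' Defaults mirror a standard morphological MrBayes setup: Mkv likelihood
#' with four gamma rate categories, two runs of four Metropolis-coupled
#' chains with incremental-heating temperature 0.1, samples every 4000
#' generations, 25% burn-in. Priors the model needs but that such setups
#' leave implicit are explicit (and configurable) here: exponential(10)
#' branch and pendant lengths, exponential(1) gamma shape, uniform fossil
#' attachment over eligible branches.
#'
#' @param generations Chain length per run.
#' @param sample_every Thinning interval.
#' @param runs,chains_per_run Independent runs and coupled chains per run.
#' @param heat_temperature Incremental heating temperature (> 0); chain `j`
#'   has power `1/(1 + heat_temperature * (j - 1))`.
#' @param burnin_fraction Fraction of samples discarded per run (0, 1).
#' @param coding `"variable"` (Mkv) or `"all"`.
#' @param n_rate_categories Gamma categories.
#' @param branch_length_prior_rate Rate of the exponential prior on branch
#'   and pendant lengths.
#' @param shape_prior_rate Rate of the exponential prior on the gamma shape.
#' @param seed Integer seed; fixes the entire sampler stream.
#' @return A list of class `mk_config`.
#' @export
mk_model_config <- function(generations = 30e6, sample_every = 4000,
                            runs = 2L, chains_per_run = 4L,
                            heat_temperature = 0.1, burnin_fraction = 0.25,
                            coding = c("variable", "all"),
                            n_rate_categories = 4L,
                            branch_length_prior_rate = 10,
                            shape_prior_rate = 1, seed = 1L) {
  coding <- match.arg(coding)
  if (generations < 1) stop("generations must be positive")
  if (generations < sample_every) stop("generations must be >= sample_every")
  if (burnin_fraction <= 0 || burnin_fraction >= 1)
    stop("burnin_fraction must be in (0, 1)")
  if (heat_temperature <= 0) stop("heat_temperature must be > 0")
  structure(list(generations = as.integer(generations),
                 sample_every = as.integer(sample_every),
                 runs = as.integer(runs),
                 chains_per_run = as.integer(chains_per_run),
                 heat_temperature = heat_temperature,
                 burnin_fraction = burnin_fraction, coding = coding,
                 n_rate_categories = as.integer(n_rate_categories),
                 branch_length_prior_rate = branch_length_prior_rate,
                 shape_prior_rate = shape_prior_rate,
                 seed = as.integer(seed)),
            class = "mk_config")
}
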