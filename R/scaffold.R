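# The fixed molecular scaffold: a rooted backbone of extant taxa, optional
# fossils constrained into the tree, floating fossils awaiting placement, and
# a registry of named clades defined as tip sets.

#' Build a scaffold tree
#'
#' The scaffold is a rooted tree whose extant ("backbone") relationships are
#' treated as fixed throughout all analyses: character optimisation maps
#' states onto it and Bayesian placement never alters it. Fossils are either
#' `constrained` (present in the tree at a fixed position, like a stem taxon
#' constrained as sister to the crown group) or `floating` (absent from the
#' tree until placed by [run_mcmc()]).
#'
#' @param tree A rooted `phylo` tree containing all backbone and constrained
#'   tips. Rooting is taken as given (root on the outgroup), never inferred.
#' @param constrained Character vector of tip names in `tree` that are
#'   fossils fixed at their position.
#' @param floating Character vector of fossil names not present in `tree`.
#' @return An object of class `scaffold`, with a clade registry filled by
#'   [register_clade()].
#' @export
scaffold_tree <- function(tree, constrained = character(0),
                          floating = character(0)) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("scaffold tree must be rooted")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label in scaffold tree")
  missing_c <- setdiff(constrained, tree$tip.label)
  if (length(missing_c))
    stop("constrained tip not in tree: ", missing_c[1L])
  overlap <- intersect(floating, tree$tip.label)
  if (length(overlap))
    stop("floating fossil '", overlap[1L], "' must not appear in the tree")
  status <- setNames(rep("backbone", ape::Ntip(tree)), tree$tip.label)
  status[constrained] <- "constrained_sister"
  status <- c(status, setNames(rep("floating", length(floating)), floating))
  structure(list(tree = tree, tip_status = status, clades = list()),
            class = "scaffold")
}

#' @export
print.scaffold <- function(x, ...) {
  cat(sprintf("scaffold: %d backbone tips, %d constrained, %d floating, %d clades\n",
              sum(x$tip_status == "backbone"),
              sum(x$tip_status == "constrained_sister"),
              sum(x$tip_status == "floating"), length(x$clades)))
  invisible(x)
}

backbone_tips <- function(scaffold) {
  names(scaffold$tip_status)[scaffold$tip_status == "backbone"]
}

#' Register a named clade on the scaffold
#'
#' A clade is a named set of backbone tips (e.g. the sampled members of
#' Passeri or Tyranni) with a `concept`: `"crown"` (least inclusive clade of
#' the listed tips) or `"total"` (crown plus its stem lineage). Crown tip
#' sets must be monophyletic among backbone taxa on the scaffold.
#'
#' @param scaffold A [scaffold_tree()] object.
#' @param name Unique clade name.
#' @param tips Character vector of backbone tip names.
#' @param concept `"crown"` or `"total"`.
#' @return The updated `scaffold`.
#' @export
register_clade <- function(scaffold, name, tips, concept = c("crown", "total")) {
  stopifnot(inherits(scaffold, "scaffold"))
  concept <- match.arg(concept)
  if (name %in% names(scaffold$clades)) stop("clade '", name, "' already registered")
  bad <- setdiff(tips, backbone_tips(scaffold))
  if (length(bad)) stop("clade '", name, "' tip not on backbone: ", bad[1L])
  node <- mrca_node(scaffold$tree, tips)
  desc <- intersect(tips_below(scaffold$tree, node), backbone_tips(scaffold))
  if (!setequal(desc, tips))
    stop("clade '", name, "' is not monophyletic on the backbone (MRCA also ",
         "subtends ", setdiff(desc, tips)[1L], ")")
  scaffold$clades[[name]] <- list(name = name, tips = sort(tips),
                                  concept = concept)
  scaffold
}

#' Look up a registered clade
#' @param scaffold A `scaffold`.
#' @param name Clade name.
#' @return The clade definition (name, tips, concept).
#' @export
get_clade <- function(scaffold, name) {
  cl <- scaffold$clades[[name]]
  if (is.null(cl)) stop("clade '", name, "' not registered")
  cl
}

#' Most recent common ancestor of a tip set
#'
#' @param tree A `phylo` tree (or a `scaffold`).
#' @param tips Character vector of tip names; a single tip returns that tip's
#'   own node.
#' @return Integer node id (ape numbering).
#' @export
mrca_node <- function(tree, tips) {
  if (inherits(tree, "scaffold")) tree <- tree$tree
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("tip not in tree: ", tips[is.na(idx)][1L])
  if (length(idx) == 0L) stop("empty tip set")
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

tips_below <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  # iterative descent; handles polytomies
  stack <- node
  out <- integer(0)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v <= ntip) out <- c(out, v)
    else stack <- c(stack, children[[as.character(v)]])
  }
  tree$tip.label[out]
}

node_parent <- function(tree, node) {
  e <- tree$edge[, 1][tree$edge[, 2] == node]
  if (!length(e)) NA_integer_ else e[1L]
}

root_node <- function(tree) ape::Ntip(tree) + 1L

#' Sister node(s) of a node
#'
#' Returns the other child of the node's parent. When the parent is a
#' polytomy there is no unique sister: all co-children are returned and the
#' result carries attribute `ambiguous = TRUE`; callers evaluating
#' sister-based criteria must then handle every co-child.
#'
#' @param tree A `phylo` tree (or `scaffold`).
#' @param node Integer node id; must not be the root.
#' @return Integer vector of node ids (length 1 when the parent bifurcates),
#'   with attribute `ambiguous`.
#' @export
sister_node <- function(tree, node) {
  if (inherits(tree, "scaffold")) tree <- tree$tree
  if (node == root_node(tree)) stop("the root has no sister")
  par <- node_parent(tree, node)
  if (is.na(par)) stop("node ", node, " not found in tree")
  sibs <- tree$edge[tree$edge[, 1] == par, 2]
  sibs <- sibs[sibs != node]
  attr(sibs, "ambiguous") <- length(sibs) > 1L
  sibs
}

#' Crown and total clade membership of a placed fossil
#'
#' Given a tree in which the fossil has been attached, decides whether the
#' fossil lies within the clade's crown group (inside the least inclusive
#' clade of the registered tips) and within its total clade (crown plus stem:
#' the smallest clade containing the fossil and the clade tips contains no
#' other extant taxa). Attachment to the stem branch therefore yields
#' `crown = FALSE, total = TRUE`.
#'
#' @param fossil_tip Fossil tip label present in `placed_tree`.
#' @param placed_tree A `phylo` tree containing the fossil.
#' @param scaffold The `scaffold` whose clade registry defines the clade.
#' @param clade Registered clade name.
#' @return `list(crown = logical, total = logical)`.
#' @export
membership <- function(fossil_tip, placed_tree, scaffold, clade) {
  cl <- get_clade(scaffold, clade)
  if (!(fossil_tip %in% placed_tree$tip.label))
    stop("fossil '", fossil_tip, "' not attached in tree")
  crown_node <- mrca_node(placed_tree, cl$tips)
  joint <- mrca_node(placed_tree, c(fossil_tip, cl$tips))
  crown <- joint == crown_node
  extant_below <- intersect(tips_below(placed_tree, joint),
                            backbone_tips(scaffold))
  total <- all(extant_below %in% cl$tips)
  list(crown = crown, total = total)
}
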