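# Rule-based diagnosis of clade character states.
#
# A (clade, character, state) triple is an unreversed synapomorphy when the
# state is (i) ubiquitously present in all scored members of the clade,
# (ii) the sole MPR state at the clade's ancestral node in every
# most-parsimonious reconstruction, and (iii) absent from every MPR state set
# at the immediate sister clade's ancestral node. States inherited from
# rootward nodes are retained plesiomorphies; states failing (ii)/(iii)
# through reconstruction ambiguity are flagged as such rather than silently
# dropped, since that ambiguity is itself diagnostic information.

#' Classify one (clade, character, state) triple
#'
#' Applies, in order: the ubiquity test over scored (non-missing) clade
#' members; the retained-plesiomorphy test (state unambiguous at the clade's
#' MRCA and at its parent node); the unambiguous-MRCA test across all MPRs;
#' and the sister-absence test across all MPRs. Taxa with missing or
#' inapplicable cells cannot falsify ubiquity but are recorded. When the
#' clade's MRCA is the root there is no sister; the sister criterion is
#' skipped and noted. When the sister is ambiguous because of a polytomy, the
#' absence criterion must hold at every co-child.
#'
#' @param scaffold A [scaffold_tree()] with the clade registered.
#' @param clade Registered clade name.
#' @param char_id 1-based discrete character number.
#' @param state 0-based state code.
#' @param recon The character's `parsimony_recon` on the diagnosis tree.
#' @param m The [char_matrix()].
#' @param polymorphic_presence If `TRUE` (default) a polymorphic cell
#'   containing the state counts as presence.
#' @param sister_mode `"absent_all"` (default: state absent from the sister
#'   MPR set under every MPR) or `"not_unambiguous"` (softer: state merely
#'   not the sole sister state).
#' @return An object of class `synapo_record`.
#' @export
classify_clade_state <- function(scaffold, clade, char_id, state, recon, m,
                                 polymorphic_presence = TRUE,
                                 sister_mode = c("absent_all",
                                                 "not_unambiguous")) {
  sister_mode <- match.arg(sister_mode)
  stopifnot(inherits(recon, "parsimony_recon"), recon$kind == "discrete")
  cl <- get_clade(scaffold, clade)
  def <- m$definitions[[char_id]]
  if (def$kind != "discrete") stop("character ", char_id, " is not discrete")
  state <- as.integer(state)
  tree <- recon$tree
  notes <- character(0)

  j <- match(char_id, seq_len(n_char(m)))
  row_idx <- match(cl$tips, m$taxa)
  scored <- character(0); missing_taxa <- character(0); has_state <- character(0)
  for (i in seq_along(cl$tips)) {
    cell <- if (is.na(row_idx[i])) MISSING_TOKEN else m$cells[[row_idx[i], j]]
    if (is_blank_cell(cell)) {
      missing_taxa <- c(missing_taxa, cl$tips[i])
      next
    }
    scored <- c(scored, cl$tips[i])
    present <- if (polymorphic_presence) state %in% cell
               else identical(as.integer(cell), state)
    if (present) has_state <- c(has_state, cl$tips[i])
  }
  exceptions <- setdiff(scored, has_state)
  if (length(missing_taxa))
    notes <- c(notes, paste0("unscored: ", paste(missing_taxa, collapse = ",")))

  mrca <- mrca_node(tree, cl$tips)
  mpr_mrca <- recon$node_mpr[[mrca]]
  ubiquity <- length(scored) > 0L && length(exceptions) == 0L
  mrca_unambiguous <- identical(mpr_mrca, state)

  rt <- root_node(tree)
  if (mrca == rt) {
    sister_absent <- NA
    notes <- c(notes, "clade MRCA is the root: sister criterion not evaluable")
  } else {
    sis <- sister_node(tree, mrca)
    if (isTRUE(attr(sis, "ambiguous")))
      notes <- c(notes, "parent polytomy: sister criterion evaluated against every co-child")
    sister_absent <- all(vapply(sis, function(sn) {
      mpr <- recon$node_mpr[[sn]]
      if (sister_mode == "absent_all") !(state %in% mpr)
      else !identical(mpr, state)
    }, logical(1)))
  }

  parent <- node_parent(tree, mrca)
  retained <- mrca_unambiguous && !is.na(parent) &&
    identical(recon$node_mpr[[parent]], state)

  classification <- if (!length(has_state)) {
    "absent"
  } else if (!ubiquity) {
    if (state %in% mpr_mrca) "near_ubiquitous_diagnostic" else "homoplastic"
  } else if (retained) {
    "retained_plesiomorphy"
  } else if (mrca_unambiguous && !isFALSE(sister_absent)) {
    "unreversed_synapomorphy"
  } else {
    if (!mrca_unambiguous)
      notes <- c(notes, "ambiguous MPR at the clade's ancestral node")
    else notes <- c(notes, "state reconstructable at the sister clade's ancestral node")
    "ambiguous_not_synapomorphy"
  }

  origins <- count_state_origins(recon, state)
  structure(list(clade = clade, char_id = as.integer(char_id), state = state,
                 classification = classification,
                 exceptions = exceptions, missing_taxa = missing_taxa,
                 min_origins = origins[["min_origins"]],
                 max_origins = origins[["max_origins"]],
                 criteria = c(ubiquity = ubiquity,
                              mrca_unambiguous = mrca_unambiguous,
                              sister_absent = sister_absent),
                 notes = paste(notes, collapse = "; ")),
            class = "synapo_record")
}

classification_glyph <- function(cls) {
  switch(cls, unreversed_synapomorphy = "*", retained_plesiomorphy = "§",
         "")
}

#' @export
print.synapo_record <- function(x, ...) {
  cat(sprintf("%s char. %d(%d) [%s]: %s%s\n", x$clade, x$char_id, x$state,
              paste0(classification_glyph(x$classification), x$classification),
              sprintf("origins %d-%d", x$min_origins, x$max_origins),
              if (length(x$exceptions))
                paste0("; exceptions: ", paste(x$exceptions, collapse = ", "))
              else ""))
  invisible(x)
}

#' @export
as.data.frame.synapo_record <- function(x, ...) {
  data.frame(clade = x$clade, char_id = x$char_id, state = x$state,
             class = paste0(classification_glyph(x$classification),
                            x$classification),
             exceptions = paste(x$exceptions, collapse = ";"),
             min_origins = x$min_origins, max_origins = x$max_origins,
             notes = x$notes, stringsAsFactors = FALSE)
}

#' Diagnostic character combination for a clade
#'
#' Classifies every (character, state) pair observed among the clade's scored
#' members and returns all records that contribute to the clade's diagnosis:
#' unreversed synapomorphies, retained plesiomorphies, near-ubiquitous states
#' (with their exception lists), and states whose synapomorphy status is
#' blocked only by reconstruction ambiguity. `absent` and `homoplastic`
#' records are dropped.
#'
#' @param scaffold A `scaffold` with the clade registered.
#' @param clade Clade name.
#' @param recons Output of [optimise_matrix()] on the diagnosis tree.
#' @param m The [char_matrix()].
#' @param ... Passed to [classify_clade_state()].
#' @return List of `synapo_record`, sorted by character then state.
#' @export
diagnose_clade <- function(scaffold, clade, recons, m, ...) {
  cl <- get_clade(scaffold, clade)
  out <- list()
  for (j in discrete_char_ids(m)) {
    recon <- recons[[sprintf("char%d", j)]]
    if (is.null(recon)) stop("no reconstruction for character ", j)
    if (recon$steps == 0) next  # invariant character: diagnostic of nothing
    row_idx <- match(cl$tips, m$taxa)
    obs <- sort(unique(unlist(lapply(row_idx[!is.na(row_idx)], function(i) {
      cell <- m$cells[[i, j]]
      if (is_blank_cell(cell)) integer(0) else cell
    }))))
    for (st in obs) {
      rec <- classify_clade_state(scaffold, clade, j, st, recon, m, ...)
      if (!rec$classification %in% c("absent", "homoplastic"))
        out[[length(out) + 1L]] <- rec
    }
  }
  ord <- order(vapply(out, `[[`, integer(1), "char_id"),
               vapply(out, `[[`, integer(1), "state"))
  out[ord]
}

#' Scan for truly unique unreversed synapomorphies
#'
#' An unreversed synapomorphy is "truly unique" when the derived state arises
#' exactly once on the whole tree (outgroups included) in every
#' most-parsimonious reconstruction: `min_origins = max_origins = 1`.
#'
#' @param scaffold A `scaffold`.
#' @param recons Output of [optimise_matrix()].
#' @param m The [char_matrix()].
#' @param clades Clade names to scan (default: all registered).
#' @param ... Passed to [classify_clade_state()].
#' @return Data frame (possibly empty) with columns `clade`, `char_id`,
#'   `state`, `min_origins`, `max_origins`.
#' @export
unique_synapomorphy_scan <- function(scaffold, recons, m,
                                     clades = names(scaffold$clades), ...) {
  rows <- list()
  for (cl in clades) {
    for (rec in diagnose_clade(scaffold, cl, recons, m, ...)) {
      if (rec$classification == "unreversed_synapomorphy" &&
          rec$min_origins == 1L && rec$max_origins == 1L)
        rows[[length(rows) + 1L]] <-
          data.frame(clade = cl, char_id = rec$char_id, state = rec$state,
                     min_origins = rec$min_origins,
                     max_origins = rec$max_origins,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    data.frame(clade = character(0), char_id = integer(0), state = integer(0),
               min_origins = integer(0), max_origins = integer(0))
  else do.call(rbind, rows)
}
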