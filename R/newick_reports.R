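# Newick tree input and tabular report output.

#' Read a rooted Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]: the tree must parse,
#' carry unique tip labels, and is returned rooted as written (polytomies are
#' preserved; branch lengths are optional). Rooting is taken from the file,
#' never inferred.
#'
#' @param path Path to a Newick file (first tree is used).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  read_newick_text(txt)
}

read_newick_text <- function(txt) {
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stop("Newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, "')')")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)),
                   warning = function(w) stop("Newick parse error: ",
                                              conditionMessage(w)))
  if (is.null(tree)) stop("Newick parse error: no tree parsed")
  if (anyDuplicated(tree$tip.label)) {
    dup <- tree$tip.label[duplicated(tree$tip.label)][1L]
    stop("Newick parse error: duplicate tip label '", dup, "'")
  }
  tree
}

#' Write synapomorphy or placement results as a TSV report
#'
#' Produces a deterministic, sorted, tab-separated report. Synapomorphy
#' records are sorted by clade then character; classifications carry the
#' conventional glyphs (`*` unreversed synapomorphy, `§` retained
#' plesiomorphy). Placement summaries are written as one row per
#' (fossil, clade) with crown and total-clade posterior probabilities, and
#' the consensus tree, when present, is written alongside as Newick with
#' support annotations (same path with extension `.nwk`).
#'
#' @param records A non-empty list of `synapo_record` objects, or a single
#'   `placement_summary`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
  if (missing(records) || is.null(records) ||
      (is.list(records) && !length(records)))
    stop("write_report: empty record list")
  if (inherits(records, "placement_summary")) {
    df <- as.data.frame(records)
    df <- df[order(df$fossil, df$clade), , drop = FALSE]
    if (!is.null(records$consensus)) {
      ape::write.tree(records$consensus,
                      file = paste0(tools::file_path_sans_ext(path), ".nwk"))
    }
  } else {
    if (inherits(records, "synapo_record")) records <- list(records)
    if (!all(vapply(records, inherits, logical(1), "synapo_record")))
      stop("write_report: records must be synapo_record or placement_summary")
    df <- do.call(rbind, lapply(records, as.data.frame))
    df <- df[order(df$clade, df$char_id, df$state), , drop = FALSE]
  }
  con <- file(path, open = "wb")  # binary mode: byte-identical across calls
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}
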