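# Core container for morphological character data: a taxa x characters grid
# whose cells are discrete state sets, continuous values, missing ('?') or
# inapplicable ('-') observations, plus per-character metadata.

MISSING_TOKEN <- "?"
INAPP_TOKEN <- "-"

#' Define a single morphological character
#'
#' Characters are identified by their 1-based position in the matrix (the
#' "char. N" numbering used in anatomical character lists). Discrete
#' characters carry a number of states (codes `0 .. n_states - 1`) and may be
#' flagged as ordered, in which case the cost of a transition between states
#' `i` and `j` is `|i - j|`. Continuous characters hold real-valued ratios.
#'
#' @param char_id Integer, 1-based character number.
#' @param label Free-text character label.
#' @param kind `"discrete"` or `"continuous"`.
#' @param n_states Number of states (discrete characters only, `>= 2`).
#' @param ordered Logical; ordered characters must be discrete with at least
#'   three states (ordering binary characters is vacuous).
#' @param state_labels Optional character vector of length `n_states`.
#' @return An object of class `character_definition`.
#' @export
character_definition <- function(char_id, label = sprintf("char%d", char_id),
                                 kind = c("discrete", "continuous"),
                                 n_states = NULL, ordered = FALSE,
                                 state_labels = NULL) {
  kind <- match.arg(kind)
  char_id <- as.integer(char_id)
  stopifnot(length(char_id) == 1L, !is.na(char_id), char_id >= 1L)
  if (kind == "discrete") {
    if (is.null(n_states)) stop("discrete character ", char_id, " needs n_states")
    n_states <- as.integer(n_states)
    if (n_states < 2L) stop("character ", char_id, ": n_states must be >= 2")
    if (ordered && n_states < 3L)
      stop("character ", char_id, ": ordered requires >= 3 states")
    if (!is.null(state_labels) && length(state_labels) != n_states)
      stop("character ", char_id, ": state_labels length mismatch")
  } else {
    if (ordered) stop("character ", char_id, ": continuous characters cannot be ordered")
    n_states <- NA_integer_
    state_labels <- NULL
  }
  structure(list(char_id = char_id, label = label, kind = kind,
                 n_states = n_states, ordered = isTRUE(ordered),
                 state_labels = state_labels),
            class = "character_definition")
}

#' Assemble a character matrix
#'
#' @param taxa Character vector of unique taxon names (row order is kept).
#' @param definitions List of [character_definition()] objects with unique,
#'   contiguous 1-based `char_id`s.
#' @param cells A `length(taxa)` x `length(definitions)` list-matrix. Each
#'   cell is one of: an integer vector of state codes (a set of size one, or
#'   larger for polymorphic cells), a finite numeric scalar (continuous
#'   characters), `"?"` (missing) or `"-"` (inapplicable).
#' @return An object of class `char_matrix`.
#' @export
char_matrix <- function(taxa, definitions, cells) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon name: ",
                                taxa[duplicated(taxa)][1L])
  if (!is.list(definitions) || !length(definitions))
    stop("definitions must be a non-empty list")
  ids <- vapply(definitions, function(d) d$char_id, integer(1))
  if (!identical(sort(ids), seq_along(definitions)))
    stop("char_id values must be unique and contiguous 1..", length(definitions))
  definitions <- definitions[order(ids)]
  if (!is.matrix(cells) || !is.list(cells) ||
      nrow(cells) != length(taxa) || ncol(cells) != length(definitions))
    stop("cells must be a ", length(taxa), " x ", length(definitions),
         " list-matrix")
  dimnames(cells) <- list(taxa, vapply(definitions, function(d)
    sprintf("char%d", d$char_id), character(1)))
  m <- structure(list(taxa = taxa, definitions = definitions, cells = cells),
                 class = "char_matrix")
  validate_char_matrix(m)
  m
}

#' @export
print.char_matrix <- function(x, ...) {
  nd <- sum(vapply(x$definitions, function(d) d$kind == "discrete", logical(1)))
  cat(sprintf("char_matrix: %d taxa x %d characters (%d discrete, %d continuous)\n",
              length(x$taxa), length(x$definitions), nd,
              length(x$definitions) - nd))
  invisible(x)
}

is_missing_cell <- function(cell) is.character(cell) && identical(cell, MISSING_TOKEN)
is_inapp_cell <- function(cell) is.character(cell) && identical(cell, INAPP_TOKEN)
is_blank_cell <- function(cell) is.character(cell)

#' @rdname char_matrix
#' @param m A `char_matrix`.
#' @export
n_taxa <- function(m) length(m$taxa)

#' @rdname char_matrix
#' @export
n_char <- function(m) length(m$definitions)

validate_char_matrix <- function(m) {
  for (j in seq_along(m$definitions)) {
    def <- m$definitions[[j]]
    for (i in seq_along(m$taxa)) {
      cell <- m$cells[[i, j]]
      if (is_blank_cell(cell)) {
        if (!is_missing_cell(cell) && !is_inapp_cell(cell))
          stop("taxon ", m$taxa[i], ", character ", def$char_id,
               ": unknown token '", cell, "'")
        next
      }
      if (def$kind == "discrete") {
        if (!is.numeric(cell) || length(cell) < 1L || any(cell != floor(cell)))
          stop("taxon ", m$taxa[i], ", character ", def$char_id,
               ": discrete cell must be a set of integer state codes")
        if (any(cell < 0L) || any(cell >= def$n_states))
          stop("character ", def$char_id, ": state code out of range 0..",
               def$n_states - 1L, " for taxon ", m$taxa[i])
        if (anyDuplicated(cell))
          stop("character ", def$char_id, ": duplicated state in polymorphic cell")
      } else {
        if (!is.numeric(cell) || length(cell) != 1L || !is.finite(cell))
          stop("taxon ", m$taxa[i], ", character ", def$char_id,
               ": continuous cell must be a finite real or missing")
      }
    }
  }
  invisible(m)
}

# Full ambiguity set for a cell: missing and inapplicable cells expand to all
# states; used by every downstream inference.
cell_state_set <- function(cell, n_states) {
  if (is_blank_cell(cell)) 0:(n_states - 1L) else as.integer(sort(cell))
}

#' Extract one character as a tip-ordered column
#'
#' @param m A `char_matrix`.
#' @param char_id 1-based character number.
#' @param taxa Taxon names giving the output order (default: matrix order).
#'   Taxa absent from the matrix are treated as entirely missing.
#' @return For discrete characters, a list of integer state-set vectors
#'   (missing/inapplicable cells expanded to the full set); for continuous
#'   characters, a numeric vector with `NA` for missing.
#' @export
matrix_column <- function(m, char_id, taxa = m$taxa) {
  j <- as.integer(char_id)
  if (j < 1L || j > n_char(m)) stop("no character ", char_id)
  def <- m$definitions[[j]]
  idx <- match(taxa, m$taxa)
  if (def$kind == "discrete") {
    out <- lapply(idx, function(i) {
      if (is.na(i)) 0:(def$n_states - 1L)
      else cell_state_set(m$cells[[i, j]], def$n_states)
    })
    names(out) <- taxa
    out
  } else {
    out <- vapply(idx, function(i) {
      if (is.na(i)) NA_real_
      else if (is_blank_cell(m$cells[[i, j]])) NA_real_
      else as.numeric(m$cells[[i, j]])
    }, numeric(1))
    names(out) <- taxa
    out
  }
}

discrete_char_ids <- function(m) {
  ids <- vapply(m$definitions, function(d)
    if (d$kind == "discrete") d$char_id else NA_integer_, integer(1))
  ids[!is.na(ids)]
}

continuous_char_ids <- function(m) {
  setdiff(seq_len(n_char(m)), discrete_char_ids(m))
}
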