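# NEXUS character-matrix input/output.
#
# Supported dialect: DATA or CHARACTERS block with DIMENSIONS, FORMAT
# (DATATYPE=STANDARD, or the MrBayes-style DATATYPE=MIXED(CONTINUOUS: a-b,
# STANDARD: c-d) used for matrices that combine continuous ratio characters
# with discrete ones), non-interleaved MATRIX with '(01)'/'{01}' polymorphic
# cells, and an optional ASSUMPTIONS block whose TYPESET declares ordered
# characters ("ord: 7 9-11"). Missing and gap tokens default to '?' and '-'.

strip_nexus_comments <- function(txt) gsub("\\[[^]]*\\]", " ", txt)

nexus_blocks <- function(txt) {
  # returns named list of block bodies (uppercased names)
  out <- list()
  pat <- gregexpr("(?i)BEGIN\\s+([A-Za-z]+)\\s*;", txt, perl = TRUE)[[1]]
  if (pat[1] == -1) return(out)
  starts <- as.integer(pat)
  lens <- attr(pat, "match.length")
  ends_pat <- gregexpr("(?i)END\\s*;", txt, perl = TRUE)[[1]]
  ends <- as.integer(ends_pat)
  for (i in seq_along(starts)) {
    body_start <- starts[i] + lens[i]
    e <- ends[ends > body_start]
    if (!length(e)) stop("NEXUS format error: unterminated block")
    name <- toupper(sub("(?i)BEGIN\\s+([A-Za-z]+)\\s*;.*", "\\1",
                        substr(txt, starts[i], starts[i] + lens[i] - 1L),
                        perl = TRUE))
    out[[name]] <- substr(txt, body_start, e[1] - 1L)
  }
  out
}

parse_number_list <- function(s) {
  # "7 9-11 13" -> c(7, 9, 10, 11, 13)
  parts <- strsplit(trimws(s), "[[:space:],]+")[[1]]
  parts <- parts[nzchar(parts)]
  out <- integer(0)
  for (p in parts) {
    if (grepl("^\\d+-\\d+$", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      out <- c(out, ab[1]:ab[2])
    } else if (grepl("^\\d+$", p)) {
      out <- c(out, as.integer(p))
    } else stop("NEXUS format error: cannot parse character list token '", p, "'")
  }
  out
}

parse_format <- function(body, nchar_total) {
  fmt <- regmatches(body, regexpr("(?i)FORMAT[^;]*;", body, perl = TRUE))
  kind <- rep("discrete", nchar_total)
  missing_tok <- "?"; gap_tok <- "-"; symbols <- "0123456789"
  if (length(fmt)) {
    f <- fmt[[1]]
    if (grepl("(?i)INTERLEAVE(?!\\s*=\\s*NO)", f, perl = TRUE))
      stop("NEXUS format error: interleaved matrices are not supported")
    mx <- regmatches(f, regexpr("(?i)MISSING\\s*=\\s*\\S", f, perl = TRUE))
    if (length(mx)) missing_tok <- substr(mx, nchar(mx), nchar(mx))
    gx <- regmatches(f, regexpr("(?i)GAP\\s*=\\s*\\S", f, perl = TRUE))
    if (length(gx)) gap_tok <- substr(gx, nchar(gx), nchar(gx))
    sx <- regmatches(f, regexpr('(?i)SYMBOLS\\s*=\\s*"[^"]*"', f, perl = TRUE))
    if (length(sx)) symbols <- gsub('[" ]', "", sub("(?i)SYMBOLS\\s*=\\s*", "", sx))
    dx <- regmatches(f, regexpr("(?i)DATATYPE\\s*=\\s*MIXED\\s*\\([^)]*\\)", f,
                                perl = TRUE))
    if (length(dx)) {
      inner <- sub("^[^(]*\\(", "", sub("\\)$", "", dx))
      for (seg in strsplit(inner, ",")[[1]]) {
        kv <- strsplit(seg, ":")[[1]]
        if (length(kv) != 2) stop("NEXUS format error: bad MIXED datatype segment '", seg, "'")
        ids <- parse_number_list(kv[2])
        if (any(ids < 1 | ids > nchar_total))
          stop("NEXUS format error: MIXED range outside 1..", nchar_total)
        kind[ids] <- if (grepl("(?i)continuous", kv[1])) "continuous" else "discrete"
      }
    } else if (grepl("(?i)DATATYPE\\s*=\\s*CONTINUOUS", f, perl = TRUE)) {
      kind[] <- "continuous"
    }
  }
  list(kind = kind, missing = missing_tok, gap = gap_tok, symbols = symbols)
}

parse_matrix_rows <- function(body) {
  mpos <- regexpr("(?i)\\bMATRIX\\b", body, perl = TRUE)
  if (mpos == -1) stop("NEXUS format error: no MATRIX command")
  rest <- substr(body, mpos + attr(mpos, "match.length"), nchar(body))
  semi <- regexpr(";", rest, fixed = TRUE)
  if (semi == -1) stop("NEXUS format error: MATRIX not terminated by ';'")
  rows <- strsplit(substr(rest, 1, semi - 1L), "\n", fixed = TRUE)[[1]]
  rows <- trimws(rows)
  rows[nzchar(rows)]
}

split_row <- function(row) {
  # returns list(taxon=, rest=) handling 'quoted names'; underscores are kept
  # literal (ape convention) so names round-trip
  if (startsWith(row, "'")) {
    close <- regexpr("'", substr(row, 2, nchar(row)), fixed = TRUE)
    if (close == -1) stop("NEXUS format error: unterminated quoted taxon name")
    taxon <- substr(row, 2, close)
    rest <- substr(row, close + 2L, nchar(row))
  } else {
    sp <- regexpr("\\s", row)
    if (sp == -1) stop("NEXUS format error: matrix row without states: '", row, "'")
    taxon <- substr(row, 1, sp - 1L)
    rest <- substr(row, sp + 1L, nchar(row))
  }
  list(taxon = taxon, rest = trimws(rest))
}

parse_row_cells <- function(taxon, rest, kind, fmt) {
  tokens <- strsplit(rest, "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  cells <- vector("list", length(kind))
  ti <- 1L   # token index
  ci <- 0L   # position within current token (discrete only)
  for (j in seq_along(kind)) {
    if (kind[j] == "continuous") {
      if (ci != 0L) stop("ragged row for taxon ", taxon,
                         ": discrete symbols run into continuous character ", j)
      if (ti > length(tokens)) stop("ragged row for taxon ", taxon,
                                    ": too few cells")
      tok <- tokens[ti]; ti <- ti + 1L
      if (tok == fmt$missing) cells[[j]] <- MISSING_TOKEN
      else if (tok == fmt$gap) cells[[j]] <- INAPP_TOKEN
      else {
        v <- suppressWarnings(as.numeric(tok))
        if (is.na(v)) stop("format error in character ", j, " for taxon ",
                           taxon, ": '", tok, "' is not numeric")
        cells[[j]] <- v
      }
    } else {
      repeat {
        if (ti > length(tokens)) stop("ragged row for taxon ", taxon,
                                      ": too few cells")
        if (ci < nchar(tokens[ti])) break
        ti <- ti + 1L; ci <- 0L
      }
      ch <- substr(tokens[ti], ci + 1L, ci + 1L)
      if (ch %in% c("(", "{")) {
        closer <- if (ch == "(") ")" else "}"
        rest_tok <- substr(tokens[ti], ci + 2L, nchar(tokens[ti]))
        cl <- regexpr(closer, rest_tok, fixed = TRUE)
        if (cl == -1) stop("NEXUS format error: unclosed polymorphism for taxon ",
                           taxon, ", character ", j)
        syms <- strsplit(substr(rest_tok, 1, cl - 1L), "")[[1]]
        syms <- syms[syms != " "]
        codes <- match(syms, strsplit(fmt$symbols, "")[[1]]) - 1L
        if (anyNA(codes)) stop("undeclared state symbol in character ", j,
                               " for taxon ", taxon)
        if (length(codes) < 1L) stop("empty polymorphism for taxon ", taxon,
                                     ", character ", j)
        cells[[j]] <- sort(unique(codes))
        ci <- ci + cl + 1L
      } else {
        ci <- ci + 1L
        if (ch == fmt$missing) cells[[j]] <- MISSING_TOKEN
        else if (ch == fmt$gap) cells[[j]] <- INAPP_TOKEN
        else {
          code <- match(ch, strsplit(fmt$symbols, "")[[1]]) - 1L
          if (is.na(code)) stop("undeclared state symbol '", ch,
                                "' in character ", j, " for taxon ", taxon)
          cells[[j]] <- code
        }
      }
    }
  }
  leftover <- (ti < length(tokens)) ||
    (ti == length(tokens) && ci != 0L && ci < nchar(tokens[ti]))
  if (leftover) stop("ragged row for taxon ", taxon, ": too many cells")
  cells
}

parse_typeset_ordered <- function(assump_body, nchar_total) {
  ordered <- rep(FALSE, nchar_total)
  ts <- regmatches(assump_body,
                   regexpr("(?i)TYPESET[^;]*;", assump_body, perl = TRUE))
  if (!length(ts)) return(ordered)
  rhs <- sub("^[^=]*=", "", sub(";$", "", ts))
  for (seg in strsplit(rhs, ",")[[1]]) {
    kv <- strsplit(seg, ":")[[1]]
    if (length(kv) != 2) next
    if (grepl("(?i)^\\s*ord\\s*$", kv[1], perl = TRUE)) {
      ids <- parse_number_list(kv[2])
      if (any(ids < 1 | ids > nchar_total))
        stop("NEXUS format error: TYPESET index outside 1..", nchar_total)
      ordered[ids] <- TRUE
    }
  }
  ordered
}

#' Read a NEXUS character matrix
#'
#' Parses a DATA or CHARACTERS block into a [char_matrix()]. Continuous
#' characters are recognised from a `DATATYPE=MIXED(CONTINUOUS: ...,
#' STANDARD: ...)` or `DATATYPE=CONTINUOUS` declaration; ordered characters
#' from an ASSUMPTIONS `TYPESET` (`ord:` list). The number of states of each
#' discrete character is inferred as `max(observed code) + 1` (at least 2).
#'
#' @param path Path to a NEXUS file.
#' @return A `char_matrix`.
#' @export
read_nexus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- strip_nexus_comments(paste(readLines(path, warn = FALSE),
                                    collapse = "\n"))
  if (!grepl("(?i)^\\s*#NEXUS", txt, perl = TRUE))
    stop("NEXUS format error: missing #NEXUS header")
  blocks <- nexus_blocks(txt)
  data_body <- blocks[["DATA"]]
  if (is.null(data_body)) data_body <- blocks[["CHARACTERS"]]
  if (is.null(data_body))
    stop("NEXUS format error: no DATA or CHARACTERS block")

  dims <- regmatches(data_body,
                     regexpr("(?i)DIMENSIONS[^;]*;", data_body, perl = TRUE))
  if (!length(dims)) stop("NEXUS format error: no DIMENSIONS command")
  ntax <- as.integer(sub(".*(?i)NTAX\\s*=\\s*(\\d+).*", "\\1", dims, perl = TRUE))
  nch <- as.integer(sub(".*(?i)NCHAR\\s*=\\s*(\\d+).*", "\\1", dims, perl = TRUE))
  if (is.na(ntax) || is.na(nch))
    stop("NEXUS format error: DIMENSIONS must give NTAX and NCHAR")

  fmt <- parse_format(data_body, nch)
  rows <- parse_matrix_rows(data_body)
  if (length(rows) != ntax)
    stop("NEXUS format error: NTAX=", ntax, " but ", length(rows),
         " matrix rows found")

  taxa <- character(ntax)
  cells <- matrix(vector("list", ntax * nch), nrow = ntax)
  for (i in seq_len(ntax)) {
    sr <- split_row(rows[i])
    taxa[i] <- sr$taxon
    cells[i, ] <- parse_row_cells(sr$taxon, sr$rest, fmt$kind, fmt)
  }
  if (anyDuplicated(taxa)) stop("duplicate taxon name: ",
                                taxa[duplicated(taxa)][1L])

  ordered <- if (!is.null(blocks[["ASSUMPTIONS"]]))
    parse_typeset_ordered(blocks[["ASSUMPTIONS"]], nch) else rep(FALSE, nch)

  defs <- vector("list", nch)
  for (j in seq_len(nch)) {
    if (fmt$kind[j] == "continuous") {
      defs[[j]] <- character_definition(j, kind = "continuous")
    } else {
      obs <- unlist(lapply(seq_len(ntax), function(i) {
        cell <- cells[[i, j]]
        if (is_blank_cell(cell)) integer(0) else cell
      }))
      k <- max(2L, if (length(obs)) max(obs) + 1L else 2L)
      # an ordered flag implies at least three states even if the highest
      # one is unobserved in this sample
      if (ordered[j]) k <- max(k, 3L)
      defs[[j]] <- character_definition(j, kind = "discrete", n_states = k,
                                        ordered = ordered[j])
    }
  }
  char_matrix(taxa, defs, cells)
}

format_cell <- function(cell, def) {
  if (is_missing_cell(cell)) return("?")
  if (is_inapp_cell(cell)) return("-")
  if (def$kind == "continuous") return(sprintf("%.17g", cell))
  syms <- as.character(cell)
  if (length(syms) > 1L) paste0("(", paste(syms, collapse = ""), ")") else syms
}

#' Write a character matrix to NEXUS
#'
#' Emits a DATA block (with a `MIXED` datatype declaration when continuous
#' characters are present) and, if any character is ordered, an ASSUMPTIONS
#' block with a `TYPESET` naming the ordered characters. The output
#' round-trips through [read_nexus()] cell-for-cell.
#'
#' @param m A [char_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(m, path) {
  stopifnot(inherits(m, "char_matrix"))
  kinds <- vapply(m$definitions, `[[`, character(1), "kind")
  kmax <- suppressWarnings(max(vapply(m$definitions, function(d)
    if (d$kind == "discrete") d$n_states else 0L, integer(1))))
  if (kmax > 10L) stop("write_nexus supports at most 10 discrete states")
  symbols <- paste(0:(max(kmax, 2L) - 1L), collapse = "")
  datatype <- if (any(kinds == "continuous")) {
    sprintf("MIXED(CONTINUOUS: %s, STANDARD: %s)",
            paste(which(kinds == "continuous"), collapse = " "),
            paste(which(kinds == "discrete"), collapse = " "))
  } else "STANDARD"

  name_out <- function(x) {
    if (grepl("[^A-Za-z0-9_.]", x)) paste0("'", x, "'") else x
  }
  rows <- vapply(seq_along(m$taxa), function(i) {
    toks <- character(n_char(m))
    for (j in seq_len(n_char(m)))
      toks[j] <- format_cell(m$cells[[i, j]], m$definitions[[j]])
    # continuous tokens must stay whitespace-delimited; discrete may be run
    # together, but keeping one space everywhere is simplest and diff-able
    paste(name_out(m$taxa[i]), paste(toks, collapse = " "), sep = "\t")
  }, character(1))

  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(m), n_char(m)),
    sprintf("  FORMAT DATATYPE=%s SYMBOLS=\"%s\" MISSING=? GAP=-;",
            datatype, symbols),
    "  MATRIX",
    paste0("    ", rows),
    "  ;",
    "END;")
  ord <- which(vapply(m$definitions, `[[`, logical(1), "ordered"))
  if (length(ord)) {
    unord <- setdiff(which(kinds == "discrete"), ord)
    lines <- c(lines,
               "BEGIN ASSUMPTIONS;",
               sprintf("  TYPESET * default = ord: %s, unord: %s;",
                       paste(ord, collapse = " "),
                       paste(unord, collapse = " ")),
               "END;")
  }
  writeLines(lines, path)
  invisible(path)
}
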