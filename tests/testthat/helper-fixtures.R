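# Shared fixtures built in code.

tree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# a tiny binary matrix builder: rows named by taxa, each row a list of cells
tiny_matrix <- function(rows, n_states = 2L, ordered = FALSE) {
  taxa <- names(rows)
  nch <- length(rows[[1]])
  defs <- lapply(seq_len(nch), function(j)
    morphoscaffold::character_definition(
      j, kind = "discrete",
      n_states = if (length(n_states) > 1L) n_states[j] else n_states,
      ordered = if (length(ordered) > 1L) ordered[j] else ordered))
  cells <- matrix(vector("list", length(taxa) * nch), nrow = length(taxa))
  for (i in seq_along(taxa)) for (j in seq_len(nch))
    cells[[i, j]] <- rows[[i]][[j]]
  morphoscaffold::char_matrix(taxa, defs, cells)
}

# a small 8-tip scaffold with nested clades AB < ABCD, plus outgroups
mini_scaffold <- function() {
  tr <- ape::read.tree(text = paste0(
    "((O1:1,O2:1):1,(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1):1);"))
  sc <- morphoscaffold::scaffold_tree(tr)
  sc <- morphoscaffold::register_clade(sc, "AB", c("A", "B"))
  sc <- morphoscaffold::register_clade(sc, "CD", c("C", "D"))
  sc <- morphoscaffold::register_clade(sc, "ABCD", c("A", "B", "C", "D"))
  sc <- morphoscaffold::register_clade(sc, "EF", c("E", "F"))
  sc <- morphoscaffold::register_clade(sc, "ingroup",
                                       c("A", "B", "C", "D", "E", "F"))
  sc
}

# a small synthetic scaffold for simulation-based tests
small_synth_scaffold <- function(seed = 5L) {
  morphoscaffold::example_scaffold(
    sizes = c(outgroup = 3, acanthisitti = 2, eurylaimides = 3,
              furnariida = 5, tyrannida = 4, menurides = 2,
              climacterides = 2, meliphagides = 3, corvides = 4,
              passerides = 4),
    seed = seed)
}
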