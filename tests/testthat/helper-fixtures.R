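# Fixture builders shared across the suite.  Everything is generated in
# code; no stored data files.

ppi_row <- function(a, b, w, prov = "") {
  data.frame(a_id = a, a_kind = "PROTEIN", b_id = b, b_kind = "PROTEIN",
             etype = "PPI", weight = w, provenance = prov,
             stringsAsFactors = FALSE)
}

tfdna_row <- function(a, g, w = 1, prov = "") {
  data.frame(a_id = a, a_kind = "PROTEIN", b_id = g, b_kind = "GENE",
             etype = "TF_DNA", weight = w, provenance = prov,
             stringsAsFactors = FALSE)
}

tfmir_row <- function(a, m, w = 1) {
  data.frame(a_id = a, a_kind = "PROTEIN", b_id = m, b_kind = "MIRNA",
             etype = "TF_MIRNA", weight = w, provenance = "",
             stringsAsFactors = FALSE)
}

mirrna_row <- function(m, g, w = 1) {
  data.frame(a_id = m, a_kind = "MIRNA", b_id = g, b_kind = "GENE",
             etype = "MIRNA_RNA", weight = w, provenance = "",
             stringsAsFactors = FALSE)
}

# one PPI chain src -> ... -> TF plus a TF_DNA edge to a gene target
chain_net <- function(proteins, gene, w = 0.9) {
  rows <- list()
  for (i in seq_len(length(proteins) - 1))
    rows[[i]] <- ppi_row(proteins[i], proteins[i + 1], w)
  rows[[length(rows) + 1]] <- tfdna_row(proteins[length(proteins)], gene, w)
  interactome(do.call(rbind, rows))
}

write_edge_tsv <- function(edges, path = tempfile(fileext = ".tsv")) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# Random connected typed graph with <= max_nodes molecule nodes, one
# guaranteed source->...->TF->gene path plus random PPI/TF_DNA clutter.
# Returns the interactome plus a single source and gene target.
random_typed_graph <- function(seed, max_nodes = 8) {
  set.seed(seed)
  n_prot <- sample(3:(max_nodes - 1), 1)
  n_gene <- sample(1:min(2, max_nodes - n_prot), 1)
  prot <- sprintf("P%d", seq_len(n_prot))
  gene <- sprintf("G%d", seq_len(n_gene))
  rw <- function(n) round(runif(n, 0.2, 1), 3)

  # guaranteed path through a random protein ordering
  ord <- sample(prot)
  hops <- sample(2:min(3, n_prot), 1)
  chain <- ord[seq_len(hops)]
  rows <- list()
  for (i in seq_len(hops - 1))
    rows[[length(rows) + 1]] <- ppi_row(chain[i], chain[i + 1], rw(1))
  rows[[length(rows) + 1]] <- tfdna_row(chain[hops], gene[1], rw(1))

  # clutter
  if (n_prot >= 2) {
    pairs <- utils::combn(prot, 2)
    pick <- runif(ncol(pairs)) < 0.4
    for (j in which(pick))
      rows[[length(rows) + 1]] <- ppi_row(pairs[1, j], pairs[2, j], rw(1))
  }
  for (g in gene)
    if (runif(1) < 0.5)
      rows[[length(rows) + 1]] <- tfdna_row(sample(prot, 1), g, rw(1))

  net <- suppressWarnings(suppressMessages(
    interactome(do.call(rbind, rows))))
  list(net = net, source = chain[1], target = gene[1])
}

# Structural scan: every source -> GENE-target path in the subnetwork is a
# run of PPIs followed by a terminal regulatory segment -- one TF_DNA edge,
# or TF_MIRNA then MIRNA_RNA -- and never returns to a PPI after entering
# the regulatory layer.  The final edge into a gene is always regulatory.
# PPIs are traversed along their flow direction only.
check_path_structure <- function(sub) {
  if (!nrow(sub$edges)) return(TRUE)
  e <- sub$edges
  fwd <- if (is.null(e$flow_direction)) rep(TRUE, nrow(e))
         else e$flow_direction != "b_to_a"
  tails <- paste(ifelse(fwd, e$a_id, e$b_id), ifelse(fwd, e$a_kind, e$b_kind))
  heads <- paste(ifelse(fwd, e$b_id, e$a_id), ifelse(fwd, e$b_kind, e$a_kind))
  reg <- e$etype != "PPI"

  sources <- paste(sub$nodes$id[sub$nodes$role == "source"], "PROTEIN")
  gene_targets <- paste(sub$nodes$id[sub$nodes$role == "target" &
                                       sub$nodes$kind == "GENE"], "GENE")
  ok <- TRUE
  walk <- function(node, in_reg, last_reg, visited) {
    if (node %in% gene_targets) {
      if (!last_reg) ok <<- FALSE      # terminal edge must be regulatory
      return(invisible())
    }
    out <- which(tails == node & !(heads %in% visited))
    for (j in out) {
      if (in_reg && !reg[j]) { ok <<- FALSE; next }  # PPI after regulatory
      walk(heads[j], in_reg || reg[j], reg[j], c(visited, node))
    }
  }
  for (s in sources) walk(s, FALSE, FALSE, character())
  ok
}

subnet_edge_keys <- function(sub) {
  if (!nrow(sub$edges)) return(character())
  respnet:::layer_edge_keys(respnet:::canonicalize_edges(sub$edges))
}
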