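# Molecule kinds and edge types of the typed interactome.  A gene and its
# protein product are distinct nodes: the node key is (id, kind).
MOLECULE_KINDS <- c("PROTEIN", "GENE", "MIRNA")
EDGE_TYPES <- c("PPI", "TF_DNA", "TF_MIRNA", "MIRNA_RNA")

# etype -> required (a_kind, b_kind, directed)
ETYPE_RULES <- list(
  PPI       = list(a = "PROTEIN", b = "PROTEIN", directed = FALSE),
  TF_DNA    = list(a = "PROTEIN", b = "GENE",    directed = TRUE),
  TF_MIRNA  = list(a = "PROTEIN", b = "MIRNA",   directed = TRUE),
  MIRNA_RNA = list(a = "MIRNA",   b = "GENE",    directed = TRUE)
)

REGULATORY_ETYPES <- c("TF_DNA", "TF_MIRNA", "MIRNA_RNA")

INTERACTION_COLUMNS <- c("a_id", "a_kind", "b_id", "b_kind", "etype",
                         "weight", "provenance")

node_key <- function(id, kind) paste(id, kind, sep = "\r")

edge_key <- function(e) {
  paste(e$a_id, e$a_kind, e$b_id, e$b_kind, e$etype, sep = "\r")
}

#' Construct a validated interactome
#'
#' An interactome is the searchable universe: a set of typed molecules
#' (protein, gene, microRNA) joined by typed, weighted interactions.
#' Protein-protein interactions (PPI) are undirected and stored once under a
#' canonical endpoint order; transcription-factor-DNA (`TF_DNA`),
#' TF-microRNA (`TF_MIRNA`) and microRNA-RNA (`MIRNA_RNA`) edges are
#' directed regulatory edges.  Gene nodes are regulatory sinks: they never
#' have outgoing edges.
#'
#' Rows that violate the interaction typing rules (wrong endpoint kinds,
#' self-loops, unknown edge type) are rejected and reported via the
#' `"rejected"` attribute and a message; a weight outside the half-open
#' interval (0, 1] is a hard validation error naming the offending row.
#' Duplicate edges (same endpoints and edge type, either PPI orientation)
#' keep the maximum weight: the most reliable piece of evidence wins.
#'
#' @param edges data.frame with columns `a_id`, `a_kind`, `b_id`, `b_kind`,
#'   `etype`, `weight` and optionally `provenance`.
#' @param build_tag version string recorded on the object.
#' @return An object of class `interactome` with components `nodes`
#'   (data.frame `id`, `kind`), `edges` (canonicalized data.frame) and
#'   `build_tag`.
#' @examples
#' edges <- data.frame(a_id = "P1", a_kind = "PROTEIN",
#'                     b_id = "G1", b_kind = "GENE",
#'                     etype = "TF_DNA", weight = 1)
#' net <- interactome(edges)
#' net
#' @export
interactome <- function(edges = NULL, build_tag = "unversioned") {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- empty_edge_frame()
    net <- structure(list(nodes = data.frame(id = character(), kind = character(),
                                             stringsAsFactors = FALSE),
                          edges = edges, build_tag = build_tag),
                     class = "interactome")
    attr(net, "rejected") <- empty_rejected_frame()
    return(net)
  }
  if (is.null(edges$provenance)) edges$provenance <- ""
  edges <- edges[INTERACTION_COLUMNS]
  for (col in setdiff(INTERACTION_COLUMNS, "weight"))
    edges[[col]] <- as.character(edges[[col]])
  edges$weight <- as.numeric(edges$weight)

  bad_weight <- which(!is.na(edges$weight) &
                        (edges$weight <= 0 | edges$weight > 1))
  if (length(bad_weight))
    stop("interaction weight outside (0, 1] at row(s): ",
         paste(bad_weight, collapse = ", "), call. = FALSE)

  reasons <- validate_edge_rows(edges)
  rejected <- edges[reasons != "", , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- reasons[reasons != ""]
    rejected$row <- which(reasons != "")
    message(nrow(rejected), " interaction row(s) rejected: ",
            paste(unique(rejected$reason), collapse = "; "))
    edges <- edges[reasons == "", , drop = FALSE]
  } else {
    rejected <- empty_rejected_frame()
  }

  edges <- canonicalize_edges(edges)
  edges <- dedup_edges_max_weight(edges)
  edges <- sort_edges(edges)
  rownames(edges) <- NULL

  nodes <- unique(data.frame(
    id = c(edges$a_id, edges$b_id),
    kind = c(edges$a_kind, edges$b_kind),
    stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$id, nodes$kind), , drop = FALSE]
  rownames(nodes) <- NULL

  net <- structure(list(nodes = nodes, edges = edges, build_tag = build_tag),
                   class = "interactome")
  stopifnot(all(gene_out_degree(net) == 0L))
  attr(net, "rejected") <- rejected
  net
}

empty_edge_frame <- function() {
  data.frame(a_id = character(), a_kind = character(), b_id = character(),
             b_kind = character(), etype = character(), weight = numeric(),
             provenance = character(), stringsAsFactors = FALSE)
}

empty_rejected_frame <- function() {
  cbind(empty_edge_frame(),
        data.frame(reason = character(), row = integer(),
                   stringsAsFactors = FALSE))
}

# One reason string per row; "" means valid.
validate_edge_rows <- function(edges) {
  n <- nrow(edges)
  reasons <- character(n)
  unknown <- !(edges$etype %in% EDGE_TYPES)
  reasons[unknown] <- "unknown etype"
  bad_kind <- !(edges$a_kind %in% MOLECULE_KINDS) |
    !(edges$b_kind %in% MOLECULE_KINDS)
  reasons[reasons == "" & bad_kind] <- "unknown molecule kind"
  empty_id <- is.na(edges$a_id) | is.na(edges$b_id) |
    edges$a_id == "" | edges$b_id == ""
  reasons[reasons == "" & empty_id] <- "empty identifier"
  ok <- reasons == ""
  if (any(ok)) {
    ra <- vapply(ETYPE_RULES[edges$etype[ok]], function(r) r$a, "")
    rb <- vapply(ETYPE_RULES[edges$etype[ok]], function(r) r$b, "")
    mism <- edges$a_kind[ok] != ra | edges$b_kind[ok] != rb
    reasons[ok][mism] <- "endpoint kind incompatible with etype"
  }
  self <- reasons == "" &
    node_key(edges$a_id, edges$a_kind) == node_key(edges$b_id, edges$b_kind)
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped", call. = FALSE)
    reasons[self] <- "self-loop"
  }
  na_w <- reasons == "" & is.na(edges$weight)
  reasons[na_w] <- "missing weight"
  reasons
}

# PPIs stored once under canonical (lexicographic) endpoint order.
canonicalize_edges <- function(edges) {
  swap <- edges$etype == "PPI" & edges$a_id > edges$b_id
  if (any(swap)) {
    tmp_id <- edges$a_id[swap]; tmp_kind <- edges$a_kind[swap]
    edges$a_id[swap] <- edges$b_id[swap]
    edges$a_kind[swap] <- edges$b_kind[swap]
    edges$b_id[swap] <- tmp_id
    edges$b_kind[swap] <- tmp_kind
  }
  edges
}

dedup_edges_max_weight <- function(edges) {
  if (!nrow(edges)) return(edges)
  key <- edge_key(edges)
  o <- order(key, -edges$weight)
  edges <- edges[o, , drop = FALSE]
  edges[!duplicated(key[o]), , drop = FALSE]
}

sort_edges <- function(edges) {
  edges[order(edges$a_id, edges$a_kind, edges$b_id, edges$b_kind,
              edges$etype), , drop = FALSE]
}

gene_out_degree <- function(net) {
  genes <- net$nodes$id[net$nodes$kind == "GENE"]
  if (!length(genes)) return(integer())
  out_tail <- net$edges$a_id[net$edges$a_kind == "GENE"]
  # undirected PPIs cannot touch genes, so tails cover all outgoing edges
  vapply(genes, function(g) sum(out_tail == g), 0L)
}

#' @export
print.interactome <- function(x, ...) {
  cat("interactome [", x$build_tag, "]: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges)) {
    tab <- table(x$edges$etype)
    cat("  ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Default PPI reliability weight from supporting-publication counts
#'
#' Stand-in weighting scheme for PPI tables that carry a number of
#' supporting publications instead of a reliability weight.  A logistic
#' curve maps the publication count `n` to `1 / (1 + exp(-steepness * (n -
#' midpoint)))`, so one publication gives a modest weight and the weight
#' saturates towards 1 as independent evidence accumulates.  This default is
#' explicitly non-canonical: published interactome weighting services use
#' richer evidence models, and user-supplied weights always take precedence.
#'
#' @param n_pubs non-negative numeric vector of supporting publications.
#' @param midpoint publication count at which the weight is 0.5.
#' @param steepness logistic slope.
#' @return Numeric weights in (0, 1).
#' @export
ppi_weight_logistic <- function(n_pubs, midpoint = 2, steepness = 1) {
  stopifnot(all(n_pubs >= 0))
  1 / (1 + exp(-steepness * (n_pubs - midpoint)))
}

#' Parse an interaction table from TSV
#'
#' Reads the tab-separated interaction dialect with header columns `a_id`,
#' `a_kind`, `b_id`, `b_kind`, `etype`, `weight` (optionally `provenance`
#' and `n_pubs`).  A blank weight on a regulatory edge (`TF_DNA`,
#' `TF_MIRNA`, `MIRNA_RNA`) fills to 1.0, reflecting that transcription
#' regulation edges carry unit weight.  A blank weight on a PPI row falls
#' back to [ppi_weight_logistic()] of the `n_pubs` column when present;
#' otherwise the row is rejected as missing its weight.
#'
#' @param path TSV file path.
#' @param default_weight_policy list with elements `midpoint` and
#'   `steepness` forwarded to [ppi_weight_logistic()] for blank PPI weights.
#' @param build_tag version string for the resulting interactome.
#' @return A validated [interactome()]; rejected rows are reported via the
#'   `"rejected"` attribute.
#' @export
parse_interaction_table <- function(path,
                                    default_weight_policy = list(midpoint = 2,
                                                                 steepness = 1),
                                    build_tag = basename(path)) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           comment.char = "#", quote = "",
                           check.names = FALSE)
  required <- setdiff(INTERACTION_COLUMNS, "provenance")
  if (!all(required %in% names(raw)))
    stop("malformed interaction table header; need columns: ",
         paste(required, collapse = ", "), " (got: ",
         paste(names(raw), collapse = ", "), ")", call. = FALSE)
  if (is.null(raw$provenance)) raw$provenance <- ""
  weight <- suppressWarnings(as.numeric(raw$weight))
  blank <- is.na(weight) | trimws(raw$weight) == ""
  fill_reg <- blank & raw$etype %in% REGULATORY_ETYPES
  weight[fill_reg] <- 1.0
  fill_ppi <- blank & raw$etype == "PPI" & !is.null(raw$n_pubs)
  if (any(fill_ppi) && "n_pubs" %in% names(raw)) {
    n_pubs <- suppressWarnings(as.numeric(raw$n_pubs[fill_ppi]))
    ok <- !is.na(n_pubs)
    weight[fill_ppi][ok] <- ppi_weight_logistic(
      n_pubs[ok],
      midpoint = default_weight_policy$midpoint,
      steepness = default_weight_policy$steepness)
  }
  raw$weight <- weight
  interactome(raw[c(INTERACTION_COLUMNS)], build_tag = build_tag)
}

#' Write an interactome in the canonical TSV dialect
#'
#' Emits the same dialect accepted by [parse_interaction_table()], with rows
#' sorted and PPIs in canonical endpoint order, so that
#' `write_interactome(parse_interaction_table(path))` reproduces the
#' canonicalized table byte-identically.
#'
#' @param net interactome.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(net, path) {
  stopifnot(inherits(net, "interactome"))
  out <- net$edges
  out$weight <- format_weight(out$weight)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

format_weight <- function(w) {
  vapply(w, function(x) format(x, digits = 15, scientific = FALSE,
                               trim = TRUE), "")
}

#' Merge interactomes
#'
#' Node and edge union of several validated interactomes.  Duplicate edges
#' (same endpoints and edge type) keep the maximum weight; identical
#' endpoints under different edge types stay as distinct edges.
#'
#' @param interactomes list of interactomes.
#' @param build_tag version string for the merged interactome.
#' @return A merged [interactome()].
#' @export
merge_interactomes <- function(interactomes, build_tag = "merged") {
  stopifnot(length(interactomes) >= 1,
            all(vapply(interactomes, inherits, TRUE, "interactome")))
  if (length(interactomes) == 1L) {
    net <- interactomes[[1L]]
    attr(net, "rejected") <- empty_rejected_frame()
    return(net)
  }
  edges <- do.call(rbind, lapply(interactomes, `[[`, "edges"))
  interactome(edges, build_tag = build_tag)
}

#' Export an interactome or subnetwork as graph-viewer JSON
#'
#' Writes a JSON document with `nodes` and `edges` element arrays following
#' common graph-viewer conventions (each element has a `data` record with
#' `id`, `label`, `kind` for nodes and `source`, `target`, `etype`,
#' `weight`, and `flow` when available for edges), plus a `config` snapshot
#' when the object carries one.
#'
#' @param x interactome or subnetwork.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
graph_to_json <- function(x, path) {
  if (inherits(x, "subnetwork")) {
    nodes <- x$nodes
    edges <- x$edges
    config <- x$config
  } else if (inherits(x, "interactome")) {
    nodes <- x$nodes
    edges <- x$edges
    config <- list(build_tag = x$build_tag)
  } else stop("graph_to_json needs an interactome or subnetwork")
  node_el <- lapply(seq_len(nrow(nodes)), function(i) {
    d <- list(id = node_key(nodes$id[i], nodes$kind[i]),
              label = nodes$id[i], kind = nodes$kind[i])
    if (!is.null(nodes$role)) d$role <- nodes$role[i]
    if (!is.null(nodes$throughput)) d$throughput <- nodes$throughput[i]
    list(data = d)
  })
  edge_el <- lapply(seq_len(nrow(edges)), function(i) {
    d <- list(source = node_key(edges$a_id[i], edges$a_kind[i]),
              target = node_key(edges$b_id[i], edges$b_kind[i]),
              etype = edges$etype[i], weight = edges$weight[i])
    if (!is.null(edges$flow)) d$flow <- edges$flow[i]
    list(data = d)
  })
  doc <- list(nodes = node_el, edges = edge_el, config = config)
  ann <- attr(x, "annotations")
  if (!is.null(ann) && nrow(ann)) doc$annotations <- ann
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
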