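#' Create a layer from a subnetwork or interactome
#'
#' A layer is a named edge set used as an operand in cross-tissue or
#' cross-run comparisons.  Edge keys are (a, b, etype) under the canonical
#' PPI endpoint order, so layers produced by different runs over the same
#' interactome are directly comparable.  Flow values are run-specific and
#' are carried alongside the keys, never merged.
#'
#' @param x subnetwork, interactome, or a data.frame of edges.
#' @param name non-empty layer name.
#' @return An object of class `layer`: `name` plus an `edges` data.frame
#'   keyed by `a_id`, `a_kind`, `b_id`, `b_kind`, `etype`, with any
#'   `weight`/`flow` columns retained.
#' @export
as_layer <- function(x, name) {
  stopifnot(is.character(name), nzchar(name))
  edges <- if (inherits(x, "subnetwork") || inherits(x, "interactome"))
    x$edges else as.data.frame(x)
  keycols <- c("a_id", "a_kind", "b_id", "b_kind", "etype")
  stopifnot(all(keycols %in% names(edges)))
  extra <- intersect(c("weight", "flow", "flow.x", "flow.y", "provenance"),
                     names(edges))
  edges <- edges[c(keycols, extra)]
  edges <- canonicalize_edges(edges)
  edges <- edges[!duplicated(layer_edge_keys(edges)), , drop = FALSE]
  edges <- sort_edges(edges)
  rownames(edges) <- NULL
  structure(list(name = name, edges = edges), class = "layer")
}

layer_edge_keys <- function(edges) {
  paste(edges$a_id, edges$a_kind, edges$b_id, edges$b_kind, edges$etype,
        sep = "\r")
}

#' @export
print.layer <- function(x, ...) {
  cat("layer '", x$name, "': ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Combine two layers with a set operation
#'
#' Edge-set algebra over layers: `UNION`, `INTERSECTION`, `DIFFERENCE`
#' (x minus y; order matters) or `XOR` (symmetric difference).  The result's
#' node set is exactly the endpoints of the resulting edges.  A
#' `provenance` column marks which input contributed each edge (`"x"`,
#' `"y"` or `"both"`); per-input flow values are kept side by side as
#' `flow.x` / `flow.y` where present.
#'
#' @param x,y layers sharing the edge-key convention.
#' @param op one of `"UNION"`, `"INTERSECTION"`, `"DIFFERENCE"`, `"XOR"`
#'   (case-insensitive).
#' @param name name for the result; defaults to e.g. `"x XOR y"`.
#' @return A `layer` whose `edges` carry `provenance` and per-input flows.
#' @examples
#' a <- as_layer(data.frame(a_id = c("P1", "P2"), a_kind = "PROTEIN",
#'                          b_id = c("P2", "P3"), b_kind = "PROTEIN",
#'                          etype = "PPI"), "a")
#' b <- as_layer(data.frame(a_id = "P2", a_kind = "PROTEIN",
#'                          b_id = "P3", b_kind = "PROTEIN",
#'                          etype = "PPI"), "b")
#' combine_layers(a, b, "intersection")
#' @export
combine_layers <- function(x, y, op, name = NULL) {
  stopifnot(inherits(x, "layer"), inherits(y, "layer"))
  op <- toupper(as.character(op))
  if (!op %in% c("UNION", "INTERSECTION", "DIFFERENCE", "XOR"))
    stop("op must be one of UNION, INTERSECTION, DIFFERENCE, XOR",
         call. = FALSE)
  if (is.null(name)) name <- paste(x$name, op, y$name)

  kx <- layer_edge_keys(x$edges)
  ky <- layer_edge_keys(y$edges)
  keep_x <- switch(op,
                   UNION = rep(TRUE, length(kx)),
                   INTERSECTION = kx %in% ky,
                   DIFFERENCE = !(kx %in% ky),
                   XOR = !(kx %in% ky))
  keep_y <- switch(op,
                   UNION = !(ky %in% kx),
                   INTERSECTION = rep(FALSE, length(ky)),
                   DIFFERENCE = rep(FALSE, length(ky)),
                   XOR = !(ky %in% kx))

  keycols <- c("a_id", "a_kind", "b_id", "b_kind", "etype")
  out <- rbind(x$edges[keep_x, keycols, drop = FALSE],
               y$edges[keep_y, keycols, drop = FALSE])
  k <- layer_edge_keys(out)
  out$provenance <- ifelse(k %in% kx & k %in% ky, "both",
                           ifelse(k %in% kx, "x", "y"))
  # weights agree between runs over the same interactome; prefer x's copy
  if ("weight" %in% names(x$edges) || "weight" %in% names(y$edges)) {
    wx <- if ("weight" %in% names(x$edges)) x$edges$weight[match(k, kx)]
          else rep(NA_real_, length(k))
    wy <- if ("weight" %in% names(y$edges)) y$edges$weight[match(k, ky)]
          else rep(NA_real_, length(k))
    out$weight <- ifelse(is.na(wx), wy, wx)
  }
  # flow values are run-specific: kept side by side, never merged
  if ("flow" %in% names(x$edges)) out$flow.x <- x$edges$flow[match(k, kx)]
  if ("flow" %in% names(y$edges)) out$flow.y <- y$edges$flow[match(k, ky)]
  out <- sort_edges(out)
  rownames(out) <- NULL
  structure(list(name = name, edges = out), class = "layer")
}

#' Project a layer onto its nodes
#'
#' Convenience view for node-level comparison: the unique endpoints of the
#' layer's edges.
#'
#' @param layer a layer.
#' @return data.frame `id`, `kind`.
#' @export
layer_nodes <- function(layer) {
  stopifnot(inherits(layer, "layer"))
  nodes <- unique(data.frame(id = c(layer$edges$a_id, layer$edges$b_id),
                             kind = c(layer$edges$a_kind, layer$edges$b_kind),
                             stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$id, nodes$kind), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes
}

#' Write or read a layer as JSON
#'
#' The JSON document carries the layer name and its edge records; it is the
#' interchange format between runs (the export/import path for comparing
#' subnetworks from different sessions).
#'
#' @param layer a layer.
#' @param path JSON file path.
#' @return `path` (write) or a `layer` (read).
#' @export
write_layer <- function(layer, path) {
  stopifnot(inherits(layer, "layer"))
  jsonlite::write_json(list(name = layer$name, edges = layer$edges),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_layer
#' @export
read_layer <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as.data.frame(doc$edges, stringsAsFactors = FALSE)
  as_layer(edges, doc$name)
}
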