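#' Overlay node annotations on a network
#'
#' Attaches disease associations, drug-target lists and expression
#' variability scores to the nodes of an interactome or subnetwork.  The
#' annotation table is long-format TSV with columns `node_id`, `field`,
#' `value`; recognised fields are `disease`, `drug_target` and
#' `variability`.  Variability scores live on a 0-100 scale: zero for a
#' non-variable gene, 100 for maximum variability across individuals; a
#' node at 100 is flagged maximal.  Rows whose `node_id` matches no node in
#' the network are ignored, and their count is reported.
#'
#' @param net interactome or subnetwork.
#' @param table data.frame with columns `node_id`, `field`, `value`, or a
#'   path to a TSV file with that header.
#' @return `net` with an `"annotations"` attribute (data.frame `node_id`,
#'   `field`, `value`, `maximal_variability`) and an `"ignored"` attribute
#'   holding the unmatched-row count.
#' @examples
#' net <- interactome(data.frame(a_id = "P1", a_kind = "PROTEIN",
#'                               b_id = "G1", b_kind = "GENE",
#'                               etype = "TF_DNA", weight = 1))
#' ann <- data.frame(node_id = "P1", field = "variability", value = "100")
#' net <- annotate_network(net, ann)
#' attr(net, "annotations")
#' @export
annotate_network <- function(net, table) {
  stopifnot(inherits(net, "interactome") || inherits(net, "subnetwork"))
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.delim(table, sep = "\t", colClasses = "character",
                               quote = "", check.names = FALSE)
  if (!all(c("node_id", "field", "value") %in% names(table)))
    stop("annotation table needs columns node_id, field, value",
         call. = FALSE)
  if (nrow(table) == 0L) {
    attr(net, "annotations") <- empty_annotation_frame()
    attr(net, "ignored") <- 0L
    return(net)
  }
  table <- data.frame(node_id = as.character(table$node_id),
                      field = as.character(table$field),
                      value = as.character(table$value),
                      stringsAsFactors = FALSE)

  is_var <- table$field == "variability"
  if (any(is_var)) {
    v <- suppressWarnings(as.numeric(table$value[is_var]))
    if (anyNA(v) || any(v < 0 | v > 100))
      stop("variability scores must be numeric in [0, 100]", call. = FALSE)
  }

  ids <- node_ids(net)
  matched <- table$node_id %in% ids
  n_ignored <- sum(!matched)
  if (n_ignored)
    message(n_ignored, " annotation row(s) ignored: node id not in network")
  ann <- table[matched, , drop = FALSE]
  ann$maximal_variability <- ann$field == "variability" &
    suppressWarnings(as.numeric(ann$value)) == 100
  rownames(ann) <- NULL
  attr(net, "annotations") <- ann
  attr(net, "ignored") <- n_ignored
  net
}

empty_annotation_frame <- function() {
  data.frame(node_id = character(), field = character(), value = character(),
             maximal_variability = logical(), stringsAsFactors = FALSE)
}

node_ids <- function(net) {
  if (inherits(net, "interactome")) net$nodes$id else net$nodes$id
}
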