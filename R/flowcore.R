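#' Encode the source-to-target flow linear program
#'
#' Builds the minimum-cost-flow encoding that connects a source set of
#' proteins to a target set of genes, proteins or microRNAs through the
#' interactome.  Every interactome edge of weight w becomes one arc (two
#' antiparallel arcs for an undirected PPI) with unit cost -ln(w) >= 0 and
#' capacity `edge_capacity`.  An auxiliary source S feeds each usable source
#' s through an arc of capacity `source_weights[s]`, and each usable target
#' t drains to an auxiliary sink T through an arc of capacity
#' `target_weights[t]`; both weight vectors default to uniform and are
#' normalized to sum to 1, so total flow is bounded by 1.  The reward
#' `gamma` per unit of flow leaving S makes total flow a free variable of
#' the optimization and trades subnetwork size against edge reliability.
#'
#' Gene nodes have no outgoing interactome arcs, so any path reaching a
#' gene target necessarily ends with its single incoming regulatory edge;
#' protein targets connect directly to T with no regulatory-terminal
#' requirement; microRNA targets are reached via their incoming TF-microRNA
#' edge.  A node that is both a source and a target is duplicated: the
#' original copy keeps the S arc and all outgoing arcs, a target copy
#' receives parallels of all incoming arcs plus the arc to T, so trivial
#' S -> node -> T shortcuts cannot occur.
#'
#' Source or target identifiers absent from the interactome are not fatal:
#' they are listed in the `unmatched` report (some input proteins and genes
#' might simply not be connectable).  An empty usable source or target set
#' is an error.
#'
#' @param net interactome.
#' @param sources character vector of source protein ids, or a named numeric
#'   vector of positive weights.
#' @param targets character vector of target ids (gene, microRNA or protein;
#'   when an id exists under several kinds, GENE is preferred, then MIRNA,
#'   then PROTEIN), or a named numeric vector of positive weights.
#' @param gamma flow reward per unit of total flow (default 10).
#' @param edge_capacity capacity of every interactome arc (default 1.0,
#'   non-binding since total flow is at most 1).
#' @return An object of class `flow_problem`.
#' @export
build_flow_problem <- function(net, sources, targets, gamma = 10,
                               edge_capacity = 1.0) {
  stopifnot(inherits(net, "interactome"), gamma >= 0, edge_capacity > 0)
  src <- normalize_weighted_set(sources)
  tgt <- normalize_weighted_set(targets)

  nodes <- net$nodes
  keys <- node_key(nodes$id, nodes$kind)

  src_ok <- src$id %in% nodes$id[nodes$kind == "PROTEIN"]
  unmatched_sources <- src$id[!src_ok]
  src <- src[src_ok, , drop = FALSE]

  tgt$kind <- vapply(tgt$id, function(id) {
    kinds <- nodes$kind[nodes$id == id]
    if ("GENE" %in% kinds) "GENE"
    else if ("MIRNA" %in% kinds) "MIRNA"
    else if ("PROTEIN" %in% kinds) "PROTEIN"
    else NA_character_
  }, "")
  unmatched_targets <- tgt$id[is.na(tgt$kind)]
  tgt <- tgt[!is.na(tgt$kind), , drop = FALSE]

  if (!nrow(src)) stop("no usable source node", call. = FALSE)
  if (!nrow(tgt)) stop("no usable target node", call. = FALSE)
  src$weight <- src$weight / sum(src$weight)
  tgt$weight <- tgt$weight / sum(tgt$weight)

  src$key <- node_key(src$id, "PROTEIN")
  tgt$key <- node_key(tgt$id, tgt$kind)
  overlap <- tgt$key %in% src$key
  tgt$dup_key <- ifelse(overlap, paste0(tgt$key, "\r@target"), tgt$key)

  all_keys <- c(keys, tgt$dup_key[overlap], "\rS", "\rT")
  idx <- stats::setNames(seq_along(all_keys), all_keys)
  S <- idx[["\rS"]]; T_ <- idx[["\rT"]]

  e <- net$edges
  ka <- node_key(e$a_id, e$a_kind)
  kb <- node_key(e$b_id, e$b_kind)
  cost <- -log(e$weight)
  is_ppi <- e$etype == "PPI"

  from <- c(idx[ka], idx[kb[is_ppi]])
  to <- c(idx[kb], idx[ka[is_ppi]])
  acost <- c(cost, cost[is_ppi])
  eidx <- c(seq_len(nrow(e)), which(is_ppi))
  forward <- c(rep(TRUE, nrow(e)), rep(FALSE, sum(is_ppi)))

  # antiparallel partner bookkeeping for the cancellation post-pass
  pair <- rep(NA_integer_, length(from))
  if (any(is_ppi)) {
    fwd_pos <- which(is_ppi)                     # positions of forward PPI arcs
    bwd_pos <- nrow(e) + seq_len(sum(is_ppi))    # their antiparallel twins
    pair[fwd_pos] <- bwd_pos
    pair[bwd_pos] <- fwd_pos
  }

  # duplicated source-and-target nodes: parallel copies of incoming arcs
  if (any(overlap)) {
    for (j in which(overlap)) {
      dup <- idx[[tgt$dup_key[j]]]
      orig <- idx[[tgt$key[j]]]
      inc <- which(to == orig)
      if (length(inc)) {
        from <- c(from, from[inc]); to <- c(to, rep(dup, length(inc)))
        acost <- c(acost, acost[inc]); eidx <- c(eidx, eidx[inc])
        forward <- c(forward, forward[inc])
        pair <- c(pair, rep(NA_integer_, length(inc)))
      }
    }
  }

  arcs <- data.frame(from = unname(from), to = unname(to),
                     cap = edge_capacity, cost = unname(acost),
                     type = "edge", edge_index = unname(eidx),
                     forward = unname(forward), pair = pair,
                     stringsAsFactors = FALSE)
  s_arcs <- data.frame(from = S, to = unname(idx[src$key]), cap = src$weight,
                       cost = 0, type = "S", edge_index = NA_integer_,
                       forward = TRUE, pair = NA_integer_)
  t_arcs <- data.frame(from = unname(idx[tgt$dup_key]), to = T_,
                       cap = tgt$weight, cost = 0, type = "T",
                       edge_index = NA_integer_, forward = TRUE,
                       pair = NA_integer_)
  arcs <- rbind(arcs, s_arcs, t_arcs)
  rownames(arcs) <- NULL

  node_tab <- data.frame(
    key = all_keys,
    id = c(nodes$id, tgt$id[overlap], "<S>", "<T>"),
    kind = c(nodes$kind, tgt$kind[overlap], "AUX", "AUX"),
    stringsAsFactors = FALSE)

  structure(list(nodes = node_tab, arcs = arcs, S = S, T = T_,
                 gamma = gamma, edges = e,
                 sources = src[, c("id", "weight", "key")],
                 targets = tgt[, c("id", "kind", "weight", "key", "dup_key")],
                 unmatched = list(sources = unmatched_sources,
                                  targets = unmatched_targets),
                 build_tag = net$build_tag),
            class = "flow_problem")
}

normalize_weighted_set <- function(x) {
  if (is.numeric(x)) {
    stopifnot(!is.null(names(x)), all(x > 0))
    data.frame(id = names(x), weight = unname(x), stringsAsFactors = FALSE)
  } else {
    x <- unique(as.character(x))
    data.frame(id = x, weight = rep(1, length(x)), stringsAsFactors = FALSE)
  }
}

#' @export
print.flow_problem <- function(x, ...) {
  cat("flow_problem: ", nrow(x$nodes), " nodes, ", nrow(x$arcs),
      " arcs, gamma = ", x$gamma, "; ", nrow(x$sources), " source(s), ",
      nrow(x$targets), " target(s)\n", sep = "")
  if (length(x$unmatched$sources) || length(x$unmatched$targets))
    cat("  not connectable: ",
        paste(c(x$unmatched$sources, x$unmatched$targets), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Solve the flow linear program
#'
#' Computes an optimal solution of
#' minimize sum(cost * flow) - gamma * sum(flow out of S)
#' subject to flow conservation at every non-auxiliary node and
#' 0 <= flow <= capacity on every arc.  The optimum is found by successive
#' shortest-path augmentation with Johnson potentials: while the cheapest
#' residual S-to-T path costs less than gamma, the bottleneck amount is
#' pushed along it.  Because all arc costs are non-negative and the reward
#' applies only to flow leaving S, this yields the exact optimum of the
#' linear program.  Antiparallel flows on the two arcs of an undirected PPI
#' are cancelled pairwise afterwards (never increases cost; restores
#' physical interpretability when zero-cost regulatory arcs admit
#' degenerate optima).
#'
#' @param p flow_problem.
#' @return An object of class `flow_solution`: per-arc `flow`, `objective`,
#'   `total_flow` out of S, `status` and `solver` tag.
#' @export
solve_flow <- function(p) {
  stopifnot(inherits(p, "flow_problem"))
  n <- nrow(p$nodes)
  arcs <- p$arcs
  m <- nrow(arcs)
  tol <- 1e-12

  flow <- numeric(m)
  afrom <- arcs$from; ato <- arcs$to; acap <- arcs$cap; acost <- arcs$cost

  max_aug <- 10L * m + 100L
  for (aug in seq_len(max_aug + 1L)) {
    if (aug > max_aug)
      stop("flow solver failed to converge (", max_aug, " augmentations)",
           call. = FALSE)
    # residual network: forward arcs with spare capacity, backward arcs
    # with positive flow (negated cost)
    fw <- which(acap - flow > tol)
    bw <- which(flow > tol)
    tails <- c(afrom[fw], ato[bw])
    heads <- c(ato[fw], afrom[bw])
    costs <- c(acost[fw], -acost[bw])
    rid <- c(fw, -bw)                 # signed arc id of each residual arc

    sp <- bellman_ford(n, tails, heads, costs, p$S)
    if (!is.finite(sp$dist[p$T])) break
    if (sp$dist[p$T] >= p$gamma - 1e-9) break

    # trace the shortest S->T path and push the bottleneck along it
    path <- integer(0)
    v <- p$T
    while (v != p$S) {
      r <- sp$prev[v]
      path <- c(r, path)
      v <- tails[r]
    }
    res <- ifelse(rid[path] > 0,
                  acap[abs(rid[path])] - flow[abs(rid[path])],
                  flow[abs(rid[path])])
    bott <- min(res)
    for (r in path) {
      j <- abs(rid[r])
      flow[j] <- flow[j] + if (rid[r] > 0) bott else -bott
    }
  }

  # cancel antiparallel PPI flow
  has_pair <- which(!is.na(arcs$pair) & arcs$pair > seq_len(m))
  for (j in has_pair) {
    k <- arcs$pair[j]
    c0 <- min(flow[j], flow[k])
    if (c0 > 0) { flow[j] <- flow[j] - c0; flow[k] <- flow[k] - c0 }
  }
  flow[flow < tol] <- 0

  total_flow <- sum(flow[arcs$type == "S"])
  objective <- sum(acost * flow) - p$gamma * total_flow

  sol <- structure(list(flow = flow, objective = objective,
                        total_flow = total_flow, status = "optimal",
                        solver = paste0("respnet-ssp/",
                                        as.character(utils::packageVersion("respnet")))),
                   class = "flow_solution")
  check_conservation(sol, p)
  sol
}

# Vectorized label-correcting shortest path (synchronous Bellman-Ford
# rounds).  The residual network of a partial successive-shortest-path
# solution has no negative cycle, so at most n rounds are needed.
# prev[v] = index (into tails/heads/costs) of the arc that last improved v.
bellman_ford <- function(n, tails, heads, costs, S) {
  dist <- rep(Inf, n)
  dist[S] <- 0
  prev <- integer(n)
  if (!length(tails)) return(list(dist = dist, prev = prev))
  for (pass in seq_len(n + 1L)) {
    cand <- dist[tails] + costs
    better <- which(cand < dist[heads] - 1e-15)
    if (!length(better)) return(list(dist = dist, prev = prev))
    if (pass > n)
      stop("negative cycle in residual network", call. = FALSE)
    o <- better[order(heads[better], cand[better])]
    first <- o[!duplicated(heads[o])]
    dist[heads[first]] <- cand[first]
    prev[heads[first]] <- first
  }
  list(dist = dist, prev = prev)
}

# node balance must vanish everywhere except S and T; capacities must hold
check_conservation <- function(sol, p, tol = 1e-8) {
  arcs <- p$arcs
  bal <- numeric(nrow(p$nodes))
  for (j in seq_len(nrow(arcs))) {
    bal[arcs$from[j]] <- bal[arcs$from[j]] - sol$flow[j]
    bal[arcs$to[j]] <- bal[arcs$to[j]] + sol$flow[j]
  }
  bal[c(p$S, p$T)] <- 0
  if (any(abs(bal) > tol))
    stop("flow conservation violated (max imbalance ",
         max(abs(bal)), ")", call. = FALSE)
  if (any(sol$flow < -tol) || any(sol$flow > arcs$cap + tol))
    stop("capacity bounds violated", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("flow_solution [", x$status, "]: total flow ",
      signif(x$total_flow, 6), ", objective ", signif(x$objective, 6),
      " (", x$solver, ")\n", sep = "")
  invisible(x)
}

#' Extract the positive-flow subnetwork
#'
#' Keeps interactome arcs carrying more than `eps` flow, maps them back to
#' interactions, and drops the auxiliary arcs.  Reports the connected
#' sources (positive flow on their S arc), connected targets (positive flow
#' on their T arc), and the connecting nodes: subnetwork nodes that are
#' neither sources nor targets, the method's novel predictions.
#'
#' @param sol flow_solution.
#' @param p the flow_problem it solves.
#' @param eps flow threshold (default 1e-6, three orders of magnitude above
#'   solver tolerance).
#' @return An object of class `subnetwork` with components `edges` (with
#'   `flow` and, for PPIs, `flow_direction`), `nodes` (`id`, `kind`, `role`,
#'   `throughput`), `connected_sources`, `connected_targets`,
#'   `n_connecting` and a `config` snapshot.
#' @export
extract_subnetwork <- function(sol, p, eps = 1e-6) {
  stopifnot(inherits(sol, "flow_solution"), inherits(p, "flow_problem"),
            sol$status == "optimal")
  arcs <- p$arcs
  keep <- arcs$type == "edge" & sol$flow > eps
  # aggregate duplicated-target parallels onto their interactome edge
  ekey <- paste(arcs$edge_index, arcs$forward)
  agg <- tapply(sol$flow[keep], ekey[keep], sum)

  edges <- empty_edge_frame()
  edges$flow <- numeric(); edges$flow_direction <- character()
  if (length(agg)) {
    parts <- strsplit(names(agg), " ")
    eidx <- as.integer(vapply(parts, `[[`, "", 1L))
    fwd <- vapply(parts, `[[`, "", 2L) == "TRUE"
    # an interactome edge may appear once per direction; with antiparallel
    # cancellation at most one direction is positive for a PPI
    edges <- p$edges[eidx, , drop = FALSE]
    edges$flow <- as.numeric(agg)
    edges$flow_direction <- ifelse(fwd, "a_to_b", "b_to_a")
    o <- order(edges$a_id, edges$b_id, edges$etype)
    edges <- edges[o, , drop = FALSE]
    rownames(edges) <- NULL
  }

  s_arcs <- which(arcs$type == "S")
  t_arcs <- which(arcs$type == "T")
  connected_sources <- p$sources$id[sol$flow[s_arcs] > eps]
  connected_targets <- p$targets$id[sol$flow[t_arcs] > eps]

  nodes <- unique(data.frame(
    id = c(edges$a_id, edges$b_id),
    kind = c(edges$a_kind, edges$b_kind),
    stringsAsFactors = FALSE))
  if (nrow(nodes)) {
    key <- node_key(nodes$id, nodes$kind)
    src_keys <- p$sources$key[sol$flow[s_arcs] > eps]
    tgt_keys <- p$targets$key[sol$flow[t_arcs] > eps]
    nodes$role <- ifelse(key %in% src_keys, "source",
                         ifelse(key %in% tgt_keys, "target", "connecting"))
    nodes$throughput <- node_throughput(sol, p, key, eps)
    nodes <- nodes[order(nodes$id, nodes$kind), , drop = FALSE]
    rownames(nodes) <- NULL
  } else {
    nodes <- data.frame(id = character(), kind = character(),
                        role = character(), throughput = numeric(),
                        stringsAsFactors = FALSE)
  }

  structure(list(edges = edges, nodes = nodes,
                 connected_sources = connected_sources,
                 connected_targets = connected_targets,
                 n_connecting = sum(nodes$role == "connecting"),
                 config = list(gamma = p$gamma, eps = eps,
                               build_tag = p$build_tag,
                               solver = sol$solver,
                               objective = sol$objective,
                               total_flow = sol$total_flow)),
            class = "subnetwork")
}

# total inflow per node key (S arcs count as inflow into sources)
node_throughput <- function(sol, p, keys, eps) {
  arcs <- p$arcs
  vapply(keys, function(k) {
    v <- match(k, p$nodes$key)
    dup <- match(paste0(k, "\r@target"), p$nodes$key)
    heads <- c(v, if (!is.na(dup)) dup)
    sum(sol$flow[arcs$to %in% heads])
  }, 0)
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("subnetwork: ", nrow(x$edges), " edges, ", nrow(x$nodes), " nodes (",
      length(x$connected_sources), " sources, ",
      length(x$connected_targets), " targets, ", x$n_connecting,
      " connecting)\n", sep = "")
  cat("  gamma = ", x$config$gamma, ", total flow = ",
      signif(x$config$total_flow, 6), "\n", sep = "")
  invisible(x)
}

#' Run the full pathway inference in one call
#'
#' Convenience wrapper: build the flow problem, solve it, extract the
#' positive-flow subnetwork.
#'
#' @inheritParams build_flow_problem
#' @param eps flow threshold for extraction.
#' @return A `subnetwork`.
#' @export
infer_subnetwork <- function(net, sources, targets, gamma = 10,
                             edge_capacity = 1.0, eps = 1e-6) {
  p <- build_flow_problem(net, sources, targets, gamma = gamma,
                          edge_capacity = edge_capacity)
  extract_subnetwork(solve_flow(p), p, eps = eps)
}

#' Empirical p-value from randomization hit counts
#'
#' `(1 + hits) / (1 + n_rand)`: the add-one estimator that never returns 0
#' and equals 1 when a node appears in every randomized run.
#'
#' @param hits number of randomized runs containing the node.
#' @param n_rand number of randomized runs.
#' @return Numeric p-values in (0, 1].
#' @export
empirical_pvalue <- function(hits, n_rand) {
  stopifnot(n_rand >= 1, all(hits >= 0), all(hits <= n_rand))
  (1 + hits) / (1 + n_rand)
}

#' Empirical node significance by degree-matched randomization
#'
#' Repeats the full inference `n_rand` times with the source and target
#' sets replaced by random node sets matched on degree (each replacement is
#' drawn from nodes of the same kind within +/- 1 degree-decile bin of the
#' original, excluding the real input sets themselves -- the null asks how
#' often a node is recruited by typical inputs, so re-drawing the actual
#' inputs would defeat it; if fewer than 3 candidates exist the draw falls
#' back to uniform sampling over same-kind non-input nodes, with a
#' warning).  For every node of the real subnetwork, p = (1 + number of
#' randomized subnetworks containing it) / (1 + n_rand).
#'
#' @param net interactome.
#' @param sources,targets as in [build_flow_problem()].
#' @param n_rand number of randomizations (>= 1).
#' @param seed integer seed; fixed seed gives byte-identical reports.
#' @param gamma flow reward.
#' @param eps extraction threshold.
#' @param report `"subnetwork"` (default) scores the nodes of the real
#'   subnetwork; `"all"` scores every interactome node (useful for
#'   benchmarking the null itself).
#' @return A data.frame `id`, `kind`, `role`, `hits`, `p`, sorted by p;
#'   the real subnetwork is attached as attribute `"subnetwork"`.
#' @export
node_significance <- function(net, sources, targets, n_rand = 100, seed = 1,
                              gamma = 10, eps = 1e-6,
                              report = c("subnetwork", "all")) {
  stopifnot(n_rand >= 1)
  report <- match.arg(report)
  set.seed(seed)
  real <- infer_subnetwork(net, sources, targets, gamma = gamma, eps = eps)
  if (!nrow(real$nodes) && report == "subnetwork") {
    out <- data.frame(id = character(), kind = character(),
                      role = character(), hits = integer(), p = numeric())
    attr(out, "subnetwork") <- real
    return(out)
  }
  if (report == "subnetwork") {
    scored <- real$nodes[, c("id", "kind", "role")]
  } else {
    scored <- net$nodes
    in_real <- node_key(scored$id, scored$kind) %in%
      node_key(real$nodes$id, real$nodes$kind)
    scored$role <- ifelse(in_real,
                          real$nodes$role[match(node_key(scored$id, scored$kind),
                                                node_key(real$nodes$id,
                                                         real$nodes$kind))],
                          "absent")
  }
  real_keys <- node_key(scored$id, scored$kind)

  deg <- node_degrees(net)
  bins <- degree_decile_bins(deg)

  p0 <- build_flow_problem(net, sources, targets, gamma = gamma)
  src_ids <- p0$sources$id
  tgt_ids <- p0$targets$id
  tgt_kinds <- p0$targets$kind

  exclude <- c(node_key(src_ids, "PROTEIN"), node_key(tgt_ids, tgt_kinds))

  hits <- integer(length(real_keys))
  for (r in seq_len(n_rand)) {
    rs <- vapply(src_ids, function(id) {
      draw_degree_matched(id, "PROTEIN", net, deg, bins, exclude)
    }, "")
    rt <- vapply(seq_along(tgt_ids), function(i) {
      draw_degree_matched(tgt_ids[i], tgt_kinds[i], net, deg, bins, exclude)
    }, "")
    sub <- tryCatch(
      infer_subnetwork(net, unique(rs), unique(rt), gamma = gamma, eps = eps),
      error = function(e) NULL)
    if (is.null(sub) || !nrow(sub$nodes)) next
    keys_r <- node_key(sub$nodes$id, sub$nodes$kind)
    hits <- hits + as.integer(real_keys %in% keys_r)
  }

  out <- data.frame(id = scored$id, kind = scored$kind,
                    role = scored$role, hits = hits,
                    p = empirical_pvalue(hits, n_rand),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "subnetwork") <- real
  out
}

node_degrees <- function(net) {
  keys <- c(node_key(net$edges$a_id, net$edges$a_kind),
            node_key(net$edges$b_id, net$edges$b_kind))
  tab <- table(keys)
  all_keys <- node_key(net$nodes$id, net$nodes$kind)
  d <- stats::setNames(rep(0L, length(all_keys)), all_keys)
  d[names(tab)] <- as.integer(tab)
  d
}

degree_decile_bins <- function(deg) {
  qs <- unique(stats::quantile(deg, probs = seq(0, 1, 0.1), names = FALSE))
  if (length(qs) < 2L) return(stats::setNames(rep(1L, length(deg)), names(deg)))
  b <- cut(deg, breaks = qs, include.lowest = TRUE, labels = FALSE)
  stats::setNames(as.integer(b), names(deg))
}

draw_degree_matched <- function(id, kind, net, deg, bins,
                                exclude = character()) {
  key <- node_key(id, kind)
  same_kind <- node_key(net$nodes$id[net$nodes$kind == kind], kind)
  same_kind <- setdiff(same_kind, exclude)
  cand <- same_kind[abs(bins[same_kind] - bins[[key]]) <= 1L]
  if (length(cand) < 3L) {
    warning("insufficient degree-matched candidates for ", id,
            "; falling back to uniform sampling", call. = FALSE)
    cand <- same_kind
  }
  if (!length(cand)) return(id)  # nothing to swap with; keep the original
  picked <- cand[sample.int(length(cand), 1L)]
  strsplit(picked, "\r", fixed = TRUE)[[1L]][1L]
}

#' Write a subnetwork as TSV
#'
#' Edge table in the interaction dialect plus `flow`, `flow_direction`,
#' `a_role` and `b_role` columns; the run configuration is embedded as a
#' single `# config:` JSON comment line, so an output can be regenerated
#' from its embedded config and inputs.
#'
#' @param sub subnetwork.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subnetwork <- function(sub, path) {
  stopifnot(inherits(sub, "subnetwork"))
  role_of <- stats::setNames(sub$nodes$role,
                             node_key(sub$nodes$id, sub$nodes$kind))
  out <- sub$edges
  if (nrow(out)) {
    out$a_role <- unname(role_of[node_key(out$a_id, out$a_kind)])
    out$b_role <- unname(role_of[node_key(out$b_id, out$b_kind)])
    out$weight <- format_weight(out$weight)
  } else {
    out$a_role <- character(); out$b_role <- character()
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config: ",
                    jsonlite::toJSON(sub$config, auto_unbox = TRUE,
                                     digits = NA)), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
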