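# Independent oracles: scipy.linprog (via the system python) for the flow
# LP, edgeR for TMM factors, and a plain DFS for path enumeration.  These
# never touch the package's own solver code paths.

lp_oracle_script <- function() {
  system.file("oracle", "lp_oracle.py", package = "respnet")
}

# Enumerate all simple S->T paths of a flow_problem as 1-based arc-index
# vectors, by depth-first search over the arc list (independent of the
# solver's residual machinery).
enumerate_st_paths <- function(p, max_paths = 5000) {
  arcs <- p$arcs
  out_of <- split(seq_len(nrow(arcs)), arcs$from)
  paths <- list()
  walk <- function(v, visited, arc_path) {
    if (length(paths) >= max_paths) return(invisible())
    if (v == p$T) {
      paths[[length(paths) + 1L]] <<- arc_path
      return(invisible())
    }
    for (j in out_of[[as.character(v)]]) {
      w <- arcs$to[j]
      if (w %in% visited) next
      walk(w, c(visited, w), c(arc_path, j))
    }
  }
  walk(p$S, p$S, integer())
  paths
}

# Solve a batch of flow_problems with scipy.linprog in both the arc and the
# path-decomposition formulation.  Returns a data.frame of objectives.
scipy_lp_batch <- function(problems, with_paths = TRUE) {
  payload <- lapply(problems, function(p) {
    list(n = nrow(p$nodes), S = p$S, T = p$T, gamma = p$gamma,
         arcs = lapply(seq_len(nrow(p$arcs)), function(j) {
           list(p$arcs$from[j], p$arcs$to[j], p$arcs$cap[j], p$arcs$cost[j])
         }),
         paths = if (with_paths) enumerate_st_paths(p) else NULL)
  })
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2("python", c(lp_oracle_script(), fin, fout),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout))
    stop("lp oracle failed: ", paste(status, collapse = "\n"))
  res <- jsonlite::read_json(fout, simplifyVector = FALSE)
  data.frame(
    objective_arc = vapply(res, function(r) r$objective_arc, 0),
    objective_path = vapply(res, function(r) {
      if (is.null(r$objective_path)) NA_real_ else r$objective_path
    }, 0))
}

have_python_scipy <- function() {
  out <- suppressWarnings(
    system2("python", c("-c", "import scipy.optimize"),
            stdout = FALSE, stderr = FALSE))
  identical(out, 0L)
}

# edgeR reference TMM factors + cpm for a count_matrix
edger_tmm_oracle <- function(cm) {
  f <- edgeR::normLibSizes(cm$counts, method = "TMM")
  lib <- colSums(cm$counts)
  list(norm_factors = f,
       cpm = t(t(cm$counts) / (lib * f)) * 1e6)
}
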