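#' Generate an interactome with planted source-to-target pathways
#'
#' Builds a typed interactome containing `n_paths` planted high-weight
#' pathways buried in low-weight Erdos-Renyi PPI noise, together with the
#' matching source/target sets and a ground-truth record.  Each planted
#' path runs source protein -> (PPIs) -> transcription factor ->
#' (TF-DNA edge) -> gene target, all at weight `w_planted`; `path_len`
#' counts the edges including the terminal regulatory edge.  Noise PPIs
#' among all proteins are sampled at `noise_density` and weight `w_noise`.
#' When microRNAs are requested, each one is wired as a decoy regulatory
#' chain (noise protein -> TF_MIRNA -> microRNA -> MIRNA_RNA -> decoy
#' gene, weight 1 as all regulatory edges) reachable only through noise
#' PPIs, exercising all four edge types without touching the planted
#' truth.  Planted and noise edge sets are disjoint by construction.
#'
#' Defaults describe the benchmark world used throughout the test suite:
#' reliable pathways (w = 0.9, cost 0.105 per PPI hop) hidden among
#' unreliable noise (w = 0.2, cost 1.609), at a density giving roughly 200
#' noise PPIs among 60 proteins.
#'
#' @param n_proteins,n_genes,n_mirnas node counts per kind.
#' @param n_paths number of planted pathways.
#' @param path_len edges per planted path, >= 2 (at least one PPI plus the
#'   regulatory terminal).
#' @param w_planted,w_noise edge weights of planted and noise PPIs.
#' @param noise_density Erdos-Renyi probability of a noise PPI.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with components `net` (interactome), `sources`, `targets`
#'   (character vectors) and `truth` (class `planted_truth`: `planted_keys`,
#'   `noise_keys`, `planted_paths`, `seed`).
#' @export
make_planted_interactome <- function(n_proteins = 60, n_genes = 10,
                                     n_mirnas = 5, n_paths = 3,
                                     path_len = 3, w_planted = 0.9,
                                     w_noise = 0.2, noise_density = 0.11,
                                     seed = 1) {
  stopifnot(path_len >= 2, n_paths >= 0,
            w_planted > 0, w_planted <= 1, w_noise > 0, w_noise <= 1,
            noise_density >= 0, noise_density <= 1)
  needed <- n_paths * (path_len - 1) + n_paths  # path proteins incl. TF
  if (needed > n_proteins)
    stop("infeasible: ", n_paths, " paths of length ", path_len,
         " need more than ", n_proteins, " proteins", call. = FALSE)
  if (n_paths > n_genes)
    stop("infeasible: more paths than gene targets", call. = FALSE)
  set.seed(seed)

  proteins <- sprintf("P%03d", seq_len(n_proteins))
  genes <- sprintf("G%03d", seq_len(n_genes))
  mirnas <- if (n_mirnas > 0) sprintf("miR-%02d", seq_len(n_mirnas))
            else character()

  rows <- list()
  planted_paths <- list()
  used <- character()
  sources <- character(n_paths)
  targets <- character(n_paths)
  for (k in seq_len(n_paths)) {
    chain <- proteins[(k - 1) * path_len + seq_len(path_len)]  # src..TF
    used <- c(used, chain)
    gene <- genes[k]
    sources[k] <- chain[1L]
    targets[k] <- gene
    path_rows <- list()
    for (i in seq_len(path_len - 1L)) {
      path_rows[[i]] <- data.frame(
        a_id = chain[i], a_kind = "PROTEIN", b_id = chain[i + 1L],
        b_kind = "PROTEIN", etype = "PPI", weight = w_planted,
        provenance = "planted", stringsAsFactors = FALSE)
    }
    path_rows[[path_len]] <- data.frame(
      a_id = chain[path_len], a_kind = "PROTEIN", b_id = gene,
      b_kind = "GENE", etype = "TF_DNA", weight = w_planted,
      provenance = "planted", stringsAsFactors = FALSE)
    path_df <- do.call(rbind, path_rows)
    rows[[length(rows) + 1L]] <- path_df
    planted_paths[[k]] <- layer_edge_keys(canonicalize_edges(path_df))
  }

  planted_pairs <- character()
  if (n_paths > 0) {
    pl <- do.call(rbind, rows)
    ppi <- pl[pl$etype == "PPI", , drop = FALSE]
    planted_pairs <- paste(pmin(ppi$a_id, ppi$b_id),
                           pmax(ppi$a_id, ppi$b_id))
  }

  # Erdos-Renyi noise PPIs over all proteins, skipping planted pairs
  if (noise_density > 0 && n_proteins >= 2) {
    combs <- utils::combn(proteins, 2L)
    pair_id <- paste(pmin(combs[1L, ], combs[2L, ]),
                     pmax(combs[1L, ], combs[2L, ]))
    pick <- stats::runif(ncol(combs)) < noise_density & !(pair_id %in% planted_pairs)
    if (any(pick)) {
      rows[[length(rows) + 1L]] <- data.frame(
        a_id = combs[1L, pick], a_kind = "PROTEIN",
        b_id = combs[2L, pick], b_kind = "PROTEIN", etype = "PPI",
        weight = w_noise, provenance = "noise", stringsAsFactors = FALSE)
    }
  }

  # decoy microRNA chains on genes not used as planted targets
  if (n_mirnas > 0) {
    free_genes <- setdiff(genes, targets)
    if (length(free_genes) == 0L) free_genes <- genes[0]
    noise_prot <- setdiff(proteins, used)
    if (length(noise_prot) == 0L) noise_prot <- proteins
    for (mi in seq_along(mirnas)) {
      tf <- noise_prot[1L + (mi - 1L) %% length(noise_prot)]
      rows[[length(rows) + 1L]] <- data.frame(
        a_id = tf, a_kind = "PROTEIN", b_id = mirnas[mi], b_kind = "MIRNA",
        etype = "TF_MIRNA", weight = 1, provenance = "noise",
        stringsAsFactors = FALSE)
      if (length(free_genes)) {
        g <- free_genes[1L + (mi - 1L) %% length(free_genes)]
        rows[[length(rows) + 1L]] <- data.frame(
          a_id = mirnas[mi], a_kind = "MIRNA", b_id = g, b_kind = "GENE",
          etype = "MIRNA_RNA", weight = 1, provenance = "noise",
          stringsAsFactors = FALSE)
      }
    }
  }

  edges <- do.call(rbind, rows)
  net <- interactome(edges, build_tag = paste0("synthetic-planted-seed", seed))
  all_keys <- layer_edge_keys(net$edges)
  planted_keys <- sort(unique(unlist(planted_paths)))
  truth <- structure(list(planted_paths = planted_paths,
                          planted_keys = planted_keys,
                          noise_keys = setdiff(all_keys, planted_keys),
                          seed = seed),
                     class = "planted_truth")
  stopifnot(length(intersect(truth$planted_keys, truth$noise_keys)) == 0L)
  list(net = net, sources = sources, targets = targets, truth = truth)
}

#' Generate a GTEx-like synthetic count matrix with known expressed sets
#'
#' Negative-binomial RNA-seq counts for several tissues with a planted
#' expressed gene set per tissue.  Each tissue draws `expressed_frac` of
#' the genes as expressed at a nominal `mean_expressed_cpm`; the rest sit
#' at `mean_silent_cpm`.  Library sizes are log-uniform over
#' `libsize_range`, so TMM normalization is exercised meaningfully.
#' `dispersion = 0` gives Poisson counts.
#'
#' Counts per million are a closed composition: a small synthetic gene
#' panel cannot both sit at its nominal cpm and account for the whole
#' library.  The generator therefore adds `n_background` housekeeping
#' filler genes (ids `BG...`), expressed in every tissue, that absorb the
#' remaining library mass, so that the realized cpm of every panel gene
#' matches its nominal value.  Background genes are part of each tissue's
#' `expressed_truth` (they are genuinely expressed everywhere).
#'
#' @param genes number of genes or a character vector of gene ids.
#' @param tissues number of tissues or a character vector of tissue names.
#' @param samples_per_tissue samples per tissue (default 20, enough for the
#'   default at-least-10-samples filters).
#' @param expressed_frac fraction of genes expressed per tissue.
#' @param mean_expressed_cpm,mean_silent_cpm nominal cpm of expressed and
#'   silent genes.
#' @param libsize_range range of library sizes (log-uniform draw).
#' @param dispersion negative-binomial dispersion (variance = mu + disp*mu^2).
#' @param n_background housekeeping filler genes absorbing the library mass
#'   not taken by the panel (see Details).
#' @param seed integer seed.
#' @return list with components `cm` (a [count_matrix()]) and `truth`
#'   (`expressed_truth`: tissue -> character vector; `seed`).
#' @export
make_counts <- function(genes = 500, tissues = 2, samples_per_tissue = 20,
                        expressed_frac = 0.3, mean_expressed_cpm = 50,
                        mean_silent_cpm = 0.5,
                        libsize_range = c(5e5, 2e6), dispersion = 0.1,
                        n_background = 50, seed = 1) {
  stopifnot(all(libsize_range > 0), length(libsize_range) == 2,
            dispersion >= 0, expressed_frac >= 0, expressed_frac <= 1,
            n_background >= 1)
  set.seed(seed)
  if (is.numeric(genes)) genes <- sprintf("ENSG%06d", seq_len(genes))
  if (is.numeric(tissues)) tissues <- sprintf("tissue%02d", seq_len(tissues))
  n_genes <- length(genes)

  n_expr <- round(expressed_frac * n_genes)
  panel_total <- n_expr * mean_expressed_cpm +
    (n_genes - n_expr) * mean_silent_cpm
  if (panel_total >= 1e6)
    stop("infeasible: panel cpm already exceeds one million; reduce gene ",
         "count or nominal cpm", call. = FALSE)
  bg_cpm <- (1e6 - panel_total) / n_background
  bg_genes <- sprintf("BG%04d", seq_len(n_background))

  samples <- character(0)
  tissue_of <- character(0)
  expressed_truth <- list()
  mu_cpm <- matrix(numeric(0), nrow = n_genes + n_background, ncol = 0)
  for (t in tissues) {
    expr <- sort(sample(genes, n_expr))
    expressed_truth[[t]] <- c(expr, bg_genes)
    s <- paste0(t, "_s", sprintf("%02d", seq_len(samples_per_tissue)))
    samples <- c(samples, s)
    tissue_of <- c(tissue_of, stats::setNames(rep(t, length(s)), s))
    mu_t <- rep(mean_silent_cpm, n_genes)
    mu_t[genes %in% expr] <- mean_expressed_cpm
    mu_t <- c(mu_t, rep(bg_cpm, n_background))
    mu_cpm <- cbind(mu_cpm, matrix(mu_t, length(mu_t), length(s)))
  }
  colnames(mu_cpm) <- samples
  genes <- c(genes, bg_genes)
  n_genes <- length(genes)

  libsizes <- exp(stats::runif(length(samples), log(libsize_range[1]),
                               log(libsize_range[2])))
  mu <- t(t(mu_cpm) * libsizes) / 1e6
  counts <- if (dispersion == 0) {
    matrix(stats::rpois(length(mu), lambda = mu), n_genes)
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           n_genes)
  }
  dimnames(counts) <- list(genes, samples)

  cm <- count_matrix(counts, tissue_of)
  truth <- structure(list(expressed_truth = expressed_truth, seed = seed),
                     class = "expressed_truth")
  list(cm = cm, truth = truth)
}
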