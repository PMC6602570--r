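#' Construct a raw RNA-seq count matrix with a sample-to-tissue map
#'
#' @param counts non-negative integer matrix, genes in rows (rownames set),
#'   samples in columns (colnames set).
#' @param tissue_of named character vector mapping every sample to a tissue.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, tissue_of) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts must have gene rownames", call. = FALSE)
  if (is.null(colnames(counts)))
    stop("counts must have sample colnames", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  missing <- setdiff(colnames(counts), names(tissue_of))
  if (length(missing))
    stop("samples without a tissue label: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  structure(list(counts = counts,
                 tissue_of = tissue_of[colnames(counts)]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples, ", length(unique(x$tissue_of)), " tissue(s)\n", sep = "")
  invisible(x)
}

#' Read a counts TSV and its sample-to-tissue map
#'
#' The counts file has a `gene_id` first column and one column per sample;
#' the tissue map is a two-column TSV (`sample`, `tissue`).
#'
#' @param counts_path counts TSV path.
#' @param tissues_path tissue map TSV path.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, tissues_path) {
  tab <- utils::read.delim(counts_path, sep = "\t", check.names = FALSE,
                           quote = "")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  tiss <- utils::read.delim(tissues_path, sep = "\t",
                            colClasses = "character", quote = "")
  count_matrix(m, stats::setNames(tiss[[2]], tiss[[1]]))
}

#' Write a count matrix and tissue map as TSV
#' @param cm count_matrix.
#' @param counts_path,tissues_path output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(cm, counts_path, tissues_path) {
  out <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(out, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = names(cm$tissue_of),
                                tissue = unname(cm$tissue_of)),
                     tissues_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Prefilter low-count genes
#'
#' Keeps a gene only if it has more than `min_count` read counts (strict
#' inequality) in at least `min_samples` samples, the usual coarse filter
#' applied to GTEx-scale count matrices before normalization.  With the
#' defaults, a gene needs more than five reads in at least 10 samples; a
#' gene sitting at exactly 5 everywhere is dropped.
#'
#' @param cm count_matrix.
#' @param min_count count that must be strictly exceeded (default 5).
#' @param min_samples minimum number of qualifying samples (default 10).
#' @return A filtered [count_matrix()].
#' @export
prefilter_counts <- function(cm, min_count = 5, min_samples = 10) {
  stopifnot(inherits(cm, "count_matrix"), min_count >= 0, min_samples >= 0)
  if (min_samples > ncol(cm$counts))
    warning("min_samples exceeds the number of samples; result may be empty",
            call. = FALSE)
  keep <- rowSums(cm$counts > min_count) >= min_samples
  count_matrix(cm$counts[keep, , drop = FALSE], cm$tissue_of)
}

#' TMM normalization to counts per million
#'
#' Between-sample normalization by the trimmed mean of M-values: a scaling
#' factor per library is estimated from a doubly trimmed, variance-weighted
#' mean of per-gene log2 expression ratios against a reference sample, and
#' counts are converted to cpm against the product of library size and
#' factor.  The reference is the sample whose upper-quartile of
#' library-scaled counts is closest to the mean upper-quartile.  Genes with
#' a zero in either the sample or the reference are excluded; the top and
#' bottom `trim_M` of M-values and `trim_A` of A-values are removed; the
#' remaining M-values are averaged with inverse asymptotic-variance weights;
#' factors are rescaled to geometric mean 1.  These are the method's
#' standard published defaults.
#'
#' With `weighted = TRUE` (the method's default) the factor is only
#' asymptotically invariant to rescaling one library by a constant: the
#' variance weights depend on absolute counts, so the factor moves by
#' O(1/count).  `weighted = FALSE` (plain trimmed mean) is exactly
#' scale-invariant.
#'
#' @param cm count_matrix with at least 2 samples and no all-zero sample.
#' @param trim_M fraction of extreme M-values trimmed from each tail.
#' @param trim_A fraction of extreme A-values trimmed from each tail.
#' @param weighted use inverse asymptotic-variance weights (default TRUE).
#' @return An object of class `cpm_matrix` with components `cpm` (matrix),
#'   `norm_factors`, `lib_size` and `tissue_of`.
#' @export
tmm_normalize <- function(cm, trim_M = 0.30, trim_A = 0.05, weighted = TRUE) {
  stopifnot(inherits(cm, "count_matrix"))
  x <- cm$counts
  if (ncol(x) < 2L) stop("TMM needs at least 2 samples", call. = FALSE)
  lib_size <- colSums(x)
  if (any(lib_size == 0)) stop("all-zero sample", call. = FALSE)

  xs <- x[rowSums(x > 0) > 0L, , drop = FALSE]  # drop all-zero genes
  f75 <- apply(xs, 2L, stats::quantile, probs = 0.75) / lib_size
  if (stats::median(f75) < 1e-20) {
    ref <- which.max(colSums(sqrt(xs)))
  } else {
    ref <- which.min(abs(f75 - mean(f75)))
  }

  f <- vapply(seq_len(ncol(xs)), function(i) {
    tmm_pair_factor(xs[, i], xs[, ref], lib_size[i], lib_size[ref],
                    trim_M, trim_A, weighted)
  }, 0)
  f <- f / exp(mean(log(f)))  # geometric mean 1
  names(f) <- colnames(x)

  cpm <- t(t(x) / (lib_size * f)) * 1e6
  structure(list(cpm = cpm, norm_factors = f, lib_size = lib_size,
                 tissue_of = cm$tissue_of),
            class = "cpm_matrix")
}

# Scaling factor for one sample against the reference: 2^(weighted trimmed
# mean of M), weights = inverse asymptotic (binomial) variances.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_M, trim_A,
                            weighted = TRUE) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR)) {
    warning("sample shares no nonzero gene with the reference; factor = 1",
            call. = FALSE)
    return(1)
  }
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  keep <- rank(logR) >= loM & rank(logR) <= hiM &
    rank(absE) >= loA & rank(absE) <= hiA
  f <- if (weighted) {
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(logR[keep], na.rm = TRUE)
  }
  if (is.na(f)) f <- 0
  2^f
}

#' @export
print.cpm_matrix <- function(x, ...) {
  cat("cpm_matrix: ", nrow(x$cpm), " genes x ", ncol(x$cpm), " samples; ",
      "norm factors in [", round(min(x$norm_factors), 3), ", ",
      round(max(x$norm_factors), 3), "]\n", sep = "")
  invisible(x)
}

#' Call the expressed gene set of a tissue
#'
#' Two-stage expression call within the tissue's samples.  Stage 1 keeps
#' genes whose cpm reaches `cpm_threshold` (inclusive) in at least
#' `min_samples` samples.  Stage 2 merges the tissue's samples by setting
#' each gene's expression to its median cpm across samples and keeps genes
#' whose median reaches `median_threshold`.  By default both thresholds are
#' read on the cpm scale; `median_scale = "log2cpm"` instead compares
#' log2(median cpm) against `median_threshold`.
#'
#' @param cpmM cpm_matrix.
#' @param tissue tissue name; must appear in the sample map.
#' @param cpm_threshold stage-1 cpm cutoff (default 8, inclusive).
#' @param min_samples stage-1 sample count (default 10).
#' @param median_threshold stage-2 cutoff on the median (default 8).
#' @param median_scale `"cpm"` (default) or `"log2cpm"`.
#' @return An object of class `expression_call` with components `tissue`,
#'   `expressed` (character vector of gene ids) and `config`.
#' @export
call_expressed <- function(cpmM, tissue, cpm_threshold = 8, min_samples = 10,
                           median_threshold = 8,
                           median_scale = c("cpm", "log2cpm")) {
  stopifnot(inherits(cpmM, "cpm_matrix"))
  median_scale <- match.arg(median_scale)
  samples <- names(cpmM$tissue_of)[cpmM$tissue_of == tissue]
  if (!length(samples))
    stop("unknown tissue: ", tissue, call. = FALSE)
  m <- cpmM$cpm[, samples, drop = FALSE]
  stage1 <- rowSums(m >= cpm_threshold) >= min_samples
  med <- apply(m, 1L, stats::median)
  stage2 <- if (median_scale == "cpm") med >= median_threshold
            else log2(med) >= median_threshold
  expressed <- rownames(m)[stage1 & stage2]
  structure(list(tissue = tissue, expressed = expressed,
                 config = list(cpm_threshold = cpm_threshold,
                               min_samples = min_samples,
                               median_threshold = median_threshold,
                               median_scale = median_scale)),
            class = "expression_call")
}

#' @export
print.expression_call <- function(x, ...) {
  cat("expression_call [", x$tissue, "]: ", length(x$expressed),
      " expressed genes\n", sep = "")
  invisible(x)
}

#' Build a tissue-specific interactome
#'
#' Restricts the global interactome to a tissue: a PPI is kept only if both
#' pair mates are expressed in the tissue; interactions involving microRNAs
#' (`TF_MIRNA`, `MIRNA_RNA`) are not filtered; `TF_DNA` edges are kept
#' unconditionally unless `filter_tf = TRUE`, which additionally drops
#' TF-DNA edges whose TF protein is unexpressed.  Nodes left without any
#' edge are dropped.
#'
#' @param global the global [interactome()].
#' @param call an [call_expressed()] result for the tissue.
#' @param filter_tf also require TF expression on TF_DNA edges.
#' @return A tissue interactome whose `build_tag` records the tissue and
#'   threshold configuration.
#' @export
build_tissue_interactome <- function(global, call, filter_tf = FALSE) {
  stopifnot(inherits(global, "interactome"),
            inherits(call, "expression_call"))
  if (!length(call$expressed))
    warning("expressed set is empty; result contains only microRNA/",
            "regulatory edges", call. = FALSE)
  e <- global$edges
  expressed <- call$expressed
  keep <- rep(TRUE, nrow(e))
  is_ppi <- e$etype == "PPI"
  keep[is_ppi] <- e$a_id[is_ppi] %in% expressed &
    e$b_id[is_ppi] %in% expressed
  if (filter_tf) {
    is_tf <- e$etype == "TF_DNA"
    keep[is_tf] <- e$a_id[is_tf] %in% expressed
  }
  tag <- paste0(global$build_tag, "|tissue=", call$tissue,
                "|cpm>=", call$config$cpm_threshold,
                ",n>=", call$config$min_samples,
                ",median>=", call$config$median_threshold,
                "(", call$config$median_scale, ")",
                if (filter_tf) ",filter_tf" else "")
  suppressMessages(interactome(e[keep, , drop = FALSE], build_tag = tag))
}
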