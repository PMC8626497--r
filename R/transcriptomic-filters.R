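#' Quality-control filter for single cells
#'
#' Two-stage filter on a per-cell QC table: (1) discard cells whose UMI
#' count or detected-gene count falls outside `mean +/- 2 SD`, each metric
#' using its own mean and SD over the input table (Gaussian assumption on
#' library size); (2) among the remaining cells, discard those with a
#' mitochondrial count fraction at or above `mito_cutoff` (default 30%,
#' threshold-inclusive). Discard reasons are recorded (`"umi"`, `"gene"`,
#' `"umi;gene"`, `"mito"`) and partition the discarded set;
#' `kept + discarded` is the input.
#'
#' @param cells data frame with columns `umi_count`, `gene_count`,
#'   `mito_fraction` (at least 2 rows, so the SD is defined).
#' @param mito_cutoff mitochondrial-fraction cutoff, inclusive.
#' @param scale `"raw"` (default): the 2-SD band is computed on raw counts;
#'   `"log"`: on `log1p(count)`.
#' @return list with `kept` (data frame) and `discarded` (data frame with an
#'   added `reason` column).
#' @export
qc_filter_cells <- function(cells, mito_cutoff = 0.30,
                            scale = c("raw", "log")) {
  scale <- match.arg(scale)
  need <- c("umi_count", "gene_count", "mito_fraction")
  if (!all(need %in% names(cells)))
    stop_gq("`cells` must have columns ", paste(need, collapse = ", "))
  if (nrow(cells) < 2L)
    stop_gq("need at least 2 cells to compute the SD band")
  if (any(cells$mito_fraction < 0 | cells$mito_fraction > 1))
    stop_gq("`mito_fraction` must lie in [0, 1]")
  in_band <- function(x) {
    if (scale == "log") x <- log1p(x)
    m <- mean(x); s <- sd(x)
    x >= m - 2 * s & x <= m + 2 * s
  }
  ok_umi <- in_band(cells$umi_count)
  ok_gene <- in_band(cells$gene_count)
  reason <- rep(NA_character_, nrow(cells))
  reason[!ok_umi & ok_gene] <- "umi"
  reason[ok_umi & !ok_gene] <- "gene"
  reason[!ok_umi & !ok_gene] <- "umi;gene"
  mito_bad <- is.na(reason) & cells$mito_fraction >= mito_cutoff
  reason[mito_bad] <- "mito"
  discard <- !is.na(reason)
  discarded <- cells[discard, , drop = FALSE]
  discarded$reason <- reason[discard]
  list(kept = cells[!discard, , drop = FALSE], discarded = discarded)
}

#' Differential-expression significance filter
#'
#' Keeps rows with `p_value < p_cutoff` and `|log2fc| > lfc_cutoff` (both
#' strict, defaults p < 0.05 and |log2FC| > 0.58, i.e. about 1.5-fold).
#' Row order is preserved; the filter is idempotent and monotone. P-values
#' are taken as supplied — no multiple-testing correction is applied;
#' `adjust = "BH"` applies Benjamini-Hochberg to the p-values before
#' thresholding.
#'
#' @param rows data frame with columns `log2fc` and `p_value`.
#' @param p_cutoff,lfc_cutoff strict thresholds.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return the passing rows, in input order.
#' @export
deg_filter <- function(rows, p_cutoff = 0.05, lfc_cutoff = 0.58,
                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!all(c("log2fc", "p_value") %in% names(rows)))
    stop_gq("`rows` must have columns log2fc and p_value")
  if (nrow(rows) == 0L) return(rows)
  if (any(rows$p_value <= 0 | rows$p_value > 1))
    stop_gq("p-values must lie in (0, 1]")
  p <- if (adjust == "BH") p.adjust(rows$p_value, method = "BH")
       else rows$p_value
  rows[p < p_cutoff & abs(rows$log2fc) > lfc_cutoff, , drop = FALSE]
}

#' Hypergeometric over-representation test for gene-set terms
#'
#' For each term, the upper-tail probability `P(X >= k)` of drawing at least
#' the observed overlap `k` when `n` query genes are sampled without
#' replacement from a universe of `N` genes of which `K` belong to the term
#' (`X ~ Hypergeometric(N, K, n)`). Query and term genes outside the
#' universe are trimmed with a warning. Results are sorted by p-value.
#'
#' @param query character vector of query genes (e.g. the DEGs).
#' @param terms named list of character vectors (term -> gene set), e.g.
#'   from [read_gmt()].
#' @param universe character vector of all testable genes; must be
#'   non-empty.
#' @param adjust `"none"` (default, raw hypergeometric p-values) or `"BH"`.
#' @return data frame with `term_id`, `k`, `K`, `n`, `N`, `p_value` (and
#'   `p_adjust` when requested), sorted by `p_value`.
#' @export
hypergeom_enrich <- function(query, terms, universe,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop_gq("empty universe")
  query <- unique(as.character(query))
  if (!all(query %in% universe)) {
    warning("trimming ", sum(!(query %in% universe)),
            " query gene(s) outside the universe", call. = FALSE)
    query <- query[query %in% universe]
  }
  trimmed <- vapply(terms, function(g) sum(!(unique(g) %in% universe)), 0L)
  if (any(trimmed > 0L))
    warning("trimming ", sum(trimmed),
            " term gene(s) outside the universe", call. = FALSE)
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(terms), function(tid) {
    g <- unique(terms[[tid]])
    g <- g[g %in% universe]
    K <- length(g)
    k <- length(intersect(query, g))
    data.frame(term_id = tid, k = k, K = K, n = n, N = N,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0))
  if (adjust == "BH") out$p_adjust <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene-set terms from a GMT file
#'
#' @param path GMT file path (term, description, then genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop_gq("reading GMT files requires the fgsea package")
  fgsea::gmtPathways(path)
}

#' Derive a per-cell QC table from an MTX count matrix
#'
#' Reads a MatrixMarket sparse gene-by-cell count matrix with its features
#' and barcodes files and computes per-cell UMI totals, detected-gene counts
#' and mitochondrial fractions (mitochondrial genes identified by name
#' prefix, default `"mt-"` as in mouse gene symbols).
#'
#' @param mtx_path MTX file (genes in rows, cells in columns).
#' @param features_path one gene name per line (or TSV whose last column is
#'   the symbol).
#' @param barcodes_path one cell barcode per line.
#' @param mito_prefix gene-name prefix marking mitochondrial genes.
#' @return data frame with `cell_id`, `umi_count`, `gene_count`,
#'   `mito_fraction`.
#' @export
cell_qc_from_mtx <- function(mtx_path, features_path, barcodes_path,
                             mito_prefix = "mt-") {
  if (!requireNamespace("Matrix", quietly = TRUE))
    stop_gq("reading MTX files requires the Matrix package")
  m <- Matrix::readMM(mtx_path)
  feat <- read.delim(features_path, header = FALSE,
                     stringsAsFactors = FALSE)
  genes <- feat[[ncol(feat)]]
  barcodes <- readLines(barcodes_path)
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    stop_gq("matrix dimensions do not match features/barcodes")
  umi <- Matrix::colSums(m)
  gene_count <- Matrix::colSums(m > 0)
  mito <- startsWith(tolower(genes), tolower(mito_prefix))
  mito_counts <- if (any(mito)) Matrix::colSums(m[mito, , drop = FALSE])
                 else rep(0, ncol(m))
  data.frame(cell_id = barcodes,
             umi_count = as.integer(umi),
             gene_count = as.integer(gene_count),
             mito_fraction = ifelse(umi > 0, mito_counts / umi, 0))
}
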