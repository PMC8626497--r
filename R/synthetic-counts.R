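#' Parameters for synthetic single-cell QC and differential tables
#'
#' Emulates the tabular inputs of droplet single-cell QC and differential
#' expression: per-cell UMI totals are log-normal around `mean_umi` with
#' coefficient of variation `umi_cv`; detected-gene counts are an affine,
#' tightly correlated function of UMI (as in real droplet data, where both
#' track library size). Planted pathologies: `outlier_fraction` of cells are
#' placed at mean +/- 5 SD of the clean UMI (or gene) distribution, and
#' `high_mito_fraction` of cells get a mitochondrial read fraction above
#' 30%. The differential table has `n_true_degs` genes at
#' `|log2FC| = lfc_effect` with p-values below 0.05; null genes draw p from
#' U(0.05, 1) so they can never pass the significance rule.
#'
#' @param n_cells,n_genes table sizes.
#' @param mean_umi,umi_cv mean and CV of the per-cell UMI distribution.
#' @param outlier_fraction fraction of cells planted as count outliers.
#' @param high_mito_fraction fraction of cells planted with >= 30%
#'   mitochondrial counts.
#' @param n_true_degs number of genes planted as differentially expressed.
#' @param lfc_effect absolute log2 fold change of the planted DEGs.
#' @param seed integer seed.
#' @return A validated list of class `counts_sim_params`.
#' @export
counts_sim_params <- function(n_cells = 2000L,
                              n_genes = 10000L,
                              mean_umi = 20000,
                              umi_cv = 0.2,
                              outlier_fraction = 0.02,
                              high_mito_fraction = 0.03,
                              n_true_degs = 135L,
                              lfc_effect = 1.0,
                              seed = 1L) {
  p <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
            mean_umi = as.numeric(mean_umi), umi_cv = as.numeric(umi_cv),
            outlier_fraction = as.numeric(outlier_fraction),
            high_mito_fraction = as.numeric(high_mito_fraction),
            n_true_degs = as.integer(n_true_degs),
            lfc_effect = as.numeric(lfc_effect), seed = as.integer(seed))
  if (p$n_cells < 0 || p$n_genes < 0) stop_gq("sizes must be nonnegative")
  if (p$mean_umi <= 0 || p$umi_cv <= 0)
    stop_gq("`mean_umi` and `umi_cv` must be positive")
  if (p$outlier_fraction < 0 || p$outlier_fraction > 1 ||
      p$high_mito_fraction < 0 || p$high_mito_fraction > 1)
    stop_gq("fractions must lie in [0, 1]")
  if (p$n_true_degs > p$n_genes)
    stop_gq("`n_true_degs` cannot exceed `n_genes`")
  if (p$lfc_effect <= 0) stop_gq("`lfc_effect` must be positive")
  class(p) <- "counts_sim_params"
  p
}

#' Generate per-cell QC and per-gene differential tables with truth labels
#'
#' @param params a [counts_sim_params()] object.
#' @return list with `cell_qc` (data frame: `cell_id`, `umi_count`,
#'   `gene_count`, `mito_fraction`), `deg_table` (data frame: `gene`,
#'   `log2fc`, `p_value`) and `truth` (per-cell `planted_outlier` in
#'   `none/umi/gene`, `planted_high_mito`; per-gene `is_deg`).
#' @export
generate_counts_table <- function(params) {
  stopifnot(inherits(params, "counts_sim_params"))
  p <- params
  gene_scale <- 0.3
  with_seed(p$seed, {
    n <- p$n_cells
    if (n == 0L) {
      cell_qc <- data.frame(cell_id = character(0), umi_count = integer(0),
                            gene_count = integer(0),
                            mito_fraction = numeric(0))
      cell_truth <- data.frame(cell_id = character(0),
                               planted_outlier = character(0),
                               planted_high_mito = logical(0))
    } else {
      sdlog <- sqrt(log(1 + p$umi_cv^2))
      umi <- rlnorm(n, meanlog = log(p$mean_umi) - sdlog^2 / 2, sdlog = sdlog)
      gene <- gene_scale * umi *
        exp(rnorm(n, 0, 0.01))  # near-linear in UMI: corr ~ 0.998
      planted <- rep("none", n)
      n_out <- round(p$outlier_fraction * n)
      if (n_out > 0) {
        who <- sample.int(n, n_out)
        mu_u <- mean(umi); s_u <- sd(umi)
        mu_g <- mean(gene); s_g <- sd(gene)
        for (i in seq_len(n_out)) {
          cell <- who[i]
          side <- if (i %% 2L == 0L) -1 else 1
          if (i %% 4L < 2L) {  # UMI outlier, gene left typical
            umi[cell] <- max(mu_u + side * 5 * s_u, 0.01 * mu_u)
            gene[cell] <- mu_g
            planted[cell] <- "umi"
          } else {             # gene outlier, UMI left typical
            gene[cell] <- max(mu_g + side * 5 * s_g, 0.01 * mu_g)
            umi[cell] <- mu_u
            planted[cell] <- "gene"
          }
        }
      }
      mito <- runif(n, 0, 0.10)
      n_mito <- round(p$high_mito_fraction * n)
      if (n_mito > 0) {
        eligible <- which(planted == "none")
        if (length(eligible) < n_mito)
          stop_gq("too few non-outlier cells to plant high-mito cells")
        hm <- sample(eligible, n_mito)
        mito[hm] <- runif(n_mito, 0.35, 0.80)
      } else hm <- integer(0)
      cell_qc <- data.frame(cell_id = sprintf("cell_%05d", seq_len(n)),
                            umi_count = as.integer(round(umi)),
                            gene_count = as.integer(round(gene)),
                            mito_fraction = mito)
      cell_truth <- data.frame(cell_id = cell_qc$cell_id,
                               planted_outlier = planted,
                               planted_high_mito = seq_len(n) %in% hm)
    }
    m <- p$n_genes
    if (m == 0L) {
      deg_table <- data.frame(gene = character(0), log2fc = numeric(0),
                              p_value = numeric(0))
      gene_truth <- data.frame(gene = character(0), is_deg = logical(0))
    } else {
      is_deg <- seq_len(m) %in% sample.int(m, p$n_true_degs)
      log2fc <- rnorm(m, 0, 0.25)
      pval <- runif(m, 0.05, 1)
      k <- sum(is_deg)
      if (k > 0) {
        log2fc[is_deg] <- p$lfc_effect * sample(c(-1, 1), k, replace = TRUE)
        pval[is_deg] <- runif(k, 1e-8, 0.0499)
      }
      deg_table <- data.frame(gene = sprintf("gene_%05d", seq_len(m)),
                              log2fc = log2fc, p_value = pval)
      gene_truth <- data.frame(gene = deg_table$gene, is_deg = is_deg)
    }
    list(cell_qc = cell_qc, deg_table = deg_table,
         truth = list(cells = cell_truth, genes = gene_truth))
  })
}
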