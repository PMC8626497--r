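test_that("QC bands keep identical cells and catch planted outliers", {
  same <- data.frame(umi_count = rep(1000L, 5), gene_count = rep(400L, 5),
                     mito_fraction = 0)
  r <- qc_filter_cells(same)
  expect_identical(nrow(r$kept), 5L)
  expect_identical(nrow(r$discarded), 0L)
  # planted outliers at +/- 5 SD are exactly the discards, with reasons
  g <- generate_counts_table(counts_sim_params(
    n_cells = 1000L, n_genes = 10L, outlier_fraction = 0.03,
    high_mito_fraction = 0.02, n_true_degs = 0L, seed = 14L))
  r <- qc_filter_cells(g$cell_qc)
  tr <- g$truth$cells
  planted_bad <- tr$cell_id[tr$planted_outlier != "none" |
                              tr$planted_high_mito]
  expect_true(all(planted_bad %in% r$discarded$cell_id))
  # reasons match what was planted
  m <- match(r$discarded$cell_id, tr$cell_id)
  planted_reason <- ifelse(tr$planted_high_mito[m], "mito",
                           tr$planted_outlier[m])
  organic <- planted_reason == "none"  # unplanted tail cells may also fall
  expect_identical(r$discarded$reason[!organic], planted_reason[!organic])
  # partition: kept + discarded = input
  expect_identical(nrow(r$kept) + nrow(r$discarded), nrow(g$cell_qc))
  expect_identical(sort(c(r$kept$cell_id, r$discarded$cell_id)),
                   sort(g$cell_qc$cell_id))
})

test_that("mito rule is threshold-inclusive at 30% and applied after bands", {
  cells <- data.frame(umi_count = c(1000L, 1010L, 990L, 1005L),
                      gene_count = c(400L, 404L, 396L, 402L),
                      mito_fraction = c(0.05, 0.30, 0.299, 0.8))
  r <- qc_filter_cells(cells)
  expect_identical(r$discarded$reason, c("mito", "mito"))
  expect_identical(nrow(r$kept), 2L)
  expect_error(qc_filter_cells(cells[1, ]), "at least 2")
})

test_that("Gaussian-distributed counts retain about the 2-SD mass", {
  set.seed(202)
  umi <- round(rnorm(10000, 20000, 4000))
  cells <- data.frame(umi_count = umi, gene_count = round(0.3 * umi),
                      mito_fraction = 0)
  r <- qc_filter_cells(cells)
  retained <- 100 * nrow(r$kept) / nrow(cells)
  # oracle: P(|Z| < 2) ~ 95.45%
  expect_lt(abs(retained - 100 * (stats::pnorm(2) - stats::pnorm(-2))), 1)
})

test_that("DEG filter applies strict thresholds, preserving order", {
  rows <- data.frame(gene = c("a", "b", "c", "d"),
                     log2fc = c(0.60, 0.58, 3.0, -0.70),
                     p_value = c(0.01, 0.01, 0.06, 0.04))
  out <- deg_filter(rows)
  expect_identical(out$gene, c("a", "d"))  # b fails |lfc|, c fails p
  # idempotent and monotone: removing rows never adds passers
  expect_identical(deg_filter(out), out)
  expect_true(all(deg_filter(rows[-1, ])$gene %in% out$gene))
  expect_identical(nrow(deg_filter(rows[0, ])), 0L)
  expect_error(deg_filter(data.frame(log2fc = 1, p_value = 0)), "p-values")
})

test_that("planted DEG tables pass the filter exactly", {
  g <- generate_counts_table(counts_sim_params(
    n_cells = 10L, n_genes = 3000L, n_true_degs = 135L, lfc_effect = 1.0,
    seed = 25L))
  out <- deg_filter(g$deg_table)
  expect_identical(nrow(out), 135L)
  expect_identical(out$gene, g$deg_table$gene[g$truth$genes$is_deg])
})

test_that("hypergeometric p-values match exhaustive subset enumeration", {
  # brute force: overlap distribution over all C(N, n) query draws
  brute_upper <- function(N, K, n, k) {
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= K)  # genes 1..K form the term
    mean(hits >= k)
  }
  for (N in c(5L, 8L)) {
    for (K in 0:N) for (n in 1:N) {
      for (k in max(0L, n - (N - K)):min(K, n)) {
        # term genes are 1..K; build a query realising overlap exactly k
        q <- as.character(c(seq_len(k), seq.int(K + 1, length.out = n - k)))
        res <- hypergeom_enrich(q, list(t1 = as.character(seq_len(K))),
                                as.character(seq_len(N)))
        expect_equal(res$p_value, brute_upper(N, K, n, k), tolerance = 1e-12)
      }
    }
  }
  # the worked configuration N=20, K=5, n=5, k=3
  res <- hypergeom_enrich(as.character(c(1:3, 6:7)),
                          list(t1 = as.character(1:5)),
                          as.character(1:20))
  expect_equal(res$p_value, brute_upper(20L, 5L, 5L, 3L), tolerance = 1e-12)
})

test_that("enrichment edge cases and trimming behave as documented", {
  uni <- as.character(1:10)
  # term = universe: overlap is forced, p = 1
  res <- hypergeom_enrich(as.character(1:3), list(all = uni), uni)
  expect_equal(res$p_value, 1)
  # k = n = K: p = 1 / C(N, n)
  res <- hypergeom_enrich(as.character(1:3), list(t = as.character(1:3)), uni)
  expect_equal(res$p_value, 1 / choose(10, 3))
  expect_error(hypergeom_enrich("a", list(t = "a"), character(0)), "universe")
  expect_warning(hypergeom_enrich(c("1", "zzz"), list(t = c("1", "2")), uni),
                 "trimming")
  # p decreases as overlap k grows, all in (0, 1]
  ps <- vapply(0:3, function(k) {
    q <- as.character(c(seq_len(k), seq.int(5, length.out = 3 - k)))
    hypergeom_enrich(q, list(t = as.character(1:3)), uni)$p_value
  }, 0)
  expect_true(all(ps > 0 & ps <= 1))
  expect_true(all(diff(ps) < 0))
})

test_that("QC tables can be derived from a sparse MTX triplet", {
  skip_if_not_installed("Matrix")
  m <- Matrix::sparseMatrix(i = c(1, 2, 3, 1, 3), j = c(1, 1, 1, 2, 2),
                            x = c(5, 3, 2, 4, 6), dims = c(3, 2))
  dir <- tempfile(); dir.create(dir)
  Matrix::writeMM(m, file.path(dir, "m.mtx"))
  writeLines(c("mt-Nd1", "Gfap", "Aif1"), file.path(dir, "features.tsv"))
  writeLines(c("AAA", "CCC"), file.path(dir, "barcodes.tsv"))
  qc <- cell_qc_from_mtx(file.path(dir, "m.mtx"),
                         file.path(dir, "features.tsv"),
                         file.path(dir, "barcodes.tsv"))
  expect_identical(qc$umi_count, c(10L, 10L))
  expect_identical(qc$gene_count, c(3L, 2L))
  expect_equal(qc$mito_fraction, c(0.5, 0.4))
  unlink(dir, recursive = TRUE)
})

test_that("GMT term files are parsed into named gene-set lists", {
  skip_if_not_installed("fgsea")
  f <- tempfile(fileext = ".gmt")
  writeLines(c("phagocytosis\tdesc\tMegf10\tMertk\tC1qa",
               "lysosome\tdesc\tLamp2"), f)
  terms <- read_gmt(f)
  expect_named(terms, c("phagocytosis", "lysosome"))
  expect_identical(terms$phagocytosis, c("Megf10", "Mertk", "C1qa"))
  unlink(f)
})
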