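## End-to-end orchestration: train a ModelStore from matched methylation and
## expression matrices, apply a store to new methylation data (450K or EPIC
## probe subsets), and score concordance between inferred and observed
## expression.

#' Configuration for training and inference
#'
#' Defaults follow the published procedure where a value is printed there
#' (P < 0.01 screen, <= 100 CpG sites per sign, 10 x 10-fold CV, >= 5%
#' relative RMSE rule, R^2 > 0.16 gate); the remaining knobs are this
#' implementation's documented choices.
#'
#' @param seed Integer master seed for the split and CV folds.
#' @param p_threshold Spearman screening significance cutoff.
#' @param max_per_side Maximum CpG sites per sign per gene.
#' @param r2_gate MethCORR-gene R^2 threshold (both discovery and validation
#'   must exceed it).
#' @param rmse_rule Minimum relative CV-RMSE decrease for a polynomial model
#'   to replace the linear one.
#' @param min_probe_coverage Minimum fraction of a gene's probes available in
#'   a sample for a direct (non-imputed) MethCORR score.
#' @param knn_k Neighbour genes averaged when imputing missing scores.
#' @param n_folds,n_repeats Cross-validation scheme.
#' @param min_pair_n Minimum complete observations per correlation pair.
#' @param min_cpg_total Minimum selected pos + neg CpG sites for a gene to be
#'   scored at all.
#' @param min_validation_n Minimum validation samples per gene model.
#' @param cancer_type,platform Metadata labels stored with the model.
#' @return A list of class `methcorr_config`.
#' @export
methcorr_config <- function(seed = 1L, p_threshold = 0.01, max_per_side = 100L,
                            r2_gate = 0.16, rmse_rule = 0.05,
                            min_probe_coverage = 0.5, knn_k = 10L,
                            n_folds = 10L, n_repeats = 10L, min_pair_n = 15L,
                            min_cpg_total = 10L, min_validation_n = 10L,
                            cancer_type = NA_character_, platform = "450K") {
  structure(
    list(seed = as.integer(seed), p_threshold = p_threshold,
         max_per_side = as.integer(max_per_side), r2_gate = r2_gate,
         rmse_rule = rmse_rule, min_probe_coverage = min_probe_coverage,
         knn_k = as.integer(knn_k), n_folds = as.integer(n_folds),
         n_repeats = as.integer(n_repeats), min_pair_n = as.integer(min_pair_n),
         min_cpg_total = as.integer(min_cpg_total),
         min_validation_n = as.integer(min_validation_n),
         cancer_type = cancer_type, platform = platform),
    class = "methcorr_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Train a MethCORR model store
#'
#' Runs the full training pipeline on matched matrices: 40/40/20 sample
#' split, Spearman screening in each discovery set, rank-sum combination,
#' CpG selection, MethCORR-score computation and imputation, per-gene
#' cross-validated regression on the discovery samples, and independent
#' validation on the held-out set. Only MethCORR-flagged genes (discovery
#' and validation R^2 above the gate) enter the store; excluded genes are
#' recorded in the `rejected` sidecar with a reason
#' (`too_few_cpgs`, `low_discovery_r2`, `low_validation_r2`).
#'
#' @param meth Probe x sample beta-value matrix (or path readable by
#'   [read_matrix()]).
#' @param expr Gene x sample expression matrix on a log scale.
#' @param config A [methcorr_config()].
#' @return A `methcorr_model_store`.
#' @export
train <- function(meth, expr, config = methcorr_config()) {
  if (is.character(meth)) meth <- read_matrix(meth, "methylation")
  if (is.character(expr)) expr <- read_matrix(expr, "expression")
  validate_methylation_matrix(meth)
  validate_expression_matrix(expr)
  shared <- intersect(colnames(expr), colnames(meth))
  if (length(shared) < 50L)
    stop("need at least 50 samples shared between the methylation and ",
         "expression matrices, got ", length(shared))
  meth <- meth[, shared, drop = FALSE]
  expr <- expr[, shared, drop = FALSE]

  split <- run_stage("split_samples", split_samples(shared, config$seed))
  rec1 <- run_stage("spearman_screen", spearman_screen(
    expr, meth, split$discovery1, 1L,
    p_threshold = config$p_threshold, min_pair_n = config$min_pair_n))
  rec2 <- run_stage("spearman_screen", spearman_screen(
    expr, meth, split$discovery2, 2L,
    p_threshold = config$p_threshold, min_pair_n = config$min_pair_n))
  ranked <- run_stage("combine_rank_sum", combine_rank_sum(rec1, rec2))
  cpg_sites <- run_stage("select_top_cpgs", select_top_cpgs(
    ranked, max_per_side = config$max_per_side,
    min_cpg_total = config$min_cpg_total))
  if (nrow(cpg_sites) == 0L)
    stop("stage 'select_top_cpgs' failed: no gene retained any ",
         "expression-correlated CpG sites", call. = FALSE)

  mcs <- run_stage("compute_mcs", compute_mcs(
    meth, cpg_sites, min_probe_coverage = config$min_probe_coverage))
  mcs <- run_stage("impute_missing_mcs", impute_missing_mcs(mcs, config$knn_k))

  discovery <- c(split$discovery1, split$discovery2)
  validation <- split$validation
  genes <- rownames(mcs)

  rejected_sel <- attr(cpg_sites, "dropped")
  rejected <- list()
  if (!is.null(rejected_sel) && nrow(rejected_sel))
    rejected[[1L]] <- tibble::tibble(gene = rejected_sel$gene,
                                     reason = "too_few_cpgs")
  # Genes never reaching selection at all (no common candidates) are also
  # recorded so the sidecar accounts for the full expression universe.
  never <- setdiff(rownames(expr), c(genes, rejected_sel$gene))
  if (length(never))
    rejected[[length(rejected) + 1L]] <-
      tibble::tibble(gene = never, reason = "too_few_cpgs")

  models <- vector("list", length(genes))
  report <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    m <- run_stage("fit_gene_model", fit_gene_model(
      mcs[g, discovery], expr[g, discovery], seed = config$seed, gene = g,
      n_folds = config$n_folds, n_repeats = config$n_repeats,
      rmse_rule = config$rmse_rule))
    m <- run_stage("validate_gene_model", validate_gene_model(
      m, mcs[g, validation], expr[g, validation],
      r2_gate = config$r2_gate, min_validation_n = config$min_validation_n))
    models[[i]] <- m
    cvb <- m$cv_rmse_by_degree %||% rep(NA_real_, 4L)
    report[[i]] <- tibble::tibble(
      gene = g, rmse_d1 = cvb[1L], rmse_d2 = cvb[2L], rmse_d3 = cvb[3L],
      rmse_d4 = cvb[4L], chosen_degree = m$degree,
      rule = if (m$degree > 1L) "polynomial_selected" else "linear_kept")
  }
  flags <- vapply(models, function(m) m$methcorr_flag, logical(1))
  for (m in models[!flags]) {
    reason <- if (m$r2_discovery <= config$r2_gate) "low_discovery_r2"
              else "low_validation_r2"
    rejected[[length(rejected) + 1L]] <-
      tibble::tibble(gene = m$gene, reason = reason)
  }
  kept <- models[flags]
  if (!length(kept))
    stop("stage 'validate_gene_model' failed: no gene passed the R^2 gate ",
         "in both discovery and validation", call. = FALSE)

  model_tbl <- dplyr::bind_rows(lapply(kept, model_to_row))
  rejected_tbl <- dplyr::arrange(dplyr::bind_rows(rejected), .data$gene)
  sites_kept <- dplyr::filter(cpg_sites, .data$gene %in% model_tbl$gene)
  attr(sites_kept, "dropped") <- NULL
  metadata <- list(
    cancer_type = config$cancer_type, platform = config$platform,
    seed = config$seed, n_samples = length(shared),
    n_discovery = length(discovery), n_validation = length(validation)
  )
  model_store(sites_kept, model_tbl, metadata,
              rejected = rejected_tbl,
              fit_report = dplyr::bind_rows(report))
}

#' Infer expression from methylation with a trained store
#'
#' Computes each gene's MethCORR score over whatever store probes the input
#' array provides (EPIC subsets are handled by the adaptive coverage rule),
#' imputes scores that fall below coverage, and evaluates each gene's
#' regression model. Fails with a platform-mismatch error when under 10% of
#' the store's probes are present.
#'
#' @param store A `methcorr_model_store` (or directory path).
#' @param meth Probe x sample beta-value matrix (or path).
#' @param min_probe_coverage,knn_k Score coverage rule and imputation
#'   neighbours, as in [methcorr_config()].
#' @return A list of class `methcorr_inference`: `irna` (gene x sample
#'   inferred-expression matrix) and `report` (per-sample tibble with
#'   `sample`, `n_genes_inferred` = genes scored directly before imputation,
#'   `probe_coverage` = fraction of store probes available).
#' @export
infer <- function(store, meth, min_probe_coverage = 0.5, knn_k = 10L) {
  if (is.character(store)) store <- read_model_store(store)
  stopifnot(inherits(store, "methcorr_model_store"))
  if (is.character(meth)) meth <- read_matrix(meth, "methylation")
  validate_methylation_matrix(meth)

  probes <- unique(store$cpg_sites$probe)
  overlap <- mean(probes %in% rownames(meth))
  if (overlap < 0.10)
    stop("platform mismatch: only ", round(100 * overlap, 1),
         "% of the model store's CpG probes are present in the input")

  genes <- unique(store$models$gene)
  if (ncol(meth) == 0L) {
    irna <- matrix(numeric(0), length(genes), 0L,
                   dimnames = list(genes, character()))
    report <- tibble::tibble(sample = character(), n_genes_inferred = integer(),
                             probe_coverage = double())
    return(structure(list(irna = irna, report = report),
                     class = "methcorr_inference"))
  }

  mcs <- compute_mcs(meth, store$cpg_sites,
                     min_probe_coverage = min_probe_coverage)
  n_direct <- colSums(!is.na(mcs))
  if (anyNA(mcs)) mcs <- impute_missing_mcs(mcs, k = knn_k)

  irna <- matrix(NA_real_, nrow(mcs), ncol(mcs), dimnames = dimnames(mcs))
  for (i in seq_len(nrow(store$models))) {
    m <- row_to_model(store$models[i, ])
    irna[m$gene, ] <- predict(m, mcs[m$gene, ])
  }

  pm <- intersect(probes, rownames(meth))
  cov <- colSums(!is.na(meth[pm, , drop = FALSE])) / length(probes)
  report <- tibble::tibble(
    sample = colnames(meth),
    n_genes_inferred = as.integer(n_direct),
    probe_coverage = as.numeric(cov)
  )
  structure(list(irna = irna, report = report), class = "methcorr_inference")
}

#' @export
print.methcorr_inference <- function(x, ...) {
  cat("MethCORR inference: ", nrow(x$irna), " genes x ", ncol(x$irna),
      " samples\n", sep = "")
  if (nrow(x$report))
    cat("  median probe coverage: ",
        signif(median(x$report$probe_coverage), 3), "\n", sep = "")
  invisible(x)
}

#' Per-sample concordance between inferred and observed expression
#'
#' For every shared sample, the intra-sample squared Pearson correlation
#' (over shared genes) and RMSE between inferred and observed expression.
#'
#' @param inferred,observed Gene x sample expression matrices.
#' @return Tibble of class `methcorr_concordance` with columns `sample`,
#'   `n_genes`, `r2`, `rmse`; attributes `median_r2` and `median_rmse` hold
#'   the summary medians (also available via [glance()]).
#' @export
evaluate_concordance <- function(inferred, observed) {
  genes <- intersect(rownames(inferred), rownames(observed))
  if (!length(genes)) stop("no shared genes between inferred and observed")
  samples <- intersect(colnames(inferred), colnames(observed))
  if (!length(samples)) stop("no shared samples between inferred and observed")
  res <- tibble::tibble(
    sample = samples,
    n_genes = length(genes),
    r2 = vapply(samples, function(s)
      squared_correlation(inferred[genes, s], observed[genes, s]),
      double(1), USE.NAMES = FALSE),
    rmse = vapply(samples, function(s)
      rmse(observed[genes, s], inferred[genes, s]),
      double(1), USE.NAMES = FALSE)
  )
  attr(res, "median_r2") <- median(res$r2)
  attr(res, "median_rmse") <- median(res$rmse)
  class(res) <- c("methcorr_concordance", class(res))
  res
}

#' @export
glance.methcorr_concordance <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x), n_genes = x$n_genes[1] %||% NA_integer_,
                 median_r2 = attr(x, "median_r2"),
                 median_rmse = attr(x, "median_rmse"))
}
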