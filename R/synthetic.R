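## Synthetic matched cohorts with known ground truth.
##
## Each signal gene g carries a latent per-sample methylation signal
## z ~ U(0, 1). Its positive readout probes have beta = clip(z + noise) and
## its negative probes beta = clip(1 - z + noise), so the gene's MethCORR
## score reconstructs z. Expression is b0 + b1*z (+ b2*z^2 for degree-2
## genes) plus Gaussian noise scaled so the latent signal explains a target
## share of the expression variance (signal_fraction). Null genes get
## independent uniform beta-values and Gaussian expression: no
## methylation-expression link at all. Generation is fully seeded.

#' Specification for a synthetic cohort
#'
#' Defaults describe the benchmark cohort used throughout the package's
#' tests: 200 samples, 100 signal genes whose latent methylation signal
#' explains 60% of expression variance through 10 positive and 10 negative
#' readout probes each, and 100 unlinked null genes.
#'
#' @param n_samples Number of samples.
#' @param n_signal_genes,n_null_genes Gene counts.
#' @param probes_per_gene_pos,probes_per_gene_neg Readout probes per signal
#'   gene and sign (null genes get the same probe budget, unlinked).
#' @param signal_fraction Target share of expression variance explained by
#'   the latent signal, in `[0, 1]`.
#' @param degree Generating polynomial degree, 1 or 2.
#' @param beta_noise_sd Gaussian noise on probe beta-values before clipping.
#' @param seed Integer seed.
#' @return A list of class `methcorr_synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 200L, n_signal_genes = 100L,
                           n_null_genes = 100L, probes_per_gene_pos = 10L,
                           probes_per_gene_neg = 10L, signal_fraction = 0.6,
                           degree = 1L, beta_noise_sd = 0.05, seed = 1L) {
  stopifnot(signal_fraction >= 0, signal_fraction <= 1,
            degree %in% c(1L, 2L),
            n_samples > 0, n_signal_genes > 0, n_null_genes >= 0,
            probes_per_gene_pos > 0, probes_per_gene_neg > 0,
            beta_noise_sd >= 0)
  structure(
    list(n_samples = as.integer(n_samples),
         n_signal_genes = as.integer(n_signal_genes),
         n_null_genes = as.integer(n_null_genes),
         probes_per_gene_pos = as.integer(probes_per_gene_pos),
         probes_per_gene_neg = as.integer(probes_per_gene_neg),
         signal_fraction = signal_fraction, degree = as.integer(degree),
         beta_noise_sd = beta_noise_sd, seed = as.integer(seed)),
    class = "methcorr_synthetic_spec"
  )
}

#' Generate a matched synthetic methylation/expression cohort
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `methcorr_synthetic_cohort`: `meth` (probe x
#'   sample beta matrix), `expr` (gene x sample expression matrix), and
#'   `truth` with elements `genes` (tibble: gene, type, degree, b0, b1, b2,
#'   noise_sd), `probes` (tibble: gene, probe, direction; signal genes
#'   only), and `z` (signal-gene x sample latent matrix).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "methcorr_synthetic_spec"))
  withr::with_seed(spec$seed, {
    ns <- spec$n_samples
    samples <- sprintf("S%04d", seq_len(ns))
    sig_genes <- sprintf("GSIG%04d", seq_len(spec$n_signal_genes))
    nul_genes <- if (spec$n_null_genes)
      sprintf("GNUL%04d", seq_len(spec$n_null_genes)) else character()
    ppg <- spec$probes_per_gene_pos + spec$probes_per_gene_neg
    n_probes <- (spec$n_signal_genes + spec$n_null_genes) * ppg
    probes <- sprintf("cg%08d", seq_len(n_probes))

    z <- matrix(runif(spec$n_signal_genes * ns), spec$n_signal_genes, ns,
                dimnames = list(sig_genes, samples))

    meth <- matrix(NA_real_, n_probes, ns, dimnames = list(probes, samples))
    probe_map <- vector("list", spec$n_signal_genes)
    offset <- 0L
    for (i in seq_len(spec$n_signal_genes)) {
      np <- spec$probes_per_gene_pos
      nn <- spec$probes_per_gene_neg
      pos_idx <- offset + seq_len(np)
      neg_idx <- offset + np + seq_len(nn)
      noise_p <- matrix(rnorm(np * ns, 0, spec$beta_noise_sd), np, ns)
      noise_n <- matrix(rnorm(nn * ns, 0, spec$beta_noise_sd), nn, ns)
      meth[pos_idx, ] <- clip01(rep(z[i, ], each = np) + noise_p)
      meth[neg_idx, ] <- clip01(rep(1 - z[i, ], each = nn) + noise_n)
      probe_map[[i]] <- tibble::tibble(
        gene = sig_genes[i],
        probe = probes[c(pos_idx, neg_idx)],
        direction = rep(c("pos", "neg"), c(np, nn))
      )
      offset <- offset + ppg
    }
    # null-gene probes: independent uniform beta-values
    if (spec$n_null_genes) {
      null_rows <- (offset + 1L):n_probes
      meth[null_rows, ] <- runif(length(null_rows) * ns)
    }

    n_genes <- spec$n_signal_genes + spec$n_null_genes
    b0 <- runif(n_genes, 2, 8)
    expr <- matrix(NA_real_, n_genes, ns,
                   dimnames = list(c(sig_genes, nul_genes), samples))
    b1 <- b2 <- noise_sd <- numeric(n_genes)
    for (i in seq_len(spec$n_signal_genes)) {
      if (spec$degree == 1L) {
        b1[i] <- runif(1, 2, 4)
        signal <- b1[i] * z[i, ]
      } else {
        b1[i] <- runif(1, 0, 2)
        b2[i] <- runif(1, 6, 10)
        signal <- b1[i] * z[i, ] + b2[i] * z[i, ]^2
      }
      f <- spec$signal_fraction
      noise_sd[i] <- if (f >= 1) 0 else if (f <= 0) 1
                     else sd(signal) * sqrt((1 - f) / f)
      expr[i, ] <- b0[i] + (if (f > 0) signal else 0) +
        rnorm(ns, 0, noise_sd[i])
    }
    if (spec$n_null_genes) {
      for (i in seq_len(spec$n_null_genes)) {
        j <- spec$n_signal_genes + i
        noise_sd[j] <- 1
        expr[j, ] <- b0[j] + rnorm(ns, 0, 1)
      }
    }

    truth <- list(
      genes = tibble::tibble(
        gene = c(sig_genes, nul_genes),
        type = rep(c("signal", "null"),
                   c(spec$n_signal_genes, spec$n_null_genes)),
        degree = ifelse(c(rep(TRUE, spec$n_signal_genes),
                          rep(FALSE, spec$n_null_genes)),
                        spec$degree, NA_integer_),
        b0 = b0, b1 = b1, b2 = b2, noise_sd = noise_sd
      ),
      probes = dplyr::bind_rows(probe_map),
      z = z
    )
    structure(list(meth = meth, expr = expr, truth = truth, spec = spec),
              class = "methcorr_synthetic_cohort")
  })
}

#' @export
print.methcorr_synthetic_cohort <- function(x, ...) {
  cat("Synthetic MethCORR cohort: ", ncol(x$meth), " samples, ",
      x$spec$n_signal_genes, " signal + ", x$spec$n_null_genes,
      " null genes, ", nrow(x$meth), " probes\n", sep = "")
  invisible(x)
}

#' Ground-truth recovery report for a trained store
#'
#' Compares a store trained on a synthetic cohort with the generator's
#' ground truth.
#'
#' @param store A `methcorr_model_store` trained on the cohort's matrices.
#' @param cohort The `methcorr_synthetic_cohort` the store was trained on.
#' @return One-row tibble: `sensitivity` (fraction of signal genes flagged),
#'   `null_flag_rate` (fraction of null genes flagged), `probe_recall`
#'   (mean fraction of true readout probes among each flagged signal gene's
#'   selected CpGs, sign-matched), `degree_accuracy` (fraction of flagged
#'   signal genes whose chosen degree matches the generating one; degree-2
#'   generation counts any degree >= 2 as correct), and
#'   `median_r2_validation` over flagged signal genes.
#' @export
recovery_report <- function(store, cohort) {
  stopifnot(inherits(store, "methcorr_model_store"),
            inherits(cohort, "methcorr_synthetic_cohort"))
  truth <- cohort$truth
  sig <- truth$genes$gene[truth$genes$type == "signal"]
  nul <- truth$genes$gene[truth$genes$type == "null"]
  flagged <- store$models$gene[store$models$methcorr_flag]
  sens <- mean(sig %in% flagged)
  null_rate <- if (length(nul)) mean(nul %in% flagged) else 0

  flagged_sig <- intersect(sig, flagged)
  recall <- NA_real_
  if (length(flagged_sig)) {
    sel <- dplyr::filter(store$cpg_sites, .data$gene %in% flagged_sig)
    per_gene <- vapply(flagged_sig, function(g) {
      tp <- truth$probes[truth$probes$gene == g, ]
      sp <- sel[sel$gene == g, ]
      mean(paste(tp$gene, tp$direction, tp$probe) %in%
             paste(sp$gene, sp$direction, sp$probe))
    }, double(1))
    recall <- mean(per_gene)
  }

  gen_degree <- cohort$spec$degree
  mdl_sig <- dplyr::filter(store$models, .data$gene %in% flagged_sig)
  degree_acc <- if (nrow(mdl_sig)) {
    if (gen_degree == 1L) mean(mdl_sig$degree == 1L)
    else mean(mdl_sig$degree >= 2L)
  } else NA_real_

  tibble::tibble(
    sensitivity = sens,
    null_flag_rate = null_rate,
    probe_recall = recall,
    degree_accuracy = degree_acc,
    median_r2_validation = if (nrow(mdl_sig))
      median(mdl_sig$r2_validation) else NA_real_
  )
}
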