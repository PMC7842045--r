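## MethCORR scores.
##
## For a gene with selected positively and negatively expression-correlated
## CpG sites, the MethCORR score (MCS) of a sample is
##
##   MCS = ( sum_pos beta + sum_neg (1 - beta) ) / n_available
##
## i.e. the average methylation signal over the gene's expression-correlated
## sites, with negative sites flipped so every contribution points the same
## way. The denominator counts the probes actually available (present on the
## array and non-missing in the sample), which is what makes the score
## tolerant of probe subsets such as EPIC arrays.

#' Compute MethCORR scores
#'
#' @param meth Probe x sample beta-value matrix.
#' @param cpg_sites MethCORR matrix tibble (`gene`, `direction`, `rank`,
#'   `probe`), e.g. from [select_top_cpgs()] or a model store.
#' @param min_probe_coverage Minimum fraction of a gene's listed probes that
#'   must be available in a sample for a valid score (default 0.5); below it
#'   the score is `NA` and must be imputed with [impute_missing_mcs()].
#' @return Gene x sample numeric matrix of scores in `[0, 1]`, `NA` where
#'   coverage was insufficient.
#' @examples
#' meth <- matrix(c(0.8, 0.6, 0.2, 0.4), 4, 1,
#'                dimnames = list(paste0("cg0", 1:4), "s1"))
#' sites <- tibble::tibble(gene = "G1", direction = c("pos", "pos", "neg", "neg"),
#'                         rank = c(1L, 2L, 1L, 2L), probe = paste0("cg0", 1:4))
#' compute_mcs(meth, sites)  # (0.8 + 0.6 + 0.8 + 0.6) / 4 = 0.7
#' @export
compute_mcs <- function(meth, cpg_sites, min_probe_coverage = 0.5) {
  validate_methylation_matrix(meth)
  cpg_sites <- tibble::as_tibble(cpg_sites)
  genes <- unique(cpg_sites$gene)
  counts <- table(cpg_sites$gene)
  if (any(counts == 0L) || !all(genes %in% names(counts)))
    stop("gene with zero listed probes in the MethCORR matrix")
  n_samp <- ncol(meth)

  idx <- match(cpg_sites$probe, rownames(meth))
  present <- !is.na(idx)
  vals <- matrix(NA_real_, nrow(cpg_sites), n_samp)
  if (any(present)) {
    vals[present, ] <- meth[idx[present], , drop = FALSE]
    neg <- cpg_sites$direction == "neg" & present
    vals[neg, ] <- 1 - vals[neg, , drop = FALSE]
  }
  avail <- !is.na(vals)
  vals[!avail] <- 0
  gf <- factor(cpg_sites$gene, levels = genes)
  sums <- rowsum(vals, gf)
  n_avail <- rowsum(avail + 0, gf)
  total <- as.vector(counts[genes])
  mcs <- sums / n_avail
  mcs[n_avail / total < min_probe_coverage] <- NA_real_
  mcs[n_avail == 0L] <- NA_real_
  dimnames(mcs) <- list(genes, colnames(meth))
  mcs
}

#' Impute missing MethCORR scores by gene-neighbour averaging
#'
#' A missing score for gene g in sample s is replaced by the mean score in s
#' of the k genes nearest to g, where distance is Euclidean over the samples
#' in which both genes are observed (scaled to the full sample count, as in
#' `stats::dist`). Fewer than k eligible neighbours triggers a warning and
#' uses all available; none is an error. Imputed values are clipped to
#' `[0, 1]`.
#'
#' @param mcs Gene x sample MCS matrix, possibly with `NA` entries.
#' @param k Number of neighbour genes to average (default 10).
#' @return The matrix with no missing values.
#' @export
impute_missing_mcs <- function(mcs, k = 10L) {
  stopifnot(is.matrix(mcs), is.numeric(mcs))
  if (!anyNA(mcs)) return(mcs)
  obs_frac <- colMeans(!is.na(mcs))
  if (any(obs_frac < 0.5)) {
    bad <- colnames(mcs)[obs_frac < 0.5]
    stop("sample(s) with under 50% of genes scored cannot be imputed: ",
         paste(head(bad, 5L), collapse = ", "))
  }
  D <- as.matrix(stats::dist(mcs))
  diag(D) <- NA_real_
  out <- mcs
  miss <- which(is.na(mcs), arr.ind = TRUE)
  short <- FALSE
  for (r in seq_len(nrow(miss))) {
    g <- miss[r, 1L]; s <- miss[r, 2L]
    elig <- which(!is.na(mcs[, s]) & is.finite(D[g, ]))
    if (!length(elig))
      stop("no eligible neighbour genes to impute the score of ",
           rownames(mcs)[g], " in sample ", colnames(mcs)[s])
    if (length(elig) < k) short <- TRUE
    nb <- elig[order(D[g, elig])][seq_len(min(k, length(elig)))]
    out[g, s] <- clip01(mean(mcs[nb, s]))
  }
  if (short)
    warning("fewer than k = ", k, " eligible neighbour genes for some ",
            "imputations; used all available")
  out
}
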