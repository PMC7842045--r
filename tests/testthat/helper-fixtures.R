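# Small in-code fixtures shared across test files.

# probe x sample beta matrix with optional NA entries
tiny_meth <- function(values, probes = NULL, samples = NULL) {
  m <- matrix(values, nrow = length(values) / 2)
  probes <- probes %||% sprintf("cg%05d", seq_len(nrow(m)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(probes, samples)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Spearman oracle: Pearson correlation of midranks
oracle_spearman <- function(x, y) cor(rank(x), rank(y))

# independent two-sided p oracle: t approximation on n - 2 df
oracle_spearman_p <- function(rho, n) {
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tval), df = n - 2)
}

# closed-form OLS oracle via the normal equations
oracle_ols <- function(x, y, degree = 1L) {
  X <- outer(x, 0:degree, `^`)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# a tiny hand-assembled model store with two genes (degrees 1 and 3)
tiny_store <- function() {
  cpg <- tibble::tibble(
    gene = c("G1", "G1", "G1", "G2", "G2"),
    direction = c("pos", "pos", "neg", "pos", "neg"),
    rank = c(1L, 2L, 1L, 1L, 1L),
    probe = c("cg00001", "cg00002", "cg00003", "cg00004", "cg00005")
  )
  models <- tibble::tibble(
    gene = c("G1", "G2"),
    degree = c(1L, 3L),
    b0 = c(1.25, -0.5), b1 = c(2.5, 1/3), b2 = c(NA, exp(1)),
    b3 = c(NA, -pi), b4 = c(NA_real_, NA_real_),
    cv_rmse = c(0.31, 0.12345678901234567),
    r2_discovery = c(0.8, 0.55), r2_validation = c(0.75, 0.42),
    methcorr_flag = c(TRUE, TRUE)
  )
  model_store(cpg, models,
              metadata = list(cancer_type = "SYNTH", seed = 3L),
              rejected = tibble::tibble(gene = "G9", reason = "too_few_cpgs"))
}

# quick trained store on a small synthetic cohort, memoised per session
trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(n_samples = 120, n_signal_genes = 15,
                             n_null_genes = 10, signal_fraction = 0.6,
                             seed = 11)
      cohort <- generate_cohort(spec)
      store <- suppressMessages(
        train(cohort$meth, cohort$expr, methcorr_config(seed = 5))
      )
      cache <<- list(cohort = cohort, store = store)
    }
    cache
  }
})
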