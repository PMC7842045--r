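mcs_sites <- function(n_pos, n_neg, gene = "G1") tibble::tibble(
  gene = gene,
  direction = rep(c("pos", "neg"), c(n_pos, n_neg)),
  rank = c(seq_len(n_pos), seq_len(n_neg)),
  probe = sprintf("cg%05d", seq_len(n_pos + n_neg))
)

beta4 <- function() matrix(c(0.8, 0.6, 0.2, 0.4), 4, 2,
                           dimnames = list(sprintf("cg%05d", 1:4),
                                           c("s1", "s2")))

test_that("the MCS formula is evaluated exactly on hand-built cases", {
  sites <- mcs_sites(2, 2)
  m <- beta4()                                 # 4 probes x 2 samples
  m[, 2] <- c(1, 1, 0, 0)
  mcs <- compute_mcs(m, sites)
  expect_equal(mcs["G1", "s1"], 0.7, tolerance = 1e-12)   # (0.8+0.6+0.8+0.6)/4
  expect_equal(mcs["G1", "s2"], 1, tolerance = 1e-12)     # extremal
  m[, 1] <- 0.5
  expect_equal(compute_mcs(m, sites)["G1", "s1"], 0.5, tolerance = 1e-12)
})

test_that("the denominator adapts to available probes and enforces coverage", {
  sites <- mcs_sites(2, 2)
  m <- beta4()
  m["cg00002", "s1"] <- NA                         # 3 of 4 available
  mcs <- compute_mcs(m, sites)
  expect_equal(mcs["G1", "s1"], (0.8 + 0.8 + 0.6) / 3, tolerance = 1e-12)

  # a probe absent from the array behaves like a missing beta (EPIC case)
  m2 <- m[rownames(m) != "cg00002", , drop = FALSE]
  expect_equal(compute_mcs(m2, sites)["G1", "s1"], (0.8 + 0.8 + 0.6) / 3,
               tolerance = 1e-12)

  # below 50% coverage the score is missing
  m3 <- m
  m3[c("cg00002", "cg00003", "cg00004"), "s1"] <- NA
  expect_true(is.na(compute_mcs(m3, sites)["G1", "s1"]))
  expect_false(is.na(compute_mcs(m3, sites, min_probe_coverage = 0.25)["G1", "s1"]))
})

test_that("MCS is monotone in probe betas and always within [0, 1]", {
  set.seed(201)
  sites <- mcs_sites(3, 3)
  for (i in 1:20) {
    m <- tiny_meth(runif(12))
    base <- compute_mcs(m, sites)
    stopifnot(!anyNA(base))
    expect_true(all(base >= 0 & base <= 1))
    up <- m
    up["cg00001", ] <- pmin(up["cg00001", ] + 0.1, 1)   # positive probe up
    expect_true(all(compute_mcs(up, sites) >= base - 1e-12))
    dn <- m
    dn["cg00004", ] <- pmin(dn["cg00004", ] + 0.1, 1)   # negative probe up
    expect_true(all(compute_mcs(dn, sites) <= base + 1e-12))
  }
})

test_that("MCS is robust to random 20% probe deletion", {
  cohort <- generate_cohort(synthetic_spec(
    n_samples = 80, n_signal_genes = 20, n_null_genes = 0,
    probes_per_gene_pos = 10, probes_per_gene_neg = 10, seed = 23
  ))
  sites <- dplyr::mutate(cohort$truth$probes,
                         rank = 1L)
  full <- compute_mcs(cohort$meth, sites)
  set.seed(202)
  keep <- sample(rownames(cohort$meth),
                 round(0.8 * nrow(cohort$meth)))
  sub <- compute_mcs(cohort$meth[keep, ], sites)
  expect_lt(median(abs(full - sub), na.rm = TRUE), 0.05)
})

test_that("kNN imputation honours its contracts", {
  # identity neighbour, k = 1
  mcs <- rbind(g1 = c(0.2, 0.4, NA, 0.8),
               g2 = c(0.2, 0.4, 0.6, 0.8),
               g3 = c(0.9, 0.1, 0.3, 0.2))
  colnames(mcs) <- sprintf("s%d", 1:4)
  out <- impute_missing_mcs(mcs, k = 1)
  expect_equal(out["g1", "s3"], 0.6)
  expect_identical(out[!is.na(mcs)], mcs[!is.na(mcs)])

  # no missing entries: exact no-op
  complete <- matrix(runif(12), 3, 4,
                     dimnames = list(rownames(mcs), colnames(mcs)))
  expect_identical(impute_missing_mcs(complete, k = 3), complete)

  # fewer than k eligible neighbours warns; imputation still completes
  expect_warning(out2 <- impute_missing_mcs(mcs, k = 10), "fewer than k")
  expect_false(anyNA(out2))

  # a sample with under half its genes scored is an error
  bad <- mcs
  bad[c("g1", "g2"), "s1"] <- NA
  expect_error(impute_missing_mcs(bad, k = 1), "50%")
})

test_that("imputation error is small on a smooth synthetic score matrix", {
  set.seed(203)
  n_genes <- 60; n_samp <- 50
  latent <- matrix(runif(5 * n_samp), 5, n_samp)
  load <- matrix(runif(n_genes * 5), n_genes, 5)
  load <- load / rowSums(load)
  truth <- load %*% latent          # smooth, correlated genes, values in [0,1]
  dimnames(truth) <- list(sprintf("g%02d", 1:n_genes), sprintf("s%02d", 1:n_samp))
  masked <- truth
  holes <- sample(length(truth), round(0.05 * length(truth)))
  masked[holes] <- NA
  filled <- impute_missing_mcs(masked, k = 10)
  expect_false(anyNA(filled))
  expect_true(all(filled >= 0 & filled <= 1))
  expect_lt(mean(abs(filled[holes] - truth[holes])), 0.05)
})
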