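test_that("40/40/20 split has the right sizes, is disjoint and seeded", {
  ids <- sprintf("s%03d", 1:100)
  sp <- split_samples(ids, seed = 3)
  expect_length(sp$discovery1, 40)
  expect_length(sp$discovery2, 40)
  expect_length(sp$validation, 20)
  all_ids <- c(sp$discovery1, sp$discovery2, sp$validation)
  expect_setequal(all_ids, ids)
  expect_false(anyDuplicated(all_ids) > 0)

  expect_identical(split_samples(ids, 3), sp)           # determinism
  expect_false(identical(split_samples(ids, 1)$discovery1,
                         split_samples(ids, 2)$discovery1))
  # order of the input IDs must not matter
  expect_identical(split_samples(rev(ids), 3), sp)
  expect_error(split_samples(ids[1:14], 1), "15")
})

test_that("split sizes follow round(0.4 n) for awkward n", {
  for (n in c(15, 17, 23, 51)) {
    sp <- split_samples(sprintf("x%02d", 1:n), seed = 1)
    expect_length(sp$discovery1, round(0.4 * n))
    expect_length(sp$discovery2, round(0.4 * n))
    expect_length(sp$validation, n - 2 * round(0.4 * n))
  }
})

test_that("screening rho agrees with the midrank-Pearson oracle, ties included", {
  set.seed(101)
  expr <- matrix(rnorm(40), 2, 20,
                 dimnames = list(c("gA", "gB"), sprintf("s%02d", 1:20)))
  # probe betas with deliberate ties
  meth <- rbind(round(runif(20), 1), runif(20), round(runif(20), 1))
  dimnames(meth) <- list(c("cg1", "cg2", "cg3"), colnames(expr))
  rec <- spearman_screen(expr, meth, colnames(expr), 1L,
                         p_threshold = 1.0000001)
  expect_identical(nrow(rec), 6L)
  for (i in seq_len(nrow(rec))) {
    x <- expr[rec$gene[i], ]
    y <- meth[rec$probe[i], ]
    expect_equal(rec$rho[i], oracle_spearman(x, y), tolerance = 1e-12)
    expect_equal(rec$p[i], oracle_spearman_p(rec$rho[i], 20), tolerance = 1e-12)
  }
})

test_that("monotone and anti-monotone vectors give rho of +-1 and -0.5 toy case", {
  e <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g", c("a", "b", "c")))
  m <- rbind(c(0.1, 0.2, 0.3), c(0.9, 0.5, 0.1), c(0.3, 0.1, 0.2))
  dimnames(m) <- list(c("up", "down", "mix"), c("a", "b", "c"))
  rec <- spearman_screen(e, m, c("a", "b", "c"), 1L,
                         p_threshold = 2, min_pair_n = 3)
  expect_equal(rec$rho[rec$probe == "up"], 1)
  expect_equal(rec$rho[rec$probe == "down"], -1)
  expect_equal(rec$rho[rec$probe == "mix"], -0.5)
})

test_that("pairs are computed over complete observations and respect min_pair_n", {
  set.seed(102)
  n <- 40
  expr <- matrix(rnorm(n), 1, n, dimnames = list("g", sprintf("s%02d", 1:n)))
  beta <- runif(n)
  beta[1:10] <- NA
  meth <- matrix(beta, 1, n, dimnames = list("cg1", colnames(expr)))
  rec <- spearman_screen(expr, meth, colnames(expr), 1L, p_threshold = 2)
  ok <- !is.na(beta)
  expect_equal(rec$rho, oracle_spearman(expr[1, ok], beta[ok]), tolerance = 1e-12)
  expect_equal(rec$p, oracle_spearman_p(rec$rho, sum(ok)), tolerance = 1e-12)

  meth2 <- meth
  meth2[1, 1:30] <- NA  # only 10 complete pairs < min_pair_n = 15
  expect_identical(nrow(spearman_screen(expr, meth2, colnames(expr), 1L,
                                        p_threshold = 2)), 0L)
})

test_that("exact small-n p-values match cor.test's exact distribution", {
  set.seed(103)
  for (i in 1:10) {
    x <- rnorm(7)
    y <- rnorm(7)
    st <- methcorr:::spearman_test(x, y)
    ct <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(st$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(st$p, ct$p.value, tolerance = 1e-10)
  }
})

test_that("zero-variance vectors are skipped, not propagated", {
  e <- matrix(c(1, 2, 3, 4, 2, 2, 2, 2), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "gflat"), sprintf("s%d", 1:4)))
  m <- matrix(c(0.1, 0.4, 0.2, 0.9, 0.5, 0.5, 0.5, 0.5), 2, 4, byrow = TRUE,
              dimnames = list(c("cg1", "cgflat"), colnames(e)))
  expect_message(
    rec <- spearman_screen(e, m, colnames(e), 1L, p_threshold = 2,
                           min_pair_n = 4),
    "zero-variance"
  )
  expect_identical(sort(unique(rec$gene)), "g1")
  expect_identical(sort(unique(rec$probe)), "cg1")
})

test_that("rank-sum combination keeps concordant candidates and breaks ties as documented", {
  r1 <- tibble::tibble(
    gene = "g", probe = c("cgA", "cgB", "cgOnly1", "cgFlip"),
    rho = c(0.90, 0.80, 0.70, 0.60), p = 1e-5, set_label = 1L
  )
  r2 <- tibble::tibble(
    gene = "g", probe = c("cgA", "cgB", "cgFlip"),
    rho = c(0.70, 0.85, -0.50), p = 1e-5, set_label = 2L
  )
  comb <- combine_rank_sum(r1, r2)
  # cgOnly1 significant in one set only; cgFlip discordant sign: both excluded
  expect_setequal(comb$probe, c("cgA", "cgB"))
  # ranks: cgA (1, 2), cgB (2, 1) -> tie at ranksum 3; mean |rho| breaks it:
  # cgB (0.825) > cgA (0.80)
  expect_identical(comb$probe, c("cgB", "cgA"))
  expect_equal(comb$ranksum, c(3, 3))
})

test_that("rank-sum tie at equal mean |rho| falls back to probe ID", {
  r1 <- tibble::tibble(gene = "g", probe = c("cgZ", "cgA"),
                       rho = c(0.8, 0.7), p = 1e-5, set_label = 1L)
  r2 <- tibble::tibble(gene = "g", probe = c("cgZ", "cgA"),
                       rho = c(0.7, 0.8), p = 1e-5, set_label = 2L)
  comb <- combine_rank_sum(r1, r2)
  expect_identical(comb$probe, c("cgA", "cgZ"))
})

test_that("negative candidates are ranked most-negative first", {
  r1 <- tibble::tibble(gene = "g", probe = c("n1", "n2"),
                       rho = c(-0.9, -0.5), p = 1e-6, set_label = 1L)
  r2 <- tibble::tibble(gene = "g", probe = c("n1", "n2"),
                       rho = c(-0.8, -0.6), p = 1e-6, set_label = 2L)
  comb <- combine_rank_sum(r1, r2)
  expect_identical(comb$direction, c("neg", "neg"))
  expect_identical(comb$probe, c("n1", "n2"))
  expect_equal(comb$rank_set1, c(1, 2))
})

test_that("selection truncates per sign, drops sparse genes, matches exhaustive sort", {
  # gene with 150 positive and 30 negative candidates
  mk <- function(gene, n, sign) tibble::tibble(
    gene = gene,
    probe = sprintf("%s_%s%04d", gene, sign, seq_len(n)),
    rho = sign_val <- if (sign == "p") seq(0.99, 0.3, length.out = n)
          else seq(-0.99, -0.3, length.out = n),
    p = 1e-6
  )
  r1 <- dplyr::bind_rows(mk("gBig", 150, "p"), mk("gBig", 30, "n"),
                         mk("gSmall", 4, "p"))
  r2 <- r1
  r2$rho <- r2$rho * 0.9
  r1$set_label <- 1L; r2$set_label <- 2L
  sel <- suppressMessages(select_top_cpgs(combine_rank_sum(r1, r2),
                                          max_per_side = 100,
                                          min_cpg_total = 10))
  counts <- table(sel$gene, sel$direction)
  expect_identical(as.integer(counts["gBig", "pos"]), 100L)
  expect_identical(as.integer(counts["gBig", "neg"]), 30L)
  expect_false("gSmall" %in% sel$gene)
  expect_identical(attr(sel, "dropped")$gene, "gSmall")
})

test_that("selected top-100 equals the brute-force rank-sum sort on shuffled candidates", {
  set.seed(104)
  n <- 250
  probes <- sprintf("cg%06d", sample(1e6, n))
  rho1 <- runif(n, 0.2, 0.99)
  rho2 <- runif(n, 0.2, 0.99)
  r1 <- tibble::tibble(gene = "g", probe = probes, rho = rho1, p = 1e-8,
                       set_label = 1L)
  r2 <- tibble::tibble(gene = "g", probe = probes, rho = rho2, p = 1e-8,
                       set_label = 2L)
  sel <- select_top_cpgs(combine_rank_sum(r1, r2), max_per_side = 100)

  # exhaustive oracle: rank within each set, order by rank-sum with the
  # documented tie-breaks, take the first 100
  rs <- rank(-rho1) + rank(-rho2)
  ord <- order(rs, -(abs(rho1) + abs(rho2)) / 2, probes)
  expect_identical(sel$probe, probes[ord][1:100])

  # permutation invariance: shuffling candidate row order changes nothing
  shuf <- sample(n)
  sel2 <- select_top_cpgs(combine_rank_sum(r1[shuf, ], r2[rev(shuf), ]),
                          max_per_side = 100)
  expect_identical(sel2$probe, sel$probe)
})

test_that("true readout probes are recovered from a strong synthetic signal", {
  cohort <- generate_cohort(synthetic_spec(
    n_samples = 250, n_signal_genes = 8, n_null_genes = 4,
    signal_fraction = 0.8, beta_noise_sd = 0.05, seed = 21
  ))
  sp <- split_samples(colnames(cohort$meth), seed = 9)
  r1 <- spearman_screen(cohort$expr, cohort$meth, sp$discovery1, 1L)
  r2 <- spearman_screen(cohort$expr, cohort$meth, sp$discovery2, 2L)
  sel <- select_top_cpgs(combine_rank_sum(r1, r2))
  truth <- cohort$truth$probes
  recall <- vapply(unique(truth$gene), function(g) {
    mean(paste(truth$direction[truth$gene == g], truth$probe[truth$gene == g]) %in%
           paste(sel$direction[sel$gene == g], sel$probe[sel$gene == g]))
  }, double(1))
  expect_true(mean(recall) >= 0.9)
  # selected signs must be concordant in both discovery sets
  comb <- combine_rank_sum(r1, r2)
  expect_true(all(sign(comb$rho_set1) == sign(comb$rho_set2)))
})
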