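## Discovery of expression-correlated CpG sites.
##
## Samples are partitioned 40/40/20 into two discovery sets and a held-out
## validation set. Genome-wide Spearman correlations between each gene's
## expression and each CpG site's beta-value are screened independently in
## the two discovery sets at P < 0.01; candidates significant with concordant
## sign in both sets are ranked per set by rho and combined by rank-sum, and
## up to 100 CpG sites per sign are retained per gene (the MethCORR matrix).

#' Split samples into two discovery sets and a validation set
#'
#' Deterministic for a given seed and sample-ID set, regardless of input
#' order. Discovery sets 1 and 2 each take `round(0.4 * n)` samples; the
#' validation set takes the remainder (~20%).
#'
#' @param sample_ids Character vector of unique sample IDs (n >= 15).
#' @param seed Integer seed.
#' @return A list of class `methcorr_split` with elements `discovery1`,
#'   `discovery2`, `validation` (character vectors) and `seed`.
#' @export
split_samples <- function(sample_ids, seed) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample IDs must be unique")
  n <- length(sample_ids)
  if (n < 15L) stop("need at least 15 samples to form a 40/40/20 split, got ", n)
  n1 <- round(0.4 * n)
  n2 <- round(0.4 * n)
  perm <- withr::with_seed(seed, sample(sort(sample_ids)))
  structure(
    list(discovery1 = perm[seq_len(n1)],
         discovery2 = perm[n1 + seq_len(n2)],
         validation = perm[(n1 + n2 + 1L):n],
         seed = as.integer(seed)),
    class = "methcorr_split"
  )
}

# Two-sided p for Spearman's rho via the large-sample t approximation on
# n - 2 degrees of freedom.
spearman_p_approx <- function(rho, n) {
  rho <- pmin(pmax(rho, -1), 1)
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df = n - 2)
  p[abs(rho) >= 1] <- 0
  p
}

# All permutations of 1..n as an n! x n matrix (n <= 9).
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 9L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    shifted <- sub + (sub >= i)
    out[[i]] <- cbind(rep(i, nrow(sub)), shifted)
  }
  do.call(rbind, out)
}

# Exact two-sided permutation p-value for rho at small n (handles ties:
# permutes the midranks themselves).
spearman_p_exact <- function(rx, ry, rho) {
  n <- length(rx)
  P <- all_permutations(n)
  a <- (rx - mean(rx)) / sd(rx)
  b <- (ry - mean(ry)) / sd(ry)
  rho_perm <- (matrix(b[P], nrow(P)) %*% a) / (n - 1)
  mean(abs(rho_perm) >= abs(rho) - 1e-12)
}

# Spearman rho (Pearson on midranks) and two-sided p for one pair.
# Exact permutation p for n < exact_below; t approximation otherwise.
spearman_test <- function(x, y, exact_below = 10L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(NULL)
  if (sd(x) == 0 || sd(y) == 0) return(NULL)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NULL)
  rho <- min(max(cor(rx, ry), -1), 1)
  p <- if (n < exact_below) spearman_p_exact(rx, ry, rho)
       else spearman_p_approx(rho, n)
  list(rho = rho, p = p, n = n)
}

# Midrank-transform matrix rows, flagging zero-variance rows as NA.
rank_rows <- function(mat) {
  r <- t(apply(mat, 1L, rank))
  const <- apply(mat, 1L, function(v) length(unique(v)) == 1L)
  r[const, ] <- NA_real_
  r
}

#' Screen genome-wide CpG-gene Spearman correlations in one discovery set
#'
#' Computes Spearman's rho (Pearson correlation of midranks, average ranks
#' for ties) between every gene's expression and every CpG probe's
#' beta-value over the given samples, with a two-sided p-value from the
#' t approximation on n - 2 degrees of freedom (exact permutation p when a
#' pair has fewer than 10 complete observations). Pairs are computed over
#' samples where the beta-value is non-missing; pairs with fewer than
#' `min_pair_n` complete observations, zero-variance vectors, or
#' `p >= p_threshold` are discarded.
#'
#' @param expr Gene x sample expression matrix.
#' @param meth Probe x sample beta-value matrix.
#' @param samples Sample IDs of the discovery set (present in both matrices).
#' @param set_label Discovery-set label (1 or 2), carried into the records.
#' @param p_threshold Significance cutoff (default 0.01).
#' @param min_pair_n Minimum complete observations per pair (default 15).
#' @return Tibble with columns `gene`, `probe`, `rho`, `p`, `set_label`.
#' @export
spearman_screen <- function(expr, meth, samples, set_label,
                            p_threshold = 0.01, min_pair_n = 15L) {
  samples <- as.character(samples)
  if (!all(samples %in% colnames(expr)) || !all(samples %in% colnames(meth)))
    stop("some samples are absent from the expression or methylation matrix")
  e <- expr[, samples, drop = FALSE]
  m <- meth[, samples, drop = FALSE]
  n <- length(samples)
  empty <- tibble::tibble(gene = character(), probe = character(),
                          rho = double(), p = double(), set_label = integer())
  if (nrow(e) == 0L || nrow(m) == 0L || n < 3L) return(empty)

  er <- rank_rows(e)
  n_skipped <- sum(is.na(er[, 1L]))
  out <- list()

  probe_has_na <- rowSums(is.na(m)) > 0L
  # Fast path: complete probes share one rank transform; rho for all
  # gene x probe pairs comes from a single cross-correlation of midranks.
  if (any(!probe_has_na) && n >= min_pair_n && n >= 3L) {
    mc <- m[!probe_has_na, , drop = FALSE]
    mr <- rank_rows(mc)
    n_skipped <- n_skipped + sum(is.na(mr[, 1L]))
    R <- suppressWarnings(cor(t(er), t(mr)))
    if (n < 10L) {
      # exact p per significant-looking pair is handled pair-wise below the
      # default min_pair_n; at the matrix scale n >= min_pair_n >= 10 in
      # practice, but fall back cleanly if configured lower
      idx <- which(is.finite(R), arr.ind = TRUE)
      recs <- lapply(seq_len(nrow(idx)), function(k) {
        i <- idx[k, 1L]; j <- idx[k, 2L]
        st <- spearman_test(e[i, ], mc[j, ])
        if (is.null(st) || st$p >= p_threshold) return(NULL)
        tibble::tibble(gene = rownames(e)[i], probe = rownames(mc)[j],
                       rho = st$rho, p = st$p)
      })
      out <- c(out, recs)
    } else {
      P <- spearman_p_approx(R, n)
      keep <- which(is.finite(R) & P < p_threshold, arr.ind = TRUE)
      if (nrow(keep)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          gene = rownames(e)[keep[, 1L]],
          probe = rownames(mc)[keep[, 2L]],
          rho = R[keep], p = P[keep]
        )
      }
    }
  } else if (any(!probe_has_na)) {
    n_skipped <- n_skipped + sum(!probe_has_na) * nrow(e)
  }

  # Pairwise path for probes with missing beta-values.
  for (j in which(probe_has_na)) {
    ok <- !is.na(m[j, ])
    nn <- sum(ok)
    if (nn < min_pair_n || nn < 3L) next
    bv <- m[j, ok]
    if (length(unique(bv)) == 1L) { n_skipped <- n_skipped + 1L; next }
    rb <- rank(bv)
    es <- e[, ok, drop = FALSE]
    ers <- rank_rows(es)
    rho <- suppressWarnings(as.vector(cor(t(ers), rb)))
    p <- if (nn < 10L) {
      vapply(seq_len(nrow(es)), function(i) {
        if (!is.finite(rho[i])) return(NA_real_)
        spearman_p_exact(ers[i, ], rb, rho[i])
      }, double(1))
    } else spearman_p_approx(rho, nn)
    keep <- which(is.finite(rho) & p < p_threshold)
    if (length(keep)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        gene = rownames(e)[keep], probe = rownames(m)[j],
        rho = rho[keep], p = p[keep]
      )
    }
  }

  if (n_skipped > 0L)
    message("spearman_screen: skipped ", n_skipped,
            " zero-variance or under-covered vectors (set ", set_label, ")")
  res <- if (length(out)) dplyr::bind_rows(out) else empty
  res$set_label <- as.integer(set_label)
  res[order(res$gene, res$probe), , drop = FALSE]
}

#' Combine two discovery screens by rank-sum
#'
#' Candidates are (gene, probe) pairs significant at the screening threshold
#' with the same correlation sign in both discovery sets. Within each gene,
#' sign and set, candidates are ranked by rho (descending for positive,
#' ascending for negative; rank 1 = strongest; average ranks on ties) and
#' ordered by ascending rank-sum across the two sets. Rank-sum ties are
#' broken by larger mean |rho| across the sets, then lexicographic probe ID.
#'
#' @param records_set1,records_set2 Tibbles from [spearman_screen()].
#' @return Tibble with columns `gene`, `direction`, `probe`, `rho_set1`,
#'   `rho_set2`, `rank_set1`, `rank_set2`, `ranksum`, ordered by gene,
#'   direction, then final rank.
#' @export
combine_rank_sum <- function(records_set1, records_set2) {
  merged <- dplyr::inner_join(
    dplyr::select(records_set1, "gene", "probe", rho_set1 = "rho"),
    dplyr::select(records_set2, "gene", "probe", rho_set2 = "rho"),
    by = c("gene", "probe")
  )
  merged <- dplyr::filter(merged, .data$rho_set1 * .data$rho_set2 > 0)
  merged$direction <- ifelse(merged$rho_set1 > 0, "pos", "neg")
  merged <- dplyr::group_by(merged, .data$gene, .data$direction)
  merged <- dplyr::mutate(
    merged,
    rank_set1 = ifelse(.data$direction == "pos",
                       rank(-.data$rho_set1), rank(.data$rho_set1)),
    rank_set2 = ifelse(.data$direction == "pos",
                       rank(-.data$rho_set2), rank(.data$rho_set2)),
    ranksum = .data$rank_set1 + .data$rank_set2,
    mean_abs_rho = (abs(.data$rho_set1) + abs(.data$rho_set2)) / 2
  )
  merged <- dplyr::arrange(merged, .data$ranksum,
                           dplyr::desc(.data$mean_abs_rho), .data$probe,
                           .by_group = TRUE)
  merged <- dplyr::ungroup(merged)
  dplyr::select(merged, "gene", "direction", "probe", "rho_set1", "rho_set2",
                "rank_set1", "rank_set2", "ranksum")
}

#' Select the top CpG sites per gene and sign
#'
#' Truncates the rank-sum-ordered candidate lists to at most `max_per_side`
#' probes per sign per gene. Genes whose retained positive + negative total
#' falls below `min_cpg_total` are dropped (they cannot support a stable
#' MethCORR score) and reported in the `dropped` attribute.
#'
#' @param ranked Tibble from [combine_rank_sum()].
#' @param max_per_side Maximum probes per sign (default 100).
#' @param min_cpg_total Minimum pos + neg probes to keep a gene (default 10).
#' @return Tibble with columns `gene`, `direction`, `rank` (1-based within
#'   gene and sign), `probe` — the MethCORR matrix. Attribute `dropped` holds
#'   a tibble (`gene`, `n_candidates`) of excluded genes.
#' @export
select_top_cpgs <- function(ranked, max_per_side = 100L, min_cpg_total = 10L) {
  sel <- dplyr::group_by(ranked, .data$gene, .data$direction)
  sel <- dplyr::slice_head(sel, n = max_per_side)
  sel <- dplyr::mutate(sel, rank = dplyr::row_number())
  sel <- dplyr::ungroup(sel)
  totals <- dplyr::count(sel, .data$gene, name = "n_candidates")
  drop <- dplyr::filter(totals, .data$n_candidates < min_cpg_total)
  if (nrow(drop))
    message("select_top_cpgs: dropped ", nrow(drop),
            " gene(s) with fewer than ", min_cpg_total, " selected CpG sites")
  sel <- dplyr::filter(sel, !.data$gene %in% drop$gene)
  out <- dplyr::select(sel, "gene", "direction", "rank", "probe")
  out$rank <- as.integer(out$rank)
  attr(out, "dropped") <- drop
  out
}
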