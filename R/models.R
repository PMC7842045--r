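## Per-gene regression: expression = B0 + B1*MCS + ... + Bn*MCS^n, n in 1..4.
##
## Candidate degrees 1-4 are scored by 10x repeated 10-fold cross-validated
## RMSE (mean of the 100 held-out fold RMSEs). The best polynomial (degree
## 2-4 by CV RMSE) replaces the simple linear model only when it improves
## CV RMSE by at least 5% relative to linear; otherwise the linear model is
## kept. Coefficients are refit on all discovery samples at the chosen
## degree. Discovery R^2 is the squared Pearson correlation between
## cross-validated out-of-fold predictions (averaged over the 10 repeats)
## and observed expression, counting only positive association as skill
## (see model_r2); validation R^2 is computed the same way on the held-out
## 20% set. A gene is a MethCORR gene when both exceed 0.16.

MAX_DEGREE <- 4L

# Fold labels for repeated k-fold CV, keyed to sample IDs: the id -> fold
# map depends only on the id set and the seed, so CV results are invariant
# to the order samples arrive in. Rows follow `ids`; columns are repeats.
fold_assignments <- function(ids, n_folds = 10L, n_repeats = 10L, seed = 1L) {
  n <- length(ids)
  o <- order(ids)
  f <- withr::with_seed(seed, vapply(
    seq_len(n_repeats),
    function(r) sample(rep_len(seq_len(n_folds), n)),
    integer(n)
  ))
  out <- matrix(0L, n, n_repeats)
  out[o, ] <- f
  out
}

poly_design <- function(x, degree) outer(x, 0:degree, `^`)

# OLS via QR; rank-deficient columns get zero coefficients.
ols_coef <- function(X, y) {
  co <- qr.coef(qr(X), y)
  co[is.na(co)] <- 0
  co
}

eval_poly <- function(coefficients, x) {
  out <- rep(coefficients[[1L]], length(x))
  xp <- x
  for (j in seq_along(coefficients)[-1L]) {
    out <- out + coefficients[[j]] * xp
    xp <- xp * x
  }
  out[is.na(x)] <- NA_real_
  out
}

new_gene_model <- function(gene, degree, coefficients, cv_rmse,
                           r2_discovery, r2_validation = NA_real_,
                           methcorr_flag = FALSE, cv_rmse_by_degree = NULL) {
  structure(
    list(gene = gene, degree = as.integer(degree),
         coefficients = stats::setNames(as.numeric(coefficients),
                                        paste0("b", seq_along(coefficients) - 1L)),
         cv_rmse = cv_rmse, r2_discovery = r2_discovery,
         r2_validation = r2_validation, methcorr_flag = methcorr_flag,
         cv_rmse_by_degree = cv_rmse_by_degree),
    class = "methcorr_gene_model"
  )
}

#' Fit the per-gene MCS-to-expression regression model
#'
#' @param mcs Numeric vector of MethCORR scores over discovery samples,
#'   ideally named by sample ID (names key the CV folds so results do not
#'   depend on sample order). `NA` scores are dropped with their pair.
#' @param expr Numeric expression vector aligned with `mcs`.
#' @param seed Integer seed for the CV fold assignment.
#' @param gene Gene label carried into the model.
#' @param n_folds,n_repeats Cross-validation scheme (default 10 x 10).
#' @param rmse_rule Minimum relative CV-RMSE decrease for a polynomial to
#'   replace the linear model (default 0.05).
#' @return A `methcorr_gene_model` with discovery fields set;
#'   `r2_validation` and `methcorr_flag` are filled by
#'   [validate_gene_model()].
#' @export
fit_gene_model <- function(mcs, expr, seed, gene = "gene",
                           n_folds = 10L, n_repeats = 10L, rmse_rule = 0.05) {
  stopifnot(length(mcs) == length(expr))
  ids <- names(mcs) %||% as.character(seq_along(mcs))
  ok <- !is.na(mcs) & is.finite(expr)
  mcs <- mcs[ok]; expr <- expr[ok]; ids <- ids[ok]
  n <- length(mcs)
  if (n < 30L)
    stop("fit_gene_model needs at least 30 discovery samples with a valid ",
         "MethCORR score, got ", n)
  if (length(unique(mcs)) == 1L) {
    return(new_gene_model(gene, 1L, c(mean(expr), 0), cv_rmse = sd(expr),
                          r2_discovery = 0,
                          cv_rmse_by_degree = rep(NA_real_, MAX_DEGREE)))
  }

  Xfull <- poly_design(mcs, MAX_DEGREE)
  folds <- fold_assignments(ids, n_folds, n_repeats, seed)
  fold_rmse <- array(NA_real_, c(n_folds * n_repeats, MAX_DEGREE))
  oof_sum <- matrix(0, n, MAX_DEGREE)
  oof_n <- matrix(0L, n, MAX_DEGREE)
  row <- 0L
  for (r in seq_len(n_repeats)) {
    for (f in seq_len(n_folds)) {
      row <- row + 1L
      te <- folds[, r] == f
      if (!any(te)) next
      tr <- !te
      if (sum(tr) < MAX_DEGREE + 2L) next
      for (d in seq_len(MAX_DEGREE)) {
        co <- ols_coef(Xfull[tr, 1:(d + 1L), drop = FALSE], expr[tr])
        pred <- drop(Xfull[te, 1:(d + 1L), drop = FALSE] %*% co)
        fold_rmse[row, d] <- rmse(expr[te], pred)
        oof_sum[te, d] <- oof_sum[te, d] + pred
        oof_n[te, d] <- oof_n[te, d] + 1L
      }
    }
  }
  cv_rmse <- colMeans(fold_rmse, na.rm = TRUE)
  poly_degrees <- 2:MAX_DEGREE
  # Parsimony band: take the lowest polynomial degree whose CV RMSE is within
  # 1% (plus an absolute floor for near-perfect fits) of the best polynomial,
  # so float-level differences between equivalent degrees cannot inflate the
  # chosen degree.
  tol <- min(cv_rmse[poly_degrees]) * 1.01 + 1e-9 * sd(expr)
  best_poly <- poly_degrees[which(cv_rmse[poly_degrees] <= tol)[1L]]
  rel_gain <- (cv_rmse[1L] - cv_rmse[best_poly]) / cv_rmse[1L]
  # A linear CV RMSE at numerical zero cannot be meaningfully improved; the
  # >= 5% relative rule only applies when there is real residual error.
  degree <- if (is.finite(rel_gain) && rel_gain >= rmse_rule &&
                cv_rmse[1L] > 1e-8 * sd(expr)) best_poly else 1L

  coefficients <- ols_coef(Xfull[, 1:(degree + 1L), drop = FALSE], expr)
  oof_pred <- ifelse(oof_n[, degree] > 0, oof_sum[, degree] / oof_n[, degree],
                     NA_real_)
  model <- new_gene_model(gene, degree, coefficients,
                          cv_rmse = cv_rmse[degree],
                          r2_discovery = model_r2(oof_pred, expr),
                          cv_rmse_by_degree = cv_rmse)
  model
}

#' Validate a gene model on held-out samples
#'
#' Sets `r2_validation` (squared Pearson correlation between predicted and
#' observed expression on the validation samples; degenerate cases and
#' negative association count as 0, since a model predicting in the wrong
#' direction has no skill) and the MethCORR flag: `TRUE` iff discovery and
#' validation R^2 both exceed `r2_gate`.
#'
#' @param model A `methcorr_gene_model`.
#' @param mcs_validation,expr_validation Aligned vectors over validation
#'   samples (disjoint from discovery); `NA` scores are dropped pairwise.
#' @param r2_gate R^2 threshold (default 0.16).
#' @param min_validation_n Below this many usable validation samples the
#'   model is flagged `FALSE` with a warning (default 10).
#' @return The model with validation fields set.
#' @export
validate_gene_model <- function(model, mcs_validation, expr_validation,
                                r2_gate = 0.16, min_validation_n = 10L) {
  stopifnot(inherits(model, "methcorr_gene_model"),
            length(mcs_validation) == length(expr_validation))
  ok <- !is.na(mcs_validation) & is.finite(expr_validation)
  mcs_validation <- mcs_validation[ok]
  expr_validation <- expr_validation[ok]
  if (length(mcs_validation) < min_validation_n) {
    warning("gene ", model$gene, ": fewer than ", min_validation_n,
            " validation samples; MethCORR flag forced FALSE")
    model$r2_validation <- 0
    model$methcorr_flag <- FALSE
    return(model)
  }
  pred <- eval_poly(model$coefficients, mcs_validation)
  model$r2_validation <- model_r2(pred, expr_validation)
  model$methcorr_flag <- isTRUE(model$r2_discovery > r2_gate &&
                                model$r2_validation > r2_gate)
  model
}

#' Predict expression from MethCORR scores
#'
#' Deterministic polynomial evaluation; `NA` scores give `NA` predictions
#' (impute scores first with [impute_missing_mcs()]).
#'
#' @param object A `methcorr_gene_model`.
#' @param mcs Numeric vector of scores in `[0, 1]`.
#' @param ... Unused.
#' @return Numeric vector of inferred expression values.
#' @export
predict.methcorr_gene_model <- function(object, mcs, ...) {
  eval_poly(object$coefficients, mcs)
}

#' @export
print.methcorr_gene_model <- function(x, ...) {
  cat("MethCORR gene model: ", x$gene, " (degree ", x$degree, ")\n", sep = "")
  cat("  coefficients: ", paste(signif(x$coefficients, 4), collapse = ", "),
      "\n  cv RMSE ", signif(x$cv_rmse, 4),
      "; discovery R^2 ", signif(x$r2_discovery, 4),
      "; validation R^2 ", signif(x$r2_validation, 4),
      "; MethCORR ", x$methcorr_flag, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.methcorr_gene_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(x$coefficients))
}

#' @export
glance.methcorr_gene_model <- function(x, ...) {
  tibble::tibble(gene = x$gene, degree = x$degree, cv_rmse = x$cv_rmse,
                 r2_discovery = x$r2_discovery,
                 r2_validation = x$r2_validation,
                 methcorr_flag = x$methcorr_flag)
}

# model <-> table-row conversions used by the store.
model_to_row <- function(m) {
  b <- rep(NA_real_, 5L)
  b[seq_along(m$coefficients)] <- m$coefficients
  tibble::tibble(gene = m$gene, degree = m$degree,
                 b0 = b[1L], b1 = b[2L], b2 = b[3L], b3 = b[4L], b4 = b[5L],
                 cv_rmse = m$cv_rmse, r2_discovery = m$r2_discovery,
                 r2_validation = m$r2_validation,
                 methcorr_flag = m$methcorr_flag)
}

row_to_model <- function(row) {
  co <- as.numeric(row[COEF_COLS])[seq_len(row$degree + 1L)]
  new_gene_model(row$gene, row$degree, co, cv_rmse = row$cv_rmse,
                 r2_discovery = row$r2_discovery,
                 r2_validation = row$r2_validation,
                 methcorr_flag = row$methcorr_flag)
}
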