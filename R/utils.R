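## Internal helpers shared across modules.

# Deterministic child seed for a pipeline stage; stays inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647L)
}

# Squared Pearson correlation with the degenerate cases pinned to 0:
# zero variance on either side (constant predictions or observations) is 0,
# not NA, so the R^2 > 0.16 gate can always be evaluated.
squared_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2L) return(0)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)^2
}

# Model-performance R^2: squared correlation between predictions and
# observations, counting only positive association as skill. Cross-validated
# predictions of a null model are weakly ANTI-correlated with the held-out
# observations (each is roughly the training mean, which excludes the
# held-out value), and squaring would convert that artifact into apparent
# skill; a model predicting in the wrong direction has none.
model_r2 <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  if (sum(ok) < 2L) return(0)
  pred <- pred[ok]; obs <- obs[ok]
  if (sd(pred) == 0 || sd(obs) == 0) return(0)
  max(cor(pred, obs), 0)^2
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
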