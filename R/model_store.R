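## ModelStore: the serializable unit produced by train() and consumed by
## infer(). A store bundles the per-gene CpG-site lists (the MethCORR matrix),
## the per-gene regression model table, a rejected-gene sidecar, a per-gene
## fit report, and metadata. On disk it is a directory of diff-able
## tab-separated tables plus one JSON metadata document; coefficients are
## written with 17 significant digits so inference is bit-stable across
## save/load.

STORE_FORMAT_VERSION <- "1.0"

COEF_COLS <- paste0("b", 0:4)

#' Construct a model store
#'
#' Usually produced by [train()]; exposed so stores can be assembled or
#' subset programmatically.
#'
#' @param cpg_sites Tibble with columns `gene`, `direction` (`"pos"`/`"neg"`),
#'   `rank` (1 = strongest), `probe` — the MethCORR matrix.
#' @param models Tibble with columns `gene`, `degree`, `b0`..`b4`, `cv_rmse`,
#'   `r2_discovery`, `r2_validation`, `methcorr_flag`.
#' @param metadata Named list; `cancer_type`, `platform`, `seed`, `version`
#'   and `format_version` are filled in when absent.
#' @param rejected Optional tibble (`gene`, `reason`) of genes excluded during
#'   training.
#' @param fit_report Optional per-gene fit diagnostics tibble.
#' @return An object of class `methcorr_model_store`.
#' @export
model_store <- function(cpg_sites, models, metadata = list(),
                        rejected = NULL, fit_report = NULL) {
  cpg_sites <- tibble::as_tibble(cpg_sites)
  models <- tibble::as_tibble(models)
  stopifnot(all(c("gene", "direction", "rank", "probe") %in% names(cpg_sites)),
            all(c("gene", "degree", COEF_COLS, "cv_rmse",
                  "r2_discovery", "r2_validation", "methcorr_flag")
                %in% names(models)))
  metadata$format_version <- metadata$format_version %||% STORE_FORMAT_VERSION
  metadata$version <- metadata$version %||%
    as.character(utils::packageVersion("methcorr"))
  metadata$platform <- metadata$platform %||% "450K"
  store <- structure(
    list(cpg_sites = cpg_sites, models = models, metadata = metadata,
         rejected = if (!is.null(rejected)) tibble::as_tibble(rejected),
         fit_report = if (!is.null(fit_report)) tibble::as_tibble(fit_report)),
    class = "methcorr_model_store"
  )
  validate_model_store(store)
}

validate_model_store <- function(store) {
  g_models <- sort(unique(store$models$gene))
  g_sites <- sort(unique(store$cpg_sites$gene))
  if (!identical(g_models, g_sites))
    stop("model store invariant violated: genes in the model table and the ",
         "CpG-site table must coincide")
  if (nrow(store$cpg_sites) &&
      !all(store$cpg_sites$direction %in% c("pos", "neg")))
    stop("CpG-site direction must be 'pos' or 'neg'")
  invisible(store)
}

#' @export
print.methcorr_model_store <- function(x, ...) {
  cat("MethCORR model store\n")
  cat("  genes:      ", length(unique(x$models$gene)), "\n")
  cat("  CpG sites:  ", nrow(x$cpg_sites), " (",
      length(unique(x$cpg_sites$probe)), " unique probes)\n", sep = "")
  cat("  platform:   ", x$metadata$platform %||% "?", "\n")
  if (!is.null(x$rejected))
    cat("  rejected:   ", nrow(x$rejected), " genes\n", sep = "")
  invisible(x)
}

fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_exact <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt17)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
}

read_tsv_typed <- function(path, col_types) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "NA")
  df <- tibble::as_tibble(dt)
  for (nm in names(col_types)) {
    if (!nm %in% names(df)) stop("column ", nm, " missing from ", path)
    df[[nm]] <- switch(col_types[[nm]],
      d = as.numeric(df[[nm]]),
      i = as.integer(df[[nm]]),
      l = as.logical(df[[nm]]),
      c = df[[nm]]
    )
  }
  df[names(col_types)]
}

#' Write a model store to a directory
#'
#' Writes `cpg_sites.tsv`, `models.tsv`, `metadata.json` and, when present,
#' `rejected_genes.tsv` and `fit_report.tsv`. Reading the directory back with
#' [read_model_store()] reproduces every field exactly (coefficients are
#' compared as their serialized 17-significant-digit decimal text).
#'
#' @param store A `methcorr_model_store`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model_store <- function(store, dir) {
  stopifnot(inherits(store, "methcorr_model_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_exact(store$cpg_sites, file.path(dir, "cpg_sites.tsv"))
  write_tsv_exact(store$models, file.path(dir, "models.tsv"))
  jsonlite::write_json(store$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(store$rejected))
    write_tsv_exact(store$rejected, file.path(dir, "rejected_genes.tsv"))
  if (!is.null(store$fit_report))
    write_tsv_exact(store$fit_report, file.path(dir, "fit_report.tsv"))
  invisible(dir)
}

#' Read a model store from a directory
#'
#' @param dir Directory written by [write_model_store()].
#' @return A `methcorr_model_store`.
#' @export
read_model_store <- function(dir) {
  if (!dir.exists(dir)) stop("no such model store directory: ", dir)
  models_path <- file.path(dir, "models.tsv")
  sites_path <- file.path(dir, "cpg_sites.tsv")
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(models_path))
    stop("model store at ", dir, " is missing its models table (models.tsv)")
  if (!file.exists(sites_path))
    stop("model store at ", dir, " is missing its CpG-site table (cpg_sites.tsv)")
  metadata <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  fv <- metadata$format_version %||% STORE_FORMAT_VERSION
  if (!identical(as.character(fv), STORE_FORMAT_VERSION))
    stop("model store format version mismatch: store was written as version ",
         fv, " but this build reads version ", STORE_FORMAT_VERSION)

  cpg_sites <- read_tsv_typed(sites_path,
    c(gene = "c", direction = "c", rank = "i", probe = "c"))
  model_types <- c(gene = "c", degree = "i",
                   stats::setNames(rep("d", 5), COEF_COLS),
                   cv_rmse = "d", r2_discovery = "d", r2_validation = "d",
                   methcorr_flag = "l")
  models <- read_tsv_typed(models_path, model_types)

  rej_path <- file.path(dir, "rejected_genes.tsv")
  rejected <- if (file.exists(rej_path))
    read_tsv_typed(rej_path, c(gene = "c", reason = "c"))
  rep_path <- file.path(dir, "fit_report.tsv")
  fit_report <- if (file.exists(rep_path)) {
    hdr <- names(data.table::fread(rep_path, sep = "\t", nrows = 0L))
    types <- stats::setNames(rep("d", length(hdr)), hdr)
    for (nm in intersect(c("gene", "rule"), hdr)) types[[nm]] <- "c"
    if ("chosen_degree" %in% hdr) types[["chosen_degree"]] <- "i"
    read_tsv_typed(rep_path, types)
  }
  model_store(cpg_sites, models, metadata,
              rejected = rejected, fit_report = fit_report)
}

#' @export
tidy.methcorr_model_store <- function(x, ...) x$models

#' @export
glance.methcorr_model_store <- function(x, ...) {
  tibble::tibble(
    n_genes = length(unique(x$models$gene)),
    n_cpg_sites = nrow(x$cpg_sites),
    n_rejected = if (is.null(x$rejected)) NA_integer_ else nrow(x$rejected),
    median_r2_discovery = median(x$models$r2_discovery),
    median_r2_validation = median(x$models$r2_validation),
    frac_polynomial = mean(x$models$degree > 1L)
  )
}
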