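#' Synchrony analysis configuration
#'
#' @param n_surrogates number of surrogate randomizations for the pairwise
#'   null (default 100).
#' @param significance_quantile per-pair null quantile a correlation must
#'   exceed to be retained (default 0.95).
#' @param rng_seed integer seed for the surrogate shifts (mandatory for
#'   reproducible runs).
#' @return A `synchrony_config` list. Surrogates are circular shifts of
#'   each trace by an independent uniform offset: they preserve each
#'   trace's autocorrelation but destroy cross-correlation, giving a null
#'   for the pairwise correlations.
#' @export
synchrony_config <- function(n_surrogates = 100, significance_quantile = 0.95,
                             rng_seed = 1L) {
  stopifnot(n_surrogates >= 1, significance_quantile > 0,
            significance_quantile < 1)
  structure(list(n_surrogates = as.integer(n_surrogates),
                 significance_quantile = significance_quantile,
                 rng_seed = as.integer(rng_seed)),
            class = "synchrony_config")
}

#' Surrogate-corrected pairwise correlation matrix
#'
#' Pearson correlations between all ROI pairs of a dF/F matrix, compared
#' against a circular-shift surrogate null: each surrogate iteration
#' shifts every trace by an independent uniform offset and recomputes the
#' full correlation matrix; a pair whose observed correlation does not
#' exceed its null's `significance_quantile` is zeroed (the diagonal stays
#' 1). Zero-variance traces get zero off-diagonals with a warning.
#'
#' @param dff a [dff_matrix()] with at least 2 ROIs.
#' @param cfg a [synchrony_config()].
#' @return A list with `corr_matrix` (thresholded), `raw_corr` (before
#'   zeroing), `pair_threshold` (R x R matrix of null quantiles) and
#'   `surrogate_matrices` (list of the surrogate correlation matrices,
#'   reused by [cluster_rois()]).
#' @export
pairwise_correlation <- function(dff, cfg = synchrony_config()) {
  stopifnot(inherits(dff, "dff_matrix"), inherits(cfg, "synchrony_config"))
  v <- dff$values
  r <- nrow(v)
  if (r < 2) stop("need at least 2 ROIs", call. = FALSE)
  v[is.na(v)] <- 0
  sds <- apply(v, 1, sd)
  flat <- sds == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance trace(s); off-diagonals set to 0")
    v[flat, 1] <- v[flat, 1] + 1e-12 # avoid NaN; entries zeroed below
  }
  raw <- cor(t(v))
  raw[is.na(raw)] <- 0
  diag(raw) <- 1

  tt <- ncol(v)
  set.seed(cfg$rng_seed)
  surr <- vector("list", cfg$n_surrogates)
  null_vals <- array(NA_real_, c(r, r, cfg$n_surrogates))
  for (s in seq_len(cfg$n_surrogates)) {
    off <- sample.int(tt - 1L, r, replace = TRUE)
    vs <- v
    for (i in seq_len(r))
      vs[i, ] <- v[i, c((off[i] + 1L):tt, 1L:off[i])]
    cm <- cor(t(vs))
    cm[is.na(cm)] <- 0
    diag(cm) <- 1
    surr[[s]] <- cm
    null_vals[, , s] <- cm
  }
  thr <- apply(null_vals, c(1, 2), quantile,
               probs = cfg$significance_quantile, names = FALSE)
  out <- raw
  out[raw <= thr] <- 0
  out[flat, ] <- 0
  out[, flat] <- 0
  diag(out) <- 1
  list(corr_matrix = out, raw_corr = raw, pair_threshold = thr,
       surrogate_matrices = surr)
}

#' Eigenvalue-based synchronization index
#'
#' `SI = (lambda_max - 1) / (R - 1)` with `lambda_max` the largest
#' eigenvalue of the R x R pairwise correlation matrix, clipped to `[0, 1]`
#' against numerical noise. 0 for uncorrelated ROIs (identity matrix),
#' 1 for a perfectly synchronous field (all-ones matrix).
#'
#' @param corr_matrix symmetric correlation matrix with unit diagonal,
#'   `R >= 2`.
#' @return SI in `[0, 1]`.
#' @examples
#' synchronization_index(diag(5))              # 0
#' synchronization_index(matrix(1, 5, 5))      # 1
#' @export
synchronization_index <- function(corr_matrix) {
  stopifnot(is.matrix(corr_matrix), nrow(corr_matrix) == ncol(corr_matrix))
  r <- nrow(corr_matrix)
  if (r < 2) stop("synchronization index is undefined for a single ROI",
                  call. = FALSE)
  lmax <- eigen(corr_matrix, symmetric = TRUE, only.values = TRUE)$values[1]
  min(1, max(0, (lmax - 1) / (r - 1)))
}

#' Eigen-clusters of co-active ROIs
#'
#' Eigenvalues of the correlation matrix exceeding the largest eigenvalue
#' observed across the surrogate correlation matrices are significant;
#' each defines one cluster. ROI `i`'s participation in cluster `k` is
#' `lambda_k * v_ki^2` (unit eigenvector `v_k`); the ROI joins the cluster
#' maximizing its participation, or stays unclustered (0) when its best
#' participation is below the uninformative level `1/R`. Per-cluster SI is
#' `(lambda_k - 1) / (R - 1)` clipped to `[0, 1]`.
#'
#' @param corr_matrix R x R correlation matrix (typically the thresholded
#'   matrix from [pairwise_correlation()]).
#' @param surrogate_matrices list of surrogate correlation matrices.
#' @return A list with `n_clusters`, `cluster_assignment` (integer vector,
#'   0 = unclustered), `cluster_si` (numeric, one per cluster) and
#'   `null_max_eigenvalue`.
#' @export
cluster_rois <- function(corr_matrix, surrogate_matrices) {
  stopifnot(is.matrix(corr_matrix))
  r <- nrow(corr_matrix)
  null_max <- max(vapply(surrogate_matrices, function(m)
    eigen(m, symmetric = TRUE, only.values = TRUE)$values[1], numeric(1)))
  eg <- eigen(corr_matrix, symmetric = TRUE)
  sig <- which(eg$values > null_max)
  if (!length(sig))
    return(list(n_clusters = 0L, cluster_assignment = integer(r),
                cluster_si = numeric(0), null_max_eigenvalue = null_max))
  part <- sapply(sig, function(k) eg$values[k] * eg$vectors[, k]^2)
  part <- cbind(part)
  assign <- apply(part, 1, which.max)
  best <- part[cbind(seq_len(r), assign)]
  assign[best < 1 / r] <- 0L
  list(n_clusters = length(sig), cluster_assignment = as.integer(assign),
       cluster_si = pmin(1, pmax(0, (eg$values[sig] - 1) / (r - 1))),
       null_max_eigenvalue = null_max)
}

#' Full synchrony analysis of a field
#'
#' Runs [pairwise_correlation()], [synchronization_index()] and
#' [cluster_rois()] and bundles the results.
#'
#' @param dff a [dff_matrix()] with at least 2 ROIs.
#' @param cfg a [synchrony_config()].
#' @return A `synchrony_result`: `corr_matrix` (thresholded), `raw_corr`,
#'   `sync_index`, `n_clusters`, `cluster_assignment` (named by `roi_id`),
#'   `cluster_si`.
#' @export
compute_synchrony <- function(dff, cfg = synchrony_config()) {
  pc <- pairwise_correlation(dff, cfg)
  cl <- cluster_rois(pc$corr_matrix, pc$surrogate_matrices)
  structure(list(corr_matrix = pc$corr_matrix, raw_corr = pc$raw_corr,
                 sync_index = synchronization_index(pc$corr_matrix),
                 n_clusters = cl$n_clusters,
                 cluster_assignment = setNames(cl$cluster_assignment,
                                               dff$roi_ids),
                 cluster_si = cl$cluster_si,
                 roi_ids = dff$roi_ids),
            class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf("<synchrony_result> %d ROIs, SI = %.3f, %d cluster(s)\n",
              nrow(x$corr_matrix), x$sync_index, x$n_clusters))
  invisible(x)
}

#' Turn a result object into a per-observation tibble
#'
#' @param x a result object.
#' @param ... passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Turn a result object into a one-row summary tibble
#'
#' @param x a result object.
#' @param ... passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Tidy a synchrony result
#'
#' @param x a `synchrony_result`.
#' @param ... unused.
#' @return A tibble with one row per ROI: `roi_id`, `cluster` (0 =
#'   unclustered), `cluster_si`.
#' @export
tidy.synchrony_result <- function(x, ...) {
  cl <- unname(x$cluster_assignment)
  tibble::tibble(roi_id = x$roi_ids, cluster = cl,
                 cluster_si = ifelse(cl > 0, x$cluster_si[pmax(cl, 1)],
                                     NA_real_))
}

#' One-row summary of a synchrony result
#'
#' @param x a `synchrony_result`.
#' @param ... unused.
#' @return A tibble: `n_roi`, `sync_index`, `n_clusters`.
#' @export
glance.synchrony_result <- function(x, ...) {
  tibble::tibble(n_roi = nrow(x$corr_matrix), sync_index = x$sync_index,
                 n_clusters = x$n_clusters)
}
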