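# Pearson correlation matrix with p-values, and PCA of the fitted model
# parameters with a deterministic sign convention.

#' Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson correlations between the dielectric
#' parameters and covariates, with two-sided p-values from the t transform
#' on n - 2 degrees of freedom.  Zero-variance columns are flagged and
#' their pairs reported as `NA` rather than propagating `NaN`.  P-values
#' are unadjusted.
#'
#' @param table data.frame holding all variables.
#' @param dielectric_vars,covariate_vars character vectors of column
#'   names; the matrix covers their union (so dielectric-dielectric and
#'   covariate-covariate pairs are included too).
#' @return list of class `correlation_matrix`: `r`, `p`, `n` (pairwise
#'   complete counts), `variables`, `degenerate` (zero-variance columns).
#' @export
correlation_matrix <- function(table,
                               dielectric_vars = c("delta_eps", "tau_ps",
                                                   "alpha", "sigma_dc"),
                               covariate_vars = c("fat_pct", "protein_pct",
                                                  "lactose_pct")) {
  vars <- unique(c(dielectric_vars, covariate_vars))
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols))
    stop("correlation_matrix: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  n <- matrix(0L, k, k, dimnames = list(vars, vars))
  degenerate <- vars[vapply(vars, function(v) {
    x <- table[[v]][is.finite(table[[v]])]
    length(x) < 2 || stats::sd(x) == 0
  }, logical(1))]
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j < i) next
      x <- table[[vars[i]]]
      y <- table[[vars[j]]]
      ok <- is.finite(x) & is.finite(y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 0
        next
      }
      if (vars[i] %in% degenerate || vars[j] %in% degenerate) next
      if (sum(ok) < 3) next
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n, variables = vars,
                 degenerate = degenerate),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlation matrix (r):\n")
  print(round(x$r, digits))
  if (length(x$degenerate))
    cat("zero-variance columns flagged:",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' PCA of the fitted model parameters
#'
#' Standardises the selected columns to zero mean and unit variance
#' (mandatory here: relaxation times in ps and broadening exponents near 1
#' live on very different scales), then eigendecomposes the correlation
#' matrix.  Constant columns are dropped with a warning.  Loadings carry a
#' deterministic sign: the largest-magnitude entry of each component is
#' positive.
#'
#' @param table data.frame with the variables.
#' @param vars columns to project (default: the four model parameters).
#' @param n_components number of components to retain.
#' @return list of class `pca_result`: `scores` (n x n_components),
#'   `loadings` (variables x components, orthonormal columns),
#'   `explained_variance_ratio`, `center`, `scale`, `vars`.
#' @export
pca_project <- function(table,
                        vars = c("delta_eps", "tau_ps", "alpha", "sigma_dc"),
                        n_components = 2L) {
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols))
    stop("pca_project: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- as.matrix(table[vars])
  if (any(!is.finite(x)))
    stop("pca_project: non-finite values in input columns", call. = FALSE)
  const <- vars[apply(x, 2, function(col) stats::sd(col) == 0)]
  if (length(const)) {
    warning("pca_project: dropping constant column(s): ",
            paste(const, collapse = ", "))
    vars <- setdiff(vars, const)
    x <- x[, vars, drop = FALSE]
  }
  if (nrow(x) < n_components + 1)
    stop("pca_project: need at least n_components + 1 rows", call. = FALSE)
  if (ncol(x) < n_components)
    stop("pca_project: fewer usable variables than components", call. = FALSE)
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  keep <- seq_len(n_components)
  load <- pr$rotation[, keep, drop = FALSE]
  scores <- pr$x[, keep, drop = FALSE]
  for (j in keep) {                      # deterministic sign convention
    imax <- which.max(abs(load[, j]))
    if (load[imax, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = scores, loadings = load,
                 explained_variance_ratio = evr[keep],
                 center = pr$center, scale = pr$scale, vars = vars),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples on %d components (%s of variance)\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = " + ")))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Plot-ready biplot table
#'
#' Long-format export of PCA sample scores (with their stage / status
#' labels) and variable loading arrows, ready for any plotting front end;
#' no rendering logic lives here.
#'
#' @param pca a [pca_project()] result.
#' @param labels per-sample labels aligned with the score rows.
#' @return data.frame with `kind` (`"score"` or `"loading"`), `label`
#'   (sample label or variable name) and one column per component.
#' @export
biplot_export <- function(pca, labels) {
  stopifnot(inherits(pca, "pca_result"))
  if (length(labels) != nrow(pca$scores))
    stop("biplot_export: labels must align with score rows", call. = FALSE)
  pcs <- colnames(pca$scores)
  scores <- data.frame(kind = "score", label = as.character(labels),
                       pca$scores, row.names = NULL)
  loads <- data.frame(kind = "loading", label = rownames(pca$loadings),
                      pca$loadings, row.names = NULL)
  names(scores)[-(1:2)] <- pcs
  names(loads)[-(1:2)] <- pcs
  rbind(scores, loads)
}

#' Mean silhouette of a two-group score split
#'
#' Compares how cleanly two stages separate in PC space.  When the two
#' clusters have very unequal spreads (a compact established-pregnancy
#' cluster inside or beside a broad pre-insemination cloud), the
#' all-points mean silhouette is dominated by the broad cluster and says
#' little about whether a compact cluster has emerged -- which is the
#' visual signature of pregnancy in the per-cow biplots.  `focus`
#' restricts the average to one group's points to ask exactly that.
#'
#' @param scores numeric matrix of PC scores.
#' @param groups two-level grouping vector.
#' @param focus optional group label: average the silhouette over this
#'   group's points only (default: all points).
#' @return mean silhouette width.
#' @export
silhouette_mean <- function(scores, groups, focus = NULL) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("silhouette_mean: need exactly two groups", call. = FALSE)
  d <- as.matrix(stats::dist(scores))
  s <- vapply(seq_len(nrow(d)), function(i) {
    own <- groups == groups[i]
    other <- !own
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- mean(d[i, other])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  if (!is.null(focus)) {
    if (!focus %in% lev)
      stop("silhouette_mean: focus must be one of the group labels", call. = FALSE)
    return(mean(s[groups == focus]))
  }
  mean(s)
}
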