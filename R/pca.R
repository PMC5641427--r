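# PCA over flattened EFD shape vectors: contribution rates, factor
# loadings, mean +/- k SD shape reconstruction, and the two-pass
# PC1-score abnormality filter.

#' Principal component analysis of EFD shape vectors
#'
#' Eigen-decomposition of the sample covariance matrix (divisor n - 1) of
#' the \eqn{4N - 3} normalized coefficients; scores are the centered data
#' projected on the eigenvectors. Covariance (not correlation) PCA is used:
#' the coefficients share a dimensionless scale after first-harmonic
#' normalization.
#'
#' Sign convention: PC1 is oriented so that the \code{d1} entry of its
#' eigenvector is non-negative (higher PC1 = rounder first harmonic, which
#' puts hook-lacking round abnormal heads at high positive PC1 scores);
#' every other PC is oriented so that its largest-magnitude entry is
#' positive.
#'
#' @param x Numeric matrix, specimens x coefficients, with column names as
#'   produced by [flatten_coeffs()] and (ideally) specimen ids as row names.
#' @return An object of class \code{"efd_pca"}: list with
#'   \code{mean_vector}, \code{eigenvectors} (columns = PCs),
#'   \code{eigenvalues}, \code{contribution_rates}, \code{scores},
#'   \code{n_specimens}.
#' @export
efd_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("PCA needs at least 3 specimens")
  bad <- !stats::complete.cases(x) | apply(x, 1L, function(r) any(!is.finite(r)))
  if (any(bad))
    stop("non-finite coefficients for specimens: ",
         paste(if (is.null(rownames(x))) which(bad) else rownames(x)[bad],
               collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  scores <- pc$x
  # orientation conventions
  j_d1 <- match("d1", rownames(rot))
  if (!is.na(j_d1) && rot[j_d1, 1L] < 0) {
    rot[, 1L] <- -rot[, 1L]; scores[, 1L] <- -scores[, 1L]
  }
  if (ncol(rot) > 1L) {
    for (k in 2:ncol(rot)) {
      jmax <- which.max(abs(rot[, k]))
      if (rot[jmax, k] < 0) { rot[, k] <- -rot[, k]; scores[, k] <- -scores[, k] }
    }
  }
  ev <- pc$sdev^2
  structure(list(
    mean_vector = pc$center,
    eigenvectors = rot,
    eigenvalues = ev,
    contribution_rates = ev / sum(ev),
    scores = scores,
    n_specimens = nrow(x)
  ), class = "efd_pca")
}

#' @export
print.efd_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat(sprintf("EFD PCA: %d specimens, %d coefficients\n",
              x$n_specimens, nrow(x$eigenvectors)))
  cat("  contribution rates:",
      paste0(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$contribution_rates[1:k]),
             collapse = ", "), "\n")
  invisible(x)
}

#' Factor loadings of the original coefficients on the PC scores
#'
#' The loading of variable j on component k is the Pearson correlation
#' between the variable and the score (equivalently
#' \eqn{e_{jk}\sqrt{\lambda_k}/s_j}). The biplot arrow length for the
#' (PC1, PC2) plane is \eqn{\sqrt{l_{j1}^2 + l_{j2}^2}}; arrows longer than
#' 0.1 are flagged for display.
#'
#' @param model A fitted [efd_pca()] model.
#' @param x The matrix the model was fitted on.
#' @param n_pcs Number of components to report (default 2).
#' @return Data frame: \code{variable}, one loading column per PC,
#'   \code{arrow_length}, \code{display}.
#' @export
factor_loadings <- function(model, x, n_pcs = 2L) {
  stopifnot(inherits(model, "efd_pca"))
  x <- as.matrix(x)
  n_pcs <- min(n_pcs, ncol(model$scores))
  s <- apply(x, 2L, stats::sd)
  L <- matrix(0, ncol(x), n_pcs,
              dimnames = list(colnames(x), paste0("PC", seq_len(n_pcs))))
  for (k in seq_len(n_pcs)) {
    lam <- model$eigenvalues[k]
    if (lam > 0) {
      L[, k] <- ifelse(s > 0, model$eigenvectors[, k] * sqrt(lam) / s, 0)
    }
  }
  if (any(s == 0)) warning("zero-variance variables have loading 0: ",
                           paste(colnames(x)[s == 0], collapse = ", "))
  arrow <- if (n_pcs >= 2L) sqrt(L[, 1L]^2 + L[, 2L]^2) else abs(L[, 1L])
  out <- data.frame(variable = colnames(x), L, arrow_length = arrow,
                    display = arrow > 0.1, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Reconstruct the head contour at mean + k SD along a principal component
#'
#' Builds the coefficient vector \eqn{\bar{x} + k\sqrt{\lambda_{pc}}\,e_{pc}},
#' restores the fixed first-harmonic terms, and evaluates the Fourier
#' series, yielding the -2 SD / mean / +2 SD shape panels used to visualize
#' what a component encodes.
#'
#' @param model A fitted [efd_pca()] model.
#' @param pc Component index.
#' @param k SD multiple in [-3, 3].
#' @param n_points Contour points to evaluate.
#' @return A contour matrix.
#' @export
reconstruct_along_pc <- function(model, pc = 1L, k = 0, n_points = 360L) {
  stopifnot(inherits(model, "efd_pca"))
  if (abs(k) > 3) stop("|k| must be <= 3")
  if (pc < 1L || pc > ncol(model$eigenvectors)) stop("no such component: ", pc)
  v <- model$mean_vector + k * sqrt(model$eigenvalues[pc]) * model$eigenvectors[, pc]
  if (v[["d1"]] <= 0)
    stop("reconstruction leaves the valid shape space (d1 <= 0)")
  efd_reconstruct(unflatten_coeffs(v), n_points = n_points)
}

#' Two-pass abnormality filter on PC1 scores
#'
#' Pass 1 fits a PCA to all specimens; specimens whose PC1 score exceeds
#' \code{threshold} are excluded as abnormal (size outliers largely lacking
#' the hook-shaped head); pass 2 refits the PCA on the remainder. Both
#' models are returned so that scores and reconstructions can be inspected
#' on either pass.
#'
#' @param x Coefficient matrix (specimens x coefficients, row names = ids).
#' @param threshold PC1 score cut-off (default 0.55).
#' @return List with \code{normal} (retained matrix), \code{abnormal_ids},
#'   \code{pass1} and \code{pass2} models, and \code{pass1_scores}.
#' @export
filter_abnormal <- function(x, threshold = 0.55) {
  x <- as.matrix(x)
  pass1 <- efd_pca(x)
  s1 <- pass1$scores[, 1L]
  drop <- s1 > threshold
  if (all(drop)) stop("abnormality filter excluded every specimen")
  normal <- x[!drop, , drop = FALSE]
  pass2 <- efd_pca(normal)
  ids <- if (is.null(rownames(x))) as.character(which(drop)) else rownames(x)[drop]
  list(normal = normal, abnormal_ids = ids, pass1 = pass1, pass2 = pass2,
       pass1_scores = s1)
}
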