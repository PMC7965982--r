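#' Two-stage (dual) regression of template networks on a 4D series
#'
#' Stage 1 (temporal): each timepoint's volume is regressed on the
#' template spatial maps jointly, yielding one time course per network.
#' Stage 2 (spatial): each voxel's time series is regressed on the
#' variance-normalized time courses jointly, yielding per-network beta
#' maps. Each beta map is z-normalized by its voxelwise regression
#' standard error (`z = beta / se`); voxels with a vanishing residual
#' variance get `z = 0` (degenerate, noiseless fit).
#'
#' @param series_4d 4D array (x, y, z, t).
#' @param templates list of `network_template`s on the series grid;
#'   their vectorized maps must be linearly independent.
#' @return list of objects of class `subject_network_map`, one per
#'   template, each with `beta` and `z` 3D arrays, `name`, `affine`,
#'   `timecourse`.
#' @export
dual_regression <- function(series_4d, templates) {
  dims <- dim(series_4d)
  if (length(dims) != 4L) abort("`series_4d` must be a 4D array (x, y, z, t).")
  grid <- dims[1:3]
  Tn <- dims[4]
  K <- length(templates)
  if (Tn <= K + 1L) {
    abort("need n_timepoints > n_networks + 1 for a determined regression.")
  }
  V <- prod(grid)
  X <- vapply(templates, function(tp) {
    if (!all(dim(tp$z_map) == grid)) abort("template grid mismatch.")
    as.numeric(tp$z_map)
  }, numeric(V))                           # V x K

  kappa_X <- kappa(X, exact = FALSE)
  if (qr(X)$rank < K) {
    abort(sprintf(
      "template maps are rank-deficient (condition number %.3g).", kappa_X))
  }

  Y <- t(matrix(series_4d, nrow = V))      # T x V
  XtX_inv <- solve(crossprod(X))
  TC <- Y %*% X %*% XtX_inv                # T x K time courses

  # variance-normalize the time courses (constant columns left untouched)
  sds <- apply(TC, 2, sd)
  G <- sweep(TC, 2, ifelse(sds > 0, sds, 1), "/")

  GtG <- crossprod(G)
  kappa_G <- kappa(GtG, exact = FALSE)
  if (qr(G)$rank < K) {
    # all-zero input series: return all-zero maps rather than failing
    if (max(abs(Y)) == 0) {
      zero <- array(0, dim = grid)
      return(lapply(templates, function(tp) {
        structure(list(beta = zero, z = zero, name = tp$name,
                       affine = tp$affine,
                       timecourse = matrix(0, Tn, 1)),
                  class = "subject_network_map")
      }))
    }
    abort(sprintf(
      "recovered time courses are rank-deficient (condition number %.3g).",
      kappa_G))
  }
  GtG_inv <- solve(GtG)
  B <- GtG_inv %*% crossprod(G, Y)         # K x V betas
  resid <- Y - G %*% B
  sigma2 <- colSums(resid^2) / (Tn - K)    # per-voxel residual variance
  lapply(seq_len(K), function(k) {
    se <- sqrt(sigma2 * GtG_inv[k, k])
    z <- B[k, ] / se
    z[!is.finite(z)] <- 0
    structure(
      list(beta = array(B[k, ], dim = grid),
           z = array(z, dim = grid),
           name = templates[[k]]$name,
           affine = templates[[k]]$affine,
           timecourse = TC[, k, drop = FALSE]),
      class = "subject_network_map")
  })
}

#' @export
print.subject_network_map <- function(x, ...) {
  cat(sprintf("<subject_network_map> '%s' %s\n", x$name,
              paste(dim(x$beta), collapse = "x")))
  invisible(x)
}
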