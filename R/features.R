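#' Raw taxel features
#'
#' The first feature pipeline feeds the 288 low-pass-filtered taxel readings
#' directly to the ridge regression ("RR"), in flattening order.
#'
#' @param frame a [tactile_frame()].
#' @return A named numeric feature vector of length 288 with attribute
#'   `method = "raw"`.
#' @export
extract_raw <- function(frame) {
  if (!inherits(frame, "tactile_frame"))
    stop_validation("extract_raw() expects a tactile_frame")
  structure(setNames(as.numeric(frame), taxel_names()), method = "raw")
}

#' Region-of-interest layout
#'
#' Each of the 9 boards is split into two non-overlapping 4x4 taxel squares:
#' rows 0-3 (top) and rows 4-7 (bottom), all 4 columns. The 18 ROIs tile the
#' 288 taxels exactly once. ROI indices run board-major, top before bottom.
#' The interest point of an ROI is its upper-left corner `(x0, y0)`, with x
#' along the 8-cell row axis and y along the 4-cell column axis.
#'
#' @return A data frame with columns `roi` (1..18), `board` (0..8), `x0`
#'   (0 or 4), `y0` (always 0).
#' @export
roi_layout <- function() {
  data.frame(roi = 1:18,
             board = rep(0:(N_BOARDS - 1), each = 2),
             x0 = rep(c(0L, 4L), times = N_BOARDS),
             y0 = 0L)
}

#' Partition a frame into its 18 ROIs
#'
#' @param frame a [tactile_frame()].
#' @return A list of 18 objects of class `roi`, each with elements `index`,
#'   `board`, `origin` (`c(x0, y0)`) and `patch`, a 4x4 matrix `G[x, y]` of
#'   gray values with x (rows) along the row axis and y (columns) along the
#'   column axis.
#' @export
partition_rois <- function(frame) {
  if (!inherits(frame, "tactile_frame"))
    stop_validation("partition_rois() expects a tactile_frame")
  lay <- roi_layout()
  vals <- as.numeric(frame)
  lapply(seq_len(nrow(lay)), function(k) {
    b <- lay$board[k]; x0 <- lay$x0[k]; y0 <- lay$y0[k]
    patch <- matrix(0, 4, 4)
    for (xo in 0:3)
      patch[xo + 1L, ] <- vals[taxel_index(b, x0 + xo, y0 + 0:3)]
    structure(list(index = lay$roi[k], board = b, origin = c(x0, y0),
                   patch = patch),
              class = "roi")
  })
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi %d> board %d, origin (%d, %d)\n", x$index, x$board,
              x$origin[1], x$origin[2]))
  print(x$patch)
  invisible(x)
}

# Design matrix for the first-order plane over a 4x4 patch, flattened
# row-major (for each x offset, all y offsets). Columns match w = (alpha,
# beta, gamma): [x - x0, y - y0, 1].
roi_design_matrix <- function(centered = FALSE) {
  xo <- rep(0:3, each = 4)
  yo <- rep(0:3, times = 4)
  if (centered) {
    xo <- xo - 1.5
    yo <- yo - 1.5
  }
  cbind(x = xo, y = yo, intercept = 1)
}

#' First-order plane fit over one ROI
#'
#' Approximates the gray-value distribution of a 4x4 ROI by the plane
#' `G^(x, y) = alpha * (x - x0) + beta * (y - y0) + gamma`, where `(x0, y0)`
#' is the ROI's upper-left interest point. The coefficients minimize the
#' ridge-penalized sum of squared distances between the plane and the
#' observed taxels, solved in closed form as
#' `w = (A'A + lambda I)^-1 A'r` with `w = (alpha, beta, gamma)`, `A` the
#' 16x3 matrix of local coordinates and `r` the flattened (row-major) patch.
#' All three coefficients, including the offset, are penalized. `alpha` is
#' the mean gradient along x (rows), `beta` along y (columns); `gamma` is
#' the plane's value at the interest point. With `centered = TRUE` local
#' coordinates are centered on the patch instead, making `gamma` the patch
#' mean at `lambda = 0`.
#'
#' @param roi an `roi` from [partition_rois()], or a bare 4x4 matrix.
#' @param lambda ridge penalty for the plane fit (>= 0). The pipeline-wide
#'   default is 1; `lambda = 0` gives the plain least-squares plane.
#' @param centered use patch-centered local coordinates instead of the
#'   upper-left corner convention.
#' @return An object of class `plane_fit` with elements `alpha`, `beta`,
#'   `gamma`, `residual` (the sum of squared plane-to-taxel distances of the
#'   returned plane) and `lambda`.
#' @export
fit_roi_plane <- function(roi, lambda = 1, centered = FALSE) {
  patch <- if (inherits(roi, "roi")) roi$patch else as.matrix(roi)
  if (!all(dim(patch) == c(4, 4)))
    stop_validation("ROI patch must be 4x4, got ",
                    paste(dim(patch), collapse = "x"))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stop_validation("lambda must be a single number >= 0")
  A <- roi_design_matrix(centered)
  r <- as.numeric(t(patch))  # row-major: x outer, y inner
  w <- solve(crossprod(A) + lambda * diag(3), crossprod(A, r))
  res <- sum((A %*% w - r)^2)
  structure(list(alpha = w[1], beta = w[2], gamma = w[3],
                 residual = res, lambda = lambda),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("<plane_fit> alpha %.4g, beta %.4g, gamma %.4g, eps^2 %.4g (lambda = %g)\n",
              x$alpha, x$beta, x$gamma, x$residual, x$lambda))
  invisible(x)
}

#' ROI-gradient features (RR-ROIG pipeline)
#'
#' Extracts the plane-fit triple `(alpha, beta, gamma)` from each of the 18
#' ROIs of a frame and concatenates them in ROI order, giving the
#' 54-dimensional feature vector of the reduced pipeline -- one sixth of the
#' raw dimensionality.
#'
#' @inheritParams fit_roi_plane
#' @param frame a [tactile_frame()].
#' @return A named numeric vector of length 54
#'   (`b0_roi0_alpha, b0_roi0_beta, b0_roi0_gamma, b0_roi1_alpha, ...`) with
#'   attribute `method = "roig"`.
#' @export
extract_roig <- function(frame, lambda = 1, centered = FALSE) {
  rois <- partition_rois(frame)
  vals <- unlist(lapply(rois, function(r) {
    f <- fit_roi_plane(r, lambda = lambda, centered = centered)
    c(f$alpha, f$beta, f$gamma)
  }))
  structure(setNames(vals, roig_names()), method = "roig")
}

roig_names <- function() {
  lay <- roi_layout()
  unlist(lapply(seq_len(nrow(lay)), function(k) {
    sprintf("b%d_roi%d_%s", lay$board[k], (lay$roi[k] - 1L) %% 2L,
            c("alpha", "beta", "gamma"))
  }))
}

#' Linear map from taxels to ROI-gradient features
#'
#' The penalized plane fit is linear in the patch values, so the whole
#' 54-dimensional ROIG extraction is one fixed 54x288 linear map. This is
#' how feature matrices are computed efficiently for long streams; it agrees
#' exactly with per-frame [extract_roig()].
#'
#' @inheritParams fit_roi_plane
#' @return A 54x288 matrix `M` with `roig = M %*% taxels`.
#' @export
roig_transform <- function(lambda = 1, centered = FALSE) {
  A <- roi_design_matrix(centered)
  # 3x16 solver matrix: w = S r for one patch
  S <- solve(crossprod(A) + lambda * diag(3), t(A))
  lay <- roi_layout()
  M <- matrix(0, nrow = 54, ncol = N_TAXELS,
              dimnames = list(roig_names(), taxel_names()))
  for (k in seq_len(nrow(lay))) {
    cols <- unlist(lapply(0:3, function(xo)
      taxel_index(lay$board[k], lay$x0[k] + xo, lay$y0[k] + 0:3)))
    M[(k - 1L) * 3L + 1:3, cols] <- S
  }
  M
}

#' Feature matrix for a whole stream
#'
#' @param stream a [tactile_stream()] (already low-pass filtered in the
#'   standard pipeline).
#' @param method `"raw"` (288 columns) or `"roig"` (54 columns).
#' @inheritParams fit_roi_plane
#' @return An n x D numeric matrix with named columns.
#' @export
feature_matrix <- function(stream, method = c("raw", "roig"), lambda = 1,
                           centered = FALSE) {
  method <- match.arg(method)
  if (method == "raw") return(stream$values)
  t(roig_transform(lambda = lambda, centered = centered) %*% t(stream$values))
}
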