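#' Ridge-regression intent detection
#'
#' Fits the mapping matrix `W` (D x d) from feature vectors to graded
#' activation levels in closed form:
#' `W = (X'X + lambda I)^-1 X'Y`,
#' with `X` the m x D matrix of training features, `Y` the m x d matrix of
#' stimulus activation labels and `lambda` the regularization coefficient
#' (default 1, the standard pipeline value). The model is applied exactly as
#' written: no intercept column and no feature standardization (centering is
#' available, off by default, for experiments).
#'
#' @param X m x D numeric feature matrix.
#' @param Y m x d numeric label matrix (or vector for d = 1); column names
#'   are taken as activation names.
#' @param lambda regularization coefficient; `lambda = 0` is accepted only
#'   when `X'X` is full rank.
#' @param method feature-method tag stored with the model (`"raw"`,
#'   `"roig"`, or any label for experiments).
#' @param center center feature columns before fitting (stored and re-applied
#'   at prediction); off by default.
#' @return An object of class `ridge_model` with elements `W`, `lambda`,
#'   `method`, `activations`, `D`, `d`, `m`, plus the sufficient statistics
#'   `XtX`, `XtY` used by [retrain()] in append mode.
#' @examples
#' X <- diag(4)
#' Y <- matrix(runif(8), 4, 2)
#' m <- fit_ridge(X, Y, lambda = 1)   # W = Y / 2 for identity X
#' all.equal(m$W, Y / 2, check.attributes = FALSE)
#' @export
fit_ridge <- function(X, Y, lambda = 1, method = "raw", center = FALSE) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop_validation("X and Y must have the same number of rows (",
                    nrow(X), " vs ", nrow(Y), ")")
  if (nrow(X) < 1L) stop_validation("training set is empty")
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stop_validation("lambda must be a single number >= 0")
  mu <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, mu)
  XtX <- crossprod(Xc)
  XtY <- crossprod(Xc, Y)
  W <- ridge_solve(XtX, XtY, lambda)
  acts <- colnames(Y)
  if (is.null(acts)) acts <- paste0("a", seq_len(ncol(Y)))
  dimnames(W) <- list(colnames(X), acts)
  structure(list(W = W, lambda = lambda, method = method,
                 activations = acts, D = ncol(X), d = ncol(Y), m = nrow(X),
                 center = mu, XtX = XtX, XtY = XtY,
                 trained_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "ridge_model")
}

ridge_solve <- function(XtX, XtY, lambda) {
  K <- XtX + lambda * diag(nrow(XtX))
  W <- tryCatch(solve(K, XtY), error = function(e) NULL)
  if (is.null(W))
    stop_validation("X'X + lambda*I is singular; use lambda > 0 or ",
                    "full-rank features")
  W
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("<ridge_model> %s features, D = %d -> d = %d, lambda = %g, m = %d\n",
              x$method, x$D, x$d, x$lambda, x$m))
  invisible(x)
}

#' Predict activation levels
#'
#' Applies `y^ = W' x^` and clamps each activation to `[0, 1]`, the graded
#' output range driving the virtual hand. Clamping happens after the linear
#' map, never inside training.
#'
#' @param object a `ridge_model`.
#' @param x a feature vector of length D, or an n x D matrix.
#' @param clamp clamp outputs to `[0, 1]` (default `TRUE`).
#' @param ... unused.
#' @return A named activation vector (or n x d matrix for matrix input).
#' @export
predict.ridge_model <- function(object, x, clamp = TRUE, ...) {
  single <- is.null(dim(x))
  X <- if (single) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  if (ncol(X) != object$D)
    stop_validation("feature dimension ", ncol(X),
                    " does not match model D = ", object$D)
  Y <- sweep(X, 2, object$center) %*% object$W
  if (clamp) Y <- clamp01(Y)
  colnames(Y) <- object$activations
  if (single) Y[1, ] else Y
}

#' Retrain a model on fresh data
#'
#' Pressure-based signals drift over a session, so the decoder is retrained
#' periodically. `mode = "replace"` (the default) fits on the new data only:
#' the newest signals supersede stale ones. `mode = "append"` fits on the
#' concatenation of old and new rows, via the stored sufficient statistics.
#'
#' @param model a `ridge_model`.
#' @param X,Y new training data, shapes compatible with the model.
#' @param mode `"replace"` or `"append"`.
#' @param lambda regularization for the refit (defaults to the model's).
#' @return A new `ridge_model`.
#' @export
retrain <- function(model, X, Y, mode = c("replace", "append"),
                    lambda = model$lambda) {
  mode <- match.arg(mode)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) > 0 && (ncol(X) != model$D || ncol(Y) != model$d))
    stop_validation("new data shape (D = ", ncol(X), ", d = ", ncol(Y),
                    ") incompatible with model (D = ", model$D,
                    ", d = ", model$d, ")")
  if (mode == "replace")
    return(fit_ridge(X, Y, lambda = lambda, method = model$method))
  if (is.null(model$XtX))
    stop_validation("append retraining needs the model's sufficient ",
                    "statistics, which serialized models do not carry")
  if (any(model$center != 0))
    stop_validation("append retraining is not supported for centered models")
  XtX <- model$XtX
  XtY <- model$XtY
  if (nrow(X) > 0) {
    XtX <- XtX + crossprod(X)
    XtY <- XtY + crossprod(X, Y)
  }
  W <- ridge_solve(XtX, XtY, lambda)
  dimnames(W) <- dimnames(model$W)
  out <- model
  out$W <- W
  out$lambda <- lambda
  out$XtX <- XtX
  out$XtY <- XtY
  out$m <- model$m + nrow(X)
  out$trained_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  out
}

#' Serialize a ridge model to JSON
#'
#' Writes a self-describing text artifact: lambda, feature method,
#' activation names, shape, and `W` in row-major order. Sufficient
#' statistics are not serialized, so a reloaded model supports prediction
#' and replace-mode retraining but not append mode.
#'
#' @param model a `ridge_model`.
#' @param path output file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` a
#'   `ridge_model`.
#' @export
write_model <- function(model, path) {
  obj <- list(format = "tactomyo-ridge-model", version = 1L,
              lambda = model$lambda, method = model$method,
              activations = model$activations,
              D = model$D, d = model$d, m = model$m,
              center = as.numeric(model$center),
              trained_at = model$trained_at,
              W_row_major = as.numeric(t(model$W)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "tactomyo-ridge-model")
    stop_format("not a tactomyo ridge model file: ", path)
  W <- matrix(obj$W_row_major, nrow = obj$D, ncol = obj$d, byrow = TRUE,
              dimnames = list(NULL, obj$activations))
  structure(list(W = W, lambda = obj$lambda, method = obj$method,
                 activations = obj$activations, D = obj$D, d = obj$d,
                 m = obj$m, center = obj$center, XtX = NULL, XtY = NULL,
                 trained_at = obj$trained_at),
            class = "ridge_model")
}
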