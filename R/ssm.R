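# Point-based statistical shape model: generalized Procrustes
# standardization (location, unit centroid size, rotation) followed by PCA
# of the corresponded vertex sets.  A shape is expressed as the mean plus a
# linear combination of the n-1 nontrivial modes; fitting to a point cloud
# solves for the mode coefficients inside an ICP loop.

centroid_size <- function(X) sqrt(sum(sweep(X, 2, colMeans(X))^2))

#' Procrustes standardization of corresponded vertex sets
#'
#' Centres each vertex set at the origin, scales it to unit centroid size
#' (root-sum-of-squared distances to the centroid), and rotates it by
#' orthogonal Procrustes onto the (centred, unit-size) reference.
#' Reflection is never introduced.
#'
#' @param vertex_sets list of V x 3 matrices in vertex correspondence.
#' @param reference V x 3 matrix (e.g. the undeformed template).
#' @return list of standardized V x 3 matrices.
#' @export
procrustes_standardize <- function(vertex_sets, reference) {
  ref <- sweep(as.matrix(reference), 2, colMeans(reference))
  ref <- ref / centroid_size(ref)
  lapply(vertex_sets, function(X) {
    X <- as.matrix(X)
    if (nrow(X) != nrow(ref))
      stop("correspondence error: vertex count differs from reference")
    X <- sweep(X, 2, colMeans(X))
    X <- X / centroid_size(X)
    sv <- svd(crossprod(ref, X))        # rotate X onto ref, proper only
    S <- diag(3)
    if (det(sv$u) * det(sv$v) < 0) S[3, 3] <- -1
    X %*% (sv$v %*% S %*% t(sv$u))
  })
}

#' Build a statistical shape model
#'
#' Standardizes the training sets with [procrustes_standardize()] and runs
#' principal component analysis on the stacked coordinate vectors.  The
#' modes are the n-1 nontrivial eigenvectors of the sample covariance,
#' computed through the thin SVD of the centred n x 3V data matrix (the
#' explicit 3V x 3V covariance is never formed).
#'
#' @param vertex_sets list of n >= 2 corresponded V x 3 matrices.
#' @param reference V x 3 matrix; also stored for initializing fits.
#' @param faces optional face matrix carried for mesh reconstruction.
#' @return An object of class `shape_model`: `mean_shape` (3V vector, x,y,z
#'   per vertex), `modes` (3V x (n-1), orthonormal columns), `eigenvalues`
#'   (descending), `faces`, `reference`, `n_training`.
#' @export
build_ssm <- function(vertex_sets, reference, faces = NULL) {
  n <- length(vertex_sets)
  if (n < 2) stop("need at least 2 training shapes")
  std <- procrustes_standardize(vertex_sets, reference)
  X <- do.call(rbind, lapply(std, function(m) as.numeric(t(m))))
  mean_shape <- colMeans(X)
  Xc <- sweep(X, 2, mean_shape)
  sv <- svd(Xc, nu = 0, nv = n - 1)
  structure(list(mean_shape = mean_shape,
                 modes = sv$v,
                 eigenvalues = sv$d[seq_len(n - 1)]^2 / (n - 1),
                 faces = faces,
                 reference = as.matrix(reference),
                 n_training = n),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> %d training shapes, %d vertices, %d modes\n",
              x$n_training, length(x$mean_shape) / 3, ncol(x$modes)))
  cat("  eigenvalues:", format(signif(x$eigenvalues, 3)), "\n")
  invisible(x)
}

.shape_to_matrix <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Reconstruct a shape from model coefficients
#'
#' @param model a `shape_model`.
#' @param coefficients numeric vector of mode weights (length <= n-1).
#' @return V x 3 vertex matrix in the model (unit-size) frame.
#' @export
ssm_shape <- function(model, coefficients = numeric(0)) {
  v <- model$mean_shape
  if (length(coefficients))
    v <- v + model$modes[, seq_along(coefficients), drop = FALSE] %*% coefficients
  .shape_to_matrix(v)
}

#' Project a corresponded shape onto the model
#'
#' Standardizes the shape into the model frame and returns its mode
#' coefficients.
#'
#' @param model a `shape_model`.
#' @param vertices V x 3 matrix.
#' @export
ssm_project <- function(model, vertices) {
  std <- procrustes_standardize(list(vertices), model$reference)[[1]]
  as.numeric(crossprod(model$modes, as.numeric(t(std)) - model$mean_shape))
}

#' SSM-constrained ICP fit to a point cloud
#'
#' Iterates: (a) pair each current model vertex with its nearest cloud
#' point (pairs beyond `trim_factor` x median distance are dropped); (b)
#' re-estimate the similarity transform mapping the model frame to the data
#' frame from the current pairs (unless frozen); (c) solve the linear
#' least-squares problem for the shape coefficients over all modes in the
#' model frame.  Updating the pose before the coefficients keeps the
#' redundant pose/shape parameterization well-behaved: the similarity
#' absorbs as much of the residual as it can and the coefficients only
#' capture genuine shape deviation.  The fit is parameter-free in the sense
#' that all available modes are used and unconstrained; `clamp_sd`
#' optionally clamps coefficients to that many model standard deviations
#' per mode.
#'
#' @param model a `shape_model`.
#' @param cloud a `point_cloud` or m x 3 matrix.
#' @param init `similarity_transform` from the similarity-ICP stage, mapping
#'   the *reference template* frame to the data frame.
#' @param iters iteration budget (default 50).
#' @param trim_factor pair trimming multiple (default 3).
#' @param freeze_similarity keep the initial similarity fixed instead of
#'   re-estimating it each iteration.
#' @param pose_iters similarity-only ICP iterations on the mean shape run
#'   before the joint pose/shape loop; the coarse-to-fine start stops the
#'   redundant pose and shape parameters from drifting jointly.
#' @param clamp_sd clamp coefficients to +/- this many standard deviations
#'   (default `Inf`, i.e. no constraint).
#' @param tol early-stop tolerance on the mean pair distance (mm).
#' @return list with `mesh` (fitted `trimesh` in data frame),
#'   `coefficients`, `transform`, and the `mean_pair_distance` trace.
#' @export
ssm_fit <- function(model, cloud, init = NULL, iters = 50, trim_factor = 3,
                    freeze_similarity = FALSE, clamp_sd = Inf, tol = 1e-9,
                    pose_iters = 10) {
  P <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  if (nrow(P) == 0) stop("empty cloud")
  M0 <- .shape_to_matrix(model$mean_shape)
  if (is.null(init)) init <- similarity_transform()
  # seed the model-frame -> data-frame similarity from the template's pose,
  # then settle the pose alone before releasing the shape coefficients
  tf <- .umeyama(M0, apply_transform(init, model$reference),
                 reflect = init$reflect)
  if (!freeze_similarity && pose_iters > 0)
    tf <- icp_similarity(M0, P, tf, iters = pose_iters,
                         trim_factor = trim_factor)
  S <- numeric(ncol(model$modes))
  X <- M0
  trace <- numeric(0)
  sdev <- sqrt(pmax(model$eigenvalues, 0))
  for (it in seq_len(iters)) {
    Xt <- apply_transform(tf, X)
    nn <- cpp_nn(P, Xt)
    d <- nn$distance
    med <- median(d)
    keep <- if (med > 0) d <= trim_factor * med else rep(TRUE, length(d))
    trace <- c(trace, mean(d[keep]^2))
    Y <- P[nn$index, , drop = FALSE]
    if (!freeze_similarity)
      tf <- .umeyama(X[keep, , drop = FALSE], Y[keep, , drop = FALSE],
                     reflect = tf$reflect)
    # solve for coefficients in the model frame
    Ym <- apply_transform(invert_transform(tf), Y)
    rows <- rep((which(keep) - 1) * 3, each = 3) + 1:3
    A <- model$modes[rows, , drop = FALSE]
    b <- as.numeric(t(Ym[keep, , drop = FALSE])) - model$mean_shape[rows]
    S <- qr.solve(A, b)
    if (is.finite(clamp_sd)) {
      lim <- clamp_sd * sdev
      pos <- sdev > 0
      S[pos] <- pmin(lim[pos], pmax(-lim[pos], S[pos]))
      S[!pos] <- 0
    }
    X <- ssm_shape(model, S)
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) break
  }
  fitted <- apply_transform(tf, X)
  mesh <- if (!is.null(model$faces)) trimesh(fitted, model$faces) else fitted
  list(mesh = mesh, coefficients = as.numeric(S), transform = tf,
       mean_pair_distance = trace, iterations = length(trace))
}
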