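# Similarity transforms: x -> scale * R * M * x + t, where M mirrors the
# first coordinate when reflect is TRUE and R is a proper rotation.

.mirror3 <- diag(c(-1, 1, 1))

#' Construct a similarity transform
#'
#' A similarity transform combines a proper rotation, an isotropic scale, a
#' translation and an optional reflection.  The reflection, when present, is
#' a fixed mirror applied before the rotation, so the linear part is
#' `scale * rotation %*% diag(c(-1, 1, 1))`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param scale positive isotropic scale factor.
#' @param translation length-3 translation (mm).
#' @param reflect logical; apply a mirror before the rotation.
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(rotation = diag(3), scale = 1,
                                 translation = c(0, 0, 0), reflect = FALSE) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3,
            is.finite(scale), scale > 0)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation must be proper (det +1); use reflect for mirroring")
  structure(list(rotation = rotation, scale = scale,
                 translation = as.numeric(translation),
                 reflect = isTRUE(reflect)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity transform> scale %.6g, reflect %s\n",
              x$scale, x$reflect))
  cat("  translation:", sprintf("%.4f", x$translation), "mm\n")
  invisible(x)
}

# linear part (3x3) including scale and reflection
.linear_part <- function(tf) {
  L <- tf$scale * tf$rotation
  if (tf$reflect) L <- L %*% .mirror3
  L
}

#' Apply a similarity transform to points
#'
#' @param tf a `similarity_transform`.
#' @param x an n x 3 matrix of points (mm), or a `trimesh`.
#' @return Transformed points (or mesh).
#' @export
apply_transform <- function(tf, x) {
  if (inherits(x, "trimesh")) {
    x$vertices <- apply_transform(tf, x$vertices)
    return(x)
  }
  x <- rbind(x)  # promote vectors
  sweep(x %*% t(.linear_part(tf)), 2, -tf$translation)
}

#' Compose two similarity transforms
#'
#' `compose_transform(b, a)` returns the transform equivalent to applying
#' `a` first and then `b`.
#'
#' @param b,a `similarity_transform` objects.
#' @export
compose_transform <- function(b, a) {
  La <- .linear_part(a); Lb <- .linear_part(b)
  L <- Lb %*% La
  s <- b$scale * a$scale
  reflect <- xor(a$reflect, b$reflect)
  R <- L / s
  if (reflect) R <- R %*% .mirror3
  similarity_transform(R, s, as.numeric(Lb %*% a$translation) + b$translation,
                       reflect)
}

#' Invert a similarity transform
#'
#' @param tf a `similarity_transform`.
#' @export
invert_transform <- function(tf) {
  L <- .linear_part(tf)
  Linv <- t(L) / tf$scale^2            # (sRM)^-1 = (1/s) M' R'
  R <- tf$scale * Linv
  if (tf$reflect) R <- R %*% .mirror3
  similarity_transform(R, 1 / tf$scale, as.numeric(-Linv %*% tf$translation),
                       tf$reflect)
}

# Closed-form least-squares similarity (Umeyama), optionally weighted.
# src, dst: n x 3.  When reflect is TRUE, src is mirrored before fitting a
# proper rotation.
.umeyama <- function(src, dst, reflect = FALSE, with_scale = TRUE,
                     weights = NULL) {
  n <- nrow(src)
  if (reflect) src <- src %*% .mirror3
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  mu_s <- colSums(src * w); mu_d <- colSums(dst * w)
  xs <- sweep(src, 2, mu_s); xd <- sweep(dst, 2, mu_d)
  sigma2 <- sum(w * rowSums(xs^2))
  H <- crossprod(xd * w, xs)           # 3x3, maps src-dev to dst-dev
  sv <- svd(H)
  S <- diag(3)
  if (det(sv$u) * det(sv$v) < 0) S[3, 3] <- -1
  R <- sv$u %*% S %*% t(sv$v)
  s <- if (with_scale) sum(diag(S) * sv$d) / sigma2 else 1
  t <- mu_d - s * as.numeric(R %*% mu_s)
  similarity_transform(R, s, t, reflect)
}

.rms_residual <- function(tf, src, dst) {
  sqrt(mean(rowSums((apply_transform(tf, src) - dst)^2)))
}

#' Landmark-based similarity alignment
#'
#' Computes the closed-form least-squares similarity transform (rotation,
#' isotropic scale, translation) mapping the source landmark triad onto the
#' destination triad.  With `reflect = "auto"` the mirrored solution is
#' adopted when it strictly lowers the residual.  Note that for exactly three
#' landmarks the mirrored configuration can always be matched by a proper
#' rotation as well, so reflection is genuinely ambiguous from a triad alone;
#' use `reflect = "force"` to encode the operator's left/right decision.
#'
#' @param src,dst landmark sets: either named lists with entries `apex`,
#'   `oval_window`, `canal_bifurcation`, or n x 3 matrices (n >= 3).
#' @param reflect one of "auto", "never", "force".
#' @return A `similarity_transform` with an `rms_residual` attribute (mm).
#' @export
landmark_similarity <- function(src, dst, reflect = c("auto", "never", "force")) {
  reflect <- match.arg(reflect)
  src <- as_landmark_matrix(src); dst <- as_landmark_matrix(dst)
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 3)
  for (m in list(src, dst))
    if (svd(sweep(m, 2, colMeans(m)))$d[2] < 1e-9 * max(1, max(abs(m))))
      stop("degenerate landmarks: points are collinear")
  fit <- function(refl) {
    tf <- .umeyama(src, dst, reflect = refl)
    attr(tf, "rms_residual") <- .rms_residual(tf, src, dst)
    tf
  }
  out <- switch(reflect,
    never = fit(FALSE),
    force = fit(TRUE),
    auto = {
      a <- fit(FALSE); b <- fit(TRUE)
      if (attr(b, "rms_residual") < attr(a, "rms_residual") - 1e-12) b else a
    })
  out
}

# Accept a named landmark list or a plain matrix.
as_landmark_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x)) {
    need <- c("apex", "oval_window", "canal_bifurcation")
    if (!all(need %in% names(x)))
      stop("landmark set must contain: ", paste(need, collapse = ", "))
    return(do.call(rbind, x[need]))
  }
  stop("cannot interpret landmarks")
}
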