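# Independent oracles used across the test suite.  These deliberately avoid
# the package's own code paths: lengths come from fine-step quadrature,
# nearest neighbours from brute force, rigid fits from a hand-rolled Kabsch.

# Dense quadrature arc length of a parametric curve function f(t) on [a, b].
quad_arc_length <- function(f, a, b, n = 2e4) {
  t <- seq(a, b, length.out = n)
  p <- f(t)
  sum(sqrt(rowSums(diff(p)^2)))
}

# Brute-force nearest distances from each row of q to the rows of p.
brute_nn_dist <- function(p, q) {
  apply(q, 1, function(x) sqrt(min(rowSums(sweep(p, 2, x)^2))))
}

# Rotation matrix about a (non-unit) axis.
rot3 <- function(axis, angle) {
  ax <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# Closed-form rigid Kabsch fit mapping src to dst (no scale); proper only.
kabsch_fit <- function(src, dst) {
  sc <- colMeans(src); dc <- colMeans(dst)
  H <- t(sweep(src, 2, sc)) %*% sweep(dst, 2, dc)
  sv <- svd(H)
  S <- diag(3)
  if (det(sv$u) * det(sv$v) < 0) S[3, 3] <- -1
  R <- sv$v %*% S %*% t(sv$u)
  list(R = R, t = dc - as.numeric(R %*% sc))
}

# Analytic planar log spiral sampled as an n x 3 polyline.
log_spiral <- function(A = 5, b = 0.1, theta_max = 3 * pi, n = 2001, z = NULL) {
  th <- seq(0, theta_max, length.out = n)
  zz <- if (is.null(z)) rep(0, n) else z(th)
  cbind(A * exp(-b * th) * cos(th), A * exp(-b * th) * sin(th), zz)
}

# Brute-force evaluation of the basal-window measurements on a dense curve:
# cumulative turning by summed tangent angles, TLS plane by eigen of the
# covariance, mean |distance| and max distance from the start.
brute_measures <- function(pts, window_deg = 270) {
  seg <- diff(pts)
  t <- seg / sqrt(rowSums(seg^2))
  ang <- acos(pmin(1, pmax(-1, rowSums(t[-nrow(t), ] * t[-1, ])))) * 180 / pi
  cum <- c(0, 0, cumsum(ang))
  k <- max(which(cum <= window_deg))
  w <- pts[1:k, , drop = FALSE]
  ctr <- colMeans(w)
  ev <- eigen(cov(w))
  nrm <- ev$vectors[, 3]
  h <- as.numeric(sweep(w, 2, ctr) %*% nrm)
  list(non_planarity = mean(abs(h)),
       reach = max(sqrt(rowSums(sweep(w, 2, pts[1, ])^2))),
       duct_length = sum(sqrt(rowSums(seg^2))),
       window_end = k)
}
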