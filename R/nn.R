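# Minimal dense feed-forward engine for the per-element correction
# networks.  Everything here is exact: reverse-mode for parameter and
# input gradients, forward-over-reverse duals for mixed input/parameter
# second derivatives (force-loss training), and a layerwise recursion for
# the exact input Hessian (analytical network Hessians).

# GELU x * Phi(x) and its first two derivatives
gelu <- function(x) x * stats::pnorm(x)
gelu_d1 <- function(x) stats::pnorm(x) + x * stats::dnorm(x)
gelu_d2 <- function(x) stats::dnorm(x) * (2 - x * x)

#' Initialise a per-element feed-forward network
#'
#' Hidden layers use the GELU activation; the output layer is linear
#' with a single unit (the atomic energy contribution in Hartree).
#'
#' @param n_input input (descriptor) dimension
#' @param hidden integer vector of hidden-layer widths
#' @return list of layers, each `list(W, b)`.
#' @keywords internal
init_mlp <- function(n_input, hidden) {
  sizes <- c(n_input, hidden, 1L)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    n_in <- sizes[l]; n_out <- sizes[l + 1L]
    sd <- sqrt(1 / n_in)
    layers[[l]] <- list(W = matrix(stats::rnorm(n_out * n_in, 0, sd), n_out, n_in),
                        b = numeric(n_out))
  }
  # zero output layer: the untrained correction predicts exactly the
  # self-energy baseline, the natural origin for a delta model
  L <- length(layers)
  layers[[L]]$W[] <- 0
  layers
}

# Batched forward + reverse pass.
#   X    : n x D input matrix (one row per atom)
#   ybar : length-n reverse seed (row i's contribution weight)
#   Xdot : optional n x D dual (directional derivative of the input),
#          propagated forward over the whole forward+reverse computation
# Returns y, ydot, dX (row i = ybar_i * dy_i/dx_i), param grads
# (sum_i ybar_i dy_i/dtheta) and, when Xdot is given, the dual of those
# param grads (the mixed second derivative contracted with Xdot).
mlp_backprop <- function(layers, X, ybar = NULL, Xdot = NULL,
                         want_param_grads = TRUE) {
  L <- length(layers)
  n <- nrow(X)
  dual <- !is.null(Xdot)
  A <- vector("list", L + 1L); Ad <- vector("list", L + 1L)
  Z <- vector("list", L); Zd <- vector("list", L)
  S1 <- vector("list", L)   # cached GELU first derivative per layer
  S2 <- vector("list", L)   # cached second derivative (dual passes)
  A[[1L]] <- X
  if (dual) Ad[[1L]] <- Xdot
  for (l in seq_len(L)) {
    W <- layers[[l]]$W; b <- layers[[l]]$b
    Z[[l]] <- tcrossprod(A[[l]], W) + matrix(b, n, length(b), byrow = TRUE)
    if (dual) Zd[[l]] <- tcrossprod(Ad[[l]], W)
    if (l < L) {
      z <- Z[[l]]
      Phi <- stats::pnorm(z); phi <- stats::dnorm(z)
      A[[l + 1L]] <- z * Phi
      S1[[l]] <- Phi + z * phi
      if (dual) {
        S2[[l]] <- phi * (2 - z * z)
        Ad[[l + 1L]] <- S1[[l]] * Zd[[l]]
      }
    }
  }
  y <- as.vector(Z[[L]])
  ydot <- if (dual) as.vector(Zd[[L]]) else NULL
  if (is.null(ybar)) ybar <- rep(1, n)
  grads <- if (want_param_grads) vector("list", L)
  dgrads <- if (want_param_grads && dual) vector("list", L)
  # reverse pass: dZ holds ybar_i-scaled dy_i/dz, dZd its dual
  dZ <- matrix(ybar, n, 1L)
  dZd <- if (dual) matrix(0, n, 1L)
  for (l in rev(seq_len(L))) {
    if (want_param_grads) {
      grads[[l]] <- list(W = crossprod(dZ, A[[l]]), b = colSums(dZ))
      if (dual)
        dgrads[[l]] <- list(W = crossprod(dZd, A[[l]]) + crossprod(dZ, Ad[[l]]),
                            b = colSums(dZd))
    }
    dA <- dZ %*% layers[[l]]$W
    if (dual) dAd <- dZd %*% layers[[l]]$W
    if (l > 1L) {
      dZ <- S1[[l - 1L]] * dA
      if (dual) dZd <- S2[[l - 1L]] * Zd[[l - 1L]] * dA + S1[[l - 1L]] * dAd
    } else {
      dX <- dA
      dXd <- if (dual) dAd
    }
  }
  list(y = y, ydot = ydot, dX = dX, grads = grads,
       dgrads = if (dual) dgrads)
}

# network value for a batch of inputs
mlp_value <- function(layers, X) {
  L <- length(layers)
  A <- X
  for (l in seq_len(L)) {
    n <- nrow(A)
    Z <- tcrossprod(A, layers[[l]]$W) +
      matrix(layers[[l]]$b, n, length(layers[[l]]$b), byrow = TRUE)
    A <- if (l < L) gelu(Z) else Z
  }
  as.vector(A)
}

# Exact Hessian of the scalar network output with respect to a single
# input vector g (length D), by layerwise propagation of Jacobians and
# second-derivative stacks.
mlp_input_hessian <- function(layers, g) {
  D <- length(g)
  L <- length(layers)
  a <- g
  J <- diag(D)                       # n_units x D
  Hmat <- matrix(0, D, D * D)        # n_units x (D*D), row i = vec(H_i)
  for (l in seq_len(L)) {
    W <- layers[[l]]$W; b <- layers[[l]]$b
    z <- as.vector(W %*% a + b)
    Jz <- W %*% J
    Hz <- W %*% Hmat
    if (l < L) {
      s1 <- gelu_d1(z); s2 <- gelu_d2(z)
      a <- gelu(z)
      J <- s1 * Jz
      Hmat <- matrix(0, length(z), D * D)
      for (i in seq_along(z)) {
        Hmat[i, ] <- s2[i] * as.vector(outer(Jz[i, ], Jz[i, ])) + s1[i] * Hz[i, ]
      }
    } else {
      J <- Jz
      Hmat <- Hz
    }
  }
  list(grad = as.vector(J), hess = matrix(Hmat[1L, ], D, D))
}

# flatten / restore parameters (used by the freeze contract and tests)
mlp_flatten <- function(layers) {
  unlist(lapply(layers, function(l) c(as.vector(l$W), l$b)))
}
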