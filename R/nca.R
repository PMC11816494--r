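#' Neighborhood component analysis feature weights
#'
#' Fits per-feature relevance weights by maximizing the NCA leave-one-out
#' soft-neighbor objective with a diagonal metric: the weighted squared
#' Euclidean distance `D_ij = sum_f w_f^2 (x_if - x_jf)^2` defines soft
#' neighbor probabilities `p_ij = exp(-D_ij) / sum_k exp(-D_ik)`, and the
#' objective `sum_i sum_{j in class(i)} p_ij - lambda * sum_f w_f^2` is
#' maximized by projected gradient ascent with an adaptive step. Distances are
#' rescaled internally so the mean pairwise distance at the uniform start is
#' 1, making the soft-neighbor kernel scale-free; the optimization itself is
#' deterministic (no random initialization).
#'
#' @param x Numeric matrix, observations x features.
#' @param y Class labels (>= 2 distinct values among the observations).
#' @param lambda Ridge penalty on the weights; drives uninformative features
#'   toward zero. Default `1`.
#' @param max_iter Maximum gradient iterations (default 100).
#' @param tol Convergence tolerance on the objective change (default 1e-6).
#' @param standardize Standardize columns to unit variance first (default
#'   `FALSE`; the reference pipeline feeds raw histogram counts).
#' @return An object of class `nca_weights`: list with `w` (nonnegative
#'   weights), `idx` (feature indices by descending weight, ties broken by
#'   ascending index), `objective` (trace), `converged`.
#' @export
nca_weights <- function(x, y, lambda = 1, max_iter = 100, tol = 1e-6,
                        standardize = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) {
    abort("NCA requires >= 2 classes.", class = "cubicpat_config_error")
  }
  no <- nrow(x)
  d <- ncol(x)
  if (length(y) != no) {
    abort("length(y) must equal nrow(x).", class = "cubicpat_shape_error")
  }
  if (standardize) {
    s <- apply(x, 2L, stats::sd)
    s[s == 0] <- 1
    x <- sweep(x, 2L, s, "/")
  }
  same <- outer(y, y, "==")
  diag(same) <- FALSE

  sq_dist <- function(z) {
    a <- rowSums(z * z)
    dd <- outer(a, a, "+") - 2 * tcrossprod(z)
    dd[dd < 0] <- 0
    dd
  }
  # scale-free kernel: mean pairwise distance at w = 1 becomes 1
  d0 <- sq_dist(x)
  m0 <- mean(d0[upper.tri(d0)])
  if (m0 <= 0) m0 <- 1
  x <- x / sqrt(m0)
  x2 <- x * x

  objective_grad <- function(w) {
    z <- sweep(x, 2L, w, "*")
    dd <- sq_dist(z)
    k <- exp(-(dd - apply(dd + diag(Inf, no), 1L, min)))
    diag(k) <- 0
    rs <- rowSums(k)
    rs[rs == 0] <- .Machine$double.eps
    p <- k / rs
    pi_i <- rowSums(p * same)
    obj <- sum(pi_i) - lambda * sum(w * w)
    # grad_f = 2 w_f * sum_ij c_ij (x_if - x_jf)^2, c = p_i * p - p * same
    cmat <- pi_i * p - p * same
    r <- rowSums(cmat)
    s <- colSums(cmat)
    cross <- colSums(x * (cmat %*% x)) + colSums(x * (t(cmat) %*% x))
    gsum <- drop(crossprod(x2, r)) + drop(crossprod(x2, s)) - cross
    grad <- 2 * w * gsum - 2 * lambda * w
    list(obj = obj, grad = grad)
  }

  w <- rep(1, d)
  eta <- 0.1
  og <- objective_grad(w)
  trace <- og$obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w_new <- pmax(w + eta * og$grad, 0)
    og_new <- objective_grad(w_new)
    if (og_new$obj >= og$obj) {
      improved <- og_new$obj - og$obj
      w <- w_new
      og <- og_new
      eta <- eta * 1.1
      trace <- c(trace, og$obj)
      if (improved < tol) {
        converged <- TRUE
        break
      }
    } else {
      eta <- eta / 2
      if (eta < 1e-12) {
        converged <- TRUE
        break
      }
    }
  }
  w <- pmax(w, 0)
  structure(list(w = w, idx = order(-w, method = "radix"),
                 objective = trace, converged = converged),
            class = "nca_weights")
}

#' @export
print.nca_weights <- function(x, ...) {
  cat(sprintf("<nca_weights> %d features, top index %d (w = %.4g), %s\n",
              length(x$w), x$idx[1L], x$w[x$idx[1L]],
              if (x$converged) "converged" else "max iterations reached"))
  invisible(x)
}

#' @describeIn nca_weights tidy method: one row per feature with its weight
#'   and rank.
#' @param x,... Method arguments.
#' @method tidy nca_weights
#' @export
tidy.nca_weights <- function(x, ...) {
  tibble(feature = seq_along(x$w), weight = x$w,
         rank = match(seq_along(x$w), x$idx))
}
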