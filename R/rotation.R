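#' Rotation-module state
#'
#' An orthogonal matrix `Q` whose first `n_classes` columns are aligned,
#' during training, with the class-conditional mean activations of the
#' whitened latent space; the remaining `d - n_classes` axes are free.
#' Class `i` (in the factor-level order of the labels) maps to column `i`.
#'
#' @param d latent dimension (number of channels).
#' @param n_classes number of classes `Nc <= d`.
#' @param step_size Cayley ascent step.
#' @return object of class `rotation_state`.
#' @export
rotation_state <- function(d, n_classes, step_size = 0.05) {
  stopifnot(n_classes <= d, step_size > 0)
  structure(list(d = as.integer(d), n_classes = as.integer(n_classes),
                 Q = diag(d), step_size = step_size, num_updates = 0L),
            class = "rotation_state")
}

#' Class-alignment objective of a rotation
#'
#' Sum over classes of the mean activation of that class's samples
#' projected on the class axis:
#' `sum_i (1/m_i) q_i' XW_ci 1_{m_i}`, where `q_i` is the `i`th column of
#' `Q` and `XW_ci` the whitened activations of class `i`.
#'
#' @param XW `d x m` whitened activation matrix.
#' @param labels class labels of the `m` columns (factor or integer).
#' @param Q orthogonal `d x d` matrix.
#' @return scalar objective value.
#' @export
rotation_objective <- function(XW, labels, Q) {
  M <- class_means(XW, labels)
  sum(Q[, seq_len(ncol(M)), drop = FALSE] * M)
}

# per-class column means of XW; columns ordered by factor level
class_means <- function(XW, labels) {
  labels <- as.factor(labels)
  lev <- levels(labels)
  counts <- tabulate(labels, length(lev))
  if (any(counts == 0))
    stop("every class must have at least one sample for the rotation objective")
  M <- vapply(seq_along(lev),
              function(i) rowMeans(XW[, labels == lev[i], drop = FALSE]),
              numeric(nrow(XW)))
  M
}

#' One Cayley ascent step of the rotation matrix
#'
#' Performs one step of gradient ascent on the class-alignment objective
#' restricted to the orthogonal group. The Euclidean gradient `G` has the
#' class-conditional mean activations in its first `Nc` columns and zeros
#' elsewhere; the skew-symmetric relative gradient `A = Q G' - G Q'` feeds
#' the Cayley retraction
#' `Q <- (I + eta/2 A)^{-1} (I - eta/2 A) Q`,
#' which preserves orthogonality to machine precision. (With this sign of
#' `A` the retraction moves `Q` along `+G`, i.e. uphill on the objective.)
#' If accumulated roundoff drifts `Q' Q` away from the identity by more
#' than `1e-6`, `Q` is re-orthogonalized via its polar factor.
#'
#' @param XW `d x m` whitened activation matrix of the current batch.
#' @param labels class labels of the `m` columns.
#' @param state a [rotation_state()].
#' @param step_size optional override of `state$step_size`.
#' @return the updated `rotation_state`.
#' @export
update_rotation <- function(XW, labels, state, step_size = NULL) {
  stopifnot(inherits(state, "rotation_state"))
  eta <- if (is.null(step_size)) state$step_size else step_size
  d <- state$d
  labels <- as.factor(labels)
  G <- matrix(0, d, d)
  for (i in seq_along(levels(labels))) {
    sel <- labels == levels(labels)[i]
    # classes absent from this batch contribute nothing to the gradient
    if (any(sel)) G[, i] <- rowMeans(XW[, sel, drop = FALSE])
  }
  Q <- state$Q
  A <- Q %*% t(G) - G %*% t(Q)   # skew-symmetric; -A is the descent generator
  lhs <- diag(d) + (eta / 2) * A
  rhs <- diag(d) - (eta / 2) * A
  Qnew <- tryCatch(solve(lhs, rhs %*% Q),
                   error = function(e)
                     stop("singular Cayley factor; reduce the rotation step size"))
  drift <- max(abs(crossprod(Qnew) - diag(d)))
  if (drift > 1e-6) {
    sv <- svd(Qnew)
    Qnew <- sv$u %*% t(sv$v)
  }
  state$Q <- Qnew
  state$num_updates <- state$num_updates + 1L
  state
}

#' Fit a rotation by Cayley ascent from both orthogonal components
#'
#' The Cayley retraction keeps `det(Q)` fixed, so ascent started from the
#' identity explores rotations only. Because any orthogonal matrix is an
#' admissible alignment (reflections included), this driver runs the
#' ascent from the identity and from a reflected start and returns the
#' state with the larger objective.
#'
#' @param XW `d x m` whitened activation matrix.
#' @param labels class labels of the `m` columns.
#' @param n_classes number of classes.
#' @param steps number of ascent iterations per component.
#' @param step_size Cayley step.
#' @return the fitted [rotation_state()].
#' @export
fit_rotation <- function(XW, labels, n_classes, steps = 500L,
                         step_size = 0.1) {
  d <- nrow(XW)
  run <- function(Q0) {
    st <- rotation_state(d, n_classes, step_size)
    st$Q <- Q0
    for (i in seq_len(steps)) st <- update_rotation(XW, labels, st)
    st
  }
  refl <- diag(d); refl[1, 1] <- -1
  cand <- list(run(diag(d)), run(refl))
  objs <- vapply(cand, function(st) rotation_objective(XW, labels, st$Q),
                 numeric(1))
  cand[[which.max(objs)]]
}

#' Apply a rotation to whitened activations
#'
#' Returns `Q' XW`. Because `Q` is orthogonal the covariance transforms as
#' `Q' cov(XW) Q`, so whitened inputs stay whitened.
#'
#' @param XW `d x m` whitened activation matrix.
#' @param Q orthogonal `d x d` matrix.
#' @return `d x m` matrix of rotated activations.
#' @export
apply_rotation <- function(XW, Q) crossprod(Q, XW)
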