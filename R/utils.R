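# shared numeric helpers

# row-wise softmax with max-shift for stability
softmax_rows <- function(Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# uniform Glorot/Xavier initialization
xavier_mat <- function(n_in, n_out) {
  bound <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out)
}

# recursive SGD-with-momentum update over nested lists of numeric arrays;
# returns list(params, velocity)
sgd_update <- function(params, grads, vel, lr, momentum) {
  if (is.list(params)) {
    if (is.null(vel))
      vel <- stats::setNames(vector("list", length(params)), names(params))
    keys <- if (is.null(names(params))) seq_along(params) else names(params)
    for (nm in keys) {
      if (is.null(grads[[nm]])) next
      upd <- sgd_update(params[[nm]], grads[[nm]], vel[[nm]], lr, momentum)
      params[[nm]] <- upd$params
      vel[[nm]] <- upd$vel
    }
    list(params = params, vel = vel)
  } else if (is.numeric(params)) {
    if (is.null(vel)) vel <- params * 0
    vel <- momentum * vel + grads
    list(params = params - lr * vel, vel = vel)
  } else list(params = params, vel = vel)
}

# global L2 norm over a nested list of numeric arrays
grad_global_norm <- function(g) {
  acc <- function(x) if (is.list(x)) sum(vapply(x, acc, numeric(1)))
    else if (is.numeric(x)) sum(x^2) else 0
  sqrt(acc(g))
}

# rescale a nested gradient list so its global norm is <= clip
clip_gradients <- function(g, clip) {
  nrm <- grad_global_norm(g)
  if (!is.finite(nrm) || nrm <= clip) return(g)
  scale_rec <- function(x, s) if (is.list(x)) lapply(x, scale_rec, s)
    else if (is.numeric(x)) x * s else x
  scale_rec(g, clip / nrm)
}

#' Cosine learning-rate schedule
#'
#' `lr(step) = lr_init * 0.5 * (1 + cos(pi * step / total_steps))` for
#' `step = 0, ..., total_steps - 1`: starts at `lr_init` and decays to
#' (near) zero by the final step.
#'
#' @param step 0-based step index.
#' @param total_steps Total number of optimization steps.
#' @param lr_init Initial learning rate.
#' @return The learning rate for `step`.
#' @export
cosine_lr <- function(step, total_steps, lr_init) {
  lr_init * 0.5 * (1 + cos(pi * step / total_steps))
}
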