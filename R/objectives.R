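#' Cell-similarity matrix of a minibatch
#'
#' Gaussian kernel on cell embeddings: `s_ij = exp(-||c_i - c_j||^2)`
#' (squared Euclidean by default, plain Euclidean via
#' `similarity = "euclid"`). Symmetric with unit diagonal; entries in
#' (0, 1].
#'
#' @param embeddings N x h matrix of cell embeddings.
#' @param similarity `"sq_euclid"` (default) or `"euclid"`.
#' @return N x N similarity matrix.
#' @export
similarity_matrix <- function(embeddings, similarity = c("sq_euclid", "euclid")) {
  similarity <- match.arg(similarity)
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, ncol = 1)
  if (any(!is.finite(embeddings))) stop("non-finite embeddings")
  sq <- rowSums(embeddings^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(embeddings)
  D2[D2 < 0] <- 0
  S <- if (similarity == "sq_euclid") exp(-D2) else exp(-sqrt(D2))
  diag(S) <- 1
  (S + t(S)) / 2
}

#' Divergence-based clustering loss
#'
#' Penalizes similarity-weighted correlation between the per-class logit
#' vectors of a minibatch, pushing the soft assignments of different
#' classes apart:
#' `L1 = (1/k) * sum_{a<b} (Ya S Yb') / sqrt((Ya S Ya')(Yb S Yb'))`
#' where `Ya` is the length-N vector of class-a logits. With the default
#' square-root normalization each pairwise term is a cosine-like ratio
#' (identical assignments give 1, orthogonal give 0); `raw_denominator`
#' implements the unnormalized product form.
#'
#' @param logits N x k logits matrix.
#' @param S N x N similarity matrix ([similarity_matrix()]).
#' @param raw_denominator Use the literal product denominator instead of
#'   its square root.
#' @param eps Guard added to degenerate (near-zero) denominators.
#' @param grad Return gradients as well.
#' @return The scalar loss, or (with `grad = TRUE`) a list
#'   `list(value, d_logits, d_S)`.
#' @export
clustering_divergence_loss <- function(logits, S, raw_denominator = FALSE,
                                       eps = 1e-12, grad = FALSE) {
  logits <- as.matrix(logits)
  k <- ncol(logits)
  if (k < 2) stop("need k >= 2 classes")
  SY <- S %*% logits                       # column a = S %*% Y_a
  G <- crossprod(logits, SY)               # G[a,b] = Ya' S Yb
  nrm <- diag(G)
  if (any(nrm < eps)) {
    warning("near-zero class assignment norm; adding epsilon guard")
    nrm <- nrm + eps
  }
  val <- 0
  dY <- matrix(0, nrow(logits), k)
  dS <- if (grad) matrix(0, nrow(S), ncol(S)) else NULL
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      denom <- if (raw_denominator) nrm[a] * nrm[b] else sqrt(nrm[a] * nrm[b])
      r <- G[a, b] / denom
      val <- val + r
      if (grad) {
        if (raw_denominator) {
          dY[, a] <- dY[, a] + SY[, b] / denom - 2 * r * SY[, a] / nrm[a]
          dY[, b] <- dY[, b] + SY[, a] / denom - 2 * r * SY[, b] / nrm[b]
          dS <- dS + tcrossprod(logits[, a], logits[, b]) / denom -
            r * (tcrossprod(logits[, a]) / nrm[a] +
                   tcrossprod(logits[, b]) / nrm[b])
        } else {
          dY[, a] <- dY[, a] + SY[, b] / denom - r * SY[, a] / nrm[a]
          dY[, b] <- dY[, b] + SY[, a] / denom - r * SY[, b] / nrm[b]
          dS <- dS + tcrossprod(logits[, a], logits[, b]) / denom -
            (r / 2) * (tcrossprod(logits[, a]) / nrm[a] +
                         tcrossprod(logits[, b]) / nrm[b])
        }
      }
    }
  }
  val <- val / k
  if (!grad) return(val)
  list(value = val, d_logits = dY / k, d_S = dS / k)
}

# gradient of the similarity matrix w.r.t. embeddings, given dL/dS.
# s_ij = exp(-||ci - cj||^2): d s_ij / d ci = -2 s_ij (ci - cj).
similarity_backward <- function(embeddings, S, dS) {
  W <- (dS + t(dS)) * S
  diag(W) <- 0
  # d_emb_i = -2 * sum_j W_ij (c_i - c_j)
  rs <- rowSums(W)
  -2 * (rs * embeddings - W %*% embeddings)
}

#' Cross-entropy loss
#'
#' `L2 = -(1/N) sum_i g_i' log softmax(y_i)` for one-hot labels g.
#'
#' @param logits N x k logits.
#' @param onehot N x k one-hot label matrix, or an integer/character label
#'   vector (converted using column order / `classes`).
#' @param classes Class labels used to convert a label vector.
#' @param grad Return the gradient w.r.t. logits as well.
#' @return Scalar loss or `list(value, d_logits)`.
#' @export
cross_entropy_loss <- function(logits, onehot, classes = NULL, grad = FALSE) {
  logits <- as.matrix(logits)
  N <- nrow(logits); k <- ncol(logits)
  if (is.null(dim(onehot))) {
    lab <- onehot
    if (is.character(lab) || is.factor(lab)) {
      if (is.null(classes)) stop("classes required for label vectors")
      lab <- match(as.character(lab), classes)
    }
    if (any(is.na(lab)) || any(lab < 1) || any(lab > k))
      stop("label index outside 1..k")
    onehot <- matrix(0, N, k)
    onehot[cbind(seq_len(N), lab)] <- 1
  }
  if (any(abs(rowSums(onehot) - 1) > 1e-8))
    stop("onehot rows must sum to 1")
  P <- softmax_rows(logits)
  val <- -sum(onehot * log(pmax(P, 1e-300))) / N
  if (!grad) return(val)
  list(value = val, d_logits = (P - onehot) / N)
}

#' Temperature-scaled distillation loss
#'
#' `L3 = (1/N) sum_i KL(softmax(y_teacher/T) || softmax(y_student/T))`;
#' the Teacher's tempered distribution is the (constant) target, so the
#' gradient flows only to the Student. Zero iff the tempered distributions
#' match.
#'
#' @param student_logits,teacher_logits N x k matrices.
#' @param T Temperature (> 0); default 3.
#' @param grad Return the gradient w.r.t. student logits.
#' @return Scalar loss or `list(value, d_logits)`.
#' @export
distillation_loss <- function(student_logits, teacher_logits, T = 3,
                              grad = FALSE) {
  if (!is.numeric(T) || T <= 0) stop("temperature T must be > 0")
  Ps <- softmax_rows(as.matrix(student_logits) / T)
  Pt <- softmax_rows(as.matrix(teacher_logits) / T)
  N <- nrow(Ps)
  val <- sum(Pt * (log(pmax(Pt, 1e-300)) - log(pmax(Ps, 1e-300)))) / N
  if (!grad) return(val)
  list(value = val, d_logits = (Ps - Pt) / (N * T))
}

#' Self-entropy loss
#'
#' Computed on the minibatch-mean Student logits `y_mean`:
#' `L4 = -(1/k) sum_a y_mean[a] * log softmax(y_mean)[a]` (softmax over
#' the k-vector). Counteracts the over-smoothing induced by soft-label
#' training. Two further readings are provided: `"mean_entropy"`, the
#' Shannon entropy of `softmax(y_mean)`, and `"sample_entropy"`, the mean
#' per-cell Shannon entropy of `softmax(y_i)` (bounded in `[0, ln k]`;
#' minimizing it sharpens each cell's prediction, which is the reading
#' used by the default trainer).
#'
#' @param student_logits N x k logits.
#' @param mode `"literal"` (default), `"mean_entropy"` or
#'   `"sample_entropy"`.
#' @param grad Return the gradient w.r.t. the logits.
#' @return Scalar loss or `list(value, d_logits)`.
#' @export
self_entropy_loss <- function(student_logits,
                              mode = c("literal", "mean_entropy",
                                       "sample_entropy"),
                              grad = FALSE) {
  mode <- match.arg(mode)
  Y <- as.matrix(student_logits)
  N <- nrow(Y); k <- ncol(Y)
  if (mode == "sample_entropy") {
    P <- softmax_rows(Y)
    LP <- log(pmax(P, 1e-300))
    H <- -rowSums(P * LP)
    val <- mean(H)
    if (!grad) return(val)
    # dH_i/dz_b = -p_b (log p_b + H_i)
    return(list(value = val, d_logits = -P * (LP + H) / N))
  }
  ym <- colMeans(Y)
  p <- drop(softmax_rows(ym))
  lp <- log(pmax(p, 1e-300))
  if (mode == "literal") {
    val <- -sum(ym * lp) / k
    if (!grad) return(val)
    # d/d ym[b]: -(1/k) [ lp[b] + ym[b] - p[b] * sum(ym) ]
    dym <- -(lp + ym - p * sum(ym)) / k
  } else {
    val <- -sum(p * lp)
    if (!grad) return(val)
    dym <- -p * (lp - sum(p * lp))
  }
  list(value = val, d_logits = matrix(dym, N, k, byrow = TRUE) / N)
}
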