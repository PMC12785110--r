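#' Initialize Teacher parameters
#'
#' The Teacher is: Navigator (m masked linear projections into h-wide
#' pattern tokens), a learnable cls token, one self-attention layer with
#' two heads (shared h x h query/key/value maps followed by per-head
#' h -> h/2 projections and an output mix), and a linear classifier from
#' the post-attention cls embedding to k class logits.
#'
#' @param n_genes Gene-space size n.
#' @param classes Character vector of class labels (length k).
#' @param mask Optional [build_knowledge_mask()] result; fixes m to the
#'   number of pathways.
#' @param m Number of patterns when no mask is given (default 64).
#' @param h Token width (default 48; must be divisible by `n_heads`).
#' @param n_heads Number of attention heads (default 2).
#' @param mask_mode Passed to [navigator_init()].
#' @param classifier_hidden Optional hidden width for a 2-layer classifier;
#'   `NULL` (default) uses a single linear layer.
#' @return A `TeacherParams` list.
#' @export
teacher_init <- function(n_genes, classes, mask = NULL, m = NULL, h = 48,
                         n_heads = 2, mask_mode = "persistent",
                         classifier_hidden = NULL) {
  classes <- as.character(classes)
  k <- length(classes)
  if (k < 2) stop("need at least 2 classes")
  if (h %% n_heads != 0) stop("h must be divisible by n_heads")
  d <- h %/% n_heads
  nav <- navigator_init(n_genes, m = m, h = h, mask = mask,
                        mask_mode = mask_mode)
  heads <- lapply(seq_len(n_heads), function(i)
    list(Wq = xavier_mat(d, h), Wk = xavier_mat(d, h), Wv = xavier_mat(d, h)))
  attn <- list(Wq = xavier_mat(h, h), Wk = xavier_mat(h, h),
               Wv = xavier_mat(h, h), heads = heads, Wo = xavier_mat(h, h))
  cls <- stats::runif(h, -sqrt(6 / h), sqrt(6 / h))
  classifier <- if (is.null(classifier_hidden)) {
    list(W = xavier_mat(h, k), b = numeric(k))
  } else {
    list(W1 = xavier_mat(h, classifier_hidden), b1 = numeric(classifier_hidden),
         W = xavier_mat(classifier_hidden, k), b = numeric(k))
  }
  structure(list(navigator = nav, cls = cls, attn = attn,
                 classifier = classifier, classes = classes, k = k,
                 h = as.integer(h), m = nav$m, n_heads = as.integer(n_heads),
                 d_head = as.integer(d)),
            class = "TeacherParams")
}

#' @export
print.TeacherParams <- function(x, ...) {
  cat("TeacherParams:", x$navigator$n_genes, "genes ->", x$m,
      "patterns (h =", x$h, "),", x$n_heads, "attention heads,", x$k,
      "classes;", format(teacher_n_params(x), big.mark = ","),
      "parameters\n")
  invisible(x)
}

#' Count trainable parameters of a Teacher or Student
#' @param params `TeacherParams` or `StudentParams`.
#' @return Integer parameter count.
#' @export
teacher_n_params <- function(params) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1)))
    else if (is.numeric(x)) length(x) else 0
  if (inherits(params, "TeacherParams"))
    cnt(params$navigator$W) + length(params$cls) + cnt(params$attn) +
      cnt(params$classifier)
  else cnt(params$layers)
}

# Batched Teacher forward. X: cells x genes matrix. Returns list with
# logits (N x k), embedding (N x h), tokens (N x m x h, pre-attention),
# updated_tokens (N x m x h) and, when keep = TRUE, the cache needed for
# the backward pass.
teacher_forward_batch <- function(params, X, keep = FALSE) {
  stopifnot(inherits(params, "TeacherParams"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  nav <- params$navigator
  N <- nrow(X); m <- params$m; h <- params$h
  mp1 <- m + 1L
  tokens <- navigator_forward(X, nav)
  A <- array(0, dim = c(N, mp1, h))
  A[, seq_len(m), ] <- tokens
  A[, mp1, ] <- matrix(params$cls, N, h, byrow = TRUE)
  Iflat <- matrix(aperm(A, c(2, 1, 3)), nrow = mp1 * N)

  at <- params$attn
  Qs <- Iflat %*% at$Wq
  Ks <- Iflat %*% at$Wk
  Vs <- Iflat %*% at$Wv
  d <- params$d_head
  scl <- 1 / sqrt(d)
  nh <- params$n_heads
  Qh <- Kh <- Vh <- Hh <- vector("list", nh)
  Attw <- vector("list", nh)
  for (i in seq_len(nh)) {
    hd <- at$heads[[i]]
    Qh[[i]] <- Qs %*% t(hd$Wq)
    Kh[[i]] <- Ks %*% t(hd$Wk)
    Vh[[i]] <- Vs %*% t(hd$Wv)
    Hh[[i]] <- matrix(0, mp1 * N, d)
    Attw[[i]] <- array(0, dim = c(N, mp1, mp1))
  }
  for (cidx in seq_len(N)) {
    rows <- ((cidx - 1L) * mp1 + 1L):(cidx * mp1)
    for (i in seq_len(nh)) {
      S <- (Qh[[i]][rows, , drop = FALSE] %*%
              t(Kh[[i]][rows, , drop = FALSE])) * scl
      W <- softmax_rows(S)
      Attw[[i]][cidx, , ] <- W
      Hh[[i]][rows, ] <- W %*% Vh[[i]][rows, , drop = FALSE]
    }
  }
  Hflat <- do.call(cbind, Hh)
  Oflat <- Hflat %*% at$Wo
  cls_rows <- seq_len(N) * mp1
  emb <- Oflat[cls_rows, , drop = FALSE]
  Oarr <- aperm(array(Oflat, c(mp1, N, h)), c(2, 1, 3))
  logits <- classifier_forward(params$classifier, emb)

  out <- list(logits = logits$logits, embedding = emb, tokens = tokens,
              updated_tokens = Oarr[, seq_len(m), , drop = FALSE])
  if (keep)
    out$cache <- list(X = X, Iflat = Iflat, Qs = Qs, Ks = Ks, Vs = Vs,
                      Qh = Qh, Kh = Kh, Vh = Vh, Attw = Attw,
                      Hflat = Hflat, emb = emb, cls_hidden = logits$hidden,
                      N = N, mp1 = mp1)
  out
}

classifier_forward <- function(cl, emb) {
  if (!is.null(cl$W1)) {
    z <- sweep(emb %*% cl$W1, 2, cl$b1, "+")
    a <- pmax(z, 0)
    list(logits = sweep(a %*% cl$W, 2, cl$b, "+"), hidden = list(z = z, a = a))
  } else {
    list(logits = sweep(emb %*% cl$W, 2, cl$b, "+"), hidden = NULL)
  }
}

# Backward pass. d_logits: N x k; d_emb_extra: N x h gradient reaching the
# embedding directly (e.g. through the similarity matrix of the clustering
# loss); either may be NULL. Returns gradients in the shape of params.
teacher_backward_batch <- function(params, cache, d_logits = NULL,
                                   d_emb_extra = NULL) {
  N <- cache$N; mp1 <- cache$mp1
  m <- params$m; h <- params$h; d <- params$d_head
  nh <- params$n_heads
  at <- params$attn
  cl <- params$classifier
  if (is.null(d_logits)) d_logits <- matrix(0, N, params$k)

  # classifier
  if (!is.null(cl$W1)) {
    gW <- crossprod(cache$cls_hidden$a, d_logits)
    gb <- colSums(d_logits)
    da <- d_logits %*% t(cl$W)
    dz <- da * (cache$cls_hidden$z > 0)
    gW1 <- crossprod(cache$emb, dz)
    gb1 <- colSums(dz)
    d_emb <- dz %*% t(cl$W1)
    g_classifier <- list(W1 = gW1, b1 = gb1, W = gW, b = gb)
  } else {
    gW <- crossprod(cache$emb, d_logits)
    gb <- colSums(d_logits)
    d_emb <- d_logits %*% t(cl$W)
    g_classifier <- list(W = gW, b = gb)
  }
  if (!is.null(d_emb_extra)) d_emb <- d_emb + d_emb_extra

  cls_rows <- seq_len(N) * mp1
  dO <- matrix(0, mp1 * N, h)
  dO[cls_rows, ] <- d_emb

  gWo <- crossprod(cache$Hflat, dO)
  dH <- dO %*% t(at$Wo)

  scl <- 1 / sqrt(d)
  dQh <- dKh <- dVh <- vector("list", nh)
  for (i in seq_len(nh)) dQh[[i]] <- dKh[[i]] <- dVh[[i]] <-
    matrix(0, mp1 * N, d)
  for (cidx in seq_len(N)) {
    rows <- ((cidx - 1L) * mp1 + 1L):(cidx * mp1)
    for (i in seq_len(nh)) {
      dHi <- dH[rows, (i - 1L) * d + seq_len(d), drop = FALSE]
      W <- matrix(cache$Attw[[i]][cidx, , ], mp1, mp1)
      Vi <- cache$Vh[[i]][rows, , drop = FALSE]
      dW <- dHi %*% t(Vi)
      dVh[[i]][rows, ] <- crossprod(W, dHi)
      dS <- W * (dW - rowSums(dW * W))
      dQh[[i]][rows, ] <- (dS %*% cache$Kh[[i]][rows, , drop = FALSE]) * scl
      dKh[[i]][rows, ] <- (crossprod(dS, cache$Qh[[i]][rows, , drop = FALSE])) * scl
    }
  }

  dQs <- matrix(0, mp1 * N, h); dKs <- dQs; dVs <- dQs
  g_heads <- vector("list", nh)
  for (i in seq_len(nh)) {
    hd <- at$heads[[i]]
    g_heads[[i]] <- list(Wq = crossprod(dQh[[i]], cache$Qs),
                         Wk = crossprod(dKh[[i]], cache$Ks),
                         Wv = crossprod(dVh[[i]], cache$Vs))
    dQs <- dQs + dQh[[i]] %*% hd$Wq
    dKs <- dKs + dKh[[i]] %*% hd$Wk
    dVs <- dVs + dVh[[i]] %*% hd$Wv
  }
  gWq <- crossprod(cache$Iflat, dQs)
  gWk <- crossprod(cache$Iflat, dKs)
  gWv <- crossprod(cache$Iflat, dVs)
  dI <- dQs %*% t(at$Wq) + dKs %*% t(at$Wk) + dVs %*% t(at$Wv)

  dIarr <- aperm(array(dI, c(mp1, N, h)), c(2, 1, 3))
  g_cls <- colSums(matrix(dIarr[, mp1, ], N, h))
  dT <- dIarr[, seq_len(m), , drop = FALSE]
  g_nav <- navigator_backward(cache$X, params$navigator, dT)

  list(navigator = list(W = g_nav), cls = g_cls,
       attn = list(Wq = gWq, Wk = gWk, Wv = gWv, heads = g_heads, Wo = gWo),
       classifier = g_classifier)
}

#' Teacher forward pass for one cell
#'
#' @param x Length-n expression vector.
#' @param params A [teacher_init()] `TeacherParams`.
#' @return A `TeacherOutput` list: `embedding` (length h, the
#'   post-attention cls token), `updated_tokens` (m x h), `logits`
#'   (length k, named by class).
#' @export
teacher_forward <- function(x, params) {
  out <- teacher_forward_batch(params, matrix(x, nrow = 1))
  structure(list(embedding = drop(out$embedding),
                 updated_tokens = matrix(out$updated_tokens[1, , ],
                                         params$m, params$h),
                 logits = stats::setNames(drop(out$logits), params$classes)),
            class = "TeacherOutput")
}

#' Standalone single-layer multi-head self-attention
#'
#' Applies the Teacher's attention layer to an arbitrary (m+1) x h token
#' matrix. Exposed mainly for inspection and testing; every row of each
#' head's attention-weight matrix sums to 1.
#'
#' @param tokens (m+1) x h numeric matrix.
#' @param attn The `attn` component of a `TeacherParams`.
#' @param d_head Per-head width.
#' @return List with `output` ((m+1) x h) and `weights` (list of per-head
#'   attention matrices).
#' @export
self_attention_layer <- function(tokens, attn, d_head = ncol(tokens) %/% length(attn$heads)) {
  if (any(!is.finite(tokens))) stop("non-finite attention input")
  Qs <- tokens %*% attn$Wq; Ks <- tokens %*% attn$Wk; Vs <- tokens %*% attn$Wv
  scl <- 1 / sqrt(d_head)
  Hs <- list(); Ws <- list()
  for (i in seq_along(attn$heads)) {
    hd <- attn$heads[[i]]
    Qi <- Qs %*% t(hd$Wq); Ki <- Ks %*% t(hd$Wk); Vi <- Vs %*% t(hd$Wv)
    W <- softmax_rows(Qi %*% t(Ki) * scl)
    Ws[[i]] <- W
    Hs[[i]] <- W %*% Vi
  }
  list(output = do.call(cbind, Hs) %*% attn$Wo, weights = Ws)
}
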