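#' Training configuration
#'
#' @param epochs Number of passes over the reference (default 6; the model
#'   is designed to converge within six epochs).
#' @param batch_size Minibatch size (default 256).
#' @param lr Initial learning rate for SGD (default 0.1), decayed to ~0 by
#'   [cosine_lr()].
#' @param momentum SGD momentum (default 0.9).
#' @param clip_grad Global-norm gradient clipping threshold (default 5;
#'   `Inf` disables).
#' @param seed Integer seed governing initialization and shuffling.
#' @param lambda1,lambda2 Teacher loss weights: clustering divergence and
#'   cross-entropy (both default 1).
#' @param lambda3,lambda4 Student loss weights: distillation KL
#'   (default 1) and self-entropy (default 0.1; a sharpening regulariser
#'   kept deliberately weaker than the distillation target).
#' @param temperature Distillation temperature T (default 3).
#' @param h Token width of the Teacher.
#' @param m Number of patterns when training without a knowledge mask.
#' @param mask_mode `"persistent"` or `"init_only"` (see
#'   [navigator_init()]).
#' @param student_hidden Hidden widths of the Student MLP.
#' @param classifier_hidden Optional hidden width of the Teacher
#'   classifier (`NULL` = single linear layer).
#' @param use_hard_labels Also add `lambda2 * L2` on hard labels to the
#'   Student objective (off by default: the Student's target is the
#'   Teacher's soft labels).
#' @param similarity,raw_denominator,self_entropy_mode Variant switches of
#'   the objectives (see [similarity_matrix()],
#'   [clustering_divergence_loss()], [self_entropy_loss()]).
#' @return A `TrainConfig` list.
#' @export
train_config <- function(epochs = 6, batch_size = 256, lr = 0.1,
                         momentum = 0.9, clip_grad = 5, seed = 1,
                         lambda1 = 1, lambda2 = 1,
                         lambda3 = 1, lambda4 = 0.1, temperature = 3, h = 48,
                         m = NULL, mask_mode = "persistent",
                         student_hidden = c(256, 64),
                         classifier_hidden = NULL, use_hard_labels = FALSE,
                         similarity = "sq_euclid", raw_denominator = FALSE,
                         self_entropy_mode = "sample_entropy") {
  cfg <- as.list(environment())
  if (cfg$epochs < 1) stop("epochs must be >= 1")
  if (cfg$lr <= 0) stop("lr must be > 0")
  if (cfg$batch_size < 2) stop("batch_size must be >= 2")
  if (cfg$temperature <= 0) stop("temperature must be > 0")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "TrainConfig")
}

#' Train the Teacher
#'
#' Minimizes `lambda1 * L1 + lambda2 * L2` (clustering divergence +
#' cross-entropy) by minibatch SGD with momentum and cosine learning-rate
#' decay. The similarity matrix of the clustering loss is computed per
#' minibatch from the current cell embeddings, so its gradient flows into
#' both the classifier logits and the embedding.
#'
#' @param reference A normalized [expression_matrix()] carrying `cell_type`
#'   labels (or supply `labels`).
#' @param config A [train_config()].
#' @param mask Optional [build_knowledge_mask()] knowledge mask.
#' @param labels Optional per-cell labels overriding `reference$cell_type`.
#' @return A `TeacherParams` with attached `gene_names`, `loss_log`
#'   (per-epoch data frame) and `config`.
#' @export
train_teacher <- function(reference, config = train_config(), mask = NULL,
                          labels = NULL) {
  stopifnot(inherits(reference, "ExpressionMatrix"),
            inherits(config, "TrainConfig"))
  if (is.null(labels)) labels <- reference$cell_type
  if (is.null(labels)) stop("reference labels required")
  if (!reference$normalized)
    warning("reference does not look normalized; call normalize_log1p() first")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes in the reference")
  small <- names(which(table(labels) < 2))
  if (length(small))
    warning("classes with fewer than 2 cells: ", paste(small, collapse = ", "))

  X <- reference$values
  N <- nrow(X)
  set.seed(config$seed)
  params <- teacher_init(ncol(X), classes, mask = mask, m = config$m,
                         h = config$h, mask_mode = config$mask_mode,
                         classifier_hidden = config$classifier_hidden)
  lab_idx <- match(labels, classes)
  onehot <- matrix(0, N, params$k)
  onehot[cbind(seq_len(N), lab_idx)] <- 1

  n_batches <- ceiling(N / config$batch_size)
  total_steps <- config$epochs * n_batches
  vel <- NULL
  step <- 0L
  log <- data.frame(epoch = integer(0), L1 = numeric(0), L2 = numeric(0),
                    total = numeric(0), lr = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ord <- sample(N)
    e1 <- e2 <- 0; nb <- 0
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, N)]
      if (length(idx) < 2) next
      lr <- cosine_lr(step, total_steps, config$lr)
      fw <- teacher_forward_batch(params, X[idx, , drop = FALSE], keep = TRUE)
      ce <- cross_entropy_loss(fw$logits, onehot[idx, , drop = FALSE],
                               grad = TRUE)
      d_logits <- config$lambda2 * ce$d_logits
      d_emb <- NULL
      l1v <- 0
      if (config$lambda1 != 0) {
        S <- similarity_matrix(fw$embedding, similarity = config$similarity)
        cl <- clustering_divergence_loss(fw$logits, S,
                                         raw_denominator = config$raw_denominator,
                                         grad = TRUE)
        l1v <- cl$value
        d_logits <- d_logits + config$lambda1 * cl$d_logits
        d_emb <- config$lambda1 *
          similarity_backward(fw$embedding, S, cl$d_S)
      }
      grads <- teacher_backward_batch(params, fw$cache, d_logits, d_emb)
      grads <- clip_gradients(grads, config$clip_grad)
      upd <- sgd_update(params[c("navigator", "cls", "attn", "classifier")],
                        grads, vel, lr, config$momentum)
      params[c("navigator", "cls", "attn", "classifier")] <- upd$params
      vel <- upd$vel
      e1 <- e1 + l1v; e2 <- e2 + ce$value; nb <- nb + 1
      step <- step + 1L
    }
    log <- rbind(log, data.frame(epoch = ep, L1 = e1 / nb, L2 = e2 / nb,
                                 total = (config$lambda1 * e1 +
                                            config$lambda2 * e2) / nb,
                                 lr = cosine_lr(step - 1L, total_steps,
                                                config$lr)))
  }
  params$gene_names <- reference$gene_names
  params$loss_log <- log
  params$config <- config
  params
}

#' Distill the Student from a frozen Teacher
#'
#' Minimizes `lambda3 * L3 + lambda4 * L4` (tempered KL to the Teacher's
#' soft labels + self-entropy) by minibatch SGD. The reference's hard
#' labels are not used unless `use_hard_labels` is set in the config; the
#' Teacher's logits are computed once and treated as constants.
#'
#' @param reference A normalized [expression_matrix()] in the Teacher's
#'   gene space.
#' @param teacher A trained [train_teacher()] `TeacherParams`.
#' @param config A [train_config()].
#' @param labels Optional hard labels (only used with `use_hard_labels`).
#' @return A `StudentParams` with attached `gene_names`, `loss_log` and
#'   `config`.
#' @export
train_student <- function(reference, teacher, config = teacher$config,
                          labels = NULL) {
  stopifnot(inherits(reference, "ExpressionMatrix"),
            inherits(teacher, "TeacherParams"))
  if (!is.null(teacher$gene_names) &&
      !identical(reference$gene_names, teacher$gene_names))
    stop("gene space differs from the Teacher's; use align_genes()")
  X <- reference$values
  N <- nrow(X)
  t_logits <- predict_logits(teacher, X)

  onehot <- NULL
  if (isTRUE(config$use_hard_labels)) {
    if (is.null(labels)) labels <- reference$cell_type
    if (is.null(labels)) stop("use_hard_labels requires labels")
    li <- match(as.character(labels), teacher$classes)
    if (any(is.na(li))) stop("labels outside the Teacher's classes")
    onehot <- matrix(0, N, teacher$k)
    onehot[cbind(seq_len(N), li)] <- 1
  }

  set.seed(config$seed)
  params <- student_init(ncol(X), teacher$classes,
                         hidden = config$student_hidden)
  n_batches <- ceiling(N / config$batch_size)
  total_steps <- config$epochs * n_batches
  vel <- NULL
  step <- 0L
  log <- data.frame(epoch = integer(0), L3 = numeric(0), L4 = numeric(0),
                    total = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ord <- sample(N)
    e3 <- e4 <- 0; nb <- 0
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, N)]
      lr <- cosine_lr(step, total_steps, config$lr)
      fw <- student_forward_batch(params, X[idx, , drop = FALSE], keep = TRUE)
      kd <- distillation_loss(fw$logits, t_logits[idx, , drop = FALSE],
                              T = config$temperature, grad = TRUE)
      se <- self_entropy_loss(fw$logits, mode = config$self_entropy_mode,
                              grad = TRUE)
      d_logits <- config$lambda3 * kd$d_logits + config$lambda4 * se$d_logits
      if (!is.null(onehot)) {
        ce <- cross_entropy_loss(fw$logits, onehot[idx, , drop = FALSE],
                                 grad = TRUE)
        d_logits <- d_logits + config$lambda2 * ce$d_logits
      }
      grads <- student_backward_batch(params, fw$cache, d_logits)
      grads <- clip_gradients(grads, config$clip_grad)
      upd <- sgd_update(params["layers"], grads["layers"], vel, lr,
                        config$momentum)
      params["layers"] <- upd$params
      vel <- upd$vel
      e3 <- e3 + kd$value; e4 <- e4 + se$value; nb <- nb + 1
      step <- step + 1L
    }
    log <- rbind(log, data.frame(epoch = ep, L3 = e3 / nb, L4 = e4 / nb,
                                 total = (config$lambda3 * e3 +
                                            config$lambda4 * e4) / nb))
  }
  params$gene_names <- reference$gene_names
  params$loss_log <- log
  params$config <- config
  params
}

# raw logits for a matrix of cells, chunked to bound memory
predict_logits <- function(params, X, chunk = 1024L) {
  N <- nrow(X)
  out <- matrix(0, N, params$k)
  for (s in seq(1L, N, by = chunk)) {
    idx <- s:min(s + chunk - 1L, N)
    out[idx, ] <- if (inherits(params, "TeacherParams"))
      teacher_forward_batch(params, X[idx, , drop = FALSE])$logits
    else
      student_forward_batch(params, X[idx, , drop = FALSE])$logits
  }
  colnames(out) <- params$classes
  out
}

#' Predict cell types
#'
#' Works with either a trained Teacher or Student. The predicted label is
#' the argmax of the logits (ties broken by the lowest class index);
#' probabilities are the softmax of the logits.
#'
#' @param params `TeacherParams` or `StudentParams` with `gene_names`.
#' @param X An [expression_matrix()] aligned to the model's gene space.
#' @return A data frame: `cell_id`, `predicted_type`, `max_prob`, then one
#'   probability column per class.
#' @export
predict_cells <- function(params, X) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (!is.null(params$gene_names) &&
      !identical(X$gene_names, params$gene_names))
    stop("gene space not aligned with the model; use align_genes()")
  logits <- predict_logits(params, X$values)
  P <- softmax_rows(logits)
  pred <- params$classes[apply(logits, 1, which.max)]
  out <- data.frame(cell_id = X$cell_ids, predicted_type = pred,
                    max_prob = apply(P, 1, max), stringsAsFactors = FALSE)
  colnames(P) <- paste0("prob_", params$classes)
  cbind(out, as.data.frame(P))
}

#' @export
predict.TeacherParams <- function(object, newdata, ...)
  predict_cells(object, newdata)

#' @export
predict.StudentParams <- function(object, newdata, ...)
  predict_cells(object, newdata)

#' Extract cell embeddings from the Teacher
#'
#' The embedding of a cell is its post-attention cls token.
#'
#' @param teacher A trained `TeacherParams`.
#' @param X An [expression_matrix()] in the Teacher's gene space.
#' @param chunk Cells per forward chunk.
#' @return A cells x h numeric matrix with cell ids as row names.
#' @export
embed_cells <- function(teacher, X, chunk = 1024L) {
  stopifnot(inherits(teacher, "TeacherParams"),
            inherits(X, "ExpressionMatrix"))
  if (!is.null(teacher$gene_names) &&
      !identical(X$gene_names, teacher$gene_names))
    stop("gene space not aligned with the model; use align_genes()")
  N <- nrow(X$values)
  out <- matrix(0, N, teacher$h, dimnames = list(X$cell_ids, NULL))
  for (s in seq(1L, N, by = chunk)) {
    idx <- s:min(s + chunk - 1L, N)
    out[idx, ] <- teacher_forward_batch(teacher,
                                        X$values[idx, , drop = FALSE])$embedding
  }
  out
}

#' Extract per-cell pattern tokens from the Teacher
#'
#' @param teacher A trained `TeacherParams`.
#' @param X An [expression_matrix()] in the Teacher's gene space.
#' @param updated Return post-attention tokens instead of the Navigator's
#'   pre-attention tokens.
#' @return A cells x m x h array.
#' @export
pattern_tokens <- function(teacher, X, updated = FALSE) {
  stopifnot(inherits(teacher, "TeacherParams"),
            inherits(X, "ExpressionMatrix"))
  N <- nrow(X$values)
  out <- array(0, dim = c(N, teacher$m, teacher$h))
  for (s in seq(1L, N, by = 1024L)) {
    idx <- s:min(s + 1023L, N)
    fw <- teacher_forward_batch(teacher, X$values[idx, , drop = FALSE])
    out[idx, , ] <- if (updated) fw$updated_tokens else fw$tokens
  }
  out
}
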