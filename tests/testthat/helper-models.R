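# lazily trained models at the default simulation conditions, shared by the
# acceptance tests so each (seed, variant) is trained once per session
.model_cache <- new.env(parent = emptyenv())

# default-condition dataset split into reference (batch1) and query (batch2)
acc_data <- function(seed) {
  key <- paste0("data", seed)
  if (is.null(.model_cache[[key]])) {
    sim <- simulate_cells(simulation_config(seed = seed))
    norm <- normalize_log1p(sim$expression)
    .model_cache[[key]] <- list(
      sim = sim,
      mask = build_knowledge_mask(sim$expression$gene_names,
                                  sim$planted_sets),
      norm = norm,
      ref = subset_cells(norm, which(sim$true_batch == "batch1")),
      qry = subset_cells(norm, which(sim$true_batch == "batch2")))
  }
  .model_cache[[key]]
}

# variant: "full" (default objective), "ablated" (lambda1 = lambda4 = 0),
# "noisy" (20% corrupted reference labels)
acc_models <- function(seed, variant = "full") {
  key <- paste0("model", seed, variant)
  if (is.null(.model_cache[[key]])) {
    d <- acc_data(seed)
    cfg <- switch(variant,
                  full = train_config(seed = seed),
                  ablated = train_config(seed = seed, lambda1 = 0,
                                         lambda4 = 0),
                  noisy = train_config(seed = seed))
    labels <- if (variant == "noisy")
      corrupt_labels(d$ref$cell_type, 0.2, seed = seed) else NULL
    teacher <- train_teacher(d$ref, cfg, mask = d$mask, labels = labels)
    student <- train_student(d$ref, teacher, cfg)
    .model_cache[[key]] <- list(teacher = teacher, student = student,
                                config = cfg)
  }
  .model_cache[[key]]
}

accuracy_on <- function(params, X) {
  mean(predict_cells(params, X)$predicted_type == X$cell_type)
}
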