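## Serialized-weights layout: an RDS file holding the config, every trainable
## parameter array (in deterministic module-traversal order), the batch-norm
## running statistics, and whether the weights are the train-mode or the
## fused deploy-mode structure.

# collect batch-norm state environments in traversal order
collect_bn_states <- function(m) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x) && !is_node(x)) {
      out[[length(out) + 1L]] <<- x
    } else if (is.list(x) && !is_node(x)) {
      for (el in x) walk(el)
    }
  }
  walk(m)
  out
}

#' Save / load detector checkpoints
#'
#' A checkpoint stores the detector configuration, all parameter values, the
#' batch-norm running statistics and a deploy flag; [load_checkpoint()]
#' rebuilds the module structure from the config (fusing it first for
#' deploy-mode checkpoints) and restores the values.
#'
#' @param model a `palm_detector`.
#' @param path RDS file path.
#' @export
save_checkpoint <- function(model, path) {
  st <- list(
    cfg = model$cfg,
    fused = is_fused(model),
    params = lapply(collect_params(model), function(p) p$v),
    bn = lapply(collect_bn_states(model), function(e)
      list(mean = e$running_mean, var = e$running_var)))
  saveRDS(st, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns the restored `palm_detector`.
#' @export
load_checkpoint <- function(path) {
  st <- readRDS(path)
  model <- build_detector(st$cfg, seed = 0L)
  if (st$fused) model <- fuse_module(model)
  ps <- collect_params(model)
  if (length(ps) != length(st$params))
    stop("checkpoint structure mismatch: ", length(st$params),
         " stored parameters vs ", length(ps), " in the rebuilt model")
  for (i in seq_along(ps)) {
    if (length(ps[[i]]$v) != length(st$params[[i]]))
      stop("checkpoint parameter ", i, " has wrong size")
    ps[[i]]$v <- st$params[[i]]
  }
  bs <- collect_bn_states(model)
  if (length(bs) != length(st$bn)) stop("checkpoint norm-state mismatch")
  for (i in seq_along(bs)) {
    bs[[i]]$running_mean <- st$bn[[i]]$mean
    bs[[i]]$running_var <- st$bn[[i]]$var
  }
  model
}
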