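# Checkpoints: weights in R's native serialized container (.rds) plus a
# JSON sidecar recording the model specification; loading validates that
# the stored weights match the spec they claim.

#' Save an encoder or classifier checkpoint
#'
#' @param model an encoder, classifier or contrastive model
#' @param path_base file path without extension; writes `path_base.rds`
#'   (weights) and `path_base.json` (spec sidecar)
#' @return the two paths, invisibly
#' @export
save_checkpoint <- function(model, path_base) {
  if (inherits(model, "ecgtl_encoder")) {
    st <- encoder_state(model); kind <- "encoder"; spec <- model$spec
  } else if (inherits(model, "ecgtl_classifier")) {
    st <- model_state(model); kind <- "classifier"; spec <- model$spec
  } else if (inherits(model, "ecgtl_cpc")) {
    st <- list(enc = encoder_state(model$encoder),
               pool = lapply(attention_pool_layers(model$pool), layer_state),
               ap_spec = model$ap_spec)
    kind <- "cpc"; spec <- model$spec
  } else stop("cannot checkpoint object of class ", class(model)[1])
  saveRDS(list(kind = kind, state = st), paste0(path_base, ".rds"))
  sidecar <- list(kind = kind, spec = unclass(spec))
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA),
             paste0(path_base, ".json"))
  invisible(paste0(path_base, c(".rds", ".json")))
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path_base file path without extension
#' @return the reconstructed model
#' @export
load_checkpoint <- function(path_base) {
  blob <- readRDS(paste0(path_base, ".rds"))
  side <- jsonlite::fromJSON(paste0(path_base, ".json"))
  if (!identical(blob$kind, side$kind))
    stop("checkpoint sidecar disagrees with weights about the model kind")
  if (blob$kind == "encoder") {
    enc <- build_encoder(blob$state$spec)
    for (f in c("depth", "in_channels", "stages_used"))
      if (!isTRUE(side$spec[[f]] == enc$spec[[f]]))
        stop("sidecar spec incompatible with stored weights (", f, ")")
    encoder_load_state(enc, blob$state)
    enc
  } else if (blob$kind == "classifier") {
    sp <- blob$state$spec
    m <- build_classifier(sp, blob$state$activation)
    model_load_state(m, blob$state)
    m
  } else {
    m <- build_cpc_model(blob$state$enc$spec, blob$state$ap_spec)
    encoder_load_state(m$encoder, blob$state$enc)
    pls <- attention_pool_layers(m$pool)
    for (i in seq_along(pls)) layer_load_state(pls[[i]], blob$state$pool[[i]])
    m
  }
}
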