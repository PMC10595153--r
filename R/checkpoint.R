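# Text (JSON) model checkpoints: parameters + configuration + featurization
# descriptor, refusing to load against a different featurization layout.

#' Save a fitted model or parameter set
#'
#' Writes a single JSON file holding the parameters, the model configuration,
#' and the featurization descriptor. [read_fragsol()] refuses to load a
#' checkpoint whose descriptor does not match the running package's
#' featurization.
#'
#' @param object A fitted [fragsol()] model, or a [fragsol_params()] set (then
#'   `cfg` must be given).
#' @param path Output file path.
#' @param cfg The [fragsol_config()] when `object` is a raw parameter set.
#' @param null_fragment Stored ablation flag when `object` is a raw set.
#' @return `path`, invisibly.
#' @export
write_fragsol <- function(object, path, cfg = NULL, null_fragment = FALSE) {
  if (inherits(object, "fragsol")) {
    params <- object$params
    cfg <- object$config
    null_fragment <- object$null_fragment
    descriptor <- object$feature_descriptor
  } else {
    stopifnot(!is.null(cfg))
    params <- object
    descriptor <- feature_config()$descriptor
  }
  payload <- list(
    format = "fragsol-checkpoint-1",
    version = as.character(utils::packageVersion("fragsol")),
    feature_descriptor = descriptor,
    null_fragment = null_fragment,
    config = unclass(cfg),
    params = lapply(params, function(x) {
      if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
      else list(dim = NULL, data = as.numeric(x))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [write_fragsol()].
#' @return List with `params`, `config`, `null_fragment`, `version`.
#' @export
read_fragsol <- function(path) {
  if (!file.exists(path))
    stop(sprintf("checkpoint not found: '%s'", path), call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "fragsol-checkpoint-1"))
    stop("not a fragsol checkpoint", call. = FALSE)
  current <- feature_config()$descriptor
  if (!identical(payload$feature_descriptor, current))
    stop(paste("checkpoint featurization does not match this package version;",
               "refusing to load"), call. = FALSE)
  cfg <- do.call(fragsol_config, payload$config[c("hidden_width",
                                                 "atom_layers", "mol_layers",
                                                 "dropout", "leaky_slope")])
  params <- lapply(payload$params, function(p) {
    if (is.null(p$dim) || length(p$dim) == 0) {
      if (length(p$data) == 1) p$data else as.numeric(p$data)
    } else matrix(p$data, p$dim[1], p$dim[2])
  })
  class(params) <- "fragsol_params"
  list(params = params, config = cfg,
       null_fragment = isTRUE(payload$null_fragment),
       version = payload$version)
}
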