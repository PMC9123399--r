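#' Save a fitted model to a JSON file
#'
#' Writes a self-contained JSON representation: the layer-1 projection
#' matrix, the (i, j, scale) construction records of the deeper layers, the
#' readout coefficients, and for ensembles the member models with their
#' (alpha, epsilon) lists. Numbers are written at full precision so a
#' save/load round trip preserves predictions bit-for-bit.
#'
#' @param model an `nlpnn_model` or `aepnn_model`.
#' @param path output file.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON model file.
#' @return The restored `nlpnn_model` or `aepnn_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  model_from_list(obj)
}

# doubles are serialized as %.17g strings: 17 significant digits round-trip
# IEEE-754 doubles exactly, which keeps reloaded predictions bit-identical
enc_num <- function(x) sprintf("%.17g", x)

enc_matrix <- function(m) {
  lapply(seq_len(nrow(m)), function(i) enc_num(m[i, ]))
}

model_to_list <- function(model) {
  if (inherits(model, "aepnn_model")) {
    return(list(
      type = "aepnn",
      alpha = enc_num(model$alpha),
      epsilon = model$epsilon,
      L = model$L,
      history = as.list(model$history),
      history_n_pos = attr(model$history, "n_pos"),
      members = lapply(model$members, model_to_list)
    ))
  }
  stopifnot(inherits(model, "nlpnn_model"))
  layers <- lapply(model$stack$layers, function(l) {
    if (l$level == 1L) {
      list(level = 1L, projection = enc_matrix(l$construction))
    } else {
      recs <- lapply(l$construction, function(r) {
        list(i = r$i, j = r$j, scale = enc_num(r$scale))
      })
      list(level = l$level, records = recs)
    }
  })
  list(
    type = "nlpnn",
    n = model$stack$n,
    layers = layers,
    readout = list(nu = enc_num(model$readout$nu),
                   lambda = model$readout$lambda_,
                   m = model$readout$m,
                   train_objective = model$readout$train_objective),
    config = unclass(model$config)
  )
}

json_num <- function(x) as.numeric(unlist(x, use.names = FALSE))

json_matrix <- function(rows) {
  do.call(rbind, lapply(rows, json_num))
}

model_from_list <- function(obj) {
  if (identical(obj$type, "aepnn")) {
    history <- as.data.frame(lapply(obj$history, json_num))
    attr(history, "n_pos") <- as.integer(obj$history_n_pos)
    return(structure(
      list(members = lapply(obj$members, model_from_list),
           alpha = json_num(obj$alpha),
           epsilon = json_num(obj$epsilon),
           L = as.integer(obj$L),
           history = history),
      class = "aepnn_model"
    ))
  }
  stopifnot(identical(obj$type, "nlpnn"))
  # the training feature matrices are not serialized: prediction needs only
  # the construction records, so F is left NULL on load
  layers <- lapply(obj$layers, function(l) {
    if (as.integer(l$level) == 1L) {
      new_basis_layer(1L, F = NULL, construction = json_matrix(l$projection))
    } else {
      recs <- lapply(l$records, function(r) {
        list(i = as.integer(r$i), j = as.integer(r$j),
             scale = as.numeric(r$scale))
      })
      new_basis_layer(as.integer(l$level), F = NULL, construction = recs)
    }
  })
  cfg <- obj$config
  config <- nlpnn_config(
    omega = json_num(cfg$omega),
    lambda_grid = json_num(cfg$lambda_grid),
    rank_tol = as.numeric(cfg$rank_tol),
    seed = as.integer(cfg$seed),
    epochs = as.integer(cfg$epochs),
    batch_size = as.integer(cfg$batch_size),
    eta0 = if (length(cfg$eta0)) as.numeric(cfg$eta0) else NULL,
    validation_fraction = as.numeric(cfg$validation_fraction)
  )
  readout <- structure(
    list(nu = json_num(obj$readout$nu),
         lambda_ = as.numeric(obj$readout$lambda),
         m = as.integer(obj$readout$m),
         train_objective = as.numeric(obj$readout$train_objective)),
    class = "readout_model"
  )
  structure(
    list(stack = new_feature_stack(layers, as.integer(obj$n)),
         readout = readout, config = config,
         label_map = c(negative = -1, positive = 1)),
    class = "nlpnn_model"
  )
}
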