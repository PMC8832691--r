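# Dose-to-image response network: architecture/training specs, training on
# a DatasetBundle, and prediction.

#' Construct a network architecture spec
#'
#' Full scale is depth 5 with 64 base channels on the 256 x 192 grid
#' (bottleneck 8 x 6); tests and desk-scale runs use depth 3 with 8-16 base
#' channels on smaller grids.
#'
#' @param depth encoder blocks / poolings.
#' @param baseChannels first-level channel count (doubled per level).
#' @param height,width input grid size (crossline, inline); each must be
#'   divisible by `2^depth`.
#' @return A [NetworkSpec-class].
#' @export
networkSpec <- function(depth = 5L, baseChannels = 64L,
                        height = 256L, width = 192L) {
  new("NetworkSpec", depth = as.integer(depth),
      baseChannels = as.integer(baseChannels), height = as.integer(height),
      width = as.integer(width))
}

#' Construct a training spec
#'
#' Defaults follow the reference recipe: MSE loss, Adam at learning rate
#' 1e-4 with conventional remaining hyperparameters, batch size 12, 2000
#' epochs. `epochs` and `learningRate` are the scale knobs for desk-size
#' runs.
#'
#' @param learningRate Adam step size.
#' @param batchSize mini-batch size.
#' @param epochs passes over the training split.
#' @param seed integer seed (weight init + batch shuffling).
#' @param lrDecayAt integer epochs at which the step size is halved (step
#'   decay; empty for a constant rate as in the reference recipe).
#' @param doseScale,tiScale input/target scaling constants; `NA` = compute
#'   from the training split (its maxima) and store with the model.
#' @return A [TrainSpec-class].
#' @export
trainSpec <- function(learningRate = 1e-4, batchSize = 12L, epochs = 2000L,
                      seed = 1L, lrDecayAt = integer(0),
                      doseScale = NA_real_, tiScale = NA_real_) {
  new("TrainSpec", learningRate = learningRate,
      lrDecayAt = as.integer(lrDecayAt),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed), doseScale = doseScale, tiScale = tiScale)
}

#' Build an untrained network
#'
#' He-initialised weights for the given architecture; mostly useful for
#' inspecting the architecture and for the residual-identity property
#' (zeroing the final projection makes the network an identity map).
#'
#' @param spec a [NetworkSpec-class].
#' @param seed integer seed for the weight initialisation.
#' @return list with `weights` and `spec`.
#' @export
buildNetwork <- function(spec, seed = 1L) {
  stopifnot(is(spec, "NetworkSpec"))
  list(weights = cpp_unet_init(spec@depth, spec@baseChannels, spec@height,
                               spec@width, as.integer(seed)),
       spec = spec)
}

#' Forward pass of an (un)trained network on raw values
#'
#' @param network a list from [buildNetwork()] or a [TrainedModel-class].
#' @param x input matrix matching the network shape (no scaling applied).
#' @return output matrix of the same shape.
#' @export
forwardNetwork <- function(network, x) {
  if (is(network, "TrainedModel")) {
    spec <- network@networkSpec; w <- network@weights
  } else { spec <- network$spec; w <- network$weights }
  if (!identical(dim(x), c(spec@height, spec@width)))
    stop("input shape ", paste(dim(x), collapse = "x"),
         " does not match the network (", spec@height, "x", spec@width, ")")
  cpp_unet_predict(w, x, spec@depth, spec@baseChannels)
}

#' Train the dose-to-image response network
#'
#' Minimises the mean squared error between predicted and target images on
#' scaled values (inputs divided by `doseScale`, targets by `tiScale`;
#' computed from the training split when not given). Weight initialisation
#' and batch order are seeded, so runs are reproducible at a fixed thread
#' count. Per-epoch training and validation losses are recorded.
#'
#' @param data a [DatasetBundle-class].
#' @param spec a [NetworkSpec-class] matching the bundle grid.
#' @param train a [TrainSpec-class].
#' @return A [TrainedModel-class].
#' @export
trainResponseNet <- function(data, spec, train = trainSpec()) {
  stopifnot(is(data, "DatasetBundle"), is(spec, "NetworkSpec"),
            is(train, "TrainSpec"))
  d1 <- dim(data@inputs[[1]])
  if (!identical(d1, c(spec@height, spec@width)))
    stop("dataset grid ", paste(d1, collapse = "x"),
         " does not match the network spec")
  as_cube <- function(idx, what) {
    if (!length(idx)) return(array(0, c(spec@height, spec@width, 0)))
    simplify2array(slot(data, what)[idx])
  }
  tx <- as_cube(data@splitTrain, "inputs")
  ty <- as_cube(data@splitTrain, "targets")
  if (is.na(train@doseScale)) train@doseScale <- max(tx)
  if (is.na(train@tiScale)) train@tiScale <- max(ty)
  vx <- as_cube(data@splitVal, "inputs") / train@doseScale
  vy <- as_cube(data@splitVal, "targets") / train@tiScale
  lr_epoch <- train@learningRate *
    0.5^findInterval(seq_len(train@epochs), sort(train@lrDecayAt) + 0.5)
  fit <- cpp_unet_train(tx / train@doseScale, ty / train@tiScale, vx, vy,
                        spec@depth, spec@baseChannels, train@epochs,
                        train@batchSize, lr_epoch, train@seed)
  new("TrainedModel", weights = fit$weights, networkSpec = spec,
      trainSpec = train,
      lossHistory = data.frame(epoch = seq_len(train@epochs),
                               train = fit$train_loss, val = fit$val_loss))
}

#' Predict a transmission image from an equivalent-EPID dose map
#'
#' Applies the stored input scaling, runs the forward pass, and inverts the
#' target scaling. The dose must already be cropped/resampled to the
#' network grid (see [cropResample()]).
#'
#' @param model a [TrainedModel-class].
#' @param dose a [TransmissionImage-class]-shaped resampled dose grid, a
#'   [PlanarDose-class] on the network grid, or a bare matrix.
#' @return A [TransmissionImage-class] with provenance `"predicted"`.
#' @export
predictTI <- function(model, dose) {
  stopifnot(is(model, "TrainedModel"))
  v <- if (is(dose, "TransmissionImage") || is(dose, "PlanarDose"))
    dose@values else dose
  spec <- model@networkSpec
  if (!identical(dim(v), c(spec@height, spec@width)))
    stop("dose shape ", paste(dim(v), collapse = "x"),
         " does not match the trained network (", spec@height, "x",
         spec@width, ")")
  out <- cpp_unet_predict(model@weights, v / model@trainSpec@doseScale,
                          spec@depth, spec@baseChannels)
  transmissionImage(pmax(out * model@trainSpec@tiScale, 0),
                    provenance = "predicted")
}
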