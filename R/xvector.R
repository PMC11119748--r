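# x-vector speaker-embedding extractor: five frame-level TDNN layers with
# growing temporal context, statistics pooling (mean + standard deviation),
# and two segment-level fully connected layers. The embedding is the affine
# (pre-nonlinearity) output of a designated segment layer, 512-dimensional
# for any input duration.

#' Extractor architecture description
#'
#' The canonical x-vector recipe: frame-level temporal contexts
#' \{t-2..t+2\}, \{t-2,t,t+2\}, \{t-3,t,t+3\}, \{t\}, \{t\} with output
#' dimensions 512, 512, 512, 512, 1500; statistics pooling to 3000; two
#' segment-level layers of 512.
#'
#' @param n_mels input feature dimension (mel filters).
#' @param tap_layer which segment layer's affine output is the embedding:
#'   \code{"last"} (second segment layer) or \code{"first"}.
#' @return list describing the architecture.
#' @export
xvector_config <- function(n_mels = 24L, tap_layer = c("last", "first")) {
  tap_layer <- match.arg(tap_layer)
  list(
    n_mels = as.integer(n_mels),
    contexts = list(c(-2L, -1L, 0L, 1L, 2L), c(-2L, 0L, 2L), c(-3L, 0L, 3L),
                    0L, 0L),
    frame_dims = c(512L, 512L, 512L, 512L, 1500L),
    seg_dims = c(512L, 512L),
    tap_layer = tap_layer
  )
}

# minimum frames the stacked contexts require
receptive_field <- function(config) {
  1L + sum(vapply(config$contexts, function(cc) max(cc) - min(cc), integer(1)))
}

#' Seeded random extractor weights
#'
#' A reproducible test double for externally trained weights: Glorot-normal
#' initialization of every affine layer. Weights pass the same shape
#' validation as imported ones.
#'
#' @param seed integer seed.
#' @param config architecture from \code{\link{xvector_config}}.
#' @return object of class \code{extractor_weights}.
#' @export
init_random_weights <- function(seed, config = xvector_config()) {
  layers <- with_seed(seed, {
    dims_in <- c(config$n_mels, config$frame_dims[-length(config$frame_dims)])
    frame <- lapply(seq_along(config$frame_dims), function(l) {
      fan_in <- dims_in[l] * length(config$contexts[[l]])
      fan_out <- config$frame_dims[l]
      sd <- sqrt(2 / (fan_in + fan_out))
      list(W = matrix(stats::rnorm(fan_in * fan_out, 0, sd), fan_in, fan_out),
           b = numeric(fan_out))
    })
    pool_dim <- 2L * config$frame_dims[length(config$frame_dims)]
    seg_in <- c(pool_dim, config$seg_dims[-length(config$seg_dims)])
    seg <- lapply(seq_along(config$seg_dims), function(l) {
      sd <- sqrt(2 / (seg_in[l] + config$seg_dims[l]))
      list(W = matrix(stats::rnorm(seg_in[l] * config$seg_dims[l], 0, sd),
                      seg_in[l], config$seg_dims[l]),
           b = numeric(config$seg_dims[l]))
    })
    list(frame = frame, segment = seg)
  })
  w <- structure(list(config = config, frame = layers$frame,
                      segment = layers$segment,
                      provenance = sprintf("random(seed=%d)", seed)),
                 class = "extractor_weights")
  validate_extractor_weights(w)
  w
}

#' Validate extractor weight shapes against the architecture
#'
#' @param w an \code{extractor_weights} object.
#' @return `w`, invisibly; errors name the first offending layer.
#' @export
validate_extractor_weights <- function(w) {
  ps_validate(inherits(w, "extractor_weights"),
              "weights must be an extractor_weights object")
  cfg <- w$config
  dims_in <- c(cfg$n_mels, cfg$frame_dims[-length(cfg$frame_dims)])
  for (l in seq_along(cfg$frame_dims)) {
    want <- c(dims_in[l] * length(cfg$contexts[[l]]), cfg$frame_dims[l])
    got <- dim(w$frame[[l]]$W)
    if (!identical(as.integer(got), as.integer(want))) {
      ps_stop(sprintf("frame layer %d: weight shape %s, expected %s", l,
                      paste(got, collapse = "x"),
                      paste(want, collapse = "x")),
              "ps_config_error")
    }
  }
  pool_dim <- 2L * cfg$frame_dims[length(cfg$frame_dims)]
  seg_in <- c(pool_dim, cfg$seg_dims[-length(cfg$seg_dims)])
  for (l in seq_along(cfg$seg_dims)) {
    want <- c(seg_in[l], cfg$seg_dims[l])
    got <- dim(w$segment[[l]]$W)
    if (!identical(as.integer(got), as.integer(want))) {
      ps_stop(sprintf("segment layer %d: weight shape %s, expected %s", l,
                      paste(got, collapse = "x"),
                      paste(want, collapse = "x")),
              "ps_config_error")
    }
  }
  invisible(w)
}

# TDNN layer: splice the context offsets, affine, ReLU.
tdnn_layer <- function(h, context, W, b) {
  Tn <- nrow(h)
  lo <- -min(context); hi <- max(context)
  valid <- (1L + lo):(Tn - hi)
  spliced <- do.call(cbind, lapply(context, function(o) {
    h[valid + o, , drop = FALSE]
  }))
  a <- sweep(spliced %*% W, 2L, b, `+`)
  pmax(a, 0)
}

#' Statistics pooling
#'
#' Aggregates frame-level activations into a fixed-length vector: the
#' per-dimension mean concatenated with the per-dimension standard deviation
#' (population convention). Invariant under frame permutation.
#'
#' @param frames numeric matrix, frames x dims (at least one frame).
#' @return numeric vector of length \code{2 * ncol(frames)}.
#' @export
statistics_pool <- function(frames) {
  frames <- as.matrix(frames)
  ps_validate(nrow(frames) >= 1L, "statistics pooling requires at least one frame")
  mu <- colMeans(frames)
  sd_pop <- sqrt(pmax(colMeans(frames^2) - mu^2, 0))
  c(mu, sd_pop)
}

#' Extract a speaker embedding
#'
#' Runs the log-mel front end, the frame-level TDNN stack, statistics
#' pooling, and the segment-level layers, returning the affine output of the
#' tap layer: a 512-dimensional vector for any valid input duration,
#' deterministic for fixed weights.
#'
#' @param w a 16 kHz \code{waveform}.
#' @param weights \code{extractor_weights}.
#' @param tap override the weights' configured tap layer (\code{"last"} or
#'   \code{"first"}).
#' @return numeric vector of length 512.
#' @export
extract_embedding <- function(w, weights, tap = NULL) {
  validate_extractor_weights(weights)
  cfg <- weights$config
  tap <- if (is.null(tap)) cfg$tap_layer else match.arg(tap, c("last", "first"))
  feats <- compute_features(w, n_mels = cfg$n_mels)
  ps_validate(nrow(feats) >= receptive_field(cfg),
              sprintf("input yields %d frames; the TDNN stack needs at least %d",
                      nrow(feats), receptive_field(cfg)))
  h <- unclass(feats)
  for (l in seq_along(cfg$frame_dims)) {
    h <- tdnn_layer(h, cfg$contexts[[l]], weights$frame[[l]]$W,
                    weights$frame[[l]]$b)
  }
  pooled <- statistics_pool(h)
  a1 <- drop(pooled %*% weights$segment[[1L]]$W) + weights$segment[[1L]]$b
  if (tap == "first") return(as.numeric(a1))
  h1 <- pmax(a1, 0)
  as.numeric(drop(h1 %*% weights$segment[[2L]]$W) + weights$segment[[2L]]$b)
}

#' Weight manifest
#'
#' One row per affine layer: name, input and output dimension. Used as the
#' index of the plain-text weight interchange format.
#'
#' @param w \code{extractor_weights}.
#' @return data.frame with columns \code{layer}, \code{dim_in}, \code{dim_out}.
#' @export
weights_manifest <- function(w) {
  validate_extractor_weights(w)
  rows <- c(
    lapply(seq_along(w$frame), function(l) {
      data.frame(layer = sprintf("frame%d", l), dim_in = nrow(w$frame[[l]]$W),
                 dim_out = ncol(w$frame[[l]]$W))
    }),
    lapply(seq_along(w$segment), function(l) {
      data.frame(layer = sprintf("segment%d", l),
                 dim_in = nrow(w$segment[[l]]$W),
                 dim_out = ncol(w$segment[[l]]$W))
    })
  )
  do.call(rbind, rows)
}

#' Export extractor weights to a plain-text directory
#'
#' Writes \code{manifest.tsv} plus one TSV matrix per layer (weights with the
#' bias as the final row), the documented interchange format for externally
#' trained weights.
#'
#' @param w \code{extractor_weights}.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_weights_tsv <- function(w, dir) {
  validate_extractor_weights(w)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- weights_manifest(w)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  all_layers <- c(stats::setNames(w$frame, sprintf("frame%d", seq_along(w$frame))),
                  stats::setNames(w$segment,
                                  sprintf("segment%d", seq_along(w$segment))))
  for (nm in names(all_layers)) {
    m <- rbind(all_layers[[nm]]$W, all_layers[[nm]]$b)
    utils::write.table(format(m, digits = 17), file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(dir)
}

#' Import extractor weights from the plain-text directory format
#'
#' @param dir directory written by \code{\link{export_weights_tsv}} (or an
#'   external exporter following the same manifest).
#' @param config architecture the weights must match.
#' @return validated \code{extractor_weights}.
#' @export
import_weights_tsv <- function(dir, config = xvector_config()) {
  man_path <- file.path(dir, "manifest.tsv")
  ps_input(file.exists(man_path), sprintf("no manifest.tsv in %s", dir))
  man <- utils::read.table(man_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  read_layer <- function(nm) {
    m <- as.matrix(utils::read.table(file.path(dir, paste0(nm, ".tsv")),
                                     sep = "\t", header = FALSE))
    list(W = unname(m[-nrow(m), , drop = FALSE]), b = unname(m[nrow(m), ]))
  }
  frame_names <- grep("^frame", man$layer, value = TRUE)
  seg_names <- grep("^segment", man$layer, value = TRUE)
  w <- structure(list(config = config,
                      frame = lapply(sort(frame_names), read_layer),
                      segment = lapply(sort(seg_names), read_layer),
                      provenance = sprintf("imported(%s)", dir)),
                 class = "extractor_weights")
  validate_extractor_weights(w)
  w
}

#' Save / load extractor weights (binary, runtime only)
#'
#' RDS round-trip is bit-exact; use the TSV format for interchange.
#' @param w \code{extractor_weights}.
#' @param path file path.
#' @return `path` (save) or the weights (load).
#' @export
save_extractor_weights <- function(w, path) {
  validate_extractor_weights(w)
  saveRDS(w, path)
  invisible(path)
}

#' @rdname save_extractor_weights
#' @export
load_extractor_weights <- function(path) {
  w <- readRDS(path)
  validate_extractor_weights(w)
  w
}
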