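# Model persistence: one portable file = a JSON header line (format
# version, shapes, config, class ordering) followed by all parameter blocks
# as little-endian 64-bit floats in a fixed order.

SDAE_FORMAT_VERSION <- 1L

model_blocks <- function(model) {
  blocks <- list()
  for (l in seq_along(model$layers)) {
    lay <- model$layers[[l]]
    blocks[[paste0("layer", l, ".W1")]] <- lay$W1
    blocks[[paste0("layer", l, ".b1")]] <- lay$b1
    blocks[[paste0("layer", l, ".W2")]] <- lay$W2
    blocks[[paste0("layer", l, ".b2")]] <- lay$b2
  }
  if (!is.null(model$head)) {
    blocks[["head.W"]] <- model$head$W
    blocks[["head.b"]] <- model$head$b
  }
  blocks
}

#' Save a stacked model to a single portable file
#'
#' @param model An `sdae` (pretrained or fine-tuned).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_sdae()]
#' @export
save_sdae <- function(model, path) {
  stopifnot(inherits(model, "sdae"))
  blocks <- model_blocks(model)
  header <- list(
    format_version = SDAE_FORMAT_VERSION,
    dims = lapply(blocks, function(b) if (is.matrix(b)) dim(b) else length(b)),
    corruption = vapply(model$layers, `[[`, numeric(1), "corruption"),
    classes = model$classes,
    config = unclass(model$config),
    has_head = !is.null(model$head)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(paste0(jsonlite::toJSON(header, auto_unbox = TRUE, null = "null"), "\n"))
  writeBin(hdr, con)
  for (b in blocks) writeBin(as.numeric(b), con, size = 8, endian = "little")
  invisible(path)
}

#' Load a stacked model saved by [save_sdae()]
#'
#' Validates the format version and that consecutive layer dimensions chain
#' correctly before rebuilding the model.
#'
#' @param path File written by [save_sdae()].
#' @return An `sdae` model.
#' @export
load_sdae <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_bytes <- raw(0)
  repeat {
    byte <- readBin(con, "raw", 1)
    if (!length(byte)) stop_invalid("truncated model file: ", path)
    if (byte == charToRaw("\n")) break
    hdr_bytes <- c(hdr_bytes, byte)
  }
  header <- jsonlite::fromJSON(rawToChar(hdr_bytes), simplifyVector = TRUE)
  if (!identical(as.integer(header$format_version), SDAE_FORMAT_VERSION)) {
    stop_invalid("unsupported model format version: ", header$format_version)
  }
  blocks <- list()
  for (nm in names(header$dims)) {
    d <- header$dims[[nm]]
    vals <- readBin(con, "numeric", prod(d), size = 8, endian = "little")
    if (length(vals) != prod(d)) stop_invalid("truncated model file: ", path)
    blocks[[nm]] <- if (length(d) == 2) matrix(vals, d[1], d[2]) else vals
  }
  n_layers <- length(header$corruption)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    layers[[l]] <- structure(
      list(
        W1 = blocks[[paste0("layer", l, ".W1")]],
        b1 = blocks[[paste0("layer", l, ".b1")]],
        W2 = blocks[[paste0("layer", l, ".W2")]],
        b2 = blocks[[paste0("layer", l, ".b2")]],
        corruption = header$corruption[l]
      ),
      class = "dae_layer"
    )
    if (l > 1 && nrow(layers[[l]]$W1) != ncol(layers[[l - 1]]$W1)) {
      stop_invalid("layer dimension chain broken at layer ", l)
    }
  }
  head <- NULL
  if (isTRUE(header$has_head)) {
    head <- list(W = blocks[["head.W"]], b = blocks[["head.b"]])
    if (nrow(head$W) != ncol(layers[[n_layers]]$W1)) {
      stop_invalid("softmax head does not match the last hidden layer")
    }
  }
  cfg <- header$config
  config <- train_config(
    hidden_sizes = cfg$hidden_sizes, corruption = cfg$corruption,
    pretrain_lr = cfg$pretrain_lr, finetune_lr = cfg$finetune_lr,
    pretrain_epochs = cfg$pretrain_epochs, finetune_epochs = cfg$finetune_epochs,
    batch_size = cfg$batch_size, seed = cfg$seed
  )
  structure(
    list(layers = layers, head = head, classes = header$classes,
         config = config, pretrain_traces = NULL, finetune_trace = NULL),
    class = "sdae"
  )
}
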