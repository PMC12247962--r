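# Cell-level autoencoder: ReLU MLP encoder/decoder with hand-derived
# reverse-mode gradients (no external autodiff).  The encoder output is the
# q-dimensional latent embedding consumed by the GP layer.

#' Autoencoder configuration
#'
#' @param input_dim Number of markers `p`.
#' @param hidden_dims Encoder hidden-layer widths.  Default `16` (one hidden
#'   layer) for cytometry; use `c(256, 64, 16)` for scRNA-seq expression.
#' @param latent_dim Latent dimension `q` (default 4); must satisfy `q < p`.
#' @param seed Seed for weight initialization.
#' @return List of class `ae_config`.
#' @details Hidden layers use ReLU; the output layers of both encoder and
#'   decoder are linear, since targets are real-valued (arcsinh) intensities.
#'   The decoder mirrors the encoder's widths in reverse (no weight tying).
#' @export
ae_config <- function(input_dim, hidden_dims = 16L, latent_dim = 4L,
                      seed = 1L) {
  input_dim <- as.integer(input_dim)
  hidden_dims <- as.integer(hidden_dims)
  latent_dim <- as.integer(latent_dim)
  if (latent_dim >= input_dim) {
    stop("`latent_dim` must be smaller than `input_dim`", call. = FALSE)
  }
  if (any(hidden_dims < 1L)) stop("all hidden widths must be >= 1",
                                  call. = FALSE)
  structure(list(input_dim = input_dim, hidden_dims = hidden_dims,
                 latent_dim = latent_dim, seed = as.integer(seed)),
            class = "ae_config")
}

# one MLP: list of W (in x out) and b; ReLU on all but the last layer
mlp_init <- function(dims, seed) {
  with_seed(seed, {
    layers <- vector("list", length(dims) - 1L)
    for (l in seq_along(layers)) {
      fan_in <- dims[l]
      layers[[l]] <- list(
        W = matrix(stats::rnorm(fan_in * dims[l + 1L], sd = sqrt(1 / fan_in)),
                   fan_in, dims[l + 1L]),
        b = numeric(dims[l + 1L]))
    }
    layers
  })
}

# forward pass; returns output and per-layer caches for backprop
mlp_forward <- function(X, layers, cache = FALSE) {
  A <- X
  caches <- if (cache) vector("list", length(layers)) else NULL
  nl <- length(layers)
  for (l in seq_len(nl)) {
    Zl <- A %*% layers[[l]]$W
    Zl <- sweep(Zl, 2L, layers[[l]]$b, "+")
    if (cache) caches[[l]] <- list(input = A, pre = Zl)
    A <- if (l < nl) pmax(Zl, 0) else Zl
  }
  list(out = A, caches = caches)
}

# backward pass: dOut is gradient wrt the MLP output.
# Returns gradients per layer plus the gradient wrt the input matrix.
mlp_backward <- function(dOut, layers, caches) {
  nl <- length(layers)
  grads <- vector("list", nl)
  delta <- dOut
  for (l in rev(seq_len(nl))) {
    if (l < nl) delta <- delta * (caches[[l]]$pre > 0)
    grads[[l]] <- list(W = crossprod(caches[[l]]$input, delta),
                       b = colSums(delta))
    delta <- delta %*% t(layers[[l]]$W)
  }
  list(layers = grads, input = delta)
}

# flatten/unflatten MLP params for the Adam helper
mlp_flatten <- function(layers, prefix) {
  out <- list()
  for (l in seq_along(layers)) {
    out[[paste0(prefix, "W", l)]] <- layers[[l]]$W
    out[[paste0(prefix, "b", l)]] <- layers[[l]]$b
  }
  out
}
mlp_unflatten <- function(flat, layers, prefix) {
  for (l in seq_along(layers)) {
    layers[[l]]$W <- flat[[paste0(prefix, "W", l)]]
    layers[[l]]$b <- flat[[paste0(prefix, "b", l)]]
  }
  layers
}

#' Initialize autoencoder parameters
#'
#' @param config An [ae_config()].
#' @return List of class `ae_params` with `encoder` and `decoder` layer
#'   lists (decoder widths are the encoder's reversed) and the config.
#' @export
ae_init <- function(config) {
  enc_dims <- c(config$input_dim, config$hidden_dims, config$latent_dim)
  dec_dims <- rev(enc_dims)
  structure(list(
    encoder = mlp_init(enc_dims, config$seed),
    decoder = mlp_init(dec_dims, config$seed + 1L),
    config = config), class = "ae_params")
}

#' Encode cells into the latent space
#'
#' A cell-wise map: row `i` of the output depends only on row `i` of the
#' input, so the embedding is invariant to cell order.
#'
#' @param X Cells x p matrix (or [cell_matrix()]).
#' @param params An [ae_init()]/[pretrain()] result.
#' @return Cells x q matrix of latent embeddings.
#' @export
encode <- function(X, params) {
  if (inherits(X, "cell_matrix")) X <- X$values
  X <- as.matrix(X)
  if (ncol(X) != params$config$input_dim) {
    stop(sprintf("expected %d input columns, got %d",
                 params$config$input_dim, ncol(X)), call. = FALSE)
  }
  if (nrow(X) == 0L) return(matrix(numeric(0), 0L, params$config$latent_dim))
  mlp_forward(X, params$encoder)$out
}

#' Decode latent embeddings back to marker space
#'
#' @param H Cells x q latent matrix.
#' @param params An `ae_params` object.
#' @return Cells x p reconstruction.
#' @export
decode <- function(H, params) {
  H <- as.matrix(H)
  if (ncol(H) != params$config$latent_dim) {
    stop(sprintf("expected %d latent columns, got %d",
                 params$config$latent_dim, ncol(H)), call. = FALSE)
  }
  if (nrow(H) == 0L) return(matrix(numeric(0), 0L, params$config$input_dim))
  mlp_forward(H, params$decoder)$out
}

#' Pretrain the autoencoder by reconstruction
#'
#' Minimizes the mean squared reconstruction error
#' `(1/M) * sum_i ||x_i - x~_i||^2` over all cells pooled across subjects and
#' timepoints, with Adam.  No outcome labels are used at this stage, so the
#' vast cell count compensates for small subject numbers.
#'
#' @param X M x p matrix of all (preprocessed) cells.
#' @param config An [ae_config()].
#' @param epochs,batch_size,lr Optimization settings.  Defaults follow the
#'   cytometry schedule (1000 epochs, batch 128, learning rate 1e-6); for
#'   scRNA-seq use 200 epochs, batch 256, lr 1e-3.  Pass `batch_size >= M`
#'   for full-batch training.
#' @param seed Seed controlling initialization and batch shuffling.
#' @return An `ae_params` object with a `history` attribute: the mean squared
#'   reconstruction loss per epoch.
#' @export
pretrain <- function(X, config, epochs = 1000L, batch_size = 128L,
                     lr = 1e-6, seed = config$seed) {
  X <- as.matrix(X)
  M <- nrow(X)
  if (M < 1L) stop("pretraining needs at least one cell", call. = FALSE)
  config$seed <- as.integer(seed)
  params <- ae_init(config)
  flat <- c(mlp_flatten(params$encoder, "enc_"),
            mlp_flatten(params$decoder, "dec_"))
  opt <- adam_init(flat)
  history <- numeric(epochs)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- if (batch_size < M) sample.int(M) else seq_len(M)
      starts <- seq(1L, M, by = batch_size)
      ep_loss <- 0
      for (st in starts) {
        idx <- ord[st:min(st + batch_size - 1L, M)]
        Xb <- X[idx, , drop = FALSE]
        enc <- mlp_forward(Xb, params$encoder, cache = TRUE)
        dec <- mlp_forward(enc$out, params$decoder, cache = TRUE)
        R <- dec$out - Xb
        loss <- sum(R * R) / nrow(Xb)
        if (!is.finite(loss)) {
          stop("pretraining diverged (non-finite loss); try a smaller lr",
               call. = FALSE)
        }
        ep_loss <- ep_loss + loss * nrow(Xb)
        dRec <- 2 * R / nrow(Xb)
        bdec <- mlp_backward(dRec, params$decoder, dec$caches)
        benc <- mlp_backward(bdec$input, params$encoder, enc$caches)
        grads <- c(stats::setNames(
          unlist(lapply(benc$layers, function(g) list(g$W, g$b)),
                 recursive = FALSE),
          names(mlp_flatten(params$encoder, "enc_"))),
          stats::setNames(
            unlist(lapply(bdec$layers, function(g) list(g$W, g$b)),
                   recursive = FALSE),
            names(mlp_flatten(params$decoder, "dec_"))))
        upd <- adam_step(flat, grads, opt, lr)
        flat <- upd$params; opt <- upd$state
        params$encoder <- mlp_unflatten(flat, params$encoder, "enc_")
        params$decoder <- mlp_unflatten(flat, params$decoder, "dec_")
      }
      history[ep] <- ep_loss / M
    }
  })
  attr(params, "history") <- history
  params
}

#' Mean squared reconstruction error
#'
#' @param X Cells x p matrix.
#' @param params An `ae_params` object.
#' @return `(1/M) * sum_i ||x_i - x~_i||^2`.
#' @export
reconstruction_error <- function(X, params) {
  X <- as.matrix(X)
  R <- decode(encode(X, params), params) - X
  sum(R * R) / nrow(X)
}
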