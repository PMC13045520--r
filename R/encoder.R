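## Hybrid encoder configuration and the standalone token operations.
##
## The encoder is a three-layer convolutional stem (3x3 conv + batch norm +
## ReLU, 2x2 max-pooling between the layers, total downsampling 4x),
## followed by tokenization of the stem output into non-overlapping P x P
## patches, a learned linear projection E plus position embeddings E_pos
## (z0 = [x_p^1 E; ...; x_p^N E] + E_pos), n pre-norm transformer layers
## (z'_l = MSA(LN(z_{l-1})) + z_{l-1}; z_l = MLP(LN(z'_l)) + z'_l) and a
## row-major reshape of the N tokens back to an (H/P) x (W/P) x D grid.

#' Encoder configuration
#'
#' @param stemChannels three channel counts for the convolutional stem.
#' @param patchSize patch side P in pixels of the stem output (16 for the
#'   speech configuration).
#' @param embedDim transformer embedding dimension D.
#' @param depth number n of transformer layers.
#' @param heads attention heads (must divide `embedDim`).
#' @param mlpDim hidden width of the transformer MLP block.
#' @return A list of class `"EncoderConfig"`.
#' @export
encoderConfig <- function(stemChannels = c(64, 128, 256), patchSize = 16,
                          embedDim = 768, depth = 12, heads = 12,
                          mlpDim = 3072) {
  stopifnot(length(stemChannels) == 3, all(stemChannels >= 1),
            patchSize >= 1, embedDim >= 1, depth >= 0, heads >= 1,
            mlpDim >= 1)
  if (embedDim %% heads != 0) stop("embedDim must be divisible by heads")
  if (patchSize > 1 && bitwAnd(patchSize, patchSize - 1L) != 0)
    stop("patchSize must be a power of 2")
  structure(list(stemChannels = as.integer(stemChannels),
                 patchSize = as.integer(patchSize),
                 embedDim = as.integer(embedDim),
                 depth = as.integer(depth), heads = as.integer(heads),
                 mlpDim = as.integer(mlpDim)),
            class = "EncoderConfig")
}

#' Speech-configuration encoder (P = 16, ViT-Base-sized transformer)
#' @return An `"EncoderConfig"` with P = 16, D = 768, 12 layers, 12 heads.
#' @export
speechEncoderConfig <- function() encoderConfig()

#' Desk-scale encoder for tests and smoke runs
#' @return An `"EncoderConfig"` with D = 64, 2 layers, 4 heads, P = 4.
#' @export
tinyEncoderConfig <- function()
  encoderConfig(stemChannels = c(8, 16, 32), patchSize = 4, embedDim = 64,
                depth = 2, heads = 4, mlpDim = 128)

#' Tokenize a feature grid into patch embeddings
#'
#' Flattens non-overlapping P x P patches of `features` (row-major over the
#' patch grid), applies the linear projection `E` and adds the position
#' embeddings: z0 = [x_p^1 E; ...; x_p^N E] + E_pos.
#'
#' @param features numeric array h x w x C (or h x w).
#' @param patchSize patch side P; h and w must be divisible by it.
#' @param E projection matrix (P^2 C) x D; `NULL` gives the identity
#'   (D = P^2 C).
#' @param Epos N x D position embedding; `NULL` adds zeros.
#' @return N x D numeric matrix of tokens with attribute `"patchGrid"` =
#'   c(h/P, w/P).
#' @export
tokenize <- function(features, patchSize, E = NULL, Epos = NULL) {
  if (length(dim(features)) == 2) dim(features) <- c(dim(features), 1L)
  x <- features; dim(x) <- c(dim(features), 1L)
  pf <- patchify_fwd(x, patchSize)
  tok <- pf$y[, , 1, drop = FALSE]
  dim(tok) <- dim(pf$y)[1:2]
  if (!is.null(E)) {
    if (nrow(E) != ncol(tok))
      stop(sprintf("E must have %d rows", ncol(tok)))
    tok <- tok %*% E
  }
  if (!is.null(Epos)) {
    if (!all(dim(Epos) == dim(tok))) stop("Epos dims must match tokens")
    tok <- tok + Epos
  }
  structure(tok, patchGrid = c(pf$cache$hp, pf$cache$wp))
}

#' Reshape a token sequence back to a spatial grid
#'
#' Inverse of the row-major patch flattening: token t = (i-1)*wp + j maps
#' to grid cell (i, j).
#'
#' @param tokens N x D matrix; its `"patchGrid"` attribute (or `gridDims`)
#'   supplies (hp, wp) with hp*wp = N.
#' @param gridDims optional c(hp, wp) overriding the attribute.
#' @return hp x wp x D numeric array.
#' @export
reshapeTokens <- function(tokens, gridDims = attr(tokens, "patchGrid")) {
  if (is.null(gridDims)) stop("token patch-grid dims unknown")
  hp <- gridDims[1]; wp <- gridDims[2]
  if (hp * wp != nrow(tokens))
    stop(sprintf("N = %d does not match %dx%d patch grid",
                 nrow(tokens), hp, wp))
  tok3 <- array(tokens, c(nrow(tokens), ncol(tokens), 1L))
  g <- tok2grid(tok3, hp, wp)
  array(g, dim(g)[1:3])
}

# parameter initialisation for one transformer layer
.init_tf_layer <- function(D, mlpDim, prefix) {
  p <- list()
  p[[paste0(prefix, ".ln1.g")]] <- rep(1, D)
  p[[paste0(prefix, ".ln1.b")]] <- rep(0, D)
  for (nm in c("Wq", "Wk", "Wv", "Wo"))
    p[[paste0(prefix, ".", nm)]] <- matrix(.truncnorm(D * D), D, D)
  for (nm in c("bq", "bk", "bv", "bo"))
    p[[paste0(prefix, ".", nm)]] <- rep(0, D)
  p[[paste0(prefix, ".ln2.g")]] <- rep(1, D)
  p[[paste0(prefix, ".ln2.b")]] <- rep(0, D)
  p[[paste0(prefix, ".W1")]] <- matrix(.truncnorm(D * mlpDim), D, mlpDim)
  p[[paste0(prefix, ".b1")]] <- rep(0, mlpDim)
  p[[paste0(prefix, ".W2")]] <- matrix(.truncnorm(mlpDim * D), mlpDim, D)
  p[[paste0(prefix, ".b2")]] <- rep(0, D)
  p
}

# one transformer layer forward on [N,D,B]; pre-norm residual form
.tf_layer_fwd <- function(tok, params, prefix, heads) {
  P <- function(nm) params[[paste0(prefix, ".", nm)]]
  l1 <- ln_fwd(tok, P("ln1.g"), P("ln1.b"))
  at <- msa_fwd(l1$y, list(Wq = P("Wq"), Wk = P("Wk"), Wv = P("Wv"),
                           Wo = P("Wo"), bq = P("bq"), bk = P("bk"),
                           bv = P("bv"), bo = P("bo")), heads)
  z1 <- tok + at$y
  l2 <- ln_fwd(z1, P("ln2.g"), P("ln2.b"))
  f1 <- lin_fwd(l2$y, P("W1"), P("b1"))
  ac <- gelu_fwd(f1$y)
  f2 <- lin_fwd(ac$y, P("W2"), P("b2"))
  y <- z1 + f2$y
  list(y = y, cache = list(l1 = l1$cache, at = at$cache, l2 = l2$cache,
                           f1 = f1$cache, ac = ac$cache, f2 = f2$cache))
}

.tf_layer_bwd <- function(dy, cache, params, prefix, heads) {
  P <- function(nm) params[[paste0(prefix, ".", nm)]]
  g <- list()
  G <- function(nm, val) g[[paste0(prefix, ".", nm)]] <<- val
  b2 <- lin_bwd(dy, cache$f2)
  G("W2", b2$dW); G("b2", b2$db)
  dac <- gelu_bwd(b2$dx, cache$ac)
  b1 <- lin_bwd(dac, cache$f1)
  G("W1", b1$dW); G("b1", b1$db)
  l2 <- ln_bwd(b1$dx, cache$l2)
  G("ln2.g", l2$dgamma); G("ln2.b", l2$dbeta)
  dz1 <- dy + l2$dx
  at <- msa_bwd(dz1, cache$at, list(Wq = P("Wq"), Wk = P("Wk"),
                                    Wv = P("Wv"), Wo = P("Wo"),
                                    bq = P("bq"), bk = P("bk"),
                                    bv = P("bv"), bo = P("bo")))
  for (nm in names(at$grads)) G(nm, at$grads[[nm]])
  l1 <- ln_bwd(at$dx, cache$l1)
  G("ln1.g", l1$dgamma); G("ln1.b", l1$dbeta)
  list(dx = dz1 + l1$dx, grads = g)
}

#' Run a stack of transformer layers over a token sequence
#'
#' Applies n pre-norm layers z'_l = MSA(LN(z_{l-1})) + z_{l-1};
#' z_l = MLP(LN(z'_l)) + z'_l. With `depth = 0` this is the identity.
#'
#' @param tokens N x D matrix (attributes preserved).
#' @param model a model built by [buildModel()], or `NULL` with
#'   `params`/`config` given explicitly (internal use).
#' @return N x D matrix of encoded tokens.
#' @export
transformerForward <- function(tokens, model) {
  cfg <- model$encoderConfig
  tok3 <- array(tokens, c(nrow(tokens), ncol(tokens), 1L))
  for (l in seq_len(cfg$depth))
    tok3 <- .tf_layer_fwd(tok3, model$params, paste0("tf", l), cfg$heads)$y
  out <- matrix(tok3, nrow(tokens), ncol(tokens))
  attributes(out) <- attributes(tokens)
  out
}
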