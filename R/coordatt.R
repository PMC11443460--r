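#' @include AllClasses.R AllGenerics.R
NULL

.sigmoid <- function(x) 1 / (1 + exp(-x))
.relu <- function(x) pmax(x, 0)

#' Construct coordinate-attention weights
#'
#' `caWeights()` wraps explicit matrices; `caWeightsZero()` builds an
#' all-zero set for a given channel count, handy as a fixture (zero logits
#' make both attention maps 0.5 everywhere, so the block scales its input by
#' 0.25); `caWeightsRandom()` draws small random weights reproducibly.
#'
#' @param reduce `(C/r) x C` reduction matrix.
#' @param expandH,expandW `C x (C/r)` expansion matrices for the height and
#'   width attention paths.
#' @param reduceBias,expandHBias,expandWBias biases (default zero).
#' @param r reduction ratio (default 32; must divide `C`).
#' @param C channel count for the zero/random constructors.
#' @param seed RNG seed for `caWeightsRandom()`.
#' @param sd weight scale for `caWeightsRandom()`.
#' @return A [CAWeights-class].
#' @export
caWeights <- function(reduce, expandH, expandW,
                      reduceBias = numeric(nrow(reduce)),
                      expandHBias = numeric(nrow(expandH)),
                      expandWBias = numeric(nrow(expandW)),
                      r = 32L) {
  new("CAWeights", reduce = reduce, reduceBias = reduceBias,
      expandH = expandH, expandW = expandW,
      expandHBias = expandHBias, expandWBias = expandWBias,
      r = as.integer(r))
}

#' @rdname caWeights
#' @export
caWeightsZero <- function(C, r = 32L) {
  if (C %% r != 0L) stop("r must divide the channel count C")
  cr <- C %/% r
  caWeights(matrix(0, cr, C), matrix(0, C, cr), matrix(0, C, cr), r = r)
}

#' @rdname caWeights
#' @export
caWeightsRandom <- function(C, r = 32L, seed = 1L, sd = 0.1) {
  if (C %% r != 0L) stop("r must divide the channel count C")
  cr <- C %/% r
  set.seed(seed)
  caWeights(
    matrix(stats::rnorm(cr * C, sd = sd), cr, C),
    matrix(stats::rnorm(C * cr, sd = sd), C, cr),
    matrix(stats::rnorm(C * cr, sd = sd), C, cr),
    reduceBias = stats::rnorm(cr, sd = sd),
    expandHBias = stats::rnorm(C, sd = sd),
    expandWBias = stats::rnorm(C, sd = sd),
    r = r)
}

setMethod("show", "CAWeights", function(object) {
  cat(sprintf("CAWeights: C = %d, r = %d (reduced to %d channels)\n",
              ncol(object@reduce), object@r, nrow(object@reduce)))
})

#' Forward pass of the coordinate-attention block
#'
#' Channel attention that keeps positional information by pooling the input
#' separately along width and along height. The input is mean-pooled along
#' width into a per-(channel, row) profile and along height into a
#' per-(channel, column) profile; the two profiles are concatenated along
#' the spatial axis, passed through the shared reduction transform and a
#' ReLU, split back, expanded per path, and squashed with a logistic to give
#' attention maps `a_h` (C x H) and `a_w` (C x W) in `[0, 1]`. The output is
#' `x[c, i, j] * a_h[c, i] * a_w[c, j]` -- same shape as the input, never
#' larger in magnitude. Batch normalisation is omitted: weights are
#' injected, never trained here.
#'
#' @param x numeric array of dimension `(C, H, W)` with finite values.
#' @param w a [CAWeights-class] whose channel count matches `x`.
#' @return List with `output` (array, same shape as `x`), `ah` (`C x H`) and
#'   `aw` (`C x W`) attention maps.
#' @examples
#' x <- array(runif(4 * 3 * 5), dim = c(4, 3, 5))
#' res <- coordinateAttention(x, caWeightsZero(4, r = 2))
#' all.equal(res$output, 0.25 * x)
#' @export
setMethod("coordinateAttention", signature("array", "CAWeights"), function(x, w) {
  d <- dim(x)
  if (length(d) != 3L) stop("x must be a (channel, height, width) array")
  C <- d[1L]; H <- d[2L]; W <- d[3L]
  if (ncol(w@reduce) != C)
    stop(sprintf("weights expect %d channels but x has %d", ncol(w@reduce), C))
  if (any(!is.finite(x))) stop("x must contain only finite values")

  pooledH <- apply(x, c(1, 2), mean)              # C x H, mean over width
  pooledW <- apply(x, c(1, 3), mean)              # C x W, mean over height

  joint <- cbind(pooledH, pooledW)                # C x (H + W)
  mid <- .relu(w@reduce %*% joint + w@reduceBias) # (C/r) x (H + W)

  ah <- .sigmoid(w@expandH %*% mid[, seq_len(H), drop = FALSE] + w@expandHBias)
  aw <- .sigmoid(w@expandW %*% mid[, H + seq_len(W), drop = FALSE] + w@expandWBias)

  ahFull <- array(ah, dim = c(C, H, W))             # ah[c, i] broadcast over j
  awFull <- aperm(array(aw, dim = c(C, W, H)), c(1, 3, 2))  # aw[c, j] over i
  list(output = x * ahFull * awFull, ah = ah, aw = aw)
})
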