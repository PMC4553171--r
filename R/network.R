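#' Feed-forward network topology
#'
#' A single-hidden-layer architecture `n_in`-`n_hidden`-`n_out` with
#' hyperbolic-tangent hidden units and a linear output unit.  The benchmark
#' uses 4 inputs and 1 output, so the topology is written 4-N-1.
#'
#' @param n_in Number of inputs (default 4).
#' @param n_hidden Number of hidden neurons.
#' @param n_out Number of outputs (fixed at 1).
#' @return An object of class `"nn_topology"`.
#' @export
nn_topology <- function(n_in = 4, n_hidden = 6, n_out = 1) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out == 1)
  structure(list(n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
                 n_out = as.integer(n_out)),
            class = "nn_topology")
}

#' @rdname nn_topology
#' @param topology An `"nn_topology"`.
#' @return `nn_n_params` returns the flat parameter count
#'   `n_in*n_hidden + n_hidden + n_hidden*n_out + n_out`.
#' @export
nn_n_params <- function(topology) {
  with(topology, n_in * n_hidden + n_hidden + n_hidden * n_out + n_out)
}

# index map into the flat parameter vector; ordering convention:
# [hidden weights (row per hidden neuron, input-major within a row),
#  hidden biases, output weights, output bias]
nn_index <- function(topology) {
  ni <- topology$n_in; nh <- topology$n_hidden
  wh_end <- ni * nh
  list(wh = seq_len(wh_end),
       bh = wh_end + seq_len(nh),
       wo = wh_end + nh + seq_len(nh),
       bo = wh_end + 2L * nh + 1L)
}

#' Pack / unpack network parameters
#'
#' `nn_unpack` splits a flat parameter vector into structured weights and
#' biases; `nn_pack` is its inverse.  The flat ordering is: hidden weight
#' matrix (one row per hidden neuron), hidden biases, output weights, output
#' bias.  This convention is shared by the swarm optimizer, checkpoints and
#' tests so that parameter vectors agree bit-for-bit.
#'
#' @param theta Flat numeric parameter vector.
#' @param topology An [nn_topology()].
#' @return `nn_unpack`: a list with `Wh` (n_hidden x n_in matrix), `bh`,
#'   `wo`, `bo`.  `nn_pack`: the flat vector.
#' @export
nn_unpack <- function(theta, topology) {
  if (length(theta) != nn_n_params(topology))
    stop("parameter vector has length ", length(theta), ", expected ",
         nn_n_params(topology))
  ix <- nn_index(topology)
  list(Wh = matrix(theta[ix$wh], topology$n_hidden, topology$n_in,
                   byrow = TRUE),
       bh = theta[ix$bh], wo = theta[ix$wo], bo = theta[ix$bo])
}

#' @rdname nn_unpack
#' @param parts A list as returned by `nn_unpack`.
#' @export
nn_pack <- function(parts, topology) {
  theta <- c(as.numeric(t(parts$Wh)), parts$bh, parts$wo, parts$bo)
  if (length(theta) != nn_n_params(topology))
    stop("structured parameters do not match the topology")
  theta
}

#' Hyperbolic-tangent sigmoid activation
#'
#' The hidden-unit transfer function `(e^v - e^-v) / (e^v + e^-v)`, evaluated
#' through `tanh()` so it saturates to +/-1 for large `|v|` without overflow.
#'
#' @param v Numeric input (vectorized).
#' @export
tansig <- function(v) tanh(v)

#' Forward pass of the network
#'
#' Evaluates `bo + sum_j wo_j * tansig(bh_j + sum_i Wh[j,i] * p_i)` for one
#' or many input patterns.  Inputs are expected on the normalized scale.
#'
#' @param theta Flat parameter vector.
#' @param topology An [nn_topology()].
#' @param inputs A numeric vector of length `n_in`, or a matrix with `n_in`
#'   columns (one row per pattern).
#' @return Numeric vector of outputs, one per pattern.
#' @export
nn_forward <- function(theta, topology, inputs) {
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1L)
  if (ncol(inputs) != topology$n_in)
    stop("input has ", ncol(inputs), " columns, expected ", topology$n_in)
  p <- nn_unpack(theta, topology)
  H <- tansig(sweep(inputs %*% t(p$Wh), 2L, p$bh, `+`))
  as.numeric(H %*% p$wo + p$bo)
}

# batched forward pass over many parameter vectors at once (the swarm
# fitness hot path, implemented in C++).
# Theta: n_params x n_particles matrix; returns n_patterns x n_particles.
nn_forward_batch <- function(Theta, topology, inputs) {
  if (nrow(Theta) != nn_n_params(topology))
    stop("parameter matrix has ", nrow(Theta), " rows, expected ",
         nn_n_params(topology))
  if (ncol(inputs) != topology$n_in)
    stop("input has ", ncol(inputs), " columns, expected ", topology$n_in)
  .cpp_forward_batch(Theta, inputs, topology$n_hidden)
}

# per-dimension search-space bounds: weights in [-wb, wb], biases in [-bb, bb]
nn_bounds <- function(topology, weight_bound = 100, bias_bound = 10) {
  ix <- nn_index(topology)
  b <- numeric(nn_n_params(topology))
  b[c(ix$wh, ix$wo)] <- weight_bound
  b[c(ix$bh, ix$bo)] <- bias_bound
  b
}

#' Random network initialization
#'
#' Draws each weight uniformly from the weight box `[-100, 100]` and each
#' bias from `[-10, 10]` (the swarm search box), deterministically for a
#' given seed.
#'
#' @param topology An [nn_topology()].
#' @param seed Optional integer seed.
#' @param weight_bound,bias_bound Half-widths of the uniform boxes.
#' @return A flat parameter vector.
#' @export
nn_init <- function(topology, seed = NULL, weight_bound = 100,
                    bias_bound = 10) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  b <- nn_bounds(topology, weight_bound, bias_bound)
  stats::runif(length(b), -b, b)
}
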