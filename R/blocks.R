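# Block-structured containers for brain states and transitions.
#
# The observed brain state x_k is not a single matrix but four labeled
# correlation blocks derived from the 7-channel montage:
#   mc     3x3  motor-cortex subnetwork            (C3, Cz, C4)
#   loc    4x4  left-occipital subnetwork          (P7, Pz, PO3, Oz)
#   mc_loc 3x4  motor-to-occipital cross block     (rows MC, cols LOC)
#   mnet   3x3  mesoscale network over pooled regions (LMC, RMC, LOC)
#
# A transition A maps x_(k-1) to x_k block-wise by left multiplication,
# so the mc_loc transition block is 3x3 (it acts on the 3x4 cross block
# from the left).

MC_CHANNELS  <- c("C3", "Cz", "C4")
LOC_CHANNELS <- c("P7", "Pz", "PO3", "Oz")
MNET_REGIONS <- c("LMC", "RMC", "LOC")

OBS_BLOCK_DIMS <- list(mc = c(3L, 3L), loc = c(4L, 4L),
                       mc_loc = c(3L, 4L), mnet = c(3L, 3L))
TRANS_BLOCK_DIMS <- list(mc = c(3L, 3L), loc = c(4L, 4L),
                         mc_loc = c(3L, 3L), mnet = c(3L, 3L))
BLOCK_NAMES <- c("mc", "loc", "mc_loc", "mnet")

block_dimnames <- function(block, transition = FALSE) {
  switch(block,
    mc = list(MC_CHANNELS, MC_CHANNELS),
    loc = list(LOC_CHANNELS, LOC_CHANNELS),
    mc_loc = if (transition) list(MC_CHANNELS, MC_CHANNELS)
             else list(MC_CHANNELS, LOC_CHANNELS),
    mnet = list(MNET_REGIONS, MNET_REGIONS))
}

check_blocks <- function(blocks, dims, what) {
  for (b in BLOCK_NAMES) {
    m <- blocks[[b]]
    if (is.null(m)) stopf("%s: missing block '%s'", what, b)
    if (!is.matrix(m) || !identical(dim(m), dims[[b]]))
      stopf("%s: block '%s' must be a %dx%d matrix", what, b,
            dims[[b]][1], dims[[b]][2])
    if (!all(is.finite(m)))
      stopf("%s: block '%s' has non-finite entries", what, b)
  }
  invisible(blocks)
}

#' Brain-state observation matrix
#'
#' Bundles the four correlation blocks that make up one observed brain
#' state x_k: the MC, LOC and MC-LOC subnetworks of the full 7-channel
#' Spearman network plus the mesoscale network over pooled regions.
#'
#' @param mc 3x3 motor-cortex block.
#' @param loc 4x4 left-occipital block.
#' @param mc_loc 3x4 cross block (MC rows, LOC columns).
#' @param mnet 3x3 mesoscale block (LMC, RMC, LOC).
#' @return an object of class `observation_matrix`.
#' @export
observation_matrix <- function(mc, loc, mc_loc, mnet) {
  blocks <- lapply(list(mc = mc, loc = loc, mc_loc = mc_loc, mnet = mnet),
                   function(m) {
                     m <- as.matrix(m)
                     storage.mode(m) <- "double"
                     m
                   })
  check_blocks(blocks, OBS_BLOCK_DIMS, "observation_matrix")
  for (b in BLOCK_NAMES)
    dimnames(blocks[[b]]) <- block_dimnames(b, transition = FALSE)
  structure(blocks, class = "observation_matrix")
}

#' Brain-state transition matrix
#'
#' Block-structured linear map A carrying x_(k-1) to x_k. Every block
#' left-multiplies the matching observation block, so the mc_loc block is
#' a 3x3 map acting on the rectangular 3x4 cross block.
#'
#' @param mc,loc,mc_loc,mnet numeric blocks (3x3, 4x4, 3x3, 3x3).
#' @return an object of class `transition_matrix`.
#' @export
transition_matrix <- function(mc, loc, mc_loc, mnet) {
  blocks <- lapply(list(mc = mc, loc = loc, mc_loc = mc_loc, mnet = mnet),
                   function(m) {
                     m <- as.matrix(m)
                     storage.mode(m) <- "double"
                     m
                   })
  check_blocks(blocks, TRANS_BLOCK_DIMS, "transition_matrix")
  for (b in BLOCK_NAMES)
    dimnames(blocks[[b]]) <- block_dimnames(b, transition = TRUE)
  structure(blocks, class = "transition_matrix")
}

#' Apply a transition to an observation
#'
#' Computes `A %*% x` block-wise.
#'
#' @param A a `transition_matrix`.
#' @param x an `observation_matrix`.
#' @return an `observation_matrix`.
#' @export
apply_transition <- function(A, x) {
  stopifnot(inherits(A, "transition_matrix"), inherits(x, "observation_matrix"))
  observation_matrix(A$mc %*% x$mc, A$loc %*% x$loc,
                     A$mc_loc %*% x$mc_loc, A$mnet %*% x$mnet)
}

# Element-wise arithmetic over the four blocks (used for noise injection,
# bias handling and denoising).
block_map <- function(x, y = NULL, f) {
  out <- lapply(BLOCK_NAMES, function(b) {
    if (is.null(y)) f(x[[b]]) else f(x[[b]], y[[b]])
  })
  names(out) <- BLOCK_NAMES
  structure(out, class = class(x))
}

obs_add <- function(x, y) block_map(x, y, `+`)
obs_sub <- function(x, y) block_map(x, y, `-`)
obs_scale <- function(x, s) block_map(x, f = function(m) m * s)
obs_clip <- function(x, lo = -1, hi = 1) block_map(x, f = function(m) clamp(m, lo, hi))

#' Zero-valued observation-shaped blocks
#'
#' Used to initialize process-noise states and session biases.
#' @return an `observation_matrix` with all entries 0 (class retained;
#'   note a zero state is not a valid correlation matrix, it is a
#'   noise/bias container).
#' @export
zero_observation <- function() {
  structure(lapply(OBS_BLOCK_DIMS, function(d) matrix(0, d[1], d[2])),
            class = "observation_matrix")
}

#' Linearize a transition matrix
#'
#' Deterministic row-major concatenation mc, loc, mc_loc, mnet giving a
#' weight vector of length 9 + 16 + 9 + 9 = 43. This fixed layout is the
#' coordinate system for the covariance loss and all weight-wise
#' statistics.
#'
#' @param A a `transition_matrix`.
#' @return numeric vector of length 43, named `block:row:col`.
#' @export
linearize <- function(A) {
  stopifnot(inherits(A, "transition_matrix"))
  unlist(lapply(BLOCK_NAMES, function(b) {
    m <- A[[b]]
    v <- as.vector(t(m))  # row-major
    dn <- dimnames(m)
    names(v) <- as.vector(t(outer(dn[[1]], dn[[2]],
                                  function(r, c) paste(b, r, c, sep = ":"))))
    v
  }), use.names = TRUE)
}

#' Rebuild a transition matrix from its 43-vector
#'
#' Inverse of [linearize()].
#' @param v numeric vector of length 43.
#' @return a `transition_matrix`.
#' @export
delinearize <- function(v) {
  if (length(v) != 43L) stopf("delinearize: expected length 43, got %d", length(v))
  at <- 0L
  blocks <- lapply(TRANS_BLOCK_DIMS, function(d) {
    n <- d[1] * d[2]
    m <- matrix(v[(at + 1L):(at + n)], d[1], d[2], byrow = TRUE)
    at <<- at + n
    m
  })
  transition_matrix(blocks$mc, blocks$loc, blocks$mc_loc, blocks$mnet)
}

# Table describing the linearized layout: block and row/col labels per
# position; used by the weight-wise statistics to label results.
linearize_layout <- function() {
  rows <- do.call(rbind, lapply(BLOCK_NAMES, function(b) {
    dn <- block_dimnames(b, transition = TRUE)
    expand_rows <- expand.grid(col = dn[[2]], row = dn[[1]],
                               stringsAsFactors = FALSE)[, c("row", "col")]
    # expand.grid varies the first factor fastest; with col first we get
    # row-major order matching linearize().
    data.frame(block = b, expand_rows, stringsAsFactors = FALSE)
  }))
  rows$position <- seq_len(nrow(rows))
  rows
}

# Linearize an observation's blocks (length 9+16+12+9 = 46); used by the
# raw-network KNN baseline and session-bias estimation.
linearize_observation <- function(x) {
  stopifnot(inherits(x, "observation_matrix"))
  unlist(lapply(BLOCK_NAMES, function(b) as.vector(t(x[[b]]))), use.names = FALSE)
}

delinearize_observation <- function(v) {
  if (length(v) != 46L)
    stopf("delinearize_observation: expected length 46, got %d", length(v))
  at <- 0L
  blocks <- lapply(OBS_BLOCK_DIMS, function(d) {
    n <- d[1] * d[2]
    m <- matrix(v[(at + 1L):(at + n)], d[1], d[2], byrow = TRUE)
    at <<- at + n
    m
  })
  structure(blocks, class = "observation_matrix")
}

#' @export
print.observation_matrix <- function(x, ...) {
  cat("<observation_matrix> blocks: mc 3x3, loc 4x4, mc_loc 3x4, mnet 3x3\n")
  invisible(x)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> blocks: mc 3x3, loc 4x4, mc_loc 3x3, mnet 3x3\n")
  invisible(x)
}
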