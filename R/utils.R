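#' @keywords internal
"_PACKAGE"

# Canonical 7-channel montage shared by every module. Order is fixed:
# downstream block extraction and linearization depend on it.
CANONICAL_CHANNELS <- c("C3", "Cz", "C4", "P7", "Pz", "PO3", "Oz")

`%||%` <- function(a, b) if (is.null(a)) b else a

frob <- function(m) sqrt(sum(m^2))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Moore-Penrose pseudoinverse
#'
#' Minimum-norm least-squares inverse via SVD, used wherever a transition
#' block is solved from a (possibly rank-deficient) state block.
#'
#' @param m numeric matrix.
#' @param tol singular values below `tol * max(d)` are treated as zero.
#' @return matrix of dimension `ncol(m) x nrow(m)`.
#' @export
pinv <- function(m, tol = .Machine$double.eps * 100) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, .Machine$double.xmin)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Derive a reproducible child seed from a parent seed and a stream index.
# Kept below 2^31 so the result is a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
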