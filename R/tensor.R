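#' Khatri-Rao product (column-wise Kronecker product)
#'
#' Column \code{j} of the result is \code{kronecker(A[, j], B[, j])}: the row
#' block structure has A's row index varying slowest and B's fastest. This is
#' the ordering used by all three cube unfoldings in this package, so that the
#' mode-m unfolding of a CP model equals \code{khatri_rao(...) \%*\% t(Fm)}.
#'
#' @param A m x k matrix.
#' @param B n x k matrix with the same number of columns as \code{A}.
#' @return An (m*n) x k matrix.
#' @examples
#' khatri_rao(diag(2), diag(2))
#' @export
khatri_rao <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("khatri_rao: column counts differ (", ncol(A), " vs ", ncol(B), ")")
  m <- nrow(A); n <- nrow(B)
  A[rep(seq_len(m), each = n), , drop = FALSE] *
    B[rep.int(seq_len(n), m), , drop = FALSE]
}

## Unfolding convention (fixed package-wide):
##   gene mode  : (c*d) x g rows indexed (sample fastest, layer slowest)
##   sample mode: (g*d) x c rows indexed (gene fastest, layer slowest)
##   layer mode : (g*c) x d rows indexed (gene fastest, sample slowest)
## Under this convention the CP model satisfies
##   X_(gene)   = khatri_rao(D, C) %*% t(G)
##   X_(sample) = khatri_rao(D, G) %*% t(C)
##   X_(layer)  = khatri_rao(C, G) %*% t(D)

#' Unfold (matricize) a three-way array along one mode
#'
#' @param x A 3-way array (genes x samples x layers) or a \code{data_cube}.
#' @param mode One of \code{"gene"}, \code{"sample"}, \code{"layer"}.
#' @return An object of class \code{"unfolding"}: the unfolded matrix with the
#'   original dimensions and mode stored as attributes, so \code{refold()} can
#'   rebuild the array exactly.
#' @seealso [refold()], [khatri_rao()]
#' @export
unfold <- function(x, mode = c("gene", "sample", "layer")) {
  mode <- match.arg(mode)
  a <- cube_values(x)
  dm <- dim(a)
  m <- switch(mode,
    gene   = matrix(aperm(a, c(2, 3, 1)), nrow = dm[2] * dm[3], ncol = dm[1]),
    sample = matrix(aperm(a, c(1, 3, 2)), nrow = dm[1] * dm[3], ncol = dm[2]),
    layer  = matrix(a, nrow = dm[1] * dm[2], ncol = dm[3]))
  structure(m, cube_dim = dm, mode = mode, class = c("unfolding", "matrix", "array"))
}

#' Refold an unfolding back into the original three-way array
#'
#' Exact inverse of [unfold()]: \code{refold(unfold(x, m))} reproduces
#' \code{x} for every mode.
#'
#' @param u An \code{"unfolding"} as returned by [unfold()].
#' @return The original 3-way array.
#' @export
refold <- function(u) {
  dm <- attr(u, "cube_dim")
  mode <- attr(u, "mode")
  if (is.null(dm) || is.null(mode)) stop("refold: not an unfolding")
  v <- as.vector(u)
  switch(mode,
    gene   = aperm(array(v, dim = dm[c(2, 3, 1)]), c(3, 1, 2)),
    sample = aperm(array(v, dim = dm[c(1, 3, 2)]), c(1, 3, 2)),
    layer  = array(v, dim = dm))
}

## Build the mode unfolding of a rank-k CP model without forming the full array.
model_unfolding <- function(G, C, D, mode) {
  switch(mode,
    gene   = khatri_rao(D, C) %*% t(G),
    sample = khatri_rao(D, G) %*% t(C),
    layer  = khatri_rao(C, G) %*% t(D))
}

## Reconstruction as a dense g x c x d array (scales absorbed into G if given).
cp_reconstruct <- function(G, C, D, scales = NULL) {
  if (!is.null(scales)) G <- sweep(as.matrix(G), 2, scales, "*")
  dm <- c(nrow(G), nrow(C), nrow(D))
  array(model_unfolding(G, C, D, "layer"), dim = dm)
}
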