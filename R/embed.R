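#' Principal-component embedding of a distance matrix
#'
#' Default method treats each sequence's row of pairwise distances as its
#' feature vector and runs centered PCA on those rows. Classical principal
#' coordinates (metric MDS, double-centering of squared distances) is
#' available as `method = "pcoa"`.
#'
#' @param dm a [fitch_distance()] result (complete, no NA).
#' @param k number of components to keep (default 3, at most n - 1).
#' @param method `"rows"` (PCA on distance rows) or `"pcoa"`.
#' @return object of class `hu_embedding`: `ids`, `coords` (n x k),
#'   `explained` (variance fractions, non-increasing), `total_variance`.
#' @export
pca_embed <- function(dm, k = 3, method = c("rows", "pcoa")) {
  method <- match.arg(method)
  stopifnot(inherits(dm, "hu_dist"))
  X <- dm$mat
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 sequences")
  if (anyNA(X)) stop("distance matrix contains missing values")
  if (k > n - 1L) stop("k must be at most n - 1")
  if (method == "rows") {
    pr <- prcomp(X, center = TRUE, scale. = FALSE)
    vars <- pr$sdev^2
    total <- sum(vars)
    if (total < 1e-300) {
      coords <- matrix(0, n, k)
      explained <- rep(0, k)
    } else {
      coords <- pr$x[, seq_len(k), drop = FALSE]
      explained <- (vars / total)[seq_len(k)]
    }
  } else {
    mds <- cmdscale(X, k = k, eig = TRUE)
    pos <- pmax(mds$eig, 0)
    total <- sum(pos)
    coords <- mds$points
    if (ncol(coords) < k)  # degenerate: pad collapsed dimensions
      coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
    explained <- if (total < 1e-300) rep(0, k) else (pos / total)[seq_len(k)]
  }
  rownames(coords) <- dm$ids
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(ids = dm$ids, coords = coords,
                 explained = explained, total_variance = total,
                 method = method),
            class = "hu_embedding")
}
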