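#' Fingerprint similarity indices
#'
#' Tanimoto, Dice and cosine similarity between two fingerprints of the same
#' kind and length. For binary fingerprints, with `c` shared on-bits and `A`,
#' `B` on-bit counts: Tanimoto `c/(A+B-c)`, Dice `2c/(A+B)`, cosine
#' `c/sqrt(A*B)`. For count fingerprints the natural real-valued
#' generalizations are used: Tanimoto `a.b/(|a|^2+|b|^2-a.b)`, Dice
#' `2 a.b/(|a|^2+|b|^2)`, cosine `a.b/(|a||b|)`.
#'
#' Two empty fingerprints are defined to have similarity 1 (trivially
#' maximally similar) with a warning, since 0/0 carries no information; an
#' empty against a non-empty fingerprint has similarity 0.
#'
#' @param a,b `qsar_fingerprint` objects of the same kind and length.
#' @param index one of `"tanimoto"`, `"dice"`, `"cosine"`.
#' @return similarity in `[0, 1]`.
#' @export
fingerprint_similarity <- function(a, b,
                                   index = c("tanimoto", "dice", "cosine")) {
  index <- match.arg(index)
  stopifnot(inherits(a, "qsar_fingerprint"), inherits(b, "qsar_fingerprint"))
  if (!identical(a$kind, b$kind) || !identical(a$length, b$length))
    stop("fingerprint kind/length mismatch: ",
         sprintf("%s[%d] vs %s[%d]", a$kind, a$length, b$kind, b$length),
         call. = FALSE)
  na <- length(a$on); nb <- length(b$on)
  if (na == 0L && nb == 0L) {
    warning("both fingerprints empty; similarity defined as 1", call. = FALSE)
    return(1)
  }
  if (na == 0L || nb == 0L) return(0)
  if (is.null(a$counts) && is.null(b$counts)) {
    cc <- length(intersect(a$on, b$on))
    switch(index,
           tanimoto = cc / (na + nb - cc),
           dice = 2 * cc / (na + nb),
           cosine = cc / sqrt(na * nb))
  } else {
    av <- numeric(a$length); bv <- numeric(b$length)
    av[a$on + 1L] <- if (is.null(a$counts)) 1 else a$counts
    bv[b$on + 1L] <- if (is.null(b$counts)) 1 else b$counts
    ab <- sum(av * bv); aa <- sum(av^2); bb <- sum(bv^2)
    switch(index,
           tanimoto = ab / (aa + bb - ab),
           dice = 2 * ab / (aa + bb),
           cosine = ab / sqrt(aa * bb))
  }
}

#' Find nearest training-set neighbors of a target fingerprint
#'
#' Ranks training chemicals by ascending distance `1 - similarity` to the
#' target; ties are broken by training order so results are reproducible.
#'
#' @param target a `qsar_fingerprint`.
#' @param training list of `qsar_fingerprint`s (names used as training ids).
#' @param index similarity index, see [fingerprint_similarity()].
#' @param k number of neighbors to return (default 5); `k > n` returns all.
#' @param y optional numeric or character vector of training endpoint values
#'   aligned to `training`, echoed into the result.
#' @return data frame with columns `rank`, `training_id`, `similarity`,
#'   `distance` and, when `y` given, `y`; sorted by ascending distance.
#' @export
find_neighbors <- function(target, training,
                           index = c("tanimoto", "dice", "cosine"),
                           k = 5L, y = NULL) {
  index <- match.arg(index)
  stopifnot(k >= 1L, length(training) >= 1L)
  sims <- vapply(training, function(fp)
    suppressWarnings(fingerprint_similarity(target, fp, index)), numeric(1))
  ids <- names(training)
  if (is.null(ids)) ids <- sprintf("train%03d", seq_along(training))
  ord <- order(1 - sims, seq_along(sims))   # stable: ties keep input order
  keep <- ord[seq_len(min(k, length(ord)))]
  out <- data.frame(rank = seq_along(keep), training_id = ids[keep],
                    similarity = sims[keep], distance = 1 - sims[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(y)) out$y <- y[keep]
  rownames(out) <- NULL
  out
}
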