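#' Generate target--lure embedding pairs with planted angular separation
#'
#' Builds an embedding set of `n_pairs` target--lure pairs of unit vectors in
#' `dim` dimensions, where the angle between the members of each pair is
#' planted exactly. These stand in for the feature vectors a pretrained
#' network would assign to a target image and its similar lure: the cosine
#' geometry, which is all the lossiness estimator consumes, is controlled.
#'
#' @param n_pairs number of target--lure pairs (>= 1).
#' @param dim embedding dimensionality (>= 2).
#' @param separation planted angle(s) in radians, in (0, pi). Either a
#'   numeric vector recycled across pairs, or a list `list(min=, max=)`
#'   from which per-pair angles are drawn uniformly.
#' @param seed integer seed; the generator is bitwise reproducible.
#' @return An object of class `embedding_set`: a list with `items` (an
#'   `2*n_pairs x dim` matrix of unit rows), `ids`, `pairs` (data frame of
#'   `target`/`lure` ids) and `meta` (planted angles and seed).
#' @examples
#' es <- gen_embedding_pairs(3, dim = 8, separation = pi / 2, seed = 1)
#' # orthogonal pairs: cosine distance 1
#' 1 - sum(es$items[1, ] * es$items[2, ])
#' @export
gen_embedding_pairs <- function(n_pairs, dim, separation, seed) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  dim <- check_count(dim, "dim", min = 2L)
  with_seed(seed, {
    if (is.list(separation)) {
      lo <- separation$min
      hi <- separation$max
      if (is.null(lo) || is.null(hi) || lo <= 0 || hi >= pi || lo > hi) {
        stop_rdmem("separation spec needs 0 < min <= max < pi",
                   class = "rdmem_invalid_parameter")
      }
      angles <- runif(n_pairs, lo, hi)
    } else {
      angles <- rep_len(as.numeric(separation), n_pairs)
    }
    if (any(!is.finite(angles)) || any(angles <= 0) || any(angles >= pi)) {
      stop_rdmem("planted angles must lie strictly inside (0, pi)",
                 class = "rdmem_invalid_parameter")
    }
    items <- matrix(0, nrow = 2L * n_pairs, ncol = dim)
    for (p in seq_len(n_pairs)) {
      t <- rnorm(dim)
      t <- t / sqrt(sum(t^2))
      v <- rnorm(dim)
      v <- v - sum(v * t) * t
      v <- v / sqrt(sum(v^2))
      l <- cos(angles[p]) * t + sin(angles[p]) * v
      items[2L * p - 1L, ] <- t
      items[2L * p, ] <- l
    }
    ids <- as.vector(rbind(
      sprintf("pair%03d_target", seq_len(n_pairs)),
      sprintf("pair%03d_lure", seq_len(n_pairs))
    ))
    rownames(items) <- ids
    structure(
      list(
        items = items,
        ids = ids,
        pairs = data.frame(
          target = ids[seq(1L, by = 2L, length.out = n_pairs)],
          lure = ids[seq(2L, by = 2L, length.out = n_pairs)],
          angle = angles,
          stringsAsFactors = FALSE
        ),
        meta = list(n_pairs = n_pairs, dim = dim, angles = angles,
                    seed = check_seed(seed))
      ),
      class = "embedding_set"
    )
  })
}

#' Wrap an externally computed embedding matrix as an embedding set
#'
#' Ingests feature matrices produced elsewhere (e.g. activations of a
#' pretrained classification or vision--language network, exported as a
#' delimited text matrix). Tensor-valued activations (one array slab per
#' item, item index first) are flattened row-wise in C order: the last array
#' index varies fastest.
#'
#' @param x a numeric `items x dim` matrix, or an array whose first margin
#'   indexes items (flattened per item as documented).
#' @param ids character vector of unique item identifiers, one per item.
#' @param pairs optional data frame with `target` and `lure` id columns.
#' @return An `embedding_set`.
#' @export
encode_external <- function(x, ids, pairs = NULL) {
  if (is.array(x) && length(dim(x)) > 2L) {
    d <- dim(x)
    # reverse the trailing margins so the last array index varies fastest
    # across columns (C order), with items kept on the rows
    perm <- c(1L, rev(seq_along(d)[-1L]))
    x <- matrix(aperm(x, perm), nrow = d[1L])
  }
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_rdmem("embedding matrix must be finite numeric",
               class = "rdmem_validation")
  }
  ids <- as.character(ids)
  if (length(ids) != nrow(x)) {
    stop_rdmem("row count must equal id count", class = "rdmem_validation")
  }
  if (anyDuplicated(ids)) {
    stop_rdmem("duplicate item ids", class = "rdmem_validation")
  }
  if (!is.null(pairs)) {
    stopifnot(all(c("target", "lure") %in% names(pairs)))
    if (!all(c(pairs$target, pairs$lure) %in% ids)) {
      stop_rdmem("pairs reference unknown ids", class = "rdmem_validation")
    }
  }
  rownames(x) <- ids
  structure(
    list(items = x, ids = ids, pairs = pairs,
         meta = list(source = "external", dim = ncol(x))),
    class = "embedding_set"
  )
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d items x %d dims", nrow(x$items),
              ncol(x$items)))
  if (!is.null(x$pairs)) cat(sprintf(", %d target-lure pairs", nrow(x$pairs)))
  cat("\n")
  invisible(x)
}
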