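## MinHash sketches and Mash distances between mobile-element sequences.
##
## A sketch keeps the s smallest 64-bit hash values over the canonical
## k-mers of a sequence (bottom-s sketch). The Mash distance between two
## sketches is d = -(1/k) * ln(2j / (1 + j)), with j the Jaccard index
## estimated from the bottom-s sketch of the merged hash sets. Hash values
## are stored as fixed-width lowercase hex strings: lexicographic order is
## numeric order, and 64-bit values survive untouched in R.

#' Build the bottom-s MinHash sketch of a sequence
#'
#' Canonical k-mers (the lexicographic minimum of a k-mer and its reverse
#' complement) are hashed with a MurmurHash3-style 64-bit hash under a
#' fixed seed; the sketch keeps the `s` smallest distinct values. K-mers
#' containing characters other than A/C/G/T (e.g. N) are skipped. The
#' sketch is deterministic for fixed (sequence, k, s, seed).
#'
#' @param seq nucleotide sequence (character), length >= k.
#' @param mge_id identifier carried by the sketch.
#' @param k odd k-mer size (default 21).
#' @param s sketch size (default 1000).
#' @param seed hash seed (default 42; fixed across a run).
#' @return Object of class `minhash_sketch`: list with `mge_id`, `k`,
#'   `s`, `seed` and `hashes` (strictly increasing hex strings,
#'   `min(s, #distinct canonical k-mers)` of them).
#' @export
sketch <- function(seq, mge_id = "seq", k = ta_defaults()$k,
                   s = ta_defaults()$s, seed = ta_defaults()$hash_seed) {
  seq <- as.character(seq)
  if (nchar(seq) < k)
    stop("sequence length ", nchar(seq), " is below k = ", k)
  if (k %% 2L == 0L) stop("k must be odd so no k-mer is its own reverse complement")
  h <- .sketch_hashes(seq, as.integer(k), as.integer(s), as.integer(seed))
  structure(list(mge_id = mge_id, k = as.integer(k), s = as.integer(s),
                 seed = as.integer(seed), hashes = h),
            class = "minhash_sketch")
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat(sprintf("minhash_sketch %s: k=%d s=%d seed=%d, %d hashes\n",
              x$mge_id, x$k, x$s, x$seed, length(x$hashes)))
  invisible(x)
}

#' Mash distance between two sketches
#'
#' Estimates the k-mer Jaccard index `j` from the bottom-s sketch of the
#' union of the two hash sets (shared hashes among the `s'` smallest of
#' the merged set, divided by `s'`), then applies
#' `d = -(1/k) * ln(2j / (1+j))`. A zero estimate saturates at `d = 1`;
#' identical sketches give `d = 0`.
#'
#' @param a,b `minhash_sketch` objects with matching `k` and `s`.
#' @return Mash distance in \[0, 1\].
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (a$k != b$k || a$s != b$s)
    stop("sketch parameter mismatch: k ", a$k, "/", b$k, ", s ", a$s, "/", b$s)
  merged <- sort(unique(c(a$hashes, b$hashes)), method = "radix")
  sprime <- min(a$s, length(merged))
  if (sprime == 0L) return(1.0)
  bottom <- merged[seq_len(sprime)]
  shared <- sum(bottom %in% a$hashes & bottom %in% b$hashes)
  j <- shared / sprime
  if (j <= 0) return(1.0)
  if (j >= 1) return(0.0)
  d <- -(1 / a$k) * log(2 * j / (1 + j))
  min(max(d, 0), 1)
}

#' Similar-MGE edges from pairwise Mash distances
#'
#' All unordered pairs of sketches with Mash distance strictly below the
#' threshold (default 0.01); no self-edges.
#'
#' @param sketches list of `minhash_sketch` objects.
#' @param threshold strict upper bound on the distance.
#' @return data.frame with `mge_a`, `mge_b`, `distance`, one row per
#'   similar pair.
#' @export
similar_edges <- function(sketches, threshold = ta_defaults()$mash_threshold) {
  n <- length(sketches)
  rows <- list()
  if (n >= 2) for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- mash_distance(sketches[[i]], sketches[[j]])
    if (d < threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        mge_a = sketches[[i]]$mge_id, mge_b = sketches[[j]]$mge_id,
        distance = d, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(mge_a = character(), mge_b = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Serialize / read sketches as JSON
#'
#' One JSON object per sketch with `mge_id`, `k`, `s`, `seed` and the hex
#' hash list, wrapped in a top-level array.
#'
#' @param sketches list of `minhash_sketch` objects.
#' @param path JSON file path.
#' @return `path` (writer) or the list of sketches (reader).
#' @export
write_sketches_json <- function(sketches, path) {
  payload <- lapply(sketches, function(x)
    list(mge_id = x$mge_id, k = x$k, s = x$s, seed = x$seed,
         hashes = as.character(x$hashes)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sketches_json
#' @export
read_sketches_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(x)
    structure(list(mge_id = x$mge_id, k = as.integer(x$k),
                   s = as.integer(x$s), seed = as.integer(x$seed),
                   hashes = as.character(x$hashes)),
              class = "minhash_sketch"))
}
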