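#' Pairwise p-distance between two dosage vectors
#'
#' Over sites where both calls are non-missing, the per-site distance is
#' `|g_i - g_j| / 2` (identical genotypes 0, heterozygote vs homozygote 0.5,
#' opposite homozygotes 1); the returned distance is the mean over those
#' pairwise-complete sites.
#'
#' @param g_i,g_j equal-length dosage vectors (0/1/2/`NA`).
#' @return list with `distance` and `n_used` (number of pairwise-complete
#'   sites).
#' @export
p_distance_pair <- function(g_i, g_j) {
  if (length(g_i) != length(g_j)) stop("dosage vectors differ in length")
  ok <- !is.na(g_i) & !is.na(g_j)
  n_used <- sum(ok)
  if (n_used == 0L) stop("no pairwise-complete sites between the two samples")
  list(distance = sum(abs(g_i[ok] - g_j[ok])) / (2 * n_used), n_used = n_used)
}

#' Pairwise p-distance matrix
#'
#' Computes all pairwise p-distances (see [p_distance_pair()]) with
#' pairwise-complete deletion of missing calls. Implemented with cross
#' products on dosage indicator matrices, so it scales to cohorts with tens
#' of thousands of sites.
#'
#' @param G dosage matrix (samples x sites); needs at least 2 samples.
#' @return an object of class `p_distance`: list with `values` (symmetric
#'   matrix in \[0,1\], zero diagonal), `labels`, and `n_used` (matrix of
#'   pairwise-complete site counts).
#' @export
p_distance_matrix <- function(G) {
  n <- nrow(G)
  if (is.null(n) || n < 2L) stop("need at least 2 samples")
  labels <- rownames(G)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))

  M <- (!is.na(G)) * 1
  A <- G
  A[is.na(A)] <- 0
  storage.mode(A) <- "double"
  n_used <- tcrossprod(M)
  off <- n_used == 0 & !diag(TRUE, n)
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("no pairwise-complete sites for pair(s): ",
         paste(labels[bad[, 1]], labels[bad[, 2]], sep = "/", collapse = ", "))
  }
  A2 <- A * A
  # sum over complete sites of (a_i - a_j)^2, then correct squared 2s to |2|
  s2 <- A2 %*% t(M) + M %*% t(A2) - 2 * tcrossprod(A)
  i0 <- (A == 0 & M == 1) * 1
  i2 <- (A == 2) * 1
  n02 <- i0 %*% t(i2)
  sabs <- s2 - 2 * (n02 + t(n02))
  D <- sabs / (2 * pmax(n_used, 1))
  D[D < 0] <- 0 # guard against floating-point dust
  diag(D) <- 0
  dimnames(D) <- list(labels, labels)
  dimnames(n_used) <- dimnames(D)
  structure(list(values = D, labels = labels, n_used = n_used),
            class = "p_distance")
}

#' @export
as.matrix.p_distance <- function(x, ...) x$values

#' @exportS3Method base::print
print.p_distance <- function(x, ...) {
  cat("p-distance matrix over", length(x$labels), "samples\n")
  cat("range:", format(range(x$values[upper.tri(x$values)]), digits = 4), "\n")
  invisible(x)
}

#' Bootstrap p-distance matrices by site resampling
#'
#' Each replicate resamples sites with replacement to the original site
#' count, then recomputes the p-distance matrix. A replicate in which some
#' pair has no pairwise-complete site is redrawn (bounded retries).
#'
#' @param G dosage matrix.
#' @param B number of replicates.
#' @param seed integer seed; the replicate stream is reproducible.
#' @param max_retries redraw attempts per replicate before failing.
#' @return list of `B` `p_distance` objects.
#' @export
bootstrap_distance_matrices <- function(G, B = 100, seed = 1, max_retries = 10) {
  if (B < 1) stop("B must be >= 1")
  L <- ncol(G)
  set.seed(seed)
  out <- vector("list", B)
  for (b in seq_len(B)) {
    for (try in seq_len(max_retries)) {
      idx <- sample.int(L, L, replace = TRUE)
      D <- tryCatch(p_distance_matrix(G[, idx, drop = FALSE]),
                    error = function(e) NULL)
      if (!is.null(D)) break
      message("bootstrap replicate ", b, " redrawn (zero-overlap pair)")
    }
    if (is.null(D)) stop("bootstrap replicate ", b, " failed after ",
                         max_retries, " redraws")
    out[[b]] <- D
  }
  out
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param D a `p_distance` object or plain symmetric matrix.
#' @param path output path.
#' @param digits decimal digits (default 6).
#' @return `path`, invisibly.
#' @export
write_phylip <- function(D, path, digits = 6) {
  m <- as.matrix(D)
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(m)))
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste0(formatC(labels[i], width = -11),
           paste(formatC(m[i, ], format = "f", digits = digits),
                 collapse = "  "))
  }, character(1))
  writeLines(c(formatC(nrow(m), width = 5), rows), path)
  invisible(path)
}
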