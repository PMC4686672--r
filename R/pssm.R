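.nucleotides <- c("A", "C", "G", "T")

#' Construct a position-specific scoring matrix
#'
#' Converts a 4-by-width nucleotide count matrix into frequencies with a
#' pseudocount spread evenly over the four bases,
#' `f = (count + 0.25 * pseudo_total) / (column_total + pseudo_total)`,
#' and log2-odds weights against an order-0 background.
#'
#' @param counts Numeric 4-by-width matrix with rows A, C, G, T
#'   (non-negative).
#' @param name Matrix (transcription factor) name.
#' @param background Named base probabilities (A, C, G, T); default uniform.
#' @param pseudo_total Total pseudocount added per column. Default 1.
#' @return An object of class `pssm`: list with `name`, `width`, `counts`,
#'   `freq`, `weights` (log2-odds), `background`.
#' @export
#' @examples
#' m <- matrix(c(8, 0, 0, 0, 0, 8, 0, 0, 0, 0, 8, 0), nrow = 4,
#'             dimnames = list(c("A", "C", "G", "T"), NULL))
#' pssm(m, "toy")
pssm <- function(counts, name = "pssm",
                 background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                 pseudo_total = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("PSSM counts need 4 rows (A, C, G, T).")
  rownames(counts) <- .nucleotides
  if (any(counts < 0)) abort("PSSM counts must be non-negative.")
  tot <- colSums(counts)
  if (any(tot + pseudo_total <= 0))
    abort("A column has zero counts and no pseudocount.")
  freq <- sweep(counts + 0.25 * pseudo_total, 2, tot + pseudo_total, "/")
  background <- background[.nucleotides] / sum(background[.nucleotides])
  weights <- log2(freq / background)
  structure(list(name = name, width = ncol(counts), counts = counts,
                 freq = freq, weights = weights, background = background),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("pssm '%s': width %d, consensus %s\n", x$name, x$width,
              paste(.nucleotides[apply(x$freq, 2, which.max)], collapse = "")))
  invisible(x)
}

#' Load position-specific scoring matrices from TRANSFAC or JASPAR files
#'
#' JASPAR count format: a `>name` header followed by four lines
#' `A [ 1 2 ... ]` (brackets optional). TRANSFAC format: records delimited by
#' `//` with a `P0 A C G T` column header and numbered per-position count
#' rows. Multiple matrices per file are supported.
#'
#' @param path File path.
#' @param format `"JASPAR"` or `"TRANSFAC"`.
#' @param background,pseudo_total Passed to [pssm()].
#' @return A named list of [pssm()] objects.
#' @export
load_pssm <- function(path, format = c("JASPAR", "TRANSFAC"),
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      pseudo_total = 1) {
  format <- match.arg(format)
  lines <- readLines(path)
  out <- if (format == "JASPAR") parse_jaspar(lines) else parse_transfac(lines)
  if (!length(out)) abort("No matrices found (format error).")
  lapply(out, function(rec) pssm(rec$counts, rec$name, background, pseudo_total))
}

parse_jaspar <- function(lines) {
  lines <- trimws(lines)
  heads <- grep("^>", lines)
  if (!length(heads)) abort("JASPAR file must contain '>' headers (format error).")
  recs <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    block <- lines[(heads[i] + 1):(bounds[i + 1] - 1)]
    block <- block[nzchar(block)]
    rows <- lapply(.nucleotides, function(nt) {
      ln <- block[grepl(paste0("^", nt, "\\b"), block)]
      if (length(ln) != 1) abort("Malformed JASPAR record (format error).")
      nums <- gsub("[][]", " ", sub(paste0("^", nt), "", ln))
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1) abort("Ragged JASPAR matrix (format error).")
    recs[[name]] <- list(name = name, counts = do.call(rbind, rows))
  }
  recs
}

parse_transfac <- function(lines) {
  lines <- trimws(lines)
  recs <- list()
  cur_name <- NULL; cur_rows <- list(); in_matrix <- FALSE
  flush <- function() {
    if (length(cur_rows)) {
      counts <- t(do.call(rbind, cur_rows))   # rows become A C G T
      nm <- cur_name %||% paste0("matrix_", length(recs) + 1)
      recs[[nm]] <<- list(name = nm, counts = counts)
    }
    cur_name <<- NULL; cur_rows <<- list(); in_matrix <<- FALSE
  }
  for (ln in lines) {
    if (grepl("^//", ln)) { flush(); next }
    if (grepl("^(ID|NA|AC)\\s", ln)) {
      if (is.null(cur_name)) cur_name <- strsplit(ln, "\\s+")[[1]][2]
      next
    }
    if (grepl("^P0\\b", ln) || grepl("^PO\\b", ln)) { in_matrix <- TRUE; next }
    if (in_matrix && grepl("^[0-9]+\\s", ln)) {
      parts <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts[2:5]))
      if (anyNA(vals)) abort("Malformed TRANSFAC count row (format error).")
      cur_rows[[length(cur_rows) + 1]] <- vals
    }
  }
  flush()
  recs
}

#' Exact score distribution of a PSSM under an order-0 background
#'
#' Discretizes the per-position log2-odds weights to a grid of width
#' `bin_width` and convolves the position-wise score distributions of a
#' random background word, yielding the exact distribution of the (binned)
#' site score and its upper-tail p-values `p(s) = P(score >= s)`.
#'
#' @param pssm A [pssm()].
#' @param background Optional order-0 background overriding the matrix's
#'   own.
#' @param bin_width Score discretization step in log2-odds units.
#'   Default 0.01.
#' @return A list of class `score_distribution`: integer-bin grid `bins`,
#'   `prob`, `tail_p`, `bin_width`, and the binned weight matrix
#'   `binned_weights` used for scoring.
#' @export
score_distribution <- function(pssm, background = NULL, bin_width = 0.01) {
  stopifnot(inherits(pssm, "pssm"))
  if (bin_width <= 0) abort("`bin_width` must be positive.")
  bg <- background %||% pssm$background
  bg <- bg[.nucleotides] / sum(bg[.nucleotides])
  W <- round(log2(pssm$freq / bg) / bin_width)    # integer bins per position

  # position-wise convolution over the integer score grid; `offset` tracks
  # the bin value of the first array element
  dist <- 1; offset <- 0L
  for (j in seq_len(pssm$width)) {
    wj <- W[, j]
    mn <- min(wj); mx <- max(wj)
    new_len <- length(dist) + (mx - mn)
    new <- numeric(new_len)
    for (b in seq_len(4)) {
      sh <- wj[b] - mn
      new[(1 + sh):(length(dist) + sh)] <-
        new[(1 + sh):(length(dist) + sh)] + bg[b] * dist
    }
    dist <- new
    offset <- offset + mn
  }
  bins <- seq.int(offset, by = 1L, length.out = length(dist))
  tail_p <- rev(cumsum(rev(dist)))
  structure(list(bins = bins, prob = dist, tail_p = pmin(tail_p, 1),
                 bin_width = bin_width, binned_weights = W),
            class = "score_distribution")
}

# upper-tail p of binned scores (vectorized); scores beyond the grid get 1/0
score_p_value <- function(sd, binned_scores) {
  idx <- binned_scores - sd$bins[1] + 1L
  p <- numeric(length(idx))
  p[idx <= 0] <- 1
  inside <- idx >= 1 & idx <= length(sd$tail_p)
  p[inside] <- sd$tail_p[idx[inside]]
  p[idx > length(sd$tail_p)] <- 0
  p
}
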