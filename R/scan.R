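#' Read promoter sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(seqs)), names(seqs))
}

#' @rdname read_promoters
#' @param sequences Named character vector of sequences.
#' @export
write_promoters <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(seq, NULL),
                                  function(x) paste(rev(x), collapse = ""),
                                  character(1)))
}

# integer-encode a sequence; N and anything else becomes NA
encode_seq <- function(seq) {
  code <- match(strsplit(toupper(seq), NULL)[[1]], .nucleotides)
  code
}

# binned window scores at every start position; windows touching N are NA
window_scores <- function(code, W) {
  w <- ncol(W)
  L <- length(code)
  if (L < w) return(integer(0))
  n_win <- L - w + 1
  s <- numeric(n_win)
  ok <- !logical(n_win)
  for (j in seq_len(w)) {
    cj <- code[j:(j + n_win - 1)]
    bad <- is.na(cj)
    ok <- ok & !bad
    cj[bad] <- 1L
    s <- s + W[cbind(cj, j)]
  }
  s[!ok] <- NA
  s
}

#' Scan a promoter with position-specific scoring matrices
#'
#' Scores every window of the sequence (both strands by default) against
#' each matrix, converts scores to exact upper-tail p-values under the
#' order-0 Markov background via [score_distribution()], and reports hits
#' with `p_site < p_threshold`. Windows containing `N` are skipped. The
#' per-matrix aggregate p-value is the binomial upper tail `P(X >= k)` over
#' the number of scanned windows at success probability `p_threshold`.
#'
#' @param seq Nucleotide sequence over `A, C, G, T, N` (character scalar).
#' @param pssms A [pssm()] or list of them.
#' @param background Order-0 background; by default estimated from the
#'   scanned sequence (uniform if the sequence is all-N).
#' @param p_threshold Per-site p-value cutoff. Default 1e-4.
#' @param both_strands Scan the reverse strand too. Default TRUE.
#' @param bin_width Score discretization passed to [score_distribution()].
#' @param promoter_id Identifier used in the report. Default `"promoter"`.
#' @return A list of class `scan_report`: `hits` (tibble: promoter, tf,
#'   position (0-based on the forward strand), strand, score, p_site) and
#'   `summary` (tibble: promoter, tf, n_sites, n_windows, p_aggregate).
#' @export
scan_promoter <- function(seq, pssms, background = NULL, p_threshold = 1e-4,
                          both_strands = TRUE, bin_width = 0.01,
                          promoter_id = "promoter") {
  if (inherits(pssms, "pssm")) pssms <- list(pssms)
  if (is.null(names(pssms)))
    names(pssms) <- vapply(pssms, function(p) p$name, character(1))
  code_f <- encode_seq(seq)
  code_r <- encode_seq(revcomp(seq))
  L <- length(code_f)

  if (is.null(background)) {
    # Laplace-smoothed so a base absent from a short sequence keeps a
    # nonzero probability (log-odds stay finite)
    tab <- tabulate(code_f, 4)
    background <- (tab + 1) / (sum(tab) + 4)
    names(background) <- .nucleotides
  }

  hit_rows <- list(); sum_rows <- list()
  for (nm in names(pssms)) {
    pm <- pssms[[nm]]
    sdist <- score_distribution(pm, background, bin_width)
    W <- sdist$binned_weights
    sf <- window_scores(code_f, W)
    strands <- list(`+` = sf)
    if (both_strands) strands$`-` <- window_scores(code_r, W)
    n_windows <- sum(vapply(strands, function(s) sum(!is.na(s)), numeric(1)))

    rows <- list()
    for (st in names(strands)) {
      s <- strands[[st]]
      if (!length(s)) next
      p <- rep(NA_real_, length(s))
      p[!is.na(s)] <- score_p_value(sdist, s[!is.na(s)])
      sel <- which(!is.na(p) & p < p_threshold)
      if (!length(sel)) next
      pos0 <- if (st == "+") sel - 1L else L - pm$width - (sel - 1L)
      rows[[st]] <- tibble(promoter = promoter_id, tf = nm,
                           position = pos0, strand = st,
                           score = s[sel] * bin_width, p_site = p[sel])
    }
    hits <- bind_rows(rows)
    k <- nrow(hits)
    hit_rows[[nm]] <- hits
    sum_rows[[nm]] <- tibble(
      promoter = promoter_id, tf = nm, n_sites = k, n_windows = n_windows,
      p_aggregate = if (n_windows == 0) 1
      else pbinom(k - 1, n_windows, p_threshold, lower.tail = FALSE)
    )
  }
  all_hits <- bind_rows(hit_rows)
  if (nrow(all_hits) == 0)
    all_hits <- tibble(promoter = character(), tf = character(),
                       position = integer(), strand = character(),
                       score = numeric(), p_site = numeric())
  structure(list(hits = arrange(all_hits, .data$tf, .data$position),
                 summary = bind_rows(sum_rows),
                 p_threshold = p_threshold, region_length = L),
            class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("scan_report: %d hits over %d matrices (p < %g, %d bp region)\n",
              nrow(x$hits), nrow(x$summary), x$p_threshold, x$region_length))
  invisible(x)
}

#' Rank transcription factors by promoter-site evidence
#'
#' Orders scanned matrices by descending number of sites below the p-value
#' threshold, then by ascending aggregate binding p-value. Matrices without
#' any site are dropped; ties after both keys are reported.
#'
#' @param report A `scan_report` (or its `summary` tibble).
#' @return Tibble of `tf`, `n_sites`, `p_aggregate`, `rank`.
#' @export
rank_tfs <- function(report) {
  summary <- if (inherits(report, "scan_report")) report$summary else report
  ranked <- summary |>
    filter(.data$n_sites >= 1) |>
    arrange(dplyr::desc(.data$n_sites), .data$p_aggregate, .data$tf) |>
    mutate(rank = dplyr::row_number()) |>
    select("tf", "n_sites", "p_aggregate", "rank")
  dup <- ranked |>
    count(.data$n_sites, .data$p_aggregate) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0)
    inform(sprintf("%d ties on (site count, aggregate p) broken by name.",
                   nrow(dup)))
  ranked
}
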