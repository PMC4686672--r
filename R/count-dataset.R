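#' Construct a count dataset
#'
#' Bundles one species' gene-by-sample read-count matrix with its sample
#' design (age group per sample) and optional transcript lengths. All
#' downstream differential-expression functions operate on this container.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers). Non-negative.
#' @param design Data frame with at least columns `sample` and `age_group`;
#'   `species`, `replicate` and a numeric `age` column are carried along when
#'   present. Every column of `counts` must appear in `design$sample`.
#' @param lengths Optional named numeric vector of transcript lengths in bp
#'   (names = gene identifiers); required only for RPKM computation.
#'
#' @return An object of class `count_dataset`: a list with elements `counts`,
#'   `design` (tibble, one row per sample, in column order of `counts`) and
#'   `lengths`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 20), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' d <- data.frame(sample = paste0("s", 1:4),
#'                 age_group = rep(c("young", "old"), each = 2))
#' cd <- count_dataset(m, d)
#' cd
count_dataset <- function(counts, design, lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("`counts` needs gene rownames and sample colnames.")
  if (anyNA(counts) || any(counts < 0))
    abort("Counts must be non-negative and complete (format error).")
  if (any(abs(counts - round(counts)) > 1e-8))
    abort("Counts must be integers (format error).")
  storage.mode(counts) <- "integer"

  design <- as_tibble(design)
  if (!all(c("sample", "age_group") %in% names(design)))
    abort("`design` must contain columns `sample` and `age_group`.")
  missing_samples <- setdiff(colnames(counts), design$sample)
  if (length(missing_samples))
    abort(paste0("Samples absent from design (design error): ",
                 paste(missing_samples, collapse = ", ")))
  extra <- setdiff(design$sample, colnames(counts))
  if (length(extra))
    abort(paste0("Design lists samples absent from the matrix (design error): ",
                 paste(extra, collapse = ", ")))
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]

  if (!is.null(lengths)) {
    lengths <- lengths[rownames(counts)[rownames(counts) %in% names(lengths)]]
    if (any(lengths <= 0, na.rm = TRUE))
      abort("Transcript lengths must be positive.")
  }

  structure(list(counts = counts, design = design, lengths = lengths),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  grp <- table(x$design$age_group)
  cat(sprintf("count_dataset: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  age groups:", paste(sprintf("%s (n=%d)", names(grp), grp),
                             collapse = ", "), "\n")
  if (!is.null(x$lengths)) cat("  transcript lengths available\n")
  invisible(x)
}

#' @export
dim.count_dataset <- function(x) dim(x$counts)

#' Read and write count datasets
#'
#' The on-disk format is a tab-separated matrix with gene identifiers in the
#' first column and sample identifiers in the header, accompanied by a design
#' table (TSV with columns `sample`, `age_group` and optionally `species`,
#' `age`, `replicate`).
#'
#' @param path Path of the count matrix TSV.
#' @param design_path Path of the design TSV.
#' @param lengths_path Optional TSV with columns `gene`, `length`.
#' @return `read_count_dataset` returns a [count_dataset()].
#' @export
read_count_dataset <- function(path, design_path, lengths_path = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genes <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat))
    abort("Count matrix contains non-numeric entries (format error).")
  rownames(mat) <- genes
  design <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- readr::read_tsv(lengths_path, show_col_types = FALSE, progress = FALSE)
    lengths <- setNames(lt$length, lt$gene)
  }
  count_dataset(mat, design, lengths)
}

#' @rdname read_count_dataset
#' @param x A `count_dataset`.
#' @export
write_count_dataset <- function(x, path, design_path = NULL) {
  stopifnot(inherits(x, "count_dataset"))
  out <- tibble(gene = rownames(x$counts)) |>
    dplyr::bind_cols(as_tibble(x$counts))
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(design_path))
    readr::write_tsv(x$design, design_path, progress = FALSE)
  invisible(path)
}

#' Read an orthology map
#'
#' Orthology relations are triples (species, gene, ortholog group); the
#' relation may be many-to-many. Duplicate triples are collapsed with a
#' warning.
#'
#' @param path TSV with columns `species`, `gene`, `group` (no header needed
#'   if exactly three columns; a header row naming them is also accepted).
#' @return A tibble of class `orthology_map` with columns `species`, `gene`,
#'   `group`.
#' @export
read_orthology <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(raw) == 0) return(orthology_map(tibble(species = character(),
                                                  gene = character(),
                                                  group = character())))
  if (ncol(raw) != 3)
    abort("Orthology file must have exactly three columns (format error).")
  names(raw) <- c("species", "gene", "group")
  if (identical(tolower(as.character(raw[1, ])), c("species", "gene", "group")))
    raw <- raw[-1, , drop = FALSE]
  orthology_map(raw)
}

#' Construct an orthology map from a data frame
#'
#' @param x Data frame with columns `species`, `gene`, `group`.
#' @return A tibble of class `orthology_map`.
#' @export
orthology_map <- function(x) {
  x <- as_tibble(x)[, c("species", "gene", "group")]
  x <- dplyr::mutate(x, across(dplyr::everything(), as.character))
  if (anyNA(x)) abort("Malformed orthology row (format error).")
  n0 <- nrow(x)
  x <- distinct(x)
  if (nrow(x) < n0)
    warn(sprintf("Collapsed %d duplicate orthology rows.", n0 - nrow(x)))
  class(x) <- c("orthology_map", class(x))
  x
}

#' Restrict an orthology map to one-to-one relations
#'
#' Keeps only ortholog groups in which no species contributes more than one
#' gene.
#'
#' @param map An `orthology_map`.
#' @return A filtered `orthology_map`.
#' @export
one_to_one <- function(map) {
  bad <- map |>
    count(.data$group, .data$species) |>
    filter(.data$n > 1) |>
    pull(.data$group) |>
    unique()
  out <- filter(map, !.data$group %in% bad)
  class(out) <- c("orthology_map", setdiff(class(out), "orthology_map"))
  out
}

#' Look up ortholog groups by gene or genes by group
#'
#' @param map An `orthology_map`.
#' @param genes,groups Character vectors to look up.
#' @return A filtered tibble.
#' @export
orthologs_of <- function(map, genes = NULL, groups = NULL) {
  out <- map
  if (!is.null(genes)) out <- filter(out, .data$gene %in% genes)
  if (!is.null(groups)) out <- filter(out, .data$group %in% groups)
  as_tibble(out)
}
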